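# Independent oracles. These deliberately re-implement rule application and
# grammar search by different algorithms than the package (naive scanning
# with explicit Kleene-star unrolling; plain nested-loop enumeration with
# forward derivation), so agreement is evidence of correctness rather than
# of shared code.

# --- rule application oracle -----------------------------------------------

# memoized membership test (caches results of the exported matches());
# the matching *algorithm* below remains independent of the package's
.oracle_memo <- new.env(parent = emptyenv())
oracle_matches <- function(p, fm, fs) {
  key <- paste(fs$name, length(fs$symbols), format(fm), p)
  hit <- .oracle_memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- matches(p, fm, fs)
  .oracle_memo[[key]] <- val
  val
}

# expand a trigger into all star-unrolled literal element sequences (up to
# `reps` repetitions per starred element)
oracle_trigger_variants <- function(tr, reps = 4L) {
  seqs <- list(list())
  for (e in tr$elements) {
    if (e$star) {
      new <- list()
      for (s in seqs) for (k in 0:reps) {
        new[[length(new) + 1L]] <- c(s, rep(list(e$fm), k))
      }
      seqs <- new
    } else {
      seqs <- lapply(seqs, function(s) c(s, list(e$fm)))
    }
  }
  seqs
}

oracle_side_ok <- function(tr, ph, from, dir, fs, reps = 4L) {
  for (var in oracle_trigger_variants(tr, reps)) {
    elems <- if (dir < 0) rev(var) else var
    j <- from
    ok <- TRUE
    for (fm in elems) {
      if (j < 1 || j > length(ph) || !oracle_matches(ph[j], fm, fs)) {
        ok <- FALSE
        break
      }
      j <- j + dir
    }
    if (ok && tr$boundary && !(j < 1 || j > length(ph))) ok <- FALSE
    if (ok) return(TRUE)
  }
  FALSE
}

oracle_apply <- function(r, form, fs, reps = 4L) {
  ph <- if (length(form) > 1L) as.character(form)
  else tokenize_form(form, fs)
  n <- length(ph)
  ch <- r$change
  if (ch$kind == "copy") {
    # same observable contract, separate implementation
    if (ch$unit == "syllable") {
      sf <- tryCatch(syllabify(ph, fs), error = function(e) NULL)
      if (is.null(sf) || !length(sf$syllables)) return(ph)
      seg <- sf$syllables[[if (ch$source == "first") 1 else
        length(sf$syllables)]]
    } else {
      if (n < ch$n_phonemes) return(ph)
      seg <- ph[if (ch$source == "first") ch$n_phonemes else
        n - ch$n_phonemes + 1L]
    }
    return(if (ch$target == "begin") c(seg, ph) else c(ph, seg))
  }
  if (is.null(r$focus)) {
    out <- character()
    for (g in 0:n) {
      if (oracle_side_ok(r$left, ph, g, -1L, fs, reps) &&
          oracle_side_ok(r$right, ph, g + 1L, 1L, fs, reps)) {
        out <- c(out, ch$phonemes)
      }
      if (g < n) out <- c(out, ph[g + 1L])
    }
    return(out)
  }
  hit <- vapply(seq_len(n), function(i) {
    oracle_matches(ph[i], r$focus, fs) &&
      oracle_side_ok(r$left, ph, i - 1L, -1L, fs, reps) &&
      oracle_side_ok(r$right, ph, i + 1L, 1L, fs, reps)
  }, TRUE)
  out <- character()
  for (i in seq_len(n)) {
    if (!hit[i]) {
      out <- c(out, ph[i])
    } else if (ch$kind == "delete") {
      # drop
    } else {
      fm <- ch$fm
      if (!is.null(ch$alpha)) {
        j <- if (ch$alpha_side == "left") i - 1L else i + 1L
        if (j < 1L || j > n) { out <- c(out, ph[i]); next }
        sgn <- if (ch$alpha %in% fs$plus[[ph[j]]]) "+"
        else if (ch$alpha %in% fs$minus[[ph[j]]]) "-" else NA
        if (is.na(sgn)) { out <- c(out, ph[i]); next }
        fm <- feature_matrix(c(fm$literals, paste0(sgn, ch$alpha)))
      }
      q <- apply_feature_change(ph[i], fm, fs, strict = FALSE)
      out <- c(out, if (is.na(q)) ph[i] else q)
    }
  }
  out
}

oracle_derive <- function(rules, u, fs) {
  if (inherits(rules, "phon_theory")) rules <- rules$rules
  for (r in rules) u <- oracle_apply(r, u, fs)
  u
}

# --- brute-force synthesis enumerator --------------------------------------

# all stems over `alphabet` up to max_len, shortest-first then lexicographic
oracle_all_stems <- function(alphabet, max_len) {
  out <- list(character())
  layer <- list(character())
  for (len in seq_len(max_len)) {
    new <- list()
    for (s in layer) for (p in alphabet) {
      new[[length(new) + 1L]] <- c(s, p)
    }
    out <- c(out, new)
    layer <- new
  }
  out
}

# Max objective over: theories (integer index vectors into `pool`),
# per-column suffix candidates, stems up to max_len; pure forward derivation
# throughout. One application of one rule to one string is computed once.
oracle_best_score <- function(X, pool, theories, sfx_cands, alphabet,
                              max_len, cm, fs) {
  lexemes <- unique(X$stem_id)
  infls <- unique(X$inflection)
  cell <- function(l, i) {
    f <- X$form[X$stem_id == l & X$inflection == i]
    if (length(f)) f else NA
  }
  targets <- lapply(lexemes, function(l) {
    vapply(infls, function(i) cell(l, i), "")
  })
  stems <- oracle_all_stems(alphabet, max_len)
  all_sfx <- unique(unlist(lapply(infls, function(i) {
    lapply(sfx_cands[[i]], paste, collapse = "\1")
  })))
  sfx_of <- lapply(all_sfx, function(k) {
    if (nzchar(k)) strsplit(k, "\1", fixed = TRUE)[[1]] else character()
  })
  unit <- cm$lexicon_phoneme
  pool_bits <- vapply(pool, rule_cost, 0, cm = cm)
  best <- -Inf
  apply_memo <- new.env(parent = emptyenv())
  apply_cached <- function(ri, u) {
    key <- paste0(ri, "\2", paste(u, collapse = "\1"))
    hit <- apply_memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- oracle_apply(pool[[ri]], u, fs)
    apply_memo[[key]] <- val
    val
  }
  derive_cached <- function(th, u) {
    for (ri in th) u <- apply_cached(ri, u)
    u
  }
  for (th in theories) {
    rb <- if (length(th)) sum(pool_bits[th]) else 0
    # derive every stem + suffix pair once: D[[si]][sk] = surface string
    D <- lapply(seq_along(stems), function(si) {
      vapply(seq_along(sfx_of), function(sk) {
        paste(derive_cached(th, c(stems[[si]], sfx_of[[sk]])),
              collapse = "")
      }, "")
    })
    skey <- function(s) match(paste(s, collapse = "\1"), all_sfx)
    grid <- expand.grid(lapply(infls, function(i) seq_along(sfx_cands[[i]])))
    for (gi in seq_len(nrow(grid))) {
      ab <- 0
      sidx <- integer(length(infls))
      for (ci in seq_along(infls)) {
        s <- sfx_cands[[infls[ci]]][[grid[gi, ci]]]
        sidx[ci] <- skey(s)
        ab <- ab + length(s) * unit
      }
      sb <- 0
      ok <- TRUE
      for (li in seq_along(lexemes)) {
        found <- NA
        for (si in seq_along(stems)) {
          hit <- TRUE
          for (ci in seq_along(infls)) {
            target <- targets[[li]][ci]
            if (is.na(target)) next
            if (D[[si]][sidx[ci]] != target) { hit <- FALSE; break }
          }
          if (hit) { found <- length(stems[[si]]) * unit; break }
        }
        if (is.na(found)) { ok <- FALSE; break }
        sb <- sb + found
      }
      if (ok) best <- max(best, -(rb + ab + sb))
    }
  }
  best
}

# enumerate every theory of 0..K ordered rules as index vectors into a pool
oracle_theories <- function(rules, K) {
  n <- length(rules)
  out <- list(integer())
  if (K >= 1) for (i in seq_len(n)) out[[length(out) + 1L]] <- i
  if (K >= 2) for (i in seq_len(n)) for (j in seq_len(n)) {
    out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

# suffix candidates matching the "inventory" affix space (length <= 1)
oracle_sfx_cands <- function(X, fs) {
  infls <- unique(X$inflection)
  cands <- c(list(character()), as.list(fs$symbols))
  setNames(replicate(length(infls), cands, simplify = FALSE), infls)
}

# --- AGL frontier enumerator ------------------------------------------------

# Non-dominated (parsimony, fit) point set of the bounded copy-grammar space
# for a training set, by plain enumeration with the oracle rule applier.
oracle_agl_frontier <- function(X, cfg) {
  fs <- cfg$inventory$fs
  pool <- phonosynth:::agl_rule_pool(cfg)
  words <- X$form
  units_of <- function(w) {
    if (cfg$mode == "syllabic") {
      vapply(syllabify(w, fs)$syllables, paste, "", collapse = "")
    } else tokenize_form(w, fs)
  }
  wunits <- lapply(words, units_of)
  edge <- function(side) {
    out <- list(character())
    for (u in wunits) {
      for (len in seq_len(min(cfg$max_affix_units, length(u)))) {
        out[[length(out) + 1L]] <- if (side == "pfx") u[seq_len(len)]
        else u[seq(length(u) - len + 1L, length(u))]
      }
    }
    out[!duplicated(vapply(out, paste, "", collapse = "\1"))]
  }
  pfxs <- edge("pfx"); sfxs <- edge("sfx")
  ths <- lapply(oracle_theories(pool, cfg$max_rules), function(idx) pool[idx])
  pts <- list()
  for (th in ths) {
    rb <- if (length(th)) sum(vapply(th, rule_cost, 0,
                                     cm = cfg$cost_model)) else 0
    for (pfx in pfxs) for (sfx in sfxs) {
      fit <- 0
      ok <- TRUE
      for (wi in seq_along(words)) {
        u_all <- wunits[[wi]]
        best <- NULL
        subs <- list(character())
        for (i in seq_along(u_all)) for (j in i:length(u_all)) {
          subs[[length(subs) + 1L]] <- u_all[i:j]
        }
        for (u in subs) {
          np <- length(pfx); ns <- length(sfx)
          len <- length(u) - np - ns
          if (len < 0 || len > cfg$max_stem_units) next
          if (np && !identical(u[seq_len(np)], pfx)) next
          if (ns && !identical(u[seq(length(u) - ns + 1L, length(u))],
                               sfx)) next
          got <- paste(oracle_derive(
            th, tokenize_form(paste(u, collapse = ""), fs), fs),
            collapse = "")
          if (got != words[wi]) next
          b <- len * cfg$unit_bits + 1
          if (is.null(best) || b < best) best <- b
        }
        if (is.null(best)) { ok <- FALSE; break }
        fit <- fit + best
      }
      if (!ok) next
      pars <- rb +
        (if (length(pfx)) length(pfx) * cfg$unit_bits + 1 else 0) +
        (if (length(sfx)) length(sfx) * cfg$unit_bits + 1 else 0)
      pts[[length(pts) + 1L]] <- c(pars, fit)
    }
  }
  m <- unique(do.call(rbind, pts))
  dom <- vapply(seq_len(nrow(m)), function(i) {
    any(m[, 1] <= m[i, 1] & m[, 2] <= m[i, 2] &
          (m[, 1] < m[i, 1] | m[, 2] < m[i, 2]))
  }, TRUE)
  m <- m[!dom, , drop = FALSE]
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

frontier_points <- function(fr) {
  m <- unique(cbind(fr$parsimony_bits, fr$fit_bits))
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

# --- shared tiny fixtures ---------------------------------------------------

toy_fs <- function(symbols = c("p", "b", "t", "d", "a", "i")) {
  load_feature_system("articulatory", restrict = symbols)
}

plural_fs <- function() {
  load_feature_system("articulatory",
                      restrict = c("d", "a", "g", "k", "æ", "t", "h", "ɔ",
                                   "r", "s", "z", "ә"))
}

plural_problem <- function() {
  problem_data(tibble::tibble(
    stem_id = rep(c("DOG", "CAT", "HORSE"), each = 2),
    inflection = rep(c("sg", "pl"), 3),
    form = c("dag", "dagz", "kæt", "kæts", "hɔrs", "hɔrsәz")))
}

serbo_fs <- function() {
  load_feature_system("articulatory",
                      restrict = c("y", "a", "s", "n", "m", "l", "d", "r",
                                   "o", "k", "v", "b", "t"))
}

# Simplified masculine/feminine adjective paradigm: feminine appends /a/,
# and /a/ is inserted before a word-final consonant cluster.
serbo_grammar <- function(fs) {
  list(theory = theory(parse_rule("∅ -> a / C _ C #", fs)),
       lexicon = lexicon(
         stems = list(CLEAR = "yasn", FAMOUS = "slavn", DEAD = "mrtv",
                      GREEN = "zelen")[c("CLEAR")],
         suffixes = setNames(list("a"),
                             bundle_key(inflection_bundle(infl = "fem")))))
}

expect_form <- function(actual, expected) {
  expect_identical(form_string(actual), expected)
}
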