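# Few-shot artificial-grammar-learning (AGL) simulation. Training words come
# from reduplicative templates over CV syllables (ABB, ABA, AAB, AAx, AxA);
# the learner entertains a small space of copy + constant-affix grammars and
# scores held-out words by marginalizing over the Pareto-optimal grammars of
# the training set.

#' AGL inventory and configuration
#'
#' The stimulus inventory is a set of CV syllables built from consonant and
#' vowel pools over the articulatory feature table. The syllable universe
#' (all CxV combinations) fixes the per-unit code length used to price stems.
#'
#' @param consonants,vowels Pools used to build CV syllables.
#' @return List with the restricted `feature_system` and the syllable
#'   universe.
#' @export
agl_inventory <- function(consonants = c("w", "f", "m", "k", "b", "l", "d", "n"),
                          vowels = c("o", "e", "i", "a", "u")) {
  fs <- load_feature_system("articulatory", restrict = c(consonants, vowels))
  sylls <- as.vector(outer(consonants, vowels, paste0))
  list(fs = fs, consonants = consonants, vowels = vowels, syllables = sylls)
}

#' @rdname agl_inventory
#' @param mode `"syllabic"` (units are syllables; rules copy peripheral
#'   syllables) or `"segmental"` (units are phonemes; rules copy one or two
#'   peripheral phonemes).
#' @param inventory An [agl_inventory()].
#' @param cost_model A [cost_model()]; uniform coding is the default so that
#'   stem codes form subprobabilities.
#' @param max_rules Rule bound for the copy-grammar space.
#' @param max_affix_units Longest constant affix, in units.
#' @param max_stem_units Longest stem, in units (3 syllables or 6 phonemes by
#'   default, enough to memorize any stimulus).
#' @export
agl_config <- function(mode = c("syllabic", "segmental"),
                       inventory = agl_inventory(),
                       cost_model = phonosynth::cost_model(
                         phoneme_coding = "uniform"),
                       max_rules = 2L,
                       max_affix_units = 2L,
                       max_stem_units = if (match.arg(mode) == "syllabic")
                         3L else 6L) {
  mode <- match.arg(mode)
  universe <- if (mode == "syllabic") length(inventory$syllables)
  else length(inventory$fs$symbols)
  structure(list(mode = mode, inventory = inventory, cost_model = cost_model,
                 max_rules = as.integer(max_rules),
                 max_affix_units = as.integer(max_affix_units),
                 max_stem_units = as.integer(max_stem_units),
                 unit_bits = log2(universe) + 1),
            class = "agl_config")
}

#' AGL stimulus patterns
#'
#' Template names follow the syllable-structure convention: A and B are
#' variable syllables (sampled fresh per word, A != B), x is one constant
#' syllable shared by the whole stimulus set.
#'
#' @param name One of `"ABB"`, `"ABA"`, `"AAB"`, `"AAx"`, `"AxA"`.
#' @param x The constant syllable, for patterns that use one.
#' @return An object of class `agl_pattern`.
#' @export
agl_pattern <- function(name = c("ABB", "ABA", "AAB", "AAx", "AxA"),
                        x = "ko") {
  name <- match.arg(name)
  structure(list(name = name, x = x,
                 uses_x = grepl("x", name)), class = "agl_pattern")
}

pattern_word <- function(p, A, B) {
  switch(p$name,
         ABB = c(A, B, B), ABA = c(A, B, A), AAB = c(A, A, B),
         AAx = c(A, A, p$x), AxA = c(A, p$x, A))
}

#' Generate AGL stimuli
#'
#' Draws `n` pairwise-distinct words matching the pattern's template, as a
#' single-column paradigm matrix (each word is its own stem). Reproducible
#' given `seed`.
#'
#' @param pattern An [agl_pattern()].
#' @param n Number of words.
#' @param seed Integer seed.
#' @param cfg An [agl_config()] (supplies the syllable inventory).
#' @return A [problem_data()] with one inflection column `word`.
#' @export
generate_stimuli <- function(pattern, n, seed, cfg = agl_config()) {
  sylls <- setdiff(cfg$inventory$syllables,
                   if (pattern$uses_x) pattern$x else character())
  if (n == 0L) {
    return(tibble::tibble(stem_id = character(), inflection = character(),
                          form = character()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  words <- character()
  guard <- 0L
  while (length(words) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("syllable inventory exhausted")
    AB <- sample(sylls, 2L)
    w <- paste(pattern_word(pattern, AB[1], AB[2]), collapse = "")
    if (!w %in% words) words <- c(words, w)
  }
  problem_data(tibble::tibble(
    stem_id = sprintf("%s_%02d", pattern$name, seq_len(n)),
    inflection = "word", form = words))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# ---------------------------------------------------------------------------
# units and copy-grammar evaluation

word_units <- function(word, cfg) {
  fs <- cfg$inventory$fs
  if (cfg$mode == "syllabic") {
    vapply(syllabify(word, fs)$syllables, paste, "", collapse = "")
  } else {
    tokenize_form(word, fs)
  }
}

units_to_form <- function(units, cfg) {
  tokenize_form(paste(units, collapse = ""), cfg$inventory$fs)
}

agl_rule_pool <- function(cfg) {
  out <- list()
  if (cfg$mode == "syllabic") {
    for (src in c("first", "last")) for (tgt in c("begin", "end")) {
      out[[length(out) + 1L]] <- rule(NULL, change_copy(src, tgt, "syllable"))
    }
  } else {
    # without syllables, rules copy one phoneme at a time: the phoneme at
    # offset j from an edge is copied to that edge (reduplicating a CV
    # syllable therefore takes two rule applications)
    for (j in 1:4) {
      out[[length(out) + 1L]] <-
        rule(NULL, change_copy("first", "begin", "phoneme", j))
      out[[length(out) + 1L]] <-
        rule(NULL, change_copy("last", "end", "phoneme", j))
    }
  }
  out
}

agl_theories <- function(cfg) {
  pool <- agl_rule_pool(cfg)
  out <- list(integer())
  if (cfg$max_rules >= 1L) {
    for (i in seq_along(pool)) out[[length(out) + 1L]] <- i
  }
  if (cfg$max_rules >= 2L) {
    for (i in seq_along(pool)) for (j in seq_along(pool)) {
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  list(pool = pool, theories = out)
}

# apply a copy-rule theory to a unit sequence
agl_apply <- function(rules, units, cfg) {
  ph <- units_to_form(units, cfg)
  out <- apply_rule_sequence(rules, ph, cfg$inventory$fs, validate = FALSE)
  form_string(out)
}

# all contiguous unit substrings of a word, including the empty one
unit_substrings <- function(units) {
  n <- length(units)
  out <- list(character())
  for (i in seq_len(n)) for (j in i:n) {
    out[[length(out) + 1L]] <- units[i:j]
  }
  out[!duplicated(vapply(out, paste, "", collapse = "\1"))]
}

affix_entry_bits <- function(units, cfg) {
  if (!length(units)) 0 else length(units) * cfg$unit_bits + 1
}

stem_bits_agl <- function(len, cfg) len * cfg$unit_bits + 1

# minimal stem bits for one word under (theory, pfx, sfx); NULL if none fits.
# Copy rules only add peripheral copies, so the underlying form is a
# contiguous substring of the surface word.
agl_stem_fit <- function(rules, pfx, sfx, word, cfg,
                         subs = NULL, derived_ok = NULL) {
  units <- word_units(word, cfg)
  target <- paste(units_to_form(units, cfg), collapse = "")
  subs <- subs %||% unit_substrings(units)
  if (is.null(derived_ok)) {
    derived_ok <- vapply(subs, function(u) {
      identical(agl_apply(rules, u, cfg), target)
    }, TRUE)
  }
  best <- NULL
  for (k in seq_along(subs)) {
    if (!derived_ok[k]) next
    u <- subs[[k]]
    np <- length(pfx); ns <- length(sfx)
    len <- length(u) - np - ns
    if (len < 0L || len > cfg$max_stem_units) next
    if (np && !identical(u[seq_len(np)], pfx)) next
    if (ns && !identical(u[seq(length(u) - ns + 1L, length(u))], sfx)) next
    stem <- if (len) u[seq(np + 1L, np + len)] else character()
    b <- stem_bits_agl(len, cfg)
    if (is.null(best) || b < best$bits) best <- list(stem = stem, bits = b)
  }
  best
}

#' Pareto frontier of copy grammars for an AGL training set
#'
#' Enumerates the bounded space of copy rules (at most `max_rules`) and
#' constant affixes (edge substrings of the training words, up to
#' `max_affix_units`), keeps the grammars consistent with every training
#' word, deduplicates by analysis, and returns the set not dominated on
#' (parsimony bits, fit bits). The memorizing grammar (no rules, no affixes)
#' is always on the frontier.
#'
#' @param X_train A [problem_data()] of training words (single column).
#' @param cfg An [agl_config()].
#' @return A `pareto_frontier` tibble (see [pareto_synthesize()]).
#' @export
agl_pareto <- function(X_train, cfg = agl_config()) {
  cm <- cfg$cost_model
  words <- X_train$form
  th <- agl_theories(cfg)
  word_subs <- lapply(words, function(w) unit_substrings(word_units(w, cfg)))
  word_target <- unname(vapply(words, function(w) {
    paste(units_to_form(word_units(w, cfg), cfg), collapse = "")
  }, ""))

  # affix candidates: empty plus edge substrings of the training words
  edge_cands <- function(side) {
    out <- list(character())
    for (w in words) {
      u <- word_units(w, cfg)
      for (len in seq_len(min(cfg$max_affix_units, length(u)))) {
        s <- if (side == "pfx") u[seq_len(len)]
        else u[seq(length(u) - len + 1L, length(u))]
        out[[length(out) + 1L]] <- s
      }
    }
    out[!duplicated(vapply(out, paste, "", collapse = "\1"))]
  }
  pfxs <- edge_cands("pfx")
  sfxs <- edge_cands("sfx")

  rows <- list()
  for (ti in seq_along(th$theories)) {
    rules <- th$pool[th$theories[[ti]]]
    rule_bits <- if (length(rules)) {
      sum(vapply(rules, rule_cost, 0, cm = cm))
    } else 0
    # derive each substring once per theory
    ok <- lapply(seq_along(words), function(wi) {
      vapply(word_subs[[wi]], function(u) {
        identical(agl_apply(rules, u, cfg), word_target[wi])
      }, TRUE)
    })
    for (pi in seq_along(pfxs)) for (si in seq_along(sfxs)) {
      pfx <- pfxs[[pi]]; sfx <- sfxs[[si]]
      fits <- lapply(seq_along(words), function(wi) {
        agl_stem_fit(rules, pfx, sfx, words[wi], cfg,
                     subs = word_subs[[wi]], derived_ok = ok[[wi]])
      })
      if (any(vapply(fits, is.null, TRUE))) next
      pars <- rule_bits + affix_entry_bits(pfx, cfg) +
        affix_entry_bits(sfx, cfg)
      fit <- sum(vapply(fits, function(f) f$bits, 0))
      stems <- setNames(lapply(fits, `[[`, "stem"), X_train$stem_id)
      rows[[length(rows) + 1L]] <- list(
        theory = theory(rules),
        pfx = pfx, sfx = sfx, stems = stems,
        parsimony_bits = pars, fit_bits = fit,
        sig = paste(c(vapply(stems, paste, "", collapse = "."), "|",
                      pfx, "|", sfx), collapse = ","))
    }
  }
  if (!length(rows)) {
    stop(structure(class = c("phonosynth_unsat", "error", "condition"),
                   list(message = "no consistent copy grammar", call = NULL)))
  }
  pars <- vapply(rows, `[[`, 0, "parsimony_bits")
  fit <- vapply(rows, `[[`, 0, "fit_bits")
  ord <- order(pars + fit, pars, method = "radix")
  rows <- rows[ord]; pars <- pars[ord]; fit <- fit[ord]
  first <- !duplicated(vapply(rows, `[[`, "", "sig"))
  rows <- rows[first]; pars <- pars[first]; fit <- fit[first]
  dom <- vapply(seq_along(rows), function(i) {
    any(pars <= pars[i] & fit <= fit[i] & (pars < pars[i] | fit < fit[i]))
  }, TRUE)
  rows <- rows[!dom]; pars <- pars[!dom]; fit <- fit[!dom]
  out <- tibble::tibble(
    parsimony_bits = pars, fit_bits = fit, joint_bits = pars + fit,
    theory = lapply(rows, `[[`, "theory"),
    lexicon = lapply(rows, function(r) {
      key <- bundle_key(inflection_bundle(infl = "word"))
      lexicon(stems = r$stems,
              prefixes = if (length(r$pfx))
                setNames(list(units_to_form(r$pfx, cfg)), key) else list(),
              suffixes = if (length(r$sfx))
                setNames(list(units_to_form(r$sfx, cfg)), key) else list())
    }),
    label = vapply(rows, function(r) {
      lab <- if (!length(r$theory$rules)) "memorize"
      else paste(vapply(r$theory$rules, format_rule, ""), collapse = "; ")
      aff <- c(if (length(r$pfx)) paste0(paste(r$pfx, collapse = ""), "+"),
               if (length(r$sfx)) paste0("+", paste(r$sfx, collapse = "")))
      paste(c(lab, aff), collapse = " ")
    }, ""))
  out <- out[order(out$parsimony_bits, out$fit_bits), ]
  class(out) <- c("pareto_frontier", class(out))
  attr(out, "config") <- cfg
  out
}

frontier_grammar_lik <- function(frontier, i, word, cfg) {
  g <- frontier$theory[[i]]
  L <- frontier$lexicon[[i]]
  pfx <- if (length(L$prefixes)) {
    u <- L$prefixes[[1]]
    word_units(paste(u, collapse = ""), cfg)
  } else character()
  sfx <- if (length(L$suffixes)) {
    word_units(paste(L$suffixes[[1]], collapse = ""), cfg)
  } else character()
  fit <- agl_stem_fit(g$rules, pfx, sfx, word, cfg)
  if (is.null(fit)) 0 else 2^(-fit$bits)
}

#' Held-out scoring by Pareto-marginal likelihood
#'
#' The probability of a held-out word given the training set: grammars on the
#' training frontier are weighted by their (normalized) joint training
#' probability, and each scores the new word by its best-stem likelihood
#' bound.
#'
#' @param X_train,X_test [problem_data()] of training and held-out words
#'   (test stems unseen).
#' @param cfg An [agl_config()].
#' @param frontier Optionally a precomputed [agl_pareto()] frontier for
#'   `X_train`.
#' @return Natural-log probability of the test set.
#' @export
score_heldout <- function(X_train, X_test, cfg = agl_config(),
                          frontier = NULL) {
  frontier <- frontier %||% agl_pareto(X_train, cfg)
  w <- 2^(-(frontier$joint_bits - min(frontier$joint_bits)))
  w <- w / sum(w)
  p <- 0
  for (i in seq_len(nrow(frontier))) {
    lik <- 1
    for (word in X_test$form) {
      lik <- lik * frontier_grammar_lik(frontier, i, word, cfg)
    }
    p <- p + w[i] * lik
  }
  log(p)
}

#' Log-odds discrimination between consistent and inconsistent test words
#'
#' For each paired consistent/inconsistent word, the difference in held-out
#' log-probability given the training set; positive values mean the learner
#' prefers pattern-consistent words.
#'
#' @param X_train Training [problem_data()].
#' @param consistent,inconsistent Equal-length character vectors of test
#'   words (or single-column [problem_data()]s).
#' @param cfg An [agl_config()].
#' @return List with `pairs` (tibble: `consistent`, `inconsistent`,
#'   `log_odds`), `mean` and `sd`.
#' @export
log_odds <- function(X_train, consistent, inconsistent,
                     cfg = agl_config()) {
  wc <- if (inherits(consistent, "data.frame")) consistent$form
  else consistent
  wi <- if (inherits(inconsistent, "data.frame")) inconsistent$form
  else inconsistent
  stopifnot(length(wc) == length(wi))
  frontier <- agl_pareto(X_train, cfg)
  w <- 2^(-(frontier$joint_bits - min(frontier$joint_bits)))
  w <- w / sum(w)
  score1 <- function(word) {
    p <- 0
    for (i in seq_len(nrow(frontier))) {
      p <- p + w[i] * frontier_grammar_lik(frontier, i, word, cfg)
    }
    log(p)
  }
  lo <- vapply(seq_along(wc), function(k) score1(wc[k]) - score1(wi[k]), 0)
  list(pairs = tibble::tibble(consistent = wc, inconsistent = wi,
                              log_odds = lo),
       mean = mean(lo), sd = stats::sd(lo))
}
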