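#' Description-length cost model
#'
#' All grammar components are priced in bits; the prior probability of a
#' grammar is `2^-bits`. The defaults live in one versioned YAML file
#' (`inst/extdata/cost_model_default.yaml`) and can be overridden per call;
#' result files echo the constants used.
#'
#' @param ... Overrides for the default constants, e.g. `max_stem_len = 5`,
#'   `allow_star = FALSE`, `phoneme_coding = "uniform"`. `phoneme_coding`
#'   selects how lexicon material is priced: `"flat"` charges
#'   `lexicon_phoneme` bits per phoneme; `"uniform"` charges
#'   `log2(alphabet size) + 1` bits per unit (the +1 continue/stop bit makes
#'   the code a subprobability over all finite strings).
#' @param file Optional path to a YAML file of constants to start from.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(..., file = NULL) {
  path <- file %||% system.file("extdata", "cost_model_default.yaml",
                                package = "phonosynth")
  cm <- yaml::read_yaml(path)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cm)))
  if (length(unknown)) stop("unknown cost-model field(s): ",
                            paste(unknown, collapse = ", "))
  cm[names(dots)] <- dots
  numfields <- c("rule_base", "feature_literal", "kleene_star",
                 "trigger_element", "boundary", "alpha_variable",
                 "lexicon_phoneme", "insert_phoneme", "copy_change")
  if (any(unlist(cm[numfields]) <= 0)) stop("all costs must be positive")
  if (cm$max_rules < 0) stop("max_rules must be >= 0")
  structure(cm, class = "cost_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

per_unit_bits <- function(cm, alphabet_size) {
  if (identical(cm$phoneme_coding, "uniform")) log2(alphabet_size) + 1
  else cm$lexicon_phoneme
}

fm_bits <- function(fm, cm) {
  if (is.null(fm)) return(0)
  if (fm_is_phoneme_literal(fm)) return(cm$insert_phoneme)
  if (length(fm$literals) && !cm$allow_features) {
    stop("feature matrices are disabled in this cost model (allow_features)")
  }
  length(fm$literals) * cm$feature_literal
}

trigger_bits <- function(tr, cm) {
  s <- 0
  for (e in tr$elements) {
    if (e$star && !cm$allow_star) {
      stop("Kleene star is disabled in this cost model (allow_star)")
    }
    s <- s + cm$trigger_element + fm_bits(e$fm, cm) +
      if (e$star) cm$kleene_star else 0
  }
  s + if (tr$boundary) cm$boundary else 0
}

#' Description length of one rule
#'
#' Base cost plus the summed costs of the focus, the structural change, both
#' triggers (feature literals, Kleene stars, boundary symbols) and any alpha
#' variable. Deterministic; structurally identical rules cost the same, and
#' adding any component strictly increases the cost.
#'
#' @param r A [rule()].
#' @param cm A [cost_model()].
#' @return Cost in bits.
#' @export
rule_cost <- function(r, cm = cost_model()) {
  ch <- r$change
  change_bits <- switch(ch$kind,
    feature = fm_bits(ch$fm, cm) +
      if (!is.null(ch$alpha)) cm$alpha_variable else 0,
    delete = 0,
    insert = length(ch$phonemes) * cm$insert_phoneme,
    copy = cm$copy_change)
  cm$rule_base + fm_bits(r$focus, cm) + change_bits +
    trigger_bits(r$left, cm) + trigger_bits(r$right, cm)
}

theory_cost <- function(T_, cm) {
  if (!length(T_$rules)) return(0)
  sum(vapply(T_$rules, rule_cost, 0, cm = cm))
}

#' Description length of a lexicon
#'
#' Every stored phoneme (stems, prefixes, suffixes) is charged per-unit bits
#' under the cost model's coding scheme.
#'
#' @param L A [lexicon()].
#' @param cm A [cost_model()].
#' @param fs Feature system (fixes the alphabet size for uniform coding).
#' @return Cost in bits.
#' @export
lexicon_cost <- function(L, cm = cost_model(), fs) {
  unit <- per_unit_bits(cm, length(fs$symbols))
  n <- sum(lengths(L$stems)) + sum(lengths(L$prefixes)) +
    sum(lengths(L$suffixes))
  n * unit
}

#' The distinguished inconsistency value
#'
#' The MAP objective is defined only for grammars that exactly reproduce the
#' data; `INCONSISTENT` marks everything else. It is a distinguished sentinel
#' rather than a large negative score.
#'
#' @export
INCONSISTENT <- structure(list(), class = "phonosynth_inconsistent")

#' @rdname INCONSISTENT
#' @param x An object.
#' @return `TRUE` iff `x` is the `INCONSISTENT` sentinel.
#' @export
is_inconsistent <- function(x) inherits(x, "phonosynth_inconsistent")

#' @export
print.phonosynth_inconsistent <- function(x, ...) {
  cat("INCONSISTENT\n")
  invisible(x)
}

#' The MAP synthesis objective
#'
#' The negated total description length of the grammar when it exactly
#' reproduces the data, else [INCONSISTENT]. Higher is better.
#'
#' @param X A [problem_data()].
#' @param T_ A [theory()].
#' @param L A [lexicon()].
#' @param cm A [cost_model()].
#' @param fs Feature system.
#' @return A (negative) score in bits, or [INCONSISTENT].
#' @export
objective <- function(X, T_, L, cm = cost_model(), fs) {
  if (!check_consistency(T_, L, X, fs)$consistent) return(INCONSISTENT)
  -(theory_cost(T_, cm) + lexicon_cost(L, cm, fs))
}

# Enumerate candidate stems in deterministic order: shortest first, then
# lexicographic in the order of `alphabet`. Returns a list of integer index
# vectors into alphabet (length 0 included).
stem_index_grid <- function(n_alpha, len) {
  if (len == 0L) return(list(integer()))
  grids <- rev(expand.grid(rev(replicate(len, seq_len(n_alpha),
                                         simplify = FALSE))))
  lapply(seq_len(nrow(grids)), function(i) as.integer(grids[i, ]))
}

#' Best-fitting underlying stem for one paradigm row
#'
#' Exhaustively searches stems over `alphabet` up to `max_len` units,
#' shortest first then lexicographic, and returns the first (hence
#' minimal-cost) stem whose derivations reproduce every observed cell of the
#' row, together with its description length. `NULL` means no stem fits.
#'
#' @param T_ A [theory()].
#' @param affixes A [lexicon()] holding prefixes/suffixes (stems ignored).
#' @param row A [problem_data()] subset containing a single stem's cells.
#' @param cm A [cost_model()].
#' @param fs Feature system.
#' @param alphabet Units the stem may be built from: phoneme symbols by
#'   default, or multi-phoneme strings (e.g. syllables) for syllabic search.
#' @param max_len Maximum stem length in units (default `cm$max_stem_len`).
#' @return `list(stem = <phoneme vector>, bits = <cost>)` or `NULL`.
#' @export
stem_fit <- function(T_, affixes, row, cm = cost_model(), fs,
                     alphabet = fs$symbols, max_len = cm$max_stem_len) {
  stopifnot(nrow(row) >= 1L)
  if (length(unique(row$stem_id)) != 1L) {
    stop("`row` must contain exactly one stem's cells")
  }
  for (r in T_$rules) validate_rule(r, fs)
  crs <- lapply(T_$rules, compile_rule, fs = fs)
  units <- lapply(alphabet, tokenize_form, fs = fs)
  unit_bits <- per_unit_bits(cm, length(alphabet))

  cells <- lapply(seq_len(nrow(row)), function(i) {
    b <- problem_bundle(row, row$inflection[i])
    list(pfx = lexicon_affix(affixes, b, "pfx"),
         sfx = lexicon_affix(affixes, b, "sfx"),
         target = form_string(tokenize_form(row$form[i], fs)))
  })

  n_alpha <- length(alphabet)
  for (len in 0:max_len) {
    if (len > 0L && n_alpha^len > 2e5) {
      stop("stem search space too large; restrict `alphabet` or `max_len`")
    }
    for (idx in stem_index_grid(n_alpha, len)) {
      stem <- unlist(units[idx], use.names = FALSE)
      if (is.null(stem)) stem <- character()
      ok <- TRUE
      for (cl in cells) {
        ph <- c(cl$pfx, stem, cl$sfx)
        for (cr in crs) ph <- apply_compiled(cr, ph)
        if (!identical(form_string(ph), cl$target)) { ok <- FALSE; break }
      }
      if (ok) {
        bits <- if (identical(cm$phoneme_coding, "uniform"))
          len * unit_bits + 1  # terminating stop bit: stem codes sum to <= 1
        else length(stem) * unit_bits
        return(list(stem = stem, bits = bits))
      }
    }
  }
  NULL
}

#' Lower bound on the stem-marginal likelihood of unseen data
#'
#' For data whose stems are disjoint from the lexicon's, the marginal
#' likelihood sums over all stem assignments; taking only the most likely
#' underlying form per row gives a lower bound, tight when a row admits
#' essentially one stem. Returned as a natural-log probability (`-Inf` when
#' some row admits no stem at all).
#'
#' @param X_new A [problem_data()] with unseen stems.
#' @param T_ A [theory()].
#' @param L A [lexicon()] (affixes used; its stems must not overlap X_new's).
#' @inheritParams stem_fit
#' @return Natural-log probability (<= 0).
#' @export
likelihood_lower_bound <- function(X_new, T_, L, cm = cost_model(), fs,
                                   alphabet = fs$symbols,
                                   max_len = cm$max_stem_len) {
  clash <- intersect(unique(X_new$stem_id), names(L$stems))
  if (length(clash)) {
    stop("stems of X_new must be disjoint from the lexicon's: ",
         paste(clash, collapse = ", "))
  }
  total <- 0
  for (sid in unique(X_new$stem_id)) {
    fit <- stem_fit(T_, L, X_new[X_new$stem_id == sid, , drop = FALSE],
                    cm, fs, alphabet, max_len)
    if (is.null(fit)) return(-Inf)
    total <- total - fit$bits * log(2)
  }
  total
}

#' Exact stem-marginal likelihood by enumeration
#'
#' The enumerative counterpart of [likelihood_lower_bound()]: sums
#' `2^-bits(stem)` over every stem (up to `max_len`) whose derivations
#' reproduce the row, independently per row. Only feasible for tiny
#' alphabets; used to verify the bound's tightness.
#'
#' @inheritParams likelihood_lower_bound
#' @return Natural-log probability.
#' @export
exact_stem_marginal <- function(X_new, T_, L, cm = cost_model(), fs,
                                alphabet = fs$symbols,
                                max_len = cm$max_stem_len) {
  for (r in T_$rules) validate_rule(r, fs)
  crs <- lapply(T_$rules, compile_rule, fs = fs)
  units <- lapply(alphabet, tokenize_form, fs = fs)
  unit_bits <- per_unit_bits(cm, length(alphabet))
  n_alpha <- length(alphabet)
  total <- 0
  for (sid in unique(X_new$stem_id)) {
    row <- X_new[X_new$stem_id == sid, , drop = FALSE]
    cells <- lapply(seq_len(nrow(row)), function(i) {
      b <- problem_bundle(row, row$inflection[i])
      list(pfx = lexicon_affix(L, b, "pfx"), sfx = lexicon_affix(L, b, "sfx"),
           target = form_string(tokenize_form(row$form[i], fs)))
    })
    p_row <- 0
    for (len in 0:max_len) {
      for (idx in stem_index_grid(n_alpha, len)) {
        stem <- unlist(units[idx], use.names = FALSE)
        if (is.null(stem)) stem <- character()
        ok <- TRUE
        for (cl in cells) {
          ph <- c(cl$pfx, stem, cl$sfx)
          for (cr in crs) ph <- apply_compiled(cr, ph)
          if (!identical(form_string(ph), cl$target)) { ok <- FALSE; break }
        }
        if (ok) {
          bits <- if (identical(cm$phoneme_coding, "uniform"))
            len * unit_bits + 1
          else length(stem) * unit_bits
          p_row <- p_row + 2^(-bits)
        }
      }
    }
    if (p_row == 0) return(-Inf)
    total <- total + log(p_row)
  }
  total
}
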