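#' Phoneme substitutions
#'
#' An allophony problem pairs observed forms with a substitution: a partial,
#' injective function mapping phonemes to phonemes, relating each underlying
#' phoneme to its contextual variant. Overlapping domain and range (chain
#' shifts) are rejected.
#'
#' @param ... Named phoneme pairs, e.g. `b = "p", d = "t", g = "k"`, or a
#'   single named character vector.
#' @return An object of class `substitution`.
#' @export
substitution <- function(...) {
  v <- unlist(list(...))
  if (is.null(v)) v <- character()
  if (length(v)) {
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      stop("substitution entries must be named (domain -> range)")
    }
    if (anyDuplicated(v)) stop("substitution must be injective")
    if (length(intersect(names(v), v))) {
      stop("substitution domain and range overlap (chain shifts unsupported)")
    }
  }
  structure(list(map = v), class = "substitution")
}

s_invert <- function(s) {
  inv <- if (length(s$map)) setNames(names(s$map), s$map) else character()
  structure(list(map = inv), class = "substitution")
}

#' Apply a substitution to a form
#'
#' Pointwise: phonemes in the substitution's domain are replaced, all others
#' pass through.
#'
#' @param s A [substitution()].
#' @param form Phoneme string or tokenized character vector.
#' @param fs Feature system (for tokenization).
#' @return Character vector of phonemes.
#' @export
apply_substitution <- function(s, form, fs) {
  ph <- tokenize_form(form, fs)
  hit <- ph %in% names(s$map)
  ph[hit] <- s$map[ph[hit]]
  ph
}

solve_one_direction <- function(X, stems, cfg, fs) {
  rules <- enumerate_rule_space(fs, cfg, X)
  infls <- unique(X$inflection)
  pairs <- setNames(lapply(infls, function(i) {
    list(list(pfx = character(), sfx = character()))
  }), infls)
  data <- kernel_data(X, pairs, cfg$cost_model, fs,
                      fixed_stems = stems)
  res <- kernel_call(.kernel_search, rules, data, fs, cfg$cost_model,
                     cfg$max_rules, FALSE, NULL, TRUE)
  if (!res$found) return(NULL)
  g <- kernel_result_grammar(res, rules, data, X, fs)
  new_synthesis_result(g$theory, g$lexicon, X, fs, cfg, "exact_bounded",
                       list(rule = res$best$rule_bits,
                            affix = res$best$affix_bits,
                            stem = res$best$stem_bits))
}

#' Solve an allophony problem
#'
#' Decides which side of a substitution holds the underlying phonemes. Two
#' candidate lexica are built: direction 1 stores `s(f)` as each word's stem,
#' direction 2 stores `s^-1(f)`; for each, the objective-maximizing rule
#' theory reproducing the surface forms is synthesized, and the direction
#' with the higher joint score wins (ties go to direction 1 with a warning).
#' The chosen lexicon excludes the non-underlying allophones by construction.
#'
#' @param X A [problem_data()] (typically one column, one word per stem).
#' @param s A [substitution()].
#' @param cfg A [synthesis_config()].
#' @param fs Feature system.
#' @return List with `direction` (1, 2 or `NA` if unsolved), `solved`
#'   (following the convention that a problem counts as solved only when a
#'   rule explaining an alternation is found), `result` (winning
#'   `synthesis_result`), and `scores`/`results` for both directions.
#' @export
solve_allophony <- function(X, s, cfg = synthesis_config(), fs) {
  stopifnot(inherits(s, "substitution"))
  lexemes <- problem_lexemes(X)
  stems_for <- function(sub) {
    out <- lapply(lexemes, function(l) {
      f <- X$form[X$stem_id == l][1]
      apply_substitution(sub, f, fs)
    })
    names(out) <- lexemes
    out
  }
  stems1 <- stems_for(s)
  stems2 <- stems_for(s_invert(s))
  r1 <- solve_one_direction(X, stems1, cfg, fs)
  r2 <- solve_one_direction(X, stems2, cfg, fs)
  sc <- c(if (is.null(r1)) -Inf else r1$objective,
          if (is.null(r2)) -Inf else r2$objective)
  if (all(is.infinite(sc))) {
    return(list(direction = NA_integer_, solved = FALSE, result = NULL,
                results = list(r1, r2), scores = sc, substitution = s))
  }
  if (sc[1] == sc[2]) {
    warning("both directions score equally; choosing direction 1")
    dir <- 1L
  } else dir <- which.max(sc)
  win <- list(r1, r2)[[dir]]
  # a rule "explains an alternation" if some derivation is not the identity
  fires <- FALSE
  for (l in lexemes) {
    for (i in which(X$stem_id == l)) {
      m <- meaning(l, problem_bundle(X, X$inflection[i]))
      d <- derive(win$theory, win$lexicon, m, fs, trace = TRUE)
      if (!identical(d$underlying, d$surface)) fires <- TRUE
    }
  }
  solved <- length(s$map) == 0L || fires
  list(direction = dir, solved = solved, result = win,
       results = list(r1, r2), scores = sc, substitution = s)
}
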