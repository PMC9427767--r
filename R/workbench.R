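# Problem/grammar serialization and the seeded synthetic-problem generator
# used for parameter-recovery experiments.

#' Read and write paradigm-matrix problem files
#'
#' Problems are JSON documents with fields `feature_system` (table name),
#' `inflections` (list of `{name, bundle}`), `rows` (list of
#' `{stem_id, cells}` in data order) and optionally `substitution` (for
#' allophony problems). Cell order is preserved exactly, which the
#' counterexample schedule depends on.
#'
#' @param path File path.
#' @param fs Optional feature system used to validate every form (errors
#'   name any unknown glyph).
#' @return A [problem_data()]; a `substitution` attribute carries the
#'   allophony map when present.
#' @export
read_problem <- function(path, fs = NULL) {
  doc <- jsonlite::read_json(path)
  bundles <- NULL
  if (!is.null(doc$inflections)) {
    bundles <- setNames(lapply(doc$inflections, function(i) {
      inflection_bundle(unlist(i$bundle) %||% c(infl = i$name))
    }), vapply(doc$inflections, `[[`, "", "name"))
  }
  cells <- list()
  for (row in doc$rows) {
    for (nm in names(row$cells)) {
      cells[[length(cells) + 1L]] <- tibble::tibble(
        stem_id = row$stem_id, inflection = nm,
        form = row$cells[[nm]])
    }
  }
  X <- problem_data(dplyr::bind_rows(cells), bundles = bundles,
                    feature_system = doc$feature_system)
  if (!is.null(fs)) {
    for (f in X$form) tokenize_form(f, fs)
  }
  if (!is.null(doc$substitution)) {
    attr(X, "substitution") <- substitution(unlist(doc$substitution))
  }
  X
}

#' @rdname read_problem
#' @param X A [problem_data()].
#' @export
write_problem <- function(X, path) {
  bundles <- attr(X, "bundles")
  lex <- problem_lexemes(X)
  doc <- list(
    feature_system = attr(X, "feature_system") %||% "articulatory",
    inflections = lapply(unique(X$inflection), function(nm) {
      list(name = nm, bundle = as.list(bundles[[nm]]$pairs))
    }),
    rows = lapply(lex, function(l) {
      rows <- X[X$stem_id == l, , drop = FALSE]
      list(stem_id = l,
           cells = setNames(as.list(rows$form), rows$inflection))
    }))
  s <- attr(X, "substitution")
  if (!is.null(s) && length(s$map)) doc$substitution <- as.list(s$map)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write grammar files
#'
#' Grammars serialize as canonical SPE notation strings (ordered), the
#' lexicon, an echo of the cost-model constants, the objective breakdown,
#' and a full derivation trace (underlying form, each rule's output, the
#' surface) for every cell of the problem the grammar was fit to.
#'
#' @param res A `synthesis_result` (from [exact_synthesize()] or
#'   [incremental_synthesize()]).
#' @param path File path.
#' @export
write_grammar <- function(res, path) {
  fs <- res$feature_system
  X <- res$data
  derivs <- lapply(seq_len(nrow(X)), function(i) {
    m <- meaning(X$stem_id[i], problem_bundle(X, X$inflection[i]))
    d <- derive(res$theory, res$lexicon, m, fs, trace = TRUE)
    list(stem_id = X$stem_id[i], inflection = X$inflection[i],
         underlying = form_string(d$underlying),
         intermediates = vapply(d$intermediates, form_string, ""),
         surface = form_string(d$surface))
  })
  doc <- list(
    rules = vapply(res$theory$rules, format_rule, ""),
    lexicon = list(
      stems = lapply(res$lexicon$stems, form_string),
      prefixes = lapply(res$lexicon$prefixes, form_string),
      suffixes = lapply(res$lexicon$suffixes, form_string)),
    objective = res$objective,
    bits = list(rules = res$rule_bits, affixes = res$affix_bits,
                stems = res$stem_bits),
    backend = res$backend,
    cost_model = unclass(res$config$cost_model),
    derivations = derivs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grammar
#' @param fs Feature system used to re-parse the rule notation.
#' @return `read_grammar`: list with `theory`, `lexicon`, `objective`,
#'   `cost_model`.
#' @export
read_grammar <- function(path, fs) {
  doc <- jsonlite::read_json(path)
  T_ <- theory(lapply(doc$rules, parse_rule, fs = fs))
  L <- lexicon(stems = doc$lexicon$stems, prefixes = doc$lexicon$prefixes,
               suffixes = doc$lexicon$suffixes, fs = fs)
  list(theory = T_, lexicon = L, objective = doc$objective,
       cost_model = doc$cost_model)
}

#' Synthetic problem generator
#'
#' Samples a ground-truth grammar (rules weighted by the cost-model prior,
#' affixes, stems) and emits the paradigm it derives. Every sampled rule is
#' guaranteed to fire in at least one derivation (the grammar is resampled
#' otherwise), so the emitted data genuinely carries the rules' signal.
#' Identical specs produce identical problems.
#'
#' @param seed Integer seed.
#' @param fs Feature system (typically a small restricted inventory).
#' @param cfg A [synthesis_config()] declaring the rule space sampled from.
#' @param n_stems,n_inflections Paradigm dimensions.
#' @param n_rules Number of ordered rules.
#' @param stem_len_range,affix_len_range Bounds on sampled lengths (affixes
#'   are suffixes; the first inflection is the unaffixed base form).
#' @param max_tries Resampling budget for the fires-at-least-once guarantee.
#' @param vowels Vowel symbols for the CV stem templates; inferred from the
#'   `vowel` feature when the system has one (must be given for atomic-mode
#'   systems).
#' @return List with `theory`, `lexicon`, `data` (a [problem_data()]) and
#'   `seed`.
#' @export
sample_problem <- function(seed, fs, cfg = synthesis_config(),
                           n_stems = 5L, n_inflections = 3L, n_rules = 1L,
                           stem_len_range = c(2L, 4L),
                           affix_len_range = c(0L, 1L),
                           max_tries = 2000L, vowels = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rules_pool <- enumerate_rule_space(fs, cfg)
  # generate only conditioned rules targeting a proper class: a rewrite with
  # no environment is absorbed into the stored stems, and a universal focus
  # rewrites whole words beyond recognition; neither leaves a recoverable
  # signal, and neither resembles a textbook process
  rules_pool <- Filter(function(r) {
    conditioned <- !trigger_is_empty(r$left) || !trigger_is_empty(r$right)
    focused <- is.null(r$focus) || fm_is_phoneme_literal(r$focus) ||
      length(r$focus$literals) > 0
    conditioned && focused
  }, rules_pool)
  bits <- vapply(rules_pool, rule_cost, 0, cm = cfg$cost_model)
  w <- 2^(-(bits - min(bits)))
  infls <- paste0("infl", seq_len(n_inflections))
  if (is.null(vowels)) {
    if (!"vowel" %in% fs$feature_names) {
      stop("atomic-mode systems need an explicit `vowels` argument")
    }
    vowels <- fs$symbols[vapply(fs$symbols, is_vowel, TRUE, fs = fs)]
  }
  cons <- setdiff(fs$symbols, vowels)
  # CV-phonotactic stem templates, as in textbook problems
  templates <- list(c("C", "V"), c("C", "V", "C"), c("V", "C", "V"),
                    c("C", "V", "C", "V"), c("C", "V", "V", "C"))
  templates <- Filter(function(tp) {
    length(tp) >= stem_len_range[1] && length(tp) <= stem_len_range[2]
  }, templates)
  sample_stem <- function() {
    tp <- templates[[sample.int(length(templates), 1L)]]
    vapply(tp, function(k) {
      if (k == "V") sample(vowels, 1L) else sample(cons, 1L)
    }, "")
  }

  for (try_ in seq_len(max_tries)) {
    T_ <- theory(rules_pool[sample.int(length(rules_pool), n_rules,
                                       replace = FALSE, prob = w)])
    # base inflection is unaffixed; the others get distinct nonempty
    # suffixes so that affixal contexts vary across the paradigm
    sfx <- list(character())
    while (length(sfx) < n_inflections) {
      len <- max(1L, sample(seq(affix_len_range[1], affix_len_range[2]), 1L))
      s <- sample(fs$symbols, len, replace = TRUE)
      if (!any(vapply(sfx, identical, TRUE, y = s))) {
        sfx[[length(sfx) + 1L]] <- s
      }
    }
    # stems must jointly cover several distinct final segments, so that
    # edge-conditioned analyses are distinguishable from their competitors
    stems <- list()
    guard <- 0L
    while (length(stems) < n_stems && (guard <- guard + 1L) < 500L) {
      s <- sample_stem()
      if (!any(vapply(stems, identical, TRUE, y = s))) {
        stems[[length(stems) + 1L]] <- s
      }
      if (length(stems) == n_stems) {
        # stems must jointly cover several distinct final segments, so that
        # edge-conditioned analyses are distinguishable from competitors
        finals <- unique(vapply(stems, function(x) x[length(x)], ""))
        if (length(finals) < min(3L, n_stems)) {
          stems <- stems[-length(stems)] # keep drawing for coverage
        }
      }
    }
    if (length(stems) < n_stems) next
    names(stems) <- paste0("stem", seq_len(n_stems))
    L <- lexicon(stems = stems,
                 suffixes = setNames(lapply(seq_along(infls), function(i) {
                   sfx[[i]]
                 }), vapply(infls, function(nm) {
                   bundle_key(inflection_bundle(infl = nm))
                 }, "")))
    # each rule must alternate: fire in some cell and stay silent in another
    # cell of the same lexeme, so its effect cannot be absorbed into a stem
    fired_on <- matrix(FALSE, n_rules, n_stems)
    silent_on <- matrix(FALSE, n_rules, n_stems)
    cells <- list()
    ok <- TRUE
    for (si_idx in seq_along(stems)) {
      si <- names(stems)[si_idx]
      for (ii in seq_along(infls)) {
        m <- meaning(si, inflection_bundle(infl = infls[ii]))
        d <- derive(T_, L, m, fs, trace = TRUE)
        prev <- d$underlying
        for (k in seq_along(d$intermediates)) {
          if (!identical(prev, d$intermediates[[k]])) {
            fired_on[k, si_idx] <- TRUE
          } else silent_on[k, si_idx] <- TRUE
          prev <- d$intermediates[[k]]
        }
        if (!length(d$surface)) { ok <- FALSE; break }
        cells[[length(cells) + 1L]] <- tibble::tibble(
          stem_id = si, inflection = infls[ii],
          form = form_string(d$surface))
      }
      if (!ok) break
    }
    alternates <- all(vapply(seq_len(n_rules), function(k) {
      any(fired_on[k, ] & silent_on[k, ])
    }, TRUE))
    if (ok && alternates) {
      X <- problem_data(dplyr::bind_rows(cells))
      return(list(theory = T_, lexicon = L, data = X, seed = seed))
    }
  }
  stop("could not satisfy the fires-at-least-once constraint within ",
       max_tries, " tries")
}

#' Observational equivalence of two grammars on held-out stems
#'
#' Checks that two (theory, lexicon) pairs derive identical surface forms
#' for every given stem and inflection, using each grammar's own affixes and
#' the provided underlying stems.
#'
#' @param T1,L1 First grammar (e.g. ground truth).
#' @param T2,L2 Second grammar (e.g. synthesized).
#' @param stems Named list of underlying stem forms to test (unseen is
#'   typical).
#' @param inflections Inflection names (bundled as `infl = name`).
#' @param fs Feature system.
#' @return Logical.
#' @export
observationally_equivalent <- function(T1, L1, T2, L2, stems, inflections,
                                       fs) {
  for (nm in names(stems)) {
    L1s <- L1; L2s <- L2
    L1s$stems[[nm]] <- tokenize_form(stems[[nm]], fs)
    L2s$stems[[nm]] <- tokenize_form(stems[[nm]], fs)
    for (infl in inflections) {
      m <- meaning(nm, inflection_bundle(infl = infl))
      f1 <- derive(T1, L1s, m, fs)
      f2 <- derive(T2, L2s, m, fs)
      if (!identical(form_string(f1), form_string(f2))) return(FALSE)
    }
  }
  TRUE
}
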