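#' Inflection bundles and meanings
#'
#' A meaning pairs a stem identifier with an inflection bundle: the remaining
#' meaning features (tense, gender, case, declension class, ...) excluding the
#' stem slot. Bundles are canonically ordered, so equality is structural.
#'
#' @param ... Named values, e.g. `tense = "PAST"`, or a single named character
#'   vector. An empty bundle is allowed (uninflected forms).
#' @return An object of class `inflection_bundle`.
#' @export
inflection_bundle <- function(...) {
  v <- unlist(list(...))
  if (is.null(v)) v <- character()
  if (length(v)) {
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      stop("all bundle entries must be named meaning features")
    }
    v <- v[order(names(v))]
  }
  structure(list(pairs = v), class = "inflection_bundle")
}

#' @rdname inflection_bundle
#' @param b An [inflection_bundle()] (or its named vector); returns the
#'   canonical string key used to address affix slots in a [lexicon()].
#' @export
bundle_key <- function(b) {
  if (inherits(b, "inflection_bundle")) b <- b$pairs
  if (!length(b)) return("")
  paste(names(b), b, sep = ":", collapse = ";")
}

#' @rdname inflection_bundle
#' @param stem_id Nonempty stem symbol (the lexeme's identity).
#' @param inflection An [inflection_bundle()].
#' @export
meaning <- function(stem_id, inflection = inflection_bundle()) {
  stopifnot(is.character(stem_id), length(stem_id) == 1L, nzchar(stem_id))
  structure(list(stem_id = stem_id, inflection = inflection),
            class = "phon_meaning")
}

#' Construct a lexicon
#'
#' The lexicon maps stems to their underlying forms and inflection bundles to
#' prefix/suffix forms. Affix entries missing for a queried bundle default to
#' the empty string, as textbook paradigms habitually leave base forms
#' unaffixed.
#'
#' @param stems Named list: stem_id -> phoneme vector (or string).
#' @param prefixes,suffixes Named lists keyed by [bundle_key()] of the
#'   inflection (use [inflection_bundle()] names via `affix_key()`), value a
#'   phoneme vector or string. The empty string key "" addresses the empty
#'   bundle.
#' @param fs Optional feature system used to tokenize string-valued entries.
#' @return An object of class `phon_lexicon`.
#' @export
lexicon <- function(stems = list(), prefixes = list(), suffixes = list(),
                    fs = NULL) {
  tok <- function(x) {
    lapply(x, function(f) {
      if (is.null(fs)) {
        if (length(f) == 1L && nchar(f) > 1L) strsplit(f, "")[[1]]
        else as.character(f)
      } else tokenize_form(f, fs)
    })
  }
  structure(list(stems = tok(stems), prefixes = tok(prefixes),
                 suffixes = tok(suffixes)),
            class = "phon_lexicon")
}

lexicon_affix <- function(L, bundle, category = c("pfx", "sfx")) {
  category <- match.arg(category)
  key <- bundle_key(bundle)
  slot <- if (category == "pfx") L$prefixes else L$suffixes
  if (key %in% names(slot)) slot[[key]] else character()
}

#' Construct an ordered rule theory
#'
#' @param ... Rules ([rule()] objects) in application order (first listed
#'   applies first), or a single list of rules.
#' @return An object of class `phon_theory`.
#' @export
theory <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && !inherits(rules[[1]], "phon_rule")) {
    rules <- rules[[1]]
  }
  stopifnot(all(vapply(rules, inherits, TRUE, what = "phon_rule")))
  structure(list(rules = rules), class = "phon_theory")
}

#' @export
print.phon_theory <- function(x, ...) {
  if (!length(x$rules)) cat("<theory> (no rules)\n")
  else {
    cat("<theory>\n")
    for (k in seq_along(x$rules)) {
      cat(sprintf("  r%d: %s\n", k, format_rule(x$rules[[k]])))
    }
  }
  invisible(x)
}

#' Paradigm-matrix problem data
#'
#' Observed form/meaning pairs arranged as a paradigm matrix: rows are stems
#' (lexemes), columns are inflections, cells are surface forms. Cell order in
#' the source is preserved, which the counterexample schedule relies on.
#'
#' @param cells A data frame (or tibble) with columns `stem_id`, `inflection`
#'   and `form` (surface IPA string), one row per observed cell, in data
#'   order. Missing cells are simply absent rows and impose no constraint.
#' @param bundles Optional named list mapping inflection names to
#'   [inflection_bundle()]s; defaults to a singleton bundle
#'   `infl = <inflection name>` per column.
#' @param feature_system Name of the feature system the forms are written in
#'   (metadata; forms are validated lazily against whatever system is used).
#' @return An object of class `problem_data` (also a tibble).
#' @export
problem_data <- function(cells, bundles = NULL, feature_system = NULL) {
  cells <- tibble::as_tibble(cells)
  req <- c("stem_id", "inflection", "form")
  if (!all(req %in% names(cells))) {
    stop("`cells` needs columns stem_id, inflection, form")
  }
  if (!nrow(cells)) stop("problem data needs at least one cell")
  if (anyDuplicated(cells[c("stem_id", "inflection")])) {
    stop("duplicate paradigm cell (same stem and inflection twice)")
  }
  infls <- unique(cells$inflection)
  if (is.null(bundles)) {
    bundles <- setNames(lapply(infls, function(nm) {
      inflection_bundle(infl = nm)
    }), infls)
  }
  missing <- setdiff(infls, names(bundles))
  if (length(missing)) {
    stop("no bundle declared for inflection(s): ",
         paste(missing, collapse = ", "))
  }
  structure(cells, bundles = bundles, feature_system = feature_system,
            class = c("problem_data", class(cells)))
}

problem_bundle <- function(X, inflection) {
  attr(X, "bundles")[[inflection]]
}

problem_lexemes <- function(X) unique(X$stem_id)

#' Concatenative morphology
#'
#' Builds the underlying form of a meaning: prefix, then stem, then suffix,
#' with affixes looked up by the meaning's inflection bundle (missing entries
#' default to the empty string).
#'
#' @param L A [lexicon()].
#' @param m A [meaning()].
#' @return Character vector of phonemes (the underlying form).
#' @export
concatenate_morphology <- function(L, m) {
  if (!m$stem_id %in% names(L$stems)) {
    stop("stem absent from lexicon: ", m$stem_id)
  }
  c(lexicon_affix(L, m$inflection, "pfx"),
    L$stems[[m$stem_id]],
    lexicon_affix(L, m$inflection, "sfx"))
}

#' Derive the surface form of a meaning
#'
#' Morphology first (concatenate prefix, stem, suffix), then phonology (the
#' theory's ordered rules, one pass each).
#'
#' @param T_ A [theory()].
#' @param L A [lexicon()].
#' @param m A [meaning()].
#' @param fs Feature system.
#' @param trace Also return the full derivation (underlying form and the
#'   intermediate form after each rule).
#' @return Surface form (character vector), or with `trace = TRUE` an object
#'   of class `derivation`.
#' @export
derive <- function(T_, L, m, fs, trace = FALSE) {
  u <- concatenate_morphology(L, m)
  res <- apply_rule_sequence(T_$rules, u, fs, trace = trace)
  if (!trace) return(res)
  structure(c(list(meaning = m), res), class = "derivation")
}

#' @export
print.derivation <- function(x, ...) {
  cat(sprintf("underlying: /%s/\n", form_string(x$underlying)))
  for (k in seq_along(x$intermediates)) {
    cat(sprintf("  after r%d: /%s/\n", k, form_string(x$intermediates[[k]])))
  }
  cat(sprintf("surface:    /%s/\n", form_string(x$surface)))
  invisible(x)
}

#' Check the hard consistency constraint
#'
#' A grammar is consistent with the data iff it reproduces every observed
#' cell exactly. Inconsistency is a return value, not an error.
#'
#' @param T_ A [theory()].
#' @param L A [lexicon()].
#' @param X A [problem_data()].
#' @param fs Feature system.
#' @return List with `consistent` (logical) and `failures`, a list of the
#'   failing [meaning()]s in data order.
#' @export
check_consistency <- function(T_, L, X, fs) {
  for (r in T_$rules) validate_rule(r, fs)
  crs <- lapply(T_$rules, compile_rule, fs = fs)
  failures <- list()
  for (i in seq_len(nrow(X))) {
    m <- meaning(X$stem_id[i], problem_bundle(X, X$inflection[i]))
    u <- tryCatch(concatenate_morphology(L, m), error = function(e) NULL)
    if (is.null(u)) { # stem not yet in the lexicon: cell unexplained
      failures[[length(failures) + 1L]] <- m
      next
    }
    ph <- u
    for (cr in crs) ph <- apply_compiled(cr, ph)
    if (!identical(form_string(ph),
                   form_string(tokenize_form(X$form[i], fs)))) {
      failures[[length(failures) + 1L]] <- m
    }
  }
  list(consistent = !length(failures), failures = failures)
}
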