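#' Load a binary feature system
#'
#' A feature system grounds natural classes: it assigns every phoneme in the
#' inventory a vector of signed binary features (e.g. /m/ and /n/ are
#' `+nasal`). Two tables are bundled: `"articulatory"` (the full textbook-style
#' feature set) and `"simple"` (a reduced acoustic set whose features are a
#' strict subset of the articulatory ones), supporting ablation experiments on
#' the representation. Mode `"none"` strips all features and treats phonemes
#' as unanalysable atoms; feature matrices then reduce to singleton phoneme
#' literals.
#'
#' @param spec `"articulatory"`, `"simple"`, a path to a tab-separated feature
#'   table (first column `symbol`, one column per feature, entries `+`, `-`,
#'   or `0` for unspecified), or a data frame of the same shape.
#' @param mode Representation mode: `"features"` (default, use the table as
#'   given) or `"none"` (atoms only).
#' @param restrict Optional character vector of symbols: keep only these
#'   phonemes (used to build small problem-specific inventories).
#' @return An object of class `feature_system`.
#' @examples
#' fs <- load_feature_system("articulatory")
#' matches("m", feature_matrix("+nasal"), fs)
#' @export
load_feature_system <- function(spec = "articulatory",
                                mode = c("features", "none"),
                                restrict = NULL) {
  mode <- match.arg(mode)
  name <- "custom"
  if (is.character(spec) && length(spec) == 1L) {
    if (spec %in% c("articulatory", "simple")) {
      name <- spec
      path <- system.file("extdata", paste0("features_", spec, ".tsv"),
                          package = "phonosynth")
      tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
    } else {
      name <- basename(spec)
      tab <- read.delim(spec, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
    }
  } else if (is.data.frame(spec)) {
    tab <- as.data.frame(spec, stringsAsFactors = FALSE)
  } else {
    stop("`spec` must be a bundled table name, a file path, or a data frame")
  }
  if (!identical(names(tab)[1], "symbol")) {
    stop("malformed feature table: first column must be `symbol`")
  }
  syms <- as.character(tab$symbol)
  if (anyDuplicated(syms)) {
    stop("duplicate phoneme symbol in feature table: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  }
  feats <- names(tab)[-1]
  bad <- vapply(tab[-1], function(col) any(!col %in% c("+", "-", "0")), TRUE)
  if (any(bad)) {
    stop("malformed feature table: values must be +, - or 0 (column ",
         paste(feats[bad], collapse = ", "), ")")
  }
  if (!is.null(restrict)) {
    missing <- setdiff(restrict, syms)
    if (length(missing)) {
      stop("unknown phoneme symbol(s): ", paste(missing, collapse = ", "))
    }
    keep <- syms %in% restrict
    tab <- tab[keep, , drop = FALSE]
    syms <- syms[keep]
  }
  if (mode == "none") {
    plus <- setNames(replicate(length(syms), character()), syms)
    minus <- plus
    feats <- character()
  } else {
    plus <- setNames(lapply(seq_along(syms), function(i) {
      feats[vapply(feats, function(f) tab[[f]][i] == "+", TRUE)]
    }), syms)
    minus <- setNames(lapply(seq_along(syms), function(i) {
      feats[vapply(feats, function(f) tab[[f]][i] == "-", TRUE)]
    }), syms)
  }
  if (length(feats) > 60L) stop("at most 60 features are supported")
  fs <- structure(
    list(name = name, mode = mode, symbols = syms,
         feature_names = feats, plus = plus, minus = minus),
    class = "feature_system")
  fs
}

#' @export
print.feature_system <- function(x, ...) {
  cat(sprintf("<feature_system '%s'> %d phonemes, %d features (%s mode)\n",
              x$name, length(x$symbols), length(x$feature_names),
              if (x$mode == "none") "atomic" else "feature"))
  invisible(x)
}

#' Construct a feature matrix (conjunction of signed feature literals)
#'
#' A feature matrix denotes a natural class: the set of phonemes carrying all
#' of its literals. The empty matrix is the universal class. In an atomic
#' ("none" mode) system, a matrix may instead hold a single literal phoneme,
#' written as the bare symbol.
#'
#' @param ... Signed literals as strings (`"+nasal"`, `"-voice"`), possibly a
#'   single character vector. A bare symbol (no sign) denotes a literal
#'   phoneme, permitted in atomic mode.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(...) {
  lits <- unlist(list(...), use.names = FALSE)
  if (is.null(lits)) lits <- character()
  stopifnot(is.character(lits))
  signed <- grepl("^[+-]", lits)
  if (any(signed) && any(!signed)) {
    stop("cannot mix signed feature literals and literal phonemes")
  }
  if (any(!signed) && length(lits) > 1L) {
    stop("a literal-phoneme matrix holds exactly one phoneme")
  }
  if (all(signed) && length(lits)) {
    f <- sub("^[+-]", "", lits)
    if (anyDuplicated(f)) {
      stop("feature appears with both signs or twice: ",
           paste(unique(f[duplicated(f)]), collapse = ", "))
    }
    lits <- lits[order(f)]
  }
  structure(list(literals = lits, phoneme = if (any(!signed)) lits else NULL),
            class = "feature_matrix")
}

fm_is_phoneme_literal <- function(fm) !is.null(fm$phoneme)

#' @export
format.feature_matrix <- function(x, ...) {
  if (fm_is_phoneme_literal(x)) return(x$phoneme)
  if (!length(x$literals)) return("[ ]")
  paste0("[", paste(x$literals, collapse = " "), "]")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

check_fm_known <- function(fm, fs) {
  if (fm_is_phoneme_literal(fm)) {
    if (!fm$phoneme %in% fs$symbols) {
      stop("unknown phoneme in matrix: ", fm$phoneme)
    }
    return(invisible(TRUE))
  }
  f <- sub("^[+-]", "", fm$literals)
  unknown <- setdiff(f, fs$feature_names)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Does a phoneme match a feature matrix?
#'
#' True iff every literal of the matrix is among the phoneme's signed
#' features. The empty matrix matches every phoneme.
#'
#' @param p A phoneme symbol present in `fs`.
#' @param fm A [feature_matrix()].
#' @param fs A [load_feature_system()] object.
#' @return Logical.
#' @export
matches <- function(p, fm, fs) {
  if (!p %in% fs$symbols) stop("unknown phoneme: ", p)
  check_fm_known(fm, fs)
  if (fm_is_phoneme_literal(fm)) return(identical(p, fm$phoneme))
  if (!length(fm$literals)) return(TRUE)
  sign <- substr(fm$literals, 1, 1)
  feat <- sub("^[+-]", "", fm$literals)
  all(ifelse(sign == "+", feat %in% fs$plus[[p]], feat %in% fs$minus[[p]]))
}

#' Natural class of a feature matrix
#'
#' @inheritParams matches
#' @return Character vector of the phoneme symbols matching `fm`, in inventory
#'   order.
#' @export
natural_class <- function(fm, fs) {
  fs$symbols[vapply(fs$symbols, matches, TRUE, fm = fm, fs = fs)]
}

#' Apply a structural feature change to a phoneme
#'
#' Overwrites the phoneme's signed features with the literals of `change` and
#' looks up the phoneme realizing the resulting vector (e.g. /d/ plus
#' `[-voice]` yields /t/ under the articulatory table). If no inventory
#' phoneme, or more than one, realizes the overwritten vector, the change hits
#' an inventory gap: an error by default, `NA` with `strict = FALSE` (rule
#' application treats such sites as inapplicable).
#'
#' @inheritParams matches
#' @param change A [feature_matrix()] of literals to impose.
#' @param strict Error on gaps (default) or return `NA_character_`.
#' @return A phoneme symbol.
#' @export
apply_feature_change <- function(p, change, fs, strict = TRUE) {
  if (!p %in% fs$symbols) stop("unknown phoneme: ", p)
  check_fm_known(change, fs)
  if (fm_is_phoneme_literal(change)) return(change$phoneme)
  if (!length(change$literals)) return(p)
  sign <- substr(change$literals, 1, 1)
  feat <- sub("^[+-]", "", change$literals)
  plus <- union(setdiff(fs$plus[[p]], feat), feat[sign == "+"])
  minus <- union(setdiff(fs$minus[[p]], feat), feat[sign == "-"])
  hit <- fs$symbols[vapply(fs$symbols, function(q) {
    setequal(fs$plus[[q]], plus) && setequal(fs$minus[[q]], minus)
  }, TRUE)]
  if (length(hit) != 1L) {
    if (strict) {
      stop("no unique inventory phoneme realizes ", p, " + ",
           format(change), " (inventory gap)")
    }
    return(NA_character_)
  }
  hit
}

#' Tokenize an IPA string into inventory phonemes
#'
#' Greedy longest-match against the inventory's symbols. Character vectors of
#' length > 1 are assumed to be already tokenized and are validated only.
#'
#' @param form A single string, or a character vector of phoneme symbols.
#' @param fs A feature system.
#' @return Character vector of phoneme symbols (possibly empty).
#' @export
tokenize_form <- function(form, fs) {
  if (length(form) == 0L) return(character())
  if (length(form) > 1L || all(form %in% fs$symbols) && nzchar(form[1])) {
    unknown <- setdiff(form, fs$symbols)
    if (length(unknown)) {
      stop("unknown phoneme glyph(s): ", paste(unknown, collapse = ", "))
    }
    return(as.character(form))
  }
  s <- form
  if (!nzchar(s)) return(character())
  syms <- fs$symbols[order(-nchar(fs$symbols))]
  out <- character()
  while (nzchar(s)) {
    hit <- NULL
    for (sym in syms) {
      if (startsWith(s, sym)) { hit <- sym; break }
    }
    if (is.null(hit)) {
      stop("unknown phoneme glyph: ", substr(s, 1, 1))
    }
    out <- c(out, hit)
    s <- substr(s, nchar(hit) + 1L, nchar(s))
  }
  out
}

is_vowel <- function(p, fs) {
  if (!"vowel" %in% fs$feature_names) {
    stop("feature system has no `vowel` feature; cannot classify ", p)
  }
  if ("vowel" %in% fs$plus[[p]]) return(TRUE)
  if ("vowel" %in% fs$minus[[p]]) return(FALSE)
  stop("phoneme ", p, " is unspecified for `vowel`")
}

#' Syllabify a form (onset-maximizing CV parse)
#'
#' Each vowel heads one syllable; every consonant run between two nuclei is
#' assigned to the onset of the following syllable (maximal onset), and
#' word-final consonants close the last syllable. Deterministic;
#' concatenating the syllables reproduces the input.
#'
#' @inheritParams tokenize_form
#' @return An object of class `syllabified_form`: list with `syllables` (list
#'   of phoneme vectors) and `flat` (their concatenation).
#' @export
syllabify <- function(form, fs) {
  ph <- tokenize_form(form, fs)
  if (!length(ph)) {
    return(structure(list(syllables = list(), flat = character()),
                     class = "syllabified_form"))
  }
  v <- vapply(ph, is_vowel, TRUE, fs = fs)
  if (!any(v)) stop("unsyllabifiable form (no vowel): ", paste(ph, collapse = ""))
  nuclei <- which(v)
  starts <- c(1L, nuclei[-length(nuclei)] + 1L)
  ends <- c(nuclei[-length(nuclei)], length(ph))
  sylls <- lapply(seq_along(nuclei), function(i) ph[starts[i]:ends[i]])
  structure(list(syllables = sylls, flat = ph), class = "syllabified_form")
}

#' @export
format.syllabified_form <- function(x, ...) {
  paste(vapply(x$syllables, function(s) paste0("[", paste(s, collapse = ""), "]"),
               ""), collapse = "")
}

#' @export
print.syllabified_form <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Integer encoding of a feature system for the search kernel: 1-based phoneme
# ids plus logical phoneme-by-feature sign matrices.
fs_encode <- function(fs) {
  n <- length(fs$symbols)
  k <- length(fs$feature_names)
  plus <- matrix(FALSE, n, k, dimnames = list(fs$symbols, fs$feature_names))
  minus <- plus
  for (i in seq_len(n)) {
    plus[i, fs$plus[[i]]] <- TRUE
    minus[i, fs$minus[[i]]] <- TRUE
  }
  list(symbols = fs$symbols, plus = plus, minus = minus)
}

fm_encode <- function(fm, fs) {
  # c(pmask-ish) as feature index vectors: list(plus = int idx, minus = int idx)
  if (fm_is_phoneme_literal(fm)) {
    stop("phoneme-literal matrices are only valid in atomic mode paths")
  }
  sign <- substr(fm$literals, 1, 1)
  feat <- sub("^[+-]", "", fm$literals)
  list(plus = match(feat[sign == "+"], fs$feature_names),
       minus = match(feat[sign == "-"], fs$feature_names))
}
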