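#' Construct a trigger (rule environment)
#'
#' A trigger is a sequence of at most two feature matrices, each optionally
#' Kleene-starred (matching zero or more repetitions), with an optional word
#' boundary `#` at the outer end. Elements are given in surface order: for a
#' left trigger the last element is adjacent to the focus, for a right trigger
#' the first element is.
#'
#' @param ... Feature matrices ([feature_matrix()]), in surface order. A
#'   matrix may be wrapped in [starred()] to mark Kleene-star repetition.
#' @param boundary Require the word edge at the outer end of the trigger.
#' @return An object of class `trigger`.
#' @export
trigger <- function(..., boundary = FALSE) {
  elems <- lapply(list(...), function(e) {
    if (inherits(e, "trigger_elem")) e
    else if (inherits(e, "feature_matrix")) structure(list(fm = e, star = FALSE),
                                                      class = "trigger_elem")
    else stop("trigger elements must be feature matrices")
  })
  if (length(elems) > 2L) stop("triggers hold at most two elements")
  if (sum(vapply(elems, function(e) e$star, TRUE)) > 1L) {
    stop("at most one starred element per trigger")
  }
  structure(list(elements = elems, boundary = isTRUE(boundary)),
            class = "trigger")
}

#' @rdname trigger
#' @param fm A feature matrix to mark as Kleene-starred.
#' @export
starred <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  structure(list(fm = fm, star = TRUE), class = "trigger_elem")
}

trigger_is_empty <- function(tr) !length(tr$elements) && !tr$boundary

#' Structural changes
#'
#' Constructors for the four kinds of structural change an SPE rule can
#' perform: overwrite the focus's features, delete the focus, insert a
#' phoneme sequence at the focus site, or copy a peripheral syllable (or a
#' fixed number of peripheral phonemes) to a word edge. Copy changes are the
#' reduplicative device used in artificial-grammar-learning mode only.
#'
#' @param fm Feature matrix of literals to impose on the focus. May carry an
#'   alpha variable via `alpha`.
#' @param alpha Optional feature name whose sign is copied from the adjacent
#'   trigger phoneme on `alpha_side` into the overwrite.
#' @param alpha_side `"left"` or `"right"`: which trigger supplies the alpha
#'   sign (its focus-adjacent, non-starred element).
#' @return An object of class `structural_change`.
#' @export
change_features <- function(fm, alpha = NULL, alpha_side = "left") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(alpha)) {
    stopifnot(is.character(alpha), length(alpha) == 1L,
              alpha_side %in% c("left", "right"))
  }
  structure(list(kind = "feature", fm = fm, alpha = alpha,
                 alpha_side = if (!is.null(alpha)) alpha_side),
            class = "structural_change")
}

#' @rdname change_features
#' @export
change_delete <- function() {
  structure(list(kind = "delete"), class = "structural_change")
}

#' @rdname change_features
#' @param phonemes Character vector of phoneme symbols to insert.
#' @export
change_insert <- function(phonemes) {
  stopifnot(is.character(phonemes), length(phonemes) >= 1L)
  structure(list(kind = "insert", phonemes = phonemes),
            class = "structural_change")
}

#' @rdname change_features
#' @param source `"first"` or `"last"`: which peripheral unit to copy.
#' @param target `"begin"` or `"end"`: where the copy is placed.
#' @param unit `"syllable"` (requires a syllabifiable form; the whole
#'   peripheral syllable is copied) or `"phoneme"` (the single phoneme at
#'   offset `n_phonemes` from the chosen edge is copied to that edge).
#' @param n_phonemes Edge offset of the copied phoneme when
#'   `unit = "phoneme"`.
#' @export
change_copy <- function(source = c("first", "last"),
                        target = c("begin", "end"),
                        unit = c("syllable", "phoneme"),
                        n_phonemes = 1L) {
  structure(list(kind = "copy", source = match.arg(source),
                 target = match.arg(target), unit = match.arg(unit),
                 n_phonemes = as.integer(n_phonemes)),
            class = "structural_change")
}

#' Construct an SPE rewrite rule
#'
#' A rule `focus -> change / left _ right` rewrites, in a single simultaneous
#' pass, every site of the input where the focus matches and the triggering
#' environments occur immediately to its left and right. Rules never apply to
#' their own output within one invocation.
#'
#' @param focus A [feature_matrix()], or `NULL` for an insertion site.
#' @param change A [change_features()], [change_delete()], [change_insert()]
#'   or [change_copy()] object.
#' @param left,right [trigger()] environments (default: empty).
#' @return An object of class `phon_rule`.
#' @examples
#' fs <- load_feature_system("articulatory")
#' r <- rule(feature_matrix("-sonorant"), change_features(feature_matrix("-voice")),
#'           left = trigger(feature_matrix("-sonorant", "-voice")),
#'           right = trigger(boundary = TRUE))
#' format_rule(r)
#' @export
rule <- function(focus = NULL, change, left = trigger(), right = trigger()) {
  stopifnot(inherits(change, "structural_change"),
            inherits(left, "trigger"), inherits(right, "trigger"))
  if (!is.null(focus)) stopifnot(inherits(focus, "feature_matrix"))
  if (change$kind == "insert" && !is.null(focus)) {
    stop("insertion changes require an empty focus")
  }
  if (change$kind == "delete" && is.null(focus)) {
    stop("deletion requires a non-empty focus")
  }
  if (change$kind == "copy" && (!is.null(focus) ||
                                !trigger_is_empty(left) || !trigger_is_empty(right))) {
    stop("copy changes take no focus or triggers")
  }
  if (change$kind == "feature" && !is.null(change$alpha)) {
    tr <- if (change$alpha_side == "left") left else right
    adj <- if (change$alpha_side == "left") length(tr$elements) else 1L
    if (!length(tr$elements) || tr$elements[[adj]]$star) {
      stop("alpha variable requires a non-starred focus-adjacent element on ",
           "the ", change$alpha_side, " trigger")
    }
  }
  structure(list(focus = focus, change = change, left = left, right = right),
            class = "phon_rule")
}

#' @export
print.phon_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Canonical printer

fm_notation <- function(fm) {
  if (fm_is_phoneme_literal(fm)) return(fm$phoneme)
  if (identical(fm$literals, "-vowel")) return("C")
  if (identical(fm$literals, "+vowel")) return("V")
  format(fm)
}

trigger_notation <- function(tr, side, alpha = NULL) {
  parts <- vapply(seq_along(tr$elements), function(i) {
    e <- tr$elements[[i]]
    adjacent <- if (side == "left") i == length(tr$elements) else i == 1L
    base <- if (!is.null(alpha) && adjacent) {
      paste0("[", trimws(paste(c(e$fm$literals, paste0("α", alpha)),
                               collapse = " ")), "]")
    } else fm_notation(e$fm)
    paste0(base, if (e$star) "*")
  }, "")
  if (tr$boundary) {
    parts <- if (side == "left") c("#", parts) else c(parts, "#")
  }
  paste(parts, collapse = " ")
}

change_notation <- function(ch) {
  switch(ch$kind,
    feature = {
      if (is.null(ch$alpha)) {
        fm_notation(ch$fm)
      } else {
        inner <- paste(c(ch$fm$literals, paste0("α", ch$alpha)), collapse = " ")
        paste0("[", trimws(inner), "]")
      }
    },
    delete = "∅",
    insert = paste(ch$phonemes, collapse = ""),
    copy = if (ch$unit == "syllable") {
      sprintf("copy(%s,%s)", ch$source, ch$target)
    } else {
      sprintf("copyph(%d,%s,%s)", ch$n_phonemes, ch$source, ch$target)
    })
}

#' Format a rule in SPE notation
#'
#' Emits the canonical dialect: `FOCUS -> CHANGE / LEFT _ RIGHT` with single
#' spaces, `∅` for the empty focus/deletion, `#` for the word boundary,
#' alphabetically sorted feature literals, `C`/`V` shorthands for
#' `[-vowel]`/`[+vowel]`, and a trailing `*` for Kleene star. The environment
#' slash is omitted when both triggers are empty.
#'
#' @param r A [rule()].
#' @return A single string; `parse_rule(format_rule(r))` reproduces `r`.
#' @export
format_rule <- function(r) {
  stopifnot(inherits(r, "phon_rule"))
  focus <- if (is.null(r$focus)) "∅" else fm_notation(r$focus)
  ch <- r$change
  change <- change_notation(ch)
  alpha <- if (ch$kind == "feature") ch$alpha
  left <- trigger_notation(r$left, "left",
                           if (identical(ch$alpha_side, "left")) alpha)
  right <- trigger_notation(r$right, "right",
                            if (identical(ch$alpha_side, "right")) alpha)
  if (!nzchar(left) && !nzchar(right)) {
    sprintf("%s -> %s", focus, change)
  } else {
    env <- trimws(sprintf("%s _ %s", left, right))
    sprintf("%s -> %s / %s", focus, change, env)
  }
}

# ---------------------------------------------------------------------------
# Parser

scan_rule_tokens <- function(text) {
  s <- text
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type,
                                                                   value = value)
  while (nzchar(s <- sub("^\\s+", "", s))) {
    if (grepl("^(->|→)", s)) {
      push("arrow", "->"); s <- sub("^(->|→)", "", s)
    } else if (startsWith(s, "/")) {
      push("slash", "/"); s <- substr(s, 2, nchar(s))
    } else if (startsWith(s, "_")) {
      push("gap", "_"); s <- substr(s, 2, nchar(s))
    } else if (startsWith(s, "#")) {
      push("boundary", "#"); s <- substr(s, 2, nchar(s))
    } else if (startsWith(s, "[")) {
      close <- regexpr("\\]", s)
      if (close < 0) stop("syntax error in rule at: ", s, " (unclosed matrix)")
      body <- substr(s, 2, close - 1L)
      s <- substr(s, close + 1L, nchar(s))
      star <- FALSE
      if (startsWith(s, "*")) { star <- TRUE; s <- substr(s, 2, nchar(s)) }
      push("matrix", list(body = body, star = star))
    } else if (grepl("^copy(ph)?\\(", s)) {
      close <- regexpr("\\)", s)
      if (close < 0) stop("syntax error in rule at: ", s)
      push("copy", substr(s, 1, close))
      s <- substr(s, close + 1L, nchar(s))
    } else {
      m <- regexpr("^[^][\\s/_#*]+", s, perl = TRUE)
      word <- regmatches(s, m)
      s <- substr(s, attr(m, "match.length") + 1L, nchar(s))
      star <- FALSE
      if (startsWith(s, "*")) { star <- TRUE; s <- substr(s, 2, nchar(s)) }
      push("word", list(body = word, star = star))
    }
  }
  toks
}

parse_matrix_body <- function(body) {
  lits <- strsplit(trimws(body), "\\s+")[[1]]
  lits <- lits[nzchar(lits)]
  alpha <- grepl("^α", lits)
  fm <- feature_matrix(lits[!alpha])
  list(fm = fm, alpha = if (any(alpha)) sub("^α", "", lits[alpha][1]))
}

token_to_elem <- function(tok) {
  if (tok$type == "matrix") {
    pm <- parse_matrix_body(tok$value$body)
    structure(list(fm = pm$fm, star = tok$value$star, alpha = pm$alpha),
              class = "trigger_elem")
  } else if (tok$type == "word") {
    w <- tok$value$body
    fm <- if (identical(w, "C")) feature_matrix("-vowel")
    else if (identical(w, "V")) feature_matrix("+vowel")
    else feature_matrix(w)
    structure(list(fm = fm, star = tok$value$star, alpha = NULL),
              class = "trigger_elem")
  } else stop("unexpected token in trigger")
}

parse_trigger_tokens <- function(toks, side) {
  boundary <- FALSE
  if (length(toks)) {
    if (side == "left" && toks[[1]]$type == "boundary") {
      boundary <- TRUE; toks <- toks[-1]
    } else if (side == "right" && toks[[length(toks)]]$type == "boundary") {
      boundary <- TRUE; toks <- toks[-length(toks)]
    }
  }
  if (any(vapply(toks, function(t) t$type == "boundary", TRUE))) {
    stop("word boundary only allowed at the outer end of a trigger")
  }
  elems <- lapply(toks, token_to_elem)
  tr <- do.call(trigger, c(lapply(elems, function(e) {
    structure(list(fm = e$fm, star = e$star), class = "trigger_elem")
  }), list(boundary = boundary)))
  alpha <- unlist(lapply(elems, function(e) e$alpha))
  list(trigger = tr, alpha = if (length(alpha)) alpha[1])
}

#' Parse SPE rule notation
#'
#' Accepts the dialect `FOCUS -> CHANGE / LEFT _ RIGHT` (arrow `->` or `→`,
#' `∅`/`0` for empty focus or deletion, `#` word boundary, `[+f -g]` feature
#' matrices with optional trailing `*`, `C`/`V` shorthands, bare symbols for
#' literal phonemes/insertions, `αfeat` for a shared alpha variable, and
#' `copy(first,end)` / `copyph(2,last,begin)` reduplicative changes).
#'
#' @param text A single string of rule notation.
#' @param fs Optional feature system; when given, feature names and phoneme
#'   symbols are validated against it.
#' @return A [rule()].
#' @export
parse_rule <- function(text, fs = NULL) {
  toks <- scan_rule_tokens(text)
  arrow <- which(vapply(toks, function(t) t$type == "arrow", TRUE))
  if (length(arrow) != 1L) stop("syntax error: expected exactly one arrow in: ",
                                text)
  slash <- which(vapply(toks, function(t) t$type == "slash", TRUE))
  if (length(slash) > 1L) stop("syntax error: more than one / in: ", text)

  focus_toks <- toks[seq_len(arrow - 1L)]
  change_end <- if (length(slash)) slash - 1L else length(toks)
  change_toks <- toks[seq(arrow + 1L, change_end)]
  env_toks <- if (length(slash) && slash < length(toks)) {
    toks[seq(slash + 1L, length(toks))]
  } else list()

  if (length(focus_toks) != 1L) stop("syntax error in focus of: ", text)
  ft <- focus_toks[[1]]
  focus_alpha <- NULL
  focus <- if (ft$type == "word" && ft$value$body %in% c("∅", "0")) {
    NULL
  } else if (ft$type == "matrix") {
    pm <- parse_matrix_body(ft$value$body)
    pm$fm
  } else if (ft$type == "word") {
    token_to_elem(ft)$fm
  } else stop("syntax error in focus of: ", text)

  if (length(change_toks) != 1L) stop("syntax error in change of: ", text)
  ct <- change_toks[[1]]
  gap <- which(vapply(env_toks, function(t) t$type == "gap", TRUE))
  if (length(env_toks) && length(gap) != 1L) {
    stop("syntax error: environment needs exactly one _ in: ", text)
  }
  lt <- if (length(env_toks)) parse_trigger_tokens(env_toks[seq_len(gap - 1L)],
                                                   "left")
  else list(trigger = trigger(), alpha = NULL)
  rt <- if (length(env_toks) && gap < length(env_toks)) {
    parse_trigger_tokens(env_toks[seq(gap + 1L, length(env_toks))], "right")
  } else list(trigger = trigger(), alpha = NULL)

  change <- if (ct$type == "copy") {
    spec <- sub("\\)$", "", ct$value)
    if (startsWith(spec, "copyph(")) {
      args <- strsplit(sub("^copyph\\(", "", spec), ",")[[1]]
      change_copy(trimws(args[2]), trimws(args[3]), "phoneme",
                  as.integer(args[1]))
    } else {
      args <- strsplit(sub("^copy\\(", "", spec), ",")[[1]]
      change_copy(trimws(args[1]), trimws(args[2]), "syllable")
    }
  } else if (ct$type == "word" && ct$value$body %in% c("∅", "0")) {
    change_delete()
  } else if (ct$type == "matrix") {
    pm <- parse_matrix_body(ct$value$body)
    if (!is.null(pm$alpha)) {
      side <- if (!is.null(lt$alpha)) "left" else "right"
      if (is.null(lt$alpha) && is.null(rt$alpha)) {
        stop("alpha variable in change has no trigger occurrence in: ", text)
      }
      change_features(pm$fm, alpha = pm$alpha, alpha_side = side)
    } else change_features(pm$fm)
  } else if (ct$type == "word") {
    w <- ct$value$body
    if (w %in% c("C", "V")) change_features(token_to_elem(ct)$fm)
    else if (is.null(focus)) {
      change_insert(if (!is.null(fs)) tokenize_form(w, fs)
                    else strsplit(w, "")[[1]])
    } else change_features(feature_matrix(w))
  } else stop("syntax error in change of: ", text)

  r <- rule(focus, change, lt$trigger, rt$trigger)
  if (!is.null(fs)) validate_rule(r, fs)
  r
}

#' Validate a rule against a feature system
#'
#' Checks every feature matrix in the rule for unknown feature names or
#' phoneme symbols, and rejects representational devices the system's mode
#' forbids (feature matrices in atomic mode).
#'
#' @param r A [rule()].
#' @param fs A [load_feature_system()] object.
#' @return `r`, invisibly; errors otherwise.
#' @export
validate_rule <- function(r, fs) {
  fms <- c(list(r$focus),
           if (r$change$kind == "feature") list(r$change$fm),
           lapply(r$left$elements, function(e) e$fm),
           lapply(r$right$elements, function(e) e$fm))
  for (fm in fms) if (!is.null(fm)) {
    if (fs$mode == "none" && !fm_is_phoneme_literal(fm) && length(fm$literals)) {
      stop("atomic-mode systems admit only literal-phoneme matrices")
    }
    check_fm_known(fm, fs)
  }
  if (r$change$kind == "insert") {
    unknown <- setdiff(r$change$phonemes, fs$symbols)
    if (length(unknown)) stop("unknown phoneme(s) in insertion: ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(r$change$alpha) && !r$change$alpha %in% fs$feature_names) {
    stop("unknown alpha feature: ", r$change$alpha)
  }
  invisible(r)
}
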