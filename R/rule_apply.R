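# One-pass simultaneous application semantics for SPE rules. All matching is
# done against the pre-rule string, so a rule can never feed itself within a
# single invocation; insertion sites are enumerated left to right.
#
# Rules are "compiled" against a feature system before application: every
# feature matrix becomes a named logical membership vector over the inventory
# and every feature overwrite becomes a phoneme -> phoneme map (NA marks an
# inventory gap, which leaves the site unchanged).

nc_members <- function(fm, fs) {
  v <- vapply(fs$symbols, matches, TRUE, fm = fm, fs = fs)
  names(v) <- fs$symbols
  v
}

overwrite_map <- function(fm, fs) {
  v <- vapply(fs$symbols, apply_feature_change, "", change = fm, fs = fs,
              strict = FALSE)
  names(v) <- fs$symbols
  v
}

compile_trigger <- function(tr, fs) {
  list(members = lapply(tr$elements, function(e) nc_members(e$fm, fs)),
       star = vapply(tr$elements, function(e) e$star, TRUE),
       boundary = tr$boundary)
}

compile_rule <- function(r, fs) {
  ch <- r$change
  comp_change <- switch(ch$kind,
    feature = {
      if (is.null(ch$alpha)) {
        list(kind = "feature", map = overwrite_map(ch$fm, fs))
      } else {
        maps <- lapply(c("+", "-"), function(sgn) {
          fmx <- try(feature_matrix(c(ch$fm$literals,
                                      paste0(sgn, ch$alpha))), silent = TRUE)
          if (inherits(fmx, "try-error")) NULL else overwrite_map(fmx, fs)
        })
        list(kind = "feature", alpha = ch$alpha, alpha_side = ch$alpha_side,
             map_plus = maps[[1]], map_minus = maps[[2]])
      }
    },
    delete = list(kind = "delete"),
    insert = list(kind = "insert", phonemes = ch$phonemes),
    copy = c(list(kind = "copy"), ch[c("source", "target", "unit",
                                       "n_phonemes")]))
  list(focus = if (!is.null(r$focus)) nc_members(r$focus, fs),
       change = comp_change,
       left = compile_trigger(r$left, fs),
       right = compile_trigger(r$right, fs),
       fs = fs)
}

match_side_c <- function(ct, ph, from, dir) {
  order <- seq_along(ct$members)
  if (dir < 0) order <- rev(order)
  n <- length(ph)
  rec <- function(k, j) {
    if (k > length(order)) {
      if (ct$boundary) return(j < 1L || j > n)
      return(TRUE)
    }
    idx <- order[k]
    memb <- ct$members[[idx]]
    if (ct$star[idx]) {
      if (rec(k + 1L, j)) return(TRUE)
      j >= 1L && j <= n && memb[[ph[j]]] && rec(k, j + dir)
    } else {
      j >= 1L && j <= n && memb[[ph[j]]] && rec(k + 1L, j + dir)
    }
  }
  rec(1L, from)
}

apply_copy_change <- function(ch, ph, fs) {
  if (ch$unit == "syllable") {
    sf <- tryCatch(syllabify(ph, fs), error = function(e) NULL)
    if (is.null(sf) || !length(sf$syllables)) return(ph)
    seg <- if (ch$source == "first") sf$syllables[[1]]
    else sf$syllables[[length(sf$syllables)]]
  } else {
    # copy the single phoneme at offset n_phonemes from the chosen edge
    j <- ch$n_phonemes
    if (length(ph) < j) return(ph)
    seg <- if (ch$source == "first") ph[j] else ph[length(ph) - j + 1L]
  }
  if (ch$target == "begin") c(seg, ph) else c(ph, seg)
}

alpha_sign <- function(feature, p, fs) {
  if (feature %in% fs$plus[[p]]) return("+")
  if (feature %in% fs$minus[[p]]) return("-")
  NA_character_
}

apply_compiled <- function(cr, ph) {
  ch <- cr$change
  if (ch$kind == "copy") return(apply_copy_change(ch, ph, cr$fs))
  n <- length(ph)

  if (is.null(cr$focus)) {
    gaps <- Filter(function(g) {
      match_side_c(cr$left, ph, g, -1L) && match_side_c(cr$right, ph, g + 1L, +1L)
    }, 0:n)
    if (!length(gaps)) return(ph)
    out <- character()
    prev <- 0L
    for (g in gaps) {
      if (g >= prev + 1L) out <- c(out, ph[seq(prev + 1L, g)])
      out <- c(out, ch$phonemes)
      prev <- g
    }
    if (prev < n) out <- c(out, ph[seq(prev + 1L, n)])
    return(out)
  }

  sites <- Filter(function(i) {
    cr$focus[[ph[i]]] &&
      match_side_c(cr$left, ph, i - 1L, -1L) &&
      match_side_c(cr$right, ph, i + 1L, +1L)
  }, seq_len(n))
  if (!length(sites)) return(ph)

  if (ch$kind == "delete") return(ph[-sites])

  out <- ph
  for (i in sites) {
    if (is.null(ch$alpha)) {
      q <- ch$map[[ph[i]]]
    } else {
      j <- if (ch$alpha_side == "left") i - 1L else i + 1L
      if (j < 1L || j > n) next
      sgn <- alpha_sign(ch$alpha, ph[j], cr$fs)
      if (is.na(sgn)) next
      map <- if (sgn == "+") ch$map_plus else ch$map_minus
      if (is.null(map)) next
      q <- map[[ph[i]]]
    }
    if (!is.na(q)) out[i] <- q
  }
  out
}

#' Apply one rewrite rule to a form
#'
#' All sites where the focus and both triggering environments match the
#' pre-rule string are rewritten simultaneously in a single pass; word
#' boundaries are implicit at both edges. A feature overwrite that would land
#' in an inventory gap leaves that site unchanged.
#'
#' @param r A [rule()].
#' @param form A phoneme string or tokenized character vector.
#' @param fs A [load_feature_system()] object.
#' @param validate Check the rule against `fs` first (set to `FALSE` in inner
#'   loops that have already validated).
#' @return The rewritten form as a character vector of phoneme symbols.
#' @examples
#' fs <- load_feature_system("articulatory")
#' r <- parse_rule("[-sonorant] -> [-voice] / [-sonorant -voice] _ #", fs)
#' form_string(apply_rule(r, "wɔkd", fs))
#' @export
apply_rule <- function(r, form, fs, validate = TRUE) {
  stopifnot(inherits(r, "phon_rule"))
  if (validate) validate_rule(r, fs)
  apply_compiled(compile_rule(r, fs), tokenize_form(form, fs))
}

#' Apply an ordered sequence of rules
#'
#' Rules apply in pipeline order: the first rule listed applies first, one
#' simultaneous pass each, and later rules see the output of earlier ones.
#'
#' @param rules A list of [rule()] objects (possibly empty), or a [theory()].
#' @inheritParams apply_rule
#' @param trace Return intermediate forms as well.
#' @return The final form (character vector), or if `trace = TRUE` a list with
#'   `underlying`, `intermediates` (one per rule) and `surface`.
#' @export
apply_rule_sequence <- function(rules, form, fs, trace = FALSE,
                                validate = TRUE) {
  if (inherits(rules, "phon_theory")) rules <- rules$rules
  ph <- tokenize_form(form, fs)
  if (validate) for (r in rules) validate_rule(r, fs)
  crs <- lapply(rules, compile_rule, fs = fs)
  underlying <- ph
  inter <- vector("list", length(rules))
  for (k in seq_along(crs)) {
    ph <- apply_compiled(crs[[k]], ph)
    inter[[k]] <- ph
  }
  if (trace) list(underlying = underlying, intermediates = inter, surface = ph)
  else ph
}

#' Collapse a tokenized form to a string
#'
#' @param ph Character vector of phoneme symbols.
#' @return A single string.
#' @export
form_string <- function(ph) paste(ph, collapse = "")
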