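#' Tidy a synthesis result
#'
#' One row per grammar component (rule, affix, or stem) with its notation
#' and description-length cost.
#'
#' @param x A `synthesis_result`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `name`, `form`, `bits`.
#' @export
tidy.synthesis_result <- function(x, ...) {
  cm <- x$config$cost_model
  fs <- x$feature_system
  unit <- per_unit_bits(cm, length(fs$symbols))
  rows <- list()
  for (k in seq_along(x$theory$rules)) {
    r <- x$theory$rules[[k]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = "rule", name = sprintf("r%d", k),
      form = format_rule(r), bits = rule_cost(r, cm))
  }
  slot <- function(entries, comp) {
    for (nm in names(entries)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        component = comp, name = nm,
        form = form_string(entries[[nm]]),
        bits = length(entries[[nm]]) * unit)
    }
  }
  slot(x$lexicon$prefixes, "prefix")
  slot(x$lexicon$suffixes, "suffix")
  slot(x$lexicon$stems, "stem")
  dplyr::bind_rows(rows)
}

#' Summarize a synthesis result in one row
#'
#' @param x A `synthesis_result`.
#' @param ... Unused.
#' @return A one-row tibble: backend, rule count, bit totals, objective.
#' @export
glance.synthesis_result <- function(x, ...) {
  tibble::tibble(
    backend = x$backend,
    n_rules = length(x$theory$rules),
    n_stems = length(x$lexicon$stems),
    rule_bits = x$rule_bits,
    affix_bits = x$affix_bits,
    stem_bits = x$stem_bits,
    objective = x$objective)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
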