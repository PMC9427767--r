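#' Synthesis configuration
#'
#' Declares the bounded grammar space searched by [exact_synthesize()] and
#' friends: the cost model, the rule-shape bounds (matrix literals, trigger
#' length, Kleene star, change kinds), where affix hypotheses come from, and
#' the stem-search bounds. The exact backend certifies optimality within
#' exactly this space.
#'
#' @param cost_model A [cost_model()].
#' @param backend `"exact_bounded"` (complete bounded search) or
#'   `"incremental"` (counterexample-driven repair loop).
#' @param max_rules Bound K on the number of ordered rules (kernel backends
#'   support K <= 2).
#' @param features Feature names available to rule matrices (default: all of
#'   the system's); shrink to keep enumeration tractable.
#' @param max_matrix_literals Literals per feature matrix in enumerated rules.
#' @param max_trigger_len Elements per trigger side in enumerated rules.
#' @param allow_star,allow_insert,allow_delete,allow_feature Toggle rule
#'   devices in the enumerated space.
#' @param insert_phonemes Phonemes available to insertion rules (default: the
#'   phonemes observed in the data).
#' @param boundary_triggers Include word-boundary trigger variants.
#' @param affix_source `"inventory"` (all strings up to `max_affix_len`, the
#'   fully exact space) or `"surface"` (edge substrings of the observed
#'   column forms, a documented data-driven restriction).
#' @param max_affix_len Maximum affix length in phonemes.
#' @param allow_prefixes Search prefixes as well as suffixes.
#' @param stem_alphabet Phonemes stems may use (default: full inventory).
#' @param max_stem_len Maximum stem length.
#' @param minibatch Lexemes per counterexample batch (incremental backend).
#' @param max_repair_budget Largest edit budget tried before the incremental
#'   backend escalates to a global re-solve.
#' @param seed Integer seed recorded with results (the search itself is
#'   deterministic).
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(cost_model = phonosynth::cost_model(),
                             backend = c("exact_bounded", "incremental"),
                             max_rules = cost_model$max_rules,
                             features = NULL,
                             max_matrix_literals = 1L,
                             max_trigger_len = 1L,
                             allow_star = cost_model$allow_star,
                             allow_insert = TRUE,
                             allow_delete = TRUE,
                             allow_feature = TRUE,
                             insert_phonemes = NULL,
                             boundary_triggers = TRUE,
                             affix_source = c("inventory", "surface"),
                             max_affix_len = cost_model$max_affix_len,
                             allow_prefixes = TRUE,
                             stem_alphabet = NULL,
                             max_stem_len = cost_model$max_stem_len,
                             minibatch = 1L,
                             max_repair_budget = 8L,
                             seed = 1L) {
  structure(list(
    cost_model = cost_model, backend = match.arg(backend),
    max_rules = as.integer(max_rules), features = features,
    max_matrix_literals = as.integer(max_matrix_literals),
    max_trigger_len = as.integer(max_trigger_len),
    allow_star = isTRUE(allow_star), allow_insert = isTRUE(allow_insert),
    allow_delete = isTRUE(allow_delete), allow_feature = isTRUE(allow_feature),
    insert_phonemes = insert_phonemes,
    boundary_triggers = isTRUE(boundary_triggers),
    affix_source = match.arg(affix_source),
    max_affix_len = as.integer(max_affix_len),
    allow_prefixes = isTRUE(allow_prefixes),
    stem_alphabet = stem_alphabet,
    max_stem_len = as.integer(max_stem_len),
    minibatch = as.integer(minibatch),
    max_repair_budget = as.integer(max_repair_budget),
    seed = as.integer(seed)),
    class = "synthesis_config")
}

# ---------------------------------------------------------------------------
# bounded rule-space enumeration

enumerate_matrices <- function(fs, cfg, max_literals) {
  if (fs$mode == "none") {
    return(lapply(fs$symbols, feature_matrix))
  }
  feats <- cfg$features %||% fs$feature_names
  out <- list(feature_matrix())
  lits <- as.vector(outer(c("+", "-"), feats, paste0))
  for (l in lits) out[[length(out) + 1L]] <- feature_matrix(l)
  if (max_literals >= 2L && length(lits) >= 2L) {
    cmb <- utils::combn(lits, 2L, simplify = FALSE)
    for (pr in cmb) {
      f <- sub("^[+-]", "", pr)
      if (f[1] != f[2]) out[[length(out) + 1L]] <- feature_matrix(pr)
    }
  }
  out
}

enumerate_triggers <- function(mats, cfg) {
  out <- list(trigger(), if (cfg$boundary_triggers) trigger(boundary = TRUE))
  out <- Filter(Negate(is.null), out)
  elems <- list()
  for (m in mats) {
    elems[[length(elems) + 1L]] <- m
    if (cfg$allow_star) elems[[length(elems) + 1L]] <- starred(m)
  }
  for (e in elems) {
    out[[length(out) + 1L]] <- trigger(e)
    if (cfg$boundary_triggers) {
      out[[length(out) + 1L]] <- trigger(e, boundary = TRUE)
    }
  }
  if (cfg$max_trigger_len >= 2L) {
    for (e1 in elems) for (e2 in elems) {
      both_star <- inherits(e1, "trigger_elem") && e1$star &&
        inherits(e2, "trigger_elem") && e2$star
      if (both_star) next
      tr <- try(trigger(e1, e2), silent = TRUE)
      if (!inherits(tr, "try-error")) {
        out[[length(out) + 1L]] <- tr
        if (cfg$boundary_triggers) {
          out[[length(out) + 1L]] <- trigger(e1, e2, boundary = TRUE)
        }
      }
    }
  }
  out
}

#' Enumerate the bounded rule space of a configuration
#'
#' Every rule the exact backend can return, in canonical order (increasing
#' cost, then canonical notation). The size of this list is the honest
#' measure of the search space the optimality certificate refers to.
#'
#' @param fs Feature system.
#' @param cfg A [synthesis_config()].
#' @param X Optional [problem_data()]; when given, insertion phonemes default
#'   to the phonemes observed in it.
#' @return List of [rule()] objects.
#' @export
enumerate_rule_space <- function(fs, cfg, X = NULL) {
  cm <- cfg$cost_model
  mats <- enumerate_matrices(fs, cfg, cfg$max_matrix_literals)
  focus_mats <- mats
  change_mats <- if (fs$mode == "none") mats
  else enumerate_matrices(fs, cfg, 1L)[-1] # nonempty overwrites only
  triggers <- enumerate_triggers(mats, cfg)
  ins_ph <- cfg$insert_phonemes %||% (
    if (!is.null(X)) {
      sort(unique(unlist(lapply(X$form, tokenize_form, fs = fs))))
    } else fs$symbols)

  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r
  for (lt in triggers) for (rt in triggers) {
    if (cfg$allow_feature) {
      for (fm in focus_mats) for (ch in change_mats) {
        if (identical(format(fm), format(ch))) next # vacuous overwrite
        add(rule(fm, change_features(ch), lt, rt))
      }
    }
    if (cfg$allow_delete) {
      for (fm in focus_mats) add(rule(fm, change_delete(), lt, rt))
    }
    if (cfg$allow_insert) {
      for (p in ins_ph) add(rule(NULL, change_insert(p), lt, rt))
    }
  }
  bits <- vapply(rules, rule_cost, 0, cm = cm)
  txt <- vapply(rules, format_rule, "")
  rules[order(bits, txt, method = "radix")]
}

# Affix-pair hypotheses per inflection column, cheapest first.
affix_candidates <- function(X, cfg, fs) {
  all_strings <- function(max_len) {
    out <- list(character())
    if (max_len >= 1L) for (p in fs$symbols) out[[length(out) + 1L]] <- p
    if (max_len >= 2L) for (p in fs$symbols) for (q in fs$symbols) {
      out[[length(out) + 1L]] <- c(p, q)
    }
    out
  }
  edge_strings <- function(forms, side) {
    out <- list(character())
    for (f in forms) {
      ph <- tokenize_form(f, fs)
      for (len in seq_len(min(cfg$max_affix_len, length(ph)))) {
        s <- if (side == "pfx") ph[seq_len(len)]
        else ph[seq(length(ph) - len + 1L, length(ph))]
        out[[length(out) + 1L]] <- s
      }
    }
    out[!duplicated(vapply(out, paste, "", collapse = "\1"))]
  }
  infls <- unique(X$inflection)
  out <- lapply(infls, function(infl) {
    forms <- X$form[X$inflection == infl]
    pfxs <- if (!cfg$allow_prefixes) list(character())
    else if (cfg$affix_source == "inventory") all_strings(cfg$max_affix_len)
    else edge_strings(forms, "pfx")
    sfxs <- if (cfg$affix_source == "inventory") all_strings(cfg$max_affix_len)
    else edge_strings(forms, "sfx")
    pairs <- list()
    for (p in pfxs) for (s in sfxs) {
      pairs[[length(pairs) + 1L]] <- list(pfx = p, sfx = s)
    }
    lens <- vapply(pairs, function(pr) length(pr$pfx) + length(pr$sfx), 0L)
    key <- vapply(pairs, function(pr) {
      paste(c(pr$pfx, "|", pr$sfx), collapse = "\1")
    }, "")
    pairs[order(lens, key, method = "radix")]
  })
  names(out) <- infls
  out
}

# ---------------------------------------------------------------------------
# result container

new_synthesis_result <- function(theory, lexicon, X, fs, cfg, backend,
                                 bits, extra = list()) {
  structure(c(list(
    theory = theory, lexicon = lexicon, data = X, feature_system = fs,
    config = cfg, backend = backend,
    objective = -(bits$rule + bits$affix + bits$stem),
    rule_bits = bits$rule, affix_bits = bits$affix, stem_bits = bits$stem,
    parsimony_bits = bits$rule + bits$affix, fit_bits = bits$stem),
    extra),
    class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result> backend=%s, objective=%.2f bits\n",
              x$backend, x$objective))
  print(x$theory)
  cat("stems:\n")
  for (nm in names(x$lexicon$stems)) {
    cat(sprintf("  %s: /%s/\n", nm, form_string(x$lexicon$stems[[nm]])))
  }
  aff <- function(slot, lab) {
    for (nm in names(slot)) {
      cat(sprintf("  %s[%s]: /%s/\n", lab, nm, form_string(slot[[nm]])))
    }
  }
  aff(x$lexicon$prefixes, "pfx"); aff(x$lexicon$suffixes, "sfx")
  invisible(x)
}

#' Exact MDL-optimal grammar synthesis
#'
#' Complete search over the bounded grammar space declared by `cfg`: every
#' ordered rule sequence up to `max_rules` rules from the enumerated rule
#' space, every affix assignment from the candidate pairs, and every stem up
#' to `max_stem_len`. Returns the consistent grammar maximizing the MDL
#' objective; deterministic tie-breaking (fewer parsimony bits, then
#' canonical rule order). Errors with class `phonosynth_unsat` when no
#' consistent grammar exists in the space.
#'
#' @param X A [problem_data()].
#' @param cfg A [synthesis_config()].
#' @param fs Feature system.
#' @return A `synthesis_result`.
#' @export
exact_synthesize <- function(X, cfg = synthesis_config(), fs) {
  rules <- enumerate_rule_space(fs, cfg, X)
  pairs <- affix_candidates(X, cfg, fs)
  data <- kernel_data(X, pairs, cfg$cost_model, fs,
                      stem_alphabet = cfg$stem_alphabet %||% fs$symbols,
                      max_stem_len = cfg$max_stem_len)
  res <- kernel_call(.kernel_search, rules, data, fs, cfg$cost_model,
                     cfg$max_rules, FALSE, NULL, TRUE)
  if (res$truncated) {
    warning("preimage caps were hit; optimality certificate is weakened")
  }
  if (!res$found) {
    stop(structure(class = c("phonosynth_unsat", "error", "condition"),
                   list(message = paste0(
                     "no consistent grammar within bounds (searched ",
                     res$n_theories, " theories)"), call = NULL)))
  }
  g <- kernel_result_grammar(res, rules, data, X, fs)
  new_synthesis_result(g$theory, g$lexicon, X, fs, cfg, "exact_bounded",
                       list(rule = res$best$rule_bits,
                            affix = res$best$affix_bits,
                            stem = res$best$stem_bits),
                       list(n_theories = res$n_theories,
                            n_evaluated = res$n_evaluated,
                            rule_space = length(rules)))
}

#' Pareto-frontier synthesis
#'
#' Enumerates every consistent grammar in the bounded space, deduplicates by
#' analysis (stems and affix choice), and returns the grammars not dominated
#' on (parsimony bits, fit bits): parsimony is rule + affix size, fit is
#' total stem size, smaller better on both axes.
#'
#' @inheritParams exact_synthesize
#' @return A tibble of class `pareto_frontier`: one row per frontier grammar
#'   with columns `parsimony_bits`, `fit_bits`, `joint_bits`, `theory`,
#'   `lexicon` (list-columns) and `label`.
#' @export
pareto_synthesize <- function(X, cfg = synthesis_config(), fs) {
  if (inherits(cfg, "agl_config")) return(agl_pareto(X, cfg))
  rules <- enumerate_rule_space(fs, cfg, X)
  pairs <- affix_candidates(X, cfg, fs)
  data <- kernel_data(X, pairs, cfg$cost_model, fs,
                      stem_alphabet = cfg$stem_alphabet %||% fs$symbols,
                      max_stem_len = cfg$max_stem_len)
  res <- kernel_call(.kernel_search, rules, data, fs, cfg$cost_model,
                     cfg$max_rules, TRUE, NULL, FALSE)
  if (res$truncated) {
    warning("preimage caps were hit; frontier completeness is weakened")
  }
  if (!res$found) {
    stop(structure(class = c("phonosynth_unsat", "error", "condition"),
                   list(message = "no consistent grammar within bounds",
                        call = NULL)))
  }
  # expand every consistent theory over every affix assignment: the same
  # rule set can sit at several points of the parsimony/fit trade-off
  n_cand <- vapply(data$affix_cands, function(cc) length(cc$pfx), 0L)
  combos <- expand.grid(lapply(n_cand, seq_len))
  if (nrow(combos) > 2000L) {
    stop("affix space too large for full Pareto enumeration; ",
         "restrict the affix candidates")
  }
  masks <- fs_masks(fs)
  re <- encode_rules(rules, fs, cfg$cost_model)
  theories_distinct <- res$all_theories[!duplicated(vapply(
    res$all_theories, paste, "", collapse = ","))]
  details <- list()
  for (th in theories_distinct) {
    for (gi in seq_len(nrow(combos))) {
      data1 <- data
      for (ci in seq_along(data$affix_cands)) {
        a <- combos[gi, ci]
        data1$affix_cands[[ci]] <- list(
          pfx = data$affix_cands[[ci]]$pfx[a],
          sfx = data$affix_cands[[ci]]$sfx[a],
          bits = data$affix_cands[[ci]]$bits[a])
      }
      d <- .kernel_eval(length(fs$symbols), masks$plus, masks$minus,
                        re$fm_plus, re$fm_minus, re$fm_phlit, re$enc,
                        re$bits, data1, th)
      if (isTRUE(d$found)) {
        d$affix_choice <- vapply(seq_along(data$affix_cands), function(ci) {
          combos[gi, ci] - 1L
        }, 0L)
        details[[length(details) + 1L]] <- d
      }
    }
  }
  pareto_from_details(details, rules, data, X, fs)
}

pareto_from_details <- function(details, rules, data, X, fs) {
  sig <- vapply(details, function(d) {
    paste(c(unlist(d$stems), "|", d$affix_choice), collapse = ",")
  }, "")
  pars <- vapply(details, function(d) d$rule_bits + d$affix_bits, 0)
  fit <- vapply(details, function(d) d$stem_bits, 0)
  ord <- order(pars + fit, pars, method = "radix")
  details <- details[ord]; sig <- sig[ord]; pars <- pars[ord]; fit <- fit[ord]
  first <- !duplicated(sig)
  details <- details[first]; pars <- pars[first]; fit <- fit[first]
  dominated <- vapply(seq_along(details), function(i) {
    any(vapply(seq_along(details), function(j) {
      j != i && pars[j] <= pars[i] && fit[j] <= fit[i] &&
        (pars[j] < pars[i] || fit[j] < fit[i])
    }, TRUE))
  }, TRUE)
  details <- details[!dominated]
  pars <- pars[!dominated]; fit <- fit[!dominated]
  grams <- lapply(details, function(d) {
    kernel_result_grammar(list(best = d), rules, data, X, fs)
  })
  out <- tibble::tibble(
    parsimony_bits = pars, fit_bits = fit, joint_bits = pars + fit,
    theory = lapply(grams, `[[`, "theory"),
    lexicon = lapply(grams, `[[`, "lexicon"),
    label = vapply(grams, function(g) {
      if (!length(g$theory$rules)) "no rules"
      else paste(vapply(g$theory$rules, format_rule, ""), collapse = "; ")
    }, ""))
  out <- out[order(out$parsimony_bits, out$fit_bits), ]
  class(out) <- c("pareto_frontier", class(out))
  out
}

# ---------------------------------------------------------------------------
# incremental (counterexample-driven) backend

#' Counterexamples to a grammar
#'
#' Cells the grammar fails to reproduce, grouped by lexeme (whole paradigm
#' rows), ordered by first occurrence in the data, up to `batch` lexemes.
#' An empty result means the grammar is consistent.
#'
#' @param T_ A [theory()].
#' @param L A [lexicon()].
#' @param X A [problem_data()].
#' @param fs Feature system.
#' @param batch Maximum number of failing lexemes to return.
#' @return A [problem_data()] subset (or `NULL` when consistent).
#' @export
counterexamples <- function(T_, L, X, fs, batch = 1L) {
  cons <- check_consistency(T_, L, X, fs)
  if (cons$consistent) return(NULL)
  failing <- unique(vapply(cons$failures, function(m) m$stem_id, ""))
  lex_order <- problem_lexemes(X)
  failing <- lex_order[lex_order %in% failing]
  take <- head(failing, batch)
  X[X$stem_id %in% take, , drop = FALSE]
}

rule_slots <- function(r) {
  c(focus = if (is.null(r$focus)) "∅" else fm_notation(r$focus),
    change = change_notation(r$change),
    left = trigger_notation(r$left, "left"),
    right = trigger_notation(r$right, "right"))
}

#' Edit distance between theories
#'
#' Minimal number of atomic edits over an order-preserving alignment of the
#' two rule sequences: changing one slot of one rule (focus, change, left or
#' right trigger) costs 1; inserting or deleting a whole rule costs the full
#' slot count (4).
#'
#' @param T1,T2 [theory()] objects.
#' @return Non-negative integer.
#' @export
theory_edit_distance <- function(T1, T2) {
  s1 <- lapply(T1$rules, rule_slots)
  s2 <- lapply(T2$rules, rule_slots)
  n <- length(s1); m <- length(s2)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- seq(0L, n) * 4L
  D[1, ] <- seq(0L, m) * 4L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- sum(s1[[i]] != s2[[j]])
    D[i + 1L, j + 1L] <- min(D[i, j] + sub, D[i, j + 1L] + 4L,
                             D[i + 1L, j] + 4L)
  }
  D[n + 1L, m + 1L]
}

# Candidate theories within a given edit budget of T_cur, drawn from the
# bounded rule space. Budgets: 0 identity; 1 one slot; 2 two slots of one
# rule; 4 adds rule insertion/deletion and whole-rule replacement.
rule_space_slot_matrix <- function(rules) {
  mat <- attr(rules, "slot_matrix")
  if (is.null(mat)) {
    mat <- t(vapply(rules, rule_slots, character(4)))
    rownames(mat) <- vapply(rules, format_rule, "")
  }
  mat
}

repair_neighborhood <- function(T_cur, budget, rules, cfg, fs,
                                slot_mat = rule_space_slot_matrix(rules)) {
  rule_txt <- rownames(slot_mat) %||% vapply(rules, format_rule, "")
  base <- match(vapply(T_cur$rules, format_rule, ""), rule_txt)
  if (anyNA(base)) base <- base[!is.na(base)]
  out <- list(base)
  K <- cfg$max_rules
  nr <- length(rules)

  slot_variants <- function(idx, max_slots) {
    # rules in the space within `max_slots` slot edits of rules[[idx]]
    d <- rowSums(slot_mat != matrix(slot_mat[idx, ], nrow(slot_mat), 4L,
                                    byrow = TRUE))
    which(d >= 1L & d <= max_slots)
  }

  if (budget >= 1L && length(base)) {
    for (pos in seq_along(base)) {
      for (v in slot_variants(base[pos], min(budget, 3L))) {
        cand <- base; cand[pos] <- v
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  if (budget >= 4L) {
    if (length(base) < K) {
      for (pos in 0:length(base)) for (v in seq_len(nr)) {
        out[[length(out) + 1L]] <- append(base, v, after = pos)
      }
    }
    if (length(base)) {
      for (pos in seq_along(base)) {
        out[[length(out) + 1L]] <- base[-pos]
        for (v in seq_len(nr)) { # whole-rule replacement (4 slots)
          cand <- base; cand[pos] <- v
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out[!duplicated(vapply(out, paste, "", collapse = ","))]
}

#' Minimal-repair step of the incremental loop
#'
#' Finds the smallest edit budget within which some theory in the bounded
#' space is consistent with the accumulated data, and among theories within
#' that budget returns the objective-maximizing one. Escalates to a global
#' [exact_synthesize()] when even the largest budget fails.
#'
#' @param T_cur Current [theory()].
#' @param X_next Accumulated [problem_data()].
#' @param cfg A [synthesis_config()].
#' @param fs Feature system.
#' @param rules Pre-enumerated rule space (recomputed if `NULL`).
#' @return List with `budget`, `result` (a `synthesis_result`) and
#'   `escalated` flag.
#' @export
minimal_repair <- function(T_cur, X_next, cfg, fs, rules = NULL) {
  rules <- rules %||% enumerate_rule_space(fs, cfg, X_next)
  pairs <- affix_candidates(X_next, cfg, fs)
  data <- kernel_data(X_next, pairs, cfg$cost_model, fs,
                      stem_alphabet = cfg$stem_alphabet %||% fs$symbols,
                      max_stem_len = cfg$max_stem_len)
  budgets <- c(0L, 1L, 2L, 4L, 5L, 6L, 8L)
  budgets <- budgets[budgets <= cfg$max_repair_budget]
  slot_mat <- rule_space_slot_matrix(rules)
  for (D in budgets) {
    cands <- repair_neighborhood(T_cur, D, rules, cfg, fs, slot_mat)
    cands0 <- lapply(cands, function(v) as.integer(v) - 1L)
    res <- kernel_call(.kernel_search, rules, data, fs, cfg$cost_model,
                       cfg$max_rules, FALSE, cands0, FALSE)
    if (res$found) {
      g <- kernel_result_grammar(res, rules, data, X_next, fs)
      out <- new_synthesis_result(
        g$theory, g$lexicon, X_next, fs, cfg, "incremental",
        list(rule = res$best$rule_bits, affix = res$best$affix_bits,
             stem = res$best$stem_bits))
      return(list(budget = D, result = out, escalated = FALSE))
    }
  }
  res <- exact_synthesize(X_next, cfg, fs)
  message("minimal_repair: no local repair within budget ",
          cfg$max_repair_budget, "; escalated to global re-solve")
  list(budget = NA_integer_, result = res, escalated = TRUE)
}

#' Incremental counterexample-driven synthesis
#'
#' Starts from the empty theory and no data, repeatedly adds the earliest
#' failing lexeme's surface forms (in minibatches) and repairs the theory
#' with the smallest edit budget that restores consistency, until the whole
#' data set is explained. The full iteration trace is returned.
#'
#' @inheritParams exact_synthesize
#' @return A `synthesis_result` with an additional `trace` tibble
#'   (`t`, `lexemes`, `cells`, `budget`, `objective`).
#' @export
incremental_synthesize <- function(X, cfg = synthesis_config(), fs) {
  rules <- enumerate_rule_space(fs, cfg, X)
  attr(rules, "slot_matrix") <- rule_space_slot_matrix(rules)
  T_cur <- theory()
  L_cur <- lexicon()
  X_cur <- NULL
  trace <- list()
  t <- 0L
  repeat {
    cex <- counterexamples(T_cur, L_cur, X, fs, batch = cfg$minibatch)
    if (is.null(cex)) break
    new_rows <- cex[!paste(cex$stem_id, cex$inflection) %in%
                      if (is.null(X_cur)) character()
                    else paste(X_cur$stem_id, X_cur$inflection), ,
                    drop = FALSE]
    X_cur <- if (is.null(X_cur)) cex else {
      problem_data(dplyr::bind_rows(tibble::as_tibble(X_cur),
                                    tibble::as_tibble(new_rows)),
                   bundles = attr(X, "bundles"))
    }
    t <- t + 1L
    rep_ <- minimal_repair(T_cur, X_cur, cfg, fs, rules = rules)
    T_cur <- rep_$result$theory
    L_cur <- rep_$result$lexicon
    trace[[t]] <- tibble::tibble(
      t = t, lexemes = length(problem_lexemes(X_cur)),
      cells = nrow(X_cur), budget = rep_$budget,
      escalated = rep_$escalated, objective = rep_$result$objective)
  }
  final <- if (is.null(X_cur)) {
    # vacuously consistent from the start (empty grammar explains X)
    minimal_repair(theory(), X, cfg, fs, rules = rules)$result
  } else rep_$result
  final$backend <- "incremental"
  final$trace <- dplyr::bind_rows(trace)
  final$data <- X
  final
}
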