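# Fragment-grammar metatheory over SPE-rule syntax trees: a PCFG base
# grammar whose productions generate rule trees, augmented with cached
# fragments (partial trees with typed holes). Fragments reweight the
# distribution over rules but never change the set of generable rules.

tree_node <- function(nt, label, children = list()) {
  sig <- if (!length(children)) label
  else paste0(label, "(", paste(vapply(children, `[[`, "", "sig"),
                                collapse = ","), ")")
  list(nt = nt, label = label, children = children, sig = sig)
}
tree_hole <- function(nt) {
  list(nt = nt, label = NULL, hole = TRUE, sig = paste0("?", nt))
}
is_hole <- function(x) isTRUE(x$hole)

#' Base PCFG over rule syntax trees
#'
#' Nonterminals RULE, FOCUS, CHANGE, TRIGGER, FM, LIT and PH with the
#' productions: a rule is focus + change + two triggers; triggers are
#' (possibly starred) feature-matrix lists ending in the empty context or a
#' word boundary; feature matrices are literal lists; literals and phonemes
#' are drawn from the feature system. Production probabilities start uniform
#' per nonterminal.
#'
#' @param fs Feature system.
#' @param stop_prob Bernoulli stop probability used when pricing fragments by
#'   generation from the grammar.
#' @return An object of class `fragment_grammar` with no fragments (this is
#'   the base metatheory).
#' @export
base_grammar <- function(fs, stop_prob = 0.5) {
  lits <- as.vector(outer(c("+", "-"), fs$feature_names, paste0))
  nts <- list(
    RULE = list(rule = c("FOCUS", "CHANGE", "TRIGGER", "TRIGGER")),
    FOCUS = list(focus_empty = character(), focus_fm = "FM"),
    CHANGE = list(change_fm = "FM", change_del = character(),
                  change_ins = "PH", change_ins2 = c("PH", "PH")),
    TRIGGER = list(trig_empty = character(), trig_bound = character(),
                   trig_fm = c("FM", "TRIGGER"),
                   trig_star = c("FM", "TRIGGER")),
    FM = list(fm_empty = character(), fm_lit = c("LIT", "FM")),
    LIT = setNames(replicate(length(lits), character()),
                   paste0("lit_", lits)),
    PH = setNames(replicate(length(fs$symbols), character()),
                  paste0("ph_", fs$symbols)))
  probs <- lapply(nts, function(p) {
    setNames(rep(1 / length(p), length(p)), names(p))
  })
  structure(list(nts = nts, probs = probs, fragments = list(),
                 fragment_logp = numeric(), fs_name = fs$name,
                 feature_names = fs$feature_names, symbols = fs$symbols,
                 stop_prob = stop_prob),
            class = "fragment_grammar")
}

#' @export
print.fragment_grammar <- function(x, ...) {
  cat(sprintf("<fragment_grammar> %d nonterminals, %d fragments\n",
              length(x$nts), length(x$fragments)))
  if (length(x$fragments)) {
    for (i in seq_along(x$fragments)) {
      cat(sprintf("  frag %d [%s]: %s\n", i, x$fragments[[i]]$nt,
                  format_fragment(x$fragments[[i]]$tree)))
    }
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# rule <-> tree

fm_to_tree <- function(fm) {
  t <- tree_node("FM", "fm_empty")
  for (lit in rev(fm$literals)) {
    t <- tree_node("FM", "fm_lit",
                   list(tree_node("LIT", paste0("lit_", lit)), t))
  }
  t
}

trigger_to_tree <- function(tr, side) {
  t <- tree_node("TRIGGER", if (tr$boundary) "trig_bound" else "trig_empty")
  elems <- tr$elements
  if (side == "left") elems <- rev(elems) # adjacent-first linearization
  for (e in rev(elems)) {
    t <- tree_node("TRIGGER", if (e$star) "trig_star" else "trig_fm",
                   list(fm_to_tree(e$fm), t))
  }
  t
}

#' Syntax tree of a rule
#'
#' @param r A [rule()] (feature/delete/insert changes; the copy and alpha
#'   devices are outside the metatheory's rule language).
#' @param fs Feature system.
#' @return A rule syntax tree (nested list).
#' @export
rule_to_tree <- function(r, fs) {
  ch <- r$change
  if (ch$kind == "copy" || (ch$kind == "feature" && !is.null(ch$alpha))) {
    stop("rule outside the metatheory's rule language: ", format_rule(r))
  }
  if (!is.null(r$focus) && fm_is_phoneme_literal(r$focus)) {
    stop("literal-phoneme matrices are outside the metatheory's rule language")
  }
  focus <- if (is.null(r$focus)) tree_node("FOCUS", "focus_empty")
  else tree_node("FOCUS", "focus_fm", list(fm_to_tree(r$focus)))
  change <- switch(ch$kind,
    feature = tree_node("CHANGE", "change_fm", list(fm_to_tree(ch$fm))),
    delete = tree_node("CHANGE", "change_del"),
    insert = {
      phs <- lapply(ch$phonemes, function(p) {
        tree_node("PH", paste0("ph_", p))
      })
      if (length(phs) == 1L) tree_node("CHANGE", "change_ins", phs)
      else if (length(phs) == 2L) tree_node("CHANGE", "change_ins2", phs)
      else stop("insertions longer than 2 are outside the rule language")
    })
  tree_node("RULE", "rule",
            list(focus, change, trigger_to_tree(r$left, "left"),
                 trigger_to_tree(r$right, "right")))
}

# ---------------------------------------------------------------------------
# probability of a tree under a fragment grammar

fragment_match <- function(frag, tree) {
  # returns list of (hole nt, subtree) bindings, or NULL if no match
  if (is_hole(frag)) {
    if (!identical(frag$nt, tree$nt)) return(NULL)
    return(list(list(nt = frag$nt, tree = tree)))
  }
  if (!identical(frag$nt, tree$nt) || !identical(frag$label, tree$label) ||
      length(frag$children) != length(tree$children)) return(NULL)
  out <- list()
  for (i in seq_along(frag$children)) {
    m <- fragment_match(frag$children[[i]], tree$children[[i]])
    if (is.null(m)) return(NULL)
    out <- c(out, m)
  }
  out
}

tree_prob <- function(M, tree, memo = new.env(parent = emptyenv())) {
  rec <- function(t) {
    hit <- memo[[t$sig]]
    if (!is.null(hit)) return(hit)
    nt <- t$nt
    p <- 0
    # base production
    th <- M$probs[[nt]][[t$label]]
    if (!is.null(th) && th > 0) {
      pp <- th
      for (ch in t$children) pp <- pp * rec(ch)
      p <- p + pp
    }
    # fragments rooted at this nonterminal
    for (i in seq_along(M$fragments)) {
      fr <- M$fragments[[i]]
      if (!identical(fr$nt, nt)) next
      th_f <- M$probs[[nt]][[fr$name]]
      if (is.null(th_f) || th_f == 0) next
      m <- fragment_match(fr$tree, t)
      if (is.null(m)) next
      pp <- th_f
      for (b in m) pp <- pp * rec(b$tree)
      p <- p + pp
    }
    memo[[t$sig]] <- p
    p
  }
  rec(tree)
}

#' Vectorized rule priors under a metatheory
#'
#' Description-length (bits, `-log2 P(r|M)`) of every rule in a list, with
#' shared-subtree memoization; the workhorse behind metatheory-weighted
#' synthesis and language-preservation checks.
#'
#' @param rules List of [rule()]s (optionally carrying a `trees` attribute).
#' @param M A fragment grammar.
#' @param fs Feature system.
#' @param trees Optional precomputed [rule_to_tree()] list.
#' @return Numeric vector of bits (`Inf` for rules outside the language).
#' @export
rule_prior_bits <- function(rules, M, fs, trees = NULL) {
  trees <- trees %||% attr(rules, "trees") %||%
    lapply(rules, rule_to_tree, fs = fs)
  memo <- new.env(parent = emptyenv())
  vapply(trees, function(t) -log2(tree_prob(M, t, memo)), 0)
}

#' Prior log-probability of a rule under a metatheory
#'
#' Sums over every derivation of the rule's syntax tree (base productions
#' and cached fragments).
#'
#' @param r A [rule()].
#' @param M A [base_grammar()] / learned fragment grammar.
#' @param fs Feature system.
#' @return Natural-log probability.
#' @export
rule_prior <- function(r, M, fs) {
  log(tree_prob(M, rule_to_tree(r, fs)))
}

# ---------------------------------------------------------------------------
# antiunification

#' Antiunify two rule trees
#'
#' The least general generalization: shared structure is kept, differing
#' subtrees become typed holes.
#'
#' @param t1,t2 Trees with the same root nonterminal (see [rule_to_tree()]).
#' @return A fragment: a partial tree whose holes are labeled by
#'   nonterminals.
#' @export
antiunify <- function(t1, t2) {
  stopifnot(identical(t1$nt, t2$nt))
  if (is_hole(t1) || is_hole(t2) || !identical(t1$label, t2$label) ||
      length(t1$children) != length(t2$children)) {
    return(tree_hole(t1$nt))
  }
  tree_node(t1$nt, t1$label,
            lapply(seq_along(t1$children), function(i) {
              antiunify(t1$children[[i]], t2$children[[i]])
            }))
}

fragment_size <- function(t) {
  if (is_hole(t)) return(0L)
  1L + sum(vapply(t$children, fragment_size, 0L))
}

hole_count <- function(t) {
  if (is_hole(t)) return(1L)
  sum(vapply(t$children, hole_count, 0L))
}

#' @rdname antiunify
#' @param t A fragment or tree.
#' @return `format_fragment`: human-readable schema string with `FM`,
#'   `trigger`, `PH` slot names for holes.
#' @export
format_fragment <- function(t) {
  if (is_hole(t)) {
    return(switch(t$nt, FM = "FM", TRIGGER = "trigger", PH = "PH",
                  LIT = "lit", FOCUS = "focus", CHANGE = "change", t$nt))
  }
  kids <- vapply(t$children, format_fragment, "")
  switch(t$label,
    rule = sprintf("%s -> %s / %s _ %s", kids[1], kids[2], kids[3], kids[4]),
    focus_empty = "∅", focus_fm = kids[1],
    change_fm = kids[1], change_del = "∅",
    change_ins = kids[1], change_ins2 = paste0(kids[1], kids[2]),
    trig_empty = "", trig_bound = "#",
    trig_fm = trimws(paste(kids[1], kids[2])),
    trig_star = trimws(paste(paste0(kids[1], "*"), kids[2])),
    fm_empty = "[ ]",
    fm_lit = {
      inner <- paste(kids[1], sub("^\\[ ?", "", sub(" ?\\]$", "", kids[2])))
      paste0("[", trimws(inner), "]")
    },
    if (startsWith(t$label, "lit_")) sub("^lit_", "", t$label)
    else if (startsWith(t$label, "ph_")) sub("^ph_", "", t$label)
    else t$label)
}

# price a fragment by generating it from the grammar: each internal node
# pays (1 - stop) times its production probability, each hole pays stop
fragment_gen_logp <- function(M, frag) {
  rec <- function(t) {
    if (is_hole(t)) return(log(M$stop_prob))
    th <- M$probs[[t$nt]][[t$label]]
    if (is.null(th) || th == 0) return(-Inf)
    log1p(-M$stop_prob) + log(th) + sum(vapply(t$children, rec, 0))
  }
  rec(frag)
}

add_fragment <- function(M, frag_tree) {
  name <- sprintf("frag_%d", length(M$fragments) + 1L)
  nt <- frag_tree$nt
  lp <- fragment_gen_logp(M, frag_tree)
  M$fragments[[length(M$fragments) + 1L]] <-
    list(nt = nt, tree = frag_tree, name = name)
  M$fragment_logp <- c(M$fragment_logp, lp)
  # give the new production a share and renormalize its nonterminal
  old <- M$probs[[nt]]
  M$probs[[nt]] <- setNames(c(old * length(old), 1) /
                              (sum(old * length(old)) + 1),
                            c(names(old), name))
  M
}

metatheory_log_prior <- function(M) {
  if (!length(M$fragment_logp)) 0 else sum(M$fragment_logp)
}

# ---------------------------------------------------------------------------
# Inside-Outside parameter fitting (EM with symmetric Dirichlet, pseudocount 1)

tree_prob_counts <- function(M, tree) {
  # returns list(p, S) where S[prod] = sum over derivations of P(d) * count
  zero <- lapply(M$probs, function(v) setNames(rep(0, length(v)), names(v)))
  add_counts <- function(a, b, w = 1) {
    for (nt in names(b)) a[[nt]] <- a[[nt]] + w * b[[nt]]
    a
  }
  rec <- function(t) {
    nt <- t$nt
    p <- 0
    S <- zero
    use_option <- function(theta, own_label, subtrees) {
      subs <- lapply(subtrees, rec)
      pp <- theta * prod(vapply(subs, `[[`, 0, "p"))
      if (pp == 0) return(NULL)
      So <- zero
      So[[nt]][[own_label]] <- pp
      for (i in seq_along(subs)) {
        if (subs[[i]]$p > 0) {
          So <- add_counts(So, subs[[i]]$S, pp / subs[[i]]$p)
        }
      }
      list(p = pp, S = So)
    }
    th <- M$probs[[nt]][[t$label]]
    if (!is.null(th) && th > 0) {
      o <- use_option(th, t$label, t$children)
      if (!is.null(o)) { p <- p + o$p; S <- add_counts(S, o$S) }
    }
    for (i in seq_along(M$fragments)) {
      fr <- M$fragments[[i]]
      if (!identical(fr$nt, nt)) next
      th_f <- M$probs[[nt]][[fr$name]]
      if (is.null(th_f) || th_f == 0) next
      m <- fragment_match(fr$tree, t)
      if (is.null(m)) next
      o <- use_option(th_f, fr$name, lapply(m, `[[`, "tree"))
      if (!is.null(o)) { p <- p + o$p; S <- add_counts(S, o$S) }
    }
    list(p = p, S = S)
  }
  rec(tree)
}

#' Fit fragment-grammar parameters by Inside-Outside EM
#'
#' Re-estimates production probabilities on a weighted corpus of rule trees,
#' with a symmetric Dirichlet prior (pseudocounts 1) on every production
#' distribution. The penalized (MAP) objective is non-decreasing across
#' iterations.
#'
#' @param M A fragment grammar (structure is kept, probabilities refit).
#' @param trees List of rule trees ([rule_to_tree()]).
#' @param weights Corpus weights (default 1 per tree).
#' @param max_iter,tol EM stopping rule.
#' @return The grammar with refit probabilities; attribute `trace` holds the
#'   per-iteration objective.
#' @export
fit_parameters <- function(M, trees, weights = rep(1, length(trees)),
                           max_iter = 50L, tol = 1e-8) {
  pseudo <- 1
  objective <- function(M) {
    ll <- 0
    for (i in seq_along(trees)) {
      p <- tree_prob(M, trees[[i]])
      if (p <= 0) stop("corpus tree unparseable under the grammar")
      ll <- ll + weights[i] * log(p)
    }
    lp <- 0
    for (nt in names(M$probs)) {
      lp <- lp + sum((pseudo - 1) * log(pmax(M$probs[[nt]], 1e-300)))
    }
    ll + lp
  }
  trace <- objective(M)
  for (it in seq_len(max_iter)) {
    counts <- lapply(M$probs, function(v) {
      setNames(rep(0, length(v)), names(v))
    })
    for (i in seq_along(trees)) {
      pc <- tree_prob_counts(M, trees[[i]])
      if (pc$p <= 0) stop("corpus tree unparseable under the grammar")
      for (nt in names(counts)) {
        counts[[nt]] <- counts[[nt]] + weights[i] * pc$S[[nt]] / pc$p
      }
    }
    for (nt in names(M$probs)) {
      num <- counts[[nt]] + pseudo
      M$probs[[nt]] <- num / sum(num)
    }
    trace <- c(trace, objective(M))
    if (abs(trace[length(trace)] - trace[length(trace) - 1L]) < tol) break
  }
  attr(M, "trace") <- trace
  M
}

# ---------------------------------------------------------------------------
# particles and joint learning

#' Top-k behaviorally distinct theories under a metatheory prior
#'
#' Runs the bounded synthesis search with per-rule costs taken from the
#' metatheory (rather than the flat description-length constants) and
#' returns the k best consistent, behaviorally distinct grammars.
#'
#' @param X A [problem_data()].
#' @param M A fragment grammar.
#' @param k Number of particles.
#' @param cfg A [synthesis_config()].
#' @param fs Feature system.
#' @return A list of particles: each has `theory`, `lexicon`, `log_joint`
#'   (natural log of P(X, T, L | M)) and `bits` breakdown.
#' @export
top_k_theories <- function(X, M, k = 10L, cfg = synthesis_config(), fs,
                           rules = NULL) {
  rules <- rules %||% enumerate_rule_space(fs, cfg, X)
  bits_M <- rule_prior_bits(rules, M, fs)
  pairs <- affix_candidates(X, cfg, fs)
  data <- kernel_data(X, pairs, cfg$cost_model, fs,
                      stem_alphabet = cfg$stem_alphabet %||% fs$symbols,
                      max_stem_len = cfg$max_stem_len)
  masks <- fs_masks(fs)
  re <- attr(rules, "encoding") %||% encode_rules(rules, fs, cfg$cost_model)
  res <- .kernel_search(length(fs$symbols), masks$plus, masks$minus,
                        re$fm_plus, re$fm_minus, re$fm_phlit, re$enc,
                        bits_M, data, cfg$max_rules, TRUE, NULL, FALSE)
  if (!res$found) {
    stop(structure(class = c("phonosynth_unsat", "error", "condition"),
                   list(message = "no consistent grammar within bounds",
                        call = NULL)))
  }
  tot <- res$all_rule_bits + res$all_affix_bits + res$all_stem_bits
  ord <- order(tot, method = "radix")
  keep <- ord[!duplicated(res$all_sig[ord])]
  keep <- head(keep, k)
  lapply(keep, function(i) {
    d <- .kernel_eval(length(fs$symbols), masks$plus, masks$minus,
                      re$fm_plus, re$fm_minus, re$fm_phlit, re$enc,
                      bits_M, data, res$all_theories[[i]])
    g <- kernel_result_grammar(list(best = d), rules, data, X, fs)
    list(theory = g$theory, lexicon = g$lexicon,
         rule_bits_M = d$rule_bits,
         lex_bits = d$affix_bits + d$stem_bits,
         log_joint = -(d$rule_bits + d$affix_bits + d$stem_bits) * log(2))
  })
}

particle_log_marginal <- function(particles) {
  if (!length(particles)) return(-Inf)
  lj <- vapply(particles, `[[`, 0, "log_joint")
  m <- max(lj)
  m + log(sum(exp(lj - m)))
}

eq13_bound <- function(M, particle_sets) {
  metatheory_log_prior(M) +
    sum(vapply(particle_sets, particle_log_marginal, 0))
}

particle_rule_corpus <- function(particle_sets, fs) {
  trees <- list()
  weights <- numeric()
  rules <- list()
  for (ps in particle_sets) {
    if (!length(ps)) next
    lj <- vapply(ps, `[[`, 0, "log_joint")
    w <- exp(lj - max(lj)); w <- w / sum(w)
    for (i in seq_along(ps)) {
      for (r in ps[[i]]$theory$rules) {
        trees[[length(trees) + 1L]] <- rule_to_tree(r, fs)
        weights <- c(weights, w[i])
        rules[[length(rules) + 1L]] <- r
      }
    }
  }
  list(trees = trees, weights = weights, rules = rules)
}

#' Learn a cross-problem metatheory by variational hillclimbing
#'
#' Alternates (a) refreshing each problem's particle set (the top-k
#' consistent grammars under the current metatheory) and (b) improving the
#' metatheory: candidate fragments are proposed by antiunifying rule trees
#' across the particle sets, parameters are refit by Inside-Outside, and a
#' proposal is kept only if the variational lower bound on the joint
#' probability of metatheory and data does not decrease. Hillclimbing, not
#' MCMC.
#'
#' @param datasets List of [problem_data()] objects.
#' @param cfg A [synthesis_config()] shared by all problems.
#' @param fs Feature system.
#' @param k Particles per problem.
#' @param iters Outer iterations.
#' @param max_proposals Fragment proposals evaluated per iteration.
#' @return List with `M` (the learned grammar), `particles`, `bound_trace`
#'   (non-decreasing across accepted steps) and `accepted` fragments.
#' @export
learn_metatheory <- function(datasets, cfg = synthesis_config(), fs,
                             k = 10L, iters = 3L, max_proposals = 10L) {
  M <- base_grammar(fs)
  rules <- enumerate_rule_space(fs, cfg)
  attr(rules, "trees") <- lapply(rules, rule_to_tree, fs = fs)
  attr(rules, "encoding") <- encode_rules(rules, fs, cfg$cost_model)
  refresh <- function(M) {
    lapply(datasets, function(X) {
      tryCatch(top_k_theories(X, M, k, cfg, fs, rules = rules),
               phonosynth_unsat = function(e) {
                 warning("dataset unsolvable within bounds; dropped")
                 list()
               })
    })
  }
  particles <- refresh(M)
  corpus <- particle_rule_corpus(particles, fs)
  if (length(corpus$trees)) {
    M <- fit_parameters(M, corpus$trees, corpus$weights)
  }
  bound <- eq13_bound(M, particles)
  trace <- bound
  accepted <- list()

  for (it in seq_len(iters)) {
    corpus <- particle_rule_corpus(particles, fs)
    if (!length(corpus$trees)) break
    # propose fragments by antiunifying pairs of rule trees
    props <- list()
    keyset <- character()
    n <- length(corpus$trees)
    if (n >= 2) {
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        fr <- antiunify(corpus$trees[[i]], corpus$trees[[j]])
        if (fragment_size(fr) < 2L) next       # too general to cache
        if (hole_count(fr) == 0L) next         # a complete rule, not a schema
        key <- format_fragment(fr)
        hit <- match(key, keyset)
        if (is.na(hit)) {
          keyset <- c(keyset, key)
          props[[length(props) + 1L]] <- list(tree = fr, count = 1L)
        } else props[[hit]]$count <- props[[hit]]$count + 1L
      }
    }
    if (!length(props)) break
    ord <- order(-vapply(props, `[[`, 0L, "count"),
                 -vapply(props, function(p) fragment_size(p$tree), 0L))
    props <- props[head(ord, max_proposals)]
    improved <- FALSE
    for (pr in props) {
      M2 <- add_fragment(M, pr$tree)
      M2 <- fit_parameters(M2, corpus$trees, corpus$weights)
      particles2 <- refresh(M2)
      b2 <- eq13_bound(M2, particles2)
      if (b2 >= bound) {
        M <- M2
        particles <- particles2
        bound <- b2
        trace <- c(trace, bound)
        accepted[[length(accepted) + 1L]] <- pr$tree
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(M = M, particles = particles, bound_trace = trace,
       accepted = accepted)
}
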