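fs_m <- toy_fs(c("b", "p", "d", "t", "a", "i"))

mk_devoicing_set <- function(stems, sfx, fs) {
  devoice <- parse_rule("[ ] -> [-voice] / _ #", fs)
  L <- lexicon(stems = stems,
               suffixes = setNames(list(sfx),
                                   bundle_key(inflection_bundle(infl = "i2"))))
  T_ <- theory(devoice)
  cells <- list()
  for (nm in names(stems)) for (infl in c("i1", "i2")) {
    m <- meaning(nm, inflection_bundle(infl = infl))
    cells[[length(cells) + 1L]] <- tibble::tibble(
      stem_id = nm, inflection = infl,
      form = form_string(derive(T_, L, m, fs)))
  }
  problem_data(dplyr::bind_rows(cells))
}

meta_cfg <- synthesis_config(cost_model(), max_rules = 1,
                             features = c("voice", "vowel"),
                             allow_insert = FALSE, allow_delete = FALSE,
                             allow_star = FALSE, allow_prefixes = FALSE,
                             max_affix_len = 1, affix_source = "inventory")

test_that("the base grammar is a normalized PCFG covering bounded rules", {
  M <- base_grammar(fs_m)
  for (nt in names(M$probs)) {
    expect_equal(sum(M$probs[[nt]]), 1)
    expect_true(all(M$probs[[nt]] > 0))
  }
  # every rule in a bounded space has a derivation with positive probability
  rules <- enumerate_rule_space(fs_m, meta_cfg)
  pri <- rule_prior_bits(rules, M, fs_m)
  expect_true(all(is.finite(pri)))
  # and those probabilities sum to at most one (the grammar also generates
  # rules outside this particular bounded slice)
  expect_lte(sum(2^(-pri)), 1)
})

test_that("antiunification returns the least general shared shape", {
  r1 <- parse_rule("[ ] -> [-voice] / _ #", fs_m)
  r2 <- parse_rule("[ ] -> [-voice] / _ [+vowel]", fs_m)
  t1 <- rule_to_tree(r1, fs_m)
  t2 <- rule_to_tree(r2, fs_m)
  # identical trees antiunify to themselves (no holes)
  self <- antiunify(t1, t1)
  expect_identical(phonosynth:::hole_count(self), 0L)
  expect_identical(self$sig, t1$sig)
  # same devoicing change, different right trigger: one trigger hole
  fr <- antiunify(t1, t2)
  expect_identical(phonosynth:::hole_count(fr), 1L)
  expect_match(format_fragment(fr), "trigger")
  expect_match(format_fragment(fr), "-voice")
  # wholly different rules collapse to holes below the root
  r3 <- parse_rule("[+vowel] -> ∅ / [ ] _", fs_m)
  fr2 <- antiunify(t1, rule_to_tree(r3, fs_m))
  expect_gte(phonosynth:::hole_count(fr2), 3L)
})

test_that("fragment grammars preserve the generable rule language", {
  M <- base_grammar(fs_m)
  r1 <- parse_rule("[ ] -> [-voice] / _ #", fs_m)
  r2 <- parse_rule("[ ] -> [-voice] / _ [+vowel]", fs_m)
  frag <- antiunify(rule_to_tree(r1, fs_m), rule_to_tree(r2, fs_m))
  M2 <- phonosynth:::add_fragment(M, frag)
  for (nt in names(M2$probs)) expect_equal(sum(M2$probs[[nt]]), 1)
  # depth-bounded enumeration: a rule is generable under M2 iff under M
  rules <- enumerate_rule_space(fs_m, meta_cfg)
  p_base <- rule_prior_bits(rules, M, fs_m)
  p_frag <- rule_prior_bits(rules, M2, fs_m)
  expect_true(all(is.finite(p_frag) == is.finite(p_base)))
  expect_lte(sum(2^(-p_frag)), 1)
})

test_that("inside-outside fitting increases the penalized objective", {
  M <- base_grammar(fs_m)
  rules <- list(parse_rule("[ ] -> [-voice] / _ #", fs_m),
                parse_rule("[+vowel] -> [-voice] / _ #", fs_m),
                parse_rule("[ ] -> [-voice] / _ [+vowel]", fs_m))
  trees <- lapply(rules, rule_to_tree, fs = fs_m)
  M2 <- fit_parameters(M, trees)
  trace <- attr(M2, "trace")
  expect_true(all(diff(trace) > -1e-8))
  # the corpus becomes more probable than under uniform parameters
  expect_gt(sum(vapply(trees, function(t) log(phonosynth:::tree_prob(M2, t)),
                       0)),
            sum(vapply(trees, function(t) log(phonosynth:::tree_prob(M, t)),
                       0)))
  # a single-rule corpus concentrates probability on its own productions
  M3 <- fit_parameters(M, trees[1])
  expect_gt(phonosynth:::tree_prob(M3, trees[[1]]),
            phonosynth:::tree_prob(M, trees[[1]]))
})

test_that("top-k theories are behaviorally distinct and score-sorted", {
  X <- mk_devoicing_set(list(s1 = c("b", "a", "d"), s2 = c("d", "a", "b")),
                        "a", fs_m)
  M <- base_grammar(fs_m)
  ps <- top_k_theories(X, M, k = 5, meta_cfg, fs_m)
  expect_true(length(ps) >= 2)
  lj <- vapply(ps, `[[`, 0, "log_joint")
  expect_true(all(diff(lj) <= 1e-9)) # non-increasing
  # k = 1 reduces to the MAP grammar under the prior M
  p1 <- top_k_theories(X, M, k = 1, meta_cfg, fs_m)
  expect_identical(vapply(p1[[1]]$theory$rules, format_rule, ""),
                   vapply(ps[[1]]$theory$rules, format_rule, ""))
})

test_that("a shared devoicing family raises the schema's prior and helps", {
  sets <- list(
    mk_devoicing_set(list(s1 = c("b", "a", "d"), s2 = c("d", "a", "b")),
                     "a", fs_m),
    mk_devoicing_set(list(s1 = c("d", "i", "b"), s2 = c("b", "i", "d")),
                     "i", fs_m),
    mk_devoicing_set(list(s1 = c("b", "a", "b"), s2 = c("d", "a", "d")),
                     "a", fs_m),
    mk_devoicing_set(list(s1 = c("d", "a", "b"), s2 = c("b", "i", "b")),
                     "i", fs_m))
  fit <- learn_metatheory(sets, meta_cfg, fs_m, k = 4, iters = 2)
  # the variational bound never decreases across accepted steps
  expect_true(all(diff(fit$bound_trace) > -1e-9))
  expect_gte(length(fit$accepted), 1)
  # the shared word-final devoicing rule becomes more probable than under
  # the base grammar
  devoice <- parse_rule("[ ] -> [-voice] / _ #", fs_m)
  expect_gt(rule_prior(devoice, fit$M, fs_m),
            rule_prior(devoice, base_grammar(fs_m), fs_m))
})

test_that("a single structureless dataset accepts no fragments", {
  X <- problem_data(tibble::tibble(stem_id = "W", inflection = "i1",
                                   form = "pa"))
  fit <- learn_metatheory(list(X), meta_cfg, fs_m, k = 2, iters = 2)
  expect_length(fit$accepted, 0)
})
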