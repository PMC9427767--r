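cm <- cost_model()

test_that("rule costs count components and are strictly monotone", {
  fs <- load_feature_system("articulatory")
  # hand count: base 4 + inserted phoneme 3 + left (slot 2 + literal 1)
  #           + right (slot 2 + literal 1 + boundary 1) = 14
  r <- parse_rule("∅ -> a / C _ C #", fs)
  expect_equal(rule_cost(r, cm), 4 + 3 + (2 + 1) + (2 + 1 + 1))
  # structurally identical rules cost the same
  expect_equal(rule_cost(parse_rule("∅ -> a / C _ C #", fs), cm),
               rule_cost(r, cm))
  # adding any literal strictly increases the cost
  r2 <- parse_rule("∅ -> a / C _ [-voice -vowel] #", fs)
  expect_gt(rule_cost(r2, cm), rule_cost(r, cm))
  expect_gt(rule_cost(parse_rule("∅ -> a / C _ C* #", fs), cm),
            rule_cost(r, cm)) # star surcharge
})

test_that("ablation flags reject the corresponding devices", {
  fs <- load_feature_system("articulatory")
  nostar <- cost_model(allow_star = FALSE)
  expect_error(rule_cost(parse_rule("∅ -> a / C* _ #", fs), nostar), "star")
  nofeat <- cost_model(allow_features = FALSE)
  expect_error(rule_cost(parse_rule("[-voice] -> ∅ / _ #", fs), nofeat),
               "feature")
  expect_error(cost_model(rule_base = -1), "positive")
})

test_that("objective is the negated description length, or INCONSISTENT", {
  fs <- plural_fs()
  # single-column toy: five plural forms, all regular in /z/
  X <- problem_data(tibble::tibble(
    stem_id = paste0("w", 1:5), inflection = "pl",
    form = c("dagz", "ragz", "zagz", "gazz", "dadz")))
  key <- bundle_key(inflection_bundle(infl = "pl"))
  stems_bare <- list(w1 = "dag", w2 = "rag", w3 = "zag", w4 = "gaz",
                     w5 = "dad")
  A <- lexicon(stems = stems_bare, suffixes = setNames(list("z"), key))
  B <- lexicon(stems = list(w1 = "dagz", w2 = "ragz", w3 = "zagz",
                            w4 = "gazz", w5 = "dadz"))
  oa <- objective(X, theory(), A, cm, fs)
  ob <- objective(X, theory(), B, cm, fs)
  expect_gt(oa, ob) # shared suffix beats whole-word memorization
  expect_equal(oa, -(15 * 3 + 3))
  # an inconsistent lexicon yields the sentinel, not a number
  bad <- lexicon(stems = stems_bare)
  expect_true(is_inconsistent(objective(X, theory(), bad, cm, fs)))
  # dropping a rule that never fires strictly improves the objective
  vac <- theory(parse_rule("∅ -> ә / ә _ ә", fs))
  expect_gt(oa, objective(X, vac, A, cm, fs))
})

test_that("stem_fit recovers underlying stems shortest-first", {
  fs <- serbo_fs()
  g <- serbo_grammar(fs)
  row <- problem_data(tibble::tibble(
    stem_id = "CLEAR", inflection = c("masc", "fem"),
    form = c("yasan", "yasna")))
  fit <- stem_fit(g$theory, g$lexicon, row, cm, fs,
                  alphabet = c("y", "a", "s", "n"), max_len = 4)
  expect_form(fit$stem, "yasn")
  expect_equal(fit$bits, 4 * 3)

  # plural grammar: /dag/ fits (dag, dagz)
  fs2 <- plural_fs()
  key <- bundle_key(inflection_bundle(infl = "pl"))
  affx <- lexicon(suffixes = setNames(list("z"), key))
  row2 <- problem_data(tibble::tibble(
    stem_id = "DOG", inflection = c("sg", "pl"), form = c("dag", "dagz")))
  fit2 <- stem_fit(theory(), affx, row2, cm, fs2,
                   alphabet = c("d", "a", "g", "z"), max_len = 4)
  expect_form(fit2$stem, "dag")

  # a row no stem can reach returns NULL
  row3 <- problem_data(tibble::tibble(
    stem_id = "X", inflection = c("sg", "pl"), form = c("dag", "rag")))
  expect_null(stem_fit(theory(), affx, row3, cm, fs2,
                       alphabet = c("d", "a", "g", "r", "z"), max_len = 4))
})

test_that("the stem-marginal bound is below the exact sum, tight for unique stems", {
  fs <- toy_fs(c("p", "a", "i"))
  ucm <- cost_model(phoneme_coding = "uniform")
  del <- theory(parse_rule("[+vowel] -> ∅ / _ #", fs))
  affx <- lexicon()
  # surface /p/ is reachable from stems p, pa, pi: bound strictly below sum
  X1 <- problem_data(tibble::tibble(stem_id = "n1", inflection = "base",
                                    form = "p"))
  lb <- likelihood_lower_bound(X1, del, affx, ucm, fs, max_len = 2)
  ex <- exact_stem_marginal(X1, del, affx, ucm, fs, max_len = 2)
  expect_lt(lb, ex)
  expect_equal(lb, -(1 * (log2(3) + 1) + 1) * log(2))
  # surface /pap/ pins the stem down uniquely: bound attains the sum
  X2 <- problem_data(tibble::tibble(stem_id = "n2", inflection = "base",
                                    form = "pap"))
  lb2 <- likelihood_lower_bound(X2, theory(), affx, ucm, fs, max_len = 3)
  ex2 <- exact_stem_marginal(X2, theory(), affx, ucm, fs, max_len = 3)
  expect_equal(lb2, ex2)
  # empty new data scores log(1) = 0
  expect_equal(likelihood_lower_bound(X1[0, ], del, affx, ucm, fs), 0)
  # unreachable data has log-probability -Inf
  X3 <- problem_data(tibble::tibble(stem_id = "n3", inflection = "base",
                                    form = "pp"))
  expect_identical(
    likelihood_lower_bound(X3, del, affx, ucm, fs, max_len = 1), -Inf)
})

test_that("the objective decomposes into prior and stem-likelihood terms", {
  fs <- serbo_fs()
  g <- serbo_grammar(fs)
  X <- problem_data(tibble::tibble(
    stem_id = "CLEAR", inflection = c("masc", "fem"),
    form = c("yasan", "yasna")))
  affixes <- lexicon(suffixes = g$lexicon$suffixes)
  fit <- stem_fit(g$theory, affixes, X, cm, fs,
                  alphabet = c("y", "a", "s", "n"), max_len = 4)
  L_full <- affixes
  L_full$stems[["CLEAR"]] <- fit$stem
  obj <- objective(X, g$theory, L_full, cm, fs)
  prior_bits <- theory_cost(g$theory, cm) + lexicon_cost(affixes, cm, fs)
  lik <- likelihood_lower_bound(X, g$theory, affixes, cm, fs,
                                alphabet = c("y", "a", "s", "n"), max_len = 4)
  expect_equal(obj * log(2), -prior_bits * log(2) + lik)
})

test_that("scores are invariant under row permutation", {
  fs <- plural_fs()
  key <- bundle_key(inflection_bundle(infl = "pl"))
  L <- lexicon(stems = list(w1 = "dag", w2 = "rag"),
               suffixes = setNames(list("z"), key))
  X <- problem_data(tibble::tibble(
    stem_id = c("w1", "w2"), inflection = "pl", form = c("dagz", "ragz")))
  Xr <- problem_data(tibble::as_tibble(X)[2:1, ], bundles = attr(X, "bundles"))
  expect_equal(objective(X, theory(), L, cm, fs),
               objective(Xr, theory(), L, cm, fs))
})
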