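test_that("problem files round-trip losslessly, preserving cell order", {
  X <- problem_data(tibble::tibble(
    stem_id = c("CLEAR", "CLEAR", "BANG", "BANG"),
    inflection = c("masc", "fem", "masc", "fem"),
    form = c("yasan", "yasna", "bob", "boba")),
    bundles = list(masc = inflection_bundle(gender = "M"),
                   fem = inflection_bundle(gender = "F")))
  path <- tempfile(fileext = ".json")
  write_problem(X, path)
  Y <- read_problem(path)
  expect_identical(Y$stem_id, X$stem_id)
  expect_identical(Y$inflection, X$inflection)
  expect_identical(Y$form, X$form)
  expect_identical(bundle_key(attr(Y, "bundles")$fem),
                   bundle_key(inflection_bundle(gender = "F")))
  # writing again is byte-stable (canonical form)
  path2 <- tempfile(fileext = ".json")
  write_problem(Y, path2)
  expect_identical(readLines(path), readLines(path2))
  unlink(c(path, path2))
})

test_that("unknown glyphs are reported by name on read", {
  X <- problem_data(tibble::tibble(stem_id = "W", inflection = "base",
                                   form = "pa"))
  path <- tempfile(fileext = ".json")
  write_problem(X, path)
  doc <- jsonlite::read_json(path)
  doc$rows[[1]]$cells$base <- "pQa"
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  fs <- toy_fs(c("p", "a"))
  expect_error(read_problem(path, fs), "Q")
  unlink(path)
})

test_that("allophony substitutions survive the round trip", {
  X <- problem_data(tibble::tibble(stem_id = "w1", inflection = "word",
                                   form = "bat"))
  attr(X, "substitution") <- substitution(b = "p")
  path <- tempfile(fileext = ".json")
  write_problem(X, path)
  Y <- read_problem(path)
  expect_identical(attr(Y, "substitution")$map, c(b = "p"))
  unlink(path)
})

test_that("grammar files carry notation, lexicon, costs and derivations", {
  fs <- serbo_fs()
  X <- problem_data(tibble::tibble(
    stem_id = c("CLEAR", "CLEAR"), inflection = c("masc", "fem"),
    form = c("yasan", "yasna")))
  cfg <- synthesis_config(cost_model(), max_rules = 1,
                          features = c("vowel"), allow_feature = FALSE,
                          allow_delete = FALSE, allow_star = FALSE,
                          allow_prefixes = FALSE, affix_source = "surface",
                          max_affix_len = 1, max_stem_len = 4)
  res <- exact_synthesize(X, cfg, fs)
  path <- tempfile(fileext = ".json")
  write_grammar(res, path)
  doc <- jsonlite::read_json(path)
  expect_true(length(doc$derivations) == nrow(X))
  expect_true(all(vapply(doc$derivations, function(d) {
    !is.null(d$underlying) && !is.null(d$surface)
  }, TRUE)))
  expect_identical(doc$cost_model$rule_base, cost_model()$rule_base)
  back <- read_grammar(path, fs)
  # the reloaded grammar scores identically
  expect_equal(objective(X, back$theory, back$lexicon, cost_model(), fs),
               res$objective)
  # and its derivation traces replay
  for (d in doc$derivations) {
    m <- meaning(d$stem_id, problem_bundle(X, d$inflection))
    tr <- derive(back$theory, back$lexicon, m, fs, trace = TRUE)
    expect_identical(form_string(tr$surface), d$surface)
    expect_identical(form_string(tr$underlying), d$underlying)
  }
  unlink(path)
})

test_that("the generator is reproducible and every sampled rule fires", {
  fs <- toy_fs(c("p", "b", "t", "d", "a", "i"))
  cfg <- synthesis_config(cost_model(), max_rules = 1,
                          features = c("voice", "vowel"), allow_star = FALSE,
                          allow_prefixes = FALSE, affix_source = "inventory",
                          max_stem_len = 4)
  p1 <- sample_problem(17, fs, cfg, n_rules = 1)
  p2 <- sample_problem(17, fs, cfg, n_rules = 1)
  expect_identical(p1$data$form, p2$data$form)
  expect_identical(format_rule(p1$theory$rules[[1]]),
                   format_rule(p2$theory$rules[[1]]))
  # the rule fires in at least one cell and stays silent in another cell of
  # the same lexeme (the generator's alternation guarantee)
  fired <- silent <- character()
  for (i in seq_len(nrow(p1$data))) {
    m <- meaning(p1$data$stem_id[i],
                 problem_bundle(p1$data, p1$data$inflection[i]))
    d <- derive(p1$theory, p1$lexicon, m, fs, trace = TRUE)
    if (identical(d$underlying, d$surface)) {
      silent <- c(silent, p1$data$stem_id[i])
    } else fired <- c(fired, p1$data$stem_id[i])
  }
  expect_true(length(intersect(fired, silent)) > 0)
  # a zero-rule spec emits pure concatenations
  p0 <- sample_problem(17, fs, cfg, n_rules = 0)
  for (i in seq_len(nrow(p0$data))) {
    m <- meaning(p0$data$stem_id[i],
                 problem_bundle(p0$data, p0$data$inflection[i]))
    expect_form(concatenate_morphology(p0$lexicon, m), p0$data$form[i])
  }
})

test_that("problem datasets written by the generator re-derive after reload", {
  fs <- toy_fs(c("p", "b", "t", "d", "a", "i"))
  cfg <- synthesis_config(cost_model(), max_rules = 1,
                          features = c("voice", "vowel"), allow_star = FALSE,
                          allow_prefixes = FALSE, affix_source = "inventory")
  pr <- sample_problem(23, fs, cfg, n_rules = 1)
  path <- tempfile(fileext = ".json")
  write_problem(pr$data, path)
  Y <- read_problem(path, fs)
  expect_true(check_consistency(pr$theory, pr$lexicon, Y, fs)$consistent)
  unlink(path)
})
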