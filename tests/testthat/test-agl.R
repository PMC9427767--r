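cfg_syl <- agl_config("syllabic")
cfg_seg <- agl_config("segmental")

test_that("stimuli match their templates, are distinct, and reproduce", {
  p <- agl_pattern("ABA")
  X <- generate_stimuli(p, 8, seed = 5, cfg_syl)
  expect_identical(nrow(X), 8L)
  expect_identical(anyDuplicated(X$form), 0L)
  fs <- cfg_syl$inventory$fs
  for (w in X$form) {
    sy <- vapply(syllabify(w, fs)$syllables, paste, "", collapse = "")
    expect_length(sy, 3)
    expect_identical(sy[1], sy[3])
    expect_false(sy[1] == sy[2])
  }
  # constant-syllable patterns hold x fixed
  Xx <- generate_stimuli(agl_pattern("AAx", x = "ko"), 6, seed = 9, cfg_syl)
  for (w in Xx$form) {
    sy <- vapply(syllabify(w, fs)$syllables, paste, "", collapse = "")
    expect_identical(sy[1], sy[2])
    expect_identical(sy[3], "ko")
    expect_false(sy[1] == "ko")
  }
  expect_identical(generate_stimuli(p, 5, seed = 3, cfg_syl)$form,
                   generate_stimuli(p, 5, seed = 3, cfg_syl)$form)
  expect_identical(nrow(generate_stimuli(p, 0, seed = 1, cfg_syl)), 0L)
})

test_that("the one-word ABB frontier holds both memorization and syllable copy", {
  X1 <- generate_stimuli(agl_pattern("ABB"), 1, seed = 7, cfg_syl)
  fr <- agl_pareto(X1, cfg_syl)
  expect_true("memorize" %in% fr$label)
  expect_true(any(grepl("copy\\(last,end\\)", fr$label)))
  # no frontier point dominates another
  for (i in seq_len(nrow(fr))) {
    expect_false(any(
      fr$parsimony_bits <= fr$parsimony_bits[i] &
        fr$fit_bits <= fr$fit_bits[i] &
        (fr$parsimony_bits < fr$parsimony_bits[i] |
           fr$fit_bits < fr$fit_bits[i])))
  }
})

test_that("the frontier equals an independent enumeration of the copy space", {
  X1 <- generate_stimuli(agl_pattern("ABB"), 1, seed = 7, cfg_syl)
  fr <- agl_pareto(X1, cfg_syl)
  # independent enumeration: all copy-rule sequences (<=2) x affix pairs,
  # consistency checked with the oracle rule applier, stems by direct search
  fs <- cfg_syl$inventory$fs
  pool <- phonosynth:::agl_rule_pool(cfg_syl)
  w <- X1$form[1]
  sylls <- vapply(syllabify(w, fs)$syllables, paste, "", collapse = "")
  # affix space (a declared bound shared with the package): the empty affix
  # plus edge substrings of the training words, up to two units
  pfxs <- list(character(), sylls[1], sylls[1:2])
  sfxs <- list(character(), sylls[3], sylls[2:3])
  dedup <- function(l) l[!duplicated(vapply(l, paste, "", collapse = "."))]
  pfxs <- dedup(pfxs); sfxs <- dedup(sfxs)
  ths <- lapply(oracle_theories(pool, 2), function(idx) pool[idx])
  pts <- list()
  for (th in ths) for (pfx in pfxs) for (sfx in sfxs) {
    # stems: contiguous syllable subsequences of the word
    best <- NULL
    subs <- c(list(character()))
    for (i in seq_along(sylls)) for (j in i:length(sylls)) {
      subs[[length(subs) + 1L]] <- sylls[i:j]
    }
    for (u in subs) {
      np <- length(pfx); ns <- length(sfx); len <- length(u) - np - ns
      if (len < 0 || len > cfg_syl$max_stem_units) next
      if (np && !identical(u[seq_len(np)], pfx)) next
      if (ns && !identical(u[seq(length(u) - ns + 1, length(u))], sfx)) next
      got <- paste(oracle_derive(th, tokenize_form(paste(u, collapse = ""),
                                                   fs), fs), collapse = "")
      if (got != w) next
      b <- len * cfg_syl$unit_bits + 1
      if (is.null(best) || b < best) best <- b
    }
    if (is.null(best)) next
    pars <- (if (length(th)) sum(vapply(th, rule_cost, 0,
                                        cm = cfg_syl$cost_model)) else 0) +
      (if (length(pfx)) length(pfx) * cfg_syl$unit_bits + 1 else 0) +
      (if (length(sfx)) length(sfx) * cfg_syl$unit_bits + 1 else 0)
    pts[[length(pts) + 1L]] <- c(pars, best)
  }
  m <- unique(do.call(rbind, pts))
  dom <- vapply(seq_len(nrow(m)), function(i) {
    any(m[, 1] <= m[i, 1] & m[, 2] <= m[i, 2] &
          (m[, 1] < m[i, 1] | m[, 2] < m[i, 2]))
  }, TRUE)
  oracle_pts <- m[!dom, , drop = FALSE]
  oracle_pts <- oracle_pts[order(oracle_pts[, 1], oracle_pts[, 2]), ,
                           drop = FALSE]
  got_pts <- unique(cbind(fr$parsimony_bits, fr$fit_bits))
  got_pts <- got_pts[order(got_pts[, 1], got_pts[, 2]), , drop = FALSE]
  expect_equal(unname(got_pts), unname(oracle_pts))
})

test_that("held-out scoring is a normalized Pareto marginal", {
  X3 <- generate_stimuli(agl_pattern("ABA"), 3, seed = 13, cfg_syl)
  fr <- agl_pareto(X3, cfg_syl)
  w <- 2^(-(fr$joint_bits - min(fr$joint_bits)))
  expect_equal(sum(w / sum(w)), 1)
  # an ABA test word scores above an ABB test word after ABA training
  aba <- generate_stimuli(agl_pattern("ABA"), 1, seed = 77, cfg_syl)
  abb <- generate_stimuli(agl_pattern("ABB"), 1, seed = 78, cfg_syl)
  expect_gt(score_heldout(X3, aba, cfg_syl, frontier = fr),
            score_heldout(X3, abb, cfg_syl, frontier = fr))
})

test_that("held-out word probabilities form a subprobability (tiny universe)", {
  inv <- agl_inventory(consonants = c("w", "f"), vowels = c("o", "e"))
  cfg <- agl_config("syllabic", inventory = inv)
  X <- problem_data(tibble::tibble(
    stem_id = c("t1", "t2"), inflection = "word",
    form = c("wofefe", "fewewe")))
  fr <- agl_pareto(X, cfg)
  sylls <- inv$syllables
  total <- 0
  for (a in sylls) for (b in sylls) for (c_ in sylls) {
    word <- paste0(a, b, c_)
    Xt <- problem_data(tibble::tibble(stem_id = "h", inflection = "word",
                                      form = word))
    total <- total + exp(score_heldout(X, Xt, cfg, frontier = fr))
  }
  expect_lte(total, 1)
})

test_that("log-odds are zero for identical pairs and positive for ABB at n=3", {
  X3 <- generate_stimuli(agl_pattern("ABB"), 3, seed = 21, cfg_syl)
  same <- generate_stimuli(agl_pattern("ABB"), 4, seed = 31, cfg_syl)$form
  lo0 <- log_odds(X3, same, same, cfg_syl)
  expect_equal(lo0$mean, 0)
  cons <- generate_stimuli(agl_pattern("ABB"), 15, seed = 41, cfg_syl)$form
  incons <- generate_stimuli(agl_pattern("ABA"), 15, seed = 42, cfg_syl)$form
  lo <- log_odds(X3, cons, incons, cfg_syl)
  expect_gt(lo$mean, 0)
  expect_identical(nrow(lo$pairs), 15L)
})

test_that("discrimination sharpens with training set size", {
  means <- vapply(c(1, 3, 6), function(n) {
    tr <- generate_stimuli(agl_pattern("AAx"), n, seed = 11, cfg_syl)
    cons <- generate_stimuli(agl_pattern("AAx"), 10, seed = 51, cfg_syl)$form
    incons <- generate_stimuli(agl_pattern("AxA"), 10, seed = 52, cfg_syl)$form
    log_odds(tr, cons, incons, cfg_syl)$mean
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("segmental learners discriminate given enough examples", {
  tr <- generate_stimuli(agl_pattern("ABB"), 6, seed = 19, cfg_seg)
  cons <- generate_stimuli(agl_pattern("ABB"), 15, seed = 61, cfg_seg)$form
  incons <- generate_stimuli(agl_pattern("ABA"), 15, seed = 62, cfg_seg)$form
  expect_gt(log_odds(tr, cons, incons, cfg_seg)$mean, 0)
  # with a single example the syllabic learner discriminates more sharply
  tr1 <- generate_stimuli(agl_pattern("ABB"), 1, seed = 19, cfg_syl)
  syl1 <- log_odds(tr1, cons, incons, cfg_syl)$mean
  seg1 <- log_odds(tr1, cons, incons, cfg_seg)$mean
  expect_gt(syl1, seg1)
})
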