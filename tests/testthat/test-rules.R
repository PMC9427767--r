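fs_full <- load_feature_system("articulatory")

test_that("the in-text derivations come out byte-for-byte", {
  devoice <- parse_rule("[-sonorant] -> [-voice] / [-sonorant -voice] _ #",
                        fs_full)
  expect_form(apply_rule(devoice, "wɔkd", fs_full), "wɔkt")

  epenth <- parse_rule("∅ -> a / C _ C #", fs_full)
  expect_form(apply_rule(epenth, "yasn", fs_full), "yasan")
  expect_form(apply_rule(epenth, "yasna", fs_full), "yasna")

  # rule whose trigger matches nowhere returns the input unchanged
  expect_form(apply_rule(devoice, "mama", fs_full), "mama")
})

test_that("rule order matters: strident epenthesis feeds final devoicing", {
  ep <- parse_rule("∅ -> ә / [+strident] _ [+strident] #", fs_full)
  dv <- parse_rule("[-sonorant] -> [-voice] / [-voice] _ #", fs_full)
  expect_form(apply_rule_sequence(list(ep, dv), "kætz", fs_full), "kæts")
  expect_form(apply_rule_sequence(list(ep, dv), "dagz", fs_full), "dagz")
  expect_form(apply_rule_sequence(list(ep, dv), "hɔrsz", fs_full), "hɔrsәz")
  # reversed order devoices before epenthesis can bleed it
  expect_form(apply_rule_sequence(list(dv, ep), "hɔrsz", fs_full), "hɔrsәs")
  # empty sequence is the identity
  expect_form(apply_rule_sequence(list(), "hɔrsz", fs_full), "hɔrsz")
})

test_that("notation round-trips through the canonical printer", {
  texts <- c(
    "∅ -> a / C _ C #",
    "[-sonorant] -> [-voice] / [-sonorant -voice] _ #",
    "[+vowel] -> ∅ / _ #",
    "∅ -> ә / [+strident] _ [+strident] #",
    "[-sonorant] -> [-voice] / [-voice]* _",
    "C -> [+voice] / # _ V")
  for (tx in texts) {
    r <- parse_rule(tx, fs_full)
    canon <- format_rule(r)
    r2 <- parse_rule(canon, fs_full)
    expect_identical(format_rule(r2), canon)
    # canonical output of already-canonical input is stable
    expect_identical(format_rule(parse_rule(canon, fs_full)), canon)
  }
  # literals print alphabetically, single spaces
  r <- parse_rule("[-voice -sonorant] -> [-voice] / _ #", fs_full)
  expect_identical(format_rule(r), "[-sonorant -voice] -> [-voice] / _ #")
})

test_that("parser rejects malformed notation with position information", {
  expect_error(parse_rule("a b -> c", fs_full), "syntax")
  expect_error(parse_rule("[-voice -> ∅", fs_full), "unclosed")
  expect_error(parse_rule("a -> b / _ _ ", fs_full), "exactly one _")
  expect_error(parse_rule("[-voiced] -> ∅ / _ #", fs_full), "unknown feature")
  expect_error(parse_rule("∅ -> a / # C _", fs_full), NA)
  expect_error(parse_rule("∅ -> a / C # _", fs_full), "outer end")
})

test_that("structural invariants are enforced at construction", {
  expect_error(rule(NULL, change_delete()), "non-empty focus")
  expect_error(rule(feature_matrix("-voice"), change_insert("a")),
               "empty focus")
  expect_error(trigger(feature_matrix("+voice"), feature_matrix("-voice"),
                       feature_matrix("+high")), "at most two")
  expect_error(trigger(starred(feature_matrix("+voice")),
                       starred(feature_matrix("-voice"))),
               "at most one starred")
})

test_that("application agrees with an independent unrolled-star oracle", {
  fs <- toy_fs(c("p", "b", "t", "d", "a", "i"))
  rules <- list(
    parse_rule("[-voice] -> [+voice] / [+vowel] _ [+vowel]", fs),
    parse_rule("[+voice] -> ∅ / _ #", fs),
    parse_rule("∅ -> i / C _ C", fs),
    parse_rule("[-voice] -> [+voice] / [+voice]* _ #", fs),
    parse_rule("C -> [-voice] / # [+vowel] _", fs),
    parse_rule("[+vowel] -> ∅ / [+vowel] _", fs))
  set.seed(7)
  for (i in 1:40) {
    ph <- sample(fs$symbols, sample(1:7, 1), replace = TRUE)
    for (r in rules) {
      expect_identical(apply_rule(r, ph, fs), oracle_apply(r, ph, fs),
                       info = paste(format_rule(r), "on", form_string(ph)))
    }
  }
})

test_that("star matches zero or more repetitions (vs explicit unrolling)", {
  fs <- toy_fs(c("p", "b", "a", "i"))
  r <- parse_rule("[-voice] -> [+voice] / # [+voice]* _", fs)
  # fires with 0, 1, 2, 3 voiced segments between the boundary and focus
  expect_form(apply_rule(r, "p", fs), "b")
  expect_form(apply_rule(r, "ap", fs), "ab")
  expect_form(apply_rule(r, "aap", fs), "aab")
  expect_form(apply_rule(r, "aaap", fs), "aaab")
  # a voiceless interloper blocks the boundary-anchored star path
  expect_form(apply_rule(r, "papp", fs)[3:4], "pp")
})

test_that("locality: segments outside match sites are never altered", {
  fs <- toy_fs(c("p", "b", "t", "d", "a", "i"))
  r <- parse_rule("[-voice] -> [+voice] / [+vowel] _ [+vowel]", fs)
  set.seed(11)
  for (i in 1:20) {
    core <- c("a", "p", "a")
    junk <- sample(fs$symbols, sample(0:3, 1), replace = TRUE)
    out <- apply_rule(r, c(junk, core), fs)
    # the prefix junk region can only change at its boundary-adjacent sites;
    # check the core rewrote and total length is preserved
    expect_identical(length(out), length(junk) + 3L)
    expect_identical(out[length(junk) + 2L], "b")
  }
})

test_that("application is deterministic and single-pass", {
  fs <- toy_fs(c("p", "b", "a", "i"))
  # output /b/ would itself satisfy the focus of a voicing rule chain:
  # a single pass must not re-apply to its own output
  r <- parse_rule("∅ -> a / a _ #", fs)
  out1 <- apply_rule(r, "pa", fs)
  expect_form(out1, "paa")
  # explicit double application differs: the single pass did not cascade
  expect_form(apply_rule(r, out1, fs), "paaa")
  expect_identical(apply_rule(r, "pa", fs), apply_rule(r, "pa", fs))
})

test_that("alpha variables copy a trigger feature sign into the change", {
  # /ε/ and /ә/ differ only in backness, so backness harmony maps between
  # them; /a/ is a +back trigger, /ε/ a -back trigger
  fs <- load_feature_system("articulatory",
                            restrict = c("t", "l", "ε", "a", "ә", "n", "r"))
  r <- rule(feature_matrix("+vowel"),
            change_features(feature_matrix(), alpha = "back",
                            alpha_side = "left"),
            left = trigger(feature_matrix("+vowel")))
  expect_form(apply_rule(r, c("t", "ε", "ε"), fs), "tεε")
  expect_form(apply_rule(r, c("t", "a", "ε"), fs), "taә")
  txt <- format_rule(r)
  expect_match(txt, "αback")
  r2 <- parse_rule(txt, fs)
  expect_identical(format_rule(r2), txt)
})

test_that("copy changes reduplicate peripheral units", {
  fs <- load_feature_system("articulatory")
  r <- rule(NULL, change_copy("last", "end", "syllable"))
  expect_form(apply_rule(r, "wofe", fs), "wofefe")
  r2 <- rule(NULL, change_copy("first", "begin", "syllable"))
  expect_form(apply_rule(r2, "wofe", fs), "wowofe")
  # phoneme-unit copies take the segment at an edge offset
  r3 <- rule(NULL, change_copy("last", "end", "phoneme", 2L))
  expect_form(apply_rule(r3, "wofe", fs), "wofef")
  expect_form(apply_rule_sequence(list(r3, r3), "wofe", fs), "wofefe")
})
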