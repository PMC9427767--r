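# Encoding of feature systems, rules and paradigm data for the C++ search
# kernel. Phonemes become 0-based integer ids; feature matrices become 64-bit
# sign masks (passed as doubles; feature count is capped well below the
# mantissa width) or literal phoneme ids.

fs_masks <- function(fs) {
  idx <- seq_along(fs$feature_names)
  names(idx) <- fs$feature_names
  mask <- function(feats) if (!length(feats)) 0 else sum(2^(idx[feats] - 1))
  list(plus = vapply(fs$plus, mask, 0),
       minus = vapply(fs$minus, mask, 0))
}

encode_form <- function(form, fs) {
  match(tokenize_form(form, fs), fs$symbols) - 1L
}

decode_form <- function(ids, fs) fs$symbols[ids + 1L]

# A pool of feature matrices shared by a rule set: deduplicates by signature
# and returns per-rule encodings referencing pool indices (0-based).
fm_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$sig <- character()
  env$plus <- numeric()
  env$minus <- numeric()
  env$phlit <- integer()
  env
}

fm_pool_add <- function(pool, fm, fs) {
  idx <- seq_along(fs$feature_names)
  names(idx) <- fs$feature_names
  if (fm_is_phoneme_literal(fm)) {
    sig <- paste0("ph:", fm$phoneme)
    p <- 0; m <- 0
    lit <- match(fm$phoneme, fs$symbols) - 1L
  } else {
    sign <- substr(fm$literals, 1, 1)
    feat <- sub("^[+-]", "", fm$literals)
    p <- if (any(sign == "+")) sum(2^(idx[feat[sign == "+"]] - 1)) else 0
    m <- if (any(sign == "-")) sum(2^(idx[feat[sign == "-"]] - 1)) else 0
    lit <- -1L
    sig <- paste0("fm:", p, ":", m)
  }
  hit <- match(sig, pool$sig)
  if (!is.na(hit)) return(hit - 1L)
  pool$sig <- c(pool$sig, sig)
  pool$plus <- c(pool$plus, p)
  pool$minus <- c(pool$minus, m)
  pool$phlit <- c(pool$phlit, lit)
  length(pool$sig) - 1L
}

kernel_rule_supported <- function(r) {
  ch <- r$change
  if (ch$kind == "copy") return(FALSE)
  if (ch$kind == "feature" && !is.null(ch$alpha)) return(FALSE)
  if (ch$kind == "insert" && length(ch$phonemes) > 2L) return(FALSE)
  TRUE
}

# 15-column integer encoding; see src/kernel.cpp for the layout
encode_rules <- function(rules, fs, cm) {
  pool <- fm_pool()
  enc <- matrix(-1L, nrow = length(rules), ncol = 15L)
  bits <- numeric(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!kernel_rule_supported(r)) {
      stop("rule not supported by the search kernel: ", format_rule(r))
    }
    validate_rule(r, fs)
    bits[i] <- rule_cost(r, cm)
    if (!is.null(r$focus)) enc[i, 1] <- fm_pool_add(pool, r$focus, fs)
    ch <- r$change
    enc[i, 2] <- switch(ch$kind, feature = 0L, delete = 1L, insert = 2L)
    if (ch$kind == "feature") enc[i, 3] <- fm_pool_add(pool, ch$fm, fs)
    if (ch$kind == "insert") {
      ids <- match(ch$phonemes, fs$symbols) - 1L
      enc[i, 4] <- ids[1]
      if (length(ids) > 1L) enc[i, 5] <- ids[2]
    }
    le <- r$left$elements
    if (length(le) == 1L) {
      enc[i, 8] <- fm_pool_add(pool, le[[1]]$fm, fs)   # adjacent slot
      enc[i, 9] <- as.integer(le[[1]]$star)
    } else if (length(le) == 2L) {
      enc[i, 6] <- fm_pool_add(pool, le[[1]]$fm, fs)   # outer
      enc[i, 7] <- as.integer(le[[1]]$star)
      enc[i, 8] <- fm_pool_add(pool, le[[2]]$fm, fs)
      enc[i, 9] <- as.integer(le[[2]]$star)
    }
    enc[i, 10] <- as.integer(r$left$boundary)
    re <- r$right$elements
    if (length(re) >= 1L) {
      enc[i, 11] <- fm_pool_add(pool, re[[1]]$fm, fs)  # adjacent
      enc[i, 12] <- as.integer(re[[1]]$star)
    }
    if (length(re) == 2L) {
      enc[i, 13] <- fm_pool_add(pool, re[[2]]$fm, fs)
      enc[i, 14] <- as.integer(re[[2]]$star)
    }
    enc[i, 15] <- as.integer(r$right$boundary)
  }
  list(enc = enc, bits = bits,
       fm_plus = pool$plus, fm_minus = pool$minus, fm_phlit = pool$phlit)
}

# Per-column affix candidates; `pairs` is a list of list(pfx=, sfx=) phoneme
# vectors in deterministic order (cheapest first).
kernel_data <- function(X, affix_pairs, cm, fs,
                        stem_alphabet = fs$symbols,
                        max_stem_len = cm$max_stem_len,
                        fixed_stems = NULL) {
  lexemes <- problem_lexemes(X)
  infls <- unique(X$inflection)
  cells <- vector("list", length(lexemes) * length(infls))
  for (i in seq_len(nrow(X))) {
    r <- match(X$stem_id[i], lexemes) - 1L
    c_ <- match(X$inflection[i], infls) - 1L
    cells[[r * length(infls) + c_ + 1L]] <- encode_form(X$form[i], fs)
  }
  unit <- per_unit_bits(cm, length(stem_alphabet))
  affix_unit <- per_unit_bits(cm, length(fs$symbols))
  cands <- lapply(infls, function(infl) {
    prs <- affix_pairs[[infl]]
    list(pfx = lapply(prs, function(p) match(p$pfx, fs$symbols) - 1L),
         sfx = lapply(prs, function(p) match(p$sfx, fs$symbols) - 1L),
         bits = vapply(prs, function(p) {
           (length(p$pfx) + length(p$sfx)) * affix_unit
         }, 0))
  })
  names(cands) <- NULL
  list(nrows = length(lexemes), ncols = length(infls), cells = cells,
       affix_cands = cands, nphon = length(fs$symbols),
       stem_alphabet = match(stem_alphabet, fs$symbols) - 1L,
       max_stem_len = as.integer(max_stem_len), unit_bits = unit,
       fixed_stems = !is.null(fixed_stems),
       stems_fixed = if (!is.null(fixed_stems)) {
         lapply(lexemes, function(l) match(fixed_stems[[l]], fs$symbols) - 1L)
       } else list(),
       lexemes = lexemes, inflections = infls)
}

kernel_call <- function(fun, rules, data, fs, cm, ...) {
  masks <- fs_masks(fs)
  re <- encode_rules(rules, fs, cm)
  fun(length(fs$symbols), masks$plus, masks$minus, re$fm_plus, re$fm_minus,
      re$fm_phlit, re$enc, re$bits, data, ...)
}

# Rebuild R-level grammar objects from a kernel result
kernel_result_grammar <- function(res, rules, data, X, fs) {
  th <- theory(rules[res$best$theory + 1L])
  stems <- setNames(lapply(res$best$stems, decode_form, fs = fs),
                    data$lexemes)
  prefixes <- list()
  suffixes <- list()
  bundles <- attr(X, "bundles")
  for (ci in seq_along(data$inflections)) {
    infl <- data$inflections[ci]
    a <- res$best$affix_choice[ci] + 1L
    key <- bundle_key(bundles[[infl]])
    pfx <- decode_form(data$affix_cands[[ci]]$pfx[[a]], fs)
    sfx <- decode_form(data$affix_cands[[ci]]$sfx[[a]], fs)
    if (length(pfx)) prefixes[[key]] <- pfx
    if (length(sfx)) suffixes[[key]] <- sfx
  }
  L <- lexicon(stems, prefixes, suffixes)
  list(theory = th, lexicon = L)
}
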