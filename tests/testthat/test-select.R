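# token filters and AUC ranking

test_that("rare-token filter uses the global abstract count with boundary at 2", {
  world <- small_sim()
  fm <- world$fm
  tot <- Matrix::rowSums(fm$df)
  kept <- eliminate_rare(fm, min_abstracts = 2)
  expect_setequal(setdiff(rownames(fm$df), kept), names(tot)[tot < 2])
  # a token in exactly 2 abstracts survives; min_abstracts = 0 keeps all
  expect_true(all(names(tot)[tot == 2] %in% kept))
  expect_setequal(eliminate_rare(fm, min_abstracts = 0), rownames(fm$df))
})

test_that("common-token filter removes r2 > cutoff, keeps zero variance, skips tiny universes", {
  # constructed matrix: token "lin" has cdf exactly proportional to N_d
  # (r2 = 1), "flat" is constant (zero variance), "noise" uncorrelated
  n_d <- c(d1 = 10, d2 = 20, d3 = 30, d4 = 40)
  scores <- Matrix::Matrix(rbind(
    lin = n_d / 50,
    flat = rep(0.5, 4),
    noise = c(0.9, 0.1, 0.8, 0.2)), sparse = TRUE)
  colnames(scores) <- names(n_d)
  fm <- structure(list(measure = "cdf", scores = scores,
                       df = scores, n_abstracts = n_d,
                       total_tokens = n_d * 100), class = "freq_matrix")
  kept <- eliminate_common(fm, r2_cutoff = 0.33)
  expect_false("lin" %in% kept)
  expect_true(all(c("flat", "noise") %in% kept))

  # prescribed correlation just under / over the cutoff
  r2_of <- function(x) cor(x, n_d)^2
  lo <- c(0.2, 0.4, 0.38, 0.62)   # r2 ~ 0.80 -> removed
  expect_gt(r2_of(lo), 0.33)
  hi <- c(0.4, 0.2, 0.6, 0.5)     # r2 ~ 0.16 -> retained
  expect_lt(r2_of(hi), 0.33)
  scores2 <- Matrix::Matrix(rbind(over = lo, under = hi), sparse = TRUE)
  colnames(scores2) <- names(n_d)
  fm2 <- structure(list(measure = "cdf", scores = scores2, df = scores2,
                        n_abstracts = n_d, total_tokens = n_d),
                   class = "freq_matrix")
  kept2 <- eliminate_common(fm2, r2_cutoff = 0.33)
  expect_identical(kept2, "under")

  # fewer than 3 drugs: screen is skipped with a warning
  fm3 <- structure(list(measure = "cdf",
                        scores = scores[, 1:2], df = scores[, 1:2],
                        n_abstracts = n_d[1:2], total_tokens = n_d[1:2]),
                   class = "freq_matrix")
  expect_warning(kept3 <- eliminate_common(fm3), "skipped")
  expect_setequal(kept3, rownames(scores))
})

test_that("filters are monotone in their parameters", {
  world <- small_sim()
  fm <- world$fm
  v2 <- eliminate_rare(fm, min_abstracts = 2)
  v5 <- eliminate_rare(fm, min_abstracts = 5)
  expect_true(all(v5 %in% v2))
  c33 <- eliminate_common(fm, r2_cutoff = 0.33)
  c10 <- eliminate_common(fm, r2_cutoff = 0.10)
  expect_true(all(c10 %in% c33))
})

test_that("token_auc matches hand counts and handles ties", {
  lab <- characteristic_labels("c", c("p1", "p2"), c("p1", "p2", "n1", "n2"))
  expect_equal(token_auc(c(p1 = 0.9, p2 = 0.8, n1 = 0.1, n2 = 0.2), lab), 1)
  expect_equal(token_auc(c(p1 = 0, p2 = 0, n1 = 0, n2 = 0), lab), 0.5)
  lab2 <- characteristic_labels("c", c("p1", "p2"), c("p1", "p2", "n1"))
  # one win (0.8 > 0.5), one loss (0.2 < 0.5): AUC 0.5
  expect_equal(token_auc(c(p1 = 0.8, p2 = 0.2, n1 = 0.5), lab2), 0.5)
  # drugs missing from the score map enter at 0 (tied with each other)
  expect_equal(token_auc(c(p1 = 0.3), lab2), 0.75)
  expect_error(token_auc(c(a = 1), characteristic_labels("c", "a", "a")),
               "undefined")
})

test_that("token_auc equals the brute-force pairwise count on random instances", {
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    drugs <- paste0("d", seq_len(n))
    npos <- sample(seq_len(n - 1), 1)
    pos <- sample(drugs, npos)
    scores <- setNames(round(runif(n), 1), drugs)  # coarse grid forces ties
    keep <- runif(n) < 0.8                          # some drugs unscored
    lab <- characteristic_labels("c", pos, drugs)
    expect_equal(token_auc(scores[keep], lab),
                 brute_auc(scores[keep], pos, drugs))
  }
})

test_that("token_auc is invariant under strictly increasing transforms", {
  set.seed(302)
  drugs <- paste0("d", 1:20)
  lab <- characteristic_labels("c", drugs[1:6], drugs)
  s <- setNames(runif(20), drugs)
  a0 <- token_auc(s, lab)
  expect_equal(token_auc(exp(3 * s), lab), a0)
  expect_equal(token_auc(rank(s), lab), a0)
})

test_that("token_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(303)
  drugs <- paste0("d", 1:30)
  lab <- characteristic_labels("c", drugs[1:10], drugs)
  s <- setNames(round(runif(30), 1), drugs)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = drugs %in% lab$positives, predictor = s, quiet = TRUE,
    direction = "<")))
  expect_equal(token_auc(s, lab), ref)
})

test_that("rank_tokens sorts by AUC with lexicographic tie-break", {
  world <- small_sim()
  fm <- world$fm
  lab <- world$sim$labels$c1
  vocab <- eliminate_common(fm, vocab = eliminate_rare(fm))
  rk <- rank_tokens(fm, lab, top_n = 20, vocab = vocab)
  expect_lte(nrow(rk), 20)
  expect_true(all(diff(rk$auc) <= 0))
  ties <- split(rk$token, rk$auc)
  for (grp in ties) expect_identical(grp, sort(grp))

  # exhaustive oracle: brute-force sort over token_auc of every token
  sub_vocab <- sort(sample(vocab, 50))
  rk_all <- rank_tokens(fm, lab, top_n = 50, vocab = sub_vocab)
  brute <- sapply(sub_vocab, function(w) {
    col <- fm$scores[w, lab$universe]
    token_auc(col[col != 0], lab)
  })
  ord <- order(-brute, sub_vocab)
  expect_identical(rk_all$token, sub_vocab[ord])
  expect_equal(rk_all$auc, unname(brute[ord]))
})

test_that("rank_tokens warns on small or empty vocabularies", {
  world <- small_sim()
  lab <- world$sim$labels$c1
  expect_warning(rk <- rank_tokens(world$fm, lab, top_n = 20,
                                   vocab = rownames(world$fm$scores)[1:3]),
                 "only 3 tokens")
  expect_equal(nrow(rk), 3L)
  expect_warning(rk0 <- rank_tokens(world$fm, lab, vocab = character(0)),
                 "empty vocabulary")
  expect_equal(nrow(rk0), 0L)
})

test_that("planted signal tokens outrank background and reach AUC 1", {
  world <- small_sim()
  rk <- rank_tokens(world$fm, world$sim$labels$c1, top_n = 10,
                    vocab = eliminate_common(world$fm,
                                             vocab = eliminate_rare(world$fm)))
  sig <- world$sim$manifest$characteristics$c1$signal_tokens
  expect_gte(sum(rk$token %in% sig), 8)
  expect_equal(rk$auc[1], 1)
})

test_that("index keyword percentile reports rank, elimination and absence", {
  world <- small_sim()
  fm <- world$fm
  lab <- world$sim$labels$c1
  sig <- world$sim$manifest$characteristics$c1$signal_tokens[1]
  res <- index_keyword_percentile(fm, lab, sig)
  expect_identical(res$status, "ranked")
  expect_equal(res$percentile, 100 * res$rank / res$n_ranked)
  expect_lte(res$percentile, 1)  # a perfect token sits within the top percentile
  common <- world$sim$manifest$common_tokens[1]
  expect_identical(index_keyword_percentile(fm, lab, common)$status,
                   "eliminated")
  expect_identical(index_keyword_percentile(fm, lab, "neverseen")$status,
                   "absent")
})
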