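ALGOS <- c("NB", "IBk", "SVM_linear", "SVM_rbf")

# labeled feature table straight from matrices (bypasses ranking)
toy_table <- function(x, y, measure = "cdf") {
  structure(list(x = x, y = y, tokens = colnames(x), measure = measure),
            class = "feature_table")
}

sep_table <- function() {
  x <- matrix(c(rep(1, 5), rep(0, 5), rep(0.9, 5), rep(0.1, 5)), ncol = 2,
              dimnames = list(paste0("d", 1:10), c("t1", "t2")))
  toy_table(x, rep(c(TRUE, FALSE), each = 5))
}

test_that("every algorithm separates a linearly separable toy table", {
  tab <- sep_table()
  for (alg in ALGOS) {
    model <- drug_classifier(tab, alg, seed = 5)
    s <- predict(model, tab)
    expect_equal(drugchar:::.auc_from_scores(s, tab$y), 1, info = alg)
  }
})

test_that("training is deterministic given the seed", {
  tab <- sep_table()
  for (alg in ALGOS) {
    s1 <- predict(drug_classifier(tab, alg, seed = 9), tab)
    s2 <- predict(drug_classifier(tab, alg, seed = 9), tab)
    expect_identical(s1, s2, info = alg)
  }
})

test_that("single-class tables and feature mismatches are refused", {
  tab <- sep_table()
  bad <- toy_table(tab$x, rep(TRUE, 10))
  expect_error(drug_classifier(bad, "NB"), "both classes")
  model <- drug_classifier(tab, "NB")
  other <- toy_table(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                     c("t1", "zzz"))),
                     NULL)
  expect_error(predict(model, other), "zzz")
})

test_that("NB posterior matches the closed-form Gaussian Bayes rule", {
  # one feature, two classes; known means/variances; flat structure lets the
  # posterior be written out exactly
  x <- matrix(c(0.1, 0.3, 0.2, 0.8, 0.6, 0.7), ncol = 1,
              dimnames = list(paste0("d", 1:6), "t"))
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  model <- drug_classifier(toy_table(x, y), "NB")
  xs <- c(0.15, 0.5, 0.75)
  mu_p <- mean(x[y, 1]); v_p <- max(var(x[y, 1]), 1e-6)
  mu_n <- mean(x[!y, 1]); v_n <- max(var(x[!y, 1]), 1e-6)
  lp <- dnorm(xs, mu_p, sqrt(v_p), log = TRUE) + log(0.5)
  ln <- dnorm(xs, mu_n, sqrt(v_n), log = TRUE) + log(0.5)
  expected <- 1 / (1 + exp(ln - lp))
  newtab <- toy_table(matrix(xs, ncol = 1,
                             dimnames = list(paste0("q", 1:3), "t")), NULL)
  expect_equal(unname(predict(model, newtab)), expected, tolerance = 1e-9)
})

test_that("NB survives constant feature columns via the variance floor", {
  x <- cbind(t1 = c(1, 1, 1, 0, 0, 0), t2 = rep(0.4, 6))
  rownames(x) <- paste0("d", 1:6)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  model <- drug_classifier(toy_table(x, y), "NB")
  s <- predict(model, toy_table(x, NULL))
  expect_true(all(is.finite(s)))
  expect_true(all(s[1:3] > s[4:6]))
})

test_that("NB score for an all-zero drug is the prior-dominated posterior", {
  x <- matrix(c(0.4, 0.6, 0.4, 0.6, 0.4, 0.6,
                0.6, 0.8, 0.2, 0.4, 0.2, 0.4),
              ncol = 2, dimnames = list(paste0("d", 1:6), c("t1", "t2")))
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)  # prior P(pos) = 1/3
  model <- drug_classifier(toy_table(x, y), "NB")
  zero <- toy_table(matrix(0, 1, 2, dimnames = list("z", c("t1", "t2"))), NULL)
  loglik <- function(rows, prior) {
    mu <- colMeans(x[rows, , drop = FALSE])
    v <- pmax(apply(x[rows, , drop = FALSE], 2, var), 1e-6)
    sum(dnorm(0, mu, sqrt(v), log = TRUE)) + log(prior)
  }
  lp <- loglik(y, 1 / 3)
  ln <- loglik(!y, 2 / 3)
  expect_equal(unname(predict(model, zero)), 1 / (1 + exp(ln - lp)),
               tolerance = 1e-9)
})

test_that("IBk with k = 1 reproduces nearest-neighbour labels", {
  x <- matrix(c(0, 0.1, 0.9, 1, 0.05, 0.95), ncol = 1,
              dimnames = list(paste0("d", 1:6), "t"))
  y <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  model <- drug_classifier(toy_table(x, y), "IBk")
  model$fit$k <- 1L
  s <- predict(model, toy_table(x, NULL))
  expect_equal(unname(s), as.numeric(y))  # zero-distance self-match
  q <- toy_table(matrix(c(0.02, 0.97), ncol = 1,
                        dimnames = list(c("q1", "q2"), "t")), NULL)
  expect_equal(unname(predict(model, q)), c(0, 1))
})

test_that("IBk inverse-distance weights follow the hand computation", {
  # 5 training rows on a line; query at 0.3 with k = 3 neighbours
  x <- matrix(c(0, 0.2, 0.4, 0.8, 1), ncol = 1,
              dimnames = list(paste0("d", 1:5), "t"))
  y <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
  model <- drug_classifier(toy_table(x, y), "IBk")
  model$fit$k <- 3L
  q <- toy_table(matrix(0.3, 1, 1, dimnames = list("q", "t")), NULL)
  # neighbours: 0.2 (d=0.1, y=1), 0.4 (d=0.1, y=1), 0 (d=0.3, y=0)
  w <- c(10, 10, 10 / 3)
  expect_equal(unname(predict(model, q)), sum(w * c(1, 1, 0)) / sum(w))
  # duplicating a positive-typical row cannot lower the query's score
  x2 <- rbind(x, d6 = 0.35)
  y2 <- c(y, TRUE)
  model2 <- drug_classifier(toy_table(x2, y2), "IBk")
  model2$fit$k <- 4L
  expect_gte(unname(predict(model2, q)), unname(predict(model, q)))
})

test_that("internal k search picks small k on locally structured data", {
  set.seed(77)
  x <- matrix(c(runif(30, 0, 0.3), runif(30, 0.7, 1)), ncol = 1,
              dimnames = list(paste0("d", 1:60), "t"))
  y <- rep(c(FALSE, TRUE), each = 30)
  model <- drug_classifier(toy_table(x, y), "IBk", seed = 3)
  expect_true(model$hyper$k %in% 1:10)
  expect_equal(unname(predict(model, toy_table(x, NULL))[1]), 0)
})

test_that("SVM decision values are row-order invariant and oriented", {
  tab <- sep_table()
  perm <- sample(nrow(tab$x))
  ptab <- toy_table(tab$x[perm, ], tab$y[perm])
  for (alg in c("SVM_linear", "SVM_rbf")) {
    m1 <- drug_classifier(tab, alg, seed = 2)
    m2 <- drug_classifier(ptab, alg, seed = 2)
    s1 <- predict(m1, tab)
    s2 <- predict(m2, tab)
    expect_equal(s1, s2, tolerance = 1e-8, info = alg)
    expect_true(all(s1[1:5] > s1[6:10]), info = alg)  # positives on top
  }
})

test_that("ctf-scale features are standardized for SVMs and replayed at predict", {
  set.seed(21)
  x <- matrix(rexp(40, rate = 100), ncol = 2,
              dimnames = list(paste0("d", 1:20), c("t1", "t2")))
  x[1:10, 1] <- x[1:10, 1] + 0.05
  y <- rep(c(TRUE, FALSE), each = 10)
  model <- drug_classifier(toy_table(x, y, measure = "ctf"), "SVM_rbf")
  expect_false(is.null(model$scaling))
  s1 <- predict(model, toy_table(x, NULL, measure = "ctf"))
  s2 <- predict(model, toy_table(x, NULL, measure = "ctf"))
  expect_identical(s1, s2)
})

test_that("models are serializable and reload-stable", {
  tab <- sep_table()
  for (alg in ALGOS) {
    model <- drug_classifier(tab, alg, seed = 4)
    path <- withr::local_tempfile(fileext = ".rds")
    saveRDS(model, path)
    expect_equal(predict(readRDS(path), tab), predict(model, tab),
                 info = alg)
  }
})

test_that("cross-validated AUC on permuted labels stays near chance", {
  set.seed(88)
  n <- 200
  x <- matrix(runif(n * 5), ncol = 5,
              dimnames = list(paste0("d", 1:n), paste0("t", 1:5)))
  y <- sample(rep(c(TRUE, FALSE), c(30, n - 30)))
  fold <- sample(rep_len(1:5, n))
  s <- numeric(n)
  for (f in 1:5) {
    m <- drug_classifier(toy_table(x[fold != f, ], y[fold != f]), "NB")
    s[fold == f] <- predict(m, toy_table(x[fold == f, , drop = FALSE], NULL))
  }
  auc <- drugchar:::.auc_from_scores(s, y)
  se <- hanley_mcneil_se(0.5, 30, n - 30)
  expect_lt(abs(auc - 0.5), 3 * se)
})
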