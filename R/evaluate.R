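# Stratified cross-validation with leakage-free per-fold feature selection.
#
# For a characteristic with |C| >= 10 positives: five cycles of stratified
# 10-fold cross-validation. With 2 <= |C| < 10 positives the number of folds
# is reduced to |C| (one cycle), so every test fold holds exactly one
# positive. Characteristics with fewer than 2 positives are refused with an
# explicit non-evaluable status: no fold scheme keeps both a positive in
# training and a positive in testing.
#
# Inside every training split the whole selection pipeline is re-run: rare
# and common token elimination (the correlation screen uses no labels, but is
# still recomputed per split for strict hygiene) and AUC ranking over
# training drugs only. One ROC AUC is computed per cycle from the pooled
# test-fold scores, and the arithmetic mean over cycles is the headline
# estimate; per-fold AUCs are kept for audit. The Hanley-McNeil closed form
# provides the standard error, and significance is the one-sided z-test at
# alpha = 0.05 against AUC = 0.5.

#' Stratified fold plan for a characteristic
#'
#' Label, randomise, stratify: positives and negatives are shuffled
#' independently and dealt round-robin into folds, so per-fold positive
#' counts differ by at most one. With \eqn{|C| \ge 10}, 5 cycles of 10 folds;
#' with \eqn{2 \le |C| < 10}, one cycle of \eqn{|C|} folds (one positive per
#' test fold). Reproducible from \code{seed} (cycle seeds are drawn once from
#' the master seed).
#'
#' @param labels a [characteristic_labels()] object with at least 2
#'   positives and at least one negative.
#' @param seed master integer seed.
#' @return object of class \code{fold_plan}: list with \code{cycles} (list of
#'   named integer vectors drug -> fold), \code{n_folds}, \code{n_cycles},
#'   \code{seed}.
#' @export
make_fold_plan <- function(labels, seed = 1L) {
  stopifnot(inherits(labels, "characteristic_labels"))
  np <- length(labels$positives)
  nn <- length(labels$universe) - np
  if (np < 2L) {
    stop(structure(class = c("drugchar_non_evaluable", "error", "condition"),
                   list(message = paste0(
                     "characteristic '", labels$characteristic_id,
                     "' is non-evaluable: ", np, " positive example(s); ",
                     "at least 2 are required"),
                     call = sys.call(-1L))))
  }
  if (nn < 1L) stop("no negative drugs: nothing to discriminate")
  if (np >= 10L) {
    n_folds <- 10L
    n_cycles <- 5L
  } else {
    n_folds <- np
    n_cycles <- 1L
  }
  set.seed(seed)
  cycle_seeds <- sample.int(2147483646L, n_cycles)
  pos <- labels$positives
  neg <- setdiff(labels$universe, pos)
  cycles <- lapply(cycle_seeds, function(cs) {
    set.seed(cs)
    fold <- c(
      stats::setNames(rep_len(seq_len(n_folds), length(pos)), sample(pos)),
      stats::setNames(rep_len(seq_len(n_folds), length(neg)), sample(neg))
    )
    fold[labels$universe]
  })
  structure(list(characteristic_id = labels$characteristic_id,
                 cycles = cycles, n_folds = n_folds, n_cycles = n_cycles,
                 seed = seed, cycle_seeds = cycle_seeds),
            class = "fold_plan")
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed form for the standard error of a ROC area \eqn{A} estimated from
#' \code{n_pos} positive and \code{n_neg} negative cases:
#' \deqn{Q_1 = A/(2-A), \quad Q_2 = 2A^2/(1+A),}
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_{pos}-1)(Q_1-A^2) +
#'   (n_{neg}-1)(Q_2-A^2)}{n_{pos} \, n_{neg}}}.}
#'
#' @param auc area under the ROC curve, in \eqn{[0, 1]}.
#' @param n_pos,n_neg class sizes (each at least 1).
#' @return the standard error (non-negative).
#' @examples
#' hanley_mcneil_se(1, 10, 50)        # 0: no variance at perfect separation
#' hanley_mcneil_se(0.5, 1, 1)        # 0.5: a single Bernoulli pair
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (!is.numeric(auc) || auc < 0 || auc > 1) {
    stop("auc must lie in [0, 1]")
  }
  stopifnot(n_pos >= 1, n_neg >= 1)
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' Cross-validated performance of one algorithm on one characteristic
#'
#' Runs the full pipeline under the fold plan of [make_fold_plan()]: inside
#' every training split, rare and common tokens are eliminated and the
#' surviving tokens ranked by AUC using \emph{training drugs only}; the
#' top-\code{top_n} token scores train the classifier, which then scores the
#' held-out fold. Test scores are pooled within each cycle into one ROC AUC;
#' the mean over cycles, its Hanley-McNeil standard error (at
#' \code{n_pos = |C|}, \code{n_neg = |D\\C|}) and the one-sided significance
#' flag (\code{mean_auc - 1.645 se > 0.5}) are returned.
#'
#' \code{leak_features = TRUE} deliberately selects features once on all
#' drugs and labels (including test folds) before cross-validating — the
#' classic information-leakage bug, kept as a diagnostic mode to demonstrate
#' and regression-test the cost of skipping per-fold selection. Never use it
#' for reported results.
#'
#' @param fm a [frequency_matrix()] result covering the labels' universe.
#' @param labels a [characteristic_labels()] object.
#' @param algorithm one of \code{"NB"}, \code{"IBk"}, \code{"SVM_linear"},
#'   \code{"SVM_rbf"}.
#' @param top_n number of token features (default 20).
#' @param seed master seed (fold plan and classifier seeds derive from it).
#' @param min_abstracts,r2_cutoff elimination parameters.
#' @param leak_features diagnostic mode, see above.
#' @return object of class \code{cv_result}.
#' @export
cross_validate <- function(fm, labels, algorithm = .ALGORITHMS, top_n = 20,
                           seed = 1L, min_abstracts = 2, r2_cutoff = 0.33,
                           leak_features = FALSE) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(fm, "freq_matrix"), inherits(labels, "characteristic_labels"))
  plan <- make_fold_plan(labels, seed)
  d <- labels$universe
  y <- d %in% labels$positives

  leak_tokens <- NULL
  if (leak_features) {
    vocab <- eliminate_common(fm, r2_cutoff,
                              vocab = eliminate_rare(fm, min_abstracts))
    leak_tokens <- rank_tokens(fm, labels, top_n, vocab)$token
  }

  cycle_aucs <- numeric(plan$n_cycles)
  fold_aucs <- matrix(NA_real_, plan$n_cycles, plan$n_folds)
  selected <- vector("list", plan$n_cycles)
  for (cy in seq_len(plan$n_cycles)) {
    fold <- plan$cycles[[cy]]
    pooled <- stats::setNames(rep(NA_real_, length(d)), d)
    selected[[cy]] <- vector("list", plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      train <- d[fold != f]
      test <- d[fold == f]
      stopifnot(any(train %in% labels$positives))  # fold-plan invariant
      if (leak_features) {
        tokens <- leak_tokens
      } else {
        sub <- .subset_freq_matrix(fm, train)
        vocab <- eliminate_common(sub, r2_cutoff,
                                  vocab = eliminate_rare(sub, min_abstracts))
        tr_labels <- characteristic_labels(
          labels$characteristic_id,
          intersect(labels$positives, train), train)
        tokens <- rank_tokens(sub, tr_labels, top_n, vocab)$token
      }
      selected[[cy]][[f]] <- tokens
      tab_all <- feature_table(fm, tokens, labels)
      tr_tab <- .subset_feature_table(tab_all, train)
      te_tab <- .subset_feature_table(tab_all, test)
      model <- drug_classifier(tr_tab, algorithm,
                               seed = plan$cycle_seeds[cy] %% 1000000L + f)
      sc <- predict(model, te_tab)
      pooled[test] <- sc
      te_y <- test %in% labels$positives
      fold_aucs[cy, f] <- .auc_from_scores(sc, te_y)
    }
    cycle_aucs[cy] <- .auc_from_scores(pooled, y)
  }
  mean_auc <- mean(cycle_aucs)
  se <- hanley_mcneil_se(mean_auc, sum(y), sum(!y))
  structure(list(characteristic_id = labels$characteristic_id,
                 algorithm = algorithm, measure = fm$measure,
                 cycle_aucs = cycle_aucs, fold_aucs = fold_aucs,
                 mean_auc = mean_auc, se = se,
                 significant = (mean_auc - 1.645 * se) > 0.5,
                 n_pos = sum(y), n_neg = sum(!y),
                 selected_tokens = selected, top_n = top_n, seed = seed,
                 leak_features = leak_features),
            class = "cv_result")
}

.subset_feature_table <- function(tab, drugs) {
  idx <- match(drugs, rownames(tab$x))
  structure(list(x = tab$x[idx, , drop = FALSE],
                 y = if (is.null(tab$y)) NULL else tab$y[idx],
                 tokens = tab$tokens, measure = tab$measure),
            class = "feature_table")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation '", x$characteristic_id, "' [", x$algorithm, ", ",
      x$measure, "]\n", sep = "")
  cat(sprintf("  mean AUC %.3f (HM se %.3f)%s over %d cycle(s) x %d folds\n",
              x$mean_auc, x$se,
              if (x$significant) " *above chance (one-sided 95%)" else "",
              length(x$cycle_aucs), ncol(x$fold_aucs)))
  cat("  cycle AUCs:", paste(sprintf("%.3f", x$cycle_aucs), collapse = " "),
      "\n")
  if (x$leak_features) cat("  [diagnostic leak_features mode - not valid]\n")
  invisible(x)
}

#' Threshold summary over many cross-validation results
#'
#' Counts, per algorithm and per AUC threshold, how many characteristics
#' exceed the threshold; a \code{best_of} pseudo-algorithm takes each
#' characteristic's best mean AUC across the algorithms present, so its count
#' dominates every single algorithm's count at every threshold.
#'
#' @param results list of [cross_validate()] results (possibly several
#'   algorithms per characteristic).
#' @param thresholds AUC thresholds (default \code{c(0.80, 0.90, 0.95)}).
#' @return data frame with columns \code{algorithm}, \code{threshold},
#'   \code{count}, \code{percent} (of characteristics).
#' @export
summarize_cv <- function(results, thresholds = c(0.80, 0.90, 0.95)) {
  stopifnot(length(results) > 0L)
  tab <- data.frame(
    characteristic_id = vapply(results, `[[`, character(1), "characteristic_id"),
    algorithm = vapply(results, `[[`, character(1), "algorithm"),
    mean_auc = vapply(results, `[[`, numeric(1), "mean_auc"),
    stringsAsFactors = FALSE)
  if (length(thresholds) == 0L) {
    return(data.frame(algorithm = character(0), threshold = numeric(0),
                      count = integer(0), percent = numeric(0)))
  }
  n_char <- length(unique(tab$characteristic_id))
  best <- stats::aggregate(mean_auc ~ characteristic_id, tab, max)
  blocks <- lapply(sort(unique(tab$algorithm)), function(alg) {
    sub <- tab[tab$algorithm == alg, ]
    data.frame(algorithm = alg, threshold = thresholds,
               count = vapply(thresholds, function(t) sum(sub$mean_auc > t),
                              numeric(1)))
  })
  blocks <- c(blocks, list(
    data.frame(algorithm = "best_of", threshold = thresholds,
               count = vapply(thresholds, function(t) sum(best$mean_auc > t),
                              numeric(1)))))
  out <- do.call(rbind, blocks)
  out$percent <- 100 * out$count / n_char
  rownames(out) <- NULL
  out
}

#' Export cross-validation results as TSV
#'
#' One row per result: characteristic, algorithm, measure, class sizes, mean
#' AUC, Hanley-McNeil SE, significance flag and the semicolon-joined per-cycle
#' AUCs.
#'
#' @param results list of [cross_validate()] results.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cv_results <- function(results, path) {
  rows <- lapply(results, function(r) data.frame(
    characteristic_id = r$characteristic_id, algorithm = r$algorithm,
    measure = r$measure, n_pos = r$n_pos, n_neg = r$n_neg,
    mean_auc = r$mean_auc, se = r$se, significant = r$significant,
    cycle_aucs = paste(sprintf("%.6f", r$cycle_aucs), collapse = ";"),
    stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
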