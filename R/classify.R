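# Classifiers over the selected token scores.
#
# Four algorithm families: Gaussian naive Bayes (per-class, per-feature
# normal likelihoods with a variance floor so constant columns survive),
# inverse-distance-weighted k-nearest neighbour with k chosen by an internal
# stratified 5-fold search over 1..10, and support vector machines with
# linear and RBF kernels (cost 1; RBF gamma = 1 / (n_features * pooled
# feature variance)). NB and IBk return probability-like scores in [0, 1];
# the SVMs return decision values (margins), which are deterministic and
# monotone-equivalent for ROC purposes. Higher always means "more likely
# positive".

.ALGORITHMS <- c("NB", "IBk", "SVM_linear", "SVM_rbf")

#' Build a feature table from a ranking
#'
#' One row per universe drug, one column per selected token (in ranking
#' order), entries the drug's token scores from the matrix; token-drug pairs
#' absent from the matrix are 0. The label column comes from \code{labels}.
#'
#' @param fm a [frequency_matrix()] result.
#' @param tokens character vector of selected tokens (e.g.
#'   \code{rank_tokens(...)$token}); order is preserved.
#' @param labels a [characteristic_labels()] object; its universe defines the
#'   rows. Pass \code{NULL} for an unlabeled (prediction-time) table, in
#'   which case \code{drugs} must be given.
#' @param drugs row drugs when \code{labels} is \code{NULL}.
#' @return object of class \code{feature_table}: list with \code{x} (numeric
#'   matrix drugs x tokens), \code{y} (logical, positive indicator, or
#'   \code{NULL}), \code{tokens}, \code{measure}.
#' @export
feature_table <- function(fm, tokens, labels = NULL, drugs = NULL) {
  if (is.null(labels) && is.null(drugs)) {
    stop("need labels or an explicit drug list")
  }
  if (!is.null(labels)) drugs <- labels$universe
  stopifnot(all(drugs %in% colnames(fm$scores)))
  x <- matrix(0, nrow = length(drugs), ncol = length(tokens),
              dimnames = list(drugs, tokens))
  present <- tokens[tokens %in% rownames(fm$scores)]
  if (length(present) > 0L) {
    x[, present] <- t(as.matrix(fm$scores[present, drugs, drop = FALSE]))
  }
  y <- if (is.null(labels)) NULL else drugs %in% labels$positives
  structure(list(x = x, y = y, tokens = tokens, measure = fm$measure),
            class = "feature_table")
}

# ---- Gaussian naive Bayes ------------------------------------------------

.nb_fit <- function(x, y, var_floor = 1e-6) {
  fit <- list(var_floor = var_floor)
  for (cl in c("pos", "neg")) {
    rows <- if (cl == "pos") y else !y
    xc <- x[rows, , drop = FALSE]
    mu <- colMeans(xc)
    v <- apply(xc, 2L, function(col) {
      if (length(col) < 2L) 0 else stats::var(col)
    })
    fit[[cl]] <- list(mu = mu, var = pmax(v, var_floor),
                      logprior = log(sum(rows) / length(y)))
  }
  fit
}

.nb_score <- function(fit, x) {
  ll <- function(cl) {
    p <- fit[[cl]]
    s <- rep(p$logprior, nrow(x))
    for (j in seq_along(p$mu)) {
      s <- s + stats::dnorm(x[, j], p$mu[j], sqrt(p$var[j]), log = TRUE)
    }
    s
  }
  lp <- ll("pos")
  ln <- ll("neg")
  1 / (1 + exp(ln - lp))
}

# ---- inverse-distance-weighted kNN ---------------------------------------

.ibk_score_one_k <- function(d, y01, k) {
  # d: distances from one query to all training rows (ties broken by index)
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(min(k, length(ord)))]
  dn <- d[nn]
  if (any(dn < 1e-12)) return(mean(y01[nn[dn < 1e-12]]))
  w <- 1 / dn
  sum(w * y01[nn]) / sum(w)
}

.ibk_dist <- function(a, b) {
  # Euclidean cross-distance matrix, rows of a x rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.ibk_choose_k <- function(x, y, seed, k_grid = 1:10, n_folds = 5L) {
  np <- sum(y)
  nn <- sum(!y)
  n_folds <- min(n_folds, np, nn)
  if (n_folds < 2L) return(1L)
  set.seed(seed)
  fold <- integer(length(y))
  fold[y] <- rep_len(seq_len(n_folds), np)[sample.int(np)]
  fold[!y] <- rep_len(seq_len(n_folds), nn)[sample.int(nn)]
  scores <- matrix(NA_real_, nrow = length(y), ncol = length(k_grid))
  for (f in seq_len(n_folds)) {
    te <- fold == f
    d <- .ibk_dist(x[te, , drop = FALSE], x[!te, , drop = FALSE])
    y01 <- as.numeric(y[!te])
    kmax_f <- min(max(k_grid), sum(!te))
    for (ki in seq_along(k_grid)) {
      k <- min(k_grid[ki], kmax_f)
      scores[te, ki] <- apply(d, 1L, .ibk_score_one_k, y01 = y01, k = k)
    }
  }
  auc_k <- vapply(seq_along(k_grid), function(ki)
    .auc_from_scores(scores[, ki], y), numeric(1))
  k_grid[which.max(auc_k)]  # which.max takes the first maximum: ties -> smaller k
}

# plain AUC of scores vs logical labels (Mann-Whitney with tie credit)
.auc_from_scores <- function(s, y) {
  np <- sum(y)
  nn <- sum(!y)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

# ---- fitting -------------------------------------------------------------

#' Fit a drug-characteristic classifier
#'
#' Trains one of the four classifier families on a labeled [feature_table()].
#' Feature handling follows the measure: cdf features are already in
#' \eqn{[0,1]} and are used as-is; for the unbounded ctf / ctf-icdf scales
#' the SVMs standardize each column (recorded in the model and replayed at
#' prediction time). Fitting is deterministic given \code{seed}.
#'
#' @param table a [feature_table()] with labels and at least one positive and
#'   one negative row.
#' @param algorithm \code{"NB"}, \code{"IBk"}, \code{"SVM_linear"} or
#'   \code{"SVM_rbf"}.
#' @param seed integer seed governing the internal k search (IBk) and any
#'   library-level randomness.
#' @return object of class \code{drug_classifier} with the fitted parameters,
#'   the expected token list and training metadata; see
#'   [predict.drug_classifier()].
#' @export
drug_classifier <- function(table, algorithm = .ALGORITHMS, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(table, "feature_table"), !is.null(table$y))
  x <- table$x
  y <- table$y
  if (sum(y) == 0L || sum(!y) == 0L) {
    stop("training table must contain both classes")
  }
  scaling <- NULL
  hyper <- list()
  if (algorithm %in% c("SVM_linear", "SVM_rbf") && table$measure != "cdf") {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    scaling <- list(center = ctr, scale = scl)
    x <- scale(x, center = ctr, scale = scl)
  }
  set.seed(seed)
  fit <- switch(algorithm,
    NB = .nb_fit(x, y),
    IBk = {
      k <- .ibk_choose_k(x, y, seed = seed)
      hyper <- list(k = k)
      list(x = x, y01 = as.numeric(y), k = k)
    },
    SVM_linear = ,
    SVM_rbf = {
      kern <- if (algorithm == "SVM_linear") "linear" else "radial"
      vv <- stats::var(as.vector(x))
      gamma <- if (is.na(vv) || vv < 1e-12) 1 / ncol(x) else 1 / (ncol(x) * vv)
      hyper <- list(cost = 1, gamma = gamma, kernel = kern)
      yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
      e1071::svm(x = x, y = yf, kernel = kern, cost = 1, gamma = gamma,
                 scale = FALSE)
    })
  structure(list(algorithm = algorithm, fit = fit, tokens = table$tokens,
                 measure = table$measure, seed = seed, hyper = hyper,
                 scaling = scaling, n_pos = sum(y), n_neg = sum(!y)),
            class = "drug_classifier")
}

#' Score drugs with a fitted classifier
#'
#' Returns a continuous ranking score per drug (higher = more likely to bear
#' the characteristic), suitable as ROC input: the posterior probability of
#' the positive class for NB, the inverse-distance-weighted neighbour vote
#' for IBk, and the decision value for the SVMs. The table's columns must
#' match the model's stored token list exactly.
#'
#' @param object a [drug_classifier()].
#' @param table a [feature_table()] (labels not required).
#' @param ... unused.
#' @return named numeric vector of scores, one per table row.
#' @export
predict.drug_classifier <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(table$tokens, object$tokens)) {
    extra <- setdiff(table$tokens, object$tokens)
    miss <- setdiff(object$tokens, table$tokens)
    stop("feature mismatch; missing: [", paste(miss, collapse = ", "),
         "] unexpected: [", paste(extra, collapse = ", "), "]")
  }
  x <- table$x
  if (!is.null(object$scaling)) {
    x <- scale(x, center = object$scaling$center,
               scale = object$scaling$scale)
  }
  s <- switch(object$algorithm,
    NB = .nb_score(object$fit, x),
    IBk = {
      d <- .ibk_dist(x, object$fit$x)
      apply(d, 1L, .ibk_score_one_k, y01 = object$fit$y01, k = object$fit$k)
    },
    SVM_linear = ,
    SVM_rbf = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient so larger values favour the positive class
      if (grepl("^pos", colnames(dv)[1L])) as.numeric(dv[, 1L])
      else -as.numeric(dv[, 1L])
    })
  stats::setNames(as.numeric(s), rownames(table$x))
}

#' @export
print.drug_classifier <- function(x, ...) {
  cat("Drug-characteristic classifier [", x$algorithm, "], ",
      length(x$tokens), " token features (", x$measure, "), ",
      x$n_pos, " pos / ", x$n_neg, " neg\n", sep = "")
  if (length(x$hyper) > 0L) {
    cat("  hyperparameters:",
        paste(names(x$hyper), unlist(lapply(x$hyper, format)), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.drug_classifier <- function(object, ...) {
  print(object)
  cat("  tokens:", paste(utils::head(object$tokens, 10L), collapse = ", "),
      if (length(object$tokens) > 10L) "..." else "", "\n")
  cat("  seed:", object$seed, "\n")
  invisible(object)
}
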