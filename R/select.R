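# Feature selection: rare/common token elimination and ROC-AUC ranking.
#
# A characteristic is a binary drug property defined by a positive-example
# drug set C inside the drug universe D; every other drug is a negative.
# Surviving tokens are ranked by the AUC of the ROC traced by sweeping a
# threshold down through the token's per-drug scores: with ties handled as in
# the Mann-Whitney statistic (half credit for tied positive-negative pairs).

#' Characteristic labels
#'
#' @param characteristic_id identifier for the characteristic.
#' @param positives drug names bearing the characteristic (the example list).
#' @param universe the full drug list D; negatives are \code{setdiff(universe,
#'   positives)}.
#' @return object of class \code{characteristic_labels}.
#' @export
characteristic_labels <- function(characteristic_id, positives, universe) {
  positives <- unique(tolower(positives))
  universe <- unique(tolower(universe))
  if (!all(positives %in% universe)) {
    stop("positives outside the drug universe: ",
         paste(setdiff(positives, universe), collapse = ", "))
  }
  if (length(positives) < 1L) stop("need at least one positive example")
  structure(list(characteristic_id = as.character(characteristic_id),
                 positives = positives, universe = universe),
            class = "characteristic_labels")
}

#' @export
print.characteristic_labels <- function(x, ...) {
  cat("Characteristic '", x$characteristic_id, "': ", length(x$positives),
      " positives / ", length(x$universe), " drugs\n", sep = "")
  invisible(x)
}

#' Read characteristic label files
#'
#' Reads a tab-separated long-format table with columns
#' \code{characteristic_id} and \code{drug_name} (one positive example per
#' row).
#'
#' @param path TSV file path.
#' @param universe full drug list (e.g. the lexicon's \code{drug_name}).
#' @return named list of [characteristic_labels()] objects.
#' @export
read_labels <- function(path, universe) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("characteristic_id", "drug_name") %in% names(tab))) {
    stop("label file must have columns characteristic_id and drug_name")
  }
  ids <- unique(tab$characteristic_id)
  out <- lapply(ids, function(id)
    characteristic_labels(id, tab$drug_name[tab$characteristic_id == id],
                          universe))
  stats::setNames(out, ids)
}

#' Remove rare tokens
#'
#' Drops every token whose matched-abstract count, summed over all drugs in
#' the matrix, is below \code{min_abstracts} ("occurs in less than two
#' abstracts" across the whole drug list, with the default).
#'
#' @param fm a [frequency_matrix()] result.
#' @param min_abstracts minimum total abstract count to survive (default 2).
#' @param vocab tokens to screen; default the full matrix vocabulary.
#' @return character vector: the surviving (reduced) vocabulary.
#' @export
eliminate_rare <- function(fm, min_abstracts = 2, vocab = rownames(fm$df)) {
  tot <- Matrix::rowSums(fm$df[vocab, , drop = FALSE])
  vocab[tot >= min_abstracts]
}

#' Remove common corpus-size-correlated tokens
#'
#' For each token, the Pearson correlation r between its per-drug scores
#' (zeros included for drugs lacking the token) and the per-drug abstract
#' counts \eqn{N_d} is computed across drugs with \eqn{N_d \ge 1}; tokens
#' with \eqn{r^2 >} \code{r2_cutoff} are removed. Such tokens ("only",
#' "when", ...) track corpus size, not drug identity. Tokens with zero
#' variance in either vector have undefined r and are retained: a
#' constant-score token is no evidence of corpus-size dependence.
#'
#' @param fm a [frequency_matrix()] result.
#' @param r2_cutoff squared-correlation threshold (default 0.33).
#' @param vocab tokens to screen; default the full matrix vocabulary.
#' @return character vector: the surviving (reduced) vocabulary.
#' @export
eliminate_common <- function(fm, r2_cutoff = 0.33, vocab = rownames(fm$df)) {
  use <- fm$n_abstracts >= 1
  if (sum(use) < 3L) {
    warning("fewer than 3 drugs with abstracts; common-token screen skipped")
    return(vocab)
  }
  y <- as.numeric(fm$n_abstracts[use])
  s <- fm$scores[vocab, use, drop = FALSE]
  n <- length(y)
  my <- mean(y)
  vy <- sum((y - my)^2) / n
  sx <- Matrix::rowSums(s)
  sx2 <- Matrix::rowSums(s^2)
  sxy <- as.numeric(s %*% y)
  mx <- sx / n
  vx <- pmax(sx2 / n - mx^2, 0)
  cv <- sxy / n - mx * my
  r2 <- numeric(length(vocab))
  ok <- vx > 1e-12 & vy > 1e-12
  r2[ok] <- (cv[ok]^2) / (vx[ok] * vy)
  vocab[r2 <= r2_cutoff]
}

#' ROC AUC of one token's scores against a characteristic
#'
#' The area under the ROC curve obtained by sweeping a threshold from above
#' the largest score down through every observed value, with TPR/FPR the
#' fractions of positive/negative drugs scoring at or above the threshold.
#' Ties are handled so the result equals the Mann-Whitney statistic with half
#' credit for tied positive-negative pairs. Drugs absent from \code{scores}
#' enter with score 0.
#'
#' @param scores named numeric vector of per-drug scores (sparse: missing
#'   drugs score 0).
#' @param labels a [characteristic_labels()] object; both classes must be
#'   non-empty.
#' @return AUC in \eqn{[0, 1]}.
#' @export
token_auc <- function(scores, labels) {
  stopifnot(inherits(labels, "characteristic_labels"))
  d <- labels$universe
  pos <- d %in% labels$positives
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("AUC undefined: need at least one positive and one negative drug")
  }
  s <- stats::setNames(numeric(length(d)), d)
  got <- intersect(names(scores), d)
  s[got] <- scores[got]
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# AUC of every row of a dense score matrix (tokens x drugs) at once
.row_auc <- function(x, pos_cols) {
  np <- sum(pos_cols)
  nn <- ncol(x) - np
  r <- t(apply(x, 1L, rank, ties.method = "average"))
  (rowSums(r[, pos_cols, drop = FALSE]) - np * (np + 1) / 2) / (np * nn)
}

#' Rank tokens by discriminative power
#'
#' Computes [token_auc()] for every token in \code{vocab} (normally the
#' vocabulary surviving [eliminate_rare()] and [eliminate_common()]) and
#' returns the \code{top_n} tokens sorted by AUC descending, ties broken
#' lexicographically by token.
#'
#' @param fm a [frequency_matrix()] result.
#' @param labels a [characteristic_labels()] object; its universe must be a
#'   subset of the matrix columns.
#' @param top_n number of tokens to return (default 20); fewer are returned,
#'   with a warning, when the vocabulary is smaller.
#' @param vocab tokens eligible for ranking.
#' @return object of class \code{token_ranking}: data frame with columns
#'   \code{rank}, \code{token}, \code{auc}.
#' @export
rank_tokens <- function(fm, labels, top_n = 20, vocab = rownames(fm$scores)) {
  stopifnot(inherits(labels, "characteristic_labels"))
  d <- labels$universe
  if (!all(d %in% colnames(fm$scores))) {
    stop("labels universe contains drugs absent from the matrix")
  }
  if (length(vocab) == 0L) {
    warning("empty vocabulary: nothing to rank")
    out <- data.frame(rank = integer(0), token = character(0),
                      auc = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("token_ranking", "data.frame")
    return(out)
  }
  x <- as.matrix(fm$scores[vocab, d, drop = FALSE])
  auc <- .row_auc(x, d %in% labels$positives)
  ord <- order(-auc, vocab)
  if (length(vocab) < top_n) {
    warning("only ", length(vocab), " tokens available (top_n = ", top_n, ")")
  }
  take <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(rank = seq_along(take), token = vocab[take],
                    auc = auc[take], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("token_ranking", "data.frame")
  out
}

#' Percentile position of an index keyword in the full token ranking
#'
#' Locates the natural-language keyword naming a characteristic (its "index
#' keyword") in the full post-elimination AUC ranking. The keyword may have
#' been removed as too rare or too common, or may never occur in the corpus
#' at all; both outcomes are reported as explicit statuses rather than a
#' rank.
#'
#' @param fm a [frequency_matrix()] result.
#' @param labels a [characteristic_labels()] object.
#' @param keyword token to locate (lower-cased before lookup).
#' @param min_abstracts,r2_cutoff elimination parameters (as in
#'   [eliminate_rare()] / [eliminate_common()]).
#' @return list with \code{status} (\code{"ranked"}, \code{"eliminated"} or
#'   \code{"absent"}), \code{rank}, \code{n_ranked} and \code{percentile}
#'   (100 * rank / n; \code{NA} unless ranked).
#' @export
index_keyword_percentile <- function(fm, labels, keyword, min_abstracts = 2,
                                     r2_cutoff = 0.33) {
  keyword <- tolower(keyword)
  if (!keyword %in% rownames(fm$scores)) {
    return(list(status = "absent", rank = NA_integer_,
                n_ranked = NA_integer_, percentile = NA_real_))
  }
  vocab <- eliminate_common(fm, r2_cutoff,
                            vocab = eliminate_rare(fm, min_abstracts))
  if (!keyword %in% vocab) {
    return(list(status = "eliminated", rank = NA_integer_,
                n_ranked = NA_integer_, percentile = NA_real_))
  }
  full <- rank_tokens(fm, labels, top_n = length(vocab), vocab = vocab)
  pos <- match(keyword, full$token)
  list(status = "ranked", rank = pos, n_ranked = nrow(full),
       percentile = 100 * pos / nrow(full))
}

#' Export a token ranking as TSV
#'
#' Columns: \code{rank}, \code{token}, \code{auc}.
#'
#' @param ranking a [rank_tokens()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
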