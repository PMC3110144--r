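# Per-drug token scores.
#
# For a drug d with N_d matched abstracts, df_{w,d} abstracts containing
# token w, c_{w,d} occurrences of w counted with multiplicity, and T_d total
# token occurrences across d's abstracts:
#
#   cdf_{w,d}      = df_{w,d} / N_d                    (in [0, 1])
#   ctf_{w,d}      = c_{w,d} / T_d
#   ctf-icdf_{w,d} = ctf_{w,d} * ln(N_d / df_{w,d})    (>= 0; 0 when saturated)
#
# cdf counts abstract-level presence only, so duplicating a token inside one
# abstract moves ctf but not cdf; a token present in every abstract has
# cdf = 1 but ctf-icdf = 0. Global tf/df weights are constants across drugs
# and are deliberately not offered.

.drug_bags <- function(index, drug) {
  if (!drug %in% index$drugs) stop("unknown drug: ", drug)
  index$token_counts[index$abstract_ids[[drug]]]
}

.df_counts <- function(bags) {
  toks <- unlist(lapply(bags, names), use.names = FALSE)
  if (length(toks) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(toks)
  stats::setNames(as.integer(tab), names(tab))
}

.occ_counts <- function(bags) {
  vals <- unlist(bags, use.names = FALSE)
  toks <- unlist(lapply(bags, names), use.names = FALSE)
  if (length(vals) == 0L) return(stats::setNames(integer(0), character(0)))
  out <- rowsum(as.numeric(vals), toks)
  stats::setNames(as.integer(out[, 1L]), rownames(out))
}

#' Conditional document frequency of every token for one drug
#'
#' \code{cdf_{w,d} = df_{w,d} / N_d}: the fraction of drug \code{d}'s matched
#' abstracts that contain token \code{w}. Tokens occurring in none of the
#' drug's abstracts are absent from the result (implicitly 0).
#'
#' @param index a [build_drug_index()] result.
#' @param drug drug name (lexicon key).
#' @return named numeric vector of cdf scores in \eqn{[0, 1]}; empty (with a
#'   message) when the drug matched no abstracts.
#' @export
compute_cdf <- function(index, drug) {
  bags <- .drug_bags(index, drug)
  n <- length(bags)
  if (n == 0L) {
    message("drug '", drug, "' has no matched abstracts; no features")
    return(stats::setNames(numeric(0), character(0)))
  }
  df <- .df_counts(bags)
  df / n
}

#' Conditional term frequency of every token for one drug
#'
#' \code{ctf_{w,d} = c_{w,d} / T_d}, where \code{c_{w,d}} counts occurrences
#' of \code{w} with multiplicity across the drug's abstracts and \code{T_d}
#' is the drug's total token count; the normalization makes ctf comparable
#' across drugs with different corpus sizes, as cdf is.
#'
#' @inheritParams compute_cdf
#' @return named numeric vector of ctf scores.
#' @export
compute_ctf <- function(index, drug) {
  bags <- .drug_bags(index, drug)
  if (length(bags) == 0L) {
    message("drug '", drug, "' has no matched abstracts; no features")
    return(stats::setNames(numeric(0), character(0)))
  }
  occ <- .occ_counts(bags)
  total <- sum(occ)
  if (total == 0L) return(stats::setNames(numeric(0), character(0)))
  occ / total
}

#' ctf-icdf score of every token for one drug
#'
#' tf-idf restricted to the drug's own abstract sub-corpus:
#' \code{ctf_{w,d} * ln(N_d / df_{w,d})} (natural log). A token present in
#' every one of the drug's abstracts scores exactly 0; absent tokens carry no
#' evidence and are absent from the result.
#'
#' @inheritParams compute_cdf
#' @return named numeric vector of non-negative scores.
#' @export
compute_ctf_icdf <- function(index, drug) {
  bags <- .drug_bags(index, drug)
  n <- length(bags)
  if (n == 0L) {
    message("drug '", drug, "' has no matched abstracts; no features")
    return(stats::setNames(numeric(0), character(0)))
  }
  ctf <- compute_ctf(index, drug)
  df <- .df_counts(bags)
  ctf * log(n / df[names(ctf)])
}

#' Assemble the sparse token-by-drug score matrix
#'
#' Builds the token \eqn{\times} drug matrix of the chosen measure over the
#' union vocabulary (lexicographically ordered rows), together with the
#' per-(token, drug) abstract counts \code{df}, per-drug abstract counts
#' \code{N_d} and total token counts \code{T_d} needed by the rare/common
#' token filters.
#'
#' @param index a [build_drug_index()] result.
#' @param drugs drugs to include (columns); default all lexicon drugs.
#' @param measure one of \code{"cdf"}, \code{"ctf"}, \code{"ctf_icdf"}.
#' @return object of class \code{freq_matrix}: list with \code{measure},
#'   \code{scores} and \code{df} (sparse \pkg{Matrix} objects, tokens in
#'   rows), \code{n_abstracts}, \code{total_tokens}.
#' @export
frequency_matrix <- function(index, drugs = index$drugs,
                             measure = c("cdf", "ctf", "ctf_icdf")) {
  if (length(measure) != 1L || !measure %in% c("cdf", "ctf", "ctf_icdf")) {
    stop("unknown measure: ", paste(measure, collapse = ", "))
  }
  stopifnot(all(drugs %in% index$drugs))
  per_drug <- lapply(drugs, function(d) {
    bags <- index$token_counts[index$abstract_ids[[d]]]
    list(df = .df_counts(bags), occ = .occ_counts(bags))
  })
  names(per_drug) <- drugs
  vocab <- sort(unique(unlist(lapply(per_drug, function(p) names(p$df)),
                              use.names = FALSE)))
  n_abs <- stats::setNames(lengths(index$abstract_ids[drugs]), drugs)
  t_tok <- stats::setNames(vapply(per_drug, function(p) sum(p$occ), numeric(1)),
                           drugs)

  ii <- integer(0); jj <- integer(0); df_x <- integer(0); occ_x <- integer(0)
  for (j in seq_along(drugs)) {
    df <- per_drug[[j]]$df
    if (length(df) == 0L) next
    ridx <- match(names(df), vocab)
    ii <- c(ii, ridx)
    jj <- c(jj, rep.int(j, length(df)))
    df_x <- c(df_x, unname(df))
    occ_x <- c(occ_x, unname(per_drug[[j]]$occ[names(df)]))
  }
  dims <- c(length(vocab), length(drugs))
  dn <- list(vocab, drugs)
  df_m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(df_x),
                               dims = dims, dimnames = dn)
  scores <- switch(measure,
    cdf = {
      x <- df_x / n_abs[jj]
      Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = dims, dimnames = dn)
    },
    ctf = {
      x <- occ_x / t_tok[jj]
      Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = dims, dimnames = dn)
    },
    ctf_icdf = {
      x <- (occ_x / t_tok[jj]) * log(n_abs[jj] / df_x)
      Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = dims, dimnames = dn)
    })
  structure(list(measure = measure, scores = scores, df = df_m,
                 n_abstracts = n_abs, total_tokens = t_tok),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("Frequency matrix (", x$measure, "): ", nrow(x$scores), " tokens x ",
      ncol(x$scores), " drugs, ", length(x$scores@x), " nonzero scores\n",
      sep = "")
  invisible(x)
}

# restrict a freq_matrix to a subset of drug columns (vocabulary rows with no
# remaining support are dropped)
.subset_freq_matrix <- function(fm, drugs) {
  stopifnot(all(drugs %in% colnames(fm$scores)))
  df <- fm$df[, drugs, drop = FALSE]
  keep <- Matrix::rowSums(df) > 0
  structure(list(measure = fm$measure,
                 scores = fm$scores[keep, drugs, drop = FALSE],
                 df = df[keep, , drop = FALSE],
                 n_abstracts = fm$n_abstracts[drugs],
                 total_tokens = fm$total_tokens[drugs]),
            class = "freq_matrix")
}

.vocab_hash <- function(vocab) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vocab, tmp)
  unname(tools::md5sum(tmp))
}

#' Export a frequency matrix as sparse triplet TSV
#'
#' Writes \code{(token, drug, score, df)} triplets plus a sidecar
#' \code{<path>.meta.tsv} carrying the measure, the per-drug \code{N_d} and
#' \code{T_d} tables and a vocabulary hash; [read_frequency_matrix()] restores
#' the object loss-free.
#'
#' @param fm a [frequency_matrix()] result.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_frequency_matrix <- function(fm, path) {
  tri <- Matrix::summary(fm$df)
  vocab <- rownames(fm$df)
  drugs <- colnames(fm$df)
  out <- data.frame(token = vocab[tri$i], drug = drugs[tri$j],
                    score = fm$scores[cbind(tri$i, tri$j)],
                    df = tri$x, stringsAsFactors = FALSE)
  out <- out[order(out$token, out$drug), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(drug = drugs,
                     n_abstracts = unname(fm$n_abstracts[drugs]),
                     total_tokens = unname(fm$total_tokens[drugs]),
                     measure = fm$measure,
                     vocab_hash = .vocab_hash(vocab),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a frequency matrix written by [write_frequency_matrix()]
#'
#' @param path TSV path previously written by [write_frequency_matrix()].
#' @return object of class \code{freq_matrix}.
#' @export
read_frequency_matrix <- function(path) {
  tri <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  meta <- utils::read.delim(paste0(path, ".meta.tsv"), stringsAsFactors = FALSE)
  vocab <- sort(unique(tri$token))
  drugs <- meta$drug
  i <- match(tri$token, vocab)
  j <- match(tri$drug, drugs)
  dn <- list(vocab, drugs)
  fm <- structure(list(
    measure = meta$measure[1L],
    scores = Matrix::sparseMatrix(i = i, j = j, x = tri$score,
                                  dims = c(length(vocab), length(drugs)),
                                  dimnames = dn),
    df = Matrix::sparseMatrix(i = i, j = j, x = tri$df,
                              dims = c(length(vocab), length(drugs)),
                              dimnames = dn),
    n_abstracts = stats::setNames(as.integer(meta$n_abstracts), drugs),
    total_tokens = stats::setNames(as.numeric(meta$total_tokens), drugs)
  ), class = "freq_matrix")
  if (!fm$measure %in% c("cdf", "ctf", "ctf_icdf")) {
    stop("corrupt metadata: unknown measure ", fm$measure)
  }
  if (.vocab_hash(vocab) != meta$vocab_hash[1L]) {
    warning("vocabulary hash mismatch on import")
  }
  fm
}
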