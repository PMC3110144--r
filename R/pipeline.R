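# End-to-end orchestration: config-driven runs with logged, reproducible
# outputs. Every run directory receives the resolved configuration, a run
# log, and TSV artifacts sufficient to re-run bit-identically.

.RUN_CONFIG_FIELDS <- c("corpus", "corpus_format", "lexicon", "labels",
                        "measure", "stemming", "synonyms", "top_n",
                        "algorithms", "seed", "output_dir",
                        "min_abstracts", "r2_cutoff")

#' Read and validate a run configuration
#'
#' YAML key-value file with fields \code{corpus}, \code{corpus_format}
#' (\code{jsonl} or \code{medline_xml}), \code{lexicon}, \code{labels},
#' \code{measure} (\code{cdf}/\code{ctf}/\code{ctf_icdf}), \code{stemming},
#' \code{synonyms}, \code{top_n}, \code{algorithms}, \code{seed},
#' \code{output_dir}, and optional \code{min_abstracts} / \code{r2_cutoff}.
#' Unknown keys are rejected; defaults are filled in and the resolved
#' configuration is written to the output directory by the run functions.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .RUN_CONFIG_FIELDS)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  defaults <- list(corpus_format = "jsonl", measure = "cdf",
                   stemming = FALSE, synonyms = FALSE, top_n = 20L,
                   algorithms = .ALGORITHMS, seed = 1L,
                   min_abstracts = 2, r2_cutoff = 0.33)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("corpus", "lexicon", "labels", "output_dir")) {
    if (is.null(cfg[[k]])) stop("config field '", k, "' is required")
  }
  for (k in c("corpus", "lexicon", "labels")) {
    if (!file.exists(cfg[[k]])) stop("config path does not exist: ", cfg[[k]])
  }
  if (!cfg$measure %in% c("cdf", "ctf", "ctf_icdf")) {
    stop("unknown measure: ", cfg$measure)
  }
  if (!all(cfg$algorithms %in% .ALGORITHMS)) {
    stop("unknown algorithm(s): ",
         paste(setdiff(cfg$algorithms, .ALGORITHMS), collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

.run_log <- function(dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

.write_resolved_config <- function(cfg, dir) {
  yaml::write_yaml(unclass(cfg), file.path(dir, "resolved_config.yaml"))
}

#' Index a corpus: tokenize, match drugs, build and persist the matrix
#'
#' Loads the corpus and lexicon named in the configuration, builds the
#' drug-abstract index and the score matrix for the configured measure, and
#' writes to the output directory: the matrix (sparse triplet TSV +
#' metadata), a per-drug statistics report (abstract counts, vocabulary sizes
#' before/after rare+common elimination), the resolved configuration and a
#' run log.
#'
#' @param config a [read_run_config()] result (or a path/list accepted by
#'   it).
#' @return invisibly, a list with the \code{index}, the \code{matrix} and the
#'   output paths.
#' @export
run_index <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  .write_resolved_config(cfg, cfg$output_dir)
  .run_log(cfg$output_dir, "loading corpus ", cfg$corpus)
  records <- load_corpus(cfg$corpus, cfg$corpus_format)
  lexicon <- read_lexicon(cfg$lexicon)
  .run_log(cfg$output_dir, nrow(records), " abstracts, ", nrow(lexicon),
           " lexicon drugs")
  index <- build_drug_index(records, lexicon, use_synonyms = cfg$synonyms,
                            stemming = cfg$stemming)
  if (all(index$n_abstracts == 0L)) {
    stop("no drug matched any abstract; check corpus and lexicon")
  }
  fm <- frequency_matrix(index, measure = cfg$measure)
  matrix_path <- file.path(cfg$output_dir, "matrix.tsv")
  write_frequency_matrix(fm, matrix_path)
  saveRDS(index, file.path(cfg$output_dir, "index.rds"))

  vocab_pre <- nrow(fm$scores)
  vocab_post <- length(eliminate_common(
    fm, cfg$r2_cutoff, vocab = eliminate_rare(fm, cfg$min_abstracts)))
  stats <- data.frame(drug = index$drugs,
                      n_abstracts = unname(index$n_abstracts),
                      stringsAsFactors = FALSE)
  utils::write.table(stats, file.path(cfg$output_dir, "drug_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- data.frame(
    metric = c("n_abstracts_total", "n_drugs", "median_abstracts_per_drug",
               "iqr_low", "iqr_high", "vocab_size", "vocab_after_elimination",
               "fraction_eliminated"),
    value = c(nrow(records), length(index$drugs),
              stats::median(index$n_abstracts),
              stats::quantile(index$n_abstracts, 0.25),
              stats::quantile(index$n_abstracts, 0.75),
              vocab_pre, vocab_post, 1 - vocab_post / vocab_pre),
    stringsAsFactors = FALSE)
  utils::write.table(report, file.path(cfg$output_dir, "corpus_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .run_log(cfg$output_dir, "vocabulary ", vocab_pre, " -> ", vocab_post,
           " after elimination")
  invisible(list(index = index, matrix = fm,
                 paths = list(matrix = matrix_path,
                              report = file.path(cfg$output_dir,
                                                 "corpus_report.tsv"))))
}

#' Cross-validate every characteristic and algorithm in the configuration
#'
#' For each characteristic in the label file and each configured algorithm,
#' runs [cross_validate()] on the persisted matrix and writes
#' \code{results.tsv} plus the threshold summary \code{summary.tsv}.
#' Characteristics with fewer than 2 positives are reported with status
#' \code{non_evaluable} in \code{results_status.tsv}, not silently dropped.
#'
#' @param config a [read_run_config()] result (or path/list).
#' @param indexed optional result of [run_index()] to reuse; loaded from the
#'   output directory otherwise.
#' @return invisibly, the list of [cross_validate()] results.
#' @export
run_evaluate <- function(config, indexed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(indexed)) {
    fm <- read_frequency_matrix(file.path(cfg$output_dir, "matrix.tsv"))
  } else {
    fm <- indexed$matrix
  }
  universe <- colnames(fm$scores)
  labels <- read_labels(cfg$labels, universe)
  results <- list()
  status <- list()
  for (lab in labels) {
    if (length(lab$positives) < 2L) {
      .run_log(cfg$output_dir, "characteristic ", lab$characteristic_id,
               " non-evaluable (", length(lab$positives), " positives)")
      status[[length(status) + 1L]] <- data.frame(
        characteristic_id = lab$characteristic_id,
        status = "non_evaluable", n_pos = length(lab$positives),
        stringsAsFactors = FALSE)
      next
    }
    status[[length(status) + 1L]] <- data.frame(
      characteristic_id = lab$characteristic_id, status = "evaluated",
      n_pos = length(lab$positives), stringsAsFactors = FALSE)
    for (alg in cfg$algorithms) {
      .run_log(cfg$output_dir, "cross-validating ", lab$characteristic_id,
               " [", alg, "]")
      results[[length(results) + 1L]] <-
        cross_validate(fm, lab, alg, top_n = cfg$top_n, seed = cfg$seed,
                       min_abstracts = cfg$min_abstracts,
                       r2_cutoff = cfg$r2_cutoff)
    }
  }
  utils::write.table(do.call(rbind, status),
                     file.path(cfg$output_dir, "results_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(results) > 0L) {
    write_cv_results(results, file.path(cfg$output_dir, "results.tsv"))
    utils::write.table(summarize_cv(results),
                       file.path(cfg$output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(results)
}

#' Rank candidate drugs with a saved model
#'
#' Scores a list of drugs with a fitted [drug_classifier()] against the
#' persisted matrix and writes a descending ranking. Drugs absent from the
#' matrix are listed in a side report and excluded from the ranking.
#'
#' @param config a [read_run_config()] result (or path/list).
#' @param model a [drug_classifier()] or the path of an \code{.rds} holding
#'   one.
#' @param drugs character vector of candidate drug names; empty input yields
#'   an empty ranking.
#' @return invisibly, the ranking data frame (\code{drug}, \code{score},
#'   \code{rank}).
#' @export
run_predict <- function(config, model, drugs) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.character(model)) model <- readRDS(model)
  stopifnot(inherits(model, "drug_classifier"))
  fm <- read_frequency_matrix(file.path(cfg$output_dir, "matrix.tsv"))
  drugs <- tolower(drugs)
  known <- drugs[drugs %in% colnames(fm$scores)]
  missing <- setdiff(drugs, known)
  if (length(missing) > 0L) {
    utils::write.table(data.frame(drug = missing, status = "not_indexed"),
                       file.path(cfg$output_dir, "predict_missing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(known) == 0L) {
    out <- data.frame(drug = character(0), score = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- feature_table(fm, model$tokens, drugs = known)
    sc <- predict(model, tab)
    ord <- order(-sc, known)
    out <- data.frame(drug = known[ord], score = unname(sc[ord]),
                      rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  utils::write.table(out, file.path(cfg$output_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
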