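# Synthetic corpus generator with planted statistical structure.
#
# Emulates what the mining pipeline assumes about real literature: per-drug
# abstract counts are heavy-tailed (log-normal), token frequencies are
# heavy-tailed (Zipf background vocabulary), and three kinds of planted
# tokens exercise each pipeline stage:
#   * rare tokens      - inserted into exactly one abstract corpus-wide, so
#                        the rare-token filter must remove them;
#   * common tokens    - per-abstract occurrence probability increasing
#                        linearly with the rank of the drug's abstract count,
#                        so their cdf correlates with N_d and the r^2 screen
#                        must remove them;
#   * signal tokens    - per-abstract occurrence probability p_pos in
#                        positive drugs' abstracts vs p_neg in negatives',
#                        so ranking and classification must recover them.
# Every drug's own name is inserted into each of its abstracts, guaranteeing
# the index matches it. A truth manifest records every planted token with its
# role and the generating parameters; the expected cdf of a planted token is
# its abstract-level occurrence probability.

#' Generator configuration
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 200 drugs, log-normal abstracts-per-drug with median about 30
#' (floored at \code{min_abstracts_per_drug}, capped at three log-sds above
#' the median to bound any single drug's corpus share), Poisson-length
#' abstracts (mean 80 tokens) over a 2000-token Zipf background, 20 planted
#' rare and 20 planted common tokens, and one characteristic with 20
#' positives and 20 signal tokens at \code{p_pos} = 0.6 vs \code{p_neg} =
#' 0.05.
#'
#' @param n_drugs number of drugs in the lexicon.
#' @param abstracts_meanlog,abstracts_sdlog log-normal parameters of the
#'   abstracts-per-drug distribution.
#' @param min_abstracts_per_drug floor on abstracts per drug.
#' @param vocab_size background vocabulary size.
#' @param zipf_exponent Zipf exponent of background token probabilities.
#' @param tokens_per_abstract mean Poisson abstract length (background
#'   tokens).
#' @param n_rare number of planted rare tokens (one abstract each).
#' @param n_common number of planted common tokens.
#' @param common_p_range per-abstract probability range of a common token,
#'   mapped linearly onto the rank of \eqn{N_d}.
#' @param characteristics list of characteristic descriptors, each a list
#'   with \code{id}, \code{n_pos}, \code{n_signal}, \code{p_pos},
#'   \code{p_neg}.
#' @param seed master seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_drugs = 200L,
                             abstracts_meanlog = log(30),
                             abstracts_sdlog = 0.4,
                             min_abstracts_per_drug = 2L,
                             vocab_size = 2000L,
                             zipf_exponent = 1,
                             tokens_per_abstract = 80,
                             n_rare = 20L,
                             n_common = 20L,
                             common_p_range = c(0.15, 0.9),
                             characteristics = list(list(
                               id = "char01", n_pos = 20L, n_signal = 20L,
                               p_pos = 0.6, p_neg = 0.05)),
                             seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              abstracts_meanlog = abstracts_meanlog,
              abstracts_sdlog = abstracts_sdlog,
              min_abstracts_per_drug = as.integer(min_abstracts_per_drug),
              vocab_size = as.integer(vocab_size),
              zipf_exponent = zipf_exponent,
              tokens_per_abstract = tokens_per_abstract,
              n_rare = as.integer(n_rare), n_common = as.integer(n_common),
              common_p_range = common_p_range,
              characteristics = characteristics, seed = as.integer(seed))
  probs <- c(cfg$common_p_range,
             unlist(lapply(characteristics, function(ch) c(ch$p_pos, ch$p_neg))))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (ch in characteristics) {
    if (ch$p_pos <= ch$p_neg) {
      stop("characteristic '", ch$id, "': p_pos must exceed p_neg")
    }
    if (ch$n_pos >= cfg$n_drugs) {
      stop("characteristic '", ch$id, "': n_pos must leave negatives")
    }
  }
  if (cfg$n_rare > cfg$n_drugs * cfg$min_abstracts_per_drug) {
    stop("infeasible: more rare tokens than guaranteed abstracts; ",
         "each rare token needs its own abstract to keep its count below 2")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic corpus with planted structure
#'
#' Deterministic given \code{config$seed}: returns the corpus records, the
#' lexicon, the characteristic labels and a truth manifest naming every
#' planted token and its role. Each abstract is a shuffled bag of sampled
#' background tokens plus the drug's name and any planted tokens drawn for
#' it; titles carry the drug name, bodies the rest.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{records} (corpus data frame), \code{lexicon}
#'   ([drug_lexicon()]), \code{labels} (named list of
#'   [characteristic_labels()]), \code{manifest} (truth manifest list).
#' @export
simulate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_drugs
  drugs <- sprintf("drug%03d", seq_len(n))

  cap <- exp(config$abstracts_meanlog + 3 * config$abstracts_sdlog)
  n_abs <- pmin(round(cap), pmax(config$min_abstracts_per_drug,
                round(stats::rlnorm(n, config$abstracts_meanlog,
                                    config$abstracts_sdlog))))
  names(n_abs) <- drugs

  bg_vocab <- sprintf("w%04d", seq_len(config$vocab_size))
  bg_prob <- (1 / seq_len(config$vocab_size)^config$zipf_exponent)
  bg_prob <- bg_prob / sum(bg_prob)

  common_tokens <- if (config$n_common > 0L)
    sprintf("common%02d", seq_len(config$n_common)) else character(0)
  # occurrence probability increases linearly with the rank of N_d
  common_p <- stats::setNames(
    config$common_p_range[1L] +
      diff(config$common_p_range) * rank(n_abs, ties.method = "first") / n,
    drugs)

  chars <- lapply(config$characteristics, function(ch) {
    list(id = ch$id,
         positives = sort(sample(drugs, ch$n_pos)),
         signal_tokens = sprintf("sig_%s_%02d", ch$id, seq_len(ch$n_signal)),
         p_pos = ch$p_pos, p_neg = ch$p_neg)
  })
  names(chars) <- vapply(chars, `[[`, character(1), "id")

  ids <- character(0)
  titles <- character(0)
  bodies <- character(0)
  serial <- 0L
  for (d in drugs) {
    for (k in seq_len(n_abs[[d]])) {
      serial <- serial + 1L
      len <- stats::rpois(1L, config$tokens_per_abstract)
      toks <- if (len > 0L)
        sample(bg_vocab, len, replace = TRUE, prob = bg_prob) else character(0)
      if (length(common_tokens) > 0L) {
        hit <- stats::runif(length(common_tokens)) < common_p[[d]]
        toks <- c(toks, common_tokens[hit])
      }
      for (ch in chars) {
        p <- if (d %in% ch$positives) ch$p_pos else ch$p_neg
        hit <- stats::runif(length(ch$signal_tokens)) < p
        toks <- c(toks, ch$signal_tokens[hit])
      }
      if (length(toks) > 1L) toks <- sample(toks)
      ids <- c(ids, sprintf("a%06d", serial))
      titles <- c(titles, paste(d, "study"))
      bodies <- c(bodies, paste(toks, collapse = " "))
    }
  }

  rare_tokens <- if (config$n_rare > 0L)
    sprintf("rare%02d", seq_len(config$n_rare)) else character(0)
  if (length(rare_tokens) > 0L) {
    slots <- sample(length(ids), length(rare_tokens))
    for (i in seq_along(rare_tokens)) {
      bodies[slots[i]] <- paste(bodies[slots[i]], rare_tokens[i])
    }
  }

  records <- data.frame(abstract_id = ids, title = titles, body = bodies,
                        stringsAsFactors = FALSE)
  lexicon <- drug_lexicon(drugs)
  labels <- lapply(chars, function(ch)
    characteristic_labels(ch$id, ch$positives, drugs))
  manifest <- list(
    rare_tokens = rare_tokens,
    common_tokens = common_tokens,
    common_p = common_p,
    characteristics = lapply(chars, function(ch)
      ch[c("id", "positives", "signal_tokens", "p_pos", "p_neg")]),
    n_abstracts = n_abs,
    config = unclass(config)
  )
  list(records = records, lexicon = lexicon, labels = labels,
       manifest = manifest)
}

#' Draw a null characteristic
#'
#' Positives are sampled uniformly at random from the drug universe; no token
#' distribution depends on the label, so the pipeline's AUC on such labels
#' calibrates its behaviour under the null of no signal.
#'
#' @param drugs drug universe (character vector).
#' @param n_pos number of positives (must leave at least one negative).
#' @param seed integer seed.
#' @param characteristic_id id for the generated label set.
#' @return a [characteristic_labels()] object.
#' @export
null_characteristic <- function(drugs, n_pos, seed = 1L,
                                characteristic_id = sprintf("null%04d", seed)) {
  stopifnot(n_pos >= 1)
  if (n_pos >= length(drugs)) {
    stop("n_pos must be smaller than the number of drugs (no negatives left)")
  }
  set.seed(seed)
  characteristic_labels(characteristic_id, sample(drugs, n_pos), drugs)
}

#' Write a synthetic corpus to disk
#'
#' Emits exactly the dialects the corpus readers consume: \code{corpus.jsonl}
#' (keys \code{abstract_id}, \code{title}, \code{abstract}),
#' \code{lexicon.tsv} (\code{drug_name}, pipe-separated \code{synonyms}),
#' \code{labels.tsv} (long format \code{characteristic_id},
#' \code{drug_name}) and \code{manifest.json}.
#'
#' @param sim a [simulate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(seq_len(nrow(sim$records)), function(i)
    as.character(jsonlite::toJSON(list(
      abstract_id = sim$records$abstract_id[i],
      title = sim$records$title[i],
      abstract = sim$records$body[i]), auto_unbox = TRUE)), character(1))
  writeLines(lines, file.path(dir, "corpus.jsonl"))
  lex <- data.frame(
    drug_name = sim$lexicon$drug_name,
    synonyms = vapply(sim$lexicon$synonyms, paste, character(1),
                      collapse = "|"),
    stringsAsFactors = FALSE)
  utils::write.table(lex, file.path(dir, "lexicon.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lab <- do.call(rbind, lapply(sim$labels, function(l) data.frame(
    characteristic_id = l$characteristic_id, drug_name = l$positives,
    stringsAsFactors = FALSE)))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
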