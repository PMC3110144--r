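# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# A tiny handcrafted corpus: 8 abstracts, two drugs, a token ("inr") present
# in a known fraction of warfarin abstracts, and a synonym-only abstract for
# tramadol ("zydol").
tiny_records <- function() {
  data.frame(
    abstract_id = sprintf("pm%02d", 1:8),
    title = c("warfarin dosing", "warfarin and inr", "warfarin bleeding",
              "warfarin reversal", "warfarin genetics",
              "tramadol analgesia", "tramadol overdose", "zydol in practice"),
    body = c("stable inr control on warfarin therapy",
             "inr variability under warfarin",
             "major bleeding events",
             "vitamin k for reversal",
             "cyp2c9 and vkorc1 variants",
             "opioid receptor binding of tramadol",
             "serotonin syndrome risk",
             "postoperative pain relief"),
    stringsAsFactors = FALSE)
}

tiny_lexicon <- function() {
  drug_lexicon(c("warfarin", "tramadol"),
               synonyms = list(character(0), "Zydol SR 100"))
}

# jsonl writer for corpus data frames (mirrors the generator's dialect)
write_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i)
    as.character(jsonlite::toJSON(list(
      abstract_id = records$abstract_id[i],
      title = records$title[i],
      abstract = records$body[i]), auto_unbox = TRUE)), character(1))
  writeLines(lines, path)
  path
}

# brute-force per-abstract membership recount of cdf (independent of the
# package's counting path: works from raw text)
brute_cdf <- function(records, index, drug, stopwords = default_stopwords()) {
  ids <- index$abstract_ids[[drug]]
  texts <- paste(records$title, records$body)[match(ids, records$abstract_id)]
  sets <- lapply(texts, tokenize, stopwords = stopwords)
  toks <- sort(unique(unlist(sets)))
  sapply(toks, function(w) mean(vapply(sets, function(s) w %in% s, logical(1))))
}

# brute-force pairwise Mann-Whitney AUC (the oracle: loops over all
# positive x negative pairs, half credit for ties)
brute_auc <- function(scores, positives, universe) {
  s <- setNames(numeric(length(universe)), universe)
  s[intersect(names(scores), universe)] <-
    scores[intersect(names(scores), universe)]
  pos <- s[universe %in% positives]
  neg <- s[!universe %in% positives]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# cached default-condition simulation + matrix shared by the heavier tests
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 20260921L) {
  key <- paste0("sim", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_corpus(synthetic_config(seed = seed))
    idx <- build_drug_index(sim$records, sim$lexicon)
    fm <- frequency_matrix(idx, measure = "cdf")
    .sim_cache[[key]] <- list(sim = sim, index = idx, fm = fm)
  }
  .sim_cache[[key]]
}

# a smaller planted-signal world for fast unit tests
small_sim <- function(seed = 11L) {
  key <- paste0("small", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_corpus(synthetic_config(
      n_drugs = 60L, vocab_size = 800L, seed = seed,
      characteristics = list(list(id = "c1", n_pos = 10L, n_signal = 10L,
                                  p_pos = 0.6, p_neg = 0.05))))
    idx <- build_drug_index(sim$records, sim$lexicon)
    fm <- frequency_matrix(idx, measure = "cdf")
    .sim_cache[[key]] <- list(sim = sim, index = idx, fm = fm)
  }
  .sim_cache[[key]]
}
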