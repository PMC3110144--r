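test_that("tokenize splits on whitespace/comma/semicolon, keeps hyphens and digits", {
  expect_setequal(
    tokenize("The ST-segment and PGE2 levels", stopwords = c("the", "and")),
    c("st-segment", "pge2", "levels"))
  expect_identical(tokenize("", stopwords = character(0)), character(0))
  # set semantics + case folding: duplicates across delimiters collapse
  expect_identical(tokenize("warfarin, warfarin; WARFARIN",
                            stopwords = character(0)), "warfarin")
  # edge punctuation stripped, internal hyphens/digits preserved
  expect_setequal(
    tokenize("(5-HT3) antagonists: a review!", stopwords = c("a")),
    c("5-ht3", "antagonists", "review"))
})

test_that("tokenization is deterministic and idempotent on its own output", {
  text <- "Beta-blockers reduce mortality; carvedilol, metoprolol succinate."
  sw <- default_stopwords()
  t1 <- tokenize(text, sw)
  t2 <- tokenize(paste(t1, collapse = " "), sw)
  expect_identical(sort(t1), sort(t2))
  expect_identical(t1, tokenize(text, sw))
})

test_that("stemming never enlarges a token bag and maps to Porter stems", {
  sw <- character(0)
  raw <- tokenize("motoring motors motored motor", sw)
  stemmed <- tokenize("motoring motors motored motor", sw, stemming = TRUE)
  expect_lte(length(stemmed), length(raw))
  expect_identical(stemmed, "motor")
})

test_that("load_corpus reads JSONL, tolerates degenerate records", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"abstract_id":"a1","title":"t1","abstract":"body one"}',
    '{"abstract_id":"a2","title":"t2","abstract":"body two"}',
    '{"abstract_id":"a3","title":"t3","abstract":"body three"}'), path)
  recs <- load_corpus(path, "jsonl")
  expect_equal(nrow(recs), 3L)
  expect_identical(recs$abstract_id, c("a1", "a2", "a3"))

  # missing abstract field -> retained title-only, with warning
  writeLines(c('{"abstract_id":"a1","title":"t1"}'), path)
  expect_warning(recs <- load_corpus(path, "jsonl"), "title-only")
  expect_identical(recs$body, "")

  # malformed line -> skipped with warning; empty file -> empty collection
  writeLines(c('{"abstract_id":"a1","title":"t","abstract":"x"}', "{oops"),
             path)
  expect_warning(recs <- load_corpus(path, "jsonl"), "malformed")
  expect_equal(nrow(recs), 1L)
  writeLines(character(0), path)
  expect_equal(nrow(load_corpus(path, "jsonl")), 0L)
})

test_that("load_corpus reads PubMed citation XML", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<PubmedArticleSet>
  <PubmedArticle><MedlineCitation><PMID>101</PMID>
    <Article><ArticleTitle>Warfarin dosing</ArticleTitle>
      <Abstract><AbstractText>Part one.</AbstractText>
               <AbstractText>Part two.</AbstractText></Abstract>
    </Article></MedlineCitation></PubmedArticle>
  <PubmedArticle><MedlineCitation><PMID>102</PMID>
    <Article><ArticleTitle>No abstract here</ArticleTitle></Article>
  </MedlineCitation></PubmedArticle>
</PubmedArticleSet>', path)
  recs <- load_corpus(path, "medline_xml")
  expect_equal(nrow(recs), 2L)
  expect_identical(recs$abstract_id, c("101", "102"))
  expect_identical(recs$body[1], "Part one. Part two.")
  expect_identical(recs$body[2], "")
})

test_that("normalize_trade_name strips strength and formulation suffixes", {
  expect_identical(normalize_trade_name("Zydol SR 100"), "zydol")
  expect_identical(normalize_trade_name("Zydol SR 200"), "zydol")
  expect_identical(normalize_trade_name("Zofran syrup"), "zofran")
  expect_identical(normalize_trade_name("Zofran"), "zofran")
  # stripping everything keeps the lower-cased original, with warning
  expect_warning(out <- normalize_trade_name("SR 100"), "keeping full name")
  expect_identical(out, "sr 100")
})

test_that("build_drug_index counts matched abstracts per drug", {
  idx <- build_drug_index(tiny_records(), tiny_lexicon())
  expect_equal(unname(idx$n_abstracts["warfarin"]), 5L)
  expect_equal(unname(idx$n_abstracts["tramadol"]), 2L)
  expect_setequal(idx$abstract_ids$warfarin, sprintf("pm%02d", 1:5))

  # a drug absent from the corpus is retained with N_d = 0
  lex <- drug_lexicon(c("warfarin", "absentinib"))
  expect_message(idx0 <- build_drug_index(tiny_records(), lex), "no abstract")
  expect_equal(unname(idx0$n_abstracts["absentinib"]), 0L)
  expect_identical(idx0$abstract_ids$absentinib, character(0))
})

test_that("synonym matching adds abstracts and is always a superset", {
  no_syn <- build_drug_index(tiny_records(), tiny_lexicon(),
                             use_synonyms = FALSE)
  with_syn <- build_drug_index(tiny_records(), tiny_lexicon(),
                               use_synonyms = TRUE)
  # "zydol" (normalized from "Zydol SR 100") matches one extra abstract
  expect_true(all(no_syn$abstract_ids$tramadol %in%
                    with_syn$abstract_ids$tramadol))
  expect_equal(unname(with_syn$n_abstracts["tramadol"]), 3L)
  for (d in no_syn$drugs) {
    expect_true(all(no_syn$abstract_ids[[d]] %in% with_syn$abstract_ids[[d]]))
  }
})

test_that("multi-word names match as contiguous sequences or hyphen-joined", {
  recs <- data.frame(
    abstract_id = c("x1", "x2", "x3"),
    title = c("valproic acid monotherapy", "valproic-acid levels",
              "acid reflux and valproic metabolites"),
    body = c("", "", ""), stringsAsFactors = FALSE)
  idx <- build_drug_index(recs, drug_lexicon("valproic acid"))
  # x3 has both words but not contiguously: no match
  expect_setequal(idx$abstract_ids[["valproic acid"]], c("x1", "x2"))
})

test_that("matching sees the raw stream even when the name is a stop word casualty", {
  # stop-word removal happens after matching: a name containing "a" still works
  recs <- data.frame(abstract_id = "y1", title = "vitamin a deficiency",
                     body = "", stringsAsFactors = FALSE)
  idx <- build_drug_index(recs, drug_lexicon("vitamin a"))
  expect_equal(unname(idx$n_abstracts["vitamin a"]), 1L)
})
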