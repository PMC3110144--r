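# Corpus reading, tokenization and the drug -> abstract index.
#
# An abstract (title + body) is tokenized into maximal runs between
# whitespace, comma and semicolon delimiters; tokens are lower-cased, leading
# and trailing sentence punctuation is stripped, internal hyphens and digits
# are preserved ("st-segment", "5-ht3", "pge2"). Drug matching is a
# case-insensitive contiguous token-sequence match in the raw (pre stop-word
# removal) token stream, the closest offline analogue of a keyword query
# against a literature database.

.delim_regex <- "[\\s,;]+"
.edge_punct_regex <- "^[].()\\[{}:\"'?!]+|[].()\\[{}:\"'?!]+$"

# raw token stream: ordered, with multiplicity, lower-cased, edge punctuation
# stripped, no stop-word removal and no stemming (used for drug-name matching)
.raw_tokens <- function(text) {
  toks <- strsplit(tolower(text), .delim_regex, perl = TRUE)[[1L]]
  toks <- gsub(.edge_punct_regex, "", toks, perl = TRUE)
  toks[nzchar(toks)]
}

# processed token counts (named integer vector): stop words removed, then
# optionally stemmed, multiplicities aggregated by (stemmed) token
.token_counts <- function(raw, stopwords, stemming = FALSE) {
  toks <- raw[!(raw %in% stopwords)]
  if (length(toks) == 0L) return(stats::setNames(integer(0), character(0)))
  if (stemming) toks <- porter_stem(toks)
  tab <- table(toks)
  stats::setNames(as.integer(tab), names(tab))
}

#' Tokenize text into a bag of tokens
#'
#' Splits \code{text} on whitespace, comma and semicolon, lower-cases, strips
#' leading/trailing punctuation in \code{.()[]{}:"'?!} while preserving
#' internal hyphens and digits, removes stop words, optionally Porter-stems
#' the survivors, and returns the resulting token \emph{set} (each token at
#' most once).
#'
#' @param text character scalar (an abstract, typically title and body pasted
#'   together).
#' @param stopwords character vector of stop words to drop (compared after
#'   lower-casing); see [default_stopwords()].
#' @param stemming logical; replace each surviving token by its Porter stem?
#' @return character vector: the unordered token set (empty for empty text).
#' @examples
#' tokenize("The ST-segment and PGE2 levels", stopwords = c("the", "and"))
#' @export
tokenize <- function(text, stopwords = default_stopwords(), stemming = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  sort(unique(names(.token_counts(.raw_tokens(text), stopwords, stemming))))
}

#' Default English stop-word list
#'
#' Reads the stop-word list shipped with the package (one term per line,
#' \code{#} comments allowed). The list is a conventional English stop list
#' covering articles, conjunctions, prepositions and auxiliaries; pass a
#' different file to audit or extend it.
#'
#' @param path file to read; defaults to the packaged list.
#' @return character vector of stop words.
#' @export
default_stopwords <- function(path = system.file("extdata", "stopwords.txt",
                                                 package = "drugchar")) {
  read_wordlist(path)
}

#' Default trade-name formulation suffixes
#'
#' Formulation/strength suffix vocabulary used by [normalize_trade_name()]
#' (one term per line, \code{#} comments allowed).
#'
#' @param path file to read; defaults to the packaged list.
#' @return character vector of suffix terms (lower-case).
#' @export
default_formulation_suffixes <- function(path = system.file(
    "extdata", "formulation_suffixes.txt", package = "drugchar")) {
  read_wordlist(path)
}

#' Read a one-term-per-line word list
#'
#' @param path file path; lines starting with \code{#} and blank lines are
#'   ignored; terms are lower-cased.
#' @return character vector.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) stop("word list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tolower(lines)
}

#' Load a corpus of abstract records
#'
#' Reads abstracts either from line-delimited JSON (one object per line with
#' keys \code{abstract_id}, \code{title}, \code{abstract}) or from PubMed
#' citation XML (\code{PubmedArticleSet}; PMID, ArticleTitle and AbstractText
#' are extracted). Records with a missing abstract are retained title-only;
#' malformed records are skipped with a warning giving the count.
#'
#' @param path file path.
#' @param format \code{"jsonl"} or \code{"medline_xml"}.
#' @return data frame with columns \code{abstract_id}, \code{title},
#'   \code{body} (one row per citation).
#' @export
load_corpus <- function(path, format = c("jsonl", "medline_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  recs <- switch(format,
    jsonl = .load_jsonl(path),
    medline_xml = .load_medline_xml(path)
  )
  dup <- duplicated(recs$abstract_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate abstract_id(s) dropped (first kept)")
    recs <- recs[!dup, , drop = FALSE]
  }
  rownames(recs) <- NULL
  recs
}

.load_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  bad <- 0L
  missing_abstract <- 0L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(obj) || is.null(obj[["abstract_id"]]) ||
        is.null(obj[["title"]])) {
      bad <- bad + 1L
      next
    }
    body <- obj[["abstract"]]
    if (is.null(body)) {
      missing_abstract <- missing_abstract + 1L
      body <- ""
    }
    out[[i]] <- data.frame(abstract_id = as.character(obj[["abstract_id"]]),
                           title = as.character(obj[["title"]]),
                           body = as.character(body),
                           stringsAsFactors = FALSE)
  }
  if (bad > 0L) warning(bad, " malformed record(s) skipped")
  if (missing_abstract > 0L) {
    warning(missing_abstract, " record(s) lacked an abstract; kept title-only")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(abstract_id = character(0), title = character(0),
                      body = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.load_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  pmid <- vapply(arts, function(a)
    xml2::xml_text(xml2::xml_find_first(a, ".//PMID")), character(1))
  title <- vapply(arts, function(a)
    xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle")), character(1))
  body <- vapply(arts, function(a) {
    nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    if (length(nodes) == 0L) "" else paste(xml2::xml_text(nodes), collapse = " ")
  }, character(1))
  ok <- !is.na(pmid) & nzchar(pmid)
  if (any(!ok)) warning(sum(!ok), " malformed record(s) skipped")
  data.frame(abstract_id = pmid[ok],
             title = ifelse(is.na(title[ok]), "", title[ok]),
             body = body[ok], stringsAsFactors = FALSE)
}

#' Normalize a trade name
#'
#' Strips trailing strength tokens (pure numbers, optionally with a unit
#' suffix such as \code{mg}) and formulation-suffix terms (e.g. \code{SR},
#' \code{syrup}) from a trade name, and lower-cases the remainder, so that
#' "Zydol SR 100" and "Zydol SR 200" both reduce to "zydol". If stripping
#' would remove everything, the original lower-cased name is kept with a
#' warning.
#'
#' @param raw trade name as printed (non-empty).
#' @param suffixes formulation-suffix vocabulary; see
#'   [default_formulation_suffixes()].
#' @return normalized lower-case trade name.
#' @examples
#' normalize_trade_name("Zydol SR 100")
#' normalize_trade_name("Zofran syrup")
#' @export
normalize_trade_name <- function(raw, suffixes = default_formulation_suffixes()) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  toks <- strsplit(tolower(trimws(raw)), "\\s+")[[1L]]
  strength <- "^[0-9]+([.][0-9]+)?(mg|mcg|g|ml|iu|%)?$"
  keep <- length(toks)
  while (keep >= 1L &&
         (grepl(strength, toks[keep]) || toks[keep] %in% suffixes)) {
    keep <- keep - 1L
  }
  if (keep == 0L) {
    warning("trade name '", raw, "' reduced to nothing; keeping full name")
    return(paste(toks, collapse = " "))
  }
  paste(toks[seq_len(keep)], collapse = " ")
}

#' Read a drug lexicon
#'
#' Reads a tab-separated lexicon with columns \code{drug_name} and
#' \code{synonyms} (pipe-separated trade names, may be empty). Generic names
#' are lower-cased and must be unique; synonyms are normalized with
#' [normalize_trade_name()].
#'
#' @param path TSV file path.
#' @param suffixes formulation-suffix vocabulary for synonym normalization.
#' @return object of class \code{drug_lexicon}: data frame with columns
#'   \code{drug_name} (character) and \code{synonyms} (list of character
#'   vectors).
#' @export
read_lexicon <- function(path, suffixes = default_formulation_suffixes()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("drug_name", "synonyms") %in% names(tab))) {
    stop("lexicon must have columns drug_name and synonyms")
  }
  drug_lexicon(tab$drug_name,
               lapply(strsplit(tab$synonyms, "|", fixed = TRUE),
                      function(s) s[nzchar(s)]),
               suffixes = suffixes)
}

#' Construct a drug lexicon
#'
#' @param drug_name character vector of generic names (unique after
#'   lower-casing).
#' @param synonyms optional list (parallel to \code{drug_name}) of raw trade
#'   names; each is normalized with [normalize_trade_name()].
#' @param suffixes formulation-suffix vocabulary.
#' @return object of class \code{drug_lexicon}.
#' @export
drug_lexicon <- function(drug_name, synonyms = NULL,
                         suffixes = default_formulation_suffixes()) {
  drug_name <- tolower(trimws(drug_name))
  if (anyDuplicated(drug_name)) stop("duplicate drug names in lexicon")
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), length(drug_name))
  stopifnot(length(synonyms) == length(drug_name))
  synonyms <- lapply(synonyms, function(s) {
    if (length(s) == 0L) return(character(0))
    unique(vapply(s, normalize_trade_name, character(1),
                  suffixes = suffixes, USE.NAMES = FALSE))
  })
  out <- data.frame(drug_name = drug_name, stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  class(out) <- c("drug_lexicon", "data.frame")
  out
}

# does the (multi-word) query occur as a contiguous token run, or as a single
# hyphen-joined token, in the raw token stream?
.match_query <- function(raw, query_tokens) {
  nq <- length(query_tokens)
  if (nq == 0L) return(FALSE)
  if (nq == 1L) return(query_tokens %in% raw)
  hyph <- paste(query_tokens, collapse = "-")
  if (hyph %in% raw) return(TRUE)
  hits <- which(raw == query_tokens[1L])
  hits <- hits[hits + nq - 1L <= length(raw)]
  for (h in hits) {
    if (all(raw[h + seq_len(nq - 1L)] == query_tokens[-1L])) return(TRUE)
  }
  FALSE
}

#' Build the drug -> abstract index
#'
#' Matches every lexicon drug against every abstract (title + body): drug
#' \code{d} matches abstract \code{a} iff the lower-cased drug name occurs as
#' a contiguous token sequence (or as the hyphen-joined single token) in
#' \code{a}'s raw token stream, before stop-word removal. With
#' \code{use_synonyms = TRUE} a normalized trade-name match also counts, so
#' the matched set is always a superset of the generic-name-only set. Drugs
#' matching no abstract are retained with an empty set (the drug universe
#' stays fixed).
#'
#' @param records corpus data frame from [load_corpus()].
#' @param lexicon a [drug_lexicon()].
#' @param use_synonyms logical; also match trade-name synonyms?
#' @param stemming logical; Porter-stem the stored token bags?
#' @param stopwords stop words removed from the stored bags (matching is done
#'   on the raw stream, so stop words inside multi-word names still match).
#' @return object of class \code{drug_index}: list with elements
#'   \code{drugs}, \code{abstract_ids} (list per drug), \code{n_abstracts}
#'   (named integer, \eqn{N_d}), \code{token_counts} (named integer vector per
#'   abstract: token multiplicities after stop-word removal and optional
#'   stemming), and the flags used.
#' @export
build_drug_index <- function(records, lexicon, use_synonyms = FALSE,
                             stemming = FALSE,
                             stopwords = default_stopwords()) {
  stopifnot(inherits(lexicon, "drug_lexicon"), nrow(lexicon) > 0L)
  raw <- lapply(seq_len(nrow(records)), function(i)
    .raw_tokens(paste(records$title[i], records$body[i])))
  names(raw) <- records$abstract_id
  counts <- lapply(raw, .token_counts, stopwords = stopwords,
                   stemming = stemming)

  # postings: token -> abstract indices (on unique raw tokens)
  uniq <- lapply(raw, unique)
  post_tok <- unlist(uniq, use.names = FALSE)
  post_abs <- rep.int(seq_along(uniq), lengths(uniq))
  postings <- split(post_abs, post_tok)

  match_one <- function(queries) {
    hit <- integer(0)
    for (q in queries) {
      qt <- strsplit(q, "\\s+")[[1L]]
      qt <- qt[nzchar(qt)]
      if (length(qt) == 0L) next
      if (length(qt) == 1L) {
        hit <- c(hit, postings[[qt]])
      } else {
        cand <- postings[[qt[1L]]]
        hyph <- postings[[paste(qt, collapse = "-")]]
        if (!is.null(hyph)) hit <- c(hit, hyph)
        for (a in cand) if (.match_query(raw[[a]], qt)) hit <- c(hit, a)
      }
    }
    sort(unique(hit))
  }

  abstract_ids <- vector("list", nrow(lexicon))
  names(abstract_ids) <- lexicon$drug_name
  zero_match <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    queries <- lexicon$drug_name[i]
    if (use_synonyms) queries <- c(queries, lexicon$synonyms[[i]])
    idx <- match_one(queries)
    abstract_ids[[i]] <- records$abstract_id[idx]
    if (length(idx) == 0L) zero_match <- c(zero_match, lexicon$drug_name[i])
  }
  if (length(zero_match) > 0L) {
    message(length(zero_match), " drug(s) matched no abstract and carry no features: ",
            paste(utils::head(zero_match, 5L), collapse = ", "),
            if (length(zero_match) > 5L) ", ..." else "")
  }
  structure(list(
    drugs = lexicon$drug_name,
    abstract_ids = abstract_ids,
    n_abstracts = stats::setNames(lengths(abstract_ids), lexicon$drug_name),
    token_counts = counts,
    use_synonyms = use_synonyms,
    stemming = stemming,
    n_stopwords = length(stopwords)
  ), class = "drug_index")
}

#' @export
print.drug_index <- function(x, ...) {
  cat("Drug-abstract index:", length(x$drugs), "drugs,",
      length(x$token_counts), "abstracts\n")
  cat("  abstracts per drug: median", stats::median(x$n_abstracts),
      " range", min(x$n_abstracts), "-", max(x$n_abstracts), "\n")
  cat("  synonyms:", x$use_synonyms, " stemming:", x$stemming, "\n")
  invisible(x)
}
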