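# Porter (1980) suffix-stripping algorithm.
#
# A word is viewed as [C](VC)^m[V]; m is the "measure" of a stem. Within each
# step the longest matching suffix is taken and, if its condition fails, the
# step ends without trying shorter suffixes. Letters a,e,i,o,u are vowels; y
# is a vowel when preceded by a consonant. Non-letters (digits in tokens such
# as "pge2") are treated as consonants, which leaves them untouched by the
# alphabetic suffix rules.

.pt_is_cons <- function(letters, i) {
  ch <- letters[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(letters, i - 1L))
  }
  TRUE
}

# measure m of the first k letters
.pt_m <- function(letters, k) {
  if (k < 1L) return(0L)
  cons <- vapply(seq_len(k), function(i) .pt_is_cons(letters, i), logical(1))
  r <- rle(cons)
  v <- r$values
  if (length(v) < 2L) return(0L)
  sum(!v[-length(v)] & v[-1L])
}

.pt_has_vowel <- function(letters, k) {
  if (k < 1L) return(FALSE)
  any(!vapply(seq_len(k), function(i) .pt_is_cons(letters, i), logical(1)))
}

# stem ends with a double consonant
.pt_doublec <- function(letters, k) {
  k >= 2L && letters[k] == letters[k - 1L] && .pt_is_cons(letters, k)
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y
.pt_cvc <- function(letters, k) {
  if (k < 3L) return(FALSE)
  if (!.pt_is_cons(letters, k) || .pt_is_cons(letters, k - 1L) ||
      !.pt_is_cons(letters, k - 2L)) return(FALSE)
  !(letters[k] %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suffix) {
  nw <- nchar(word)
  ns <- nchar(suffix)
  nw > ns && substring(word, nw - ns + 1L, nw) == suffix
}

.pt_letters <- function(word) strsplit(word, "", fixed = TRUE)[[1L]]

# replace `suffix` by `repl` when m(stem) satisfies `cond` (a function of m)
.pt_rule_set <- function(word, rules, cond) {
  for (i in seq_along(rules)) {
    suf <- names(rules)[i]
    if (.pt_ends(word, suf)) {
      stem <- substring(word, 1L, nchar(word) - nchar(suf))
      L <- .pt_letters(stem)
      if (cond(.pt_m(L, length(L)))) {
        return(paste0(stem, rules[[i]]))
      }
      return(word)  # longest match found, condition failed: step over
    }
  }
  word
}

.pt_step1a <- function(word) {
  if (.pt_ends(word, "sses")) return(paste0(substring(word, 1L, nchar(word) - 4L), "ss"))
  if (.pt_ends(word, "ies"))  return(paste0(substring(word, 1L, nchar(word) - 3L), "i"))
  if (.pt_ends(word, "ss"))   return(word)
  if (.pt_ends(word, "s"))    return(substring(word, 1L, nchar(word) - 1L))
  word
}

.pt_step1b <- function(word) {
  if (.pt_ends(word, "eed")) {
    stem <- substring(word, 1L, nchar(word) - 3L)
    L <- .pt_letters(stem)
    if (.pt_m(L, length(L)) > 0L) return(paste0(stem, "ee"))
    return(word)
  }
  fired <- FALSE
  stem <- word
  if (.pt_ends(word, "ed")) {
    cand <- substring(word, 1L, nchar(word) - 2L)
    L <- .pt_letters(cand)
    if (.pt_has_vowel(L, length(L))) { stem <- cand; fired <- TRUE }
  } else if (.pt_ends(word, "ing")) {
    cand <- substring(word, 1L, nchar(word) - 3L)
    L <- .pt_letters(cand)
    if (.pt_has_vowel(L, length(L))) { stem <- cand; fired <- TRUE }
  }
  if (!fired) return(word)
  L <- .pt_letters(stem)
  k <- length(L)
  last2 <- if (k >= 2L) substring(stem, k - 1L, k) else ""
  if (last2 %in% c("at", "bl", "iz")) return(paste0(stem, "e"))
  if (.pt_doublec(L, k) && !(L[k] %in% c("l", "s", "z"))) {
    return(substring(stem, 1L, k - 1L))
  }
  if (.pt_m(L, k) == 1L && .pt_cvc(L, k)) return(paste0(stem, "e"))
  stem
}

.pt_step1c <- function(word) {
  if (.pt_ends(word, "y")) {
    stem <- substring(word, 1L, nchar(word) - 1L)
    L <- .pt_letters(stem)
    if (.pt_has_vowel(L, length(L))) return(paste0(stem, "i"))
  }
  word
}

.pt_step2_rules <- c(
  ational = "ate", ization = "ize", iveness = "ive", fulness = "ful",
  ousness = "ous", tional = "tion", biliti = "ble", entli = "ent",
  ousli = "ous", ation = "ate", alism = "al", aliti = "al", iviti = "ive",
  enci = "ence", anci = "ance", izer = "ize", abli = "able", alli = "al",
  ator = "ate", eli = "e"
)

.pt_step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ness = "", ful = ""
)

.pt_step4 <- function(word) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (suf in sufs) {
    if (.pt_ends(word, suf)) {
      stem <- substring(word, 1L, nchar(word) - nchar(suf))
      L <- .pt_letters(stem)
      k <- length(L)
      ok <- .pt_m(L, k) > 1L
      if (ok && suf == "ion") ok <- k >= 1L && L[k] %in% c("s", "t")
      if (ok) return(stem)
      return(word)
    }
  }
  word
}

.pt_step5 <- function(word) {
  if (.pt_ends(word, "e")) {
    stem <- substring(word, 1L, nchar(word) - 1L)
    L <- .pt_letters(stem)
    k <- length(L)
    a <- .pt_m(L, k)
    if (a > 1L || (a == 1L && !.pt_cvc(L, k))) word <- stem
  }
  L <- .pt_letters(word)
  k <- length(L)
  if (k >= 1L && L[k] == "l" && .pt_doublec(L, k) && .pt_m(L, k) > 1L) {
    word <- substring(word, 1L, k - 1L)
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)
  word <- .pt_step1a(word)
  word <- .pt_step1b(word)
  word <- .pt_step1c(word)
  word <- .pt_rule_set(word, .pt_step2_rules, function(m) m > 0L)
  word <- .pt_rule_set(word, .pt_step3_rules, function(m) m > 0L)
  word <- .pt_step4(word)
  .pt_step5(word)
}

#' Porter stem of a token
#'
#' Reduces each token to its stem with the Porter (1980) suffix-stripping
#' algorithm (the classic five-step rule tables, longest-match within each
#' step). Tokens are expected lower-case; tokens of one or two characters, and
#' tokens whose suffixes trigger no rule (e.g. \code{"pge2"}), are returned
#' unchanged. The mapping is deterministic and many-to-one, so stemming never
#' enlarges a vocabulary.
#'
#' @param tokens character vector of tokens.
#' @return character vector of stems, same length as \code{tokens}.
#' @examples
#' porter_stem(c("caresses", "ponies", "motoring", "sky", "pge2"))
#' @export
porter_stem <- function(tokens) {
  stopifnot(is.character(tokens))
  vapply(tokens, .porter1, character(1), USE.NAMES = FALSE)
}
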