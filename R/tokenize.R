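#' Tokenize message text
#'
#' Splits raw message text into word tokens using the conventions applied
#' throughout the package: split on runs of Unicode whitespace, strip leading
#' and trailing punctuation from each token (a leading `#` or `@` is kept, so
#' hashtags and handles survive), optionally fold case to lower. Tokens that
#' are empty after stripping are dropped.
#'
#' @param text character vector of message texts (UTF-8).
#' @param case_fold lowercase all tokens? Default `TRUE`; lowercasing
#'   maximizes matches against sentiment lexicons, which are lowercase.
#' @return a list of character vectors, one per input element; empty input
#'   text yields `character(0)`.
#' @examples
#' tokenize("My mental health matters!")[[1]]
#' tokenize("#BellLetsTalk!")[[1]]
#' @export
tokenize <- function(text, case_fold = TRUE) {
  stopifnot(is.character(text))
  if (length(text) == 0L) return(list())
  ft <- tokenize_flat(text, case_fold = case_fold)
  out <- vector("list", length(text))
  if (length(ft$midx)) {
    grp <- split(ft$tokens, ft$midx)
    out[as.integer(names(grp))] <- grp
  }
  empty <- vapply(out, is.null, logical(1))
  out[empty] <- list(character(0))
  out
}

# flat tokenization: all tokens in one vector plus the index of the message
# each token came from; the representation used by the counting hot path
tokenize_flat <- function(text, case_fold = TRUE) {
  raw <- strsplit(trimws(text), "\\s+", perl = TRUE)
  lens <- lengths(raw)
  flat <- unlist(raw, use.names = FALSE)
  if (is.null(flat) || length(flat) == 0L) {
    return(list(tokens = character(0), midx = integer(0), nmsg = length(text)))
  }
  flat <- clean_tokens(flat, case_fold = case_fold)
  idx <- rep.int(seq_along(raw), lens)
  keep <- nzchar(flat)
  list(tokens = flat[keep], midx = idx[keep], nmsg = length(text))
}

# strip leading/trailing punctuation (keeping one leading # or @);
# vectorized over a flat token vector; returns "" for tokens reduced to nothing
clean_tokens <- function(tok, case_fold = TRUE) {
  if (case_fold) tok <- tolower(tok)
  pfx <- grepl("^[#@]", tok)
  core <- tok
  if (any(pfx)) core[pfx] <- substring(core[pfx], 2L)
  dirty <- grepl("^[[:punct:]]|[[:punct:]]$", core, perl = TRUE)
  if (any(dirty)) {
    core[dirty] <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", core[dirty],
                        perl = TRUE)
  }
  out <- core
  if (any(pfx)) out[pfx] <- paste0(substring(tok[pfx], 1L, 1L), core[pfx])
  out[!nzchar(core)] <- ""
  out
}

#' Extract contiguous n-grams from a token sequence
#'
#' Returns every contiguous window of `n` tokens, joined by single spaces,
#' in message order with duplicates retained. Sequences shorter than `n`
#' yield no n-grams.
#'
#' @param tokens character vector of tokens (one message).
#' @param n n-gram order; one of 1, 2, 3.
#' @return character vector of n-grams (possibly empty).
#' @examples
#' extract_ngrams(c("a", "b", "c"), 2)
#' @export
extract_ngrams <- function(tokens, n) {
  if (!(length(n) == 1L && n %in% 1:3)) {
    stop("`n` must be one of 1, 2, 3", call. = FALSE)
  }
  n <- as.integer(n)
  m <- length(tokens)
  if (m < n) return(character(0))
  if (n == 1L) return(tokens)
  if (n == 2L) {
    return(paste(tokens[-m], tokens[-1L]))
  }
  paste(tokens[seq_len(m - 2L)], tokens[2:(m - 1L)], tokens[3:m])
}
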