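#' Normalize a surface string for dictionary matching
#'
#' Case-fold, map punctuation to spaces, collapse runs of whitespace and
#' trim. This is the canonical normalization applied to both lexicon
#' synonyms and candidate text spans.
#'
#' @param x Character vector.
#' @return Character vector of normalized strings.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Matcher configuration
#'
#' @param threshold Minimum normalized string similarity in `[0, 1]` for a
#'   span to count as a match (default 0.8). Similarity 1 means exact
#'   normalized equality; below 1 a normalized edit-ratio is used.
#' @param case_fold Fold case before matching (default `TRUE`).
#' @param strip_punctuation Treat punctuation as token separators
#'   (default `TRUE`).
#' @return An object of class `matcher_config`.
#' @export
matcher_config <- function(threshold = 0.8, case_fold = TRUE,
                           strip_punctuation = TRUE) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  structure(list(threshold = threshold, case_fold = isTRUE(case_fold),
                 strip_punctuation = isTRUE(strip_punctuation)),
            class = "matcher_config")
}

# Tokenize text keeping 0-based half-open character offsets into the
# original string.
.tokenize_offsets <- function(text, strip_punctuation = TRUE, case_fold = TRUE) {
  pat <- if (strip_punctuation) "[[:alnum:]]+" else "[^[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tok <- substring(text, starts, starts + lens - 1L)
  if (case_fold) tok <- tolower(tok)
  data.frame(token = tok, start = starts - 1L, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

# Synonym lookup structures for a given config. The default-config version
# is cached on the lexicon after first use.
.syn_tables <- function(lexicon, config) {
  default <- config$case_fold && config$strip_punctuation
  if (default && !is.null(lexicon$cache$syn_tables)) {
    return(lexicon$cache$syn_tables)
  }
  norm <- function(s) {
    if (config$case_fold) s <- tolower(s)
    if (config$strip_punctuation) s <- gsub("[^[:alnum:][:space:]]+", " ", s)
    gsub("[[:space:]]+", " ", trimws(s))
  }
  e <- lexicon$entries
  syn <- unlist(e$synonyms, use.names = FALSE)
  cid <- rep(e$concept_id, lengths(e$synonyms))
  key <- norm(syn)
  keep <- nzchar(key)
  tab <- data.frame(key = key[keep], concept_id = cid[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(paste0(tab$key, "\r", tab$concept_id)), , drop = FALSE]
  tab$ntok <- lengths(strsplit(tab$key, " ", fixed = TRUE))
  tab$nchr <- nchar(tab$key)
  tab$first <- substr(tab$key, 1, 1)
  idx <- split(tab$concept_id, tab$key)
  by_ntok <- split(tab, tab$ntok)
  # per n-gram size, an inverted token index for fuzzy candidate blocking
  by_ntok <- lapply(by_ntok, function(p) {
    tok <- strsplit(p$key, " ", fixed = TRUE)
    inv <- split(rep(seq_len(nrow(p)), lengths(tok)), unlist(tok))
    # keep only informative tokens: near-ubiquitous ones ("of", "the",
    # shared unit words) explode the candidate set without adding signal
    inv <- inv[lengths(inv) <= max(3, 0.05 * nrow(p))]
    attr(p, "token_index") <- inv
    p
  })
  res <- list(index = idx, by_ntok = by_ntok, max_ntok = max(tab$ntok))
  if (default) lexicon$cache$syn_tables <- res
  res
}

#' Match lexicon concepts in free text
#'
#' Deterministic dictionary matcher: the text is tokenized under the
#' configured normalization and candidate spans (token n-grams up to the
#' longest synonym length) are compared to lexicon synonyms. Exact
#' normalized equality scores similarity 1; otherwise a normalized
#' edit-ratio `1 - dist/max(nchar)` is used and spans scoring below
#' `config$threshold` are dropped. Matching is greedy longest-span-first
#' with left-to-right tie-breaking; a token position participates in at
#' most one match per concept, but overlapping matches of *different*
#' concepts are all kept.
#'
#' @param text A single character string (empty text gives zero matches).
#' @param lexicon A [concept_lexicon()].
#' @param config A [matcher_config()].
#' @return A data.frame with columns `concept_id`, `start`, `end` (0-based
#'   half-open character offsets into `text`), `matched_text` and
#'   `similarity`, ordered by `start`, `end`, `concept_id`.
#' @export
match_concepts <- function(text, lexicon, config = matcher_config()) {
  stopifnot(inherits(lexicon, "concept_lexicon"))
  empty <- data.frame(concept_id = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  if (is.null(text) || !length(text) || is.na(text) || !nzchar(text)) return(empty)
  if (!nrow(lexicon$entries)) stop("empty lexicon")
  st <- .syn_tables(lexicon, config)
  toks <- .tokenize_offsets(text, config$strip_punctuation, config$case_fold)
  m <- nrow(toks)
  if (!m) return(empty)
  cand <- vector("list", 64L); nc <- 0L
  for (n in seq(min(st$max_ntok, m), 1L)) {
    n_spans <- m - n + 1L
    keys <- if (n == 1L) toks$token else
      vapply(seq_len(n_spans),
             function(i) paste(toks$token[i:(i + n - 1L)], collapse = " "),
             character(1))
    hit <- keys %in% names(st$index)
    for (i in which(hit)) {
      ids <- st$index[[keys[i]]]
      nc <- nc + 1L
      cand[[nc]] <- data.frame(
        concept_id = ids, tok_start = i, tok_len = n,
        start = toks$start[i], end = toks$end[i + n - 1L],
        similarity = 1.0, stringsAsFactors = FALSE)
    }
    if (config$threshold < 1 && any(!hit)) {
      pool <- st$by_ntok[[as.character(n)]]
      if (!is.null(pool) && nrow(pool)) {
        miss <- which(!hit)
        tok_index <- attr(pool, "token_index")
        memo <- lexicon$cache$fuzzy_memo
        if (is.null(memo)) {
          memo <- new.env(parent = emptyenv(), hash = TRUE)
          lexicon$cache$fuzzy_memo <- memo
        }
        memo_ok <- config$threshold == 0.8 && config$case_fold &&
          config$strip_punctuation
        for (uk in unique(keys[miss])) {
          mk <- paste0(n, "\r", uk)
          best <- if (memo_ok) memo[[mk]] else NULL
          if (is.null(best)) {
            la <- nchar(uk)
            # candidate blocking: a near-match at this threshold must share
            # at least one informative token, and sit in a tight length band
            rows <- unique(unlist(tok_index[strsplit(uk, " ", fixed = TRUE)[[1]]],
                                  use.names = FALSE))
            best <- numeric(0)
            if (length(rows)) {
              band <- abs(pool$nchr[rows] - la) <=
                (1 - config$threshold) * pmax(pool$nchr[rows], la)
              rows <- rows[band]
            }
            if (length(rows)) {
              sub <- pool[rows, , drop = FALSE]
              d <- utils::adist(uk, sub$key)[1, ]
              sim <- 1 - d / pmax(la, sub$nchr)
              ok <- sim >= config$threshold
              if (any(ok)) {
                bt <- tapply(sim[ok], sub$concept_id[ok], max)
                best <- stats::setNames(as.numeric(bt), names(bt))
              }
            }
            if (memo_ok) memo[[mk]] <- best
          }
          if (!length(best)) next
          for (i in miss[keys[miss] == uk]) {
            nc <- nc + 1L
            if (nc > length(cand)) cand <- c(cand, vector("list", length(cand)))
            cand[[nc]] <- data.frame(
              concept_id = names(best), tok_start = i, tok_len = n,
              start = toks$start[i], end = toks$end[i + n - 1L],
              similarity = as.numeric(best), stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (nc == length(cand)) cand <- c(cand, vector("list", length(cand)))
  }
  if (!nc) return(empty)
  cand <- do.call(rbind, cand[seq_len(nc)])
  # Greedy longest-span-first, left-to-right; per-concept position exclusivity.
  ord <- order(-cand$tok_len, cand$tok_start, -cand$similarity, cand$concept_id)
  cand <- cand[ord, , drop = FALSE]
  consumed <- new.env(parent = emptyenv())
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    cid <- cand$concept_id[r]
    span <- seq(cand$tok_start[r], length.out = cand$tok_len[r])
    used <- consumed[[cid]]
    if (is.null(used) || !any(span %in% used)) {
      keep[r] <- TRUE
      consumed[[cid]] <- c(used, span)
    }
  }
  out <- cand[keep, c("concept_id", "start", "end", "similarity"), drop = FALSE]
  out$matched_text <- substring(text, out$start + 1L, out$end)
  out <- out[order(out$start, out$end, out$concept_id),
             c("concept_id", "start", "end", "matched_text", "similarity")]
  rownames(out) <- NULL
  out
}
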