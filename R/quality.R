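#' Split text into sentences
#'
#' A sentence is a maximal run of text terminated by `.`, `!` or `?` (runs
#' of terminators count once); a trailing fragment without a terminator
#' also counts if it contains any word character.
#'
#' @param text A single character string.
#' @return Character vector of trimmed sentences.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || !length(text) || is.na(text)) return(character())
  parts <- strsplit(text, "[.!?]+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[grepl("[[:alnum:]]", parts)]
}

# Vowel-group syllable heuristic with a silent-e rule: count maximal vowel
# groups (aeiouy); a terminal lone "e" is silent unless the word ends in
# "le" after a consonant; every word has at least one syllable.
count_syllables <- function(words) {
  w <- tolower(words)
  n <- vapply(gregexpr("[aeiouy]+", w), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  silent_e <- grepl("[^aeiouy]e$", w) & !grepl("[^aeiouy]le$", w) & n > 1L
  n <- n - as.integer(silent_e)
  pmax(n, 1L)
}

#' SMOG readability grade
#'
#' The Simple Measure of Gobbledygook estimates the education grade level
#' needed to understand a text from the density of polysyllabic words
#' (three or more syllables): `grade = 1.0430 * sqrt(polysyllables * 30 /
#' sentences) + 3.1291`. Higher values indicate denser prose; 13-16 is
#' roughly college level.
#'
#' @param text A single character string with at least one sentence.
#' @return A list of class `readability_result` with `sentence_count`,
#'   `polysyllable_count` and `smog_grade`.
#' @export
smog_score <- function(text) {
  sentences <- split_sentences(text)
  if (!length(sentences)) stop("smog_score needs at least one sentence")
  words <- unlist(regmatches(sentences, gregexpr("[[:alpha:]']+", sentences)),
                  use.names = FALSE)
  poly <- if (length(words)) sum(count_syllables(words) >= 3L) else 0L
  grade <- 1.0430 * sqrt(poly * 30 / length(sentences)) + 3.1291
  structure(list(sentence_count = length(sentences),
                 polysyllable_count = poly,
                 smog_grade = grade),
            class = "readability_result")
}

#' @export
print.readability_result <- function(x, ...) {
  cat(sprintf("SMOG grade %.2f (%d sentences, %d polysyllabic words)\n",
              x$smog_grade, x$sentence_count, x$polysyllable_count))
  invisible(x)
}

#' Jaccard similarity of two concept sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined to be
#' identical (similarity 1).
#'
#' @param set_a,set_b Character vectors of concept ids (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
concept_jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(1.0)
  length(intersect(a, b)) / u
}

#' Unique concept counts per semantic group
#'
#' Counts distinct concept ids per semantic group across a knowledge
#' base's profile-level concept sets. A concept matched several times in
#' one profile counts once for that profile; distinctness for the returned
#' counts is across the whole knowledge base.
#'
#' @param kb A `knowledge_base`.
#' @return Named integer vector over [SEMANTIC_GROUPS].
#' @export
unique_concept_counts <- function(kb) {
  ids <- unique(unlist(lapply(names(kb$profiles), kb_profile_concepts, kb = kb),
                       use.names = FALSE))
  grp <- factor(concept_group(kb$lexicon, ids), levels = SEMANTIC_GROUPS)
  out <- table(grp)
  stats::setNames(as.integer(out), names(out))
}

#' Quadratic-weighted Cohen's kappa
#'
#' Inter-rater agreement for ordinal ratings with quadratic weights
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2` over `k` ordered categories, so
#' near-misses are penalized less than distant disagreements.
#'
#' @param scores_a,scores_b Parallel vectors of ordinal ratings.
#' @param levels Ordered category values; defaults to the sorted union of
#'   observed ratings.
#' @return Kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(scores_a, scores_b, levels = NULL) {
  if (length(scores_a) != length(scores_b)) stop("rating vectors differ in length")
  if (length(scores_a) < 2) stop("need at least 2 rating pairs")
  if (is.null(levels)) levels <- sort(unique(c(scores_a, scores_b)))
  k <- length(levels)
  if (k < 2) stop("all ratings fall in a single category; kappa undefined")
  fa <- factor(scores_a, levels = levels)
  fb <- factor(scores_b, levels = levels)
  obs <- table(fa, fb) / length(scores_a)
  expd <- outer(rowSums(obs), colSums(obs))
  w <- 1 - outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2) / (k - 1)^2
  denom <- 1 - sum(w * expd)
  if (denom <= .Machine$double.eps) {
    stop("degenerate marginals; weighted kappa undefined")
  }
  1 - (1 - sum(w * obs)) / denom
}

# Host -> category table for reference typing, shipped as extensible TSV.
.reference_host_table <- function() {
  path <- system.file("extdata", "reference_hosts.tsv", package = "rdrkit")
  if (!nzchar(path)) stop("reference_hosts.tsv not found in package extdata")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The six reference-source categories
#' @format Character vector.
#' @export
REFERENCE_CATEGORIES <- c(
  "government_official_db", "rare_disease_db", "clinical_reference",
  "encyclopedia", "academic_journal_portal", "other"
)

#' Categorize a citation by its host
#'
#' Extracts the first URL host from a raw citation string and assigns one
#' of six source categories (government/official biomedical database,
#' rare-disease database, clinical reference, encyclopedia, academic
#' journal portal, other) via a shipped host table. The most specific
#' (longest) matching host suffix wins; unknown hosts and citations
#' without a URL fall back to `other`.
#'
#' @param raw_citation Citation string.
#' @param host_table Optional replacement host table with columns `host`
#'   and `category`.
#' @return A list of class `reference_record` with `raw_citation`, `host`
#'   and `category`.
#' @export
categorize_reference <- function(raw_citation, host_table = NULL) {
  if (is.null(host_table)) host_table <- .reference_host_table()
  m <- regmatches(raw_citation,
                  regexpr("(https?://|www\\.)[^\\s)\\]>,;\"']+", raw_citation,
                          perl = TRUE))
  host <- ""
  category <- "other"
  if (length(m) && nzchar(m)) {
    host <- sub("^https?://", "", m)
    host <- sub("^www\\.", "", host)
    host <- tolower(sub("[/:].*$", "", host))
    # longest suffix match against the table
    hits <- host_table[host == host_table$host |
                         endsWith(host, paste0(".", host_table$host)), , drop = FALSE]
    if (nrow(hits)) {
      category <- hits$category[which.max(nchar(hits$host))]
    }
  }
  structure(list(raw_citation = raw_citation, host = host, category = category),
            class = "reference_record")
}

#' Per-source knowledge quality report
#'
#' One row per disease: SMOG readability over the profile text, reference
#' count and per-category reference counts, and per-group unique concept
#' counts for that profile.
#'
#' @param kb A `knowledge_base`.
#' @return A data.frame.
#' @export
quality_report <- function(kb) {
  host_table <- .reference_host_table()
  rows <- lapply(names(kb$profiles), function(d) {
    p <- kb$profiles[[d]]
    txt <- paste(unlist(p$sections), collapse = " ")
    smog <- if (length(split_sentences(txt))) smog_score(txt)$smog_grade else NA_real_
    cats <- vapply(p$references, function(r) categorize_reference(r, host_table)$category,
                   character(1))
    cat_counts <- table(factor(cats, levels = REFERENCE_CATEGORIES))
    ids <- kb_profile_concepts(kb, d)
    grp_counts <- table(factor(concept_group(kb$lexicon, ids), levels = SEMANTIC_GROUPS))
    cbind(data.frame(disease_id = d, source_id = kb$source_id,
                     smog_grade = smog, n_references = length(p$references),
                     stringsAsFactors = FALSE),
          as.data.frame(t(as.matrix(cat_counts))),
          as.data.frame(t(as.matrix(grp_counts))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
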