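#' Construct a ranked list of disease candidates
#'
#' The currency of both screening stages and the ensemble: an ordered list
#' of unique disease ids with non-increasing scores; the rank of a disease
#' is its 1-based position. Input need not be pre-sorted: items are ordered
#' by decreasing score, with ties broken by `tie_rank` (a better
#' pre-existing rank wins) and then by disease id.
#'
#' An unscored tail is allowed (scores `NA`), used by reranking where only
#' the top block is rescored; `NA` scores must form a contiguous tail and
#' such items keep their given relative order after all scored items.
#'
#' @param disease_id Character vector of unique disease ids.
#' @param score Numeric scores (may contain a trailing `NA` block).
#' @param query_id Optional identifier of the query/patient.
#' @param tie_rank Optional numeric vector used to break score ties
#'   (smaller wins).
#' @return An object of class `ranked_list`: a data.frame with columns
#'   `disease_id`, `score` and attribute `query_id`.
#' @export
ranked_list <- function(disease_id, score, query_id = NA_character_,
                        tie_rank = NULL) {
  disease_id <- as.character(disease_id)
  if (anyDuplicated(disease_id)) stop("duplicate disease_id in ranked list")
  if (length(score) != length(disease_id)) stop("score length mismatch")
  if (is.null(tie_rank)) tie_rank <- seq_along(disease_id)
  scored <- !is.na(score)
  ord_s <- order(-score[scored], tie_rank[scored], disease_id[scored])
  idx <- c(which(scored)[ord_s], which(!scored)[order(tie_rank[!scored])])
  out <- data.frame(disease_id = disease_id[idx], score = score[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, query_id = query_id, class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  qid <- attr(x, "query_id")
  cat("<ranked_list>", if (!is.na(qid)) paste0(" query '", qid, "'"),
      " with ", nrow(x), " diseases\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("  ... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Rank of diseases within a ranked list
#'
#' @param rl A `ranked_list`.
#' @param disease_id Character vector of ids.
#' @return Integer 1-based positions (`NA` for absent ids).
#' @export
rank_of <- function(rl, disease_id) {
  match(disease_id, rl$disease_id)
}

#' Top-k disease ids of a ranked list
#' @param rl A `ranked_list`.
#' @param k Number of leading items.
#' @return Character vector of at most `k` ids.
#' @export
top_k <- function(rl, k) {
  utils::head(rl$disease_id, k)
}
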