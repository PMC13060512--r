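#' Ensemble gating configuration
#'
#' @param top_k Number of leading diseases per ranking entering the
#'   correlation (default 3; rankings beyond the top few are less
#'   confident, so agreement is judged on the head of each list).
#' @param source_priority Ordered character vector of source ids used to
#'   break agreement ties; default is the input order of the rankings.
#' @param union_restricted Alternative correlation mode: restrict to
#'   diseases present in both top-k blocks rather than imputing rank
#'   `top_k + 1` for absentees.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(top_k = 3, source_priority = NULL,
                            union_restricted = FALSE) {
  stopifnot(top_k >= 2)
  structure(list(top_k = as.integer(top_k), source_priority = source_priority,
                 union_restricted = isTRUE(union_restricted)),
            class = "ensemble_config")
}

#' Spearman correlation of two rankings over their top-k diseases
#'
#' Computes Spearman's rho over the union of the two lists' top-k disease
#' sets. A disease absent from one list's top-k receives rank `top_k + 1`
#' in that list, so disagreement about membership is penalized but
#' bounded. Identical top-k blocks give 1; a union of size one is defined
#' as 1 (degenerate agreement).
#'
#' @param a,b [ranked_list()]s (each with at least one item).
#' @param top_k Number of leading diseases considered per list.
#' @param union_restricted If `TRUE`, correlate only over diseases in both
#'   top-k blocks instead of imputing.
#' @return Correlation in `[-1, 1]`.
#' @export
topk_rank_correlation <- function(a, b, top_k = 3, union_restricted = FALSE) {
  if (!nrow(a) || !nrow(b)) stop("empty ranking")
  ta <- top_k(a, top_k); tb <- top_k(b, top_k)
  ids <- if (union_restricted) intersect(ta, tb) else union(ta, tb)
  if (length(ids) <= 1L) return(1.0)
  ra <- match(ids, ta); ra[is.na(ra)] <- top_k + 1L
  rb <- match(ids, tb); rb[is.na(rb)] <- top_k + 1L
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    return(if (all(ra == rb)) 1.0 else 0.0)
  }
  stats::cor(ra, rb, method = "spearman")
}

#' Gated selection of one ranking among knowledge sources
#'
#' For each source, sums its pairwise top-k Spearman correlations with
#' every other source's ranking, and selects the ranking with the highest
#' total agreement — per-patient consensus gating rather than score
#' averaging. Ties are resolved by `source_priority` order.
#'
#' @param rankings Named list (source id -> [ranked_list()]), at least
#'   two sources, each with at least `top_k` items.
#' @param config An [ensemble_config()].
#' @return A list of class `gate_result`: `chosen_source`,
#'   `chosen_ranking` and `agreement_sums` (named numeric).
#' @export
gated_select <- function(rankings, config = ensemble_config()) {
  if (length(rankings) < 2) stop("gated selection needs at least 2 sources")
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    stop("rankings must be a named list of sources")
  }
  short <- names(rankings)[vapply(rankings, nrow, integer(1)) < config$top_k]
  if (length(short)) {
    stop("rankings shorter than top_k: ", paste(short, collapse = ", "))
  }
  priority <- config$source_priority %||% names(rankings)
  missing_src <- setdiff(names(rankings), priority)
  if (length(missing_src)) {
    stop("source_priority does not cover: ", paste(missing_src, collapse = ", "))
  }
  srcs <- names(rankings)
  sums <- stats::setNames(numeric(length(srcs)), srcs)
  for (i in seq_along(srcs)) {
    for (j in seq_along(srcs)) {
      if (i == j) next
      sums[i] <- sums[i] + topk_rank_correlation(
        rankings[[i]], rankings[[j]], config$top_k, config$union_restricted)
    }
  }
  best <- max(sums)
  tied <- srcs[sums >= best - 1e-12]
  chosen <- priority[priority %in% tied][1]
  structure(list(chosen_source = chosen,
                 chosen_ranking = rankings[[chosen]],
                 agreement_sums = sums),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result> chosen source: ", x$chosen_source, "\n", sep = "")
  s <- sort(x$agreement_sums, decreasing = TRUE)
  for (nm in names(s)) cat(sprintf("  %s: %.4f\n", nm, s[[nm]]))
  invisible(x)
}
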