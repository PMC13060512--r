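#' Recall at k
#'
#' Fraction of cases whose true disease appears within the top `k` of its
#' ranking; a truth absent from the ranking counts as a miss.
#'
#' @param rankings List of [ranked_list()]s, one per case.
#' @param truths Character vector of true disease ids, parallel to
#'   `rankings`.
#' @param k Cutoff rank (`>= 1`).
#' @return Proportion in `[0, 1]`.
#' @export
recall_at_k <- function(rankings, truths, k) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(length(rankings) == length(truths))
  hits <- mapply(function(rl, t) {
    r <- rank_of(rl, t)
    !is.na(r) && r <= k
  }, rankings, truths)
  mean(hits)
}

#' Mean reciprocal rank
#'
#' Average of `1 / rank(truth)` over cases; a truth absent from its
#' ranking contributes 0.
#'
#' @inheritParams recall_at_k
#' @return MRR in `[0, 1]`.
#' @export
mean_reciprocal_rank <- function(rankings, truths) {
  if (!length(rankings)) stop("empty case set")
  stopifnot(length(rankings) == length(truths))
  rr <- mapply(function(rl, t) {
    r <- rank_of(rl, t)
    if (is.na(r)) 0 else 1 / r
  }, rankings, truths)
  mean(rr)
}

#' Semantic match rate of an embedder
#'
#' Judges an embedding model by top-1 retrieval over note collections:
#' for each disease and patient, the maximum embedding similarity between
#' the disease document and any of the patient's notes is taken; diseases
#' are ranked per patient by that maximum; the semantic match rate is the
#' fraction of patients whose true disease ranks first. Patients with no
#' notes are skipped with a warning. Ties in the per-patient ranking are
#' broken by disease id.
#'
#' @param note_sets Named list (patient id -> character vector of note
#'   texts).
#' @param truths Named character vector (patient id -> true disease id).
#' @param kb A `knowledge_base` supplying disease documents.
#' @param embedder Embedding function (default [hashed_embedder()]).
#' @param names_only Embed bare disease names instead of full documents.
#' @return Proportion in `[0, 1]`.
#' @export
semantic_match_rate <- function(note_sets, truths, kb,
                                embedder = hashed_embedder(),
                                names_only = FALSE) {
  dis_mat <- .doc_embeddings(kb, embedder, names_only = names_only)
  hits <- logical(0)
  for (p in names(note_sets)) {
    notes <- note_sets[[p]]
    if (!length(notes)) {
      warning("patient ", p, " has no notes; skipped")
      next
    }
    note_vecs <- lapply(notes, embedder)
    best <- apply(dis_mat, 2, function(dv)
      max(vapply(note_vecs, .cosine, numeric(1), y = dv)))
    ord <- order(-best, colnames(dis_mat))
    hits <- c(hits, colnames(dis_mat)[ord[1]] == truths[[p]])
  }
  if (!length(hits)) stop("no patient had notes")
  mean(hits)
}

#' Rank gains attributable to reranking
#'
#' For each knowledge source, identifies the patients whose true disease
#' ranks strictly better after stage-2 reranking than in stage 1, and
#' reports all subset-intersection cardinalities across sources
#' (upset-plot style).
#'
#' @param stage1,stage2 Named lists (source id -> list of per-patient
#'   [ranked_list()]s, each named by patient id).
#' @param truths Named character vector (patient id -> truth).
#' @return A list of class `rank_gain_sets`: `improved` (source -> patient
#'   id vector) and `intersections` (data.frame `sources`, `count` over
#'   every non-empty source subset).
#' @export
rank_gain_sets <- function(stage1, stage2, truths) {
  stopifnot(identical(sort(names(stage1)), sort(names(stage2))))
  improved <- lapply(names(stage1), function(src) {
    r1 <- stage1[[src]]; r2 <- stage2[[src]]
    if (!identical(sort(names(r1)), sort(names(r2)))) {
      stop("misaligned patient ids for source ", src)
    }
    pats <- names(r1)
    keep <- vapply(pats, function(p) {
      a <- rank_of(r1[[p]], truths[[p]])
      b <- rank_of(r2[[p]], truths[[p]])
      !is.na(a) && !is.na(b) && b < a
    }, logical(1))
    pats[keep]
  })
  names(improved) <- names(stage1)
  srcs <- names(improved)
  subsets <- unlist(lapply(seq_along(srcs), function(m)
    utils::combn(srcs, m, simplify = FALSE)), recursive = FALSE)
  inter <- data.frame(
    sources = vapply(subsets, paste, character(1), collapse = "+"),
    count = vapply(subsets, function(ss)
      length(Reduce(intersect, improved[ss])), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(improved = improved, intersections = inter),
            class = "rank_gain_sets")
}

#' Relationship categories between a top-ranked and a true disease
#'
#' Enumeration of the five relationship labels used when manually
#' annotating why a near-miss disease outranked the ground truth:
#' broader/narrower class, same disease family, etiologically related,
#' common differential diagnosis, or unrelated.
#'
#' @format Character vector of five labels.
#' @export
RELATIONSHIP_CATEGORIES <- c(
  "broader_narrower", "same_category", "etiologically_related",
  "differential_diagnosis", "unrelated"
)

#' Evaluation report for a set of screened cases
#'
#' @param rankings List of [ranked_list()]s, one per case.
#' @param truths Parallel character vector of truths.
#' @param ks Integer vector of recall cutoffs (default `c(1, 3, 5)`).
#' @return A list of class `eval_report`: `recall_at` (named numeric),
#'   `mrr`, `n_cases`.
#' @export
eval_report <- function(rankings, truths, ks = c(1, 3, 5)) {
  rec <- vapply(ks, function(k) recall_at_k(rankings, truths, k), numeric(1))
  structure(list(recall_at = stats::setNames(rec, paste0("recall@", ks)),
                 mrr = mean_reciprocal_rank(rankings, truths),
                 n_cases = length(rankings)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_cases, " cases\n", sep = "")
  for (nm in names(x$recall_at)) {
    cat(sprintf("  %s: %.3f\n", nm, x$recall_at[[nm]]))
  }
  cat(sprintf("  MRR: %.3f\n", x$mrr))
  invisible(x)
}
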