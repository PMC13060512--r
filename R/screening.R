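#' BM25 configuration
#'
#' Okapi BM25 parameters for the sparse retrieval channel over concept-id
#' tokens: `k1` controls term-frequency saturation, `b` the strength of
#' document-length normalization.
#'
#' @param k1 Saturation parameter, `> 0` (default 1.5).
#' @param b Length-normalization parameter in `[0, 1]` (default 0.75).
#' @return An object of class `bm25_config`.
#' @export
bm25_config <- function(k1 = 1.5, b = 0.75) {
  stopifnot(k1 > 0, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "bm25_config")
}

#' Reciprocal rank fusion configuration
#'
#' @param s Smoothing constant added to each rank (default 60).
#' @return An object of class `rrf_config`.
#' @export
rrf_config <- function(s = 60) {
  stopifnot(s > 0)
  structure(list(s = s), class = "rrf_config")
}

#' Screening configuration
#'
#' @param rerank_k Number of fused top candidates rescored in stage 2
#'   (default 20).
#' @param bm25 A [bm25_config()].
#' @param rrf An [rrf_config()].
#' @param embedder Embedding function for the dense channel; `NULL` uses
#'   the shipped [hashed_embedder()].
#' @param reranker Pairwise relevance function for stage 2; `NULL` uses
#'   the shipped [idf_overlap_reranker()].
#' @param names_only Stage-2 ablation: rerank against bare disease names
#'   instead of full disease documents.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(rerank_k = 20, bm25 = bm25_config(),
                          rrf = rrf_config(), embedder = NULL,
                          reranker = NULL, names_only = FALSE) {
  stopifnot(rerank_k >= 1)
  structure(list(rerank_k = as.integer(rerank_k), bm25 = bm25, rrf = rrf,
                 embedder = embedder, reranker = reranker,
                 names_only = isTRUE(names_only)),
            class = "screen_config")
}

# BM25 index over the per-disease concept bags, cached on the kb.
.bm25_index <- function(kb) {
  if (!is.null(kb$cache$bm25)) return(kb$cache$bm25)
  bags <- kb_concept_bags(kb)
  ids <- names(bags)
  vocab <- sort(unique(unlist(bags, use.names = FALSE)))
  tf <- matrix(0, nrow = length(vocab), ncol = length(ids),
               dimnames = list(vocab, ids))
  for (j in seq_along(bags)) {
    if (!length(bags[[j]])) next
    t <- table(bags[[j]])
    tf[names(t), j] <- as.numeric(t)
  }
  doclen <- colSums(tf)
  avgdl <- mean(doclen)
  if (avgdl == 0) avgdl <- 1
  df <- rowSums(tf > 0)
  n <- length(ids)
  idf <- log(1 + (n - df + 0.5) / (df + 0.5))
  res <- list(tf = tf, doclen = doclen, avgdl = avgdl, idf = idf, ids = ids)
  kb$cache$bm25 <- res
  res
}

#' Sparse BM25 ranking of diseases for a patient concept bag
#'
#' Scores every disease in the knowledge base with Okapi BM25 over
#' concept-id tokens. Documents are the per-disease concept bags drawn
#' from the four core profile sections; the query is the patient's
#' extracted concept multiset (repeated concepts count with multiplicity).
#' The inverse document frequency is the non-negative variant
#' `ln(1 + (N - df + 0.5)/(df + 0.5))`. Ties are broken by disease id.
#'
#' @param patient_concepts Character vector (multiset) of concept ids.
#' @param kb A `knowledge_base`.
#' @param config A [bm25_config()].
#' @param query_id Optional patient identifier.
#' @return A [ranked_list()] over all diseases in `kb`.
#' @export
bm25_rank <- function(patient_concepts, kb, config = bm25_config(),
                      query_id = NA_character_) {
  if (!length(kb$profiles)) stop("empty knowledge base")
  ix <- .bm25_index(kb)
  scores <- stats::setNames(numeric(length(ix$ids)), ix$ids)
  if (!length(patient_concepts)) {
    warning("empty patient concept list; ranking by tie-break only")
  } else {
    qf <- table(patient_concepts)
    qterms <- intersect(names(qf), rownames(ix$tf))
    denom_norm <- config$k1 * (1 - config$b + config$b * ix$doclen / ix$avgdl)
    for (t in qterms) {
      tfr <- ix$tf[t, ]
      scores <- scores + as.numeric(qf[[t]]) * ix$idf[[t]] *
        tfr * (config$k1 + 1) / (tfr + denom_norm)
    }
  }
  ranked_list(ix$ids, as.numeric(scores), query_id = query_id,
              tie_rank = rep(1L, length(ix$ids)))
}

#' Deterministic hashed term-frequency embedder
#'
#' The shipped fallback for the dense channel: texts are tokenized under
#' the standard normalization and each token is hashed into a fixed number
#' of buckets with a deterministic polynomial string hash; the embedding
#' is the bucketed term-frequency vector. No model weights are required
#' and identical text always yields an identical vector. Any replacement
#' embedder must satisfy the same contract: text in, fixed-length numeric
#' vector out, deterministic for fixed input.
#'
#' @param dim Number of hash buckets (default 4096).
#' @return A function `text -> numeric[dim]`, with an `id` attribute used
#'   for embedding caches.
#' @export
hashed_embedder <- function(dim = 4096L) {
  dim <- as.integer(dim)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  hash_token <- function(tok) {
    h <- memo[[tok]]
    if (is.null(h)) {
      h <- 7L
      for (cc in utf8ToInt(tok)) h <- (h * 31L + cc) %% dim
      memo[[tok]] <- h
    }
    h
  }
  f <- function(text) {
    v <- numeric(dim)
    toks <- .tokenize_offsets(text)$token
    for (tok in toks) {
      i <- hash_token(tok) + 1L
      v[i] <- v[i] + 1
    }
    v
  }
  attr(f, "id") <- paste0("hashed_tf_", dim)
  f
}

.cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# Disease-document embeddings for a kb and embedder, cached.
.doc_embeddings <- function(kb, embedder, names_only = FALSE) {
  key <- paste0("emb_", attr(embedder, "id") %||% "anon",
                if (names_only) "_names" else "")
  if (!is.null(kb$cache[[key]])) return(kb$cache[[key]])
  docs <- vapply(kb$profiles, build_disease_document, character(1),
                 names_only = names_only)
  mat <- vapply(docs, embedder, numeric(length(embedder(""))))
  if (!is.null(attr(embedder, "id"))) kb$cache[[key]] <- mat
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dense embedding-similarity ranking of diseases
#'
#' Embeds the patient text and every disease's retrieval document with the
#' supplied embedder and ranks diseases by cosine similarity. A zero-norm
#' vector yields similarity 0 for the pair. Ties are broken by disease id.
#'
#' @param patient_text Patient clinical presentation text.
#' @param kb A `knowledge_base`.
#' @param embedder Embedding function (default: [hashed_embedder()]).
#' @param query_id Optional patient identifier.
#' @return A [ranked_list()] over all diseases in `kb`.
#' @export
dense_rank <- function(patient_text, kb, embedder = hashed_embedder(),
                       query_id = NA_character_) {
  if (!length(kb$profiles)) stop("empty knowledge base")
  mat <- .doc_embeddings(kb, embedder)
  q <- embedder(patient_text)
  sims <- apply(mat, 2, .cosine, y = q)
  ranked_list(colnames(mat), as.numeric(sims), query_id = query_id,
              tie_rank = rep(1L, ncol(mat)))
}

#' Fuse two rankings by reciprocal rank fusion
#'
#' Each disease's fused score is `1/(s + rank_dense) + 1/(s + rank_sparse)`
#' with smoothing constant `s` (default 60). The fusion depends only on
#' ranks, so it is invariant to the score scales of its inputs; it rewards
#' diseases near the top of either list and discounts those ranked poorly
#' in both. Both input lists must rank the identical disease set (stage 1
#' scores the whole space); with `impute_missing = TRUE` a disease absent
#' from one list instead receives rank `length(list) + 1` there.
#'
#' @param dense,sparse [ranked_list()]s over the same disease set.
#' @param config An [rrf_config()].
#' @param impute_missing Opt-in imputation for diseases missing from one
#'   list (default `FALSE`: an error).
#' @return A fused [ranked_list()]; ties are broken by the better of the
#'   two input ranks, then disease id.
#' @export
rrf_fuse <- function(dense, sparse, config = rrf_config(),
                     impute_missing = FALSE) {
  ids <- union(dense$disease_id, sparse$disease_id)
  rd <- rank_of(dense, ids)
  rs <- rank_of(sparse, ids)
  if (anyNA(rd) || anyNA(rs)) {
    if (!impute_missing) {
      stop("rankings cover different disease sets; stage 1 must rank the whole space")
    }
    rd[is.na(rd)] <- nrow(dense) + 1L
    rs[is.na(rs)] <- nrow(sparse) + 1L
  }
  score <- 1 / (config$s + rd) + 1 / (config$s + rs)
  ranked_list(ids, score, query_id = attr(dense, "query_id"),
              tie_rank = pmin(rd, rs))
}

#' IDF-weighted concept-overlap reranker
#'
#' The shipped deterministic stand-in for a neural pairwise reranker: the
#' relevance of a disease document to a patient text is the sum, over
#' concepts found by the dictionary matcher in *both* texts, of the
#' concept's inverse document frequency across the knowledge base's
#' disease documents. Rare shared concepts therefore move a candidate more
#' than ubiquitous ones. Matching results are memoized per text, so
#' reranking many candidates for many patients stays fast.
#'
#' @param kb A `knowledge_base` (provides the lexicon and IDF statistics).
#' @param config A [matcher_config()].
#' @return A function `(patient_text, disease_document) -> numeric score`.
#' @export
idf_overlap_reranker <- function(kb, config = matcher_config()) {
  n <- length(kb$profiles)
  doc_sets <- lapply(names(kb$profiles), function(d)
    kb_profile_concepts(kb, d, sections = CORE_SECTIONS))
  cnt <- table(unlist(doc_sets, use.names = FALSE))
  idf_env <- new.env(parent = emptyenv())
  for (cid in names(cnt)) idf_env[[cid]] <- log((n + 1) / (cnt[[cid]] + 1)) + 1
  idf <- function(cid) {
    v <- idf_env[[cid]]
    if (is.null(v)) log(n + 1) + 1 else v
  }
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  concepts_of <- function(text) {
    key <- paste0("t", substr(text, 1, 200), nchar(text))
    v <- memo[[key]]
    if (is.null(v)) {
      v <- unique(match_concepts(text, kb$lexicon, config)$concept_id)
      memo[[key]] <- v
    }
    v
  }
  function(patient_text, disease_document) {
    shared <- intersect(concepts_of(patient_text), concepts_of(disease_document))
    if (!length(shared)) return(0)
    sum(vapply(shared, idf, numeric(1)))
  }
}

#' Knowledge-boosted reranking of the fused top candidates
#'
#' Re-evaluates the top `rerank_k` diseases of a fused ranking against the
#' patient's clinical presentation using a pairwise reranker over each
#' disease's retrieval document (name plus the four core sections; with
#' `names_only = TRUE`, the bare name — the ablation that strips profile
#' knowledge from stage 2). The rescored block is reordered by reranker
#' score (ties: better fused rank, then disease id); diseases beyond
#' `rerank_k` keep their stage-1 relative order after the block, with
#' score `NA`.
#'
#' @param patient_text Patient clinical presentation text.
#' @param fused A fused [ranked_list()] from [rrf_fuse()].
#' @param kb A `knowledge_base`.
#' @param reranker Pairwise scorer `(patient_text, document) -> numeric`;
#'   default [idf_overlap_reranker()] on `kb`.
#' @param config A [screen_config()] (supplies `rerank_k`, `names_only`).
#' @return A [ranked_list()] over the same disease set as `fused`.
#' @export
knowledge_boosted_rerank <- function(patient_text, fused, kb,
                                     reranker = NULL,
                                     config = screen_config()) {
  if (is.null(reranker)) reranker <- config$reranker %||% idf_overlap_reranker(kb)
  k <- min(config$rerank_k, nrow(fused))
  head_ids <- fused$disease_id[seq_len(k)]
  docs <- vapply(head_ids, function(d)
    build_disease_document(kb$profiles[[d]], names_only = config$names_only),
    character(1))
  new_scores <- vapply(seq_len(k), function(i) reranker(patient_text, docs[[i]]),
                       numeric(1))
  tail_ids <- if (nrow(fused) > k) fused$disease_id[seq(k + 1L, nrow(fused))] else character()
  ranked_list(c(head_ids, tail_ids),
              c(new_scores, rep(NA_real_, length(tail_ids))),
              query_id = attr(fused, "query_id"),
              tie_rank = seq_len(nrow(fused)))
}

#' Two-stage screening of one patient
#'
#' Stage 1 extracts the patient's concepts, ranks the whole disease space
#' by sparse BM25 and dense embedding similarity, and fuses the two lists
#' by reciprocal rank fusion. Stage 2 rescores the fused top candidates
#' with the knowledge-boosted reranker. Fully deterministic for fixed
#' inputs.
#'
#' @param patient_text Clinical presentation text.
#' @param kb A `knowledge_base` (its lexicon drives concept extraction).
#' @param config A [screen_config()].
#' @param query_id Optional patient identifier carried into the outputs.
#' @param matcher A [matcher_config()] for patient concept extraction.
#' @return List with elements `stage1` and `stage2`, both [ranked_list()]s
#'   over the full disease set.
#' @export
screen_patient <- function(patient_text, kb, config = screen_config(),
                           query_id = NA_character_,
                           matcher = matcher_config()) {
  embedder <- config$embedder %||% kb$cache$default_embedder
  if (is.null(embedder)) {
    embedder <- hashed_embedder()
    kb$cache$default_embedder <- embedder
  }
  concepts <- match_concepts(patient_text, kb$lexicon, matcher)$concept_id
  sparse <- bm25_rank(concepts, kb, config$bm25, query_id = query_id)
  dense <- dense_rank(patient_text, kb, embedder, query_id = query_id)
  stage1 <- rrf_fuse(dense, sparse, config$rrf)
  reranker <- config$reranker %||% kb$cache$default_reranker
  if (is.null(reranker)) {
    reranker <- idf_overlap_reranker(kb)
    kb$cache$default_reranker <- reranker
  }
  stage2 <- knowledge_boosted_rerank(patient_text, stage1, kb,
                                     reranker = reranker, config = config)
  list(stage1 = stage1, stage2 = stage2)
}

#' Screen a batch of patient cases
#'
#' @param cases A data.frame with columns `patient_id` and `text` (and
#'   optionally `truth_disease_id`, carried through).
#' @param kb A `knowledge_base`.
#' @param config A [screen_config()].
#' @param top_n Number of leading stage-2 candidates to report per patient
#'   (default: all).
#' @return A long data.frame: `patient_id`, `rank`, `disease_id`,
#'   `stage1_score`, `stage2_score`, ordered by the stage-2 ranking; plus
#'   an attribute `rankings` holding the per-patient `stage1`/`stage2`
#'   ranked lists.
#' @export
screen_cases <- function(cases, kb, config = screen_config(), top_n = Inf) {
  stopifnot(all(c("patient_id", "text") %in% names(cases)))
  rankings <- vector("list", nrow(cases))
  names(rankings) <- cases$patient_id
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    res <- screen_patient(cases$text[i], kb, config,
                          query_id = cases$patient_id[i])
    rankings[[i]] <- res
    n <- min(top_n, nrow(res$stage2))
    ids <- res$stage2$disease_id[seq_len(n)]
    rows[[i]] <- data.frame(
      patient_id = cases$patient_id[i], rank = seq_len(n), disease_id = ids,
      stage1_score = res$stage1$score[rank_of(res$stage1, ids)],
      stage2_score = res$stage2$score[seq_len(n)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rankings") <- rankings
  out
}
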