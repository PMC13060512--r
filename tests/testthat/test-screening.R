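test_that("BM25 ranks the exclusive-signal disease first", {
  kb <- tiny_kb()
  # C005 (exertional dyspnea) occurs only in D1's core sections
  rl <- bm25_rank(c("C005", "C005"), kb)
  expect_s3_class(rl, "ranked_list")
  expect_equal(rl$disease_id[1], "D1")
  expect_true(rl$score[1] > 0)
  expect_true(all(rl$score[-1] == 0))

  # no shared concept: all scores zero, tie-break by disease id
  rl0 <- bm25_rank("C999", kb)
  expect_true(all(rl0$score == 0))
  expect_equal(rl0$disease_id, c("D1", "D2", "D3"))
  expect_warning(bm25_rank(character(), kb), "empty")
})

test_that("BM25 scores match a hand computation on a printed toy corpus", {
  # concept bags: D1 = {a, a, b}, D2 = {b, c}, D3 = {c, c, c}
  lex <- concept_lexicon(data.frame(
    concept_id = c("a", "b", "c"),
    preferred_name = c("alpha sign", "beta sign", "gamma sign"),
    synonyms = "", semantic_group = "symptoms_conditions",
    stringsAsFactors = FALSE))
  mk <- function(id, clin) disease_profile(id, paste("disease", id), "s",
                                           list(clinical_presentation = clin))
  kb <- build_knowledge_base(list(
    mk("D1", "alpha sign with alpha sign and beta sign."),
    mk("D2", "beta sign and gamma sign."),
    mk("D3", "gamma sign, gamma sign, gamma sign.")), lex)
  # matcher dedup makes section sets, so bags are sets per section:
  # D1 = {a, b}, D2 = {b, c}, D3 = {c}; lengths 2, 2, 1; avgdl = 5/3
  k1 <- 1.5; b <- 0.75
  idf <- function(df) log(1 + (3 - df + 0.5) / (df + 0.5))
  sc <- function(tf, dl) tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / (5 / 3)))
  expected <- c(
    D1 = idf(1) * sc(1, 2) + idf(2) * sc(1, 2),  # query {a, b}
    D2 = idf(2) * sc(1, 2),
    D3 = 0)
  rl <- bm25_rank(c("a", "b"), kb)
  got <- stats::setNames(rl$score, rl$disease_id)[names(expected)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
})

test_that("dense ranking equals brute-force cosine on count vectors", {
  kb <- tiny_kb()
  emb <- hashed_embedder()
  d1_doc <- build_disease_document(kb$profiles$D1)
  rl <- dense_rank(d1_doc, kb, emb)
  expect_equal(rl$disease_id[1], "D1")
  expect_equal(rl$score[1], 1.0, tolerance = 1e-12)

  # brute-force oracle: cosine on raw token-count vectors
  toks <- function(x) table(strsplit(normalize_text(x), " ")[[1]])
  cos <- function(a, b) {
    u <- union(names(a), names(b))
    va <- as.numeric(a[u]); va[is.na(va)] <- 0
    vb <- as.numeric(b[u]); vb[is.na(vb)] <- 0
    if (sum(va^2) == 0 || sum(vb^2) == 0) return(0)
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  q <- "chronic dry cough with velcro crackles"
  brute <- vapply(kb_disease_ids(kb), function(d)
    cos(toks(q), toks(build_disease_document(kb$profiles[[d]]))), numeric(1))
  rl2 <- dense_rank(q, kb, emb)
  expect_equal(rl2$disease_id, names(sort(-brute)))

  # orthogonal bags of words give similarity zero
  expect_equal(dense_rank("zzz qqq xxx", kb, emb)$score, rep(0, 3))
})

test_that("RRF follows the printed equation and a score-and-sort oracle", {
  # both-rank-1 score is exactly 2/61
  a <- rl_from_order(c("X", "Y", "Z"))
  b <- rl_from_order(c("X", "Z", "Y"))
  fused <- rrf_fuse(a, b)
  expect_equal(fused$score[fused$disease_id == "X"], 2 / 61,
               tolerance = 1e-12)

  # fusing a ranking with itself preserves its order
  self <- rrf_fuse(a, a)
  expect_equal(self$disease_id, a$disease_id)

  # 200 random permutation pairs over 50 diseases against the oracle
  set.seed(1234)
  ids <- sprintf("D%02d", 1:50)
  for (i in 1:200) {
    pa <- sample(ids); pb <- sample(ids)
    fu <- rrf_fuse(rl_from_order(pa), rl_from_order(pb))
    score <- 1 / (60 + match(ids, pa)) + 1 / (60 + match(ids, pb))
    oracle <- ids[order(-score, pmin(match(ids, pa), match(ids, pb)), ids)]
    expect_identical(fu$disease_id, oracle)
    expect_equal(stats::setNames(fu$score, fu$disease_id)[ids],
                 stats::setNames(score, ids), tolerance = 1e-12)
  }
})

test_that("RRF is scale-invariant and bounded", {
  set.seed(77)
  ids <- letters[1:12]
  a <- rl_from_order(sample(ids)); b <- rl_from_order(sample(ids))
  # multiply scores by arbitrary positive scale: ranks unchanged
  a2 <- ranked_list(a$disease_id, a$score * 1000 + 5)
  b2 <- ranked_list(b$disease_id, b$score * 0.001)
  expect_identical(rrf_fuse(a, b)$disease_id, rrf_fuse(a2, b2)$disease_id)
  f <- rrf_fuse(a, b)
  expect_true(all(f$score > 0 & f$score <= 2 / 61))
})

test_that("RRF rejects mismatched disease sets unless imputation is requested", {
  a <- rl_from_order(c("X", "Y", "Z"))
  b <- rl_from_order(c("X", "Y"))
  expect_error(rrf_fuse(a, b), "whole space")
  f <- rrf_fuse(a, b, impute_missing = TRUE)
  expect_equal(f$score[f$disease_id == "Z"], 1 / 63 + 1 / 63)
})

test_that("knowledge-boosted reranking reorders only the top block", {
  kb <- tiny_kb()
  fused <- rl_from_order(c("D3", "D2", "D1"), query_id = "p1")
  # identity reranker on fused scores is a fixed point
  fixed <- knowledge_boosted_rerank(
    "whatever", fused, kb,
    reranker = local({
      sc <- stats::setNames(fused$score, fused$disease_id)
      nm <- vapply(kb$profiles, `[[`, character(1), "name")
      function(pt, doc) {
        d <- names(nm)[vapply(nm, function(x) startsWith(doc, x), logical(1))][1]
        sc[[d]]
      }
    }),
    config = screen_config(rerank_k = 3))
  expect_identical(fixed$disease_id, fused$disease_id)

  # dominance: a strictly highest reranker score lifts the last candidate to 1
  dom <- knowledge_boosted_rerank(
    "q", fused, kb,
    reranker = function(pt, doc) if (startsWith(doc, "fibrotic")) 10 else 0,
    config = screen_config(rerank_k = 3))
  expect_equal(dom$disease_id[1], "D1")

  # beyond rerank_k, stage-1 relative order is retained with NA scores
  part <- knowledge_boosted_rerank(
    "q", fused, kb, reranker = function(pt, doc) 0,
    config = screen_config(rerank_k = 2))
  expect_equal(part$disease_id[3], "D1")
  expect_true(is.na(part$score[3]))
})

test_that("names-only reranking never sees section text", {
  lex <- tiny_lexicon()
  p_full <- tiny_profile("D1", "alpha disease", sections = list(
    clinical_presentation = "Chronic dry cough dominates."))
  p_alt <- tiny_profile("D1", "alpha disease", sections = list(
    clinical_presentation = "Exertional dyspnea dominates."))
  q_prof <- tiny_profile("D2", "beta disease", sections = list(
    clinical_presentation = "Finger clubbing is typical."))
  kb_a <- build_knowledge_base(list(p_full, q_prof), lex)
  kb_b <- build_knowledge_base(list(p_alt, q_prof), lex)
  fused <- rl_from_order(c("D1", "D2"))
  cfg <- screen_config(rerank_k = 2, names_only = TRUE)
  out_a <- knowledge_boosted_rerank("chronic dry cough", fused, kb_a,
                                    reranker = idf_overlap_reranker(kb_a),
                                    config = cfg)
  out_b <- knowledge_boosted_rerank("chronic dry cough", fused, kb_b,
                                    reranker = idf_overlap_reranker(kb_b),
                                    config = cfg)
  expect_identical(out_a$disease_id, out_b$disease_id)
  expect_identical(out_a$score, out_b$score)
})

test_that("two-stage screening is deterministic and permutation-consistent", {
  kb <- tiny_kb()
  res <- screen_patient("chronic dry cough with velcro crackles", kb,
                        query_id = "p1")
  expect_setequal(res$stage1$disease_id, res$stage2$disease_id)
  expect_equal(res$stage2$disease_id[1], "D1")
  res2 <- screen_patient("chronic dry cough with velcro crackles", kb,
                         query_id = "p1")
  expect_identical(as.data.frame(res$stage2), as.data.frame(res2$stage2))
  expect_warning(screen_patient("", kb), "empty")
})

test_that("a synthetic case emitting most signature concepts is recovered", {
  b <- generate_benchmark(bench_gen_config(n_diseases = 40, n_cases = 20,
                                           signature_emission_rate = 0.9,
                                           seed = 303))
  kb <- build_knowledge_base(b$profiles, b$lexicon)
  hits <- 0
  for (i in seq_len(nrow(b$cases))) {
    res <- screen_patient(b$cases$text[i], kb)
    r <- rank_of(res$stage2, b$cases$truth_disease_id[i])
    if (!is.na(r) && r <= 5) hits <- hits + 1
  }
  expect_gte(hits / nrow(b$cases), 0.9)
})
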