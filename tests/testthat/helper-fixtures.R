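# Shared in-code fixtures: a small hand-written lexicon and profile set
# used across module tests.

tiny_lexicon <- function() {
  concept_lexicon(data.frame(
    concept_id = c("C001", "C002", "C003", "C004", "C005"),
    preferred_name = c("dry cough", "chronic dry cough", "finger clubbing",
                       "velcro crackles", "exertional dyspnea"),
    synonyms = c("nonproductive cough", "", "digital clubbing",
                 "bibasilar crackles", "dyspnea on exertion"),
    semantic_group = c("symptoms_conditions", "symptoms_conditions",
                       "symptoms_conditions", "diagnostics_lab",
                       "symptoms_conditions"),
    stringsAsFactors = FALSE))
}

tiny_profile <- function(disease_id = "D1", name = "fibrotic lung syndrome",
                         source_id = "src_a",
                         sections = NULL) {
  if (is.null(sections)) {
    sections <- list(
      clinical_presentation = "Patients develop chronic dry cough and exertional dyspnea.",
      diagnostic_evaluation = "Auscultation reveals velcro crackles.",
      subtypes_variants = "A familial and a sporadic variant exist.",
      management_standard_therapy = "Antifibrotic therapy slows decline.",
      prognosis = "Median survival is limited.")
  }
  disease_profile(disease_id, name, source_id, sections)
}

# A deterministic three-disease kb over the tiny lexicon.
tiny_kb <- function() {
  p1 <- tiny_profile("D1", "fibrotic lung syndrome",
    sections = list(
      clinical_presentation = "Patients develop chronic dry cough and exertional dyspnea.",
      diagnostic_evaluation = "Velcro crackles and finger clubbing are typical."))
  p2 <- tiny_profile("D2", "airway cough disorder",
    sections = list(
      clinical_presentation = "Dry cough dominates the picture.",
      diagnostic_evaluation = "Evaluation is unremarkable."))
  p3 <- tiny_profile("D3", "silent syndrome",
    sections = list(
      clinical_presentation = "Patients are often asymptomatic for years.",
      diagnostic_evaluation = "Imaging is normal."))
  build_knowledge_base(list(p1, p2, p3), tiny_lexicon())
}

# Build a ranked list directly from an ordered id vector.
rl_from_order <- function(ids, query_id = NA_character_) {
  ranked_list(ids, score = rev(seq_along(ids)), query_id = query_id)
}

# Independent Spearman on union-imputed rank vectors (test oracle).
oracle_topk_spearman <- function(ids_a, ids_b, k) {
  u <- union(ids_a[seq_len(min(k, length(ids_a)))],
             ids_b[seq_len(min(k, length(ids_b)))])
  if (length(u) <= 1) return(1)
  ra <- match(u, ids_a); ra[is.na(ra) | ra > k] <- k + 1
  rb <- match(u, ids_b); rb[is.na(rb) | rb > k] <- k + 1
  suppressWarnings(stats::cor(ra, rb, method = "spearman"))
}

# Independent Mann-Whitney AUROC (test oracle).
oracle_auroc <- function(scores, is_case) {
  pos <- scores[is_case]; neg <- scores[!is_case]
  if (!length(pos) || !length(neg)) return(NA_real_)
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
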