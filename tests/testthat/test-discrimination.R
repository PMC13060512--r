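test_that("rule-based context classification follows the cue table", {
  cls <- function(s, span_text) {
    st <- regexpr(span_text, s, fixed = TRUE)[1] - 1
    classify_mention_context(s, st, st + nchar(span_text))
  }
  expect_equal(cls("denies shortness of breath", "shortness of breath")$context,
               "negated")
  expect_equal(cls("No dry cough today", "dry cough")$context, "negated")
  expect_equal(cls("family history of pulmonary fibrosis",
                   "pulmonary fibrosis")$context, "family_history")
  expect_equal(cls("history of pneumonia in 2019", "pneumonia")$context,
               "historical")
  expect_equal(cls("rule out interstitial disease", "interstitial disease")$context,
               "hypothetical")
  expect_equal(cls("concern for pulmonary fibrosis", "pulmonary fibrosis")$context,
               "possible")
  r <- cls("reports worsening dry cough", "dry cough")
  expect_equal(r$context, "other")
  expect_true(r$worsening)
  expect_false(cls("reports dry cough", "dry cough")$worsening)
  # family history wins over plain history when both could fire
  expect_equal(cls("family history of dry cough", "dry cough")$context,
               "family_history")
  expect_error(classify_mention_context("short", 3, 10), "within")
})

test_that("symptom-week matrix implements the three-level code", {
  mentions <- data.frame(
    patient_id = "P1",
    concept_id = c("A", "A", "A", "B"),
    week_index = c(-20L, -20L, -20L, -18L),
    context = "other",
    worsening = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  m <- build_symptom_week_matrix(mentions, c("A", "B"))
  # week -20: A mentioned (3x collapses to one code-1), B coded 2
  expect_equal(m$code["-20", "A"], 1L)
  expect_equal(m$code["-20", "B"], 2L)
  expect_true(m$worsen["-20", "A"])
  # week -18: B coded 1, A coded 2
  expect_equal(m$code["-18", "B"], 1L)
  expect_equal(m$code["-18", "A"], 2L)
  # a week with no retained mention is all zero
  expect_true(all(m$code["-30", ] == 0L))
  # freq_pa counts weeks, not mentions
  expect_equal(unname(m$freq_pa["A"]), 1L)
  expect_equal(unname(m$freq_pa["B"]), 1L)
  # non-retained contexts are filtered out
  mentions$context <- "negated"
  m0 <- build_symptom_week_matrix(mentions, c("A", "B"))
  expect_equal(sum(m0$code), 0)
  expect_error(build_symptom_week_matrix(mentions, character()), "non-empty")
})

test_that("pair features count co-occurrence and worsening weeks", {
  mentions <- data.frame(
    patient_id = "P1",
    concept_id = c("A", "B", "A", "B", "A"),
    week_index = c(-20L, -20L, -17L, -17L, -15L),
    context = "other",
    worsening = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  m <- build_symptom_week_matrix(mentions, c("A", "B", "C"))
  pf <- extract_pair_features(m)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$concept_a, "A"); expect_equal(pf$concept_b, "B")
  expect_equal(pf$pair_week_single, 2)      # weeks -20 and -17
  expect_equal(pf$worsen_count_single, 1)   # only week -20 worsening
  # a single active concept yields no pairs
  m1 <- build_symptom_week_matrix(mentions[mentions$concept_id == "A", ],
                                  c("A", "B", "C"))
  expect_equal(nrow(extract_pair_features(m1)), 0)
})

test_that("SIS follows the pseudo-counted log2 ratio", {
  prev <- structure(list(freq_case = c(x = 10), freq_ctrl = c(x = 10),
                         pseudo_count = 5), class = "group_prevalence")
  expect_equal(unname(compute_sis(prev)$weight["x"]), 0)
  prev$freq_case <- c(x = 27); prev$freq_ctrl <- c(x = 11)
  expect_equal(unname(compute_sis(prev)$weight["x"]), 1.0)  # log2(32/16)
  prev$freq_case <- numeric(); prev$freq_ctrl <- c(y = 0)
  expect_equal(unname(compute_sis(prev)$weight["y"]), 0)    # log2(5/5)
})

test_that("group prevalence counts patients or weeks as configured", {
  mk <- function(pid, freq) {
    structure(list(patient_id = pid, weeks = -5:-1, concepts = names(freq),
                   code = NULL, worsen = NULL, freq_pa = freq),
              class = "symptom_week_matrix")
  }
  mats <- list(mk("p1", c(A = 3L, B = 0L)), mk("p2", c(A = 1L, B = 2L)),
               mk("p3", c(A = 0L, B = 1L)))
  pp <- group_prevalence(mats, c("case", "case", "control"))
  expect_equal(unname(pp$freq_case["A"]), 2)   # two case patients with A
  expect_equal(unname(pp$freq_ctrl["B"]), 1)
  pw <- group_prevalence(mats, c("case", "case", "control"), unit = "weeks")
  expect_equal(unname(pw$freq_case["A"]), 4)   # 3 + 1 patient-weeks
})

test_that("TF-IDF weights follow the frozen corpus definition", {
  mk <- function(pid, freq) {
    structure(list(patient_id = pid, freq_pa = freq),
              class = "symptom_week_matrix")
  }
  # concept A present once in every patient: idf = ln(1) + 1 = 1, weight 1
  mats <- list(mk("p1", c(A = 1L)), mk("p2", c(A = 1L)), mk("p3", c(A = 1L)))
  w <- compute_tfidf_weights(mats)
  expect_equal(unname(w$weight["A"]), 1.0, tolerance = 1e-12)
  # doubling tf doubles the weight (linearity in tf)
  mats2 <- list(mk("p1", c(A = 2L)), mk("p2", c(A = 2L)), mk("p3", c(A = 2L)))
  expect_equal(unname(compute_tfidf_weights(mats2)$weight["A"]), 2.0,
               tolerance = 1e-12)
  # a concept present in one of three patients
  mats3 <- list(mk("p1", c(A = 1L, B = 2L)), mk("p2", c(A = 1L, B = 0L)),
                mk("p3", c(A = 1L, B = 0L)))
  w3 <- compute_tfidf_weights(mats3)
  expect_equal(unname(w3$weight["B"]), mean(c(2, 0, 0) * (log(4 / 2) + 1)),
               tolerance = 1e-12)
})

test_that("the patient feature chain reproduces the worked example", {
  # one pair (A, B), two co-occurrence weeks, one worsening week,
  # SIS(A) = 1, SIS(B) = 0.5, freq_pa = 2 for both
  mentions <- data.frame(
    patient_id = "P1", concept_id = rep(c("A", "B"), 2),
    week_index = rep(c(-20L, -17L), each = 2), context = "other",
    worsening = c(TRUE, FALSE, FALSE, FALSE), stringsAsFactors = FALSE)
  m <- build_symptom_week_matrix(mentions, c("A", "B"))
  pairs <- extract_pair_features(m)
  w <- structure(list(method = "SIS", weight = c(A = 1, B = 0.5)),
                 class = "weight_table")
  f <- compute_patient_features(m, pairs, w)
  expect_equal(f$pair_week_agg, 2)
  expect_equal(f$worsen_count_agg, 1)
  expect_equal(f$total_symptom_weight, 1 * 3 + 0.5 * 3)   # 4.5 exactly
  expect_equal(f$normalized_weight, 4.5 / 3)              # 1.5 exactly
})

test_that("pair-participating concepts are deduplicated in the weight sum", {
  # A co-occurs with B, C and D: A's weight must be counted once
  mentions <- data.frame(
    patient_id = "P1",
    concept_id = c("A", "B", "A", "C", "A", "D"),
    week_index = rep(c(-20L, -18L, -16L), each = 2),
    context = "other", worsening = FALSE, stringsAsFactors = FALSE)
  m <- build_symptom_week_matrix(mentions, c("A", "B", "C", "D"))
  pairs <- extract_pair_features(m)
  expect_equal(nrow(pairs), 3)
  w <- structure(list(method = "SIS",
                      weight = c(A = 1, B = 1, C = 1, D = 1)),
                 class = "weight_table")
  f <- compute_patient_features(m, pairs, w)
  # freq_pa: A = 3, B = C = D = 1; dedup: 1*(1+3) + 3 * 1*(1+1) = 10
  expect_equal(f$total_symptom_weight, 10)
  # no pairs at all gives the all-zero feature vector
  m0 <- build_symptom_week_matrix(mentions[1, , drop = FALSE],
                                  c("A", "B", "C", "D"))
  f0 <- compute_patient_features(m0, extract_pair_features(m0), w)
  expect_equal(unlist(f0[, -1]), c(pair_week_agg = 0, worsen_count_agg = 0,
                                   total_symptom_weight = 0,
                                   normalized_weight = 0))
})

test_that("feature aggregation matches brute force on random toy matrices", {
  set.seed(606)
  for (rep in 1:10) {
    concepts <- LETTERS[1:5]
    weeks <- -8:-1
    n <- sample(5:20, 1)
    mentions <- data.frame(
      patient_id = "P1",
      concept_id = sample(concepts, n, replace = TRUE),
      week_index = sample(weeks, n, replace = TRUE),
      context = "other",
      worsening = stats::runif(n) < 0.3, stringsAsFactors = FALSE)
    m <- build_symptom_week_matrix(mentions, concepts, window = c(-56, -7))
    pairs <- extract_pair_features(m)
    # brute force over all week x pair combinations
    pres <- vapply(concepts, function(cc)
      vapply(weeks, function(w) any(mentions$concept_id == cc &
                                      mentions$week_index == w), logical(1)),
      logical(length(weeks)))
    wors <- vapply(concepts, function(cc)
      vapply(weeks, function(w) any(mentions$concept_id == cc &
                                      mentions$week_index == w &
                                      mentions$worsening), logical(1)),
      logical(length(weeks)))
    exp_pw <- 0; exp_wc <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      both <- pres[, i] & pres[, j]
      exp_pw <- exp_pw + sum(both)
      exp_wc <- exp_wc + sum(both & (wors[, i] | wors[, j]))
    }
    expect_equal(sum(pairs$pair_week_single), exp_pw)
    expect_equal(sum(pairs$worsen_count_single), exp_wc)
    expect_equal(unname(m$freq_pa), unname(colSums(pres)))
  }
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  expect_equal(youden_threshold(c(0.9, 0.8, 0.2, 0.1),
                                c("case", "case", "control", "control")), 0.8)
  # all-identical scores: J = 0 at the single candidate threshold
  expect_equal(youden_threshold(rep(0.5, 4),
                                c("case", "control", "case", "control")), 0.5)
  expect_error(youden_threshold(1:3, c("case", "case", "case")), "both classes")
  # brute-force scan oracle on random instances
  set.seed(707)
  for (rep in 1:20) {
    sc <- round(stats::runif(30), 2)
    lb <- sample(c("case", "control"), 30, replace = TRUE,
                 prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    thr <- youden_threshold(sc, lb)
    is_case <- lb == "case"
    j_at <- function(t) {
      pos <- sc >= t
      sum(pos & is_case) / sum(is_case) + sum(!pos & !is_case) / sum(!is_case) - 1
    }
    cand <- sort(unique(sc))
    best_j <- max(vapply(cand, j_at, numeric(1)))
    expect_equal(j_at(thr), best_j, tolerance = 1e-12)
    expect_equal(thr, min(cand[vapply(cand, j_at, numeric(1)) >= best_j - 1e-12]))
  }
})

test_that("bootstrap evaluation separates a separable cohort", {
  set.seed(808)
  n <- 60
  features <- data.frame(
    patient_id = sprintf("p%02d", 1:n),
    normalized_weight = c(stats::runif(n / 2, 2, 3), stats::runif(n / 2, 0, 1)),
    pair_week_agg = c(stats::rpois(n / 2, 8), stats::rpois(n / 2, 2)),
    worsen_count_agg = c(stats::rpois(n / 2, 3), stats::rpois(n / 2, 1)))
  labels <- rep(c("case", "control"), each = n / 2)
  res <- fit_and_bootstrap(features, labels,
                           bootstrap_config(repetitions = 30, seed = 5))
  expect_equal(res$mean_auroc, 1.0)
  expect_equal(res$mean_f1, 1.0)
  expect_true(res$ci95_auroc[1] <= res$mean_auroc &&
                res$mean_auroc <= res$ci95_auroc[2])
  # out-of-bag fraction concentrates near exp(-1)
  expect_gt(res$mean_oob_fraction, 0.30)
  expect_lt(res$mean_oob_fraction, 0.44)
  # reproducibility from the seed
  res2 <- fit_and_bootstrap(features, labels,
                            bootstrap_config(repetitions = 30, seed = 5))
  expect_identical(res$per_rep, res2$per_rep)
  # the split mode holds out one third exactly
  res3 <- fit_and_bootstrap(features, labels,
                            bootstrap_config(repetitions = 5, seed = 5,
                                             mode = "split"))
  expect_equal(unique(res3$per_rep$oob_fraction), 1 / 3, tolerance = 0.02)
})

test_that("reported AUROC matches the Mann-Whitney oracle", {
  set.seed(909)
  n <- 80
  features <- data.frame(
    normalized_weight = stats::rnorm(n, rep(c(0.8, 0), each = n / 2)),
    pair_week_agg = stats::rpois(n, 4),
    worsen_count_agg = stats::rpois(n, 2))
  labels <- rep(c("case", "control"), each = n / 2)
  cfg <- bootstrap_config(repetitions = 1, seed = 77)
  res <- fit_and_bootstrap(features, labels, cfg)
  # replay the single repetition to get the same out-of-bag scores
  set.seed(77)
  idx_case <- which(labels == "case"); idx_ctrl <- which(labels == "control")
  bag <- c(sample(idx_case, length(idx_case), replace = TRUE),
           sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
  test_idx <- setdiff(seq_len(n), unique(bag))
  x <- as.matrix(features)
  mu <- colMeans(x[bag, ]); sdv <- apply(x[bag, ], 2, sd); sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  fit <- suppressWarnings(glm(y ~ ., data = data.frame(y = labels[bag] == "case",
                                                       xs[bag, ]),
                              family = binomial()))
  sc <- as.numeric(predict(fit, newdata = data.frame(xs[test_idx, ]),
                           type = "response"))
  expect_equal(res$per_rep$auroc,
               oracle_auroc(sc, labels[test_idx] == "case"),
               tolerance = 1e-10)
})
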