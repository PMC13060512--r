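#' Youden-optimal classification threshold
#'
#' Scans the observed score values as candidate thresholds (classifying
#' `score >= threshold` as positive) and returns the one maximizing the
#' Youden index `J = sensitivity + specificity - 1`; ties resolve to the
#' lowest threshold.
#'
#' @param scores Numeric classifier scores.
#' @param labels Character vector with values `"case"` / `"control"` (or a
#'   logical vector, `TRUE` = case).
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  is_case <- .as_case(labels)
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    pos <- scores >= t
    sens <- sum(pos & is_case) / sum(is_case)
    spec <- sum(!pos & !is_case) / sum(!is_case)
    sens + spec - 1
  }, numeric(1))
  thr[which(j >= max(j) - 1e-12)[1]]
}

.as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case'/'control' or logical")
  }
  labels == "case"
}

# AUROC via pROC; constant scores default to 0.5 by convention.
.auroc <- function(scores, labels) {
  is_case <- .as_case(labels)
  if (length(unique(scores)) < 2) return(0.5)
  as.numeric(pROC::auc(pROC::roc(
    response = is_case, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

.f1_at <- function(scores, labels, threshold) {
  is_case <- .as_case(labels)
  pos <- scores >= threshold
  tp <- sum(pos & is_case)
  fp <- sum(pos & !is_case)
  fn <- sum(!pos & is_case)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Bootstrap evaluation configuration
#'
#' @param repetitions Number of bootstrap repetitions (default 100).
#' @param seed Optional RNG seed for reproducibility.
#' @param stratified Resample within each class (default `TRUE`).
#' @param mode `"oob"` (default): with-replacement bootstrap bags whose
#'   out-of-bag samples form the test set, giving an expected train:test
#'   ratio of about 2:1 (the out-of-bag fraction converges to
#'   `exp(-1) ~ 0.368`); `"split"`: a fixed stratified 2/3 - 1/3 split
#'   without replacement.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(repetitions = 100, seed = NULL,
                             stratified = TRUE, mode = c("oob", "split")) {
  stopifnot(repetitions >= 1)
  structure(list(repetitions = as.integer(repetitions), seed = seed,
                 stratified = isTRUE(stratified), mode = match.arg(mode)),
            class = "bootstrap_config")
}

#' Fit a logistic classifier under stratified out-of-bag bootstrap
#'
#' Per repetition: a stratified with-replacement bag (one draw of class
#' size per class) trains a logistic regression on the feature columns;
#' the out-of-bag patients form the test set. Features are standardized
#' using bag statistics only, and — when a `feature_builder` is supplied —
#' concept weights (SIS or TF-IDF) are recomputed on the bag only, so no
#' information leaks from test to train. Per repetition the function
#' records the out-of-bag AUROC, the Youden-optimal threshold on
#' out-of-bag scores, and the F1 at that threshold; summary means and
#' percentile 95% confidence intervals are taken over repetitions. A
#' repetition whose out-of-bag set is single-class is redrawn (counted in
#' `n_redrawn`); constant scores yield AUROC 0.5 by convention.
#'
#' @param features Data.frame of patient features; all numeric columns
#'   except `patient_id` are used as predictors (by default
#'   `normalized_weight`, `pair_week_agg`, `worsen_count_agg`).
#' @param labels Character vector (`"case"`/`"control"`) parallel to rows.
#' @param config A [bootstrap_config()].
#' @param feature_builder Optional function `bag_index -> features
#'   data.frame` (same rows as `features`) recomputing weight-dependent
#'   features from the bag only.
#' @return An object of class `discrimination_result`: `per_rep`
#'   (data.frame with `auroc`, `f1`, `threshold`, `oob_fraction`),
#'   `mean_auroc`, `mean_f1`, `ci95_auroc`, `ci95_f1`,
#'   `mean_oob_fraction`, `n_redrawn`.
#' @export
fit_and_bootstrap <- function(features, labels, config = bootstrap_config(),
                              feature_builder = NULL) {
  is_case <- .as_case(labels)
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(features)
  pred_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       "patient_id")
  idx_case <- which(is_case); idx_ctrl <- which(!is_case)
  per_rep <- data.frame(auroc = numeric(config$repetitions),
                        f1 = numeric(config$repetitions),
                        threshold = numeric(config$repetitions),
                        oob_fraction = numeric(config$repetitions))
  n_redrawn <- 0L
  for (rep in seq_len(config$repetitions)) {
    repeat {
      if (config$mode == "oob") {
        bag <- if (config$stratified) {
          c(sample(idx_case, length(idx_case), replace = TRUE),
            sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
        } else sample.int(n, n, replace = TRUE)
        test <- setdiff(seq_len(n), unique(bag))
      } else {
        tr_case <- sample(idx_case, round(2 / 3 * length(idx_case)))
        tr_ctrl <- sample(idx_ctrl, round(2 / 3 * length(idx_ctrl)))
        bag <- c(tr_case, tr_ctrl)
        test <- setdiff(seq_len(n), bag)
      }
      if (length(test) >= 2 && length(unique(is_case[test])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    feat <- if (is.null(feature_builder)) features else feature_builder(bag)
    x <- as.matrix(feat[, pred_cols, drop = FALSE])
    mu <- colMeans(x[bag, , drop = FALSE])
    sdv <- apply(x[bag, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    xs <- scale(x, center = mu, scale = sdv)
    dtr <- data.frame(y = is_case[bag], xs[bag, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dtr,
                                       family = stats::binomial()))
    dte <- data.frame(xs[test, , drop = FALSE])
    scores <- suppressWarnings(
      as.numeric(stats::predict(fit, newdata = dte, type = "response")))
    thr <- youden_threshold(scores, is_case[test])
    per_rep$auroc[rep] <- .auroc(scores, is_case[test])
    per_rep$threshold[rep] <- thr
    per_rep$f1[rep] <- .f1_at(scores, is_case[test], thr)
    per_rep$oob_fraction[rep] <- length(test) / n
  }
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  structure(list(per_rep = per_rep,
                 mean_auroc = mean(per_rep$auroc),
                 mean_f1 = mean(per_rep$f1),
                 ci95_auroc = ci(per_rep$auroc),
                 ci95_f1 = ci(per_rep$f1),
                 mean_oob_fraction = mean(per_rep$oob_fraction),
                 n_redrawn = n_redrawn),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %d repetitions\n", nrow(x$per_rep)))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_auroc, x$ci95_auroc[1], x$ci95_auroc[2]))
  cat(sprintf("  F1    %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_f1, x$ci95_f1[1], x$ci95_f1[2]))
  cat(sprintf("  mean out-of-bag fraction %.3f\n", x$mean_oob_fraction))
  invisible(x)
}

#' End-to-end case/control discrimination from note events
#'
#' Runs the full longitudinal pipeline: mention extraction and context
#' filtering, symptom-week coding, pair features, concept weighting (SIS
#' by default, recomputed inside each bootstrap bag; TF-IDF as the
#' alternative), patient features, and the bootstrap-evaluated logistic
#' classifier.
#'
#' @param notes Note events: `patient_id`, `day_offset`, `text`, `label`
#'   (`"case"`/`"control"`, constant within patient).
#' @param lexicon A [concept_lexicon()].
#' @param target_concepts Concept ids forming the symptom set.
#' @param weighting `"sis"` or `"tfidf"`.
#' @param config A [bootstrap_config()].
#' @param window Pre-diagnostic day-offset window.
#' @param weight_scope `"bag"` (default, leakage-safe: weights recomputed
#'   per bootstrap bag) or `"cohort"` (weights computed once on the full
#'   cohort).
#' @param prevalence_unit Counting unit for SIS prevalence, see
#'   [group_prevalence()].
#' @return A list: `result` (a `discrimination_result`), `features`
#'   (full-cohort feature table), `labels`, `weights` (full-cohort
#'   `weight_table`), `matrices`.
#' @export
discriminate_cohort <- function(notes, lexicon, target_concepts,
                                weighting = c("sis", "tfidf"),
                                config = bootstrap_config(),
                                window = c(-548, -91),
                                weight_scope = c("bag", "cohort"),
                                prevalence_unit = "patients") {
  weighting <- match.arg(weighting)
  weight_scope <- match.arg(weight_scope)
  stopifnot("label" %in% names(notes))
  mentions <- extract_mentions(notes, lexicon, target_concepts, window)
  pat <- unique(notes[, c("patient_id", "label")])
  if (anyDuplicated(pat$patient_id)) stop("inconsistent labels within patient")
  matrices <- lapply(pat$patient_id, function(p) {
    m <- mentions[mentions$patient_id == p, , drop = FALSE]
    mm <- build_symptom_week_matrix(m, target_concepts, window)
    mm$patient_id <- p
    mm
  })
  names(matrices) <- pat$patient_id
  labels <- pat$label
  pair_list <- lapply(matrices, extract_pair_features)
  make_weights <- function(idx) {
    if (weighting == "sis") {
      compute_sis(group_prevalence(matrices[idx], labels[idx],
                                   unit = prevalence_unit))
    } else {
      compute_tfidf_weights(matrices[idx])
    }
  }
  features_for <- function(w) {
    rows <- lapply(seq_along(matrices), function(i)
      compute_patient_features(matrices[[i]], pair_list[[i]], w))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  full_weights <- make_weights(seq_along(matrices))
  features <- features_for(full_weights)
  builder <- if (weight_scope == "bag") {
    function(bag) features_for(make_weights(bag))
  } else NULL
  result <- fit_and_bootstrap(features, labels, config,
                              feature_builder = builder)
  list(result = result, features = features, labels = labels,
       weights = full_weights, matrices = matrices)
}
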