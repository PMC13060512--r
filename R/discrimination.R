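#' Mention context categories
#'
#' Every concept mention in a clinical note is classified into one of six
#' contexts; only `possible` and `other` mentions describe the patient's
#' current presentation and are retained for feature building.
#'
#' @format Character vector of the six context labels.
#' @export
CONTEXT_LABELS <- c("family_history", "historical", "hypothetical",
                    "negated", "possible", "other")

# Cue tables for the rule-based context classifier. A cue fires when it
# appears in the sentence before the concept span (left scope).
.context_cues <- list(
  family_history = c("family history", "mother with", "father with",
                     "mother has", "father has"),
  negated        = c("\\bno\\b", "\\bdenies\\b", "\\bdenied\\b",
                     "\\bwithout\\b", "negative for", "\\bnot\\b"),
  historical     = c("history of", "\\bprior\\b", "\\bprevious\\b",
                     "\\bpast\\b", "\\bresolved\\b"),
  hypothetical   = c("\\bif\\b", "rule out", "\\bshould\\b.*\\bdevelop\\b"),
  possible       = c("concern for", "\\bpossible\\b", "\\bsuspected\\b",
                     "\\bmay have\\b", "\\bquestionable\\b")
)
.worsening_cues <- c("\\bworsening\\b", "\\bworsened\\b", "\\bprogressive\\b",
                     "\\bprogressing\\b", "\\bincreasing\\b", "\\bincreased\\b")

#' Rule-based mention context classification
#'
#' Deterministic cue-phrase fallback for mention context: the text to the
#' left of the concept span is scanned for cues assigning
#' `family_history`, `negated`, `historical`, `hypothetical` or
#' `possible` (checked in that order, so "family history of" wins over
#' "history of"); anything else is `other`. A worsening flag is set when
#' a worsening cue ("worsening", "progressive", "increasing", ...)
#' appears anywhere in the sentence. Any replacement classifier must
#' honour the same contract: sentence plus span in, one of the six
#' context labels plus a worsening flag out.
#'
#' @param sentence Sentence text containing the mention.
#' @param start,end 0-based half-open character offsets of the concept
#'   span within `sentence`.
#' @return List with elements `context` (one of [CONTEXT_LABELS]) and
#'   `worsening` (logical).
#' @export
classify_mention_context <- function(sentence, start, end) {
  if (start < 0 || end > nchar(sentence) || start >= end) {
    stop("span must lie within the sentence")
  }
  left <- tolower(substr(sentence, 1, start))
  context <- "other"
  for (lab in names(.context_cues)) {
    if (any(vapply(.context_cues[[lab]], grepl, logical(1), x = left))) {
      context <- lab
      break
    }
  }
  worsening <- any(vapply(.worsening_cues, grepl, logical(1),
                          x = tolower(sentence)))
  list(context = context, worsening = worsening)
}

#' Extract classified concept mentions from longitudinal note events
#'
#' Restricts events to the pre-diagnostic window, splits each note into
#' sentences, matches target concepts with the dictionary matcher, and
#' classifies each mention's context and worsening flag. Week bins are
#' `floor(day_offset / 7)` relative to the index date.
#'
#' @param notes Data.frame of note events with columns `patient_id`,
#'   `day_offset` (integer days relative to the index date, negative =
#'   before) and `text`.
#' @param lexicon A [concept_lexicon()].
#' @param target_concepts Character vector of concept ids of interest
#'   (typically the concepts of a disease profile's clinical presentation
#'   section); `NULL` keeps all lexicon concepts.
#' @param window Length-2 numeric, inclusive day-offset bounds (default
#'   `c(-548, -91)`: 18 to 3 months before diagnosis).
#' @param matcher A [matcher_config()].
#' @return Data.frame with columns `patient_id`, `concept_id`,
#'   `week_index`, `context`, `worsening`.
#' @export
extract_mentions <- function(notes, lexicon, target_concepts = NULL,
                             window = c(-548, -91),
                             matcher = matcher_config()) {
  stopifnot(all(c("patient_id", "day_offset", "text") %in% names(notes)))
  lex <- if (is.null(target_concepts)) lexicon else
    subset_lexicon(lexicon, target_concepts)
  keep <- notes$day_offset >= window[1] & notes$day_offset <= window[2]
  notes <- notes[keep, , drop = FALSE]
  # sentence-level memo: note streams reuse a limited sentence vocabulary,
  # and matching + context classification depend only on the sentence
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  analyze_sentence <- function(s) {
    res <- memo[[s]]
    if (is.null(res)) {
      m <- match_concepts(s, lex, matcher)
      res <- if (!nrow(m)) list() else {
        ctx <- lapply(seq_len(nrow(m)), function(r)
          classify_mention_context(s, m$start[r], m$end[r]))
        list(concept_id = m$concept_id,
             context = vapply(ctx, `[[`, character(1), "context"),
             worsening = vapply(ctx, `[[`, logical(1), "worsening"))
      }
      memo[[s]] <- res
    }
    res
  }
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    sents <- split_sentences(notes$text[i])
    week <- as.integer(floor(notes$day_offset[i] / 7))
    rows <- lapply(sents, function(s) {
      res <- analyze_sentence(s)
      if (!length(res)) return(NULL)
      data.frame(patient_id = notes$patient_id[i], concept_id = res$concept_id,
                 week_index = week, context = res$context,
                 worsening = res$worsening, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(patient_id = character(), concept_id = character(),
                      week_index = integer(), context = character(),
                      worsening = logical(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Build a patient's symptom-week matrix
#'
#' Assigns the three-level code per week and target concept: 1 when a
#' retained mention of the concept exists that week, 2 when the concept is
#' unmentioned although another concept is coded 1 in the same week, and 0
#' when the week has no retained mention of any concept. Multiple mentions
#' of one concept within a week collapse to a single code-1 cell; the
#' worsening flag of a cell is true when any retained mention of that
#' concept that week carries a worsening cue. `freq_pa(c)` counts the
#' weeks in which the concept was present (code 1). Only mentions with
#' context `possible` or `other` are retained.
#'
#' @param mentions Mention table as from [extract_mentions()] for a single
#'   patient (a `context` column, when present, is filtered to
#'   possible/other).
#' @param target_concepts Non-empty character vector of concept ids
#'   defining the matrix columns.
#' @param window Day-offset window defining the week rows (default
#'   `c(-548, -91)`).
#' @return An object of class `symptom_week_matrix`: `patient_id`,
#'   `weeks`, `concepts`, `code` (weeks x concepts integer matrix),
#'   `worsen` (logical matrix), `freq_pa` (named integer).
#' @export
build_symptom_week_matrix <- function(mentions, target_concepts,
                                      window = c(-548, -91)) {
  if (!length(target_concepts)) stop("target_concepts must be non-empty")
  target_concepts <- sort(unique(target_concepts))
  if ("context" %in% names(mentions)) {
    mentions <- mentions[mentions$context %in% c("possible", "other"), , drop = FALSE]
  }
  pid <- if (nrow(mentions)) unique(mentions$patient_id) else NA_character_
  if (length(pid) > 1) stop("mentions span multiple patients")
  weeks <- seq(as.integer(floor(window[1] / 7)),
               as.integer(floor(window[2] / 7)))
  code <- matrix(0L, nrow = length(weeks), ncol = length(target_concepts),
                 dimnames = list(as.character(weeks), target_concepts))
  worsen <- matrix(FALSE, nrow = length(weeks), ncol = length(target_concepts),
                   dimnames = dimnames(code))
  mentions <- mentions[mentions$concept_id %in% target_concepts &
                         mentions$week_index %in% weeks, , drop = FALSE]
  if (nrow(mentions)) {
    wi <- match(mentions$week_index, weeks)
    ci <- match(mentions$concept_id, target_concepts)
    code[cbind(wi, ci)] <- 1L
    w <- mentions$worsening
    for (r in which(w)) worsen[wi[r], ci[r]] <- TRUE
    # code 2: unmentioned concept in a week where something else is coded 1
    active <- rowSums(code == 1L) > 0
    sub <- code[active, , drop = FALSE]
    sub[sub == 0L] <- 2L
    code[active, ] <- sub
  }
  freq_pa <- stats::setNames(as.integer(colSums(code == 1L)), target_concepts)
  structure(list(patient_id = pid, weeks = weeks, concepts = target_concepts,
                 code = code, worsen = worsen, freq_pa = freq_pa),
            class = "symptom_week_matrix")
}

#' @export
print.symptom_week_matrix <- function(x, ...) {
  cat("<symptom_week_matrix> patient ", x$patient_id, ": ",
      length(x$weeks), " weeks x ", length(x$concepts), " concepts; ",
      sum(x$code == 1L), " present cells\n", sep = "")
  invisible(x)
}

#' Co-occurrence pair features from a symptom-week matrix
#'
#' For every unordered concept pair with at least one week in which both
#' are coded 1: `pair_week_single` counts the distinct co-occurrence
#' weeks and `worsen_count_single` counts those weeks in which either
#' member carries a worsening flag. Pairs with no co-occurrence week are
#' omitted.
#'
#' @param matrix A `symptom_week_matrix`.
#' @return Data.frame with columns `concept_a`, `concept_b`
#'   (`concept_a < concept_b`), `pair_week_single`, `worsen_count_single`.
#' @export
extract_pair_features <- function(matrix) {
  stopifnot(inherits(matrix, "symptom_week_matrix"))
  present <- matrix$code == 1L
  active_concepts <- which(colSums(present) > 0)
  rows <- list()
  if (length(active_concepts) >= 2) {
    combos <- utils::combn(active_concepts, 2)
    for (k in seq_len(ncol(combos))) {
      i <- combos[1, k]; j <- combos[2, k]
      both <- present[, i] & present[, j]
      pw <- sum(both)
      if (pw == 0) next
      wc <- sum(both & (matrix$worsen[, i] | matrix$worsen[, j]))
      rows[[length(rows) + 1L]] <- data.frame(
        concept_a = matrix$concepts[i], concept_b = matrix$concepts[j],
        pair_week_single = pw, worsen_count_single = wc,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(concept_a = character(), concept_b = character(),
               pair_week_single = integer(), worsen_count_single = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Case/control concept prevalence
#'
#' Counts, per concept and group, how many patients had the concept
#' present in at least one week (`unit = "patients"`, the default) or the
#' total number of patient-weeks with the concept present
#' (`unit = "weeks"`). Feeds [compute_sis()] with its +5 pseudo-count.
#'
#' @param matrices Named list of `symptom_week_matrix`, one per patient.
#' @param labels Character vector parallel to `matrices` with values
#'   `"case"` / `"control"`.
#' @param unit Counting unit.
#' @return A list of class `group_prevalence`: `freq_case`, `freq_ctrl`
#'   (named numeric), `pseudo_count = 5`.
#' @export
group_prevalence <- function(matrices, labels,
                             unit = c("patients", "weeks")) {
  unit <- match.arg(unit)
  stopifnot(length(matrices) == length(labels),
            all(labels %in% c("case", "control")))
  tally <- function(idx) {
    acc <- numeric(0)
    for (i in idx) {
      f <- matrices[[i]]$freq_pa
      v <- if (unit == "patients") stats::setNames(as.numeric(f > 0), names(f))
           else stats::setNames(as.numeric(f), names(f))
      nm <- union(names(acc), names(f))
      acc <- stats::setNames(
        ifelse(is.na(acc[nm]), 0, acc[nm]) + ifelse(is.na(v[nm]), 0, v[nm]), nm)
    }
    acc
  }
  structure(list(freq_case = tally(which(labels == "case")),
                 freq_ctrl = tally(which(labels == "control")),
                 pseudo_count = 5),
            class = "group_prevalence")
}

#' Symptom importance scores from prevalence difference
#'
#' `SIS(c) = log2((freq_case(c) + 5) / (freq_ctrl(c) + 5))`: positive for
#' concepts enriched in cases, negative for control-enriched concepts;
#' the +5 pseudo-count keeps the score finite and shrinks rare-concept
#' estimates toward 0. A concept absent from one group's map contributes
#' 0 to that count.
#'
#' @param prev A [group_prevalence()].
#' @return A list of class `weight_table` with `method = "SIS"` and
#'   `weight` (named numeric over the union of concepts).
#' @export
compute_sis <- function(prev) {
  stopifnot(inherits(prev, "group_prevalence"))
  ids <- union(names(prev$freq_case), names(prev$freq_ctrl))
  fc <- prev$freq_case[ids]; fc[is.na(fc)] <- 0
  f0 <- prev$freq_ctrl[ids]; f0[is.na(f0)] <- 0
  k <- prev$pseudo_count
  structure(list(method = "SIS",
                 weight = stats::setNames(log2((fc + k) / (f0 + k)), ids)),
            class = "weight_table")
}

#' TF-IDF concept weights as an alternative importance score
#'
#' Each patient's pre-diagnostic window is one document; the term
#' frequency of concept `c` for patient `p` is `freq_pa(c)` (weeks
#' present) and `idf(c) = ln((1 + N)/(1 + df(c))) + 1` with `N` patients
#' and `df(c)` the number of patients with the concept present at least
#' once. The table weight of `c` is the mean of `tf * idf` across all
#' patients.
#'
#' @param matrices Named list of `symptom_week_matrix`, one per patient.
#' @return A `weight_table` with `method = "TFIDF"`.
#' @export
compute_tfidf_weights <- function(matrices) {
  if (!length(matrices)) stop("need at least one patient")
  n <- length(matrices)
  ids <- sort(unique(unlist(lapply(matrices, function(m) names(m$freq_pa)))))
  tf <- vapply(matrices, function(m) {
    v <- m$freq_pa[ids]; v[is.na(v)] <- 0; as.numeric(v)
  }, numeric(length(ids)))
  tf <- matrix(tf, nrow = length(ids), dimnames = list(ids, NULL))
  df <- rowSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(method = "TFIDF",
                 weight = stats::setNames(rowMeans(tf * idf), ids)),
            class = "weight_table")
}

#' Patient-level discrimination features
#'
#' Aggregates the pair features and symptom weights of a patient:
#' `pair_week_agg` and `worsen_count_agg` sum `pair_week_single` /
#' `worsen_count_single` over all pairs; `total_symptom_weight` sums, over
#' the deduplicated set of concepts participating in any pair,
#' `weight(c) * (1 + freq_pa(c))` (a concept in several pairs is counted
#' once); `normalized_weight = total_symptom_weight / (pair_week_agg + 1)`
#' normalizes symptom burden by co-occurrence activity.
#'
#' @param matrix A `symptom_week_matrix`.
#' @param pairs Pair features from [extract_pair_features()] on `matrix`.
#' @param weights A `weight_table`.
#' @return A one-row data.frame: `patient_id`, `pair_week_agg`,
#'   `worsen_count_agg`, `total_symptom_weight`, `normalized_weight`.
#' @export
compute_patient_features <- function(matrix, pairs, weights) {
  stopifnot(inherits(matrix, "symptom_week_matrix"),
            inherits(weights, "weight_table"))
  pair_week_agg <- sum(pairs$pair_week_single)
  worsen_count_agg <- sum(pairs$worsen_count_single)
  concepts <- unique(c(pairs$concept_a, pairs$concept_b))
  w <- weights$weight[concepts]
  w[is.na(w)] <- 0
  total <- if (length(concepts)) {
    sum(w * (1 + matrix$freq_pa[concepts]))
  } else 0
  data.frame(patient_id = matrix$patient_id,
             pair_week_agg = pair_week_agg,
             worsen_count_agg = worsen_count_agg,
             total_symptom_weight = total,
             normalized_weight = total / (pair_week_agg + 1),
             stringsAsFactors = FALSE)
}

#' Feature table for a cohort
#'
#' Convenience wrapper: pair extraction plus [compute_patient_features()]
#' for every patient under a common weight table.
#'
#' @param matrices Named list of `symptom_week_matrix`.
#' @param weights A `weight_table`.
#' @return Data.frame, one row per patient.
#' @export
cohort_features <- function(matrices, weights) {
  rows <- lapply(matrices, function(m)
    compute_patient_features(m, extract_pair_features(m), weights))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
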