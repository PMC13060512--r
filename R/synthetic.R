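# Pseudo-clinical vocabulary for generated lexicons. Concept surface
# strings are unique (adjective, organ, noun) triples, so the dictionary
# matcher can always recover planted concepts exactly.
.vocab <- list(
  adj = c("nodular", "diffuse", "focal", "progressive", "recurrent",
          "chronic", "acute", "bilateral", "segmental", "atypical",
          "fibrotic", "granular", "cystic", "sclerotic", "necrotic",
          "hyperplastic", "atrophic", "edematous", "ischemic", "reactive",
          "infiltrative", "obstructive", "restrictive", "erosive",
          "ulcerative", "papular", "vesicular", "mottled", "indurated",
          "friable", "calcified", "pigmented", "telangiectatic", "bullous",
          "lobular", "perihilar", "subpleural", "periportal", "cortical",
          "medullary"),
  organ = c("pulmonary", "hepatic", "renal", "cardiac", "splenic",
            "pancreatic", "dermal", "osseous", "synovial", "neural",
            "retinal", "cochlear", "adrenal", "thyroid", "gastric",
            "colonic", "esophageal", "bronchial", "pleural", "pericardial",
            "vascular", "lymphatic", "muscular", "tendinous", "meningeal",
            "corneal", "gingival", "nasal"),
  noun = c("sclerosis", "dystrophy", "granuloma", "effusion", "stenosis",
           "ectasia", "atrophy", "hypertrophy", "dysplasia", "neuropathy",
           "myopathy", "angiopathy", "fibrosis", "calcinosis", "purpura",
           "erythema", "induration", "ulceration", "nodularity",
           "opacification", "thickening", "crepitus", "rigidity",
           "tenderness")
)

# Deterministic unique concept surface forms: index -> (adj, organ, noun).
.concept_surface <- function(i) {
  na <- length(.vocab$adj); no <- length(.vocab$organ); nn <- length(.vocab$noun)
  if (i > na * no * nn) stop("concept namespace exhausted")
  j <- i - 1L
  a <- .vocab$adj[j %% na + 1L]
  o <- .vocab$organ[(j %/% na) %% no + 1L]
  n <- .vocab$noun[(j %/% (na * no)) %% nn + 1L]
  list(preferred = paste(a, o, n), alt = paste(a, n, "of the", o, "region"))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Benchmark generator configuration
#'
#' Study conditions of the synthetic screening benchmark: each disease
#' owns a disjoint set of signature concepts plus a few concepts from a
#' shared background pool; a case emits each of its disease's signature
#' concepts independently at `signature_emission_rate` and adds noise
#' concepts sampled from other diseases.
#'
#' @param n_diseases Number of diseases (default 200).
#' @param concepts_per_disease Signature concepts per disease (default 6).
#' @param shared_background_concepts Size of the shared background pool
#'   (default 30); every profile references 3 of them.
#' @param n_cases Number of patient cases (default 500).
#' @param signature_emission_rate Probability that a case mentions each
#'   signature concept (default 0.7).
#' @param noise_concepts_per_case Concepts sampled from other diseases'
#'   signatures per case (default 3).
#' @param seed RNG seed; identical configs generate identical output.
#' @return An object of class `bench_gen_config`.
#' @export
bench_gen_config <- function(n_diseases = 200, concepts_per_disease = 6,
                             shared_background_concepts = 30, n_cases = 500,
                             signature_emission_rate = 0.7,
                             noise_concepts_per_case = 3, seed = 20260101) {
  stopifnot(n_diseases >= 1, concepts_per_disease >= 1,
            signature_emission_rate >= 0, signature_emission_rate <= 1,
            noise_concepts_per_case >= 0, shared_background_concepts >= 0)
  structure(list(n_diseases = as.integer(n_diseases),
                 concepts_per_disease = as.integer(concepts_per_disease),
                 shared_background_concepts = as.integer(shared_background_concepts),
                 n_cases = as.integer(n_cases),
                 signature_emission_rate = signature_emission_rate,
                 noise_concepts_per_case = as.integer(noise_concepts_per_case),
                 seed = seed),
            class = "bench_gen_config")
}

.case_sentence <- function(syn) {
  tpl <- c("The patient presents with %s.",
           "Examination is notable for %s.",
           "The patient reports %s.")
  sprintf(sample(tpl, 1), syn)
}

#' Generate a synthetic screening benchmark
#'
#' Produces a concept lexicon, one ten-section profile per disease whose
#' core sections embed the disease's signature and background concept
#' synonyms in templated clinical-style sentences, and patient cases whose
#' text emits the true disease's signature concepts at the configured
#' rate plus noise concepts from other diseases. The ground-truth disease
#' of every case is recorded.
#'
#' @param config A [bench_gen_config()].
#' @return List with `lexicon` ([concept_lexicon()]), `profiles` (list of
#'   [disease_profile()]), `cases` (data.frame `patient_id`, `text`,
#'   `truth_disease_id`), `signatures` (disease -> concept ids) and
#'   `background` (disease -> background concept ids).
#' @export
generate_benchmark <- function(config = bench_gen_config()) {
  .with_seed(config$seed, {
    nd <- config$n_diseases
    cpd <- config$concepts_per_disease
    n_con <- nd * cpd + config$shared_background_concepts
    surfaces <- lapply(seq_len(n_con), .concept_surface)
    lex_df <- data.frame(
      concept_id = sprintf("C%07d", seq_len(n_con)),
      preferred_name = vapply(surfaces, `[[`, character(1), "preferred"),
      synonyms = vapply(surfaces, `[[`, character(1), "alt"),
      semantic_group = SEMANTIC_GROUPS[(seq_len(n_con) - 1L) %% 4L + 1L],
      stringsAsFactors = FALSE)
    lexicon <- concept_lexicon(lex_df)
    sig_ids <- split(lex_df$concept_id[seq_len(nd * cpd)],
                     rep(seq_len(nd), each = cpd))
    bg_pool <- lex_df$concept_id[seq_len(config$shared_background_concepts) + nd * cpd]
    syn_of <- function(cid) {
      i <- match(cid, lex_df$concept_id)
      if (stats::runif(1) < 0.5) lex_df$preferred_name[i] else
        strsplit(lex_df$synonyms[i], "|", fixed = TRUE)[[1]][1]
    }
    disease_ids <- sprintf("D%04d", seq_len(nd))
    disease_names <- paste(
      .vocab$adj[(seq_len(nd) - 1L) %% length(.vocab$adj) + 1L],
      .vocab$organ[((seq_len(nd) - 1L) %/% length(.vocab$adj)) %% length(.vocab$organ) + 1L],
      "syndrome")
    backgrounds <- lapply(seq_len(nd), function(i)
      if (length(bg_pool)) sample(bg_pool, min(3L, length(bg_pool))) else character())
    profiles <- lapply(seq_len(nd), function(i) {
      sig <- sig_ids[[i]]
      n_clin <- ceiling(length(sig) * 0.6)
      clin <- vapply(sig[seq_len(n_clin)], function(cid)
        sprintf("Patients typically present with %s.", syn_of(cid)), character(1))
      diag_ids <- sig[setdiff(seq_along(sig), seq_len(n_clin))]
      diag <- c(
        vapply(diag_ids, function(cid)
          sprintf("Evaluation commonly reveals %s.", syn_of(cid)), character(1)),
        vapply(backgrounds[[i]][seq_len(min(2, length(backgrounds[[i]])))],
               function(cid) sprintf("Workup may show %s.", syn_of(cid)),
               character(1)))
      mgmt <- c("Management is supportive and multidisciplinary.",
                if (length(backgrounds[[i]]) >= 3)
                  sprintf("Therapy targets %s when present.",
                          syn_of(backgrounds[[i]][3])))
      disease_profile(
        disease_ids[i], disease_names[i], "synthetic_source",
        sections = list(
          overview = sprintf("%s is a rare disorder described here for benchmarking.",
                             disease_names[i]),
          synonyms_abbreviations = sprintf("Also known as %s.",
                                           toupper(substr(disease_names[i], 1, 3))),
          subtypes_variants = sprintf("A classic and an attenuated variant of %s are recognized.",
                                      disease_names[i]),
          epidemiology = "Estimated prevalence is below one in fifty thousand.",
          etiology_pathogenesis = "The underlying mechanism is incompletely understood.",
          clinical_presentation = paste(clin, collapse = " "),
          diagnostic_evaluation = paste(diag, collapse = " "),
          management_standard_therapy = paste(mgmt, collapse = " "),
          investigational_therapies = "Several agents are under early investigation.",
          prognosis = "Prognosis varies with the extent of organ involvement."),
        references = sprintf("Synthetic reference https://example.org/%s", disease_ids[i]))
    })
    names(profiles) <- disease_ids
    truth <- disease_ids[(seq_len(config$n_cases) - 1L) %% nd + 1L]
    all_sig <- unlist(sig_ids, use.names = FALSE)
    cases <- lapply(seq_len(config$n_cases), function(i) {
      sig <- sig_ids[[match(truth[i], disease_ids)]]
      emitted <- sig[stats::runif(length(sig)) < config$signature_emission_rate]
      noise <- if (config$noise_concepts_per_case > 0) {
        sample(setdiff(all_sig, sig), config$noise_concepts_per_case)
      } else character()
      sents <- vapply(c(emitted, noise), function(cid)
        .case_sentence(syn_of(cid)), character(1))
      data.frame(patient_id = sprintf("P%05d", i),
                 text = paste(sample(sents), collapse = " "),
                 truth_disease_id = truth[i],
                 emitted = length(emitted), n_signature = length(sig),
                 stringsAsFactors = FALSE)
    })
    cases <- do.call(rbind, cases)
    list(lexicon = lexicon, profiles = profiles, cases = cases,
         signatures = sig_ids, background = stats::setNames(backgrounds, disease_ids),
         config = config)
  })
}

#' Generate a benchmark with complementary channel failure modes
#'
#' Builds the same knowledge artifacts as [generate_benchmark()], but
#' splits the cases in two halves with opposite retrieval difficulty. In
#' *sparse-masked* cases the text contains no lexicon synonyms at all —
#' only the true disease's name and shuffled words from its retrieval
#' document plus its shared background concepts — so concept-based BM25
#' is nearly uninformative while word-level dense similarity still works.
#' In *dense-masked* cases the signature synonyms are present verbatim,
#' but the text is flooded with words sampled from other diseases'
#' documents, degrading the dense channel while sparse matching stays
#' strong. The degraded channel is weakened, not destroyed: it retains
#' enough signal to keep the truth in its upper ranks, the regime in
#' which reciprocal rank fusion recovers both halves.
#'
#' @param config A [bench_gen_config()].
#' @param foreign_words Number of words sampled from other diseases'
#'   documents into each dense-masked case (default 60).
#' @return As [generate_benchmark()], with an extra `cases$mask` column
#'   (`"sparse"` or `"dense"`).
#' @export
generate_masked_benchmark <- function(config = bench_gen_config(),
                                      foreign_words = 60) {
  base <- generate_benchmark(config)
  .with_seed(config$seed + 1L, {
    lex_df <- base$lexicon$entries
    docs <- vapply(base$profiles, build_disease_document, character(1))
    doc_words <- lapply(docs, function(d) .tokenize_offsets(d)$token)
    disease_ids <- names(base$profiles)
    syn_of <- function(cid) {
      i <- match(cid, lex_df$concept_id)
      lex_df$preferred_name[i]
    }
    n <- nrow(base$cases)
    mask <- rep(c("sparse", "dense"), length.out = n)
    texts <- character(n)
    for (i in seq_len(n)) {
      d <- base$cases$truth_disease_id[i]
      di <- match(d, disease_ids)
      if (mask[i] == "sparse") {
        # lexically masked: the only extractable concept is one shared
        # background concept, so BM25 cannot separate its ~20 carriers;
        # name + shuffled single document words keep the dense channel alive
        w <- sample(doc_words[[di]], min(25, length(doc_words[[di]])))
        bg <- syn_of(sample(base$background[[d]], 1))
        texts[i] <- paste(c(base$profiles[[di]]$name, sample(w),
                            sprintf("Workup shows %s.", bg)),
                          collapse = " ")
      } else {
        sig <- base$signatures[[di]]
        own <- vapply(sig, syn_of, character(1))
        others <- sample(setdiff(seq_along(disease_ids), di), 10)
        foreign <- sample(unlist(doc_words[others], use.names = FALSE),
                          foreign_words)
        texts[i] <- paste(c(vapply(own, function(s)
          sprintf("The patient presents with %s.", s), character(1)),
          sample(foreign)), collapse = " ")
      }
    }
    base$cases$text <- texts
    base$cases$mask <- mask
    base
  })
}

#' Cohort generator configuration
#'
#' Study conditions of the synthetic longitudinal cohort: each concept
#' carries a planted log2 prevalence ratio between cases and controls,
#' realized exactly on the pseudo-counted patient-level prevalence used
#' by the symptom importance score, i.e. the case presence probability
#' `q_case` solves `n*q_case + 5 = 2^effect * (n*q_ctrl + 5)`.
#'
#' @param n_cases,n_controls Patients per group (default 200 each).
#' @param concept_effects Named numeric vector: concept index ->
#'   planted log2 prevalence ratio. Default: four blocks of 8 concepts at
#'   effects 0, 0.5, 1 and 2.
#' @param base_prevalence Control-group probability that a concept is
#'   present for a patient (default 0.2).
#' @param visit_rate Probability that a week in the window carries a note
#'   (default 0.35).
#' @param mention_rate Per visit-week probability that a present concept
#'   is mentioned (default 0.3).
#' @param worsening_rate Named vector `c(case=, control=)`: probability
#'   that a mention carries a worsening cue (default 0.15 / 0.05).
#' @param distractor_rates Named vector `c(negated=, family=,
#'   historical=)`: per visit-week probabilities of inserting a distractor
#'   sentence whose mention must be filtered out by context
#'   classification (defaults 0.05, 0.03, 0.03).
#' @param seed RNG seed.
#' @return An object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_cases = 200, n_controls = 200,
                              concept_effects = NULL,
                              base_prevalence = 0.2, visit_rate = 0.35,
                              mention_rate = 0.3,
                              worsening_rate = c(case = 0.15, control = 0.05),
                              distractor_rates = c(negated = 0.05,
                                                   family = 0.03,
                                                   historical = 0.03),
                              seed = 20260102) {
  if (is.null(concept_effects)) {
    concept_effects <- rep(c(0, 0.5, 1, 2), each = 8)
  }
  if (length(worsening_rate) == 1) {
    worsening_rate <- c(case = unname(worsening_rate),
                        control = unname(worsening_rate))
  }
  stopifnot(base_prevalence > 0, base_prevalence < 1,
            all(distractor_rates >= 0 & distractor_rates <= 1),
            all(worsening_rate >= 0 & worsening_rate <= 1))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 concept_effects = concept_effects,
                 base_prevalence = base_prevalence,
                 visit_rate = visit_rate, mention_rate = mention_rate,
                 worsening_rate = worsening_rate,
                 distractor_rates = distractor_rates, seed = seed),
            class = "cohort_gen_config")
}

#' Generate a synthetic case/control longitudinal cohort
#'
#' Emits one note per patient visit-week across the 18-to-3-month
#' pre-index window (weeks -78 to -14, day offsets well inside
#' `[-548, -91]`). A concept is present for a patient with the
#' group-specific probability realizing its planted log2 prevalence
#' ratio; present concepts are mentioned in visit-week notes at
#' `mention_rate`, optionally with a worsening cue; negated, family
#' history and historical distractor sentences are inserted at the
#' configured rates and carry no usable evidence once context filtering
#' is applied.
#'
#' @param config A [cohort_gen_config()].
#' @return List with `lexicon`, `notes` (data.frame `patient_id`,
#'   `day_offset`, `text`, `label`), `target_concepts`,
#'   `planted_effects` (named by concept id), `presence` (patients x
#'   concepts logical matrix of planted presence) and `config`.
#' @export
generate_cohort <- function(config = cohort_gen_config()) {
  .with_seed(config$seed, {
    k <- length(config$concept_effects)
    surfaces <- lapply(seq_len(k), function(i) .concept_surface(i + 5000L))
    lex_df <- data.frame(
      concept_id = sprintf("S%05d", seq_len(k)),
      preferred_name = vapply(surfaces, `[[`, character(1), "preferred"),
      synonyms = vapply(surfaces, `[[`, character(1), "alt"),
      semantic_group = "symptoms_conditions",
      stringsAsFactors = FALSE)
    lexicon <- concept_lexicon(lex_df)
    effects <- stats::setNames(as.numeric(config$concept_effects),
                               lex_df$concept_id)
    n <- config$n_cases
    q0 <- config$base_prevalence
    q_case <- (2^effects * (n * q0 + 5) - 5) / n
    if (any(q_case > 1)) {
      warning("planted effects too large for base prevalence; clipping")
      q_case <- pmin(q_case, 1)
    }
    weeks <- seq(-78L, -14L)
    labels <- c(rep("case", config$n_cases), rep("control", config$n_controls))
    pids <- sprintf("PT%04d", seq_along(labels))
    presence <- matrix(FALSE, length(pids), k,
                       dimnames = list(pids, lex_df$concept_id))
    notes <- vector("list", length(pids))
    for (p in seq_along(pids)) {
      q <- if (labels[p] == "case") q_case else rep(q0, k)
      pres <- stats::runif(k) < q
      presence[p, ] <- pres
      wr <- config$worsening_rate[[labels[p]]]
      visit <- weeks[stats::runif(length(weeks)) < config$visit_rate]
      wk_notes <- lapply(visit, function(w) {
        sents <- character()
        mentioned <- which(pres)[stats::runif(sum(pres)) < config$mention_rate]
        for (ci in mentioned) {
          syn <- lex_df$preferred_name[ci]
          sents <- c(sents, if (stats::runif(1) < wr)
            sprintf("Patient reports worsening %s.", syn)
            else sprintf("Patient reports %s.", syn))
        }
        dr <- config$distractor_rates
        if (stats::runif(1) < dr[["negated"]]) {
          sents <- c(sents, sprintf("No %s.", lex_df$preferred_name[sample(k, 1)]))
        }
        if (stats::runif(1) < dr[["family"]]) {
          sents <- c(sents, sprintf("Family history of %s.",
                                    lex_df$preferred_name[sample(k, 1)]))
        }
        if (stats::runif(1) < dr[["historical"]]) {
          sents <- c(sents, sprintf("History of %s, resolved.",
                                    lex_df$preferred_name[sample(k, 1)]))
        }
        if (!length(sents)) sents <- "Routine follow up visit."
        data.frame(patient_id = pids[p], day_offset = w * 7L + 3L,
                   text = paste(sample(sents), collapse = " "),
                   label = labels[p], stringsAsFactors = FALSE)
      })
      notes[[p]] <- do.call(rbind, wk_notes)
    }
    notes <- do.call(rbind, notes)
    rownames(notes) <- NULL
    list(lexicon = lexicon, notes = notes,
         target_concepts = lex_df$concept_id,
         planted_effects = effects, presence = presence, config = config)
  })
}
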