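test_that("profile parsing maps headers onto the ten-section schema", {
  doc <- paste(
    "Test disease",
    "# Disease Overview", "An overview.",
    "# Synonyms and Abbreviations", "Also TD.",
    "# Subtypes or Variants", "Two variants.",
    "# Epidemiology", "Very rare.",
    "# Etiology and Pathogenesis", "Unknown cause.",
    "# Clinical Presentation", "Cough and dyspnea.",
    "# Diagnostic Evaluation", "Imaging and biopsy.",
    "# Management and Standard Therapy", "Supportive care.",
    "# Investigational or Emerging Therapies", "Trials ongoing.",
    "# Prognosis", "Variable.",
    sep = "\n")
  p <- parse_profile(doc, "src", "DX")
  expect_setequal(names(p$sections), PROFILE_SECTIONS)
  expect_equal(p$sections$clinical_presentation, "Cough and dyspnea.")
  expect_equal(p$name, "Test disease")

  # a missing section is absent, not an empty placeholder
  doc9 <- sub("# Prognosis\nVariable.", "", doc, fixed = TRUE)
  p9 <- parse_profile(doc9, "src", "DX")
  expect_length(p9$sections, 9)
  expect_false("prognosis" %in% names(p9$sections))

  # alias headers resolve through the alias table
  pa <- parse_profile("X\n# Signs and Symptoms\nWheezing.", "src", "DY")
  expect_equal(pa$sections$clinical_presentation, "Wheezing.")

  # unrecognized headers are preserved as diagnostics, not dropped
  pu <- parse_profile("X\n# Clinical Presentation\nCough.\n# Folk Remedies\nTea.",
                      "src", "DZ")
  expect_equal(pu$diagnostics, "Folk Remedies")
})

test_that("profile parsing enforces its format contract", {
  expect_error(parse_profile("", "src", "D1"), "empty")
  expect_error(parse_profile("X\n# Prognosis\nA.\n# Outlook\nB.", "src", "D1"),
               "duplicate")
  expect_error(disease_profile("D1", "", "src"), "non-empty")
  expect_error(disease_profile("D1", "n", "src", sections = list(foo = "x")),
               "unknown")
})

test_that("write_profile / parse_profile round-trips a valid profile", {
  p <- tiny_profile()
  p$references <- c("Ref one https://pubmed.ncbi.nlm.nih.gov/1",
                    "Ref two https://orpha.net/disease/2")
  q <- parse_profile(write_profile(p), p$source_id, p$disease_id)
  expect_mapequal(q$sections, p$sections)
  expect_equal(q$references, p$references)
  expect_equal(q$name, p$name)
})

test_that("dictionary matcher finds exact synonyms with similarity 1", {
  lex <- tiny_lexicon()
  m <- match_concepts("dry cough", lex)
  expect_true("C001" %in% m$concept_id)
  expect_equal(m$similarity[m$concept_id == "C001"], 1.0)
  expect_equal(m$start[m$concept_id == "C001"], 0)
  expect_equal(m$end[m$concept_id == "C001"], 9)

  expect_equal(nrow(match_concepts("entirely unrelated words", lex)), 0)
  expect_equal(nrow(match_concepts("", lex)), 0)
})

test_that("matcher is greedy longest-span-first per concept", {
  lex <- tiny_lexicon()
  # "chronic dry cough" (C002) contains "dry cough" (C001): both concepts
  # are matched (overlaps of different concepts are kept), and within each
  # concept only the longest available span is used
  m <- match_concepts("chronic dry cough for months", lex)
  expect_setequal(unique(m$concept_id), c("C001", "C002"))
  m2 <- m[m$concept_id == "C002", ]
  expect_equal(m2$matched_text, "chronic dry cough")
  # exhaustive span enumeration oracle: every reported span must be a
  # normalized synonym, and no longer matchable span exists for the concept
  txt <- "chronic dry cough and digital clubbing with dry cough again"
  m3 <- match_concepts(txt, lex)
  syns <- unlist(lex$entries$synonyms)
  for (r in seq_len(nrow(m3))) {
    expect_true(normalize_text(m3$matched_text[r]) %in% normalize_text(syns))
  }
  # the same concept never claims overlapping character spans
  for (cid in unique(m3$concept_id)) {
    s <- m3[m3$concept_id == cid, ]
    if (nrow(s) > 1) {
      s <- s[order(s$start), ]
      expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
  }
})

test_that("matcher is deterministic and normalization-invariant", {
  lex <- tiny_lexicon()
  a <- match_concepts("Chronic DRY cough; velcro crackles!", lex)
  b <- match_concepts("Chronic DRY cough; velcro crackles!", lex)
  expect_identical(a, b)
  c1 <- match_concepts("dry cough", lex)
  c2 <- match_concepts("  DRY   COUGH  ", lex)
  expect_identical(c1$concept_id, c2$concept_id)
  expect_identical(c1$similarity, c2$similarity)
})

test_that("fuzzy matching honours the similarity threshold", {
  lex <- tiny_lexicon()
  m <- match_concepts("patient has velcro crakles at bases",
                      lex, matcher_config(threshold = 0.8))
  expect_true("C004" %in% m$concept_id)
  expect_true(all(m$similarity >= 0.8))
  m2 <- match_concepts("patient has velcro crakles at bases",
                       lex, matcher_config(threshold = 1.0))
  expect_false("C004" %in% m2$concept_id)
})

test_that("disease documents use name plus the four core sections in order", {
  p <- tiny_profile()
  doc <- build_disease_document(p)
  expect_match(doc, "^fibrotic lung syndrome")
  pos <- vapply(c("Clinical Presentation", "Diagnostic Evaluation",
                  "Subtypes or Variants", "Management and Standard Therapy"),
                function(s) regexpr(s, doc, fixed = TRUE)[1], numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_false(grepl("Median survival", doc))  # prognosis is not core

  # non-core sections do not affect the document
  p2 <- p; p2$sections$epidemiology <- "One in a million."
  expect_identical(build_disease_document(p2), doc)

  p3 <- tiny_profile(sections = list(clinical_presentation = "Cough."))
  expect_equal(build_disease_document(p3),
               "fibrotic lung syndrome\nClinical Presentation: Cough.")
  p4 <- tiny_profile(sections = list(prognosis = "Poor."))
  expect_warning(d4 <- build_disease_document(p4), "core")
  expect_equal(d4, "fibrotic lung syndrome")
  expect_equal(build_disease_document(p, names_only = TRUE), p$name)
})

test_that("knowledge base indexes concepts per section and semantic group", {
  kb <- tiny_kb()
  expect_setequal(kb_disease_ids(kb), c("D1", "D2", "D3"))
  cp <- kb$concept_index$D1$clinical_presentation
  expect_setequal(cp, c("C001", "C002", "C005"))
  de <- kb$concept_index$D1$diagnostic_evaluation
  expect_setequal(de, c("C003", "C004"))
  # group index is consistent with concept index plus the lexicon
  for (d in kb_disease_ids(kb)) {
    ids <- kb_profile_concepts(kb, d)
    if (!length(ids)) next
    regroup <- split(ids, concept_group(kb$lexicon, ids))
    for (g in names(regroup)) {
      expect_setequal(kb$group_index[[d]][[g]], regroup[[g]])
    }
  }
  # a concept mentioned in two sections appears once in each section set
  p <- tiny_profile("D9", "double mention disease", sections = list(
    clinical_presentation = "Dry cough at night with dry cough by day.",
    diagnostic_evaluation = "Persistent dry cough observed."))
  kb2 <- build_knowledge_base(list(p), tiny_lexicon())
  expect_equal(sum(kb2$concept_index$D9$clinical_presentation == "C001"), 1)
  expect_equal(sum(kb2$concept_index$D9$diagnostic_evaluation == "C001"), 1)

  expect_error(build_knowledge_base(list(tiny_profile("D1", "a"),
                                         tiny_profile("D1", "b")),
                                    tiny_lexicon()),
               "duplicate")
  empty <- build_knowledge_base(list(), tiny_lexicon())
  expect_length(empty, 0)
})

test_that("unique concept counts match a brute-force substring scan", {
  kb <- tiny_kb()
  lex <- tiny_lexicon()
  # brute force: scan every synonym against every profile's text
  brute <- character()
  for (d in kb_disease_ids(kb)) {
    txt <- normalize_text(paste(unlist(kb$profiles[[d]]$sections), collapse = " "))
    for (i in seq_len(nrow(lex$entries))) {
      hits <- vapply(lex$entries$synonyms[[i]], function(s)
        grepl(normalize_text(s), txt, fixed = TRUE), logical(1))
      if (any(hits)) brute <- c(brute, lex$entries$concept_id[i])
    }
  }
  brute_counts <- table(factor(concept_group(lex, unique(brute)),
                               levels = SEMANTIC_GROUPS))
  expect_equal(unname(unique_concept_counts(kb)),
               as.integer(brute_counts))
})

test_that("lexicon TSV round-trips and validates", {
  lex <- tiny_lexicon()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  expect_equal(lex2$entries$concept_id, lex$entries$concept_id)
  expect_equal(lex2$entries$synonyms, lex$entries$synonyms,
               ignore_attr = TRUE)
  bad <- data.frame(concept_id = c("C1", "C1"), preferred_name = c("a", "b"),
                    synonyms = c("", ""), semantic_group = "symptoms_conditions")
  expect_error(concept_lexicon(bad), "duplicate")
  bad2 <- data.frame(concept_id = "C1", preferred_name = "a",
                     synonyms = "", semantic_group = "weird_group")
  expect_error(concept_lexicon(bad2), "semantic_group")
})
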