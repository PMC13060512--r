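#' The ten-section disease profile schema
#'
#' Disease profiles follow a fixed ten-section schema covering the axes a
#' clinician needs to recognize and manage a rare disease.
#'
#' @format Character vector of the ten section keys, in canonical order.
#' @export
PROFILE_SECTIONS <- c(
  "overview",
  "synonyms_abbreviations",
  "subtypes_variants",
  "epidemiology",
  "etiology_pathogenesis",
  "clinical_presentation",
  "diagnostic_evaluation",
  "management_standard_therapy",
  "investigational_therapies",
  "prognosis"
)

#' The four core sections used for retrieval
#'
#' Screening builds each disease document from the disease name plus four
#' core sections: clinical presentation, diagnostic evaluation, subtypes or
#' variants, and management and standard therapy, in that fixed order.
#'
#' @format Character vector of the four core section keys.
#' @export
CORE_SECTIONS <- c(
  "clinical_presentation",
  "diagnostic_evaluation",
  "subtypes_variants",
  "management_standard_therapy"
)

# Canonical display titles for section headers when writing profiles.
.section_titles <- c(
  overview                    = "Disease Overview",
  synonyms_abbreviations      = "Synonyms and Abbreviations",
  subtypes_variants           = "Subtypes or Variants",
  epidemiology                = "Epidemiology",
  etiology_pathogenesis       = "Etiology and Pathogenesis",
  clinical_presentation       = "Clinical Presentation",
  diagnostic_evaluation       = "Diagnostic Evaluation",
  management_standard_therapy = "Management and Standard Therapy",
  investigational_therapies   = "Investigational or Emerging Therapies",
  prognosis                   = "Prognosis"
)

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

# Header alias table: normalized header title -> section key. Includes the
# canonical titles plus common variants seen in disease write-ups.
.header_aliases <- local({
  canon <- stats::setNames(names(.section_titles), normalize_header(.section_titles))
  extra <- c(
    "overview"                        = "overview",
    "disease overview"                = "overview",
    "summary"                         = "overview",
    "synonyms"                        = "synonyms_abbreviations",
    "synonyms and abbreviations"      = "synonyms_abbreviations",
    "alternative names"               = "synonyms_abbreviations",
    "subtypes"                        = "subtypes_variants",
    "subtypes and variants"           = "subtypes_variants",
    "variants"                        = "subtypes_variants",
    "epidemiology"                    = "epidemiology",
    "prevalence"                      = "epidemiology",
    "etiology"                        = "etiology_pathogenesis",
    "etiology and pathogenesis"       = "etiology_pathogenesis",
    "causes"                          = "etiology_pathogenesis",
    "pathogenesis"                    = "etiology_pathogenesis",
    "clinical presentation"           = "clinical_presentation",
    "signs and symptoms"              = "clinical_presentation",
    "clinical features"               = "clinical_presentation",
    "symptoms"                        = "clinical_presentation",
    "diagnostic evaluation"           = "diagnostic_evaluation",
    "diagnosis"                       = "diagnostic_evaluation",
    "diagnostic workup"               = "diagnostic_evaluation",
    "management"                      = "management_standard_therapy",
    "treatment"                       = "management_standard_therapy",
    "management and standard therapy" = "management_standard_therapy",
    "standard therapies"              = "management_standard_therapy",
    "investigational therapies"       = "investigational_therapies",
    "investigational or emerging therapies" = "investigational_therapies",
    "emerging therapies"              = "investigational_therapies",
    "clinical trials"                 = "investigational_therapies",
    "prognosis"                       = "prognosis",
    "outlook"                         = "prognosis",
    "references"                      = ".references"
  )
  out <- c(canon, extra)
  out[!duplicated(names(out))]
})

#' Construct a disease profile
#'
#' @param disease_id Opaque disease identifier.
#' @param name Disease name (non-empty).
#' @param source_id Knowledge-source label (e.g., which generator or
#'   curated database produced the profile).
#' @param sections Named list of section texts; names must be a subset of
#'   [PROFILE_SECTIONS]. Missing sections are simply absent.
#' @param references Character vector of citation strings.
#' @return An object of class `disease_profile`.
#' @export
disease_profile <- function(disease_id, name, source_id,
                            sections = list(), references = character()) {
  if (!nzchar(name)) stop("profile name must be non-empty")
  bad <- setdiff(names(sections), PROFILE_SECTIONS)
  if (length(bad)) stop("unknown profile sections: ", paste(bad, collapse = ", "))
  sections <- sections[vapply(sections, function(s) nzchar(trimws(s)), logical(1))]
  structure(
    list(disease_id = as.character(disease_id), name = name,
         source_id = as.character(source_id),
         sections = sections, references = as.character(references),
         diagnostics = character()),
    class = "disease_profile"
  )
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("<disease_profile> ", x$disease_id, " (", x$name, ") from source '",
      x$source_id, "'\n", sep = "")
  cat("  sections: ", paste(names(x$sections), collapse = ", "), "\n", sep = "")
  if (length(x$references)) cat("  references: ", length(x$references), "\n", sep = "")
  invisible(x)
}

#' Parse a markdown disease profile
#'
#' Profiles are stored one disease per markdown file with top-level
#' `# Section Title` headers. Header titles are normalized and mapped onto
#' the ten-section schema through a fixed alias table (e.g., "Signs and
#' Symptoms" maps to `clinical_presentation`). A `# References` header
#' collects citation lines (one per non-empty line). Unrecognized headers
#' are preserved in the profile's `diagnostics` field rather than silently
#' dropped.
#'
#' @param document Markdown text (single string or character vector of lines).
#' @param source_id Knowledge-source label.
#' @param disease_id Disease identifier.
#' @param name Disease name; if `NULL`, the text before the first header (or
#'   the first header line itself when it does not map to a section) must
#'   carry it — otherwise `disease_id` is used.
#' @return A `disease_profile`.
#' @export
parse_profile <- function(document, source_id, disease_id, name = NULL) {
  lines <- if (length(document) == 1L) strsplit(document, "\n", fixed = TRUE)[[1]] else document
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop("empty profile document for disease ", disease_id)
  }
  hdr <- grep("^#[^#]", lines)
  sections <- list()
  references <- character()
  diagnostics <- character()
  seen <- character()
  preamble <- if (length(hdr)) lines[seq_len(max(hdr[1] - 1, 0))] else lines
  if (is.null(name)) {
    nm <- trimws(sub("^#*", "", preamble[nzchar(trimws(preamble))][1]))
    name <- if (is.na(nm) || !nzchar(nm)) as.character(disease_id) else nm
  }
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    title <- trimws(sub("^#\\s*", "", lines[hdr[i]]))
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body_txt <- trimws(paste(body, collapse = "\n"))
    key <- .header_aliases[normalize_header(title)]
    if (is.na(key)) {
      diagnostics <- c(diagnostics, title)
      next
    }
    if (key %in% seen) stop("duplicate profile header: '", title, "'")
    seen <- c(seen, key)
    if (key == ".references") {
      refs <- trimws(sub("^[-*0-9.)[:space:]]+", "", body[nzchar(trimws(body))]))
      references <- refs[nzchar(refs)]
    } else if (nzchar(body_txt)) {
      sections[[key]] <- body_txt
    }
  }
  p <- disease_profile(disease_id, name, source_id, sections, references)
  p$diagnostics <- diagnostics
  p
}

#' Serialize a disease profile to markdown
#'
#' Inverse of [parse_profile()]: writing then re-parsing reproduces the
#' profile's sections and references.
#'
#' @param profile A `disease_profile`.
#' @return Markdown text as a single string.
#' @export
write_profile <- function(profile) {
  stopifnot(inherits(profile, "disease_profile"))
  out <- profile$name
  for (key in PROFILE_SECTIONS) {
    if (!is.null(profile$sections[[key]])) {
      out <- c(out, paste0("# ", .section_titles[[key]]), profile$sections[[key]])
    }
  }
  if (length(profile$references)) {
    out <- c(out, "# References", paste0("- ", profile$references))
  }
  paste(out, collapse = "\n\n")
}

#' Read a directory of profile files for one knowledge source
#'
#' Layout: `<dir>/<disease_id>.md`, one disease per file.
#'
#' @param dir Directory of markdown files.
#' @param source_id Knowledge-source label; defaults to the directory name.
#' @return List of `disease_profile` objects keyed by disease id.
#' @export
read_profile_dir <- function(dir, source_id = basename(dir)) {
  files <- sort(list.files(dir, pattern = "\\.md$", full.names = TRUE))
  if (!length(files)) stop("no profile files (*.md) found in ", dir)
  profiles <- lapply(files, function(f) {
    parse_profile(readLines(f, warn = FALSE), source_id,
                  disease_id = sub("\\.md$", "", basename(f)))
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "disease_id")
  profiles
}

#' Build the retrieval document for a disease
#'
#' Concatenates the disease name with the four core sections
#' (clinical presentation, diagnostic evaluation, subtypes or variants,
#' management and standard therapy) in that fixed order, each introduced by
#' its section label. Missing core sections are omitted; when all four are
#' absent a warning is emitted and the bare name is returned.
#'
#' @param profile A `disease_profile`.
#' @param names_only If `TRUE`, return the bare disease name (the
#'   names-only ablation of the reranker input).
#' @return A single character string.
#' @export
build_disease_document <- function(profile, names_only = FALSE) {
  stopifnot(inherits(profile, "disease_profile"))
  if (names_only) return(profile$name)
  present <- intersect(CORE_SECTIONS, names(profile$sections))
  if (!length(present)) {
    warning("profile ", profile$disease_id, " has no core sections; using name only")
    return(profile$name)
  }
  parts <- vapply(present, function(k) {
    paste0(.section_titles[[k]], ": ", profile$sections[[k]])
  }, character(1))
  paste(c(profile$name, parts), collapse = "\n")
}
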