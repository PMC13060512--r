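#' Build a knowledge base from one source's disease profiles
#'
#' Runs the dictionary matcher over every section of every profile and
#' organizes the results into per-section and per-semantic-group concept
#' sets — the computable disease-knowledge layer that screening and
#' discrimination consume. Construction is idempotent for fixed inputs.
#'
#' @param profiles List of [disease_profile()] objects sharing one
#'   `source_id`.
#' @param lexicon A [concept_lexicon()].
#' @param config A [matcher_config()].
#' @return An object of class `knowledge_base` with elements `source_id`,
#'   `profiles` (named list), `concept_index` (disease -> section ->
#'   character vector of concept ids), `group_index` (disease ->
#'   semantic group -> character vector) and `lexicon`.
#' @export
build_knowledge_base <- function(profiles, lexicon, config = matcher_config()) {
  stopifnot(length(profiles) >= 0, inherits(lexicon, "concept_lexicon"))
  ids <- vapply(profiles, `[[`, character(1), "disease_id")
  if (anyDuplicated(ids)) {
    stop("duplicate disease_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  src <- unique(vapply(profiles, `[[`, character(1), "source_id"))
  if (length(src) > 1) stop("profiles mix sources: ", paste(src, collapse = ", "))
  names(profiles) <- ids
  concept_index <- lapply(profiles, function(p) {
    sec <- lapply(p$sections, function(txt) {
      sort(unique(match_concepts(txt, lexicon, config)$concept_id))
    })
    sec[lengths(sec) > 0]
  })
  group_index <- lapply(concept_index, function(sec) {
    all_ids <- sort(unique(as.character(unlist(sec, use.names = FALSE))))
    grp <- concept_group(lexicon, all_ids)
    out <- split(all_ids, factor(grp, levels = SEMANTIC_GROUPS))
    lapply(out, as.character)
  })
  structure(
    list(source_id = if (length(src)) src else NA_character_,
         profiles = profiles, concept_index = concept_index,
         group_index = group_index, lexicon = lexicon,
         cache = new.env(parent = emptyenv())),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  n_con <- length(unique(unlist(x$concept_index, use.names = FALSE)))
  cat("<knowledge_base> source '", x$source_id, "': ",
      length(x$profiles), " diseases, ", n_con,
      " distinct concepts indexed\n", sep = "")
  invisible(x)
}

#' @export
length.knowledge_base <- function(x) length(x$profiles)

#' Disease ids in a knowledge base
#' @param kb A `knowledge_base`.
#' @return Character vector.
#' @export
kb_disease_ids <- function(kb) names(kb$profiles)

#' Profile-level concept set for a disease
#'
#' Concepts are deduplicated across the profile's sections (each concept is
#' counted once per profile even if matched in several sections).
#'
#' @param kb A `knowledge_base`.
#' @param disease_id Disease identifier.
#' @param sections Optional subset of section keys to pool over; default
#'   all sections.
#' @return Sorted character vector of concept ids.
#' @export
kb_profile_concepts <- function(kb, disease_id, sections = NULL) {
  sec <- kb$concept_index[[disease_id]]
  if (is.null(sec)) stop("unknown disease: ", disease_id)
  if (!is.null(sections)) sec <- sec[intersect(sections, names(sec))]
  sort(unique(unlist(sec, use.names = FALSE)))
}

#' Per-disease concept bags over the core sections
#'
#' The sparse-retrieval document for each disease: the multiset of concept
#' ids over the four core sections (a concept indexed in two core sections
#' contributes two tokens).
#'
#' @param kb A `knowledge_base`.
#' @return Named list of character vectors (one bag per disease).
#' @export
kb_concept_bags <- function(kb) {
  lapply(kb$concept_index, function(sec) {
    as.character(unlist(sec[intersect(CORE_SECTIONS, names(sec))],
                        use.names = FALSE))
  })
}

#' Export a knowledge base's concept index as a triple table
#'
#' @param kb A `knowledge_base`.
#' @param path Optional TSV path; when given, the table is also written.
#' @return A data.frame of (disease_id, section, concept_id) triples.
#' @export
kb_concept_table <- function(kb, path = NULL) {
  rows <- lapply(names(kb$concept_index), function(d) {
    sec <- kb$concept_index[[d]]
    if (!length(sec)) return(NULL)
    data.frame(disease_id = d,
               section = rep(names(sec), lengths(sec)),
               concept_id = unlist(sec, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(disease_id = character(), section = character(),
                      concept_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
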