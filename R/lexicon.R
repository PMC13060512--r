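#' Clinical semantic groups used for concept extraction
#'
#' Concept extraction is restricted to four clinically oriented semantic
#' groups: symptoms and conditions, diagnostics and laboratory findings,
#' drugs and procedures, and genetics and molecular biology.
#'
#' @format Character vector of the four group keys.
#' @export
SEMANTIC_GROUPS <- c(
  "symptoms_conditions",
  "diagnostics_lab",
  "drugs_procedures",
  "genetics_molecular"
)

#' Construct a concept lexicon
#'
#' A concept lexicon maps surface strings (preferred names and synonyms) to
#' opaque concept identifiers (CUI-like), each tagged with one of the four
#' semantic groups. It is the dictionary behind [match_concepts()].
#'
#' @param entries A data.frame with columns `concept_id`, `preferred_name`,
#'   `synonyms` (list column of character vectors, or pipe-separated
#'   strings) and `semantic_group`.
#' @return An object of class `concept_lexicon` with elements `entries`
#'   (normalized data.frame with a list column `synonyms`) and
#'   `synonym_index` (environment mapping normalized surface string to
#'   character vector of concept ids).
#' @export
concept_lexicon <- function(entries) {
  stopifnot(is.data.frame(entries))
  req <- c("concept_id", "preferred_name", "synonyms", "semantic_group")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop("lexicon is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  entries$concept_id <- as.character(entries$concept_id)
  entries$preferred_name <- as.character(entries$preferred_name)
  if (!is.list(entries$synonyms)) {
    entries$synonyms <- strsplit(as.character(entries$synonyms), "|", fixed = TRUE)
  }
  if (any(!nzchar(entries$concept_id))) stop("empty concept_id in lexicon")
  if (anyDuplicated(entries$concept_id)) {
    stop("duplicate concept_id in lexicon: ",
         paste(unique(entries$concept_id[duplicated(entries$concept_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(entries$semantic_group), SEMANTIC_GROUPS)
  if (length(bad)) stop("unknown semantic_group: ", paste(bad, collapse = ", "))
  # preferred_name is always matchable
  entries$synonyms <- Map(function(p, s) unique(c(p, s[nzchar(s)])),
                          entries$preferred_name, entries$synonyms)
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(entries))) {
    for (syn in entries$synonyms[[i]]) {
      key <- normalize_text(syn)
      if (!nzchar(key)) next
      idx[[key]] <- unique(c(idx[[key]], entries$concept_id[i]))
    }
  }
  structure(
    list(entries = entries, synonym_index = idx,
         cache = new.env(parent = emptyenv())),
    class = "concept_lexicon"
  )
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat("<concept_lexicon> ", nrow(x$entries), " concepts, ",
      length(ls(x$synonym_index)), " distinct surface strings\n", sep = "")
  tab <- table(x$entries$semantic_group)
  for (g in names(tab)) cat("  ", g, ": ", tab[[g]], "\n", sep = "")
  invisible(x)
}

#' @export
length.concept_lexicon <- function(x) nrow(x$entries)

#' Subset a lexicon to a set of concept ids
#'
#' @param lexicon A `concept_lexicon`.
#' @param concept_ids Character vector of ids to retain.
#' @return A new `concept_lexicon`.
#' @export
subset_lexicon <- function(lexicon, concept_ids) {
  stopifnot(inherits(lexicon, "concept_lexicon"))
  keep <- lexicon$entries$concept_id %in% concept_ids
  concept_lexicon(lexicon$entries[keep, , drop = FALSE])
}

#' Look up semantic groups for concept ids
#'
#' @param lexicon A `concept_lexicon`.
#' @param concept_ids Character vector.
#' @return Character vector of semantic groups, `NA` for unknown ids.
#' @export
concept_group <- function(lexicon, concept_ids) {
  lexicon$entries$semantic_group[match(concept_ids, lexicon$entries$concept_id)]
}

#' Read a concept lexicon from TSV
#'
#' Expected columns: `concept_id`, `preferred_name`, `synonyms`
#' (pipe-separated) and `semantic_group`.
#'
#' @param path Path to the TSV file.
#' @return A `concept_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  concept_lexicon(df)
}

#' Write a concept lexicon to TSV
#'
#' @param lexicon A `concept_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "concept_lexicon"))
  df <- lexicon$entries
  df$synonyms <- vapply(df$synonyms, paste, character(1), collapse = "|")
  utils::write.table(df[, c("concept_id", "preferred_name", "synonyms", "semantic_group")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
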