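#' Read patient cases from JSONL
#'
#' One JSON object per line with fields `patient_id`, `text` and
#' optionally `truth_disease_id`.
#'
#' @param path JSONL file path.
#' @return Data.frame of cases.
#' @export
read_cases_jsonl <- function(path) {
  if (!file.exists(path)) stop("cases file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(patient_id = x$patient_id, text = x$text,
               truth_disease_id = x$truth_disease_id %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write patient cases to JSONL
#' @param cases Data.frame with `patient_id`, `text` and optionally
#'   `truth_disease_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cases_jsonl <- function(cases, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cases))) {
    rec <- list(patient_id = cases$patient_id[i], text = cases$text[i])
    if (!is.null(cases$truth_disease_id) && !is.na(cases$truth_disease_id[i])) {
      rec$truth_disease_id <- cases$truth_disease_id[i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read longitudinal note events from JSONL
#'
#' One JSON object per line with fields `patient_id`, `day_offset`,
#' `text` and optionally `label` (`"case"`/`"control"`).
#'
#' @param path JSONL file path.
#' @return Data.frame of note events.
#' @export
read_notes_jsonl <- function(path) {
  if (!file.exists(path)) stop("notes file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(patient_id = x$patient_id,
               day_offset = as.integer(x$day_offset), text = x$text,
               label = x$label %||% NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write note events to JSONL
#' @param notes Data.frame with `patient_id`, `day_offset`, `text` and
#'   optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(patient_id = notes$patient_id[i],
                day_offset = notes$day_offset[i], text = notes$text[i])
    if (!is.null(notes$label) && !is.na(notes$label[i])) {
      rec$label <- notes$label[i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# Fixed rankings TSV header shared by writers/readers and the CLI.
.rankings_header <- c("patient_id", "rank", "disease_id",
                      "stage1_score", "stage2_score")

#' Write a screening rankings table to TSV
#'
#' Fixed column set: `patient_id`, `rank`, `disease_id`, `stage1_score`,
#' `stage2_score`.
#'
#' @param rankings Data.frame as produced by [screen_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankings_tsv <- function(rankings, path) {
  missing_cols <- setdiff(.rankings_header, names(rankings))
  if (length(missing_cols)) {
    stop("rankings table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.table(rankings[, .rankings_header], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rankings TSV back into per-patient ranked lists
#'
#' @param path Rankings TSV path.
#' @return Named list (patient id -> [ranked_list()], ordered by `rank`,
#'   scored by `stage2_score` where present else `stage1_score`).
#' @export
read_rankings_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.rankings_header, names(df))
  if (length(missing_cols)) {
    stop("rankings file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  lapply(split(df, df$patient_id), function(g) {
    g <- g[order(g$rank), ]
    rl <- ranked_list(g$disease_id, rep(NA_real_, nrow(g)),
                      query_id = g$patient_id[1], tie_rank = g$rank)
    rl$score <- ifelse(is.na(g$stage2_score), g$stage1_score, g$stage2_score)
    rl
  })
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration snapshot, seed, package
#' version and input digests so outputs can be reproduced exactly.
#'
#' @param out_dir Output directory.
#' @param command Command name.
#' @param config List of configuration values (must be JSON-serializable).
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Seed used, if any.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(out_dir, command, config = list(),
                           inputs = character(), seed = NULL) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    command = command,
    version = as.character(utils::packageVersion("rdrkit")),
    seed = seed, config = config, input_digests = digests)
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Dispatch a pipeline command
#'
#' Single programmatic entry point behind the command-line tool.
#' Supported commands: `simulate-benchmark`, `simulate-cohort`,
#' `build-kb`, `quality`, `screen`, `ensemble`, `discriminate`,
#' `evaluate`. Each run writes its outputs plus a manifest into
#' `config$out`. Messages go to standard error; machine-readable output
#' goes to files only.
#'
#' @param command One of the supported command names.
#' @param config Named list of command options (paths, seeds, parameters).
#'   Unknown keys are rejected.
#' @return Invisible list of produced artifact paths.
#' @export
run <- function(command, config = list()) {
  commands <- c("simulate-benchmark", "simulate-cohort", "build-kb",
                "quality", "screen", "ensemble", "discriminate", "evaluate")
  if (!command %in% commands) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  }
  known <- c("out", "seed", "kb", "lexicon", "patients", "notes", "profile",
             "profiles", "rankings", "truths", "ks", "names_only",
             "rerank_k", "rrf_s", "top_k", "weighting", "reps", "top_n",
             "n_diseases", "n_cases", "n_controls", "masked")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(field) {
    v <- config[[field]]
    if (is.null(v)) stop("missing required config field: ", field)
    v
  }
  need_file <- function(field) {
    v <- need(field)
    if (!file.exists(v)) stop("config field '", field, "': path not found: ", v)
    v
  }
  artifacts <- character()
  inputs <- character()
  switch(command,
    "simulate-benchmark" = {
      cfg <- bench_gen_config(
        n_diseases = config$n_diseases %||% 200,
        n_cases = config$n_cases %||% 500,
        seed = config$seed %||% 20260101)
      bench <- if (isTRUE(config$masked)) generate_masked_benchmark(cfg)
               else generate_benchmark(cfg)
      lex_path <- file.path(out_dir, "lexicon.tsv")
      write_lexicon(bench$lexicon, lex_path)
      prof_dir <- file.path(out_dir, "profiles", "synthetic_source")
      dir.create(prof_dir, showWarnings = FALSE, recursive = TRUE)
      for (p in bench$profiles) {
        writeLines(write_profile(p), file.path(prof_dir, paste0(p$disease_id, ".md")))
      }
      case_path <- file.path(out_dir, "cases.jsonl")
      write_cases_jsonl(bench$cases, case_path)
      artifacts <- c(lex_path, prof_dir, case_path)
    },
    "simulate-cohort" = {
      cfg <- cohort_gen_config(
        n_cases = config$n_cases %||% 200,
        n_controls = config$n_controls %||% 200,
        seed = config$seed %||% 20260102)
      coh <- generate_cohort(cfg)
      lex_path <- file.path(out_dir, "lexicon.tsv")
      write_lexicon(coh$lexicon, lex_path)
      notes_path <- file.path(out_dir, "notes.jsonl")
      write_notes_jsonl(coh$notes, notes_path)
      artifacts <- c(lex_path, notes_path)
    },
    "build-kb" = {
      lexicon <- read_lexicon(need_file("lexicon"))
      profiles <- read_profile_dir(need_file("profiles"))
      kb <- build_knowledge_base(profiles, lexicon)
      kb_path <- file.path(out_dir, "kb_concepts.tsv")
      kb_concept_table(kb, kb_path)
      artifacts <- kb_path
      inputs <- config$lexicon
    },
    "quality" = {
      lexicon <- read_lexicon(need_file("lexicon"))
      profiles <- read_profile_dir(need_file("profiles"))
      kb <- build_knowledge_base(profiles, lexicon)
      rep_path <- file.path(out_dir, "quality_report.tsv")
      utils::write.table(quality_report(kb), rep_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts <- rep_path
      inputs <- config$lexicon
    },
    "screen" = {
      lexicon <- read_lexicon(need_file("lexicon"))
      profiles <- read_profile_dir(need_file("kb"))
      cases <- read_cases_jsonl(need_file("patients"))
      kb <- build_knowledge_base(profiles, lexicon)
      scfg <- screen_config(rerank_k = config$rerank_k %||% 20,
                            rrf = rrf_config(s = config$rrf_s %||% 60),
                            names_only = isTRUE(config$names_only))
      res <- screen_cases(cases, kb, scfg, top_n = config$top_n %||% 20)
      out_path <- file.path(out_dir, "rankings.tsv")
      write_rankings_tsv(res, out_path)
      artifacts <- out_path
      inputs <- c(config$lexicon, config$patients)
    },
    "ensemble" = {
      paths <- strsplit(need("rankings"), ",", fixed = TRUE)[[1]]
      if (length(paths) < 2) stop("ensemble needs at least 2 rankings files")
      per_source <- lapply(paths, read_rankings_tsv)
      names(per_source) <- tools::file_path_sans_ext(basename(paths))
      pats <- Reduce(intersect, lapply(per_source, names))
      cfg <- ensemble_config(top_k = config$top_k %||% 3)
      rows <- lapply(pats, function(p) {
        g <- gated_select(lapply(per_source, `[[`, p), cfg)
        data.frame(patient_id = p, chosen_source = g$chosen_source,
                   rank = seq_len(nrow(g$chosen_ranking)),
                   disease_id = g$chosen_ranking$disease_id,
                   stringsAsFactors = FALSE)
      })
      out_path <- file.path(out_dir, "ensemble_rankings.tsv")
      utils::write.table(do.call(rbind, rows), out_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts <- out_path
      inputs <- paths
    },
    "discriminate" = {
      lexicon <- read_lexicon(need_file("lexicon"))
      notes <- read_notes_jsonl(need_file("notes"))
      target <- if (!is.null(config$profile)) {
        p <- parse_profile(readLines(need_file("profile"), warn = FALSE),
                           "cli", "target")
        unique(match_concepts(p$sections$clinical_presentation %||% "",
                              lexicon)$concept_id)
      } else lexicon$entries$concept_id
      cfg <- bootstrap_config(repetitions = config$reps %||% 100,
                              seed = config$seed)
      res <- discriminate_cohort(notes, lexicon, target,
                                 weighting = config$weighting %||% "sis",
                                 config = cfg)
      feat_path <- file.path(out_dir, "features.tsv")
      utils::write.table(cbind(res$features, label = res$labels), feat_path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      met_path <- file.path(out_dir, "metrics.tsv")
      utils::write.table(res$result$per_rep, met_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      message(sprintf("mean AUROC %.3f, mean F1 %.3f",
                      res$result$mean_auroc, res$result$mean_f1))
      artifacts <- c(feat_path, met_path)
      inputs <- c(config$lexicon, config$notes)
    },
    "evaluate" = {
      rankings <- read_rankings_tsv(need_file("rankings"))
      truths_df <- utils::read.delim(need_file("truths"), stringsAsFactors = FALSE)
      stopifnot(all(c("patient_id", "truth_disease_id") %in% names(truths_df)))
      pats <- intersect(names(rankings), truths_df$patient_id)
      truths <- truths_df$truth_disease_id[match(pats, truths_df$patient_id)]
      ks <- as.integer(strsplit(as.character(config$ks %||% "1,3,5"),
                                ",", fixed = TRUE)[[1]])
      rep <- eval_report(rankings[pats], truths, ks)
      out_path <- file.path(out_dir, "evaluation.tsv")
      utils::write.table(
        data.frame(metric = c(names(rep$recall_at), "mrr", "n_cases"),
                   value = c(unname(rep$recall_at), rep$mrr, rep$n_cases)),
        out_path, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- out_path
      inputs <- c(config$rankings, config$truths)
    })
  write_manifest(out_dir, command, config, inputs, seed = config$seed)
  invisible(artifacts)
}
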