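# Audit sampling, summary tables and auditor-ready reports.

#' Draw the random audit sample of sets
#'
#' Uniform sample without replacement from the pool of sets matching
#' \code{kind_filter} with at most \code{max_set_size} members. Deterministic
#' given the pool and seed; selection order is preserved in the result. If
#' the pool is smaller than \code{sample_size} the whole pool is returned
#' (with a warning when it is empty).
#'
#' @param classifications Table from [classify_sets()].
#' @param sample_size Number of sets to draw. Default 50.
#' @param max_set_size Largest admissible set. Default 4 (sets of two, three
#'   or four concepts).
#' @param kind_filter \code{"DIFF"} (default), \code{"SAME"} or \code{"ALL"}.
#' @param seed Integer RNG seed; recorded in the run log and report header.
#' @return Character vector of selected set ids, in selection order.
#' @export
sample_sets <- function(classifications, sample_size = 50L,
                        max_set_size = 4L, kind_filter = "DIFF",
                        seed = 1L) {
  pool <- classifications[classifications$n_members <= max_set_size, ]
  if (kind_filter != "ALL") pool <- pool[pool$kind == kind_filter, ]
  pool_ids <- sort(pool$set_id, method = "radix")
  if (!length(pool_ids)) {
    warning("empty sampling pool (kind_filter = ", kind_filter,
            ", max_set_size = ", max_set_size, ")")
    return(character(0))
  }
  n <- min(as.integer(sample_size), length(pool_ids))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  pool_ids[sample.int(length(pool_ids), n)]
}

#' Summary of similarity sets and classifications
#'
#' Mirrors the shape of a release-level results table: totals and integer
#' percentages for Same/Diff sets, concept coverage, synonym-enabled sets,
#' and per-subtype (Diff-Par / Diff-Rel / Diff-Grp / Overall-Diff) set and
#' concept counts. Subtype flags overlap, so subtype counts may sum to more
#' than the Diff total. A concept in several sets is counted once for
#' coverage.
#'
#' @param classifications Table from [classify_sets()].
#' @param sets Set table from [form_sets()].
#' @param n_hierarchy_concepts Optional total number of active concepts in
#'   the audited hierarchy, enabling the coverage percentage.
#' @return Object of class \code{audit_summary}: a list with scalar counts
#'   (\code{n_sets}, \code{n_same}, \code{n_diff}, \code{pct_same},
#'   \code{pct_diff}, \code{n_concepts_in_sets}, \code{pct_concepts_covered},
#'   \code{n_synonym_only_sets}, \code{n_multi_set_concepts}) and a
#'   \code{data.table} \code{by_type} with one row per subtype plus Overall.
#' @export
summarize_audit <- function(classifications, sets,
                            n_hierarchy_concepts = NULL) {
  stopifnot(identical(classifications$set_id, sets$set_id))
  n_sets <- nrow(sets)
  n_diff <- sum(classifications$kind == "DIFF")
  n_same <- n_sets - n_diff
  pct <- function(part, total) {
    if (total == 0) 0L else as.integer(round(100 * part / total))
  }
  all_members <- unlist(sets$member_ids, use.names = FALSE)
  concepts <- unique(all_members)
  multi <- sum(table(all_members) > 1L)
  syn_only <- vapply(sets$evidence, function(ev) all(ev$kind == "SYNONYM"),
                     logical(1))
  subtype_row <- function(label, sel) {
    ids <- unique(unlist(sets$member_ids[sel], use.names = FALSE))
    data.table::data.table(set_type = label, n_sets = sum(sel),
                           n_concepts = length(ids))
  }
  is_diff <- classifications$kind == "DIFF"
  by_type <- data.table::rbindlist(list(
    subtype_row("Diff-Par", classifications$diff_par),
    subtype_row("Diff-Rel", classifications$diff_rel),
    subtype_row("Diff-Grp", classifications$diff_grp),
    subtype_row("Overall", is_diff)
  ))
  structure(list(
    n_sets = n_sets,
    n_same = n_same,
    n_diff = n_diff,
    pct_same = pct(n_same, n_sets),
    pct_diff = pct(n_diff, n_sets),
    n_concepts_in_sets = length(concepts),
    pct_concepts_covered = if (is.null(n_hierarchy_concepts)) NA_integer_
                           else pct(length(concepts), n_hierarchy_concepts),
    n_hierarchy_concepts = if (is.null(n_hierarchy_concepts)) NA_integer_
                           else as.integer(n_hierarchy_concepts),
    n_synonym_only_sets = sum(syn_only),
    n_multi_set_concepts = as.integer(multi),
    by_type = by_type
  ), class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat("Similarity-set audit summary\n")
  cat(sprintf("  sets: %d  (Diff: %d = %d%%, Same: %d = %d%%)\n",
              x$n_sets, x$n_diff, x$pct_diff, x$n_same, x$pct_same))
  if (!is.na(x$pct_concepts_covered))
    cat(sprintf("  concepts in sets: %d of %d active (%d%%)\n",
                x$n_concepts_in_sets, x$n_hierarchy_concepts,
                x$pct_concepts_covered))
  else
    cat(sprintf("  concepts in sets: %d\n", x$n_concepts_in_sets))
  cat(sprintf("  synonym-only sets: %d; concepts in >1 set: %d\n",
              x$n_synonym_only_sets, x$n_multi_set_concepts))
  print(x$by_type)
  invisible(x)
}

#' Write auditor-ready report files
#'
#' Emits, under \code{out_dir}:
#' \describe{
#'   \item{sets.csv}{one row per set member across all sets: set id, concept
#'     id, FSN, evidence term and kind, template, differing word, the three
#'     structural counts, classification flags.}
#'   \item{sets.jsonl}{one JSON object per set (members, template, differing
#'     words, evidence, classification).}
#'   \item{audit_sample.csv}{the sampled sets in the same row shape, plus an
#'     empty \code{auditor_verdict} column for the human auditor — the tool
#'     flags candidates, it never claims an inconsistency verdict.}
#'   \item{summary.csv}{the by-type summary table.}
#'   \item{run_log.txt}{tool version, configuration, seed, input digests and
#'     counts. No timestamps, so identical runs are byte-identical.}
#' }
#'
#' @param sets Set table from [form_sets()].
#' @param profiles Table from [structural_profiles()].
#' @param classifications Table from [classify_sets()].
#' @param sample_ids Set ids from [sample_sets()].
#' @param descriptions Description table (for FSN lookup).
#' @param out_dir Output directory (created if needed).
#' @param summary Optional [summarize_audit()] result for summary.csv.
#' @param run_info Optional named list of extra key/value lines for the run
#'   log (e.g. input paths, seed, config).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(sets, profiles, classifications, sample_ids,
                         descriptions, out_dir, summary = NULL,
                         run_info = list()) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fsn <- descriptions[descriptions$active & descriptions$type == "FSN", ]
  fsn_of <- stats::setNames(fsn$term, fsn$concept_id)
  cls <- classifications[match(sets$set_id, classifications$set_id), ]
  rows <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    ev <- sets$evidence[[i]]
    p <- profiles[match(ev$concept_id, profiles$concept_id), ]
    flags <- c("Diff-Par", "Diff-Rel", "Diff-Grp")[
      c(cls$diff_par[i], cls$diff_rel[i], cls$diff_grp[i])]
    rows[[i]] <- data.table::data.table(
      set_id = sets$set_id[i],
      concept_id = ev$concept_id,
      fsn = unname(fsn_of[ev$concept_id]),
      evidence_kind = ev$kind,
      evidence_description_id = ev$description_id,
      differing_word = ev$word,
      template = paste(sets$template[[i]], collapse = " "),
      parent_count = p$parent_count,
      attribute_count = p$attribute_count,
      role_group_count = p$role_group_count,
      set_kind = cls$kind[i],
      flags = paste(flags, collapse = ";")
    )
  }
  long <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(set_id = character(0))
  paths <- c(sets_csv = file.path(out_dir, "sets.csv"),
             sets_jsonl = file.path(out_dir, "sets.jsonl"),
             sample_csv = file.path(out_dir, "audit_sample.csv"),
             summary_csv = file.path(out_dir, "summary.csv"),
             run_log = file.path(out_dir, "run_log.txt"))
  data.table::fwrite(long, paths[["sets_csv"]])
  con <- file(paths[["sets_jsonl"]], open = "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(sets))) {
    obj <- list(set_id = sets$set_id[i],
                member_ids = sets$member_ids[[i]],
                template = sets$template[[i]],
                diff_words = as.list(sets$diff_words[[i]]),
                evidence = sets$evidence[[i]],
                kind = cls$kind[i],
                diff_par = cls$diff_par[i], diff_rel = cls$diff_rel[i],
                diff_grp = cls$diff_grp[i])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  samp <- long[long$set_id %in% sample_ids, ]
  samp <- samp[order(match(samp$set_id, sample_ids)), ]
  samp$auditor_verdict <- ""
  data.table::fwrite(samp, paths[["sample_csv"]])
  if (!is.null(summary)) {
    data.table::fwrite(summary$by_type, paths[["summary_csv"]])
  } else {
    data.table::fwrite(data.table::data.table(), paths[["summary_csv"]])
  }
  log_lines <- c(
    paste0("simaudit version: ",
           as.character(utils::packageVersion("simaudit"))),
    vapply(names(run_info), function(k)
      paste0(k, ": ", paste(run_info[[k]], collapse = " ")), character(1)),
    paste0("sets: ", nrow(sets)),
    paste0("sampled sets: ", length(sample_ids))
  )
  writeLines(log_lines, paths[["run_log"]])
  invisible(paths)
}

#' Run the full contextual lexical audit pipeline
#'
#' Reads an RF2 snapshot, restricts to the active members of the chosen
#' hierarchy, builds token bags for eligible concepts, forms similarity
#' sets, classifies them structurally, draws the audit sample and writes the
#' report files.
#'
#' @param concepts_path,descriptions_path,relationships_path Paths to the
#'   three RF2 snapshot files.
#' @param root_id Hierarchy root concept id. Default [SCT_PROCEDURE_ROOT].
#' @param config A [normalization_config()].
#' @param sample_size,max_set_size,seed Audit-sample parameters, see
#'   [sample_sets()].
#' @param language_filter Optional language code passed to
#'   [read_descriptions()].
#' @param out_dir Report directory; if \code{NULL} nothing is written.
#' @return A list with \code{bags}, \code{sets}, \code{profiles},
#'   \code{classifications}, \code{sample_ids}, \code{summary},
#'   \code{hierarchy} (member ids) and \code{report_paths} (or \code{NULL}).
#' @export
run_audit <- function(concepts_path, descriptions_path, relationships_path,
                      root_id = SCT_PROCEDURE_ROOT,
                      config = normalization_config(),
                      sample_size = 50L, max_set_size = 4L, seed = 1L,
                      language_filter = NULL, out_dir = NULL) {
  concepts <- read_concepts(concepts_path)
  descriptions <- read_descriptions(descriptions_path,
                                    language_filter = language_filter)
  relationships <- read_relationships(relationships_path)
  members <- hierarchy_members(root_id, concepts, relationships)
  bags <- token_bags(descriptions, config, concept_filter = members)
  sets <- similarity_sets(bags)
  profiles <- structural_profiles(
    unique(unlist(sets$member_ids, use.names = FALSE)), relationships)
  classifications <- classify_sets(sets, profiles)
  sample_ids <- if (nrow(sets)) {
    sample_sets(classifications, sample_size = sample_size,
                max_set_size = max_set_size, seed = seed)
  } else character(0)
  summary <- summarize_audit(classifications, sets,
                             n_hierarchy_concepts = length(members))
  report_paths <- NULL
  if (!is.null(out_dir)) {
    run_info <- list(
      concepts = concepts_path, descriptions = descriptions_path,
      relationships = relationships_path, root = root_id,
      stop_words = paste(config$stop_words, collapse = ","),
      min_words = config$min_words,
      strip_semantic_tag = config$strip_semantic_tag,
      count_tag_for_threshold = config$count_tag_for_threshold,
      sample_size = sample_size, max_set_size = max_set_size, seed = seed,
      hierarchy_concepts = length(members),
      eligible_bags = nrow(bags),
      similarity_sets = summary$n_sets,
      diff_sets = summary$n_diff,
      same_sets = summary$n_same,
      pct_diff = summary$pct_diff,
      pct_same = summary$pct_same,
      concepts_in_sets = summary$n_concepts_in_sets,
      pct_concepts_covered = summary$pct_concepts_covered,
      synonym_only_sets = summary$n_synonym_only_sets
    )
    report_paths <- write_report(sets, profiles, classifications, sample_ids,
                                 descriptions, out_dir, summary = summary,
                                 run_info = run_info)
  }
  list(bags = bags, sets = sets, profiles = profiles,
       classifications = classifications, sample_ids = sample_ids,
       summary = summary, hierarchy = members, report_paths = report_paths)
}
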