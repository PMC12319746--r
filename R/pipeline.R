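#' Run the full ROI pipeline on a synthetic cohort
#'
#' One reproducible end-to-end run: simulates a cohort under the
#' configured ground-truth profile, computes the per-subject
#' encoding-retrieval and retrieval-retrieval similarity tables, the
#' 2x2x2 repeated-measures ANOVAs, behavioral summaries, and (optionally)
#' the label-permutation group tests for the two headline contrasts.
#' Outputs are written as plain-text CSV plus a run log; identical
#' configurations produce byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param permutation_tests run the permutation group tests (slower).
#' @return list with `similarity` (long data frame: subject, analysis,
#'   cell, mean_z, n_pairs), `anova` (list: `ERS`, `RRS`), `behavior`,
#'   and optionally `permutation` (list of the two headline tests).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         permutation_tests = FALSE) {
  truth <- do.call(region_profile, c(list(name = config$profile), config$gains))
  cohort <- simulate_cohort(config$n_subjects, truth, config$n_voxels,
                            seed = config$seed,
                            n_objects = config$n_objects,
                            n_scenes = config$n_scenes,
                            n_runs = config$n_runs, n_reps = config$n_reps)

  ers <- lapply(cohort, roi_similarity, analysis = "ERS")
  rrs <- lapply(cohort, roi_similarity, analysis = "RRS")

  long <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    rbind(cbind(subject = i, analysis = "ERS", ers[[i]]),
          cbind(subject = i, analysis = "RRS", rrs[[i]]))
  }))
  rownames(long) <- NULL

  anova <- list(ERS = rm_anova_2x2x2(cells_matrix(ers)),
                RRS = rm_anova_2x2x2(cells_matrix(rrs)))
  behavior <- behavior_stats(cohort)

  result <- list(similarity = long, anova = anova, behavior = behavior,
                 config = config)

  if (permutation_tests) {
    result$permutation <- list(
      ers_memory_by_overlap = permutation_group_test(
        lapply(ers, attr, "pairs"), "memory_by_overlap",
        n_perm = config$n_perm, seed = config$seed + 7L),
      rrs_overlap = permutation_group_test(
        lapply(rrs, attr, "pairs"), "overlap",
        n_perm = config$n_perm, seed = config$seed + 11L))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
    stats_df <- rbind(cbind(analysis = "ERS", as.data.frame(anova$ERS)),
                      cbind(analysis = "RRS", as.data.frame(anova$RRS)))
    utils::write.csv(stats_df, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    log <- c(
      sprintf("scenersa run: profile=%s n_subjects=%d n_voxels=%d seed=%d",
              config$profile, config$n_subjects, config$n_voxels, config$seed),
      sprintf("retained pairs per cell (ERS, subject means): %s",
              paste(sprintf("%s=%.1f", condition_cells(),
                            colMeans(t(vapply(ers, function(x) x$n_pairs,
                                              integer(8))))), collapse = " ")),
      sprintf("retained pairs per cell (RRS, subject means): %s",
              paste(sprintf("%s=%.1f", condition_cells(),
                            colMeans(t(vapply(rrs, function(x) x$n_pairs,
                                              integer(8))))), collapse = " ")))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  result
}

#' Read a long similarity CSV back into per-subject cell tables
#'
#' Ingests a similarity table in the package's long CSV layout (columns
#' `subject`, `analysis`, `cell`, `mean_z`, `n_pairs`) — the same layout
#' used for deposited per-subject ROI similarity values — and returns the
#' subjects-by-8 cell matrix for one analysis, ready for
#' [rm_anova_2x2x2()].
#'
#' @param path CSV path.
#' @param analysis `"ERS"` or `"RRS"`.
#' @return subjects-by-8 numeric matrix (canonical cell order).
#' @export
read_similarity_cells <- function(path, analysis = c("ERS", "RRS")) {
  analysis <- match.arg(analysis)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  tb <- tb[tb$analysis == analysis, ]
  subjects <- sort(unique(tb$subject))
  m <- t(vapply(subjects, function(s) {
    rows <- tb[tb$subject == s, ]
    rows$mean_z[match(condition_cells(), rows$cell)]
  }, numeric(8)))
  colnames(m) <- condition_cells()
  m
}
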