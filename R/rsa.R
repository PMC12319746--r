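#' Fisher z transform of a Pearson correlation
#'
#' `z = atanh(r)`. Degenerate correlations (|r| within 1e-7 of 1) are
#' rejected rather than clipped: with noisy data they indicate a bug (e.g.
#' a duplicated or constant pattern), not a signal.
#'
#' @param r correlation value(s), |r| <= 1.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  if (any(abs(r) >= 1 - 1e-7, na.rm = TRUE)) {
    stop("degenerate correlation (|r| ~ 1): identical or constant patterns",
         call. = FALSE)
  }
  atanh(r)
}

# rows standardized to zero mean / unit sum of squares; errors on
# zero-variance rows (constant patterns cannot enter a correlation)
.standardize_rows <- function(m, what = "pattern") {
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- sqrt(rowSums(ctr^2))
  if (any(ss == 0)) {
    stop("zero-variance ", what, " row(s): ",
         paste(utils::head(which(ss == 0), 5), collapse = ", "), call. = FALSE)
  }
  ctr / ss
}

#' Fisher-z correlation matrix between two pattern sets
#'
#' Pearson correlations across voxels between every row of `a` and every
#' row of `b`, Fisher z transformed. Zero-variance rows and degenerate
#' (|r| ~ 1) correlations raise errors (see [fisher_z()]).
#'
#' @param a,b trials-by-voxels matrices with identical voxel counts.
#' @return `nrow(a)` x `nrow(b)` matrix of Fisher z values.
#' @export
pattern_zcor <- function(a, b) {
  fisher_z(.pattern_rcor(a, b))
}

# plain Pearson correlation matrix between row patterns (no transform)
.pattern_rcor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("voxel counts differ", call. = FALSE)
  r <- tcrossprod(.standardize_rows(a), .standardize_rows(b))
  pmin(pmax(r, -1), 1)
}

#' Enumerate encoding-retrieval trial pairs under the inclusion rules
#'
#' Candidate pairs join one encoding and one retrieval trial. A pair is
#' retained iff (i) the two trials do not share the object (same-object
#' pairs would inflate same-scene similarity through perceptual identity),
#' (ii) both trials belong to the same reward-by-memory condition (HR, HF,
#' LR or LF; an encoding trial inherits its object's retrieval outcome),
#' and (iii) both objects were answered correctly on *every* encoding
#' repetition. Scene overlap is `"same"` iff the scenes match; because
#' reward is a function of the scene, same-condition different-scene pairs
#' always join the two scenes of one reward level.
#'
#' @param encoding,retrieval trial tables with behavior filled.
#' @return data frame with columns `trial_a` (encoding row), `trial_b`
#'   (retrieval row), `condition`, `overlap`, `cell` and attribute
#'   `analysis = "ERS"`.
#' @export
enumerate_ers_pairs <- function(encoding, retrieval) {
  ok_obj <- object_fully_correct(encoding)
  rem_of_object <- rep(NA, max(encoding$object_id))
  rem_of_object[retrieval$object_id] <- retrieval$remembered

  rem_enc <- rem_of_object[encoding$object_id]
  enc_cond <- condition_code(encoding$reward, rem_enc)
  ret_cond <- condition_code(retrieval$reward, retrieval$remembered)
  enc_ok <- ok_obj[encoding$object_id] & !is.na(rem_enc)
  ret_ok <- ok_obj[retrieval$object_id]

  keep <- outer(enc_ok, ret_ok, "&") &
    outer(enc_cond, ret_cond, "==") &
    outer(encoding$object_id, retrieval$object_id, "!=")
  idx <- which(keep, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  overlap <- ifelse(encoding$scene_id[i] == retrieval$scene_id[j],
                    "same", "diff")
  out <- data.frame(trial_a = i, trial_b = j,
                    condition = enc_cond[i], overlap = overlap,
                    stringsAsFactors = FALSE)
  out$cell <- cell_label(out$condition, out$overlap)
  attr(out, "analysis") <- "ERS"
  out
}

#' Enumerate retrieval-retrieval trial pairs under the inclusion rules
#'
#' Unordered pairs of retrieval trials, retained iff they come from
#' different runs, belong to the same reward-by-memory condition, and both
#' objects were answered correctly on every encoding repetition.
#'
#' @param retrieval retrieval trial table with behavior filled.
#' @param encoding encoding trial table (supplies per-object correctness).
#' @return data frame as in [enumerate_ers_pairs()] with `trial_a <
#'   trial_b` (both retrieval rows) and attribute `analysis = "RRS"`.
#' @export
enumerate_rrs_pairs <- function(retrieval, encoding) {
  ok_obj <- object_fully_correct(encoding)
  cond <- condition_code(retrieval$reward, retrieval$remembered)
  ok <- ok_obj[retrieval$object_id]

  keep <- outer(ok, ok, "&") &
    outer(cond, cond, "==") &
    outer(retrieval$run, retrieval$run, "!=")
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  overlap <- ifelse(retrieval$scene_id[i] == retrieval$scene_id[j],
                    "same", "diff")
  out <- data.frame(trial_a = i, trial_b = j,
                    condition = cond[i], overlap = overlap,
                    stringsAsFactors = FALSE)
  out$cell <- cell_label(out$condition, out$overlap)
  attr(out, "analysis") <- "RRS"
  out
}

#' Attach Fisher-z similarities to an enumerated pair list
#'
#' @param pairs pair list from [enumerate_ers_pairs()] /
#'   [enumerate_rrs_pairs()].
#' @param patterns_a patterns indexed by `trial_a` (encoding patterns for
#'   ERS, retrieval patterns for RRS).
#' @param patterns_b patterns indexed by `trial_b` (retrieval patterns).
#'   Defaults to `patterns_a` for RRS.
#' @return `pairs` with a `z` column added.
#' @export
pair_similarities <- function(pairs, patterns_a, patterns_b = patterns_a) {
  r <- .pattern_rcor(patterns_a, patterns_b)
  pairs$z <- fisher_z(r[cbind(pairs$trial_a, pairs$trial_b)])
  pairs
}

#' Mean similarity per condition cell
#'
#' Unweighted mean of the pair Fisher-z values in each of the 8 condition
#' cells. Cells with no retained pair are reported with `n_pairs = 0` and
#' `mean_z = NA`.
#'
#' @param pairs pair list with `z` filled (see [pair_similarities()]).
#' @return data frame with one row per cell (canonical order): `cell`,
#'   `mean_z`, `n_pairs`; attribute `analysis` carried over.
#' @export
condition_means <- function(pairs) {
  cells <- condition_cells()
  mz <- rep(NA_real_, 8)
  np <- integer(8)
  if (nrow(pairs)) {
    agg_n <- table(factor(pairs$cell, levels = cells))
    np <- as.integer(agg_n)
    sums <- tapply(pairs$z, factor(pairs$cell, levels = cells), sum)
    mz <- ifelse(np > 0, as.numeric(sums) / np, NA_real_)
  }
  out <- data.frame(cell = cells, mean_z = mz, n_pairs = np,
                    stringsAsFactors = FALSE)
  attr(out, "analysis") <- attr(pairs, "analysis")
  out
}

#' Average cell means across hemispheres
#'
#' For bilateral regions, similarity is computed separately per hemisphere
#' and the *cell means* (not the pooled pairs) are averaged. A cell missing
#' in either hemisphere is missing in the result.
#'
#' @param left,right per-hemisphere cell-mean tables from
#'   [condition_means()].
#' @return combined cell-mean table; `n_pairs` is the summed pair count.
#' @export
combine_hemispheres <- function(left, right) {
  stopifnot(identical(left$cell, right$cell))
  out <- left
  out$mean_z <- (left$mean_z + right$mean_z) / 2
  out$n_pairs <- left$n_pairs + right$n_pairs
  attr(out, "analysis") <- attr(left, "analysis")
  out
}

#' ROI similarity table for one subject
#'
#' Convenience wrapper: enumerates the pairs for the requested analysis,
#' computes the pair similarities from the subject's ROI pattern matrices,
#' and returns the 8 cell means.
#'
#' @param subject list with `encoding`, `retrieval` (tables) and
#'   `patterns` (list with `encoding`, `retrieval` matrices), as produced
#'   by [simulate_cohort()].
#' @param analysis `"ERS"` or `"RRS"`.
#' @return cell-mean table (see [condition_means()]); the pair list with z
#'   values is attached as attribute `"pairs"`.
#' @export
roi_similarity <- function(subject, analysis = c("ERS", "RRS")) {
  analysis <- match.arg(analysis)
  if (analysis == "ERS") {
    pairs <- enumerate_ers_pairs(subject$encoding, subject$retrieval)
    pairs <- pair_similarities(pairs, subject$patterns$encoding,
                               subject$patterns$retrieval)
  } else {
    pairs <- enumerate_rrs_pairs(subject$retrieval, subject$encoding)
    pairs <- pair_similarities(pairs, subject$patterns$retrieval)
  }
  out <- condition_means(pairs)
  attr(out, "pairs") <- pairs
  out
}

#' Single-trial same-minus-different similarity indices
#'
#' For each retrieval trial, the mean Fisher-z similarity to same-scene
#' partners minus the mean similarity to different-scene partners, within
#' the trial's own condition. Applied to encoding-retrieval pairs this is
#' the single-trial scene-reinstatement index; applied to
#' retrieval-retrieval pairs it is the single-trial overlap (convergence)
#' index. Trials lacking a same-scene or a different-scene partner get `NA`
#' and are counted in the `"n_dropped"` attribute.
#'
#' @param pairs pair list with `z` filled. For ERS pairs the retrieval
#'   trial is `trial_b`; for RRS pairs each pair contributes to both of its
#'   trials.
#' @param n_retrieval number of retrieval trials (index range).
#' @return numeric vector of length `n_retrieval` with attribute
#'   `"n_dropped"`.
#' @export
single_trial_index <- function(pairs, n_retrieval) {
  analysis <- attr(pairs, "analysis")
  if (identical(analysis, "RRS")) {
    trial <- c(pairs$trial_a, pairs$trial_b)
    z <- c(pairs$z, pairs$z)
    overlap <- c(pairs$overlap, pairs$overlap)
  } else {
    trial <- pairs$trial_b
    z <- pairs$z
    overlap <- pairs$overlap
  }
  out <- rep(NA_real_, n_retrieval)
  same <- tapply(z[overlap == "same"], factor(trial[overlap == "same"],
                                              levels = seq_len(n_retrieval)), mean)
  diff <- tapply(z[overlap == "diff"], factor(trial[overlap == "diff"],
                                              levels = seq_len(n_retrieval)), mean)
  out <- as.numeric(same) - as.numeric(diff)
  attr(out, "n_dropped") <- sum(is.na(out))
  out
}
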