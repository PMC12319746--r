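#' One-sample and paired t tests (closed form)
#'
#' Thin closed-form implementations used throughout the group-level stage,
#' returning the statistic, degrees of freedom and p value. `paired_t(a,b)`
#' is `one_sample_t(a - b)`. With zero variance (all values identical) the
#' statistic is undefined and reported as `NA` with a `"note"` attribute,
#' except in the degenerate-but-consistent case mean 0, where t = 0.
#'
#' @param x,a,b numeric vectors (paired: equal length).
#' @param mu null value for the mean.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(x, mu = 0, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    if (m == mu) {
      out <- list(t = 0, df = n - 1, p = 1, mean = m)
    } else {
      out <- list(t = NA_real_, df = n - 1, p = NA_real_, mean = m)
      attr(out, "note") <- "zero variance with nonzero mean difference: t undefined"
    }
    return(out)
  }
  tval <- (m - mu) / (s / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tval), n - 1),
    greater = stats::pt(tval, n - 1, lower.tail = FALSE),
    less = stats::pt(tval, n - 1))
  list(t = tval, df = n - 1, p = p, mean = m)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  one_sample_t(a - b, mu = 0, alternative = match.arg(alternative))
}

#' 2x2x2 repeated-measures ANOVA on the 8 condition-cell means
#'
#' Within-subject ANOVA with factors reward, memory and scene overlap,
#' implemented by per-subject contrast scores: for every effect, each
#' subject's score is the [effect_contrast()] weighting of their 8 cell
#' means, and the effect's F(1, n-1) equals the squared one-sample t of the
#' scores against zero. For two-level within-subject designs this is exact
#' and identical to the classical sums-of-squares decomposition (verified
#' against an independent implementation in the test suite). Subjects with
#' any missing cell are dropped with a message.
#'
#' @param cells numeric subjects-by-8 matrix of cell means, columns in
#'   canonical order ([condition_cells()]), or a data frame coercible to
#'   one.
#' @return object of class `rm_anova_cells`: data frame of the seven
#'   effects (`effect`, `F`, `df1`, `df2`, `p`) with the per-subject
#'   contrast scores in attribute `"scores"` and `n` in attribute `"n"`.
#' @export
rm_anova_2x2x2 <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 8) stop("expected 8 condition-cell columns", call. = FALSE)
  drop <- apply(cells, 1, anyNA)
  if (any(drop)) {
    message(sum(drop), " subject(s) with missing cells excluded from ANOVA")
    cells <- cells[!drop, , drop = FALSE]
  }
  n <- nrow(cells)
  if (n < 3) stop("need at least 3 complete subjects", call. = FALSE)
  effects <- c("reward", "memory", "overlap", "reward_by_memory",
               "reward_by_overlap", "memory_by_overlap",
               "reward_by_memory_by_overlap")
  scores <- sapply(effects, function(e) {
    w <- effect_contrast(e) / 4  # mean-difference scaling
    as.numeric(cells %*% w)
  })
  # cancellation guard: contrast scores at rounding-error scale relative to
  # the cell values are numerical zeros, not effects
  tol <- 64 * .Machine$double.eps * max(abs(cells), 1e-300)
  scores[abs(scores) < tol] <- 0
  res <- lapply(effects, function(e) {
    tt <- one_sample_t(scores[, e])
    data.frame(effect = e, F = tt$t^2, df1 = 1, df2 = tt$df,
               p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  attr(out, "n") <- n
  class(out) <- c("rm_anova_cells", "data.frame")
  out
}

#' @export
print.rm_anova_cells <- function(x, ...) {
  cat("Repeated-measures 2x2x2 ANOVA (reward x memory x overlap), n =",
      attr(x, "n"), "\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-subject effect scores from a stack of cell-mean tables
#'
#' @param cell_tables list of per-subject cell-mean tables
#'   (see [condition_means()]) or a subjects-by-8 matrix.
#' @param effect effect name (see [effect_contrast()]) or a length-8
#'   weight vector.
#' @return numeric vector of per-subject scores (contrast weighted cell
#'   means, scaled to a mean difference by dividing the weights by 4).
#' @export
effect_scores <- function(cell_tables, effect) {
  w <- if (is.character(effect)) effect_contrast(effect) else effect
  if (length(w) != 8 || abs(sum(w)) > 1e-12) {
    stop("effect weights must be 8 values summing to zero", call. = FALSE)
  }
  m <- cells_matrix(cell_tables)
  as.numeric(m %*% (w / 4))
}

#' Stack per-subject cell-mean tables into a subjects-by-8 matrix
#'
#' @param cell_tables list of per-subject cell-mean tables from
#'   [condition_means()] / [roi_similarity()] (a matrix passes through).
#' @return subjects-by-8 numeric matrix in canonical cell order, ready for
#'   [rm_anova_2x2x2()].
#' @export
cells_matrix <- function(cell_tables) {
  if (is.matrix(cell_tables)) return(cell_tables)
  t(vapply(cell_tables, function(tb) {
    stopifnot(identical(tb$cell, condition_cells()))
    tb$mean_z
  }, numeric(8)))
}

#' Is a retrieval-retrieval effect larger than its encoding-retrieval twin?
#'
#' Computes each subject's effect score in both analyses and tests the
#' difference with a paired t test. A convergence effect genuinely larger
#' than the corresponding reinstatement effect argues that retrieval
#' convergence is not a byproduct of reinstatement.
#'
#' @param rrs_tables,ers_tables lists of per-subject cell-mean tables (or
#'   subjects-by-8 matrices) for the retrieval-retrieval and
#'   encoding-retrieval analyses.
#' @inheritParams effect_scores
#' @return list with the paired test (`t`, `df`, `p`) plus the two score
#'   vectors.
#' @export
rrs_vs_ers_contrast <- function(rrs_tables, ers_tables, effect) {
  a <- effect_scores(rrs_tables, effect)
  b <- effect_scores(ers_tables, effect)
  out <- paired_t(a, b)
  out$rrs_scores <- a
  out$ers_scores <- b
  out
}

#' Across-subject correlation of two effect-score vectors
#'
#' @param effect_a,effect_b per-subject effect scores.
#' @return list with `r`, `t`, `df`, `p` (two-sided).
#' @export
across_subject_corr <- function(effect_a, effect_b) {
  ok <- !is.na(effect_a) & !is.na(effect_b)
  a <- effect_a[ok]; b <- effect_b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  r <- stats::cor(a, b)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tval, df = n - 2, p = 2 * stats::pt(-abs(tval), n - 2))
}

#' Within-subject slope regression of convergence on reinstatement
#'
#' Per subject, the OLS slope of the single-trial overlap (convergence)
#' index on the single-trial reinstatement index across retrieval trials;
#' the slopes are then tested against zero with a group-level one-sample t
#' test. Trials with a missing index are dropped; subjects with fewer than
#' `min_trials` usable trials are dropped with a message.
#'
#' @param x_list,y_list per-subject numeric vectors: single-trial
#'   reinstatement indices (`x`) and overlap indices (`y`), equal lengths
#'   within subject (see [single_trial_index()]).
#' @param min_trials minimum usable trials per subject.
#' @return list with `slopes` (per subject; `NA` where dropped) and the
#'   group test `t`, `df`, `p`, `mean`.
#' @export
slope_regression <- function(x_list, y_list, min_trials = 3) {
  stopifnot(length(x_list) == length(y_list))
  slopes <- mapply(function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_trials || stats::var(x) == 0) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }, x_list, y_list)
  if (anyNA(slopes)) {
    message(sum(is.na(slopes)), " subject(s) without usable slope dropped")
  }
  gt <- one_sample_t(slopes[!is.na(slopes)])
  list(slopes = slopes, t = gt$t, df = gt$df, p = gt$p, mean = gt$mean)
}

#' Within-subject label-permutation z score of a cell contrast
#'
#' The true effect is the contrast weighting of the 8 cell means of the
#' included pair similarities. A null distribution is built by permuting
#' the cell labels across *all* included pairs as a whole, so every
#' permutation preserves the observed per-cell pair counts; the effect is
#' recomputed on each permuted labelling. The subject's z score is
#' `(true - mean(null)) / sd(null)`.
#'
#' @param z pair Fisher-z values for one subject.
#' @param cells cell label per pair (values among [condition_cells()]).
#' @param effect effect name or length-8 weight vector.
#' @param n_perm number of label permutations (>= 100; study-scale ROI
#'   default 10000).
#' @param seed integer seed.
#' @return object of class `permutation_result`: list with `true_effect`,
#'   `null_mean`, `null_sd`, `z`, `n_perm`, `seed`.
#' @export
permutation_z <- function(z, cells, effect, n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  w <- if (is.character(effect)) effect_contrast(effect) else effect
  f <- factor(cells, levels = condition_cells())
  counts <- as.integer(table(f))
  touched <- counts > 0 & w != 0
  if (sum(touched) < 2) {
    stop("need at least 2 nonempty cells touched by the contrast", call. = FALSE)
  }
  if (any(counts == 0 & w != 0)) {
    stop("contrast touches empty cell(s): ",
         paste(condition_cells()[counts == 0 & w != 0], collapse = ", "),
         call. = FALSE)
  }
  wl <- (w / 4)[as.integer(f)] / counts[as.integer(f)]  # per-pair weight
  true_effect <- sum(wl * z)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) sum(wl * z[sample.int(length(z))]),
                 numeric(1))
  ns <- stats::sd(null)
  if (ns == 0) {
    stop("degenerate null distribution (sd = 0): pair values carry no variability",
         call. = FALSE)
  }
  structure(list(true_effect = true_effect, null_mean = mean(null),
                 null_sd = ns, z = (true_effect - mean(null)) / ns,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Label-permutation test (%d permutations): true effect %.4g, null %.4g +/- %.4g, z = %.3f\n",
              x$n_perm, x$true_effect, x$null_mean, x$null_sd, x$z))
  invisible(x)
}

#' Group-level permutation test across subjects
#'
#' Computes [permutation_z()] for every subject and tests the z scores
#' against zero with a one-sided (greater) one-sample t test, the
#' imbalance-robust companion to the ANOVA effect.
#'
#' @param pair_lists list of per-subject pair lists with `z` filled.
#' @inheritParams permutation_z
#' @return list with `z` (per-subject z scores), `t`, `df`, `p`
#'   (one-sided).
#' @export
permutation_group_test <- function(pair_lists, effect, n_perm = 10000, seed = 1) {
  zs <- vapply(seq_along(pair_lists), function(i) {
    p <- pair_lists[[i]]
    permutation_z(p$z, p$cell, effect, n_perm = n_perm,
                  seed = seed + i)$z
  }, numeric(1))
  gt <- one_sample_t(zs, alternative = "greater")
  list(z = zs, t = gt$t, df = gt$df, p = gt$p)
}

#' Behavioral summary statistics for a cohort
#'
#' Per subject: encoding accuracy and median correct-response RT by reward,
#' and scene-recall accuracy by reward restricted to objects answered
#' correctly on both encoding repetitions. Each measure is compared across
#' reward levels with a paired t test.
#'
#' @param cohort list of subjects (elements with `encoding` and
#'   `retrieval` tables).
#' @return list with `per_subject` (data frame) and `tests` (list of
#'   paired t results for `encoding_accuracy`, `encoding_rt`,
#'   `recall_accuracy`).
#' @export
behavior_stats <- function(cohort) {
  per <- lapply(cohort, function(s) {
    enc <- s$encoding; ret <- s$retrieval
    ok <- object_fully_correct(enc)
    acc <- tapply(enc$encoding_correct, enc$reward, mean)
    rt <- tapply(ifelse(enc$encoding_correct, enc$rt, NA_real_), enc$reward,
                 stats::median, na.rm = TRUE)
    keep <- ok[ret$object_id]
    rec <- tapply(ret$remembered[keep], ret$reward[keep], mean)
    data.frame(enc_acc_high = acc[["high"]], enc_acc_low = acc[["low"]],
               enc_rt_high = rt[["high"]], enc_rt_low = rt[["low"]],
               recall_high = rec[["high"]], recall_low = rec[["low"]])
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_subject = per,
       tests = list(
         encoding_accuracy = paired_t(per$enc_acc_high, per$enc_acc_low),
         encoding_rt = paired_t(per$enc_rt_high, per$enc_rt_low),
         recall_accuracy = paired_t(per$recall_high, per$recall_low)))
}
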