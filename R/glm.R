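#' Canonical double-gamma hemodynamic response kernel
#'
#' The widely used canonical HRF: a gamma density peaking near 5 s minus a
#' later gamma undershoot (delay 6 / 16 s, dispersion 1 / 1, peak-to-
#' undershoot ratio 6), sampled on a regular grid.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel support in seconds.
#' @return numeric vector: the kernel sampled at `seq(0, duration, by = dt)`.
#' @export
hrf_kernel <- function(dt, duration = 32) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  t <- seq(0, duration, by = dt)
  stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
}

# HRF-convolved boxcar regressor for a set of onsets within one run,
# sampled at scan times 0, tr, 2*tr, ... (length n_scans); built on a fine
# grid (dt seconds) then read out at scan times
convolved_regressor <- function(onsets, durations, n_scans, tr, dt = 0.1) {
  run_len <- n_scans * tr
  n_fine <- ceiling(run_len / dt) + 1L
  stick <- numeric(n_fine)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- min(n_fine, floor((onsets[k] + max(durations[k], dt)) / dt))
    if (i0 <= n_fine) stick[i0:max(i0, i1)] <- stick[i0:max(i0, i1)] + 1
  }
  h <- hrf_kernel(dt)
  conv <- stats::convolve(stick, rev(h), type = "open")[seq_len(n_fine)] * dt
  conv[pmin(n_fine, round((seq_len(n_scans) - 1L) * tr / dt) + 1L)]
}

#' Simulate 4D BOLD data from trial-wise pattern amplitudes
#'
#' Produces a concatenated-run BOLD matrix whose expected per-trial response
#' amplitudes equal the supplied pattern values: each trial contributes its
#' HRF-convolved boxcar regressor scaled, voxel by voxel, by the trial's row
#' of `amplitudes`, plus optional linear drift and white noise. A confound
#' table (six smooth motion-like series plus framewise displacement) is
#' generated alongside; the confounds do not enter the signal.
#'
#' @param events one-phase trial table (columns `run`, `onset`, `duration`).
#' @param amplitudes trials-by-voxels matrix, rows aligned to `events`
#'   (e.g. a matrix from [simulate_patterns()]).
#' @param tr repetition time in seconds (scan protocol default 2).
#' @param noise_sd white-noise standard deviation.
#' @param drift per-run linear drift amplitude.
#' @param pad seconds of rest appended after the last trial of each run.
#' @param seed integer seed.
#' @return list with `bold` (scans-by-voxels matrix, runs concatenated),
#'   `run_lengths` (scans per run), `tr`, and `confounds`
#'   (scans-by-7 data frame).
#' @export
simulate_bold <- function(events, amplitudes, tr = 2, noise_sd = 0,
                          drift = 0, pad = 20, seed = 1) {
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != nrow(events)) {
    stop("amplitudes must have one row per event", call. = FALSE)
  }
  if (any(duplicated(events[, c("run", "onset")]))) {
    stop("overlapping identical onsets within a run are not identifiable", call. = FALSE)
  }
  set.seed(seed)
  runs <- sort(unique(events$run))
  n_vox <- ncol(amplitudes)
  bold_runs <- vector("list", length(runs))
  run_lengths <- integer(length(runs))
  for (ri in seq_along(runs)) {
    idx <- which(events$run == runs[ri])
    n_scans <- ceiling((max(events$onset[idx] + events$duration[idx]) + pad) / tr)
    run_lengths[ri] <- n_scans
    y <- matrix(0, n_scans, n_vox)
    for (k in idx) {
      reg <- convolved_regressor(events$onset[k], events$duration[k], n_scans, tr)
      y <- y + outer(reg, amplitudes[k, ])
    }
    if (drift != 0) {
      y <- y + drift * seq(-1, 1, length.out = n_scans)
    }
    bold_runs[[ri]] <- y
  }
  bold <- do.call(rbind, bold_runs)
  if (noise_sd > 0) {
    bold <- bold + matrix(stats::rnorm(length(bold), sd = noise_sd), nrow(bold))
  }
  n_total <- sum(run_lengths)
  motion <- vapply(1:6, function(j) {
    cumsum(stats::rnorm(n_total, sd = 0.02))
  }, numeric(n_total))
  fd <- c(0, rowSums(abs(diff(motion))))
  confounds <- as.data.frame(motion)
  names(confounds) <- c(paste0("trans_", c("x", "y", "z")),
                        paste0("rot_", c("x", "y", "z")))
  confounds$framewise_displacement <- fd
  list(bold = bold, run_lengths = run_lengths, tr = tr, confounds = confounds)
}

#' Build the design matrix for one trial's GLM
#'
#' One GLM per trial: a dedicated HRF-convolved regressor for the trial of
#' interest; HRF-convolved "all other onsets" regressors, one per condition
#' (HR/HF/LR/LF from the `condition` column if present, otherwise a single
#' group); an HRF-convolved button-press regressor (from `button_onset` if
#' present); the supplied non-convolved confound columns; and one constant
#' per concatenated run. Condition groups left empty after removing the
#' trial of interest are omitted (with a notice) rather than entered as
#' all-zero columns.
#'
#' @param trial_index row index of the trial of interest in `events`.
#' @param events one-phase trial table (columns `run`, `onset`, `duration`;
#'   optional `condition`, `button_onset`).
#' @param confounds scans-by-k matrix/data frame of non-convolved nuisance
#'   series (may be `NULL`).
#' @param run_lengths scans per run, in run order.
#' @param tr repetition time (s).
#' @param trial_duration overrides the events' `duration` for the
#'   convolution boxcar if non-`NULL`.
#' @return numeric design matrix (scans x regressors) with named columns;
#'   the trial-of-interest column is named `"trial"`.
#' @export
build_design <- function(trial_index, events, confounds, run_lengths, tr,
                         trial_duration = NULL) {
  if (trial_index < 1 || trial_index > nrow(events)) {
    stop("trial_index out of range", call. = FALSE)
  }
  runs <- sort(unique(events$run))
  if (length(runs) != length(run_lengths)) {
    stop("run_lengths must have one entry per run present in events", call. = FALSE)
  }
  n_total <- sum(run_lengths)
  offsets <- c(0, cumsum(run_lengths))[seq_along(runs)]
  names(offsets) <- as.character(runs)

  dur <- if (is.null(trial_duration)) events$duration else
    rep(trial_duration, nrow(events))

  conv_column <- function(rows) {
    col <- numeric(n_total)
    for (ri in seq_along(runs)) {
      sel <- rows[events$run[rows] == runs[ri]]
      if (!length(sel)) next
      reg <- convolved_regressor(events$onset[sel], dur[sel],
                                 run_lengths[ri], tr)
      span <- offsets[ri] + seq_len(run_lengths[ri])
      col[span] <- col[span] + reg
    }
    col
  }

  cols <- list(trial = conv_column(trial_index))

  others <- setdiff(seq_len(nrow(events)), trial_index)
  if (!is.null(events$condition)) {
    for (cc in unique(events$condition)) {
      rows <- others[events$condition[others] == cc]
      if (!length(rows)) {
        message("condition group '", cc,
                "' empty after removing the trial of interest; column omitted")
        next
      }
      cols[[paste0("others_", cc)]] <- conv_column(rows)
    }
  } else if (length(others)) {
    cols[["others"]] <- conv_column(others)
  }

  if (!is.null(events$button_onset) && any(!is.na(events$button_onset))) {
    rows <- which(!is.na(events$button_onset))
    col <- numeric(n_total)
    for (ri in seq_along(runs)) {
      sel <- rows[events$run[rows] == runs[ri]]
      if (!length(sel)) next
      reg <- convolved_regressor(events$button_onset[sel],
                                 rep(0, length(sel)), run_lengths[ri], tr)
      span <- offsets[ri] + seq_len(run_lengths[ri])
      col[span] <- reg
    }
    cols[["buttons"]] <- col
  }

  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_total) {
      stop("confounds must have one row per scan (", n_total, ")", call. = FALSE)
    }
    for (j in seq_len(ncol(confounds))) {
      nm <- colnames(confounds)[j]
      cols[[if (is.null(nm) || nm == "") paste0("confound_", j) else nm]] <-
        confounds[, j]
    }
  }

  for (ri in seq_along(runs)) {
    const <- numeric(n_total)
    const[offsets[ri] + seq_len(run_lengths[ri])] <- 1
    cols[[paste0("run_", runs[ri])]] <- const
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit one trial's GLM and return its beta and t values
#'
#' Ordinary least squares over all voxels simultaneously; the t statistic
#' for the trial-of-interest column uses the residual variance with
#' `df = scans - rank(X)` degrees of freedom.
#'
#' @param ts scans-by-voxels data matrix (or vector for one voxel).
#' @param X design matrix from [build_design()] (full column rank).
#' @param column name of the column of interest (default `"trial"`).
#' @return list with `beta` and `t` (numeric vectors over voxels) and `df`.
#' @export
fit_trial <- function(ts, X, column = "trial") {
  ts <- as.matrix(ts)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta_all <- qr.coef(qx, ts)
  res <- ts - X %*% beta_all
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  j <- match(column, colnames(X))
  if (is.na(j)) stop("no column named '", column, "' in design", call. = FALSE)
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- beta_all[j, ]
  t <- ifelse(se > 0, beta / se, NA_real_)
  list(beta = unname(beta), t = unname(t), df = df)
}

#' Estimate a beta series: one statistical map per trial
#'
#' Loops [build_design()] + [fit_trial()] over every trial of the events
#' table, yielding trials-by-voxels matrices of betas and t values.
#'
#' @inheritParams build_design
#' @param bold scans-by-voxels data matrix (runs concatenated).
#' @return list with matrices `beta` and `t` (trials x voxels) and `df`.
#' @export
beta_series <- function(bold, events, confounds, run_lengths, tr,
                        trial_duration = NULL) {
  n_trials <- nrow(events)
  n_vox <- ncol(as.matrix(bold))
  beta <- matrix(NA_real_, n_trials, n_vox)
  tval <- matrix(NA_real_, n_trials, n_vox)
  df <- NA_integer_
  for (i in seq_len(n_trials)) {
    X <- build_design(i, events, confounds, run_lengths, tr, trial_duration)
    fit <- fit_trial(bold, X)
    beta[i, ] <- fit$beta
    tval[i, ] <- fit$t
    df <- fit$df
  }
  list(beta = beta, t = tval, df = df)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths with a separable Gaussian kernel of the given full width at half
#' maximum; per axis, `sigma = fwhm / (2 * sqrt(2 * log(2)))` converted to
#' voxel units. Edges use zero padding (the kernel is normalized to unit
#' sum, so the total image sum is conserved for features away from the
#' border). `fwhm_mm = 0` returns the input unchanged.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm kernel FWHM in millimetres (>= 0).
#' @param voxel_size_mm voxel edge length in millimetres (scalar or
#'   length-3).
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm = 2) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(volume)
  d <- dim(volume)
  if (length(d) != 3) stop("volume must be a 3D array", call. = FALSE)
  vs <- rep(voxel_size_mm, length.out = 3)
  out <- volume
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[ax]
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    out <- .conv_axis(out, k, ax)
  }
  out
}

# zero-padded 1D convolution of a 3D array along axis `ax`
.conv_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, dp[1], dp[2] * dp[3])
  n <- dp[1]
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    shift <- j - r - 1L
    src <- seq_len(n) + shift
    ok <- src >= 1 & src <= n
    res[ok, ] <- res[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  out <- array(res, dp)
  aperm(out, order(perm))
}
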