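#' Simulate trial-wise voxel patterns with planted similarity structure
#'
#' Generates one trials-by-voxels pattern matrix per phase according to the
#' generative model described in [synthetic_truth()]. Scene retrieval
#' prototypes `Q_s` are drawn independently of the encoding prototypes
#' `P_s` and then orthogonalized against the span of all `P_s` (and
#' re-normalized), so planted retrieval-retrieval convergence cannot be a
#' byproduct of planted reinstatement.
#'
#' @param encoding,retrieval trial tables with behavior filled
#'   (see [simulate_behavior()]).
#' @param truth a [synthetic_truth()] object.
#' @param n_voxels number of voxels (>= 10).
#' @param seed integer seed.
#' @return list with elements `encoding` and `retrieval` (numeric matrices,
#'   one row per trial in table order) and `prototypes` (list with `P`, `Q`
#'   as `n_scenes x n_voxels` matrices and `objects` as
#'   `n_objects x n_voxels`), for recovery tests.
#' @export
simulate_patterns <- function(encoding, retrieval, truth = synthetic_truth(),
                              n_voxels = 150, seed = 1) {
  if (n_voxels < 10) stop("n_voxels must be >= 10", call. = FALSE)
  if (anyNA(retrieval$remembered)) {
    stop("behavior not simulated: 'remembered' contains NA", call. = FALSE)
  }
  set.seed(seed)
  n_scenes <- max(encoding$scene_id)
  n_objects <- max(encoding$object_id)
  if (n_voxels < 2 * n_scenes) {
    stop("n_voxels must be at least twice n_scenes for prototype orthogonalization",
         call. = FALSE)
  }

  unit_rows <- function(m) m / sqrt(rowSums(m^2))
  P <- unit_rows(matrix(stats::rnorm(n_scenes * n_voxels), n_scenes))
  Q <- matrix(stats::rnorm(n_scenes * n_voxels), n_scenes)
  # orthogonalize each Q_s against span(P_1..P_S), then re-normalize
  Pq <- qr.Q(qr(t(P)))
  Q <- Q - (Q %*% Pq) %*% t(Pq)
  Q <- unit_rows(Q)
  O <- unit_rows(matrix(stats::rnorm(n_objects * n_voxels), n_objects))

  enc <- truth$encoding_scene_gain * P[encoding$scene_id, , drop = FALSE] +
    truth$object_gain * O[encoding$object_id, , drop = FALSE]
  if (truth$noise_sd > 0) {
    enc <- enc + matrix(stats::rnorm(length(enc), sd = truth$noise_sd), nrow(enc))
  }

  g_reinst <- ifelse(retrieval$remembered,
                     truth$reinstatement_gain_remembered,
                     truth$reinstatement_gain_forgotten)
  g_conv <- ifelse(retrieval$reward == "high",
                   truth$convergence_gain_high, truth$convergence_gain_low)
  ret <- g_reinst * P[retrieval$scene_id, , drop = FALSE] +
    g_conv * Q[retrieval$scene_id, , drop = FALSE] +
    truth$object_gain * O[retrieval$object_id, , drop = FALSE]
  if (truth$noise_sd > 0) {
    ret <- ret + matrix(stats::rnorm(length(ret), sd = truth$noise_sd), nrow(ret))
  }

  list(encoding = enc, retrieval = ret,
       prototypes = list(P = P, Q = Q, objects = O))
}

#' Simulate a cohort of synthetic subjects
#'
#' Convenience wrapper generating `n_subjects` independent subjects (design,
#' behavior, patterns) under one ground-truth profile. Per-subject seeds are
#' derived deterministically from `seed`.
#'
#' @param n_subjects number of subjects (study default 40).
#' @param truth a [synthetic_truth()] object, e.g. from [region_profile()].
#' @param n_voxels voxels per subject.
#' @param seed integer master seed.
#' @param n_objects,n_scenes,n_runs,n_reps design parameters, see
#'   [make_design()].
#' @return list of subjects; each subject is a list with `encoding`,
#'   `retrieval` (trial tables), `patterns` (from [simulate_patterns()]).
#' @export
simulate_cohort <- function(n_subjects = 40, truth = synthetic_truth(),
                            n_voxels = 150, seed = 1,
                            n_objects = 160, n_scenes = 4, n_runs = 4,
                            n_reps = 2) {
  lapply(seq_len(n_subjects), function(i) {
    s <- (seed * 1000L + i) %% .Machine$integer.max
    d <- make_design(n_objects, n_scenes, n_runs, n_reps, seed = s)
    b <- simulate_behavior(d$encoding, d$retrieval, truth, seed = s + 1L)
    p <- simulate_patterns(b$encoding, b$retrieval, truth, n_voxels, seed = s + 2L)
    list(encoding = b$encoding, retrieval = b$retrieval, patterns = p)
  })
}
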