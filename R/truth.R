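#' Ground-truth parameters for the synthetic generator
#'
#' Collects every parameter of the generative model for synthetic subjects.
#' Voxel patterns are built from unit-norm prototype vectors: four scene
#' encoding prototypes `P_s`, four independent (and orthogonalized) scene
#' retrieval prototypes `Q_s`, and one unit vector per object. An encoding
#' trial's pattern is
#' `encoding_scene_gain * P_s + object_gain * O_o + noise`, and a retrieval
#' trial's pattern is
#' `g_reinst * P_s + g_conv * Q_s + object_gain * O_o + noise`, where
#' `g_reinst` is `reinstatement_gain_remembered` or `_forgotten` by the
#' trial's memory outcome and `g_conv` is `convergence_gain_high` or `_low`
#' by its reward. Because `Q_s` is orthogonal to the span of the `P_s`,
#' retrieval-retrieval convergence is planted independently of
#' encoding-pattern reinstatement.
#'
#' Since prototypes are unit-norm, a gain `g` contributes variance `g^2/V`
#' per voxel for `V` voxels; with the default `noise_sd = 1` the expected
#' pair correlation induced by two components with gains `g1`, `g2` on a
#' shared prototype is approximately `g1 * g2 / (V * s1 * s2)` with `s`
#' the per-voxel pattern standard deviations.
#'
#' @param encoding_scene_gain weight of the scene encoding prototype in
#'   encoding patterns.
#' @param object_gain weight of the object component (both phases).
#' @param reinstatement_gain_remembered,reinstatement_gain_forgotten weight
#'   of the scene *encoding* prototype in retrieval patterns, by memory
#'   outcome (reinstatement).
#' @param convergence_gain_high,convergence_gain_low weight of the scene
#'   *retrieval* prototype in retrieval patterns, by reward (convergence
#'   onto a transformed shared representation).
#' @param noise_sd i.i.d. Gaussian voxel noise standard deviation.
#' @param p_encoding_correct probability each encoding repetition is
#'   answered correctly.
#' @param p_remember_high,p_remember_low probability an object's scene is
#'   recalled, by reward.
#' @param p_dont_know probability a non-remembered response is "dont_know"
#'   rather than a wrong scene.
#' @return object of class `synthetic_truth` (a named list).
#' @seealso [region_profile()] for presets mirroring characteristic
#'   regional result patterns.
#' @export
synthetic_truth <- function(encoding_scene_gain = 10,
                            object_gain = 8,
                            reinstatement_gain_remembered = 0,
                            reinstatement_gain_forgotten = 0,
                            convergence_gain_high = 0,
                            convergence_gain_low = 0,
                            noise_sd = 1,
                            p_encoding_correct = 0.97,
                            p_remember_high = 0.537,
                            p_remember_low = 0.513,
                            p_dont_know = 0.5) {
  gains <- c(encoding_scene_gain, object_gain,
             reinstatement_gain_remembered, reinstatement_gain_forgotten,
             convergence_gain_high, convergence_gain_low, noise_sd)
  if (any(gains < 0)) stop("all gains and noise_sd must be nonnegative", call. = FALSE)
  probs <- c(p_encoding_correct, p_remember_high, p_remember_low, p_dont_know)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(
    encoding_scene_gain = encoding_scene_gain,
    object_gain = object_gain,
    reinstatement_gain_remembered = reinstatement_gain_remembered,
    reinstatement_gain_forgotten = reinstatement_gain_forgotten,
    convergence_gain_high = convergence_gain_high,
    convergence_gain_low = convergence_gain_low,
    noise_sd = noise_sd,
    p_encoding_correct = p_encoding_correct,
    p_remember_high = p_remember_high,
    p_remember_low = p_remember_low,
    p_dont_know = p_dont_know), class = "synthetic_truth")
}

#' Regional ground-truth presets
#'
#' Four presets encode the characteristic regional result patterns the
#' pipeline is designed to detect, as planted ground truth:
#' \describe{
#'   \item{`phc_like`}{memory-gated scene reinstatement: the scene encoding
#'     prototype reappears in retrieval patterns of remembered trials only
#'     (`reinstatement_gain_remembered = 0.15`, all convergence gains 0).
#'     Detected as a memory-by-overlap interaction in encoding-retrieval
#'     similarity.}
#'   \item{`mpfc_like`}{reward-independent convergence: retrieval patterns
#'     of same-scene trials share a transformed scene prototype regardless
#'     of reward (`convergence_gain_high = convergence_gain_low = 1`).
#'     Detected as an overlap main effect in retrieval-retrieval
#'     similarity.}
#'   \item{`ahc_like`}{reward-gated convergence
#'     (`convergence_gain_high = 1`, `convergence_gain_low = 0`). Detected
#'     as a reward-by-overlap interaction in retrieval-retrieval similarity
#'     with the simple overlap effect present under high reward only.}
#'   \item{`null`}{no structure at all (every gain 0): patterns are pure
#'     i.i.d. noise, the exchangeable null for calibration.}
#' }
#'
#' The reinstatement gain is deliberately an order of magnitude smaller
#' than the convergence gains: encoding-retrieval similarity scales with
#' `encoding_scene_gain * g_reinst` (first order) while the
#' retrieval-retrieval similarity this reinstatement induces as a byproduct
#' scales with `g_reinst^2` (second order), so a small `g_reinst` yields a
#' well-powered reinstatement effect whose leakage into
#' retrieval-retrieval similarity stays near the false-positive level.
#'
#' @param name `"phc_like"`, `"mpfc_like"`, `"ahc_like"` or `"null"`.
#' @param ... overrides passed on to [synthetic_truth()].
#' @return a `synthetic_truth` object.
#' @export
region_profile <- function(name = c("phc_like", "mpfc_like", "ahc_like", "null"),
                           ...) {
  name <- match.arg(name)
  preset <- switch(name,
    phc_like = list(reinstatement_gain_remembered = 0.15),
    mpfc_like = list(convergence_gain_high = 1, convergence_gain_low = 1),
    ahc_like = list(convergence_gain_high = 1, convergence_gain_low = 0),
    null = list(encoding_scene_gain = 0, object_gain = 0))
  args <- utils::modifyList(preset, list(...))
  truth <- do.call(synthetic_truth, args)
  attr(truth, "profile") <- name
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  prof <- attr(x, "profile")
  cat("Synthetic ground truth", if (!is.null(prof)) paste0("(profile: ", prof, ")"), "\n")
  cat(sprintf("  gains: enc-scene %.3g, object %.3g, reinstatement R/F %.3g/%.3g, convergence H/L %.3g/%.3g\n",
              x$encoding_scene_gain, x$object_gain,
              x$reinstatement_gain_remembered, x$reinstatement_gain_forgotten,
              x$convergence_gain_high, x$convergence_gain_low))
  cat(sprintf("  noise sd %.3g; P(enc correct) %.3g; P(recall) high %.3g / low %.3g; P(dont_know) %.3g\n",
              x$noise_sd, x$p_encoding_correct, x$p_remember_high,
              x$p_remember_low, x$p_dont_know))
  invisible(x)
}
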