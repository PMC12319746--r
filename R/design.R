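#' Generate a balanced object-scene encoding/retrieval design
#'
#' Builds the trial tables for one subject of the object-scene reward task:
#' an incidental encoding phase in which each of `n_objects` objects is
#' paired with one of `n_scenes` recurring scenes and presented `n_reps`
#' times within one of `n_runs` runs, and a next-day retrieval phase in
#' which each object is shown once and the paired scene must be recalled.
#' Half of the scenes carry high reward, half low reward; reward is a pure
#' function of the scene. The trial order is pseudo-randomized under two
#' constraints: each scene occurs equally often in each run, and within a
#' run every object-scene pair is presented once before any repetition.
#'
#' With the default arguments the encoding table has 320 rows (160 objects
#' x 2 repetitions over 4 runs) and the retrieval table 160 rows over 4
#' runs.
#'
#' @param n_objects number of objects; must be divisible by
#'   `n_scenes * n_runs`.
#' @param n_scenes number of recurring scenes (even; half high reward).
#' @param n_runs number of runs per phase.
#' @param n_reps encoding repetitions of each object-scene pair (within run).
#' @param seed integer seed controlling every random choice.
#' @param iti_range inter-trial interval range in seconds.
#' @param enc_duration,ret_duration stimulus durations (s) used for the
#'   `duration` column (simulation window at encoding, object cue at
#'   retrieval).
#' @return list with elements `encoding` and `retrieval`, each a
#'   `data.frame` of trial events (one row per presented trial) with columns
#'   `phase`, `object_id`, `scene_id`, `reward`, `run`, `onset`, `duration`,
#'   and phase-specific columns (`repetition`, `encoding_correct` /
#'   `recall_response`, `remembered`, `confidence`, `rt`). Behavioral
#'   columns are `NA` until filled by [simulate_behavior()].
#' @seealso [simulate_behavior()], [simulate_patterns()]
#' @export
make_design <- function(n_objects = 160, n_scenes = 4, n_runs = 4,
                        n_reps = 2, seed = 1,
                        iti_range = c(1.75, 5.75),
                        enc_duration = 3.75, ret_duration = 3) {
  if (n_objects %% (n_scenes * n_runs) != 0) {
    stop("n_objects (", n_objects, ") must be divisible by n_scenes * n_runs (",
         n_scenes * n_runs, ") so that each scene occurs equally often in each run",
         call. = FALSE)
  }
  if (n_scenes %% 2 != 0) {
    stop("n_scenes must be even: half the scenes carry high reward, half low",
         call. = FALSE)
  }
  set.seed(seed)

  reward_of_scene <- rep(c("high", "low"), each = n_scenes / 2)

  # objects -> scenes, uniformly at random, balanced
  scene_of_object <- sample(rep(seq_len(n_scenes), each = n_objects / n_scenes))

  # objects -> encoding runs, balanced per scene so each scene occurs
  # equally often in each run
  per_scene_run <- n_objects / (n_scenes * n_runs)
  enc_run_of_object <- integer(n_objects)
  for (s in seq_len(n_scenes)) {
    objs <- sample(which(scene_of_object == s))
    enc_run_of_object[objs] <- rep(seq_len(n_runs), each = per_scene_run)
  }

  # encoding order: within each run, one full random pass over the run's
  # objects before any repetition pass
  enc_rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_objs <- which(enc_run_of_object == r)
    order_obj <- unlist(lapply(seq_len(n_reps), function(p) sample(run_objs)))
    rep_idx <- rep(seq_len(n_reps), each = length(run_objs))
    n_tr <- length(order_obj)
    iti <- stats::runif(n_tr, iti_range[1], iti_range[2])
    # trial length: simulation window + response window + feedback
    onset <- cumsum(iti + c(0, rep(enc_duration + 2.5, n_tr - 1)))
    enc_rows[[r]] <- data.frame(
      phase = "encoding", object_id = order_obj,
      scene_id = scene_of_object[order_obj],
      reward = reward_of_scene[scene_of_object[order_obj]],
      run = r, onset = onset, duration = enc_duration,
      repetition = rep_idx, encoding_correct = NA, rt = NA_real_,
      stringsAsFactors = FALSE)
  }
  encoding <- do.call(rbind, enc_rows)
  rownames(encoding) <- NULL

  # retrieval: each object once; scenes balanced within run; random order
  ret_run_of_object <- integer(n_objects)
  for (s in seq_len(n_scenes)) {
    objs <- sample(which(scene_of_object == s))
    ret_run_of_object[objs] <- rep(seq_len(n_runs), each = per_scene_run)
  }
  ret_rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    order_obj <- sample(which(ret_run_of_object == r))
    n_tr <- length(order_obj)
    iti <- stats::runif(n_tr, iti_range[1], iti_range[2])
    onset <- cumsum(iti + c(0, rep(ret_duration + 4, n_tr - 1)))
    ret_rows[[r]] <- data.frame(
      phase = "retrieval", object_id = order_obj,
      scene_id = scene_of_object[order_obj],
      reward = reward_of_scene[scene_of_object[order_obj]],
      run = r, onset = onset, duration = ret_duration,
      recall_response = NA_character_, remembered = NA,
      confidence = NA_integer_, rt = NA_real_,
      stringsAsFactors = FALSE)
  }
  retrieval <- do.call(rbind, ret_rows)
  rownames(retrieval) <- NULL

  list(encoding = encoding, retrieval = retrieval)
}

#' Simulate behavioral outcomes on a generated design
#'
#' Fills the behavioral columns of the trial tables: each encoding
#' repetition is answered correctly with probability
#' `truth$p_encoding_correct` (independently per repetition); each object is
#' remembered at retrieval with probability `truth$p_remember_high` or
#' `truth$p_remember_low` according to its scene's reward. Remembered
#' objects yield the correct scene label as `recall_response`; for the rest
#' the response is "dont_know" with probability `truth$p_dont_know`,
#' otherwise one of the wrong scene labels uniformly. Encoding response
#' times and retrieval confidence ratings are generated but carry no planted
#' structure.
#'
#' @param encoding,retrieval trial tables from [make_design()].
#' @param truth a [synthetic_truth()] object (probabilities used here).
#' @param seed integer seed.
#' @return list with elements `encoding` and `retrieval`, behavioral
#'   columns filled. `remembered` is `TRUE` iff `recall_response` equals
#'   `scene<scene_id>`.
#' @export
simulate_behavior <- function(encoding, retrieval, truth = synthetic_truth(),
                              seed = 1) {
  set.seed(seed)
  n_objects <- max(encoding$object_id)

  encoding$encoding_correct <-
    stats::runif(nrow(encoding)) < truth$p_encoding_correct
  # correct-response RT within the 1.5 s response window; small speedup for
  # high reward is NOT planted (reward label ignored)
  encoding$rt <- round(0.35 + stats::rbeta(nrow(encoding), 2, 3), 3)
  encoding$rt[!encoding$encoding_correct] <- NA_real_

  p_rem <- ifelse(retrieval$reward == "high",
                  truth$p_remember_high, truth$p_remember_low)
  remembered <- stats::runif(nrow(retrieval)) < p_rem

  n_scenes <- max(retrieval$scene_id)
  resp <- character(nrow(retrieval))
  resp[remembered] <- paste0("scene", retrieval$scene_id[remembered])
  for (i in which(!remembered)) {
    if (stats::runif(1) < truth$p_dont_know) {
      resp[i] <- "dont_know"
    } else {
      wrong <- setdiff(seq_len(n_scenes), retrieval$scene_id[i])
      resp[i] <- paste0("scene", if (length(wrong) == 1) wrong else sample(wrong, 1))
    }
  }
  retrieval$recall_response <- resp
  retrieval$remembered <- resp == paste0("scene", retrieval$scene_id)
  retrieval$confidence <- ifelse(resp == "dont_know", NA_integer_,
                                 sample(1:4, nrow(retrieval), replace = TRUE))
  retrieval$rt <- round(0.5 + stats::rbeta(nrow(retrieval), 2, 2) * 1.5, 3)

  list(encoding = encoding, retrieval = retrieval)
}

#' Per-object encoding correctness
#'
#' An object counts as correctly encoded only if *every* one of its
#' encoding repetitions was answered correctly; all similarity analyses
#' restrict to such objects.
#'
#' @param encoding encoding table with `encoding_correct` filled.
#' @return logical vector indexed by object id (length `max(object_id)`).
#' @export
object_fully_correct <- function(encoding) {
  if (anyNA(encoding$encoding_correct)) {
    stop("encoding_correct contains NA; run simulate_behavior() first or supply real behavior",
         call. = FALSE)
  }
  ok <- tapply(encoding$encoding_correct, encoding$object_id, all)
  out <- logical(max(encoding$object_id))
  out[as.integer(names(ok))] <- as.logical(ok)
  out
}
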