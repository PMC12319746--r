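# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by the most literal route available
# (double loops, textbook formulas, stats::aov) and never call the package
# code paths they are checking.

# exhaustive double-loop enumeration of encoding-retrieval pairs:
# (i) not the same object, (ii) both members in the same reward x memory
# condition, (iii) both objects correct on every encoding repetition
brute_ers_pairs <- function(enc, ret) {
  ok <- tapply(enc$encoding_correct, enc$object_id, all)
  ok_obj <- function(o) isTRUE(ok[[as.character(o)]])
  rem <- ret$remembered[match(enc$object_id, ret$object_id)]
  out <- list()
  for (i in seq_len(nrow(enc))) {
    for (j in seq_len(nrow(ret))) {
      if (enc$object_id[i] == ret$object_id[j]) next
      if (!ok_obj(enc$object_id[i]) || !ok_obj(ret$object_id[j])) next
      cond_i <- paste0(ifelse(enc$reward[i] == "high", "H", "L"),
                       ifelse(rem[i], "R", "F"))
      cond_j <- paste0(ifelse(ret$reward[j] == "high", "H", "L"),
                       ifelse(ret$remembered[j], "R", "F"))
      if (is.na(rem[i]) || cond_i != cond_j) next
      out[[length(out) + 1]] <- data.frame(
        trial_a = i, trial_b = j, condition = cond_i,
        overlap = if (enc$scene_id[i] == ret$scene_id[j]) "same" else "diff",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(trial_a = integer(), trial_b = integer(),
                                      condition = character(),
                                      overlap = character()))
  do.call(rbind, out)
}

# exhaustive double-loop enumeration of retrieval-retrieval pairs:
# unordered, different runs, same condition, both objects fully correct
brute_rrs_pairs <- function(ret, enc) {
  ok <- tapply(enc$encoding_correct, enc$object_id, all)
  ok_obj <- function(o) isTRUE(ok[[as.character(o)]])
  out <- list()
  n <- nrow(ret)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ret$run[i] == ret$run[j]) next
      if (!ok_obj(ret$object_id[i]) || !ok_obj(ret$object_id[j])) next
      cond_i <- paste0(ifelse(ret$reward[i] == "high", "H", "L"),
                       ifelse(ret$remembered[i], "R", "F"))
      cond_j <- paste0(ifelse(ret$reward[j] == "high", "H", "L"),
                       ifelse(ret$remembered[j], "R", "F"))
      if (cond_i != cond_j) next
      out[[length(out) + 1]] <- data.frame(
        trial_a = i, trial_b = j, condition = cond_i,
        overlap = if (ret$scene_id[i] == ret$scene_id[j]) "same" else "diff",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(trial_a = integer(), trial_b = integer(),
                                      condition = character(),
                                      overlap = character()))
  do.call(rbind, out)
}

pair_key <- function(p) sort(paste(p$trial_a, p$trial_b, p$condition, p$overlap))

# classical sums-of-squares repeated-measures ANOVA for the 2x2x2
# within-subject design, computed with stats::aov error strata
oracle_rm_anova <- function(cells) {
  n <- nrow(cells)
  cl <- scenersa::condition_cells()
  long <- data.frame(
    y = as.numeric(t(cells)),
    subj = factor(rep(seq_len(n), each = 8)),
    reward = factor(rep(substr(cl, 1, 1), n)),
    memory = factor(rep(substr(cl, 2, 2), n)),
    overlap = factor(rep(sub(".*-", "", cl), n)))
  fit <- stats::aov(y ~ reward * memory * overlap +
                      Error(subj / (reward * memory * overlap)), data = long)
  sm <- summary(fit)
  out <- c()
  for (stratum in sm) {
    tb <- stratum[[1]]
    rn <- trimws(rownames(tb))
    for (k in seq_along(rn)) {
      if (rn[k] == "Residuals") next
      out[rn[k]] <- tb[k, "F value"]
    }
  }
  # map aov term names onto the package's effect names
  c(reward = out[["reward"]], memory = out[["memory"]],
    overlap = out[["overlap"]],
    reward_by_memory = out[["reward:memory"]],
    reward_by_overlap = out[["reward:overlap"]],
    memory_by_overlap = out[["memory:overlap"]],
    reward_by_memory_by_overlap = out[["reward:memory:overlap"]])
}

# small random task design with random behavior, for property tests
random_toy_subject <- function(seed, n_objects = 16, n_scenes = 4,
                               n_runs = 2, n_reps = 2,
                               p_correct = 0.85, p_rem = 0.5) {
  d <- scenersa::make_design(n_objects, n_scenes, n_runs, n_reps, seed = seed)
  truth <- scenersa::synthetic_truth(p_encoding_correct = p_correct,
                                     p_remember_high = p_rem,
                                     p_remember_low = p_rem)
  scenersa::simulate_behavior(d$encoding, d$retrieval, truth, seed = seed + 1)
}

# fully correct, fully remembered subject with patterns
perfect_subject <- function(seed, profile = "null", n_objects = 16,
                            n_scenes = 4, n_runs = 2, n_voxels = 40, ...) {
  d <- scenersa::make_design(n_objects, n_scenes, n_runs, 2, seed = seed)
  truth <- scenersa::region_profile(profile, p_encoding_correct = 1,
                                    p_remember_high = 1, p_remember_low = 1, ...)
  b <- scenersa::simulate_behavior(d$encoding, d$retrieval, truth, seed = seed + 1)
  p <- scenersa::simulate_patterns(b$encoding, b$retrieval, truth, n_voxels,
                                   seed = seed + 2)
  list(encoding = b$encoding, retrieval = b$retrieval, patterns = p, truth = truth)
}

# all encoding responses correct, exactly the even-numbered objects
# remembered: deterministic behavior that populates all 8 condition cells
half_remembered_subject <- function(seed, profile = "null", n_objects = 32,
                                    n_scenes = 4, n_runs = 2, n_voxels = 40,
                                    ...) {
  d <- scenersa::make_design(n_objects, n_scenes, n_runs, 2, seed = seed)
  truth <- scenersa::region_profile(profile, p_encoding_correct = 1,
                                    p_remember_high = 1, p_remember_low = 1, ...)
  b <- scenersa::simulate_behavior(d$encoding, d$retrieval, truth, seed = seed + 1)
  ret <- b$retrieval
  ret$remembered <- ret$object_id %% 2 == 0
  ret$recall_response <- ifelse(ret$remembered,
                                paste0("scene", ret$scene_id), "dont_know")
  p <- scenersa::simulate_patterns(b$encoding, ret, truth, n_voxels,
                                   seed = seed + 2)
  list(encoding = b$encoding, retrieval = ret, patterns = p, truth = truth)
}
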