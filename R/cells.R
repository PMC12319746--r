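#' Condition cells and effect contrasts
#'
#' Similarity values are binned into 8 condition cells: the crossing of
#' reward (high/low), subsequent memory (remembered/forgotten) and scene
#' overlap (same/different scene). The fixed cell order used throughout the
#' package is HR-same, HR-diff, HF-same, HF-diff, LR-same, LR-diff, LF-same,
#' LF-diff, where e.g. "HR" = high reward / remembered and "LF" = low reward
#' / forgotten.
#'
#' @return `condition_cells()` returns the 8 cell labels in canonical order.
#' @export
condition_cells <- function() {
  c("HR-same", "HR-diff", "HF-same", "HF-diff",
    "LR-same", "LR-diff", "LF-same", "LF-diff")
}

#' Signed contrast weights over the 8 condition cells
#'
#' Returns the weight vector defining a within-subject effect as a linear
#' contrast over the 8 cell means (canonical order, see
#' [condition_cells()]). Weights always sum to zero. The two headline
#' contrasts are `memory_by_overlap` (`[1 -1 -1 1 1 -1 -1 1]`), used for
#' encoding-retrieval similarity, and `overlap` (`[1 -1 1 -1 1 -1 1 -1]`),
#' used for retrieval-retrieval similarity.
#'
#' @param effect one of `"reward"`, `"memory"`, `"overlap"`,
#'   `"reward_by_memory"`, `"reward_by_overlap"`, `"memory_by_overlap"`,
#'   `"reward_by_memory_by_overlap"`.
#' @return named numeric vector of length 8 summing to zero.
#' @examples
#' effect_contrast("memory_by_overlap")
#' @export
effect_contrast <- function(effect = c("reward", "memory", "overlap",
                                       "reward_by_memory",
                                       "reward_by_overlap",
                                       "memory_by_overlap",
                                       "reward_by_memory_by_overlap")) {
  effect <- match.arg(effect)
  reward  <- c(1, 1, 1, 1, -1, -1, -1, -1)
  memory  <- c(1, 1, -1, -1, 1, 1, -1, -1)
  overlap <- c(1, -1, 1, -1, 1, -1, 1, -1)
  w <- switch(effect,
    reward = reward,
    memory = memory,
    overlap = overlap,
    reward_by_memory = reward * memory,
    reward_by_overlap = reward * overlap,
    memory_by_overlap = memory * overlap,
    reward_by_memory_by_overlap = reward * memory * overlap)
  names(w) <- condition_cells()
  w
}

# cell label from condition (HR/HF/LR/LF) and overlap (same/diff)
cell_label <- function(condition, overlap) {
  paste(condition, overlap, sep = "-")
}

# condition code for trials: reward (high/low) x remembered (TRUE/FALSE)
condition_code <- function(reward, remembered) {
  paste0(ifelse(reward == "high", "H", "L"), ifelse(remembered, "R", "F"))
}
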