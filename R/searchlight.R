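#' Integer voxel offsets of a searchlight sphere
#'
#' All integer lattice displacements with squared norm `<= radius^2`,
#' center included. Radius 3 yields 123 offsets.
#'
#' @param radius sphere radius in voxels (>= 0).
#' @return integer matrix, one row per offset, columns x/y/z.
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE])
}

#' Moving-sphere searchlight map of a condition-cell contrast
#'
#' Repeats the ROI similarity analysis within a sphere centered on every
#' in-mask voxel: pair similarities are computed over the sphere's in-mask
#' voxels, binned into the 8 condition cells, and combined with the effect
#' contrast; the resulting value is written to the center voxel. The pair
#' list (with all inclusion rules) is enumerated once from the trial tables
#' and reused at every center. Centers whose sphere contains fewer than
#' `min_voxels` in-mask voxels, or where a contrast-touched cell is empty,
#' get `NA`.
#'
#' @param ret_maps 4D array (x, y, z, trial) of retrieval-trial statistical
#'   maps.
#' @param enc_maps 4D array of encoding-trial maps (required for
#'   `analysis = "ERS"`).
#' @param encoding,retrieval trial tables with behavior filled.
#' @param mask logical/0-1 3D array; spheres and centers are restricted to
#'   it.
#' @param effect effect name or length-8 weight vector (see
#'   [effect_contrast()]).
#' @param analysis `"ERS"` or `"RRS"`.
#' @param radius sphere radius in voxels (study default 3).
#' @param min_voxels minimum in-mask voxels per sphere; default half the
#'   full sphere size (at least 2, since a correlation needs two voxels).
#' @return 3D array of per-center effect values (`NA` outside the mask).
#' @export
searchlight_effects <- function(ret_maps, enc_maps = NULL,
                                encoding, retrieval, mask,
                                effect, analysis = c("ERS", "RRS"),
                                radius = 3, min_voxels = NULL) {
  analysis <- match.arg(analysis)
  d <- dim(ret_maps)[1:3]
  if (!identical(dim(mask)[1:3], d)) stop("mask and maps dimensions differ", call. = FALSE)
  offs <- sphere_offsets(radius)
  if (is.null(min_voxels)) min_voxels <- max(2, floor(nrow(offs) / 2))
  w <- if (is.character(effect)) effect_contrast(effect) else effect

  if (analysis == "ERS") {
    if (is.null(enc_maps)) stop("ERS searchlight needs enc_maps", call. = FALSE)
    pairs <- enumerate_ers_pairs(encoding, retrieval)
  } else {
    pairs <- enumerate_rrs_pairs(retrieval, encoding)
  }
  cellf <- factor(pairs$cell, levels = condition_cells())
  counts <- as.integer(table(cellf))
  if (any(counts == 0 & w != 0)) {
    stop("contrast touches empty condition cell(s) for this subject", call. = FALSE)
  }
  # per-pair weights reproducing w/4 %*% cell_means
  wl <- (w / 4)[as.integer(cellf)] / counts[as.integer(cellf)]

  mask <- array(as.logical(mask), d)
  ret_flat <- matrix(ret_maps, prod(d), dim(ret_maps)[4])
  enc_flat <- if (!is.null(enc_maps)) matrix(enc_maps, prod(d), dim(enc_maps)[4])

  centers <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (ci in seq_len(nrow(centers))) {
    nb <- sweep(offs, 2, centers[ci, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    lin <- lin[mask[lin]]
    if (length(lin) < min_voxels) next
    ret_pat <- t(ret_flat[lin, , drop = FALSE])
    r <- if (analysis == "ERS") {
      .pattern_rcor(t(enc_flat[lin, , drop = FALSE]), ret_pat)
    } else {
      .pattern_rcor(ret_pat, ret_pat)
    }
    z <- fisher_z(r[cbind(pairs$trial_a, pairs$trial_b)])
    out[centers[ci, 1], centers[ci, 2], centers[ci, 3]] <- sum(wl * z)
  }
  out
}

#' Second-level one-sample t map across subjects
#'
#' Per voxel, the one-sample t of the subject effect values against zero.
#' Voxels where all subjects are zero give t = 0; zero-variance voxels
#' with nonzero mean give `NA`.
#'
#' @param effect_maps subjects-by-voxels matrix, or a list of equally
#'   dimensioned arrays (stacked and flattened).
#' @return list with `t` and `mean` vectors (or arrays, matching the input
#'   maps), and `df`.
#' @export
group_tmap <- function(effect_maps) {
  dims <- NULL
  if (is.list(effect_maps)) {
    dims <- dim(effect_maps[[1]])
    effect_maps <- t(vapply(effect_maps, as.numeric,
                            numeric(length(effect_maps[[1]]))))
  }
  n <- nrow(effect_maps)
  m <- colMeans(effect_maps)
  s <- apply(effect_maps, 2, stats::sd)
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, NA_real_))
  if (!is.null(dims)) {
    t <- array(t, dims); m <- array(m, dims)
  }
  list(t = t, mean = m, df = n - 1)
}

#' Peak-level family-wise-error corrected p values by sign-flip permutation
#'
#' Under the group null of symmetrically distributed subject effects, the
#' subject maps are randomly sign-flipped; each permutation's maximum |t|
#' over the evaluated voxels forms the max-statistic null distribution, and
#' a voxel's corrected p is the proportion of permutations (plus the
#' observed map) whose maximum reaches its observed |t|. The smallest
#' attainable p is `1 / (n_perm + 1)`. Restricting `small_volume` to a
#' subset of voxels can only shrink corrected p values.
#'
#' @param effect_maps subjects-by-voxels matrix (in-mask voxels).
#' @param n_perm number of sign-flip permutations (searchlight-scale
#'   default 1000).
#' @param seed integer seed.
#' @param small_volume optional logical/integer index restricting the
#'   family of voxels over which the maximum is taken (and for which p
#'   values are returned).
#' @return list with `t` (observed t over evaluated voxels), `p_fwe`
#'   (corrected p), `max_null` (the permutation maxima), `df`.
#' @export
fwe_maxstat <- function(effect_maps, n_perm = 1000, seed = 1,
                        small_volume = NULL) {
  if (!is.null(small_volume)) {
    effect_maps <- effect_maps[, small_volume, drop = FALSE]
  }
  drop_na <- colSums(is.na(effect_maps)) > 0
  keep <- which(!drop_na)
  maps <- effect_maps[, keep, drop = FALSE]
  n <- nrow(maps)
  tfun <- function(m) {
    mu <- colMeans(m)
    v <- (colSums(m * m) - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    ifelse(v > 0, mu / sqrt(v / n), 0)
  }
  t_obs <- tfun(maps)
  set.seed(seed)
  max_null <- vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    max(abs(tfun(maps * flips)))
  }, numeric(1))
  p <- vapply(abs(t_obs), function(tv) {
    (1 + sum(max_null >= tv)) / (n_perm + 1)
  }, numeric(1))
  t_full <- rep(NA_real_, ncol(effect_maps)); t_full[keep] <- t_obs
  p_full <- rep(NA_real_, ncol(effect_maps)); p_full[keep] <- p
  list(t = t_full, p_fwe = p_full, max_null = max_null, df = n - 1)
}
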