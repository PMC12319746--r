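test_that("closed-form t tests agree with stats::t.test", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  ref <- t.test(x, mu = 0.3)
  mine <- one_sample_t(x, mu = 0.3)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  refp <- t.test(x, y, paired = TRUE)
  minep <- paired_t(x, y)
  expect_equal(minep$t, unname(refp$statistic), tolerance = 1e-12)
  expect_equal(minep$p, refp$p.value, tolerance = 1e-12)
  ref1 <- t.test(x, alternative = "greater")
  mine1 <- one_sample_t(x, alternative = "greater")
  expect_equal(mine1$p, ref1$p.value, tolerance = 1e-12)
})

test_that("degenerate t-test inputs are handled explicitly", {
  a <- c(1, 2, 3)
  eq <- paired_t(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # symmetric +/- c data: mean zero, t = 0
  expect_equal(one_sample_t(c(-2, 2, -2, 2))$t, 0)
  # zero variance with nonzero mean: undefined, flagged
  nv <- one_sample_t(c(1, 1, 1))
  expect_true(is.na(nv$t))
  expect_match(attr(nv, "note"), "zero variance")
})

test_that("all-equal cells give F = 0 and the ANOVA refuses tiny samples", {
  cells <- matrix(rep(rnorm(5), 8), 5, 8)   # constant within subject
  a <- rm_anova_2x2x2(cells)
  expect_true(all(a$F == 0))
  expect_error(rm_anova_2x2x2(matrix(rnorm(16), 2, 8)), "at least 3")
})

test_that("contrast-score ANOVA matches the classical SS oracle and F = t^2", {
  set.seed(9)
  for (k in 1:5) {
    cells <- matrix(rnorm(80), 10, 8)
    mine <- rm_anova_2x2x2(cells)
    oracle <- oracle_rm_anova(cells)
    expect_equal(mine$F, unname(oracle[mine$effect]), tolerance = 1e-8)
    scores <- attr(mine, "scores")
    for (i in seq_len(nrow(mine))) {
      tt <- one_sample_t(scores[, mine$effect[i]])
      expect_equal(mine$F[i], tt$t^2, tolerance = 1e-10)
      expect_equal(mine$p[i], tt$p, tolerance = 1e-10)
    }
  }
})

test_that("subjects with missing cells are excluded with a message", {
  set.seed(4)
  cells <- matrix(rnorm(80), 10, 8)
  cells[3, 5] <- NA
  expect_message(a <- rm_anova_2x2x2(cells), "excluded")
  expect_equal(attr(a, "n"), 9)
  expect_equal(a$F, rm_anova_2x2x2(cells[-3, ])$F, tolerance = 1e-12)
})

test_that("the RRS-vs-ERS contrast composes paired_t on effect scores", {
  set.seed(12)
  rrs <- matrix(rnorm(64, mean = 0.05), 8, 8)
  ers <- matrix(rnorm(64), 8, 8)
  out <- rrs_vs_ers_contrast(rrs, ers, "overlap")
  ref <- paired_t(effect_scores(rrs, "overlap"), effect_scores(ers, "overlap"))
  expect_equal(out$t, ref$t, tolerance = 1e-12)
  expect_equal(out$p, ref$p, tolerance = 1e-12)
  same <- rrs_vs_ers_contrast(rrs, rrs, "overlap")
  expect_equal(same$t, 0)
})

test_that("across-subject correlation matches cor.test and handles identity", {
  set.seed(3)
  a <- rnorm(20); b <- a * 0.5 + rnorm(20)
  out <- across_subject_corr(a, b)
  ref <- cor.test(a, b)
  expect_equal(out$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(out$p, ref$p.value, tolerance = 1e-12)
  expect_equal(across_subject_corr(a, a)$r, 1)
})

test_that("slope regression recovers exact linear relations and formula slopes", {
  x <- list(c(1, 2, 3, 4, 5))
  y <- list(c(2, 4, 6, 8, 10))
  out <- suppressMessages(slope_regression(rep(x, 4), rep(y, 4)))
  expect_equal(out$slopes, rep(2, 4))
  # all slopes equal: zero variance, group t undefined and flagged as NA
  expect_true(is.na(out$t))
  # formula oracle on a 5-point toy
  xv <- c(0.2, 1.1, -0.4, 0.9, 2.2); yv <- c(1, 0.4, -0.2, 1.4, 2.0)
  sl <- suppressMessages(slope_regression(list(xv, xv + 1), list(yv, yv)))
  expect_equal(sl$slopes[1], cov(xv, yv) / var(xv), tolerance = 1e-12)
  expect_equal(sl$slopes[1], unname(coef(lm(yv ~ xv))[2]), tolerance = 1e-12)
  # trials with missing indices are dropped per subject
  sl2 <- suppressMessages(slope_regression(list(c(xv, NA), xv + 1),
                                           list(c(yv, 1), yv)))
  expect_equal(sl2$slopes[[1]], cov(xv, yv) / var(xv), tolerance = 1e-12)
})

test_that("independent single-trial indices give alpha-level slope rejections", {
  set.seed(21)
  rejections <- replicate(200, {
    x <- lapply(1:10, function(i) rnorm(20))
    y <- lapply(1:10, function(i) rnorm(20))
    slope_regression(x, y)$p < 0.05
  })
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("permutation z is seed-deterministic and shift invariant", {
  set.seed(8)
  n <- 240
  cells <- sample(condition_cells(), n, replace = TRUE)
  z <- rnorm(n)
  a <- permutation_z(z, cells, "overlap", n_perm = 300, seed = 5)
  b <- permutation_z(z, cells, "overlap", n_perm = 300, seed = 5)
  expect_identical(a, b)
  shifted <- permutation_z(z + 10, cells, "overlap", n_perm = 300, seed = 5)
  expect_equal(shifted$z, a$z, tolerance = 1e-9)
  expect_equal(shifted$true_effect, a$true_effect, tolerance = 1e-12)
})

test_that("degenerate permutation nulls raise errors", {
  cells <- rep(condition_cells(), 10)
  expect_error(permutation_z(rep(0.5, 80), cells, "overlap", n_perm = 100),
               "degenerate")
  expect_error(permutation_z(rnorm(80), cells, "overlap", n_perm = 10),
               ">= 100")
  # contrast touching an empty cell
  some <- cells[!(cells %in% "HR-same")]
  expect_error(permutation_z(rnorm(length(some)), some, "overlap", n_perm = 100),
               "empty cell")
})

test_that("behavior stats use only fully correct objects in recall denominators", {
  co <- lapply(1:4, function(i) {
    d <- make_design(32, 4, 2, 2, seed = 50 + i)
    simulate_behavior(d$encoding, d$retrieval,
                      synthetic_truth(p_encoding_correct = 0.8), seed = 60 + i)
  })
  bs <- behavior_stats(co)
  for (i in seq_along(co)) {
    enc <- co[[i]]$encoding; ret <- co[[i]]$retrieval
    # brute-force filter: objects with every repetition correct
    good <- vapply(unique(enc$object_id),
                   function(o) all(enc$encoding_correct[enc$object_id == o]),
                   logical(1))
    names(good) <- unique(enc$object_id)
    keep <- good[as.character(ret$object_id)]
    expect_equal(bs$per_subject$recall_high[i],
                 mean(ret$remembered[keep & ret$reward == "high"]))
    expect_equal(bs$per_subject$recall_low[i],
                 mean(ret$remembered[keep & ret$reward == "low"]))
  }
})

test_that("all-correct encoding yields accuracy 1 and a flagged no-variance test", {
  co <- lapply(1:3, function(i) {
    d <- make_design(16, 4, 2, 2, seed = i)
    simulate_behavior(d$encoding, d$retrieval,
                      synthetic_truth(p_encoding_correct = 1), seed = i + 10)
  })
  bs <- behavior_stats(co)
  expect_true(all(bs$per_subject$enc_acc_high == 1))
  expect_true(all(bs$per_subject$enc_acc_low == 1))
  tt <- bs$tests$encoding_accuracy
  expect_true(tt$t == 0 || is.na(tt$t))
})
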