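test_that("fisher_z matches atanh and rejects degenerate correlations", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "degenerate")
  expect_error(fisher_z(-1), "degenerate")
  expect_error(fisher_z(1.2), "<= 1")
})

test_that("zero-variance patterns are rejected rather than clipped", {
  a <- rbind(rnorm(10), rep(2, 10))
  expect_error(pattern_zcor(a, a[1, , drop = FALSE]), "zero-variance")
  # duplicated rows across sets -> r = 1 -> degenerate
  b <- rbind(rnorm(10))
  expect_error(pattern_zcor(b, b), "degenerate")
})

test_that("pair enumeration matches the exhaustive double-loop oracle", {
  for (seed in 1:10) {
    s <- random_toy_subject(seed * 17)
    ers <- enumerate_ers_pairs(s$encoding, s$retrieval)
    rrs <- enumerate_rrs_pairs(s$retrieval, s$encoding)
    expect_identical(pair_key(ers), pair_key(brute_ers_pairs(s$encoding, s$retrieval)))
    expect_identical(pair_key(rrs), pair_key(brute_rrs_pairs(s$retrieval, s$encoding)))
  }
})

test_that("a single incorrect encoding repetition removes every pair touching that object", {
  s <- perfect_subject(seed = 21)
  enc <- s$encoding
  bad <- enc$object_id[5]
  enc$encoding_correct[which(enc$object_id == bad)[2]] <- FALSE
  ers <- enumerate_ers_pairs(enc, s$retrieval)
  rrs <- enumerate_rrs_pairs(s$retrieval, enc)
  bad_enc_rows <- which(enc$object_id == bad)
  bad_ret_row <- which(s$retrieval$object_id == bad)
  expect_false(any(ers$trial_a %in% bad_enc_rows))
  expect_false(any(ers$trial_b == bad_ret_row))
  expect_false(any(rrs$trial_a == bad_ret_row | rrs$trial_b == bad_ret_row))
})

test_that("no retrieval trial pairs with its own object's encoding repetitions", {
  s <- perfect_subject(seed = 8, n_objects = 32, n_runs = 4)
  ers <- enumerate_ers_pairs(s$encoding, s$retrieval)
  obj_a <- s$encoding$object_id[ers$trial_a]
  obj_b <- s$retrieval$object_id[ers$trial_b]
  expect_true(all(obj_a != obj_b))
})

test_that("RRS pairs are unordered, cross-run, and same-scene implies same reward", {
  s <- perfect_subject(seed = 12, n_objects = 32, n_runs = 4)
  rrs <- enumerate_rrs_pairs(s$retrieval, s$encoding)
  expect_true(all(rrs$trial_a < rrs$trial_b))
  expect_false(any(duplicated(rrs[c("trial_a", "trial_b")])))
  expect_true(all(s$retrieval$run[rrs$trial_a] != s$retrieval$run[rrs$trial_b]))
  for (p in list(rrs, enumerate_ers_pairs(s$encoding, s$retrieval))) {
    same <- p[p$overlap == "same", ]
    a_tab <- if (identical(attr(p, "analysis"), "ERS")) s$encoding else s$retrieval
    expect_true(all(a_tab$reward[same$trial_a] ==
                      s$retrieval$reward[same$trial_b]))
  }
  # all retrieval trials in one run -> no RRS pairs
  one_run <- s$retrieval
  one_run$run <- 1
  expect_equal(nrow(enumerate_rrs_pairs(one_run, s$encoding)), 0)
})

test_that("condition means equal a hand computation on a small fixture", {
  # 2 encoding and 3 retrieval trials, 4 voxels, all HR condition
  enc <- data.frame(phase = "encoding", object_id = c(1, 2), scene_id = c(1, 2),
                    reward = "high", run = 1, onset = c(0, 10), duration = 3,
                    repetition = 1, encoding_correct = TRUE)
  ret <- data.frame(phase = "retrieval", object_id = c(3, 4, 5),
                    scene_id = c(1, 2, 1), reward = "high", run = 2,
                    onset = c(0, 10, 20), duration = 3,
                    recall_response = c("scene1", "scene2", "scene1"),
                    remembered = TRUE, confidence = 2, rt = 1)
  # objects 3..5 never encoded: make them exist and correct
  enc_full <- rbind(enc, data.frame(phase = "encoding", object_id = 3:5,
                                    scene_id = c(1, 2, 1), reward = "high",
                                    run = 1, onset = c(20, 30, 40), duration = 3,
                                    repetition = 1, encoding_correct = TRUE))
  pe <- matrix(c(1, 0, 2, 1,
                 0, 1, 1, 2,
                 1, 2, 0, 1,
                 2, 1, 1, 0,
                 0, 2, 1, 1), 5, 4, byrow = TRUE)
  pairs <- enumerate_ers_pairs(enc_full, ret)
  pairs <- pair_similarities(pairs, pe, pe[3:5, ] + 0.1)
  m <- condition_means(pairs)
  # hand oracle: objects 1-2 have no retrieval outcome so their encoding
  # trials drop out; same-object pairs drop out; remaining pairs by scene:
  # same = (enc obj3, ret obj5), (enc obj5, ret obj3); the rest diff
  expect_z <- function(i, j) atanh(cor(pe[i, ], (pe[3:5, ] + 0.1)[j, ]))
  same <- c(expect_z(3, 3), expect_z(5, 1))
  diff <- c(expect_z(3, 2), expect_z(4, 1), expect_z(4, 3), expect_z(5, 2))
  expect_equal(m$mean_z[m$cell == "HR-same"], mean(same), tolerance = 1e-12)
  expect_equal(m$n_pairs[m$cell == "HR-same"], 2)
  expect_equal(m$mean_z[m$cell == "HR-diff"], mean(diff), tolerance = 1e-12)
  expect_equal(m$n_pairs[m$cell == "HR-diff"], 4)
  expect_true(all(is.na(m$mean_z[m$n_pairs == 0])))
})

test_that("condition means are invariant to trial order permutation", {
  s <- perfect_subject(seed = 30, profile = "mpfc_like", n_objects = 16,
                       n_runs = 2, n_voxels = 30)
  m1 <- roi_similarity(s, "RRS")
  set.seed(2)
  perm <- sample(nrow(s$retrieval))
  s2 <- s
  s2$retrieval <- s$retrieval[perm, ]
  s2$patterns$retrieval <- s$patterns$retrieval[perm, ]
  m2 <- roi_similarity(s2, "RRS")
  expect_equal(m1$mean_z, m2$mean_z, tolerance = 1e-12)
  expect_equal(m1$n_pairs, m2$n_pairs)
})

test_that("hemisphere averaging combines cell means, not pooled pairs", {
  s <- perfect_subject(seed = 14, n_voxels = 40)
  set.seed(3)
  left <- s
  right <- s
  right$patterns$encoding <- s$patterns$encoding + matrix(rnorm(length(s$patterns$encoding), sd = 2), nrow(s$patterns$encoding))
  right$patterns$retrieval <- s$patterns$retrieval + matrix(rnorm(length(s$patterns$retrieval), sd = 2), nrow(s$patterns$retrieval))
  ml <- roi_similarity(left, "ERS")
  mr <- roi_similarity(right, "ERS")
  comb <- combine_hemispheres(ml, mr)
  expect_equal(comb$mean_z, (ml$mean_z + mr$mean_z) / 2, tolerance = 1e-15)
  expect_equal(comb$n_pairs, ml$n_pairs + mr$n_pairs)
})

test_that("single-trial indices equal brute-force recomputation from the pair list", {
  s <- perfect_subject(seed = 44, profile = "mpfc_like", n_objects = 16,
                       n_runs = 2, n_voxels = 30)
  for (analysis in c("ERS", "RRS")) {
    m <- roi_similarity(s, analysis)
    pairs <- attr(m, "pairs")
    idx <- single_trial_index(pairs, nrow(s$retrieval))
    for (j in seq_len(nrow(s$retrieval))) {
      if (analysis == "ERS") {
        mine <- pairs[pairs$trial_b == j, ]
      } else {
        mine <- pairs[pairs$trial_a == j | pairs$trial_b == j, ]
      }
      zs <- mine$z[mine$overlap == "same"]
      zd <- mine$z[mine$overlap == "diff"]
      if (!length(zs) || !length(zd)) {
        expect_true(is.na(idx[j]))
      } else {
        expect_equal(idx[j], mean(zs) - mean(zd), tolerance = 1e-12)
      }
    }
  }
})

test_that("noiseless planted reinstatement gives positive single-trial indices", {
  s <- perfect_subject(seed = 3, profile = "phc_like", noise_sd = 0,
                       reinstatement_gain_remembered = 5, object_gain = 1,
                       n_objects = 16, n_voxels = 40)
  m <- roi_similarity(s, "ERS")
  idx <- single_trial_index(attr(m, "pairs"), nrow(s$retrieval))
  expect_true(all(idx > 0, na.rm = TRUE))
  expect_gt(sum(!is.na(idx)), 0)
})

test_that("null-profile single-trial indices center on zero", {
  # pool trials over a few subjects; mean should sit within 3 SE of 0
  idx <- unlist(lapply(1:4, function(k) {
    s <- simulate_cohort(1, region_profile("null"), n_voxels = 60,
                         seed = 100 + k, n_objects = 40, n_runs = 2)[[1]]
    m <- roi_similarity(s, "ERS")
    single_trial_index(attr(m, "pairs"), nrow(s$retrieval))
  }))
  idx <- idx[!is.na(idx)]
  expect_gt(length(idx), 120)
  expect_lt(abs(mean(idx)), 3 * sd(idx) / sqrt(length(idx)))
})
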