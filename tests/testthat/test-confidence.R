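test_that("jackknife with zero dropout reproduces the reference refold", {
  gt <- simulate_structure(80, seed = 4, perturb_sd = 0)
  seq <- attr(gt, "sequence")
  prof <- simulate_reactivities(gt, "SHAPE", sim_params(dropout = 0),
                                seed = 14)
  refold <- fold_mfe(seq, prof)
  conf <- jackknife_confidence(seq, prof, refold, n_reps = 5,
                               drop_frac = 0, seed = 3)
  expect_true(all(conf$confidence == 100))
  # against a different reference, confidence is the fixed agreement
  conf2 <- jackknife_confidence(seq, prof, gt, n_reps = 5,
                                drop_frac = 0, seed = 3)
  agree <- ifelse(is.na(refold$partner), 0L, refold$partner) ==
    ifelse(is.na(gt$partner), 0L, gt$partner)
  expect_equal(conf2$confidence, 100 * as.numeric(agree))
})

test_that("jackknife is deterministic given the seed and bounded", {
  gt <- simulate_structure(80, seed = 6)
  seq <- attr(gt, "sequence")
  prof <- simulate_reactivities(gt, "SHAPE", seed = 16)
  c1 <- jackknife_confidence(seq, prof, gt, n_reps = 15, seed = 9)
  c2 <- jackknife_confidence(seq, prof, gt, n_reps = 15, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$confidence >= 0 & c1$confidence <= 100))
  expect_error(jackknife_confidence(seq, prof, gt, drop_frac = 1),
               class = "shapefold_param_error")
})

test_that("Shannon entropy closed forms are exact", {
  P <- matrix(0, 6, 6)
  P[1, 5] <- P[5, 1] <- 1
  S <- shannon_entropy(structure(P, class = "pair_probability_matrix"))
  expect_equal(S$entropy[1], 0, tolerance = 1e-12)

  P2 <- matrix(0, 6, 6)
  P2[1, 5] <- P2[5, 1] <- 0.5
  S2 <- shannon_entropy(structure(P2, class = "pair_probability_matrix"))
  expect_equal(S2$entropy[1], -0.5 * log10(0.5), tolerance = 1e-12)
  expect_equal(round(S2$entropy[1], 4), 0.1505)

  P3 <- matrix(0, 6, 6)
  P3[1, 5] <- P3[5, 1] <- 0.5
  P3[1, 6] <- P3[6, 1] <- 0.5
  S3 <- shannon_entropy(structure(P3, class = "pair_probability_matrix"))
  expect_equal(S3$entropy[1], -log10(0.5), tolerance = 1e-12)
  expect_equal(round(S3$entropy[1], 4), 0.3010)
})

test_that("entropy is bounded by the uniform-partner maximum", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    P <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      mass <- runif(1)
      parts <- sample(setdiff(seq_len(n), i), sample(1:3, 1))
      w <- runif(length(parts)); w <- mass * w / sum(w)
      P[i, parts] <- pmax(P[i, parts], w)
    }
    P <- pmin((P + t(P)) / 2, 1)
    S <- shannon_entropy(structure(P, class = "pair_probability_matrix"))
    p_tot <- rowSums(P)
    bound <- ifelse(p_tot > 0,
                    p_tot * log10(n - 1) - p_tot * log10(pmax(p_tot, 1e-300)),
                    0)
    expect_true(all(S$entropy <= bound + 1e-9))
    expect_true(all(S$entropy >= 0))
  }
})

test_that("well-defined region detection finds exactly the passing runs", {
  n <- 300
  expect_equal(nrow(find_well_defined_regions(rep(100, n), rep(1, n))), 0)
  whole <- find_well_defined_regions(rep(100, n), rep(0, n))
  expect_equal(whole$start, 1L)
  expect_equal(whole$end, n)
  expect_equal(whole$mean_confidence, 100)
  expect_equal(whole$mean_entropy, 0)

  # step tracks crafted so exactly 100..199 passes
  conf <- rep(30, n); conf[100:199] <- 90
  ent <- rep(0.9, n); ent[100:199] <- 0.05
  reg <- find_well_defined_regions(conf, ent, smooth_window = 11)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(100L, 199L))
  expect_equal(reg$mean_confidence, 90)
  expect_equal(reg$mean_entropy, 0.05)

  # regions are disjoint, sorted, in bounds
  conf2 <- rep(90, n); ent2 <- rep(0, n)
  ent2[120:160] <- 1; ent2[230:280] <- 1
  reg2 <- find_well_defined_regions(conf2, ent2, smooth_window = 5)
  expect_true(all(diff(as.vector(rbind(reg2$start, reg2$end))) > 0))
  expect_true(all(reg2$start >= 1 & reg2$end <= n))

  expect_error(find_well_defined_regions(conf, ent, smooth_window = 10),
               class = "shapefold_param_error")
  expect_error(find_well_defined_regions(conf, ent[-1]),
               class = "shapefold_length_error")
})
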