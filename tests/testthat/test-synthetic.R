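test_that("generators are pure functions of their seeds", {
  s1 <- simulate_structure(80, seed = 3)
  s2 <- simulate_structure(80, seed = 3)
  expect_identical(attr(s1, "sequence"), attr(s2, "sequence"))
  expect_identical(s1$partner, s2$partner)
  expect_identical(attr(s1, "perturbation"), attr(s2, "perturbation"))

  p1 <- simulate_reactivities(s1, "SHAPE", seed = 4)
  p2 <- simulate_reactivities(s1, "SHAPE", seed = 4)
  expect_identical(p1$reactivity, p2$reactivity)

  a1 <- simulate_homologs(attr(s1, "sequence"), s1, n_seqs = 10, seed = 5)
  a2 <- simulate_homologs(attr(s1, "sequence"), s1, n_seqs = 10, seed = 5)
  expect_identical(a1$sequences, a2$sequences)

  # the RNG state of the session is left untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_structure(60, seed = 9))
  expect_identical(before, .Random.seed)
})

test_that("simulated structures satisfy the contract", {
  for (seed in 1:5) {
    s <- simulate_structure(100, seed = seed)
    expect_silent(validate_structure(s))
    expect_gte(structure_stats(s)$percent_paired, 30)
  }
  expect_error(simulate_structure(20), "length")
})

test_that("simulated reactivities separate structural classes", {
  gt <- simulate_structure(300, seed = 7)
  prof <- simulate_reactivities(gt, "SHAPE", sim_params(dropout = 0),
                                seed = 17)
  expect_false(anyNA(prof$reactivity))
  paired <- !is.na(gt$partner)
  expect_gt(mean(prof$reactivity[!paired]),
            mean(prof$reactivity[paired]))

  # dropout produces no-data at the requested rate, roughly
  prof2 <- simulate_reactivities(gt, "SHAPE",
                                 sim_params(dropout = 0.2), seed = 18)
  expect_gt(sum(is.na(prof2$reactivity)), 20)

  dms <- simulate_reactivities(gt, "DMS", seed = 19)
  expect_true(all(is.na(dms$reactivity[dms$base %in% c("G", "U")])))
})

test_that("fragments share the latent stream with the full-length probe", {
  gt <- simulate_structure(200, seed = 10)
  seq <- attr(gt, "sequence")
  lat <- reactivity_latent(200, seed = 30)
  # zero-noise limit with the identical structure: r is exactly 1
  quiet <- sim_params(dropout = 0, noise_sd = 0)
  full <- simulate_reactivities(gt, "SHAPE", quiet, seed = 31,
                                latent = lat)
  mods <- modular_fragments(gt, min_len = 50)
  if (nrow(mods)) {
    fp <- simulate_fragment(seq, mods[1, ], quiet, seed = 32,
                            perturbation = attr(gt, "perturbation"),
                            latent = lat)
    r <- fragment_correlation(full, fp, mods[1, ])$r
    expect_equal(r, 1, tolerance = 1e-9)
  }
})

test_that("homolog alignments preserve designed compensatory pairs", {
  gt <- simulate_structure(120, seed = 11)
  seq <- attr(gt, "sequence")
  aln0 <- simulate_homologs(seq, gt, n_seqs = 8, background_rate = 0,
                            seed = 1)
  expect_true(all(aln0$sequences == seq))
  expect_equal(average_identity(aln0), 100)

  pr <- shapefold:::structure_pairs(gt)
  cv <- pr[seq_len(5), , drop = FALSE]
  aln <- simulate_homologs(seq, gt, n_seqs = 25, background_rate = 0.3,
                           covarying_pairs = cv, seed = 2)
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (r in seq_len(nrow(cv))) {
    duplexes <- vapply(aln$sequences, function(s)
      paste0(substr(s, cv[r, 1], cv[r, 1]),
             substr(s, cv[r, 2], cv[r, 2])), "")
    expect_true(all(duplexes %in% canonical))
  }
  expect_error(simulate_homologs(seq, gt, covarying_pairs = cbind(1, 2)),
               class = "shapefold_spec_error")
})
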