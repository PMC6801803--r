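toy_stockholm <- function(path) {
  writeLines(c(
    "# STOCKHOLM 1.0",
    "ref          GGGAAACCC",
    "hom1         GGGAAACCC",
    "#=GC SS_cons <<<...>>>",
    "//"), path)
  path
}

test_that("Stockholm parsing, SS_cons pairs, and roundtrip", {
  f <- withr::local_tempfile()
  toy_stockholm(f)
  aln <- read_stockholm(f)
  expect_equal(length(aln$sequences), 2L)
  expect_equal(nrow(aln$column_pairs), 3L)
  expect_equal(aln$column_pairs[, 1], c(1L, 2L, 3L))
  expect_equal(aln$column_pairs[, 2], c(9L, 8L, 7L))

  f2 <- withr::local_tempfile()
  write_stockholm(aln, f2)
  back <- read_stockholm(f2)
  expect_equal(back$sequences, aln$sequences)
  expect_equal(back$column_pairs, aln$column_pairs)

  # interleaved blocks accumulate
  f3 <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0",
               "a GGGA", "b GGGA", "",
               "a AACCC", "b AACCC",
               "#=GC SS_cons ...(.",
               "#=GC SS_cons ...)",
               "//"), f3)
  aln3 <- read_stockholm(f3)
  expect_equal(nchar(aln3$sequences[["a"]]), 9L)
  expect_equal(nrow(aln3$column_pairs), 1L)

  f4 <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0", "a GGG", "b GGGA",
               "//"), f4)
  expect_error(read_stockholm(f4), class = "shapefold_format_error")

  f5 <- withr::local_tempfile()
  writeLines(c("# STOCKHOLM 1.0", "a GGGAAACCC",
               "#=GC SS_cons <<<...>>.", "//"), f5)
  expect_error(read_stockholm(f5), class = "shapefold_format_error")
})

test_that("average identity follows the co-ungapped convention", {
  expect_equal(average_identity(structural_alignment(
    c(a = "ACGU", b = "ACGU"))), 100)
  expect_equal(average_identity(structural_alignment(
    c(a = "ACGU", b = "ACGA"))), 75)
  expect_equal(average_identity(structural_alignment(
    c(a = "AC-U", b = "ACGU"))), 100)
  # permutation invariance over sequence order
  seqs <- c(x = "ACGUAC", y = "AAGUUC", z = "ACGAAC")
  expect_equal(average_identity(structural_alignment(seqs)),
               average_identity(structural_alignment(rev(seqs))))
})

test_that("structure-to-alignment mapping shifts with reference gaps", {
  s <- rna_structure("GGGAAACCC", "(((...)))")
  aln <- structural_alignment(c(ref = "GGGAAACCC", h = "GGGAAACCC"))
  m <- map_structure_to_alignment(s, aln)
  expect_equal(m$col_i, m$ref_i)   # ungapped: identity mapping

  aln2 <- structural_alignment(c(ref = "GG-GAAACCC",
                                 h   = "GGCGAAACCC"))
  m2 <- map_structure_to_alignment(s, aln2)
  expect_equal(m2$col_i, c(1L, 2L, 4L))
  expect_equal(m2$col_j, c(10L, 9L, 8L))

  aln3 <- structural_alignment(c(ref = "GGGAAACCG", h = "GGGAAACCC"))
  expect_error(map_structure_to_alignment(s, aln3),
               class = "shapefold_aln_error")
})

test_that("mutual information: invariant columns, compensatory pairs, APC", {
  # invariant columns carry zero MI
  aln <- structural_alignment(setNames(rep("GGGAAACCC", 6),
                                       paste0("s", 1:6)))
  sc <- covariation_scores(aln, cbind(1, 9))
  expect_equal(sc$mi, 0)

  # 50/50 GC <-> AU perfectly compensatory pair: exactly 1 bit
  seqs <- c(rep("GAAAC", 10), rep("AAAAU", 10))
  names(seqs) <- paste0("s", 1:20)
  aln2 <- structural_alignment(seqs)
  sc2 <- covariation_scores(aln2, cbind(1, 5))
  expect_equal(sc2$mi, 1.0)
  expect_equal(sc2$n_eff, 20L)

  # pairs with fewer than 5 co-ungapped sequences are undefined
  gappy <- c(rep("G---C", 3), rep("GAAAC", 3))
  names(gappy) <- paste0("g", 1:6)
  sc3 <- covariation_scores(structural_alignment(gappy), cbind(2, 4))
  expect_true(is.na(sc3$mi))

  expect_error(covariation_scores(structural_alignment(
    c(a = "GAAAC", b = "GAAAC")), cbind(1, 5)),
    class = "shapefold_aln_error")
})

test_that("permutation null separates compensatory pairs from shuffles", {
  gt <- simulate_structure(100, seed = 12)
  pr <- shapefold:::structure_pairs(gt)
  cv <- pr[seq_len(6), , drop = FALSE]
  aln <- simulate_homologs(attr(gt, "sequence"), gt, n_seqs = 40,
                           background_rate = 0.25, covarying_pairs = cv,
                           seed = 22)
  cov <- covariation_significance(aln, cv, n_perm = 200, seed = 5)
  expect_true(all(cov$significant))
  # same seed -> identical q values; different seed -> same calls
  cov2 <- covariation_significance(aln, cv, n_perm = 200, seed = 5)
  expect_identical(cov$q, cov2$q)

  # invariant columns are never significant
  inv <- structural_alignment(setNames(rep("GGGGAAAACCCC", 8),
                                       paste0("s", 1:8)))
  cinv <- covariation_significance(inv, cbind(c(1, 2), c(12, 11)),
                                   n_perm = 200, seed = 3)
  expect_true(all(cinv$p > 0.9))
  expect_false(any(cinv$significant))

  expect_warning(covariation_significance(inv, cbind(1, 12), n_perm = 50,
                                          seed = 1),
                 class = "shapefold_param_warning")

  # shuffling one column of the compensatory alignment kills the signal
  seqs <- c(rep("GAAAC", 10), rep("AAAAU", 10))
  names(seqs) <- paste0("s", 1:20)
  aln2 <- structural_alignment(seqs)
  obs <- covariation_scores(aln2, cbind(1, 5))$mi
  set.seed(99)
  null_mi <- replicate(50, {
    perm <- sample(20)
    shuf <- vapply(seq_along(seqs), function(i) {
      x <- strsplit(seqs[[i]], "")[[1]]
      x[1] <- substr(seqs[[perm[i]]], 1, 1)
      paste(x, collapse = "")
    }, "")
    names(shuf) <- names(seqs)
    covariation_scores(structural_alignment(shuf), cbind(1, 5))$mi
  })
  expect_lt(mean(null_mi), obs)
})
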