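test_that("pseudo-energy term follows the Deigan form", {
  mod <- energy_model()
  expect_equal(pseudo_energy(0, mod), -0.8)
  expect_equal(pseudo_energy(NA, mod), 0)
  expect_equal(pseudo_energy(exp(1) - 1, mod), 2.6 - 0.8)
  expect_equal(pseudo_energy(c(0, NA), mod), c(-0.8, 0))
  expect_error(pseudo_energy(-0.1, mod), class = "shapefold_value_error")
})

test_that("fold_mfe handles degenerate sequences", {
  s <- fold_mfe("AAAAAA")
  expect_true(all(is.na(s$partner)))
  expect_equal(attr(s, "energy"), 0)
  expect_true(all(is.na(fold_mfe("GAAC")$partner)))  # j - i >= 4 impossible
  expect_error(fold_mfe("GANC"), class = "shapefold_sequence_error")
})

test_that("MFE equals the exhaustive minimum, with and without profiles", {
  mod <- energy_model()
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(9:14, 1)
    seq <- random_rna(n)
    g <- if (rep %% 2 == 0) runif(n, -1, 2) else NULL
    enum <- enumerate_structures(seq, mod, profile = g)
    s <- fold_mfe(seq, g, mod)
    expect_equal(attr(s, "energy"), min(enum$energy), tolerance = 1e-12)
    # DP structure rescored from scratch gives the same energy
    expect_equal(structure_energy(s, g, mod), attr(s, "energy"),
                 tolerance = 1e-9)
  }
})

test_that("enumeration oracle matches the nested-pairing recurrence", {
  # count nested structures (hairpin >= 3, canonical pairs) independently
  count_structs <- function(seq) {
    base <- strsplit(seq, "")[[1]]
    can <- function(i, j) shapefold:::.pair_type_table[base[i], base[j]] > 0
    cnt <- function(i, j) {
      if (j - i < 4) return(1)
      total <- cnt(i, j - 1)
      for (k in i:(j - 4)) if (can(k, j))
        total <- total + (if (k > i) cnt(i, k - 1) else 1) * cnt(k + 1, j - 1)
      total
    }
    cnt(1, nchar(seq))
  }
  for (seq in c("GGAAACC", "GAAAC", "GGGGAAAACCCC", "AAAAA")) {
    expect_equal(nrow(enumerate_structures(seq)), count_structs(seq))
  }
  expect_equal(nrow(enumerate_structures("AAAAA")), 1L)
  expect_equal(nrow(enumerate_structures("GAAAC")), 2L)
  expect_error(enumerate_structures(strrep("A", 21)),
               class = "shapefold_size_error")
})

test_that("suboptimal ensemble is complete, distinct and energy-sorted", {
  mod <- energy_model()
  sub <- fold_suboptimal("GAAAC", window = 50, max_models = 10)
  expect_equal(nrow(sub), 2L)
  expect_setequal(sub$dotbracket, c(".....", "(...)"))

  set.seed(33)
  for (rep in 1:6) {
    seq <- random_rna(sample(10:14, 1))
    g <- if (rep %% 2 == 0) runif(nchar(seq), -1, 2) else NULL
    win <- 6
    sub <- fold_suboptimal(seq, g, mod, max_models = 500, window = win)
    enum <- enumerate_structures(seq, mod, profile = g)
    keep <- enum[enum$energy <= min(enum$energy) + win + 1e-9, ]
    expect_equal(sort(sub$dotbracket), sort(keep$dotbracket))
    expect_false(any(duplicated(sub$dotbracket)))
    expect_false(is.unsorted(sub$energy))
    # reported energies match from-scratch rescoring
    rescored <- purrr::map_dbl(sub$structure, structure_energy,
                               profile = g, model = mod)
    expect_equal(rescored, sub$energy, tolerance = 1e-9)
    # first element is the deterministic MFE structure
    expect_equal(sub$dotbracket[1], dot_bracket(fold_mfe(seq, g, mod)))
  }

  # window 0 with a unique MFE keeps only the MFE structure
  sub0 <- fold_suboptimal("GGGGAAAACCCC", window = 0)
  expect_equal(nrow(sub0), 1L)
})

test_that("pair probabilities match enumeration Boltzmann averages", {
  mod <- energy_model()
  expect_true(all(unclass(partition_function("AAAAAA")) == 0))
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(9:14, 1)
    seq <- random_rna(n)
    g <- if (rep %% 2 == 0) runif(n, -1, 2) else NULL
    P <- partition_function(seq, g, mod)
    enum <- enumerate_structures(seq, mod, profile = g)
    Pe <- enumeration_pair_probs(enum, n, mod$RT)
    expect_lt(max(abs(unclass(P) - Pe)), 1e-6)
    expect_true(all(rowSums(unclass(P)) <= 1 + 1e-9))
  }
})

test_that("raising a reactivity never increases pairing probability", {
  mod <- energy_model()
  seq <- "GGGGAAAACCCC"
  n <- nchar(seq)
  for (k in c(2, 3, 10)) {
    prev <- Inf
    for (r in c(0, 0.5, 1, 2, 4)) {
      reac <- rep(0.2, n)
      reac[k] <- r
      prof <- reactivity_profile(seq, reac)
      P <- partition_function(seq, prof, mod)
      p_paired <- sum(unclass(P)[k, ])
      expect_lte(p_paired, prev + 1e-9)
      prev <- p_paired
    }
  }
})
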