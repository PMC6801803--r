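test_that("fragment correlation recovers identity and order sensitivity", {
  set.seed(9)
  full <- reactivity_profile(random_rna(120), rgamma(120, 2))
  spec <- fragment_spec("F", 31, 90, strict = FALSE)
  slice <- full$reactivity[31:90]
  frag <- reactivity_profile(paste(full$base[31:90], collapse = ""), slice)
  expect_equal(fragment_correlation(full, frag, spec)$r, 1.0)

  rev_frag <- reactivity_profile(paste(full$base[31:90], collapse = ""),
                                 rev(slice))
  expect_lt(fragment_correlation(full, rev_frag, spec)$r, 1)

  short <- reactivity_profile("GAU", c(1, 2, 3))
  expect_error(fragment_correlation(full, short, spec),
               class = "shapefold_spec_error")
  expect_error(fragment_spec("x", 10, 5),
               class = "shapefold_spec_error")
  expect_error(fragment_spec("x", 1, 30), class = "shapefold_spec_error")
})

test_that("independence threshold separates observed correlation classes", {
  # correlations in the dependent band stay below, independent band above
  expect_false(is_independent_subdomain(0.31))
  expect_false(is_independent_subdomain(0.63))
  expect_false(is_independent_subdomain(0.70))
  expect_true(is_independent_subdomain(0.93))
  expect_true(is_independent_subdomain(0.89))
  expect_true(is_independent_subdomain(0.85))   # boundary convention
})

test_that("external pair fraction counts crossing pairs", {
  # all pairs inside the fragment
  s <- rna_structure("AGGGAAACCCAAA", ".(((...)))...")
  expect_equal(external_pair_fraction(s, fragment_spec("a", 1, 12,
                                                       strict = FALSE)), 0)
  # hairpin straddling the boundary: every touching pair crosses
  expect_equal(external_pair_fraction(s, fragment_spec("b", 1, 5,
                                                       strict = FALSE)), 1)
  # 3 internal + 1 crossing pair touching the region
  db <- "((((....))))...."
  sq <- "GGGGAAAACCCCAAAA"
  s2 <- rna_structure(sq, db)
  # region 1..11 contains pairs (2,11),(3,10),(4,9) fully, (1,12) crosses
  expect_equal(external_pair_fraction(
    s2, fragment_spec("c", 1, 11, strict = FALSE)), 0.25)
  # no pair touches the region at all
  expect_equal(external_pair_fraction(
    s2, fragment_spec("d", 13, 16, strict = FALSE)), 0)
})

test_that("model selection eliminates fragment-inconsistent candidates", {
  sq <- "GGGGAAAACCCCAAGGGGAAAACCCC"
  local_model <- rna_structure(sq, "((((....))))..((((....))))")
  # long-range decoy pairing the two ends together
  decoy <- {
    p <- rep(NA_integer_, 26)
    p[c(1, 2, 3, 4)] <- c(26, 25, 24, 23)
    p[c(26, 25, 24, 23)] <- c(1, 2, 3, 4)
    rna_structure(sq, partner = p)
  }
  attr(local_model, "energy") <- -10
  attr(decoy, "energy") <- -12
  frags <- dplyr::bind_rows(
    tibble::tibble(name = "left", start = 1, end = 13, r = 0.95))
  sel <- select_model(list(local_model, decoy), frags)
  expect_true(sel$consistent[1])
  expect_false(sel$consistent[2])
  expect_equal(sel$rank[1], 1L)
  expect_true(is.na(sel$rank[2]))
  expect_identical(dot_bracket(selected_structure(sel)),
                   dot_bracket(local_model))

  # tolerance 1 never eliminates anyone
  sel2 <- select_model(list(local_model, decoy), frags, tolerance = 1)
  expect_true(all(sel2$consistent))
  expect_equal(sel2$rank, c(2L, 1L))   # ranked by energy

  # a dependent fragment imposes no constraint
  frags_dep <- tibble::tibble(name = "left", start = 1, end = 13, r = 0.4)
  sel3 <- select_model(list(local_model, decoy), frags_dep)
  expect_true(all(sel3$consistent))

  # single candidate, no fragments: rank 1 trivially
  sel4 <- select_model(list(local_model), frags[0, ])
  expect_equal(sel4$rank, 1L)

  # empty survivor set: everything flagged, warning raised
  frags_both <- tibble::tibble(name = "mid", start = 8, end = 20, r = 0.95)
  expect_warning(sel5 <- select_model(list(local_model), frags_both),
                 class = "shapefold_none_consistent")
  expect_true(attr(sel5, "none_consistent"))
  expect_equal(sel5$rank, 1L)
})

test_that("selection is stable under candidate permutation", {
  set.seed(21)
  gt <- simulate_structure(150, seed = 2)
  cands <- fold_suboptimal(attr(gt, "sequence"), max_models = 6,
                           window = 8)
  frags <- modular_fragments(gt, min_len = 40)
  frags$r <- 0.95
  sel <- select_model(cands, frags)
  perm <- sample(nrow(cands))
  sel_p <- select_model(cands$structure[perm], frags)
  expect_equal(sel$consistent[perm], sel_p$consistent)
  expect_equal(sel$rank[perm], sel_p$rank)
})

test_that("fragment specs roundtrip through CSV and JSON", {
  specs <- dplyr::bind_rows(fragment_spec("F1", 1, 340),
                            fragment_spec("F5", 472, 683))
  f1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(specs, f1, row.names = FALSE)
  expect_equal(as.data.frame(read_fragment_specs(f1)),
               as.data.frame(specs))
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(specs, f2)
  expect_equal(as.data.frame(read_fragment_specs(f2)),
               as.data.frame(specs))
})
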