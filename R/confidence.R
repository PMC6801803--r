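# Per-nucleotide confidence by jackknife resampling of the reactivity
# data, Shannon entropy of pairing-partner probabilities, and detection of
# well-defined (high-confidence, low-entropy) regions.

# Evaluate code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Jackknife resampling confidence per nucleotide
#'
#' Generates `n_reps` mock datasets by setting a random
#' `floor(drop_frac * n_defined)`-subset of the *defined* reactivities to
#' no data, refolds each with [fold_mfe()], and scores every nucleotide by
#' how often the refolded structure agrees with the reference. Agreement
#' is exact-partner match by default (`mode = "partner"`: unpaired counts
#' as partner "none"); `mode = "status"` relaxes this to paired/unpaired
#' status only.
#'
#' @inheritParams fold_mfe
#' @param reference Reference [rna_structure()] to score against.
#' @param n_reps Number of mock datasets.
#' @param drop_frac Fraction of defined reactivities removed per mock, in
#'   `[0, 1)`.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param mode Agreement metric, `"partner"` or `"status"`.
#' @return A tibble of class `confidence_profile` with `position`, `base`
#'   and `confidence` (percent in `[0, 100]`); parameters kept as
#'   attributes.
#' @export
jackknife_confidence <- function(sequence, profile, reference,
                                 model = energy_model(), n_reps = 100,
                                 drop_frac = 0.10, seed = 1,
                                 mode = c("partner", "status")) {
  mode <- match.arg(mode)
  if (drop_frac < 0 || drop_frac >= 1)
    abort("drop_frac must be in [0, 1)", class = "shapefold_param_error")
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (nrow(reference) != n)
    abort("reference structure length does not match sequence",
          class = "shapefold_length_error")
  stopifnot(inherits(profile, "reactivity_profile"), nrow(profile) == n)
  defined <- which(!is.na(profile$reactivity))
  n_drop <- floor(drop_frac * length(defined))
  ref_partner <- ifelse(is.na(reference$partner), 0L, reference$partner)
  agree <- integer(n)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      mock <- profile
      if (n_drop > 0)
        mock$reactivity[sample(defined, n_drop)] <- NA
      refold <- fold_mfe(sequence, mock, model)
      got <- ifelse(is.na(refold$partner), 0L, refold$partner)
      hit <- if (mode == "partner") got == ref_partner
      else (got > 0L) == (ref_partner > 0L)
      agree <- agree + hit
    }
  })
  out <- tibble(position = seq_len(n),
                base = strsplit(sequence, "")[[1]],
                confidence = 100 * agree / n_reps)
  attr(out, "n_replicates") <- as.integer(n_reps)
  attr(out, "drop_fraction") <- drop_frac
  attr(out, "seed") <- as.integer(seed)
  attr(out, "mode") <- mode
  class(out) <- c("confidence_profile", class(out))
  out
}

#' Shannon entropy of pairing-partner probabilities
#'
#' Per-nucleotide conformational entropy
#' `S(i) = -sum_j P(i,j) log10 P(i,j)` over that nucleotide's pairing
#' partners (terms with `P = 0` contribute 0; the unpaired mass is not a
#' term). Base-10 logarithms, the convention under which the usual
#' "low entropy < 0.2" threshold is interpreted.
#'
#' @param P A `pair_probability_matrix` from [partition_function()].
#' @return A tibble of class `entropy_profile` with `position`, `entropy`.
#' @examples
#' P <- partition_function("GGGGAAAACCCC")
#' shannon_entropy(P)
#' @export
shannon_entropy <- function(P) {
  M <- unclass(P)
  terms <- ifelse(M > 0, -M * log10(M), 0)
  diag(terms) <- 0
  out <- tibble(position = seq_len(nrow(M)), entropy = rowSums(terms))
  class(out) <- c("entropy_profile", class(out))
  out
}

#' Detect well-defined structural regions
#'
#' Median-smooths the confidence and entropy tracks with a centered
#' window, then reports maximal runs where smoothed entropy stays at or
#' below `ent_max` and smoothed confidence at or above `conf_min`, of
#' length at least `min_len`. Per-region means are computed on the
#' unsmoothed tracks.
#'
#' @param conf A `confidence_profile` (or numeric percent vector).
#' @param ent An `entropy_profile` (or numeric vector), same length.
#' @param conf_min Minimum smoothed confidence (percent).
#' @param ent_max Maximum smoothed Shannon entropy.
#' @param min_len Minimum region length (nt).
#' @param smooth_window Odd centered window width for the running median;
#'   capped at the track length.
#' @return Tibble with `start`, `end`, `length`, `mean_confidence`,
#'   `mean_entropy`, sorted and disjoint.
#' @export
find_well_defined_regions <- function(conf, ent, conf_min = 70,
                                      ent_max = 0.2, min_len = 40,
                                      smooth_window = 51) {
  cv <- if (is.data.frame(conf)) conf$confidence else as.numeric(conf)
  ev <- if (is.data.frame(ent)) ent$entropy else as.numeric(ent)
  if (length(cv) != length(ev))
    abort("confidence and entropy tracks differ in length",
          class = "shapefold_length_error")
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    abort("smooth_window must be odd and >= 1",
          class = "shapefold_param_error")
  n <- length(cv)
  k <- min(smooth_window, if (n %% 2 == 1) n else n - 1)
  cs <- if (k >= 3) as.numeric(runmed(cv, k)) else cv
  es <- if (k >= 3) as.numeric(runmed(ev, k)) else ev
  ok <- es <= ent_max & cs >= conf_min
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_len)
  purrr::map_dfr(keep, function(i)
    tibble(start = starts[i], end = ends[i],
           length = runs$lengths[i],
           mean_confidence = mean(cv[starts[i]:ends[i]]),
           mean_entropy = mean(ev[starts[i]:ends[i]])))
}

#' Per-nucleotide track table
#'
#' Joins reactivity, confidence and entropy into the per-nucleotide CSV
#' track emitted by the pipeline.
#'
#' @param profile A [reactivity_profile()].
#' @param conf A `confidence_profile`.
#' @param ent An `entropy_profile`.
#' @param structure Optional [rna_structure()] contributing `partner`.
#' @return A tibble with one row per nucleotide.
#' @export
nucleotide_track <- function(profile, conf, ent, structure = NULL) {
  out <- tibble(position = seq_len(nrow(profile)),
                base = profile$base,
                reactivity = profile$reactivity,
                confidence = conf$confidence,
                entropy = ent$entropy)
  if (!is.null(structure)) out$partner <- structure$partner
  out
}
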