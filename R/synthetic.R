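# Synthetic probing data: ground-truth structures, reagent-faithful SHAPE
# and DMS reactivity profiles, independently refolded fragments, and
# homolog alignments carrying compensatory mutations. Everything is a
# pure function of (parameters, seed).

#' Simulation parameters for synthetic reactivities
#'
#' Each nucleotide carries a *latent* intrinsic reactivity drawn from a
#' gamma distribution chosen by its structural class (the distribution
#' family used throughout the SHAPE likelihood literature): paired and
#' unpaired classes have separate shape/mean, and helix-terminus
#' nucleotides express the unpaired distribution with probability
#' `terminus_unpaired_prob` (terminal pairs breathe). Every probing
#' experiment then observes the latent value under multiplicative
#' log-normal measurement noise (`noise_sd` on the log scale) and a
#' `dropout` fraction of no-data positions - so two probes of the same
#' fold correlate strongly (as real replicates do) while positions whose
#' pairing state changes decorrelate. Defaults give overlapping
#' paired/unpaired classes: realistic difficulty rather than a separable
#' toy.
#'
#' @param paired_shape,paired_mean Gamma shape/mean for paired positions.
#' @param unpaired_shape,unpaired_mean Gamma shape/mean for unpaired
#'   positions.
#' @param terminus_unpaired_prob Probability that a helix-terminus
#'   nucleotide expresses the unpaired distribution.
#' @param dropout No-data probability per position and experiment.
#' @param noise_sd Log-scale s.d. of the per-experiment measurement
#'   noise.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(paired_shape = 1.0, paired_mean = 0.12,
                       unpaired_shape = 1.5, unpaired_mean = 0.90,
                       terminus_unpaired_prob = 0.5, dropout = 0.05,
                       noise_sd = 0.25) {
  stopifnot(paired_mean > 0, unpaired_mean > 0,
            paired_mean < unpaired_mean,
            dropout >= 0, dropout < 1, noise_sd >= 0,
            terminus_unpaired_prob >= 0, terminus_unpaired_prob <= 1)
  structure(list(paired_shape = paired_shape, paired_mean = paired_mean,
                 unpaired_shape = unpaired_shape,
                 unpaired_mean = unpaired_mean,
                 terminus_unpaired_prob = terminus_unpaired_prob,
                 dropout = dropout, noise_sd = noise_sd),
            class = "sim_params")
}

#' Latent per-nucleotide reactivity stream
#'
#' The position-level randomness shared by every probe of the same RNA:
#' class-quantile uniforms for the paired and unpaired distributions and
#' the helix-terminus breathing indicator. Probing the full-length RNA
#' and its fragments with the same latent stream (but different
#' measurement seeds) reproduces the replicate-to-replicate correlation
#' structure the 3S experiment relies on.
#'
#' @param n RNA length.
#' @param seed Integer seed.
#' @return A list of three length-`n` uniform vectors.
#' @export
reactivity_latent <- function(n, seed = 1) {
  with_seed(seed, list(u_paired = runif(n), u_unpaired = runif(n),
                       u_flip = runif(n)))
}

#' Simulate a ground-truth structure
#'
#' Draws a random sequence (GC fraction `gc`) and folds it under the
#' nearest-neighbor model *plus* a random per-nucleotide pseudo-energy
#' perturbation (s.d. `perturb_sd`, kcal/mol, applied like SHAPE terms).
#' The perturbation emulates the tertiary and cellular effects that real
#' structures experience but the thermodynamic model does not capture, so
#' the unconstrained MFE fold recovers the ground truth only partially -
#' as in real prediction benchmarks - while probing data simulated *from*
#' the ground truth restores accuracy. Resamples (bounded retries) until
#' at least `min_paired` percent of nucleotides pair.
#'
#' @param length Sequence length (>= 30).
#' @param seed Integer seed; the result is a pure function of the
#'   arguments.
#' @param gc GC fraction of the random sequence.
#' @param perturb_sd Standard deviation of the ground-truth pseudo-energy
#'   perturbation (kcal/mol); 0 makes the ground truth the plain MFE.
#' @param min_paired Minimum percent of paired nucleotides.
#' @param max_tries Resampling bound.
#' @param model An [energy_model()].
#' @return An [rna_structure()]; the perturbation vector is kept in
#'   `attr(, "perturbation")`.
#' @export
simulate_structure <- function(length, seed = 1, gc = 0.5,
                               perturb_sd = 0.2, min_paired = 30,
                               max_tries = 20, model = energy_model()) {
  stopifnot(length >= 30)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      sequence <- paste(sample(names(probs), length, TRUE, probs),
                        collapse = "")
      eps <- rnorm(length, 0, perturb_sd)
      s <- fold_mfe(sequence, eps, model)
      if (100 * sum(!is.na(s$partner)) / length >= min_paired) {
        attr(s, "perturbation") <- eps
        attr(s, "seed") <- as.integer(seed)
        return(s)
      }
    }
    abort("could not reach the paired-fraction floor; try another seed",
          class = "shapefold_seed_error")
  })
}

#' Simulate reactivities from a known structure
#'
#' Expresses each nucleotide's latent reactivity according to its
#' structural class in `structure` (paired / unpaired / breathing helix
#' terminus), applies multiplicative measurement noise and dropout, and
#' passes the result through the 2%/8% normalization, like real data.
#' DMS profiles carry no data at G/U.
#'
#' @param structure Ground-truth [rna_structure()].
#' @param reagent `"SHAPE"` or `"DMS"`.
#' @param params A [sim_params()].
#' @param seed Integer seed for the measurement (noise + dropout; also
#'   the latent stream when `latent` is not supplied).
#' @param rna_id Profile id.
#' @param latent Optional [reactivity_latent()] stream of matching
#'   length, shared across probes of the same RNA.
#' @return A [reactivity_profile()].
#' @export
simulate_reactivities <- function(structure, reagent = c("SHAPE", "DMS"),
                                  params = sim_params(), seed = 1,
                                  rna_id = "sim", latent = NULL) {
  reagent <- match.arg(reagent)
  n <- nrow(structure)
  if (is.null(latent)) latent <- reactivity_latent(n, seed)
  if (length(latent$u_paired) != n)
    abort("latent stream length does not match the structure",
          class = "shapefold_length_error")
  paired <- !is.na(structure$partner)
  lp <- stats::qgamma(latent$u_paired, shape = params$paired_shape,
                      rate = params$paired_shape / params$paired_mean)
  lu <- stats::qgamma(latent$u_unpaired, shape = params$unpaired_shape,
                      rate = params$unpaired_shape / params$unpaired_mean)
  r <- ifelse(paired, lp, lu)
  term <- helix_terminus_positions(structure)
  if (length(term)) {
    flip <- term[latent$u_flip[term] < params$terminus_unpaired_prob]
    r[flip] <- lu[flip]
  }
  with_seed(seed, {
    if (params$noise_sd > 0)
      r <- r * exp(rnorm(n, 0, params$noise_sd))
    if (params$dropout > 0)
      r[runif(n) < params$dropout] <- NA
    prof <- reactivity_profile(attr(structure, "sequence"), r,
                               reagent = reagent, rna_id = rna_id)
    normalize_reactivities(prof)
  })
}

#' Simulate probing of an isolated fragment
#'
#' Refolds the fragment subsequence in isolation with [fold_mfe()] (under
#' the fragment's slice of the ground-truth perturbation, when given) and
#' simulates reactivities from the fragment's own structure - so modular
#' fragments reproduce the full-length pattern and boundary-breaking
#' fragments do not.
#'
#' @param full_sequence Full-length sequence.
#' @param spec A [fragment_spec()].
#' @param params A [sim_params()].
#' @param seed Integer seed for the fragment's measurement noise.
#' @param model An [energy_model()].
#' @param perturbation Optional full-length pseudo-energy perturbation
#'   (from [simulate_structure()]); its slice directs the fragment
#'   refold.
#' @param latent Optional full-length [reactivity_latent()] stream; its
#'   slice is shared with the full-length probe, as when fragment and
#'   full-length are probed side by side.
#' @return A [reactivity_profile()] with `offset = spec$start`.
#' @export
simulate_fragment <- function(full_sequence, spec, params = sim_params(),
                              seed = 1, model = energy_model(),
                              perturbation = NULL, latent = NULL) {
  spec <- as_fragment_tbl(spec)
  full_sequence <- normalize_rna(full_sequence)
  if (spec$end > nchar(full_sequence))
    abort("spec outside the sequence", class = "shapefold_spec_error")
  idx <- spec$start:spec$end
  sub <- substr(full_sequence, spec$start, spec$end)
  eps <- if (is.null(perturbation)) NULL else perturbation[idx]
  s <- fold_mfe(sub, eps, model)
  sub_latent <- if (is.null(latent)) NULL
  else lapply(latent, `[`, idx)
  prof <- simulate_reactivities(s, "SHAPE", params, seed = seed,
                                rna_id = spec$name, latent = sub_latent)
  attr(prof, "offset") <- spec$start
  prof$position <- prof$position + spec$start - 1L
  prof
}

#' Simulate a homolog alignment with compensatory pairs
#'
#' Each homolog mutates positions independently at `background_rate`
#' (uniform choice among the other three bases); positions belonging to
#' `covarying_pairs` instead mutate jointly - with probability
#' `background_rate` the pair is replaced by a random canonical pair
#' type, so complementarity is preserved in every homolog. The alignment
#' is ungapped and includes the reference as its first row; consensus
#' pairs are the ground-truth pairs.
#'
#' @param sequence Reference sequence.
#' @param structure Ground-truth [rna_structure()].
#' @param n_seqs Number of homologs (reference included).
#' @param background_rate Per-position substitution probability, < 0.5.
#' @param covarying_pairs 2-column matrix of designed compensatory pairs
#'   (subset of the structure's pairs).
#' @param seed Integer seed.
#' @return A [structural_alignment()].
#' @export
simulate_homologs <- function(sequence, structure, n_seqs = 50,
                              background_rate = 0.2,
                              covarying_pairs = NULL, seed = 1) {
  stopifnot(background_rate >= 0, background_rate < 0.5)
  sequence <- normalize_rna(sequence)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  pr <- structure_pairs(structure)
  if (!is.null(covarying_pairs)) {
    covarying_pairs <- as.matrix(covarying_pairs)
    have <- paste(pr[, 1], pr[, 2])
    want <- paste(pmin(covarying_pairs[, 1], covarying_pairs[, 2]),
                  pmax(covarying_pairs[, 1], covarying_pairs[, 2]))
    if (!all(want %in% have))
      abort("covarying_pairs must be a subset of the structure's pairs",
            class = "shapefold_spec_error")
  } else covarying_pairs <- matrix(integer(0), ncol = 2)
  cov_pos <- as.integer(covarying_pairs)
  pair_strings <- c("AU", "UA", "GC", "CG", "GU", "UG")
  seqs <- character(n_seqs)
  seqs[1] <- sequence
  with_seed(seed, {
    for (h in seq_len(n_seqs - 1)) {
      mut <- chars
      free <- setdiff(seq_len(n), cov_pos)
      hit <- free[runif(length(free)) < background_rate]
      if (length(hit))
        mut[hit] <- vapply(mut[hit], function(b)
          sample(setdiff(BASES, b), 1), "")
      if (nrow(covarying_pairs))
        for (r in seq_len(nrow(covarying_pairs))) {
          if (runif(1) < background_rate) {
            pp <- strsplit(sample(pair_strings, 1), "")[[1]]
            mut[covarying_pairs[r, 1]] <- pp[1]
            mut[covarying_pairs[r, 2]] <- pp[2]
          }
        }
      seqs[h + 1] <- paste(mut, collapse = "")
    }
  })
  names(seqs) <- c("ref", paste0("hom", seq_len(n_seqs - 1)))
  structural_alignment(seqs, ref = "ref", column_pairs = pr)
}

#' Fragment specs from a structure's modular architecture
#'
#' `modular_fragments()` returns one spec per exterior-level subtree of
#' at least `min_len` nt - intervals no base pair crosses, i.e. the
#' independently folding subdomains of the ground truth.
#' `bisecting_fragment()` returns a spec that cuts through the largest
#' exterior-level subtree, deliberately severing its long-range pairs
#' (the negative control of the 3S simulation).
#'
#' @param structure An [rna_structure()].
#' @param min_len Minimum fragment length.
#' @return A tibble of fragment specs.
#' @export
modular_fragments <- function(structure, min_len = 50) {
  ch <- loop_children(structure$partner, 0L, nrow(structure) + 1L)
  keep <- which(ch[, 2] - ch[, 1] + 1 >= min_len)
  purrr::map_dfr(seq_along(keep), function(k)
    fragment_spec(paste0("D", k), ch[keep[k], 1], ch[keep[k], 2],
                  strict = FALSE))
}

#' @rdname modular_fragments
#' @export
bisecting_fragment <- function(structure, min_len = 50) {
  ch <- loop_children(structure$partner, 0L, nrow(structure) + 1L)
  if (!nrow(ch))
    abort("structure has no exterior-level subtree",
          class = "shapefold_spec_error")
  big <- which.max(ch[, 2] - ch[, 1])
  a <- ch[big, 1]; b <- ch[big, 2]
  m <- max(a + min_len - 1L, as.integer(floor((a + b) / 2)))
  m <- min(m, b - 1L)
  fragment_spec("bisect", a, m, strict = FALSE)
}
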