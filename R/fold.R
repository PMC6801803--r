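# SHAPE-directed thermodynamic folding: MFE structure, bounded suboptimal
# ensemble, partition function / pair probabilities, and the exhaustive
# enumeration oracle used to verify the dynamic programs.

#' Minimum free energy structure
#'
#' Folds an RNA under the nearest-neighbor model, optionally directed by a
#' reactivity profile whose Deigan pseudo-energies are added once per
#' stacked nucleotide. The traceback is deterministic (ties resolved by
#' preferring unpaired, then the smallest opening position), so repeated
#' calls are bit-reproducible.
#'
#' @param sequence RNA sequence (character scalar; T is read as U).
#' @param profile Optional [reactivity_profile()] of matching length, or a
#'   numeric per-nucleotide pseudo-energy vector (`NA` treated as 0).
#' @param model An [energy_model()].
#' @return An [rna_structure()] with the free energy in `attr(, "energy")`.
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(sequence, profile = NULL, model = energy_model()) {
  sequence <- normalize_rna(sequence)
  enc <- encode_sequence(sequence)
  g <- pseudo_vector(length(enc), profile, model)
  res <- c_fold_mfe(enc, g, model_for_cpp(model))
  rna_structure(sequence, partner = res$partner, energy = res$energy,
                validate = FALSE)
}

#' Bounded suboptimal structure ensemble
#'
#' Complete suboptimal enumeration in the style of Wuchty et al.: all
#' distinct structures within `window` kcal/mol of the MFE are generated
#' in increasing energy order (best-first search over the folding grammar,
#' which produces each structure exactly once) and truncated to
#' `max_models`. The first row is always the MFE structure.
#'
#' @inheritParams fold_mfe
#' @param max_models Maximum number of candidate structures.
#' @param window Energy window above the MFE (kcal/mol); default 20% of
#'   |MFE|.
#' @param max_states Search-state cap guarding against degenerate
#'   near-tie explosions.
#' @return A tibble of class `fold_candidates` with columns `model`,
#'   `energy`, `n_pairs`, `dotbracket` and a `structure` list-column of
#'   [rna_structure()] objects.
#' @examples
#' fold_suboptimal("GGGGAAAACCCC", max_models = 5, window = 10)
#' @export
fold_suboptimal <- function(sequence, profile = NULL, model = energy_model(),
                            max_models = 20, window = NULL,
                            max_states = 5e6) {
  stopifnot(max_models >= 1)
  sequence <- normalize_rna(sequence)
  enc <- encode_sequence(sequence)
  g <- pseudo_vector(length(enc), profile, model)
  mfe <- fold_mfe(sequence, profile, model)
  if (is.null(window)) window <- 0.2 * abs(attr(mfe, "energy"))
  stopifnot(window >= 0)
  raw <- c_subopt(enc, g, model_for_cpp(model), as.integer(max_models),
                  window, max_states)
  structures <- purrr::map(raw, function(r)
    rna_structure(sequence, partner = r$partner, energy = r$energy,
                  validate = FALSE))
  # put the deterministic MFE traceback first among energy ties
  dbs <- purrr::map_chr(structures, dot_bracket)
  hit <- which(dbs == dot_bracket(mfe))
  if (length(hit) == 1 && hit != 1) {
    structures <- c(structures[hit], structures[-hit])
  } else if (!length(hit)) {
    structures <- c(list(mfe), head(structures, max_models - 1))
  }
  tibble(model = seq_along(structures),
         energy = purrr::map_dbl(structures, attr, "energy"),
         n_pairs = purrr::map_dbl(structures,
                                  ~ sum(!is.na(.x$partner)) / 2),
         dotbracket = purrr::map_chr(structures, dot_bracket),
         structure = structures) %>%
    structure(class = c("fold_candidates", class(.)))
}

#' @export
tidy.fold_candidates <- function(x, ...) {
  out <- as_tibble(x)[, c("model", "energy", "n_pairs", "dotbracket")]
  class(out) <- setdiff(class(out), "fold_candidates")
  out
}

#' Partition function and base-pair probabilities
#'
#' McCaskill inside-outside recursions at the model temperature, over the
#' same energy rules (including SHAPE pseudo-energies) as [fold_mfe()].
#' Computations are per-nucleotide rescaled so the result is finite for
#' sequences up to ~2000 nt.
#'
#' @inheritParams fold_mfe
#' @return A symmetric n x n matrix of class `pair_probability_matrix`
#'   with `P[i, j]` the equilibrium probability that i pairs with j; the
#'   sequence is kept in `attr(, "sequence")`.
#' @examples
#' P <- partition_function("GGGGAAAACCCC")
#' unpaired_probability(P)
#' @export
partition_function <- function(sequence, profile = NULL,
                               model = energy_model()) {
  sequence <- normalize_rna(sequence)
  enc <- encode_sequence(sequence)
  if (length(enc) > 2000)
    abort("partition function supported for n <= 2000",
          class = "shapefold_size_error")
  g <- pseudo_vector(length(enc), profile, model)
  P <- c_partition(enc, g, model_for_cpp(model))
  dimnames(P) <- NULL
  structure(P, sequence = sequence, class = "pair_probability_matrix")
}

#' @rdname partition_function
#' @param P A `pair_probability_matrix`.
#' @return `unpaired_probability()`: numeric vector `1 - rowSums(P)`.
#' @export
unpaired_probability <- function(P) {
  pmax(0, 1 - rowSums(unclass(P)))
}

#' @export
print.pair_probability_matrix <- function(x, ...) {
  cat("<pair_probability_matrix>  n =", nrow(x),
      " sum P =", round(sum(x) / 2, 2), "expected pairs\n")
  invisible(x)
}

#' @export
tidy.pair_probability_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x) & unclass(x) > 0, arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2],
         probability = unclass(x)[idx])
}

#' Exhaustively enumerate all nested structures
#'
#' Generates every structure satisfying the secondary-structure
#' invariants (nested canonical pairs, hairpins >= 3 nt) by direct
#' recursion, scoring each with the from-scratch loop-decomposition
#' scorer [structure_energy()]. Serves as the independent oracle for the
#' dynamic programs; refuses sequences longer than 20 nt.
#'
#' @inheritParams fold_mfe
#' @return A tibble with `energy`, `dotbracket` and a `structure`
#'   list-column, sorted by energy.
#' @examples
#' enumerate_structures("GAAAC")
#' @export
enumerate_structures <- function(sequence, model = energy_model(),
                                 profile = NULL) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n > 20)
    abort("enumeration limited to n <= 20", class = "shapefold_size_error")
  base <- strsplit(sequence, "")[[1]]
  can_pair <- function(i, j) .pair_type_table[base[i], base[j]] > 0
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i < 4) return(list(NULL))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(gen(i, j - 1), identity)
    for (k in i:(j - 4)) {
      if (!can_pair(k, j)) next
      left <- if (k > i) gen(i, k - 1) else list(NULL)
      inner <- gen(k + 1, j - 1)
      for (L in left) for (Rr in inner)
        out[[length(out) + 1]] <- rbind(L, Rr, c(k, j))
    }
    memo[[key]] <- out
    out
  }
  structs <- gen(1, n)
  g <- pseudo_vector(n, profile, model)
  rows <- purrr::map(structs, function(pr) {
    partner <- rep(NA_integer_, n)
    if (!is.null(pr)) {
      partner[pr[, 1]] <- pr[, 2]
      partner[pr[, 2]] <- pr[, 1]
    }
    s <- rna_structure(sequence, partner = partner, validate = FALSE)
    e <- structure_energy(s, g, model)
    attr(s, "energy") <- e
    tibble(energy = e, dotbracket = dot_bracket(s), structure = list(s))
  })
  bind_rows(rows) %>% arrange(.data$energy)
}
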