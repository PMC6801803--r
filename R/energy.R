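# Nearest-neighbor energy model: canonical pair stacking, loop-length
# penalties with Jacobson-Stockmayer extrapolation, linear multibranch
# penalty, and Deigan-style SHAPE pseudo-energies.

# Canonical pair types, fixed order used by every lookup table.
PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

BASES <- c("A", "C", "G", "U")

# 4x4 base -> pair-type index (0 = not pairable).
.pair_type_table <- local({
  m <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  m["C", "G"] <- 1L; m["G", "C"] <- 2L
  m["G", "U"] <- 3L; m["U", "G"] <- 4L
  m["A", "U"] <- 5L; m["U", "A"] <- 6L
  m
})

# Stacking free energies at 37 C (kcal/mol), standard published
# nearest-neighbor values over the six canonical pair types.
# Row: closing pair (i,j); column: pair (j-1, i+1) (strand-reversed inner
# pair), under which convention the table is symmetric.
.stack_table <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
  nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

# Loop-length penalties (kcal/mol), index = number of unpaired nucleotides.
.hairpin_table <- c(Inf, Inf, 5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40,
                    6.50, 6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10,
                    7.20, 7.20, 7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50,
                    7.60, 7.60, 7.70)
.bulge_table <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80,
                  4.90, 5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50,
                  5.60, 5.70, 5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00,
                  6.00, 6.00, 6.10)
.internal_table <- c(Inf, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40,
                     2.50, 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10,
                     3.20, 3.30, 3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60,
                     3.60, 3.70, 3.70)

#' Construct a nearest-neighbor RNA energy model
#'
#' Bundles the thermodynamic parameters used by [fold_mfe()],
#' [fold_suboptimal()], [partition_function()] and [structure_energy()]:
#' stacking free energies over the six canonical pair types, tabulated
#' hairpin/bulge/internal loop-length penalties (Jacobson-Stockmayer
#' extrapolated beyond 30 nt), a linear multibranch-loop penalty, and the
#' slope/intercept of the Deigan pseudo-energy term that converts SHAPE
#' reactivities into folding constraints.
#'
#' The model is deliberately simplified relative to a full Turner model:
#' terminal mismatches, dangling ends, coaxial stacking, terminal AU
#' penalties and the special small internal-loop tables are omitted. All
#' components are plug-replaceable through the arguments.
#'
#' @param temperature Folding temperature in kelvin; enters the partition
#'   function through RT.
#' @param shape_m,shape_b Slope (kcal/mol) and intercept (kcal/mol) of the
#'   SHAPE pseudo-energy `m * ln(reactivity + 1) + b`, applied per stacked
#'   nucleotide.
#' @param ml_offset,ml_branch,ml_unpaired Multibranch loop penalty:
#'   offset per loop, per-branch and per-unpaired-nucleotide terms
#'   (kcal/mol).
#' @param ninio_m,ninio_max Internal-loop asymmetry penalty slope and cap
#'   (kcal/mol).
#' @param max_loop Largest internal/bulge loop (unpaired nucleotides, both
#'   sides) searched by the dynamic programs.
#' @param stack 6x6 stacking table (kcal/mol) over `PAIR_TYPES`; rows index
#'   the closing pair (i,j), columns the strand-reversed inner pair.
#' @param hairpin,bulge,internal Length-30 penalty tables (kcal/mol).
#' @param lxc Jacobson-Stockmayer extrapolation coefficient:
#'   `penalty(n > 30) = penalty(30) + lxc * ln(n/30)`.
#' @return An object of class `energy_model`.
#' @examples
#' mod <- energy_model()
#' pseudo_energy(c(0, exp(1) - 1, NA), mod)
#' @export
energy_model <- function(temperature = 310.15,
                         shape_m = 2.6, shape_b = -0.8,
                         ml_offset = 3.4, ml_branch = 0.4, ml_unpaired = 0.0,
                         ninio_m = 0.6, ninio_max = 3.0,
                         max_loop = 30L,
                         stack = .stack_table,
                         hairpin = .hairpin_table,
                         bulge = .bulge_table,
                         internal = .internal_table,
                         lxc = 1.07856) {
  stopifnot(temperature > 0, is.matrix(stack), all(dim(stack) == c(6, 6)),
            length(hairpin) == 30, length(bulge) == 30,
            length(internal) == 30, max_loop >= 1)
  if (max(abs(stack - t(stack))) > 1e-9)
    abort("stacking table must be symmetric under strand reversal",
          class = "shapefold_model_error")
  structure(list(
    temperature = temperature,
    RT = 0.00198717 * temperature,
    shape_m = shape_m, shape_b = shape_b,
    ml_offset = ml_offset, ml_branch = ml_branch, ml_unpaired = ml_unpaired,
    ninio_m = ninio_m, ninio_max = ninio_max,
    max_loop = as.integer(max_loop),
    stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
    lxc = lxc
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>  T =", x$temperature, "K,  RT =",
      signif(x$RT, 4), "kcal/mol\n")
  cat("  SHAPE pseudo-energy: m =", x$shape_m, " b =", x$shape_b, "kcal/mol\n")
  cat("  multibranch (offset/branch/unpaired):",
      x$ml_offset, "/", x$ml_branch, "/", x$ml_unpaired, "kcal/mol\n")
  invisible(x)
}

#' SHAPE pseudo-energy of a reactivity value
#'
#' Deigan-style per-nucleotide folding bonus/penalty
#' `dG = m * ln(r + 1) + b`, added once for each stack a nucleotide
#' participates in. Missing reactivities (`NA`, "no data") contribute 0.
#'
#' @param reactivity Numeric vector of normalized reactivities (`NA` for
#'   no data).
#' @param model An [energy_model()].
#' @return Numeric vector of pseudo-energies (kcal/mol).
#' @export
pseudo_energy <- function(reactivity, model = energy_model()) {
  if (any(reactivity < 0, na.rm = TRUE))
    abort("reactivities must be >= 0 or NA", class = "shapefold_value_error")
  out <- model$shape_m * log(reactivity + 1) + model$shape_b
  out[is.na(reactivity)] <- 0
  out
}

# Loop-length penalty with Jacobson-Stockmayer extrapolation past 30.
loop_penalty <- function(model, type = c("hairpin", "bulge", "internal"),
                         size) {
  type <- match.arg(type)
  tab <- model[[type]]
  ifelse(size < 1, Inf,
         ifelse(size <= 30, tab[pmax(size, 1)],
                tab[30] + model$lxc * log(size / 30)))
}

# Integer encoding used by the C++ kernels: A=0, C=1, G=2, U=3.
encode_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "T"] <- "U"
  idx <- match(chars, BASES)
  if (anyNA(idx))
    abort(paste0("sequence contains characters outside ACGUT: ",
                 paste(unique(chars[is.na(idx)]), collapse = ", ")),
          class = "shapefold_sequence_error")
  idx - 1L
}

pair_type <- function(a, b) .pair_type_table[a, b]

# Flat parameter list handed to the C++ kernels.
model_for_cpp <- function(model) {
  big <- 1e9
  f <- function(v) { v[!is.finite(v)] <- big; v }
  list(stack = model$stack,
       hairpin = f(model$hairpin), bulge = f(model$bulge),
       internal = f(model$internal), lxc = model$lxc,
       ml_a = model$ml_offset, ml_b = model$ml_branch,
       ml_c = model$ml_unpaired,
       ninio_m = model$ninio_m, ninio_max = model$ninio_max,
       max_loop = as.integer(model$max_loop), RT = model$RT)
}

# Per-nucleotide pseudo-energy vector for folding: from a reactivity
# profile (via the Deigan term) or an explicit numeric vector.
pseudo_vector <- function(n, profile = NULL, model = energy_model()) {
  if (is.null(profile)) return(numeric(n))
  if (is.numeric(profile)) {
    stopifnot(length(profile) == n)
    g <- profile
    g[is.na(g)] <- 0
    return(g)
  }
  stopifnot(inherits(profile, "reactivity_profile"))
  if (nrow(profile) != n)
    abort("profile length does not match sequence length",
          class = "shapefold_length_error")
  pseudo_energy(profile$reactivity, model)
}
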