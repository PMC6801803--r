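# Secondary structure container and structural bookkeeping: nested pair
# tables, dot-bracket / CT interchange, element decomposition (helices,
# loops, junctions) and a from-scratch loop-decomposition energy scorer.

#' Build a secondary structure object
#'
#' A secondary structure is a tibble with one row per nucleotide
#' (`position`, `base`, `partner`; `partner` is `NA` for unpaired) plus a
#' `sequence` attribute and an optional free `energy` (kcal/mol).
#' Structures are nested (pseudoknot-free), hairpin loops hold at least 3
#' unpaired nucleotides, and pairs are restricted to the six canonical
#' types AU/UA/GC/CG/GU/UG.
#'
#' @param sequence RNA sequence (ACGU; T accepted and converted).
#' @param dotbracket Optional dot-bracket string (`.`, `(`, `)`).
#' @param partner Optional integer partner vector (NA = unpaired); exactly
#'   one of `dotbracket`/`partner` may be given, otherwise the structure is
#'   fully unpaired.
#' @param energy Optional free energy in kcal/mol.
#' @param validate Check the structural invariants (default TRUE).
#' @return An object of class `rna_structure`.
#' @examples
#' s <- rna_structure("GGGAAACCC", "(((...)))")
#' structure_stats(s)
#' @export
rna_structure <- function(sequence, dotbracket = NULL, partner = NULL,
                          energy = NA_real_, validate = TRUE) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (!is.null(dotbracket) && !is.null(partner))
    abort("give either dotbracket or partner, not both",
          class = "shapefold_structure_error")
  if (!is.null(dotbracket)) partner <- parse_dotbracket(dotbracket)
  if (is.null(partner)) partner <- rep(NA_integer_, n)
  partner <- as.integer(ifelse(is.na(partner) | partner == 0L, NA, partner))
  if (length(partner) != n)
    abort("partner vector length does not match sequence",
          class = "shapefold_structure_error")
  out <- tibble(position = seq_len(n),
                base = strsplit(sequence, "")[[1]],
                partner = partner)
  attr(out, "sequence") <- sequence
  attr(out, "energy") <- energy
  class(out) <- c("rna_structure", class(out))
  if (validate) validate_structure(out)
  out
}

normalize_rna <- function(sequence) {
  sequence <- chartr("tT", "uU", toupper(sequence))
  chartr("T", "U", sequence)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure>  n =", nrow(x), "nt,",
      sum(!is.na(x$partner)) / 2, "pairs")
  if (!is.na(attr(x, "energy")))
    cat(",  dG =", round(attr(x, "energy"), 2), "kcal/mol")
  cat("\n", dot_bracket(x), "\n", sep = "")
  invisible(x)
}

#' Validate the invariants of a secondary structure
#'
#' Checks partner involution, absence of pseudoknots, the minimum hairpin
#' size (3 unpaired nucleotides) and that all pairs are canonical.
#'
#' @param s An [rna_structure()].
#' @return `s`, invisibly; aborts on violation.
#' @export
validate_structure <- function(s) {
  p <- s$partner
  n <- length(p)
  paired <- which(!is.na(p))
  if (any(p[paired] < 1 | p[paired] > n, na.rm = TRUE))
    abort("partner index out of range", class = "shapefold_invariant_error")
  if (any(p[p[paired]] != paired))
    abort("partner table is not an involution",
          class = "shapefold_invariant_error")
  i <- paired[paired < p[paired]]
  j <- p[i]
  if (any(j - i < 4))
    abort("hairpin loop smaller than 3 unpaired nucleotides",
          class = "shapefold_invariant_error")
  if (length(i)) {
    pt <- .pair_type_table[cbind(s$base[i], s$base[j])]
    if (any(pt == 0))
      abort("non-canonical base pair", class = "shapefold_invariant_error")
    # nestedness: opened pairs must close in LIFO order
    stack <- integer(0)
    for (k in seq_len(n)) {
      if (is.na(p[k])) next
      if (p[k] > k) stack <- c(stack, p[k])
      else {
        if (!length(stack) || tail(stack, 1) != k)
          abort("pseudoknotted (crossing) pairs",
                class = "shapefold_invariant_error")
        stack <- stack[-length(stack)]
      }
    }
  }
  invisible(s)
}

#' @rdname rna_structure
#' @param s An `rna_structure`.
#' @export
dot_bracket <- function(s) {
  p <- s$partner
  out <- rep(".", length(p))
  out[!is.na(p) & p > seq_along(p)] <- "("
  out[!is.na(p) & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c(".", "(", ")")))
    abort("dot-bracket may contain only '.', '(' and ')'",
          class = "shapefold_format_error")
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack))
        abort("unbalanced brackets in dot-bracket",
              class = "shapefold_format_error")
      i <- tail(stack, 1); stack <- stack[-length(stack)]
      partner[i] <- k; partner[k] <- i
    }
  }
  if (length(stack))
    abort("unbalanced brackets in dot-bracket",
          class = "shapefold_format_error")
  partner
}

#' Read and write structures as dot-bracket or CT files
#'
#' `write_dotbracket()` emits an optional `>` header, the sequence and the
#' one-line dot-bracket string; `read_dotbracket()` accepts the same layout
#' with or without header. `write_ct()`/`read_ct()` use the standard
#' 6-column connectivity table.
#'
#' @param s An [rna_structure()].
#' @param path File path.
#' @param id Record identifier for the header / CT title.
#' @return The structure (readers) or `path`, invisibly (writers).
#' @export
write_dotbracket <- function(s, path, id = "structure") {
  writeLines(c(paste0(">", id), attr(s, "sequence"), dot_bracket(s)), path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2)
    abort("dot-bracket file needs a sequence and a structure line",
          class = "shapefold_format_error")
  rna_structure(lines[1], dotbracket = lines[2])
}

#' @rdname write_dotbracket
#' @export
write_ct <- function(s, path, id = "structure") {
  n <- nrow(s)
  energy <- attr(s, "energy")
  header <- sprintf("%5d %s%s", n,
                    if (!is.na(energy)) sprintf("ENERGY = %.2f  ", energy)
                    else "", id)
  p <- ifelse(is.na(s$partner), 0L, s$partner)
  rows <- sprintf("%5d %s %7d %4d %4d %4d",
                  s$position, s$base, s$position - 1L,
                  ifelse(s$position == n, 0L, s$position + 1L),
                  p, s$position)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  energy <- NA_real_
  em <- regmatches(lines[1], regexec("ENERGY *= *(-?[0-9.]+)", lines[1]))[[1]]
  if (length(em) == 2) energy <- as.numeric(em[2])
  fields <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  base <- vapply(fields, `[`, "", 2)
  partner <- as.integer(vapply(fields, `[`, "", 5))
  rna_structure(paste(base, collapse = ""), partner = partner,
                energy = energy)
}

# ---- element decomposition ------------------------------------------------

# Pairs (i, j) with i < j, as a two-column matrix.
structure_pairs <- function(s) {
  p <- if (inherits(s, "rna_structure")) s$partner else s
  i <- which(!is.na(p) & p > seq_along(p))
  cbind(i = i, j = p[i])
}

# Direct children pairs of the loop closed by (i, j); use i = 0, j = n + 1
# for the exterior loop. Returns matrix of (i, j) rows.
loop_children <- function(partner, i, j) {
  ch <- NULL
  k <- i + 1
  while (k < j) {
    pk <- partner[k]
    if (!is.na(pk) && pk > k) {
      ch <- rbind(ch, c(k, pk))
      k <- pk + 1
    } else k <- k + 1
  }
  if (is.null(ch)) matrix(integer(0), ncol = 2) else ch
}

# Maximal helices: list of matrices of stacked pairs (outermost first).
helix_list <- function(s) {
  pr <- structure_pairs(s)
  if (!nrow(pr)) return(list())
  pr <- pr[order(pr[, 1]), , drop = FALSE]
  key <- paste(pr[, 1], pr[, 2])
  seen <- character(0)
  helices <- list()
  for (r in seq_len(nrow(pr))) {
    if (key[r] %in% seen) next
    i <- pr[r, 1]; j <- pr[r, 2]
    run <- matrix(c(i, j), ncol = 2)
    p <- if (inherits(s, "rna_structure")) s$partner else s
    while (!is.na(p[run[nrow(run), 1] + 1]) &&
           p[run[nrow(run), 1] + 1] == run[nrow(run), 2] - 1) {
      run <- rbind(run, c(run[nrow(run), 1] + 1, run[nrow(run), 2] - 1))
    }
    seen <- c(seen, paste(run[, 1], run[, 2]))
    helices[[length(helices) + 1]] <- run
  }
  helices
}

#' Positions at helix termini
#'
#' Positions belonging to the first or last base pair of each maximal
#' helix (a lone pair is a helix of length one: both its positions count).
#'
#' @param s An [rna_structure()].
#' @return Sorted integer vector of positions.
#' @examples
#' helix_terminus_positions(rna_structure("GGGAAACCC", "(((...)))"))
#' @export
helix_terminus_positions <- function(s) {
  hx <- helix_list(s)
  if (!length(hx)) return(integer(0))
  pos <- unlist(lapply(hx, function(h)
    c(h[1, ], h[nrow(h), ])))
  sort(unique(as.integer(pos)))
}

#' Structural element counts
#'
#' Decomposes a structure into elements and reports the percentage of
#' paired nucleotides, the number of maximal helices, internal loops
#' (bulges included; `n_asymmetric` counts those with unequal strand
#' lengths), terminal (hairpin) loops, and multibranch junctions by degree
#' (number of helices meeting the loop, closing helix included).
#'
#' @param s An [rna_structure()].
#' @return A one-row tibble with counts and a `junction_degrees`
#'   list-column.
#' @examples
#' structure_stats(rna_structure("GGAGGAAACCCCA", "((.((...))))."))
#' @export
structure_stats <- function(s) {
  validate_structure(s)
  partner <- s$partner
  n <- length(partner)
  pr <- structure_pairs(s)
  n_internal <- 0L; n_asym <- 0L; n_hairpin <- 0L
  degrees <- integer(0)
  if (nrow(pr)) for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    ch <- loop_children(partner, i, j)
    if (nrow(ch) == 0) n_hairpin <- n_hairpin + 1L
    else if (nrow(ch) == 1) {
      n1 <- ch[1, 1] - i - 1L
      n2 <- j - ch[1, 2] - 1L
      if (n1 + n2 > 0) {
        n_internal <- n_internal + 1L
        if (n1 != n2) n_asym <- n_asym + 1L
      }
    } else degrees <- c(degrees, nrow(ch) + 1L)
  }
  tibble(percent_paired = 100 * nrow(pr) * 2 / n,
         n_helices = length(helix_list(s)),
         n_internal_loops = n_internal,
         n_asymmetric = n_asym,
         n_terminal_loops = n_hairpin,
         n_junctions = length(degrees),
         junction_degrees = list(sort(degrees)))
}

#' @export
glance.rna_structure <- function(x, ...) {
  st <- structure_stats(x)
  tibble(n = nrow(x), energy = attr(x, "energy"),
         n_pairs = sum(!is.na(x$partner)) / 2) %>%
    dplyr::bind_cols(st)
}

#' @export
tidy.rna_structure <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rna_structure")
  out
}

# ---- reference energy scorer ---------------------------------------------

#' Score a structure's free energy from scratch
#'
#' Loop-decomposition evaluation of the nearest-neighbor energy (plus
#' SHAPE pseudo-energies, applied per stacked nucleotide) of an explicit
#' structure. Implemented independently of the dynamic-programming engine
#' so the two can be cross-checked.
#'
#' @param s An [rna_structure()].
#' @param profile Optional [reactivity_profile()] or numeric pseudo-energy
#'   vector.
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol.
#' @export
structure_energy <- function(s, profile = NULL, model = energy_model()) {
  partner <- s$partner
  n <- length(partner)
  g <- pseudo_vector(n, profile, model)
  base <- s$base
  pt <- function(a, b) .pair_type_table[base[a], base[b]]
  pr <- structure_pairs(s)
  E <- 0
  if (nrow(pr)) for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    ch <- loop_children(partner, i, j)
    if (nrow(ch) == 0) {
      E <- E + loop_penalty(model, "hairpin", j - i - 1)
    } else if (nrow(ch) == 1) {
      k <- ch[1, 1]; l <- ch[1, 2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0 && n2 == 0) {
        E <- E + model$stack[pt(i, j), pt(l, k)] + g[i] + g[j] + g[k] + g[l]
      } else if (n1 == 0 || n2 == 0) {
        E <- E + loop_penalty(model, "bulge", n1 + n2)
        if (n1 + n2 == 1) E <- E + model$stack[pt(i, j), pt(l, k)]
      } else {
        E <- E + loop_penalty(model, "internal", n1 + n2) +
          min(model$ninio_max, model$ninio_m * abs(n1 - n2))
      }
    } else {
      unpaired <- (j - i - 1) - sum(ch[, 2] - ch[, 1] + 1)
      E <- E + model$ml_offset + model$ml_branch * (nrow(ch) + 1) +
        model$ml_unpaired * unpaired
    }
  }
  E
}
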