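# Alignment-based conservation: Stockholm I/O with consensus structure,
# average pairwise identity, reference-to-alignment coordinate mapping,
# and a transparent mutual-information covariation screen (APC-corrected)
# with a within-column permutation null and BH correction. This is a
# deliberately auditable analog of heavyweight covariation tools, not a
# reimplementation of their phylogeny-aware statistics.

#' Build a structure-annotated multiple alignment
#'
#' Aligned sequences (gap `-`, stored uppercase with T normalized to U)
#' keyed by id, a reference id, and a consensus pair list given as
#' alignment-column pairs (nested).
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences.
#' @param ref Reference sequence id (default: first).
#' @param column_pairs Optional 2-column matrix of paired alignment
#'   columns.
#' @return An object of class `structural_alignment`.
#' @export
structural_alignment <- function(sequences, ref = names(sequences)[1],
                                 column_pairs = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    abort("sequences must be named", class = "shapefold_aln_error")
  sequences <- vapply(sequences, function(s)
    chartr("tT", "uU", toupper(s)), "")
  sequences <- vapply(sequences, function(s) chartr("T", "U", s), "")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1)
    abort("ragged alignment: sequences differ in length",
          class = "shapefold_format_error")
  if (!ref %in% names(sequences))
    abort("reference id not in alignment", class = "shapefold_aln_error")
  if (!is.null(column_pairs)) {
    column_pairs <- as.matrix(column_pairs)
    stopifnot(ncol(column_pairs) == 2)
    if (any(column_pairs < 1 | column_pairs > widths[1]))
      abort("column pair outside alignment", class = "shapefold_aln_error")
  }
  structure(list(sequences = sequences, ref = ref,
                 column_pairs = column_pairs,
                 width = unname(widths[1])),
            class = "structural_alignment")
}

#' @export
print.structural_alignment <- function(x, ...) {
  cat("<structural_alignment> ", length(x$sequences), "sequences x",
      x$width, "columns, ref =", x$ref, "\n")
  if (!is.null(x$column_pairs))
    cat("  consensus pairs:", nrow(x$column_pairs), "\n")
  invisible(x)
}

# Alignment column of each ungapped reference position.
reference_columns <- function(aln) {
  chars <- strsplit(aln$sequences[[aln$ref]], "")[[1]]
  which(chars != "-")
}

#' @rdname structural_alignment
#' @param aln A `structural_alignment`.
#' @return `reference_sequence()`: the ungapped reference string.
#' @export
reference_sequence <- function(aln) {
  gsub("-", "", aln$sequences[[aln$ref]], fixed = TRUE)
}

# WUSS/dot-bracket consensus line -> nested column pairs.
parse_ss_cons <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  open <- c("<", "(", "[", "{")
  close <- c(">", ")", "]", "}")
  stack <- integer(0)
  pairs <- NULL
  for (k in seq_along(chars)) {
    if (chars[k] %in% open) stack <- c(stack, k)
    else if (chars[k] %in% close) {
      if (!length(stack))
        abort("unbalanced brackets in SS_cons",
              class = "shapefold_format_error")
      pairs <- rbind(pairs, c(tail(stack, 1), k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    abort("unbalanced brackets in SS_cons", class = "shapefold_format_error")
  if (is.null(pairs)) matrix(integer(0), ncol = 2)
  else pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Read and write Stockholm 1.0 alignments
#'
#' Minimal Stockholm support: sequence rows (interleaved blocks
#' accumulated), the `#=GC SS_cons` consensus-structure line (WUSS
#' brackets `<>()[]{}`; other symbols unpaired), other annotations
#' ignored. `write_stockholm()` emits a single block; a write/read
#' roundtrip is stable.
#'
#' @param path File path.
#' @param ref Reference id (default: first sequence).
#' @return A [structural_alignment()].
#' @export
read_stockholm <- function(path, ref = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    abort("not a Stockholm 1.0 file", class = "shapefold_format_error")
  seqs <- list()
  ss <- ""
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#=GC\\s+SS_cons\\s+(\\S+)", ln))[[1]]
      if (length(m) == 2) ss <- paste0(ss, m[2])
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2)
      abort(paste0("malformed sequence row: ", ln),
            class = "shapefold_format_error")
    seqs[[f[1]]] <- paste0(seqs[[f[1]]] %||% "", f[2])
  }
  if (!length(seqs))
    abort("no sequences in Stockholm file", class = "shapefold_format_error")
  sequences <- unlist(seqs)
  pairs <- NULL
  if (nzchar(ss)) {
    if (nchar(ss) != nchar(sequences[1]))
      abort("SS_cons length does not match alignment",
            class = "shapefold_format_error")
    pairs <- parse_ss_cons(ss)
  }
  structural_alignment(sequences,
                       ref = ref %||% names(sequences)[1],
                       column_pairs = pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_stockholm
#' @param aln A [structural_alignment()].
#' @export
write_stockholm <- function(aln, path) {
  ids <- names(aln$sequences)
  wid <- max(nchar(ids), nchar("#=GC SS_cons"))
  rows <- sprintf(paste0("%-", wid, "s %s"), ids, aln$sequences)
  out <- c("# STOCKHOLM 1.0", rows)
  if (!is.null(aln$column_pairs)) {
    ss <- rep(".", aln$width)
    if (nrow(aln$column_pairs)) {
      ss[aln$column_pairs[, 1]] <- "<"
      ss[aln$column_pairs[, 2]] <- ">"
    }
    out <- c(out, sprintf(paste0("%-", wid, "s %s"), "#=GC SS_cons",
                          paste(ss, collapse = "")))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

#' Average pairwise percent identity
#'
#' Mean over all unordered sequence pairs of
#' `100 * identical columns / co-ungapped columns`. Pairs with no
#' co-ungapped columns are skipped with a warning.
#'
#' @param aln A [structural_alignment()].
#' @return Percent identity.
#' @export
average_identity <- function(aln) {
  seqs <- lapply(aln$sequences, function(s) strsplit(s, "")[[1]])
  ids <- names(seqs)
  if (length(ids) < 2)
    abort("need at least 2 sequences", class = "shapefold_aln_error")
  vals <- c()
  for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
    x <- seqs[[a]]; y <- seqs[[b]]
    ok <- x != "-" & y != "-"
    if (!any(ok)) {
      warn(paste0("no co-ungapped columns for ", ids[a], "/", ids[b],
                  "; pair skipped"))
      next
    }
    vals <- c(vals, 100 * sum(x[ok] == y[ok]) / sum(ok))
  }
  mean(vals)
}

#' Map a reference structure onto alignment columns
#'
#' Each pair (i, j) of the reference structure becomes the column pair
#' (col(i), col(j)), where col() maps ungapped reference positions to
#' alignment columns.
#'
#' @param ref_structure An [rna_structure()] whose sequence equals the
#'   ungapped reference sequence of `aln`.
#' @param aln A [structural_alignment()].
#' @return Tibble with `ref_i`, `ref_j`, `col_i`, `col_j`.
#' @export
map_structure_to_alignment <- function(ref_structure, aln) {
  refseq <- reference_sequence(aln)
  if (!identical(normalize_rna(refseq), attr(ref_structure, "sequence")))
    abort("alignment reference sequence does not match the structure",
          class = "shapefold_aln_error")
  cols <- reference_columns(aln)
  pr <- structure_pairs(ref_structure)
  tibble(ref_i = pr[, 1], ref_j = pr[, 2],
         col_i = cols[pr[, 1]], col_j = cols[pr[, 2]])
}

# Integer-encode one alignment column (0 = gap/other).
encode_column <- function(aln, col) {
  ch <- vapply(aln$sequences, function(s) substr(s, col, col), "")
  code <- match(ch, BASES)
  code[is.na(code)] <- 0L
  code
}

mi_bits <- function(a, b) {
  ok <- a > 0L & b > 0L
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  joint <- tabulate((a - 1L) * 4L + b, nbins = 16L) / n
  pa <- tabulate(a, nbins = 4L) / n
  pb <- tabulate(b, nbins = 4L) / n
  mi <- 0
  for (x in 1:4) for (y in 1:4) {
    p <- joint[(x - 1L) * 4L + y]
    if (p > 0) mi <- mi + p * log2(p / (pa[x] * pb[y]))
  }
  max(mi, 0)
}

#' Covariation scores for paired alignment columns
#'
#' Mutual information (bits) of the joint base distribution of each
#' column pair, over sequences ungapped in both columns
#' (pairwise-deletion; gaps are not an alphabet symbol), with the average
#' product correction (APC) computed over the scored pair set:
#' `MIp = MI - mean_i * mean_j / grand_mean` where `mean_i` is the mean
#' MI of pairs involving column i.
#'
#' @param aln A [structural_alignment()].
#' @param column_pairs 2-column matrix/data frame of alignment column
#'   pairs; default: the alignment's consensus pairs.
#' @return Tibble with `col_i`, `col_j`, `n_eff`, `mi`, `mip` (`NA` when
#'   fewer than 5 co-ungapped sequences).
#' @export
covariation_scores <- function(aln, column_pairs = aln$column_pairs) {
  if (length(aln$sequences) < 5)
    abort("need at least 5 sequences", class = "shapefold_aln_error")
  cp <- as.matrix(column_pairs)
  if (!nrow(cp)) return(tibble(col_i = integer(0), col_j = integer(0),
                               n_eff = integer(0), mi = numeric(0),
                               mip = numeric(0)))
  cols <- lapply(seq_len(aln$width), function(i) NULL)
  getcol <- function(i) {
    if (is.null(cols[[i]])) cols[[i]] <<- encode_column(aln, i)
    cols[[i]]
  }
  out <- purrr::map_dfr(seq_len(nrow(cp)), function(r) {
    a <- getcol(cp[r, 1]); b <- getcol(cp[r, 2])
    n_eff <- sum(a > 0L & b > 0L)
    mi <- if (n_eff >= 5) mi_bits(a, b) else NA_real_
    tibble(col_i = cp[r, 1], col_j = cp[r, 2],
           n_eff = as.integer(n_eff), mi = mi)
  })
  out$mip <- apc_correct(out)
  out
}

apc_correct <- function(tab) {
  ok <- !is.na(tab$mi)
  if (!any(ok)) return(rep(NA_real_, nrow(tab)))
  grand <- mean(tab$mi[ok])
  colmean <- function(col)
    mean(tab$mi[ok & (tab$col_i == col | tab$col_j == col)])
  apc <- vapply(seq_len(nrow(tab)), function(r) {
    if (!ok[r]) return(NA_real_)
    if (grand <= 0) return(0)
    colmean(tab$col_i[r]) * colmean(tab$col_j[r]) / grand
  }, 0.0)
  ifelse(ok, tab$mi - apc, NA_real_)
}

#' Permutation significance of covariation
#'
#' Null distribution per column pair from `n_perm` shuffles of each
#' column's residues across sequences (independently per column, gaps
#' kept in place), using mutual information as the statistic:
#' `p = (1 + #null >= observed) / (1 + n_perm)`, Benjamini-Hochberg
#' corrected across the scored pairs. Reproducible given `seed`.
#'
#' @inheritParams covariation_scores
#' @param n_perm Number of permutations (warning below 100: the
#'   attainable p floor is unstable).
#' @param fdr Significance level on BH-adjusted q values.
#' @param seed Integer seed.
#' @return [covariation_scores()] columns plus `p`, `q`, `significant`.
#' @export
covariation_significance <- function(aln, column_pairs = aln$column_pairs,
                                     n_perm = 1000, fdr = 0.05, seed = 1) {
  if (n_perm < 100)
    warn("n_perm < 100: permutation p-values are unstable",
         class = "shapefold_param_warning")
  obs <- covariation_scores(aln, column_pairs)
  ok <- which(!is.na(obs$mi))
  p <- rep(NA_real_, nrow(obs))
  with_seed(seed, {
    for (r in ok) {
      a <- encode_column(aln, obs$col_i[r])
      b <- encode_column(aln, obs$col_j[r])
      ia <- which(a > 0L); ib <- which(b > 0L)
      hits <- 0L
      for (pm in seq_len(n_perm)) {
        ap <- a; bp <- b
        ap[ia] <- a[sample(ia)]
        bp[ib] <- b[sample(ib)]
        if (mi_bits(ap, bp) >= obs$mi[r] - 1e-12) hits <- hits + 1L
      }
      p[r] <- (1 + hits) / (1 + n_perm)
    }
  })
  obs$p <- p
  obs$q <- NA_real_
  obs$q[ok] <- p.adjust(p[ok], method = "BH")
  obs$significant <- !is.na(obs$q) & obs$q <= fdr
  obs
}

#' Export per-pair covariation CSV
#'
#' Emits `col_i, col_j, ref_i, ref_j, mi, mip, p, q, significant`; the
#' reference coordinates come from a column map as produced by
#' [map_structure_to_alignment()].
#'
#' @param cov Output of [covariation_significance()].
#' @param path Output path.
#' @param column_map Optional tibble with `col_i`, `col_j`, `ref_i`,
#'   `ref_j`.
#' @export
write_covariation_csv <- function(cov, path, column_map = NULL) {
  out <- cov
  if (!is.null(column_map))
    out <- left_join(out, column_map, by = c("col_i", "col_j"))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
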