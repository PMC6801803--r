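# Per-nucleotide chemical reactivity profiles: constructors, .shape/.map
# dialect I/O, 2%/8% normalization and missing-data-aware correlation.

#' Build a per-nucleotide reactivity profile
#'
#' A reactivity profile is a tibble with one row per nucleotide
#' (`position`, `base`, `reactivity`) and attributes `rna_id`, `reagent`
#' (`"SHAPE"` or `"DMS"`) and `offset` (1-based coordinate of the first
#' position). "No data" is represented as `NA` internally and as the
#' sentinel `-999` in files; it is never silently treated as 0. Negative
#' raw values other than the sentinel are clamped to 0 (pseudo-energy
#' terms require non-negative reactivities). For DMS, reactivities at G/U
#' positions are forced to `NA` (dimethyl sulfate probes only unpaired A
#' and C).
#'
#' @param sequence RNA sequence (T read as U; stored uppercase).
#' @param reactivities Numeric vector, same length as the sequence; `NA`
#'   or `-999` for no data.
#' @param reagent `"SHAPE"` or `"DMS"`.
#' @param rna_id Identifier for the RNA.
#' @param offset 1-based position of the first nucleotide.
#' @return A tibble of class `reactivity_profile`.
#' @examples
#' reactivity_profile("GGGAAACCC", c(0.1, NA, 0.2, 1.5, 2, 1.1, 0.3, 0, 0.1))
#' @export
reactivity_profile <- function(sequence, reactivities,
                               reagent = c("SHAPE", "DMS"),
                               rna_id = "rna", offset = 1L) {
  reagent <- match.arg(reagent)
  sequence <- normalize_rna(sequence)
  base <- strsplit(sequence, "")[[1]]
  if (length(reactivities) != length(base))
    abort("reactivities and sequence differ in length",
          class = "shapefold_length_error")
  r <- as.numeric(reactivities)
  r[r == NO_DATA_SENTINEL] <- NA
  r[!is.na(r) & r < 0] <- 0
  if (reagent == "DMS") r[base %in% c("G", "U")] <- NA
  out <- tibble(position = seq_along(base) + as.integer(offset) - 1L,
                base = base, reactivity = r)
  attr(out, "rna_id") <- rna_id
  attr(out, "reagent") <- reagent
  attr(out, "offset") <- as.integer(offset)
  class(out) <- c("reactivity_profile", class(out))
  out
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat("<reactivity_profile> ", attr(x, "rna_id"), " (", attr(x, "reagent"),
      "), n = ", nrow(x), ", ", sum(is.na(x$reactivity)), " no-data\n",
      sep = "")
  NextMethod()
}

profile_sequence <- function(profile) paste(profile$base, collapse = "")

#' Read and write reactivity files
#'
#' `read_shape()` reads the two-column whitespace-delimited
#' `position reactivity` dialect; `read_map()` the four-column
#' `position reactivity stderr nucleotide` dialect (the nucleotide column
#' populates the sequence). Positions must be contiguous and ascending;
#' the sentinel `-999` (or `nan`) becomes no data. `write_shape()` /
#' `write_map()` emit the same dialects; a write/read roundtrip preserves
#' all values.
#'
#' @param path File path.
#' @param sequence Sequence for `read_shape()` (the dialect carries none);
#'   if `NULL`, bases are set to `N`-free placeholder `A` and should be
#'   replaced before folding.
#' @param reagent,rna_id Passed to [reactivity_profile()].
#' @return A [reactivity_profile()] (readers); `path` invisibly (writers).
#' @export
read_shape <- function(path, sequence = NULL, reagent = "SHAPE",
                       rna_id = basename(path)) {
  tab <- parse_reactivity_table(path, n_cols = 2)
  n <- nrow(tab)
  seq <- if (is.null(sequence)) strrep("A", n) else sequence
  if (nchar(seq) != n)
    abort("sequence length does not match file rows",
          class = "shapefold_format_error")
  reactivity_profile(seq, tab$reactivity, reagent = reagent,
                     rna_id = rna_id, offset = tab$position[1])
}

#' @rdname read_shape
#' @export
read_map <- function(path, reagent = "SHAPE", rna_id = basename(path)) {
  tab <- parse_reactivity_table(path, n_cols = 4)
  reactivity_profile(paste(tab$base, collapse = ""), tab$reactivity,
                     reagent = reagent, rna_id = rna_id,
                     offset = tab$position[1])
}

parse_reactivity_table <- function(path, n_cols) {
  if (!file.exists(path))
    abort(paste0("no such file: ", path), class = "shapefold_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < n_cols)
  if (length(bad))
    abort(paste0("row ", bad[1], " has fewer than ", n_cols, " fields"),
          class = "shapefold_format_error")
  position <- as.integer(vapply(fields, `[`, "", 1))
  rtxt <- tolower(vapply(fields, `[`, "", 2))
  reactivity <- suppressWarnings(as.numeric(rtxt))
  reactivity[rtxt == "nan"] <- NA
  if (anyNA(position))
    abort("non-integer position field", class = "shapefold_format_error")
  if (any(diff(position) != 1L)) {
    first_bad <- which(diff(position) != 1L)[1] + 1L
    abort(paste0("positions not contiguous ascending at row ", first_bad),
          class = "shapefold_format_error")
  }
  neg <- which(!is.na(reactivity) & reactivity < 0 &
                 reactivity != NO_DATA_SENTINEL)
  if (length(neg))
    abort(paste0("negative reactivity (not the -999 sentinel) at row ",
                 neg[1]),
          class = "shapefold_format_error")
  out <- tibble(position = position, reactivity = reactivity)
  if (n_cols >= 4) {
    out$stderr <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    out$base <- vapply(fields, `[`, "", 4)
  }
  out
}

#' @rdname read_shape
#' @param profile A [reactivity_profile()].
#' @export
write_shape <- function(profile, path) {
  r <- ifelse(is.na(profile$reactivity), NO_DATA_SENTINEL,
              profile$reactivity)
  writeLines(sprintf("%d\t%.6g", profile$position, r), path)
  invisible(path)
}

#' @rdname read_shape
#' @param stderr Optional standard-error column for the .map dialect.
#' @export
write_map <- function(profile, path, stderr = NULL) {
  r <- ifelse(is.na(profile$reactivity), NO_DATA_SENTINEL,
              profile$reactivity)
  se <- if (is.null(stderr)) rep(0, nrow(profile)) else stderr
  writeLines(sprintf("%d\t%.6g\t%.6g\t%s", profile$position, r, se,
                     profile$base), path)
  invisible(path)
}

#' Normalize reactivities by the 2%/8% rule
#'
#' Standard SHAPE normalization: the defined values are sorted in
#' descending order, the top 2% are excluded as outliers, and every value
#' is divided by the mean of the next 8%. No-data positions pass through
#' unchanged. The operation is scale-invariant and idempotent.
#'
#' @param raw Numeric vector of non-negative reactivities with `NA` for
#'   no data, or a [reactivity_profile()].
#' @return Same shape as the input.
#' @examples
#' normalize_reactivities(c(rep(0.5, 99), NA))
#' @export
normalize_reactivities <- function(raw) {
  if (inherits(raw, "reactivity_profile")) {
    raw$reactivity <- normalize_reactivities(raw$reactivity)
    return(raw)
  }
  defined <- raw[!is.na(raw)]
  if (length(defined) < 20)
    abort("normalization needs at least 20 defined reactivities",
          class = "shapefold_data_error")
  if (any(defined < 0))
    abort("reactivities must be non-negative", class = "shapefold_value_error")
  srt <- sort(defined, decreasing = TRUE)
  n_excl <- ceiling(0.02 * length(srt))
  n_avg <- ceiling(0.08 * length(srt))
  divisor <- mean(srt[(n_excl + 1):(n_excl + n_avg)])
  if (!is.finite(divisor) || divisor <= 0)
    abort("degenerate profile: normalization divisor <= 0",
          class = "shapefold_data_error")
  raw / divisor
}

#' Pearson correlation with pairwise deletion of missing data
#'
#' Positions where either vector is `NA` are excluded pairwise; at least
#' 3 usable pairs are required and both vectors must vary.
#'
#' @param x,y Numeric vectors of equal length (`NA` = no data).
#' @return A one-row tibble with `r` and `n_used`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    abort("vectors differ in length", class = "shapefold_length_error")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    abort("fewer than 3 usable pairs", class = "shapefold_data_error")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    abort("zero variance: correlation undefined",
          class = "shapefold_data_error")
  tibble(r = cor(x[ok], y[ok]), n_used = sum(ok))
}

#' Combined per-nucleotide CSV export
#'
#' Writes `position, base, reactivity, reagent` (empty reactivity for no
#' data) for one or more profiles.
#'
#' @param profiles A [reactivity_profile()] or list of them.
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "reactivity_profile")) profiles <- list(profiles)
  tab <- purrr::map_dfr(profiles, function(p)
    tibble(rna_id = attr(p, "rna_id"), position = p$position,
           base = p$base, reactivity = p$reactivity,
           reagent = attr(p, "reagent")))
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
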