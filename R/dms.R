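# DMS validation: reactivity classification of A/C nucleotides and the
# structural-agreement statistic (highly reactive nucleotides should sit
# in loops or at helix termini).

#' Classify DMS reactivities
#'
#' Splits A/C nucleotides with data into low (`r < low`), mid
#' (`low <= r <= high`, both boundaries inclusive) and high (`r > high`)
#' reactivity classes. Dimethyl sulfate methylates only single-stranded
#' adenosines and cytidines, so G/U positions carry no data by
#' construction.
#'
#' @param profile A DMS [reactivity_profile()].
#' @param low,high Class boundaries (defaults 0.4 and 0.85).
#' @return A tibble of class `dms_classification`: `position`, `base`,
#'   `reactivity`, `class` (factor low/mid/high, `NA` where no data).
#' @examples
#' p <- reactivity_profile("AACA", c(0.1, 0.4, NA, 0.9), reagent = "DMS")
#' classify_dms(p)
#' @export
classify_dms <- function(profile, low = 0.4, high = 0.85) {
  if (!identical(attr(profile, "reagent"), "DMS"))
    abort("profile reagent must be DMS", class = "shapefold_reagent_error")
  r <- profile$reactivity
  cls <- rep(NA_character_, length(r))
  usable <- !is.na(r) & profile$base %in% c("A", "C")
  cls[usable & r < low] <- "low"
  cls[usable & r >= low & r <= high] <- "mid"
  cls[usable & r > high] <- "high"
  out <- tibble(position = profile$position, base = profile$base,
                reactivity = r,
                class = factor(cls, levels = c("low", "mid", "high")))
  class(out) <- c("dms_classification", class(out))
  out
}

#' @rdname classify_dms
#' @param x A `dms_classification`.
#' @return `dms_class_counts()`: one-row tibble `n_low`, `n_mid`,
#'   `n_high`.
#' @export
dms_class_counts <- function(x) {
  tb <- table(x$class)
  tibble(n_low = as.integer(tb[["low"]]),
         n_mid = as.integer(tb[["mid"]]),
         n_high = as.integer(tb[["high"]]))
}

#' DMS / structure agreement statistic
#'
#' Among A/C nucleotides with DMS reactivity above `high`, the percentage
#' that the structural model leaves unpaired or places at a helix
#' terminus (see [helix_terminus_positions()]). High agreement indicates
#' the model is consistent with the orthogonal probe.
#'
#' @param s An [rna_structure()].
#' @param dms A DMS [reactivity_profile()] of matching length.
#' @param high High-reactivity threshold.
#' @return Percent in `[0, 100]`; `NA` with a warning when no nucleotide
#'   is highly reactive (statistic undefined, not 0).
#' @export
agreement_statistic <- function(s, dms, high = 0.85) {
  if (nrow(s) != nrow(dms))
    abort("structure and profile differ in length",
          class = "shapefold_length_error")
  hot <- which(!is.na(dms$reactivity) & dms$base %in% c("A", "C") &
                 dms$reactivity > high)
  if (!length(hot)) {
    warn("no highly reactive nucleotides: agreement statistic undefined",
         class = "shapefold_undefined_statistic")
    return(NA_real_)
  }
  ok_pos <- union(which(is.na(s$partner)), helix_terminus_positions(s))
  100 * mean(hot %in% ok_pos)
}
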