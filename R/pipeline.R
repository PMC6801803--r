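# End-to-end analysis: normalize -> candidate ensemble -> 3S selection ->
# jackknife confidence -> partition function -> entropy -> well-defined
# regions -> DMS agreement -> conservation, with a reproducible output
# bundle and JSON manifest.

#' Read an RNA sequence from FASTA
#'
#' First record unless `id` is given; T is converted to U.
#'
#' @param path FASTA path.
#' @param id Optional record id.
#' @return Named character scalar.
#' @export
read_rna_fasta <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  idx <- if (is.null(id)) 1L else match(id, nm)
  if (is.na(idx))
    abort(paste0("record not found: ", id), class = "shapefold_io_error")
  setNames(normalize_rna(as.character(set[[idx]])), nm[idx])
}

#' Write an RNA sequence to FASTA
#'
#' @param sequence Character scalar.
#' @param path Output path.
#' @param id Record id.
#' @export
write_rna_fasta <- function(sequence, path, id = "rna") {
  writeLines(c(paste0(">", id),
               gsub("(.{60})", "\\1\n", sequence, perl = TRUE)), path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(normalize = TRUE, max_models = 20, window = NULL,
       threshold = 0.85, tolerance = 0.05,
       n_reps = 100, drop_frac = 0.10,
       conf_min = 70, ent_max = 0.2, min_len = 40, smooth_window = 51,
       dms_high = 0.85, dms_low = 0.4,
       n_perm = 1000, fdr = 0.05, seed = 1)
}

load_profile_input <- function(x, sequence = NULL, reagent = "SHAPE") {
  if (is.null(x) || inherits(x, "reactivity_profile")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.map$", x, ignore.case = TRUE))
      return(read_map(x, reagent = reagent))
    return(read_shape(x, sequence = sequence, reagent = reagent))
  }
  abort("profile input must be a reactivity_profile or a file path",
        class = "shapefold_io_error")
}

#' Run the full structure-inference pipeline
#'
#' Executes, in order: reactivity normalization, SHAPE-directed
#' suboptimal folding, 3S model selection (when fragment data are given),
#' jackknife confidence, partition function and Shannon entropy,
#' well-defined-region detection, DMS agreement (when a DMS profile is
#' given) and conservation/covariation (when an alignment is given). Any
#' stage failure aborts with the stage name. When `out_dir` is given the
#' chosen model (CT + dot-bracket), candidate table, per-nucleotide
#' track, regions, covariation table and a JSON run manifest (input
#' hashes, seed, parameters, package version, output hashes) are
#' written; reruns with the same inputs and seed are byte-identical.
#'
#' @param sequence RNA sequence, or a FASTA path.
#' @param shape SHAPE [reactivity_profile()] or .shape/.map path.
#' @param dms Optional DMS profile or path.
#' @param fragments Optional data frame `name,start,end` of fragment
#'   specs.
#' @param fragment_profiles Optional named list (by fragment name) of
#'   fragment [reactivity_profile()]s or file paths.
#' @param alignment Optional [structural_alignment()] or Stockholm path.
#' @param out_dir Optional output directory (created if missing).
#' @param config Optional list or JSON path supplying any of the above
#'   plus tuning parameters; explicit arguments win over config entries.
#' @param ... Tuning parameters overriding the defaults: `normalize`,
#'   `max_models`, `window`, `threshold`, `tolerance`, `n_reps`,
#'   `drop_frac`, `conf_min`, `ent_max`, `min_len`, `smooth_window`,
#'   `dms_low`, `dms_high`, `n_perm`, `fdr`, `seed`.
#' @param model An [energy_model()].
#' @return An object of class `shapefold_run`.
#' @export
run_pipeline <- function(sequence = NULL, shape = NULL, dms = NULL,
                         fragments = NULL, fragment_profiles = NULL,
                         alignment = NULL, out_dir = NULL, config = NULL,
                         model = energy_model(), ...) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- utils::modifyList(pipeline_defaults(), config %||% list())
  dots <- list(...)
  cfg <- utils::modifyList(cfg, dots)
  sequence <- sequence %||% cfg$sequence
  shape <- shape %||% cfg$shape
  dms <- dms %||% cfg$dms
  fragments <- fragments %||% cfg$fragments
  fragment_profiles <- fragment_profiles %||% cfg$fragment_profiles
  alignment <- alignment %||% cfg$alignment
  out_dir <- out_dir %||% cfg$out_dir

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "shapefold_pipeline_error"))
  }

  input_paths <- list()
  note_input <- function(label, x)
    if (is.character(x) && length(x) == 1 && file.exists(x))
      input_paths[[label]] <<- x

  note_input("sequence", sequence)
  note_input("shape", shape)
  note_input("dms", dms)
  note_input("alignment", alignment)

  if (is.null(sequence)) abort("a sequence is required",
                               class = "shapefold_io_error")
  if (is.character(sequence) && file.exists(sequence))
    sequence <- read_rna_fasta(sequence)
  rna_id <- names(sequence) %||% "rna"
  sequence <- normalize_rna(unname(sequence))

  shape <- stage("profiles", {
    p <- load_profile_input(shape, sequence = sequence)
    if (is.null(p)) abort("a SHAPE profile is required")
    if (cfg$normalize) p <- normalize_reactivities(p)
    p
  })
  dms <- stage("profiles", load_profile_input(dms, sequence = sequence,
                                              reagent = "DMS"))

  candidates <- stage("fold", fold_suboptimal(
    sequence, shape, model, max_models = cfg$max_models,
    window = cfg$window))

  frag_r <- NULL
  selection <- NULL
  if (!is.null(fragments) && nrow(as_tibble(fragments))) {
    frag_r <- stage("shotgun", {
      fr <- as_tibble(fragments)
      purrr::map_dfr(seq_len(nrow(fr)), function(i) {
        fp <- fragment_profiles[[fr$name[i]]]
        fp <- load_profile_input(fp)
        fragment_correlation(shape, fp, fr[i, ])
      })
    })
    selection <- stage("shotgun", select_model(
      candidates, frag_r, threshold = cfg$threshold,
      tolerance = cfg$tolerance))
    chosen <- selected_structure(selection)
  } else chosen <- candidates$structure[[1]]

  conf <- stage("confidence", jackknife_confidence(
    sequence, shape, chosen, model, n_reps = cfg$n_reps,
    drop_frac = cfg$drop_frac, seed = cfg$seed))
  P <- stage("entropy", partition_function(sequence, shape, model))
  ent <- stage("entropy", shannon_entropy(P))
  regions <- stage("domains", find_well_defined_regions(
    conf, ent, conf_min = cfg$conf_min, ent_max = cfg$ent_max,
    min_len = cfg$min_len, smooth_window = cfg$smooth_window))

  dms_result <- NULL
  if (!is.null(dms)) dms_result <- stage("dms", {
    cl <- classify_dms(dms, low = cfg$dms_low, high = cfg$dms_high)
    list(classes = cl, counts = dms_class_counts(cl),
         agreement = agreement_statistic(chosen, dms,
                                         high = cfg$dms_high))
  })

  cons_result <- NULL
  if (!is.null(alignment)) cons_result <- stage("conserve", {
    aln <- if (is.character(alignment)) read_stockholm(alignment)
    else alignment
    cmap <- map_structure_to_alignment(chosen, aln)
    cov <- covariation_significance(
      aln, cmap[, c("col_i", "col_j")], n_perm = cfg$n_perm,
      fdr = cfg$fdr, seed = cfg$seed)
    list(alignment = aln, column_map = cmap, covariation = cov,
         average_identity = average_identity(aln))
  })

  run <- structure(list(
    rna_id = rna_id, sequence = sequence, shape = shape, dms = dms,
    candidates = candidates, fragment_correlations = frag_r,
    selection = selection, chosen = chosen, confidence = conf,
    pair_probabilities = P, entropy = ent, regions = regions,
    dms_result = dms_result, conservation = cons_result,
    parameters = cfg[setdiff(names(cfg),
                             c("sequence", "shape", "dms", "fragments",
                               "fragment_profiles", "alignment",
                               "out_dir"))],
    input_paths = input_paths), class = "shapefold_run")

  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

hash_file <- function(path) unname(tools::md5sum(path))

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_ct(run$chosen, fp("chosen.ct"), id = run$rna_id)
  write_dotbracket(run$chosen, fp("chosen.db"), id = run$rna_id)
  write.csv(tidy(run$candidates), fp("candidates.csv"), row.names = FALSE)
  track <- nucleotide_track(run$shape, run$confidence, run$entropy,
                            run$chosen)
  write.csv(track, fp("track.csv"), row.names = FALSE, na = "")
  write.csv(run$regions, fp("regions.csv"), row.names = FALSE)
  outputs <- c("chosen.ct", "chosen.db", "candidates.csv", "track.csv",
               "regions.csv")
  if (!is.null(run$selection)) {
    write.csv(tidy(run$selection), fp("selection.csv"), row.names = FALSE)
    outputs <- c(outputs, "selection.csv")
  }
  if (!is.null(run$conservation)) {
    write_covariation_csv(run$conservation$covariation,
                          fp("covariation.csv"),
                          run$conservation$column_map)
    outputs <- c(outputs, "covariation.csv")
  }
  if (!is.null(run$dms_result)) {
    jsonlite::write_json(
      list(counts = as.list(run$dms_result$counts),
           agreement_percent = run$dms_result$agreement),
      fp("dms_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
    outputs <- c(outputs, "dms_summary.json")
  }
  manifest <- list(
    package = "shapefold",
    version = as.character(utils::packageVersion("shapefold")),
    rna_id = run$rna_id,
    sequence_md5 = {
      tf <- tempfile(); writeLines(run$sequence, tf)
      on.exit(unlink(tf), add = TRUE); hash_file(tf)
    },
    n = nchar(run$sequence),
    seed = run$parameters$seed,
    parameters = run$parameters,
    inputs = lapply(run$input_paths, hash_file),
    outputs = setNames(lapply(outputs, function(o) hash_file(fp(o))),
                       outputs))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  run$out_dir <- out_dir
  run$manifest <- manifest
  run
}

#' @export
print.shapefold_run <- function(x, ...) {
  cat("<shapefold_run> ", x$rna_id, " (", nchar(x$sequence), " nt)\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
glance.shapefold_run <- function(x, ...) {
  st <- structure_stats(x$chosen)
  tibble(
    n = nchar(x$sequence),
    energy = attr(x$chosen, "energy"),
    percent_paired = st$percent_paired,
    n_helices = st$n_helices,
    n_candidates = nrow(x$candidates),
    n_consistent = if (is.null(x$selection)) NA_integer_
                   else sum(x$selection$consistent),
    mean_confidence = mean(x$confidence$confidence),
    median_entropy = stats::median(x$entropy$entropy),
    n_regions = nrow(x$regions),
    dms_agreement = if (is.null(x$dms_result)) NA_real_
                    else x$dms_result$agreement,
    average_identity = if (is.null(x$conservation)) NA_real_
                       else x$conservation$average_identity,
    n_covarying = if (is.null(x$conservation)) NA_integer_
                  else sum(x$conservation$covariation$significant))
}

#' @export
tidy.shapefold_run <- function(x, ...) {
  nucleotide_track(x$shape, x$confidence, x$entropy, x$chosen)
}
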