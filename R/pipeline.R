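#' Pipeline run configuration
#'
#' @param input path to a nucleus centroid table (CSV/TSV), or \code{NULL}
#'   to simulate inputs from \code{synthetic}.
#' @param frame \code{\linkS4class{CanonicalFrame}} for table input.
#' @param synthetic a \code{\link{syntheticConfig}} used when
#'   \code{input} is \code{NULL}.
#' @param rotationCutoff complete-rotation cutoff, degrees.
#' @param columnCutoff column/cluster cutoff, degrees.
#' @param mergeThreshold multiclone merge distance, um.
#' @param matchThreshold cell/nucleus match distance, um.
#' @param filters a \code{\link{filterSpec}}, or \code{NULL} to skip
#'   volume filtering.
#' @param seed RNG seed; required whenever inputs are simulated.
#' @return A list of class \code{runConfig}.
#' @export
runConfig <- function(input = NULL, frame = canonicalFrame(),
                      synthetic = syntheticConfig(),
                      rotationCutoff = 60, columnCutoff = 60,
                      mergeThreshold = 15, matchThreshold = 20,
                      filters = NULL, seed = NULL) {
  stopifnot(rotationCutoff > 0, columnCutoff > 0, mergeThreshold > 0,
            matchThreshold > 0)
  structure(as.list(environment()), class = "runConfig")
}

#' Run the full clonal-architecture pipeline
#'
#' Loads (or simulates) nuclei, applies volume filters, identifies
#' doublets, computes elevation angles and per-clone profiles, derives
#' clone shapes and column/cluster classes, merges multiclones, and writes
#' per-doublet, per-clone, merged and summary tables plus a JSON summary
#' into \code{outdir}. Deterministic given the configuration and seed;
#' partial outputs are removed on error.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$input) && is.null(config$seed))
    stop("validation error: a seed is required to simulate inputs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  failed <- TRUE
  on.exit({
    # remove partial outputs if we error below
    if (failed) unlink(written)
  })
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)

  truth <- NULL
  cs <- tryCatch({
    if (is.null(config$input)) {
      sim <- simulateGrowthPlate(config$synthetic, seed = config$seed)
      truth <- sim$truth
      sim$clones
    } else readNucleusTable(config$input, config$frame)
  }, error = function(e) fail("load", e))

  res <- tryCatch({
    if (!is.null(config$filters)) cs <- applyFilters(cs, config$filters)
    doublets <- identifyDoublets(cs)
    elev <- doubletElevationTable(cs, doublets, config$rotationCutoff)
    profiles <- cloneElevationProfiles(cs, doublets,
                                       config$rotationCutoff)
    shapes <- cloneShapeTable(cs, config$columnCutoff)
    mc <- mergeClones(cs, config$mergeThreshold)
    mcReport <- multicloneReport(mc, config$columnCutoff)

    emit(nuclei(cs), "nuclei.csv")
    emit(elev, "doublets.csv")
    emit(dStarTable(doublets), "dstar.csv")
    emit(elevationProfileTable(profiles), "profiles.csv")
    emit(shapes, "shapes.csv")
    emit(mcReport, "multiclones.csv")
    if (!is.null(truth)) emit(truth, "truth.csv")

    cls <- stats::setNames(shapes$class, shapes$clone_id)
    byClass <- function(cl) {
      ids <- shapes$clone_id[shapes$class == cl]
      a <- elev$elevation_deg[elev$clone_id %in% ids]
      if (!length(a)) NA else mean(a >= config$rotationCutoff)
    }
    sizes <- cloneSizes(cs)
    summary <- list(
      thresholds = list(rotation_cutoff_deg = config$rotationCutoff,
                        column_cutoff_deg = config$columnCutoff,
                        merge_threshold_um = config$mergeThreshold,
                        match_threshold_um = config$matchThreshold),
      seed = config$seed,
      n_nuclei = nrow(nuclei(cs)),
      n_clones = length(cloneIds(cs)),
      n_doublets = nrow(elev),
      complete_fraction = if (nrow(elev))
        mean(elev$elevation_deg >= config$rotationCutoff) else NA,
      complete_fraction_columns = byClass("column"),
      complete_fraction_clusters = byClass("cluster"),
      n_columns = sum(shapes$class == "column"),
      n_clusters = sum(shapes$class == "cluster"),
      column_fraction = if (nrow(shapes))
        mean(shapes$class == "column") else NA,
      n_multiclones = length(groups(mc)),
      clone_size_histogram = as.list(table(sizes)))
    json <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, json)
    summary
  }, error = function(e) fail("analysis", e))
  failed <- FALSE
  invisible(res)
}
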