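.ELEVATION_BIN_LOWER <- c(0, 15, 30, 45, 60, 70, 80)
.ELEVATION_BIN_LABELS <- c("[0,15)", "[15,30)", "[30,45)", "[45,60)",
                           "[60,70)", "[70,80)", "[80,90]")

#' Elevation angle of a doublet
#'
#' The doublet midpoint is shifted to the origin and the angle between the
#' inter-centroid vector and the equatorial (XY) plane is measured in the
#' canonical frame, where +Z is the P-D bone axis: 0 degrees means the two
#' nuclei lie in the same equatorial plane, 90 degrees that one sits
#' directly above the other. The two nuclei of a doublet mirror each other,
#' so the absolute value is used and the result is symmetric in (p, q).
#'
#' @param p,q 3-vectors, canonical coordinates in micrometres.
#' @return Angle in degrees in [0, 90], with attribute \code{radius}: half
#'   the inter-centroid distance (the doublet's spherical radius, um).
#' @examples
#' elevationAngle(c(0, 0, 0), c(0, 0, 2))  # 90, perfectly stacked
#' elevationAngle(c(0, 0, 0), c(3, 4, 0))  # 0, same equatorial plane
#' @export
elevationAngle <- function(p, q) {
  d <- as.numeric(q) - as.numeric(p)
  nrm <- sqrt(sum(d^2))
  if (nrm < .DIST_TOL)
    stop("degenerate doublet: coincident centroids")
  ang <- abs(asin(d[3] / nrm)) * 180 / pi
  attr(ang, "radius") <- nrm / 2
  ang
}

# vectorized: dz and norm per edge
.elevationAngles <- function(dz, nrm) {
  if (any(nrm < .DIST_TOL))
    stop("degenerate doublet: coincident centroids")
  abs(asin(pmin(1, abs(dz) / nrm))) * 180 / pi
}

#' Classify a rotation as complete or incomplete
#'
#' Complete division-plane rotations correspond to elevation angles of
#' 60-90 degrees (exactly 60 counts as complete); incomplete rotations are
#' under 60 degrees.
#'
#' @param angle elevation angle(s) in degrees, in [0, 90].
#' @param cutoff classification cutoff in degrees (default 60).
#' @return Character vector, \code{"complete"} or \code{"incomplete"}.
#' @export
classifyRotation <- function(angle, cutoff = 60) {
  stopifnot(all(angle >= 0 & angle <= 90))
  ifelse(angle >= cutoff, "complete", "incomplete")
}

#' Bin an elevation angle into the seven reporting categories
#'
#' Bins are [0,15), [15,30), [30,45), [45,60), [60,70), [70,80) and
#' [80,90] (the last bin is closed).
#'
#' @param angle elevation angle(s) in degrees, in [0, 90].
#' @return Integer bin index 1..7.
#' @export
binElevation <- function(angle) {
  stopifnot(all(angle >= 0 & angle <= 90))
  findInterval(angle, .ELEVATION_BIN_LOWER, rightmost.closed = FALSE)
}

#' Build an elevation profile from a set of angles
#'
#' @param angles numeric vector of elevation angles in degrees.
#' @param cloneId optional clone label for bookkeeping.
#' @param cutoff complete-rotation cutoff in degrees.
#' @return An \code{\linkS4class{ElevationProfile}}; with no angles the
#'   complete fraction is \code{NA} (undefined, never 0).
#' @export
elevationProfile <- function(angles, cloneId = NA_integer_, cutoff = 60) {
  n <- length(angles)
  if (!n)
    return(new("ElevationProfile", cloneId = as.integer(cloneId),
               counts = integer(7), binMeans = rep(NA_real_, 7),
               completeFraction = NA_real_, nDoublets = 0L))
  b <- binElevation(angles)
  counts <- tabulate(b, 7L)
  means <- vapply(1:7, function(i)
    if (counts[i]) mean(angles[b == i]) else NA_real_, numeric(1))
  new("ElevationProfile", cloneId = as.integer(cloneId),
      counts = as.integer(counts), binMeans = means,
      completeFraction = mean(angles >= cutoff), nDoublets = n)
}

#' Per-doublet elevation table
#'
#' Computes the elevation angle, bin and rotation class for every doublet
#' edge of every clone.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param doublets list of \code{\linkS4class{DoubletSet}} from
#'   \code{\link{identifyDoublets}} on the same object.
#' @param cutoff complete-rotation cutoff in degrees.
#' @return data.frame with columns \code{clone_id, id_a, id_b, distance_um,
#'   elevation_deg, bin, rotation_class}.
#' @export
doubletElevationTable <- function(x, doublets, cutoff = 60) {
  df <- nuclei(x)
  tab <- doubletTable(doublets)
  if (!nrow(tab))
    return(cbind(tab, elevation_deg = numeric(0), bin = integer(0),
                 rotation_class = character(0)))
  za <- df$z[match(tab$id_a, df$id)]
  zb <- df$z[match(tab$id_b, df$id)]
  ang <- .elevationAngles(zb - za, tab$distance_um)
  tab$elevation_deg <- ang
  tab$bin <- binElevation(ang)
  tab$rotation_class <- classifyRotation(ang, cutoff)
  tab
}

#' Per-clone elevation profile of doublet angles
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param doublets list of \code{\linkS4class{DoubletSet}} for \code{x}.
#' @param cutoff complete-rotation cutoff in degrees.
#' @return Named list of \code{\linkS4class{ElevationProfile}}, one per
#'   clone (clones without doublets get an empty, flagged profile).
#' @export
cloneElevationProfiles <- function(x, doublets, cutoff = 60) {
  tab <- doubletElevationTable(x, doublets, cutoff)
  ids <- cloneIds(x)
  out <- lapply(ids, function(ci)
    elevationProfile(tab$elevation_deg[tab$clone_id == ci], ci, cutoff))
  names(out) <- ids
  out
}

#' Long-format elevation profile table
#'
#' Stacked-histogram-ready: one row per clone and bin.
#'
#' @param profiles list of \code{\linkS4class{ElevationProfile}}.
#' @return data.frame with columns \code{clone_id, bin, bin_label, count,
#'   fraction, mean_angle_deg, complete_fraction, n_doublets}.
#' @export
elevationProfileTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(clone_id = p@cloneId, bin = 1:7,
               bin_label = .ELEVATION_BIN_LABELS, count = p@counts,
               fraction = if (p@nDoublets) p@counts / p@nDoublets
                          else NA_real_,
               mean_angle_deg = p@binMeans,
               complete_fraction = p@completeFraction,
               n_doublets = p@nDoublets)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of complete-rotation proportions to neighbour count
#'
#' For each k in \code{kRange}, doublet edges are restricted to
#' k-nearest-neighbour pairs and the proportion of elevation angles of
#' 60-90 degrees is computed per clone, split by column/cluster class.
#' A two-sided two-sample t-test then compares the per-clone proportions
#' between the low-k and high-k groups within each class.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param doublets list of \code{\linkS4class{DoubletSet}} for \code{x}.
#' @param classes named character vector mapping clone id to
#'   \code{"column"}/\code{"cluster"} (see \code{\link{cloneShapeTable}}).
#' @param kRange integer vector of neighbour counts (default 1:10).
#' @param lowK,highK the two k-groups compared (defaults 1:5 vs 6:10).
#' @param cutoff complete-rotation cutoff in degrees.
#' @return List with \code{table} (clone_id, class, k, n_doublets,
#'   complete_fraction) and \code{tests} (class, p_value, mean_low,
#'   mean_high).
#' @export
neighborSensitivity <- function(x, doublets, classes, kRange = 1:10,
                                lowK = 1:5, highK = 6:10, cutoff = 60) {
  if (is.null(classes) || !length(classes))
    stop("clone classes missing: classify clones first (see cloneShapeTable)")
  ids <- cloneIds(x)
  rows <- list()
  for (ci in ids) {
    pts <- clonePoints(x, ci)
    ds <- doublets[[as.character(ci)]]
    if (is.null(ds) || !nrow(edges(ds))) next
    cls <- classes[[as.character(ci)]]
    if (is.null(cls) || is.na(cls))
      stop("clone ", ci, " has no class label")
    df <- nuclei(x)
    for (k in kRange) {
      e <- edges(knnRestrict(pts, ds, k))
      if (!nrow(e)) next
      za <- df$z[match(e$id_a, df$id)]
      zb <- df$z[match(e$id_b, df$id)]
      ang <- .elevationAngles(zb - za, e$distance)
      rows[[length(rows) + 1L]] <-
        data.frame(clone_id = ci, class = cls, k = k,
                   n_doublets = nrow(e),
                   complete_fraction = mean(ang >= cutoff))
    }
  }
  tab <- do.call(rbind, rows)
  tests <- lapply(unique(tab$class), function(cl) {
    lo <- tab$complete_fraction[tab$class == cl & tab$k %in% lowK]
    hi <- tab$complete_fraction[tab$class == cl & tab$k %in% highK]
    p <- tryCatch(stats::t.test(lo, hi)$p.value, error = function(e)
      NA_real_)
    data.frame(class = cl, p_value = p, mean_low = mean(lo),
               mean_high = mean(hi))
  })
  list(table = tab, tests = do.call(rbind, tests))
}
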