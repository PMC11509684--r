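#' Growth-plate elongation distance
#'
#' With the bone aligned so the P-D axis is vertical, elongation is the
#' distance from the median Z coordinate of the COJ voxels to the
#' longitudinal origin of the bone (an input; defined anatomically as the
#' thinnest point of the cartilaginous template).
#'
#' @param coj a \code{\linkS4class{COJSurface}}.
#' @param originZ longitudinal origin, um.
#' @param mirror negate Z first (orientation convention for distal growth
#'   plates).
#' @return Distance in micrometres.
#' @export
elongationDistance <- function(coj, originZ, mirror = FALSE) {
  z <- voxels(coj)[, 3]
  if (!length(z)) stop("empty voxel set")
  if (mirror) z <- -z
  abs(stats::median(z) - originZ)
}

#' Equivalent radius of a COJ surface
#'
#' PCA aligns the voxel cloud so its smallest-variance axis is the surface
#' normal; voxels are projected onto the principal plane and rasterized on
#' a grid with cell size equal to the voxel pitch. The in-plane grid axes
#' are the projections of the world axes most parallel to the plane, so
#' that the rasterization grid stays registered with the acquisition voxel
#' lattice (a grid rotated against the lattice would collapse distinct
#' voxels into shared cells and underestimate the footprint). The projected
#' area A is the occupied cell count times pitch^2 and the equivalent
#' radius is sqrt(A / pi), the radius of the circle with the same footprint
#' area.
#'
#' @param coj a \code{\linkS4class{COJSurface}} with >= 3 non-collinear
#'   voxels.
#' @return Equivalent radius in micrometres.
#' @export
equivalentRadius <- function(coj) {
  v <- voxels(coj)
  if (nrow(v) < 3L) stop("need at least 3 voxels")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2] < 1e-9)
    stop("degenerate (collinear) voxel set")
  normal <- pc$rotation[, 3]
  # in-plane basis: world axis most parallel to the plane, projected
  e <- diag(3)[, which.min(abs(normal))]
  u <- e - sum(e * normal) * normal
  u <- u / sqrt(sum(u^2))
  w <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  s <- sweep(v, 2, colMeans(v)) %*% cbind(u, w)
  # symmetric binning: cells are centred on the grid
  cells <- unique(round(sweep(s, 2, pitch(coj), `/`)))
  area <- nrow(cells) * pitch(coj)^2
  sqrt(area / pi)
}

#' Single-stage growth measurement
#'
#' @param distance elongation distance, um (see
#'   \code{\link{elongationDistance}}).
#' @param radius equivalent radius, um (see \code{\link{equivalentRadius}}).
#' @param time stage time, days.
#' @return A list of class \code{growthMeasurement}.
#' @export
growthMeasurement <- function(distance, radius, time) {
  stopifnot(radius >= 0)
  structure(list(distance = distance, radius = radius, time = time),
            class = "growthMeasurement")
}

#' Measure one COJ surface
#'
#' @param coj a \code{\linkS4class{COJSurface}} with its stage time set.
#' @param originZ longitudinal origin, um.
#' @param mirror see \code{\link{elongationDistance}}.
#' @return A \code{\link{growthMeasurement}}.
#' @export
measureCOJ <- function(coj, originZ, mirror = FALSE) {
  growthMeasurement(elongationDistance(coj, originZ, mirror),
                    equivalentRadius(coj), coj@time)
}

#' Elongation and expansion rates between two stages
#'
#' Elongation rate is the change in elongation distance per day; expansion
#' rate the change in equivalent radius per day; the expansion:elongation
#' (E:E) ratio is their quotient. Zero expansion gives an E:E of 0; a zero
#' elongation rate leaves the ratio undefined and flagged.
#'
#' @param m1,m2 \code{\link{growthMeasurement}} objects with
#'   \code{m2$time > m1$time}.
#' @return List with \code{elongation_rate} and \code{expansion_rate}
#'   (um/day), \code{ee_ratio}, and \code{ee_defined}.
#' @export
growthRates <- function(m1, m2) {
  stopifnot(m2$time > m1$time)
  dt <- m2$time - m1$time
  el <- (m2$distance - m1$distance) / dt
  ex <- (m2$radius - m1$radius) / dt
  if (el == 0) {
    warning("zero elongation rate; E:E ratio undefined")
    ee <- NA_real_
    def <- FALSE
  } else {
    ee <- ex / el
    def <- TRUE
  }
  list(elongation_rate = el, expansion_rate = ex, ee_ratio = ee,
       ee_defined = def)
}

#' Read a COJ voxel table
#'
#' @param path CSV with columns \code{x, y, z} (um).
#' @param pitch isotropic voxel edge, um.
#' @param bone,stage identifiers.
#' @param time stage time, days.
#' @return A \code{\linkS4class{COJSurface}}.
#' @export
readCOJTable <- function(path, pitch, bone = "bone", stage = "stage",
                         time = NA_real_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  COJSurface(df[, c("x", "y", "z")], pitch, bone, stage, time)
}
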