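#' Principal axes and ellipsoid ratios of a clone
#'
#' Unweighted PCA on the clone's nuclear centroids. PC1 is the long axis of
#' the clone, PC2 the medium axis and PC3 the short axis; axis lengths are
#' the standard deviations along the components (square roots of the
#' covariance eigenvalues, um). Ratios PC2/PC1, PC3/PC1 and PC3/PC2 near 1
#' indicate a spherical clone; near 0 a flattened ellipsoid. Two-nucleus
#' clones take the inter-centroid direction as PC1 with zero ratios.
#' Eigenvector signs are fixed (non-negative Z component, falling back to
#' the largest-magnitude component) so exports are deterministic.
#'
#' @param points centroid matrix of one clone (>= 2 rows, um).
#' @return List with \code{axes} (3x3 matrix, rows PC1..PC3), \code{lengths}
#'   (ordered standard deviations, um) and \code{ratios} (named pc2_pc1,
#'   pc3_pc1, pc3_pc2; 0/0 guarded to 0).
#' @export
principalAxes <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("clone shape undefined for a single nucleus")
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  lens <- numeric(3)
  lens[seq_along(pc$sdev)] <- pc$sdev
  axes <- matrix(0, 3, 3)
  axes[seq_len(ncol(pc$rotation)), ] <- t(pc$rotation)
  # complete a right-handed orthonormal triad for rank-deficient clouds
  if (ncol(pc$rotation) < 3L) {
    for (i in (ncol(pc$rotation) + 1L):3L) {
      cand <- diag(3)
      resid <- apply(cand, 1, function(v) {
        w <- v
        for (j in seq_len(i - 1L)) w <- w - sum(w * axes[j, ]) * axes[j, ]
        sqrt(sum(w^2))
      })
      w <- cand[which.max(resid), ]
      for (j in seq_len(i - 1L)) w <- w - sum(w * axes[j, ]) * axes[j, ]
      axes[i, ] <- w / sqrt(sum(w^2))
    }
  }
  for (i in 1:3) {
    v <- axes[i, ]
    s <- if (abs(v[3]) > 1e-9) sign(v[3]) else sign(v[which.max(abs(v))])
    axes[i, ] <- v * s
  }
  safe <- function(a, b) if (b < 1e-12) 0 else a / b
  list(axes = axes, lengths = lens,
       ratios = c(pc2_pc1 = safe(lens[2], lens[1]),
                  pc3_pc1 = safe(lens[3], lens[1]),
                  pc3_pc2 = safe(lens[3], lens[2])))
}

#' Alignment angle between a clone's long axis and the P-D axis
#'
#' The angle theta between PC1 and the P-D axis is computed as
#' \code{atan2(norm(cross(u, v)), dot(u, v))}; values above 90 degrees are
#' folded to 180 - theta (axes are directionless), and the result is
#' reported as 90 - theta so that a clone whose long axis is parallel to
#' the P-D axis reports 90 degrees and a perpendicular one reports 0,
#' matching the elevation-angle convention.
#'
#' @param pc1 nonzero 3-vector, the clone's long axis in canonical
#'   coordinates.
#' @param frame \code{\linkS4class{CanonicalFrame}} (the P-D axis is +Z in
#'   canonical coordinates).
#' @return Angle in degrees in [0, 90].
#' @export
pdAlignmentAngle <- function(pc1, frame = canonicalFrame()) {
  u <- as.numeric(pc1)
  if (sqrt(sum(u^2)) < 1e-12) stop("zero-length axis vector")
  v <- c(0, 0, 1)  # P-D axis in the canonical frame
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  theta <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
  if (theta > 90) theta <- 180 - theta
  90 - theta
}

#' Classify a clone as column or cluster
#'
#' A clone is a column when the reported angle between its long axis and
#' the P-D bone axis is 60-90 degrees (exactly 60 counts as column), and a
#' cluster below 60.
#'
#' @param pdAngle reported P-D alignment angle(s), degrees in [0, 90].
#' @param cutoff classification cutoff (default 60 degrees).
#' @return Character vector, \code{"column"} or \code{"cluster"}.
#' @export
classifyClone <- function(pdAngle, cutoff = 60) {
  stopifnot(all(pdAngle >= 0 & pdAngle <= 90))
  ifelse(pdAngle >= cutoff, "column", "cluster")
}

#' Convert a planar deviation threshold to the elevation convention
#'
#' 2D column criteria are stated as a deviation of the long axis from the
#' P-D axis (e.g. 12 degrees for single columns, 20 for multicolumns). In
#' the 3D spherical convention used here (angle from the equatorial plane)
#' these correspond to 90 minus the deviation: 78 and 70 degrees.
#'
#' @param planarDeviation deviation from the P-D axis, degrees in [0, 90].
#' @return \code{90 - planarDeviation}.
#' @export
threshold2dToElevation <- function(planarDeviation) {
  stopifnot(all(planarDeviation >= 0 & planarDeviation <= 90))
  90 - planarDeviation
}

#' Shape and orientation table for all clones
#'
#' Computes principal axes, ellipsoid ratios, P-D alignment angle and
#' column/cluster class per clone. The table doubles as the orientation-map
#' export: each clone contributes its centroid, PC1 direction and PC1
#' length, suitable for drawing orientation lines in two orthogonal 2D
#' projections.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param cutoff column/cluster cutoff in degrees.
#' @return data.frame with columns \code{clone_id, size, cx, cy, cz,
#'   pc1_x, pc1_y, pc1_z, pc_len_1, pc_len_2, pc_len_3, ratio_21, ratio_31,
#'   ratio_32, pd_angle_deg, class}. Singleton clones are omitted.
#' @export
cloneShapeTable <- function(x, cutoff = 60) {
  ids <- cloneIds(x)
  rows <- lapply(ids, function(ci) {
    pts <- clonePoints(x, ci)
    if (nrow(pts) < 2L) return(NULL)
    sh <- principalAxes(pts)
    ang <- pdAlignmentAngle(sh$axes[1, ], frameOf(x))
    ctr <- colMeans(pts)
    data.frame(clone_id = ci, size = nrow(pts),
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               pc1_x = sh$axes[1, 1], pc1_y = sh$axes[1, 2],
               pc1_z = sh$axes[1, 3],
               pc_len_1 = sh$lengths[1], pc_len_2 = sh$lengths[2],
               pc_len_3 = sh$lengths[3],
               ratio_21 = sh$ratios[["pc2_pc1"]],
               ratio_31 = sh$ratios[["pc3_pc1"]],
               ratio_32 = sh$ratios[["pc3_pc2"]],
               pd_angle_deg = ang,
               class = classifyClone(ang, cutoff))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(clone_id = integer(0), size = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      pc1_x = numeric(0), pc1_y = numeric(0),
                      pc1_z = numeric(0), pc_len_1 = numeric(0),
                      pc_len_2 = numeric(0), pc_len_3 = numeric(0),
                      ratio_21 = numeric(0), ratio_31 = numeric(0),
                      ratio_32 = numeric(0), pd_angle_deg = numeric(0),
                      class = character(0))
  rownames(out) <- NULL
  out
}
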