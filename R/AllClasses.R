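#' @import methods
NULL

.AXIS_LABELS <- c("+x", "-x", "+y", "-y", "+z", "-z")

#' Canonical proximal-distal coordinate frame
#'
#' The whole pipeline measures angles against the proximal-distal (P-D) bone
#' axis, which is fixed internally as the +Z axis of a canonical frame.
#' A \code{CanonicalFrame} declares which (signed) axis of the input data
#' corresponds to the P-D axis; canonicalization is the unique right-handed
#' rotation built from that declaration, so all pairwise distances are
#' preserved.
#'
#' @slot pdAxis unit 3-vector: the P-D axis expressed in input coordinates.
#' @slot sourceAxis one of \code{"+x","-x","+y","-y","+z","-z"}.
#' @slot rotation 3x3 rotation matrix mapping input to canonical coordinates
#'   (rows are the canonical X, Y, Z axes in input coordinates).
#' @export
setClass("CanonicalFrame",
  representation(pdAxis = "numeric", sourceAxis = "character",
                 rotation = "matrix"))

setValidity("CanonicalFrame", function(object) {
  msg <- NULL
  if (length(object@pdAxis) != 3L ||
      abs(sqrt(sum(object@pdAxis^2)) - 1) > 1e-9)
    msg <- c(msg, "pdAxis must be a unit 3-vector")
  if (!(object@sourceAxis %in% .AXIS_LABELS))
    msg <- c(msg, "sourceAxis must be one of +x,-x,+y,-y,+z,-z")
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-9 ||
      abs(det(R) - 1) > 1e-9)
    msg <- c(msg, "rotation must be a proper 3x3 rotation matrix")
  if (is.null(msg)) TRUE else msg
})

#' Construct a canonical frame from a signed axis label
#'
#' @param axis signed axis label naming which input axis is the P-D bone
#'   axis, e.g. \code{"+z"} (the default, identity frame) or \code{"-y"}
#'   (input -Y becomes canonical +Z).
#' @return A \code{\linkS4class{CanonicalFrame}}.
#' @examples
#' canonicalize(canonicalFrame("-y"), matrix(c(0, 5, 0), 1))  # -> (0, 0, -5)
#' @export
canonicalFrame <- function(axis = "+z") {
  axis <- match.arg(axis, .AXIS_LABELS)
  sgn <- if (substr(axis, 1, 1) == "-") -1 else 1
  ax <- substr(axis, 2, 2)
  e <- diag(3)
  idx <- match(ax, c("x", "y", "z"))
  w <- sgn * e[idx, ]
  # in-plane convention: canonical X is the next axis cyclically (x->y->z->x)
  u <- e[idx %% 3L + 1L, ]
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  new("CanonicalFrame", pdAxis = w, sourceAxis = axis,
      rotation = rbind(u, v, w, deparse.level = 0))
}

#' Apply a canonical frame to coordinates
#'
#' Rotates input coordinates so the declared P-D axis becomes +Z. An
#' isometry: pairwise distances are unchanged.
#'
#' @param frame a \code{\linkS4class{CanonicalFrame}}.
#' @param xyz numeric matrix with 3 columns (rows are points, micrometres).
#' @return Matrix of the same shape in canonical coordinates.
#' @export
canonicalize <- function(frame, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  out <- xyz %*% t(frame@rotation)
  dimnames(out) <- list(rownames(xyz), c("x", "y", "z"))
  out
}

.NUCLEUS_COLS <- c("id", "x", "y", "z", "clone_id", "color", "volume", "zone")
.COLORS <- c("cfp", "yfp", "rfp", "gfp", "synthetic")
.ZONES <- c("RZ", "PZ", "PHZ", "HZ", "unknown")

#' Set of labeled nuclei grouped into clones
#'
#' The central container: one row per segmented nucleus, with canonical
#' (P-D = Z) centroid coordinates in micrometres, the clone label, the
#' Confetti color channel, and (optionally) nuclear volume and growth-plate
#' zone.
#'
#' @slot nuclei data.frame with columns \code{id, x, y, z, clone_id, color,
#'   volume, zone}. Coordinates are canonical micrometres.
#' @slot frame the \code{\linkS4class{CanonicalFrame}} already applied to the
#'   coordinates.
#' @export
setClass("CloneSet",
  representation(nuclei = "data.frame", frame = "CanonicalFrame"))

setValidity("CloneSet", function(object) {
  df <- object@nuclei
  msg <- NULL
  missing <- setdiff(.NUCLEUS_COLS, names(df))
  if (length(missing))
    msg <- c(msg, paste("missing nucleus columns:",
                        paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(df)) {
    if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
      msg <- c(msg, "non-finite centroid coordinates")
    v <- df$volume
    if (any(!is.na(v) & v <= 0))
      msg <- c(msg, "nuclear volumes must be positive when present")
    if (anyDuplicated(df$id))
      msg <- c(msg, "duplicate nucleus ids")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CloneSet
#'
#' @param nuclei data.frame with at least \code{x, y, z, clone_id}; optional
#'   \code{id} (defaults to row number), \code{color}, \code{volume},
#'   \code{zone}.
#' @param frame \code{\linkS4class{CanonicalFrame}} describing the input
#'   orientation; coordinates are rotated into the canonical frame unless
#'   \code{canonicalized = TRUE}.
#' @param canonicalized set to \code{TRUE} when \code{nuclei} coordinates are
#'   already canonical (P-D on +Z).
#' @return A \code{\linkS4class{CloneSet}}.
#' @export
CloneSet <- function(nuclei, frame = canonicalFrame(), canonicalized = FALSE) {
  nuclei <- as.data.frame(nuclei)
  need <- c("x", "y", "z", "clone_id")
  missing <- setdiff(need, names(nuclei))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  n <- nrow(nuclei)
  if (is.null(nuclei$id)) nuclei$id <- seq_len(n)
  if (is.null(nuclei$color)) nuclei$color <- rep("synthetic", n)
  if (is.null(nuclei$volume)) nuclei$volume <- rep(NA_real_, n)
  if (is.null(nuclei$zone)) nuclei$zone <- rep("unknown", n)
  for (cc in c("x", "y", "z", "volume")) nuclei[[cc]] <- as.numeric(nuclei[[cc]])
  nuclei$id <- as.integer(nuclei$id)
  nuclei$clone_id <- as.integer(nuclei$clone_id)
  bad <- which(!is.finite(as.matrix(nuclei[, c("x", "y", "z")])),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite coordinate in row ", bad[1, 1])
  if (!canonicalized && n > 0) {
    xyz <- canonicalize(frame, as.matrix(nuclei[, c("x", "y", "z")]))
    nuclei[, c("x", "y", "z")] <- xyz
  }
  # keep row order within clone as given
  nuclei <- nuclei[order(nuclei$clone_id), , drop = FALSE]
  rownames(nuclei) <- NULL
  new("CloneSet", nuclei = nuclei[, .NUCLEUS_COLS], frame = frame)
}

#' Doublet edges of one clone
#'
#' The result of the sorted-edge single-connected-component procedure on a
#' clone: all nucleus pairs whose centroid distance does not exceed the
#' connectivity threshold \code{dStar} (the minimum-spanning-tree bottleneck
#' distance). Each retained edge is a doublet.
#'
#' @slot cloneId integer clone label.
#' @slot edges data.frame with columns \code{id_a, id_b, distance} (um).
#' @slot dStar connectivity threshold in micrometres (\code{NA} for
#'   singleton clones, whose edge set is empty).
#' @export
setClass("DoubletSet",
  representation(cloneId = "integer", edges = "data.frame", dStar = "numeric"))

setValidity("DoubletSet", function(object) {
  e <- object@edges
  msg <- NULL
  if (!all(c("id_a", "id_b", "distance") %in% names(e)))
    msg <- c(msg, "edges needs columns id_a, id_b, distance")
  if (!length(msg) && nrow(e) && !is.na(object@dStar) &&
      any(e$distance > object@dStar + 1e-9))
    msg <- c(msg, "edge distance exceeds dStar")
  if (is.null(msg)) TRUE else msg
})

#' Per-clone distribution of doublet elevation angles
#'
#' Seven-bin histogram of absolute elevation angles
#' ([0,15), [15,30), [30,45), [45,60), [60,70), [70,80), [80,90]) together
#' with the complete-rotation fraction (angles >= 60 degrees).
#'
#' @slot cloneId integer clone label (\code{NA} for pooled profiles).
#' @slot counts integer vector of length 7, one per bin.
#' @slot binMeans mean angle per bin (NA for empty bins).
#' @slot completeFraction proportion of doublets with angle >= 60 degrees
#'   (\code{NA} when there are no doublets).
#' @slot nDoublets number of doublets.
#' @export
setClass("ElevationProfile",
  representation(cloneId = "integer", counts = "integer",
                 binMeans = "numeric", completeFraction = "numeric",
                 nDoublets = "integer"))

setValidity("ElevationProfile", function(object) {
  msg <- NULL
  if (length(object@counts) != 7L)
    msg <- c(msg, "counts must have 7 bins")
  else if (sum(object@counts) != object@nDoublets)
    msg <- c(msg, "bin counts must sum to nDoublets")
  if (object@nDoublets > 0 &&
      (is.na(object@completeFraction) ||
       abs(object@completeFraction -
           sum(object@counts[5:7]) / object@nDoublets) > 1e-12))
    msg <- c(msg, "completeFraction must equal last-three-bin mass")
  if (is.null(msg)) TRUE else msg
})

#' Partition of clones into multiclones
#'
#' @slot groups named list mapping multiclone group id to member clone ids.
#' @slot merged a \code{\linkS4class{CloneSet}} whose \code{clone_id} column
#'   holds the multiclone group ids.
#' @slot threshold the merge distance in micrometres.
#' @export
setClass("MulticloneSet",
  representation(groups = "list", merged = "CloneSet", threshold = "numeric"))

#' Chondro-osseous junction voxel surface
#'
#' Voxel-centre coordinates (micrometres) of a COJ surface extracted from
#' micro-CT, with the isotropic voxel pitch and stage metadata.
#'
#' @slot voxels numeric matrix, one row per voxel (x, y, z in um).
#' @slot pitch isotropic voxel edge length, um.
#' @slot bone bone/growth-plate identifier.
#' @slot stage stage label (free text).
#' @slot time stage time in days (used for rate computations).
#' @export
setClass("COJSurface",
  representation(voxels = "matrix", pitch = "numeric", bone = "character",
                 stage = "character", time = "numeric"))

setValidity("COJSurface", function(object) {
  msg <- NULL
  if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must have 3 columns")
  if (!(length(object@pitch) == 1L && object@pitch > 0))
    msg <- c(msg, "pitch must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a COJSurface
#'
#' @param voxels matrix or data.frame of voxel coordinates (um).
#' @param pitch isotropic voxel edge (um).
#' @param bone,stage identifiers.
#' @param time stage time in days.
#' @return A \code{\linkS4class{COJSurface}}.
#' @export
COJSurface <- function(voxels, pitch, bone = "bone", stage = "stage",
                       time = NA_real_) {
  voxels <- as.matrix(voxels)
  colnames(voxels) <- c("x", "y", "z")
  new("COJSurface", voxels = voxels, pitch = as.numeric(pitch),
      bone = bone, stage = stage, time = as.numeric(time))
}
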