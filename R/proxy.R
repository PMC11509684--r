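#' Mutual-nearest matching of cell and nucleus centroids
#'
#' A cell and a nucleus are matched when each is the other's nearest
#' neighbour (mutual nearest) and their centroid distance is strictly less
#' than \code{maxDist} (default 20 um). Equidistant ties are broken by the
#' smallest id for determinism. Each cell and each nucleus appears in at
#' most one pair, and the procedure is symmetric in the two roles.
#'
#' @param cells,nucleiCoords data.frames with columns \code{id, x, y, z}
#'   (um), or plain 3-column matrices (ids default to row number).
#' @param maxDist maximum match distance, um.
#' @return data.frame with columns \code{cell_id, nucleus_id, distance_um}.
#' @export
matchCellsNuclei <- function(cells, nucleiCoords, maxDist = 20) {
  a <- .asPointFrame(cells)
  b <- .asPointFrame(nucleiCoords)
  if (!nrow(a) || !nrow(b)) stop("both centroid lists must be non-empty")
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  D2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * tcrossprod(am, bm)
  D2[D2 < 0] <- 0
  # smallest-id tie-break: rows/cols are in increasing id order and
  # which.min returns the first minimum
  nnOf <- function(M) apply(M, 1, which.min)
  nnA <- nnOf(D2)       # nearest nucleus per cell
  nnB <- nnOf(t(D2))    # nearest cell per nucleus
  keep <- which(nnB[nnA] == seq_along(nnA))
  d <- sqrt(D2[cbind(keep, nnA[keep])])
  ok <- d < maxDist
  data.frame(cell_id = a$id[keep][ok], nucleus_id = b$id[nnA[keep]][ok],
             distance_um = d[ok])
}

.asPointFrame <- function(p) {
  p <- as.data.frame(p)
  if (!all(c("x", "y", "z") %in% names(p))) {
    stopifnot(ncol(p) >= 3L)
    names(p)[1:3] <- c("x", "y", "z")
  }
  if (is.null(p$id)) p$id <- seq_len(nrow(p))
  p <- p[order(p$id), c("id", "x", "y", "z")]
  rownames(p) <- NULL
  p
}

#' Sample a random clone from matched cells
#'
#' Emulates clone construction in unlabelled data: candidate cells are the
#' matched cells inside a sphere of the given radius whose P-D coordinate
#' lies within a window of +/- \code{heightFrac} of the P-D height around
#' the sphere centre. When more candidates than the target size are found,
#' cells are pruned by repeatedly taking the current largest pairwise
#' distance and deleting its farther endpoint (larger mean distance to the
#' remaining candidates; ties broken by smallest id), re-sorting after each
#' deletion, until the target size is reached. Any remainder forms a single
#' connected component under \code{\link{identifyDoublets}} by construction
#' of the connectivity threshold.
#'
#' @param matchedCells data.frame \code{id, x, y, z} of matched cell
#'   centroids (um).
#' @param size target clone size, >= 2.
#' @param radius sphere radius, um.
#' @param center 3-vector sphere centre (its Z is the P-D position), um.
#' @param pdHeight total P-D height of the growth plate, um.
#' @param heightFrac window half-width as a fraction of \code{pdHeight}
#'   (default 0.15).
#' @return data.frame of the selected cells, or \code{NULL} when fewer
#'   candidates than \code{size} exist (sampling failure; caller
#'   resamples).
#' @export
sampleRandomClone <- function(matchedCells, size, radius, center,
                              pdHeight, heightFrac = 0.15) {
  stopifnot(size >= 2)
  p <- .asPointFrame(matchedCells)
  d <- sqrt((p$x - center[1])^2 + (p$y - center[2])^2 +
            (p$z - center[3])^2)
  inWin <- d <= radius & abs(p$z - center[3]) <= heightFrac * pdHeight
  cand <- p[inWin, , drop = FALSE]
  if (nrow(cand) < size) return(NULL)
  while (nrow(cand) > size) {
    m <- as.matrix(cand[, c("x", "y", "z")])
    D <- as.matrix(stats::dist(m))
    far <- which(D == max(D), arr.ind = TRUE)[1, ]
    meanD <- rowMeans(D)
    pick <- far[order(-meanD[far], cand$id[far])][1]
    cand <- cand[-pick, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Correlation of clone-mean elevation angles: cells vs nuclei
#'
#' For each clone, doublets are identified and elevation angles computed
#' twice, once on cell centroids and once on the paired nuclear centroids
#' (doublet graphs are recomputed per coordinate set, not frozen). The
#' Pearson correlation of the clone-mean angles across clones quantifies
#' how well nuclear centroids proxy cell centroids.
#'
#' @param cloneAssignments list; each element is an integer vector of pair
#'   indices (rows into the coordinate matrices) forming one clone.
#' @param cellCoords,nucleusCoords numeric matrices (n_pairs x 3, um),
#'   row i of each being a matched cell/nucleus pair.
#' @return List with \code{r} (Pearson correlation, \code{NA} with a
#'   warning when either vector has zero variance), \code{n} (number of
#'   clones used) and \code{table} (clone, mean_cell_deg,
#'   mean_nucleus_deg).
#' @export
elevationCorrelation <- function(cloneAssignments, cellCoords,
                                 nucleusCoords) {
  cellCoords <- as.matrix(cellCoords)
  nucleusCoords <- as.matrix(nucleusCoords)
  meanAngle <- function(pts) {
    if (nrow(pts) < 2L) return(NA_real_)
    rownames(pts) <- NULL
    e <- edges(identifyDoublets(pts))
    if (!nrow(e)) return(NA_real_)
    dz <- pts[e$id_b, 3] - pts[e$id_a, 3]
    mean(.elevationAngles(dz, e$distance))
  }
  mc <- vapply(cloneAssignments, function(i)
    meanAngle(cellCoords[i, , drop = FALSE]), numeric(1))
  mn <- vapply(cloneAssignments, function(i)
    meanAngle(nucleusCoords[i, , drop = FALSE]), numeric(1))
  ok <- !is.na(mc) & !is.na(mn)
  if (sum(ok) < 3L) stop("need at least 3 clones with doublets")
  if (stats::sd(mc[ok]) < 1e-12 || stats::sd(mn[ok]) < 1e-12) {
    warning("zero variance in clone-mean angles; correlation undefined")
    r <- NA_real_
  } else r <- stats::cor(mc[ok], mn[ok])
  list(r = r, n = sum(ok),
       table = data.frame(clone = seq_along(cloneAssignments),
                          mean_cell_deg = mc, mean_nucleus_deg = mn))
}
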