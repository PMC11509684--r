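#' Number of candidate edges in a clone
#'
#' All unordered nucleus pairs are candidate doublet edges: a clone with
#' five nuclei has 10 potential edges.
#'
#' @param n clone size (number of nuclei), n >= 1.
#' @return \code{n * (n - 1) / 2}.
#' @export
candidateEdgeCount <- function(n) {
  if (any(n < 1)) stop("clone size must be >= 1")
  n * (n - 1) / 2
}

# distance tie tolerance, micrometres
.DIST_TOL <- 1e-9

.pairwiseDistances <- function(points) {
  as.matrix(stats::dist(points))
}

#' Connectivity threshold distance of a point set
#'
#' The smallest distance d such that the graph on the points with all edges
#' of length <= d forms a single connected component. Edges are conceptually
#' added sorted from low to high until one connected component is achieved;
#' the threshold equals the largest edge of a minimum spanning tree (the
#' bottleneck distance). Computed by a Prim-style sweep in O(n^2).
#'
#' @param points numeric matrix of centroids (rows are points, um); at
#'   least 2 rows.
#' @return The connectivity threshold distance in micrometres.
#' @export
connectivityThreshold <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  D <- .pairwiseDistances(points)
  inTree <- rep(FALSE, n)
  inTree[1] <- TRUE
  best <- D[1, ]
  dStar <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    j <- cand[which.min(best[cand])]
    dStar <- max(dStar, best[j])
    inTree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  dStar
}

.doubletEdges <- function(points) {
  n <- nrow(points)
  ids <- suppressWarnings(as.integer(rownames(points)))
  if (length(ids) != n || anyNA(ids)) ids <- seq_len(n)
  if (n < 2L)
    return(list(edges = data.frame(id_a = integer(0), id_b = integer(0),
                                   distance = numeric(0)),
                dStar = NA_real_))
  dStar <- connectivityThreshold(points)
  D <- .pairwiseDistances(points)
  pair <- which(upper.tri(D) & D <= dStar + .DIST_TOL, arr.ind = TRUE)
  a <- pmin(ids[pair[, 1]], ids[pair[, 2]])
  b <- pmax(ids[pair[, 1]], ids[pair[, 2]])
  o <- order(a, b)
  list(edges = data.frame(id_a = a[o], id_b = b[o],
                          distance = D[pair][o]),
       dStar = dStar)
}

#' Identify doublets by the single-connected-component procedure
#'
#' Pairwise centroid distances within a clone are sorted from low to high
#' and added as edges until the clone's nuclei form a single connected
#' component; every retained edge is a doublet. This is realised
#' order-independently as the threshold graph at the connectivity radius:
#' all pairs with distance <= d* (ties at d* included, tolerance 1e-9 um).
#' A five-nucleus clone in a linear topology therefore yields 4 doublets,
#' while a spherical-like topology can yield all 10.
#'
#' @param x a \code{\linkS4class{CloneSet}}, or a numeric centroid matrix
#'   for a single clone (optionally with nucleus ids as rownames).
#' @param ... unused.
#' @return For a matrix, a \code{\linkS4class{DoubletSet}}; for a
#'   \code{CloneSet}, a named list of \code{DoubletSet}, one per clone
#'   (singleton clones yield an empty edge set with \code{dStar = NA}).
#' @examples
#' pts <- cbind(x = 0:4, y = 0, z = 0)  # linear topology
#' edges(identifyDoublets(pts))         # 4 doublets
#' @name identifyDoublets
NULL

#' @rdname identifyDoublets
#' @export
setMethod("identifyDoublets", "matrix", function(x, ...) {
  res <- .doubletEdges(x)
  new("DoubletSet", cloneId = NA_integer_, edges = res$edges,
      dStar = res$dStar)
})

#' @rdname identifyDoublets
#' @export
setMethod("identifyDoublets", "CloneSet", function(x, ...) {
  ids <- cloneIds(x)
  out <- lapply(ids, function(ci) {
    res <- .doubletEdges(clonePoints(x, ci))
    new("DoubletSet", cloneId = as.integer(ci), edges = res$edges,
        dStar = res$dStar)
  })
  names(out) <- ids
  out
})

#' Restrict a doublet set to k-nearest-neighbour edges
#'
#' Keeps an edge (i, j) when j is among the k nearest member nuclei of i or
#' i is among the k nearest of j (ties at the k-th distance included). With
#' k >= clone size - 1 the input is returned unchanged. Used to test the
#' sensitivity of elevation statistics to the number of neighbours
#' considered.
#'
#' @param points centroid matrix of the clone (nucleus ids as rownames).
#' @param doublets the clone's \code{\linkS4class{DoubletSet}}.
#' @param k number of nearest neighbours, >= 1.
#' @return A \code{\linkS4class{DoubletSet}} with the restricted edge set.
#' @export
knnRestrict <- function(points, doublets, k) {
  stopifnot(k >= 1)
  e <- edges(doublets)
  n <- nrow(points)
  if (n < 2L || !nrow(e) || k >= n - 1L) return(doublets)
  ids <- suppressWarnings(as.integer(rownames(points)))
  if (length(ids) != n || anyNA(ids)) ids <- seq_len(n)
  D <- .pairwiseDistances(points)
  diag(D) <- Inf
  # k-th neighbour radius per nucleus, ties included
  kthR <- apply(D, 1, function(d) sort(d)[k])
  names(kthR) <- ids
  ra <- kthR[as.character(e$id_a)]
  rb <- kthR[as.character(e$id_b)]
  keep <- e$distance <= ra + .DIST_TOL | e$distance <= rb + .DIST_TOL
  new("DoubletSet", cloneId = doublets@cloneId,
      edges = e[keep, , drop = FALSE], dStar = dStar(doublets))
}

#' Combined doublet table for a clone set
#'
#' @param doublets list of \code{\linkS4class{DoubletSet}} as returned by
#'   \code{\link{identifyDoublets}} on a \code{CloneSet}.
#' @return data.frame with columns \code{clone_id, id_a, id_b, distance_um}.
#' @export
doubletTable <- function(doublets) {
  rows <- lapply(doublets, function(d) {
    e <- edges(d)
    if (!nrow(e)) return(NULL)
    data.frame(clone_id = d@cloneId, id_a = e$id_a, id_b = e$id_b,
               distance_um = e$distance)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(clone_id = integer(0), id_a = integer(0),
                      id_b = integer(0), distance_um = numeric(0))
  rownames(out) <- NULL
  out
}

#' Per-clone connectivity threshold table
#'
#' @param doublets list of \code{\linkS4class{DoubletSet}}.
#' @return data.frame with columns \code{clone_id, n_doublets, d_star_um}.
#' @export
dStarTable <- function(doublets) {
  data.frame(clone_id = vapply(doublets, slot, integer(1), "cloneId"),
             n_doublets = vapply(doublets, function(d) nrow(edges(d)),
                                 integer(1)),
             d_star_um = vapply(doublets, dStar, numeric(1)),
             row.names = NULL)
}
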