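# Shared fixtures and independent oracles, built in code.

# Brute-force doublet oracle: scan every distinct pairwise distance as a
# threshold (plain BFS connectivity, no package code) and return the edge
# set at the smallest threshold where the graph is one connected component.
bruteForceDoublets <- function(pts) {
  D <- as.matrix(dist(pts))
  n <- nrow(pts)
  connected <- function(adj) {
    seen <- logical(n)
    seen[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    all(seen)
  }
  for (d in sort(unique(D[upper.tri(D)]))) {
    adj <- D <= d + 1e-9
    diag(adj) <- FALSE
    if (connected(adj)) {
      idx <- which(upper.tri(D) & D <= d + 1e-9, arr.ind = TRUE)
      o <- order(idx[, 1], idx[, 2])
      return(list(dStar = d,
                  edges = cbind(a = idx[o, 1], b = idx[o, 2])))
    }
  }
}

# random rigid motion (rotation + translation)
randomRigidMotion <- function(pts) {
  M <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(pts %*% t(R), 2, runif(3, -50, 50), `+`)
}

# CloneSet from a bare centroid matrix, one clone
cloneFromPoints <- function(pts, cloneId = 1L) {
  CloneSet(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      clone_id = cloneId),
           canonicalized = TRUE)
}

# unit square corners in XY plus an apex on the square's central axis,
# farther from each corner than the square diagonal: the spherical-like
# limit case where the graph only connects at the maximum pairwise distance
squarePlusApex <- function(height = 2) {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
        c(0.5, 0.5, height))
}

# pooled doublet elevations of n size-2 clones with the given mixture
# (a size-2 clone's single doublet angle is exactly the drawn division
# angle, so the pooled set samples the mixture directly)
doubletLevelAngles <- function(n, pComplete, seed, ...) {
  set.seed(seed)
  seeds <- sample.int(2^30, n)
  vapply(seeds, function(s) {
    cl <- simulateClone(2, pComplete, seed = s, ...)
    doubletElevationTable(cl, identifyDoublets(cl))$elevation_deg
  }, numeric(1))
}
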