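#' Synthetic growth-plate configuration
#'
#' Defaults describe a desk-scale postnatal-like growth plate: 100 clones
#' of 2-30 nuclei, 30 percent grown in column mode (high probability of
#' complete division-plane rotations) and the rest in cluster mode, with
#' 10 um inter-sister spacing in a 500 x 500 x 300 um box. Within-class
#' rotation angles default to uniform on the class interval ([60, 90] for
#' complete, [0, 60) for incomplete), the maximum-entropy choice.
#'
#' @param nClones number of clones.
#' @param sizeRange inclusive clone-size range (nuclei per clone, 2-100
#'   supported).
#' @param columnFraction fraction of clones grown with
#'   \code{pCompleteColumn}.
#' @param pCompleteColumn,pCompleteCluster probability that a division's
#'   elevation angle is drawn from the complete (>= 60 degree) mixture
#'   component, per generator class.
#' @param completeDist,incompleteDist samplers \code{function(n)} returning
#'   angles in degrees on [60, 90] and [0, 60) respectively.
#' @param step inter-sister centroid spacing, um.
#' @param plateExtent box dimensions (x, y, z), um.
#' @param cellNucleusOffsetSigma isotropic cell-nucleus offset SD, um.
#' @return A list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nClones = 100,
                            sizeRange = c(2, 30),
                            columnFraction = 0.3,
                            pCompleteColumn = 0.8,
                            pCompleteCluster = 0.15,
                            completeDist = function(n) stats::runif(n, 60, 90),
                            incompleteDist = function(n) stats::runif(n, 0, 60),
                            step = 10,
                            plateExtent = c(500, 500, 300),
                            cellNucleusOffsetSigma = 1) {
  stopifnot(columnFraction >= 0, columnFraction <= 1,
            pCompleteColumn >= 0, pCompleteColumn <= 1,
            pCompleteCluster >= 0, pCompleteCluster <= 1,
            sizeRange[1] >= 2, sizeRange[2] <= 100, step > 0)
  structure(as.list(environment()), class = "syntheticConfig")
}

# draw one division's elevation angle (degrees) from the mixture
.sampleElevation <- function(n, pComplete, completeDist, incompleteDist) {
  complete <- stats::runif(n) < pComplete
  out <- numeric(n)
  if (any(complete)) out[complete] <- completeDist(sum(complete))
  if (any(!complete)) out[!complete] <- incompleteDist(sum(!complete))
  out
}

# grow one clone with the current RNG stream
.growClone <- function(size, pComplete, step, completeDist, incompleteDist,
                       minSpacingFactor = 0.5, maxTries = 2000L) {
  pts <- matrix(0, nrow = size, ncol = 3)
  if (size == 1L) return(pts[1, , drop = FALSE])
  minSp <- minSpacingFactor * step
  for (i in 2:size) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      parent <- pts[sample.int(i - 1L, 1L), ]
      phi <- .sampleElevation(1, pComplete, completeDist, incompleteDist) *
        pi / 180
      # mirror symmetry: a doublet's elevation is sign-free, so sisters
      # may stack upward or downward
      phi <- phi * sample(c(-1, 1), 1)
      theta <- stats::runif(1, 0, 2 * pi)
      cand <- parent + step * c(cos(phi) * cos(theta),
                                cos(phi) * sin(theta), sin(phi))
      d <- sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2,
                              cand)^2))
      if (min(d) >= minSp - 1e-12) { pts[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not place nucleus ", i,
                      " at the requested spacing")
  }
  pts
}

#' Simulate one clone by sequential divisions
#'
#' Growth starts from a single nucleus at the origin; each new nucleus is
#' placed at distance \code{step} from a uniformly chosen existing nucleus,
#' in a direction whose elevation angle is drawn from the complete
#' component with probability \code{pComplete} and from the incomplete
#' component otherwise (azimuth uniform; elevation sign random, since a
#' doublet's elevation angle is mirror-symmetric). Rejection sampling keeps
#' every inter-nucleus distance at least half a step.
#'
#' @param size clone size, >= 1.
#' @param pComplete probability of a complete (>= 60 degree) rotation per
#'   division.
#' @param step inter-sister spacing, um.
#' @param seed RNG seed (required: every stochastic call is seeded).
#' @param completeDist,incompleteDist angle samplers, see
#'   \code{\link{syntheticConfig}}.
#' @return A \code{\linkS4class{CloneSet}} with one clone (clone_id 1,
#'   synthetic color, volume 600 um^3).
#' @export
simulateClone <- function(size, pComplete, step = 10, seed,
                          completeDist = function(n) stats::runif(n, 60, 90),
                          incompleteDist = function(n) stats::runif(n, 0, 60)) {
  if (size < 1) stop("clone size must be >= 1")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  pts <- .growClone(size, pComplete, step, completeDist, incompleteDist)
  CloneSet(data.frame(id = seq_len(size), x = pts[, 1], y = pts[, 2],
                      z = pts[, 3], clone_id = 1L, color = "synthetic",
                      volume = 600, zone = "unknown"),
           canonicalized = TRUE)
}

#' Simulate a growth plate of column- and cluster-grown clones
#'
#' Generates \code{round(nClones * columnFraction)} clones in column mode
#' and the remainder in cluster mode, places each at a uniform position in
#' the plate box (rejecting placements that bring nuclei of different
#' clones closer than half a step), and records the generator truth per
#' clone.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param seed RNG seed.
#' @return List with \code{clones} (a \code{\linkS4class{CloneSet}}) and
#'   \code{truth} (data.frame: clone_id, class_truth, p_complete, size).
#' @export
simulateGrowthPlate <- function(config = syntheticConfig(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- config$nClones
  if (n == 0)
    return(list(clones = CloneSet(data.frame(x = numeric(0),
                                             y = numeric(0),
                                             z = numeric(0),
                                             clone_id = integer(0)),
                                  canonicalized = TRUE),
                truth = data.frame(clone_id = integer(0),
                                   class_truth = character(0),
                                   p_complete = numeric(0),
                                   size = integer(0))))
  nCol <- round(n * config$columnFraction)
  isColumn <- seq_len(n) <= nCol
  sizes <- sample(seq(config$sizeRange[1], config$sizeRange[2]), n,
                  replace = TRUE)
  placedAll <- NULL
  rows <- vector("list", n)
  minSp <- 0.5 * config$step
  for (ci in seq_len(n)) {
    p <- if (isColumn[ci]) config$pCompleteColumn else
      config$pCompleteCluster
    pts <- .growClone(sizes[ci], p, config$step, config$completeDist,
                      config$incompleteDist)
    ok <- FALSE
    for (try in 1:500) {
      off <- stats::runif(3) * config$plateExtent
      cand <- sweep(pts, 2, off, `+`)
      if (is.null(placedAll) ||
          .minInterDistance(cand, placedAll) >= minSp) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: box too small for requested clones")
    placedAll <- rbind(placedAll, cand)
    rows[[ci]] <- data.frame(x = cand[, 1], y = cand[, 2], z = cand[, 3],
                             clone_id = ci)
  }
  df <- do.call(rbind, rows)
  df$id <- seq_len(nrow(df))
  df$color <- "synthetic"
  df$volume <- 600
  df$zone <- "unknown"
  list(clones = CloneSet(df, canonicalized = TRUE),
       truth = data.frame(clone_id = seq_len(n),
                          class_truth = ifelse(isColumn, "column",
                                               "cluster"),
                          p_complete = ifelse(isColumn,
                                              config$pCompleteColumn,
                                              config$pCompleteCluster),
                          size = sizes))
}

#' Simulate paired cell and nucleus centroids
#'
#' Nuclear centroids are taken from the clone set; cell centroids are the
#' nuclei plus isotropic Gaussian offsets, emulating the imperfect
#' concentricity of cell and nucleus.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param offsetSigma isotropic offset SD, um (>= 0).
#' @param seed RNG seed.
#' @return List with \code{cells} and \code{nucleiCoords}: data.frames
#'   \code{id, x, y, z, clone_id}, row-aligned pairs.
#' @export
simulateCellsAndNuclei <- function(x, offsetSigma, seed) {
  stopifnot(offsetSigma >= 0)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  df <- nuclei(x)
  nuc <- df[, c("id", "x", "y", "z", "clone_id")]
  cells <- nuc
  if (nrow(cells))
    cells[, c("x", "y", "z")] <- cells[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(cells), 0, offsetSigma), ncol = 3)
  list(cells = cells, nucleiCoords = nuc)
}

#' Simulate a chondro-osseous-junction voxel surface
#'
#' A disc of the given radius is voxelized on an in-plane grid at the voxel
#' pitch, tilted about the X axis, jittered along the surface normal and
#' translated along Z.
#'
#' @param radius disc radius, um.
#' @param tilt tilt about the X axis, degrees.
#' @param pitch voxel edge, um.
#' @param noiseSigma Gaussian jitter SD along the surface normal, um.
#' @param zOffset translation along Z, um.
#' @param seed RNG seed.
#' @param bone,stage,time metadata passed to the surface.
#' @return A \code{\linkS4class{COJSurface}}.
#' @export
simulateCOJ <- function(radius, tilt = 0, pitch = 7, noiseSigma = 0,
                        zOffset = 0, seed, bone = "synthetic",
                        stage = "synthetic", time = NA_real_) {
  stopifnot(radius > 0, pitch > 0)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  g <- seq(-radius, radius, by = pitch)
  grid <- expand.grid(x = g, y = g)
  grid <- grid[grid$x^2 + grid$y^2 <= radius^2, ]
  t <- tilt * pi / 180
  y <- grid$y * cos(t)
  z <- grid$y * sin(t)
  normal <- c(0, -sin(t), cos(t))
  jit <- stats::rnorm(nrow(grid), 0, noiseSigma)
  v <- cbind(x = grid$x + jit * normal[1],
             y = y + jit * normal[2],
             z = z + jit * normal[3] + zOffset)
  COJSurface(v, pitch, bone, stage, time)
}
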