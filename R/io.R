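#' Read a nucleus centroid table
#'
#' Reads a delimited table of nuclear centroids (micrometres) with columns
#' \code{x, y, z, clone_id} and optional \code{id, color, volume, zone},
#' rotates the coordinates into the canonical frame (P-D on +Z) and groups
#' records by clone.
#'
#' @param path CSV or TSV file with a header row (delimiter auto-detected
#'   from the extension: \code{.tsv}/\code{.txt} means tab).
#' @param frame \code{\linkS4class{CanonicalFrame}} declaring which input
#'   axis is the P-D bone axis.
#' @return A \code{\linkS4class{CloneSet}}.
#' @export
readNucleusTable <- function(path, frame = canonicalFrame()) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "clone_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  CloneSet(df, frame = frame)
}

#' Write a nucleus centroid table
#'
#' Writes canonical-frame coordinates; reading the file back with the
#' identity frame round-trips clone membership and centroids.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNucleusTable <- function(x, path) {
  utils::write.csv(nuclei(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract nucleus records from a 3D label mask
#'
#' One record per nonzero label. Voxel grid positions are 0-based, so a
#' voxel at array index \code{(i, j, k)} sits at
#' \code{((i, j, k) - 1) * voxelSize} micrometres; the centroid is the mean
#' position over the label's voxels and the volume is the voxel count times
#' the voxel volume.
#'
#' @param mask 3D integer array (0 = background), or the path to a
#'   multi-page TIFF label image (pages are Z slices).
#' @param voxelSize length-3 positive numeric, micrometres per voxel along
#'   (x, y, z).
#' @return data.frame with columns \code{id, x, y, z, volume}.
#' @export
centroidsFromLabelMask <- function(mask, voxelSize) {
  if (is.character(mask)) mask <- readLabelMask(mask)
  voxelSize <- as.numeric(voxelSize)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (length(voxelSize) != 3L || any(!is.finite(voxelSize)) ||
      any(voxelSize <= 0))
    stop("config error: voxelSize must be 3 positive values")
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  idx <- which(mask != 0)
  if (!length(idx))
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), volume = numeric(0)))
  labels <- as.integer(mask[idx])
  ai <- arrayInd(idx, dim(mask))
  coords <- sweep(ai - 1, 2, voxelSize, `*`)
  ids <- sort(unique(labels))
  vpv <- prod(voxelSize)
  out <- lapply(ids, function(l) {
    rows <- labels == l
    c(colMeans(coords[rows, , drop = FALSE]), sum(rows) * vpv)
  })
  out <- do.call(rbind, out)
  data.frame(id = ids, x = out[, 1], y = out[, 2], z = out[, 3],
             volume = out[, 4])
}

#' Read a multi-page TIFF label image as a 3D integer array
#'
#' @param path TIFF file; each page is one Z slice.
#' @return 3D integer array indexed (x, y, z).
#' @export
readLabelMask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                           length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(t(pages[[k]]))
  arr
}

#' Write a 3D integer label array as a multi-page TIFF
#'
#' @param mask 3D integer array indexed (x, y, z).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  mx <- max(mask)
  bits <- if (mx < 2^8) 8L else if (mx < 2^16) 16L else 32L
  pages <- lapply(seq_len(dim(mask)[3]),
                  function(k) t(mask[, , k]) / (2^bits - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Volume filter specification
#'
#' Defaults follow the study's feature-extraction filters: nuclei are kept
#' in the inclusive volume range 100-1200 um^3; clone surfaces are kept when
#' strictly greater than 150 um^3. The clone volume upper bound is
#' configurable and unbounded by default.
#'
#' @param nucleusVolumeRange inclusive [min, max] nuclear volume, um^3.
#' @param cloneSurfaceMin clones with total volume strictly greater than
#'   this are kept, um^3.
#' @param cloneVolumeMax optional upper bound on clone volume, um^3.
#' @return A list of class \code{filterSpec}.
#' @export
filterSpec <- function(nucleusVolumeRange = c(100, 1200),
                       cloneSurfaceMin = 150,
                       cloneVolumeMax = Inf) {
  stopifnot(length(nucleusVolumeRange) == 2L,
            nucleusVolumeRange[1] < nucleusVolumeRange[2])
  structure(list(nucleusVolumeRange = nucleusVolumeRange,
                 cloneSurfaceMin = cloneSurfaceMin,
                 cloneVolumeMax = cloneVolumeMax),
            class = "filterSpec")
}

#' Apply volume filters to a CloneSet
#'
#' Removes nuclei whose volume falls outside the inclusive nuclear range,
#' then removes clones whose total volume (sum of remaining nuclear volumes)
#' is not strictly greater than \code{cloneSurfaceMin} or exceeds
#' \code{cloneVolumeMax}. Records without a volume pass with a warning.
#' Filtering is idempotent.
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param spec a \code{\link{filterSpec}}.
#' @return Filtered \code{\linkS4class{CloneSet}}.
#' @export
applyFilters <- function(x, spec = filterSpec()) {
  df <- nuclei(x)
  if (!nrow(df)) return(x)
  v <- df$volume
  if (anyNA(v))
    warning(sum(is.na(v)), " nuclei lack a volume and pass unfiltered")
  keep <- is.na(v) | (v >= spec$nucleusVolumeRange[1] &
                      v <= spec$nucleusVolumeRange[2])
  df <- df[keep, , drop = FALSE]
  if (nrow(df)) {
    cv <- tapply(df$volume, df$clone_id, function(w)
      if (all(is.na(w))) NA_real_ else sum(w, na.rm = TRUE))
    drop <- names(cv)[!is.na(cv) & (cv <= spec$cloneSurfaceMin |
                                    cv > spec$cloneVolumeMax)]
    df <- df[!(as.character(df$clone_id) %in% drop), , drop = FALSE]
  }
  rownames(df) <- NULL
  new("CloneSet", nuclei = df, frame = frameOf(x))
}
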