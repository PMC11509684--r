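#' Accessors for CloneSet objects
#'
#' @param x a \code{\linkS4class{CloneSet}}.
#' @param cloneId integer clone label.
#' @return \code{nuclei} returns the nucleus data.frame; \code{frameOf} the
#'   \code{\linkS4class{CanonicalFrame}}; \code{cloneIds} the sorted clone
#'   labels; \code{cloneSizes} a named integer vector of nucleus counts
#'   (clone size is defined as the number of nuclei); \code{clonePoints}
#'   the centroid matrix of one clone with nucleus ids as rownames.
#' @name CloneSet-accessors
NULL

#' @rdname CloneSet-accessors
#' @export
setMethod("nuclei", "CloneSet", function(x) x@nuclei)

#' @rdname CloneSet-accessors
#' @export
setMethod("frameOf", "CloneSet", function(x) x@frame)

#' @rdname CloneSet-accessors
#' @export
setMethod("cloneIds", "CloneSet", function(x)
  sort(unique(x@nuclei$clone_id)))

#' @rdname CloneSet-accessors
#' @export
setMethod("cloneSizes", "CloneSet", function(x) {
  ids <- cloneIds(x)
  out <- vapply(ids, function(i) sum(x@nuclei$clone_id == i), integer(1))
  names(out) <- ids
  out
})

#' @rdname CloneSet-accessors
#' @export
setMethod("clonePoints", "CloneSet", function(x, cloneId) {
  df <- x@nuclei[x@nuclei$clone_id == cloneId, , drop = FALSE]
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$id
  m
})

setMethod("show", "CloneSet", function(object) {
  cat("CloneSet with", nrow(object@nuclei), "nuclei in",
      length(cloneIds(object)), "clones\n")
  cat("  P-D axis: input", object@frame@sourceAxis, "-> canonical +z\n")
  sz <- cloneSizes(object)
  if (length(sz))
    cat("  clone sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
})

setMethod("show", "CanonicalFrame", function(object) {
  cat("CanonicalFrame: input", object@sourceAxis, "is the P-D (+z) axis\n")
})

#' Accessors for DoubletSet objects
#'
#' @param x a \code{\linkS4class{DoubletSet}}.
#' @return \code{edges} the edge data.frame (id_a, id_b, distance);
#'   \code{dStar} the connectivity threshold in micrometres.
#' @name DoubletSet-accessors
NULL

#' @rdname DoubletSet-accessors
#' @export
setMethod("edges", "DoubletSet", function(x) x@edges)

#' @rdname DoubletSet-accessors
#' @export
setMethod("dStar", "DoubletSet", function(x) x@dStar)

setMethod("show", "DoubletSet", function(object) {
  cat("DoubletSet for clone", object@cloneId, ":", nrow(object@edges),
      "doublets, d* =", format(object@dStar, digits = 4), "um\n")
})

#' Accessors for ElevationProfile objects
#'
#' @param x an \code{\linkS4class{ElevationProfile}}.
#' @return \code{completeFraction} the proportion of doublets with elevation
#'   >= 60 degrees; \code{nDoublets} the doublet count; \code{binCounts} the
#'   7-bin histogram counts.
#' @name ElevationProfile-accessors
NULL

#' @rdname ElevationProfile-accessors
#' @export
setMethod("completeFraction", "ElevationProfile", function(x)
  x@completeFraction)

#' @rdname ElevationProfile-accessors
#' @export
setMethod("nDoublets", "ElevationProfile", function(x) x@nDoublets)

#' @rdname ElevationProfile-accessors
#' @export
setMethod("binCounts", "ElevationProfile", function(x) {
  out <- x@counts
  names(out) <- .ELEVATION_BIN_LABELS
  out
})

setMethod("show", "ElevationProfile", function(object) {
  cat("ElevationProfile (clone ",
      ifelse(is.na(object@cloneId), "pooled", object@cloneId), "): ",
      object@nDoublets, " doublets, complete fraction ",
      format(object@completeFraction, digits = 3), "\n", sep = "")
})

#' Accessors for MulticloneSet objects
#'
#' @param x a \code{\linkS4class{MulticloneSet}}.
#' @return \code{groups} the list of member clone ids per multiclone;
#'   \code{mergedClones} the merged \code{\linkS4class{CloneSet}} (clone ids
#'   are multiclone group ids).
#' @name MulticloneSet-accessors
NULL

#' @rdname MulticloneSet-accessors
#' @export
setMethod("groups", "MulticloneSet", function(x) x@groups)

#' @rdname MulticloneSet-accessors
#' @export
setMethod("mergedClones", "MulticloneSet", function(x) x@merged)

setMethod("show", "MulticloneSet", function(object) {
  cat("MulticloneSet:", length(object@groups), "multiclones at <",
      object@threshold, "um\n")
})

#' Accessors for COJSurface objects
#'
#' @param x a \code{\linkS4class{COJSurface}}.
#' @return \code{voxels} the voxel coordinate matrix (um); \code{pitch} the
#'   isotropic voxel edge (um).
#' @name COJSurface-accessors
NULL

#' @rdname COJSurface-accessors
#' @export
setMethod("voxels", "COJSurface", function(x) x@voxels)

#' @rdname COJSurface-accessors
#' @export
setMethod("pitch", "COJSurface", function(x) x@pitch)

setMethod("show", "COJSurface", function(object) {
  cat("COJSurface", object@bone, object@stage, ":", nrow(object@voxels),
      "voxels at", object@pitch, "um pitch\n")
})
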