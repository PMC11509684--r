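#' Merge neighbouring clones into multiclones
#'
#' Two clones are adjacent when the distance between any nucleus of one and
#' any nucleus of the other is strictly less than \code{threshold}
#' (default 15 um). The pairwise criterion alone does not define a
#' partition, so groups are the connected components of the adjacency
#' relation; a merged clone's nucleus count equals the sum over its
#' members, and all downstream properties (doublets, elevation, shape,
#' classification) are computed on merged clones exactly as for individual
#' clones.
#'
#' @param x a \code{\linkS4class{CloneSet}} in a common canonical frame.
#' @param threshold merge distance, um (strict inequality).
#' @param sameColorOnly restrict merging to clones of the same color
#'   channel (default \code{FALSE}: embryonic columns may be multiclonal
#'   across channels).
#' @return A \code{\linkS4class{MulticloneSet}}.
#' @export
mergeClones <- function(x, threshold = 15, sameColorOnly = FALSE) {
  df <- nuclei(x)
  if (anyDuplicated(df$id))
    stop("duplicate nucleus ids across clones")
  ids <- cloneIds(x)
  n <- length(ids)
  pts <- lapply(ids, function(ci) clonePoints(x, ci))
  colr <- vapply(ids, function(ci)
    df$color[df$clone_id == ci][1], character(1))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(if (i > 1) i - 1 else 0)) {
    if (sameColorOnly && colr[i] != colr[j]) next
    adj[i, j] <- adj[j, i] <- .minInterDistance(pts[[i]], pts[[j]]) <
      threshold
  }
  if (n) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  } else comp <- integer(0)
  groups <- split(ids, comp)
  names(groups) <- seq_along(groups)
  merged <- df
  gid <- integer(nrow(df))
  for (g in seq_along(groups))
    gid[df$clone_id %in% groups[[g]]] <- g
  merged$clone_id <- gid
  merged <- merged[order(merged$clone_id), , drop = FALSE]
  rownames(merged) <- NULL
  new("MulticloneSet", groups = groups,
      merged = new("CloneSet", nuclei = merged, frame = frameOf(x)),
      threshold = threshold)
}

# minimum Euclidean distance between two point sets
.minInterDistance <- function(a, b) {
  cross <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(cross)))
}

#' Multiclone merge report
#'
#' Re-runs shape analysis and classification on the merged clones.
#'
#' @param mc a \code{\linkS4class{MulticloneSet}}.
#' @param cutoff column/cluster cutoff in degrees.
#' @return data.frame with columns \code{group_id, member_clone_ids,
#'   merged_size, merged_pd_angle_deg, merged_class}.
#' @export
multicloneReport <- function(mc, cutoff = 60) {
  sh <- cloneShapeTable(mergedClones(mc), cutoff)
  members <- vapply(groups(mc), function(g)
    paste(sort(g), collapse = ";"), character(1))
  sizes <- cloneSizes(mergedClones(mc))
  data.frame(group_id = as.integer(names(groups(mc))),
             member_clone_ids = members,
             merged_size = as.integer(sizes[names(groups(mc))]),
             merged_pd_angle_deg =
               sh$pd_angle_deg[match(as.integer(names(groups(mc))),
                                     sh$clone_id)],
             merged_class = sh$class[match(as.integer(names(groups(mc))),
                                           sh$clone_id)],
             row.names = NULL)
}
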