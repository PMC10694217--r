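# Single-linkage spatial clustering of group-specific residues on a
# structure.

#' Spatially cluster residues by single linkage
#'
#' Two residues share a cluster iff they are connected by a chain of
#' C-alpha distances at or below the cutoff (single-linkage = connected
#' components of the distance graph). Clusters of at least `min_size`
#' members are labelled `c1`, `c2`, ... by decreasing size; smaller
#' components are reported as `sparse`, matching the reading of a few
#' specific residues being "more sparsely distributed" outside the main
#' clusters.
#'
#' @param positions n x 3 matrix (or data frame with columns x, y, z) of
#'   C-alpha coordinates, optionally with rownames identifying residues.
#' @param cutoff Linkage distance cutoff in angstroms (default 15).
#' @param min_size Minimum members for a named cluster (default 5).
#' @return Data frame of class `residue_clusters`: `member` (rowname or
#'   index), `cluster` (c1, c2, ... or `sparse`), plus a `summary`
#'   attribute with per-cluster size, centroid and diameter.
#' @export
cluster_residues <- function(positions, cutoff = 15, min_size = 5L) {
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 1L) stop("need at least one position")
  ids <- rownames(positions)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- if (n == 1L) 1L else {
    hc <- hclust(dist(positions), method = "single")
    cutree(hc, h = cutoff)
  }
  sizes <- table(comp)
  big <- names(sizes)[sizes >= min_size]
  # deterministic labelling: by size desc, ties by smallest member index
  first_idx <- vapply(big, function(g) min(which(comp == g)), integer(1L))
  big <- big[order(-sizes[big], first_idx)]
  label <- rep("sparse", n)
  for (i in seq_along(big)) label[comp == as.integer(big[i])] <-
    paste0("c", i)
  out <- data.frame(member = ids, cluster = label,
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(unique(label), function(lb) {
    sub <- positions[label == lb, , drop = FALSE]
    data.frame(cluster = lb, size = nrow(sub),
               x = mean(sub[, 1]), y = mean(sub[, 2]), z = mean(sub[, 3]),
               diameter = if (nrow(sub) > 1L) max(dist(sub)) else 0)
  }))
  attr(out, "summary") <- summ[order(summ$cluster == "sparse",
                                     -summ$size), , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  class(out) <- c("residue_clusters", class(out))
  out
}

#' Number of named (non-sparse) clusters
#'
#' @param clusters A `residue_clusters` object.
#' @return Integer count.
#' @export
n_clusters <- function(clusters) {
  length(setdiff(unique(clusters$cluster), "sparse"))
}
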