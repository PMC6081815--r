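## Hierarchical clustering of abundance profiles with bootstrap branch
## support (ordinary bootstrap proportions over feature resampling).

#' Hierarchical clustering with bootstrap branch support
#'
#' Clusters the columns of \code{matrix} (euclidean distance, complete
#' linkage by default).  Branch support is the fraction of bootstrap trees
#' (rows resampled with replacement) containing each observed branch's
#' leaf set; branches at or above \code{support_min} are flagged.
#'
#' @param matrix numeric matrix; columns are clustered, rows are the
#'   resampled features.
#' @param distance distance measure for \code{\link[stats]{dist}}.
#' @param linkage agglomeration method for \code{\link[stats]{hclust}}.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param support_min flag threshold (default 0.95).
#' @param seed integer seed for the resampling.
#' @return a \code{\link{DendrogramWithSupport}}.
#' @export
clusterHeatmap <- function(matrix, distance = "euclidean",
                           linkage = "complete", n_boot = 1000L,
                           support_min = 0.95, seed = 1L) {
  stopifnot(ncol(matrix) >= 2)
  d <- dist(t(matrix), method = distance)
  if (all(d == 0)) warning("constant matrix: all distances are zero")
  hc <- hclust(d, method = linkage)
  obs_sets <- branchLeafSets(hc)
  hits <- numeric(length(obs_sets))
  withSeed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(matrix), replace = TRUE)
      hb <- hclust(dist(t(matrix[idx, , drop = FALSE]), method = distance),
                   method = linkage)
      bs <- branchLeafSets(hb)
      hits <- hits + (obs_sets %in% bs)
    }
  })
  new("DendrogramWithSupport", hclust = hc, support = hits / n_boot,
      n_boot = as.integer(n_boot), support_min = support_min)
}

## canonical string per internal branch: sorted leaf labels of the subtree
branchLeafSets <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- character(nrow(hc$merge))
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    take <- function(j) if (j < 0) labs[-j] else members[[j]]
    members[[i]] <- c(take(m[1]), take(m[2]))
    sets[i] <- paste(sort(members[[i]]), collapse = "\r")
  }
  sets
}

#' Newick string of a supported dendrogram
#'
#' Serializes the clustering with bootstrap supports as internal node
#' labels and merge heights as branch lengths.
#'
#' @param x a \code{\link{DendrogramWithSupport}}.
#' @return a newick string (terminated by ";").
#' @export
supportNewick <- function(x) {
  hc <- x@hclust
  height_of <- function(j) if (j < 0) 0 else hc$height[j]
  node <- function(j, parent_h) {
    if (j < 0)
      return(sprintf("%s:%g", hc$labels[-j], parent_h))
    m <- hc$merge[j, ]
    sprintf("(%s,%s)%g:%g",
            node(m[1], hc$height[j] - height_of(m[1])),
            node(m[2], hc$height[j] - height_of(m[2])),
            x@support[j], parent_h)
  }
  top <- nrow(hc$merge)
  m <- hc$merge[top, ]
  sprintf("(%s,%s)%g;",
          node(m[1], hc$height[top] - height_of(m[1])),
          node(m[2], hc$height[top] - height_of(m[2])),
          x@support[top])
}

#' Branches flagged as well supported
#'
#' @param x a \code{\link{DendrogramWithSupport}}.
#' @return data.frame with branch (merge step), support, and the leaf set.
#' @export
flaggedBranches <- function(x) {
  sets <- branchLeafSets(x@hclust)
  df <- data.frame(branch = seq_along(sets), support = x@support,
                   leaves = gsub("\r", ",", sets, fixed = TRUE),
                   stringsAsFactors = FALSE)
  df[df$support >= x@support_min, , drop = FALSE]
}
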