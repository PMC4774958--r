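# Species feature vectors, max-normalization, Euclidean distances, and
# unweighted average-linkage (UPGMA) dendrograms with deterministic
# tie-breaking.

#' Species-by-parameter mean table at one vane position
#'
#' @param dataset a measurement table.
#' @param position vane position (0.2/0.4/0.6/0.8).
#' @return matrix: rows species, columns the three shape parameters, values
#'   sample means.
#' @export
parameter_means <- function(dataset, position) {
  d <- dataset[dataset$position == position, ]
  if (nrow(d) == 0) stop("no measurements at position ", position)
  sp <- unique(d$species)
  m <- t(vapply(sp, function(s) {
    ds <- d[d$species == s, ]
    c(inclination_deg = mean(ds$inclination_deg),
      tip_displacement_deg = mean(ds$tip_displacement_deg),
      length_mm = mean(ds$length_mm))
  }, numeric(3)))
  rownames(m) <- sp
  m
}

#' Max-normalize a species-by-parameter mean table
#'
#' Each parameter (column) is divided by its maximum over species, so the
#' species with the highest value of a parameter sits at exactly 1.
#'
#' @param means numeric matrix (rows species, columns parameters) of strictly
#'   positive means, or a data.frame with a `species` column.
#' @return Normalized numeric matrix with each column maximum equal to 1.
#' @export
normalize_parameter_means <- function(means) {
  if (is.data.frame(means)) {
    if ("species" %in% names(means)) {
      rn <- means$species
      means <- as.matrix(means[setdiff(names(means), "species")])
      rownames(means) <- rn
    } else {
      means <- as.matrix(means)
    }
  }
  if (any(!is.finite(means))) stop("means must be finite and complete")
  if (any(means <= 0)) stop("means must be strictly positive")
  sweep(means, 2, apply(means, 2, max), "/")
}

#' Pairwise Euclidean distances between species feature vectors
#'
#' @param features numeric matrix, rows species.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(features) {
  if (any(!is.finite(features))) stop("features must be finite and complete")
  as.matrix(dist(features, method = "euclidean"))
}

#' UPGMA (unweighted average-linkage) clustering
#'
#' Iteratively merges the closest pair of clusters; the distance between two
#' clusters is the unweighted arithmetic mean of all original distances
#' across the pair.  Ties in the minimum distance are broken by the
#' lexicographically smallest label pair, so trees are reproducible across
#' platforms.  Merge heights carry the linkage distance itself.
#'
#' @param dist_matrix symmetric, zero-diagonal, non-negative distance matrix
#'   (or a `dist` object) over at least two labelled items.
#' @return A `serration_dendrogram`: list with hclust-style `merge`,
#'   `height`, and `labels`.
#' @export
upgma <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (n < 2) stop("need at least two items")
  if (any(d < 0)) stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters: list of leaf index vectors; id: hclust code (-leaf / +row)
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  first_label <- labels # lexicographic representative per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  avg_dist <- function(a, b) mean(d[members[[a]], members[[b]]])

  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dd <- avg_dist(i, j)
        lab <- sort(c(first_label[i], first_label[j]))
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = dd, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- best$d
    members[[i]] <- c(members[[i]], members[[j]])
    first_label[i] <- min(first_label[i], first_label[j])
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
    first_label <- first_label[-j]
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "serration_dendrogram")
}

#' @export
print.serration_dendrogram <- function(x, ...) {
  cat("serration_dendrogram over", length(x$labels), "leaves; root height",
      format(max(x$height), digits = 4), "\n")
  cat(dendrogram_newick(x), "\n")
  invisible(x)
}

# leaves (label indices) under hclust-style node code
node_leaves <- function(tree, code) {
  if (code < 0) return(-code)
  c(node_leaves(tree, tree$merge[code, 1]),
    node_leaves(tree, tree$merge[code, 2]))
}

#' Convert to an hclust object
#'
#' @param tree a `serration_dendrogram`.
#' @return A `stats::hclust` object (for cophenetic distances, plotting).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "serration_dendrogram"))
  n <- length(tree$labels)
  ord <- node_leaves(tree, n - 1L)
  structure(list(merge = tree$merge, height = tree$height, order = ord,
                 labels = tree$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Newick serialization of a dendrogram
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0), so the root-to-leaf path length equals the root
#' merge height.  Spaces in labels become underscores.
#'
#' @param tree a `serration_dendrogram`.
#' @param digits significant digits for branch lengths.
#' @return A Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "serration_dendrogram"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  build <- function(code, parent_height) {
    if (code < 0) {
      lab <- gsub(" ", "_", tree$labels[-code], fixed = TRUE)
      return(paste0(lab, ":", fmt(parent_height)))
    }
    h <- tree$height[code]
    paste0("(", build(tree$merge[code, 1], h), ",",
           build(tree$merge[code, 2], h), "):", fmt(parent_height - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", build(tree$merge[root, 1], h), ",",
         build(tree$merge[root, 2], h), ");")
}

#' Does the root split separate nocturnal from diurnal species?
#'
#' `TRUE` iff the two subtrees under the root partition the leaves exactly
#' into the nocturnal and the diurnal species (both sides non-empty and
#' pure).
#'
#' @param tree a `serration_dendrogram` over species leaves.
#' @param species_info data.frame with `species` and `activity` (defaults to
#'   the packaged [species_table()]).
#' @return Logical flag.
#' @export
activity_bipartition <- function(tree, species_info = species_table()) {
  stopifnot(inherits(tree, "serration_dendrogram"))
  act <- setNames(species_info$activity, species_info$species)
  if (!all(tree$labels %in% names(act)))
    stop("unknown leaf species: ",
         paste(setdiff(tree$labels, names(act)), collapse = ", "))
  root <- nrow(tree$merge)
  left <- tree$labels[node_leaves(tree, tree$merge[root, 1])]
  right <- tree$labels[node_leaves(tree, tree$merge[root, 2])]
  al <- unique(act[left]); ar <- unique(act[right])
  length(al) == 1 && length(ar) == 1 && al != ar
}

#' Label of the first leaf to be isolated at the root
#'
#' When the root split is (single leaf) vs (rest), returns that leaf's label,
#' otherwise `NA` -- used to check, e.g., that the largest species separates
#' first at vane position 0.2.
#'
#' @param tree a `serration_dendrogram`.
#' @return Leaf label or `NA_character_`.
#' @export
root_isolated_leaf <- function(tree) {
  stopifnot(inherits(tree, "serration_dendrogram"))
  root <- nrow(tree$merge)
  for (side in 1:2) {
    code <- tree$merge[root, side]
    if (code < 0) return(tree$labels[-code])
  }
  NA_character_
}
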