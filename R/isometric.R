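#' Isometric-graph coordinates for a layered tree
#'
#' Projects a depth-layered tree onto a grid in which all cells of depth `m`
#' lie on the diagonal isoline `x + y = N_m - 1`, where `N_m` is the number
#' of cells the tree actually has at that depth. A cell that is `n`-th
#' (0-based, left to right under `reference_ordering`) among the `N_m` cells
#' of its depth maps to `x = n`, `y = N_m - 1 - n`; the root maps to (0,0).
#' Each point carries the cell's lineage-vs-differentiation Hamming distance
#' and its display bin.
#'
#' @param tree a `lineage_tree`
#' @param reference_ordering ordering that defines left-to-right position:
#'   `"differentiation"` (the active order after volume ordering; default)
#'   or `"lineage"` (the as-loaded order)
#' @param bin_breaks upper edges of the Hamming display bins after the
#'   zero bin; default `c(0, 3, 6)` gives bins 0, 1-3, 4-6, 7+
#' @return data.frame `cell, m, n, x, y, hamming, hamming_bin`
#' @export
isometric_coordinates <- function(tree,
                                  reference_ordering = c("differentiation",
                                                         "lineage"),
                                  bin_breaks = c(0, 3, 6)) {
  reference_ordering <- match.arg(reference_ordering)
  ht <- hamming_table(tree)
  if (reference_ordering == "differentiation" && tree$ordering == "lineage") {
    tree <- order_differentiation(tree)
  }
  children <- if (reference_ordering == "lineage") {
    tree$children_lineage
  } else {
    tree$children
  }
  ord <- preorder_cells(tree, children = children)
  depth <- cell_depth(tree, ord)
  n_at <- table(depth)
  pos <- stats::ave(seq_along(ord), depth, FUN = seq_along) - 1L
  N_m <- as.integer(n_at[as.character(depth)])
  out <- data.frame(cell = ord, m = as.integer(depth), n = as.integer(pos),
                    x = as.integer(pos), y = N_m - 1L - as.integer(pos),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$hamming <- ht$hamming[match(out$cell, ht$cell)]
  out$hamming_bin <- hamming_bin(out$hamming, bin_breaks)
  out
}

#' Bin Hamming distances for display
#'
#' Default bins follow the isometric-graph convention: 0, 1-3, 4-6, 7+.
#'
#' @param dh integer Hamming distances
#' @param bin_breaks ascending upper bin edges; the final bin is open
#' @return character vector of bin labels
#' @export
hamming_bin <- function(dh, bin_breaks = c(0, 3, 6)) {
  stopifnot(!is.unsorted(bin_breaks))
  lo <- c(bin_breaks[1], bin_breaks[-length(bin_breaks)] + 1)
  labels <- ifelse(lo == bin_breaks, as.character(bin_breaks),
                   paste0(lo, "-", bin_breaks))
  labels <- c(labels, paste0(bin_breaks[length(bin_breaks)] + 1, "+"))
  idx <- findInterval(dh, c(bin_breaks + 1L)) + 1L
  labels[idx]
}

#' Null distribution of Hamming distances from random orderings
#'
#' Re-orders every division of `shape_tree` independently and uniformly at
#' random (left/right swapped with probability 1/2), computes each cell's
#' Hamming distance to its lineage code, and repeats. Under this null the
#' per-cell distance at depth `d` is Binomial(`d`, 1/2). Used to contrast
#' the non-random structure of real differentiation trees.
#'
#' @param shape_tree a `lineage_tree` supplying the topology
#' @param n_replicates number of random orderings (>= 1)
#' @param seed integer seed; the draw is reproducible
#' @return data.frame `replicate, cell, depth, hamming`
#' @export
random_code_null <- function(shape_tree, n_replicates, seed = 1L) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  lin <- assign_codes(shape_tree, which = "lineage")
  cells <- shape_tree$nodes$cell
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    shuf <- shuffle_children(shape_tree$children_lineage)
    tmp <- shape_tree
    tmp$children <- shuf
    rnd <- assign_codes(tmp, which = "active")
    dh <- mapply(hamming_distance, lin[cells], rnd[cells], USE.NAMES = FALSE)
    out[[r]] <- data.frame(replicate = r, cell = cells,
                           depth = shape_tree$nodes$depth,
                           hamming = as.integer(dh),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

# internal: swap each division's child pair with probability 1/2
shuffle_children <- function(children) {
  flip <- stats::runif(length(children)) < 0.5
  children[flip] <- lapply(children[flip], rev)
  children
}

#' Join nucleus positions with per-cell Hamming distances
#'
#' Produces the table behind 3D scatter views of where in the embryo the
#' lineage and differentiation orderings disagree. Cells without a recorded
#' position are dropped with a warning giving the count.
#'
#' @param tree a `lineage_tree` with `x`, `y`, `z` positions
#' @return data.frame `cell, x, y, z, hamming`
#' @export
spatial_hamming_export <- function(tree) {
  ht <- hamming_table(tree)
  nd <- tree$nodes
  keep <- !is.na(nd$x) & !is.na(nd$y) & !is.na(nd$z)
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) without positions omitted from spatial export")
  }
  out <- data.frame(cell = nd$cell[keep], x = nd$x[keep], y = nd$y[keep],
                    z = nd$z[keep],
                    hamming = ht$hamming[match(nd$cell[keep], ht$cell)],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
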