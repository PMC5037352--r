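#' Reorder a lineage tree into a differentiation tree
#'
#' At every division the smaller daughter is placed on the left and the
#' larger on the right; topology is untouched (the result is graph-isomorphic
#' to the input). Divisions whose daughters are tied in volume (relative
#' difference `<= eps`) or where a sibling volume is missing keep their
#' current order and are flagged in `tree$tie_flags`.
#'
#' @param tree a `lineage_tree`
#' @param tie_policy how to resolve tied sibling volumes: `"lineage"`
#'   (keep the current left/right order; default), `"name"` (alphabetical),
#'   or `"flag-only"` (same as lineage; the flag is the only effect).
#' @param eps relative tolerance `|C_i - C_j| / (C_i + C_j)` below or at
#'   which siblings count as tied. Default 0 (exact equality only).
#' @return the tree with `ordering = "differentiation"`
#' @export
order_differentiation <- function(tree,
                                  tie_policy = c("lineage", "name", "flag-only"),
                                  eps = 0) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(eps >= 0)
  vol <- stats::setNames(tree$nodes$volume, tree$nodes$cell)
  ties <- character(0)
  for (m in names(tree$children)) {
    ch <- tree$children[[m]]
    v <- vol[ch]
    if (anyNA(v)) {               # unknown: keep lineage order, flag
      ties <- c(ties, m)
      next
    }
    tied <- if (sum(v) > 0) abs(v[1] - v[2]) / sum(v) <= eps else TRUE
    if (tied) {
      ties <- c(ties, m)
      if (tie_policy == "name") tree$children[[m]] <- sort(ch)
    } else if (v[1] > v[2]) {
      tree$children[[m]] <- ch[2:1]
    }
  }
  tree$ordering <- "differentiation"
  tree$tie_flags <- ties
  tree
}

#' Override the child order at stated divisions
#'
#' Builds a composite ordering: named divisions take the supplied order
#' (e.g. from cell-polarity knowledge at the two- and four-cell stages),
#' all other divisions keep the tree's current (typically volume-based)
#' order.
#'
#' @param tree a `lineage_tree` (usually differentiation-ordered)
#' @param overrides named list: mother name -> character(2) giving its
#'   children in the desired left-to-right order
#' @return the tree with `ordering = "composite"`
#' @export
apply_ordering_overrides <- function(tree, overrides) {
  stopifnot(is.list(overrides))
  for (m in names(overrides)) {
    ch <- as.character(overrides[[m]])
    cur <- tree$children[[m]]
    if (is.null(cur)) stop("override names unknown or childless cell: ", m)
    if (length(ch) != 2 || !setequal(ch, cur)) {
      stop("override for ", m, " must list exactly its two children (",
           paste(cur, collapse = ", "), ")")
    }
    tree$children[[m]] <- ch
    tree$tie_flags <- setdiff(tree$tie_flags, m)
  }
  tree$ordering <- "composite"
  tree
}

#' Assign binary codes under the tree's active ordering
#'
#' Every cell receives the bit string built by walking from the root: `0`
#' for each left branch and `1` for each right branch. Code length equals
#' depth; the root has the empty code. Codes are absolute addresses: see
#' [decode_code()].
#'
#' @param tree a `lineage_tree`
#' @param which `"active"` (default) codes the current child order;
#'   `"lineage"` codes the immutable as-loaded order.
#' @return named character vector of `0`/`1` strings (empty for the root)
#' @export
assign_codes <- function(tree, which = c("active", "lineage")) {
  which <- match.arg(which)
  children <- if (which == "lineage") tree$children_lineage else tree$children
  codes <- stats::setNames(rep(NA_character_, n_cells(tree)), tree$nodes$cell)
  codes[tree$root] <- ""
  frontier <- tree$root
  while (length(frontier)) {
    nxt <- character(0)
    for (m in frontier) {
      ch <- children[[m]]
      if (is.null(ch)) next
      codes[ch[1]] <- paste0(codes[m], "0")
      codes[ch[2]] <- paste0(codes[m], "1")
      nxt <- c(nxt, ch)
    }
    frontier <- nxt
  }
  codes
}

#' Resolve a binary code back to its cell
#'
#' @param tree a `lineage_tree`
#' @param code a `0`/`1` string (empty string addresses the root)
#' @param which which child map to walk, as in [assign_codes()]
#' @return the cell name at that address
#' @export
decode_code <- function(tree, code, which = c("active", "lineage")) {
  which <- match.arg(which)
  children <- if (which == "lineage") tree$children_lineage else tree$children
  cur <- tree$root
  if (nchar(code) == 0) return(cur)
  for (b in strsplit(code, "")[[1]]) {
    ch <- children[[cur]]
    if (is.null(ch)) stop("code walks past a terminal cell at ", cur)
    cur <- if (b == "0") ch[1] else ch[2]
  }
  cur
}

#' Hamming distance between two equal-length binary codes
#'
#' Counts the positions at which the bits differ; defined only for codes of
#' the same length (cells at the same depth).
#'
#' @param x,y `0`/`1` strings or integer vectors of bits
#' @return integer in `[0, k]` where `k` is the common length
#' @export
hamming_distance <- function(x, y) {
  bx <- if (is.character(x)) as.integer(strsplit(x, "")[[1]]) else as.integer(x)
  by <- if (is.character(y)) as.integer(strsplit(y, "")[[1]]) else as.integer(y)
  if (length(bx) != length(by)) {
    stop("codes must have equal length (", length(bx), " vs ", length(by), ")")
  }
  sum(bx != by)
}

#' Per-cell lineage vs differentiation codes and their Hamming distance
#'
#' For every cell, the bit string under the as-loaded lineage ordering is
#' compared with the bit string under the volume ordering (or the tree's own
#' composite/differentiation ordering if it already has one). A cell's two
#' codes always have the same length (its depth), so the Hamming distance is
#' bounded by depth.
#'
#' @param tree a `lineage_tree`
#' @param tie_policy,eps passed to [order_differentiation()] when the tree
#'   is still lineage-ordered
#' @return data.frame `cell, depth, lineage_code, differentiation_code,
#'   hamming`
#' @export
hamming_table <- function(tree, tie_policy = "lineage", eps = 0) {
  lin <- assign_codes(tree, which = "lineage")
  dtree <- if (tree$ordering == "lineage") {
    order_differentiation(tree, tie_policy = tie_policy, eps = eps)
  } else {
    tree
  }
  dif <- assign_codes(dtree, which = "active")
  cells <- tree$nodes$cell
  dh <- mapply(hamming_distance, lin[cells], dif[cells], USE.NAMES = FALSE)
  data.frame(cell = cells, depth = tree$nodes$depth,
             lineage_code = unname(lin[cells]),
             differentiation_code = unname(dif[cells]),
             hamming = as.integer(dh),
             stringsAsFactors = FALSE, row.names = NULL)
}
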