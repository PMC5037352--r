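#' Construct a rooted binary cell-lineage tree
#'
#' A `lineage_tree` holds one cell per row of `nodes` together with an
#' ordered parent-to-children map. Exactly one cell (the one-cell stage) has
#' no parent; every internal cell has exactly two ordered children, so the
#' structure is a rooted, planar, ordered binary tree. Two child maps are
#' kept: the immutable `children_lineage` map fixed at construction (the
#' published anatomical left/right order) and the active `children` map that
#' ordering operations such as [order_differentiation()] rearrange.
#'
#' @param nodes data.frame with at least columns `cell` and `parent`
#'   (`NA` for the root). Optional columns: `volume` (non-negative; relative
#'   fraction of the embryo or cubic microns), `birth_time`, `division_time`
#'   (minutes), `x`, `y`, `z` (nucleus position, microns).
#' @param children optional named list mapping each mother to a character
#'   vector of its two children in left-to-right order; derived from row
#'   order of `nodes` when `NULL`.
#' @param ordering one of `"lineage"`, `"differentiation"`, `"composite"`;
#'   the convention the active child order follows.
#' @param volume_units free-text unit label (e.g. `"relative"`, `"um3"`).
#' @param conservation_tol relative tolerance for the daughter-volume
#'   conservation check (warning only); `NULL` disables the check.
#' @return object of class `lineage_tree`.
#' @export
lineage_tree <- function(nodes, children = NULL,
                         ordering = c("lineage", "differentiation", "composite"),
                         volume_units = "relative",
                         conservation_tol = 0.1) {
  ordering <- match.arg(ordering)
  stopifnot(is.data.frame(nodes))
  need <- c("cell", "parent")
  if (!all(need %in% names(nodes))) {
    stop("`nodes` must have columns 'cell' and 'parent'")
  }
  nodes$cell <- as.character(nodes$cell)
  nodes$parent <- as.character(nodes$parent)
  nodes$parent[!is.na(nodes$parent) & nodes$parent == ""] <- NA_character_
  for (col in c("volume", "birth_time", "division_time", "x", "y", "z")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_real_
    nodes[[col]] <- as.numeric(nodes[[col]])
  }

  if (anyDuplicated(nodes$cell)) {
    stop("duplicate cell names: ",
         paste(unique(nodes$cell[duplicated(nodes$cell)]), collapse = ", "))
  }
  root <- nodes$cell[is.na(nodes$parent)]
  if (length(root) != 1) {
    stop("tree must have exactly one root (found ", length(root), ")")
  }
  orphan <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$cell)
  if (length(orphan)) {
    stop("orphan parent references: ", paste(orphan, collapse = ", "))
  }
  if (any(nodes$volume < 0, na.rm = TRUE)) {
    stop("negative volume for: ",
         paste(nodes$cell[which(nodes$volume < 0)], collapse = ", "))
  }
  bad_t <- !is.na(nodes$birth_time) & !is.na(nodes$division_time) &
    nodes$division_time < nodes$birth_time
  if (any(bad_t)) {
    stop("division_time earlier than birth_time for: ",
         paste(nodes$cell[bad_t], collapse = ", "))
  }

  if (is.null(children)) {
    kids <- split(nodes$cell[!is.na(nodes$parent)],
                  factor(nodes$parent[!is.na(nodes$parent)],
                         levels = unique(nodes$parent[!is.na(nodes$parent)])))
    children <- lapply(kids, as.character)
  }
  n_kids <- lengths(children)
  if (any(n_kids == 1)) {
    stop("non-binary division: cell(s) with a single recorded child: ",
         paste(names(children)[n_kids == 1], collapse = ", "))
  }
  if (any(n_kids > 2)) {
    stop("non-binary division: cell(s) with more than two children: ",
         paste(names(children)[n_kids > 2], collapse = ", "))
  }
  children <- children[n_kids == 2]

  # BFS from the root: assigns depths and catches cycles / disconnection
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$cell)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (m in frontier) {
      for (ch in children[[m]]) {
        if (!is.na(depth[ch])) stop("cycle detected at cell ", ch)
        depth[ch] <- depth[m] + 1L
        nxt <- c(nxt, ch)
      }
    }
    frontier <- nxt
  }
  if (anyNA(depth)) {
    stop("tree not connected: unreachable cell(s): ",
         paste(names(depth)[is.na(depth)], collapse = ", "))
  }
  nodes$depth <- as.integer(depth[nodes$cell])

  # measurement-noise tolerant consistency checks (warnings only)
  pm <- match(nodes$parent, nodes$cell)
  both <- !is.na(pm) & !is.na(nodes$birth_time) & !is.na(nodes$division_time[pm])
  off <- both & abs(nodes$birth_time - nodes$division_time[pm]) > 1e-6
  if (any(off)) {
    warning(sum(off), " cell(s) whose birth_time differs from the mother's ",
            "division_time (kept as recorded)")
  }
  if (!is.null(conservation_tol)) {
    nonc <- 0L
    for (m in names(children)) {
      vm <- nodes$volume[nodes$cell == m]
      vc <- nodes$volume[match(children[[m]], nodes$cell)]
      if (!is.na(vm) && vm > 0 && !anyNA(vc) &&
          abs(sum(vc) - vm) / vm > conservation_tol) {
        nonc <- nonc + 1L
      }
    }
    if (nonc > 0) {
      warning(nonc, " division(s) where daughter volumes do not sum to the ",
              "mother volume within ", conservation_tol * 100, "% tolerance")
    }
  }

  structure(
    list(nodes = nodes, children = children, children_lineage = children,
         root = root, ordering = ordering, volume_units = volume_units,
         tie_flags = character(0)),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", nrow(x$nodes), " cells, ",
      length(x$children), " divisions, max depth ",
      max(x$nodes$depth), "\n", sep = "")
  cat("  root: ", x$root, " | ordering: ", x$ordering,
      " | volume units: ", x$volume_units, "\n", sep = "")
  if (length(x$tie_flags)) {
    cat("  tie/unknown-flagged divisions: ", length(x$tie_flags), "\n", sep = "")
  }
  invisible(x)
}

#' Number of cells in a tree
#' @param tree a `lineage_tree`
#' @return integer
#' @export
n_cells <- function(tree) nrow(tree$nodes)

#' Depth of one or more cells
#'
#' Depth is the number of tree edges (division events) from the one-cell
#' stage; the root has depth 0.
#'
#' @param tree a `lineage_tree`
#' @param cells character vector of cell names (default: all)
#' @return named integer vector
#' @export
cell_depth <- function(tree, cells = tree$nodes$cell) {
  idx <- match(cells, tree$nodes$cell)
  if (anyNA(idx)) stop("unknown cell name(s): ",
                       paste(cells[is.na(idx)], collapse = ", "))
  stats::setNames(tree$nodes$depth[idx], cells)
}

#' Cell lifetime
#'
#' The lifetime of a cell is the span from its birth by division of its
#' mother to its own division into two daughters. Terminal cells (no
#' recorded division) and cells lacking either timestamp return `NA`.
#'
#' @param tree a `lineage_tree`
#' @param cell cell name
#' @return minutes, or `NA`
#' @export
cell_lifetime <- function(tree, cell) {
  i <- match(cell, tree$nodes$cell)
  if (is.na(i)) stop("unknown cell name: ", cell)
  b <- tree$nodes$birth_time[i]
  d <- tree$nodes$division_time[i]
  if (is.na(b) || is.na(d) || !(cell %in% names(tree$children))) {
    return(NA_real_)
  }
  d - b
}

#' Lifetimes of every dividing cell
#'
#' @param tree a `lineage_tree`
#' @return data.frame with columns `cell`, `depth`, `volume`, `lifetime`,
#'   `division_time`; one row per cell with a defined lifetime
#' @export
lifetime_table <- function(tree) {
  div <- intersect(tree$nodes$cell, names(tree$children))
  lt <- vapply(div, function(cl) cell_lifetime(tree, cl), numeric(1))
  i <- match(div, tree$nodes$cell)
  out <- data.frame(cell = div, depth = tree$nodes$depth[i],
                    volume = tree$nodes$volume[i], lifetime = lt,
                    division_time = tree$nodes$division_time[i],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!is.na(out$lifetime), , drop = FALSE]
}

# internal: ordered left-to-right cell sequence at each depth (DFS, left first)
preorder_cells <- function(tree, children = tree$children) {
  out <- character(n_cells(tree))
  k <- 0L
  stack <- list(tree$root)
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    k <- k + 1L
    out[k] <- cur
    ch <- children[[cur]]
    if (!is.null(ch)) stack <- c(as.list(ch), stack)
  }
  out
}
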