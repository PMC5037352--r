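#' Read a per-cell lineage table
#'
#' The standard dialect is a UTF-8 CSV/TSV with a header and columns
#' `cell,parent,volume,birth_time,division_time,x,y,z,side`. Only `cell` is
#' mandatory. Parentage is taken from the `parent` column when present;
#' otherwise Sulston-style nomenclature is assumed (a child's name is its
#' mother's name plus one trailing character, e.g. `ABa` under `AB`). When
#' both are available the explicit column wins. Child left/right order comes
#' from an explicit `side` column (`L`/`R`) when present, else from row
#' order.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param column_map optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(cell = "Cell Name", volume = "Vol")`.
#' @param units volume unit label recorded on the tree.
#' @param sep field separator; derived from the extension when `NULL`.
#' @inheritParams lineage_tree
#' @return a validated [lineage_tree()] in lineage ordering
#' @export
read_lineage_table <- function(path, column_map = NULL, units = "relative",
                               sep = NULL, conservation_tol = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           check.names = FALSE, comment.char = "#")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) stop("mapped column not in file: ", src)
      names(raw)[names(raw) == src] <- std
    }
  }
  if (!"cell" %in% names(raw)) stop("column 'cell' is required")
  raw$cell <- as.character(raw$cell)

  if (!"parent" %in% names(raw) || all(is.na(raw$parent) | raw$parent == "")) {
    raw$parent <- sulston_parents(raw$cell)
  } else {
    raw$parent <- as.character(raw$parent)
    miss <- is.na(raw$parent) | raw$parent == ""
    if (sum(miss) > 1) {
      # fall back to nomenclature for rows without an explicit parent
      inferred <- sulston_parents(raw$cell)
      raw$parent[miss] <- inferred[miss]
    }
  }

  children <- NULL
  if ("side" %in% names(raw)) {
    has_parent <- !is.na(raw$parent) & raw$parent != ""
    kid <- raw[has_parent, c("cell", "parent", "side")]
    kid$side <- toupper(as.character(kid$side))
    if (!all(kid$side %in% c("L", "R"))) stop("side column must be L or R")
    children <- lapply(split(kid, kid$parent), function(d) {
      d$cell[order(match(d$side, c("L", "R")))]
    })
  }
  raw$side <- NULL
  lineage_tree(raw, children = children, ordering = "lineage",
               volume_units = units, conservation_tol = conservation_tol)
}

# internal: infer parents from suffix nomenclature (child = mother + 1 char);
# cells with no prefix match get NA (candidates for the root)
sulston_parents <- function(cells) {
  cand <- substr(cells, 1L, nchar(cells) - 1L)
  ifelse(cand %in% cells & nchar(cells) > 1L, cand, NA_character_)
}

#' Write a lineage tree back to the standard table dialect
#'
#' Rows are emitted in left-first depth-first order of the active ordering
#' and the `side` column records each cell's left/right position under it,
#' so `read_lineage_table(write_lineage_table(tree))` round-trips both the
#' fields and the child order.
#'
#' @param tree a `lineage_tree`
#' @param path output path; `.tsv`/`.txt` write tab-separated
#' @return `path`, invisibly
#' @export
write_lineage_table <- function(tree, path) {
  ord <- preorder_cells(tree)
  nodes <- tree$nodes[match(ord, tree$nodes$cell), , drop = FALSE]
  side <- rep(NA_character_, nrow(nodes))
  for (m in names(tree$children)) {
    ch <- tree$children[[m]]
    side[match(ch, nodes$cell)] <- c("L", "R")
  }
  out <- data.frame(cell = nodes$cell, parent = nodes$parent,
                    volume = nodes$volume, birth_time = nodes$birth_time,
                    division_time = nodes$division_time,
                    x = nodes$x, y = nodes$y, z = nodes$z, side = side,
                    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a tree as a Newick string
#'
#' Labels are cell names; child order follows the tree's active ordering.
#' With `annotations = TRUE` each labelled node carries a
#' `[&volume=...,t_birth=...,t_div=...]` comment (missing fields omitted).
#'
#' @param tree a `lineage_tree`
#' @param annotations include volume/time comment annotations?
#' @return a single Newick string terminated by `;`
#' @export
to_newick <- function(tree, annotations = TRUE) {
  ann <- function(i) {
    if (!annotations) return("")
    parts <- character(0)
    if (!is.na(tree$nodes$volume[i]))
      parts <- c(parts, paste0("volume=", format(tree$nodes$volume[i])))
    if (!is.na(tree$nodes$birth_time[i]))
      parts <- c(parts, paste0("t_birth=", format(tree$nodes$birth_time[i])))
    if (!is.na(tree$nodes$division_time[i]))
      parts <- c(parts, paste0("t_div=", format(tree$nodes$division_time[i])))
    if (!length(parts)) return("")
    paste0("[&", paste(parts, collapse = ","), "]")
  }
  rec <- function(cell) {
    i <- match(cell, tree$nodes$cell)
    ch <- tree$children[[cell]]
    lab <- paste0(cell, ann(i))
    if (is.null(ch)) return(lab)
    paste0("(", rec(ch[1]), ",", rec(ch[2]), ")", lab)
  }
  paste0(rec(tree$root), ";")
}

#' Strip comment annotations from a Newick string
#'
#' Utility for feeding annotated output of [to_newick()] to parsers that do
#' not accept `[...]` comments (e.g. `ape::read.tree`).
#'
#' @param newick a Newick string
#' @return the string with all `[...]` segments removed
#' @export
strip_newick_annotations <- function(newick) {
  gsub("\\[[^]]*\\]", "", newick)
}
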