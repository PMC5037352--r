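# Fixture builders and independent oracles shared across the test files.

# Hand-built worm-like tree, depth 2, volumes chosen so the lineage order
# and the volume order disagree at P0 and EMS but agree at AB.
worm_nodes <- function() {
  data.frame(
    cell = c("P0", "AB", "P1", "ABa", "ABp", "EMS", "P2"),
    parent = c(NA, "P0", "P0", "AB", "AB", "P1", "P1"),
    volume = c(1.00, 0.54, 0.46, 0.26, 0.28, 0.30, 0.16),
    birth_time = c(0, 10, 10, 28, 28, 35, 35),
    division_time = c(10, 28, 35, NA, NA, NA, NA),
    x = c(0, -5, 5, -8, -3, 3, 8),
    y = c(0, 1, -1, 2, 1, -1, -2),
    z = c(0, 0, 0, 1, -1, 1, -1),
    stringsAsFactors = FALSE
  )
}

worm_tree <- function() lineage_tree(worm_nodes(), volume_units = "relative")

# complete tree whose lineage order already equals the volume order
volume_ordered_tree <- function(depth = 3, seed = 11) {
  tr <- simulate_tree(simulation_config(max_depth = depth, seed = seed,
                                        asym_fraction = 0.5,
                                        asym_onset_depth = 0))
  ord <- order_differentiation(tr)
  tr$children <- ord$children
  tr$children_lineage <- ord$children
  tr$ordering <- "lineage"
  tr
}

# all cells in the subtree rooted at `cell`, excluding the root of the subtree
subtree_cells <- function(tree, cell) {
  out <- character(0)
  frontier <- tree$children[[cell]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(x) tree$children[[x]]))
  }
  out
}

# independent brute-force global aligner over whole tokens (match/gap only):
# enumerates all alignments recursively; usable only for tiny sequences
brute_force_align_score <- function(a, b, match = 1, gap = -1) {
  if (!length(a)) return(gap * length(b))
  if (!length(b)) return(gap * length(a))
  best <- max(brute_force_align_score(a[-1], b, match, gap) + gap,
              brute_force_align_score(a, b[-1], match, gap) + gap)
  if (a[1] == b[1]) {
    best <- max(best, brute_force_align_score(a[-1], b[-1], match, gap) + match)
  }
  best
}

# closed form for canonical sequences with substitutions disallowed:
# matches = multiset intersection, gaps = everything unmatched
closed_form_alignment <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  matches <- sum(pmin(ta[common], tb[common]))
  gaps <- length(a) + length(b) - 2 * matches
  list(matches = matches, gaps = gaps, length = matches + gaps,
       score = matches - gaps)
}

# random CAST token multiset drawn from a small alphabet of valid tokens
random_cast_tokens <- function(n, max_depth = 4) {
  pool <- unlist(lapply(seq_len(max_depth), function(d) {
    paste0(d, ".", vapply(0:(2^d - 1), function(v) {
      bits <- as.integer(intToBits(v))[seq_len(d)]
      paste(c("C", "E")[rev(bits) + 1], collapse = "")
    }, character(1)))
  }))
  sample(pool, n, replace = TRUE)
}

# leaves of `tree` in left-first depth-first order, computed independently
# of the package's traversal (recursive walk over the child map)
preorder_cells_for_test <- function(tree, keep = tree$nodes$cell) {
  walk <- function(cell) {
    ch <- tree$children[[cell]]
    if (is.null(ch)) return(cell)
    c(cell, walk(ch[1]), walk(ch[2]))
  }
  intersect(walk(tree$root), keep)
}

# path to the (optional) supplementary fixtures converted to plain text
supp_path <- function(name) {
  system.file("extdata", "supplementary", name, package = "difftree")
}
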