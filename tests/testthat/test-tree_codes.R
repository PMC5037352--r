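test_that("order_differentiation puts the smaller daughter left", {
  tr <- worm_tree()                       # P0 lineage order: AB (0.54), P1 (0.46)
  d <- order_differentiation(tr)
  expect_equal(d$children[["P0"]], c("P1", "AB"))
  expect_equal(d$children[["AB"]], c("ABa", "ABp"))  # already small-first
  expect_equal(d$children[["P1"]], c("P2", "EMS"))
  expect_equal(d$ordering, "differentiation")
  expect_length(d$tie_flags, 0)

  # idempotence: reordering an already volume-ordered tree changes nothing
  d2 <- order_differentiation(d)
  expect_equal(d2$children, d$children)

  # topology is preserved: the (parent, child) edge multiset is unchanged
  edges <- function(t) {
    sort(unlist(lapply(names(t$children),
                       function(m) paste(m, t$children[[m]]))))
  }
  expect_equal(edges(d), edges(tr))
})

test_that("ties and missing volumes fall back to lineage order with flags", {
  nd <- worm_nodes()
  nd$volume[4:5] <- 0.27                  # ABa == ABp
  tr <- suppressWarnings(lineage_tree(nd))
  d <- order_differentiation(tr)
  expect_equal(d$children[["AB"]], c("ABa", "ABp"))
  expect_true("AB" %in% d$tie_flags)

  d_name <- order_differentiation(tr, tie_policy = "name")
  expect_equal(d_name$children[["AB"]], c("ABa", "ABp"))  # already sorted

  nd2 <- worm_nodes()
  nd2$volume[6] <- NA                     # EMS volume unknown
  tr2 <- lineage_tree(nd2)
  d2 <- order_differentiation(tr2)
  expect_equal(d2$children[["P1"]], c("EMS", "P2"))  # lineage order kept
  expect_true("P1" %in% d2$tie_flags)

  # eps propagates a near-tie into the flag set
  d3 <- order_differentiation(worm_tree(), eps = 0.1)
  expect_true("AB" %in% d3$tie_flags)     # |0.26-0.28|/0.54 ~ 0.037 <= 0.1
})

test_that("ordering overrides build a composite ordering", {
  d <- order_differentiation(worm_tree())
  comp <- apply_ordering_overrides(d, list(P0 = c("AB", "P1")))
  expect_equal(comp$children[["P0"]], c("AB", "P1"))
  expect_equal(comp$children[["P1"]], d$children[["P1"]])  # untouched
  expect_equal(comp$ordering, "composite")

  same <- apply_ordering_overrides(d, list())
  expect_equal(same$children, d$children)

  expect_error(apply_ordering_overrides(d, list(P0 = c("AB", "EMS"))),
               "two children")
  expect_error(apply_ordering_overrides(d, list(ABa = c("x", "y"))),
               "unknown or childless")
})

test_that("binary codes are root-path addresses", {
  tr <- worm_tree()
  codes <- assign_codes(tr)
  expect_equal(unname(codes["P0"]), "")
  expect_equal(unname(codes["AB"]), "0")
  expect_equal(unname(codes["P1"]), "1")
  expect_equal(unname(codes["P2"]), "11")
  expect_equal(unname(nchar(codes)),
               unname(cell_depth(tr, names(codes))))

  # child code extends the parent code by exactly one bit
  for (m in names(tr$children)) {
    for (ch in tr$children[[m]]) {
      expect_equal(unname(substr(codes[ch], 1, nchar(codes[m]))),
                   unname(codes[m]))
      expect_equal(unname(nchar(codes[ch])), unname(nchar(codes[m])) + 1L)
    }
  }
})

test_that("codes sorted as binary integers enumerate the left-right order", {
  tr <- simulate_tree(simulation_config(max_depth = 4, seed = 7))
  codes <- assign_codes(tr)
  for (d in 1:4) {
    at_d <- tr$nodes$cell[tr$nodes$depth == d]
    sorted <- at_d[order(codes[at_d])]      # lexicographic == binary, fixed length
    expect_equal(sorted, preorder_cells_for_test(tr, at_d), info = paste("depth", d))
  }
})

test_that("codes are unique addresses: decode inverts assign", {
  for (seed in c(1, 5, 9)) {
    tr <- simulate_tree(simulation_config(max_depth = 5, seed = seed))
    codes <- assign_codes(tr)
    expect_false(anyDuplicated(codes) > 0)
    pick <- sample(names(codes), 20)
    expect_equal(vapply(codes[pick], function(cd) decode_code(tr, cd),
                        character(1), USE.NAMES = FALSE), pick)
  }
})

test_that("hamming_distance counts differing bits", {
  expect_equal(hamming_distance("0101", "0101"), 0L)
  expect_equal(hamming_distance("000", "111"), 3L)
  expect_equal(hamming_distance("0110", "1100"), 2L)
  expect_equal(hamming_distance(c(0L, 1L), c(1L, 1L)), 1L)
  expect_error(hamming_distance("01", "011"), "equal length")
})

test_that("hamming_table is zero iff lineage order equals volume order", {
  tr <- volume_ordered_tree(depth = 4)
  ht <- hamming_table(tr)
  expect_true(all(ht$hamming == 0))
  expect_true(all(ht$hamming <= ht$depth))

  # swapping the root's lineage children flips every cell's leading bit
  swapped <- tr
  swapped$children_lineage[[swapped$root]] <-
    rev(swapped$children_lineage[[swapped$root]])
  ht2 <- hamming_table(swapped)
  expect_true(all(ht2$hamming[ht2$depth > 0] >= 1))
  expect_equal(ht2$hamming[ht2$depth > 0], rep(1L, sum(ht2$depth > 0)))
})

test_that("a single internal swap only affects that cell's subtree", {
  tr <- volume_ordered_tree(depth = 5)
  internal <- setdiff(names(tr$children), tr$root)
  m <- internal[5]
  swapped <- tr
  swapped$children_lineage[[m]] <- rev(swapped$children_lineage[[m]])
  ht <- hamming_table(swapped)
  inside <- subtree_cells(swapped, m)
  expect_true(all(ht$hamming[ht$cell %in% inside] == 1))
  expect_true(all(ht$hamming[!ht$cell %in% inside] == 0))
})

test_that("isometric coordinates satisfy the isoline identity", {
  tr <- simulate_tree(simulation_config(max_depth = 5, seed = 3))
  iso <- isometric_coordinates(tr)
  expect_equal(iso[iso$cell == tr$root, c("x", "y")],
               data.frame(x = 0L, y = 0L), ignore_attr = TRUE)
  n_at <- table(iso$m)
  expect_true(all(iso$x + iso$y == as.integer(n_at[as.character(iso$m)]) - 1L))
  expect_true(all(iso$n >= 0 & iso$n <= as.integer(n_at[as.character(iso$m)]) - 1L))
  # complete depth-5 level: 32 cells, isoline crossing both axes at 31
  at5 <- iso[iso$m == 5, ]
  expect_equal(nrow(at5), 32)
  expect_equal(range(at5$x), c(0, 31))
  expect_equal(range(at5$y), c(0, 31))
  # the n-th cell along the isoline is the n-th cell of that depth in the tree
  dtree <- order_differentiation(tr)
  at3 <- iso[iso$m == 3, ]
  expect_equal(at3$cell[order(at3$n)],
               preorder_cells_for_test(dtree, at3$cell))
})

test_that("hamming display bins follow the 0 / 1-3 / 4-6 / 7+ convention", {
  expect_equal(hamming_bin(c(0, 1, 3, 4, 6, 7, 12)),
               c("0", "1-3", "1-3", "4-6", "4-6", "7+", "7+"))
  expect_equal(hamming_bin(2, bin_breaks = c(0, 1)), "2+")
})

test_that("random_code_null is seeded and binomial under the null", {
  tr <- simulate_tree(simulation_config(max_depth = 4, seed = 8))
  a <- random_code_null(tr, n_replicates = 5, seed = 42)
  b <- random_code_null(tr, n_replicates = 5, seed = 42)
  expect_identical(a, b)

  # depth-1 tree: DH is 0 or 1 with equal frequency
  mini <- lineage_tree(data.frame(cell = c("P0", "AB", "P1"),
                                  parent = c(NA, "P0", "P0")))
  nul <- random_code_null(mini, n_replicates = 10000, seed = 1)
  frac1 <- mean(nul$hamming[nul$depth == 1] == 1)
  expect_lt(abs(frac1 - 0.5), 0.02)

  # complete tree: E[DH at depth d] = d/2 (bits flip independently w.p. 1/2)
  nul2 <- random_code_null(tr, n_replicates = 800, seed = 2)
  means <- tapply(nul2$hamming, nul2$depth, mean)
  for (d in 1:4) {
    expect_lt(abs(means[[as.character(d)]] - d / 2), 0.12)
  }
})

test_that("spatial export joins positions with hamming distances", {
  tr <- worm_tree()
  sp <- spatial_hamming_export(tr)
  expect_equal(nrow(sp), n_cells(tr))        # all cells have positions
  ht <- hamming_table(tr)
  expect_equal(sp$hamming, ht$hamming[match(sp$cell, ht$cell)])

  nd <- worm_nodes()
  nd[c("x", "y", "z")] <- NA_real_
  bare <- lineage_tree(nd)
  expect_warning(sp2 <- spatial_hamming_export(bare), "omitted")
  expect_equal(nrow(sp2), 0)
})
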