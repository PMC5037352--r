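#' Asymmetry statistic for a daughter-cell pair
#'
#' The default statistic is the relative volume difference
#' `A = |C_i - C_j| / (C_i + C_j)`, a dimensionless, scale-invariant value in
#' `[0, 1)`: 0 for a perfectly symmetric division, approaching 1 as one
#' daughter vanishes. Two variants are kept for comparison with the
#' confidence-interval formula as printed elsewhere: `"halved"` is `A / 2`
#' and `"printed"` is `(A / 2) * h` (which requires `h` and, being capped at
#' `h / 2`, can never exceed a positive threshold `h` — see the package
#' vignette for why `"relative"` is the calibrated default).
#'
#' @param c_i,c_j daughter volumes (any common unit); vectorized
#' @param variant `"relative"` (default), `"halved"`, or `"printed"`
#' @param h threshold, needed only by `variant = "printed"`
#' @return dimensionless statistic, symmetric in its arguments
#' @export
asymmetry_statistic <- function(c_i, c_j,
                                variant = c("relative", "halved", "printed"),
                                h = NULL) {
  variant <- match.arg(variant)
  s <- c_i + c_j
  if (any(s <= 0, na.rm = TRUE)) stop("both daughter volumes are zero")
  a <- abs(c_i - c_j) / s
  switch(variant,
         relative = a,
         halved = a / 2,
         printed = {
           if (is.null(h)) stop("variant 'printed' requires h")
           (a / 2) * h
         })
}

#' Classify one division as asymmetric (g = 1) or not (g = 0)
#'
#' The statistic is compared to the confidence-interval threshold `h` with a
#' strict inequality: `g = 1` iff statistic `> h`.
#'
#' @inheritParams asymmetry_statistic
#' @param h positive threshold
#' @return integer 0/1 (vectorized)
#' @export
classify_division <- function(c_i, c_j, h,
                              variant = c("relative", "halved", "printed")) {
  if (any(h <= 0)) stop("threshold h must be positive")
  variant <- match.arg(variant)
  as.integer(asymmetry_statistic(c_i, c_j, variant = variant, h = h) > h)
}

#' Size ratio of a daughter pair
#'
#' Smaller over larger volume: 1 for a symmetric pair, decreasing towards 0
#' as the asymmetry grows. Exactly related to the relative-difference
#' statistic by `A = (1 - ratio) / (1 + ratio)`.
#'
#' @param c_s smaller daughter volume
#' @param c_l larger daughter volume (`> 0`, `>= c_s`)
#' @return ratio in `(0, 1]`
#' @export
size_ratio <- function(c_s, c_l) {
  if (any(c_l <= 0)) stop("larger volume must be positive")
  if (any(c_s > c_l)) stop("c_s must not exceed c_l; order the pair first")
  c_s / c_l
}

#' Extract one record per complete division
#'
#' A division is complete when both daughter volumes are known; others are
#' excluded (and counted in a warning) so asymmetry statistics are computed
#' on measured pairs only.
#'
#' @param tree a `lineage_tree`
#' @param variant statistic variant, see [asymmetry_statistic()]
#' @return data.frame `mother, daughter_small, daughter_large, C_S, C_L,
#'   ratio, statistic, depth` (depth is the daughters' depth)
#' @export
division_records <- function(tree, variant = "relative") {
  vol <- stats::setNames(tree$nodes$volume, tree$nodes$cell)
  rows <- lapply(names(tree$children), function(m) {
    ch <- tree$children[[m]]
    v <- vol[ch]
    if (anyNA(v)) return(NULL)
    s <- order(v)
    data.frame(mother = m,
               daughter_small = ch[s[1]], daughter_large = ch[s[2]],
               C_S = unname(v[s[1]]), C_L = unname(v[s[2]]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " division(s) with missing daughter volumes excluded")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no division with both daughter volumes known")
  out$ratio <- size_ratio(out$C_S, out$C_L)
  out$statistic <- asymmetry_statistic(out$C_S, out$C_L, variant = variant,
                                       h = 1)
  out$depth <- tree$nodes$depth[match(out$daughter_small, tree$nodes$cell)]
  row.names(out) <- NULL
  out
}

#' Count divisions above each confidence-interval threshold
#'
#' Mirrors the published threshold-table layout: for each `h`, the number of
#' divisions whose asymmetry statistic strictly exceeds `h`, and that count
#' as a proportion of all divisions. Counts are non-increasing in `h`.
#'
#' @param divisions data.frame from [division_records()], or a
#'   `lineage_tree` (converted internally)
#' @param thresholds positive thresholds `h`
#' @param variant statistic variant, see [asymmetry_statistic()]
#' @return data.frame `h, count, proportion, total`
#' @export
threshold_table <- function(divisions, thresholds = c(0.05, 0.1, 0.25, 0.5),
                            variant = "relative") {
  if (inherits(divisions, "lineage_tree")) {
    divisions <- division_records(divisions, variant = variant)
  }
  if (nrow(divisions) == 0) stop("empty division set")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  g <- vapply(thresholds, function(h) {
    sum(classify_division(divisions$C_S, divisions$C_L, h, variant = variant))
  }, numeric(1))
  data.frame(h = thresholds, count = as.integer(g),
             proportion = g / nrow(divisions), total = nrow(divisions))
}

#' Per-depth range of daughter size ratios
#'
#' Summarizes [size_ratio()] by the daughters' lineage depth: the minimum,
#' mean, and maximum over all complete divisions whose daughters sit at that
#' depth.
#'
#' @param tree a `lineage_tree`
#' @return data.frame `depth, n_divisions, min, mean, max`
#' @export
ratio_depth_summary <- function(tree) {
  dv <- division_records(tree)
  agg <- split(dv$ratio, dv$depth)
  data.frame(depth = as.integer(names(agg)),
             n_divisions = vapply(agg, length, integer(1)),
             min = vapply(agg, min, numeric(1)),
             mean = vapply(agg, mean, numeric(1)),
             max = vapply(agg, max, numeric(1)),
             row.names = NULL)
}
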