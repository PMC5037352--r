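#' Configuration for the mosaic-embryo simulator
#'
#' Describes a complete binary lineage tree in which each division splits
#' the mother volume into fractions `(f, 1 - f)`. With probability
#' `asym_fraction` (and only once the daughters' depth reaches
#' `asym_onset_depth`) the smaller fraction `f` is drawn from the
#' *asymmetric* regime `0.5 * Beta(split_alpha, split_beta)`; otherwise from
#' the *near-symmetric* regime `min(u, 1 - u)` with
#' `u ~ Beta(sym_concentration, sym_concentration)`
#' (`sym_concentration = Inf` makes those divisions exactly symmetric).
#' Cell lifetime follows the power law
#' `lifetime = lifetime_coeff * volume^lifetime_exponent` with multiplicative
#' lognormal noise of coefficient of variation `lifetime_noise_cv`, so
#' smaller cells live longer when the exponent is negative and
#' (volume, lifetime) pairs are exactly log-linear in expectation.
#'
#' @param max_depth depth of the complete tree (terminal cells at this depth)
#' @param split_alpha,split_beta Beta shape parameters of the asymmetric
#'   regime's smaller-daughter fraction (support `(0, 0.5)`)
#' @param asym_fraction probability a division uses the asymmetric regime
#' @param asym_onset_depth daughters shallower than this always divide
#'   near-symmetrically (default 3: the 8-cell stage, where real embryos
#'   first show clear size asymmetries)
#' @param sym_concentration Beta concentration of the near-symmetric regime;
#'   `Inf` for exactly symmetric splits
#' @param lifetime_coeff lifetime (minutes) of a cell of unit volume
#' @param lifetime_exponent power-law exponent (negative: smaller cells
#'   live longer)
#' @param lifetime_noise_cv coefficient of variation of lognormal lifetime
#'   noise
#' @param conserve_volume if `TRUE` recorded daughter volumes sum exactly to
#'   the mother volume; if `FALSE` each recorded volume gets independent
#'   multiplicative lognormal measurement noise of CV `volume_noise_cv`
#'   (emulating nucleus-derived volume estimates, which do not conserve
#'   volume)
#' @param volume_noise_cv measurement-noise CV used when
#'   `conserve_volume = FALSE`
#' @param seed integer seed; every random draw flows through it
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(max_depth = 9L,
                              split_alpha = 2, split_beta = 2,
                              asym_fraction = 0.2,
                              asym_onset_depth = 3L,
                              sym_concentration = 200,
                              lifetime_coeff = 10,
                              lifetime_exponent = -0.8,
                              lifetime_noise_cv = 0.1,
                              conserve_volume = TRUE,
                              volume_noise_cv = 0.05,
                              seed = 1L) {
  stopifnot(max_depth >= 1, split_alpha > 0, split_beta > 0,
            asym_fraction >= 0, asym_fraction <= 1,
            sym_concentration > 0, lifetime_coeff > 0,
            lifetime_noise_cv >= 0, volume_noise_cv >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 split_alpha = split_alpha, split_beta = split_beta,
                 asym_fraction = asym_fraction,
                 asym_onset_depth = as.integer(asym_onset_depth),
                 sym_concentration = sym_concentration,
                 lifetime_coeff = lifetime_coeff,
                 lifetime_exponent = lifetime_exponent,
                 lifetime_noise_cv = lifetime_noise_cv,
                 conserve_volume = isTRUE(conserve_volume),
                 volume_noise_cv = volume_noise_cv,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# internal: lognormal multiplier with mean 1 and the given CV
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a mosaic-embryo lineage tree
#'
#' Builds a complete binary tree to `config$max_depth` with root volume 1.0
#' at time 0, partitioning volumes and accumulating lifetimes as described
#' in [simulation_config()]. The smaller daughter's left/right position in
#' the emitted lineage order is random (fair coin), so the lineage and
#' differentiation orderings genuinely differ. Cell names encode the path
#' from the root `Z` with suffix `a` (left) / `b` (right), so the
#' nomenclature fallback of [read_lineage_table()] can re-derive parentage.
#'
#' @param config a [simulation_config()]
#' @return a validated [lineage_tree()] in lineage ordering
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_total <- 2^(config$max_depth + 1L) - 1L
  cells <- character(n_total)
  parent <- rep(NA_character_, n_total)
  volume <- numeric(n_total)
  birth <- numeric(n_total)
  division <- rep(NA_real_, n_total)
  depth <- integer(n_total)

  cells[1] <- "Z"; volume[1] <- 1; birth[1] <- 0; depth[1] <- 0L
  k <- 1L
  frontier <- 1L
  while (length(frontier) && depth[frontier[1]] < config$max_depth) {
    nxt <- integer(0)
    for (i in frontier) {
      d_child <- depth[i] + 1L
      lt <- config$lifetime_coeff * volume[i]^config$lifetime_exponent *
        lognoise(1, config$lifetime_noise_cv)
      division[i] <- birth[i] + lt
      asym <- d_child >= config$asym_onset_depth &&
        stats::runif(1) < config$asym_fraction
      f <- if (asym) {
        0.5 * stats::rbeta(1, config$split_alpha, config$split_beta)
      } else if (is.finite(config$sym_concentration)) {
        u <- stats::rbeta(1, config$sym_concentration, config$sym_concentration)
        min(u, 1 - u)
      } else {
        0.5
      }
      v_small <- f * volume[i]
      v_large <- (1 - f) * volume[i]
      # random anatomical placement of the smaller daughter
      small_left <- stats::runif(1) < 0.5
      v_lr <- if (small_left) c(v_small, v_large) else c(v_large, v_small)
      for (s in 1:2) {
        k <- k + 1L
        cells[k] <- paste0(cells[i], c("a", "b")[s])
        parent[k] <- cells[i]
        volume[k] <- v_lr[s]
        birth[k] <- division[i]
        depth[k] <- d_child
        nxt <- c(nxt, k)
      }
    }
    frontier <- nxt
  }

  vol_rec <- volume
  if (!config$conserve_volume) {
    vol_rec <- volume * lognoise(n_total, config$volume_noise_cv)
    vol_rec[1] <- volume[1]
  }
  nodes <- data.frame(cell = cells, parent = parent, volume = vol_rec,
                      birth_time = birth, division_time = division,
                      stringsAsFactors = FALSE)
  tree <- lineage_tree(nodes, ordering = "lineage", volume_units = "relative",
                       conservation_tol = NULL)
  attr(tree, "config") <- config
  tree
}

#' Uniformly shuffle the child order of every division
#'
#' The random-tree null model: topology, volumes, and times are untouched;
#' each division's left/right order is independently swapped with
#' probability 1/2. Both the active and the lineage child maps are replaced
#' (the result is a new "organism", not a reordering of the old one).
#'
#' @param tree a `lineage_tree`
#' @param seed integer seed
#' @return a `lineage_tree` with shuffled child order
#' @export
simulate_code_shuffle <- function(tree, seed = 1L) {
  set.seed(seed)
  shuf <- shuffle_children(tree$children)
  tree$children <- shuf
  tree$children_lineage <- shuf
  tree$ordering <- "lineage"
  tree
}
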