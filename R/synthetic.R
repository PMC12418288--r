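#' Configuration of a synthetic realm
#'
#' Bundles everything the generators need: community sizes, the grid, the
#' generating mode and the planted coefficients that downstream
#' parameter-recovery tests try to re-estimate.
#'
#' Richness mode plants a negative-binomial richness model on the log-mean
#' scale, `log mu_i = b0 + b_BM ln(BM_i) + b_GR ln(GR_i) + b_DF ln(DF_i) +
#' b_HB HB_i`; sharing mode plants a logistic distance decay
#' `P(infested) = plogis(a_true + b_true * D(h_p, i))` around a random focal
#' host per parasite.
#'
#' @param n_hosts number of host species (>= 10).
#' @param n_parasites number of parasite species (>= 1).
#' @param grid a [grid_spec()] with >= 25 cells.
#' @param seed integer RNG seed; every generated object is a pure function
#'   of (config, seed).
#' @param mode `"richness"` or `"sharing"`.
#' @param richness_betas named vector `(b0, b_BM, b_GR, b_DF, b_HB)`.
#' @param nb_theta negative-binomial dispersion (> 0).
#' @param sharing_coefs vector `(a_true, b_true)`.
#' @param sharing_distance which distance drives sharing-mode generation:
#'   one of `"phylo"`, `"trait"`, `"geo"`, `"env"`.
#' @param range_median_cells,range_sdlog lognormal range-size law: the cell
#'   count of each range is `round(exp(Normal(log(range_median_cells),
#'   range_sdlog)))`, truncated to the grid.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_hosts = 150, n_parasites = 60,
                         grid = grid_spec(-10, 10, -10, 10, 1),
                         seed = 1L,
                         mode = c("sharing", "richness"),
                         richness_betas = c(b0 = -2, b_BM = -0.3, b_GR = 0.4,
                                            b_DF = 0, b_HB = 0),
                         nb_theta = 2,
                         sharing_coefs = c(a_true = 2, b_true = -6),
                         sharing_distance = c("trait", "phylo", "geo", "env"),
                         range_median_cells = 40, range_sdlog = 0.7) {
  mode <- match.arg(mode)
  sharing_distance <- match.arg(sharing_distance)
  stopifnot(n_hosts >= 10, n_parasites >= 1, nb_theta > 0,
            length(richness_betas) == 5, length(sharing_coefs) == 2,
            inherits(grid, "grid_spec"), grid$n_cells >= 25,
            range_median_cells >= 1, range_sdlog > 0)
  cfg <- list(n_hosts = as.integer(n_hosts),
              n_parasites = as.integer(n_parasites), grid = grid,
              seed = as.integer(seed), mode = mode,
              richness_betas = stats::setNames(as.numeric(richness_betas),
                                               c("b0", "b_BM", "b_GR", "b_DF", "b_HB")),
              nb_theta = nb_theta,
              sharing_coefs = stats::setNames(as.numeric(sharing_coefs),
                                              c("a_true", "b_true")),
              sharing_distance = sharing_distance,
              range_median_cells = range_median_cells,
              range_sdlog = range_sdlog)
  class(cfg) <- "world_config"
  cfg
}

host_labels <- function(n) sprintf("host_%03d", seq_len(n))
parasite_labels <- function(n) sprintf("parasite_%03d", seq_len(n))

#' Simulate a pure-birth ultrametric host phylogeny
#'
#' @param n_hosts number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return an ultrametric binary `phylo` with tips `host_001 ...`.
#' @export
generate_phylogeny <- function(n_hosts, seed = 1L) {
  if (n_hosts < 2) stop("need at least 2 hosts")
  tree <- withr::with_seed(seed, ape::rphylo(n_hosts, birth = 1, death = 0))
  tree$tip.label <- host_labels(n_hosts)
  tree
}

## Map a standard-normal-ish Brownian tip vector to a positive trait scale.
bm_to_lognormal <- function(z, meanlog, sdlog) {
  exp(meanlog + sdlog * (z - mean(z)) / stats::sd(z))
}

bm_to_levels <- function(z, levels) {
  q <- stats::quantile(z, probs = seq_len(length(levels) - 1) / length(levels))
  levels[findInterval(z, q) + 1]
}

#' Simulate the 18-trait host table on a phylogeny
#'
#' Twelve continuous traits are Brownian motion realisations on the tree
#' mapped to positive trait scales (so phylogenetic signal is preserved on
#' the log scale); habitat breadth is a small positive integer; the
#' geographic range size column is a placeholder that [simulate_world()]
#' overwrites with the size of the generated range. Two binary and four
#' categorical traits are thresholded Brownian latents, giving the Gower
#' machinery all three code paths.
#'
#' @param tree ultrametric `phylo` (tips name the hosts).
#' @param seed integer RNG seed.
#' @param missingness fraction of continuous trait values set to `NA`
#'   (default 0: complete table).
#' @return data frame with `host_id` plus the 18 columns of
#'   [default_trait_spec()].
#' @export
generate_traits <- function(tree, seed = 1L, missingness = 0) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  withr::with_seed(seed, {
    lat <- replicate(18, ape::rTraitCont(tree, model = "BM", sigma = 1))
    rownames(lat) <- tree$tip.label
    hb <- 1L + stats::qpois(stats::pnorm(scale(lat[, 11])[, 1]), lambda = 2)
    tr <- data.frame(
      host_id = tree$tip.label,
      body_mass_g = bm_to_lognormal(lat[, 1], meanlog = 4.5, sdlog = 1.2),
      rel_brain_mass = bm_to_lognormal(lat[, 2], -4, 0.4),
      max_longevity_y = bm_to_lognormal(lat[, 3], 1.5, 0.4),
      age_first_repro_d = bm_to_lognormal(lat[, 4], 4.5, 0.5),
      gestation_d = bm_to_lognormal(lat[, 5], 3.2, 0.4),
      litter_size = bm_to_lognormal(lat[, 6], 1.2, 0.4),
      litters_per_year = bm_to_lognormal(lat[, 7], 0.7, 0.5),
      weaning_age_d = bm_to_lognormal(lat[, 8], 3.4, 0.4),
      generation_length_d = bm_to_lognormal(lat[, 9], 6.5, 0.4),
      dispersal_km = bm_to_lognormal(lat[, 10], 0, 0.8),
      habitat_breadth = hb,
      range_size_km2 = bm_to_lognormal(lat[, 12], 12, 1),
      hibernation = as.integer(lat[, 13] > stats::median(lat[, 13])),
      fossoriality = as.integer(lat[, 14] > stats::median(lat[, 14])),
      trophic_level = bm_to_levels(lat[, 15], c("herbivore", "omnivore", "insectivore")),
      foraging_stratum = bm_to_levels(lat[, 16], c("ground", "scansorial", "arboreal")),
      activity_cycle = bm_to_levels(lat[, 17], c("nocturnal", "cathemeral", "diurnal")),
      social_system = bm_to_levels(lat[, 18], c("solitary", "pair", "group")),
      row.names = NULL, stringsAsFactors = FALSE)
    if (missingness > 0) {
      cont <- default_trait_spec()
      cont <- cont$name[cont$scale == "continuous"]
      for (cl in cont) {
        hit <- stats::runif(n) < missingness
        tr[[cl]][hit] <- NA
      }
    }
    tr
  })
}

grow_range <- function(n_row, n_col, seed_cell, target) {
  occupied <- logical(n_row * n_col)
  occupied[seed_cell] <- TRUE
  frontier <- cell_neighbors(seed_cell, n_row, n_col)
  size <- 1L
  while (size < target && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    occupied[pick] <- TRUE
    size <- size + 1L
    nb <- cell_neighbors(pick, n_row, n_col)
    frontier <- setdiff(unique(c(frontier, nb)), which(occupied))
  }
  which(occupied)
}

## 4-neighbours of a 1-based row-major cell index.
cell_neighbors <- function(idx, n_row, n_col) {
  r <- (idx - 1L) %/% n_col
  c <- (idx - 1L) %% n_col
  nb <- integer(0)
  if (r > 0) nb <- c(nb, idx - n_col)
  if (r < n_row - 1L) nb <- c(nb, idx + n_col)
  if (c > 0) nb <- c(nb, idx - 1L)
  if (c < n_col - 1L) nb <- c(nb, idx + 1L)
  nb
}

#' Simulate contiguous gridded host ranges
#'
#' Each host range is grown by 4-neighbour accretion from a uniformly drawn
#' seed cell up to a target cell count drawn from a lognormal law
#' (median `range_median_cells`, log-sd `range_sdlog`), truncated to the
#' grid, so every range is contiguous and occupies at least one cell.
#'
#' @param grid a [grid_spec()] with >= 25 cells.
#' @param n_hosts number of hosts.
#' @param seed integer RNG seed.
#' @param range_median_cells,range_sdlog lognormal range-size parameters.
#' @return binary host x cell matrix (rows `host_001 ...`, columns
#'   [cell_labels()]).
#' @export
generate_ranges <- function(grid, n_hosts, seed = 1L,
                            range_median_cells = 40, range_sdlog = 0.7) {
  stopifnot(inherits(grid, "grid_spec"), grid$n_cells >= 25)
  withr::with_seed(seed, {
    targets <- pmax(1L, as.integer(round(exp(stats::rnorm(
      n_hosts, mean = log(range_median_cells), sd = range_sdlog)))))
    if (any(targets > grid$n_cells)) {
      warning("range target size exceeds the grid; truncated to the full grid")
      targets <- pmin(targets, grid$n_cells)
    }
    pam <- matrix(0L, n_hosts, grid$n_cells,
                  dimnames = list(host_labels(n_hosts), cell_labels(grid)))
    for (i in seq_len(n_hosts)) {
      seed_cell <- sample.int(grid$n_cells, 1L)
      pam[i, grow_range(grid$n_row, grid$n_col, seed_cell, targets[i])] <- 1L
    }
    pam
  })
}

smooth_field <- function(u, v, n_waves = 6) {
  f <- matrix(stats::runif(2 * n_waves, 0.5, 3), ncol = 2)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  a <- stats::rnorm(n_waves)
  z <- rep(0, length(u))
  for (k in seq_len(n_waves))
    z <- z + a[k] * cos(2 * pi * (f[k, 1] * u + f[k, 2] * v) + ph[k])
  as.numeric(scale(z))
}

#' Simulate correlated environmental layers on a grid
#'
#' Twelve layers built from three latent fields (a latitude-gradient field,
#' a longitude-gradient field and a pure smooth field), each latent being a
#' linear gradient plus smooth spatially autocorrelated noise. Every layer
#' is a fixed loading combination of the latents plus a small idiosyncratic
#' smooth term, so the layers are strongly cross-correlated -- mirroring
#' real climate variable sets where a handful of principal components carry
#' most of the variance.
#'
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed.
#' @return matrix, cells in rows ([cell_labels()] order), 12 named
#'   climate-style variables in columns.
#' @export
generate_environment <- function(grid, seed = 1L) {
  cc <- cell_centers(grid)
  u <- (cc$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  v <- (cc$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
  vars <- c("isothermality", "temp_seasonality", "temp_warmest_q",
            "temp_coldest_q", "annual_precip", "precip_seasonality",
            "precip_warmest_q", "precip_coldest_q", "moisture_index",
            "rel_humidity", "pet", "npp")
  ## rows: layers; columns: loadings on (lat latent, lon latent, free latent)
  loadings <- rbind(
    c(1.0, 0.2, 0.1), c(0.9, -0.3, 0.2), c(0.8, 0.4, -0.2), c(0.9, 0.1, 0.3),
    c(0.2, 1.0, 0.1), c(-0.3, 0.9, 0.2), c(0.3, 0.8, -0.3), c(0.1, 0.9, 0.2),
    c(0.2, 0.1, 1.0), c(-0.2, 0.3, 0.9), c(0.3, -0.2, 0.9), c(0.1, 0.2, 0.8))
  withr::with_seed(seed, {
    lat_grad <- as.numeric(scale(v))
    lon_grad <- as.numeric(scale(u))
    latents <- cbind(0.85 * lat_grad + 0.35 * smooth_field(u, v),
                     0.85 * lon_grad + 0.35 * smooth_field(u, v),
                     smooth_field(u, v))
    env <- sapply(seq_along(vars), function(j) {
      latents %*% loadings[j, ] + 0.25 * smooth_field(u, v)
    })
    dimnames(env) <- list(cc$cell, vars)
    env
  })
}

#' Predictor table for the richness model
#'
#' Assembles the per-host predictors on the scales the richness model uses:
#' `ln_BM` (log body mass, g), `ln_GR` (log range size, km^2), `ln_DF` (log
#' diversity field; hosts with a zero diversity field get `log1p` with a
#' warning) and `HB` (habitat breadth, untransformed).
#'
#' @param traits trait table with `host_id`, `body_mass_g`,
#'   `habitat_breadth`.
#' @param ranges range summary with `host_id`, `range_size_km2`,
#'   `diversity_field` (as from [range_summary()]).
#' @return data frame `host_id`, `ln_BM`, `ln_GR`, `ln_DF`, `HB`.
#' @export
richness_predictors <- function(traits, ranges) {
  stopifnot(setequal(traits$host_id, ranges$host_id))
  ranges <- ranges[match(traits$host_id, ranges$host_id), ]
  df <- ranges$diversity_field
  if (any(df == 0)) {
    warning(sum(df == 0), " host(s) with zero diversity field; using log1p")
    ln_df <- log1p(df)
  } else ln_df <- log(df)
  data.frame(host_id = traits$host_id,
             ln_BM = log(traits$body_mass_g),
             ln_GR = log(ranges$range_size_km2),
             ln_DF = ln_df,
             HB = as.numeric(traits$habitat_breadth),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a parasite x host incidence matrix with planted coefficients
#'
#' Richness mode: host `i`'s parasite richness is drawn from a negative
#' binomial with `mu_i = exp(b0 + b_BM ln BM_i + b_GR ln GR_i + b_DF ln DF_i
#' + b_HB HB_i)` and dispersion `nb_theta`; that many distinct parasite
#' identities are then assigned uniformly at random. Sharing mode: each
#' parasite gets a uniformly drawn focal host `h_p` and every host `i` is
#' infested independently with probability
#' `plogis(a_true + b_true * D(h_p, i))` on the supplied normalized
#' distance matrix.
#'
#' @param world a world list from [simulate_world()] (or any list with
#'   `config`, `predictors` and -- in sharing mode -- nothing else needed).
#' @param distances normalized host x host distance matrix driving sharing
#'   mode; ignored in richness mode.
#' @param seed integer RNG seed (defaults to the config seed).
#' @return binary parasite x host matrix; attributes `mode` and `focal_hosts`
#'   (sharing mode) record the generating truth.
#' @export
generate_incidence <- function(world, distances = NULL, seed = NULL) {
  cfg <- world$config
  stopifnot(inherits(cfg, "world_config"))
  if (is.null(seed)) seed <- cfg$seed
  hosts <- host_labels(cfg$n_hosts)
  paras <- parasite_labels(cfg$n_parasites)
  inc <- withr::with_seed(seed, {
    if (cfg$mode == "richness") {
      pred <- world$predictors
      if (is.null(pred)) stop("richness mode needs world$predictors")
      if (any(!is.finite(as.matrix(pred[c("ln_BM", "ln_GR", "ln_DF", "HB")]))))
        stop("non-finite richness predictors")
      b <- cfg$richness_betas
      mu <- exp(b["b0"] + b["b_BM"] * pred$ln_BM + b["b_GR"] * pred$ln_GR +
                  b["b_DF"] * pred$ln_DF + b["b_HB"] * pred$HB)
      y <- stats::rnbinom(cfg$n_hosts, mu = mu, size = cfg$nb_theta)
      y <- pmin(y, cfg$n_parasites)
      m <- matrix(0L, cfg$n_parasites, cfg$n_hosts,
                  dimnames = list(paras, hosts))
      for (i in seq_len(cfg$n_hosts))
        if (y[i] > 0) m[sample.int(cfg$n_parasites, y[i]), i] <- 1L
      attr(m, "richness") <- stats::setNames(y, hosts)
      m
    } else {
      if (is.null(distances)) stop("sharing mode needs a distance matrix")
      validate_dist(distances, require_normalized = TRUE)
      stopifnot(identical(rownames(distances), hosts))
      a <- cfg$sharing_coefs["a_true"]; b <- cfg$sharing_coefs["b_true"]
      focal <- sample.int(cfg$n_hosts, cfg$n_parasites, replace = TRUE)
      m <- matrix(0L, cfg$n_parasites, cfg$n_hosts,
                  dimnames = list(paras, hosts))
      for (p in seq_len(cfg$n_parasites)) {
        pr <- stats::plogis(a + b * distances[focal[p], ])
        m[p, ] <- as.integer(stats::runif(cfg$n_hosts) < pr)
      }
      attr(m, "focal_hosts") <- hosts[focal]
      m
    }
  })
  if (all(inc == 0)) {
    warning("all-zero incidence matrix; regenerating with seed + 1")
    return(generate_incidence(world, distances, seed = seed + 1L))
  }
  attr(inc, "mode") <- cfg$mode
  inc
}

#' Simulate a complete synthetic realm
#'
#' Runs every generator under per-stage substreams of the config seed:
#' phylogeny, traits (with the range-size column overwritten by the
#' generated range sizes), contiguous ranges, environmental layers, the four
#' normalized distance matrices and the incidence matrix for the configured
#' mode. The returned list carries the planted truth for parameter-recovery
#' tests.
#'
#' @param config a [world_config()].
#' @return list with `config`, `tree`, `traits`, `pam`, `grid`, `env`,
#'   `ranges` (range summary), `predictors`, `distances` (PD/TD/GD/ED +
#'   `pca` report) and `incidence`.
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  s <- config$seed
  tree <- generate_phylogeny(config$n_hosts, seed = s + 1L)
  traits <- generate_traits(tree, seed = s + 2L)
  pam <- generate_ranges(config$grid, config$n_hosts, seed = s + 3L,
                         range_median_cells = config$range_median_cells,
                         range_sdlog = config$range_sdlog)
  env <- generate_environment(config$grid, seed = s + 4L)
  ranges <- range_summary(pam, config$grid)
  traits$range_size_km2 <- ranges$range_size_km2[match(traits$host_id,
                                                       ranges$host_id)]
  dists <- host_distances(tree, traits, pam, config$grid, env, seed = s + 5L)
  predictors <- richness_predictors(traits, ranges)
  world <- list(config = config, tree = tree, traits = traits, pam = pam,
                grid = config$grid, env = env, ranges = ranges,
                predictors = predictors, distances = dists)
  dmat <- switch(config$sharing_distance, phylo = dists$PD, trait = dists$TD,
                 geo = dists$GD, env = dists$ED)
  world$incidence <- generate_incidence(world, distances = dmat,
                                        seed = s + 6L)
  world
}
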