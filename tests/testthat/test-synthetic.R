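test_that("generated phylogenies are ultrametric, binary and reproducible", {
  tr <- generate_phylogeny(2, seed = 1)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(d[1], d[2])
  expect_equal(length(tr$tip.label), 2)
  tr1 <- generate_phylogeny(30, seed = 7)
  tr2 <- generate_phylogeny(30, seed = 7)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(ape::is.binary(tr1))
  expect_true(ape::is.ultrametric(tr1, tol = 1e-8))
  # cophenetic max equals twice the tree depth
  big <- generate_phylogeny(100, seed = 3)
  depth <- max(ape::node.depth.edgelength(big)[1:100])
  expect_equal(max(cophenetic_matrix(big)), 2 * depth, tolerance = 1e-8)
  expect_error(generate_phylogeny(1), "at least 2")
})

test_that("generated traits follow the 18-trait schema deterministically", {
  tree <- generate_phylogeny(25, seed = 2)
  tr <- generate_traits(tree, seed = 2)
  spec <- default_trait_spec()
  expect_named(tr, c("host_id", spec$name))
  expect_setequal(tr$host_id, tree$tip.label)
  expect_true(all(tr$hibernation %in% 0:1))
  expect_true(all(tr$fossoriality %in% 0:1))
  expect_true(all(tr$habitat_breadth >= 1 &
                    tr$habitat_breadth == round(tr$habitat_breadth)))
  expect_true(all(tr$trophic_level %in% c("herbivore", "omnivore", "insectivore")))
  cont <- spec$name[spec$scale == "continuous"]
  expect_true(all(sapply(tr[cont], function(x) all(x > 0))))
  expect_identical(tr, generate_traits(tree, seed = 2))
  # injectable missingness hits only continuous traits
  trm <- generate_traits(tree, seed = 2, missingness = 0.3)
  expect_gt(sum(is.na(trm[cont])), 0)
  expect_equal(sum(is.na(trm[setdiff(names(trm), cont)])), 0)
})

test_that("Brownian continuous traits carry phylogenetic signal near K = 1", {
  ks <- vapply(1:10, function(s) {
    tree <- generate_phylogeny(100, seed = s)
    tr <- generate_traits(tree, seed = s + 500)
    x <- log(tr$gestation_d)
    names(x) <- tr$host_id
    blomberg_k(tree, x, variant = "K", n_perm = 99, seed = s)$statistic
  }, numeric(1))
  expect_gt(mean(ks), 0.7)
  expect_lt(mean(ks), 1.3)
})

test_that("generated ranges are non-empty, contiguous and lognormal-sized", {
  g <- toy_grid()
  pam <- generate_ranges(g, 80, seed = 4)
  expect_true(all(rowSums(pam) >= 1))
  expect_identical(pam, generate_ranges(g, 80, seed = 4))
  # contiguity: flood fill from any occupied cell reaches the whole range
  flood <- function(occ_idx, n_row, n_col) {
    seen <- occ_idx[1]
    frontier <- seen
    while (length(frontier)) {
      nb <- unlist(lapply(frontier, function(i) {
        r <- (i - 1) %/% n_col; c <- (i - 1) %% n_col
        cand <- c(if (r > 0) i - n_col, if (r < n_row - 1) i + n_col,
                  if (c > 0) i - 1, if (c < n_col - 1) i + 1)
        cand
      }))
      frontier <- setdiff(intersect(nb, occ_idx), seen)
      seen <- c(seen, frontier)
    }
    length(seen) == length(occ_idx)
  }
  for (i in seq_len(20))
    expect_true(flood(which(pam[i, ] == 1), g$n_row, g$n_col))
  # moment check of ln(cell count) against the configured lognormal law
  big <- generate_ranges(grid_spec(-30, 30, -30, 30, 1), 500, seed = 5,
                         range_median_cells = 40, range_sdlog = 0.7)
  ln_sizes <- log(rowSums(big))
  se <- 0.7 / sqrt(500)
  expect_lt(abs(mean(ln_sizes) - log(40)), 3 * se + 0.05) # 0.05 rounding slack
  expect_lt(abs(sd(ln_sizes) - 0.7), 0.1)
})

test_that("oversized range targets are truncated to the grid with a warning", {
  g <- grid_spec(0, 5, 0, 5, 1)
  expect_warning(pam <- generate_ranges(g, 10, seed = 1,
                                        range_median_cells = 100,
                                        range_sdlog = 0.2),
                 "truncated")
  expect_true(all(rowSums(pam) <= g$n_cells))
})

test_that("environmental layers are gradient-structured and low-rank", {
  g <- toy_grid()
  env <- generate_environment(g, seed = 6)
  expect_equal(dim(env), c(g$n_cells, 12))
  expect_identical(env, generate_environment(g, seed = 6))
  cc <- cell_centers(g)
  # a gradient-dominated layer tracks latitude
  expect_gt(abs(cor(env[, "isothermality"], cc$lat)), 0.5)
  # 3 principal components explain > 70% of the variance
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  expect_gt(sum(pc$sdev[1:3]^2) / sum(pc$sdev^2), 0.7)
})

test_that("sharing-mode incidence follows the planted logistic kernel", {
  cfg <- world_config(n_hosts = 120, n_parasites = 40, seed = 8,
                      mode = "sharing", sharing_coefs = c(1, 0))
  # flat kernel (b = 0): infestation frequency ~ plogis(1) everywhere
  D <- matrix(0.5, 120, 120, dimnames = list(host_labels_for_test(120),
                                             host_labels_for_test(120)))
  diag(D) <- 0
  attr(D, "normalized") <- TRUE
  world <- list(config = cfg)
  inc <- generate_incidence(world, distances = D, seed = 9)
  p_hat <- mean(inc)
  p0 <- plogis(1)
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / length(inc)))
  expect_identical(inc, generate_incidence(world, distances = D, seed = 9))
})

test_that("richness-mode incidence reproduces the planted NB mean", {
  # intercept-only betas: mean richness ~ e
  cfg <- world_config(n_hosts = 500, n_parasites = 100, seed = 10,
                      mode = "richness",
                      richness_betas = c(1, 0, 0, 0, 0), nb_theta = 1e6)
  pred <- data.frame(host_id = host_labels_for_test(500),
                     ln_BM = rnorm(500), ln_GR = rnorm(500),
                     ln_DF = rnorm(500), HB = rpois(500, 3))
  world <- list(config = cfg, predictors = pred)
  inc <- generate_incidence(world, seed = 11)
  rich <- colSums(inc)
  expect_lt(abs(mean(rich) - exp(1)), 3 * sqrt(exp(1) / 500))
  expect_error(generate_incidence(list(config = cfg,
                                       predictors = transform(pred, ln_BM = NA)),
                                  seed = 1),
               "non-finite")
})

test_that("simulated worlds are deterministic and round-trip through CSV", {
  cfg <- world_config(n_hosts = 20, n_parasites = 10, seed = 12,
                      grid = grid_spec(-5, 5, -5, 5, 1),
                      range_median_cells = 8)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$incidence, w2$incidence)
  expect_equal(w1$distances$TD, w2$distances$TD)
  td <- tempfile(); dir.create(td)
  write_matrix_csv(w1$pam, file.path(td, "pam.csv"))
  expect_identical(read_matrix_csv(file.path(td, "pam.csv")) * 1L, w1$pam)
  write_traits_csv(w1$traits, file.path(td, "traits.csv"))
  expect_equal(read_traits_csv(file.path(td, "traits.csv")), w1$traits,
               tolerance = 1e-12)
  write_dist_csv(w1$distances$PD, file.path(td, "pd.csv"))
  expect_equal(read_dist_csv(file.path(td, "pd.csv"), kind = "PD"),
               w1$distances$PD, ignore_attr = TRUE, tolerance = 1e-12)
  write_matrix_csv(w1$incidence, file.path(td, "inc.csv"),
                   label = "parasite_id")
  expect_identical(read_matrix_csv(file.path(td, "inc.csv")) * 1L,
                   matrix(as.integer(w1$incidence), nrow(w1$incidence),
                          dimnames = dimnames(w1$incidence)))
  unlink(td, recursive = TRUE)
})
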