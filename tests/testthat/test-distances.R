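test_that("ultrametrize-extend lengthens only terminal branches", {
  tr <- ape::read.tree(text = "((A:2,B:1):1,C:3);")
  out <- ultrametrize_extend(tr)
  depths <- ape::node.depth.edgelength(out)[1:3]
  expect_equal(depths, rep(3, 3))
  # internal branch untouched
  internal <- out$edge[, 2] > length(out$tip.label)
  expect_equal(out$edge.length[internal], tr$edge.length[internal])
  # fixed point on an already-ultrametric tree
  tr2 <- generate_phylogeny(20, seed = 5)
  expect_equal(ultrametrize_extend(tr2)$edge.length, tr2$edge.length)
  # random jittered tree: all depths equal the pre-existing maximum
  withr::with_seed(8, {
    tr3 <- tr2
    term <- match(1:20, tr3$edge[, 2])
    tr3$edge.length[term] <- pmax(tr3$edge.length[term] - runif(20, 0, 0.2), 0)
  })
  maxd <- max(ape::node.depth.edgelength(tr3)[1:20])
  out3 <- ultrametrize_extend(tr3)
  expect_equal(ape::node.depth.edgelength(out3)[1:20], rep(maxd, 20))
})

test_that("ultrametrize-extend agrees with the phytools reference", {
  tr <- ape::read.tree(text = "((A:2,B:1):1,(C:3,D:0.5):0.2);")
  expect_equal(ultrametrize_extend(tr)$edge.length,
               phytools::force.ultrametric(tr, method = "extend",
                                           message = FALSE)$edge.length,
               tolerance = 1e-12)
})

test_that("polytomy resolution inserts zero-length edges and preserves paths", {
  tri <- ape::read.tree(text = "(A:1,B:1,C:1);")
  out <- resolve_polytomies(tri, seed = 2)
  expect_true(ape::is.binary(out))
  expect_equal(sort(out$edge.length), c(0, 1, 1, 1))
  # 10-tip star: cophenetic matrix identical before/after
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:10, ":1",
                                                   collapse = ","), ");"))
  before <- cophenetic_matrix(star)
  after <- cophenetic_matrix(resolve_polytomies(star, seed = 3))
  expect_equal(after[rownames(before), colnames(before)], before,
               ignore_attr = TRUE, tolerance = 1e-12)
  # already-binary tree unchanged
  bin <- generate_phylogeny(8, seed = 1)
  expect_equal(resolve_polytomies(bin, seed = 1)$edge, bin$edge)
})

test_that("cophenetic distances are path sums", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(cophenetic_matrix(cherry)["A", "B"], 2)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- cophenetic_matrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  # random ultrametric tree vs explicit root-path enumeration oracle
  tr2 <- generate_phylogeny(10, seed = 4)
  d2 <- cophenetic_matrix(tr2)
  o2 <- oracle_cophenetic(tr2)
  expect_equal(unclass(d2)[rownames(o2), colnames(o2)], o2,
               ignore_attr = TRUE, tolerance = 1e-10)
  depth <- max(ape::node.depth.edgelength(tr2)[1:10])
  expect_true(all(d2 <= 2 * depth + 1e-9))
  dup <- cherry; dup$tip.label <- c("A", "A")
  expect_error(cophenetic_matrix(dup), "duplicate")
})

test_that("cophenetic distances satisfy the four-point condition on small trees", {
  for (s in 1:3) {
    tr <- generate_phylogeny(8, seed = s)
    d <- cophenetic_matrix(tr)
    combos <- utils::combn(8, 4)
    for (k in seq_len(ncol(combos))) {
      q <- combos[, k]
      sums <- c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]])
      two_max <- sort(sums, decreasing = TRUE)[1:2]
      expect_lt(abs(two_max[1] - two_max[2]), 1e-9)
    }
  }
})

test_that("Gower distance follows the weighted mixed-type formula", {
  spec <- default_trait_spec()
  tree <- generate_phylogeny(12, seed = 6)
  traits <- generate_traits(tree, seed = 6)
  d <- gower_matrix(traits, spec)
  expect_equal(unname(diag(d)), rep(0, 12))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, oracle_gower(traits, spec), ignore_attr = TRUE,
               tolerance = 1e-12)
  # identical rows -> 0
  t2 <- traits
  t2[2, -1] <- t2[1, -1]
  t2$host_id <- paste0("h", 1:12)
  expect_equal(gower_matrix(t2, spec)["h1", "h2"], 0)
  # hosts 1 and 2 identical except body mass, at that trait's range extremes
  t3 <- traits
  t3[2, setdiff(names(t3), c("host_id", "body_mass_g"))] <-
    t3[1, setdiff(names(t3), c("host_id", "body_mass_g"))]
  t3$body_mass_g[1] <- min(traits$body_mass_g)
  t3$body_mass_g[2] <- max(traits$body_mass_g)
  expect_equal(gower_matrix(t3, spec)[1, 2], 1 / 18, tolerance = 1e-12)
  # complete mismatch on a categorical-only spec -> 1
  cat_spec <- spec[spec$scale == "categorical", ]
  t4 <- data.frame(host_id = c("x", "y"),
                   trophic_level = c("herbivore", "omnivore"),
                   foraging_stratum = c("ground", "arboreal"),
                   activity_cycle = c("nocturnal", "diurnal"),
                   social_system = c("solitary", "group"))
  expect_equal(gower_matrix(t4, cat_spec)["x", "y"], 1)
})

test_that("Gower handles missingness, constant traits and empty overlap", {
  spec <- default_trait_spec()
  tree <- generate_phylogeny(8, seed = 2)
  traits <- generate_traits(tree, seed = 2, missingness = 0.2)
  d <- gower_matrix(traits, spec)
  expect_equal(d, oracle_gower(traits, spec), ignore_attr = TRUE,
               tolerance = 1e-12)
  # constant continuous trait dropped with a warning
  tc <- generate_traits(tree, seed = 3)
  tc$litter_size <- 2
  expect_warning(gower_matrix(tc, spec), "constant continuous trait")
  # zero comparable traits -> error naming the pair
  two_spec <- spec[spec$name %in% c("body_mass_g", "litter_size"), ]
  tbad <- data.frame(host_id = c("u", "v", "w"),
                     body_mass_g = c(1, NA, 2),
                     litter_size = c(NA, 3, 4))
  expect_error(gower_matrix(tbad, two_spec), "\\(u, v\\)")
})

test_that("Gower agrees with cluster::daisy on complete continuous+factor data", {
  tree <- generate_phylogeny(10, seed = 9)
  traits <- generate_traits(tree, seed = 9)
  spec <- default_trait_spec()
  ours <- gower_matrix(traits, spec)
  df <- traits[spec$name]
  for (nm in spec$name[spec$scale != "continuous"]) df[[nm]] <- factor(df[[nm]])
  for (nm in spec$name[spec$scale == "continuous"]) df[[nm]] <- as.numeric(df[[nm]])
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unclass(ours), ref, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("environmental profiles average cells inside the buffer", {
  g <- grid_spec(0, 3, 0, 3, 1)
  env <- matrix(seq_len(g$n_cells * 2), g$n_cells, 2,
                dimnames = list(cell_labels(g), c("v1", "v2")))
  # tiny buffer -> exactly the centroid's own cell
  p <- environmental_profile(env, g, 1.5, 1.5, buffer_km = 1)
  own <- which(cell_centers(g)$lon == 1.5 & cell_centers(g)$lat == 1.5)
  expect_equal(unname(p), unname(env[own, ]))
  # uniform layer -> the constant
  envu <- matrix(7, g$n_cells, 1, dimnames = list(cell_labels(g), "u"))
  expect_equal(unname(environmental_profile(envu, g, 1.2, 2.2, 150)), 7)
  # hand enumeration: cells whose centres lie within 120 km of (1.5, 1.5)
  cc <- cell_centers(g)
  d <- oracle_haversine(1.5, 1.5, cc$lon, cc$lat)
  sel <- d <= 120
  expect_equal(unname(environmental_profile(env, g, 1.5, 1.5, 120)),
               unname(colMeans(env[sel, ])))
  expect_error(environmental_profile(env, g, 10, 10), "outside")
})

test_that("environmental PCA distance retains components and matches scores", {
  # two-factor structure: 2 components reach >= 95% variance
  withr::with_seed(5, {
    f <- matrix(rnorm(40 * 2), 40, 2)
    load <- matrix(runif(2 * 12, -1, 1), 2, 12)
    prof <- f %*% load + matrix(rnorm(40 * 12, sd = 0.05), 40, 12)
  })
  dimnames(prof) <- list(paste0("h", 1:40), paste0("v", 1:12))
  res <- env_pca_distance(prof, min_variance = 0.95)
  expect_lte(res$n_components, 3)
  expect_gte(res$cum_variance, 0.95)
  # oracle: Euclidean distance between retained scores
  sc <- stats::prcomp(prof, center = TRUE, scale. = TRUE)$x[, 1:res$n_components]
  expect_equal(unclass(res$distances), as.matrix(stats::dist(sc)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # identical profiles -> all distances 0
  same <- matrix(rep(prof[1, ], each = 5), 5, 12,
                 dimnames = list(paste0("s", 1:5), colnames(prof)))
  expect_warning(res0 <- env_pca_distance(same), "identical")
  expect_true(all(res0$distances == 0))
  # invariance to positive rescaling of any input variable
  prof2 <- prof
  prof2[, 3] <- prof2[, 3] * 1000
  res2 <- env_pca_distance(prof2, n_components = 3)
  res3 <- env_pca_distance(prof, n_components = 3)
  expect_equal(res2$distances, res3$distances, tolerance = 1e-8)
  # duplicated variable adds no independent axis
  dup <- cbind(prof[, 1:2], v2b = prof[, 2])
  resd <- env_pca_distance(dup, n_components = 2)
  expect_gte(resd$cum_variance, 0.99)
  expect_error(env_pca_distance(prof, n_components = 13), "n_components")
})

test_that("normalization maps distances onto [0, 1] preserving order", {
  withr::with_seed(11, {
    m <- matrix(runif(36, 0, 5), 6, 6)
  })
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("h", 1:6), paste0("h", 1:6))
  nm <- normalize01(m)
  expect_equal(max(nm[upper.tri(nm)]), 1)
  expect_true(all(nm >= 0 & nm <= 1))
  expect_true(isTRUE(attr(nm, "normalized")))
  # order preserved
  o <- order(m[upper.tri(m)])
  expect_equal(order(nm[upper.tri(nm)]), o)
  # all off-diagonal equal -> all become 1
  eq <- matrix(3, 4, 4); diag(eq) <- 0
  dimnames(eq) <- list(letters[1:4], letters[1:4])
  neq <- normalize01(eq)
  expect_true(all(neq[upper.tri(neq)] == 1))
  # all-zero matrix unchanged with warning
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(nz <- normalize01(z), "all-zero")
  expect_equal(unclass(nz), z, ignore_attr = TRUE)
  neg <- m; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(normalize01(neg), "negative")
})
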