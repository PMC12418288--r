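# Small deterministic fixtures shared across test files.

toy_grid <- function() grid_spec(-10, 10, -10, 10, 1)

host_labels_for_test <- function(n) sprintf("host_%03d", seq_len(n))

# 3-host presence-absence toy on a 1x2 grid region of a larger grid:
# A in cells {0, 1}, B in {0}, C in {0, 1}.
toy_pam <- function(grid = toy_grid()) {
  pam <- matrix(0L, 3, grid$n_cells,
                dimnames = list(c("A", "B", "C"), cell_labels(grid)))
  pam["A", c("cell_0", "cell_1")] <- 1L
  pam["B", "cell_0"] <- 1L
  pam["C", c("cell_0", "cell_1")] <- 1L
  pam
}

random_pam <- function(n_hosts, grid, seed = 1) {
  withr::with_seed(seed, {
    pam <- matrix(0L, n_hosts, grid$n_cells,
                  dimnames = list(sprintf("h%02d", seq_len(n_hosts)),
                                  cell_labels(grid)))
    for (i in seq_len(n_hosts))
      pam[i, sample.int(grid$n_cells, sample(1:12, 1))] <- 1L
    pam
  })
}

# Brute-force oracles, written as plain loops independent of the package
# implementations they check.

oracle_range_size <- function(pam, grid) {
  areas <- grid_cell_areas(grid)
  out <- numeric(nrow(pam))
  for (i in seq_len(nrow(pam))) {
    s <- 0
    for (j in seq_len(ncol(pam))) if (pam[i, j] == 1) s <- s + areas[j]
    out[i] <- s
  }
  names(out) <- rownames(pam)
  out
}

oracle_diversity_field <- function(pam) {
  out <- numeric(nrow(pam))
  for (i in seq_len(nrow(pam))) {
    cells <- which(pam[i, ] == 1)
    vals <- numeric(length(cells))
    for (k in seq_along(cells)) vals[k] <- sum(pam[, cells[k]]) - 1
    out[i] <- mean(vals)
  }
  names(out) <- rownames(pam)
  out
}

oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad; dlam <- (lon2 - lon1) * to_rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * R * asin(sqrt(h))
}

oracle_gower <- function(traits, spec) {
  ids <- traits$host_id
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (k in seq_len(nrow(spec))) {
      xi <- traits[[spec$name[k]]][i]
      xj <- traits[[spec$name[k]]][j]
      if (is.na(xi) || is.na(xj)) next
      if (spec$scale[k] == "continuous") {
        rng <- diff(range(traits[[spec$name[k]]], na.rm = TRUE))
        if (rng == 0) next
        dk <- abs(xi - xj) / rng
      } else dk <- as.numeric(xi != xj)
      num <- num + spec$weight[k] * dk
      den <- den + spec$weight[k]
    }
    d[i, j] <- num / den
  }
  d
}

# Path-sum cophenetic distance by explicit root-path enumeration.
oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    s <- 0
    while (node != root) { s <- s + elen[node]; node <- parent[node] }
    s
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    anc <- intersect(path_to_root(i), path_to_root(j))
    mrca <- anc[which.max(vapply(anc, depth, numeric(1)))]
    d[i, j] <- depth(i) + depth(j) - 2 * depth(mrca)
  }
  d
}
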