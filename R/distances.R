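#' Kind and normalization tags of a distance matrix
#'
#' Between-host distance matrices carry a `kind` attribute (`"PD"`
#' phylogenetic, `"TD"` trait, `"GD"` geographic, `"ED"` environmental) and a
#' logical `normalized` attribute set by [normalize01()].
#'
#' @param d a distance matrix.
#' @return the `kind` attribute (or `NA` if untagged).
#' @export
dist_kind <- function(d) {
  k <- attr(d, "kind")
  if (is.null(k)) NA_character_ else k
}

validate_dist <- function(d, require_normalized = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix must have a zero diagonal")
  if (require_normalized && max(d) > 1 + 1e-8)
    stop("distance matrix must be normalized to [0, 1]")
  invisible(TRUE)
}

#' Make a rooted tree ultrametric by extending terminal branches
#'
#' Each terminal branch is lengthened by the difference between the maximum
#' root-to-tip depth and its own tip's depth; topology and internal branch
#' lengths are untouched. This is the "extend" style of forcing
#' ultrametricity and is appropriate when tip-depth differences reflect
#' rounding rather than true non-contemporaneous tips.
#'
#' @param tree a rooted `phylo` with non-negative branch lengths.
#' @return an ultrametric `phylo`.
#' @export
ultrametrize_extend <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  term <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (max(depth) - depth)
  tree
}

#' Resolve polytomies into zero-length bifurcations
#'
#' Multifurcations are replaced by a random sequence of bifurcations whose
#' inserted edges have length zero, so all cophenetic (path) distances are
#' preserved exactly.
#'
#' @param tree a rooted `phylo`.
#' @param seed integer RNG seed controlling which resolution is drawn.
#' @return a binary `phylo`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  withr::with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Phylogenetic (cophenetic) distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the tree path between
#' tips i and j.
#'
#' @param tree a `phylo` with unique tip labels.
#' @return symmetric matrix tagged `kind = "PD"`, tips in `tree$tip.label`
#'   order.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  attr(d, "kind") <- "PD"
  d
}

#' Default 18-trait specification
#'
#' The trait schema used throughout: 12 continuous traits (life history,
#' body mass, habitat breadth, geographic range size), 2 binary
#' (hibernation/torpor, fossoriality) and 4 categorical (trophic level,
#' foraging stratum, activity cycle, social system).
#'
#' @param weights optional named numeric vector of positive per-trait
#'   weights (default all 1).
#' @return data frame with columns `name`, `scale`, `weight`.
#' @export
default_trait_spec <- function(weights = NULL) {
  spec <- data.frame(
    name = c("body_mass_g", "rel_brain_mass", "max_longevity_y",
             "age_first_repro_d", "gestation_d", "litter_size",
             "litters_per_year", "weaning_age_d", "generation_length_d",
             "dispersal_km", "habitat_breadth", "range_size_km2",
             "hibernation", "fossoriality",
             "trophic_level", "foraging_stratum", "activity_cycle",
             "social_system"),
    scale = c(rep("continuous", 12), rep("binary", 2), rep("categorical", 4)),
    weight = 1,
    stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    stopifnot(all(names(weights) %in% spec$name), all(weights > 0))
    spec$weight[match(names(weights), spec$name)] <- weights
  }
  spec
}

#' Gower mixed-trait distance matrix
#'
#' `d(i, j) = sum_k w_k delta_ijk d_ijk / sum_k w_k delta_ijk`, with
#' `d_ijk = |x_ik - x_jk| / range_k` for continuous traits and the mismatch
#' indicator for binary/categorical traits; `delta_ijk = 0` (pairwise trait
#' exclusion) when either value is missing. Constant continuous traits
#' (range 0) are dropped with a warning; a pair of hosts with no comparable
#' trait at all is an error.
#'
#' @param traits data frame of trait values, one row per host, with a
#'   `host_id` column or row names.
#' @param trait_spec a trait specification as from [default_trait_spec()];
#'   every `name` must be a column of `traits`.
#' @return symmetric matrix in `[0, 1]` tagged `kind = "TD"`.
#' @export
gower_matrix <- function(traits, trait_spec = default_trait_spec()) {
  if (!is.null(traits$host_id)) {
    ids <- as.character(traits$host_id)
  } else {
    ids <- rownames(traits)
  }
  if (is.null(ids) || anyDuplicated(ids)) stop("hosts must have unique ids")
  n <- length(ids)
  if (n < 2) stop("need at least 2 hosts")
  missing_cols <- setdiff(trait_spec$name, names(traits))
  if (length(missing_cols))
    stop("traits table lacks declared columns: ", paste(missing_cols, collapse = ", "))

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in seq_len(nrow(trait_spec))) {
    x <- traits[[trait_spec$name[k]]]
    w <- trait_spec$weight[k]
    ok <- !is.na(x)
    delta <- outer(ok, ok, "&")
    if (trait_spec$scale[k] == "continuous") {
      x <- as.numeric(x)
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("constant continuous trait dropped: ", trait_spec$name[k])
        next
      }
      x0 <- ifelse(ok, x, 0)
      dk <- abs(outer(x0, x0, "-")) / rng
    } else {
      x0 <- as.character(x)
      x0[!ok] <- ""
      dk <- outer(x0, x0, "!=") * 1
    }
    num <- num + w * delta * dk
    den <- den + w * delta
  }
  off <- upper.tri(den)
  if (any(den[off] == 0)) {
    bad <- which(den == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable traits for host pair (%s, %s)",
                 ids[bad[1]], ids[bad[2]]))
  }
  d <- num / den
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(ids, ids)
  attr(d, "kind") <- "TD"
  d
}

#' Environmental profile of a host range centroid
#'
#' Per-variable mean of the environmental layers over all grid cells whose
#' centres lie within `buffer_km` (haversine) of the centroid; the cell
#' containing the centroid is always included. If no cell centre falls
#' within the buffer, the nearest cell is used with a warning.
#'
#' @param env matrix of environmental values, cells in rows (labelled as in
#'   [cell_labels()]), variables in columns.
#' @param grid the [grid_spec()] the layers live on.
#' @param centroid_lon,centroid_lat centroid coordinates in degrees.
#' @param buffer_km buffer radius in km (default 100).
#' @return named numeric vector, one mean per variable.
#' @export
environmental_profile <- function(env, grid, centroid_lon, centroid_lat,
                                  buffer_km = 100) {
  stopifnot(nrow(env) == grid$n_cells)
  if (centroid_lon < grid$lon_min || centroid_lon > grid$lon_max ||
      centroid_lat < grid$lat_min || centroid_lat > grid$lat_max)
    stop("centroid outside the grid bounding box")
  cc <- cell_centers(grid)
  phi1 <- centroid_lat * pi / 180
  phi2 <- cc$lat * pi / 180
  h <- sin((phi2 - phi1) / 2)^2 +
    cos(phi1) * cos(phi2) * sin((cc$lon - centroid_lon) * pi / 360)^2
  d <- 2 * EARTH_RADIUS_KM * asin(sqrt(pmin(h, 1)))
  sel <- d <= buffer_km
  col0 <- min(max(floor((centroid_lon - grid$lon_min) / grid$resolution), 0),
              grid$n_col - 1)
  row0 <- min(max(floor((grid$lat_max - centroid_lat) / grid$resolution), 0),
              grid$n_row - 1)
  sel[row0 * grid$n_col + col0 + 1] <- TRUE
  if (!any(sel)) { # unreachable once the own cell is forced in; kept defensive
    warning("no cell within buffer; falling back to nearest cell")
    sel[which.min(d)] <- TRUE
  }
  colMeans(env[sel, , drop = FALSE])
}

#' Environmental profiles for many hosts
#'
#' @param env,grid,buffer_km as in [environmental_profile()].
#' @param centroids data frame with `host_id`, `centroid_lon`,
#'   `centroid_lat` (as from [range_centroid()]).
#' @return matrix, hosts in rows, environmental variables in columns.
#' @export
env_profiles <- function(env, grid, centroids, buffer_km = 100) {
  out <- t(vapply(seq_len(nrow(centroids)), function(i) {
    environmental_profile(env, grid, centroids$centroid_lon[i],
                          centroids$centroid_lat[i], buffer_km)
  }, numeric(ncol(env))))
  rownames(out) <- centroids$host_id
  out
}

#' Environmental distance from PCA scores
#'
#' Variables are centred and scaled to unit variance (correlation-matrix
#' PCA: the raw layers have incommensurable units), zero-variance variables
#' are dropped with a warning, and the environmental distance between two
#' hosts is the Euclidean distance between their retained principal
#' component scores. Retain either an explicit number of components or the
#' smallest number reaching `min_variance` cumulative variance.
#'
#' @param profiles hosts x variables matrix (as from [env_profiles()]).
#' @param n_components explicit number of components to retain, or `NULL`.
#' @param min_variance cumulative variance fraction target used when
#'   `n_components` is `NULL` (default 0.75).
#' @return list with `distances` (symmetric matrix tagged `kind = "ED"`),
#'   `n_components`, `variance_fractions` (per retained component) and
#'   `cum_variance` (total fraction retained).
#' @export
env_pca_distance <- function(profiles, n_components = NULL, min_variance = 0.75) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 3)
  v <- apply(profiles, 2, stats::var)
  if (all(v == 0)) {
    warning("all environmental profiles identical; distances are all zero")
    d <- matrix(0, nrow(profiles), nrow(profiles),
                dimnames = list(rownames(profiles), rownames(profiles)))
    attr(d, "kind") <- "ED"
    return(list(distances = d, n_components = 0L,
                variance_fractions = numeric(0), cum_variance = 0))
  }
  if (any(v == 0)) {
    warning("zero-variance environmental variable(s) dropped: ",
            paste(colnames(profiles)[v == 0], collapse = ", "))
    profiles <- profiles[, v > 0, drop = FALSE]
  }
  p <- ncol(profiles)
  if (!is.null(n_components) && n_components > p)
    stop("n_components exceeds the number of (non-constant) variables")
  pc <- stats::prcomp(profiles, center = TRUE, scale. = TRUE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_components)) n_components
       else which(cumsum(fr) >= min_variance)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d <- as.matrix(stats::dist(scores))
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  attr(d, "kind") <- "ED"
  list(distances = d, n_components = k,
       variance_fractions = fr[seq_len(k)], cum_variance = sum(fr[seq_len(k)]))
}

#' Normalize a distance matrix to [0, 1]
#'
#' Every entry is divided by the maximum off-diagonal entry, preserving the
#' ordering of entries; the minimum of a distance matrix is 0 by definition
#' (the diagonal), so this maps the range onto `[0, 1]` with max exactly 1.
#' An all-zero matrix is returned unchanged with a warning.
#'
#' @param d symmetric non-negative matrix with zero diagonal.
#' @return the normalized matrix with `normalized = TRUE`; `kind` is kept.
#' @export
normalize01 <- function(d) {
  validate_dist(d)
  m <- max(d[upper.tri(d)])
  if (m == 0) {
    warning("all-zero distance matrix; returned unchanged")
    attr(d, "normalized") <- TRUE
    return(d)
  }
  out <- d / m
  attr(out, "kind") <- attr(d, "kind")
  attr(out, "normalized") <- TRUE
  attr(out, "norm_constant") <- m
  out
}

#' Build the four normalized between-host distance matrices
#'
#' Phylogenetic (cophenetic on the ultrametrized, polytomy-resolved tree),
#' trait (Gower), geographic (haversine between range centroids) and
#' environmental (Euclidean on PCA scores of buffered environmental
#' profiles), each normalized to `[0, 1]`, rows/columns aligned to the
#' presence-absence matrix host order.
#'
#' @param tree rooted `phylo` covering all hosts.
#' @param traits trait table (see [gower_matrix()]).
#' @param pam,grid presence-absence matrix and its grid.
#' @param env cells x variables environmental matrix.
#' @param trait_spec trait declaration, default [default_trait_spec()].
#' @param n_components,min_variance PCA retention rule, see
#'   [env_pca_distance()].
#' @param buffer_km environmental buffer radius, default 100.
#' @param seed seed for the polytomy resolution draw.
#' @return named list `PD`, `TD`, `GD`, `ED` of normalized matrices plus
#'   `pca` (the PCA report).
#' @export
host_distances <- function(tree, traits, pam, grid, env,
                           trait_spec = default_trait_spec(),
                           n_components = NULL, min_variance = 0.75,
                           buffer_km = 100, seed = 1L) {
  hosts <- rownames(pam)
  tree <- resolve_polytomies(ultrametrize_extend(tree), seed = seed)
  pd <- cophenetic_matrix(tree)[hosts, hosts]
  attr(pd, "kind") <- "PD"
  td <- gower_matrix(traits, trait_spec)[hosts, hosts]
  attr(td, "kind") <- "TD"
  cen <- range_centroid(pam, grid)
  gd <- haversine_matrix(cen)
  pca <- env_pca_distance(env_profiles(env, grid, cen, buffer_km),
                          n_components = n_components,
                          min_variance = min_variance)
  ed <- pca$distances[hosts, hosts]
  attr(ed, "kind") <- "ED"
  list(PD = normalize01(pd), TD = normalize01(td), GD = normalize01(gd),
       ED = normalize01(ed), pca = pca[c("n_components", "variance_fractions",
                                         "cum_variance")])
}
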