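#' Geographic range size per host
#'
#' Sum of the spherical areas of all grid cells a host occupies. Cell
#' membership is binary at the whole-cell level (ranges are rasterised to the
#' grid before any computation), so range size is additive over cells.
#' Downstream richness models use `ln(GR)`.
#'
#' @param pam binary host x cell presence-absence matrix (hosts in rows, cell
#'   labels in columns, row-major grid order).
#' @param grid the [grid_spec()] the matrix columns refer to.
#' @return named numeric vector of range sizes in km^2, one per host.
#' @export
range_size <- function(pam, grid) {
  validate_pam(pam, grid)
  areas <- grid_cell_areas(grid)
  out <- as.vector(pam %*% areas)
  names(out) <- rownames(pam)
  out
}

#' Geographic range centroid per host
#'
#' Unweighted arithmetic mean of the occupied cell centres in lon/lat.
#' Ranges that straddle the antimeridian are handled by re-mapping longitudes
#' to `[0, 360)` when the range's longitudinal extent is smaller in that
#' frame, which keeps the centroid inside the range's longitudinal span.
#'
#' @inheritParams range_size
#' @return data frame with columns `host_id`, `centroid_lon`, `centroid_lat`.
#' @export
range_centroid <- function(pam, grid) {
  validate_pam(pam, grid)
  cc <- cell_centers(grid)
  t(apply(pam, 1, function(occ) {
    lon <- cc$lon[occ == 1]
    lat <- cc$lat[occ == 1]
    ext180 <- diff(range(lon))
    lon360 <- lon %% 360
    if (diff(range(lon360)) < ext180) {
      m <- mean(lon360)
      if (m >= 180) m <- m - 360
    } else {
      m <- mean(lon)
    }
    c(centroid_lon = m, centroid_lat = mean(lat))
  })) -> xy
  data.frame(host_id = rownames(pam), centroid_lon = xy[, 1],
             centroid_lat = xy[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Diversity field per host
#'
#' The mean number of *other* species co-occurring within a focal host's
#' range: for host `i` occupying cells `C_i`,
#' `DF_i = mean over c in C_i of (S_c - 1)` where `S_c` is the number of
#' hosts present in cell `c`. Every host in the matrix counts as a potential
#' co-occurrer, regardless of whether parasites were recorded on it.
#'
#' @inheritParams range_size
#' @return named numeric vector of diversity fields (>= 0), one per host.
#' @export
diversity_field <- function(pam) {
  validate_pam(pam)
  s <- colSums(pam)
  out <- as.vector(pam %*% (s - 1)) / rowSums(pam)
  names(out) <- rownames(pam)
  out
}

#' Pairwise haversine great-circle distances
#'
#' `d = 2 R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2)))`
#' with `R = EARTH_RADIUS_KM`.
#'
#' @param lon,lat coordinate vectors in degrees; `names(lon)` (or the
#'   `host_id` column when a centroid data frame is passed as `lon`) label
#'   the result.
#' @return symmetric matrix of distances in km with zero diagonal, tagged
#'   with `kind = "GD"` (see [dist_kind()]).
#' @examples
#' haversine_matrix(c(a = 0, b = 90), c(a = 0, b = 0))["a", "b"] # quarter circle
#' @export
haversine_matrix <- function(lon, lat = NULL) {
  if (is.data.frame(lon)) {
    df <- lon
    lon <- df$centroid_lon
    lat <- df$centroid_lat
    names(lon) <- df$host_id
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -360 | lon > 360)) stop("longitude outside valid degrees")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  h <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  d <- 2 * EARTH_RADIUS_KM * asin(sqrt(pmin(pmax(h, 0), 1)))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(names(lon), names(lon))
  attr(d, "kind") <- "GD"
  d
}

#' Per-host range summaries
#'
#' Convenience wrapper combining [range_size()], [range_centroid()] and
#' [diversity_field()] into the per-host table consumed by the richness
#' models.
#'
#' @inheritParams range_size
#' @return data frame with columns `host_id`, `range_size_km2`,
#'   `centroid_lon`, `centroid_lat`, `diversity_field`.
#' @export
range_summary <- function(pam, grid) {
  cen <- range_centroid(pam, grid)
  data.frame(host_id = rownames(pam),
             range_size_km2 = unname(range_size(pam, grid)),
             centroid_lon = cen$centroid_lon,
             centroid_lat = cen$centroid_lat,
             diversity_field = unname(diversity_field(pam)),
             row.names = NULL, stringsAsFactors = FALSE)
}
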