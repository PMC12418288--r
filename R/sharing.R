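#' Parasites eligible for the sharing analysis
#'
#' Only parasites recorded on at least `min_hosts` host species enter the
#' sharing regressions; original row order is preserved.
#'
#' @param incidence binary parasite x host matrix.
#' @param min_hosts minimum number of hosts (default 6).
#' @return character vector of eligible parasite ids (empty, with a
#'   warning, when none qualifies).
#' @export
eligible_parasites <- function(incidence, min_hosts = 6) {
  stopifnot(is.matrix(incidence), all(incidence %in% c(0, 1)))
  keep <- rowSums(incidence) >= min_hosts
  if (!any(keep)) {
    warning("no parasite recorded on >= ", min_hosts,
            " hosts; sharing analysis cannot run")
    return(character(0))
  }
  rownames(incidence)[keep]
}

#' Build the source/target cases for one parasite's sharing regression
#'
#' Every host carrying the parasite acts in turn as the source: each other
#' carrier contributes a response-1 case at their between-host distance, and
#' a uniform without-replacement sample of non-carriers of size
#' `min(#carriers - 1, #non-carriers)` (a balanced negative sample per
#' source) contributes the response-0 cases. Cases are pooled over sources.
#' Draws come from the current RNG stream unless `seed` is given, so the
#' bootstrap can take fresh negatives at every iteration.
#'
#' @param parasite parasite id (row of `incidence`).
#' @param incidence binary parasite x host matrix.
#' @param dmatrix normalized host x host distance matrix with the same host
#'   labels.
#' @param seed optional integer seed for a reproducible stand-alone draw.
#' @return data frame with columns `source`, `target`, `D`, `response`.
#' @export
build_sharing_cases <- function(parasite, incidence, dmatrix, seed = NULL) {
  validate_dist(dmatrix, require_normalized = TRUE)
  stopifnot(identical(colnames(incidence), rownames(dmatrix)))
  row <- incidence[parasite, ]
  carriers <- names(row)[row == 1]
  noncar <- names(row)[row == 0]
  if (length(noncar) == 0)
    stop("parasite ", parasite, " infests every host; no negative cases")
  build <- function() {
    nc <- length(carriers)
    n_neg <- min(nc - 1L, length(noncar))
    ## positives: every ordered carrier pair (source, other carrier)
    pos_src <- rep(carriers, each = nc - 1L)
    pos_tgt <- as.vector(vapply(seq_len(nc), function(i) carriers[-i],
                                character(nc - 1L)))
    ## negatives: per source, a fresh without-replacement sample of non-carriers
    neg_tgt <- as.vector(vapply(carriers, function(s)
      sample(noncar, n_neg, replace = FALSE), character(n_neg)))
    neg_src <- rep(carriers, each = n_neg)
    src <- c(pos_src, neg_src)
    tgt <- c(pos_tgt, neg_tgt)
    data.frame(source = src, target = tgt,
               D = dmatrix[cbind(src, tgt)],
               response = rep(c(1L, 0L), c(length(pos_src), length(neg_src))),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Logistic regression of sharing cases on distance
#'
#' Maximum-likelihood logistic regression of the binary response on the
#' between-host distance `D` (IRLS via `stats::glm.fit`). Fits showing
#' (quasi-)separation, a degenerate design or non-convergence are flagged
#' so the pooling step can exclude them.
#'
#' @param cases data frame from [build_sharing_cases()] (needs `D` and
#'   `response`).
#' @return list with `a` (intercept), `b` (slope), `se` (length-2),
#'   `converged`, `n_cases`.
#' @export
fit_sharing_logistic <- function(cases) {
  y <- cases$response
  if (length(unique(y)) < 2) stop("need both response classes")
  X <- cbind(`(Intercept)` = 1, D = cases$D)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  bad <- is.null(fit) || !fit$converged || fit$boundary ||
    anyNA(fit$coefficients) || max(abs(fit$coefficients)) > 25
  if (!is.null(fit) && !anyNA(fit$coefficients)) {
    co <- fit$coefficients
    w <- fit$weights
    se <- tryCatch(sqrt(diag(solve(crossprod(X * sqrt(w))))),
                   error = function(e) c(NA_real_, NA_real_))
  } else {
    co <- c(NA_real_, NA_real_)
    se <- c(NA_real_, NA_real_)
  }
  list(a = unname(co[1]), b = unname(co[2]), se = unname(se),
       converged = !bad, n_cases = length(y))
}

fit_one_parasite <- function(parasite, incidence, dmatrix) {
  cases <- build_sharing_cases(parasite, incidence, dmatrix)
  fit_sharing_logistic(cases)
}

#' Per-parasite sharing coefficients
#'
#' One logistic fit per eligible parasite (fresh negative samples), the
#' ingredient of [pns()] and of the bootstrap in [pooled_coefficients()].
#'
#' @inheritParams pooled_coefficients
#' @return data frame with `parasite_id`, `n_hosts`, `a_p`, `b_p`,
#'   `converged`.
#' @export
per_parasite_fits <- function(incidence, dmatrix, min_hosts = 6, seed = 1L) {
  elig <- eligible_parasites(incidence, min_hosts)
  if (length(elig) == 0) stop("no eligible parasite")
  withr::with_seed(seed, {
    per <- lapply(elig, fit_one_parasite, incidence = incidence,
                  dmatrix = dmatrix)
    data.frame(parasite_id = elig,
               n_hosts = rowSums(incidence[elig, , drop = FALSE]),
               a_p = vapply(per, `[[`, numeric(1), "a"),
               b_p = vapply(per, `[[`, numeric(1), "b"),
               converged = vapply(per, `[[`, logical(1), "converged"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Proportion of negative slopes
#'
#' Among converged per-parasite fits, the proportion with a strictly
#' negative slope (a slope of exactly zero counts as non-negative).
#'
#' @param per_parasite data frame with columns `b_p` and `converged` (as in
#'   the `per_parasite` element of a [pooled_coefficients()] result).
#' @return proportion in `[0, 1]`.
#' @export
pns <- function(per_parasite) {
  ok <- per_parasite$converged
  if (!any(ok)) stop("no converged per-parasite fit; PNS undefined")
  mean(per_parasite$b_p[ok] < 0)
}

#' Pooled sharing coefficients by species bootstrap
#'
#' Per-parasite logistic fits are computed once (with fresh negative
#' samples) to give the per-parasite coefficient table and PNS. The pooled
#' coefficients then come from `n_iter` bootstrap iterations: each draws a
#' with-replacement random set of eligible parasites (of the full pool
#' size), refits every drawn parasite with fresh negative samples and
#' records the iteration's mean intercept and slope; the pooled `a` and `b`
#' are the means of those iteration means -- the central tendency of each
#' coefficient distribution.
#'
#' @param incidence binary parasite x host matrix.
#' @param dmatrix normalized host x host distance matrix (same host order).
#' @param n_iter bootstrap iterations (default 1000).
#' @param min_hosts eligibility threshold (default 6).
#' @param seed integer RNG seed.
#' @param replace draw bootstrap sets with replacement (default `TRUE`);
#'   `FALSE` gives without-replacement subsets of the same size, i.e. the
#'   identity resample, kept as an explicit switch.
#' @return object of class `sharing_fit`: list with `per_parasite` (data
#'   frame `parasite_id`, `n_hosts`, `a_p`, `b_p`, `converged`), `pns`,
#'   `a`, `b` (pooled means), `boot_a`, `boot_b` (iteration-mean
#'   distributions), `n_iter`, `n_dropped`, `kind` (distance kind).
#' @export
pooled_coefficients <- function(incidence, dmatrix, n_iter = 1000,
                                min_hosts = 6, seed = 1L, replace = TRUE) {
  elig <- eligible_parasites(incidence, min_hosts)
  if (length(elig) == 0) stop("no eligible parasite; cannot pool")
  withr::with_seed(seed, {
    per <- lapply(elig, fit_one_parasite, incidence = incidence,
                  dmatrix = dmatrix)
    per_df <- data.frame(
      parasite_id = elig,
      n_hosts = rowSums(incidence[elig, , drop = FALSE]),
      a_p = vapply(per, `[[`, numeric(1), "a"),
      b_p = vapply(per, `[[`, numeric(1), "b"),
      converged = vapply(per, `[[`, logical(1), "converged"),
      row.names = NULL, stringsAsFactors = FALSE)
    boot_a <- boot_b <- rep(NA_real_, n_iter)
    for (it in seq_len(n_iter)) {
      draw <- sample(elig, length(elig), replace = replace)
      fits <- lapply(draw, fit_one_parasite, incidence = incidence,
                     dmatrix = dmatrix)
      ok <- vapply(fits, `[[`, logical(1), "converged")
      if (!any(ok)) next
      boot_a[it] <- mean(vapply(fits[ok], `[[`, numeric(1), "a"))
      boot_b[it] <- mean(vapply(fits[ok], `[[`, numeric(1), "b"))
    }
    dropped <- sum(is.na(boot_a))
    if (dropped > 0.1 * n_iter)
      stop("more than 10% of bootstrap iterations had no converged fit")
    out <- list(per_parasite = per_df, pns = pns(per_df),
                a = mean(boot_a, na.rm = TRUE), b = mean(boot_b, na.rm = TRUE),
                boot_a = boot_a, boot_b = boot_b, n_iter = n_iter,
                n_dropped = dropped, kind = dist_kind(dmatrix))
    class(out) <- "sharing_fit"
    out
  })
}

#' @export
print.sharing_fit <- function(x, ...) {
  cat(sprintf("Parasite-sharing fit (%s distance)\n",
              ifelse(is.na(x$kind), "?", x$kind)))
  cat(sprintf("  eligible parasites: %d (%d converged)\n",
              nrow(x$per_parasite), sum(x$per_parasite$converged)))
  cat(sprintf("  pooled intercept a = %.3f, pooled slope b = %.3f (%d iterations)\n",
              x$a, x$b, x$n_iter))
  cat(sprintf("  PNS = %.3f\n", x$pns))
  invisible(x)
}

#' Sharing probability curve
#'
#' `P(D) = 1 / (1 + exp(-(a + b D)))`: the standard logistic orientation,
#' so a negative slope gives a probability that decreases with distance.
#'
#' @param a intercept (pooled mean).
#' @param b slope (pooled mean).
#' @param D_grid distances in `[0, 1]` (default a 101-point grid).
#' @return data frame with columns `D` and `P`.
#' @export
sharing_probability <- function(a, b, D_grid = seq(0, 1, length.out = 101)) {
  stopifnot(all(D_grid >= 0 & D_grid <= 1))
  data.frame(D = D_grid, P = stats::plogis(a + b * D_grid))
}
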