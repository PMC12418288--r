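#' Fit a negative-binomial GLM with log link
#'
#' Maximum-likelihood NB2 fit (alternating IRLS for the coefficients with ML
#' updates of the dispersion), as implemented by `MASS::glm.nb`. The AIC
#' counts the dispersion `theta` as one estimated parameter,
#' `AIC = -2 logLik + 2 (k + 1)`.
#'
#' When the data are equi- or under-dispersed the likelihood increases
#' monotonically in `theta` and the ML solution sits at the Poisson
#' boundary; `theta` then diverges and the alternating algorithm cannot
#' terminate. In that case the fit falls back to the Poisson-limit solution
#' (Poisson IRLS coefficients, `theta` capped at 1e5, NB log-likelihood and
#' deviances evaluated at the cap) and is flagged `theta_boundary = TRUE`,
#' keeping all 2^4 candidate models comparable on the same NB likelihood
#' scale during model selection.
#'
#' @param y non-negative integer response (parasite species richness).
#' @param X data frame or matrix of predictors (an intercept is always
#'   included; pass a zero-column `X` for the intercept-only model).
#' @return an object of class `nb_fit`: list with `coefficients`, `theta`,
#'   `logLik`, `df` (estimated parameters incl. theta), `AIC`, `deviance`,
#'   `se`, `fitted`, `n`, `predictors` and the underlying `fit`.
#' @export
nb_glm_fit <- function(y, X = NULL) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integers")
  y <- as.integer(round(y))
  if (is.null(X) || NCOL(X) == 0) {
    dat <- data.frame(y = y)
    form <- y ~ 1
    preds <- character(0)
  } else {
    X <- as.data.frame(X)
    if (qr(cbind(1, as.matrix(X)))$rank < ncol(X) + 1)
      stop("design matrix (with intercept) is rank deficient")
    dat <- cbind(data.frame(y = y), X)
    preds <- names(X)
    form <- stats::reformulate(preds, response = "y")
  }
  boundary <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(form, data = dat, control = stats::glm.control(maxit = 200)),
      warning = function(w) {
        if (grepl("iteration limit", conditionMessage(w)))
          boundary <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || !is.finite(fit$theta) ||
      fit$theta > 1e5 || as.numeric(stats::logLik(fit)) > 0) {
    ## theta diverged: the NB likelihood is maximized at the Poisson
    ## boundary, so take the Poisson coefficients with theta capped high
    boundary <- TRUE
    pois <- stats::glm(form, data = dat, family = stats::poisson())
    if (!pois$converged) stop("negative-binomial fit did not converge")
    theta <- 1e5
    mu <- stats::fitted(pois)
    nb_dev <- function(mu) {
      t1 <- ifelse(y == 0, 0, y * log(y / mu))
      2 * sum(t1 - (y + theta) * log((y + theta) / (mu + theta)))
    }
    ll <- sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
    k <- length(stats::coef(pois)) + 1
    out <- list(coefficients = stats::coef(pois), theta = theta,
                logLik = ll, df = k, AIC = -2 * ll + 2 * k,
                deviance = nb_dev(mu),
                null_deviance = nb_dev(rep(mean(y), length(y))),
                se = sqrt(diag(stats::vcov(pois))), fitted = mu,
                n = length(y), predictors = preds, fit = pois,
                theta_boundary = TRUE)
    class(out) <- "nb_fit"
    return(out)
  }
  ll <- stats::logLik(fit)
  out <- list(coefficients = stats::coef(fit), theta = fit$theta,
              logLik = as.numeric(ll), df = attr(ll, "df"),
              AIC = -2 * as.numeric(ll) + 2 * attr(ll, "df"),
              deviance = fit$deviance, null_deviance = fit$null.deviance,
              se = sqrt(diag(stats::vcov(fit))),
              fitted = stats::fitted(fit), n = length(y),
              predictors = preds, fit = fit, theta_boundary = boundary)
  class(out) <- "nb_fit"
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n")
  cat("  predictors:", if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  theta = %.3f, logLik = %.2f, AIC = %.2f\n",
              x$theta, x$logLik, x$AIC))
  invisible(x)
}

#' Explained deviance and Nagelkerke pseudo-R-squared
#'
#' `ED = 100 (1 - deviance_model / deviance_null)` (percent) and
#' `R2_N = R2_CS / (1 - exp((2/n) ll_null))` with the Cox-Snell
#' `R2_CS = 1 - exp((2/n) (ll_null - ll_model))`.
#'
#' For a negative-binomial fit the two deviances are only comparable at a
#' common dispersion, so ED uses the null deviance evaluated at the model's
#' own `theta` (the `null.deviance` of the fit). The pseudo-R-squared part
#' uses the log-likelihood of the separately fitted intercept-only model.
#' `model` / `null_model` may also be given as bare log-likelihood numbers,
#' in which case only the R-squared values are computed (and `n` must be
#' supplied).
#'
#' @param model,null_model `nb_fit` objects fitted to the same data
#'   (`null_model` intercept-only), or numeric log-likelihoods.
#' @param n number of observations (defaults to `model$n`).
#' @return list with `explained_deviance_percent`, `cox_snell_r2` and
#'   `nagelkerke_r2`.
#' @export
fit_summaries <- function(model, null_model, n = model$n) {
  if (n <= 0) stop("n must be positive")
  ll1 <- if (is.numeric(model)) model else model$logLik
  ll0 <- if (is.numeric(null_model)) null_model else null_model$logLik
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2_n <- r2_cs / (1 - exp((2 / n) * ll0))
  ed <- if (is.numeric(model)) NA_real_
        else 100 * (1 - model$deviance / model$null_deviance)
  list(explained_deviance_percent = ed, cox_snell_r2 = r2_cs,
       nagelkerke_r2 = r2_n)
}

#' All-subsets AIC model selection for the richness model
#'
#' Fits all 16 subsets of the four candidate predictors (`ln_BM`, `ln_GR`,
#' `ln_DF`, `HB`), including the intercept-only model, and ranks them by
#' AIC (ties broken by fewer parameters). AICc is available as a switch.
#'
#' @param dataset a richness dataset: data frame with `richness` plus the
#'   four predictor columns (see [build_richness_dataset()]).
#' @param aicc use the small-sample corrected criterion instead of plain
#'   AIC (default `FALSE`).
#' @return list with `table` (one row per candidate model: `predictors`,
#'   `df`, `logLik`, `AIC`, `delta_AIC`, ranked) and `best` (the best
#'   `nb_fit`, with `$summaries` attached).
#' @export
all_subsets_select <- function(dataset, aicc = FALSE) {
  cand <- c("ln_BM", "ln_GR", "ln_DF", "HB")
  stopifnot(all(c("richness", cand) %in% names(dataset)))
  subsets <- unlist(lapply(0:4, function(k)
    utils::combn(cand, k, simplify = FALSE)), recursive = FALSE)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    preds <- subsets[[i]]
    fit <- tryCatch(nb_glm_fit(dataset$richness, dataset[preds]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("model {", paste(preds, collapse = ", "), "} failed: ",
              conditionMessage(fit), "; excluded from ranking")
      next
    }
    crit <- fit$AIC
    if (aicc) crit <- crit + 2 * fit$df * (fit$df + 1) / (fit$n - fit$df - 1)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      predictors = if (length(preds)) paste(preds, collapse = "+") else "(intercept)",
      df = fit$df, logLik = fit$logLik, AIC = crit,
      stringsAsFactors = FALSE)
  }
  ok <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[ok])
  fits <- fits[ok]
  ord <- order(tab$AIC, tab$df)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  best <- fits[[1]]
  null_fit <- fits[[which(tab$predictors == "(intercept)")]]
  best$summaries <- fit_summaries(best, null_fit)
  list(table = tab, best = best, null = null_fit)
}

#' Assemble a per-host richness dataset
#'
#' Per-host parasite species richness (column sums of the incidence matrix)
#' joined to the model predictors. Ubiquitous, near-commensal hosts should
#' be excluded upstream before the incidence matrix is built.
#'
#' @param incidence binary parasite x host matrix.
#' @param predictors predictor table from [richness_predictors()].
#' @return data frame `host_id`, `richness`, `ln_BM`, `ln_GR`, `ln_DF`,
#'   `HB`.
#' @export
build_richness_dataset <- function(incidence, predictors) {
  stopifnot(all(colnames(incidence) %in% predictors$host_id))
  rich <- colSums(incidence)
  out <- predictors[match(colnames(incidence), predictors$host_id), ]
  out$richness <- as.integer(rich)
  out[c("host_id", "richness", "ln_BM", "ln_GR", "ln_DF", "HB")]
}

k_ratio <- function(x, V_inv, a) {
  n <- length(x)
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% V_inv %*% r) / (n - 1)
  mse0 / mse
}

#' Blomberg's K / K* phylogenetic signal test
#'
#' With `V` the Brownian covariance implied by the tree, the observed ratio
#' `MSE0 / MSE` compares the ordinary sum of squares about a central value
#' `a` with the V-weighted (generalized) sum of squares about the same `a`;
#' `K` divides it by its Brownian expectation
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. Variant `"K"` uses the GLS ancestral
#' mean for `a`; variant `"K*"` uses the arithmetic tip mean. Significance
#' is by permutation of values across tips: `p = (1 + #{K_perm >= K_obs}) /
#' (n_perm + 1)`.
#'
#' @param tree ultrametric `phylo`.
#' @param values named numeric vector (names = tip labels).
#' @param variant `"K"` or `"K*"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed for the permutations.
#' @return list with `statistic`, `variant`, `n_perm`, `p_value`.
#' @export
blomberg_k <- function(tree, values, variant = c("K", "K*"), n_perm = 999,
                       seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(tree, "phylo"), n_perm >= 99)
  if (!setequal(names(values), tree$tip.label))
    stop("value names do not match tree tip labels")
  x <- as.numeric(values[tree$tip.label])
  n <- length(x)
  V <- ape::vcv(tree)
  V_inv <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  expected <- (sum(diag(V)) - n / sum(V_inv)) / (n - 1)
  ones <- rep(1, n)
  central <- function(z) {
    if (variant == "K") as.numeric(t(ones) %*% V_inv %*% z) / sum(V_inv)
    else mean(z)
  }
  k_obs <- k_ratio(x, V_inv, central(x)) / expected
  k_perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    z <- x[sample.int(n)]
    k_ratio(z, V_inv, central(z)) / expected
  }, numeric(1)))
  list(statistic = k_obs, variant = variant, n_perm = n_perm,
       p_value = (1 + sum(k_perm >= k_obs)) / (n_perm + 1))
}

#' Phylogenetic-signal gate for the richness analysis
#'
#' Runs [blomberg_k()] on per-host richness and warns -- without applying
#' any phylogenetic correction -- when significant signal is detected, the
#' decision rule used before fitting the (non-phylogenetic) NB models.
#'
#' @inheritParams blomberg_k
#' @param richness named integer vector of per-host richness.
#' @param alpha warning threshold on the permutation p-value (default 0.05).
#' @return the [blomberg_k()] result, invisibly warning when
#'   `p_value < alpha`.
#' @export
signal_gate <- function(tree, richness, variant = "K*", n_perm = 999,
                        seed = 1L, alpha = 0.05) {
  res <- blomberg_k(tree, richness, variant = variant, n_perm = n_perm,
                    seed = seed)
  if (res$p_value < alpha)
    warning(sprintf(
      "phylogenetic signal detected in richness (%s = %.3f, p = %.4f); %s",
      res$variant, res$statistic, res$p_value,
      "models are fitted without phylogenetic correction regardless"))
  res
}
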