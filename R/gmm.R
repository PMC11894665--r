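#' Fit a Gaussian mixture to a peptidoform's calibrated mass errors
#'
#' Fits univariate Gaussian mixtures with 1 to `max_k` components by
#' expectation-maximization and selects the number of components by BIC with
#' a parsimony rule: starting from one component, a larger model is adopted
#' only when its BIC is at least `delta` points smaller than the current
#' choice (comparisons are sequential, 1 vs 2, then the winner vs 3). One
#' component models a pure population (all-phospho, or all-sulfo); two
#' components capture a site that is sometimes phosphorylated and sometimes
#' sulfated; three components cover mixtures of no/single/double sulfation.
#'
#' For `k = 1` the EM reduces to the closed-form Gaussian maximum-likelihood
#' estimate (sample mean, population-style standard deviation). For larger
#' `k`, means are initialized at evenly spaced sample quantiles and the best
#' of `n_restarts` jittered restarts is kept; a variance floor guards against
#' components collapsing onto repeated values.
#'
#' @param errors Numeric vector of calibrated mass errors (Da).
#' @param max_k Largest number of components considered (default 3).
#' @param delta BIC improvement required to accept a larger model
#'   (default 10, "very strong evidence").
#' @param seed Integer seed making the restart jitter reproducible.
#' @param n_restarts EM restarts per k (default 5).
#' @param tol Convergence tolerance on the change in mean log-likelihood
#'   per observation (default 1e-8).
#' @param max_iter EM iteration cap (default 500); hitting it is recorded in
#'   the `converged` field, not an error.
#' @param var_floor Minimum component variance in Da^2 (default 1e-8).
#' @return An object of class `mass_error_gmm`: a list with `components`
#'   (data.frame of `weight`, `mean`, `sd` for the selected model),
#'   `selected_k`, `bic_by_k`, `log_likelihood`, `n`, `converged`, `seed`,
#'   and `fits` (per-k component tables).
#' @examples
#' x <- rnorm(200, -0.0095, 0.002)
#' fit <- fit_mass_error_gmm(x, seed = 1)
#' coef(fit)
#' @export
fit_mass_error_gmm <- function(errors, max_k = 3L, delta = 10, seed = 1L,
                               n_restarts = 5L, tol = 1e-8, max_iter = 500L,
                               var_floor = 1e-8) {
  errors <- as.numeric(errors)
  stopifnot(all(is.finite(errors)))
  n <- length(errors)
  if (n < 2L) stop("need at least 2 mass errors to fit a mixture")
  max_k <- as.integer(max_k)
  ks <- seq_len(max_k)
  ks <- ks[n >= pmax(2L * ks, 2L)]
  if (!length(ks)) stop("too few samples for any candidate model")

  fits <- with_seed(seed, {
    lapply(ks, function(k) {
      .fit_gmm_k(errors, k, n_restarts = n_restarts, tol = tol,
                 max_iter = max_iter, var_floor = var_floor)
    })
  })
  names(fits) <- as.character(ks)
  bic_by_k <- vapply(fits, function(f) {
    bic_score(f$log_likelihood, f$k, n)
  }, 0)
  selected_k <- select_components(bic_by_k, delta = delta)
  best <- fits[[as.character(selected_k)]]
  structure(list(
    components = best$components,
    selected_k = selected_k,
    bic_by_k = bic_by_k,
    log_likelihood = best$log_likelihood,
    n = n,
    converged = best$converged,
    seed = seed,
    errors = errors,
    fits = lapply(fits, `[[`, "components")
  ), class = "mass_error_gmm")
}

# EM for a fixed k; returns the best of n_restarts runs.
.fit_gmm_k <- function(x, k, n_restarts, tol, max_iter, var_floor) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(
      k = 1L, log_likelihood = ll, converged = TRUE,
      components = data.frame(weight = 1, mean = mu, sd = sqrt(v))
    ))
  }
  base_mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  spread <- max(stats::sd(x), sqrt(var_floor))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1L) base_mu else base_mu + stats::rnorm(k, 0, spread / k)
    fit <- .em_univariate(x, k, mu0 = mu0,
                          v0 = rep(max(stats::var(x) / k^2, var_floor), k),
                          w0 = rep(1 / k, k), tol = tol,
                          max_iter = max_iter, var_floor = var_floor)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  comp <- data.frame(weight = best$w, mean = best$mu, sd = sqrt(best$v))
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  list(k = k, log_likelihood = best$log_likelihood,
       converged = best$converged, components = comp)
}

# Vectorized EM for a univariate Gaussian mixture. The observed-data
# log-likelihood is monotone nondecreasing across iterations up to floating
# point and variance flooring.
.em_univariate <- function(x, k, mu0, v0, w0, tol, max_iter, var_floor) {
  n <- length(x)
  mu <- mu0; v <- pmax(v0, var_floor); w <- w0
  log2pi <- log(2 * pi)
  # weighted log-density matrix (n x k), computed without per-row apply
  log_dens <- function(mu, v, w) {
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      logd[, j] <- log(w[j]) - 0.5 * (log2pi + log(v[j])) -
        (x - mu[j])^2 / (2 * v[j])
    }
    logd
  }
  row_lse <- function(logd) {
    m <- logd[, 1L]
    for (j in seq_len(k)[-1L]) m <- pmax(m, logd[, j])
    m + log(rowSums(exp(logd - m)))
  }
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logd <- log_dens(mu, v, w)
    lse <- row_lse(logd)
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    if ((ll - ll_old) / n < tol && iter > 1L) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  # final log-likelihood under the last parameter update
  ll <- sum(row_lse(log_dens(mu, v, w)))
  list(mu = mu, v = v, w = w, log_likelihood = ll, converged = converged)
}

#' Bayesian information criterion for a univariate Gaussian mixture
#'
#' `BIC = p * ln(n) - 2 * logLik` with `p = 3k - 1` free parameters
#' (k means, k standard deviations, k - 1 free weights). Lower is better.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of components.
#' @param n Number of observations.
#' @return BIC value.
#' @export
bic_score <- function(log_likelihood, k, n) {
  stopifnot(n >= 1)
  (3 * k - 1) * log(n) - 2 * log_likelihood
}

#' Select the number of mixture components from BIC scores
#'
#' Scans upward from the smallest model: the current choice `c` is replaced
#' by a larger `k` only if `BIC(k) <= BIC(c) - delta`. With the default
#' `delta = 10` a larger model must show very strong evidence to displace a
#' smaller one.
#'
#' @param bic_by_k Named numeric vector of BIC scores, names "1", "2", ...
#' @param delta Required BIC improvement (default 10).
#' @return Selected number of components (integer).
#' @examples
#' select_components(c(`1` = 100, `2` = 89, `3` = 79))  # 3
#' @export
select_components <- function(bic_by_k, delta = 10) {
  ks <- sort(as.integer(names(bic_by_k)))
  stopifnot(all(is.finite(bic_by_k)))
  chosen <- ks[1]
  for (k in ks[-1]) {
    if (bic_by_k[[as.character(k)]] <= bic_by_k[[as.character(chosen)]] - delta) {
      chosen <- k
    }
  }
  chosen
}

#' @export
print.mass_error_gmm <- function(x, ...) {
  cat("Mass-error Gaussian mixture (", x$n, " PSMs)\n", sep = "")
  cat("Selected k = ", x$selected_k, " (BIC: ",
      paste(sprintf("k=%s %.1f", names(x$bic_by_k), x$bic_by_k),
            collapse = ", "), ")\n", sep = "")
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  comp %d: weight %.3f, mean %+.5f Da, sd %.5f Da\n",
                i, comp$weight[i], comp$mean[i], comp$sd[i]))
  }
  invisible(x)
}

#' @method summary mass_error_gmm
#' @export
summary.mass_error_gmm <- function(object, ...) {
  structure(list(
    components = object$components,
    selected_k = object$selected_k,
    bic_by_k = object$bic_by_k,
    log_likelihood = object$log_likelihood,
    n = object$n,
    converged = object$converged
  ), class = "summary.mass_error_gmm")
}

#' @export
print.summary.mass_error_gmm <- function(x, ...) {
  cat("Gaussian mixture over calibrated precursor mass error\n")
  cat("n =", x$n, " selected k =", x$selected_k,
      " logLik =", format(x$log_likelihood, digits = 6),
      if (!x$converged) " (EM hit iteration cap)" else "", "\n")
  print(x$components, digits = 4)
  invisible(x)
}

#' @method coef mass_error_gmm
#' @export
coef.mass_error_gmm <- function(object, ...) {
  object$components
}

#' @method logLik mass_error_gmm
#' @export
logLik.mass_error_gmm <- function(object, ...) {
  structure(object$log_likelihood,
            df = 3 * object$selected_k - 1, nobs = object$n,
            class = "logLik")
}

#' Mixture density of a fitted mass-error model
#'
#' @param object A `mass_error_gmm` fit.
#' @param newdata Mass-error values (Da) at which to evaluate the density;
#'   defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of density values.
#' @export
predict.mass_error_gmm <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$errors
  comp <- object$components
  d <- numeric(length(x))
  for (i in seq_len(nrow(comp))) {
    d <- d + comp$weight[i] * stats::dnorm(x, comp$mean[i], comp$sd[i])
  }
  d
}

#' @export
simulate.mass_error_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    comp <- object$components
    j <- sample.int(nrow(comp), object$n, replace = TRUE, prob = comp$weight)
    stats::rnorm(object$n, comp$mean[j], comp$sd[j])
  }
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  as.data.frame(stats::setNames(sims, paste0("sim_", seq_len(nsim))))
}

#' Plot a fitted mass-error mixture over its histogram
#'
#' @param x A `mass_error_gmm` fit.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments to [graphics::hist()].
#' @method plot mass_error_gmm
#' @export
plot.mass_error_gmm <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$errors, breaks = breaks, freq = FALSE,
                      xlab = "calibrated mass error (Da)",
                      main = "Peptidoform mass-error mixture", ...)
  grid_x <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  graphics::lines(grid_x, predict(x, grid_x), lwd = 2)
  invisible(x)
}
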