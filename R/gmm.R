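#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Fits a `k`-component normal mixture to a vector of log10 expression values
#' by expectation-maximisation. With `k = 2` this is the deconvolution used to
#' separate receptor-negative from receptor-positive tumour populations; the
#' positivity threshold is then the density intersection between the two
#' components (see [gaussian_intersection()]).
#'
#' Initialisation splits the data at the median (for `k = 2`) or at the
#' `k`-quantiles and assigns hard responsibilities, which makes the default fit
#' deterministic. Optional random restarts (`n_restarts > 1`) perturb the
#' initial split using `seed`; the restart with the highest log-likelihood
#' wins. The log-likelihood is checked to be non-decreasing at every EM step.
#' A variance floor of `var_floor` prevents component collapse onto a single
#' point; if it is ever hit the fit is flagged via `vfloor_hit`.
#'
#' @param values Numeric vector of (typically log10-transformed) values.
#'   At least 10 finite values with positive variance are required.
#' @param k Number of components, 1 or 2.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed used only for random restarts beyond the first
#'   deterministic one.
#' @param n_restarts Number of EM starts; the first is the deterministic
#'   quantile split.
#' @param var_floor Lower bound on component variances.
#'
#' @return An object of class `gmm_fit`: a list with `weight`, `mean`, `sd`
#'   (each length `k`, components sorted by mean), `loglik`, `n_iter`,
#'   `converged`, `vfloor_hit` and `n`.
#'
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0, 0.4), rnorm(700, 2.5, 0.5))
#' fit <- fit_gmm1d(x)
#' tidy(fit)
#' gaussian_intersection(fit)
#' @seealso [gaussian_intersection()], [receptor_thresholds()]
#' @export
fit_gmm1d <- function(values, k = 2, tol = 1e-8, max_iter = 500, seed = NULL,
                      n_restarts = 1, var_floor = 1e-6) {
  x <- values[is.finite(values)]
  if (length(x) < 10) {
    stop("fit_gmm1d() needs at least 10 finite values, got ", length(x))
  }
  if (stats::var(x) <= 0) {
    stop("fit_gmm1d(): input is constant; a mixture cannot be identified")
  }
  stopifnot(k %in% c(1L, 2L), n_restarts >= 1)

  if (k == 1L) {
    mu <- mean(x)
    sdev <- stats::sd(x)
    ll <- sum(stats::dnorm(x, mu, sdev, log = TRUE))
    return(new_gmm_fit(1, mu, sdev, ll, 0L, TRUE, FALSE, length(x)))
  }

  starts <- list(x <= stats::median(x))
  if (n_restarts > 1) {
    extra <- withr::with_seed(seed %||% 1L, {
      purrr::map(seq_len(n_restarts - 1L), function(i) {
        cut <- stats::runif(1, 0.25, 0.75)
        x <= stats::quantile(x, cut)
      })
    })
    starts <- c(starts, extra)
  }

  fits <- purrr::map(starts, function(below) {
    em_gmm2(x, below, tol = tol, max_iter = max_iter, var_floor = var_floor)
  })
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  ord <- order(best$mean)
  new_gmm_fit(best$weight[ord], best$mean[ord], best$sd[ord],
              best$loglik, best$n_iter, best$converged, best$vfloor_hit,
              length(x))
}

# One EM run for k = 2 from hard initial responsibilities.
em_gmm2 <- function(x, below, tol, max_iter, var_floor) {
  n <- length(x)
  # degenerate split (all on one side) -> nudge one observation across
  if (all(below) || !any(below)) below[which.min(x)] <- TRUE
  r1 <- as.numeric(below)
  w <- c(mean(r1), 1 - mean(r1))
  mu <- c(stats::weighted.mean(x, r1), stats::weighted.mean(x, 1 - r1))
  s2 <- c(
    max(stats::weighted.mean((x - mu[1])^2, r1), var_floor),
    max(stats::weighted.mean((x - mu[2])^2, 1 - r1), var_floor)
  )
  vfloor_hit <- FALSE
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step in log space for stability
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(s2[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(s2[2]), log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(lse)
    if (ll < ll_old - 1e-8) {
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    }
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    g1 <- exp(l1 - lse)
    # M step
    n1 <- sum(g1)
    n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) {
      vfloor_hit <- TRUE
      break
    }
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    s2_new <- c(sum(g1 * (x - mu[1])^2) / n1, sum((1 - g1) * (x - mu[2])^2) / n2)
    if (any(s2_new < var_floor)) vfloor_hit <- TRUE
    s2 <- pmax(s2_new, var_floor)
  }
  list(weight = w, mean = mu, sd = sqrt(s2), loglik = ll_old,
       n_iter = iter, converged = converged, vfloor_hit = vfloor_hit)
}

new_gmm_fit <- function(weight, mean, sd, loglik, n_iter, converged,
                        vfloor_hit, n) {
  structure(
    list(weight = weight, mean = mean, sd = sd, loglik = loglik,
         n_iter = n_iter, converged = converged, vfloor_hit = vfloor_hit,
         n = n),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  k <- length(x$mean)
  cat("<gmm_fit> ", k, " component(s), n = ", x$n,
      ", loglik = ", format(x$loglik, digits = 6),
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a Gaussian mixture fit
#'
#' @param x A `gmm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `mean`, `sd`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$mean),
    weight = x$weight,
    mean = x$mean,
    sd = x$sd
  )
}

#' Glance at a Gaussian mixture fit
#'
#' @param x A `gmm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `n_iter`, `converged`,
#'   `vfloor_hit`, `nobs`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    vfloor_hit = x$vfloor_hit, nobs = x$n
  )
}

#' Positivity threshold from the intersection of two Gaussian components
#'
#' Solves for the point between the two component means where the weighted
#' component densities are equal,
#' `w1 * dnorm(x, mu1, sd1) = w2 * dnorm(x, mu2, sd2)`.
#' Equating log densities gives a quadratic in `x` when the component
#' standard deviations differ and a linear equation when they are equal.
#' The root inside `(mu1, mu2)` is the biologically meaningful boundary
#' between the negative and positive populations; if neither root falls in
#' that interval, the root nearest to it is returned and flagged through the
#' `in_interval` attribute.
#'
#' @param fit A two-component `gmm_fit` (or any list with `weight`, `mean`,
#'   `sd` of length 2).
#' @return A single numeric threshold with attribute `in_interval` (logical).
#' @examples
#' fit <- list(weight = c(0.5, 0.5), mean = c(0, 2), sd = c(1, 1))
#' gaussian_intersection(fit)  # 1 by symmetry
#' @export
gaussian_intersection <- function(fit) {
  stopifnot(length(fit$mean) == 2L)
  mu <- fit$mean
  sdev <- fit$sd
  w <- fit$weight
  if (mu[1] == mu[2]) stop("gaussian_intersection(): component means are equal")
  if (mu[1] > mu[2]) {
    ord <- order(mu)
    mu <- mu[ord]; sdev <- sdev[ord]; w <- w[ord]
  }
  if (isTRUE(all.equal(sdev[1], sdev[2], tolerance = 1e-12))) {
    # equal variances: log-density difference is linear in x
    s2 <- sdev[1]^2
    root <- (mu[1] + mu[2]) / 2 + s2 * log(w[1] / w[2]) / (mu[2] - mu[1])
    roots <- root
  } else {
    # quadratic a x^2 + b x + c = 0 from equating log densities
    a <- 1 / (2 * sdev[2]^2) - 1 / (2 * sdev[1]^2)
    b <- mu[1] / sdev[1]^2 - mu[2] / sdev[2]^2
    cc <- mu[2]^2 / (2 * sdev[2]^2) - mu[1]^2 / (2 * sdev[1]^2) +
      log(w[1] / w[2]) + log(sdev[2] / sdev[1])
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      # densities never cross: fall back to the stationary point of the
      # log-density difference, the closest approach
      roots <- -b / (2 * a)
    } else {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    }
  }
  inside <- roots > mu[1] & roots < mu[2]
  if (any(inside)) {
    thr <- roots[inside][1]
    attr(thr, "in_interval") <- TRUE
  } else {
    dist <- pmax(mu[1] - roots, roots - mu[2], 0)
    thr <- roots[which.min(dist)]
    attr(thr, "in_interval") <- FALSE
    warning("no density intersection between the component means; ",
            "returning nearest root ", format(thr, digits = 4))
  }
  thr
}

#' Plot a fitted mixture over the data histogram
#'
#' @param object A `gmm_fit`.
#' @param values Optional numeric vector of the data that was fitted, drawn as
#'   a density histogram behind the component curves.
#' @param threshold Optional vertical line, e.g. from
#'   [gaussian_intersection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_fit <- function(object, values = NULL, threshold = NULL, ...) {
  rng <- range(object$mean) + c(-4, 4) * max(object$sd)
  grid <- seq(rng[1], rng[2], length.out = 400)
  dens <- purrr::map_dfr(seq_along(object$mean), function(i) {
    tibble::tibble(
      component = factor(i),
      x = grid,
      density = object$weight[i] * stats::dnorm(grid, object$mean[i], object$sd[i])
    )
  })
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density))
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = values),
      mapping = ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 50, fill = "grey85", colour = "grey70"
    )
  }
  p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$component), linewidth = 0.8)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(threshold), linetype = "dashed")
  }
  p + ggplot2::labs(x = "log10 expression", y = "density")
}
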