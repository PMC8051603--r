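#' Kernel-density estimate of a Ks distribution
#'
#' Gaussian-kernel KDE evaluated on a 512-point grid over `[0, ks_ceiling]`,
#' renormalised to unit trapezoid integral over the grid. Values outside
#' `[0, ks_ceiling]` are excluded (and counted); the default ceiling of 2.5
#' keeps the ancient-triplication range of eudicots while discarding
#' saturated estimates.
#'
#' @param ks_values numeric Ks values.
#' @param bandwidth kernel bandwidth, or `"auto"` for Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]).
#' @param ks_ceiling upper Ks bound.
#' @param n_grid grid size.
#' @return list of class `ks_density`: `grid`, `density`, `bandwidth`,
#'   `ks_ceiling`, `n_used`, `n_filtered`.
#' @export
estimate_density <- function(ks_values, bandwidth = "auto", ks_ceiling = 2.5,
                             n_grid = 512L) {
  v <- ks_values[is.finite(ks_values)]
  v <- v[v >= 0 & v <= ks_ceiling]
  n_filtered <- length(ks_values) - length(v)
  if (length(v) < 10)
    stop("estimate_density: need at least 10 usable Ks values, got ", length(v))
  if (n_filtered)
    wgd_log("estimate_density: %d values filtered (non-finite or outside [0, %g])",
            n_filtered, ks_ceiling)
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(v) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, diff(range(v)) / 100, 1e-3)
  d <- stats::density(v, bw = bw, kernel = "gaussian", from = 0, to = ks_ceiling,
                      n = n_grid)
  dens <- d$y
  area <- trapz(d$x, dens)
  if (area > 0) dens <- dens / area
  structure(list(grid = d$x, density = dens, bandwidth = bw,
                 ks_ceiling = ks_ceiling, n_used = length(v),
                 n_filtered = n_filtered),
            class = "ks_density")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

gaussian_mixture_curve <- function(x, w, mu, sigma) {
  out <- numeric(length(x))
  for (i in seq_along(w)) out <- out + w[i] * stats::dnorm(x, mu[i], sigma[i])
  out
}

r_squared <- function(obs, fit) {
  ss_res <- sum((obs - fit)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  1 - ss_res / ss_tot
}

# weighted quantiles of the density curve (inverse CDF by interpolation)
curve_quantiles <- function(curve, probs) {
  cdf <- cumsum(c(0, diff(curve$grid) * (head(curve$density, -1) +
                                           tail(curve$density, -1)) / 2))
  cdf <- cdf / max(cdf)
  stats::approx(cdf, curve$grid, xout = probs, ties = "ordered", rule = 2)$y
}

fit_k_gaussians <- function(curve, k, starts) {
  x <- curve$grid; y <- curve$density
  best <- NULL
  for (st in starts) {
    par0 <- c(log(st$w), st$mu, log(st$sigma))
    res <- tryCatch(minpack.lm::nls.lm(
      par = par0,
      fn = function(p) {
        w <- exp(p[seq_len(k)])
        mu <- p[k + seq_len(k)]
        s <- exp(p[2 * k + seq_len(k)])
        gaussian_mixture_curve(x, w, mu, s) - y
      },
      control = minpack.lm::nls.lm.control(maxiter = 300)), error = function(e) NULL)
    if (is.null(res)) next
    p <- res$par
    w <- exp(p[seq_len(k)]); mu <- p[k + seq_len(k)]; s <- exp(p[2 * k + seq_len(k)])
    if (any(!is.finite(c(w, mu, s)))) next
    if (any(mu < min(x) - diff(range(x)) * 0.05 |
            mu > max(x) + diff(range(x)) * 0.05)) next
    fit <- gaussian_mixture_curve(x, w, mu, s)
    r2 <- r_squared(y, fit)
    if (is.null(best) || r2 > best$r2)
      best <- list(w = w, mu = mu, sigma = s, r2 = r2)
  }
  best
}

#' Fit a Gaussian multi-peak model to a Ks density curve
#'
#' For k = 1..`n_max`, a k-component Gaussian sum is fitted to the KDE curve
#' by nonlinear least squares (Levenberg-Marquardt, seeded multi-start from
#' quantile-spread means plus a start grown from the best (k-1)-fit). The
#' smallest k whose coefficient of determination reaches `r2_min` is
#' returned; if none does, the best fit is returned flagged below threshold.
#'
#' @param curve a [estimate_density()] result.
#' @param n_max maximal component count (1..6).
#' @param r2_min R-squared acceptance threshold (0.95 follows the standard
#'   curve-fitting acceptance rule for Ks peak decomposition).
#' @param n_starts random multi-starts per k.
#' @param seed seed for the multi-start jitter.
#' @return list of class `peak_model`: `components` (data.frame
#'   `weight, mean, sd`, sorted by mean), `r_squared`, `n_components`,
#'   `meets_threshold`, `r2_by_k`.
#' @export
fit_peak_model <- function(curve, n_max = 3L, r2_min = 0.95, n_starts = 5L,
                           seed = 1L) {
  stopifnot(inherits(curve, "ks_density"), n_max >= 1, n_max <= 6)
  with_seed(seed, {
    rng <- range(curve$grid)
    span <- diff(rng)
    best_by_k <- vector("list", n_max)
    for (k in seq_len(n_max)) {
      starts <- list()
      base_mu <- curve_quantiles(curve, (seq_len(k) - 0.5) / k)
      starts[[1]] <- list(w = rep(1 / k, k), mu = base_mu,
                          sigma = rep(span / (4 * k), k))
      for (s in seq_len(max(0L, n_starts - 1L))) {
        starts[[length(starts) + 1L]] <- list(
          w = rep(1 / k, k) * exp(stats::rnorm(k, 0, 0.3)),
          mu = pmin(pmax(base_mu + stats::rnorm(k, 0, span / 10), rng[1]), rng[2]),
          sigma = rep(span / (4 * k), k) * exp(stats::rnorm(k, 0, 0.3)))
      }
      if (k > 1 && !is.null(best_by_k[[k - 1]])) {
        prev <- best_by_k[[k - 1]]
        resid <- curve$density -
          gaussian_mixture_curve(curve$grid, prev$w, prev$mu, prev$sigma)
        peak_at <- curve$grid[which.max(resid)]
        starts[[length(starts) + 1L]] <- list(
          w = c(prev$w, max(max(resid), 1e-3) * span / 10),
          mu = c(prev$mu, peak_at),
          sigma = c(prev$sigma, span / 20))
      }
      best_by_k[[k]] <- fit_k_gaussians(curve, k, starts)
    }
    fitted_k <- which(!vapply(best_by_k, is.null, logical(1)))
    if (!length(fitted_k))
      stop("fit_peak_model: optimizer failed at all starts for every k")
    r2s <- vapply(best_by_k[fitted_k], function(b) b$r2, numeric(1))
    ok <- fitted_k[r2s >= r2_min]
    pick <- if (length(ok)) min(ok) else fitted_k[which.max(r2s)]
    b <- best_by_k[[pick]]
    ord <- order(b$mu)
    structure(list(components = data.frame(weight = b$w[ord], mean = b$mu[ord],
                                           sd = b$sigma[ord]),
                   r_squared = b$r2, n_components = length(ord),
                   meets_threshold = b$r2 >= r2_min,
                   r2_by_k = stats::setNames(r2s, fitted_k)),
              class = "peak_model")
  })
}

#' Write a peak report TSV (`dataset k w_i mu_i sigma_i r_squared`)
#' @param model a `peak_model`.
#' @param dataset dataset label.
#' @param path output path.
#' @export
write_peak_report <- function(model, dataset, path) {
  df <- data.frame(dataset = dataset, k = model$n_components,
                   component = seq_len(model$n_components),
                   w = model$components$weight, mu = model$components$mean,
                   sigma = model$components$sd, r_squared = model$r_squared)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
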