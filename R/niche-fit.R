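#' Prior for the bivariate isotopic niche model
#'
#' Hyperparameters of the conjugate normal-inverse-Wishart prior on the mean
#' vector and covariance of a group's (d13C, d15N) distribution:
#' \eqn{\Sigma \sim IW(\nu_0, \Psi_0)}, \eqn{\mu | \Sigma \sim N(\mu_0,
#' \Sigma/\kappa_0)}. Defaults are deliberately vague: the prior mean carries
#' almost no weight (\eqn{\kappa_0 = 10^{-3}}), the degrees of freedom are
#' the minimum proper value for two dimensions, and the scale is the
#' identity (permil squared).
#'
#' @param mean Prior mean 2-vector (permil); irrelevant under the default
#'   `strength`.
#' @param strength Prior pseudo-sample size \eqn{\kappa_0 > 0}.
#' @param df Prior degrees of freedom \eqn{\nu_0 \ge 3} (dimension + 1).
#' @param scale 2x2 symmetric positive-definite prior scale matrix
#'   \eqn{\Psi_0}.
#' @return An object of class `niche_prior`.
#' @export
niche_prior <- function(mean = c(0, 0), strength = 1e-3, df = 3,
                        scale = diag(2)) {
  stopifnot(length(mean) == 2, is.finite(mean), strength > 0, df >= 3)
  scale <- as.matrix(scale)
  if (!isTRUE(all.equal(scale, t(scale))) || nrow(scale) != 2)
    stop("prior scale must be a symmetric 2x2 matrix")
  ev <- eigen(scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("prior scale must be positive definite")
  structure(list(mean = as.numeric(mean), strength = strength,
                 df = df, scale = scale),
            class = "niche_prior")
}

# relative eigenvalue tolerance for positive semi-definiteness checks
.pd_tol <- 1e-10

#' Standard ellipse area of a bivariate covariance
#'
#' Area of the 1-sigma ("standard") ellipse of a bivariate normal
#' distribution with covariance `sigma`:
#' \eqn{SEA = \pi \sqrt{\lambda_1 \lambda_2} = \pi \sqrt{\det \Sigma}}
#' where \eqn{\lambda} are the eigenvalues (squared semi-axis lengths). This
#' ellipse contains roughly 40% of the probability mass; the convention is
#' fixed and the area is reported in permil squared.
#'
#' @param sigma 2x2 symmetric positive semi-definite covariance (permil^2).
#' @return Ellipse area (permil^2).
#' @examples
#' sea_from_covariance(diag(2))        # pi
#' sea_from_covariance(diag(c(4, 1)))  # 2 * pi
#' @export
sea_from_covariance <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != 2 || ncol(sigma) != 2 ||
      !isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    stop("sigma must be a symmetric 2x2 matrix")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.pd_tol * max(abs(ev), 1))
    stop("sigma has a negative eigenvalue beyond tolerance")
  ev <- pmax(ev, 0)
  pi * sqrt(ev[1] * ev[2])
}

#' Small-sample correction of a standard ellipse area
#'
#' Rescales SEA by \eqn{(n-1)/(n-2)} to counter the downward bias of
#' covariance-based ellipse areas at small sample sizes, giving SEAc. The
#' correction requires at least 3 observations and vanishes as n grows.
#'
#' @param sea Standard ellipse area(s), permil^2.
#' @param n Sample size of the group (>= 3).
#' @return Corrected area(s), permil^2.
#' @examples
#' sea_c_correct(pi, 3)  # 2 * pi
#' @export
sea_c_correct <- function(sea, n) {
  if (length(n) != 1 || !is.finite(n) || n <= 2)
    stop("SEAc correction requires n >= 3")
  sea * (n - 1) / (n - 2)
}

#' Plug-in (non-Bayesian) SEAc point estimate
#'
#' Computes SEAc from the sample covariance (n - 1 denominator) of a group's
#' isotope values. This deterministic companion to [fit_niche()] is what the
#' drawn ellipses in [plot.niche_fit()] use.
#'
#' @param x A two-column matrix or data frame of (d13C, d15N) values, or an
#'   isotope record data frame containing `d13C` and `d15N` columns.
#' @return SEAc in permil^2.
#' @export
sea_c_point_estimate <- function(x) {
  X <- .iso_matrix(x)
  n <- nrow(X)
  if (n < 3) stop("SEAc requires at least 3 observations")
  sea_c_correct(sea_from_covariance(stats::var(X)), n)
}

.iso_matrix <- function(x) {
  if (is.data.frame(x) && all(c("d13C", "d15N") %in% names(x)))
    x <- cbind(x$d13C, x$d15N)
  X <- as.matrix(x)
  if (ncol(X) != 2) stop("expected two columns (d13C, d15N)")
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("isotope values must be finite")
  X
}

# Exact joint draws from the normal-inverse-Wishart posterior of one group.
# Sigma = W^{-1} with W ~ Wishart(nu_n, Psi_n^{-1}); mu | Sigma ~
# N(mu_n, Sigma / kappa_n). 2x2 inversion and Cholesky are done in closed
# form across all draws at once.
.niw_draws <- function(X, prior, n_draws) {
  n <- nrow(X)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))
  k0 <- prior$strength; nu0 <- prior$df
  kn <- k0 + n; nun <- nu0 + n
  mun <- (k0 * prior$mean + n * xbar) / kn
  d <- xbar - prior$mean
  Psin <- prior$scale + S + (k0 * n / kn) * tcrossprod(d)
  W <- stats::rWishart(n_draws, df = nun, Sigma = solve(Psin))
  detW <- W[1, 1, ] * W[2, 2, ] - W[1, 2, ]^2
  s11 <- W[2, 2, ] / detW
  s22 <- W[1, 1, ] / detW
  s12 <- -W[1, 2, ] / detW
  # lower Cholesky of Sigma / kn, vectorized
  l11 <- sqrt(s11 / kn)
  l21 <- (s12 / kn) / l11
  l22 <- sqrt(pmax(s22 / kn - l21^2, 0))
  z1 <- stats::rnorm(n_draws); z2 <- stats::rnorm(n_draws)
  mu <- cbind(mu_C = mun[1] + l11 * z1,
              mu_N = mun[2] + l21 * z1 + l22 * z2)
  sea <- pi / sqrt(detW)  # = pi * sqrt(det Sigma)
  list(mu = mu, sigma = cbind(s11 = s11, s12 = s12, s22 = s22),
       sea = sea, mean = xbar, cov = S / (n - 1), mu_n = mun, Psi_n = Psin)
}

#' Fit the Bayesian niche posterior of a single group
#'
#' Draws exact joint samples of the mean vector and covariance of one
#' group's (d13C, d15N) distribution from the conjugate
#' normal-inverse-Wishart posterior, and derives standard ellipse area (SEA)
#' and its small-sample-corrected version (SEAc) for every draw. Sampling is
#' exact (no MCMC), so no convergence diagnostics are needed.
#'
#' @param x Two-column matrix/data frame of isotope values, or an isotope
#'   record data frame (columns `d13C`, `d15N`).
#' @param label Group label carried through to summaries.
#' @param prior A [niche_prior()].
#' @param n_draws Number of posterior draws (default 10^4, minimum 100).
#' @param seed Optional integer seed; identical seed, data and prior give
#'   bit-identical draws.
#' @return An object of class `niche_posterior`: list with `label`, `n`,
#'   `mu` (n_draws x 2 matrix of mean draws), `sigma` (n_draws x 3 matrix of
#'   covariance components s11, s12, s22), `sea`, `sea_c` (draw vectors,
#'   permil^2), the sample `mean` and `cov`, `singular` flag, `prior` and
#'   `seed`.
#' @export
fit_group_posterior <- function(x, label = "group", prior = niche_prior(),
                                n_draws = 10000, seed = NULL) {
  X <- .iso_matrix(x)
  n <- nrow(X)
  if (n < 3)
    stop("non-estimable group '", label, "': n = ", n,
         " (need >= 3 for SEAc)")
  if (n_draws < 100) stop("n_draws must be at least 100")
  if (!inherits(prior, "niche_prior")) stop("prior must be a niche_prior()")
  if (!is.null(seed)) set.seed(seed)
  S <- crossprod(sweep(X, 2, colMeans(X)))
  evS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  singular <- min(evS) <= .pd_tol * max(evS, 1)  # collinear sample; prior keeps posterior proper
  dr <- .niw_draws(X, prior, n_draws)
  structure(list(label = label, n = n, mu = dr$mu, sigma = dr$sigma,
                 sea = dr$sea, sea_c = dr$sea * (n - 1) / (n - 2),
                 mean = dr$mean, cov = dr$cov, singular = singular,
                 n_draws = n_draws, prior = prior, seed = seed),
            class = "niche_posterior")
}

#' @export
print.niche_posterior <- function(x, ...) {
  qs <- stats::quantile(x$sea_c, c(0.025, 0.5, 0.975))
  cat(sprintf("Niche posterior '%s': n = %d, %d draws\n", x$label, x$n,
              x$n_draws))
  cat(sprintf("  SEAc (permil^2): median %.3f, 95%% CI [%.3f, %.3f]\n",
              qs[2], qs[1], qs[3]))
  if (x$singular) cat("  note: sample is (near-)collinear\n")
  invisible(x)
}

#' Fit Bayesian isotopic niches for all groups in a data set
#'
#' The core fitting function of the package. Splits the records by the
#' grouping columns (default species within area), fits each group's
#' bivariate (d13C, d15N) posterior with [fit_group_posterior()], and drops
#' groups below the minimum sample size with a warning (mirroring the
#' exclusion of species caught too rarely to estimate an ellipse).
#'
#' Group fits consume a single random stream seeded once, in alphabetical
#' group order, so results are reproducible and independent of input row
#' order.
#'
#' @param data Isotope record data frame (see [read_isotope_csv()]).
#' @param by Character vector of grouping columns (default
#'   `c("species", "area")`).
#' @param prior A [niche_prior()].
#' @param n_draws Posterior draws per group (default 10^4).
#' @param seed Integer seed for the posterior sampler.
#' @param min_n Minimum group size (default 3).
#' @return An object of class `niche_fit`: list with `groups` (named list of
#'   `niche_posterior`), `keys` (data frame of grouping values per fitted
#'   group), `dropped` (data frame of skipped groups), plus call metadata.
#' @seealso [summary.niche_fit()], [plot.niche_fit()],
#'   [as.data.frame.niche_fit()], [community_metrics()]
#' @examples
#' sim <- generate_isotope_dataset(niche_scenario("H3"), seed = 1)
#' fit <- fit_niche(sim$data, n_draws = 500, seed = 1)
#' summary(fit)
#' @export
fit_niche <- function(data, by = c("species", "area"), prior = niche_prior(),
                      n_draws = 10000, seed = NULL, min_n = 3) {
  if (!all(by %in% names(data)))
    stop("grouping columns absent from data: ",
         paste(setdiff(by, names(data)), collapse = ", "))
  key <- interaction(data[by], sep = " | ", drop = TRUE)
  labs <- sort(levels(key))
  if (!is.null(seed)) set.seed(seed)
  groups <- list(); keys <- list(); dropped <- list()
  for (lab in labs) {
    rows <- data[key == lab, , drop = FALSE]
    kv <- rows[1, by, drop = FALSE]
    if (nrow(rows) < min_n) {
      dropped[[lab]] <- cbind(kv, n = nrow(rows))
      next
    }
    groups[[lab]] <- fit_group_posterior(rows, label = lab, prior = prior,
                                         n_draws = n_draws, seed = NULL)
    keys[[lab]] <- kv
  }
  if (length(dropped))
    warning("dropped non-estimable group(s) (n < ", min_n, "): ",
            paste(names(dropped), collapse = "; "))
  structure(list(groups = groups,
                 keys = if (length(keys)) do.call(rbind, keys) else NULL,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
                 by = by, n_draws = n_draws, seed = seed, prior = prior,
                 call = match.call()),
            class = "niche_fit")
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("Bayesian isotopic niche fit (normal-inverse-Wishart)\n")
  cat(sprintf("  %d group(s) by %s; %d draws each\n", length(x$groups),
              paste(x$by, collapse = " x "), x$n_draws))
  if (!is.null(x$dropped))
    cat("  dropped:", paste(rownames(x$dropped), collapse = "; "), "\n")
  print(summary(x))
  invisible(x)
}

#' Summarize a niche fit
#'
#' @param object A [fit_niche()] result.
#' @param probs Quantiles of the SEAc posterior to report.
#' @param ... Unused.
#' @return A data frame with one row per group: grouping columns, `n`, the
#'   plug-in `sea_c_ml`, and SEAc posterior quantiles.
#' @export
summary.niche_fit <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                              ...) {
  rows <- lapply(names(object$groups), function(lab) {
    g <- object$groups[[lab]]
    qs <- stats::quantile(g$sea_c, probs)
    ml <- sea_c_correct(sea_from_covariance(g$cov), g$n)
    cbind(object$keys[lab, , drop = FALSE],
          data.frame(n = g$n, sea_c_ml = ml, t(qs), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  names(out) <- c(object$by, "n", "sea_c_ml",
                  paste0("sea_c_q", formatC(100 * probs, format = "fg")))
  rownames(out) <- NULL
  out
}

#' Posterior mean vectors per group
#'
#' @param object A [fit_niche()] result.
#' @param ... Unused.
#' @return Matrix with one row per group, columns `mu_C`, `mu_N` (posterior
#'   means of the group mean vector).
#' @export
coef.niche_fit <- function(object, ...) {
  t(vapply(object$groups, function(g) colMeans(g$mu), numeric(2)))
}

#' Export posterior draws in long format
#'
#' @param x A [fit_niche()] result.
#' @param ... Unused.
#' @return Data frame with columns `draw`, `group`, `mu_C`, `mu_N`, `s11`,
#'   `s12`, `s22`, `sea`, `sea_c` — the CSV exchange layout for draw sets.
#' @export
as.data.frame.niche_fit <- function(x, ...) {
  out <- lapply(names(x$groups), function(lab) {
    g <- x$groups[[lab]]
    data.frame(draw = seq_len(g$n_draws), group = lab,
               mu_C = g$mu[, 1], mu_N = g$mu[, 2],
               s11 = g$sigma[, 1], s12 = g$sigma[, 2], s22 = g$sigma[, 3],
               sea = g$sea, sea_c = g$sea_c)
  })
  do.call(rbind, out)
}

# parametric 1-sigma ellipse outline for plotting
.ellipse_path <- function(mu, sigma, k = 1, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  L <- chol((sigma + t(sigma)) / 2)
  t(mu + t(k * cbind(cos(th), sin(th)) %*% L))
}

#' Isotope biplot with point-estimate standard ellipses
#'
#' Plots the raw (d13C, d15N) observations colored by group and overlays
#' each fitted group's sample-covariance 1-sigma ellipse.
#'
#' @param x A [fit_niche()] result.
#' @param data Optional isotope record data frame to show as points.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.niche_fit <- function(x, data = NULL, ...) {
  cols <- grDevices::hcl.colors(max(length(x$groups), 3), "Dark 3")
  paths <- lapply(names(x$groups), function(lab) {
    g <- x$groups[[lab]]
    .ellipse_path(g$mean, g$cov)
  })
  rng <- apply(do.call(rbind, paths), 2, range)
  if (!is.null(data)) {
    rng[, 1] <- range(rng[, 1], data$d13C)
    rng[, 2] <- range(rng[, 2], data$d15N)
  }
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2],
                 xlab = expression(delta^13 * C ~ "(‰)"),
                 ylab = expression(delta^15 * N ~ "(‰)"), ...)
  for (i in seq_along(paths))
    graphics::lines(paths[[i]], col = cols[i], lwd = 2)
  if (!is.null(data)) {
    key <- interaction(data[x$by], sep = " | ", drop = TRUE)
    idx <- match(as.character(key), names(x$groups))
    graphics::points(data$d13C, data$d15N, col = cols[idx], pch = 16,
                     cex = 0.7)
  }
  graphics::legend("topleft", legend = names(x$groups),
                   col = cols[seq_along(x$groups)], lwd = 2, cex = 0.7,
                   bty = "n")
  invisible(x)
}
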