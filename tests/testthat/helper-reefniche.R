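# shared fixtures and independent oracles, all built in code

# independent hull-area oracle: fan triangulation from the centroid of the
# hull vertices (interior for a convex polygon)
fan_hull_area <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  v <- pts[h, , drop = FALSE]
  ctr <- colMeans(v)
  s <- 0
  for (i in seq_len(nrow(v))) {
    a <- v[i, ] - ctr
    b <- v[if (i == nrow(v)) 1 else i + 1, ] - ctr
    s <- s + abs(a[1] * b[2] - a[2] * b[1]) / 2
  }
  s
}

# bivariate normal draws without external dependencies
rmvn2 <- function(n, mu, sigma) {
  L <- chol(sigma)
  sweep(matrix(rnorm(2 * n), n, 2) %*% L, 2, mu, `+`)
}

# brute-force variance-ratio grid oracle for the random-intercept ML fit
grid_ri_loglik <- function(y, X, g, lambdas) {
  n <- length(y)
  vapply(lambdas, function(lam) {
    idx <- split(seq_len(n), g)
    Vi <- matrix(0, n, n)
    for (i in idx) {
      ng <- length(i)
      Vi[i, i] <- diag(ng) - lam / (1 + lam * ng)
    }
    A <- t(X) %*% Vi %*% X
    b <- t(X) %*% Vi %*% y
    beta <- solve(A, b)
    rss <- drop(t(y) %*% Vi %*% y - t(b) %*% beta)
    s2 <- rss / n
    ldV <- sum(vapply(idx, function(i) log1p(lam * length(i)), numeric(1)))
    -0.5 * (n * log(2 * pi * s2) + ldV + n)
  }, numeric(1))
}

# tiny isotope record data frame with an exact layout
make_iso_df <- function(d13C, d15N, species = "sp", site = "s1",
                        area = "A", status = "fished", length = 30) {
  n <- length(d13C)
  data.frame(fish_id = sprintf("f%02d", seq_len(n)), species = species,
             site = site, area = area,
             status = factor(status, levels = c("fished", "protected"),
                             ordered = TRUE),
             length = length, weight = NA_real_, d13C = d13C, d15N = d15N)
}

# minimal iso_model stub for the averaging layer
stub_model <- function(name, logLik, K, n, est, se = NULL) {
  se <- se %||% rep(0.1, length(est))
  cf <- cbind(Estimate = est, `Std. Error` = se)
  rownames(cf) <- names(est)
  structure(list(name = name, response = "y", terms = names(est),
                 has_random_intercept = FALSE, logLik = logLik, K = K,
                 n = n, coefficients = cf, r2_marginal = NA),
            class = "iso_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scenario used for model-selection power checks: no between-species d15N
# spread, so the interaction effect size is governed by the analytic SE
interaction_scenario <- function(beta_ls) {
  niche_scenario("H3",
                 mu_d15N = c(black = 14.2, canary = 14.2, china = 14.2,
                             copper = 14.2, quillback = 14.2),
                 beta_ls = beta_ls, length_sdlog = 0.2)
}
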