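#' Gaussian linear model fit for the selection layer
#'
#' Exact least-squares fit via [stats::lm()], wrapped so the
#' information-theoretic layer sees a uniform interface: name, Gaussian
#' log-likelihood at the maximum-likelihood variance, parameter count K
#' (coefficients + residual variance), n, and a coefficient table.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param name Model name used in selection tables (default: deparsed
#'   formula).
#' @return An object of class `iso_model`.
#' @seealso [fit_random_intercept()], [selection_table()]
#' @export
fit_linear <- function(formula, data, name = NULL) {
  fm <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fm)))) {
    bad <- names(stats::coef(fm))[is.na(stats::coef(fm))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  ll <- stats::logLik(fm)
  sm <- summary(fm)
  cf <- sm$coefficients[, 1:2, drop = FALSE]
  r2 <- sm$r.squared
  structure(list(name = name %||% deparse(formula),
                 formula = formula, response = all.vars(formula)[1],
                 terms = attr(stats::terms(fm), "term.labels"),
                 has_random_intercept = FALSE,
                 logLik = as.numeric(ll), K = attr(ll, "df"),
                 n = stats::nobs(fm),
                 coefficients = cf, r2_marginal = r2,
                 sigma2 = sum(stats::resid(fm)^2) / stats::nobs(fm),
                 fit = fm),
            class = "iso_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian mixed model with one random intercept
#'
#' Fits `response ~ fixed effects + (1 | group)` by maximizing the profiled
#' (restricted) log-likelihood over the between-group variance ratio
#' \eqn{\lambda = \sigma^2_{group}/\sigma^2_{resid}}. For a single grouping
#' factor the marginal covariance is block diagonal,
#' \eqn{V_g = I + \lambda J}, so the Woodbury identity gives
#' \eqn{V_g^{-1} = I - \frac{\lambda}{1+\lambda n_g} J} and
#' \eqn{\log|V_g| = \log(1+\lambda n_g)}; the fixed effects and residual
#' variance are profiled out in closed form and the remaining 1-D problem in
#' \eqn{\log\lambda} is solved with [stats::optimize()]. The boundary
#' \eqn{\lambda = 0} (no between-group variance) is checked explicitly and
#' flagged; there the fit collapses to [fit_linear()].
#'
#' ML fits are comparable across fixed-effect structures and are what the
#' model-selection layer uses; REML is provided for variance-component
#' reporting. K counts fixed effects plus the two variance components.
#'
#' @param formula Fixed-effects formula (response on the left).
#' @param data Data frame.
#' @param group Name of the grouping column (e.g. `"site"`).
#' @param method `"ML"` (default) or `"REML"`.
#' @param name Model name for selection tables.
#' @return An object of class `iso_model` with additional elements
#'   `lambda`, `sigma2` (residual variance), `sigma2_group`
#'   (between-group variance) and `boundary` flag.
#' @export
fit_random_intercept <- function(formula, data, group, method = c("ML", "REML"),
                                 name = NULL) {
  method <- match.arg(method)
  if (!group %in% names(data)) stop("grouping column not found: ", group)
  mf <- stats::model.frame(formula, data = data)
  if (nrow(mf) != nrow(data))
    stop("missing values in model variables; drop incomplete rows first")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- length(y); p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the parameter count")
  if (qr(X)$rank < p) stop("rank-deficient fixed-effects design")
  prof <- .ri_profile_factory(y, X, g, method)
  # optimize over log-lambda; check the lambda = 0 boundary explicitly
  opt <- stats::optimize(function(th) -prof(exp(th))$ll,
                         interval = c(-14, 14), tol = 1e-10)
  cand <- list(prof(exp(opt$minimum)), prof(0))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "ll"))]]
  if (!is.finite(best$ll))
    stop("random-intercept fit failed to converge; profiled likelihood ",
         "non-finite on bracket [exp(-14), exp(14)]")
  cf <- cbind(Estimate = best$beta, `Std. Error` = best$se)
  rownames(cf) <- colnames(X)
  # marginal R2: fixed-effects variance share
  fitted_fe <- drop(X %*% best$beta)
  r2m <- stats::var(fitted_fe) /
    (stats::var(fitted_fe) + best$sigma2 * (1 + best$lambda))
  structure(list(name = name %||% paste0(deparse(formula), " + (1|", group, ")"),
                 formula = formula, response = all.vars(formula)[1],
                 terms = attr(stats::terms(stats::lm(formula, data)), "term.labels"),
                 has_random_intercept = TRUE, group = group, method = method,
                 logLik = best$ll, K = p + 2, n = n,
                 coefficients = cf, r2_marginal = r2m,
                 lambda = best$lambda, sigma2 = best$sigma2,
                 sigma2_group = best$lambda * best$sigma2,
                 boundary = best$lambda < 1e-8),
            class = "iso_model")
}

# closure evaluating the profiled (RE)ML log-likelihood at a given variance
# ratio lambda; returns beta, SEs and the profiled sigma2 as well
.ri_profile_factory <- function(y, X, g, method) {
  n <- length(y); p <- ncol(X)
  idx <- split(seq_len(n), g)
  ng <- lengths(idx)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  sx <- do.call(rbind, lapply(idx, function(i) colSums(X[i, , drop = FALSE])))
  sy <- vapply(idx, function(i) sum(y[i]), numeric(1))
  function(lambda) {
    cg <- lambda / (1 + lambda * ng)
    A <- XtX - crossprod(sx * sqrt(cg))          # X' V^-1 X
    b <- Xty - colSums(sx * (cg * sy))           # X' V^-1 y
    yVy <- yty - sum(cg * sy^2)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf, lambda = lambda))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- yVy - sum(b * beta)
    ldV <- sum(log1p(lambda * ng))
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + ldV + n)
    } else {
      s2 <- rss / (n - p)
      ldA <- 2 * sum(log(diag(ch)))
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + ldV + ldA + (n - p))
    }
    Ainv <- chol2inv(ch)
    list(ll = ll, lambda = lambda, beta = drop(beta),
         se = sqrt(s2 * diag(Ainv)), sigma2 = s2)
  }
}

#' @export
print.iso_model <- function(x, ...) {
  cat(sprintf("%s fit '%s': logLik = %.3f, K = %d, n = %d\n",
              if (x$has_random_intercept)
                sprintf("Random-intercept (%s)", x$method) else "Linear",
              x$name, x$logLik, x$K, x$n))
  if (x$has_random_intercept) {
    cat(sprintf("  variance components: residual %.4f, %s %.4f%s\n",
                x$sigma2, x$group, x$sigma2_group,
                if (x$boundary) " (boundary)" else ""))
  }
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
logLik.iso_model <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$n, class = "logLik")
}

#' @export
coef.iso_model <- function(object, ...) object$coefficients[, 1]
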