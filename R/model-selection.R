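#' Two-SD predictor standardization
#'
#' Centers a continuous predictor and divides by twice its standard
#' deviation (n - 1 denominator), putting continuous coefficients on the
#' same scale as binary-predictor coefficients so averaged parameter
#' estimates are directly comparable.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardized vector with attributes `center` and `scale`.
#' @examples
#' standardize_2sd(c(0, 2))
#' @export
standardize_2sd <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
  out <- (x - mean(x)) / (2 * s)
  attr(out, "center") <- mean(x)
  attr(out, "scale") <- 2 * s
  out
}

#' Small-sample-corrected Akaike information criterion
#'
#' \deqn{AICc = -2\log L + 2K + \frac{2K(K+1)}{n - K - 1}}
#' where K counts every estimated parameter (fixed effects plus variance
#' components). Requires `n > K + 1`; AICc converges to AIC as n grows.
#'
#' @param logLik Maximized log-likelihood(s).
#' @param K Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value(s).
#' @examples
#' aicc(-77.97, 5, 87)
#' @export
aicc <- function(logLik, K, n) {
  if (any(n <= K + 1)) stop("AICc requires n > K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

.as_fit_frame <- function(fits) {
  if (is.data.frame(fits)) {
    need <- c("name", "logLik", "K", "n")
    if (!all(need %in% names(fits)))
      stop("fit table needs columns: ", paste(need, collapse = ", "))
    fits$terms <- fits$terms %||% NA
    return(fits)
  }
  if (inherits(fits, "iso_model")) fits <- list(fits)
  data.frame(name = vapply(fits, `[[`, character(1), "name"),
             logLik = vapply(fits, `[[`, numeric(1), "logLik"),
             K = vapply(fits, `[[`, numeric(1), "K"),
             n = vapply(fits, `[[`, numeric(1), "n"))
}

#' AICc model-selection table
#'
#' Ranks candidate models by AICc. \eqn{\Delta AICc_i = AICc_i - \min AICc};
#' Akaike weights \eqn{W_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}.
#' Models with \eqn{\Delta \le 2} are flagged well-supported and models with
#' \eqn{\Delta < 4} form the averaging set. Candidates must share the same
#' response data (equal n); externally produced (name, logLik, K, n) rows
#' are accepted so fits from other engines can enter the table.
#'
#' @param fits List of [fit_linear()]/[fit_random_intercept()] objects, or a
#'   data frame with columns `name`, `logLik`, `K`, `n`.
#' @param delta_support Well-supported cutoff (default 2).
#' @param delta_average Averaging-set cutoff (default 4).
#' @return A data frame of class `selection_table`, sorted by AICc, with
#'   columns `name`, `K`, `logLik`, `AICc`, `delta`, `weight`,
#'   `well_supported`, `averaging_set`, and attribute `fits` retaining the
#'   input models (when given as objects).
#' @examples
#' selection_table(data.frame(
#'   name = c("interaction", "additive"),
#'   logLik = c(-77.97, -80.19), K = c(5, 4), n = 87))
#' @export
selection_table <- function(fits, delta_support = 2, delta_average = 4) {
  tab <- .as_fit_frame(fits)
  if (length(unique(tab$n)) != 1)
    stop("models fitted to different n are not comparable")
  tab$AICc <- aicc(tab$logLik, tab$K, tab$n)
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$well_supported <- tab$delta <= delta_support
  tab$averaging_set <- tab$delta < delta_average
  tab <- tab[order(tab$delta), ]
  rownames(tab) <- NULL
  out <- tab[, c("name", "K", "logLik", "AICc", "delta", "weight",
                 "well_supported", "averaging_set")]
  attr(out, "fits") <- if (!is.data.frame(fits)) fits else NULL
  attr(out, "n") <- tab$n[1]
  class(out) <- c("selection_table", "data.frame")
  out
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  cat(sprintf("Model selection (AICc, n = %d)\n", attr(x, "n")))
  show <- data.frame(Model = x$name, K = x$K,
                     `Log(L)` = round(x$logLik, 2),
                     AICc = round(x$AICc, 1),
                     dAICc = round(x$delta, 2),
                     Wi = round(x$weight, digits),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Model-averaged estimates, unconditional variance and RVI
#'
#' Natural-average (conditional) model averaging over the averaging set
#' (\eqn{\Delta AICc <} `delta_average`): each predictor's estimate is the
#' weight-renormalized average over the models containing it, with
#' unconditional standard error in Buckland form
#' \eqn{se_u = \sum_i w_i \sqrt{var_i + (\hat\theta_i - \bar\theta)^2}}.
#' Relative variable importance (RVI) is the sum of Akaike weights, over the
#' full candidate set, of the models in which the predictor appears.
#'
#' @param fits List of fitted `iso_model` objects (the full candidate set).
#' @param table Optional [selection_table()] for `fits`; computed if
#'   missing.
#' @param delta_average Averaging-set cutoff (default 4).
#' @return Data frame per coefficient: `term`, `estimate`,
#'   `se_unconditional`, `rvi`, `n_models`.
#' @export
model_average <- function(fits, table = NULL, delta_average = 4) {
  if (inherits(fits, "iso_model")) fits <- list(fits)
  if (is.null(table)) table <- selection_table(fits,
                                               delta_average = delta_average)
  nm <- vapply(fits, `[[`, character(1), "name")
  w_full <- table$weight[match(nm, table$name)]
  in_avg <- table$averaging_set[match(nm, table$name)]
  if (!any(in_avg)) stop("averaging set is empty")
  terms_all <- unique(unlist(lapply(fits, function(f)
    rownames(f$coefficients))))
  rows <- lapply(terms_all, function(tm) {
    has <- vapply(fits, function(f) tm %in% rownames(f$coefficients),
                  logical(1))
    use <- has & in_avg
    if (!any(use)) return(NULL)
    w <- w_full[use] / sum(w_full[use])
    est <- vapply(fits[use], function(f) f$coefficients[tm, 1], numeric(1))
    se <- vapply(fits[use], function(f) f$coefficients[tm, 2], numeric(1))
    avg <- sum(w * est)
    se_u <- sum(w * sqrt(se^2 + (est - avg)^2))
    data.frame(term = tm, estimate = avg, se_unconditional = se_u,
               rvi = sum(w_full[has]), n_models = sum(use))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate model set for delta-15N versus length and protection
#'
#' Builds the standard five-model candidate set explaining individual
#' delta-15N from body length and protection status, each with a site
#' random intercept fitted by ML (so likelihoods are comparable across
#' fixed-effect structures): intercept-only, length, status,
#' length + status, and length + status + their interaction (marginality is
#' respected: interactions always carry their main effects). Length is 2-SD
#' standardized beforehand.
#'
#' @param data Isotope record data frame (columns `d15N`, `length`,
#'   `status`, `site`).
#' @param group Random-intercept grouping column (default `"site"`).
#' @return Named list of `iso_model` fits.
#' @seealso [selection_table()], [model_average()]
#' @export
d15n_model_set <- function(data, group = "site") {
  data$length_s <- standardize_2sd(data$length)
  data$status <- factor(as.character(data$status),
                        levels = c("fished", "protected"))
  forms <- list(
    "Intercept"                      = d15N ~ 1,
    "Length"                         = d15N ~ length_s,
    "Status"                         = d15N ~ status,
    "Length + Status"                = d15N ~ length_s + status,
    "Length + Status + Length*Status" = d15N ~ length_s * status)
  out <- lapply(names(forms), function(nm)
    fit_random_intercept(forms[[nm]], data, group = group, method = "ML",
                         name = nm))
  names(out) <- names(forms)
  out
}
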