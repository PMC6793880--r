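# Layman-style community metrics over (d13C, d15N) points, deterministic
# geometry first, then the posterior-propagating version.

.points2 <- function(points) {
  X <- as.matrix(points)
  if (ncol(X) != 2) stop("expected two columns (d13C, d15N)")
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("points must be finite")
  X
}

#' Convex hull area of isotope points
#'
#' Area of the convex hull of a set of (d13C, d15N) points — the community
#' total area (TA) metric. Hull vertices come from [grDevices::chull()]; the
#' area is the shoelace sum over those vertices. Collinear point sets have
#' zero area.
#'
#' @param points Two-column matrix or data frame of points (permil).
#' @return Hull area in permil^2.
#' @examples
#' convex_hull_area(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
convex_hull_area <- function(points) {
  X <- .points2(points)
  if (nrow(X) < 3) stop("convex hull area requires at least 3 points")
  .hull_area(X)
}

.hull_area <- function(X) {
  h <- grDevices::chull(X[, 1], X[, 2])
  if (length(h) < 3) return(0)
  x <- X[h, 1]; y <- X[h, 2]
  j <- c(seq_along(h)[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Nitrogen and carbon ranges
#'
#' NR is the spread (max - min) of d15N across the community points and
#' reflects vertical (trophic-level) structure; CR is the spread of d13C and
#' indexes the diversity of basal carbon sources. Hull vertices and raw
#' points give identical answers since the extrema are hull vertices.
#'
#' @param points Two-column matrix or data frame, columns (d13C, d15N).
#' @return Range in permil.
#' @export
nitrogen_range <- function(points) {
  X <- .points2(points)
  if (nrow(X) < 2) stop("range metrics require at least 2 points")
  diff(range(X[, 2]))
}

#' @rdname nitrogen_range
#' @export
carbon_range <- function(points) {
  X <- .points2(points)
  if (nrow(X) < 2) stop("range metrics require at least 2 points")
  diff(range(X[, 1]))
}

#' Mean distance to centroid
#'
#' Mean Euclidean distance of each point to the arithmetic centroid of all
#' points — the CD metric, a measure of average trophic diversity and
#' species spacing.
#'
#' @inheritParams nitrogen_range
#' @return Mean centroid distance in permil.
#' @export
centroid_distance <- function(points) {
  X <- .points2(points)
  if (nrow(X) < 2) stop("centroid distance requires at least 2 points")
  ctr <- colMeans(X)
  mean(sqrt((X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2))
}

#' Community niche metric posteriors per area
#'
#' Propagates species-level posterior uncertainty into community-wide
#' metrics. For each posterior draw d, the species mean vectors
#' \eqn{\{\mu_s^{(d)}\}} of one area form a point set over which TA, NR, CR
#' and CD are computed, giving full posterior distributions of the four
#' metrics. TA requires at least 3 species; with fewer, TA is `NA` and the
#' remaining metrics are still computed (the area is flagged).
#'
#' @param fit A [fit_niche()] result whose grouping includes `area_col`.
#' @param area_col Name of the grouping column holding the area label
#'   (default `"area"`).
#' @return An object of class `community_metrics`: named list (one element
#'   per area) of lists with `area`, `species`, `n_draws`, `ta_ok` and
#'   `draws` (n_draws x 4 matrix, columns TA, NR, CR, CD).
#' @seealso [compare_communities()], [community_point_estimates()]
#' @export
community_metrics <- function(fit, area_col = "area") {
  if (!inherits(fit, "niche_fit")) stop("fit must be a niche_fit")
  if (!area_col %in% fit$by)
    stop("fit was not grouped by '", area_col, "'")
  areas <- sort(unique(fit$keys[[area_col]]))
  out <- lapply(areas, function(a) {
    labs <- rownames(fit$keys)[fit$keys[[area_col]] == a]
    gs <- fit$groups[labs]
    nd <- unique(vapply(gs, function(g) g$n_draws, numeric(1)))
    if (length(nd) != 1)
      stop("groups have mismatched n_draws within area ", a)
    S <- length(gs)
    MC <- vapply(gs, function(g) g$mu[, 1], numeric(nd))
    MN <- vapply(gs, function(g) g$mu[, 2], numeric(nd))
    nr <- .row_range(MN)
    cr <- .row_range(MC)
    cbarC <- rowMeans(MC); cbarN <- rowMeans(MN)
    cd <- rowMeans(sqrt((MC - cbarC)^2 + (MN - cbarN)^2))
    ta_ok <- S >= 3
    ta <- if (ta_ok) {
      vapply(seq_len(nd), function(d) .hull_area(cbind(MC[d, ], MN[d, ])),
             numeric(1))
    } else rep(NA_real_, nd)
    list(area = a, species = labs, n_draws = nd, ta_ok = ta_ok,
         draws = cbind(TA = ta, NR = nr, CR = cr, CD = cd))
  })
  names(out) <- areas
  structure(out, class = "community_metrics")
}

.row_range <- function(M) {
  mx <- M[, 1]; mn <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) {
    mx <- pmax(mx, M[, j]); mn <- pmin(mn, M[, j])
  }
  mx - mn
}

#' @export
print.community_metrics <- function(x, ...) {
  cat("Community niche metric posteriors\n")
  print(summary(x))
  invisible(x)
}

#' Summarize community metric posteriors
#'
#' @param object A [community_metrics()] result.
#' @param probs Posterior quantiles to report (default median and central
#'   50/95% intervals).
#' @param ... Unused.
#' @return Long data frame: area, metric, n_species, and the requested
#'   quantiles.
#' @export
summary.community_metrics <- function(object,
                                      probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                      ...) {
  rows <- lapply(unclass(object), function(cm) {
    qs <- apply(cm$draws, 2, stats::quantile, probs = probs, na.rm = TRUE)
    data.frame(area = cm$area, metric = colnames(cm$draws),
               n_species = length(cm$species), t(qs), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("area", "metric", "n_species",
                  paste0("q", formatC(100 * probs, format = "fg")))
  rownames(out) <- NULL
  out
}

#' Deterministic community metrics from sample means
#'
#' Point-estimate companion to [community_metrics()]: computes TA, NR, CR
#' and CD from the species sample-mean vectors of each area. Optionally CD
#' can instead be computed over individual fish (distance of each fish to
#' the community centroid), a variant reported alongside when it differs
#' appreciably from the species-mean version.
#'
#' @param data Isotope record data frame.
#' @param species_col,area_col Grouping column names.
#' @param cd_variant `"species_mean"` (default) or `"individual"`.
#' @return Data frame with one row per area: n_species, TA, NR, CR, CD.
#' @export
community_point_estimates <- function(data, species_col = "species",
                                      area_col = "area",
                                      cd_variant = c("species_mean",
                                                     "individual")) {
  cd_variant <- match.arg(cd_variant)
  rows <- lapply(split(data, data[[area_col]]), function(rec) {
    mc <- tapply(rec$d13C, rec[[species_col]], mean)
    mn <- tapply(rec$d15N, rec[[species_col]], mean)
    pts <- cbind(mc, mn)
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 3)
      stop("area ", rec[[area_col]][1], ": fewer than 3 species")
    cd <- if (cd_variant == "individual") {
      centroid_distance(cbind(rec$d13C, rec$d15N))
    } else centroid_distance(pts)
    data.frame(area = rec[[area_col]][1], n_species = nrow(pts),
               TA = convex_hull_area(pts), NR = nitrogen_range(pts),
               CR = carbon_range(pts), CD = cd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
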