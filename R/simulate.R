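# Synthetic-data generators. The design emulates a nested field survey:
# three areas (two fished, one protected), three rocky-reef sites per area,
# five rockfish species, roughly 87 fish in total. Every generator returns
# its true parameters in a manifest so parameter-recovery tests never peek
# at the data.

.default_species <- c("black", "canary", "china", "copper", "quillback")
.default_areas <- data.frame(
  area = c("Fished North", "Fished South", "MPA"),
  status = c("fished", "fished", "protected"),
  abbrev = c("FN", "FS", "MPA"))

#' Scenario specification for the isotope generator
#'
#' Encodes one of three hypothesized responses of rockfish community niche
#' width to spatial protection as a parameter pattern:
#' * `H1` — carbon expansion: species d13C means spread `cr_effect` permil
#'   wider in the protected area (diversified basal resources).
#' * `H2` — nitrogen expansion: species d15N means spread `nr_effect`
#'   permil wider in the protected area (expanded trophic-level range).
#' * `H3` — no change: identical parameters in all areas.
#'
#' Each species-by-area cell is bivariate normal in (d13C, d15N) with
#' covariance `sigma`. Individual d15N is generated from a linear model in
#' body length whose slope is `beta_l` in fished areas and
#' `beta_l + beta_ls` under protection, plus a site-level random intercept;
#' d13C is then drawn conditionally so the cell covariance hits `sigma`
#' exactly. Effect sizes for H1/H2 are fixture conventions of this
#' generator, not field estimates.
#'
#' @param hypothesis `"H1"`, `"H2"` or `"H3"`.
#' @param species Species labels.
#' @param mu_d13C,mu_d15N Named base mean vectors (permil), one per species.
#' @param sigma 2x2 within-cell covariance (permil^2).
#' @param n_per_area Named fish counts per species within each area (split
#'   as evenly as possible across sites).
#' @param sites_per_area Number of sites per area (default 3).
#' @param length_meanlog,length_sdlog Lognormal body-length parameters (cm).
#' @param beta_l d15N slope on length in fished areas (permil per cm).
#' @param beta_ls Additional slope under protection.
#' @param site_sd SD of site-level d15N intercepts (permil).
#' @param nr_effect,cr_effect Widening of the species-mean d15N / d13C range
#'   in the protected area under H2 / H1 (permil).
#' @param lw_a,lw_b Length-weight power-law coefficients (W = a L^b, g).
#' @return An object of class `niche_scenario`.
#' @export
niche_scenario <- function(hypothesis = c("H3", "H1", "H2"),
                           species = .default_species,
                           mu_d13C = c(black = -18.5, canary = -17.5,
                                       china = -16.5, copper = -16.0,
                                       quillback = -17.0),
                           mu_d15N = c(black = 13.0, canary = 13.8,
                                       china = 14.8, copper = 14.2,
                                       quillback = 15.0),
                           sigma = matrix(c(0.25, 0.075, 0.075, 0.25), 2),
                           n_per_area = c(black = 6, canary = 5, china = 6,
                                          copper = 6, quillback = 6),
                           sites_per_area = 3,
                           length_meanlog = log(30), length_sdlog = 0.25,
                           beta_l = 0.02, beta_ls = 0.03, site_sd = 0.15,
                           nr_effect = 2, cr_effect = 2,
                           lw_a = 0.0105, lw_b = 3.05) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(length(mu_d13C) == length(species),
            length(mu_d15N) == length(species),
            length(n_per_area) == length(species),
            all(n_per_area >= 0), site_sd >= 0, length_sdlog > 0)
  sigma <- as.matrix(sigma)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma must be positive definite")
  structure(list(hypothesis = hypothesis, species = species,
                 mu_d13C = mu_d13C, mu_d15N = mu_d15N, sigma = sigma,
                 n_per_area = n_per_area, sites_per_area = sites_per_area,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 beta_l = beta_l, beta_ls = beta_ls, site_sd = site_sd,
                 nr_effect = nr_effect, cr_effect = cr_effect,
                 lw_a = lw_a, lw_b = lw_b),
            class = "niche_scenario")
}

# widen a mean vector's range about its midpoint by `effect` permil
.widen <- function(mu, effect) {
  r <- diff(range(mu))
  if (r == 0 || effect == 0) return(mu)
  mid <- mean(range(mu))
  mid + (mu - mid) * (r + effect) / r
}

# species-by-area target means implied by a scenario
.scenario_means <- function(spec) {
  areas <- .default_areas
  mc <- sapply(areas$area, function(a) spec$mu_d13C)
  mn <- sapply(areas$area, function(a) spec$mu_d15N)
  prot <- areas$area[areas$status == "protected"]
  if (spec$hypothesis == "H1") mc[, prot] <- .widen(mc[, prot], spec$cr_effect)
  if (spec$hypothesis == "H2") mn[, prot] <- .widen(mn[, prot], spec$nr_effect)
  list(mu_C = mc, mu_N = mn, areas = areas)
}

#' Generate a synthetic per-fish isotope data set
#'
#' Draws body lengths, then d15N from the length model (site intercept plus
#' residual noise, with the residual variance chosen so each cell's marginal
#' d15N variance equals the scenario covariance), then d13C conditionally on
#' d15N so the full cell covariance matches the target exactly. Weights
#' follow the scenario's length-weight power law with small lognormal
#' scatter. Deterministic under `seed`.
#'
#' @param spec A [niche_scenario()].
#' @param seed Integer seed.
#' @return List with `data` (isotope record data frame, see
#'   [read_isotope_csv()]) and `truth` (the parameter manifest: target
#'   means, covariance, slopes, realized site offsets, residual SDs, and
#'   expected species-mean community metrics per area).
#' @examples
#' sim <- generate_isotope_dataset(niche_scenario("H2"), seed = 1)
#' table(sim$data$species, sim$data$area)
#' @export
generate_isotope_dataset <- function(spec, seed = NULL) {
  if (!inherits(spec, "niche_scenario")) stop("spec must be a niche_scenario")
  if (!is.null(seed)) set.seed(seed)
  mm <- .scenario_means(spec)
  areas <- mm$areas
  S <- spec$sigma
  varL <- (exp(spec$length_sdlog^2) - 1) *
    exp(2 * spec$length_meanlog + spec$length_sdlog^2)
  meanL <- exp(spec$length_meanlog + spec$length_sdlog^2 / 2)
  rows <- list()
  site_off <- list()
  for (ai in seq_len(nrow(areas))) {
    a <- areas$area[ai]
    protected <- areas$status[ai] == "protected"
    b <- spec$beta_l + if (protected) spec$beta_ls else 0
    s2_eps <- S[2, 2] - b^2 * varL - spec$site_sd^2
    if (s2_eps <= 0)
      stop("infeasible covariance: length slope and site variance exceed ",
           "the target d15N variance in area ", a)
    sites <- paste0(areas$abbrev[ai], seq_len(spec$sites_per_area))
    u <- stats::rnorm(length(sites), 0, spec$site_sd)
    names(u) <- sites
    site_off[[a]] <- u
    for (si in seq_along(spec$species)) {
      sp <- spec$species[si]
      n <- spec$n_per_area[[sp]]
      if (n == 0) next
      per_site <- diff(round(seq(0, n, length.out = length(sites) + 1)))
      for (k in seq_along(sites)) {
        nk <- per_site[k]
        if (nk == 0) next
        L <- stats::rlnorm(nk, spec$length_meanlog, spec$length_sdlog)
        d15N <- mm$mu_N[si, a] + b * (L - meanL) + u[k] +
          stats::rnorm(nk, 0, sqrt(s2_eps))
        devN <- d15N - mm$mu_N[si, a]
        d13C <- mm$mu_C[si, a] + (S[1, 2] / S[2, 2]) * devN +
          stats::rnorm(nk, 0, sqrt(S[1, 1] - S[1, 2]^2 / S[2, 2]))
        W <- spec$lw_a * L^spec$lw_b * exp(stats::rnorm(nk, 0, 0.05))
        rows[[length(rows) + 1]] <- data.frame(
          fish_id = sprintf("%s_%s_%s_%02d", areas$abbrev[ai], sites[k],
                            sp, seq_len(nk)),
          species = sp, site = sites[k], area = a,
          status = areas$status[ai],
          length = L, weight = W, d13C = d13C, d15N = d15N)
      }
    }
  }
  data <- do.call(rbind, rows)
  data$status <- factor(data$status, levels = c("fished", "protected"),
                        ordered = TRUE)
  rownames(data) <- NULL
  expected <- lapply(areas$area, function(a) {
    pts <- cbind(mm$mu_C[, a], mm$mu_N[, a])
    list(TA = convex_hull_area(pts), NR = nitrogen_range(pts),
         CR = carbon_range(pts), CD = centroid_distance(pts))
  })
  names(expected) <- areas$area
  truth <- list(hypothesis = spec$hypothesis, mu_C = mm$mu_C,
                mu_N = mm$mu_N, sigma = S,
                beta_l = spec$beta_l, beta_ls = spec$beta_ls,
                site_sd = spec$site_sd, site_offsets = site_off,
                length_meanlog = spec$length_meanlog,
                length_sdlog = spec$length_sdlog,
                mean_length = meanL, var_length = varL,
                lw_a = spec$lw_a, lw_b = spec$lw_b,
                expected_community = expected, seed = seed)
  list(data = data, truth = truth)
}

#' Generate synthetic stomach-content records
#'
#' Draws, for each group, a configurable number of non-empty stomachs; prey
#' counts are multinomial over the group's taxon profile (1 + Poisson total
#' prey per stomach) and per-taxon masses are gamma distributed. Groups with
#' richer configured profiles yield higher expected observed richness.
#'
#' @param profiles Named list (one element per group, e.g. per area) of data
#'   frames with columns `taxon`, `weight` (relative abundance) and
#'   `mass_mean` (mean individual prey mass, g). `NULL` uses a default in
#'   which the protected area's prey pool is richer (12 taxa) than the
#'   fished areas' (7).
#' @param stomachs Named integer vector of non-empty stomachs per group;
#'   default 22 in the MPA, 20 in each fished area (62 total).
#' @param mean_prey Mean additional prey items per stomach beyond the first.
#' @param seed Integer seed.
#' @return List with `data` (diet record data frame) and `truth` (profiles
#'   and sizes).
#' @export
generate_diet_dataset <- function(profiles = NULL, stomachs = NULL,
                                  mean_prey = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profiles)) {
    mk <- function(k) data.frame(
      taxon = sprintf("taxon_%02d", seq_len(k)),
      weight = 1 / seq_len(k),
      mass_mean = 0.2 + 2 / seq_len(k))
    profiles <- list(`Fished North` = mk(7), `Fished South` = mk(7),
                     MPA = mk(12))
  }
  if (is.null(stomachs))
    stomachs <- stats::setNames(c(20, 20, 22)[seq_along(profiles)],
                                names(profiles))
  rows <- list()
  for (g in names(profiles)) {
    pr <- profiles[[g]]
    if (!nrow(pr)) stop("empty prey profile for group ", g)
    w <- pr$weight / sum(pr$weight)
    n_st <- stomachs[[g]]
    for (s in seq_len(n_st)) {
      tot <- 1 + stats::rpois(1, mean_prey)
      cnt <- drop(stats::rmultinom(1, tot, w))
      hit <- which(cnt > 0)
      mass <- vapply(hit, function(i)
        sum(stats::rgamma(cnt[i], shape = 2, scale = pr$mass_mean[i] / 2)),
        numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        predator_id = sprintf("%s_st%02d", gsub(" ", "", g), s),
        predator_species = sample(.default_species, 1),
        area = g, prey_taxon = pr$taxon[hit],
        prey_count = cnt[hit], prey_mass = mass)
    }
  }
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(predator_id = character(), predator_species = character(),
               area = character(), prey_taxon = character(),
               prey_count = numeric(), prey_mass = numeric())
  rownames(data) <- NULL
  list(data = data,
       truth = list(profiles = profiles, stomachs = stomachs,
                    mean_prey = mean_prey, seed = seed))
}

#' Generate synthetic belt-transect survey records
#'
#' Poisson counts per transect with a log-linear rate in ordinal habitat,
#' kelp and depth codes; estimated lengths are lognormal. Four transects per
#' site (two per depth stratum).
#'
#' @param sites Site labels.
#' @param species Species labels.
#' @param b0 Baseline log rate per transect.
#' @param b_hab,b_kelp,b_depth Log-linear coefficients on the benthic
#'   habitat code (1-6), kelp code (0-2) and deep stratum indicator.
#' @param length_meanlog,length_sdlog Lognormal length parameters (cm).
#' @param seed Integer seed.
#' @return List with `data` (survey record data frame) and `truth`.
#' @export
generate_survey_dataset <- function(sites = paste0("S", 1:9),
                                    species = .default_species,
                                    b0 = 0.5, b_hab = 0.15, b_kelp = 0.2,
                                    b_depth = -0.1,
                                    length_meanlog = log(28),
                                    length_sdlog = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (s in sites) {
    for (tr in 1:4) {
      depth <- if (tr <= 2) "shallow" else "deep"
      hab <- sample(1:6, 1)
      kelp <- sample(0:2, 1)
      lam <- exp(b0 + b_hab * hab + b_kelp * kelp +
                   b_depth * (depth == "deep"))
      for (sp in species) {
        cnt <- stats::rpois(1, lam)
        rows[[length(rows) + 1]] <- data.frame(
          site = s, transect_id = sprintf("%s_T%d", s, tr),
          depth_stratum = depth, benthic_habitat = hab, kelp = kelp,
          species = sp, count = cnt,
          length = if (cnt > 0)
            mean(stats::rlnorm(cnt, length_meanlog, length_sdlog)) else NA_real_)
      }
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(b0 = b0, b_hab = b_hab, b_kelp = b_kelp,
                    b_depth = b_depth, length_meanlog = length_meanlog,
                    length_sdlog = length_sdlog, seed = seed))
}

#' Biomass from a length-weight power law
#'
#' Species-specific length-weight regression \eqn{W = a L^b} converting
#' estimated lengths (cm) to wet weight (g) for survey biomass summaries.
#'
#' @param length Length(s) in cm.
#' @param a,b Power-law coefficients.
#' @return Weight(s) in g.
#' @examples
#' biomass_lw(10, a = 0.01, b = 3)  # 10 g
#' @export
biomass_lw <- function(length, a, b) {
  if (any(length < 0, na.rm = TRUE)) stop("length must be non-negative")
  a * length^b
}
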