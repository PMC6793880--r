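test_that("the default scenario reproduces the nested study dimensions", {
  sim <- generate_isotope_dataset(niche_scenario("H3"), seed = 41)
  d <- sim$data
  expect_equal(nrow(d), 87)
  expect_equal(length(unique(d$area)), 3)
  expect_equal(length(unique(d$site)), 9)
  expect_equal(length(unique(d$species)), 5)
  expect_equal(sum(d$status == "protected"), 29)
  expect_true(all(d$length > 0))
  expect_true(all(is.finite(d$d13C) & is.finite(d$d15N)))
  # a fixed seed reproduces the data set exactly
  sim2 <- generate_isotope_dataset(niche_scenario("H3"), seed = 41)
  expect_identical(sim$data, sim2$data)
  expect_identical(sim$truth$site_offsets, sim2$truth$site_offsets)
})

test_that("the truth manifest carries recoverable parameters", {
  spec <- niche_scenario("H2")
  sim <- generate_isotope_dataset(spec, seed = 42)
  tr <- sim$truth
  expect_equal(tr$sigma, spec$sigma)
  expect_equal(tr$beta_ls, spec$beta_ls)
  # H2 widens the protected area's species-mean d15N range by nr_effect
  nr <- vapply(tr$expected_community, `[[`, numeric(1), "NR")
  expect_equal(unname(nr["MPA"] - nr["Fished North"]), spec$nr_effect)
  cr <- vapply(tr$expected_community, `[[`, numeric(1), "CR")
  expect_equal(unname(cr["MPA"] - cr["Fished North"]), 0)
  # H3 leaves every area identical
  tr3 <- generate_isotope_dataset(niche_scenario("H3"), seed = 42)$truth
  expect_equal(tr3$expected_community[["MPA"]],
               tr3$expected_community[["Fished South"]])
})

test_that("cell covariance converges to the scenario covariance", {
  spec <- niche_scenario("H3", n_per_area = c(black = 500, canary = 0,
                                              china = 0, copper = 0,
                                              quillback = 0))
  sim <- generate_isotope_dataset(spec, seed = 43)
  d <- sim$data[sim$data$area == "MPA", ]
  S_hat <- stats::cov(cbind(d$d13C, d$d15N))
  frob <- sqrt(sum((S_hat - spec$sigma)^2)) / sqrt(sum(spec$sigma^2))
  expect_lt(frob, 0.10)
})

test_that("d15N tracks length with a steeper slope under protection", {
  spec <- niche_scenario("H3")
  slopes <- sapply(1:30, function(i) {
    d <- generate_isotope_dataset(spec, seed = 100 + i)$data
    prot <- d[d$status == "protected", ]
    fis <- d[d$status == "fished", ]
    c(coef(lm(d15N ~ length, prot))[2], coef(lm(d15N ~ length, fis))[2])
  })
  # absolute bounds ~3 SEs of the replicate means
  expect_lt(abs(mean(slopes[1, ]) - (spec$beta_l + spec$beta_ls)), 0.02)
  expect_lt(abs(mean(slopes[2, ]) - spec$beta_l), 0.015)
  expect_gt(mean(slopes[1, ] > slopes[2, ]), 0.6)
})

test_that("an infeasible slope/variance combination is a scenario error", {
  spec <- niche_scenario("H3", beta_ls = 0.2)  # slope variance > target
  expect_error(generate_isotope_dataset(spec, seed = 1),
               "infeasible covariance")
})

test_that("H2 widens the empirical nitrogen range of the protected area", {
  spec <- niche_scenario("H2", n_per_area = c(black = 30, canary = 30,
                                              china = 30, copper = 30,
                                              quillback = 30))
  hits <- vapply(1:100, function(i) {
    d <- generate_isotope_dataset(spec, seed = 200 + i)$data
    nr <- vapply(split(d, d$area), function(a) {
      mu <- tapply(a$d15N, a$species, mean)
      diff(range(mu))
    }, numeric(1))
    nr["MPA"] > max(nr[c("Fished North", "Fished South")])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("H3 areas differ only by sampling noise", {
  reps <- vapply(1:60, function(i) {
    d <- generate_isotope_dataset(niche_scenario("H3"), seed = 300 + i)$data
    nr <- vapply(split(d, d$area), function(a)
      diff(range(tapply(a$d15N, a$species, mean))), numeric(1))
    nr["MPA"] - nr["Fished North"]
  }, numeric(1))
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("diet generator respects profiles, richness gradients and edge cases", {
  # a single-taxon profile collapses the IRI table to 100%
  pr <- list(G = data.frame(taxon = "only", weight = 1, mass_mean = 1))
  sim <- generate_diet_dataset(pr, stomachs = c(G = 10), seed = 44)
  expect_equal(iri_table(sim$data, by = NULL)$pct_iri, 100)
  # zero stomachs -> empty collection
  sim0 <- generate_diet_dataset(pr, stomachs = c(G = 0), seed = 44)
  expect_equal(nrow(sim0$data), 0)
  # an empty profile is an error
  expect_error(generate_diet_dataset(
    list(G = data.frame(taxon = character(), weight = numeric(),
                        mass_mean = numeric())), c(G = 2)),
    "empty prey profile")
  # richer prey pools yield higher mean observed richness
  mk <- function(k) data.frame(taxon = sprintf("t%02d", 1:k),
                               weight = 1 / (1:k), mass_mean = 1)
  rich <- vapply(1:200, function(i) {
    s <- generate_diet_dataset(list(poor = mk(10), rich = mk(20)),
                               stomachs = c(poor = 15, rich = 15),
                               seed = 400 + i)
    r <- prey_richness(s$data, by = "area")
    r$richness[r$area == "rich"] - r$richness[r$area == "poor"]
  }, numeric(1))
  expect_gt(mean(rich), 0)
})

test_that("survey generator follows its Poisson rate and power-law biomass", {
  expect_equal(biomass_lw(10, a = 0.01, b = 3), 10)
  expect_error(biomass_lw(-1, 0.01, 3), "non-negative")
  s1 <- generate_survey_dataset(sites = paste0("S", 1:40), b0 = 0.3,
                                b_hab = 0, b_kelp = 0, b_depth = 0,
                                seed = 45)
  s2 <- generate_survey_dataset(sites = paste0("S", 1:40),
                                b0 = 0.3 + log(2), b_hab = 0, b_kelp = 0,
                                b_depth = 0, seed = 46)
  expect_equal(mean(s2$data$count) / mean(s1$data$count), 2,
               tolerance = 0.05)
  expect_true(all(s1$data$count >= 0))
  expect_true(all(s1$data$benthic_habitat %in% 1:6))
  expect_true(all(s1$data$kelp %in% 0:2))
})
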