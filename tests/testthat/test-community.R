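test_that("hull area matches hand geometry and the fan oracle", {
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  # collinear input has zero area
  expect_equal(convex_hull_area(cbind(1:5, 2 * (1:5))), 0)
  expect_error(convex_hull_area(rbind(c(0, 0), c(1, 1))), "3 points")
  set.seed(3)
  for (i in 1:200) {
    pts <- matrix(rnorm(2 * sample(3:20, 1)), ncol = 2)
    expect_equal(convex_hull_area(pts), fan_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("nitrogen and carbon ranges are coordinate spreads", {
  pts <- rbind(c(-18, 12), c(-16, 15), c(-17, 13))
  expect_equal(nitrogen_range(pts), 3)
  expect_equal(carbon_range(pts), 2)
  expect_equal(nitrogen_range(rbind(c(1, 2), c(1, 2))), 0)
  expect_error(nitrogen_range(rbind(c(1, 2))), "2 points")
  # hull vertices and raw points give identical ranges
  set.seed(4)
  P <- matrix(rnorm(40), ncol = 2)
  hull <- P[grDevices::chull(P[, 1], P[, 2]), ]
  expect_equal(nitrogen_range(P), nitrogen_range(hull))
  expect_equal(carbon_range(P), carbon_range(hull))
})

test_that("centroid distance matches closed forms", {
  expect_equal(centroid_distance(rbind(c(0, 0), c(2, 0))), 1)
  # equilateral triangle side s: every vertex sits at the circumradius s/sqrt(3)
  s <- 2.5
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  expect_equal(centroid_distance(tri), s / sqrt(3))
  expect_equal(centroid_distance(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
})

test_that("all metrics are translation invariant; scaling laws hold", {
  set.seed(5)
  P <- matrix(rnorm(16), ncol = 2)
  Q <- sweep(P, 2, c(3.2, -1.7), `+`)
  expect_equal(convex_hull_area(Q), convex_hull_area(P))
  expect_equal(nitrogen_range(Q), nitrogen_range(P))
  expect_equal(carbon_range(Q), carbon_range(P))
  expect_equal(centroid_distance(Q), centroid_distance(P))
  c2 <- 1.9
  expect_equal(convex_hull_area(c2 * P), c2^2 * convex_hull_area(P))
  expect_equal(nitrogen_range(c2 * P), c2 * nitrogen_range(P))
  expect_equal(centroid_distance(c2 * P), c2 * centroid_distance(P))
})

test_that("community posteriors concentrate on true-mean geometry at large n", {
  set.seed(6)
  mus <- list(A = c(0, 0), B = c(2, 0), C = c(0, 2))
  rows <- lapply(names(mus), function(sp) {
    X <- rmvn2(200, mus[[sp]], 0.25 * diag(2))
    make_iso_df(X[, 1], X[, 2], species = sp, area = "X")
  })
  fit <- fit_niche(do.call(rbind, rows), n_draws = 1500, seed = 2)
  cm <- community_metrics(fit)
  med <- apply(cm$X$draws, 2, median)
  expect_equal(unname(med["TA"]), 2, tolerance = 0.1)
  expect_equal(unname(med["NR"]), 2, tolerance = 0.1)
  expect_equal(unname(med["CR"]), 2, tolerance = 0.1)
  # hull always fits inside its bounding box, on every draw
  expect_true(all(cm$X$draws[, "TA"] <=
                    cm$X$draws[, "NR"] * cm$X$draws[, "CR"] + 1e-12))
  # CD never exceeds the max pairwise distance of the means involved
  expect_true(all(cm$X$draws[, "CD"] <=
                    sqrt(cm$X$draws[, "NR"]^2 + cm$X$draws[, "CR"]^2)))
})

test_that("a degenerate community has near-zero metrics", {
  set.seed(7)
  rows <- lapply(c("A", "B", "C"), function(sp) {
    X <- rmvn2(150, c(-16, 14), 1e-4 * diag(2))
    make_iso_df(X[, 1], X[, 2], species = sp, area = "X")
  })
  fit <- fit_niche(do.call(rbind, rows), n_draws = 800, seed = 3)
  cm <- community_metrics(fit)
  expect_true(all(apply(cm$X$draws, 2, median) < 0.05))
})

test_that("metric draws do not depend on input row order", {
  sim <- generate_isotope_dataset(niche_scenario("H3"), seed = 9)
  fit1 <- fit_niche(sim$data, n_draws = 500, seed = 4)
  set.seed(99)
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  fit2 <- fit_niche(shuffled, n_draws = 500, seed = 4)
  expect_equal(summary(community_metrics(fit1)),
               summary(community_metrics(fit2)))
})

test_that("fewer than 3 species leaves TA unavailable but keeps ranges", {
  set.seed(8)
  rows <- lapply(c("A", "B"), function(sp) {
    X <- rmvn2(10, c(as.numeric(charToRaw(sp)) / 10, 14), 0.2 * diag(2))
    make_iso_df(X[, 1], X[, 2], species = sp, area = "X")
  })
  fit <- fit_niche(do.call(rbind, rows), n_draws = 400, seed = 5)
  cm <- community_metrics(fit)
  expect_false(cm$X$ta_ok)
  expect_true(all(is.na(cm$X$draws[, "TA"])))
  expect_true(all(is.finite(cm$X$draws[, c("NR", "CR", "CD")])))
})

test_that("point estimates match hand geometry and the posterior at large n", {
  df <- rbind(make_iso_df(-18, 12, species = "A", area = "Z"),
              make_iso_df(-16, 12, species = "B", area = "Z"),
              make_iso_df(-17, 14, species = "C", area = "Z"))
  pe <- community_point_estimates(df)
  expect_equal(pe$TA, 2)       # triangle base 2, height 2
  expect_equal(pe$NR, 2)
  expect_equal(pe$CR, 2)
  # collinear species means give zero hull area
  df2 <- rbind(make_iso_df(-18, 12, species = "A", area = "Z"),
               make_iso_df(-17, 13, species = "B", area = "Z"),
               make_iso_df(-16, 14, species = "C", area = "Z"))
  expect_equal(community_point_estimates(df2)$TA, 0)
  # large-n posterior medians agree with the deterministic version
  set.seed(9)
  rows <- lapply(list(A = c(-18, 12), B = c(-16, 13), C = c(-17, 15)),
                 function(mu) rmvn2(300, mu, 0.2 * diag(2)))
  df3 <- do.call(rbind, Map(function(X, sp)
    make_iso_df(X[, 1], X[, 2], species = sp, area = "Z"),
    rows, names(rows)))
  fit <- fit_niche(df3, n_draws = 1200, seed = 6)
  cm <- community_metrics(fit)
  pe3 <- community_point_estimates(df3)
  med <- apply(cm$Z$draws, 2, median)
  expect_equal(unname(med), unname(unlist(pe3[c("TA", "NR", "CR", "CD")])),
               tolerance = 0.08)
})
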