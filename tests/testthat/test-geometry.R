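test_that("cosine stenosis profile hits throat, edges and healthy limit", {
  sp <- stenosis_spec(D = 2, eps = 0.5, centers = 6.5, Ls = 1,
                      domain_length = 13)
  expect_equal(stenosis_half_height(6.5, sp), 0.5)         # 0.5 D - eps
  expect_equal(stenosis_half_height(c(6, 7), sp), c(1, 1)) # lesion edges
  expect_equal(stenosis_half_height(2, sp), 1)             # healthy section
  sp0 <- stenosis_spec(eps = 0)
  x <- seq(0, 15, length.out = 200)
  expect_equal(stenosis_half_height(x, sp0), rep(1, 200))
})

test_that("stenosis profile is continuous across lesion boundaries", {
  sp <- stenosis_spec()
  for (edge in c(6, 7, 8, 9)) {
    lo <- stenosis_half_height(edge - 1e-12, sp)
    hi <- stenosis_half_height(edge + 1e-12, sp)
    expect_lt(abs(hi - lo), 1e-10)
  }
})

test_that("invalid stenosis specs are rejected", {
  expect_error(stenosis_spec(eps = 1), "eps")
  expect_error(stenosis_spec(eps = 1.2), "eps")
  expect_error(stenosis_spec(centers = c(6.5, 7.2), Ls = 1), "overlap")
  expect_error(stenosis_spec(centers = 0.2, Ls = 1), "inside the domain")
})

test_that("quartic aneurysm ratio matches direct polynomial evaluation", {
  sp <- aneurysm_spec(R0 = 1, eps = 1, l0 = 6, la = 1, domain_length = 13)
  expect_equal(aneurysm_radius_ratio(c(6, 7), sp), c(1, 1))   # ends vanish
  expect_equal(aneurysm_radius_ratio(6.5, sp), 1.25)          # midpoint
  t6 <- 1 / 6
  poly <- 11 * t6 - 47 * t6^2 + 72 * t6^3 - 36 * t6^4
  expect_equal(aneurysm_radius_ratio(6 + 1 / 6, sp), 1 + 0.5 * poly)
  expect_true(all(aneurysm_radius_ratio(seq(6, 7, by = 0.01), sp) >= 1))
  expect_error(aneurysm_spec(la = 0), "la")
  expect_error(aneurysm_spec(R0 = 0), "R0")
})

test_that("increasing eps deepens the throat and raises the apex", {
  eps <- c(0.1, 0.3, 0.5, 0.7)
  throat <- vapply(eps, function(e)
    stenosis_half_height(6.5, stenosis_spec(eps = e)), 0)
  expect_true(all(diff(throat) < 0))
  apex <- vapply(eps, function(e)
    max(aneurysm_radius_ratio(seq(6, 7, by = 1e-3), aneurysm_spec(eps = e))), 0)
  expect_true(all(diff(apex) > 0))
})

test_that("build_channel produces a closed, mirror-symmetric tagged loop", {
  g <- build_channel(stenosis_spec())
  p <- g$polyline
  n <- nrow(p) / 2
  bottom <- p[1:n, ]; top <- p[(2 * n):(n + 1), ]
  expect_equal(bottom[, 1], top[, 1])
  expect_equal(bottom[, 2], -top[, 2])           # mirror symmetry
  expect_equal(nrow(g$lesions), 2)
  expect_equal(sum(g$landmarks$kind == "throat"), 2)
  g0 <- build_channel(stenosis_spec(eps = 0, centers = numeric(0)))
  expect_equal(range(g0$polyline[, 2]), c(-1, 1)) # plain rectangle
  expect_error(build_channel(stenosis_spec(), n_samples = 20), "coarse")
})

test_that("aneurysm apex found by refinement matches dense-grid oracle", {
  sp <- aneurysm_spec()
  g <- build_channel(sp)
  lm <- g$landmarks
  ## brute-force oracle on the first lesion
  tg <- seq(0, 1, length.out = 200001)
  poly <- 11 * tg - 47 * tg^2 + 72 * tg^3 - 144 * 0 # placeholder
  poly <- 11 * tg - 47 * tg^2 + 72 * tg^3 - 36 * tg^4
  t_star <- tg[which.max(poly)]
  h_star <- sp$R0 * (1 + sp$eps / (2 * sp$R0) * max(poly))
  first <- lm[lm$lesion == 1, ]
  expect_lt(min(abs(first$x - (6 + t_star))), 1e-4)
  expect_lt(abs(max(first$half_height) - h_star), 1e-8)
  ## derivative root oracle: maximizer solves 11 - 94t + 216t^2 - 144t^3 = 0
  dp <- function(t) 11 - 94 * t + 216 * t^2 - 144 * t^3
  t_bis <- uniroot(dp, c(0.05, 0.3), tol = 1e-12)$root
  expect_lt(abs(t_star - t_bis), 1e-4)
  ## two apex humps per lesion; midpoint excursion is eps/(4 R0)
  expect_equal(sum(lm$lesion == 1), 2)
  expect_equal(first$midpoint_ratio[1], 1 + sp$eps / (4 * sp$R0))
  ## throat of the cosine lesion sits exactly at the center
  gs <- build_channel(stenosis_spec())
  expect_equal(gs$landmarks$x, gs$spec$centers, tolerance = 1e-7)
})

test_that("channel boundary exports round-trip through CSV and geo text", {
  g <- build_channel(stenosis_spec(), n_samples = 200)
  csv <- tempfile(fileext = ".csv")
  write_channel(g, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), nrow(g$polyline))
  expect_equal(df$x, g$polyline[, 1])
  geo <- tempfile(fileext = ".geo")
  write_channel(g, geo, format = "geo")
  expect_true(any(grepl("Curve Loop", readLines(geo))))
})
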