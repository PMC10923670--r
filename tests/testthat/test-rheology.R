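test_that("strain-rate tensor discards rotation and keeps symmetric part", {
  gd <- 1.7
  V <- strain_rate_tensor(matrix(c(0, gd, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(V, matrix(c(0, gd / 2, gd / 2, 0), 2, 2))
  expect_equal(strain_rate_tensor(matrix(c(0, -3, 3, 0), 2, 2)),
               matrix(0, 2, 2))
  s <- 0.4
  Vext <- strain_rate_tensor(diag(c(s, -s)))
  expect_equal(Vext, diag(c(s, -s)))
  expect_equal(sum(diag(Vext)), 0)
})

test_that("shear rate reduces to |du/dy| in simple shear", {
  gd0 <- 2.3
  V <- matrix(c(0, gd0 / 2, gd0 / 2, 0), 2, 2)
  expect_equal(shear_rate(V), gd0)
  expect_equal(shear_rate(matrix(0, 2, 2)), 0)
  s <- 0.7
  expect_equal(shear_rate(diag(c(s, -s))), 2 * s)
  expect_error(shear_rate(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("Cross viscosity hits its limits and the printed blood parameters", {
  p <- cross_params()
  expect_equal(cross_viscosity(0, p), 0.16)
  expect_equal(cross_viscosity(1e12, p), 0.0036, tolerance = 1e-6)
  ## gamma_dot = 1/lambda: mu = mu_inf + (mu0 - mu_inf)/2^a
  expect_equal(cross_viscosity(1 / p$lam, p),
               0.0036 + 0.1564 / 2^1.23, tolerance = 1e-12)
  expect_error(cross_viscosity(-1, p), "non-negative")
  expect_error(cross_params(mu0 = 0.001, mu_inf = 0.01), "mu0")
})

test_that("Cross viscosity is monotone and bounded for random parameters", {
  set.seed(42)
  for (rep in 1:20) {
    p <- cross_params(mu0 = runif(1, 0.01, 1), mu_inf = runif(1, 1e-4, 0.01),
                      lam = runif(1, 0.1, 20), a = runif(1, 0.2, 3),
                      b = runif(1, 0.2, 2))
    g <- sort(c(0, 10^runif(40, -4, 5)))
    mu <- cross_viscosity(g, p)
    expect_true(all(diff(mu) <= 1e-12))
    expect_true(all(mu <= p$mu0 + 1e-12 & mu >= p$mu_inf - 1e-12))
  }
})

test_that("mu0 = mu_inf collapses the Cross law to a constant", {
  p <- cross_params(mu0 = 0.0036, mu_inf = 0.0036)
  g <- 10^seq(-3, 4, length.out = 30)
  expect_equal(cross_viscosity(g, p), rep(0.0036, 30))
})

test_that("retardation/relaxation ratio invariant is enforced", {
  op <- oldroyd_params(mu_n = 0.0036, mu_v = 0.0072, lam_x = 0.1)
  expect_equal(op$lam_d / op$lam_x, op$mu_n / (op$mu_n + op$mu_v))
  op2 <- oldroyd_params(mu_v = 0)
  expect_equal(op2$lam_d, op2$lam_x)
})

test_that("viscosity split follows the constitutive case", {
  cn <- case_config("newtonian")
  expect_equal(viscosity_split(cn, 10),
               list(mu_n = 0.0036, mu_v = 0, beta = 1))
  cod <- case_config("oldroyd_b", oldroyd = oldroyd_params(mu_v = 0.0036))
  expect_equal(viscosity_split(cod, 10)$beta, 0.5)
  cgd <- case_config("gen_oldroyd_b")
  expect_equal(viscosity_split(cgd, 0)$mu_n, 0.16)  # zero-shear branch
  expect_error(case_config("bogus"))
})

test_that("dimensionless groups keep degeneracies exact", {
  ## Oldroyd-B with mu_v = 0 has the same groups as Newtonian
  cn <- case_config("newtonian")
  c0 <- case_config("oldroyd_b", oldroyd = oldroyd_params(mu_v = 0))
  gn <- dimensionless_groups(cn, 500)
  g0 <- dimensionless_groups(c0, 500)
  expect_equal(gn$mu_ref, g0$mu_ref)
  expect_equal(g0$mu_v_star, 0)
  expect_equal(gn$beta_fun(2), g0$beta_fun(2))
  ## generalized case with mu0 = mu_inf matches plain Oldroyd-B
  cgd <- case_config("gen_oldroyd_b", cross = cross_params(mu0 = 0.0036))
  cod <- case_config("oldroyd_b")
  expect_equal(dimensionless_groups(cgd, 800)$beta_fun(c(0.1, 5)),
               dimensionless_groups(cod, 800)$beta_fun(c(0.1, 5)))
})
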