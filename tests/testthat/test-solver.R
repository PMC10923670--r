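test_that("Newtonian channel solve recovers Poiseuille to solver precision", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  cfg <- solver_config(Re = 100, case = case_config("newtonian"), Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = FALSE)
  st <- newton_solve(m, dof, cfg)
  expect_true(attr(st, "converged"))
  fix <- poiseuille_fixture(Ui = 0.046, L = 6)
  ue <- fix$u(m$coords[, 1], m$coords[, 2])
  rel <- sqrt(sum((st$u - ue)^2) + sum(st$v^2)) / sqrt(sum(ue^2))
  expect_lt(rel, 1e-10)
  pe <- fix$p(m$coords[seq_len(m$n_corner), 1], 0)
  expect_lt(max(abs(st$p - pe)), 1e-10)
})

test_that("continuation through a Reynolds ramp matches the direct solve", {
  m <- straight_mesh(L = 4, h = 0.5, ny = 8)
  cc <- case_config("newtonian")
  dof <- dof_map(m, elastic = FALSE)
  direct <- newton_solve(m, dof, solver_config(Re = 100, case = cc,
                                               stabilize = "off"))
  st <- NULL
  for (re in c(1, 10, 100))
    st <- newton_solve(m, dof, solver_config(Re = re, case = cc,
                                             stabilize = "off"),
                       initial_state = st)
  expect_lt(max(abs(st$u - direct$u)), 1e-6)
  expect_lt(max(abs(st$p - direct$p)), 1e-6)
})

test_that("constitutive degeneracies hold to nodal precision", {
  g <- small_stenosis_geom()
  m <- small_mesh(g)
  ## Oldroyd-B with mu_v = 0 equals Newtonian
  st_n <- solve_case(case = "newtonian", Re = 300, Wi = 0, geom = g, mesh = m)
  cc0 <- case_config("oldroyd_b", oldroyd = oldroyd_params(mu_v = 0))
  st_0 <- solve_case(case = cc0, Re = 300, Wi = 0.6, geom = g, mesh = m)
  expect_lt(max(abs(st_0$u - st_n$u)), 1e-10)
  expect_lt(max(abs(st_0$s11)), 1e-10)
  ## generalized Newtonian with mu0 = mu_inf equals Newtonian
  ccg <- case_config("gen_newtonian", cross = cross_params(mu0 = 0.0036))
  st_g <- solve_case(case = ccg, Re = 300, Wi = 0, geom = g, mesh = m)
  expect_lt(max(abs(st_g$u - st_n$u)), 1e-10)
  ## generalized Oldroyd-B with mu0 = mu_inf equals Oldroyd-B
  st_od <- solve_case(case = "oldroyd_b", Re = 300, Wi = 0.6, geom = g,
                      mesh = m)
  ccgd <- case_config("gen_oldroyd_b", cross = cross_params(mu0 = 0.0036))
  st_gd <- solve_case(case = ccgd, Re = 300, Wi = 0.6, geom = g, mesh = m)
  expect_lt(max(abs(st_gd$u - st_od$u)), 1e-10)
  expect_lt(max(abs(st_gd$s12 - st_od$s12)), 1e-10)
})

test_that("converged lesion flows conserve mass and stay symmetric", {
  st <- cached_run("stenosis", "newtonian", Re = 1000, Wi = 0)
  m <- attr(st, "mesh")
  expect_true(attr(st, "converged"))
  f_in <- flux(st, m, 0.5); f_out <- flux(st, m, 14.5)
  expect_lt(abs(f_in - f_out) / abs(f_in), 1e-6)
  ## flux constant across interior stations
  fs <- vapply(c(2, 5, 7.5, 10, 13), function(x0) flux(st, m, x0), 0)
  expect_lt(max(abs(fs - f_in)) / abs(f_in), 1e-5)
  ## direct line integration agrees with the conservative functional
  expect_lt(abs(flux(st, m, 7.5, method = "line") - f_in) / abs(f_in), 1e-3)
  ## mirror symmetry: u even, v odd in y
  mm <- mirror_map(m)
  expect_lt(max(abs(st$u - st$u[mm])), 1e-8)
  expect_lt(max(abs(st$v + st$v[mm])), 1e-8)
})

test_that("fully developed Oldroyd-B region reproduces the analytic stresses", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  cc <- case_config("oldroyd_b")
  cfg <- solver_config(Re = 100, Wi = 0.1, case = cc, Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = TRUE)
  st <- newton_solve(m, dof, cfg)
  expect_true(attr(st, "converged"))
  gd <- -3 * 0.046 * m$coords[, 2]
  ex <- shear_fixture(gd, mu_v = 0.5, Wi = 0.1)
  scale11 <- max(abs(2 * 0.5 * 0.1 * gd^2))
  expect_lt(max(abs(st$s11 - 2 * 0.5 * 0.1 * gd^2)) / scale11, 0.01)
  expect_lt(max(abs(st$s12 - 0.5 * gd)) / max(abs(0.5 * gd)), 0.01)
  expect_lt(max(abs(st$s22)), 1e-8)
})

test_that("stabilization is residual-consistent", {
  ## on a developed channel flow the strong residual vanishes, so SUPG must
  ## leave the discrete solution untouched
  ms <- straight_mesh(L = 6, h = 0.5, ny = 8)
  cc <- case_config("newtonian")
  dofs <- dof_map(ms, elastic = FALSE)
  off_s <- newton_solve(ms, dofs, solver_config(Re = 100, case = cc,
                                                stabilize = "off"))
  on_s <- newton_solve(ms, dofs, solver_config(Re = 100, case = cc,
                                               stabilize = "on"))
  expect_lt(max(abs(on_s$u - off_s$u)), 1e-10)
  ## on a lesion flow at low Re the two solutions stay close (consistency)
  g <- small_stenosis_geom()
  m <- small_mesh(g)
  dof <- dof_map(m, elastic = FALSE)
  off <- newton_solve(m, dof, solver_config(Re = 100, case = cc,
                                            stabilize = "off"))
  on <- newton_solve(m, dof, solver_config(Re = 100, case = cc,
                                           stabilize = "on"))
  expect_lt(max(abs(on$u - off$u)) / max(abs(off$u)), 0.05)
})

test_that("flow states and solutions export to VTU", {
  st <- cached_run("stenosis", "newtonian", Re = 1000, Wi = 0)
  f <- tempfile(fileext = ".vtu")
  write_state_vtu(st, attr(st, "mesh"), f)
  txt <- readLines(f)
  expect_true(any(grepl('Name="speed"', txt)))
})
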