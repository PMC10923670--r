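test_that("velocity magnitude is the Euclidean norm", {
  st <- structure(list(u = c(3, 0, 1), v = c(4, 0, 0)), class = "flow_state")
  expect_equal(velocity_magnitude(st), c(5, 0, 1))
})

test_that("percent deviation reproduces the printed severity arithmetic", {
  expect_equal(round(percent_deviation(0.1478, 0.1074), 2), 27.33)
  expect_equal(round(percent_deviation(0.152, 0.072), 2), 52.63)
  expect_equal(round(percent_deviation(0.133, 0.056), 2), 57.89)
  expect_equal(percent_deviation(0.7, 0.7), 0)
  expect_error(percent_deviation(0, 1), "non-zero")
})

test_that("axial profiles of developed channel flow are flat and linear", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  g <- straight_geom(L = 6)
  cfg <- solver_config(Re = 100, case = case_config("newtonian"), Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = FALSE)
  st <- newton_solve(m, dof, cfg)
  attr(st, "geom") <- g; attr(st, "mesh") <- m
  prof <- axial_profiles(st, g, m, n_stations = 200)
  expect_lt(max(prof$speed) - min(prof$speed), 1e-6)
  resid <- residuals(lm(p ~ x, data = prof))
  expect_lt(max(abs(resid)) / diff(range(prof$p)), 1e-8)
  expect_equal(max(prof$speed), 1.5 * 0.046, tolerance = 1e-8)
})

test_that("wall shear stress matches the analytic Poiseuille value", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  cfg <- solver_config(Re = 100, case = case_config("newtonian"), Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = FALSE)
  st <- newton_solve(m, dof, cfg)
  w <- wall_shear_stress(st, m)
  fix <- poiseuille_fixture(Ui = 0.046)
  expect_lt(max(abs(w$wss - fix$wss)) / fix$wss, 0.01)
  expect_true(all(diff(w$x) > 0))
  ## top wall gives the same positive forward-drag value by symmetry
  wt <- wall_shear_stress(st, m, wall = "top")
  expect_equal(w$wss, wt$wss, tolerance = 1e-10)
  ## zero flow has identically zero WSS
  st0 <- st; st0$u[] <- 0; st0$v[] <- 0
  expect_equal(max(abs(wall_shear_stress(st0, m)$wss)), 0)
})

test_that("recirculation detection is empty for unidirectional flow", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  g <- straight_geom(L = 6)
  cfg <- solver_config(Re = 100, case = case_config("newtonian"), Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = FALSE)
  st <- newton_solve(m, dof, cfg)
  attr(st, "geom") <- g; attr(st, "mesh") <- m
  rec <- recirculation_zones(st, m, g)
  expect_equal(nrow(rec$wall), 0)
  expect_equal(nrow(rec$velocity), 0)
  expect_equal(rec$extent, 0)
  ## consistency: wall detection empty whenever min WSS >= 0
  w <- wall_shear_stress(st, m)
  expect_gte(min(w$wss), 0)
})

test_that("stenotic flow puts the speed maximum in a lesion and recirculates", {
  st <- cached_run("stenosis", "newtonian", Re = 1000, Wi = 0)
  mt <- cached_metrics("stenosis", "newtonian", Re = 1000, Wi = 0)
  g <- attr(st, "geom")
  iv <- g$lesions
  ## jet window: the lesion interval plus the attached jet core, which at
  ## these Reynolds numbers peaks within half a lesion length of the throat
  Ls <- g$spec$Ls
  in_jet <- any(mt$x_umax >= iv$start & mt$x_umax <= iv$end + Ls / 2)
  expect_true(in_jet)
  rec <- recirculation_zones(st)
  expect_gte(nrow(rec$wall), 1)
  ## reversed flow sits downstream of a throat
  expect_gte(max(rec$wall$end), iv$center[1])
  ## the two detectors agree where both fire
  expect_equal(nrow(rec$velocity) > 0, nrow(rec$wall) > 0)
})

test_that("metrics rows are deterministic and flat flow deviates by ~0", {
  m <- straight_mesh(L = 6, h = 0.5, ny = 8)
  g <- straight_geom(L = 6)
  cfg <- solver_config(Re = 100, case = case_config("newtonian"), Ui = 0.046,
                       stabilize = "off")
  dof <- dof_map(m, elastic = FALSE)
  st <- newton_solve(m, dof, cfg)
  attr(st, "geom") <- g; attr(st, "mesh") <- m
  r1 <- build_metrics(st, g, m)
  r2 <- build_metrics(st, g, m)
  expect_identical(r1, r2)
  expect_lt(abs(r1$vel_pct_dev), 0.01)
})
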