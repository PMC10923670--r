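test_that("zero state with zero forcing gives zero residual", {
  m <- straight_mesh(L = 2, h = 0.5, ny = 6)
  cc <- case_config("gen_oldroyd_b")
  cfg <- solver_config(Re = 100, Wi = 0.5, case = cc, stabilize = "off")
  dof <- dof_map(m, elastic = TRUE)
  sys <- assemble(m, dof, numeric(dof$ndof), cfg, jacobian = FALSE)
  expect_equal(max(abs(sys$r)), 0)
})

test_that("interpolated Poiseuille/Oldroyd state annihilates interior residuals", {
  m <- straight_mesh(L = 4, h = 0.5, ny = 8)
  cc <- case_config("oldroyd_b")
  cfg <- solver_config(Re = 100, Wi = 0.6, case = cc, Ui = 0.05,
                       stabilize = "off")
  dof <- dof_map(m, elastic = TRUE)
  fix <- poiseuille_fixture(Ui = 0.05, L = 4)
  x <- numeric(dof$ndof)
  x[dof$u] <- fix$u(m$coords[, 1], m$coords[, 2])
  x[dof$p] <- fix$p(m$coords[seq_len(m$n_corner), 1], 0)
  gd <- fix$dudy(m$coords[, 2])
  x[dof$s11] <- 2 * 0.5 * 0.6 * gd^2
  x[dof$s12] <- 0.5 * gd
  sys <- assemble(m, dof, x, cfg, jacobian = FALSE)
  bnodes <- unique(c(m$boundary$n1, m$boundary$n2, m$boundary$mid))
  interior <- setdiff(seq_len(m$n_nodes), bnodes)
  idx <- c(dof$u[interior], dof$v[interior], dof$p,
           dof$s11[interior], dof$s12[interior], dof$s22[interior])
  expect_lt(max(abs(sys$r[idx])), 1e-12)
})

test_that("assembled Jacobian matches finite differences of the residual", {
  g <- build_channel(stenosis_spec(eps = 0, centers = numeric(0),
                                   domain_length = 1), n_samples = 10)
  m <- mesh_channel(g, h_far = 0.5, h_lesion = 0.5, ny = 6)
  for (case in c("newtonian", "gen_oldroyd_b")) {
    cc <- case_config(case)
    cfg <- solver_config(Re = 50, Wi = if (cc$elastic) 0.3 else 0, case = cc,
                         stabilize = "off")
    dof <- dof_map(m, elastic = cc$elastic)
    set.seed(7)
    x0 <- runif(dof$ndof, -0.3, 0.3)
    d <- runif(dof$ndof, -1, 1); d <- d / sqrt(sum(d^2))
    Jd <- as.vector(assemble(m, dof, x0, cfg)$J %*% d)
    h <- 1e-6
    rp <- assemble(m, dof, x0 + h * d, cfg, jacobian = FALSE)$r
    rm_ <- assemble(m, dof, x0 - h * d, cfg, jacobian = FALSE)$r
    rel <- max(abs((rp - rm_) / (2 * h) - Jd)) / max(abs(Jd))
    expect_lt(rel, 1e-6)
  }
})

test_that("inlet profile peaks at 1.5 Ui, vanishes at walls, means to Ui", {
  m <- straight_mesh(L = 2, h = 0.5, ny = 8)
  cc <- case_config("oldroyd_b")
  cfg <- solver_config(Re = 100, Wi = 0.6, case = cc, Ui = 0.2,
                       stabilize = "off")
  dof <- dof_map(m, elastic = TRUE)
  bc <- bc_data(m, dof, cfg)
  g <- setNames(bc$val, bc$idx)
  axis_node <- which(m$coords[, 1] == 0 & m$coords[, 2] == 0)
  expect_equal(unname(g[as.character(dof$u[axis_node])]), 0.3)  # 1.5 Ui
  wall_node <- which(m$coords[, 1] == 0 & abs(m$coords[, 2]) == 1)
  expect_equal(unname(g[as.character(dof$u[wall_node])]), c(0, 0))
  ## analytic mean of 1.5 Ui (1 - eta^2) over eta in [-1, 1] is Ui
  f <- function(eta) 1.5 * 0.2 * (1 - eta^2) / 2
  expect_equal(integrate(f, -1, 1)$value, 0.2)
  ## inlet stresses follow the fully developed Oldroyd-B state
  ynode <- which(m$coords[, 1] == 0 & m$coords[, 2] == 0.5)
  gd <- -3 * 0.2 * 0.5
  expect_equal(unname(g[as.character(dof$s12[ynode])]), 0.5 * gd)
  expect_equal(unname(g[as.character(dof$s11[ynode])]), 2 * 0.5 * 0.6 * gd^2)
})

test_that("untagged boundary edges are a hard error", {
  m <- straight_mesh(L = 2, h = 0.5, ny = 6)
  m$boundary$tag[3] <- NA
  cfg <- solver_config(Re = 100, case = case_config("newtonian"))
  dof <- dof_map(m, elastic = FALSE)
  expect_error(bc_data(m, dof, cfg), "untagged")
})

test_that("solver configuration enforces the stated parameter ranges", {
  expect_error(solver_config(Re = 0), "Re")
  expect_error(solver_config(Re = 3500), "Re")
  expect_error(solver_config(Re = 100, Wi = 1.5), "Wi")
  expect_error(solver_config(Re = 100, tol = 0), "tol")
})
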