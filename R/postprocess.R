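#' Velocity magnitude field
#'
#' Pointwise Euclidean norm `|U| = sqrt(u^2 + v^2)` of the nodal velocity.
#'
#' @param state a `flow_state`.
#' @return non-negative nodal vector.
#' @export
velocity_magnitude <- function(state) sqrt(state$u^2 + state$v^2)

#' Percent deviation between two extrema
#'
#' `100 (a - b) / a`, the severity metric used for velocity and pressure
#' extrema comparisons.
#'
#' @param a reference extremum (non-zero).
#' @param b second extremum.
#' @return percentage.
#' @export
percent_deviation <- function(a, b) {
  if (any(a == 0)) stop("reference extremum must be non-zero")
  100 * (a - b) / a
}

## analysis windows along the axis, derived from the geometry
axis_windows <- function(geom) {
  L <- geom$domain_length
  D <- geom$inlet_height
  iv <- geom$lesions
  list(mask = c(D, L - D),                                   # excl. ends
       between = if (nrow(iv) >= 2) c(iv$center[1], iv$center[nrow(iv)])
                 else c(D, L - D),
       lesion_span = if (nrow(iv) >= 1) c(iv$start[1], iv$end[nrow(iv)])
                     else c(D, L - D))
}

#' Axial profiles of velocity magnitude and pressure
#'
#' Samples `|U|` and `p` along the vessel axis (`y = 0`) at `n_stations`
#' equispaced stations by element-local interpolation, and attaches the
#' analysis windows (inlet/outlet exclusion of one channel height, the
#' closed between-lesion interval, and the lesion span).
#'
#' @param state a `flow_state` from [newton_solve()] / [solve_case()].
#' @param geom the channel geometry (defaults to `attr(state, "geom")`).
#' @param mesh the mesh (defaults to `attr(state, "mesh")`).
#' @param n_stations number of axial sample stations.
#' @return data frame `x`, `speed`, `p` with attribute `windows`; class
#'   `axial_profile`.
#' @export
axial_profiles <- function(state, geom = attr(state, "geom"),
                           mesh = attr(state, "mesh"), n_stations = 400) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(mesh, "tri_mesh"))
  L <- geom$domain_length
  x <- seq(L * 1e-9, L * (1 - 1e-9), length.out = n_stations)
  loc <- locate_points(mesh, x, rep(0, n_stations))
  u <- eval_p2(mesh, state$u, loc)
  v <- eval_p2(mesh, state$v, loc)
  p <- eval_p1(mesh, state$p, loc)
  out <- data.frame(x = x, speed = sqrt(u^2 + v^2), p = p)
  attr(out, "windows") <- axis_windows(geom)
  class(out) <- c("axial_profile", "data.frame")
  out
}

#' Wall shear stress along a channel wall
#'
#' Tangential component of the deviatoric fluid traction on the wall,
#' `WSS = (sigma . n) . t`, where `sigma` is the total deviatoric stress
#' (Newtonian part `2 mu_n V` plus the transported extra stress for elastic
#' cases), `n` the wall normal pointing into the fluid, and `t` the unit
#' tangent oriented with the flow, so positive WSS drags the wall forward
#' and negative WSS marks reversed near-wall flow.
#'
#' @param state a `flow_state` (its solver configuration supplies the
#'   viscosity model).
#' @param mesh the mesh (defaults to `attr(state, "mesh")`).
#' @param wall `"bottom"` or `"top"`.
#' @return data frame `x`, `s` (arc length), `wss`; class `wss_curve`.
#' @export
wall_shear_stress <- function(state, mesh = attr(state, "mesh"),
                              wall = c("bottom", "top")) {
  wall <- match.arg(wall)
  cfg <- attr(state, "cfg")
  stopifnot(inherits(mesh, "tri_mesh"))
  b <- mesh$boundary
  mid_y <- mesh$coords[b$mid, 2]
  sel <- b$tag == "wall" & if (wall == "bottom") mid_y < 0 else mid_y > 0
  edges <- b[sel, , drop = FALSE]
  edges <- edges[order(pmin(mesh$coords[edges$n1, 1],
                            mesh$coords[edges$n2, 1])), , drop = FALSE]
  ref_xy <- rbind(c(0, 0), c(1, 0), c(0, 1),
                  c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  elastic <- !is.null(state$s11)
  beta_fun <- if (!is.null(cfg)) cfg$groups$beta_fun else function(g) rep(1, length(g))
  rows <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    e <- edges$elem[k]
    nodes <- c(edges$n1[k], edges$mid[k], edges$n2[k])
    loc <- match(nodes, mesh$tri[e, ])
    if (anyNA(loc)) stop("boundary edge not contained in its parent element")
    ## discrete edge tangent oriented with +x
    pa <- mesh$coords[edges$n1[k], ]; pb <- mesh$coords[edges$n2[k], ]
    tv <- pb - pa
    if (tv[1] < 0) tv <- -tv
    tv <- tv / sqrt(sum(tv^2))
    nv <- if (wall == "bottom") c(-tv[2], tv[1]) else c(tv[2], -tv[1])
    p1 <- mesh$coords[mesh$tri[e, 1], ]; p2 <- mesh$coords[mesh$tri[e, 2], ]
    p3 <- mesh$coords[mesh$tri[e, 3], ]
    J <- rbind(c(p2[1] - p1[1], p3[1] - p1[1]),
               c(p2[2] - p1[2], p3[2] - p1[2]))
    wss_k <- numeric(3)
    for (m in 1:3) {
      d <- tri6_dshape(ref_xy[loc[m], 1], ref_xy[loc[m], 2])
      G <- t(solve(t(J), t(d)))
      ux <- sum(G[, 1] * state$u[mesh$tri[e, ]])
      uy <- sum(G[, 2] * state$u[mesh$tri[e, ]])
      vx <- sum(G[, 1] * state$v[mesh$tri[e, ]])
      vy <- sum(G[, 2] * state$v[mesh$tri[e, ]])
      gam <- sqrt(2 * (ux^2 + vy^2) + (uy + vx)^2)
      bet <- beta_fun(gam)
      S <- 2 * bet * matrix(c(ux, (uy + vx) / 2, (uy + vx) / 2, vy), 2, 2)
      if (elastic) {
        nd <- mesh$tri[e, ]
        Nv <- numeric(6); Nv[loc[m]] <- 1  # nodal evaluation
        S <- S + matrix(c(sum(Nv * state$s11[nd]), sum(Nv * state$s12[nd]),
                          sum(Nv * state$s12[nd]), sum(Nv * state$s22[nd])),
                        2, 2)
      }
      wss_k[m] <- sum(tv * (S %*% nv))
    }
    xk <- mesh$coords[nodes, 1]
    rows[[k]] <- data.frame(x = xk, wss = wss_k)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$x), , drop = FALSE]
  out <- out[order(out$x), , drop = FALSE]
  ## arc length along the wall polyline
  yv <- stats::approx(mesh$grid$xcols,
                      if (wall == "bottom") -mesh$grid$wcol else mesh$grid$wcol,
                      xout = out$x)$y
  out$s <- c(0, cumsum(sqrt(diff(out$x)^2 + diff(yv)^2)))
  rownames(out) <- NULL
  class(out) <- c("wss_curve", "data.frame")
  out
}

intervals_from_mask <- function(x, neg) {
  if (!any(neg)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = x[starts[keep]], end = x[ends[keep]])
}

#' Recirculation zones
#'
#' Detects reversed near-wall flow twice: maximal wall intervals with
#' negative wall shear stress, and maximal axial intervals where the axial
#' velocity sampled just inside the wall is negative.  The two detections
#' agree whenever the minimum wall WSS is non-negative (both empty).
#'
#' @param state a `flow_state`.
#' @param mesh the mesh (defaults to `attr(state, "mesh")`).
#' @param geom the geometry (defaults to `attr(state, "geom")`).
#' @param offset fractional distance from the wall (of the local half-height)
#'   for the near-wall velocity probe.
#' @param n_stations probe stations.
#' @return list with data frames `wall` (negative-WSS intervals), `velocity`
#'   (reversed-velocity intervals) and scalar `extent` (total negative-WSS
#'   wall length along x).
#' @export
recirculation_zones <- function(state, mesh = attr(state, "mesh"),
                                geom = attr(state, "geom"), offset = 0.1,
                                n_stations = 400) {
  w <- wall_shear_stress(state, mesh, wall = "bottom")
  wall_iv <- intervals_from_mask(w$x, w$wss < 0)
  L <- geom$domain_length
  x <- seq(L * 1e-9, L * (1 - 1e-9), length.out = n_stations)
  wlin <- stats::approx(mesh$grid$xcols, mesh$grid$wcol, xout = x)$y
  y <- -(1 - offset) * wlin
  loc <- locate_points(mesh, x, y)
  u <- eval_p2(mesh, state$u, loc)
  vel_iv <- intervals_from_mask(x, u < 0)
  list(wall = wall_iv, velocity = vel_iv,
       extent = if (nrow(wall_iv)) sum(wall_iv$end - wall_iv$start) else 0)
}

#' Scalar metrics of one run
#'
#' Extracts the per-run severity metrics: masked axial `|U|` extrema (one
#' channel height excluded at each end), the between-lesion minimum, percent
#' deviations, axial pressure extrema over the between-lesion and lesion-span
#' windows, WSS extrema with locations, and the recirculation extent.  The
#' canonical velocity percent deviation pairs the masked maximum with the
#' between-lesion minimum for stenoses (where the jet hub carries the
#' maximum) and with the masked minimum for aneurysms (where the slowest
#' axial flow sits inside a bulge).
#'
#' @param state a converged `flow_state` from [solve_case()].
#' @param geom,mesh geometry and mesh (default from the state's attributes).
#' @param n_stations axial sampling density.
#' @return one-row data frame (a `MetricsTable` row).
#' @export
build_metrics <- function(state, geom = attr(state, "geom"),
                          mesh = attr(state, "mesh"), n_stations = 400) {
  prof <- axial_profiles(state, geom, mesh, n_stations = n_stations)
  win <- attr(prof, "windows")
  inw <- function(xr) prof$x >= xr[1] & prof$x <= xr[2]
  masked <- inw(win$mask)
  between <- inw(win$between)
  span <- inw(win$lesion_span)
  umax <- max(prof$speed[masked]); x_umax <- prof$x[masked][which.max(prof$speed[masked])]
  umin_masked <- min(prof$speed[masked])
  x_umin_masked <- prof$x[masked][which.min(prof$speed[masked])]
  umin_between <- min(prof$speed[between])
  u_mean_between <- mean(prof$speed[between])
  pmin_between <- min(prof$p[between]); pmax_between <- max(prof$p[between])
  x_pmin_between <- prof$x[between][which.min(prof$p[between])]
  pmin_span <- min(prof$p[span]); pmax_span <- max(prof$p[span])
  wss <- wall_shear_stress(state, mesh)
  wmask <- wss$x >= win$mask[1] & wss$x <= win$mask[2]
  rec <- recirculation_zones(state, mesh, geom)
  vel_pct_between <- percent_deviation(umax, umin_between)
  vel_pct_masked <- percent_deviation(umax, umin_masked)
  model <- geom$model
  data.frame(
    model = model, case = attr(state, "case") %||% NA_character_,
    Re = attr(state, "Re") %||% NA_real_, Wi = attr(state, "Wi") %||% NA_real_,
    converged = isTRUE(attr(state, "converged")),
    iterations = attr(state, "iterations") %||% NA_integer_,
    umax = umax, x_umax = x_umax,
    umin_between = umin_between, umin_masked = umin_masked,
    x_umin_masked = x_umin_masked,
    u_mean_between = u_mean_between,
    vel_pct_dev = if (model == "stenosis") vel_pct_between else vel_pct_masked,
    vel_pct_dev_between = vel_pct_between,
    vel_pct_dev_masked = vel_pct_masked,
    pmin_between = pmin_between, pmax_between = pmax_between,
    x_pmin_between = x_pmin_between,
    pmin_span = pmin_span, pmax_span = pmax_span,
    p_pct_dev = if (pmax_between != 0)
      percent_deviation(pmax_between, pmin_between) else NA_real_,
    wss_max = max(wss$wss[wmask]),
    wss_max_x = wss$x[wmask][which.max(wss$wss[wmask])],
    wss_min = min(wss$wss[wmask]),
    wss_min_x = wss$x[wmask][which.min(wss$wss[wmask])],
    recirc_extent = rec$extent, n_recirc = nrow(rec$wall),
    stringsAsFactors = FALSE)
}
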