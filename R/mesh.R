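#' Mesh a channel geometry with six-node triangles
#'
#' Generates a boundary-fitted triangulation of a [build_channel()] geometry:
#' axial node columns graded from `h_far` (straight sections) down to
#' `h_lesion` (inside and around lesions), and `ny` element rows spanning the
#' local channel gap.  Each grid cell is split into two straight-sided
#' six-node triangles (quadratic velocity/stress nodes at corners and edge
#' midpoints; pressure supported on corner nodes only).  The diagonal pattern
#' is mirrored about the channel axis so the mesh is exactly symmetric under
#' `y -> -y`, and generation is fully deterministic.
#'
#' @param geom a [build_channel()] geometry.
#' @param h_far target axial spacing away from lesions.
#' @param h_lesion refined axial spacing in a band around each lesion
#'   (`h_lesion <= h_far`).
#' @param ny number of element rows across the channel (even, `>= 6`); default
#'   resolves the inlet height with spacing about `h_lesion`.
#' @param band half-width of the refinement band appended to each lesion
#'   interval.
#' @return an object of class `tri_mesh`.
#' @export
mesh_channel <- function(geom, h_far = 0.35, h_lesion = 0.15, ny = NULL,
                         band = 0.5) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (h_lesion > h_far) stop("h_lesion must be <= h_far")
  L <- geom$domain_length
  D <- geom$inlet_height
  if (is.null(ny)) ny <- max(8L, 2L * as.integer(ceiling(D / h_lesion / 2)))
  ny <- as.integer(ny)
  if (ny %% 2L != 0L) ny <- ny + 1L
  if (ny < 6L)
    stop(sprintf("ny = %d cannot resolve the narrowest gap with >= 6 element rows; use ny >= 6", ny))

  ## axial spacing density: h_lesion inside lesion +/- band, h_far outside,
  ## with a linear blend of width `band` on each side.
  iv <- geom$lesions
  target_h <- function(x) {
    h <- rep(h_far, length(x))
    if (nrow(iv)) for (k in seq_len(nrow(iv))) {
      d <- pmax(0, pmax(iv$start[k] - band - x, x - iv$end[k] - band))
      blend <- pmin(1, d / band)
      h <- pmin(h, h_lesion + (h_far - h_lesion) * blend)
    }
    h
  }
  xf <- seq(0, L, length.out = 4096)
  dens <- 1 / target_h(xf)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xf)))
  ncol_ <- max(4L, as.integer(ceiling(cum[length(cum)])))
  xcols <- stats::approx(cum, xf, xout = seq(0, cum[length(cum)],
                                             length.out = ncol_ + 1))$y
  xcols[1] <- 0; xcols[length(xcols)] <- L
  if (nrow(iv)) {
    per_lesion <- vapply(seq_len(nrow(iv)), function(k)
      sum(xcols >= iv$start[k] & xcols <= iv$end[k]), 0)
    if (any(per_lesion < 4)) {
      bad <- which(per_lesion < 4)[1]
      stop(sprintf("lesion %d resolved by only %d columns; reduce h_lesion to <= %.3g",
                   bad, per_lesion[bad], (iv$end[bad] - iv$start[bad]) / 4))
    }
  }
  nx <- length(xcols) - 1L

  ## corner grid; eta exactly antisymmetric so the mesh mirrors bit-exactly
  eta <- ((0:ny) - ny / 2) / (ny / 2)
  wcol <- geom$half_height(xcols)
  ncorner <- (nx + 1L) * (ny + 1L)
  cid <- function(i, j) (i - 1L) * (ny + 1L) + j
  xx <- rep(xcols, each = ny + 1L)
  yy <- as.vector(outer(eta, wcol, `*`))
  coords <- cbind(xx, yy)

  ## cells -> two triangles; diagonal mirrored between lower and upper half
  tri1 <- matrix(0L, nx * ny * 2L, 3L)
  e <- 0L
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      a <- cid(i, j); b <- cid(i + 1L, j)
      cc <- cid(i + 1L, j + 1L); d <- cid(i, j + 1L)
      if (j <= ny / 2) {
        tri1[e + 1L, ] <- c(a, b, cc); tri1[e + 2L, ] <- c(a, cc, d)
      } else {
        tri1[e + 1L, ] <- c(a, b, d); tri1[e + 2L, ] <- c(b, cc, d)
      }
      e <- e + 2L
    }
  }
  nel <- e

  ## midside nodes via unique edge table
  pairs <- rbind(tri1[, c(1, 2)], tri1[, c(2, 3)], tri1[, c(3, 1)])
  key_lo <- pmin(pairs[, 1], pairs[, 2])
  key_hi <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(key_lo, key_hi)
  uid <- match(key, unique(key))
  nedge <- max(uid)
  first <- !duplicated(uid)
  edge_lo <- key_lo[first][order(uid[first])]
  edge_hi <- key_hi[first][order(uid[first])]
  mid_xy <- (coords[edge_lo, , drop = FALSE] + coords[edge_hi, , drop = FALSE]) / 2
  coords <- rbind(coords, mid_xy)
  midnode <- ncorner + seq_len(nedge)
  m12 <- midnode[uid[seq_len(nel)]]
  m23 <- midnode[uid[nel + seq_len(nel)]]
  m31 <- midnode[uid[2L * nel + seq_len(nel)]]
  tri <- cbind(tri1, m12, m23, m31)
  colnames(tri) <- NULL

  midnode_of <- function(n1, n2) {
    k <- match(paste(pmin(n1, n2), pmax(n1, n2)),
               paste(edge_lo, edge_hi))
    midnode[k]
  }

  ## boundary edges with tags and parent elements
  cid_cell <- function(i, j, ny) (i - 1L) * ny + j
  bottom <- data.frame(n1 = cid(seq_len(nx), 1L), n2 = cid(seq_len(nx) + 1L, 1L),
                       tag = "wall",
                       elem = ((cid_cell(seq_len(nx), 1L, ny) - 1L) * 2L + 1L))
  top <- data.frame(n1 = cid(seq_len(nx) + 1L, ny + 1L),
                    n2 = cid(seq_len(nx), ny + 1L), tag = "wall",
                    elem = ((cid_cell(seq_len(nx), ny, ny) - 1L) * 2L + 2L))
  inlet <- data.frame(n1 = cid(1L, seq_len(ny) + 1L), n2 = cid(1L, seq_len(ny)),
                      tag = "inlet",
                      elem = ifelse(seq_len(ny) <= ny / 2,
                                    (cid_cell(1L, seq_len(ny), ny) - 1L) * 2L + 2L,
                                    (cid_cell(1L, seq_len(ny), ny) - 1L) * 2L + 1L))
  outlet <- data.frame(n1 = cid(nx + 1L, seq_len(ny)),
                       n2 = cid(nx + 1L, seq_len(ny) + 1L), tag = "outlet",
                       elem = ifelse(seq_len(ny) <= ny / 2,
                                     (cid_cell(nx, seq_len(ny), ny) - 1L) * 2L + 1L,
                                     (cid_cell(nx, seq_len(ny), ny) - 1L) * 2L + 2L))
  boundary <- rbind(bottom, top, inlet, outlet)
  boundary$mid <- midnode_of(boundary$n1, boundary$n2)
  rownames(boundary) <- NULL

  structure(list(coords = coords, tri = tri, n_corner = ncorner,
                 n_nodes = nrow(coords), n_elem = nel,
                 boundary = boundary,
                 grid = list(xcols = xcols, eta = eta, nx = nx, ny = ny,
                             wcol = wcol),
                 h_far = h_far, h_lesion = h_lesion),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d six-node triangles, %d nodes (%d corner), %d boundary edges>\n",
              x$n_elem, x$n_nodes, x$n_corner, nrow(x$boundary)))
  invisible(x)
}

## signed areas of the corner triangles
tri_signed_area <- function(mesh) {
  p1 <- mesh$coords[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$coords[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$coords[mesh$tri[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

#' Validate a six-node triangular mesh
#'
#' Checks the structural invariants: positive signed element areas, midside
#' nodes at edge midpoints, one tag per boundary edge, and the Euler relation
#' `V - E + F = 1` on the corner graph of a simply connected channel.
#'
#' @param mesh a [mesh_channel()] mesh.
#' @param tol geometric tolerance for the midside test.
#' @return list with `min_angle` (degrees), `min_area`, counts, and a
#'   character vector `violations` (empty when the mesh is acceptable).
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  violations <- character(0)
  areas <- tri_signed_area(mesh)
  if (any(areas <= 0))
    violations <- c(violations, sprintf("%d elements with non-positive area",
                                        sum(areas <= 0)))
  ## midside positions
  mid_ok <- TRUE
  for (k in 1:3) {
    c1 <- mesh$tri[, k]; c2 <- mesh$tri[, k %% 3 + 1]; m <- mesh$tri[, 3 + k]
    d <- abs((mesh$coords[c1, , drop = FALSE] +
                mesh$coords[c2, , drop = FALSE]) / 2 -
               mesh$coords[m, , drop = FALSE])
    if (max(d) > tol) mid_ok <- FALSE
  }
  if (!mid_ok) violations <- c(violations, "midside off edge midpoint")
  ## Euler relation on the corner graph
  pairs <- rbind(mesh$tri[, c(1, 2)], mesh$tri[, c(2, 3)], mesh$tri[, c(3, 1)])
  ekey <- unique(paste(pmin(pairs[, 1], pairs[, 2]),
                       pmax(pairs[, 1], pairs[, 2])))
  euler <- mesh$n_corner - length(ekey) + mesh$n_elem
  if (euler != 1L)
    violations <- c(violations, sprintf("Euler relation V-E+F = %d != 1", euler))
  ## every boundary edge tagged exactly once
  bkey <- paste(pmin(mesh$boundary$n1, mesh$boundary$n2),
                pmax(mesh$boundary$n1, mesh$boundary$n2))
  if (anyDuplicated(bkey))
    violations <- c(violations, "boundary edge with multiple tags")
  tab <- table(paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
  nbnd <- sum(tab == 1)
  if (nbnd != length(bkey))
    violations <- c(violations, sprintf("%d boundary edges but %d tagged",
                                        nbnd, length(bkey)))
  ## angles
  ang <- function(a, b, cc) {
    u <- b - a; v <- cc - a
    acos(pmin(1, pmax(-1, rowSums(u * v) /
                        sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  p1 <- mesh$coords[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$coords[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$coords[mesh$tri[, 3], , drop = FALSE]
  angles <- cbind(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2))
  list(min_angle = min(angles) * 180 / pi, min_area = min(areas),
       n_elem = mesh$n_elem, n_nodes = mesh$n_nodes, euler = euler,
       violations = violations)
}

## ---- point location and field evaluation -------------------------------

## Locate points in the structured channel mesh.  Returns element ids and
## reference coordinates (xi, eta) for each (x, y).
locate_points <- function(mesh, x, y) {
  g <- mesh$grid
  i <- findInterval(x, g$xcols, all.inside = TRUE)
  ## discrete half-height is linear between columns
  t <- (x - g$xcols[i]) / (g$xcols[i + 1] - g$xcols[i])
  wlin <- g$wcol[i] * (1 - t) + g$wcol[i + 1] * t
  etav <- pmin(1 - 1e-12, pmax(-1 + 1e-12, y / wlin))
  j <- findInterval(etav, g$eta, all.inside = TRUE)
  base <- ((i - 1L) * g$ny + (j - 1L)) * 2L
  el <- integer(length(x)); xi <- numeric(length(x)); et <- numeric(length(x))
  for (k in seq_along(x)) {
    found <- FALSE
    for (cand in c(base[k] + 1L, base[k] + 2L)) {
      p1 <- mesh$coords[mesh$tri[cand, 1], ]
      p2 <- mesh$coords[mesh$tri[cand, 2], ]
      p3 <- mesh$coords[mesh$tri[cand, 3], ]
      det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
        (p3[1] - p1[1]) * (p2[2] - p1[2])
      l2 <- ((x[k] - p1[1]) * (p3[2] - p1[2]) -
               (y[k] - p1[2]) * (p3[1] - p1[1])) / det
      l3 <- ((y[k] - p1[2]) * (p2[1] - p1[1]) -
               (x[k] - p1[1]) * (p2[2] - p1[2])) / det
      if (l2 >= -1e-9 && l3 >= -1e-9 && l2 + l3 <= 1 + 1e-9) {
        el[k] <- cand; xi[k] <- l2; et[k] <- l3; found <- TRUE; break
      }
    }
    if (!found) { # fall back on closer of the two candidates
      el[k] <- base[k] + 1L
      p1 <- mesh$coords[mesh$tri[el[k], 1], ]
      p2 <- mesh$coords[mesh$tri[el[k], 2], ]
      p3 <- mesh$coords[mesh$tri[el[k], 3], ]
      det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
        (p3[1] - p1[1]) * (p2[2] - p1[2])
      xi[k] <- ((x[k] - p1[1]) * (p3[2] - p1[2]) -
                  (y[k] - p1[2]) * (p3[1] - p1[1])) / det
      et[k] <- ((y[k] - p1[2]) * (p2[1] - p1[1]) -
                  (x[k] - p1[1]) * (p2[2] - p1[2])) / det
    }
  }
  list(elem = el, xi = xi, eta = et)
}

## Evaluate a quadratic nodal field at located points.
eval_p2 <- function(mesh, nodal, loc) {
  out <- numeric(length(loc$elem))
  for (k in seq_along(loc$elem)) {
    N <- tri6_shape(loc$xi[k], loc$eta[k])
    out[k] <- sum(N * nodal[mesh$tri[loc$elem[k], ]])
  }
  out
}

## Evaluate a corner (linear) nodal field at located points.
eval_p1 <- function(mesh, nodal_corner, loc) {
  out <- numeric(length(loc$elem))
  for (k in seq_along(loc$elem)) {
    H <- tri3_shape(loc$xi[k], loc$eta[k])
    out[k] <- sum(H * nodal_corner[mesh$tri[loc$elem[k], 1:3]])
  }
  out
}

## Gradient of a quadratic nodal field at located points; returns cbind(dx, dy).
eval_p2_grad <- function(mesh, nodal, loc) {
  out <- matrix(0, length(loc$elem), 2)
  for (k in seq_along(loc$elem)) {
    e <- loc$elem[k]
    d <- tri6_dshape(loc$xi[k], loc$eta[k])
    p1 <- mesh$coords[mesh$tri[e, 1], ]; p2 <- mesh$coords[mesh$tri[e, 2], ]
    p3 <- mesh$coords[mesh$tri[e, 3], ]
    J <- rbind(c(p2[1] - p1[1], p3[1] - p1[1]),
               c(p2[2] - p1[2], p3[2] - p1[2]))
    g <- t(solve(t(J), t(d)))           # d/dx, d/dy per basis fn
    vals <- nodal[mesh$tri[e, ]]
    out[k, ] <- c(sum(g[, 1] * vals), sum(g[, 2] * vals))
  }
  out
}
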