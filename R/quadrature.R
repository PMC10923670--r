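## Reference six-node (P2) triangle and quadrature.
##
## Reference element: vertices (0,0), (1,0), (0,1); barycentrics
## L1 = 1 - xi - eta, L2 = xi, L3 = eta.  Node order: 3 corners, then
## midsides 4 = (1,2), 5 = (2,3), 6 = (3,1).  Pressure uses the linear
## corner basis H = (L1, L2, L3).

tri6_shape <- function(xi, eta) {
  L1 <- 1 - xi - eta; L2 <- xi; L3 <- eta
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
}

tri6_dshape <- function(xi, eta) {
  L1 <- 1 - xi - eta; L2 <- xi; L3 <- eta
  ## rows: basis functions; cols: d/dxi, d/deta
  cbind(c(1 - 4 * L1, 4 * L2 - 1, 0, 4 * (L1 - L2), 4 * L3, -4 * L3),
        c(1 - 4 * L1, 0, 4 * L3 - 1, -4 * L2, 4 * L2, 4 * (L1 - L3)))
}

tri3_shape <- function(xi, eta) c(1 - xi - eta, xi, eta)

## 7-point degree-5 rule; weights sum to 1/2 (reference-triangle area).
tri_quad7 <- function() {
  a1 <- 0.4701420641051151; a2 <- 0.1012865073234563
  w1 <- 0.1323941527885062 / 2; w2 <- 0.1259391805448271 / 2
  pts <- rbind(c(1 / 3, 1 / 3),
               c(a1, a1), c(1 - 2 * a1, a1), c(a1, 1 - 2 * a1),
               c(a2, a2), c(1 - 2 * a2, a2), c(a2, 1 - 2 * a2))
  w <- c(0.1125, w1, w1, w1, w2, w2, w2)
  list(pts = pts, w = w)
}

## Precomputed reference data at the quadrature points: N (6 x nq),
## dN/dxi, dN/deta (6 x nq), H (3 x nq).
tri6_ref_data <- function(rule = tri_quad7()) {
  nq <- length(rule$w)
  N <- matrix(0, 6, nq); Dxi <- matrix(0, 6, nq); Deta <- matrix(0, 6, nq)
  H <- matrix(0, 3, nq)
  for (q in seq_len(nq)) {
    xi <- rule$pts[q, 1]; eta <- rule$pts[q, 2]
    N[, q] <- tri6_shape(xi, eta)
    d <- tri6_dshape(xi, eta)
    Dxi[, q] <- d[, 1]; Deta[, q] <- d[, 2]
    H[, q] <- tri3_shape(xi, eta)
  }
  list(N = N, Dxi = Dxi, Deta = Deta, H = H, w = rule$w, pts = rule$pts)
}
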