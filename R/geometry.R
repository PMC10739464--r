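# Rigid-body and internal-coordinate geometry used by the conformer engine,
# the evaluation module and the fixture generator. All distances in Angstrom,
# all angles in degrees.

IDEAL_GEOM <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.5
)

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# NeRF atom placement: position d such that |c-d| = bond, angle(b,c,d) = angle
# and torsion(a,b,c,d) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Least-squares rigid superposition (Kabsch). Fits P onto Q (both n x 3
# matrices of paired points); returns the rotation (applied as X %*% R),
# translation, and the post-fit RMSD. Proper rotation only (no reflection).
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) {
    abort_pmhc("need at least 3 paired atoms for a rigid fit",
               "pmhc_superpose_error")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - as.numeric(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, FUN = "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

apply_rigid <- function(X, fit) {
  sweep(X %*% fit$rotation, 2, fit$translation, FUN = "+")
}

# Build an n-residue backbone segment (N, CA, C, O per residue) with ideal
# bond lengths/angles and uniform (phi, psi, omega) torsions. Returns a list
# of n matrices (4 x 3, rows N/CA/C/O).
build_ideal_segment <- function(n, phi, psi, omega = 180) {
  g <- IDEAL_GEOM
  res <- vector("list", n)
  # seed residue near the origin
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_n_ca, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, g$b_ca_c, g$a_n_ca_c, 180)
  prev <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)) {
    if (i > 1) {
      Nn <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi)
      CAn <- place_atom(prev$CA, prev$C, Nn, g$b_n_ca, g$a_c_n_ca, omega)
      Cn <- place_atom(prev$C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi)
      cur <- list(N = Nn, CA = CAn, C = Cn)
    } else {
      cur <- prev
    }
    O <- place_atom(cur$N, cur$CA, cur$C, g$b_c_o, g$a_ca_c_o, psi + 180)
    res[[i]] <- rbind(N = cur$N, CA = cur$CA, C = cur$C, O = O)
    prev <- cur
  }
  res
}

# Rigidly re-orient a segment so the first->last CA axis runs along
# `direction` and the first CA sits at `origin`. X is an m x 3 matrix,
# ca_idx the row indices of the CA atoms.
orient_segment <- function(X, ca_idx, origin = c(0, 0, 0),
                           direction = c(1, 0, 0)) {
  axis <- X[ca_idx[length(ca_idx)], ] - X[ca_idx[1], ]
  axis <- axis / vnorm(axis)
  dir <- direction / vnorm(direction)
  v <- vcross(axis, dir)
  s <- vnorm(v)
  co <- sum(axis * dir)
  if (s < 1e-12) {
    R <- if (co > 0) diag(3) else diag(c(-1, -1, 1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - co) / s^2)
    R <- t(R)  # applied as X %*% R on row vectors
  }
  X0 <- sweep(X, 2, X[ca_idx[1], ])
  Xr <- X0 %*% R
  sweep(Xr, 2, origin, FUN = "+")
}

# Ideal CB position from backbone N, CA, C.
place_cb <- function(N, CA, C) {
  g <- IDEAL_GEOM
  place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, 122.6)
}
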