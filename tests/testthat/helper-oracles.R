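# Independent oracles used across the suite. These deliberately take a
# different computational route from the package (numeric root-finding,
# explicit loops, exhaustive search) so agreement is informative.

# Fraction bound by numeric root of (P - x)(L - x) = K x, solved with
# uniroot on [0, min(P, L)].
oracle_fraction_bound <- function(P, L, K) {
  if (L == 0) return(0)
  f <- function(x) (P - x) * (L - x) - K * x
  x <- stats::uniroot(f, c(0, min(P, L)), tol = 1e-13)$root
  x / P
}

# Per-injection ITC heats recomputed with an explicit loop and the uniroot
# isotherm.
oracle_itc_heats <- function(expt, kd, dh, n) {
  v <- 0
  Qprev <- 0
  q <- numeric(length(expt$injection_volumes))
  for (i in seq_along(q)) {
    dV <- expt$injection_volumes[i]
    v <- v + dV
    P <- expt$cell_conc * (1 - v / (2 * expt$cell_volume)) /
      (1 + v / (2 * expt$cell_volume))
    L <- expt$syringe_conc * (v / expt$cell_volume) /
      (1 + v / (2 * expt$cell_volume))
    fb <- oracle_fraction_bound(n * P, L, kd)
    Q <- dh * expt$cell_volume * (n * P * fb) * 1e-3
    q[i] <- Q - Qprev + (dV / expt$cell_volume) * (Q + Qprev) / 2
    Qprev <- Q
  }
  q
}

# Minimal RMSD over rigid transforms found by general-purpose optimization
# over Euler angles (brute-force alternative to the closed-form Kabsch
# solution); adequate for <= 10-atom toys.
oracle_min_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A0 %*% t(rot(ang)) - B0)^2)))
  best <- Inf
  for (s in seq_len(8)) {
    st <- stats::optim(stats::runif(3, -pi, pi), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, st$value)
  }
  best
}

# Signed helix rotation per residue from CA positions: fit the helix axis
# as the mean rise direction, project CAs on the orthogonal plane and
# accumulate signed angle increments about the axis.
oracle_rotation_per_residue <- function(ca) {
  axis <- colMeans(diff(ca))
  axis <- axis / sqrt(sum(axis^2))
  centre <- colMeans(ca)
  proj <- t(apply(ca, 1, function(p) {
    d <- p - centre
    d - sum(d * axis) * axis
  }))
  ref <- proj[1, ] / sqrt(sum(proj[1, ]^2))
  perp <- c(axis[2] * ref[3] - axis[3] * ref[2],
            axis[3] * ref[1] - axis[1] * ref[3],
            axis[1] * ref[2] - axis[2] * ref[1])
  ang <- atan2(proj %*% perp, proj %*% ref) * 180 / pi
  diffs <- diff(as.numeric(ang))
  diffs <- (diffs + 180) %% 360 - 180
  mean(diffs)
}

# Deterministic toy coordinate set (non-degenerate, 10 atoms).
toy_coords <- function(n = 10, seed = 7) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 3), n, 3)
}

random_rigid_transform <- function(xyz, seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, stats::rnorm(3, sd = 5), `+`)
}

# Tiny synthetic titration series built by hand (no generator) for
# contract tests.
manual_series <- function() {
  apo <- titration_point(200, 0, peak_list(
    c("Y470", "Y479", "Y495"), c(8.10, 8.40, 8.90), c(120.0, 117.5, 124.0)))
  mid <- titration_point(200, 400, peak_list(
    c("Y470", "Y479", "Y495"), c(8.12, 8.43, 8.95), c(120.2, 117.9, 124.3)))
  sat <- titration_point(200, 2000, peak_list(
    c("Y470", "Y479", "Y495"), c(8.14, 8.46, 9.00), c(120.4, 118.3, 124.6)))
  titration_series(list(apo, mid, sat))
}
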