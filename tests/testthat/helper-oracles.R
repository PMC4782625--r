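# Independent oracles, written deliberately apart from the package internals:
# explicit loops, own constants, no shared helpers.

# brute-force screened cross-pair sum over all A x B pairs, kcal/mol
oracle_cross_energy <- function(posA, qA, posB, qB, kappa, a, dielectric) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; NAv <- 6.02214076e23
  total <- 0
  for (i in seq_len(nrow(posA))) {
    for (j in seq_len(nrow(posB))) {
      r <- sqrt(sum((posA[i, ] - posB[j, ])^2))
      coul <- qA[i] * qB[j] * e^2 / (4 * pi * eps0 * dielectric * r * 1e-10)
      total <- total + coul * exp(-kappa * (r - a)) / (1 + kappa * a)
    }
  }
  total * NAv / 4184
}

# unscreened Coulomb pair sum over unordered pairs, kcal/mol
oracle_coulomb_self <- function(pos, q, dielectric) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; NAv <- 6.02214076e23
  total <- 0
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      total <- total + q[i] * q[j] * e^2 /
        (4 * pi * eps0 * dielectric * r * 1e-10)
    }
  }
  total * NAv / 4184
}

# random charge set: n charges in a box, unit-scale charges, min separation
random_charge_positions <- function(n, spread = 20, min_sep = 1) {
  repeat {
    pos <- matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
    if (n < 2 || min(stats::dist(pos)) > min_sep) return(pos)
  }
}

# composite trapezoid on a fine grid: integral of f from x0 to each x in xs
oracle_fine_quadrature <- function(force_fn, xs, refine = 100) {
  out <- numeric(length(xs))
  for (k in seq_along(xs)) {
    grid <- seq(xs[1], xs[k], length.out = max(2, refine * (k - 1) + 1))
    y <- force_fn(grid)
    h <- diff(grid)
    out[k] <- sum(h * (y[-1] + y[-length(y)]) / 2)
  }
  out
}

# independent re-implementation of the greedy disjoint clustering rule:
# visit points in order, seed a cluster from every unassigned point using
# plain loops and explicit Euclidean distances
oracle_greedy_sites <- function(pos, capture_radius) {
  n <- nrow(pos)
  taken <- rep(FALSE, n)
  sites <- list()
  i <- 1
  while (i <= n) {
    if (!taken[i]) {
      members <- i
      for (j in seq_len(n)) {
        if (j != i && !taken[j]) {
          dx <- pos[i, 1] - pos[j, 1]
          dy <- pos[i, 2] - pos[j, 2]
          dz <- pos[i, 3] - pos[j, 3]
          if (sqrt(dx * dx + dy * dy + dz * dz) <= capture_radius)
            members <- c(members, j)
        }
      }
      if (length(members) >= 3) {
        members <- sort(members)
        for (m in members) taken[m] <- TRUE
        sites[[length(sites) + 1]] <- list(seed = i, members = members)
      }
    }
    i <- i + 1
  }
  sites
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

small_conditions <- function(...) solution_conditions(...)
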