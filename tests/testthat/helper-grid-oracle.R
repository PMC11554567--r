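# Brute-force grid-search oracle for the beta-binomial MLE, independent of
# the package's optimiser. Dense coarse grid followed by local refinement.

oracle_bb_ll <- function(k, n, pi, rho) {
  if (rho < 1e-9) return(sum(stats::dbinom(k, n, pi, log = TRUE)))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# log-likelihood of one group over a grid of pi values (fixed rho)
.oracle_ll_vec <- function(k, n, pi_grid, rho) {
  vapply(pi_grid, function(p) oracle_bb_ll(k, n, p, rho), numeric(1))
}

# H1 fit: per-group means, shared rho; 200 x 200 x 50 coarse grid with
# two local refinement passes (final spacing ~1e-4)
oracle_grid_alt <- function(k1, n1, k2, n2,
                            pi_grid = seq(1e-6, 1 - 1e-6, length.out = 200),
                            rho_grid = c(1e-9, seq(0.0001, 0.5,
                                                   length.out = 49))) {
  best <- list(ll = -Inf)
  for (r in rho_grid) {
    l1 <- .oracle_ll_vec(k1, n1, pi_grid, r)
    l2 <- .oracle_ll_vec(k2, n2, pi_grid, r)
    tot <- max(l1) + max(l2)
    if (tot > best$ll) {
      best <- list(ll = tot, pi1 = pi_grid[which.max(l1)],
                   pi2 = pi_grid[which.max(l2)], rho = r)
    }
  }
  for (pass in 1:2) {
    dp <- diff(range(pi_grid))[1] / length(pi_grid)
    dr <- diff(range(rho_grid))[1] / length(rho_grid)
    pg1 <- seq(max(1e-6, best$pi1 - 2 * dp), min(1 - 1e-6, best$pi1 + 2 * dp),
               length.out = 41)
    pg2 <- seq(max(1e-6, best$pi2 - 2 * dp), min(1 - 1e-6, best$pi2 + 2 * dp),
               length.out = 41)
    rg <- seq(max(1e-9, best$rho - 2 * dr), min(0.5, best$rho + 2 * dr),
              length.out = 41)
    for (r in rg) {
      l1 <- .oracle_ll_vec(k1, n1, pg1, r)
      l2 <- .oracle_ll_vec(k2, n2, pg2, r)
      tot <- max(l1) + max(l2)
      if (tot > best$ll) {
        best <- list(ll = tot, pi1 = pg1[which.max(l1)],
                     pi2 = pg2[which.max(l2)], rho = r)
      }
    }
    pi_grid <- pg1; rho_grid <- rg
  }
  best
}

# H0 fit: single shared mean and rho
oracle_grid_null <- function(k, n,
                             pi_grid = seq(1e-6, 1 - 1e-6, length.out = 200),
                             rho_grid = c(1e-9, seq(0.0001, 0.5,
                                                    length.out = 49))) {
  best <- list(ll = -Inf)
  for (r in rho_grid) {
    l <- .oracle_ll_vec(k, n, pi_grid, r)
    if (max(l) > best$ll) {
      best <- list(ll = max(l), pi = pi_grid[which.max(l)], rho = r)
    }
  }
  for (pass in 1:2) {
    dp <- diff(range(pi_grid))[1] / length(pi_grid)
    dr <- diff(range(rho_grid))[1] / length(rho_grid)
    pg <- seq(max(1e-6, best$pi - 2 * dp), min(1 - 1e-6, best$pi + 2 * dp),
              length.out = 41)
    rg <- seq(max(1e-9, best$rho - 2 * dr), min(0.5, best$rho + 2 * dr),
              length.out = 41)
    for (r in rg) {
      l <- .oracle_ll_vec(k, n, pg, r)
      if (max(l) > best$ll) {
        best <- list(ll = max(l), pi = pg[which.max(l)], rho = r)
      }
    }
    pi_grid <- pg; rho_grid <- rg
  }
  best
}
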