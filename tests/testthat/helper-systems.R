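# Fixtures are generated in code.  All randomness is seeded locally.

# random connected phased graph with n sites, random weights and phases
random_phased_graph <- function(n, p_edge = 0.5, phased = TRUE) {
  repeat {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    # always keep a ring so connectivity is likely
    ring <- (pairs[, 2] - pairs[, 1]) == 1
    keep <- keep | ring
    idx <- pairs[keep, , drop = FALSE]
    g <- phased_graph(
      paste0("n", seq_len(n)),
      data.frame(from = paste0("n", idx[, 1]), to = paste0("n", idx[, 2]),
                 weight = stats::runif(nrow(idx), 0.5, 2),
                 phase = if (phased) stats::runif(nrow(idx), -pi, pi) else 0))
    return(g)
  }
}

# random tree on n sites (random parent for each non-root node)
random_tree <- function(n, phased = TRUE) {
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  phased_graph(
    paste0("t", seq_len(n)),
    data.frame(from = paste0("t", parent[-1]), to = paste0("t", 2:n),
               weight = stats::runif(n - 1, 0.5, 2),
               phase = if (phased) stats::runif(n - 1, -pi, pi) else 0))
}

# independent Lindblad right-hand side, written directly from the master
# equation in matrix form (no superoperator), for use with deSolve::zvode
lindblad_rhs_oracle <- function(h, jump_ops) {
  function(t, y, parms) {
    rho <- matrix(y, nrow(h), nrow(h))
    d <- -1i * (h %*% rho - rho %*% h)
    for (jo in jump_ops) {
      l <- jo$op
      ldl <- Conj(t(l)) %*% l
      d <- d + jo$rate * (l %*% rho %*% Conj(t(l)) -
                            0.5 * (ldl %*% rho + rho %*% ldl))
    }
    list(as.vector(d))
  }
}

# occupancy series from the zvode oracle
zvode_occupancies <- function(h, jump_ops, init_index, times) {
  n <- nrow(h)
  rho0 <- matrix(0 + 0i, n, n)
  rho0[init_index, init_index] <- 1
  sol <- deSolve::zvode(as.vector(rho0), times, lindblad_rhs_oracle(h, jump_ops),
                        parms = NULL, atol = 1e-12, rtol = 1e-10)
  t(vapply(seq_along(times), function(k) {
    rho <- matrix(sol[k, -1], n, n)
    Re(diag(rho))
  }, numeric(n)))
}

expect_all_near <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
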