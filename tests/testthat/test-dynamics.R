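test_that("unitary propagation matches closed forms", {
  # t = 0: walker stays put
  set.seed(71)
  g <- random_phased_graph(5)
  tr <- evolve_unitary(g, "n3", 0)
  expect_equal(unname(tr$occupancy[1, ]), c(0, 0, 1, 0, 0))
  # two-site hopper: P_far(t) = sin^2(t)
  g2 <- phased_graph(c("x", "y"), data.frame(from = "x", to = "y",
                                             weight = 1))
  ts <- seq(0, 6, by = 0.2)
  tr2 <- evolve_unitary(g2, "x", ts)
  expect_all_near(tr2$occupancy[, "y"], sin(ts)^2, 1e-10)
  # probability conservation
  set.seed(72)
  for (rep in 1:5) {
    g3 <- random_phased_graph(6)
    occ <- evolve_unitary(g3, "n1", seq(0, 10, by = 0.5))$occupancy
    expect_all_near(rowSums(occ), 1, 1e-8)
  }
  expect_error(evolve_unitary(matrix(c(0, 1i, 1i, 0), 2, 2), "1", 1),
               "Hermitian")
})

test_that("a pi flux on an even cycle blocks the antipodal site", {
  g <- make_cycle(6, pi_edge = TRUE)
  ts <- seq(0, 50, by = 0.05)
  occ <- evolve_unitary(g, "1", ts)$occupancy[, "4"]
  expect_lt(max(occ), 1e-10)
  # the achiral ring does transport there
  occ0 <- evolve_unitary(make_cycle(6), "1", ts)$occupancy[, "4"]
  expect_gt(max(occ0), 0.1)
})

test_that("lindblad evolution reduces to known limits", {
  g <- phased_graph(c("x", "y"), data.frame(from = "x", to = "y",
                                            weight = 1))
  ts <- seq(0, 5, by = 0.25)
  # no channels: agrees with unitary evolution
  tru <- evolve_unitary(g, "x", ts)
  trl <- evolve_lindblad(g, lindblad_spec(), "x", ts)
  expect_all_near(trl$occupancy[, c("x", "y")], tru$occupancy, 1e-8)
  # pure decay into a sink: P_src(t) = exp(-t)
  iso <- phased_graph(c("x", "y"))
  trd <- evolve_lindblad(iso, lindblad_spec(sinks = data.frame(site = "x",
                                                               rate = 1)),
                         "x", ts)
  expect_all_near(trd$occupancy[, "x"], exp(-ts), 1e-8)
  expect_all_near(trd$occupancy[, "sink_x"], 1 - exp(-ts), 1e-8)
  expect_error(lindblad_spec(sinks = data.frame(site = "x", rate = -1)),
               ">= 0")
  expect_error(evolve_lindblad(g, lindblad_spec(), "x", c(-1, 0)),
               "backward")
})

test_that("both propagation routes match an independent ODE oracle", {
  set.seed(81)
  ts <- seq(0, 4, by = 0.25)
  for (rep in 1:3) {
    g <- random_phased_graph(4)
    h <- to_hamiltonian(g)
    # two site-to-site channels plus dephasing -> full Liouvillian route
    spec <- lindblad_spec(
      channels = data.frame(from = c("n2", "n4"), to = c("n1", "n3"),
                            rate = c(0.4, 0.7)),
      dephasing = c(n1 = 0.2, n2 = 0, n3 = 0.1, n4 = 0))
    tr <- evolve_lindblad(g, spec, "n1", ts)
    jumps <- list()
    mk <- function(i, j) {
      l <- matrix(0 + 0i, 4, 4)
      l[j, i] <- 1
      l
    }
    jumps <- list(list(op = mk(2, 1), rate = 0.4),
                  list(op = mk(4, 3), rate = 0.7),
                  list(op = mk(1, 1), rate = 0.2),
                  list(op = mk(3, 3), rate = 0.1))
    oracle <- zvode_occupancies(h, jumps, 1, ts)
    expect_all_near(tr$occupancy, oracle, 1e-7)
  }
  # pure-loss fast path vs the same oracle with an explicit sink state
  g <- random_phased_graph(4)
  spec <- lindblad_spec(sinks = data.frame(site = c("n2", "n4"),
                                           rate = c(0.5, 1.2)))
  tr <- evolve_lindblad(g, spec, "n1", ts)
  h5 <- matrix(0 + 0i, 6, 6)
  h5[1:4, 1:4] <- to_hamiltonian(g)
  mk6 <- function(i, j) {
    l <- matrix(0 + 0i, 6, 6)
    l[j, i] <- 1
    l
  }
  oracle <- zvode_occupancies(h5, list(list(op = mk6(2, 5), rate = 0.5),
                                       list(op = mk6(4, 6), rate = 1.2)),
                              1, ts)
  expect_all_near(tr$occupancy[, c("n1", "n2", "n3", "n4")],
                  oracle[, 1:4], 1e-7)
  expect_all_near(tr$occupancy[, c("sink_n2", "sink_n4")],
                  oracle[, 5:6], 1e-7)
})

test_that("explicit density-matrix initial states are accepted and validated", {
  g <- phased_graph(c("x", "y"), data.frame(from = "x", to = "y",
                                            weight = 1))
  spec <- lindblad_spec(sinks = data.frame(site = "y", rate = 0.5))
  ts <- seq(0, 3, by = 0.5)
  rho0 <- matrix(0 + 0i, 3, 3)   # sites + 1 sink state
  rho0[1, 1] <- 1
  a <- evolve_lindblad(g, spec, rho0, ts)$occupancy
  b <- evolve_lindblad(g, spec, "x", ts)$occupancy
  expect_all_near(a, b, 1e-8)
  # a mixed state is fine; invalid matrices are rejected
  rho_mix <- diag(c(0.5 + 0i, 0.5 + 0i, 0))
  tr <- evolve_lindblad(g, spec, rho_mix, ts)
  expect_all_near(rowSums(tr$occupancy), 1, 1e-8)
  expect_error(evolve_lindblad(g, spec, 2 * rho0, ts), "trace")
  bad <- rho0
  bad[1, 2] <- 0.2 + 0i
  expect_error(evolve_lindblad(g, spec, bad, ts), "Hermitian")
})

test_that("density matrices stay physical along lindblad trajectories", {
  set.seed(91)
  g <- random_phased_graph(5)
  spec <- lindblad_spec(sinks = data.frame(site = "n5", rate = 0.8),
                        dephasing = c(n1 = 0.1, n2 = 0.1, n3 = 0.1,
                                      n4 = 0.1, n5 = 0.1))
  ts <- seq(0, 15, by = 0.5)
  tr <- evolve_lindblad(g, spec, "n1", ts)
  expect_true(all(tr$occupancy > -1e-8))
  expect_true(all(tr$occupancy < 1 + 1e-8))
  expect_all_near(rowSums(tr$occupancy), 1, 1e-6)
  # sink filling is monotone
  expect_true(all(diff(tr$occupancy[, "sink_n5"]) > -1e-10))
})

test_that("time reversal conjugates the Hamiltonian and reverses roles", {
  # achiral fixed point
  g0 <- phased_graph(c("a", "b"), data.frame(from = "a", to = "b",
                                             weight = 1.3))
  expect_equal(time_reverse(to_hamiltonian(g0)), to_hamiltonian(g0))
  # phases negate
  tri <- phased_graph(c("a", "b", "c"),
                      data.frame(from = c("a", "b", "a"),
                                 to = c("b", "c", "c"), weight = 1,
                                 phase = c(0, 0, 0.6)))
  expect_equal(time_reverse(tri)$edges$phase, c(0, -0.6, 0))
  # STP of the reversed walk at t equals the original at -t
  set.seed(101)
  g <- random_phased_graph(6)
  ts <- seq(0.3, 6, length.out = 20)
  a <- evolve_unitary(time_reverse(to_hamiltonian(g)), "n2", ts)$occupancy
  b <- evolve_unitary(g, "n2", -ts)$occupancy
  expect_all_near(a, b, 1e-9)
})

test_that("check_trs distinguishes symmetric and chiral transport", {
  ts <- seq(0.2, 8, length.out = 25)
  # achiral: all three series coincide
  set.seed(111)
  g0 <- random_phased_graph(5, phased = FALSE)
  r0 <- check_trs(g0, "n1", "n4", ts)
  expect_true(r0$trs)
  expect_lt(max(abs(r0$forward - r0$reversed)), 1e-9)
  # bipartite with phases: still time symmetric
  cyc <- make_cycle(6)
  cyc <- set_edge_phase(cyc, rbind(c("1", "2"), c("3", "4")), c(1.0, -0.4))
  rb <- check_trs(cyc, "1", "4", ts)
  expect_true(rb$trs)
  # the general identity P_SE(-t) = P_ES(t) holds even for chiral walks
  g <- random_phased_graph(6)
  rg <- check_trs(g, "n1", "n5", ts)
  expect_lt(rg$max_identity_residual, 1e-9)
  # the switch at theta = -pi/2 violates TRS
  sw <- make_switch(-pi / 2)
  rs <- check_trs(sw$graph, "S", "E", ts)
  expect_false(rs$trs)
  expect_lt(rs$max_identity_residual, 1e-9)
})
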