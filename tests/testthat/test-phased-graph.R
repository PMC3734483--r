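test_that("construction enforces the structural invariants", {
  expect_error(phased_graph(c("a", "a")), "duplicate")
  expect_error(phased_graph(c("a", "b"),
                            data.frame(from = "a", to = "a", weight = 1)),
               "self-loop")
  expect_error(phased_graph(c("a", "b"),
                            data.frame(from = "a", to = "b", weight = 0)),
               "positive")
  expect_error(phased_graph(c("a", "b"),
                            data.frame(from = c("a", "b"), to = c("b", "a"),
                                       weight = 1)),
               "duplicate")
  # reversed input orientation negates the stored phase
  g <- phased_graph(c("a", "b"),
                    data.frame(from = "b", to = "a", weight = 1, phase = 0.7))
  expect_equal(g$edges$from, "a")
  expect_equal(g$edges$phase, -0.7)
  # phases wrap into (-pi, pi]
  g2 <- phased_graph(c("a", "b"),
                     data.frame(from = "a", to = "b", weight = 1,
                                phase = 3 * pi))
  expect_equal(g2$edges$phase, pi)
})

test_that("to_hamiltonian realizes the phase convention", {
  # empty graph
  g0 <- phased_graph(c("a", "b"))
  expect_equal(to_hamiltonian(g0), matrix(0 + 0i, 2, 2,
                                          dimnames = list(c("a", "b"),
                                                          c("a", "b"))))
  # achiral limit: real symmetric adjacency plus diagonal
  set.seed(11)
  g1 <- random_phased_graph(5, phased = FALSE)
  g1$energy[] <- stats::rnorm(5)
  h1 <- to_hamiltonian(g1)
  expect_true(all(Im(h1) == 0))
  expect_equal(h1, t(h1))
  expect_equal(unname(Re(diag(h1))), unname(g1$energy))
  # triangle with one phased edge: exactly one complex off-diagonal pair
  th <- 1.1
  g2 <- phased_graph(c("a", "b", "c"),
                     data.frame(from = c("a", "b", "a"),
                                to = c("b", "c", "c"), weight = 1,
                                phase = c(0, 0, th)))
  h2 <- to_hamiltonian(g2)
  expect_equal(h2["a", "c"], exp(1i * th))
  expect_equal(h2["c", "a"], exp(-1i * th))
  expect_equal(h2["a", "b"], 1 + 0i)
  expect_equal(Mod(h2["a", "c"]), 1)
})

test_that("hamiltonians are always Hermitian with edge-weight moduli", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_phased_graph(sample(3:8, 1))
    h <- to_hamiltonian(g)
    expect_lt(max(Mod(h - Conj(t(h)))), 1e-12)
    for (r in seq_len(nrow(g$edges)))
      expect_equal(Mod(h[g$edges$from[r], g$edges$to[r]]), g$edges$weight[r])
  }
})

test_that("gauge transformations shift phases and cancel single edges", {
  g <- phased_graph(c("a", "b"),
                    data.frame(from = "a", to = "b", weight = 1, phase = 0.9))
  expect_equal(apply_gauge(g, c(0, 0)), g)
  # alpha = -theta on the tail endpoint removes the phase
  g0 <- apply_gauge(g, c(a = -0.9, b = 0))
  expect_equal(g0$edges$phase, 0)
  expect_equal(g0$edges$weight, g$edges$weight)
  expect_error(apply_gauge(g, c(1, 2, 3)), "length")
})

test_that("transfer probabilities are gauge invariant", {
  set.seed(31)
  ts <- seq(0.25, 8, length.out = 20)
  g <- random_phased_graph(6)
  base <- evolve_unitary(g, g$sites[1], ts)$occupancy
  for (rep in 1:20) {
    al <- stats::runif(6, -pi, pi)
    occ <- evolve_unitary(apply_gauge(g, al), g$sites[1], ts)$occupancy
    expect_all_near(occ, base, 1e-9)
  }
})

test_that("loop phase sums behave as fluxes", {
  tri <- phased_graph(c("a", "b", "c"),
                      data.frame(from = c("a", "b", "a"),
                                 to = c("b", "c", "c"),
                                 weight = 1, phase = 0))
  expect_equal(loop_phase_sum(tri, c("a", "b", "c")), 0)
  # 4-cycle with a single pi link
  sq <- make_cycle(4, pi_edge = TRUE)
  expect_equal(loop_phase_sum(sq, as.character(1:4)), pi)
  # orientation reversal flips the sign
  tri2 <- phased_graph(c("a", "b", "c"),
                       data.frame(from = c("a", "b", "a"),
                                  to = c("b", "c", "c"),
                                  weight = 1, phase = c(0.3, 0.4, 0.2)))
  expect_equal(loop_phase_sum(tri2, c("a", "b", "c")),
               -loop_phase_sum(tri2, c("c", "b", "a")))
  # a back-and-forth closed walk is legal and sums to zero
  expect_equal(loop_phase_sum(tri2, c("a", "b")), 0)
  path <- phased_graph(c("p", "q", "r"),
                       data.frame(from = c("p", "q"), to = c("q", "r"),
                                  weight = 1))
  expect_error(loop_phase_sum(path, c("p", "q", "r")), "no edge")
  # invariance under 100 random gauges
  set.seed(41)
  flux <- loop_phase_sum(tri2, c("a", "b", "c"))
  for (rep in 1:100) {
    g2 <- apply_gauge(tri2, stats::runif(3, -pi, pi))
    expect_equal(loop_phase_sum(g2, c("a", "b", "c")), flux,
                 tolerance = 1e-12)
  }
})

test_that("tree phases are removable and transport-trivial", {
  # achiral tree is left untouched
  set.seed(51)
  t0 <- random_tree(6, phased = FALSE)
  out0 <- remove_tree_phases(t0)
  expect_equal(out0$graph, t0)
  expect_true(all(unclass(out0$gauge) == 0))
  # phased path: all phases removed, gauge reproduces the output
  path <- phased_graph(paste0("p", 1:4),
                       data.frame(from = paste0("p", 1:3),
                                  to = paste0("p", 2:4), weight = 1,
                                  phase = stats::runif(3, -pi, pi)))
  out <- remove_tree_phases(path)
  expect_equal(max(abs(out$graph$edges$phase)), 0)
  expect_equal(apply_gauge(path, out$gauge), out$graph)
  # transport from root to every leaf matches the achiral tree
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    tr <- random_tree(n)
    ach <- tr
    ach$edges$phase <- 0
    ts <- seq(0.5, 6, length.out = 10)
    o1 <- evolve_unitary(tr, tr$sites[1], ts)$occupancy
    o2 <- evolve_unitary(ach, tr$sites[1], ts)$occupancy
    expect_all_near(o1, o2, 1e-9)
  }
  expect_error(remove_tree_phases(make_cycle(4)), "tree")
})

test_that("spanning-tree normalization preserves fundamental fluxes", {
  set.seed(61)
  # a tree input reduces to remove_tree_phases
  tr <- random_tree(7)
  expect_equal(normalize_spanning_tree(tr), remove_tree_phases(tr))
  # triangle: flux on different edges normalizes to the same canonical form
  mk_tri <- function(phases) phased_graph(
    c("a", "b", "c"), data.frame(from = c("a", "b", "a"),
                                 to = c("b", "c", "c"),
                                 weight = 1, phase = phases))
  th <- 0.8
  n1 <- normalize_spanning_tree(mk_tri(c(th, 0, 0)))
  n2 <- normalize_spanning_tree(mk_tri(c(0, th, 0)))
  expect_equal(n1$graph, n2$graph)
  # random connected graph: all fundamental-cycle sums preserved
  for (rep in 1:5) {
    g <- random_phased_graph(7)
    nrm <- normalize_spanning_tree(g)$graph
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$sites)
    # fundamental cycles via paths in the normalized graph's zero-phase tree
    for (r in seq_len(nrow(g$edges))) {
      cyc <- igraph::shortest_paths(
        igraph::delete_edges(ig, r), from = g$edges$from[r],
        to = g$edges$to[r])$vpath[[1]]
      if (length(cyc) < 2) next
      cyc <- names(cyc)
      expect_equal(loop_phase_sum(nrm, cyc), loop_phase_sum(g, cyc),
                   tolerance = 1e-12)
    }
  }
})
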