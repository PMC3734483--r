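# Ready-made model systems: the directional quantum switch, chains of
# triangular switches, cycles, small-world / scale-free ensembles and a
# seven-site FMO exciton model.

#' The directional quantum switch
#'
#' A central triangle of unit couplings with three linear wires ending at
#' the poles S (input), E and F (outputs).  A single control edge across
#' the junction carries the phase `theta`; at `theta = 0` the system is
#' mirror-symmetric in E and F, and the maximal directional biasing occurs
#' at \eqn{|\theta| = \pi/2}, with `theta = -pi/2` steering the walker
#' toward E and `theta = +pi/2` toward F (swapping the sign exactly swaps
#' the E and F trajectories).
#'
#' The default geometry — a one-site input wire and two-site output wires —
#' is the package's documented reference configuration for all quoted
#' switch numbers; transport biasing itself is largely independent of the
#' wire lengths.
#'
#' @param theta control-edge phase (radians).
#' @param pole_wire sites per output wire (E and F), >= 1.
#' @param source_wire sites on the input wire, >= 1.
#' @param sinks attach absorbing sinks at both poles E and F?
#' @param sink_rate absorption rate of each sink.
#' @return A `cqw_system` with `source = "S"`, `target = "E"` (or
#'   `"sink_E"` when sinks are attached) and the control edge recorded.
#' @export
make_switch <- function(theta = 0, pole_wire = 2, source_wire = 1,
                        sinks = FALSE, sink_rate = 1) {
  stopifnot(pole_wire >= 1, source_wire >= 1)
  wire <- function(prefix, len, pole) {
    if (len == 1) pole else c(paste0(prefix, seq_len(len - 1)), pole)
  }
  s_wire <- wire("s", source_wire, "S")
  e_wire <- wire("e", pole_wire, "E")
  f_wire <- wire("f", pole_wire, "F")
  sites <- c("JS", "JF", "JE", s_wire, e_wire, f_wire)
  chain <- function(from, wire_sites) {
    data.frame(from = c(from, wire_sites[-length(wire_sites)]),
               to = wire_sites, weight = 1, phase = 0)
  }
  edges <- rbind(
    data.frame(from = c("JS", "JS", "JF"), to = c("JF", "JE", "JE"),
               weight = 1, phase = c(0, 0, theta)),
    chain("JS", s_wire), chain("JE", e_wire), chain("JF", f_wire))
  g <- phased_graph(sites, edges)
  lb <- if (sinks) lindblad_spec(sinks = data.frame(
    site = c("E", "F"), rate = sink_rate)) else NULL
  sys <- cqw_system(g, lb, source = "S",
                    target = if (sinks) "sink_E" else "E",
                    control_edges = cbind(from = "JF", to = "JE"))
  sys$theta <- theta
  sys
}

#' Chain of corner-sharing triangular switches
#'
#' `n_triangles` triangles in a row, consecutive triangles sharing one
#' corner: corners `V1 ... E` joined by a path of base edges, with apex
#' `Wi` above each base edge.  The walker is injected through a one-site
#' input wire S attached to the first corner; the far corner is labelled
#' `E`.  One control edge per triangle (the `Vi - Wi` slant, the
#' translational image across the chain) carries a common phase `theta`;
#' `theta = -pi/2` maximally speeds up transport toward E and
#' `theta = +pi/2` maximally suppresses it, symmetric about
#' \eqn{\pm\pi/2}.  With `trap = TRUE` an absorbing sink (label
#' `"sink_E"`) collects the walker at E.
#'
#' @param n_triangles number of triangles, >= 1 (default 8).
#' @param theta common control phase (radians).
#' @param trap attach the absorbing trap at E?
#' @param trap_rate trap rate (coupling units); the package's documented
#'   calibration for all quoted chain numbers is the unit rate.
#' @return A `cqw_system` with `source = "S"`, `target` either `"E"` or
#'   `"sink_E"`, and the control edges recorded.
#' @export
make_triangle_chain <- function(n_triangles = 8, theta = 0, trap = FALSE,
                                trap_rate = 1) {
  stopifnot(n_triangles >= 1)
  nt <- n_triangles
  corners <- c(paste0("V", seq_len(nt)), "E")
  apexes <- paste0("W", seq_len(nt))
  sites <- c("S", corners, apexes)
  edges <- rbind(
    data.frame(from = "S", to = corners[1], weight = 1, phase = 0),
    data.frame(from = corners[seq_len(nt)], to = corners[seq_len(nt) + 1],
               weight = 1, phase = 0),                       # base path
    data.frame(from = corners[seq_len(nt)], to = apexes,
               weight = 1, phase = theta),                   # control slants
    data.frame(from = apexes, to = corners[seq_len(nt) + 1],
               weight = 1, phase = 0))
  g <- phased_graph(sites, edges)
  lb <- if (trap) lindblad_spec(sinks = data.frame(site = "E",
                                                   rate = trap_rate)) else NULL
  sys <- cqw_system(g, lb, source = "S",
                    target = if (trap) "sink_E" else "E",
                    control_edges = cbind(from = corners[seq_len(nt)],
                                          to = apexes))
  sys$theta <- theta
  sys
}

#' Unit-weight cycle, optionally with one pi-phase edge
#'
#' On even cycles a single \eqn{\pi} phase (half-quantum flux) makes the
#' transfer probability to the diametrically opposite site exactly zero at
#' all times, by destructive interference of the two arms; odd cycles can
#' only redistribute transport, never suppress it completely.
#'
#' @param n_sites ring length, >= 3.
#' @param pi_edge put phase \eqn{\pi} on one link?
#' @return A `phased_graph` with sites `"1" ... "<n>"`; the phased link,
#'   if any, is `("1", "2")`.
#' @export
make_cycle <- function(n_sites, pi_edge = FALSE) {
  stopifnot(n_sites >= 3)
  s <- as.character(seq_len(n_sites))
  edges <- data.frame(from = s, to = c(s[-1], s[1]), weight = 1, phase = 0)
  if (pi_edge) edges$phase[1] <- pi
  phased_graph(s, edges)
}

# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.from_igraph <- function(ig) {
  el <- igraph::as_edgelist(ig, names = FALSE)
  n <- igraph::vcount(ig)
  phased_graph(as.character(seq_len(n)),
               data.frame(from = as.character(el[, 1]),
                          to = as.character(el[, 2]),
                          weight = 1, phase = 0))
}

# maximally distant ("oppositely aligned") source/target pair, ties broken
# by the lexicographically smallest index pair
.opposite_pair <- function(ig) {
  d <- igraph::distances(ig)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  c(best[1, 1], best[1, 2])
}

#' Watts-Strogatz small-world graph
#'
#' A connected realization of the Watts-Strogatz model: a ring lattice of
#' `n` nodes each coupled to its `k` nearest neighbours, rewired with
#' probability `p`.  Unit weights, zero phases.  Source and target are the
#' maximally distant node pair (lowest-index pair on ties).  Disconnected
#' draws are regenerated with an incremented sub-seed.
#'
#' @param n nodes (default 32).
#' @param k mean degree, even (default 4).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed; fixed seed gives an identical graph.
#' @param max_retries regeneration cap for disconnected draws.
#' @return A `cqw_system` (no sinks attached) with attributes `p` and
#'   `seed`.
#' @export
make_watts_strogatz <- function(n = 32, k = 4, p, seed, max_retries = 100) {
  stopifnot(k %% 2 == 0, p >= 0, p <= 1)
  for (attempt in 0:max_retries) {
    ig <- .with_seed(seed + attempt, .ws_graph(n, k, p))
    if (igraph::is_connected(ig)) {
      pair <- .opposite_pair(ig)
      sys <- cqw_system(.from_igraph(ig), source = as.character(pair[1]),
                        target = as.character(pair[2]))
      attr(sys, "p") <- p
      attr(sys, "seed") <- seed + attempt
      return(sys)
    }
  }
  stop("no connected realization within the retry cap")
}

# Canonical Watts-Strogatz rewiring: start from the ring lattice and, for
# each node's own k/2 clockwise edges, replace the far endpoint with a
# uniformly random node with probability p (avoiding loops and duplicate
# edges).  Every node keeps the near end of its own ring edges, so degrees
# never drop below k/2.
.ws_graph <- function(n, k, p) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(k / 2)) {
    t0 <- (i + j - 1) %% n + 1
    adj[i, t0] <- adj[t0, i] <- TRUE
  }
  for (i in seq_len(n)) for (j in seq_len(k / 2)) {
    t0 <- (i + j - 1) %% n + 1
    if (stats::runif(1) < p && adj[i, t0]) {
      free <- which(!adj[i, ] & seq_len(n) != i)
      if (length(free)) {
        t1 <- free[sample.int(length(free), 1)]
        adj[i, t0] <- adj[t0, i] <- FALSE
        adj[i, t1] <- adj[t1, i] <- TRUE
      }
    }
  }
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Barabasi-Albert scale-free graph
#'
#' Preferential-attachment graph with `m` edges added per node; connected
#' by construction.  Roles chosen as in [make_watts_strogatz()].
#'
#' @param n nodes.
#' @param m edges attached by each incoming node.
#' @param seed integer seed.
#' @return A `cqw_system` (no sinks attached).
#' @export
make_barabasi_albert <- function(n, m, seed) {
  ig <- .with_seed(seed, igraph::sample_pa(n, m = m, directed = FALSE))
  pair <- .opposite_pair(ig)
  sys <- cqw_system(.from_igraph(ig), source = as.character(pair[1]),
                    target = as.character(pair[2]))
  attr(sys, "seed") <- seed
  sys
}

#' Load a seven-site FMO exciton model from a config file
#'
#' Builds the standard open-system description of exciton transport in the
#' Fenna-Matthews-Olson pigment-protein complex: seven sites with
#' literature site energies and couplings (supplied in cm^-1 by the config
#' file and converted to angular frequencies), per-site pure dephasing, an
#' irreversible trapping channel from site 3 into a reaction-centre sink,
#' and slow exciton recombination from every site into a loss sink.
#' Negative couplings are represented as edges of weight |J| and phase
#' \eqn{\pi}.  The config also names two edge subsets (`A1`, seven
#' strongest couplings; `A2`, three strongest) used for phase
#' optimization.
#'
#' @param config_path path to a YAML config; defaults to the packaged
#'   example (`inst/extdata/fmo_adolphs_renger.yaml`, parameters from
#'   Adolphs & Renger 2006 with standard trapping/dephasing rates).
#' @return A `cqw_system` with extra fields `edge_sets` (oriented edge
#'   matrices `A1`, `A2`) and `config` (the parsed file).
#' @export
load_fmo <- function(config_path = NULL) {
  if (is.null(config_path))
    config_path <- system.file("extdata", "fmo_adolphs_renger.yaml",
                               package = "chiralwalk")
  cfg <- yaml::read_yaml(config_path)
  need <- c("site_energies", "couplings", "conversion_rad_per_time",
            "dephasing_rate", "trap", "recombination_rate", "initial_site")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("FMO config lacks field(s): ",
                         paste(miss, collapse = ", "))
  conv <- cfg$conversion_rad_per_time
  en <- as.numeric(cfg$site_energies)
  nsite <- length(en)
  sites <- as.character(seq_len(nsite))
  cp <- do.call(rbind, lapply(cfg$couplings, function(x)
    data.frame(from = as.character(x[[1]]), to = as.character(x[[2]]),
               j = as.numeric(x[[3]]))))
  if (anyDuplicated(paste(pmin(cp$from, cp$to), pmax(cp$from, cp$to))))
    stop("duplicate coupling entries (non-Hermitian coupling table)")
  edges <- data.frame(from = cp$from, to = cp$to,
                      weight = abs(cp$j) * conv,
                      phase = ifelse(cp$j < 0, pi, 0))
  g <- phased_graph(sites, edges,
                    energy = stats::setNames(en * conv, sites))
  sinks <- rbind(
    data.frame(site = as.character(cfg$trap$site), rate = cfg$trap$rate,
               label = if (is.null(cfg$trap$label)) "RC" else cfg$trap$label),
    data.frame(site = sites, rate = cfg$recombination_rate, label = "loss"))
  lb <- lindblad_spec(sinks = sinks, dephasing = cfg$dephasing_rate)
  sys <- cqw_system(g, lb, source = as.character(cfg$initial_site),
                    target = if (is.null(cfg$target)) "RC" else cfg$target)
  sys$edge_sets <- lapply(cfg$edge_sets, function(set)
    do.call(rbind, lapply(set, function(e)
      c(from = as.character(e[[1]]), to = as.character(e[[2]])))))
  sys$config <- cfg
  sys
}
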