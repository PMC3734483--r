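#' Weighted graphs with complex hopping phases
#'
#' A `phased_graph` is an undirected, weighted graph in which every edge
#' additionally carries a phase angle.  It is the parameter set of a
#' continuous-time chiral quantum walk: hopping magnitudes \eqn{J_{nm} > 0},
#' edge phases \eqn{\theta_{nm}} (antisymmetric under orientation reversal,
#' \eqn{\theta_{mn} = -\theta_{nm}}), and real on-site energies
#' \eqn{\epsilon_n}.  Phases are stored on the canonical orientation of each
#' edge, which runs from the lower-indexed site to the higher-indexed site,
#' and are always reduced to the interval \eqn{(-\pi, \pi]}.
#'
#' @param sites character vector of site labels (order fixes site indices
#'   and hence canonical edge orientations).
#' @param edges data frame with columns `from`, `to` (site labels),
#'   `weight` (positive hopping magnitude) and optionally `phase`
#'   (radians, default 0, interpreted on the `from -> to` orientation).
#' @param energy named numeric vector of on-site energies; sites not named
#'   default to 0.  May be `NULL`.
#'
#' @return An object of class `phased_graph` with components `sites`,
#'   `edges` (canonically oriented) and `energy`.
#' @examples
#' g <- phased_graph(c("a", "b", "c"),
#'                   data.frame(from = c("a", "b", "a"),
#'                              to   = c("b", "c", "c"),
#'                              weight = 1,
#'                              phase = c(0, 0, pi / 2)))
#' to_hamiltonian(g)
#' @export
phased_graph <- function(sites, edges = NULL, energy = NULL) {
  sites <- as.character(sites)
  if (anyDuplicated(sites)) stop("duplicate site labels")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), phase = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$phase)) edges$phase <- 0
    edges <- edges[, c("from", "to", "weight", "phase")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  g <- structure(list(sites = sites, edges = edges,
                      energy = .full_energy(energy, sites)),
                 class = "phased_graph")
  validate_phased_graph(.canonicalize(g))
}

.full_energy <- function(energy, sites) {
  out <- stats::setNames(rep(0, length(sites)), sites)
  if (!is.null(energy) && length(energy)) {
    if (is.null(names(energy))) {
      if (length(energy) != length(sites))
        stop("unnamed `energy` must have one entry per site")
      names(energy) <- sites
    }
    bad <- setdiff(names(energy), sites)
    if (length(bad)) stop("energy given for unknown site(s): ",
                          paste(bad, collapse = ", "))
    out[names(energy)] <- energy
  }
  out
}

# reduce angles to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi   # in [-pi, pi)
  y[y == -pi] <- pi                # closed at +pi, open at -pi
  y
}

# put every edge on the lower-index -> higher-index orientation
.canonicalize <- function(g) {
  e <- g$edges
  if (nrow(e)) {
    i <- match(e$from, g$sites)
    j <- match(e$to, g$sites)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not in site list")
    flip <- i > j
    if (any(flip)) {
      tmp <- e$from[flip]
      e$from[flip] <- e$to[flip]
      e$to[flip] <- tmp
      e$phase[flip] <- -e$phase[flip]
    }
    e$phase <- wrap_angle(e$phase)
    o <- order(match(e$from, g$sites), match(e$to, g$sites))
    g$edges <- e[o, , drop = FALSE]
    rownames(g$edges) <- NULL
  }
  g
}

#' Validate a phased graph
#'
#' Checks the structural invariants: positive weights, no self-loops, no
#' duplicate edges, endpoints present in the site list, phases in
#' \eqn{(-\pi, \pi]}.
#'
#' @param g a `phased_graph`.
#' @return `g`, invisibly unchanged, or an error.
#' @export
validate_phased_graph <- function(g) {
  stopifnot(inherits(g, "phased_graph"))
  e <- g$edges
  if (nrow(e)) {
    if (any(e$from == e$to)) stop("self-loops are not allowed")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      stop("edge weights must be strictly positive")
    key <- paste(e$from, e$to)
    if (anyDuplicated(key)) stop("duplicate edges")
    if (any(e$phase <= -pi - 1e-12 | e$phase > pi + 1e-12))
      stop("phases must lie in (-pi, pi]")
  }
  g
}

#' @export
print.phased_graph <- function(x, ...) {
  cat(sprintf("<phased_graph> %d sites, %d edges", length(x$sites),
              nrow(x$edges)))
  nch <- sum(abs(x$edges$phase) > 1e-12)
  if (nch) cat(sprintf(" (%d phased)", nch))
  if (any(abs(x$energy) > 1e-12)) cat(", on-site energies set")
  cat("\n")
  invisible(x)
}

n_sites <- function(g) length(g$sites)

site_index <- function(g, site) {
  i <- match(as.character(site), g$sites)
  if (anyNA(i)) stop("unknown site(s): ",
                     paste(site[is.na(i)], collapse = ", "))
  i
}

# row index of an edge regardless of orientation; NA if absent
edge_row <- function(g, from, to) {
  key <- paste(g$edges$from, g$edges$to)
  i <- match(paste(from, to), key)
  j <- match(paste(to, from), key)
  ifelse(is.na(i), j, i)
}

#' Build the walk Hamiltonian of a phased graph
#'
#' Every edge contributes \eqn{J e^{i\theta}} to the matrix element
#' \eqn{\langle n|H|m\rangle} on its canonical orientation \eqn{n \to m}
#' (and the conjugate on the reverse).  On-site energies appear on the
#' diagonal.  With all phases zero this reduces to the weighted adjacency
#' matrix of an ordinary (achiral) continuous-time quantum walk.
#'
#' @param g a `phased_graph`.
#' @return A complex Hermitian matrix with site labels as dimnames.
#' @export
to_hamiltonian <- function(g) {
  n <- n_sites(g)
  h <- matrix(0 + 0i, n, n, dimnames = list(g$sites, g$sites))
  diag(h) <- g$energy + 0i
  e <- g$edges
  if (nrow(e)) {
    i <- match(e$from, g$sites)
    j <- match(e$to, g$sites)
    h[cbind(i, j)] <- e$weight * exp(1i * e$phase)
    h[cbind(j, i)] <- e$weight * exp(-1i * e$phase)
  }
  h
}

#' Gauge vectors
#'
#' A gauge vector assigns one angle \eqn{\alpha_n} per site and defines the
#' diagonal unitary \eqn{U = \mathrm{diag}(e^{i\alpha_n})}.  Conjugating the
#' walk Hamiltonian by \eqn{U} leaves weights, energies and all site-to-site
#' transfer probabilities unchanged while shifting edge phases
#' (see [apply_gauge()]).
#'
#' @param alpha numeric vector of angles (radians), optionally named by site.
#' @param g optional `phased_graph` used to validate length/names.
#' @return A named numeric vector of class `gauge_vector`, reduced to
#'   \eqn{(-\pi, \pi]}.
#' @export
gauge_vector <- function(alpha, g = NULL) {
  if (!is.null(g)) {
    if (is.null(names(alpha))) {
      if (length(alpha) != n_sites(g))
        stop("gauge vector length does not match number of sites")
      names(alpha) <- g$sites
    } else {
      if (!setequal(names(alpha), g$sites))
        stop("gauge vector names do not match graph sites")
      alpha <- alpha[g$sites]
    }
  }
  structure(wrap_angle(alpha), class = "gauge_vector")
}

#' Apply a gauge transformation to a phased graph
#'
#' Under the diagonal unitary \eqn{U = \mathrm{diag}(e^{i\alpha_n})} the
#' Hamiltonian maps to \eqn{U H U^\dagger}, so the phase of the canonical
#' edge \eqn{n \to m} shifts as
#' \eqn{\theta_{nm} \mapsto \theta_{nm} + \alpha_n - \alpha_m}.  Weights and
#' on-site energies are untouched.  Setting \eqn{\alpha_n = -\theta} on the
#' tail of a single phased edge (all other angles 0) cancels that phase.
#'
#' @param g a `phased_graph`.
#' @param alpha a [gauge_vector()] or plain numeric vector (one angle per
#'   site, in site order, or named by site).
#' @return The gauged `phased_graph`.
#' @export
apply_gauge <- function(g, alpha) {
  alpha <- gauge_vector(unclass(alpha), g)
  e <- g$edges
  if (nrow(e)) {
    e$phase <- wrap_angle(e$phase + alpha[e$from] - alpha[e$to])
    g$edges <- e
  }
  validate_phased_graph(g)
}

#' Oriented phase sum along a closed walk
#'
#' Sums edge phases along the cycle in the order given, counting a phase
#' positively when the step follows the canonical edge orientation and
#' negatively otherwise.  Loop sums are the gauge invariants of a phased
#' graph: they are unchanged by any [apply_gauge()] call.
#'
#' @param g a `phased_graph`.
#' @param cycle vector of site labels; the walk is closed implicitly
#'   (last site connects back to the first).
#' @return The loop phase, reduced to \eqn{(-\pi, \pi]}.
#' @export
loop_phase_sum <- function(g, cycle) {
  cycle <- as.character(cycle)
  if (length(cycle) < 2) stop("a cycle needs at least two sites")
  site_index(g, cycle)
  from <- cycle
  to <- c(cycle[-1], cycle[1])
  total <- 0
  for (k in seq_along(from)) {
    r <- edge_row(g, from[k], to[k])
    if (is.na(r)) stop(sprintf("no edge between '%s' and '%s'",
                               from[k], to[k]))
    sgn <- if (g$edges$from[r] == from[k]) 1 else -1
    total <- total + sgn * g$edges$phase[r]
  }
  wrap_angle(total)
}

# adjacency list in site-index order (list of integer vectors)
.adjacency <- function(g) {
  n <- n_sites(g)
  adj <- vector("list", n)
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$sites)
    j <- match(g$edges$to, g$sites)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

# BFS tree from the lowest-indexed site, neighbours visited in index order.
# Returns list(order, parent) with parent[root] = 0; error if disconnected.
.bfs_tree <- function(g) {
  n <- n_sites(g)
  adj <- .adjacency(g)
  parent <- rep(NA_integer_, n)
  parent[1] <- 0L
  queue <- 1L
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) if (is.na(parent[w])) {
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  if (length(order) < n) stop("graph is not connected")
  list(order = order, parent = parent)
}

#' Remove all phases from a tree graph
#'
#' On a connected acyclic graph every edge phase can be eliminated by a
#' gauge transformation: sweeping outward from the root, each site's gauge
#' angle is chosen to cancel the phase of the edge leading to it.  The
#' chiral and achiral walks on a tree are therefore gauge-equivalent and
#' share all site-to-site transfer probabilities.
#'
#' @param g a connected acyclic `phased_graph`.
#' @return A list with `graph` (all phases zero) and `gauge` (the
#'   [gauge_vector()] such that `apply_gauge(g, gauge)` equals `graph`).
#' @export
remove_tree_phases <- function(g) {
  if (nrow(g$edges) != n_sites(g) - 1)
    stop("graph is not a tree (edge count differs from sites - 1)")
  res <- normalize_spanning_tree(g)
  if (any(abs(res$graph$edges$phase) > 1e-12))
    stop("internal error: residual phase on a tree") # unreachable
  res
}

#' Concentrate all chirality on co-tree edges
#'
#' Generalizes [remove_tree_phases()] to arbitrary connected graphs: a
#' breadth-first spanning tree is grown from the lowest-indexed site
#' (neighbours in index order) and a gauge is constructed that zeroes the
#' phase of every tree edge.  The remaining phases sit on co-tree edges and
#' each equals (up to sign convention) the flux of its fundamental cycle,
#' which is gauge-invariant.  Two graphs differing only by a gauge share
#' this canonical form.
#'
#' @param g a connected `phased_graph`.
#' @return A list with `graph` (phases only on co-tree edges) and `gauge`.
#' @export
normalize_spanning_tree <- function(g) {
  bfs <- .bfs_tree(g)
  alpha <- rep(0, n_sites(g))
  for (v in bfs$order) {
    p <- bfs$parent[v]
    if (p == 0L) next
    r <- edge_row(g, g$sites[p], g$sites[v])
    # want theta' = theta + alpha_from - alpha_to = 0 on the tree edge
    if (g$edges$from[r] == g$sites[p]) {
      alpha[v] <- g$edges$phase[r] + alpha[p]
    } else {
      alpha[v] <- alpha[p] - g$edges$phase[r]
    }
  }
  gv <- gauge_vector(stats::setNames(alpha, g$sites))
  out <- apply_gauge(g, gv)
  # snap tree-edge residuals (pure rounding noise) to exactly zero
  tree_edges <- which(!is.na(vapply(seq_len(nrow(out$edges)), function(r) {
    i <- match(out$edges$from[r], out$sites)
    j <- match(out$edges$to[r], out$sites)
    if (bfs$parent[j] == i || bfs$parent[i] == j) 1L else NA_integer_
  }, integer(1))))
  out$edges$phase[tree_edges][abs(out$edges$phase[tree_edges]) < 1e-9] <- 0
  list(graph = out, gauge = gv)
}

#' Set the phase of given edges
#'
#' Convenience mutator used by the model systems and the optimizer.  The
#' phase is interpreted on the orientation in which the edge is supplied;
#' if that is the reverse of the canonical orientation the stored phase is
#' negated accordingly.
#'
#' @param g a `phased_graph`.
#' @param edges two-column matrix or data frame of site-label pairs
#'   (oriented `from`, `to`).
#' @param phase single angle or one angle per edge, radians.
#' @return The modified `phased_graph`.
#' @export
set_edge_phase <- function(g, edges, phase) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("`edges` must have two columns")
  phase <- rep_len(phase, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    r <- edge_row(g, edges[k, 1], edges[k, 2])
    if (is.na(r)) stop(sprintf("no edge between '%s' and '%s'",
                               edges[k, 1], edges[k, 2]))
    sgn <- if (g$edges$from[r] == edges[k, 1]) 1 else -1
    g$edges$phase[r] <- wrap_angle(sgn * phase[k])
  }
  g
}

#' Edges incident to a site
#'
#' @param g a `phased_graph`.
#' @param site a site label.
#' @return Two-column character matrix of oriented edges, each starting at
#'   the neighbour and ending at `site` (so that a common positive phase
#'   set with [set_edge_phase()] has a consistent orientation toward the
#'   site).
#' @export
incident_edges <- function(g, site) {
  site <- as.character(site)
  site_index(g, site)
  e <- g$edges
  sel <- e$from == site | e$to == site
  other <- ifelse(e$from[sel] == site, e$to[sel], e$from[sel])
  cbind(from = other, to = rep(site, length(other)))
}
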