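#' Lindblad channel specifications
#'
#' Collects the incoherent part of a Markovian open-system walk: absorbing
#' sinks (traps), site-to-site jump channels and pure dephasing.  Every jump
#' operator has the form \eqn{L = |target\rangle\langle source|} with a
#' non-negative rate; dephasing uses \eqn{L = |n\rangle\langle n|}.  Sinks
#' are realized as auxiliary absorbing basis states with no Hamiltonian
#' coupling, so the total occupancy (graph sites plus sinks) stays 1 and
#' transport efficiency is directly readable as sink occupancy.
#'
#' @param sinks data frame with columns `site` (attachment site), `rate`
#'   (absorption rate, >= 0) and optionally `label` (sink name; several rows
#'   may share a label to model a common sink).  Default label is
#'   `"sink_<site>"`.
#' @param channels data frame with columns `from`, `to`, `rate` for jump
#'   channels between graph sites.
#' @param dephasing named numeric vector of per-site dephasing rates, or a
#'   single unnamed rate applied to every site.
#' @return An object of class `lindblad_spec`.
#' @export
lindblad_spec <- function(sinks = NULL, channels = NULL, dephasing = NULL) {
  if (!is.null(sinks) && nrow(sinks)) {
    sinks <- as.data.frame(sinks, stringsAsFactors = FALSE)
    if (is.null(sinks$label)) sinks$label <- paste0("sink_", sinks$site)
    sinks$site <- as.character(sinks$site)
    sinks$label <- as.character(sinks$label)
    if (any(sinks$rate < 0)) stop("sink rates must be >= 0")
  } else sinks <- NULL
  if (!is.null(channels) && nrow(channels)) {
    channels <- as.data.frame(channels, stringsAsFactors = FALSE)
    if (any(channels$rate < 0)) stop("channel rates must be >= 0")
  } else channels <- NULL
  if (!is.null(dephasing)) {
    if (any(dephasing < 0)) stop("dephasing rates must be >= 0")
    if (all(dephasing == 0)) dephasing <- NULL
  }
  structure(list(sinks = sinks, channels = channels, dephasing = dephasing),
            class = "lindblad_spec")
}

#' @export
print.lindblad_spec <- function(x, ...) {
  cat("<lindblad_spec>",
      if (!is.null(x$sinks)) sprintf("%d sink channel(s)", nrow(x$sinks)),
      if (!is.null(x$channels)) sprintf("%d jump channel(s)", nrow(x$channels)),
      if (!is.null(x$dephasing)) "dephasing", "\n")
  invisible(x)
}

#' Bundle a phased graph with open-system terms and transport roles
#'
#' The container passed to the propagators, transport metrics and the phase
#' optimizer.  `source` and `target` name the sites between which transport
#' is measured; `target` may also be a sink label.
#'
#' @param graph a [phased_graph()].
#' @param lindblad a [lindblad_spec()] or `NULL` for closed (unitary)
#'   dynamics.
#' @param source,target site labels (target may be a sink label).
#' @param control_edges optional oriented edge matrix (see
#'   [set_edge_phase()]) singled out for phase control.
#' @return An object of class `cqw_system`.
#' @export
cqw_system <- function(graph, lindblad = NULL, source = NULL, target = NULL,
                       control_edges = NULL) {
  stopifnot(inherits(graph, "phased_graph"))
  if (!is.null(lindblad)) stopifnot(inherits(lindblad, "lindblad_spec"))
  structure(list(graph = graph, lindblad = lindblad, source = source,
                 target = target, control_edges = control_edges),
            class = "cqw_system")
}

#' @export
print.cqw_system <- function(x, ...) {
  cat("<cqw_system>\n  ")
  print(x$graph)
  if (!is.null(x$lindblad)) {
    cat("  ")
    print(x$lindblad)
  }
  if (!is.null(x$source))
    cat(sprintf("  transport: %s -> %s\n", x$source, x$target))
  invisible(x)
}

# ---- internal assembled representation --------------------------------

# Full basis = graph sites followed by distinct sink labels.
.assemble <- function(system) {
  g <- system$graph
  spec <- system$lindblad
  sites <- g$sites
  sink_labels <- character(0)
  jumps <- NULL # list of (i, j, rate): L = |j><i|
  if (!is.null(spec)) {
    if (!is.null(spec$sinks)) {
      sink_labels <- unique(spec$sinks$label)
      if (any(sink_labels %in% sites))
        stop("sink labels clash with site labels")
    }
    labels <- c(sites, sink_labels)
    if (!is.null(spec$sinks))
      jumps <- lapply(seq_len(nrow(spec$sinks)), function(r)
        list(i = match(spec$sinks$site[r], labels),
             j = match(spec$sinks$label[r], labels),
             rate = spec$sinks$rate[r]))
    if (!is.null(spec$channels))
      jumps <- c(jumps, lapply(seq_len(nrow(spec$channels)), function(r)
        list(i = match(as.character(spec$channels$from[r]), labels),
             j = match(as.character(spec$channels$to[r]), labels),
             rate = spec$channels$rate[r])))
    if (!is.null(jumps) && anyNA(unlist(lapply(jumps, `[`, c("i", "j")))))
      stop("jump channel endpoint is neither a site nor a sink label")
  }
  labels <- c(sites, sink_labels)
  n <- length(labels)
  h <- matrix(0 + 0i, n, n, dimnames = list(labels, labels))
  h[seq_along(sites), seq_along(sites)] <- to_hamiltonian(g)
  deph <- NULL
  if (!is.null(spec) && !is.null(spec$dephasing)) {
    d <- spec$dephasing
    if (is.null(names(d)) && length(d) == 1) d <- stats::setNames(
      rep(d, length(sites)), sites)
    deph <- stats::setNames(rep(0, n), labels)
    deph[names(d)] <- d
  }
  list(h = h, labels = labels, n_sites = length(sites),
       sink_labels = sink_labels, jumps = jumps, dephasing = deph)
}

# TRUE when every incoherent term is a one-way jump into an absorbing sink
# and there is no dephasing: dynamics on the site sector is then generated
# by the effective non-Hermitian Hamiltonian H - (i/2) sum_k c_k |s_k><s_k|.
.pure_loss <- function(asm) {
  if (is.null(asm$jumps) || !is.null(asm$dephasing)) return(is.null(asm$jumps))
  all(vapply(asm$jumps, function(j)
    j$i <= asm$n_sites && j$j > asm$n_sites, logical(1)))
}

# ---- occupancy evaluators ---------------------------------------------
# Each evaluator is a function(target_label) -> function(t) returning the
# occupancy <m|rho(t)|m> for a walker started at `source`, with analytic
# time dependence (exact at any t, suitable for root finding).

.evaluator_unitary <- function(h, source) {
  if (max(abs(h - Conj(t(h)))) > 1e-12) stop("Hamiltonian is not Hermitian")
  labels <- rownames(h)
  eig <- eigen(h, symmetric = TRUE)
  v <- eig$vectors
  c0 <- Conj(t(v)) %*% .basis_vec(length(labels), match(source, labels))
  function(target) {
    w <- v[match(target, labels), ] * c0[, 1]
    lam <- -1i * eig$values
    .amp2_fn(lam, w)
  }
}

# |sum_j w_j e^{lam_j t}|^2, vectorized over t
.amp2_fn <- function(lam, w) {
  keep <- Mod(w) > 1e-15
  lam <- lam[keep]
  w <- w[keep]
  function(t) {
    if (!length(w)) return(rep(0, length(t)))
    amp <- exp(outer(t, lam)) %*% w
    Mod(amp[, 1])^2
  }
}

# Re(sum_j w_j e^{mu_j t}) + c0 + c1 * t, vectorized over t
.expsum_fn <- function(mu, w, c0 = 0, c1 = 0) {
  keep <- Mod(w) > 1e-14
  mu <- mu[keep]
  w <- w[keep]
  function(t) {
    base <- c0 + c1 * t
    if (length(w)) base <- base + Re(exp(outer(t, mu)) %*% w)[, 1]
    base
  }
}

.basis_vec <- function(n, i) {
  z <- rep(0 + 0i, n)
  z[i] <- 1
  z
}

# pure-loss path: spectral decomposition of the effective Hamiltonian on the
# site sector (psi(t) = V exp(lambda t) V^{-1} psi(0)); sink occupancies from
# the closed-form time integral of the inflow c |psi_src(t)|^2.
.pure_loss_decomp <- function(asm, source) {
  ns <- asm$n_sites
  heff <- asm$h[seq_len(ns), seq_len(ns), drop = FALSE]
  rates <- rep(0, ns)
  for (j in asm$jumps) rates[j$i] <- rates[j$i] + j$rate
  diag(heff) <- diag(heff) - 1i * rates / 2
  eig <- eigen(-1i * heff)
  v <- eig$vectors
  a <- solve(v, .basis_vec(ns, match(source, asm$labels)))
  list(lam = eig$values,
       site_amp = function(i) v[i, ] * a)  # psi_i(t) = sum w e^{lam t}
}

.evaluator_pure_loss <- function(asm, source) {
  ns <- asm$n_sites
  dec <- .pure_loss_decomp(asm, source)
  lam <- dec$lam
  site_amp <- dec$site_amp
  function(target) {
    idx <- match(target, asm$labels)
    if (is.na(idx)) stop("unknown target: ", target)
    if (idx <= ns) {
      .amp2_fn(lam, site_amp(idx))
    } else {
      # sum closed-form integrals over the channels feeding this sink:
      # s(t) = sum_{jk} G_jk (e^{mu_jk t} - 1)/mu_jk,  mu = lam_j + conj(lam_k)
      chans <- Filter(function(j) j$j == idx, asm$jumps)
      gmats <- lapply(chans, function(ch) ch$rate * outer(site_amp(ch$i),
                                                          Conj(site_amp(ch$i))))
      gtot <- Reduce(`+`, gmats)
      mu <- outer(lam, Conj(lam), `+`)
      osc <- Mod(mu) >= 1e-12
      .expsum_fn(mu[osc], gtot[osc] / mu[osc],
                 c0 = -Re(sum(gtot[osc] / mu[osc])),
                 c1 = Re(sum(gtot[!osc])))
    }
  }
}

# vec (column-major) Liouvillian superoperator
.liouvillian <- function(asm) {
  n <- nrow(asm$h)
  id <- diag(1 + 0i, n)
  sup <- -1i * (kronecker(id, asm$h) - kronecker(t(asm$h), id))
  add_jump <- function(sup, l, rate) {
    ldl <- Conj(t(l)) %*% l
    sup + rate * (kronecker(Conj(l), l) -
                    0.5 * kronecker(id, ldl) -
                    0.5 * kronecker(t(ldl), id))
  }
  for (j in asm$jumps) {
    l <- matrix(0 + 0i, n, n)
    l[j$j, j$i] <- 1
    sup <- add_jump(sup, l, j$rate)
  }
  if (!is.null(asm$dephasing))
    for (i in which(asm$dephasing > 0)) {
      l <- matrix(0 + 0i, n, n)
      l[i, i] <- 1
      sup <- add_jump(sup, l, asm$dephasing[i])
    }
  sup
}

.evaluator_liouville <- function(asm, rho0) {
  n <- nrow(asm$h)
  sup <- .liouvillian(asm)
  eig <- eigen(sup)
  v <- eig$vectors
  ok <- TRUE
  a <- tryCatch(solve(v, as.vector(rho0)), error = function(e) {
    ok <<- FALSE
    NULL
  })
  if (ok && !all(is.finite(Mod(a)))) ok <- FALSE
  if (ok) {
    # guard against a numerically defective Liouvillian
    res <- max(abs(v %*% a - as.vector(rho0)))
    if (res > 1e-8) ok <- FALSE
  }
  if (ok) {
    lam <- eig$values
    function(target) {
      idx <- match(target, asm$labels)
      if (is.na(idx)) stop("unknown target: ", target)
      .expsum_fn(lam, v[(idx - 1) * n + idx, ] * a)
    }
  } else {
    .evaluator_liouville_expm(asm, sup, rho0)
  }
}

# fallback when the Liouvillian is not safely diagonalizable: propagate with
# scaling-and-squaring matrix exponentials (exact per evaluation, cached per
# time point)
.evaluator_liouville_expm <- function(asm, sup, rho0) {
  n <- nrow(asm$h)
  v0 <- as.vector(rho0)
  cache <- new.env(parent = emptyenv())
  prop <- function(tt) {
    key <- sprintf("%.12g", tt)
    if (is.null(cache[[key]]))
      cache[[key]] <- .expm_complex(sup * tt) %*% v0
    cache[[key]]
  }
  function(target) {
    idx <- match(target, asm$labels)
    if (is.na(idx)) stop("unknown target: ", target)
    function(t) vapply(t, function(tt)
      Re(prop(tt)[(idx - 1) * n + idx]), numeric(1))
  }
}

# Pade scaling-and-squaring exponential for complex matrices
.expm_complex <- function(m) {
  n <- nrow(m)
  nrm <- max(colSums(abs(m)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin) / 5.4)))
  m <- m / 2^s
  # 13/13 Pade approximant
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  id <- diag(1 + 0i, n)
  m2 <- m %*% m
  m4 <- m2 %*% m2
  m6 <- m2 %*% m4
  u <- m %*% (m6 %*% (b[14] * m6 + b[12] * m4 + b[10] * m2) +
                b[8] * m6 + b[6] * m4 + b[4] * m2 + b[2] * id)
  vv <- m6 %*% (b[13] * m6 + b[11] * m4 + b[9] * m2) +
    b[7] * m6 + b[5] * m4 + b[3] * m2 + b[1] * id
  f <- solve(vv - u, vv + u)
  for (k in seq_len(s)) f <- f %*% f
  f
}

# main dispatch: returns list(evaluator, labels, type)
.compile_dynamics <- function(system, source, rho0 = NULL) {
  asm <- .assemble(system)
  if (is.null(asm$jumps) && is.null(asm$dephasing) && is.null(rho0)) {
    list(evaluator = .evaluator_unitary(asm$h, source), labels = asm$labels,
         type = "unitary", asm = asm)
  } else if (is.null(rho0) && .pure_loss(asm)) {
    list(evaluator = .evaluator_pure_loss(asm, source), labels = asm$labels,
         type = "pure_loss", asm = asm)
  } else {
    if (is.null(rho0)) {
      n <- length(asm$labels)
      rho0 <- matrix(0 + 0i, n, n)
      i <- match(source, asm$labels)
      rho0[i, i] <- 1
    }
    list(evaluator = .evaluator_liouville(asm, rho0), labels = asm$labels,
         type = "liouville", asm = asm)
  }
}

# ---- trajectories ------------------------------------------------------

.make_trajectory <- function(comp, times, source, type) {
  occ <- vapply(comp$labels, function(lab) comp$evaluator(lab)(times),
                numeric(length(times)))
  occ <- matrix(occ, nrow = length(times),
                dimnames = list(NULL, comp$labels))
  structure(list(times = times, occupancy = occ, source = source,
                 type = type, labels = comp$labels,
                 sink_labels = comp$asm$sink_labels),
            class = "cqw_trajectory")
}

#' @export
print.cqw_trajectory <- function(x, ...) {
  cat(sprintf("<cqw_trajectory> %d time points, %d sites%s, source '%s' (%s)\n",
              length(x$times), length(x$labels) - length(x$sink_labels),
              if (length(x$sink_labels))
                sprintf(" + %d sink(s)", length(x$sink_labels)) else "",
              x$source, x$type))
  invisible(x)
}

#' @export
as.data.frame.cqw_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$occupancy, check.names = FALSE)
}

#' Propagate a closed (unitary) chiral walk
#'
#' Evolves \eqn{|\psi(t)\rangle = e^{-iHt}|source\rangle} via the spectral
#' decomposition of the Hermitian walk Hamiltonian and records the site
#' occupancies \eqn{P_{s\to m}(t) = |\langle m|e^{-iHt}|s\rangle|^2}.
#' Couplings are dimensionless, so time is measured in inverse coupling
#' units (\eqn{\hbar = 1}).  Negative times are allowed and correspond to
#' backward evolution.
#'
#' @param h complex Hermitian matrix with site-label dimnames, from
#'   [to_hamiltonian()], or a `phased_graph`/`cqw_system`.
#' @param initial_site site label at which the walker starts.
#' @param times numeric vector of times.
#' @return A `cqw_trajectory`.
#' @export
evolve_unitary <- function(h, initial_site, times) {
  h <- .as_hamiltonian(h)
  labels <- rownames(h)
  comp <- list(evaluator = .evaluator_unitary(h, initial_site),
               labels = labels, asm = list(sink_labels = character(0)))
  .make_trajectory(comp, times, initial_site, "unitary")
}

.as_hamiltonian <- function(h) {
  if (inherits(h, "cqw_system")) h <- h$graph
  if (inherits(h, "phased_graph")) h <- to_hamiltonian(h)
  if (is.null(rownames(h))) dimnames(h) <- list(seq_len(nrow(h)),
                                                seq_len(nrow(h)))
  h
}

#' Propagate a Markovian open-system chiral walk
#'
#' Integrates the Lindblad master equation
#' \deqn{\dot\rho = -i[H,\rho] + \sum_k c_k (L_k\rho L_k^\dagger
#'   - \tfrac12\{L_k^\dagger L_k, \rho\})}
#' over the graph sites plus any auxiliary sink states.  When every
#' incoherent term is a one-way jump into a sink and the initial state is a
#' localized pure state, the site sector is propagated exactly with an
#' effective non-Hermitian Hamiltonian and sink occupancies are obtained in
#' closed form; otherwise the dense Liouvillian superoperator is
#' diagonalized (with a scaling-and-squaring matrix-exponential fallback).
#' Both routes give analytic time dependence, so trajectories are exact at
#' every requested time.
#'
#' @param h Hamiltonian (or `phased_graph`) over the graph sites.
#' @param spec a [lindblad_spec()].
#' @param initial a site label, or a density matrix over sites plus sinks.
#' @param times numeric vector of non-negative times.
#' @return A `cqw_trajectory` including per-sink occupancy columns.
#' @export
evolve_lindblad <- function(h, spec, initial, times) {
  if (any(times < 0))
    stop("backward Lindblad evolution is not defined; times must be >= 0")
  if (inherits(h, "cqw_system")) {
    system <- h
    if (!missing(spec) && !is.null(spec)) system$lindblad <- spec
  } else {
    if (inherits(h, "phased_graph")) g <- h else g <- .graph_from_matrix(h)
    system <- cqw_system(g, spec)
  }
  if (is.character(initial)) {
    comp <- .compile_dynamics(system, initial)
    .make_trajectory(comp, times, initial, comp$type)
  } else {
    validate_density(initial)
    comp <- .compile_dynamics(system, NULL, rho0 = initial)
    .make_trajectory(comp, times, "<density>", comp$type)
  }
}

# wrap a plain Hermitian matrix back into a phased_graph (used when a raw
# Hamiltonian is passed to evolve_lindblad)
.graph_from_matrix <- function(h) {
  h <- .as_hamiltonian(h)
  labels <- rownames(h)
  idx <- which(upper.tri(h) & Mod(h) > 0, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      weight = Mod(h[idx]), phase = Arg(h[idx]))
  phased_graph(labels, edges, energy = stats::setNames(Re(diag(h)), labels))
}

#' Validate a density matrix
#'
#' @param rho complex square matrix.
#' @param tol_herm,tol_trace,tol_pos tolerances for Hermiticity, unit trace
#'   and eigenvalue positivity.
#' @return `rho` invisibly, or an error.
#' @export
validate_density <- function(rho, tol_herm = 1e-10, tol_trace = 1e-8,
                             tol_pos = 1e-8) {
  if (max(Mod(rho - Conj(t(rho)))) > tol_herm)
    stop("density matrix is not Hermitian")
  if (abs(Re(sum(diag(rho))) - 1) > tol_trace)
    stop("density matrix trace differs from 1")
  if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < -tol_pos)
    stop("density matrix has a negative eigenvalue")
  invisible(rho)
}

#' Time-reverse a walk Hamiltonian
#'
#' The time-reversal operator acts as complex conjugation in the site
#' basis, so the reversed Hamiltonian is the elementwise conjugate —
#' equivalently, every edge phase is negated.  Achiral (real) Hamiltonians
#' are exactly the fixed points of this map.
#'
#' @param h complex Hermitian matrix (or `phased_graph`, in which case a
#'   `phased_graph` with negated phases is returned).
#' @return Object of the same kind as the input.
#' @export
time_reverse <- function(h) {
  if (inherits(h, "phased_graph")) {
    h$edges$phase <- wrap_angle(-h$edges$phase)
    return(h)
  }
  Conj(.as_hamiltonian(h))
}

#' Check time-reversal symmetry of site-to-site transport
#'
#' Computes the three unitary transfer-probability series
#' \eqn{P_{S\to E}(t)}, \eqn{P_{S\to E}(-t)} and \eqn{P_{E\to S}(t)}.
#' The identity \eqn{P_{S\to E}(-t) = P_{E\to S}(t)} holds for every walk
#' Hamiltonian; time-reversal symmetry additionally requires
#' \eqn{P_{S\to E}(t) = P_{S\to E}(-t)}, which chiral phases can break
#' (though not, e.g., on trees or bipartite graphs).
#'
#' @param g a `phased_graph` or Hamiltonian.
#' @param source,target site labels.
#' @param times non-negative time grid.
#' @param tol tolerance for the symmetric/asymmetric verdict.
#' @return A list with the three series, the identity residual
#'   `max_identity_residual`, the asymmetry `max_trs_violation` and logical
#'   `trs` verdict.
#' @export
check_trs <- function(g, source, target, times, tol = 1e-8) {
  h <- .as_hamiltonian(g)
  fwd <- evolve_unitary(h, source, times)$occupancy[, target]
  bwd <- evolve_unitary(h, source, -times)$occupancy[, target]
  rev <- evolve_unitary(h, target, times)$occupancy[, source]
  list(times = times,
       forward = fwd, backward = bwd, reversed = rev,
       max_identity_residual = max(abs(bwd - rev)),
       max_trs_violation = max(abs(fwd - bwd)),
       trs = max(abs(fwd - bwd)) <= tol)
}
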