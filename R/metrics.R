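# Transport figures of merit, computed from the analytic occupancy
# evaluators compiled in dynamics.R.  All times are in inverse coupling
# units; the half-arrival threshold is the closed condition occ >= 1/2.

# occupancy closure for one (source, target) pair
.occ_closure <- function(system, source, target) {
  comp <- .compile_dynamics(system, source)
  comp$evaluator(target)
}

.resolve_roles <- function(system, source, target) {
  if (is.null(source)) source <- system$source
  if (is.null(target)) target <- system$target
  if (is.null(source) || is.null(target))
    stop("source/target neither given nor stored in the system")
  list(source = source, target = target)
}

#' Half-arrival time
#'
#' The earliest time at which the occupancy of the target (a site or a
#' sink) reaches one half.  The occupancy evaluator is analytic in t, so
#' the crossing is located by a coarse scan followed by root bisection.
#' Its reciprocal is the transport speed \eqn{\nu_{1/2}}; see
#' [transport_summary()].
#'
#' @param system a `cqw_system` (sinks, if any, come from its
#'   [lindblad_spec()]).
#' @param source,target site labels (target may be a sink label); default
#'   to the roles stored in the system.
#' @param horizon search horizon (time units), must be positive.
#' @param tol absolute time tolerance of the bisection.
#' @param grid_dt coarse scan step.
#' @return The crossing time, or `NA` with attribute `reached = FALSE` if
#'   the occupancy stays below 1/2 up to the horizon.
#' @export
half_arrival_time <- function(system, source = NULL, target = NULL,
                              horizon = 100, tol = 1e-6, grid_dt = 0.05) {
  if (horizon <= 0) stop("horizon must be positive")
  r <- .resolve_roles(system, source, target)
  comp <- .compile_dynamics(system, r$source)
  occ <- comp$evaluator(r$target)
  if (r$target %in% comp$asm$sink_labels) {
    # sink occupancies are monotone non-decreasing: bisection suffices
    .first_crossing_monotone(occ, 0.5, horizon, tol)
  } else {
    .first_crossing(occ, 0.5, horizon, tol, grid_dt)
  }
}

.first_crossing_monotone <- function(occ, level, horizon, tol) {
  if (occ(horizon) < level) return(structure(NA_real_, reached = FALSE))
  if (occ(0) >= level) return(0)
  stats::uniroot(function(t) occ(t) - level, c(0, horizon), tol = tol)$root
}

.first_crossing <- function(occ, level, horizon, tol, grid_dt) {
  tg <- seq(0, horizon, by = grid_dt)
  y <- occ(tg)
  hit <- which(y >= level)
  if (!length(hit)) {
    # refine once with a finer grid in case a narrow peak was stepped over
    tg2 <- seq(0, horizon, by = grid_dt / 10)
    y2 <- occ(tg2)
    hit2 <- which(y2 >= level)
    if (!length(hit2)) return(structure(NA_real_, reached = FALSE))
    tg <- tg2
    hit <- hit2
  }
  i <- hit[1]
  if (i == 1) return(0)
  stats::uniroot(function(t) occ(t) - level, c(tg[i - 1], tg[i]),
                 tol = tol)$root
}

#' First local maximum of a target occupancy series
#'
#' For a `cqw_trajectory` the stored series is refined by spline
#' interpolation (10x the stored density) before peak detection, to avoid
#' grid aliasing; for a `cqw_system` the analytic occupancy evaluator is
#' scanned and the peak polished with [stats::optimize()].  If the series
#' is monotone over the horizon the endpoint is returned flagged as a
#' boundary.
#'
#' @param x a `cqw_trajectory` or `cqw_system`.
#' @param target column/site (or sink) label.
#' @param source source site (systems only; defaults to the stored role).
#' @param horizon scan horizon (systems only).
#' @param refine interpolation refinement factor for trajectories.
#' @param min_value ignore ripples below this occupancy.
#' @return A list with `time`, `value` and logical `boundary`.
#' @export
first_maximum <- function(x, target = NULL, source = NULL, horizon = 100,
                          refine = 10, min_value = 1e-9) {
  if (inherits(x, "cqw_trajectory")) {
    if (is.null(target)) stop("target column required")
    if (length(x$times) < 3) stop("trajectory too short")
    f <- stats::splinefun(x$times, x$occupancy[, target])
    tg <- seq(min(x$times), max(x$times),
              length.out = refine * length(x$times))
    .first_peak(f, tg, min_value)
  } else if (inherits(x, "cqw_system")) {
    r <- .resolve_roles(x, source, target)
    occ <- .occ_closure(x, r$source, r$target)
    tg <- seq(0, horizon, length.out = max(2000, 40 * horizon))
    .first_peak(occ, tg, min_value)
  } else stop("x must be a cqw_trajectory or cqw_system")
}

.first_peak <- function(f, tg, min_value) {
  y <- f(tg)
  n <- length(y)
  int <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                 y[2:(n - 1)] > min_value) + 1
  if (length(int)) {
    i <- int[1]
    o <- stats::optimize(f, c(tg[i - 1], tg[i + 1]), maximum = TRUE,
                         tol = 1e-10)
    list(time = o$maximum, value = o$objective, boundary = FALSE)
  } else {
    list(time = tg[n], value = y[n], boundary = TRUE)
  }
}

#' Asymptotic transport efficiency into a sink
#'
#' The long-time occupancy of the target sink, i.e. the probability that
#' the walker is eventually absorbed there rather than by any competing
#' sink (or retained in a dark state).  When all incoherent terms are
#' one-way sink channels the asymptote is evaluated in closed form from
#' the effective-Hamiltonian spectrum (`horizon = Inf`, the default).
#' With a finite horizon — required for general Lindblad terms — the sink
#' occupancy at the horizon is returned after checking that the total sink
#' inflow has dropped below `inflow_tol`.
#'
#' @param system a `cqw_system` with at least one sink.
#' @param source source site label.
#' @param target_sink sink label (e.g. `"sink_E"`).
#' @param horizon `Inf` for the closed-form asymptote (pure-loss systems
#'   only) or a finite convergence horizon.
#' @param inflow_tol maximum admissible total sink inflow per unit time at
#'   the horizon.
#' @return Absorption probability in `[0, 1]`.
#' @export
transport_efficiency <- function(system, source = NULL, target_sink = NULL,
                                 horizon = Inf, inflow_tol = 1e-8) {
  r <- .resolve_roles(system, source, target_sink)
  asm <- .assemble(system)
  if (!length(asm$sink_labels)) stop("system has no sinks")
  if (!(r$target %in% asm$sink_labels))
    stop("target_sink is not a sink label of this system")
  if (is.infinite(horizon)) {
    if (!.pure_loss(asm))
      stop("closed-form asymptote needs a pure-loss system; ",
           "give a finite horizon")
    return(.efficiency_closed_form(asm, r$source, r$target))
  }
  comp <- .compile_dynamics(system, r$source)
  inflow <- sum(vapply(asm$sink_labels, function(s) {
    f <- comp$evaluator(s)
    (f(horizon) - f(horizon * (1 - 1e-6))) / (horizon * 1e-6)
  }, numeric(1)))
  if (inflow > inflow_tol)
    stop(sprintf("sink inflow %.3g at horizon %g exceeds %g; use a longer horizon",
                 inflow, horizon, inflow_tol))
  comp$evaluator(r$target)(horizon)
}

.efficiency_closed_form <- function(asm, source, sink_label) {
  dec <- .pure_loss_decomp(asm, source)
  idx <- match(sink_label, asm$labels)
  chans <- Filter(function(j) j$j == idx, asm$jumps)
  mu <- outer(dec$lam, Conj(dec$lam), `+`)
  total <- 0
  for (ch in chans) {
    g <- ch$rate * outer(dec$site_amp(ch$i), Conj(dec$site_amp(ch$i)))
    dec_ok <- Re(mu) < -1e-12          # non-decaying pairs absorb nothing
    total <- total + Re(sum(-g[dec_ok] / mu[dec_ok]))
  }
  min(max(total, 0), 1)
}

#' Summarize transport between two sites
#'
#' Bundles the half-arrival time \eqn{\tau_{1/2}}, the transport speed
#' \eqn{\nu_{1/2} = 1/\tau_{1/2}}, the first occupancy maximum of the
#' target series and (when the target is a sink of a pure-loss system) the
#' asymptotic absorption efficiency.
#'
#' @inheritParams half_arrival_time
#' @return An object of class `transport_summary`.
#' @export
transport_summary <- function(system, source = NULL, target = NULL,
                              horizon = 100) {
  r <- .resolve_roles(system, source, target)
  tau <- half_arrival_time(system, r$source, r$target, horizon = horizon)
  fm <- first_maximum(system, r$target, source = r$source, horizon = horizon)
  asm <- .assemble(system)
  eff <- if (r$target %in% asm$sink_labels && .pure_loss(asm))
    .efficiency_closed_form(asm, r$source, r$target) else NA_real_
  structure(list(source = r$source, target = r$target,
                 tau_half = as.numeric(tau),
                 reached = !isFALSE(attr(tau, "reached")),
                 speed = if (is.na(tau)) NA_real_ else 1 / as.numeric(tau),
                 first_max_time = fm$time, first_max_value = fm$value,
                 first_max_boundary = fm$boundary, efficiency = eff),
            class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf("<transport_summary> %s -> %s\n", x$source, x$target))
  cat(sprintf("  tau_half: %s   speed: %s\n",
              if (x$reached) format(x$tau_half, digits = 6) else "not reached",
              if (x$reached) format(x$speed, digits = 6) else "-"))
  cat(sprintf("  first max: %.6f at t = %.4f%s\n", x$first_max_value,
              x$first_max_time,
              if (x$first_max_boundary) " (boundary)" else ""))
  if (!is.na(x$efficiency))
    cat(sprintf("  efficiency: %.4f\n", x$efficiency))
  invisible(x)
}

#' Relative transport enhancement between two summaries
#'
#' @param baseline,variant [transport_summary()] objects for the same
#'   source/target roles.
#' @return A list with `speed_enhancement_pct`
#'   (\eqn{100(\nu_{var}/\nu_{base} - 1)}), `first_max_ratio_pct`
#'   (\eqn{100\, M_{var}/M_{base}}) and `tau_reduction_pct`
#'   (\eqn{100(1 - \tau_{var}/\tau_{base})}).
#' @export
enhancement <- function(baseline, variant) {
  stopifnot(inherits(baseline, "transport_summary"),
            inherits(variant, "transport_summary"))
  if (!identical(c(baseline$source, baseline$target),
                 c(variant$source, variant$target)))
    stop("summaries refer to different source/target roles")
  if (!baseline$reached)
    stop("baseline half-arrival time was not reached")
  list(speed_enhancement_pct =
         if (variant$reached) 100 * (variant$speed / baseline$speed - 1)
       else -100,
       first_max_ratio_pct =
         100 * variant$first_max_value / baseline$first_max_value,
       tau_reduction_pct =
         if (variant$reached) 100 * (1 - variant$tau_half / baseline$tau_half)
       else NA_real_)
}
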