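# File formats: phased-graph serialization (YAML and TSV edge list),
# trajectory tables, metric records and run configurations.

#' Write a phased graph to disk
#'
#' Two plain-text formats are supported.  The YAML document stores the
#' full object (`sites`, `edges`, `site_energy`); the 4-column
#' tab-separated edge list (`site_a`, `site_b`, `weight`, `phase`, with a
#' header) is convenient for interchange but cannot carry isolated sites
#' or on-site energies.  Numbers are written with 17 significant digits so
#' a write/read round trip reproduces weights and phases exactly.
#'
#' @param g a `phased_graph`.
#' @param path output file; extension `.yaml`/`.yml` or `.tsv` selects the
#'   format unless `format` is given.
#' @param format `"yaml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_phased_graph <- function(g, path, format = NULL) {
  format <- format %||% .guess_format(path)
  if (format == "yaml") {
    doc <- list(sites = as.list(g$sites),
                edges = lapply(seq_len(nrow(g$edges)), function(r)
                  list(from = g$edges$from[r], to = g$edges$to[r],
                       weight = .num17(g$edges$weight[r]),
                       phase = .num17(g$edges$phase[r]))))
    if (any(abs(g$energy) > 0))
      doc$site_energy <- as.list(stats::setNames(
        vapply(g$energy, .num17, character(1)), names(g$energy)))
    yaml::write_yaml(doc, path)
  } else if (format == "tsv") {
    if (any(abs(g$energy) > 0))
      warning("TSV edge list drops on-site energies")
    d <- data.frame(site_a = g$edges$from, site_b = g$edges$to,
                    weight = vapply(g$edges$weight, .num17, character(1)),
                    phase = vapply(g$edges$phase, .num17, character(1)))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unknown format: ", format)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.num17 <- function(x) sprintf("%.17g", x)

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext %in% c("tsv", "txt")) "tsv"
  else stop("cannot guess graph format from extension: ", path)
}

#' Read a phased graph written by [write_phased_graph()]
#'
#' @param path input file.
#' @param format `"yaml"` or `"tsv"` (guessed from the extension by
#'   default).  For TSV the site list is the sorted set of endpoint
#'   labels.
#' @return A `phased_graph`.
#' @export
read_phased_graph <- function(path, format = NULL) {
  format <- format %||% .guess_format(path)
  if (format == "yaml") {
    doc <- yaml::read_yaml(path)
    edges <- do.call(rbind, lapply(doc$edges, function(e)
      data.frame(from = e$from, to = e$to,
                 weight = as.numeric(e$weight),
                 phase = as.numeric(e$phase %||% 0))))
    energy <- if (!is.null(doc$site_energy))
      vapply(doc$site_energy, as.numeric, numeric(1)) else NULL
    phased_graph(unlist(doc$sites), edges, energy)
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
    sites <- sort(unique(c(d$site_a, d$site_b)))
    phased_graph(sites, data.frame(from = d$site_a, to = d$site_b,
                                   weight = d$weight, phase = d$phase))
  }
}

#' Export a trajectory as a comma-separated table
#'
#' First column `time`, one column per site and sink, header row with the
#' labels.  Solver metadata (source, propagation route, labels) goes to a
#' YAML sidecar when `meta_path` is given.
#'
#' @param traj a `cqw_trajectory`.
#' @param path output CSV file.
#' @param meta_path optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, meta_path = NULL) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (!is.null(meta_path))
    yaml::write_yaml(list(source = traj$source, type = traj$type,
                          labels = traj$labels,
                          sink_labels = traj$sink_labels,
                          n_times = length(traj$times)), meta_path)
  invisible(path)
}

#' Write a transport summary as a flat key/value record
#'
#' @param summary a [transport_summary()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(summary, path) {
  stopifnot(inherits(summary, "transport_summary"))
  keys <- c("source", "target", "tau_half", "speed", "first_max_time",
            "first_max_value", "first_max_boundary", "efficiency",
            "reached")
  lines <- vapply(keys, function(k)
    sprintf("%s\t%s", k, format(summary[[k]], digits = 12)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Append a row to a comma-separated results table
#'
#' Creates the file with a header on first use.
#'
#' @param row single-row data frame.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
append_results_row <- function(row, path) {
  new <- !file.exists(path)
  utils::write.table(row, path, sep = ",", append = !new, col.names = new,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configurations ------------------------------------------------

.build_from_config <- function(cfg) {
  sys_cfg <- cfg$system
  if (is.null(sys_cfg)) stop("config lacks a `system` block")
  if (!is.null(sys_cfg$zoo)) {
    sys <- switch(sys_cfg$zoo,
      switch_ = ,
      switch = do.call(make_switch, sys_cfg$args %||% list()),
      triangle_chain = do.call(make_triangle_chain, sys_cfg$args %||% list()),
      cycle = cqw_system(do.call(make_cycle, sys_cfg$args %||% list())),
      watts_strogatz = do.call(make_watts_strogatz, sys_cfg$args %||% list()),
      barabasi_albert = do.call(make_barabasi_albert,
                                sys_cfg$args %||% list()),
      fmo = do.call(load_fmo, sys_cfg$args %||% list()),
      stop("unknown zoo system: ", sys_cfg$zoo))
  } else if (!is.null(sys_cfg$graph_file)) {
    sys <- cqw_system(read_phased_graph(sys_cfg$graph_file))
  } else stop("system block needs `zoo` or `graph_file`")
  if (!is.null(sys_cfg$source)) sys$source <- as.character(sys_cfg$source)
  if (!is.null(sys_cfg$target)) sys$target <- as.character(sys_cfg$target)
  dyn <- cfg$dynamics
  if (!is.null(dyn)) {
    sinks <- if (!is.null(dyn$sinks))
      do.call(rbind, lapply(dyn$sinks, as.data.frame))
    channels <- if (!is.null(dyn$channels))
      do.call(rbind, lapply(dyn$channels, as.data.frame))
    deph <- if (!is.null(dyn$dephasing)) unlist(dyn$dephasing)
    if (!is.null(sinks) || !is.null(channels) || !is.null(deph))
      sys$lindblad <- lindblad_spec(sinks, channels, deph)
  }
  sys
}

#' Run a simulation described by a config file
#'
#' The config (YAML file or equivalent list) names a model system (zoo
#' entry with arguments, or a graph file), optional Lindblad terms, a time
#' grid and an output directory.  Writes `trajectory.csv`, `metrics.txt`
#' and `meta.yaml` (config echo plus seed), and returns the pieces
#' invisibly.  Identical configs give byte-identical outputs.
#'
#' @param config path to a YAML file or a list.
#' @return Invisibly, a list with `system`, `trajectory` and `summary`.
#' @export
cqw_simulate <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  sys <- .build_from_config(cfg)
  tmax <- cfg$times$to %||% 20
  dt <- cfg$times$by %||% 0.1
  times <- seq(0, tmax, by = dt)
  traj <- if (is.null(sys$lindblad))
    evolve_unitary(sys$graph, sys$source, times)
  else evolve_lindblad(sys, NULL, sys$source, times)
  out <- cfg$output_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(traj, file.path(out, "trajectory.csv"),
                   file.path(out, "meta.yaml"))
  summary <- NULL
  if (!is.null(sys$target)) {
    summary <- transport_summary(sys, horizon = cfg$metric$horizon %||% 100)
    write_metrics(summary, file.path(out, "metrics.txt"))
  }
  invisible(list(system = sys, trajectory = traj, summary = summary))
}

#' Run a phase optimization described by a config file
#'
#' Builds the system as in [cqw_simulate()], optimizes the configured edge
#' subset (site pairs, or the selector `"incident-to:<site>"`) and writes
#' the result (best phases, baseline vs best metric, per-restart record)
#' to `optimization.yaml` in the output directory, appending one summary
#' row to `results.csv`.
#'
#' @param config path to a YAML file or a list.
#' @return Invisibly, the `optimization_result`.
#' @export
cqw_optimize <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  sys <- .build_from_config(cfg)
  oc <- cfg$optimization %||% list()
  edges <- if (is.null(oc$edges)) sys$control_edges
  else if (is.character(oc$edges) && length(oc$edges) == 1 &&
           startsWith(oc$edges, "incident-to:"))
    incident_edges(sys$graph, sub("^incident-to:", "", oc$edges))
  else if (length(oc$edges) == 0) matrix(character(0), 0, 2)
  else do.call(rbind, lapply(oc$edges, function(e)
    c(from = as.character(e[[1]]), to = as.character(e[[2]]))))
  res <- optimize_phases(sys, edges,
                         objective = oc$objective %||% "tau_half",
                         n_restarts = oc$n_restarts %||% 20,
                         seed = cfg$seed %||% 1,
                         horizon = oc$horizon %||% 100)
  out <- cfg$output_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(objective = res$objective,
                        direction = res$direction,
                        baseline_value = res$baseline_value,
                        best_value = res$best_value,
                        best_phases = as.list(res$best_phases),
                        seed = res$seed,
                        restarts = res$restarts$converged_value),
                   file.path(out, "optimization.yaml"))
  append_results_row(data.frame(objective = res$objective,
                                baseline = res$baseline_value,
                                best = res$best_value,
                                seed = res$seed %||% NA),
                     file.path(out, "results.csv"))
  invisible(res)
}
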