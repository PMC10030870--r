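#' Run a reproducible layout experiment
#'
#' Executes every (graph, model, seed) combination of a run configuration,
#' collecting final energies, trajectories and paired speedup metrics into a
#' results bundle. When `"fdl"` is among the models, each neural model's
#' steps/seconds-to-target are measured against the FDL run with the same
#' seed (target = that run's final energy, within `delta`). Runs are seeded
#' independently, so identical configurations reproduce identical energies.
#'
#' @param config a named list:
#' \describe{
#'   \item{graphs}{named list; each element an `nl_graph`, a file path, or a
#'     `list(family =, params =, seed =)` generator spec. A single graph may
#'     be passed as `graph`.}
#'   \item{models}{character vector from `"fdl"`, `"nodemlp"`, `"neulay"`,
#'     `"neulay2"` (at least one).}
#'   \item{seeds}{integer vector of run seeds (non-empty).}
#'   \item{eparams, stop}{an [energy_params()] / [stop_rule()], or named lists
#'     of their arguments.}
#'   \item{dim, record_every, operator, optimizer, hidden, delta}{optional
#'     run settings, as in [run_fdl()] / [train_model()] / [speedup()].}
#'   \item{out_dir}{optional directory; writes `results.csv`,
#'     per-run trajectory CSVs, and the resolved config as JSON.}
#' }
#' @return a list with `results` (data frame), `trajectories`, `layouts`,
#'   `errors` (failed runs, if any, as messages) and `config` (resolved).
#' @export
run_experiment <- function(config) {
  graphs <- config$graphs
  if (is.null(graphs)) {
    if (is.null(config$graph)) stop("config needs 'graphs' or 'graph'")
    graphs <- list(graph = config$graph)
  }
  if (is.null(names(graphs))) names(graphs) <- paste0("g", seq_along(graphs))
  models <- config$models
  if (is.null(models) || !length(models)) stop("config needs at least one model")
  seeds <- config$seeds
  if (is.null(seeds) || !length(seeds)) stop("config needs a non-empty seeds vector")
  eparams <- as_energy_params(config$eparams)
  stop_r <- as_stop_rule(config$stop)
  dim <- config$dim %||% 3
  record_every <- config$record_every %||% 10
  operator <- config$operator %||% "full"
  optimizer <- config$optimizer %||% "gd"
  delta <- config$delta %||% 0.05

  rows <- list(); trajs <- list(); layouts <- list(); errors <- list()
  for (gname in names(graphs)) {
    g <- resolve_graph(graphs[[gname]])
    for (seed in seeds) {
      for (model in models) {
        key <- paste(gname, model, seed, sep = "_")
        res <- tryCatch({
          if (model == "fdl") {
            run_fdl(g, params = eparams, stop = stop_r, dim = dim,
                    record_every = record_every, seed = seed,
                    optimizer = optimizer)
          } else {
            train_model(g, model, params = eparams, stop = stop_r, dim = dim,
                        record_every = record_every, seed = seed,
                        hidden = config$hidden, operator = operator,
                        optimizer = optimizer)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[key]] <- conditionMessage(res)
          next
        }
        tr <- res$trajectory
        trajs[[key]] <- tr
        layouts[[key]] <- res$layout
        rows[[key]] <- data.frame(
          graph = gname, model = model, seed = seed,
          n_nodes = g$n_nodes, n_links = g$n_links,
          final_energy = tail(tr$energies, 1),
          steps = max(tr$steps),
          wall_time = tail(tr$wall_times, 1),
          converged = isTRUE(tr$converged),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # paired speedups against the same-seed FDL run
  if (!is.null(results) && "fdl" %in% models) {
    results$step_ratio <- NA_real_
    results$time_ratio <- NA_real_
    for (i in seq_len(nrow(results))) {
      if (results$model[i] == "fdl") next
      ref <- paste(results$graph[i], "fdl", results$seed[i], sep = "_")
      key <- paste(results$graph[i], results$model[i], results$seed[i], sep = "_")
      if (is.null(trajs[[ref]])) next
      sp <- speedup(trajs[[ref]], trajs[[key]], delta = delta)
      results$step_ratio[i] <- sp$step_ratio
      results$time_ratio[i] <- sp$time_ratio
    }
  }

  resolved <- list(models = models, seeds = seeds,
                   eparams = unclass(eparams), stop = unclass(stop_r),
                   dim = dim, record_every = record_every,
                   operator = operator, optimizer = optimizer, delta = delta,
                   graphs = names(graphs),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("neulay")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    for (key in names(trajs)) {
      tr <- trajs[[key]]
      write.csv(data.frame(step = tr$steps, energy = tr$energies,
                           wall_time = tr$wall_times),
                file.path(config$out_dir, paste0("traj_", key, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(resolved, file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, trajectories = trajs, layouts = layouts,
       errors = errors, config = resolved)
}

as_energy_params <- function(x) {
  if (is.null(x)) return(energy_params())
  if (inherits(x, "energy_params")) return(x)
  do.call(energy_params, x)
}

as_stop_rule <- function(x) {
  if (is.null(x)) return(stop_rule())
  if (inherits(x, "stop_rule")) return(x)
  do.call(stop_rule, x)
}

resolve_graph <- function(spec) {
  if (inherits(spec, "nl_graph")) return(spec)
  if (is.character(spec)) return(read_graph_file(spec))
  if (is.list(spec) && !is.null(spec$family)) {
    return(generate_graph(spec$family, spec$params %||% list(),
                          seed = spec$seed))
  }
  stop("cannot interpret graph spec: need an nl_graph, a path, or list(family=, params=)")
}
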