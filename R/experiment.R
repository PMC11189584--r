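#' Configuration-driven experiment runners
#'
#' `run_simulate()`, `run_reconstruct()` and `run_sweep()` tie simulation,
#' reconstruction and error sweeps into reproducible, file-based
#' experiments, driven by a YAML (or in-memory list) configuration with a
#' versioned schema. Every run writes its outputs, a copy of the resolved
#' configuration and a plain-text log (one line per stage, with timings and
#' problem dimensions) into the output directory; given the same seed, runs
#' are deterministic. On failure, partially written outputs are removed.
#'
#' Configuration fields:
#' * `model`: `name` (`"lv"` or `"rossler"`) plus optional model parameters;
#' * `structure`: `fixture` (`"lv"` or `"karate"`) with its arguments, or
#'   `tsv` (path to a hyperedge TSV);
#' * `sampling`: `t_max`, `M`, optional `transient`, optional `x0`;
#' * `derivative`: `"exact"`, 1, 2 or 4;
#' * `solver`: `name` plus solver options;
#' * `sweep` (for `run_sweep`): `ratios`, optional `replicates`;
#' * `seed`, `out_dir`.
#'
#' A thin command-line wrapper with subcommands `simulate`, `reconstruct`,
#' `sweep` and `fixtures` is installed at `exec/hordyn`.
#'
#' @param config path to a YAML file, or an equivalent named list. Values
#'   in `overrides` replace config fields (flag-style overrides).
#' @param overrides named list of replacement fields.
#' @return The paths of the written outputs, invisibly.
#' @name experiment
NULL

#' @rdname experiment
#' @export
read_experiment_config <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a file path or a list", call. = FALSE)
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (!identical(cfg$schema %||% "hordyn/experiment/v1", "hordyn/experiment/v1")) {
    stop("unrecognized config schema", call. = FALSE)
  }
  cfg$schema <- "hordyn/experiment/v1"
  req_field(cfg, "model"); req_field(cfg, "model.name")
  req_field(cfg, "structure")
  if (is.null(cfg$structure$fixture) && is.null(cfg$structure$tsv)) {
    stop("config field `structure` needs `fixture` or `tsv`", call. = FALSE)
  }
  if (!is.null(cfg$structure$tsv) && !file.exists(cfg$structure$tsv)) {
    stop(sprintf("config field `structure.tsv`: file not found: %s",
                 cfg$structure$tsv), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$derivative <- cfg$derivative %||% "exact"
  cfg$solver <- cfg$solver %||% list(name = "ols")
  cfg
}

req_field <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    node <- node[[p]]
    if (is.null(node)) {
      stop(sprintf("missing config field `%s`", path), call. = FALSE)
    }
  }
  invisible(node)
}

config_model <- function(cfg) {
  mc <- cfg$model
  switch(mc$name,
    lv = lv_model(r = mc$r %||% lv_parameters()$r,
                  k = mc$k %||% lv_parameters()$k),
    rossler = rossler_model(a = mc$a %||% 0.2, b = mc$b %||% 0.2,
                            c = mc$c %||% 9,
                            sigma1 = mc$sigma1 %||% 1e-4,
                            sigma2 = mc$sigma2 %||% 1e-5),
    stop(sprintf("unknown config field `model.name`: %s", mc$name),
         call. = FALSE))
}

config_structure <- function(cfg, seed = cfg$seed) {
  sc <- cfg$structure
  if (!is.null(sc$tsv)) return(read_hyperedge_tsv(sc$tsv))
  switch(sc$fixture,
    lv = build_lv_hypergraph(weight_scale = sc$weight_scale %||% 0.01,
                             seed = seed),
    karate = build_karate_complex(delta = sc$delta %||% 1, seed = seed),
    stop(sprintf("unknown config field `structure.fixture`: %s", sc$fixture),
         call. = FALSE))
}

config_x0 <- function(cfg, structure, seed = cfg$seed) {
  x0 <- cfg$sampling$x0
  if (!is.null(x0)) return(matrix(unlist(x0), nrow = structure$n_nodes,
                                  byrow = TRUE))
  switch(cfg$model$name,
    lv = matrix(lv_parameters()$x0, ncol = 1L),
    rossler = rossler_initial_state(structure$n_nodes, seed = seed))
}

experiment_log <- function(con, stage, t0, ...) {
  extra <- paste(vapply(list(...), as.character, ""), collapse = " ")
  line <- sprintf("%s\telapsed=%.2fs\t%s", stage,
                  as.numeric(proc.time()[3L]) - t0, extra)
  writeLines(line, con)
}

with_cleanup <- function(out_dir, files, expr) {
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, files)), add = TRUE)
  res <- force(expr)
  ok <- TRUE
  res
}

finish_run <- function(cfg, out_dir, log_lines, outputs) {
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  header <- sprintf("# hordyn %s | R %s | seed %d",
                    as.character(utils::packageVersion("hordyn")),
                    paste(R.version$major, R.version$minor, sep = "."),
                    cfg$seed)
  writeLines(c(header, log_lines), file.path(out_dir, "run.log"))
  invisible(file.path(out_dir, outputs))
}

#' @rdname experiment
#' @export
run_simulate <- function(config, overrides = list()) {
  cfg <- read_experiment_config(config, overrides)
  req_field(cfg, "sampling"); req_field(cfg, "sampling.t_max")
  req_field(cfg, "sampling.M")
  out_dir <- req_field(cfg, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("trajectory.tsv", "trajectory.tsv.deriv", "structure.tsv")
  with_cleanup(out_dir, files, {
    t0 <- as.numeric(proc.time()[3L])
    model <- config_model(cfg)
    hs <- config_structure(cfg)
    x0 <- config_x0(cfg, hs)
    traj <- simulate_trajectory(model, hs, x0,
                                t_max = cfg$sampling$t_max,
                                M = cfg$sampling$M,
                                with_derivatives = TRUE,
                                transient = cfg$sampling$transient %||% 0,
                                rtol = cfg$sampling$rtol %||% 1e-12,
                                atol = cfg$sampling$atol %||% 1e-12)
    write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
    write_hyperedge_tsv(hs, file.path(out_dir, "structure.tsv"))
    log1 <- sprintf("simulate\telapsed=%.2fs\tM=%d N=%d n=%d",
                    as.numeric(proc.time()[3L]) - t0, traj$M,
                    hs$n_nodes, model$state_dim)
    finish_run(cfg, out_dir, log1, files)
  })
}

#' @rdname experiment
#' @export
run_reconstruct <- function(config, overrides = list()) {
  cfg <- read_experiment_config(config, overrides)
  out_dir <- req_field(cfg, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("reconstruction.tsv", "reconstruction.tsv.json")
  with_cleanup(out_dir, files, {
    t0 <- as.numeric(proc.time()[3L])
    model <- config_model(cfg)
    logs <- character()
    if (!is.null(cfg$trajectory)) {
      traj <- read_trajectory(cfg$trajectory)
    } else {
      req_field(cfg, "sampling.t_max"); req_field(cfg, "sampling.M")
      hs <- config_structure(cfg)
      traj <- simulate_trajectory(model, hs, config_x0(cfg, hs),
                                  t_max = cfg$sampling$t_max,
                                  M = cfg$sampling$M, with_derivatives = TRUE,
                                  transient = cfg$sampling$transient %||% 0)
      logs <- sprintf("simulate\telapsed=%.2fs\tM=%d",
                      as.numeric(proc.time()[3L]) - t0, traj$M)
    }
    t1 <- as.numeric(proc.time()[3L])
    solver_args <- cfg$solver[setdiff(names(cfg$solver), "name")]
    fit <- do.call(reconstruct,
                   c(list(traj, model,
                          solver = cfg$solver$name %||% "ols",
                          deriv = cfg$derivative,
                          convention = cfg$convention %||% "unordered"),
                     solver_args))
    write_reconstruction(fit, file.path(out_dir, "reconstruction.tsv"))
    logs <- c(logs, sprintf("reconstruct\telapsed=%.2fs\tH=%d Mtilde=%d E=%.6g",
                            as.numeric(proc.time()[3L]) - t1, fit$H,
                            length(fit$residuals[[1L]]), fit$discrepancy$E))
    finish_run(cfg, out_dir, logs, files)
  })
}

#' @rdname experiment
#' @export
run_sweep <- function(config, overrides = list()) {
  cfg <- read_experiment_config(config, overrides)
  req_field(cfg, "sweep"); req_field(cfg, "sweep.ratios")
  req_field(cfg, "sampling.t_max")
  out_dir <- req_field(cfg, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_cleanup(out_dir, "error_curve.csv", {
    t0 <- as.numeric(proc.time()[3L])
    model <- config_model(cfg)
    structure_fn <- function(seed) config_structure(cfg, seed = seed)
    x0_fn <- function(seed) config_x0(cfg, structure_fn(seed), seed = seed)
    curve <- sweep_ratio(model, structure_fn, x0_fn,
                         ratios = as.numeric(unlist(cfg$sweep$ratios)),
                         solver = cfg$solver$name %||% "ols",
                         deriv_order = cfg$derivative,
                         replicates = cfg$sweep$replicates %||% 1L,
                         seed = cfg$seed,
                         t_max = cfg$sampling$t_max,
                         transient = cfg$sampling$transient %||% 0,
                         convention = cfg$convention %||% "unordered")
    write_error_curve(curve, file.path(out_dir, "error_curve.csv"))
    log1 <- sprintf("sweep\telapsed=%.2fs\tratios=%d replicates=%d",
                    as.numeric(proc.time()[3L]) - t0, nrow(curve),
                    cfg$sweep$replicates %||% 1L)
    finish_run(cfg, out_dir, log1, "error_curve.csv")
  })
}

#' @rdname experiment
#' @param out_dir output directory (for `run_fixtures`).
#' @param seed RNG seed for the fixture draws (for `run_fixtures`).
#' @export
run_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_hyperedge_tsv(build_lv_hypergraph(seed = seed),
                      file.path(out_dir, "lv_hypergraph.tsv"))
  write_hyperedge_tsv(build_karate_complex(1, seed = seed),
                      file.path(out_dir, "karate_complex.tsv"))
  invisible(file.path(out_dir, c("lv_hypergraph.tsv", "karate_complex.tsv")))
}
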