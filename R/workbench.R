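#' Experiment configuration
#'
#' Bundles module settings, the global seed and replicate count for the
#' scripted end-to-end experiments. The shipped defaults are the scaled-down
#' desk profile (modest domain, replicate and design sizes); `profile =
#' "full"` switches to the full-scale campaign sizes (3000 parameter sets,
#' 100 replicates each, 200 replicate runs per model), which needs cluster
#' time.
#'
#' @param name experiment name.
#' @param seed global integer seed (recorded in all outputs).
#' @param replicates agent-simulation replicates per condition.
#' @param synthesis a [synthesis_params()].
#' @param sim a [simulation_config()].
#' @param reference_mass equal-total-mass constraint for model fields.
#' @param lhc_samples,lhc_replicates emulation design size and replicates per
#'   parameter set.
#' @param hidden_sizes emulator hidden-layer widths.
#' @param epochs emulator training epochs.
#' @param targets calibration targets for [objective_spec()].
#' @param pop,gens NSGA-II settings.
#' @param out_dir output directory or `NULL`.
#' @param profile `"desk"` or `"full"`.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(name = "experiment", seed = 1L,
                              replicates = 50L,
                              synthesis = synthesis_params(),
                              sim = simulation_config(),
                              reference_mass = 2000,
                              lhc_samples = 150L, lhc_replicates = 20L,
                              hidden_sizes = c(24, 16, 8), epochs = 2000,
                              targets = c(speed = 6, meandering_index = 0.4,
                                          motility_coefficient = 20),
                              pop = 100L, gens = 100L, out_dir = NULL,
                              profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    replicates <- 200L
    lhc_samples <- 3000L; lhc_replicates <- 100L
    pop <- 100L; gens <- 250L
  }
  if (replicates < 1) fs_stop("replicates must be >= 1", "follisim_invalid_input")
  cfg <- list(name = name, seed = as.integer(seed), replicates = replicates,
              synthesis = synthesis, sim = sim,
              reference_mass = reference_mass,
              lhc_samples = lhc_samples, lhc_replicates = lhc_replicates,
              hidden_sizes = hidden_sizes, epochs = epochs, targets = targets,
              pop = pop, gens = gens, out_dir = out_dir, profile = profile)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from YAML
#' @param path YAML file; keys mirror [experiment_config()] arguments.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$synthesis))
    args$synthesis <- do.call(synthesis_params, raw$synthesis)
  if (!is.null(raw$sim)) args$sim <- do.call(simulation_config, raw$sim)
  if (!is.null(raw$targets)) args$targets <- unlist(raw$targets)
  do.call(experiment_config, args)
}

# Simple per-experiment plain-text logger.
experiment_log <- function(cfg, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    cat(line, "\n", file = file.path(cfg$out_dir,
                                     paste0(cfg$name, ".log")),
        append = TRUE)
  }
  message(line)
}

# Run `n_rep` seeded replicate simulations on a fixed converged field and
# summarize each.
run_replicates <- function(cfg_sim, net, grid, n_rep, seeds,
                           dt_sample = 30) {
  lapply(seq_len(n_rep), function(r) {
    cfg_r <- cfg_sim
    cfg_r$seed <- seeds[r]
    summarize_tracks(run_simulation(cfg_r, net, grid = grid),
                     dt_sample = dt_sample)
  })
}

#' Compare immobilized (model 1) and soluble (model 2) gradients
#'
#' Synthesizes one follicular network, builds the two model fields at equal
#' total steady-state mass, runs `replicates` seeded agent simulations per
#' model on the fixed fields, and compares the emergent per-run scanning
#' rates with the Vargha-Delaney A-test.
#'
#' @param cfg an [experiment_config()].
#' @return list of class `model_comparison`: per-model scanning-rate samples
#'   and median/IQR, `A` (model 1 vs model 2), seeds, and the configuration
#'   hash.
#' @export
run_model_comparison <- function(cfg = experiment_config()) {
  seeds <- derive_seeds(cfg$seed, 2L * cfg$replicates + 1L)
  experiment_log(cfg, sprintf("synthesizing network (seed %d)", seeds[1]))
  net <- synthesize_follicle_network(cfg$synthesis, seed = seeds[1])

  fields <- lapply(1:2, function(m) {
    fp <- model_parameterization(m, cfg$reference_mass,
                                 n_fdc = sum(net$nodes$subtype == "FDC"),
                                 n_rc = sum(net$nodes$subtype != "FDC"))
    sim <- cfg$sim
    sim$D <- fp$D; sim$lam <- fp$lam
    sim$secretion_fdc <- fp$secretion_fdc; sim$secretion_rc <- fp$secretion_rc
    sim$k_on_ecm <- fp$k_on_ecm; sim$k_off_ecm <- fp$k_off_ecm
    list(sim = sim, grid = build_field(sim, net))
  })
  experiment_log(cfg, sprintf(
    "steady masses: model 1 = %.4g, model 2 = %.4g",
    total_mass(fields[[1]]$grid), total_mass(fields[[2]]$grid)))

  scan <- lapply(1:2, function(m) {
    s_off <- 1L + (m - 1L) * cfg$replicates
    reps <- run_replicates(fields[[m]]$sim, net, fields[[m]]$grid,
                           cfg$replicates, seeds[s_off + seq_len(cfg$replicates)])
    vapply(reps, function(s) s$scanning_rate, numeric(1))
  })
  A <- vargha_delaney_A(scan[[1]], scan[[2]])
  res <- list(
    scanning = data.frame(
      model = rep(1:2, each = cfg$replicates),
      scanning_rate = c(scan[[1]], scan[[2]])),
    medians = vapply(scan, stats::median, numeric(1)),
    iqr = lapply(scan, function(s) stats::quantile(s, c(0.25, 0.75))),
    A = A, seeds = seeds, config_hash = config_hash(unclass(cfg)),
    masses = c(model1 = total_mass(fields[[1]]$grid),
               model2 = total_mass(fields[[2]]$grid)))
  class(res) <- "model_comparison"
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(res$scanning,
                     file.path(cfg$out_dir, "scanning_rates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(A = as.numeric(A), medians = res$medians, seed = cfg$seed,
           config_hash = res$config_hash),
      file.path(cfg$out_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA)
  }
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (immobilized vs soluble gradients)\n")
  cat(sprintf("  scanning rate median: model 1 = %.3f, model 2 = %.3f nodes/cell/h\n",
              x$medians[1], x$medians[2]))
  cat(sprintf("  Vargha-Delaney A = %.3f (%s effect)\n",
              as.numeric(x$A), attr(x$A, "magnitude")))
  invisible(x)
}

#' Emulate-then-optimize pipeline
#'
#' Latin hypercube design over the 13 simulation parameters, replicate agent
#' simulations per design point (median responses), one feed-forward
#' emulator per output statistic, and NSGA-II over the emulators with the
#' four migration objectives. Design, responses, the Pareto set and
#' parameter marginals are returned (and written as CSV/JSON when `out_dir`
#' is set).
#'
#' @param cfg an [experiment_config()].
#' @param ranges 2 x 13 parameter ranges (default [default_param_ranges()]).
#' @return list of class `emulate_optimize_result` with `design`,
#'   `responses`, `emulators`, `front` (a `pareto_result`), `conflict`,
#'   `marginals`, `seeds`, `config_hash`.
#' @export
run_emulate_optimize <- function(cfg = experiment_config(),
                                 ranges = default_param_ranges()) {
  seeds <- derive_seeds(cfg$seed, 6L)
  net <- synthesize_follicle_network(cfg$synthesis, seed = seeds[1])
  design <- latin_hypercube(cfg$lhc_samples, ranges, seed = seeds[2])
  rep_seeds <- matrix(derive_seeds(seeds[3], cfg$lhc_samples * cfg$lhc_replicates),
                      cfg$lhc_samples)
  experiment_log(cfg, sprintf("simulating %d x %d design",
                              cfg$lhc_samples, cfg$lhc_replicates))
  outs <- c("speed", "meandering_index", "motility_coefficient",
            "scanning_rate")
  responses <- matrix(NA_real_, cfg$lhc_samples, 4L,
                      dimnames = list(NULL, outs))
  for (i in seq_len(cfg$lhc_samples)) {
    sim_i <- config_with_params(design$matrix[i, ], cfg$sim)
    grid_i <- build_field(sim_i, net)
    reps <- run_replicates(sim_i, net, grid_i, cfg$lhc_replicates,
                           rep_seeds[i, ])
    vals <- vapply(reps, summary_vector, numeric(4))
    responses[i, ] <- apply(vals, 1, stats::median)
  }
  experiment_log(cfg, "training emulators")
  emulators <- lapply(outs, function(nm)
    train_emulator(design, responses[, nm], hidden_sizes = cfg$hidden_sizes,
                   epochs = cfg$epochs, seed = seeds[4]))
  names(emulators) <- outs
  spec <- objective_spec(emulators, cfg$targets)
  experiment_log(cfg, "optimizing (NSGA-II)")
  front <- nsga2(spec$fn, ranges, sense = spec$sense, pop = cfg$pop,
                 gens = cfg$gens, seed = seeds[5])
  colnames(front$par) <- simulation_param_names()
  marg <- apply(front$par, 2, stats::quantile, c(0.25, 0.5, 0.75))
  res <- list(design = design, responses = responses, emulators = emulators,
              front = front, conflict = conflict_analysis(front),
              marginals = marg, seeds = seeds,
              config_hash = config_hash(unclass(cfg)), ranges = ranges)
  class(res) <- "emulate_optimize_result"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(design$matrix, responses),
                     file.path(cfg$out_dir, "design_responses.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(front$par, front$objectives),
                     file.path(cfg$out_dir, "pareto.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, config_hash = res$config_hash,
           marginals = as.data.frame(marg), conflict = res$conflict),
      file.path(cfg$out_dir, "optimization.json"), auto_unbox = TRUE,
      digits = NA)
    for (nm in outs)
      write_emulator(emulators[[nm]],
                     file.path(cfg$out_dir, paste0("emulator_", nm, ".json")))
  }
  res
}

#' @export
print.emulate_optimize_result <- function(x, ...) {
  cat("Emulate-then-optimize result\n")
  cat("  design:", nrow(x$design$matrix), "parameter sets;",
      "front:", nrow(x$front$par), "solutions\n")
  mid <- (x$ranges[1, ] + x$ranges[2, ]) / 2
  cat(sprintf("  diffusion D median on front: %.3g (box midpoint %.3g)\n",
              x$marginals[2, "D"], mid["D"]))
  cat(sprintf("  decay lam median on front: %.3g (box midpoint %.3g)\n",
              x$marginals[2, "lam"], mid["lam"]))
  invisible(x)
}
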