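#' Build a scenario from named presets
#'
#' Convenience constructor combining the template, transmission and
#' contribution presets of the standard experimental grid.
#'
#' @param template `"species_rich"` or `"species_poor"`.
#' @param transmission `"vertical"` (`Tv = 1, Th = 0`), `"horizontal"`
#'   (`Tv = 0, Th = 1`) or `"midway"` (`Tv = Th = 0.5`).
#' @param contribution `"uniform"`, `"midpoint"` or `"step"`.
#' @param N,replicates,seed,... passed on to [scenario_config()].
#' @return A [scenario_config()].
#' @export
#' @examples
#' scenario_preset("species_poor", "vertical", "uniform", N = 20)
scenario_preset <- function(template = c("species_rich", "species_poor"),
                            transmission = c("vertical", "horizontal",
                                             "midway"),
                            contribution = c("uniform", "midpoint", "step"),
                            N = 50, replicates = 100, seed = 1, ...) {
  template <- match.arg(template)
  transmission <- match.arg(transmission)
  contribution <- match.arg(contribution)
  tr <- switch(transmission,
               vertical = c(Tv = 1, Th = 0),
               horizontal = c(Tv = 0, Th = 1),
               midway = c(Tv = 0.5, Th = 0.5))
  scenario_config(N = N, Tv = tr[["Tv"]], Th = tr[["Th"]],
                  assembly = template, contributions = contribution,
                  replicates = replicates, seed = seed, ...)
}

#' Neutral (pure drift) reference scenario
#'
#' The microbiome is irrelevant to fitness; lineages coalesce by random
#' drift alone, which for a Wright-Fisher population takes on the order of
#' `2 * N` generations to reach a single common ancestor.
#'
#' @inheritParams scenario_preset
#' @param ... passed on to [scenario_config()].
#' @return A [scenario_config()] with `neutral = TRUE`.
#' @export
neutral_config <- function(N = 50, replicates = 100, seed = 1, ...) {
  scenario_config(N = N, replicates = replicates, seed = seed,
                  neutral = TRUE, ...)
}

#' The standard experimental grid
#'
#' Named scenario configurations covering the neutral reference plus every
#' combination of template regime, transmission scheme and contribution
#' distribution at one population size. Entry names follow
#' `"<rich|poor>_<vertical|horizontal|midway>_<uniform|midpoint|step>"`.
#'
#' @inheritParams scenario_preset
#' @param ... passed on to [scenario_config()].
#' @return Named list of [scenario_config()] objects.
#' @export
experiment_grid <- function(N = 50, replicates = 100, seed = 1, ...) {
  grid <- list(neutral = neutral_config(N, replicates, seed, ...))
  for (tpl in c("species_rich", "species_poor"))
    for (tr in c("vertical", "horizontal", "midway"))
      for (ct in c("uniform", "midpoint", "step")) {
        nm <- paste(sub("species_", "", tpl), tr, ct, sep = "_")
        grid[[nm]] <- scenario_preset(tpl, tr, ct, N = N,
                                      replicates = replicates, seed = seed,
                                      ...)
      }
  grid
}

#' Run one scenario of the experimental grid
#'
#' Runs the configured replicates and, when `out_dir` is given, writes the
#' tidy per-generation trajectories, the per-replicate summary and a JSON
#' manifest recording the full configuration (see [write_experiment()]).
#' Re-running with the same configuration and seed reproduces the files.
#'
#' @param scenario a [scenario_config()], or the name of an entry of
#'   [experiment_grid()].
#' @param ... overrides applied to the configuration (e.g. `N = 10`,
#'   `replicates = 25`, `seed = 7`).
#' @param out_dir optional output directory.
#' @param name scenario label; defaults to the preset name when `scenario`
#'   is a name.
#' @return A `holosim_experiment` (see [simulate_replicates()]).
#' @export
run_experiment <- function(scenario, ..., out_dir = NULL, name = NULL) {
  overrides <- list(...)
  if (is.character(scenario)) {
    if (is.null(name)) name <- scenario
    grid_args <- overrides[names(overrides) %in%
                             c("N", "replicates", "seed")]
    grid <- do.call(experiment_grid, grid_args)
    if (!scenario %in% names(grid))
      stop("unknown preset '", scenario, "'; available: ",
           paste(names(grid), collapse = ", "))
    config <- grid[[scenario]]
    overrides <- overrides[!names(overrides) %in% c("N", "replicates",
                                                    "seed")]
  } else {
    config <- scenario
  }
  stopifnot(inherits(config, "scenario_config"))
  if (length(overrides)) {
    args <- unclass(config)
    args[names(overrides)] <- overrides
    config <- do.call(scenario_config, args)
  }
  exp <- simulate_replicates(config, name = name)
  if (!is.null(out_dir)) write_experiment(exp, out_dir)
  exp
}

#' Write experiment results as tidy tables plus a manifest
#'
#' Writes `trajectory.tsv` (`replicate`, `generation`, `ancestor_count`,
#' `fitness_mean`, `fitness_var`, `mean_jaccard`), `summary.tsv`
#' (`replicate`, `coalescence_generation`, `censored`, first-generation
#' statistics) and `manifest.json` (configuration, seed scheme, package
#' version).
#'
#' @param exp a `holosim_experiment`.
#' @param out_dir directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(exp, out_dir) {
  stopifnot(inherits(exp, "holosim_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- do.call(rbind, lapply(seq_along(exp$trajectories), function(r)
    cbind(replicate = r, exp$trajectories[[r]])))
  write.table(tidy, file.path(out_dir, "trajectory.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(exp$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cfg <- unclass(exp$config)
  cfg$assembly <- unclass(cfg$assembly)
  cfg$contributions <- unclass(cfg$contributions)
  manifest <- list(
    name = exp$name,
    config = cfg,
    replicates = nrow(exp$summary),
    seed_scheme = "replicate r uses seed + r; template bank uses seed",
    package_version = as.character(packageVersion("holosim")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a scenario configuration from a YAML file
#'
#' The file holds [scenario_config()] arguments by name; `assembly` and
#' `contributions` may be preset names or nested parameter lists (passed to
#' [assembly_params()] / [contribution_params()]).
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  args <- yaml::read_yaml(path)
  # an unquoted `N:` key is parsed as a YAML boolean; map it back
  names(args)[names(args) %in% c("FALSE", "F")] <- "N"
  if (is.list(args$assembly))
    args$assembly <- do.call(assembly_params, args$assembly)
  if (is.list(args$contributions))
    args$contributions <- do.call(contribution_params, args$contributions)
  do.call(scenario_config, args)
}

#' Compare experiments across scenarios
#'
#' Tabulates, per scenario, the mean and median coalescence generation, the
#' population-size-normalised mean (`mean / N`), the mean first-generation
#' fitness variance, and a two-sided Welch t test of the coalescence times
#' against a reference scenario (by default the first, conventionally the
#' neutral one).
#'
#' @param experiments a list of `holosim_experiment` objects (named, or
#'   carrying their own `name`).
#' @param reference index or name of the reference experiment.
#' @return A data frame with one row per experiment.
#' @export
summarize_experiment <- function(experiments, reference = 1L) {
  if (inherits(experiments, "holosim_experiment"))
    experiments <- list(experiments)
  stopifnot(length(experiments) >= 1)
  nms <- names(experiments)
  labels <- vapply(seq_along(experiments), function(i) {
    if (!is.null(nms) && nzchar(nms[i])) return(nms[i])
    if (!is.null(experiments[[i]]$name)) return(experiments[[i]]$name)
    paste0("scenario_", i)
  }, character(1))
  if (is.character(reference)) reference <- match(reference, labels)
  ref_times <- experiments[[reference]]$summary$coalescence_generation
  rows <- lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    ct <- e$summary$coalescence_generation
    tt <- if (i == reference || length(ct[!is.na(ct)]) < 2 ||
              length(ref_times[!is.na(ref_times)]) < 2)
      list(statistic = NA_real_, p_value = NA_real_)
    else two_sided_t_test(ct[!is.na(ct)], ref_times[!is.na(ref_times)])
    data.frame(
      scenario = labels[i],
      N = e$config$N,
      replicates = nrow(e$summary),
      n_censored = sum(e$summary$censored),
      mean_coalescence = mean(ct, na.rm = TRUE),
      median_coalescence = median(ct, na.rm = TRUE),
      normalized_mean = mean(ct, na.rm = TRUE) / e$config$N,
      mean_first_gen_fitness_var = mean(e$summary$first_gen_fitness_var),
      t_vs_reference = tt$statistic,
      p_vs_reference = tt$p_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- labels[reference]
  out
}
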