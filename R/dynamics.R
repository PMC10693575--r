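#' Scenario configuration
#'
#' Collects every parameter of one simulation scenario. Defaults follow the
#' standard study conditions: `N = 50` hosts, `B = 2000` taxa, stopping when
#' the number of distinct ancestral lineages reaches `AC_threshold = 2`
#' (set `AC_threshold = 1` to follow a population all the way to a single
#' common ancestor).
#'
#' @param N positive host population size (constant over time).
#' @param B positive number of microbe taxa available in the environment.
#' @param Tv,Th non-negative vertical and horizontal transmission
#'   coefficients; `Tv + Th > 0`. `Th = 0` is pure vertical transmission,
#'   `Tv = 0` pure horizontal, `Tv = Th` the "midway" scheme.
#' @param AC_threshold stop once the number of distinct founder lineages is
#'   at or below this value (`<= N`).
#' @param assembly an [assembly_params()] object or a [template_preset()]
#'   name.
#' @param contributions a [contribution_params()] object or a
#'   [contribution_preset()] name. Ignored when `neutral = TRUE`.
#' @param bank_size number of templates pre-generated per scenario.
#' @param max_generations censoring horizon; defaults to `50 * N`.
#' @param seed integer base seed; replicate `r` runs under
#'   `seed + r` (see [simulate_replicates()]).
#' @param replicates default number of replicates for
#'   [simulate_replicates()].
#' @param neutral if `TRUE`, the microbiome is irrelevant to fitness: all
#'   hosts have fitness 1, parents are chosen uniformly and microbiome
#'   bookkeeping is skipped. This is the pure-drift reference against which
#'   microbiome-driven scenarios are compared.
#' @param record_beta record the mean pairwise Jaccard distance each
#'   generation (costs one `N x B` cross-product per generation; disable for
#'   large populations when beta-diversity trajectories are not needed).
#' @return An object of class `"scenario_config"`.
#' @export
#' @examples
#' cfg <- scenario_config(N = 10, bank_size = 20, seed = 1,
#'                        assembly = "species_poor", AC_threshold = 1)
#' run_simulation(cfg)
scenario_config <- function(N = 50, B = 2000, Tv = 1, Th = 0,
                            AC_threshold = 2,
                            assembly = "species_rich",
                            contributions = "uniform",
                            bank_size = 10000,
                            max_generations = 50 * N,
                            seed = 1, replicates = 100,
                            neutral = FALSE, record_beta = TRUE) {
  if (is.character(assembly)) assembly <- template_preset(assembly)
  if (is.character(contributions))
    contributions <- contribution_preset(contributions)
  stopifnot(
    "N must be a positive integer" = is.numeric(N) && N >= 1,
    "B must be a positive integer" = is.numeric(B) && B >= 1,
    "Tv and Th must be non-negative" = Tv >= 0 && Th >= 0,
    "Tv + Th must be positive" = Tv + Th > 0,
    "AC_threshold must be in [1, N]" =
      AC_threshold >= 1 && AC_threshold <= N,
    inherits(assembly, "assembly_params"),
    inherits(contributions, "contribution_params"),
    "bank_size must be positive" = bank_size >= 1,
    "max_generations must be positive" = max_generations >= 1,
    "seed must be an integer below 2^31 - replicates" =
      is.numeric(seed) && seed + replicates < 2^31
  )
  structure(list(N = as.integer(N), B = as.integer(B), Tv = Tv, Th = Th,
                 AC_threshold = as.integer(AC_threshold),
                 assembly = assembly, contributions = contributions,
                 bank_size = as.integer(bank_size),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 neutral = isTRUE(neutral),
                 record_beta = isTRUE(record_beta)),
            class = "scenario_config")
}

#' Host fitness from microbiome composition
#'
#' Fitness is the sum of the contributions of the taxa present in the
#' microbiome; each taxon counts once, regardless of its abundance.
#'
#' @param m a [microbiome()].
#' @param cv contribution vector of length `B` (taxon `j` at index `j`).
#' @return Non-negative raw fitness score.
#' @export
#' @examples
#' cv <- c(0.2, 0.7, 0.1)
#' host_fitness(microbiome(c(1L, 2L), c(5, 500)), cv)  # 0.9
host_fitness <- function(m, cv) {
  stopifnot(inherits(m, "microbiome"))
  if (length(m$taxa) == 0) return(0)
  if (max(m$taxa) > length(cv)) stop("taxon id outside contribution vector")
  sum(cv[m$taxa])
}

#' Normalise fitness scores to the [0, 1] range
#'
#' Raw population fitness scores are divided by the generation's maximum, so
#' the fittest host always scores exactly 1. An all-zero generation carries
#' no fitness signal and is treated as neutral (all scores set to 1).
#'
#' @param raw non-negative raw fitness scores.
#' @param quiet suppress the message emitted for all-zero generations.
#' @return Numeric vector in `[0, 1]` with maximum 1.
#' @export
normalize_population_fitness <- function(raw, quiet = FALSE) {
  stopifnot("fitness scores must be non-negative" = all(raw >= 0))
  mx <- max(raw)
  if (mx == 0) {
    if (!quiet) message("all fitness scores are zero; treating as neutral")
    return(rep(1, length(raw)))
  }
  raw / mx
}

#' Fitness-proportional parent selection
#'
#' Each of the `N` offspring independently draws a parent from the previous
#' generation with probability proportional to fitness, so fit hosts may
#' leave several offspring while the population size stays constant. Equal
#' fitness reduces to uniform (neutral Wright-Fisher) choice.
#'
#' @param fitness non-negative fitness scores of the parental generation.
#' @param N number of offspring to assign.
#' @return Integer vector of `N` parent indices.
#' @export
select_parents <- function(fitness, N) {
  stopifnot("fitness scores must be non-negative" = all(fitness >= 0),
            "N must be positive" = N >= 1)
  if (max(fitness) == 0) fitness <- rep(1, length(fitness))
  sample.int(length(fitness), N, replace = TRUE, prob = fitness)
}

#' Number of distinct ancestral lineages
#'
#' Counts the distinct generation-0 founders with living descendants in the
#' current population. The simulation stops when this count reaches the
#' configured threshold; reaching 1 means all hosts share a common ancestor.
#'
#' @param x a `host_population` (see [init_population()]) or an integer
#'   vector of founder labels.
#' @return Positive integer.
#' @export
ancestor_count <- function(x) {
  if (inherits(x, "host_population")) x <- x$founder
  length(unique(x))
}

#' Initialise the founding host generation
#'
#' Each founder draws a template uniformly from the bank and is seeded with
#' taxa drawn uniformly from the `B` available ones; fitness is computed and
#' normalised population-wide.
#'
#' @param config a [scenario_config()].
#' @param bank a [generate_template_bank()] result.
#' @param cv contribution vector of length `B`.
#' @return An object of class `"host_population"`: list with `microbiomes`
#'   (list of [microbiome()]), `parent` (NA for founders), `founder`
#'   (integer labels), `raw_fitness` and `fitness`.
#' @export
init_population <- function(config, bank, cv) {
  N <- config$N
  idx <- sample.int(length(bank), N, replace = TRUE)
  mics <- lapply(idx, function(i) seed_initial_microbiome(bank[[i]], config$B))
  raw <- vapply(mics, host_fitness, numeric(1), cv = cv)
  structure(list(microbiomes = mics,
                 parent = rep(NA_integer_, N),
                 founder = seq_len(N),
                 raw_fitness = raw,
                 fitness = normalize_population_fitness(raw, quiet = TRUE)),
            class = "host_population")
}

#' Advance the population by one generation
#'
#' For each of the `N` offspring: a parent is chosen in proportion to
#' fitness; a template is drawn from the bank; the sampling pool mixes the
#' parent's normalised microbiome (weight `Tv`) with the previous
#' population's pooled microbiome (weight `Th`); the offspring's microbiome
#' is acquired by weighted sampling without replacement; fitness is computed
#' and normalised population-wide; the founder label is inherited.
#'
#' @param pop the current `host_population`.
#' @param config a [scenario_config()].
#' @param bank template bank.
#' @param cv contribution vector.
#' @return The next `host_population`.
#' @export
advance_generation <- function(pop, config, bank, cv) {
  N <- config$N
  parents <- select_parents(pop$fitness, N)
  E <- if (config$Th > 0) population_source(pop$microbiomes, config$B)
  tidx <- sample.int(length(bank), N, replace = TRUE)
  mics <- vector("list", N)
  for (i in seq_len(N)) {
    pm <- pop$microbiomes[[parents[i]]]
    if (config$Th == 0) {
      ## pure vertical: the pool support is exactly the parent's taxa
      ids <- pm$taxa
      w <- pm$abundance
    } else {
      w <- config$Th * E
      if (config$Tv > 0)
        w[pm$taxa] <- w[pm$taxa] + config$Tv * pm$abundance / sum(pm$abundance)
      ids <- which(w > 0)
      w <- w[ids]
    }
    mics[[i]] <- .acquire_from_weights(ids, w, bank[[tidx[i]]])
  }
  raw <- vapply(mics, host_fitness, numeric(1), cv = cv)
  structure(list(microbiomes = mics,
                 parent = parents,
                 founder = pop$founder[parents],
                 raw_fitness = raw,
                 fitness = normalize_population_fitness(raw, quiet = TRUE)),
            class = "host_population")
}

## One trajectory record for the current generation.
.record <- function(generation, pop, config) {
  mj <- NA_real_
  if (config$record_beta && config$N >= 2)
    mj <- .mean_jaccard(lapply(pop$microbiomes, `[[`, "taxa"), config$B)
  data.frame(generation = generation,
             ancestor_count = ancestor_count(pop),
             fitness_mean = mean(pop$fitness),
             fitness_var = if (config$N >= 2) var(pop$fitness) else NA_real_,
             mean_jaccard = mj)
}

#' Run one replicate simulation
#'
#' Iterates [advance_generation()] from a freshly seeded founding generation
#' until the number of distinct founder lineages is at or below
#' `config$AC_threshold`, or until `config$max_generations` (the run is then
#' flagged as censored). With `config$neutral = TRUE` the microbiome
#' machinery is bypassed: fitness is identically 1 and only ancestry is
#' tracked.
#'
#' The replicate is fully reproducible: the RNG is seeded with
#' `config$seed + replicate` before anything is drawn. The contribution
#' vector (and, if not supplied, the template bank) is drawn inside that
#' stream.
#'
#' @param config a [scenario_config()].
#' @param bank optional pre-generated template bank shared across
#'   replicates; generated from `config$assembly` when `NULL`.
#' @param cv optional contribution vector; drawn from
#'   `config$contributions` when `NULL`.
#' @param replicate replicate index (>= 1), used for seeding.
#' @return An object of class `"holosim_result"`: list with
#'   `trajectory` (data frame: `generation`, `ancestor_count`,
#'   `fitness_mean`, `fitness_var`, `mean_jaccard`),
#'   `coalescence_generation` (NA if censored), `censored`,
#'   `first_gen_fitness` (normalised founder-generation scores),
#'   `replicate` and `config`.
#' @export
run_simulation <- function(config, bank = NULL, cv = NULL, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"), replicate >= 1)
  set.seed(config$seed + as.integer(replicate))
  if (config$neutral) return(.run_neutral(config, replicate))
  if (is.null(bank))
    bank <- generate_template_bank(config$bank_size, config$assembly)
  if (is.null(cv)) cv <- draw_contributions(config$B, config$contributions)
  pop <- init_population(config, bank, cv)
  first_gen_fitness <- pop$fitness
  traj <- vector("list", 64L)
  traj[[1L]] <- .record(0L, pop, config)
  g <- 0L
  coal <- if (ancestor_count(pop) <= config$AC_threshold) 0L else NA_integer_
  while (is.na(coal) && g < config$max_generations) {
    g <- g + 1L
    pop <- advance_generation(pop, config, bank, cv)
    if (g + 1L > length(traj)) traj <- c(traj, vector("list", length(traj)))
    traj[[g + 1L]] <- .record(g, pop, config)
    if (ancestor_count(pop) <= config$AC_threshold) coal <- g
  }
  structure(
    list(trajectory = do.call(rbind, traj[!vapply(traj, is.null, logical(1))]),
         coalescence_generation = coal,
         censored = is.na(coal),
         first_gen_fitness = first_gen_fitness,
         replicate = as.integer(replicate),
         config = config),
    class = "holosim_result")
}

## Pure-drift reference: fitness carries no information, so only founder
## labels are propagated. Trajectory columns keep their meaning (fitness is
## identically 1, beta diversity is not defined without microbiomes).
.run_neutral <- function(config, replicate) {
  N <- config$N
  founder <- seq_len(N)
  g <- 0L
  acs <- integer(0)
  ac <- N
  acs[1L] <- ac
  coal <- if (ac <= config$AC_threshold) 0L else NA_integer_
  while (is.na(coal) && g < config$max_generations) {
    g <- g + 1L
    founder <- founder[sample.int(N, N, replace = TRUE)]
    ac <- length(unique(founder))
    acs[g + 1L] <- ac
    if (ac <= config$AC_threshold) coal <- g
  }
  traj <- data.frame(generation = 0:g,
                     ancestor_count = acs,
                     fitness_mean = 1,
                     fitness_var = if (N >= 2) 0 else NA_real_,
                     mean_jaccard = NA_real_)
  structure(list(trajectory = traj,
                 coalescence_generation = coal,
                 censored = is.na(coal),
                 first_gen_fitness = rep(1, N),
                 replicate = as.integer(replicate),
                 config = config),
            class = "holosim_result")
}

#' Run a set of replicate simulations
#'
#' The template bank is generated once under `set.seed(config$seed)` and
#' shared by all replicates (templates are a fixed resource of the scenario,
#' as in pre-generating a large bank before any run). Replicate `r` then
#' runs under seed `config$seed + r`, drawing its own contribution vector,
#' so each replicate is an independent simulation with a fresh contribution
#' assignment.
#'
#' @param config a [scenario_config()].
#' @param replicates number of replicates; defaults to `config$replicates`.
#' @param name optional scenario label carried into summaries.
#' @return An object of class `"holosim_experiment"`: list with
#'   `summary` (data frame: `replicate`, `coalescence_generation`,
#'   `censored`, `first_gen_fitness_var`, `first_gen_mean_jaccard`),
#'   `trajectories` (list of per-replicate data frames),
#'   `first_gen_fitness` (`replicates x N` matrix of normalised scores),
#'   `config` and `name`.
#' @export
simulate_replicates <- function(config, replicates = config$replicates,
                                name = NULL) {
  stopifnot(inherits(config, "scenario_config"), replicates >= 1)
  bank <- NULL
  if (!config$neutral) {
    set.seed(config$seed)
    bank <- generate_template_bank(config$bank_size, config$assembly)
  }
  results <- lapply(seq_len(replicates), function(r)
    run_simulation(config, bank = bank, replicate = r))
  first_gen <- do.call(rbind, lapply(results, `[[`, "first_gen_fitness"))
  summ <- data.frame(
    replicate = seq_len(replicates),
    coalescence_generation =
      vapply(results, `[[`, integer(1), "coalescence_generation"),
    censored = vapply(results, `[[`, logical(1), "censored"),
    first_gen_fitness_var =
      vapply(results, function(x) x$trajectory$fitness_var[1L], numeric(1)),
    first_gen_mean_jaccard =
      vapply(results, function(x) x$trajectory$mean_jaccard[1L], numeric(1)))
  structure(list(summary = summ,
                 trajectories = lapply(results, `[[`, "trajectory"),
                 first_gen_fitness = first_gen,
                 config = config,
                 name = name),
            class = "holosim_experiment")
}
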