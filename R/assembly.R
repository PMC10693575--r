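#' Construct a microbiome
#'
#' A microbiome maps distinct taxon identifiers (integers in `1:B`) to
#' positive abundances. Abundances come from the host's template slots, taxa
#' from the sampling pool.
#'
#' @param taxa integer vector of distinct taxon ids.
#' @param abundance positive abundances, same length.
#' @return An object of class `"microbiome"`: a list with elements `taxa`
#'   and `abundance`.
#' @export
microbiome <- function(taxa, abundance) {
  stopifnot("taxa and abundance lengths differ" =
              length(taxa) == length(abundance),
            "taxa must be distinct" = !anyDuplicated(taxa),
            "abundances must be positive" = all(abundance > 0))
  structure(list(taxa = as.integer(taxa), abundance = as.numeric(abundance)),
            class = "microbiome")
}

#' Normalise one microbiome into a relative-abundance source
#'
#' @param m a [microbiome()].
#' @param B total number of taxa in the environment.
#' @return Numeric vector of length `B` of relative abundances summing to 1
#'   (zero for absent taxa).
#' @export
#' @examples
#' normalize_source(microbiome(c(3L, 7L), c(3, 1)), B = 10)
normalize_source <- function(m, B) {
  stopifnot(inherits(m, "microbiome"),
            "empty microbiome has no source" = length(m$taxa) > 0,
            "taxon id exceeds B" = max(m$taxa) <= B)
  out <- numeric(B)
  out[m$taxa] <- m$abundance / sum(m$abundance)
  out
}

#' Population-wide microbial source
#'
#' The horizontal-transmission source: per-taxon abundances summed over every
#' host of the previous generation (including the focal parent) and
#' normalised to sum to 1.
#'
#' @param microbiomes a list of [microbiome()] objects (or a
#'   `host_population`, see [init_population()]).
#' @param B total number of taxa in the environment.
#' @return Numeric vector of length `B` summing to 1.
#' @export
population_source <- function(microbiomes, B) {
  if (inherits(microbiomes, "host_population"))
    microbiomes <- microbiomes$microbiomes
  stopifnot(length(microbiomes) > 0)
  out <- numeric(B)
  for (m in microbiomes) {
    stopifnot(inherits(m, "microbiome"))
    out[m$taxa] <- out[m$taxa] + m$abundance
  }
  if (sum(out) == 0) stop("all microbiomes are empty; no population source")
  out / sum(out)
}

#' Build the offspring sampling pool
#'
#' The pool from which an offspring samples its microbes weighs the parental
#' source by the vertical transmission coefficient `Tv` and the
#' population-wide source by the horizontal coefficient `Th`:
#' `weight_i = Tv * P_i + Th * E_i`.
#'
#' @param parent_source relative-abundance vector of the parent
#'   ([normalize_source()]).
#' @param population_source relative-abundance vector of the previous
#'   population ([population_source()]).
#' @param Tv,Th non-negative transmission coefficients, `Tv + Th > 0`.
#' @return An object of class `"sampling_pool"`: a numeric weight vector of
#'   length `B` with `Tv` and `Th` attached as attributes.
#' @export
build_pool <- function(parent_source, population_source, Tv, Th) {
  stopifnot("Tv and Th must be non-negative" = Tv >= 0 && Th >= 0,
            "Tv + Th must be positive" = Tv + Th > 0,
            "source lengths differ" =
              length(parent_source) == length(population_source))
  structure(Tv * parent_source + Th * population_source,
            Tv = Tv, Th = Th, class = "sampling_pool")
}

#' Seed a first-generation microbiome
#'
#' First-generation hosts are seeded with taxa drawn uniformly without
#' replacement from the `B` available taxa, each assigned at random to a
#' distinct template slot.
#'
#' @param template slot-size vector ([generate_template()]).
#' @param B total number of taxa; must be at least the number of slots.
#' @return A [microbiome()] with one distinct taxon per slot.
#' @export
seed_initial_microbiome <- function(template, B) {
  n <- length(template)
  if (n > B) stop("template has more slots than available taxa")
  microbiome(sample.int(B, n), template)
}

## Sequential weighted sampling without replacement via exponential clocks:
## drawing taxa one at a time with probability proportional to weight among
## those not yet drawn is distributionally identical to sorting taxa by
## Exp(1)/weight and taking the smallest keys. O(n log n) instead of O(n*k).
.acquire_from_weights <- function(ids, w, template) {
  k <- min(length(template), length(ids))
  keys <- rexp(length(ids)) / w
  ord <- order(keys)[seq_len(k)]
  microbiome(ids[ord], template[seq_len(k)])
}

#' Acquire a microbiome from a sampling pool
#'
#' Taxa are drawn from the pool sequentially without replacement, each draw
#' weighted by pool abundance, and the i-th drawn taxon fills the i-th
#' template slot (establishment order). Abundant pool taxa therefore tend to
#' establish first and inhabit the larger, earlier slots. If the pool holds
#' fewer distinct taxa than the template has slots, the surplus slots remain
#' unfilled and the microbiome has fewer species.
#'
#' @param template slot-size vector ([generate_template()]).
#' @param pool a [build_pool()] result, or any non-negative weight vector
#'   indexed by taxon id.
#' @return A [microbiome()].
#' @export
acquire_microbiome <- function(template, pool) {
  ids <- which(pool > 0)
  if (length(ids) == 0) stop("empty sampling pool")
  .acquire_from_weights(ids, pool[ids], template)
}
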