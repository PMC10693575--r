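#' Parameters of the neutral microbiome-template assembly process
#'
#' A microbiome "template" is an ordered vector of abundance slots, generated
#' before any simulation by a neutral colonisation process: establishment
#' events arrive as a Poisson process with rate `lambda1`, each event's
#' waiting time is stretched by the inverse of an order-dependent
#' establishment probability, and previously established taxa grow logistically
#' until the summed abundance reaches a global carrying capacity `Cg`.
#' Taxon identities are assigned later, during a simulation.
#'
#' @param scenario establishment-probability scenario: `"null"` (all
#'   probabilities 1), `"exp_decay"` (earlier events are more likely;
#'   probabilities decay as `(Es + exp(-lambda2 * i)) / (1 + Es)`), or
#'   `"hump"` (probabilities peak after a few pioneer taxa; a parabola
#'   `a*(i-p)^2 + b*(i-p) + c` is min-max normalised over
#'   `1:max_events`, rescaled by `Hs` and floored at `Hm`).
#' @param lambda1 positive rate of the establishment Poisson process
#'   (events per unit time before probability scaling).
#' @param Es non-negative scaling factor of the `"exp_decay"` scenario.
#' @param lambda2 non-negative decay rate of the `"exp_decay"` scenario.
#' @param a,b,c parabola coefficients of the `"hump"` scenario.
#' @param p non-negative index of the event with the highest establishment
#'   priority in the `"hump"` scenario.
#' @param Hs non-negative scaling factor of the `"hump"` scenario.
#' @param Hm probability floor of the `"hump"` scenario, in (0, 1].
#' @param Cs positive per-taxon carrying capacity (maximal abundance a
#'   single taxon can reach within a host).
#' @param k positive steepness of the logistic growth curve.
#' @param m positive sigmoid midpoint of the logistic growth curve
#'   (time units since a taxon's own establishment).
#' @param Cg positive global carrying capacity: template generation stops
#'   once total abundance reaches `Cg`. Must satisfy `Cs <= Cg`.
#' @param max_events positive integer horizon over which the establishment
#'   probability vector is evaluated (and normalised, for `"hump"`); also the
#'   hard cap on the number of establishment events per template.
#'
#' @return An object of class `"assembly_params"`.
#' @seealso [template_preset()] for the calibrated species-rich and
#'   species-poor presets, [generate_template()].
#' @export
#' @examples
#' ap <- assembly_params("null", lambda1 = 2, Cs = 50, k = 2, m = 1, Cg = 100)
#' generate_template(ap)
assembly_params <- function(scenario = c("null", "exp_decay", "hump"),
                            lambda1,
                            Es = 0, lambda2 = 0,
                            a = 0, b = 0, c = 0, p = 0, Hs = 0, Hm = 0.01,
                            Cs, k, m, Cg, max_events = 500L) {
  scenario <- match.arg(scenario)
  stopifnot(
    "lambda1 must be a single positive number" =
      is.numeric(lambda1) && length(lambda1) == 1 && lambda1 > 0,
    "Es must be non-negative" = is.numeric(Es) && Es >= 0,
    "lambda2 must be non-negative" = is.numeric(lambda2) && lambda2 >= 0,
    "Hs must be non-negative" = is.numeric(Hs) && Hs >= 0,
    "Hm must be in (0, 1]" = is.numeric(Hm) && Hm > 0 && Hm <= 1,
    "Cs must be positive" = is.numeric(Cs) && Cs > 0,
    "k must be positive" = is.numeric(k) && k > 0,
    "m must be positive" = is.numeric(m) && m > 0,
    "Cg must be positive" = is.numeric(Cg) && Cg > 0,
    "Cs must not exceed Cg" = Cs <= Cg,
    "max_events must be a positive integer" =
      is.numeric(max_events) && max_events >= 1,
    "p must be non-negative" = is.numeric(p) && p >= 0
  )
  structure(
    list(scenario = scenario, lambda1 = lambda1, Es = Es, lambda2 = lambda2,
         a = a, b = b, c = c, p = p, Hs = Hs, Hm = Hm,
         Cs = Cs, k = k, m = m, Cg = Cg,
         max_events = as.integer(max_events)),
    class = "assembly_params")
}

#' Calibrated assembly presets
#'
#' Two template regimes bracket the microbiome structures seen across host
#' taxa. `"species_rich"` emulates a vertebrate-like gut community: 200-300
#' taxa per host spanning prevalent to rare abundances, generated under the
#' hump establishment scenario (pioneer taxa make the host more habitable,
#' later arrivals face increasing competition). `"species_poor"` emulates an
#' insect-like community: 2-5 taxa with one dominant symbiont holding most of
#' the biomass, generated under the exponential-decay scenario with a
#' per-taxon capacity close to the global capacity.
#'
#' @param name `"species_rich"` or `"species_poor"`.
#' @return An [assembly_params()] object.
#' @export
#' @examples
#' length(generate_template(template_preset("species_poor")))
template_preset <- function(name = c("species_rich", "species_poor")) {
  name <- match.arg(name)
  switch(name,
    species_rich = assembly_params(
      scenario = "hump", lambda1 = 2,
      a = -1, b = 0, c = 0, p = 20, Hs = 0.2, Hm = 0.05,
      Cs = 4e3, k = 0.8, m = 3, Cg = 1e6, max_events = 500L),
    species_poor = assembly_params(
      scenario = "exp_decay", lambda1 = 1, Es = 0.05, lambda2 = 1,
      Cs = 8e3, k = 1, m = 5, Cg = 1e4, max_events = 100L))
}

#' Draw raw establishment waiting times
#'
#' Waiting times between consecutive establishment events are exponentially
#' distributed with rate `lambda1`.
#'
#' @param n number of waiting times to draw (>= 1).
#' @param lambda1 positive rate; the mean waiting time is `1/lambda1`.
#' @return Numeric vector of `n` positive waiting times.
#' @export
draw_waiting_times <- function(n, lambda1) {
  stopifnot("n must be a positive integer" = is.numeric(n) && n >= 1,
            "lambda1 must be positive" = is.numeric(lambda1) && lambda1 > 0)
  rexp(n, rate = lambda1)
}

#' Establishment probability vector
#'
#' Evaluates the order-dependent probability of a successful establishment
#' event for events `1:n_events` under the scenario in `params` (see
#' [assembly_params()] for the three scenarios).
#'
#' @param params an [assembly_params()] object.
#' @param n_events number of events to evaluate; defaults to
#'   `params$max_events`. For the `"hump"` scenario the min-max normalisation
#'   is always computed over `1:params$max_events` so that probabilities do
#'   not depend on how many are requested.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
establishment_probabilities <- function(params, n_events = params$max_events) {
  stopifnot(inherits(params, "assembly_params"),
            n_events >= 1, n_events <= params$max_events)
  i <- seq_len(params$max_events)
  s <- switch(params$scenario,
    null = rep(1, params$max_events),
    exp_decay = (params$Es + exp(-params$lambda2 * i)) / (1 + params$Es),
    hump = {
      P <- params$a * (i - params$p)^2 + params$b * (i - params$p) + params$c
      if (max(P) == min(P))
        stop("degenerate hump parabola: P(i) is constant over the horizon")
      nP <- (P - min(P)) / (max(P) - min(P))
      pmax((params$Hs + nP) / (1 + params$Hs), params$Hm)
    })
  s[seq_len(n_events)]
}

#' Scale waiting times by establishment probabilities
#'
#' High-probability events are relatively hastened and low-probability events
#' delayed: the final waiting time of event `i` is `raw_waits[i] / probs[i]`.
#'
#' @param raw_waits positive raw waiting times.
#' @param probs establishment probabilities in (0, 1], same length.
#' @return An object of class `"establishment_schedule"`: a list with
#'   `raw_waits`, `probs` and `final_waits`.
#' @export
scale_waiting_times <- function(raw_waits, probs) {
  stopifnot("lengths differ" = length(raw_waits) == length(probs),
            "waiting times must be positive" = all(raw_waits > 0),
            "probabilities must be in (0, 1]" =
              all(probs > 0) && all(probs <= 1))
  structure(list(raw_waits = raw_waits, probs = probs,
                 final_waits = raw_waits / probs),
            class = "establishment_schedule")
}

#' Logistic within-host growth
#'
#' Abundance of a taxon `elapsed` time units after its own establishment:
#' `Cs / (1 + exp(-k * (elapsed - m)))`.
#'
#' @param elapsed non-negative time since the taxon established.
#' @param Cs per-taxon carrying capacity.
#' @param k logistic steepness.
#' @param m sigmoid midpoint.
#' @return Abundance in (0, Cs), non-decreasing in `elapsed`.
#' @export
logistic_abundance <- function(elapsed, Cs, k, m) {
  stopifnot("elapsed must be non-negative" = all(elapsed >= 0))
  Cs / (1 + exp(-k * (elapsed - m)))
}

## Vectorised logistic without the non-negativity guard, for internal use on
## age matrices that are masked afterwards.
.logistic <- function(elapsed, Cs, k, m) Cs / (1 + exp(-k * (elapsed - m)))

#' Generate one microbiome template
#'
#' Simulates scaled establishment events and logistic growth, and returns the
#' abundance slots present when total abundance first reaches the global
#' carrying capacity `Cg`. Growth is a function of each taxon's age (time
#' since its own establishment), so the population is checked against `Cg`
#' both at establishment events and continuously in between:
#'
#' * if the growing community crosses `Cg` between two events, the template
#'   ends at the crossing time (located by root finding) with the taxa
#'   established so far, and total abundance equals `Cg`;
#' * if an establishment event itself pushes the total to `Cg` or beyond, the
#'   newly established taxon is included and abundances are not truncated.
#'
#' Either way the invariant holds that total abundance is at least `Cg` while
#' dropping the final slot leaves it below `Cg`.
#'
#' @param params an [assembly_params()] object.
#' @param final_waits optional vector of pre-scaled waiting times. When
#'   supplied, no random draws are made, which makes the computation a
#'   deterministic function of the event sequence (used e.g. for validation
#'   against step-by-step reference simulations).
#' @return Numeric vector of positive slot sizes in establishment order
#'   (earlier slots are larger, because older taxa have grown for longer).
#' @export
generate_template <- function(params, final_waits = NULL) {
  stopifnot(inherits(params, "assembly_params"))
  if (is.null(final_waits)) {
    probs <- establishment_probabilities(params)
    raw <- draw_waiting_times(params$max_events, params$lambda1)
    final_waits <- raw / probs
  } else {
    stopifnot("final_waits must be positive" = all(final_waits > 0))
  }
  Tm <- cumsum(final_waits)
  n <- length(Tm)
  ## ages[n, i] = age of taxon i at the time of event n (negative = not yet
  ## established); abundance matrix is lower-triangular after masking
  ages <- outer(Tm, Tm, "-")
  ab <- .logistic(ages, params$Cs, params$k, params$m)
  ab[ages < 0] <- 0
  totals <- rowSums(ab)
  n0 <- which(totals >= params$Cg)[1]
  if (is.na(n0))
    stop("global capacity Cg not reached within max_events establishment ",
         "events; check assembly parameters")
  if (n0 > 1) {
    established <- Tm[seq_len(n0 - 1)]
    gap <- function(t) sum(.logistic(t - established, params$Cs, params$k,
                                     params$m)) - params$Cg
    if (gap(Tm[n0]) >= 0) {
      ## capacity is reached by growth during the waiting time before event
      ## n0; the template ends at the crossing without the n0-th taxon
      root <- uniroot(gap, c(Tm[n0 - 1], Tm[n0]), tol = 1e-12 * Tm[n0])$root
      slots <- .logistic(root - established, params$Cs, params$k, params$m)
      eps <- 1e-12 * Tm[n0]
      while (sum(slots) < params$Cg) {  # guard against root-finding slack
        root <- root + eps
        eps <- eps * 2
        slots <- .logistic(root - established, params$Cs, params$k, params$m)
      }
      return(slots)
    }
  }
  .logistic(Tm[n0] - Tm[seq_len(n0)], params$Cs, params$k, params$m)
}

#' Generate a bank of microbiome templates
#'
#' Templates are pre-generated once and sampled uniformly whenever a host is
#' created, mirroring the separation between the (slow) neutral assembly
#' process and the (fast) population dynamics.
#'
#' @param count number of templates (>= 1).
#' @param params an [assembly_params()] object.
#' @return An object of class `"template_bank"`: a list of slot-size vectors
#'   with the generating parameters attached as attribute `"params"`.
#' @export
#' @examples
#' bank <- generate_template_bank(5, template_preset("species_poor"))
#' lengths(bank)
generate_template_bank <- function(count, params) {
  stopifnot("count must be a positive integer" = is.numeric(count) && count >= 1)
  bank <- lapply(seq_len(count), function(i) generate_template(params))
  structure(bank, params = params, class = "template_bank")
}

#' Write or read a template bank as a tab-separated table
#'
#' One row per slot: `template_id`, `slot_index`, `slot_size`.
#'
#' @param bank a list of slot-size vectors (e.g. from
#'   [generate_template_bank()]).
#' @param path file path.
#' @return `write_template_bank()` returns `path` invisibly;
#'   `read_template_bank()` returns a list of slot-size vectors.
#' @export
write_template_bank <- function(bank, path) {
  df <- data.frame(
    template_id = rep(seq_along(bank), lengths(bank)),
    slot_index = unlist(lapply(lengths(bank), seq_len)),
    slot_size = unlist(bank))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("template_id", "slot_index", "slot_size") %in% names(df)))
  df <- df[order(df$template_id, df$slot_index), ]
  structure(unname(split(df$slot_size, df$template_id)),
            class = "template_bank")
}
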