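# Independent reference implementations used to validate the fast paths.

# Step-by-step template simulation on a fine time grid: establish taxa at
# the injected event times, grow every established taxon logistically with
# its age, stop at the first grid point where total abundance reaches Cg.
grid_template_oracle <- function(final_waits, params, dt = 1e-4) {
  events <- cumsum(final_waits)
  established <- numeric(0)
  t <- 0
  next_event <- 1L
  repeat {
    t <- t + dt
    while (next_event <= length(events) && events[next_event] <= t) {
      established <- c(established, events[next_event])
      next_event <- next_event + 1L
    }
    if (length(established) > 0) {
      sizes <- params$Cs / (1 + exp(-params$k * ((t - established) - params$m)))
      if (sum(sizes) >= params$Cg) return(sizes)
    }
    if (next_event > length(events) && t > max(events) + 1e4 * dt)
      stop("oracle failed to reach Cg")
  }
}

# Exact probability of drawing a given ordering under sequential weighted
# sampling without replacement.
successive_sampling_prob <- function(perm, w) {
  p <- 1
  remaining <- sum(w)
  for (i in perm) {
    p <- p * w[i] / remaining
    remaining <- remaining - w[i]
  }
  p
}

# Exhaustive genealogy tracing: given a list of parent-index vectors (one
# per generation, indices into the previous generation), walk every final
# individual back to generation 0 and count distinct founders.
trace_founders_oracle <- function(parent_vectors) {
  N <- length(parent_vectors[[length(parent_vectors)]])
  founders <- vapply(seq_len(N), function(i) {
    idx <- i
    for (g in rev(seq_along(parent_vectors))) idx <- parent_vectors[[g]][idx]
    idx
  }, integer(1))
  length(unique(founders))
}

# Small deterministic assembly parameter set for fast template tests.
toy_assembly <- function(...) {
  defaults <- list(scenario = "null", lambda1 = 1, Cs = 50, k = 1, m = 2,
                   Cg = 200, max_events = 200L)
  args <- utils::modifyList(defaults, list(...))
  do.call(assembly_params, args)
}
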