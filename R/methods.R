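#' @export
print.scenario_config <- function(x, ...) {
  mode <- if (x$neutral) "neutral (pure drift)"
  else sprintf("Tv = %g, Th = %g; %s templates, %s contributions",
               x$Tv, x$Th, x$assembly$scenario, x$contributions$scheme)
  cat(sprintf("Host-microbiome scenario: N = %d, B = %d\n", x$N, x$B))
  cat(" ", mode, "\n", sep = "")
  cat(sprintf("  stop at AC <= %d (max %d generations), seed %d\n",
              x$AC_threshold, x$max_generations, x$seed))
  invisible(x)
}

#' @export
print.holosim_result <- function(x, ...) {
  gens <- nrow(x$trajectory) - 1L
  if (x$censored)
    cat(sprintf("Simulation censored after %d generations (AC = %d)\n",
                gens, x$trajectory$ancestor_count[gens + 1L]))
  else
    cat(sprintf(
      "Coalesced to <= %d ancestral lineage(s) at generation %d\n",
      x$config$AC_threshold, x$coalescence_generation))
  cat(sprintf("  N = %d, B = %d; first-generation fitness var = %.4g\n",
              x$config$N, x$config$B, x$trajectory$fitness_var[1L]))
  invisible(x)
}

#' @export
summary.holosim_result <- function(object, ...) {
  tr <- object$trajectory
  cat(sprintf("Generations simulated: %d (coalescence at %s)\n",
              nrow(tr) - 1L,
              if (object$censored) "none [censored]"
              else object$coalescence_generation))
  print(tr[c(1L, nrow(tr)), ], row.names = FALSE)
  invisible(object)
}

#' @export
plot.holosim_result <- function(x, ...) {
  tr <- x$trajectory
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(oldpar))
  plot(tr$generation, tr$ancestor_count, type = "s",
       xlab = "generation", ylab = "ancestral lineages",
       main = "Lineage coalescence", ...)
  graphics::abline(h = x$config$AC_threshold, lty = 2)
  plot(tr$generation, tr$fitness_var, type = "l",
       xlab = "generation", ylab = "fitness variance",
       main = "Within-generation fitness variance", ...)
  invisible(x)
}

#' @export
print.holosim_experiment <- function(x, ...) {
  ct <- x$summary$coalescence_generation
  cat(sprintf("holosim experiment%s: %d replicates, N = %d\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$summary), x$config$N))
  cat(sprintf("  coalescence generation: mean %.1f, median %.1f (%d censored)\n",
              mean(ct, na.rm = TRUE), median(ct, na.rm = TRUE),
              sum(x$summary$censored)))
  cat(sprintf("  first-generation fitness variance: mean %.4g\n",
              mean(x$summary$first_gen_fitness_var)))
  invisible(x)
}

#' @export
summary.holosim_experiment <- function(object, ...) {
  summarize_experiment(list(object))
}

#' @export
plot.holosim_experiment <- function(x, ...) {
  ct <- x$summary$coalescence_generation
  graphics::hist(ct, breaks = "FD",
                 xlab = "generations to coalescence",
                 main = x$name %||% "coalescence times", ...)
  graphics::abline(v = mean(ct, na.rm = TRUE), lty = 2)
  invisible(x)
}

#' @export
print.pairwise_diversity <- function(x, ...) {
  cat(sprintf("Mean pairwise Jaccard distance: %.4f (%d pairs)\n",
              x$mean_jaccard, x$n_pairs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
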