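#' Parameters of the per-taxon fitness-contribution distribution
#'
#' Each of the `B` taxa is assigned a fixed contribution `c_j` to host
#' fitness at the start of a simulation, drawn once from a background
#' distribution on `[Cmin, Cmax]` and held constant thereafter.
#'
#' Two schemes are supported. `"step"`: taxa contribute either `Cmax` or
#' `Cmin`; with `step_mode = "probability"` each taxon independently receives
#' `Cmax` with probability `lambda3`, with `step_mode = "count"` exactly
#' `lambda3` taxa (chosen uniformly) receive `Cmax`. `"exp_decay"`:
#' `c_j = Cmin + (Cmax - Cmin) * u_j` with `u_j` drawn from an Exp(`lambda3`)
#' distribution truncated to `[0, 1]`, so that large `lambda3` concentrates
#' mass near `Cmin` with a thin high-contribution tail and `lambda3 = 0`
#' recovers the uniform distribution on `[Cmin, Cmax]`.
#'
#' @param scheme `"step"` or `"exp_decay"`.
#' @param lambda3 rate/probability/count parameter (see above).
#' @param Cmin,Cmax minimal and maximal possible contributions,
#'   `Cmin <= Cmax`.
#' @param step_mode `"probability"` or `"count"` (step scheme only).
#' @return An object of class `"contribution_params"`.
#' @seealso [contribution_preset()], [draw_contributions()].
#' @export
contribution_params <- function(scheme = c("step", "exp_decay"),
                                lambda3,
                                Cmin = 0, Cmax = 1,
                                step_mode = c("probability", "count")) {
  scheme <- match.arg(scheme)
  step_mode <- match.arg(step_mode)
  stopifnot("lambda3 must be a non-negative number" =
              is.numeric(lambda3) && length(lambda3) == 1 && lambda3 >= 0,
            "Cmin must not exceed Cmax" = Cmin <= Cmax)
  if (scheme == "step" && step_mode == "probability" && lambda3 > 1)
    stop("in probability mode lambda3 is a probability and must be in [0, 1]")
  structure(list(scheme = scheme, lambda3 = lambda3,
                 Cmin = Cmin, Cmax = Cmax, step_mode = step_mode),
            class = "contribution_params")
}

#' Named contribution presets
#'
#' The three background distributions used to contrast selection regimes:
#' * `"uniform"`: a nearly flat density (truncated-exponential with
#'   `lambda3 = 0.1`) on `[1, 2]` — every taxon contributes a similar,
#'   strictly positive amount, with all levels in the range about equally
#'   represented. The range is bounded away from zero so that this scenario
#'   isolates low relative contribution variance, as opposed to the two
#'   skewed scenarios below in which many taxa contribute next to nothing;
#' * `"midpoint"`: truncated-exponential with `lambda3 = 8` on `[0, 1]`;
#'   most taxa contribute little while a thin tail contributes greatly;
#' * `"step"`: contributions on `{0, 1}`; each taxon contributes the
#'   maximum with probability 0.025 and the minimum otherwise, i.e. 2.5% of
#'   taxa are strong contributors and the rest contribute nothing.
#'
#' The relative spread (coefficient of variation) of the per-taxon
#' contributions increases from uniform (0.19) through midpoint (about 1)
#' to step (6.2), which is what drives the increasing host fitness variance
#' across the three scenarios.
#'
#' @param name `"uniform"`, `"midpoint"` or `"step"`.
#' @return A [contribution_params()] object.
#' @export
contribution_preset <- function(name = c("uniform", "midpoint", "step")) {
  name <- match.arg(name)
  switch(name,
    uniform = contribution_params("exp_decay", lambda3 = 0.1,
                                  Cmin = 1, Cmax = 2),
    midpoint = contribution_params("exp_decay", lambda3 = 8),
    step = contribution_params("step", lambda3 = 0.025,
                               step_mode = "probability"))
}

#' Step contribution vector
#'
#' @param B number of taxa.
#' @param params a [contribution_params()] object with `scheme = "step"`.
#' @return Numeric vector of length `B` with values in `{Cmin, Cmax}`.
#' @export
step_contributions <- function(B, params) {
  stopifnot(inherits(params, "contribution_params"),
            params$scheme == "step",
            "B must be a positive integer" = is.numeric(B) && B >= 1)
  cv <- rep(params$Cmin, B)
  if (params$step_mode == "probability") {
    cv[runif(B) < params$lambda3] <- params$Cmax
  } else {
    if (params$lambda3 != round(params$lambda3) || params$lambda3 > B)
      stop("in count mode lambda3 must be an integer in [0, B]")
    if (params$lambda3 > 0)
      cv[sample.int(B, params$lambda3)] <- params$Cmax
  }
  cv
}

#' Truncated-exponential contribution vector
#'
#' Contributions are `Cmin + (Cmax - Cmin) * u` with `u ~ Exp(lambda3)`
#' truncated to `[0, 1]`, sampled by inverse CDF:
#' `u = -log(1 - U * (1 - exp(-lambda3))) / lambda3` for uniform `U`.
#' `lambda3 = 0` is the uniform limit.
#'
#' @inheritParams step_contributions
#' @param params a [contribution_params()] object with `scheme = "exp_decay"`.
#' @return Numeric vector of length `B` with values in `[Cmin, Cmax]`.
#' @export
exp_decay_contributions <- function(B, params) {
  stopifnot(inherits(params, "contribution_params"),
            params$scheme == "exp_decay",
            "B must be a positive integer" = is.numeric(B) && B >= 1)
  U <- runif(B)
  u <- if (params$lambda3 == 0) U else
    -log(1 - U * (1 - exp(-params$lambda3))) / params$lambda3
  params$Cmin + (params$Cmax - params$Cmin) * u
}

#' Draw a contribution vector under either scheme
#'
#' @inheritParams step_contributions
#' @param params a [contribution_params()] object.
#' @return Numeric vector of length `B` (taxon `j`'s contribution at index
#'   `j`), fixed for the whole simulation.
#' @export
draw_contributions <- function(B, params) {
  stopifnot(inherits(params, "contribution_params"))
  switch(params$scheme,
         step = step_contributions(B, params),
         exp_decay = exp_decay_contributions(B, params))
}

#' Write a contribution vector as a two-column table
#'
#' @param cv numeric contribution vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(cv, path) {
  write.table(data.frame(taxon_id = seq_along(cv), contribution = cv),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
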