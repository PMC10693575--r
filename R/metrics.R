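#' Jaccard distance between two taxa sets
#'
#' `1 - |A intersect B| / |A union B|`, computed on presence/absence.
#'
#' @param A,B vectors of taxon ids (duplicates ignored); at least one must
#'   be non-empty.
#' @return Distance in `[0, 1]`; 0 for identical sets, 1 for disjoint ones.
#' @export
#' @examples
#' jaccard_distance(c(1, 2, 3), c(2, 3, 4))  # 0.5
jaccard_distance <- function(A, B) {
  if (inherits(A, "microbiome")) A <- A$taxa
  if (inherits(B, "microbiome")) B <- B$taxa
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0)
    stop("Jaccard distance is undefined for two empty sets")
  1 - length(intersect(A, B)) / length(union(A, B))
}

## Mean pairwise Jaccard over a list of taxa vectors via an N x B incidence
## matrix: pairwise intersections come from one cross-product, unions from
## the row sums. Assumes no pair of sets is simultaneously empty.
.mean_jaccard <- function(taxa_list, B) {
  N <- length(taxa_list)
  M <- matrix(0, N, B)
  for (i in seq_len(N)) M[i, taxa_list[[i]]] <- 1
  I <- tcrossprod(M)
  sz <- rowSums(M)
  U <- outer(sz, sz, "+") - I
  if (any(U[upper.tri(U)] == 0))
    stop("Jaccard distance is undefined for two empty sets")
  J <- 1 - I / U
  mean(J[upper.tri(J)])
}

#' Mean pairwise Jaccard distance of a population
#'
#' The population's beta diversity: the mean of the Jaccard distances over
#' all `choose(N, 2)` unordered host pairs.
#'
#' @param x a `host_population`, a list of [microbiome()] objects, or a list
#'   of taxa vectors.
#' @param B total number of taxa (inferred from the data when omitted).
#' @return An object of class `"pairwise_diversity"`: list with
#'   `mean_jaccard` and `n_pairs`.
#' @export
mean_pairwise_jaccard <- function(x, B = NULL) {
  if (inherits(x, "host_population")) x <- x$microbiomes
  taxa <- lapply(x, function(m) if (inherits(m, "microbiome")) m$taxa else m)
  N <- length(taxa)
  if (N < 2) stop("at least two hosts are required")
  if (is.null(B)) B <- max(1L, max(unlist(taxa), 0L))
  structure(list(mean_jaccard = .mean_jaccard(taxa, B),
                 n_pairs = (N * (N - 1L)) %/% 2L),
            class = "pairwise_diversity")
}

#' Sample variance of fitness scores
#'
#' The magnitude of fitness differences within one generation, measured as
#' the unbiased (n - 1 denominator) sample variance of the normalised
#' scores.
#'
#' @param fitness numeric vector of length >= 2.
#' @return Non-negative variance.
#' @export
fitness_variance <- function(fitness) {
  if (length(fitness) < 2) stop("at least two fitness scores are required")
  var(fitness)
}

#' Two-sided two-sample t test
#'
#' Welch's unequal-variance t test, as used for all group comparisons of
#' coalescence times and fitness variances. Two identical constant groups
#' carry no evidence of a difference and are reported as `statistic = 0`,
#' `p_value = 1`; constant groups with different values as an infinite
#' statistic with `p_value = 0`.
#'
#' @param groupA,groupB numeric vectors of length >= 2.
#' @return List with `statistic` and `p_value`.
#' @export
two_sided_t_test <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(groupA) - mean(groupB)) * Inf,
                p_value = 0))
  }
  tt <- t.test(groupA, groupB, alternative = "two.sided", var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}
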