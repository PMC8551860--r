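#' Genotype-class proportions after repeated selfing
#'
#' Propagates a (hom-elite, het, hom-wild) genotype-class distribution through
#' \code{n_selfings} generations of self-fertilisation without selection.
#' Each selfing generation halves the heterozygote fraction and adds a quarter
#' of it to each homozygous class.
#'
#' @param start numeric vector of length 3: proportions of homozygous-elite,
#'   heterozygous and homozygous-wild genotypes. Must be non-negative and sum
#'   to 1.
#' @param n_selfings non-negative integer number of selfing generations.
#' @return named numeric vector \code{c(hom_elite, het, hom_wild)} summing
#'   to 1.
#' @examples
#' # BC1 distribution (0.5 elite-hom, 0.5 het) after three selfings:
#' selfing_segregation(c(0.5, 0.5, 0), 3)    # 0.71875 0.0625 0.21875
#' # a pure heterozygote after five selfings:
#' selfing_segregation(c(0, 1, 0), 5)        # 0.484375 0.03125 0.484375
#' @export
selfing_segregation <- function(start, n_selfings) {
  if (!is.numeric(start) || length(start) != 3L || anyNA(start))
    stop("'start' must be a numeric vector of 3 proportions")
  if (any(start < 0) || abs(sum(start) - 1) > 1e-9)
    stop("'start' components must be non-negative and sum to 1")
  if (!is.numeric(n_selfings) || length(n_selfings) != 1L || is.na(n_selfings) ||
      n_selfings < 0 || n_selfings != round(n_selfings))
    stop("'n_selfings' must be a single non-negative integer")
  f <- 0.5^n_selfings
  gain <- start[[2L]] * (1 - f) / 2
  c(hom_elite = start[[1L]] + gain,
    het      = start[[2L]] * f,
    hom_wild = start[[3L]] + gain)
}

.check_pool_args <- function(p_seg, pool_n, k_call) {
  if (!is.numeric(p_seg) || anyNA(p_seg) || any(p_seg < 0) || any(p_seg > 1))
    stop("'p_seg' must be a probability in [0, 1]")
  if (pool_n < 1 || pool_n != round(pool_n))
    stop("'pool_n' must be a positive integer")
  if (any(k_call < 1) || any(k_call > pool_n) || any(k_call != round(k_call)))
    stop("'k_call' must be an integer in [1, pool_n]")
  invisible(TRUE)
}

#' Exact probability of a spurious homozygous pooled call
#'
#' Closed-form binomial upper tail: the probability that at least
#' \code{k_call} of \code{pool_n} independently sampled plants belong to one
#' fixed homozygous class segregating at per-plant probability \code{p_seg},
#' so that the pooled DNA sample is called homozygous for that class.
#'
#' @param p_seg per-plant probability of the homozygous class of interest.
#' @param pool_n number of plants pooled for DNA extraction.
#' @param k_call minimum count of same-class plants that triggers a
#'   homozygous call.
#' @return probability \code{P(X >= k_call)} with
#'   \code{X ~ Binomial(pool_n, p_seg)}.
#' @seealso [pool_bias_sim()] for the Monte-Carlo counterpart.
#' @export
pool_bias_exact <- function(p_seg, pool_n = 12, k_call = pool_n) {
  .check_pool_args(p_seg, pool_n, k_call)
  stats::pbinom(k_call - 1, pool_n, p_seg, lower.tail = FALSE)
}

#' Monte-Carlo probability of a spurious homozygous pooled call
#'
#' Estimates by simulation the probability that a pooled sample of
#' \code{pool_n} plants contains at least \code{k_call} plants of one fixed
#' homozygous class, each plant independently of that class with probability
#' \code{p_seg}. This is the pooled-sampling bias that can convert a still
#' segregating line into an apparently fixed genotype call.
#'
#' The result reports one homozygous class only; for the total probability of
#' a spurious call toward either class, evaluate both class probabilities and
#' sum.
#'
#' @inheritParams pool_bias_exact
#' @param n_trials number of simulated pools.
#' @param seed optional integer seed; when \code{NULL} the current RNG stream
#'   is used.
#' @return list with components \code{estimate}, \code{std_error}
#'   (binomial standard error of the estimate), \code{closed_form}
#'   (the exact tail probability), and the input parameters.
#' @examples
#' pool_bias_sim(0.484375, pool_n = 12, k_call = 12, n_trials = 1e5, seed = 1)
#' @export
pool_bias_sim <- function(p_seg, pool_n = 12, k_call = pool_n,
                          n_trials = 1e6, seed = NULL) {
  .check_pool_args(p_seg, pool_n, k_call)
  if (length(p_seg) != 1L) stop("'p_seg' must be a single probability")
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("'n_trials' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  hits <- stats::rbinom(n_trials, pool_n, p_seg) >= k_call
  est <- mean(hits)
  list(estimate = est,
       std_error = sqrt(est * (1 - est) / n_trials),
       closed_form = pool_bias_exact(p_seg, pool_n, k_call),
       p_seg = p_seg, pool_n = pool_n, k_call = k_call,
       n_trials = n_trials)
}

#' Pooled-sampling bias across a grid of allele segregations
#'
#' Runs [pool_bias_sim()] for every combination of segregation probability
#' and call threshold, emulating the calibration of spurious homozygous-call
#' rates across simulated allele segregations (default 0.05 to 0.95).
#'
#' @param p_seg numeric vector of per-plant class probabilities.
#' @param k_call integer vector of call thresholds (counts out of
#'   \code{pool_n}).
#' @inheritParams pool_bias_sim
#' @return data frame with one row per \code{(p_seg, k_call)} combination and
#'   columns \code{p_seg}, \code{k_call}, \code{estimate}, \code{std_error},
#'   \code{closed_form}.
#' @export
pool_bias_grid <- function(p_seg = seq(0.05, 0.95, by = 0.05),
                           k_call = c(12, 9), pool_n = 12,
                           n_trials = 1e5, seed = NULL) {
  if (length(p_seg) == 0L || length(k_call) == 0L)
    stop("empty grid: 'p_seg' and 'k_call' must be non-empty")
  .check_pool_args(p_seg, pool_n, k_call)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(p_seg = p_seg, k_call = k_call,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- pool_bias_sim(grid$p_seg[i], pool_n, grid$k_call[i], n_trials,
                       seed = NULL)
    data.frame(p_seg = r$p_seg, k_call = r$k_call, estimate = r$estimate,
               std_error = r$std_error, closed_form = r$closed_form)
  })
  do.call(rbind, res)
}
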