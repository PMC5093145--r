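#' Genetic-algorithm configuration
#'
#' A small elitist GA of the kind used to tune the output-layer neuron and
#' plasticity parameters: each generation mutates the current winners by
#' multiplying every parameter with `1 + u`, `u ~ Uniform(-v, +v)` with `v`
#' at most `variation_frac` (maximum 20% relative perturbation), and keeps
#' the `n_winners` fittest candidates. The variation level `v` is halved
#' whenever the best fitness improves by less than `saturation_tol` over a
#' generation, narrowing the search as the classification rate saturates.
#'
#' @param population_size Candidates evaluated per generation.
#' @param n_winners Survivors per generation (default 4).
#' @param variation_frac Initial maximum relative perturbation (0 < v <= 0.2).
#' @param generations Number of generations.
#' @param saturation_tol Relative improvement below which `v` is halved
#'   (default 1%).
#' @param seed RNG seed for the mutation stream.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 16, n_winners = 4,
                      variation_frac = 0.2, generations = 10,
                      saturation_tol = 0.01, seed = 1L) {
  stopifnot(n_winners >= 1, n_winners <= population_size,
            variation_frac >= 0, variation_frac <= 0.2,
            generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 n_winners = as.integer(n_winners),
                 variation_frac = variation_frac,
                 generations = as.integer(generations),
                 saturation_tol = saturation_tol,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Tune parameters with a genetic algorithm
#'
#' Maximizes `fitness(params)` (e.g. the mean recognition rate on a fixed
#' synthetic dataset) over positive named parameters by elitist mutation.
#' Mutated parameters are clipped to `lower`/`upper` (with a warning) so type
#' invariants (positivity, probabilities in \[0, 1\]) are preserved;
#' non-finite fitness values discard the candidate with a warning. The best
#' fitness trace is non-decreasing because winners survive unchanged.
#'
#' @param base_params Named numeric vector of starting parameters (all > 0).
#' @param fitness Function mapping a named parameter vector to a scalar
#'   fitness (larger is better); must be deterministic given its own seed.
#' @param config A [ga_config()].
#' @param lower,upper Optional named clipping bounds.
#' @return List with `best_params`, `best_fitness`, and `trace` (data.frame
#'   per generation: `generation`, `best_fitness`, `variation`).
#' @export
ga_optimize <- function(base_params, fitness, config = ga_config(),
                        lower = NULL, upper = NULL) {
  stopifnot(is.numeric(base_params), !is.null(names(base_params)),
            all(base_params > 0))
  set.seed(substream_seed(config$seed, "ga"))
  clip <- function(p) {
    bad <- p <= 0
    if (any(bad)) {
      warning("non-positive mutated parameters clipped", call. = FALSE)
      p[bad] <- .Machine$double.eps
    }
    if (!is.null(lower)) {
      nm <- intersect(names(p), names(lower))
      p[nm] <- pmax(p[nm], lower[nm])
    }
    if (!is.null(upper)) {
      nm <- intersect(names(p), names(upper))
      p[nm] <- pmin(p[nm], upper[nm])
    }
    p
  }
  eval_fit <- function(p) {
    f <- fitness(p)
    if (!is.finite(f)) {
      warning("non-finite fitness; candidate discarded", call. = FALSE)
      return(-Inf)
    }
    f
  }

  winners <- list(base_params)
  winner_fit <- eval_fit(base_params)
  v <- config$variation_frac
  n_off <- max(1L, config$population_size %/% config$n_winners)
  trace <- data.frame(generation = integer(0), best_fitness = numeric(0),
                      variation = numeric(0))
  best_prev <- winner_fit[1]

  for (gen in seq_len(config$generations)) {
    pop <- winners
    fit <- winner_fit
    for (w in winners) {
      for (k in seq_len(n_off)) {
        u <- stats::runif(length(w), -v, v)
        cand <- clip(w * (1 + u))
        names(cand) <- names(w)
        pop <- c(pop, list(cand))
        fit <- c(fit, eval_fit(cand))
      }
    }
    ord <- order(fit, decreasing = TRUE)[seq_len(min(config$n_winners,
                                                     length(pop)))]
    winners <- pop[ord]
    winner_fit <- fit[ord]
    best <- winner_fit[1]
    improve <- if (abs(best_prev) > 0) (best - best_prev) / abs(best_prev)
      else best - best_prev
    if (is.finite(improve) && improve < config$saturation_tol) v <- v / 2
    best_prev <- best
    trace <- rbind(trace, data.frame(generation = gen, best_fitness = best,
                                     variation = v))
  }
  list(best_params = winners[[1]], best_fitness = winner_fit[1],
       trace = trace)
}
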