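# Hybrid bounded optimizer: population-based global search (genetic
# algorithm over a Latin-hypercube-seeded population) followed by local
# refinement of the elite candidates (Levenberg-Marquardt on the residual
# vector when available, otherwise L-BFGS-B). Deterministic for a fixed seed.

#' @keywords internal
hybrid_optimize <- function(objective, lower, upper, seed = 1L,
                            max_generations = 30L, population_size = 300L,
                            init_candidates = NULL, polish_candidates = NULL,
                            residual_fn = NULL,
                            local_search = TRUE, n_polish = 3L, n_hops = 0L,
                            mutation_prob = 0.15, mutation_sd = 0.1,
                            elite = 2L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower),
            max_generations >= 1, population_size >= 4)
  span <- upper - lower
  safe_obj <- function(p) {
    v <- tryCatch(objective(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pop <- lhs::randomLHS(population_size, d)
  pop <- sweep(sweep(pop, 2, span, "*"), 2, lower, "+")
  if (!is.null(init_candidates)) {
    init_candidates <- init_candidates[seq_len(min(length(init_candidates),
                                                   population_size - 1L))]
    init <- do.call(rbind, lapply(init_candidates, function(p)
      pmin(pmax(p, lower), upper)))
    pop[seq_len(nrow(init)), ] <- init
  }
  if (is.null(polish_candidates)) polish_candidates <- list()
  fit <- apply(pop, 1, safe_obj)
  n_eval <- population_size
  trace <- numeric(max_generations)

  for (gen in seq_len(max_generations)) {
    ord <- order(fit)
    new_pop <- pop[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(new_pop) < population_size) {
      # binary tournament selection of two parents
      pick <- function() {
        i <- sample.int(population_size, 2L)
        i[which.min(fit[i])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      # blend crossover
      a <- stats::runif(d, -0.25, 1.25)
      child <- a * p1 + (1 - a) * p2
      # gaussian mutation
      mut <- stats::runif(d) < mutation_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mutation_sd * span[mut])
      child <- pmin(pmax(child, lower), upper)
      new_pop <- rbind(new_pop, child)
    }
    keep_fit <- fit[ord[seq_len(elite)]]
    pop <- new_pop
    fit <- c(keep_fit, apply(pop[-seq_len(elite), , drop = FALSE], 1, safe_obj))
    n_eval <- n_eval + population_size - elite
    trace[gen] <- min(fit)
  }

  ord <- order(fit)
  best_par <- pop[ord[1], ]
  best_val <- fit[ord[1]]

  if (local_search) {
    starts <- pop[ord[seq_len(min(n_polish, population_size))], , drop = FALSE]
    # injected candidates mark distinct basins (e.g. the all-zero and the
    # heuristic mechanisms); refine them directly even if evolution dropped them
    if (length(polish_candidates))
      starts <- rbind(starts,
                      do.call(rbind, lapply(polish_candidates, function(p)
                        pmin(pmax(p, lower), upper))))
    for (i in seq_len(nrow(starts))) {
      res <- polish_candidate(starts[i, ], objective = safe_obj,
                              residual_fn = residual_fn,
                              lower = lower, upper = upper)
      n_eval <- n_eval + res$n_eval
      if (res$value < best_val) {
        best_val <- res$value
        best_par <- res$par
      }
    }
    # basin hopping: perturb the incumbent and re-refine, keeping improvements
    hop_scales <- c(0.05, 0.15, 0.3)
    for (h in seq_len(n_hops)) {
      sdv <- hop_scales[1 + (h - 1) %% 3] * pmax(abs(best_par), 0.05 * span)
      pert <- pmin(pmax(best_par + stats::rnorm(d, 0, sdv), lower), upper)
      res <- polish_candidate(pert, objective = safe_obj,
                              residual_fn = residual_fn,
                              lower = lower, upper = upper)
      n_eval <- n_eval + res$n_eval
      if (res$value < best_val) {
        best_val <- res$value
        best_par <- res$par
      }
    }
  }

  list(par = pmin(pmax(best_par, lower), upper), value = best_val,
       trace = trace, n_eval = n_eval, seed = seed,
       lower = lower, upper = upper)
}

# Local refinement. Levenberg-Marquardt needs the residual vector whose sum
# of squares is the objective; the box constraints are passed through.
polish_candidate <- function(start, objective, residual_fn, lower, upper) {
  n_eval <- 0L
  if (!is.null(residual_fn)) {
    fn <- function(p) {
      r <- tryCatch(residual_fn(pmin(pmax(p, lower), upper)),
                    error = function(e) NULL)
      n_eval <<- n_eval + 1L
      if (is.null(r) || anyNA(r)) rep(1e6, 2) else r
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      par <- pmin(pmax(fit$par, lower), upper)
      return(list(par = par, value = objective(par), n_eval = n_eval))
    }
  }
  fit <- tryCatch(
    stats::optim(start, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 300, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = start, value = objective(start), n_eval = 1L))
  list(par = fit$par, value = fit$value, n_eval = fit$counts[1])
}
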