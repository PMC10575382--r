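#' Box-constrained search domain
#'
#' @param lower,upper Numeric vectors of equal length `D` with
#'   `lower[j] < upper[j]` for every coordinate.
#' @return An object of class `search_domain`.
#' @export
search_domain <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) == 0L ||
      any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("invalid search domain")
  }
  structure(list(lower = lower, upper = upper, D = length(lower)),
            class = "search_domain")
}

#' Farmland Fertility Algorithm configuration
#'
#' The FFA is a population metaheuristic that partitions `N = k * n`
#' candidate solutions into `k` farmland "sections" of `n` solutions each,
#' scores each section by its mean fitness, and then (per iteration)
#' perturbs the worst section toward random global-memory elites, mixes the
#' remaining sections with random population members, and hybridises every
#' solution with the global or its section-local best. Elite memories hold
#' the `round(t_global * N)` / `round(t_local * n)` best solutions seen.
#'
#' @param k Number of sections (a warning is raised outside the customary
#'   2..8 band).
#' @param n Solutions per section.
#' @param alpha Scale of the worst-section step, in `[0, 1]`; the step draws
#'   `h = alpha * U(-1, 1)`.
#' @param beta Scale of the other-sections step, in `[0, 1]`;
#'   `h = beta * U(0, 1)`.
#' @param Q Probability threshold for hybridising with the global best
#'   rather than the section best (`Q > u` with `u ~ U(0,1)` selects the
#'   global branch).
#' @param omega1_init Initial weight of the global-best hybridisation step;
#'   decays geometrically by `Rv` each iteration.
#' @param Rv Decay factor, strictly inside (0, 1).
#' @param t_global,t_local Memory-size fractions, strictly inside (0.1, 1).
#' @param max_iters Iteration budget.
#' @param seed Integer seed; identical configuration and objective give an
#'   identical run.
#' @param fitness_target Optional early-stop threshold on the best fitness.
#' @return An object of class `ffa_config`.
#' @export
ffa_config <- function(k = 4L, n = 5L, alpha = 0.6, beta = 0.4, Q = 0.5,
                       omega1_init = 1.0, Rv = 0.8, t_global = 0.2,
                       t_local = 0.5, max_iters = 100L, seed = 1L,
                       fitness_target = NULL) {
  if (k < 1L || n < 1L) stop("bad population shape")
  if (k < 2L || k > 8L)
    warning("k outside the customary 2..8 band")
  if (Rv <= 0 || Rv >= 1) stop("bad decay factor")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1 || Q < 0 || Q > 1)
    stop("alpha, beta and Q must lie in [0,1]")
  if (t_global <= 0.1 || t_global >= 1 || t_local <= 0.1 || t_local >= 1)
    stop("t out of range")
  structure(list(k = as.integer(k), n = as.integer(n), alpha = alpha,
                 beta = beta, Q = Q, omega1_init = omega1_init, Rv = Rv,
                 t_global = t_global, t_local = t_local,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 fitness_target = fitness_target),
            class = "ffa_config")
}

#' Elite memory sizes
#'
#' Global memory holds `round(t_global * N)` solutions with `N = k * n`;
#' each of the `k` local memories holds `round(t_local * n)`. Rounding is
#' half away from zero with a floor of one slot.
#'
#' @param cfg An [ffa_config()].
#' @return List with integers `M_global` and `M_local`.
#' @export
ffa_memory_sizes <- function(cfg) {
  stopifnot(inherits(cfg, "ffa_config"))
  if (cfg$t_global <= 0.1 || cfg$t_global >= 1 ||
      cfg$t_local <= 0.1 || cfg$t_local >= 1) {
    stop("t out of range")
  }
  N <- cfg$k * cfg$n
  list(M_global = max(1L, as.integer(round_half_away(cfg$t_global * N))),
       M_local = max(1L, as.integer(round_half_away(cfg$t_local * cfg$n))))
}

empty_memory <- function(D) list(solutions = matrix(0, 0L, D),
                                 fitness = numeric(0))

## Merge candidates into an elite memory: stable ascending sort on fitness
## (pre-existing members win ties), exact-duplicate rows removed, truncated
## to the capacity.
merge_memory <- function(mem, solutions, fitness, capacity) {
  sols <- rbind(mem$solutions, solutions)
  fits <- c(mem$fitness, fitness)
  ord <- order(fits)  # stable
  sols <- sols[ord, , drop = FALSE]
  fits <- fits[ord]
  keep <- !duplicated(sols, MARGIN = 1L)
  sols <- sols[keep, , drop = FALSE]
  fits <- fits[keep]
  take <- seq_len(min(capacity, length(fits)))
  list(solutions = sols[take, , drop = FALSE], fitness = fits[take])
}

#' Initialise an FFA run
#'
#' Draws `N = k * n` solutions coordinate-wise uniformly within the bounds
#' from the seeded generator, evaluates them, partitions them into
#' sections, and fills the elite memories.
#'
#' @param objective Function mapping a length-`D` numeric vector to a finite
#'   scalar fitness (minimised).
#' @param domain A [search_domain()].
#' @param cfg An [ffa_config()].
#' @return An object of class `ffa_state`.
#' @export
ffa_initialize <- function(objective, domain, cfg) {
  stopifnot(inherits(domain, "search_domain"), inherits(cfg, "ffa_config"))
  if (cfg$k < 1L || cfg$n < 1L) stop("bad population shape")
  set.seed(cfg$seed)
  N <- cfg$k * cfg$n
  D <- domain$D
  pop <- matrix(stats::runif(N * D), N, D)
  pop <- sweep(sweep(pop, 2L, domain$upper - domain$lower, "*"),
               2L, domain$lower, "+")
  state <- structure(
    list(population = pop, fitness = rep(NA_real_, N),
         section_of = integer(N), section_quality = rep(NA_real_, cfg$k),
         global_memory = empty_memory(D),
         local_memories = rep(list(empty_memory(D)), cfg$k),
         best_global = NULL, best_local = vector("list", cfg$k),
         omega1 = cfg$omega1_init, iteration = 0L, evals = 0L,
         objective = objective, domain = domain, cfg = cfg),
    class = "ffa_state")
  state$fitness <- vapply(seq_len(N), function(i)
    eval_shielded(objective, pop[i, ]), numeric(1))
  state$evals <- N
  state <- ffa_partition_sections(state)
  state$section_quality <- ffa_section_quality(state)
  ffa_update_memories(state)
}

#' Assign population rows to sections
#'
#' Section `s` (1-based) holds population rows `n*(s-1)+1 .. n*s`: the
#' partition is by array order with no sorting.
#'
#' @param state An `ffa_state`.
#' @return The state with `section_of` refreshed.
#' @export
ffa_partition_sections <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  k <- state$cfg$k
  N <- nrow(state$population)
  if (N %% k != 0L) stop("indivisible population")
  state$section_of <- rep(seq_len(k), each = N %/% k)
  state
}

#' Mean fitness per section
#'
#' The worst section is the one with the largest mean fitness
#' (minimisation); ties resolve toward the lower section index.
#'
#' @param state An `ffa_state`.
#' @return Numeric vector of length `k` of section mean fitnesses.
#' @export
ffa_section_quality <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  as.numeric(tapply(state$fitness, state$section_of, mean)[
    as.character(seq_len(state$cfg$k))])
}

worst_section <- function(state) which.max(state$section_quality)

#' Refresh the elite memories and best solutions
#'
#' Merges the current population into the global memory and each section's
#' local memory (stable ascending order, duplicates dropped, truncated to
#' the capacities of [ffa_memory_sizes()]); the memory heads become
#' `best_global` / `best_local`, so the recorded best never worsens.
#'
#' @param state An `ffa_state`.
#' @return The updated state.
#' @export
ffa_update_memories <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  ms <- ffa_memory_sizes(state$cfg)
  state$global_memory <- merge_memory(state$global_memory, state$population,
                                      state$fitness, ms$M_global)
  for (s in seq_len(state$cfg$k)) {
    rows <- which(state$section_of == s)
    state$local_memories[[s]] <- merge_memory(
      state$local_memories[[s]], state$population[rows, , drop = FALSE],
      state$fitness[rows], ms$M_local)
    state$best_local[[s]] <- list(
      solution = state$local_memories[[s]]$solutions[1L, ],
      fitness = state$local_memories[[s]]$fitness[1L])
  }
  state$best_global <- list(solution = state$global_memory$solutions[1L, ],
                            fitness = state$global_memory$fitness[1L])
  state
}

clip_bounds <- function(x, domain) pmin(pmax(x, domain$lower), domain$upper)

## Propose-and-keep-if-better replacement shared by the three phases.
greedy_replace <- function(state, i, x_new) {
  x_new <- clip_bounds(x_new, state$domain)
  f_new <- eval_shielded(state$objective, x_new)
  state$evals <- state$evals + 1L
  if (f_new < state$fitness[i]) {
    state$population[i, ] <- x_new
    state$fitness[i] <- f_new
  }
  state
}

#' Worst-section update phase
#'
#' Every solution `x` in the worst-quality section takes a step
#' `x_new = h * (x - x_mem) + x` with `h = alpha * U(-1, 1)` and `x_mem`
#' drawn uniformly from the global memory; the move is clipped to the
#' bounds and kept only if it improves the solution's fitness.
#'
#' @param state An `ffa_state` with populated memories.
#' @return The updated state.
#' @export
ffa_worst_section_update <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  if (length(state$global_memory$fitness) == 0L)
    stop("memory not initialized")
  ws <- worst_section(state)
  M <- length(state$global_memory$fitness)
  for (i in which(state$section_of == ws)) {
    h <- state$cfg$alpha * stats::runif(1L, -1, 1)
    x_mem <- state$global_memory$solutions[sample.int(M, 1L), ]
    x_new <- h * (state$population[i, ] - x_mem) + state$population[i, ]
    state <- greedy_replace(state, i, x_new)
  }
  state
}

#' Other-sections update phase
#'
#' Every solution outside the worst section takes a step
#' `x_new = h * (x - x_u) + x` with `h = beta * U(0, 1)` and `x_u` an
#' arbitrary member of the current population; clipped and kept only on
#' improvement.
#'
#' @param state An `ffa_state`.
#' @return The updated state.
#' @export
ffa_other_sections_update <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  ws <- worst_section(state)
  N <- nrow(state$population)
  for (i in which(state$section_of != ws)) {
    h <- state$cfg$beta * stats::runif(1L)
    x_u <- state$population[sample.int(N, 1L), ]
    x_new <- h * (state$population[i, ] - x_u) + state$population[i, ]
    state <- greedy_replace(state, i, x_new)
  }
  state
}

#' Combination (hybridisation) phase
#'
#' Every solution draws `u ~ U(0, 1)`: if `Q > u` it moves by
#' `omega1 * (x - best_global)`, otherwise by `v * (x - best_local)` with
#' `v ~ U(0, 1)` and its own section's best; clipped, greedy replacement.
#'
#' @param state An `ffa_state` with bests available.
#' @return The updated state.
#' @export
ffa_combination_phase <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  if (is.null(state$best_global)) stop("memory not initialized")
  for (i in seq_len(nrow(state$population))) {
    x <- state$population[i, ]
    if (state$cfg$Q > stats::runif(1L)) {
      x_new <- x + state$omega1 * (x - state$best_global$solution)
    } else {
      s <- state$section_of[i]
      x_new <- x + stats::runif(1L) * (x - state$best_local[[s]]$solution)
    }
    state <- greedy_replace(state, i, x_new)
  }
  state
}

#' Decay the global-hybridisation weight
#'
#' `omega1 <- omega1 * Rv` once per iteration, `0 < Rv < 1`, so the global
#' pull fades geometrically and the search settles.
#'
#' @param state An `ffa_state`.
#' @return The updated state.
#' @export
ffa_decay_omega <- function(state) {
  stopifnot(inherits(state, "ffa_state"))
  Rv <- state$cfg$Rv
  if (Rv <= 0 || Rv >= 1) stop("bad decay factor")
  state$omega1 <- state$omega1 * Rv
  state
}

#' Run the Farmland Fertility Algorithm
#'
#' Full optimisation loop: after seeded initialisation, each iteration
#' re-partitions, recomputes section qualities, refreshes the elite
#' memories, applies the worst-section, other-sections and combination
#' phases (each with greedy keep-if-better replacement and hard clipping to
#' the bounds), and decays `omega1`. Stops at `max_iters` or when
#' `fitness_target` is reached. Greedy replacement plus elitist memories
#' make the best-so-far trace non-increasing.
#'
#' @inheritParams ffa_initialize
#' @return List of class `ffa_result`: `best` (solution vector), `fitness`,
#'   `trace` (best-so-far per iteration), `initial_fitness` (fitness of the
#'   initial population), `evals`, `iterations` and the final `state`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ffa_optimize(sphere, search_domain(c(-5, -5), c(5, 5)),
#'                     ffa_config(max_iters = 50, seed = 1))
#' res$fitness
#' @export
ffa_optimize <- function(objective, domain, cfg) {
  state <- ffa_initialize(objective, domain, cfg)
  initial_fitness <- state$fitness
  best_f <- min(state$fitness)
  best_x <- state$population[which.min(state$fitness), ]
  trace <- numeric(0)
  iters <- 0L
  for (it in seq_len(cfg$max_iters)) {
    state <- ffa_partition_sections(state)
    state$section_quality <- ffa_section_quality(state)
    state <- ffa_update_memories(state)
    state <- ffa_worst_section_update(state)
    state <- ffa_other_sections_update(state)
    state <- ffa_combination_phase(state)
    state <- ffa_decay_omega(state)
    state$iteration <- it
    iters <- it
    if (min(state$fitness) < best_f) {
      best_f <- min(state$fitness)
      best_x <- state$population[which.min(state$fitness), ]
    }
    trace[it] <- best_f
    if (!is.null(cfg$fitness_target) && best_f <= cfg$fitness_target) break
  }
  structure(list(best = best_x, fitness = best_f, trace = trace,
                 initial_fitness = initial_fitness, evals = state$evals,
                 iterations = iters, state = state),
            class = "ffa_result")
}

#' @export
print.ffa_result <- function(x, ...) {
  cat(sprintf("<ffa_result> best fitness %.6g after %d iterations (%d evaluations)\n",
              x$fitness, x$iterations, x$evals))
  invisible(x)
}
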