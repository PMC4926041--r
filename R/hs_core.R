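#' @keywords internal
clip_to_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

new_harmony_memory <- function(vectors, fitness) {
  structure(
    list(
      vectors = vectors,
      fitness = fitness,
      best_index = which.min(fitness),
      worst_index = which.max(fitness)
    ),
    class = "harmony_memory"
  )
}

#' @export
print.harmony_memory <- function(x, ...) {
  cat(sprintf(
    "<harmony_memory> %d vectors x %d dims | best f = %.6g, worst f = %.6g\n",
    nrow(x$vectors), ncol(x$vectors),
    x$fitness[x$best_index], x$fitness[x$worst_index]
  ))
  invisible(x)
}

eval_objective <- function(objective, x, context = "objective") {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop(sprintf(
      "%s returned a non-finite value at x = (%s)",
      context, paste(format(x, digits = 6), collapse = ", ")
    ))
  }
  as.numeric(f)
}

#' Initialize a harmony memory with uniform random vectors
#'
#' Fills the harmony memory with `hms` vectors drawn independently and
#' uniformly from the box `[lower_bound, upper_bound]`
#' (`x = x_L + rand * (x_U - x_L)` per coordinate) and evaluates the
#' objective on every row.  Seeds the random stream from `params$seed`, so
#' two calls with identical parameters produce identical memories.
#'
#' @param params An [hs_params()] object.
#' @param objective A function mapping a numeric vector of length
#'   `params$n_dims` to a single finite number; smaller is better.
#' @return A `harmony_memory`: list with `vectors` (hms x n_dims matrix),
#'   `fitness`, `best_index`, `worst_index` (minimization convention).
#' @export
initialize_memory <- function(params, objective) {
  validate_hs_params(params)
  set.seed(params$seed)
  n <- params$n_dims
  span <- params$upper_bound - params$lower_bound
  vectors <- matrix(runif(params$hms * n), nrow = params$hms, ncol = n)
  vectors <- sweep(sweep(vectors, 2, span, "*"), 2, params$lower_bound, "+")
  fitness <- vapply(
    seq_len(params$hms),
    function(j) eval_objective(objective, vectors[j, ], sprintf("objective (memory row %d)", j)),
    numeric(1)
  )
  new_harmony_memory(vectors, fitness)
}

#' Improvise a new candidate vector
#'
#' Builds one candidate, coordinate by coordinate: with probability `hmcr`
#' the component is copied from a uniformly chosen memory row (memory
#' consideration); a copied component is then, with probability `par`,
#' perturbed by `+/- rand * bw` (pitch adjustment, sign uniform) and clipped
#' to the box; with probability `1 - hmcr` the component is drawn uniformly
#' from its bounds (random selection).
#'
#' For reproducibility the random draws happen in a fixed vectorized order
#' regardless of which branches fire: the hmcr uniforms, the memory row
#' indices, the par uniforms, the perturbation magnitudes, the sign
#' uniforms, then the random-selection uniforms — one block of `n_dims`
#' draws each.
#'
#' @param memory A `harmony_memory`.
#' @param params An [hs_params()] object.
#' @param par Pitch adjusting rate in \[0, 1\] for this improvisation.
#' @param bw Positive bandwidth for this improvisation.
#' @return A numeric vector of length `n_dims`, inside the box.
#' @export
improvise <- function(memory, params, par = params$par_max, bw = params$bw_max) {
  stopifnot(inherits(memory, "harmony_memory"))
  stopifnot(par >= 0, par <= 1, bw > 0)
  n <- params$n_dims
  u_hmcr <- runif(n)
  rows <- sample.int(params$hms, n, replace = TRUE)
  u_par <- runif(n)
  mag <- runif(n)
  u_sign <- runif(n)
  u_rand <- runif(n)

  from_mem <- u_hmcr <= params$hmcr
  x <- params$lower_bound + u_rand * (params$upper_bound - params$lower_bound)
  mem_vals <- memory$vectors[cbind(rows, seq_len(n))]
  x[from_mem] <- mem_vals[from_mem]

  adjust <- from_mem & (u_par <= par)
  if (any(adjust)) {
    sgn <- ifelse(u_sign < 0.5, -1, 1)
    x[adjust] <- x[adjust] + sgn[adjust] * mag[adjust] * bw
  }
  clip_to_box(x, params$lower_bound, params$upper_bound)
}

#' Replace the worst harmony if the candidate improves on it
#'
#' The candidate enters the memory only if its fitness is strictly below the
#' current worst fitness; ties keep the incumbent.  Worst fitness is
#' therefore non-increasing over calls and the best row is never evicted.
#'
#' @param memory A `harmony_memory`.
#' @param candidate In-bounds numeric vector of length `n_dims`.
#' @param objective The objective function.
#' @param params An [hs_params()] object (for the bounds check).
#' @param candidate_fitness Optional precomputed fitness of `candidate`.
#' @return The updated `harmony_memory`.
#' @export
update_memory <- function(memory, candidate, objective, params,
                          candidate_fitness = NULL) {
  if (any(candidate < params$lower_bound - 1e-12) ||
      any(candidate > params$upper_bound + 1e-12)) {
    stop("candidate lies outside the box bounds")
  }
  f <- if (is.null(candidate_fitness)) {
    eval_objective(objective, candidate, "objective (candidate)")
  } else {
    candidate_fitness
  }
  if (f < memory$fitness[memory$worst_index]) {
    memory$vectors[memory$worst_index, ] <- candidate
    memory$fitness[memory$worst_index] <- f
    memory$best_index <- which.min(memory$fitness)
    memory$worst_index <- which.max(memory$fitness)
  }
  memory
}

#' Run the harmony search optimizer
#'
#' Initializes the memory, then repeats improvise/update for
#' `max_iterations` iterations (one candidate per iteration).  When no
#' schedules are supplied, PAR is held at `par_max` and BW at `bw_max`.
#' Schedules, when given, are functions of the 1-based iteration index
#' returning the PAR or BW for that iteration.
#'
#' @param params An [hs_params()] object.
#' @param objective Objective function (minimized).
#' @param par_schedule,bw_schedule Optional `function(iteration)` overrides.
#' @param memory Optional pre-built `harmony_memory` to start from (its
#'   fitness must correspond to `objective`); when supplied, the random
#'   stream is still seeded from `params$seed`.
#' @return A list of class `hs_result`: `best` (vector), `best_fitness`,
#'   `history` (data frame with columns iteration, best, worst, mean) and
#'   `memory` (final state).
#' @export
run_hs <- function(params, objective, par_schedule = NULL, bw_schedule = NULL,
                   memory = NULL) {
  validate_hs_params(params)
  if (is.null(memory)) {
    memory <- initialize_memory(params, objective)
  } else {
    set.seed(params$seed)
  }
  n_it <- params$max_iterations
  hist_best <- hist_worst <- hist_mean <- numeric(n_it)
  for (it in seq_len(n_it)) {
    par <- if (is.null(par_schedule)) params$par_max else par_schedule(it)
    bw <- if (is.null(bw_schedule)) params$bw_max else bw_schedule(it)
    cand <- improvise(memory, params, par = par, bw = bw)
    f <- tryCatch(
      eval_objective(objective, cand, "objective"),
      error = function(e) stop(sprintf("iteration %d: %s", it, conditionMessage(e)))
    )
    memory <- update_memory(memory, cand, objective, params, candidate_fitness = f)
    hist_best[it] <- memory$fitness[memory$best_index]
    hist_worst[it] <- memory$fitness[memory$worst_index]
    hist_mean[it] <- mean(memory$fitness)
  }
  structure(
    list(
      best = memory$vectors[memory$best_index, ],
      best_fitness = memory$fitness[memory$best_index],
      history = data.frame(
        iteration = seq_len(n_it),
        best = hist_best, worst = hist_worst, mean = hist_mean
      ),
      memory = memory
    ),
    class = "hs_result"
  )
}

#' @export
print.hs_result <- function(x, ...) {
  cat(sprintf(
    "<hs_result> %d iterations | best fitness %.6g at (%s)\n",
    nrow(x$history), x$best_fitness,
    paste(format(x$best, digits = 4), collapse = ", ")
  ))
  invisible(x)
}

#' Export an optimization history as CSV
#'
#' @param result An `hs_result` (from [run_hs()] or [run_improved_hs()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
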