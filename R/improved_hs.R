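# Adaptive schedules for the improved harmony search: a linear pitch
# adjusting rate ramp, a feedback statistic measuring how spread the memory
# still is (distance between the best and worst harmonies), and a two-regime
# bandwidth schedule driven by that feedback.

#' Linear pitch adjusting rate ramp
#'
#' `PAR(t) = par_min + (par_max - par_min) * t / t_max`: small early (strong
#' local exploitation around memory values), large late (wider adjustment).
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Total iteration budget, at least 1.
#' @param par_min,par_max PAR range.
#' @return The PAR for iteration `t`, in `[par_min, par_max]`.
#' @export
adapt_par <- function(t, t_max, par_min, par_max) {
  stopifnot(t_max >= 1)
  if (t < 0 || t > t_max) stop("t must lie in [0, t_max]")
  par_min + (par_max - par_min) * t / t_max
}

#' Best-worst feedback statistic of a harmony memory
#'
#' The ratio `sum_i |x_best,i - x_worst,i| / sum_i (x_best,i - x_worst,i)^2`
#' between the L1 and squared-L2 sizes of the best-minus-worst difference
#' vector.  It grows as the memory collapses (small per-coordinate
#' differences) and is 0 by convention when best and worst coincide.
#'
#' @param memory A `harmony_memory`.
#' @return A non-negative number.
#' @export
feedback_T <- function(memory) {
  stopifnot(inherits(memory, "harmony_memory"))
  diff <- memory$vectors[memory$best_index, ] - memory$vectors[memory$worst_index, ]
  denom <- sum(diff^2)
  if (denom == 0) return(0)
  sum(abs(diff)) / denom
}

#' Feedback-driven bandwidth schedule
#'
#' While the feedback statistic is below `t_max / 2` the bandwidth ramps as
#' `bw_min + (bw_max - bw_min) * feedback * t / t_max`, clamped to
#' `[bw_min, bw_max]`; once feedback reaches `t_max / 2` the bandwidth jumps
#' to `bw_max` (large steps to escape a collapsed memory).
#'
#' @param feedback Non-negative feedback statistic (see [feedback_T()]).
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Iteration budget.
#' @param bw_min,bw_max Bandwidth range.
#' @return The bandwidth for iteration `t`, in `[bw_min, bw_max]`.
#' @export
adapt_bw <- function(feedback, t, t_max, bw_min, bw_max) {
  stopifnot(feedback >= 0, t >= 0, t <= t_max)
  if (feedback >= t_max / 2) return(bw_max)
  bw <- bw_min + (bw_max - bw_min) * feedback * t / t_max
  min(max(bw, bw_min), bw_max)
}

#' Run the improved harmony search
#'
#' The improved optimizer differs from [run_hs()] in two ways: the harmony
#' memory is constructed from the data by the rough-set/KNN procedure
#' ([build_harmony_memory()]) instead of uniform sampling, and PAR/BW follow
#' the adaptive schedules [adapt_par()] and [adapt_bw()], the latter driven
#' by the best-worst feedback statistic recomputed every iteration.  The run
#' stops early once the feedback statistic falls to `stop_threshold`
#' (the memory has collapsed onto a single point); with the default 0 this
#' only triggers when best and worst coincide exactly.
#'
#' @param data Numeric vector or matrix of features the memory is built from.
#' @param rough_params A [rough_params()] object.
#' @param hs_params An [hs_params()] object.
#' @param objective Objective function (minimized), typically
#'   [clustering_fitness()] bound to `data`.
#' @param stop_threshold Early-termination threshold on the feedback
#'   statistic.
#' @return An `hs_result` whose `history` gains columns `par`, `bw`,
#'   `feedback`.
#' @export
run_improved_hs <- function(data, rough_params, hs_params, objective,
                            stop_threshold = 0) {
  memory <- build_harmony_memory(data, rough_params, hs_params, objective)
  set.seed(hs_params$seed)
  t_max <- hs_params$max_iterations
  hist <- matrix(NA_real_, nrow = t_max, ncol = 6,
                 dimnames = list(NULL, c("best", "worst", "mean", "par", "bw", "feedback")))
  n_done <- 0L
  for (it in seq_len(t_max)) {
    par <- adapt_par(it, t_max, hs_params$par_min, hs_params$par_max)
    fb <- feedback_T(memory)
    bw <- adapt_bw(fb, it, t_max, hs_params$bw_min, hs_params$bw_max)
    cand <- improvise(memory, hs_params, par = par, bw = bw)
    f <- tryCatch(
      eval_objective(objective, cand, "objective"),
      error = function(e) stop(sprintf("iteration %d: %s", it, conditionMessage(e)))
    )
    memory <- update_memory(memory, cand, objective, hs_params, candidate_fitness = f)
    hist[it, ] <- c(memory$fitness[memory$best_index],
                    memory$fitness[memory$worst_index],
                    mean(memory$fitness), par, bw, fb)
    n_done <- it
    if (fb <= stop_threshold) break
  }
  hist <- hist[seq_len(n_done), , drop = FALSE]
  structure(
    list(
      best = memory$vectors[memory$best_index, ],
      best_fitness = memory$fitness[memory$best_index],
      history = data.frame(iteration = seq_len(n_done), hist),
      memory = memory
    ),
    class = "hs_result"
  )
}
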