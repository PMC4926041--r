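# Benchmark objectives and small shared fixtures.

sphere <- function(x) sum(x^2)

rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

griewank <- function(x) {
  1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x))))
}

# exhaustive 1-D k-means over contiguous splits of the sorted data; in one
# dimension the optimal partition is contiguous in sorted order, so scanning
# all split-point combinations is a complete search
exhaustive_kmeans_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  best_centers <- NULL
  for (sp in splits) {
    bounds <- c(0, sp, n)
    cost <- 0
    centers <- numeric(k)
    for (i in seq_len(k)) {
      seg <- xs[(bounds[i] + 1):bounds[i + 1]]
      centers[i] <- mean(seg)
      cost <- cost + sum((seg - centers[i])^2)
    }
    if (cost < best) {
      best <- cost
      best_centers <- centers
    }
  }
  list(centers = best_centers, cost = best)
}

# random column-stochastic membership matrix
random_memberships <- function(c, n) {
  U <- matrix(stats::runif(c * n), c, n)
  sweep(U, 2, colSums(U), "/")
}

unit_box_params <- function(n_dims, ..., seed = 1L) {
  hs_params(n_dims = n_dims, lower_bound = 0, upper_bound = 1, seed = seed, ...)
}
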