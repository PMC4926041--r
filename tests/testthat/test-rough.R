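test_that("rough_params enforces the weight and threshold constraints", {
  p <- rough_params(3)
  expect_equal(w_up(p) + p$w_low, 1)
  expect_error(rough_params(3, w_low = 0.5), "w_low")
  expect_error(rough_params(3, w_low = 1), "w_low")
  expect_error(rough_params(3, boundary_threshold = -0.1), "boundary_threshold")
  expect_error(rough_params(0), "k_clusters")
})

test_that("initial centers are evenly spaced quantiles", {
  grid <- seq(0, 1, length.out = 101)
  expect_equal(init_centers(grid, 2),
               unname(stats::quantile(grid, c(0.25, 0.75), type = 5)))
  expect_equal(init_centers(grid, 2), c(0.25, 0.75), tolerance = 0.01)
  expect_equal(init_centers(c(3, 1, 2), 1), 2)        # k = 1 gives the median
  expect_equal(init_centers(c(0, 0.1, 0.9, 1.0), 2), c(0.05, 0.95))
  expect_error(init_centers(c(1, 2), 3), "at least k")
  expect_error(init_centers(c(1, NA), 1), "finite")
  # strictly increasing on data with enough distinct values
  set.seed(4)
  x <- runif(50)
  expect_true(all(diff(init_centers(x, 4)) > 0))
})

test_that("rough assignment splits points into lower sets and boundary", {
  # margin example: 0.4 sits within threshold of both centers
  part <- rough_assign(c(0, 0.4, 1), c(0, 1), 0.3)
  expect_equal(part$lower, list(1L, 3L))
  expect_equal(part$boundary, 2L)
  expect_equal(sort(part$upper[[1]]), c(1L, 2L))
  expect_equal(sort(part$upper[[2]]), c(2L, 3L))

  # threshold 0, no ties: everything is lower-assigned to its nearest center
  x <- c(0.05, 0.1, 0.85, 0.9)
  p0 <- rough_assign(x, c(0.1, 0.9), 0)
  expect_equal(lengths(p0$lower), c(2L, 2L))
  expect_length(p0$boundary, 0)

  # threshold >= data range: every point is a boundary point, lower sets empty
  pb <- rough_assign(x, c(0.1, 0.9), 1)
  expect_true(all(lengths(pb$lower) == 0))
  expect_equal(pb$boundary, seq_along(x))

  expect_error(rough_assign(x, c(0.5, 0.5), 0.1), "distinct")
})

test_that("rough partitions satisfy the approximation invariants", {
  set.seed(11)
  for (trial in 1:20) {
    x <- runif(60)
    k <- sample(2:4, 1)
    thr <- runif(1, 0, 0.3)
    part <- rough_assign(x, init_centers(x, k), thr)
    n <- length(x)
    in_lower <- integer(n)
    in_upper <- integer(n)
    for (i in seq_len(k)) {
      expect_true(all(part$lower[[i]] %in% part$upper[[i]]))
      in_lower[part$lower[[i]]] <- in_lower[part$lower[[i]]] + 1L
      in_upper[part$upper[[i]]] <- in_upper[part$upper[[i]]] + 1L
    }
    expect_true(all(in_lower <= 1))                  # lower sets disjoint
    expect_true(all(in_upper >= 1))                  # upper sets cover
    # exactly one lower set XOR two or more upper sets
    expect_true(all((in_lower == 1) != (in_upper >= 2)))
    expect_setequal(part$boundary, which(in_upper >= 2))
  }
})

test_that("rough center update follows the weighted cascade", {
  # lower mean 0.2, boundary mean 0.8, w_low 0.75 -> 0.35
  x <- c(0.1, 0.3, 0.8)
  part <- structure(
    list(centers = c(0.2, 0.9), lower = list(1:2, integer(0)),
         upper = list(c(1:2, 3L), 3L), boundary = 3L,
         nearest = c(1L, 1L, 2L)),
    class = "rough_partition"
  )
  out <- update_centers_rough(x, part, 0.75)
  expect_equal(out[1], 0.75 * 0.2 + 0.25 * 0.8)
  # cluster 2: lower empty -> mean of its upper approximation
  expect_equal(out[2], 0.8)

  # no boundary points: plain k-means step
  p0 <- rough_assign(c(0, 0.1, 0.9, 1), c(0.1, 0.9), 0)
  expect_equal(update_centers_rough(c(0, 0.1, 0.9, 1), p0, 0.8), c(0.05, 0.95))

  # both lower and boundary empty: center unchanged
  pe <- structure(
    list(centers = c(0.2, 0.9), lower = list(1:3, integer(0)),
         upper = list(1:3, integer(0)), boundary = integer(0),
         nearest = c(1L, 1L, 1L)),
    class = "rough_partition"
  )
  expect_equal(update_centers_rough(c(0, 0.1, 0.2), pe, 0.75)[2], 0.9)
})

test_that("KNN refinement votes among nearest lower-set points", {
  # hand example: boundary point 0.3, lower sets {0.0, 0.1} and {0.9, 1.0}
  x <- c(0.0, 0.1, 0.9, 1.0, 0.3)
  part <- structure(
    list(centers = c(0.05, 0.95), lower = list(1:2, 3:4),
         upper = list(c(1:2, 5L), c(3:4, 5L)), boundary = 5L,
         nearest = c(1L, 1L, 2L, 2L, 1L)),
    class = "rough_partition"
  )
  expect_equal(knn_refine(x, part, 3)[5], 1L)        # votes 2:1 for cluster 1
  expect_equal(knn_refine(x, part, 1)[5], 1L)        # single nearest is 0.1
  expect_equal(knn_refine(x, part, 3)[1:4], c(1L, 1L, 2L, 2L))

  # equidistant between two singleton lower sets with knn_k = 2:
  # vote ties, inverse distances tie, lowest cluster index wins
  x2 <- c(0.2, 0.8, 0.5)
  part2 <- structure(
    list(centers = c(0.2, 0.8), lower = list(1L, 2L),
         upper = list(c(1L, 3L), c(2L, 3L)), boundary = 3L,
         nearest = c(1L, 2L, 1L)),
    class = "rough_partition"
  )
  expect_equal(knn_refine(x2, part2, 2)[3], 1L)

  # empty lower set is rejected with advice
  part_bad <- part2
  part_bad$lower <- list(integer(0), 2L)
  expect_error(knn_refine(x2, part_bad, 2), "boundary_threshold")
})

test_that("weighted KNN vote can override a count majority", {
  # two far votes for cluster 2, one very close vote for cluster 1
  x <- c(0.30, 0.62, 0.64, 0.31)
  part <- structure(
    list(centers = c(0.3, 0.63), lower = list(1L, 2:3),
         upper = list(c(1L, 4L), c(2:3, 4L)), boundary = 4L,
         nearest = c(1L, 2L, 2L, 1L)),
    class = "rough_partition"
  )
  expect_equal(knn_refine(x, part, 3)[4], 2L)                  # unweighted: 2 votes
  expect_equal(knn_refine(x, part, 3, weighted = TRUE)[4], 1L) # 1/0.01 dominates
})

test_that("rough iteration with zero threshold is Lloyd k-means (exhaustive oracle)", {
  set.seed(21)
  for (trial in 1:8) {
    n <- sample(8:12, 1)
    k <- sample(2:3, 1)
    # well-separated groups so Lloyd from quantile starts finds the optimum
    x <- sort(runif(n))
    x <- x + rep(seq(0, by = 3, length.out = k), length.out = n)[order(order(x))]
    x <- sort(x)
    rp <- rough_params(k, boundary_threshold = 0, w_low = 0.75,
                       max_rounds = 50, stop_threshold = 0, seed = trial)
    hp <- hs_params(n_dims = k, lower_bound = min(x), upper_bound = max(x),
                    hms = 1, seed = trial)
    hm <- build_harmony_memory(x, rp, hp, function(v) clustering_fitness(v, x))
    oracle <- exhaustive_kmeans_1d(x, k)
    expect_equal(sort(hm$vectors[1, ]), oracle$centers, tolerance = 1e-8)
  }
})

test_that("harmony memory construction converges on separated data and is seeded", {
  # k spikes: converged centers recover the spike locations exactly
  x <- rep(c(0.1, 0.5, 0.9), each = 20)
  rp <- rough_params(3, boundary_threshold = 0.05, stop_threshold = 0,
                     max_rounds = 50, seed = 5)
  hp <- hs_params(n_dims = 3, lower_bound = 0, upper_bound = 1, hms = 10, seed = 5)
  obj <- function(v) clustering_fitness(v, x)
  hm <- build_harmony_memory(x, rp, hp, obj)
  expect_equal(hm$vectors[1, ], c(0.1, 0.5, 0.9))
  expect_true(all(hm$vectors >= 0 & hm$vectors <= 1))
  expect_equal(hm$fitness, apply(hm$vectors, 1, obj))

  hm2 <- build_harmony_memory(x, rp, hp, obj)
  expect_identical(hm$vectors, hm2$vectors)

  # max_rounds = 0: memory is built from the initial quantile centers
  rp0 <- rough_params(3, max_rounds = 0, seed = 5)
  hm0 <- build_harmony_memory(x, rp0, hp, obj)
  expect_equal(hm0$vectors[1, ], as.numeric(init_centers(x, 3)))
})

test_that("the rough-built memory starts better than a random memory", {
  set.seed(31)
  x <- c(rnorm(100, 0.25, 0.05), rnorm(100, 0.75, 0.05))
  x <- pmin(pmax(x, 0), 1)
  obj <- function(v) clustering_fitness(v, x)
  rp <- rough_params(2, seed = 1)
  better <- vapply(1:50, function(s) {
    hp <- hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1,
                    hms = 10, seed = s)
    rough_best <- min(build_harmony_memory(x, rp, hp, obj)$fitness)
    random_med <- stats::median(initialize_memory(hp, obj)$fitness)
    rough_best <= random_med
  }, logical(1))
  expect_true(all(better))
})
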