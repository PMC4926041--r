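test_that("hs_params validates its fields", {
  expect_s3_class(unit_box_params(3), "hs_params")
  expect_error(hs_params(n_dims = 2, lower_bound = 1, upper_bound = 0),
               "lower_bound")
  expect_error(hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1, hmcr = 1.2),
               "probability")
  expect_error(hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1,
                         par_min = 0.8, par_max = 0.2), "par_min")
  expect_error(hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1,
                         bw_min = 0.5, bw_max = 0.1), "bw_min")
  expect_error(hs_params(n_dims = 2, lower_bound = 0, upper_bound = Inf),
               "finite")
})

test_that("memory initialization is uniform, seeded, and box-respecting", {
  # degenerate box: every row is the single feasible point
  p <- hs_params(n_dims = 3, lower_bound = 0.4, upper_bound = 0.4, hms = 5)
  m <- initialize_memory(p, sphere)
  expect_true(all(m$vectors == 0.4))

  # seeded determinism
  p <- unit_box_params(4, seed = 99)
  m1 <- initialize_memory(p, sphere)
  m2 <- initialize_memory(p, sphere)
  expect_identical(m1$vectors, m2$vectors)
  expect_identical(m1$fitness, m2$fitness)

  # per-coordinate sample mean of a large uniform memory is near 1/2
  p <- hs_params(n_dims = 3, lower_bound = 0, upper_bound = 1,
                 hms = 10000, seed = 7)
  m <- initialize_memory(p, sphere)
  expect_true(all(colMeans(m$vectors) > 0.47 & colMeans(m$vectors) < 0.53))
  expect_true(all(m$vectors >= 0 & m$vectors <= 1))

  # fitness is the objective evaluated on each row, best/worst consistent
  expect_equal(m$fitness, apply(m$vectors, 1, sphere))
  expect_equal(m$best_index, which.min(m$fitness))
  expect_equal(m$worst_index, which.max(m$fitness))
})

test_that("initialization rejects objectives that return non-finite values", {
  p <- unit_box_params(2)
  expect_error(initialize_memory(p, function(x) NaN), "non-finite")
  expect_error(initialize_memory(p, function(x) Inf), "non-finite")
})

test_that("improvisation follows the hmcr/par branch probabilities", {
  p <- hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1, hms = 4, seed = 1)
  m <- initialize_memory(p, sphere)

  # hmcr = 1, par = 0: every component is copied verbatim from memory
  p1 <- hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1,
                  hms = 4, hmcr = 1, seed = 1)
  set.seed(5)
  for (i in 1:20) {
    x <- improvise(m, p1, par = 0, bw = 0.1)
    expect_true(all(vapply(1:2, function(j) x[j] %in% m$vectors[, j], logical(1))))
  }

  # hmcr = 0: components are fresh uniforms, never copied
  p0 <- hs_params(n_dims = 2, lower_bound = 0, upper_bound = 1,
                  hms = 4, hmcr = 0, seed = 1)
  set.seed(6)
  xs <- replicate(200, improvise(m, p0, par = 0.5, bw = 0.1))
  expect_false(any(xs %in% m$vectors))
  expect_true(all(xs >= 0 & xs <= 1))
})

test_that("memory-copy frequency matches hmcr over many improvisations", {
  p <- hs_params(n_dims = 5, lower_bound = 0, upper_bound = 1,
                 hms = 6, hmcr = 0.9, seed = 2)
  m <- initialize_memory(p, sphere)
  set.seed(10)
  n_rep <- 20000L   # 1e5 components at 5 dims each
  hits <- 0L
  for (i in seq_len(n_rep)) {
    x <- improvise(m, p, par = 0, bw = 0.1)
    hits <- hits + sum(vapply(1:5, function(j) x[j] %in% m$vectors[, j], logical(1)))
  }
  frac <- hits / (n_rep * 5)
  expect_gt(frac, 0.89)
  expect_lt(frac, 0.91)
})

test_that("memory update replaces only strictly better-than-worst candidates", {
  p <- hs_params(n_dims = 1, lower_bound = 0, upper_bound = 10, hms = 3, seed = 3)
  m <- initialize_memory(p, function(x) x[1])
  worst_before <- m$fitness[m$worst_index]

  m2 <- update_memory(m, 0, function(x) x[1], p)        # fitness 0 beats all
  expect_lte(m2$fitness[m2$worst_index], worst_before)
  expect_true(0 %in% m2$vectors)

  m3 <- update_memory(m2, 9.99, function(x) x[1], p)    # worse than worst
  expect_identical(m3$vectors, m2$vectors)

  # tie with the worst keeps the incumbent
  worst_val <- m2$vectors[m2$worst_index, 1]
  m4 <- update_memory(m2, worst_val + 1e-30, function(x) x[1], p,
                      candidate_fitness = m2$fitness[m2$worst_index])
  expect_identical(m4$vectors, m2$vectors)

  expect_error(update_memory(m2, 11, function(x) x[1], p), "outside")
})

test_that("run_hs histories are complete, monotone, in-bounds, reproducible", {
  p <- hs_params(n_dims = 3, lower_bound = -2, upper_bound = 2,
                 hms = 10, max_iterations = 300, seed = 8)
  r1 <- run_hs(p, sphere)
  r2 <- run_hs(p, sphere)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
  expect_equal(nrow(r1$history), 300)
  expect_true(all(diff(r1$history$best) <= 0))            # exact monotonicity
  expect_true(all(r1$memory$vectors >= -2 & r1$memory$vectors <= 2))

  # constant objective: best fitness 0 everywhere
  rc <- run_hs(p, function(x) 0)
  expect_true(all(rc$history$best == 0))
})

test_that("with hmcr = 0 the optimizer is a random search (order statistic law)", {
  # 1-D identity objective on [0,1]: the best after n iterations is the
  # minimum of hms + n uniforms, i.e. Beta(1, hms + n)
  hms <- 5L
  n_it <- 20L
  best <- vapply(seq_len(200), function(s) {
    p <- hs_params(n_dims = 1, lower_bound = 0, upper_bound = 1,
                   hms = hms, hmcr = 0, max_iterations = n_it, seed = s)
    run_hs(p, function(x) x[1])$best_fitness
  }, numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(best, stats::pbeta, shape1 = 1, shape2 = hms + n_it)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("history CSV round trips through disk", {
  p <- unit_box_params(2, max_iterations = 10)
  r <- run_hs(p, sphere)
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(r, path)
  back <- utils::read.csv(path)
  expect_equal(back, r$history)
})
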