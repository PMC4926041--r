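# Seeded phantom images with ground truth: k intensity classes laid out by a
# simple geometry, Gaussian class noise, and an optional smooth
# multiplicative bias field, emulating the piecewise-tissue-plus-noise
# structure of grayscale MR slices without modelling MR physics.

phantom_truth <- function(shape, k, geometry, seed) {
  nr <- shape[1]; nc <- shape[2]
  switch(
    geometry,
    stripes = {
      band <- findInterval(seq_len(nr) - 1L, seq(0, nr, length.out = k + 1L),
                           rightmost.closed = TRUE, all.inside = TRUE)
      matrix(rep(band - 1L, nc), nrow = nr)
    },
    nested_disks = {
      cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
      r <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
      cuts <- stats::quantile(r, probs = seq_len(k - 1L) / k, type = 1)
      matrix(findInterval(r, cuts), nrow = nr)
    },
    voronoi = {
      for (try in seq_len(50L)) {
        sy <- sample.int(nr, k, replace = FALSE)
        sx <- sample.int(nc, k, replace = FALSE)
        D <- vapply(seq_len(k), function(i) {
          as.vector(outer((seq_len(nr) - sy[i])^2, (seq_len(nc) - sx[i])^2, "+"))
        }, numeric(nr * nc))
        lab <- matrix(max.col(-D, ties.method = "first") - 1L, nrow = nr)
        if (min(tabulate(lab + 1L, k)) >= 0.05 * nr * nc) return(lab)
      }
      stop("could not place ", k, " voronoi regions each covering >= 5% of pixels")
    },
    stop("unknown geometry: ", geometry)
  )
}

# zero-mean low-order polynomial surface, normalized to max |.| = 1
bias_surface <- function(nr, nc) {
  x <- seq(-1, 1, length.out = nc)
  y <- seq(-1, 1, length.out = nr)
  Yx <- matrix(rep(x, each = nr), nrow = nr)
  Yy <- matrix(rep(y, nc), nrow = nr)
  coefs <- stats::rnorm(5)
  s <- coefs[1] * Yx + coefs[2] * Yy + coefs[3] * Yx * Yy +
    coefs[4] * (Yx^2) + coefs[5] * (Yy^2)
  s <- s - mean(s)
  m <- max(abs(s))
  if (m > 0) s / m else s
}

#' Generate a seeded phantom image with ground truth
#'
#' Lays out `length(class_means)` tissue-like classes by the chosen
#' geometry, sets each pixel to its class mean plus Gaussian noise with the
#' class standard deviation, optionally multiplies a smooth zero-mean bias
#' field `1 + bias_amplitude * surface`, and clips to \[0, 1\].  Every class
#' occupies at least 5 percent of the pixels.  Regeneration with the same
#' arguments is bit-identical.
#'
#' @param shape Integer vector `c(rows, cols)`, each at least 32.
#' @param class_means Strictly increasing class intensities in \[0, 1\].
#' @param class_stds Per-class noise standard deviations (scalar recycled).
#' @param geometry One of `"stripes"`, `"nested_disks"`, `"voronoi"`.
#' @param bias_amplitude Non-negative amplitude of the multiplicative bias
#'   field; 0 disables it.
#' @param seed Integer seed.
#' @return A `phantom`: list with `image` (matrix in \[0, 1\]), `truth`
#'   (integer label matrix, values `0..k-1`), `class_means`, `class_stds`,
#'   `bias_amplitude`, `seed`.
#' @examples
#' ph <- generate_phantom(c(64, 64), c(0.2, 0.5, 0.8), 0.05, seed = 1)
#' table(ph$truth)
#' @export
generate_phantom <- function(shape = c(128L, 128L),
                             class_means = c(0.2, 0.5, 0.8),
                             class_stds = 0.05,
                             geometry = c("nested_disks", "stripes", "voronoi"),
                             bias_amplitude = 0,
                             seed = 1L) {
  geometry <- match.arg(geometry)
  k <- length(class_means)
  if (k < 1L) stop("need at least one class")
  if (is.unsorted(class_means, strictly = TRUE)) {
    stop("class_means must be strictly increasing")
  }
  if (any(class_means < 0 | class_means > 1)) stop("class_means must lie in [0, 1]")
  class_stds <- rep_len(as.numeric(class_stds), k)
  if (any(class_stds < 0)) stop("class_stds must be non-negative")
  if (any(shape < 32L)) stop("shape must be at least 32 x 32")
  if (bias_amplitude < 0) stop("bias_amplitude must be non-negative")

  set.seed(seed)
  truth <- phantom_truth(shape, k, geometry, seed)
  if (min(tabulate(truth + 1L, k)) < 0.05 * prod(shape)) {
    stop("geometry infeasible: some class covers < 5% of pixels")
  }
  img <- matrix(class_means[truth + 1L], nrow = shape[1])
  noise <- matrix(stats::rnorm(prod(shape)), nrow = shape[1]) *
    matrix(class_stds[truth + 1L], nrow = shape[1])
  img <- img + noise
  if (bias_amplitude > 0) {
    img <- img * (1 + bias_amplitude * bias_surface(shape[1], shape[2]))
  }
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(
      image = img, truth = truth,
      class_means = class_means, class_stds = class_stds,
      bias_amplitude = bias_amplitude, seed = as.integer(seed)
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d | %d classes (means %s) | bias %.2f | seed %d\n",
              nrow(x$image), ncol(x$image), length(x$class_means),
              paste(format(x$class_means), collapse = "/"),
              x$bias_amplitude, x$seed))
  invisible(x)
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Permutation-invariant segmentation accuracy
#'
#' Fraction of pixels on which the label map agrees with the ground truth,
#' maximized over all relabelings of the predicted classes (exhaustive over
#' permutations; intended for up to 6 classes).  The prediction may use
#' fewer classes than the truth.
#'
#' @param labels Predicted integer label map (any label coding).
#' @param truth Ground-truth integer label map of the same shape.
#' @return Accuracy in \[0, 1\].
#' @export
segmentation_accuracy <- function(labels, truth) {
  if (!identical(dim(labels), dim(truth)) && length(labels) != length(truth)) {
    stop("labels and truth must have the same shape")
  }
  lf <- factor(as.vector(labels))
  tf <- factor(as.vector(truth))
  tab <- table(lf, tf)
  n_pred <- nlevels(lf)
  n_true <- nlevels(tf)
  if (n_pred > n_true) stop("more predicted classes than truth classes")
  if (n_true > 6L) stop("exhaustive permutation search supports at most 6 classes")
  # pad with zero rows so every permutation of truth columns is an injection
  if (n_pred < n_true) {
    tab <- rbind(tab, matrix(0, n_true - n_pred, n_true))
  }
  best <- 0
  for (p in permutations(seq_len(n_true))) {
    agree <- sum(tab[cbind(seq_len(n_true), p)])
    if (agree > best) best <- agree
  }
  best / length(labels)
}
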