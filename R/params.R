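#' Harmony search hyperparameters
#'
#' Bundles every tunable of the harmony search optimizer: the harmony memory
#' size (HMS), the harmony memory considering rate (HMCR), the range of the
#' pitch adjusting rate (PAR) and of the fine-tuning bandwidth (BW), the
#' dimensionality of the search space, its box bounds, the iteration budget
#' and the RNG seed.
#'
#' When a constant PAR or BW is wanted, set the corresponding `min` and `max`
#' fields equal; [run_hs()] uses `par_max` and `bw_max` when no schedule is
#' supplied.
#'
#' @param hms Harmony memory size, a positive integer (number of stored
#'   candidate vectors).
#' @param hmcr Harmony memory considering rate, a probability in \[0, 1\]:
#'   chance that a new component is copied from memory rather than drawn
#'   uniformly from the bounds.
#' @param par_min,par_max Bounds of the pitch adjusting rate, probabilities
#'   with `par_min <= par_max`.
#' @param bw_min,bw_max Bounds of the pitch-adjustment bandwidth, positive
#'   reals with `bw_min <= bw_max`, in the units of the search variables.
#' @param n_dims Number of decision variables.
#' @param lower_bound,upper_bound Numeric vectors of length `n_dims` (scalars
#'   are recycled) with `lower_bound <= upper_bound` elementwise.
#' @param max_iterations Iteration budget, a positive integer.
#' @param seed Integer seed for the optimizer's random stream.
#'
#' @return An object of class `hs_params` (a validated list).
#' @examples
#' p <- hs_params(n_dims = 3, lower_bound = 0, upper_bound = 1)
#' p$hmcr
#' @export
hs_params <- function(hms = 30L,
                      hmcr = 0.9,
                      par_min = 0.3,
                      par_max = 0.9,
                      bw_min = 0.01,
                      bw_max = 0.1,
                      n_dims,
                      lower_bound,
                      upper_bound,
                      max_iterations = 2000L,
                      seed = 1L) {
  n_dims <- as.integer(n_dims)
  stopifnot(length(n_dims) == 1L, n_dims >= 1L)
  lower_bound <- rep_len(as.numeric(lower_bound), n_dims)
  upper_bound <- rep_len(as.numeric(upper_bound), n_dims)
  p <- structure(
    list(
      hms = as.integer(hms), hmcr = as.numeric(hmcr),
      par_min = as.numeric(par_min), par_max = as.numeric(par_max),
      bw_min = as.numeric(bw_min), bw_max = as.numeric(bw_max),
      n_dims = n_dims,
      lower_bound = lower_bound, upper_bound = upper_bound,
      max_iterations = as.integer(max_iterations),
      seed = as.integer(seed)
    ),
    class = "hs_params"
  )
  validate_hs_params(p)
  p
}

validate_hs_params <- function(p) {
  stopifnot(inherits(p, "hs_params"))
  if (p$hms < 1L) stop("hms must be a positive integer")
  for (f in c("hmcr", "par_min", "par_max")) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("%s must be a probability in [0, 1], got %s", f, format(v)))
    }
  }
  if (p$par_min > p$par_max) stop("par_min must not exceed par_max")
  if (!is.finite(p$bw_min) || !is.finite(p$bw_max) || p$bw_min <= 0) {
    stop("bandwidths must be finite and positive")
  }
  if (p$bw_min > p$bw_max) stop("bw_min must not exceed bw_max")
  if (any(!is.finite(p$lower_bound)) || any(!is.finite(p$upper_bound))) {
    stop("bounds must be finite")
  }
  if (any(p$lower_bound > p$upper_bound)) {
    stop("lower_bound must not exceed upper_bound elementwise")
  }
  if (p$max_iterations < 1L) stop("max_iterations must be positive")
  invisible(p)
}

#' Rough-set harmony memory construction parameters
#'
#' Parameters of the data-driven harmony memory builder: the number of
#' clusters, the margin below which a point is considered ambiguous between
#' two centers (and hence a boundary point), the lower-approximation weight
#' of the rough center update, the neighbourhood size of the KNN refinement,
#' and the convergence controls of the alternating rough iteration.
#'
#' @param k_clusters Number of cluster centers, a positive integer.
#' @param boundary_threshold Non-negative margin, in the units of the data
#'   (intensities in \[0, 1\] for images): a point whose distance to a second
#'   center exceeds its nearest-center distance by no more than this margin
#'   becomes a boundary point of both.
#' @param w_low Weight of the lower-approximation mean in the rough center
#'   update, constrained to (0.5, 1); the upper/boundary weight is `1 - w_low`.
#' @param knn_k Number of nearest labeled neighbours consulted when a boundary
#'   point is resolved to a single cluster.
#' @param max_rounds Maximum number of rough assign/update rounds.
#' @param stop_threshold Convergence tolerance on the maximum center shift
#'   between rounds.
#' @param seed Integer seed (used for the perturbed harmony memory rows).
#'
#' @return An object of class `rough_params`.
#' @export
rough_params <- function(k_clusters,
                         boundary_threshold = 0.05,
                         w_low = 0.75,
                         knn_k = 5L,
                         max_rounds = 20L,
                         stop_threshold = 1e-4,
                         seed = 1L) {
  p <- structure(
    list(
      k_clusters = as.integer(k_clusters),
      boundary_threshold = as.numeric(boundary_threshold),
      w_low = as.numeric(w_low),
      knn_k = as.integer(knn_k),
      max_rounds = as.integer(max_rounds),
      stop_threshold = as.numeric(stop_threshold),
      seed = as.integer(seed)
    ),
    class = "rough_params"
  )
  validate_rough_params(p)
  p
}

validate_rough_params <- function(p) {
  stopifnot(inherits(p, "rough_params"))
  if (p$k_clusters < 1L) stop("k_clusters must be positive")
  if (!is.finite(p$boundary_threshold) || p$boundary_threshold < 0) {
    stop("boundary_threshold must be non-negative")
  }
  if (!(p$w_low > 0.5 && p$w_low < 1)) stop("w_low must lie in (0.5, 1)")
  if (p$knn_k < 1L) stop("knn_k must be at least 1")
  if (p$max_rounds < 0L) stop("max_rounds must be non-negative")
  if (!is.finite(p$stop_threshold) || p$stop_threshold < 0) {
    stop("stop_threshold must be non-negative")
  }
  invisible(p)
}

#' @export
#' @rdname rough_params
#' @param x Object to test.
w_up <- function(x) {
  stopifnot(inherits(x, "rough_params"))
  1 - x$w_low
}

#' Fuzzy c-means parameters
#'
#' @param c_clusters Number of clusters (at least 1).
#' @param fuzzifier Membership softness exponent m, strictly greater than 1.
#'   The default 2 is the universal FCM choice.
#' @param epsilon Convergence tolerance on the maximum absolute center shift.
#' @param max_iter Maximum number of membership/center update passes.
#' @param seed Integer seed, used only by randomly initialized baselines.
#'
#' @return An object of class `fcm_params`.
#' @export
fcm_params <- function(c_clusters,
                       fuzzifier = 2,
                       epsilon = 1e-5,
                       max_iter = 100L,
                       seed = 1L) {
  p <- structure(
    list(
      c_clusters = as.integer(c_clusters),
      fuzzifier = as.numeric(fuzzifier),
      epsilon = as.numeric(epsilon),
      max_iter = as.integer(max_iter),
      seed = as.integer(seed)
    ),
    class = "fcm_params"
  )
  if (p$c_clusters < 1L) stop("c_clusters must be at least 1")
  if (!is.finite(p$fuzzifier) || p$fuzzifier <= 1) stop("fuzzifier must exceed 1")
  if (!is.finite(p$epsilon) || p$epsilon <= 0) stop("epsilon must be positive")
  if (p$max_iter < 1L) stop("max_iter must be positive")
  p
}

# ---- config file round trip ------------------------------------------------

#' Read and write a segmentation config
#'
#' The config is a flat YAML file of namespaced `section.key: value` pairs
#' covering the `hs.*`, `rough.*` and `fcm.*` parameter groups; nested YAML
#' (`hs:` followed by indented keys) is accepted on read as well.  Writing a
#' config and reading it back reproduces the parameter objects exactly.
#'
#' @param path File path.
#' @param hs,rough,fcm Parameter objects ([hs_params()], [rough_params()],
#'   [fcm_params()]); any may be `NULL` to omit the section.
#' @return `read_config()` returns a list with elements `hs`, `rough`, `fcm`
#'   (those present in the file); `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]])) {
      for (sub in names(raw[[nm]])) flat[[paste(nm, sub, sep = ".")]] <- raw[[nm]][[sub]]
    } else {
      flat[[nm]] <- raw[[nm]]
    }
  }
  section <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(flat), value = TRUE)
    if (!length(keys)) return(NULL)
    vals <- flat[keys]
    names(vals) <- sub(paste0("^", prefix, "\\."), "", keys)
    vals
  }
  out <- list()
  hs <- section("hs")
  if (!is.null(hs)) out$hs <- do.call(hs_params, hs)
  rg <- section("rough")
  if (!is.null(rg)) out$rough <- do.call(rough_params, rg)
  fc <- section("fcm")
  if (!is.null(fc)) out$fcm <- do.call(fcm_params, fc)
  out
}

#' @rdname read_config
#' @export
write_config <- function(path, hs = NULL, rough = NULL, fcm = NULL) {
  flat <- list()
  add <- function(prefix, p) {
    for (nm in names(p)) flat[[paste(prefix, nm, sep = ".")]] <<- unclass(p)[[nm]]
  }
  if (!is.null(hs)) add("hs", hs)
  if (!is.null(rough)) add("rough", rough)
  if (!is.null(fcm)) add("fcm", fcm)
  yaml::write_yaml(flat, path)
  invisible(path)
}
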