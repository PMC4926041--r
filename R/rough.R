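# Data-driven harmony memory construction: candidate cluster centers are
# iterated through rough-set lower/upper approximation assignment, a weighted
# rough center update, and a KNN resolution of the boundary region; the
# converged centers seed the harmony memory.

as_data_matrix <- function(data) {
  if (is.matrix(data)) data else matrix(as.numeric(data), ncol = 1L)
}

as_center_matrix <- function(centers, d) {
  if (is.matrix(centers)) centers else matrix(as.numeric(centers), ncol = d)
}

# squared Euclidean distances, n x k
center_dist2 <- function(X, C) {
  n <- nrow(X)
  k <- nrow(C)
  D <- matrix(0, n, k)
  for (j in seq_len(ncol(X))) {
    D <- D + (outer(X[, j], C[, j], "-"))^2
  }
  D
}

#' Deterministic initial cluster centers from data quantiles
#'
#' Places the k initial centers at evenly spaced quantiles of the data
#' (probabilities (2i - 1) / 2k, mid-distribution quantiles, type 5), so the
#' starting centers are deterministic and spread across the observed range.
#' For multi-column data the quantiles are taken per column.
#'
#' @param data Numeric vector (grayscale intensities) or n x d matrix.
#' @param k Number of centers, `k <= n`.
#' @return A numeric vector of k centers (1-D data) or a k x d matrix,
#'   non-decreasing per column and strictly increasing when the data has at
#'   least k distinct values.
#' @export
init_centers <- function(data, k) {
  X <- as_data_matrix(data)
  k <- as.integer(k)
  if (nrow(X) < k) stop("need at least k data points")
  if (any(!is.finite(X))) stop("data must be finite")
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  C <- apply(X, 2, stats::quantile, probs = probs, names = FALSE, type = 5)
  C <- matrix(C, nrow = k)
  if (ncol(C) == 1L) drop(C) else C
}

#' Rough-set assignment of points to candidate centers
#'
#' Each point is compared to its nearest center (distance `d_ij`) and to
#' every other center (`d_i'j`).  Points for which some other center comes
#' within `boundary_threshold` of the nearest distance
#' (`d_i'j - d_ij <= boundary_threshold`) are ambiguous: they join the upper
#' approximations of the nearest center and of every center that qualifies.
#' Unambiguous points join the lower (and upper) approximation of their
#' nearest center.
#'
#' @param data Numeric vector or n x d matrix.
#' @param centers k distinct centers (vector or k x d matrix).
#' @param boundary_threshold Non-negative margin in data units.
#' @return A `rough_partition`: list with `centers`, `lower` and `upper`
#'   (lists of k index vectors), `boundary` (indices in two or more upper
#'   approximations), and `nearest` (nearest-center index per point).
#' @export
rough_assign <- function(data, centers, boundary_threshold) {
  X <- as_data_matrix(data)
  C <- as_center_matrix(centers, ncol(X))
  if (boundary_threshold < 0) stop("boundary_threshold must be non-negative")
  if (anyDuplicated(round(C, 12))) stop("centers must be distinct")
  k <- nrow(C)
  D <- sqrt(center_dist2(X, C))
  nearest <- max.col(-D, ties.method = "first")
  d_near <- D[cbind(seq_len(nrow(X)), nearest)]
  margin_ok <- D - d_near <= boundary_threshold   # includes the nearest itself
  n_close <- rowSums(margin_ok)
  is_boundary <- n_close >= 2L

  lower <- upper <- vector("list", k)
  for (i in seq_len(k)) {
    lower[[i]] <- which(nearest == i & !is_boundary)
    upper[[i]] <- which((nearest == i & !is_boundary) | (is_boundary & margin_ok[, i]))
  }
  structure(
    list(
      centers = centers, lower = lower, upper = upper,
      boundary = which(is_boundary), nearest = nearest
    ),
    class = "rough_partition"
  )
}

#' Rough-weighted center update
#'
#' Moves each center to the weighted mean
#' `w_low * mean(lower_i) + (1 - w_low) * mean(boundary points of upper_i)`.
#' Degenerate cases cascade: with no boundary points the center is the plain
#' lower-set mean (the k-means step); with an empty lower set it is the mean
#' of the upper approximation; with both empty it is left unchanged.
#'
#' @param data Numeric vector or n x d matrix.
#' @param partition A `rough_partition` from [rough_assign()].
#' @param w_low Lower-approximation weight in (0.5, 1).
#' @return Updated centers, same shape as `partition$centers`.
#' @export
update_centers_rough <- function(data, partition, w_low) {
  stopifnot(inherits(partition, "rough_partition"))
  X <- as_data_matrix(data)
  C <- as_center_matrix(partition$centers, ncol(X))
  k <- nrow(C)
  out <- C
  for (i in seq_len(k)) {
    lo <- partition$lower[[i]]
    bd <- setdiff(partition$upper[[i]], lo)
    if (length(lo) && length(bd)) {
      out[i, ] <- w_low * colMeans(X[lo, , drop = FALSE]) +
        (1 - w_low) * colMeans(X[bd, , drop = FALSE])
    } else if (length(lo)) {
      out[i, ] <- colMeans(X[lo, , drop = FALSE])
    } else if (length(bd)) {
      out[i, ] <- colMeans(X[partition$upper[[i]], , drop = FALSE])
    }                                        # both empty: unchanged
  }
  if (!is.matrix(partition$centers)) drop(out) else out
}

# k nearest labeled neighbours of each query point; returns for each query a
# list of (index into labeled set, distance).  1-D data uses a sorted-window
# scan; higher dimensions fall back to chunked brute force.
knn_labeled <- function(X, labeled_idx, queries, k) {
  d <- ncol(X)
  nl <- length(labeled_idx)
  k <- min(k, nl)
  if (d == 1L) {
    lv <- X[labeled_idx, 1L]
    ord <- order(lv)
    lv_sorted <- lv[ord]
    pos <- findInterval(X[queries, 1L], lv_sorted)
    lapply(seq_along(queries), function(qi) {
      q <- X[queries[qi], 1L]
      lo <- max(1L, pos[qi] - k + 1L)
      hi <- min(nl, pos[qi] + k)
      cand <- lo:hi
      dd <- abs(lv_sorted[cand] - q)
      sel <- cand[order(dd)[seq_len(k)]]
      list(idx = labeled_idx[ord[sel]], dist = abs(lv_sorted[sel] - q))
    })
  } else {
    L <- X[labeled_idx, , drop = FALSE]
    out <- vector("list", length(queries))
    chunk <- 256L
    for (s in seq(1L, length(queries), by = chunk)) {
      e <- min(s + chunk - 1L, length(queries))
      Q <- X[queries[s:e], , drop = FALSE]
      D <- sqrt(center_dist2(L, Q))        # nl x chunk
      for (j in seq_len(e - s + 1L)) {
        o <- order(D[, j])[seq_len(k)]
        out[[s + j - 1L]] <- list(idx = labeled_idx[o], dist = D[o, j])
      }
    }
    out
  }
}

#' Resolve boundary points to crisp clusters by KNN vote
#'
#' Lower-approximation points keep their cluster labels.  Every boundary
#' point is assigned the majority label among its `knn_k` nearest
#' lower-approximation points (Euclidean distance).  Vote ties are broken in
#' favour of the cluster whose voting neighbours have the larger summed
#' inverse distance, then by the lowest cluster index.  With
#' `weighted = TRUE` the vote itself is inverse-distance weighted.
#'
#' @param data Numeric vector or n x d matrix.
#' @param partition A `rough_partition`; every cluster must have a non-empty
#'   lower approximation.
#' @param knn_k Neighbourhood size.
#' @param weighted Use inverse-distance-weighted votes instead of counts.
#' @return Integer vector of cluster labels (1..k) for all n points.
#' @export
knn_refine <- function(data, partition, knn_k, weighted = FALSE) {
  stopifnot(inherits(partition, "rough_partition"))
  X <- as_data_matrix(data)
  k <- length(partition$lower)
  sizes <- lengths(partition$lower)
  if (any(sizes == 0L)) {
    stop(sprintf(
      "cluster(s) %s have empty lower approximations; lower boundary_threshold",
      paste(which(sizes == 0L), collapse = ", ")
    ))
  }
  labels <- integer(nrow(X))
  labeled_idx <- unlist(partition$lower, use.names = FALSE)
  labeled_lab <- rep.int(seq_len(k), sizes)
  labels[labeled_idx] <- labeled_lab
  lab_of <- integer(nrow(X))
  lab_of[labeled_idx] <- labeled_lab

  bpts <- partition$boundary
  if (length(bpts)) {
    nn <- knn_labeled(X, labeled_idx, bpts, knn_k)
    for (j in seq_along(bpts)) {
      ids <- nn[[j]]$idx
      dd <- nn[[j]]$dist
      labs <- lab_of[ids]
      w_vote <- if (weighted) 1 / pmax(dd, .Machine$double.eps) else rep(1, length(labs))
      votes <- vapply(seq_len(k), function(i) sum(w_vote[labs == i]), numeric(1))
      top <- which(votes == max(votes))
      if (length(top) > 1L) {
        invd <- vapply(top, function(i) {
          sum(1 / pmax(dd[labs == i], .Machine$double.eps))
        }, numeric(1))
        top <- top[invd == max(invd)]
      }
      labels[bpts[j]] <- min(top)
    }
  }
  labels
}

#' Build a harmony memory from data via the rough-set iteration
#'
#' Starting from quantile centers, alternates [rough_assign()] and
#' [update_centers_rough()] until the maximum center shift drops to
#' `stop_threshold` or `max_rounds` is reached; the final boundary region is
#' resolved by [knn_refine()] and the refined crisp cluster means become the
#' first harmony memory row.  The remaining `hms - 1` rows are the refined
#' centers plus seeded Gaussian perturbations (sd = 2 percent of each
#' coordinate's box width), clipped to the bounds, so the optimizer starts
#' from a diverse but data-informed population instead of a uniform one.
#'
#' With `max_rounds = 0` the memory is built directly from the initial
#' quantile centers.
#'
#' @param data Numeric vector or n x d matrix of features (for grayscale
#'   images, the pixel intensities).
#' @param rough_params A [rough_params()] object.
#' @param hs_params An [hs_params()] object; `n_dims` must equal
#'   `k_clusters * ncol(data)`.
#' @param objective The objective used to score the memory rows.
#' @return A `harmony_memory` whose rows encode center vectors.
#' @export
build_harmony_memory <- function(data, rough_params, hs_params, objective) {
  validate_rough_params(rough_params)
  validate_hs_params(hs_params)
  X <- as_data_matrix(data)
  k <- rough_params$k_clusters
  d <- ncol(X)
  if (hs_params$n_dims != k * d) {
    stop("hs_params$n_dims must equal k_clusters * feature dimension")
  }
  centers <- as_center_matrix(init_centers(X, k), d)
  if (rough_params$max_rounds >= 1L) {
    for (round in seq_len(rough_params$max_rounds)) {
      part <- rough_assign(X, centers, rough_params$boundary_threshold)
      new_centers <- as_center_matrix(update_centers_rough(X, part, rough_params$w_low), d)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift <= rough_params$stop_threshold) break
    }
    part <- rough_assign(X, centers, rough_params$boundary_threshold)
    labels <- knn_refine(X, part, rough_params$knn_k)
    for (i in seq_len(k)) {
      members <- which(labels == i)
      if (length(members)) centers[i, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  if (d == 1L) centers <- matrix(sort(centers[, 1L]), ncol = 1L)
  row1 <- as.numeric(centers)               # column-major flatten
  row1 <- clip_to_box(row1, hs_params$lower_bound, hs_params$upper_bound)

  set.seed(rough_params$seed)
  sigma <- 0.02 * (hs_params$upper_bound - hs_params$lower_bound)
  vectors <- matrix(rep(row1, each = hs_params$hms),
                    nrow = hs_params$hms, ncol = hs_params$n_dims)
  if (hs_params$hms > 1L) {
    noise <- matrix(stats::rnorm((hs_params$hms - 1L) * hs_params$n_dims),
                    nrow = hs_params$hms - 1L)
    noise <- sweep(noise, 2, sigma, "*")
    vectors[-1L, ] <- sweep(noise, 2, row1, "+")
    vectors <- t(apply(vectors, 1, clip_to_box,
                       lower = hs_params$lower_bound,
                       upper = hs_params$upper_bound))
    if (hs_params$n_dims == 1L) vectors <- matrix(vectors, ncol = 1L)
  }
  fitness <- vapply(
    seq_len(hs_params$hms),
    function(j) eval_objective(objective, vectors[j, ], sprintf("objective (memory row %d)", j)),
    numeric(1)
  )
  new_harmony_memory(vectors, fitness)
}
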