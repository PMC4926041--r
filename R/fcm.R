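# Fuzzy c-means on intensity features: the fuzzified within-cluster
# sum-of-squares objective, its closed-form membership and center
# coordinate minimizers, the alternating iteration, and the partition
# coefficient / partition entropy validity indices.

fcm_dist2 <- function(data, centers) {
  X <- as_data_matrix(data)
  C <- as_center_matrix(centers, ncol(X))
  t(center_dist2(X, C))                     # c x n
}

#' Fuzzy membership update
#'
#' Closed-form minimizer of the fuzzy objective for fixed centers:
#' `u_ij = (1 / d_ij^2)^(1/(m-1)) / sum_k (1 / d_kj^2)^(1/(m-1))`, with `d`
#' the Euclidean distance from point j to center i.  A point that coincides
#' with a center gets crisp membership there (split equally across
#' coincident centers).
#'
#' @param data Numeric vector or n x d matrix.
#' @param centers c distinct centers.
#' @param fuzzifier Softness exponent m > 1.
#' @return A c x n membership matrix whose columns sum to 1.
#' @export
fcm_memberships <- function(data, centers, fuzzifier) {
  stopifnot(fuzzifier > 1)
  D2 <- fcm_dist2(data, centers)
  cc <- nrow(D2)
  if (cc == 1L) return(matrix(1, 1L, ncol(D2)))
  expo <- 1 / (fuzzifier - 1)
  W <- (1 / D2)^expo                         # Inf where d = 0
  U <- sweep(W, 2, colSums(W), "/")
  zero_cols <- which(apply(D2, 2, function(col) any(col == 0)))
  for (j in zero_cols) {
    hit <- D2[, j] == 0
    U[, j] <- 0
    U[hit, j] <- 1 / sum(hit)
  }
  U
}

#' Fuzzy center update
#'
#' Closed-form minimizer of the fuzzy objective for fixed memberships: each
#' center is the `u^m`-weighted mean of the data.
#'
#' @param data Numeric vector or n x d matrix.
#' @param memberships c x n membership matrix.
#' @param fuzzifier Softness exponent m > 1.
#' @return Centers (numeric vector for 1-D data, c x d matrix otherwise).
#' @export
fcm_centers <- function(data, memberships, fuzzifier) {
  X <- as_data_matrix(data)
  W <- memberships^fuzzifier                 # c x n
  tot <- rowSums(W)
  if (any(tot == 0)) {
    stop(sprintf("cluster %d has zero total membership weight",
                 which(tot == 0)[1]))
  }
  V <- (W %*% X) / tot
  if (ncol(X) == 1L) drop(V) else V
}

#' Fuzzy within-cluster objective
#'
#' `J_m = sum_i sum_j u_ij^m d_ij^2` with Euclidean `d`.
#'
#' @inheritParams fcm_centers
#' @param centers c centers.
#' @return A non-negative number.
#' @export
fcm_objective <- function(data, memberships, centers, fuzzifier) {
  D2 <- fcm_dist2(data, centers)
  sum(memberships^fuzzifier * D2)
}

#' Run fuzzy c-means from given initial centers
#'
#' Alternates [fcm_memberships()] and [fcm_centers()] until the maximum
#' absolute center shift drops below `params$epsilon` or `params$max_iter`
#' passes have run.  The objective trace is non-increasing, the defining
#' property of the two closed-form updates as coordinate minimizers.
#'
#' @param data Numeric vector or n x d matrix.
#' @param initial_centers Starting centers (length/rows must equal
#'   `params$c_clusters`); typically the best harmony of the improved
#'   optimizer, or random draws for the baseline.
#' @param params An [fcm_params()] object.
#' @return An `fcm_result`: list with `memberships` (c x n), `centers`,
#'   `objective_trace`, `iterations`, `converged`.
#' @export
run_fcm <- function(data, initial_centers, params) {
  stopifnot(inherits(params, "fcm_params"))
  X <- as_data_matrix(data)
  cc <- params$c_clusters
  C <- as_center_matrix(initial_centers, ncol(X))
  if (nrow(C) != cc) stop("initial_centers must supply c_clusters centers")
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  U <- NULL
  for (it in seq_len(params$max_iter)) {
    U <- fcm_memberships(X, C, params$fuzzifier)
    C_new <- as_center_matrix(fcm_centers(X, U, params$fuzzifier), ncol(X))
    trace <- c(trace, fcm_objective(X, U, C_new, params$fuzzifier))
    iterations <- it
    shift <- max(abs(C_new - C))
    C <- C_new
    if (shift < params$epsilon) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      memberships = U,
      centers = if (ncol(X) == 1L) drop(C) else C,
      objective_trace = trace,
      iterations = iterations,
      converged = converged
    ),
    class = "fcm_result"
  )
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf(
    "<fcm_result> c = %d | %d iterations (%s) | J = %.6g\n",
    nrow(x$memberships), x$iterations,
    if (x$converged) "converged" else "budget reached",
    utils::tail(x$objective_trace, 1)
  ))
  invisible(x)
}

#' Partition coefficient and partition entropy
#'
#' `vpc(U) = (1/n) sum_ij u_ij^2` lies in `[1/c, 1]`;
#' `vpe(U) = -(1/n) sum_ij u_ij log u_ij` (natural log, `0 log 0 = 0`) lies
#' in `[0, log c]`.  Crisp partitions score vpc = 1, vpe = 0; the uniform
#' partition scores vpc = 1/c, vpe = log c.  Higher vpc and lower vpe mean
#' a crisper, better-defined fuzzy partition.
#'
#' @param memberships A c x n membership matrix with unit column sums.
#' @return A single number.
#' @export
vpc <- function(memberships) {
  sum(memberships^2) / ncol(memberships)
}

#' @rdname vpc
#' @export
vpe <- function(memberships) {
  u <- memberships
  term <- ifelse(u > 0, u * log(u), 0)
  -sum(term) / ncol(u)
}

#' Validity report for a fuzzy clustering result
#'
#' @param fcm_result An `fcm_result`.
#' @return A `validity_report`: list with `vpc`, `vpe`, `iterations`.
#' @export
validity_report <- function(fcm_result) {
  structure(
    list(
      vpc = vpc(fcm_result$memberships),
      vpe = vpe(fcm_result$memberships),
      iterations = fcm_result$iterations
    ),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity> vpc = %.4f | vpe = %.4f | %d iterations\n",
              x$vpc, x$vpe, x$iterations))
  invisible(x)
}
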