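# End-to-end segmentation: image -> intensity vector -> optimized cluster
# centers (improved harmony search, or baselines) -> fuzzy c-means -> label
# map, scored by the partition validity indices.

#' Load a grayscale image rescaled to \[0, 1\]
#'
#' Reads PNG, TIFF, or single-slice NIfTI (the latter via the RNifti
#' package).  Color inputs are converted to luminance (ITU-R BT.601
#' weights); intensities are then min-max rescaled to \[0, 1\].  Constant
#' images are rejected since they carry no contrast to segment.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.nii`/`.nii.gz` file.
#' @return A numeric matrix with values in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  img <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("reading NIfTI requires the RNifti package")
      }
      v <- as.array(RNifti::readNifti(path))
      if (length(dim(v)) > 2L) {
        if (all(dim(v)[-(1:2)] == 1L)) v <- array(v, dim = dim(v)[1:2])
        else stop("only single-slice NIfTI volumes are supported")
      }
      v
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img <- matrix(as.numeric(img), nrow = dim(img)[1])
  if (any(!is.finite(img))) stop("image contains non-finite values")
  rng <- range(img)
  if (rng[1] == rng[2]) stop("constant image: nothing to segment")
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Write a label map as an 8-bit grayscale PNG
#'
#' Stores the raw class labels 0..c-1 as byte values, so the file round
#' trips exactly through an 8-bit reader.
#'
#' @param label_map Integer matrix with values in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  if (any(label_map < 0) || any(label_map > 255)) stop("labels must fit in a byte")
  png::writePNG(label_map / 255, path)
  invisible(path)
}

#' Within-cluster sum of squared distances of a center vector
#'
#' The objective the harmony search minimizes: each data point is charged
#' its squared Euclidean distance to the nearest decoded center and the
#' charges are summed.  `metric = "l1"` charges the unsquared distance
#' instead.  For grayscale data the center vector is simply the c candidate
#' intensities.
#'
#' @param center_vector Numeric vector encoding c centers (for d-dimensional
#'   features, the column-major concatenation of a c x d center matrix).
#' @param data Numeric vector or n x d matrix of features.
#' @param metric `"l2"` (squared distances, default) or `"l1"`.
#' @param d Feature dimension encoded in `center_vector` (default 1).
#' @return A non-negative number.
#' @export
clustering_fitness <- function(center_vector, data, metric = c("l2", "l1"), d = 1L) {
  metric <- match.arg(metric)
  if (any(!is.finite(center_vector))) stop("centers must be finite")
  X <- as_data_matrix(data)
  C <- matrix(center_vector, ncol = d)
  if (d == 1L && ncol(X) == 1L) {
    x <- X[, 1L]
    best <- (x - C[1L, 1L])^2
    for (i in seq_len(nrow(C))[-1L]) best <- pmin(best, (x - C[i, 1L])^2)
  } else {
    D2 <- center_dist2(X, C)
    best <- do.call(pmin, asplit(D2, 2))
  }
  if (metric == "l1") sum(sqrt(best)) else sum(best)
}

default_pipeline_params <- function(data, c_clusters, seed,
                                    hs = NULL, rough = NULL, fcm = NULL) {
  rng <- range(data)
  if (is.null(hs)) {
    hs <- hs_params(n_dims = c_clusters, lower_bound = rng[1], upper_bound = rng[2],
                    seed = seed)
  } else {
    hs$seed <- as.integer(seed)
    validate_hs_params(hs)
  }
  if (is.null(rough)) {
    rough <- rough_params(k_clusters = c_clusters, seed = seed)
  } else {
    rough$seed <- as.integer(seed)
    validate_rough_params(rough)
  }
  if (is.null(fcm)) {
    fcm <- fcm_params(c_clusters = c_clusters, seed = seed)
  } else {
    fcm$seed <- as.integer(seed)
  }
  if (hs$n_dims != c_clusters) stop("hs n_dims must equal the number of clusters")
  if (rough$k_clusters != c_clusters) stop("rough k_clusters must equal c")
  if (fcm$c_clusters != c_clusters) stop("fcm c_clusters must equal c")
  list(hs = hs, rough = rough, fcm = fcm)
}

#' Segment a grayscale image by intensity clustering
#'
#' Pipelines the intensity values of `image` through one of three routes to
#' a fuzzy c-means segmentation:
#' \describe{
#'   \item{`improved`}{[run_improved_hs()] (rough-set harmony memory plus
#'     adaptive PAR/BW) optimizes the c cluster centers, which then
#'     initialize [run_fcm()].}
#'   \item{`baseline_hs`}{plain [run_hs()] with a uniform random memory
#'     optimizes the centers, which initialize [run_fcm()].}
#'   \item{`baseline_fcm`}{[run_fcm()] starts from c random centers drawn
#'     uniformly from the intensity range (the classical randomly
#'     initialized FCM).}
#' }
#' The label map assigns each pixel the cluster of maximum membership (ties
#' to the lowest cluster index).
#'
#' @param image Numeric matrix in \[0, 1\] (see [load_image()]) or a
#'   `phantom`'s `$image`.
#' @param c_clusters Number of tissue classes c.
#' @param algorithm One of `"improved"`, `"baseline_fcm"`, `"baseline_hs"`.
#' @param seed Integer seed controlling all randomness of the run.
#' @param hs,rough,fcm Optional parameter objects overriding the defaults
#'   (their seeds are replaced by `seed` so runs stay matched).
#' @param fitness_metric `"l2"` or `"l1"`, see [clustering_fitness()].
#' @return A `segmentation_result`: list with `label_map` (integer matrix,
#'   values `0..c-1`), `fcm_result`, `validity`, `fitness_summary`
#'   (best/worst/mean objective over the optimizer's final memory; for
#'   `baseline_fcm`, the objective of its random initial centers in all
#'   three slots), `initial_centers`, `hs_result` (NULL for
#'   `baseline_fcm`), and `provenance`.
#' @export
segment_image <- function(image, c_clusters,
                          algorithm = c("improved", "baseline_fcm", "baseline_hs"),
                          seed = 1L,
                          hs = NULL, rough = NULL, fcm = NULL,
                          fitness_metric = c("l2", "l1")) {
  algorithm <- match.arg(algorithm)
  fitness_metric <- match.arg(fitness_metric)
  image <- as.matrix(image)
  data <- as.vector(image)
  prm <- default_pipeline_params(data, c_clusters, seed, hs, rough, fcm)
  objective <- function(v) clustering_fitness(v, data, metric = fitness_metric)

  hs_res <- NULL
  if (algorithm == "improved") {
    hs_res <- run_improved_hs(data, prm$rough, prm$hs, objective)
    init_centers <- sort(hs_res$best)
  } else if (algorithm == "baseline_hs") {
    hs_res <- run_hs(prm$hs, objective)
    init_centers <- sort(hs_res$best)
  } else {
    set.seed(seed)
    rng <- range(data)
    init_centers <- sort(stats::runif(c_clusters, rng[1], rng[2]))
  }
  fit <- run_fcm(data, init_centers, prm$fcm)
  lab <- max.col(t(fit$memberships), ties.method = "first") - 1L
  label_map <- matrix(as.integer(lab), nrow = nrow(image), ncol = ncol(image))
  fitness_summary <- if (!is.null(hs_res)) {
    c(best = min(hs_res$memory$fitness),
      worst = max(hs_res$memory$fitness),
      mean = mean(hs_res$memory$fitness))
  } else {
    f0 <- objective(init_centers)
    c(best = f0, worst = f0, mean = f0)
  }
  structure(
    list(
      label_map = label_map,
      fcm_result = fit,
      validity = validity_report(fit),
      fitness_summary = fitness_summary,
      initial_centers = init_centers,
      hs_result = hs_res,
      provenance = list(
        algorithm = algorithm, seed = as.integer(seed),
        c_clusters = as.integer(c_clusters),
        fitness_metric = fitness_metric,
        hs = prm$hs, rough = prm$rough, fcm = prm$fcm
      )
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation> %s | c = %d | vpc = %.4f, vpe = %.4f | %d FCM iterations\n",
    x$provenance$algorithm, x$provenance$c_clusters,
    x$validity$vpc, x$validity$vpe, x$validity$iterations
  ))
  invisible(x)
}

#' Choose the number of clusters by partition coefficient
#'
#' Runs the full improved pipeline for every candidate c and returns the one
#' whose fuzzy partition scores the highest partition coefficient (ties go
#' to the smaller c), along with the per-candidate validity reports.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param c_range Candidate cluster counts, a subset of 2..8.
#' @param seed Integer seed shared by all candidate runs.
#' @inheritParams segment_image
#' @return A list with `selected_c`, `reports` (one `validity_report` per
#'   candidate, named by c), and `results` (the `segmentation_result`s).
#' @export
select_c <- function(image, c_range = 2:5, seed = 1L,
                     hs = NULL, rough = NULL, fcm = NULL) {
  c_range <- sort(unique(as.integer(c_range)))
  if (any(c_range < 2L) || any(c_range > 8L)) stop("c_range must lie within 2..8")
  results <- lapply(c_range, function(cc) {
    segment_image(image, cc, algorithm = "improved", seed = seed)
  })
  names(results) <- as.character(c_range)
  vpcs <- vapply(results, function(r) r$validity$vpc, numeric(1))
  selected <- c_range[which.max(vpcs)]      # which.max takes the first max: smaller c
  list(
    selected_c = selected,
    reports = lapply(results, `[[`, "validity"),
    results = results
  )
}

#' Compare the improved pipeline against randomly initialized FCM
#'
#' Runs the improved harmony-search pipeline and the random-initialization
#' FCM baseline with matched seeds on the same image and tabulates the
#' partition validity indices, iteration counts, and the
#' best/worst/average optimizer fitness for each.
#'
#' @inheritParams segment_image
#' @return A list of class `hs_comparison` with `table` (data frame with
#'   columns algorithm, vpc, vpe, iterations, best, worst, average) and
#'   `results` (named list of the two `segmentation_result`s).
#' @export
compare_segmentations <- function(image, c_clusters, seed = 1L,
                                  hs = NULL, rough = NULL, fcm = NULL) {
  res <- list(
    improved = segment_image(image, c_clusters, "improved", seed = seed,
                             hs = hs, rough = rough, fcm = fcm),
    baseline_fcm = segment_image(image, c_clusters, "baseline_fcm", seed = seed,
                                 hs = hs, rough = rough, fcm = fcm)
  )
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(
      algorithm = nm,
      vpc = r$validity$vpc,
      vpe = r$validity$vpe,
      iterations = r$validity$iterations,
      best = unname(r$fitness_summary["best"]),
      worst = unname(r$fitness_summary["worst"]),
      average = unname(r$fitness_summary["mean"])
    )
  }))
  structure(list(table = tab, results = res), class = "hs_comparison")
}

#' @export
print.hs_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a comparison or validity report to JSON or CSV
#'
#' @param x An `hs_comparison` or `validity_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (inherits(x, "hs_comparison")) x <- x$table
  if (inherits(x, "validity_report")) x <- unclass(x)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    stop("unsupported report format: .", ext)
  }
  invisible(path)
}
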