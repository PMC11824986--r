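#' Generate Gaussian-cluster classification data
#'
#' Draws one center per class from a scaled standard Gaussian and scatters
#' samples around their class center with isotropic Gaussian noise — the
#' controllable-overlap, controllable-imbalance benchmark the package's
#' experiments run on. Class sizes are a single multinomial draw at the given
#' proportions; rows are shuffled. Separability is governed by the ratio of
#' `cluster_separation` to `noise_sd`.
#'
#' @param n_samples Total number of samples.
#' @param n_features Number of numeric features.
#' @param n_classes Number of classes (>= 2).
#' @param class_proportions Probability per class (summing to 1); default
#'   balanced.
#' @param cluster_separation Scale of the class-center draw (centers are
#'   `N(0, cluster_separation^2)` per coordinate).
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble with numeric columns `x1..x<d>` and a factor column
#'   `label` with levels `c1..c<m>`.
#' @export
#' @examples
#' d <- generate_classification_data(n_samples = 200, n_classes = 2,
#'                                   class_proportions = c(0.9, 0.1), seed = 1)
#' table(d$label)
generate_classification_data <- function(n_samples = 300, n_features = 6,
                                         n_classes = 3,
                                         class_proportions = NULL,
                                         cluster_separation = 3,
                                         noise_sd = 1, seed = 1L) {
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  if (n_samples < n_classes) {
    stop("`n_samples` must be at least `n_classes`", call. = FALSE)
  }
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes || any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("`class_proportions` must be positive and sum to 1", call. = FALSE)
  }
  if (cluster_separation <= 0 || noise_sd <= 0) {
    stop("`cluster_separation` and `noise_sd` must be positive", call. = FALSE)
  }
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_classes * n_features,
                                   sd = cluster_separation),
                      n_classes, n_features)
    sizes <- as.vector(stats::rmultinom(1, n_samples, class_proportions))
    # guarantee every class appears at least once
    while (any(sizes == 0)) {
      donor <- which.max(sizes)
      recv <- which(sizes == 0)[1]
      sizes[donor] <- sizes[donor] - 1L
      sizes[recv] <- 1L
    }
    y <- rep(seq_len(n_classes), sizes)
    X <- centers[y, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
             n_samples, n_features)
    ord <- sample.int(n_samples)
    out <- tibble::as_tibble(as.data.frame(X[ord, , drop = FALSE]),
                             .name_repair = "minimal")
    names(out) <- paste0("x", seq_len(n_features))
    out$label <- factor(paste0("c", y[ord]),
                        levels = paste0("c", seq_len(n_classes)))
    out
  })
}

#' Min-max normalize features to [0, 1]
#'
#' Learns per-column minima and maxima on the supplied (training) data and
#' maps each numeric column affinely to `[0, 1]`. Constant columns map to 0.
#' The returned scaler reapplies the *training* bounds to new data, so test
#' values may fall outside `[0, 1]` — bounds are deliberately not re-learned
#' per split.
#'
#' @param data Data frame (non-numeric columns pass through untouched) or
#'   numeric matrix.
#' @return A list with `data` (the normalized input) and `scaler` (class
#'   `minmax_scaler`), to be used with [apply_scaler()] / [invert_scaler()].
#' @export
#' @examples
#' norm <- minmax_normalize(data.frame(a = c(2, 4, 6)))
#' norm$data$a  # 0, 0.5, 1
minmax_normalize <- function(data) {
  is_df <- is.data.frame(data)
  X <- as_feature_matrix(data)
  if (nrow(X) < 1) stop("need at least one row", call. = FALSE)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  scaler <- structure(
    list(min = lo, max = hi,
         columns = colnames(X) %||% paste0("V", seq_along(lo))),
    class = "minmax_scaler"
  )
  list(data = apply_scaler(scaler, data), scaler = scaler)
}

scale_columns <- function(scaler, data, f) {
  if (is.data.frame(data)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    for (j in seq_along(scaler$columns)) {
      nm <- if (all(scaler$columns %in% names(data))) scaler$columns[j] else num[j]
      data[[nm]] <- f(data[[nm]], scaler$min[j], scaler$max[j])
    }
    if (is.data.frame(data) && !tibble::is_tibble(data)) {
      data <- tibble::as_tibble(data)
    }
    data
  } else {
    X <- as_feature_matrix(data)
    for (j in seq_len(ncol(X))) X[, j] <- f(X[, j], scaler$min[j], scaler$max[j])
    X
  }
}

#' Apply a fitted min-max scaler to new data
#' @param scaler A `minmax_scaler` from [minmax_normalize()].
#' @param data Data frame or matrix with the same numeric columns.
#' @return The scaled data in the same container type.
#' @export
apply_scaler <- function(scaler, data) {
  scale_columns(scaler, data, function(x, lo, hi) {
    if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
  })
}

#' Invert a fitted min-max scaler
#' @inheritParams apply_scaler
#' @return Data on the original scale (constant columns are restored to
#'   their training value).
#' @export
invert_scaler <- function(scaler, data) {
  scale_columns(scaler, data, function(x, lo, hi) {
    if (hi > lo) x * (hi - lo) + lo else rep(lo, length(x))
  })
}

#' Random train/test split
#'
#' Uniform random partition into a training fraction and its complement,
#' deterministic given `seed`. Warns when a class is absent from either
#' side.
#'
#' @param data Data frame with a label column.
#' @param train_fraction Fraction in (0, 1) assigned to training (the count
#'   is `round(train_fraction * N)`, kept off 0 and `N`).
#' @param seed Integer seed.
#' @param label Label column name (used only for the coverage warning).
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.6, seed = 1L,
                             label = "label") {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  n <- nrow(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train))
  train <- tibble::as_tibble(data[idx, , drop = FALSE])
  test <- tibble::as_tibble(data[-idx, , drop = FALSE])
  if (label %in% names(data)) {
    all_classes <- unique(as.character(data[[label]]))
    missing_train <- setdiff(all_classes, as.character(train[[label]]))
    missing_test <- setdiff(all_classes, as.character(test[[label]]))
    if (length(missing_train) || length(missing_test)) {
      warning("some classes are absent from one side of the split",
              call. = FALSE)
    }
  }
  list(train = train, test = test)
}
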