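#' @title Multi-kernel ELM classifiers
#' @description
#' The plain ELM classifier (random hidden layer + ridge output weights) and
#' the two multi-kernel architectures built on REKELM-AE encoders:
#' \describe{
#'   \item{MKP-ELM}{one encoder per kernel fitted in parallel on `X`; their
#'     encodings are concatenated column-wise and fed to one final ELM
#'     classifier.}
#'   \item{MKR-ELM}{encoders stacked in series with residual connections:
#'     `Y^(0) = X`, encoder `i` is fitted on `Y^(i-1)` and
#'     `Y^(i) = Y^(i-1) + reconstruction_i(Y^(i-1))`; the classifier is
#'     fitted on `Y^(k)`. Every `Y^(i)` keeps the input width `d`.}
#' }
#' @name models
NULL

# One-hot target coding: +1 for the true class, -1 (or 0) elsewhere.
one_hot_targets <- function(y, classes, coding = "plus_minus_one") {
  off <- if (coding == "plus_minus_one") -1 else 0
  T <- matrix(off, length(y), length(classes),
              dimnames = list(NULL, as.character(classes)))
  T[cbind(seq_along(y), match(as.character(y), as.character(classes)))] <- 1
  T
}

#' Fit an ELM classifier
#'
#' Maps features through a fixed random hidden layer (uniform (-1,1) weights,
#' sigmoid activation by default) and solves the output weights by ridge
#' regression against one-hot class targets (+1 true class, -1 otherwise by
#' default).
#'
#' @param X Numeric matrix or data frame of numeric feature columns.
#' @param labels Class label per row (factor, character or integer); at least
#'   two distinct classes.
#' @param L Number of hidden nodes.
#' @param C Positive ridge regularization parameter.
#' @param seed Integer seed for the random layer.
#' @param target_coding `"plus_minus_one"` (default, centers the sigmoid used
#'   for posterior conversion) or `"zero_one"`.
#' @param sample_weights Optional positive per-sample weights; when supplied
#'   the ridge solve is error-weighted (used by [fit_celm()]).
#' @return An object of class `elm_classifier`.
#' @export
fit_elm_classifier <- function(X, labels, L = 1000, C = 100, seed = 1L,
                               target_coding = c("plus_minus_one", "zero_one"),
                               sample_weights = NULL) {
  target_coding <- match.arg(target_coding)
  X <- as_feature_matrix(X)
  if (length(labels) != nrow(X)) {
    stop("labels length must match the number of rows", call. = FALSE)
  }
  classes <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)))
  if (length(classes) < 2) {
    stop("need at least two classes to fit a classifier", call. = FALSE)
  }
  layer <- make_random_layer(ncol(X), L, distribution = "uniform_pm1",
                             activation = "sigmoid", seed = seed)
  H <- random_map(layer, X)
  T <- one_hot_targets(labels, classes, target_coding)
  beta <- if (is.null(sample_weights)) {
    ridge_solve(H, T, C, form = "auto")
  } else {
    weighted_ridge_solve(H, T, C, sample_weights)
  }
  structure(
    list(hidden_layer = layer, beta = beta, classes = classes,
         target_coding = target_coding, regularization = C,
         seed = as.integer(seed)),
    class = "elm_classifier"
  )
}

# Weighted ridge: min ||B||^2/C + sum_i w_i ||h(x_i) B - t_i||^2, solved in
# whichever Gram form inverts the smaller matrix (push-through identity):
#   B = (I/C + H'DH)^{-1} H'DT  =  H'D (I/C + HH'D)^{-1} T
weighted_ridge_solve <- function(H, T, C, w) {
  if (length(w) != nrow(H) || any(!is.finite(w)) || any(w <= 0)) {
    stop("sample weights must be positive and match the number of rows",
         call. = FALSE)
  }
  n <- nrow(H); p <- ncol(H)
  coefficients <- if (n < p) {
    crossprod(H, w * solve(diag(n) / C + tcrossprod(H) * rep(w, each = n), T))
  } else {
    solve(diag(p) / C + crossprod(H * sqrt(w)), crossprod(H, w * T))
  }
  structure(
    list(coefficients = coefficients, regularization = C,
         solve_form = if (n < p) "gram_n" else "gram_p"),
    class = "ridge_solution"
  )
}

#' @export
print.elm_classifier <- function(x, ...) {
  cat(sprintf("<elm_classifier> %d hidden nodes, %d classes (%s), C = %g\n",
              nrow(x$hidden_layer$weights), length(x$classes),
              paste(x$classes, collapse = ", "), x$regularization))
  invisible(x)
}

#' Raw classifier scores
#'
#' Returns the unthresholded network output `f(x) = h(x) %*% beta`, one
#' column per class.
#'
#' @param model An `elm_classifier`.
#' @param X Features with the training width.
#' @return Numeric matrix `N x m` with class names as columns.
#' @export
predict_scores <- function(model, X) {
  H <- random_map(model$hidden_layer, as_feature_matrix(X))
  S <- H %*% model$beta$coefficients
  colnames(S) <- model$classes
  S
}

#' @export
predict.elm_classifier <- function(object, newdata, ...) {
  S <- predict_scores(object, newdata)
  object$classes[max.col(S, ties.method = "first")]
}

clamp_int <- function(x, lo, hi) as.integer(min(max(round(x), lo), hi))

fit_rekelm_bank_input <- function(data, label, labels) {
  parts <- split_data_labels(data, label, labels)
  if (anyNA(parts$X)) stop("features contain missing values", call. = FALSE)
  parts
}

#' Fit a multi-kernel parallel ELM (MKP-ELM)
#'
#' Fits one REKELM-AE per kernel on the training features — each with
#' `L1 = round(r1 * d)` random-map nodes and `round(r2 * N)` reference points
#' and its own derived sub-seed — encodes the data through each, concatenates
#' the encodings column-wise in kernel order, and fits a final ELM classifier
#' on the concatenation.
#'
#' @param data A data frame containing numeric feature columns and a label
#'   column, or a numeric matrix (then supply `labels`).
#' @param label Name of the label column when `data` is a data frame.
#' @param labels Label vector when `data` is a matrix.
#' @param kernels List of [kernel_spec()] objects, one encoder each
#'   (default: the four-kernel bank of [default_kernels()]).
#' @param r1 Expansion ratio `L1 / d` of each encoder's random layer.
#' @param r2 Compression ratio `n_refs / N` of each encoder's reference set,
#'   in (0, 1]; the count is `round(r2 * N)` clamped to `[1, N]`.
#' @param L Hidden nodes of the final classifier.
#' @param C Ridge regularization, shared by encoders and classifier.
#' @param seed Master seed; every encoder and the classifier draw from
#'   deterministic sub-seeds.
#' @param target_coding Passed to [fit_elm_classifier()].
#' @return An object of class `c("mkp_elm", "mk_elm")`.
#' @export
#' @examples
#' d <- generate_classification_data(n_samples = 120, n_features = 4,
#'                                   n_classes = 3, seed = 1)
#' fit <- fit_mkp_elm(d, r2 = 0.1, L = 200, seed = 1)
#' head(predict(fit, d))
fit_mkp_elm <- function(data, label = "label", labels = NULL,
                        kernels = default_kernels(), r1 = 10, r2 = 0.05,
                        L = 1000, C = 100, seed = 1L,
                        target_coding = "plus_minus_one") {
  parts <- fit_rekelm_bank_input(data, label, labels)
  X <- parts$X; y <- parts$y
  if (length(kernels) < 1) stop("need at least one kernel", call. = FALSE)
  d <- ncol(X); n <- nrow(X)
  L1 <- clamp_int(r1 * d, 1, .Machine$integer.max)
  n_refs <- clamp_int(r2 * n, 1, n)
  encoders <- lapply(kernels, function(k) {
    fit_rekelm_ae(X, L1 = L1, n_refs = n_refs, kernel = k, C = C,
                  seed = kernel_subseed(seed, k))
  })
  features <- do.call(cbind, lapply(encoders, function(e) encode(e, X)))
  classifier <- fit_elm_classifier(features, y, L = L, C = C,
                                   seed = derive_seed(seed, 1000L),
                                   target_coding = target_coding)
  structure(
    list(architecture = "mkp", encoders = encoders, classifier = classifier,
         sizing = list(r1 = r1, r2 = r2, L1 = L1, n_refs = n_refs),
         L = L, C = C, seed = as.integer(seed), input_dim = d,
         label = if (is.data.frame(data)) label else NA_character_),
    class = c("mkp_elm", "mk_elm")
  )
}

#' Fit a multi-kernel residual ELM (MKR-ELM)
#'
#' Stacks one REKELM-AE per kernel in series with residual connections.
#' Starting from `Y^(0) = X`, encoder `i` is fitted on `Y^(i-1)` with kernel
#' `i`, its reconstruction of `Y^(i-1)` (an `N x d` matrix) is added back,
#' `Y^(i) = Y^(i-1) + reconstruction`, and the final ELM classifier is fitted
#' on `Y^(k)`. The residual sum requires the dimension-preserving
#' reconstruction rather than the width-changing encoding.
#'
#' @inheritParams fit_mkp_elm
#' @return An object of class `c("mkr_elm", "mk_elm")`.
#' @export
fit_mkr_elm <- function(data, label = "label", labels = NULL,
                        kernels = default_kernels(), r1 = 10, r2 = 0.05,
                        L = 1000, C = 100, seed = 1L,
                        target_coding = "plus_minus_one") {
  parts <- fit_rekelm_bank_input(data, label, labels)
  X <- parts$X; y <- parts$y
  if (length(kernels) < 1) stop("need at least one kernel", call. = FALSE)
  d <- ncol(X); n <- nrow(X)
  L1 <- clamp_int(r1 * d, 1, .Machine$integer.max)
  n_refs <- clamp_int(r2 * n, 1, n)
  Y <- X
  encoders <- vector("list", length(kernels))
  for (i in seq_along(kernels)) {
    encoders[[i]] <- fit_rekelm_ae(Y, L1 = L1, n_refs = n_refs,
                                   kernel = kernels[[i]], C = C,
                                   seed = kernel_subseed(seed, kernels[[i]]))
    Y <- Y + reconstruct(encoders[[i]], Y)
  }
  classifier <- fit_elm_classifier(Y, y, L = L, C = C,
                                   seed = derive_seed(seed, 1000L),
                                   target_coding = target_coding)
  structure(
    list(architecture = "mkr", encoders = encoders, classifier = classifier,
         sizing = list(r1 = r1, r2 = r2, L1 = L1, n_refs = n_refs),
         L = L, C = C, seed = as.integer(seed), input_dim = d,
         label = if (is.data.frame(data)) label else NA_character_),
    class = c("mkr_elm", "mk_elm")
  )
}

#' @export
print.mk_elm <- function(x, ...) {
  cat(sprintf("<%s_elm> %d kernels (%s), L1 = %d, n_refs = %d, L = %d, C = %g, seed = %d\n",
              x$architecture,
              length(x$encoders),
              paste(vapply(x$encoders, function(e) e$kernel$family, ""),
                    collapse = ", "),
              x$sizing$L1, x$sizing$n_refs, x$L, x$C, x$seed))
  cat(sprintf("  classes: %s\n", paste(x$classifier$classes, collapse = ", ")))
  invisible(x)
}

#' Reproduce the training-time feature path for new samples
#'
#' Applies exactly the transformation the final classifier was trained on:
#' concatenated encoder projections for MKP, the residual cascade for MKR.
#' On the training matrix this returns the classifier's training features
#' bit-for-bit.
#'
#' @param model A fitted `mk_elm`.
#' @param X Numeric matrix or data frame of numeric columns with the training
#'   input width (a label column, if present under the model's label name, is
#'   ignored).
#' @return Numeric feature matrix (`N x k*n_refs` for MKP, `N x d` for MKR).
#' @export
transform_features <- function(model, X) {
  if (is.data.frame(X) && !is.na(model$label) && model$label %in% names(X)) {
    X <- X[setdiff(names(X), model$label)]
  }
  X <- as_feature_matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("X has %d columns but the model expects %d",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  if (model$architecture == "mkp") {
    do.call(cbind, lapply(model$encoders, function(e) encode(e, X)))
  } else {
    Y <- X
    for (enc in model$encoders) Y <- Y + reconstruct(enc, Y)
    Y
  }
}

#' Predict from a multi-kernel ELM
#'
#' Runs new samples through the model's feature path and classifier and
#' returns a tibble. `type = "class"` gives the argmax class (or, when a
#' `cost_matrix` is supplied, the minimum-risk class); `"score"` the raw
#' per-class scores; `"posterior"` the sigmoid-normalized posterior
#' probabilities.
#'
#' @param object A fitted `mk_elm`.
#' @param newdata Data frame or matrix of features (label column ignored if
#'   present).
#' @param type `"class"`, `"score"` or `"posterior"`.
#' @param cost Optional [make_cost_matrix()] object; with `type = "class"`
#'   predictions become minimum-risk decisions instead of argmax.
#' @param ... Unused.
#' @return A tibble: `.pred_class` for `"class"`, one `.score_<class>` /
#'   `.posterior_<class>` column per class otherwise.
#' @export
predict.mk_elm <- function(object, newdata, type = c("class", "score", "posterior"),
                           cost = NULL, ...) {
  type <- match.arg(type)
  feats <- transform_features(object, newdata)
  S <- predict_scores(object$classifier, feats)
  if (type == "score") {
    colnames(S) <- paste0(".score_", colnames(S))
    return(tibble::as_tibble(S))
  }
  P <- scores_to_posteriors(S)
  if (type == "posterior") {
    colnames(P) <- paste0(".posterior_", colnames(P))
    return(tibble::as_tibble(P))
  }
  cls <- if (is.null(cost)) {
    object$classifier$classes[max.col(P, ties.method = "first")]
  } else {
    min_risk_decide(P, cost)
  }
  tibble::tibble(.pred_class = cls)
}
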