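#' Numerically safe logistic sigmoid
#'
#' Computes `1 / (1 + exp(-z))` elementwise, branching on the sign of `z` so
#' that `exp()` is never evaluated at a large positive argument (no overflow,
#' no `NaN` for extreme scores).
#'
#' @param z Numeric vector, matrix or array.
#' @return Object of the same shape as `z` with values in (0, 1).
#' @export
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1e4)    # 1 without overflow
sigmoid <- function(z) {
  out <- z
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All randomness in the package funnels through this so that fits are
# deterministic given their seed and never perturb the user's session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed scheme: one master seed per model, component seeds
# derived by a fixed affine counter kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# Sub-seed tied to the kernel family (not the list position), so permuting a
# kernel bank permutes the fitted encoders rather than redrawing them.
kernel_subseed <- function(seed, spec) {
  derive_seed(seed, sum(utf8ToInt(spec$family) * seq_along(utf8ToInt(spec$family))))
}

activation_fun <- function(name) {
  switch(name,
    sigmoid = sigmoid,
    identity = identity,
    stop("unknown activation: ", name, call. = FALSE)
  )
}

#' Construct a fixed random hidden layer
#'
#' Draws the input weights and biases of a single ELM hidden layer once and
#' freezes them. Weights and biases are i.i.d. draws from either a standard
#' Gaussian (`"gaussian01"`, mean 0 variance 1) or the uniform distribution on
#' (-1, 1) (`"uniform_pm1"`). Regenerating with the same seed reproduces the
#' layer bit-for-bit.
#'
#' @param input_dim Number of input features `d` (positive integer).
#' @param n_nodes Number of hidden nodes `L` (positive integer).
#' @param distribution `"gaussian01"` or `"uniform_pm1"`.
#' @param activation `"sigmoid"` or `"identity"`.
#' @param seed Integer seed controlling the draw.
#' @return An object of class `random_layer` with fields `weights` (`L x d`),
#'   `biases` (length `L`), `activation`, `distribution`, `seed`.
#' @export
#' @examples
#' layer <- make_random_layer(4, 40, seed = 7)
#' dim(layer$weights)
make_random_layer <- function(input_dim, n_nodes,
                              distribution = c("gaussian01", "uniform_pm1"),
                              activation = c("sigmoid", "identity"),
                              seed = 1L) {
  distribution <- match.arg(distribution)
  activation <- match.arg(activation)
  if (length(input_dim) != 1 || is.na(input_dim) || input_dim < 1) {
    stop("`input_dim` must be a positive integer", call. = FALSE)
  }
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 1) {
    stop("`n_nodes` must be a positive integer", call. = FALSE)
  }
  input_dim <- as.integer(input_dim)
  n_nodes <- as.integer(n_nodes)
  draws <- with_seed(seed, {
    n <- n_nodes * input_dim + n_nodes
    if (distribution == "gaussian01") stats::rnorm(n) else stats::runif(n, -1, 1)
  })
  structure(
    list(
      weights = matrix(draws[seq_len(n_nodes * input_dim)], nrow = n_nodes,
                       ncol = input_dim),
      biases = draws[n_nodes * input_dim + seq_len(n_nodes)],
      activation = activation,
      distribution = distribution,
      seed = as.integer(seed)
    ),
    class = "random_layer"
  )
}

#' @export
print.random_layer <- function(x, ...) {
  cat(sprintf("<random_layer> %d nodes x %d inputs, %s weights, %s activation, seed %d\n",
              nrow(x$weights), ncol(x$weights), x$distribution, x$activation,
              x$seed))
  invisible(x)
}

#' Map samples through a random hidden layer
#'
#' Row `i` of the result is `activation(W %*% x_i + b)`: the hidden-layer
#' representation `h(x_i)` of sample `i`.
#'
#' @param layer A [make_random_layer()] object.
#' @param X Numeric matrix, samples in rows; column count must equal the
#'   layer's input dimension.
#' @return Numeric matrix `N x L`.
#' @export
random_map <- function(layer, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != ncol(layer$weights)) {
    stop(sprintf("X has %d columns but the layer expects %d inputs",
                 ncol(X), ncol(layer$weights)), call. = FALSE)
  }
  Z <- tcrossprod(X, layer$weights)
  Z <- sweep(Z, 2L, layer$biases, "+")
  activation_fun(layer$activation)(Z)
}

#' Regularized least squares in both Gram forms
#'
#' Solves `min ||H B - T||_F^2 + (1/C) ||B||_F^2` in closed form. Two
#' algebraically identical expressions exist:
#' \describe{
#'   \item{`gram_n`}{`B = H' (I/C + H H')^{-1} T`, inverting an `N x N` matrix;
#'     preferred when there are fewer samples than features.}
#'   \item{`gram_p`}{`B = (I/C + H' H)^{-1} H' T`, inverting a `p x p` matrix;
#'     preferred when features are fewer.}
#' }
#' `form = "auto"` picks `gram_n` when `N < p`, else `gram_p`. The ridge term
#' enters as `I/C` added to the Gram matrix, so larger `C` means weaker
#' shrinkage.
#'
#' @param H Numeric matrix `N x p` of regressors.
#' @param T Numeric matrix `N x m` of targets (a vector is treated as one
#'   column).
#' @param C Positive regularization parameter.
#' @param form `"auto"`, `"gram_n"` or `"gram_p"`.
#' @return Object of class `ridge_solution` with fields `coefficients`
#'   (`p x m`), `regularization`, `solve_form`.
#' @export
#' @examples
#' H <- matrix(rnorm(24), 6, 4)
#' Tm <- matrix(rnorm(12), 6, 2)
#' b1 <- ridge_solve(H, Tm, C = 8, form = "gram_n")
#' b2 <- ridge_solve(H, Tm, C = 8, form = "gram_p")
#' max(abs(b1$coefficients - b2$coefficients))  # ~ 1e-15
ridge_solve <- function(H, T, C, form = c("auto", "gram_n", "gram_p")) {
  form <- match.arg(form)
  H <- as.matrix(H)
  if (is.null(dim(T))) T <- matrix(T, ncol = 1)
  T <- as.matrix(T)
  if (nrow(H) != nrow(T)) {
    stop("H and T must have the same number of rows", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1 || is.na(C) || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(H)) || !all(is.finite(T))) {
    stop("H and T must be finite", call. = FALSE)
  }
  n <- nrow(H); p <- ncol(H)
  if (form == "auto") form <- if (n < p) "gram_n" else "gram_p"
  coefficients <- if (form == "gram_n") {
    crossprod(H, solve(diag(n) / C + tcrossprod(H), T))
  } else {
    solve(diag(p) / C + crossprod(H), crossprod(H, T))
  }
  structure(
    list(coefficients = coefficients, regularization = C, solve_form = form),
    class = "ridge_solution"
  )
}

#' @export
coef.ridge_solution <- function(object, ...) object$coefficients

#' @export
print.ridge_solution <- function(x, ...) {
  cat(sprintf("<ridge_solution> %d x %d coefficients, C = %g, form = %s\n",
              nrow(x$coefficients), ncol(x$coefficients), x$regularization,
              x$solve_form))
  invisible(x)
}

# Accept a data frame (numeric columns only) or matrix as the feature matrix.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[num])
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

# Split a data frame into feature matrix + label vector; `label` is the label
# column name. Matrices pass through with an explicit `labels` vector.
split_data_labels <- function(data, label = "label", labels = NULL) {
  if (is.data.frame(data)) {
    if (!label %in% names(data)) {
      stop(sprintf("label column '%s' not found in data", label), call. = FALSE)
    }
    y <- data[[label]]
    X <- as_feature_matrix(data[setdiff(names(data), label)])
  } else {
    if (is.null(labels)) {
      stop("`labels` must be supplied when `data` is a matrix", call. = FALSE)
    }
    y <- labels
    X <- as_feature_matrix(data)
  }
  list(X = X, y = y)
}
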