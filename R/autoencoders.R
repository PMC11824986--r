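#' @title Kernel and random-map autoencoders solved in closed form
#' @description
#' Four one-layer autoencoder fits sharing the same recipe: build a hidden
#' representation `Phi(X)` of the input, then solve the ridge system
#' `Phi(X) Gamma ~= X` for the output weights `Gamma`. They differ only in
#' `Phi`:
#' \describe{
#'   \item{ELM-AE}{`Phi` is a random hidden layer (random weights, fixed).}
#'   \item{KELM-AE}{`Phi` is the full square kernel matrix of `X` against
#'     itself (`N x N`).}
#'   \item{RKELM-AE}{`Phi` is the reduced kernel matrix of `X` against a
#'     random subset of `n_refs` training rows (`N x n_refs`), cutting the
#'     solve from `O(N^3)` to an `n_refs x n_refs` system.}
#'   \item{REKELM-AE}{`X` is first expanded by a random layer to `L1`
#'     dimensions, and the reduced kernel matrix is computed between mapped
#'     rows and references drawn from the mapped rows — a random map composed
#'     with a similarity map (an expectation-kernel construction).}
#' }
#' @name autoencoders
NULL

new_encoder_model <- function(variant, gamma, C, input_dim, random_layer = NULL,
                              kernel = NULL, references = NULL) {
  structure(
    list(variant = variant, random_layer = random_layer, kernel = kernel,
         references = references, gamma = gamma, regularization = C,
         input_dim = as.integer(input_dim)),
    class = "encoder_model"
  )
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %s: gamma %d x %d, C = %g\n",
              x$variant, nrow(x$gamma), ncol(x$gamma), x$regularization))
  invisible(x)
}

check_C <- function(C) {
  if (!is.numeric(C) || length(C) != 1 || is.na(C) || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }
}

#' Fit an ELM autoencoder
#'
#' Maps `X` through a fixed random layer and solves the ridge system
#' `H Gamma ~= X` for the output weights (`L x d`).
#'
#' @param X Numeric matrix (or data frame of numeric columns), samples in
#'   rows.
#' @param layer A [make_random_layer()] whose input dimension matches
#'   `ncol(X)`.
#' @param C Positive ridge regularization parameter.
#' @return An `encoder_model` of variant `"elm_ae"`.
#' @export
fit_elm_ae <- function(X, layer, C = 100) {
  X <- as_feature_matrix(X)
  check_C(C)
  H <- random_map(layer, X)
  gamma <- ridge_solve(H, X, C, form = "auto")$coefficients
  new_encoder_model("elm_ae", gamma, C, ncol(X), random_layer = layer)
}

#' Fit a kernel ELM autoencoder (full kernel)
#'
#' Builds the full `N x N` kernel matrix `Omega` of `X` against itself and
#' solves `Gamma = (I/C + Omega)^{-1} X`. Cost grows as `O(N^3)`; the reduced
#' variants exist to avoid exactly this.
#'
#' @inheritParams fit_elm_ae
#' @param kernel A [kernel_spec()]; an RBF bandwidth of `NULL` is resolved on
#'   `X` by the median heuristic.
#' @return An `encoder_model` of variant `"kelm_ae"` whose references are all
#'   training rows.
#' @export
fit_kelm_ae <- function(X, kernel, C = 100) {
  X <- as_feature_matrix(X)
  check_C(C)
  if (nrow(X) < 2) stop("KELM-AE needs at least 2 samples", call. = FALSE)
  kernel <- resolve_sigma(kernel, X)
  refs <- structure(
    list(points = X, source_indices = seq_len(nrow(X)), seed = NA_integer_),
    class = "reference_set"
  )
  Omega <- reduced_kernel_matrix(kernel, X, refs)
  if (!all(is.finite(Omega))) stop("non-finite kernel entries", call. = FALSE)
  gamma <- solve(diag(nrow(X)) / C + Omega, X)
  new_encoder_model("kelm_ae", gamma, C, ncol(X), kernel = kernel,
                    references = refs)
}

#' Fit a reduced kernel ELM autoencoder
#'
#' Draws `n_refs` training rows as reference points, forms the rectangular
#' similarity matrix `Omega_hat` (`N x n_refs`) and solves the ridge system
#' `Gamma = (I/C + Omega_hat' Omega_hat)^{-1} Omega_hat' X`, an
#' `n_refs x n_refs` solve regardless of `N`.
#'
#' @inheritParams fit_kelm_ae
#' @param n_refs Number of reference points, `1 <= n_refs <= nrow(X)`.
#' @param seed Integer seed for the reference draw.
#' @return An `encoder_model` of variant `"rkelm_ae"` with `gamma`
#'   `n_refs x d`.
#' @export
fit_rkelm_ae <- function(X, kernel, n_refs, C = 100, seed = 1L) {
  X <- as_feature_matrix(X)
  check_C(C)
  kernel <- resolve_sigma(kernel, X)
  refs <- select_references(X, n_refs, seed)
  Om <- reduced_kernel_matrix(kernel, X, refs)
  if (!all(is.finite(Om))) stop("non-finite kernel entries", call. = FALSE)
  gamma <- ridge_solve(Om, X, C, form = "gram_p")$coefficients
  new_encoder_model("rkelm_ae", gamma, C, ncol(X), kernel = kernel,
                    references = refs)
}

#' Fit a reduced expectation kernel ELM autoencoder
#'
#' The package's central encoder. In order: (1) draw a random layer of `L1`
#' sigmoid nodes with standard-Gaussian weights; (2) map `X` to
#' `H = h(V'X)` (`N x L1`); (3) draw `n_refs` distinct rows of `H` as
#' reference points; (4) form `Omega_hat[i, j] = K(h(V'x_i), r_j)`;
#' (5) solve the ridge system `Omega_hat Gamma ~= X` for `Gamma`
#' (`n_refs x d`). The reconstruction target is the raw input `X`, not the
#' mapped `H`. Deterministic given `seed` (layer and reference draws use
#' derived sub-seeds).
#'
#' @inheritParams fit_rkelm_ae
#' @param L1 Number of random-map nodes (the expansion dimension).
#' @param activation Activation of the random layer (sigmoid by default).
#' @return An `encoder_model` of variant `"rekelm_ae"`.
#' @export
#' @examples
#' X <- matrix(rnorm(300), 50, 6)
#' enc <- fit_rekelm_ae(X, L1 = 60, n_refs = 10, kernel = kernel_spec("rbf"),
#'                      C = 100, seed = 1)
#' dim(enc$gamma)  # 10 x 6
fit_rekelm_ae <- function(X, L1, n_refs, kernel, C = 100, seed = 1L,
                          activation = "sigmoid") {
  X <- as_feature_matrix(X)
  check_C(C)
  if (length(L1) != 1 || is.na(L1) || L1 < 1) {
    stop("`L1` must be a positive integer", call. = FALSE)
  }
  layer <- make_random_layer(ncol(X), L1, distribution = "gaussian01",
                             activation = activation,
                             seed = derive_seed(seed, 1L))
  H <- random_map(layer, X)
  refs <- select_references(H, n_refs, seed = derive_seed(seed, 2L))
  kernel <- resolve_sigma(kernel, H)
  Om <- reduced_kernel_matrix(kernel, H, refs)
  if (!all(is.finite(Om))) stop("non-finite kernel entries", call. = FALSE)
  gamma <- ridge_solve(Om, X, C, form = "gram_p")$coefficients
  new_encoder_model("rekelm_ae", gamma, C, ncol(X), random_layer = layer,
                    kernel = kernel, references = refs)
}

# Recompute the hidden representation (the matrix Gamma was solved against)
# for new rows: H for elm_ae, the (reduced) kernel matrix otherwise.
hidden_representation <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("X has %d columns but the encoder expects %d",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  switch(model$variant,
    elm_ae = random_map(model$random_layer, X),
    kelm_ae = ,
    rkelm_ae = reduced_kernel_matrix(model$kernel, X, model$references),
    rekelm_ae = {
      H <- random_map(model$random_layer, X)
      reduced_kernel_matrix(model$kernel, H, model$references)
    }
  )
}

#' Encode samples with a fitted autoencoder
#'
#' The default (`method = "linear"`) is the projection `X %*% t(Gamma)`
#' applied to raw features — identical for training and unseen rows, giving a
#' `hidden-dim`-wide abstract feature per sample. `method = "kernel"` instead
#' returns the sample's hidden representation (its reduced kernel row /
#' random-map row), the space `Gamma` was actually solved in; it is offered
#' as a non-default alternative.
#'
#' @param model A fitted `encoder_model`.
#' @param X Numeric matrix or data frame of numeric columns with
#'   `model$input_dim` columns.
#' @param method `"linear"` (default) or `"kernel"`.
#' @return Numeric matrix `N x hidden-dim`.
#' @export
encode <- function(model, X, method = c("linear", "kernel")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  if (method == "kernel") return(hidden_representation(model, X))
  if (ncol(X) != model$input_dim) {
    stop(sprintf("X has %d columns but the encoder expects %d",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  tcrossprod(X, model$gamma)
}

#' Reconstruct samples through a fitted autoencoder
#'
#' Recomputes the hidden representation of `X` through the model's stored
#' layer/references and multiplies by `Gamma`. For the training matrix this
#' approximates `X`, with error shrinking as `C` grows.
#'
#' @inheritParams encode
#' @return Numeric matrix `N x input_dim`.
#' @export
reconstruct <- function(model, X) {
  hidden_representation(model, X) %*% model$gamma
}
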