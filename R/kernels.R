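#' Kernel / similarity specification
#'
#' The four similarity functions used by the multi-kernel models, computed
#' between a sample `x` and a reference point `r`:
#' \describe{
#'   \item{`rbf`}{`exp(-||x - r||_2^2 / (2 sigma^2))` — radial basis function.}
#'   \item{`euclidean_sq`}{`||x - r||_2^2` — squared Euclidean distance, used
#'     directly as a similarity feature.}
#'   \item{`manhattan`}{`||x - r||_1`.}
#'   \item{`cosine_printed`}{`(x . r) / (||x||_2^2 ||r||_2^2)` — cosine with
#'     squared norms in the denominator. This is the default cosine form.}
#'   \item{`cosine_standard`}{`(x . r) / (||x||_2 ||r||_2)` — the textbook
#'     cosine similarity, offered as an alternative.}
#' }
#' Distance families are deliberately not converted to decaying similarities:
#' the downstream ridge solve is indifferent to the monotone orientation of a
#' feature.
#'
#' @param family One of `"rbf"`, `"euclidean_sq"`, `"manhattan"`,
#'   `"cosine_printed"`, `"cosine_standard"`.
#' @param sigma Positive bandwidth, RBF only. `NULL` means "resolve at fit
#'   time by the median pairwise-distance heuristic" (see
#'   [resolve_sigma()]).
#' @return An object of class `kernel_spec`.
#' @export
#' @examples
#' kernel_spec("rbf", sigma = 1)
#' kernel_spec("manhattan")
kernel_spec <- function(family = c("rbf", "euclidean_sq", "manhattan",
                                   "cosine_printed", "cosine_standard"),
                        sigma = NULL) {
  family <- match.arg(family)
  if (family == "rbf") {
    if (!is.null(sigma) && (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)) {
      stop("`sigma` must be a positive scalar for the rbf family", call. = FALSE)
    }
  } else if (!is.null(sigma)) {
    stop("`sigma` is only meaningful for the rbf family", call. = FALSE)
  }
  structure(list(family = family, sigma = sigma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  s <- if (x$family == "rbf") {
    if (is.null(x$sigma)) " (sigma: median heuristic)" else sprintf(" (sigma = %g)", x$sigma)
  } else ""
  cat(sprintf("<kernel_spec> %s%s\n", x$family, s))
  invisible(x)
}

#' Resolve an unset RBF bandwidth by the median heuristic
#'
#' For an RBF spec with `sigma = NULL`, sets `sigma` to the median pairwise
#' Euclidean distance among the rows of `X` (the representation in which the
#' kernel will be applied). For more than 500 rows a deterministic evenly
#' spaced subset of 500 rows is used. Non-RBF specs and specs with a concrete
#' `sigma` pass through unchanged.
#'
#' @param spec A [kernel_spec()].
#' @param X Numeric matrix whose rows live in the kernel's input space.
#' @return A `kernel_spec` with a concrete `sigma` where applicable.
#' @export
resolve_sigma <- function(spec, X) {
  if (spec$family != "rbf" || !is.null(spec$sigma)) return(spec)
  X <- as_feature_matrix(X)
  if (nrow(X) > 500) {
    X <- X[unique(round(seq(1, nrow(X), length.out = 500))), , drop = FALSE]
  }
  med <- stats::median(stats::dist(X))
  if (!is.finite(med) || med <= 0) med <- 1
  spec$sigma <- med
  spec
}

kernel_sigma <- function(spec) {
  if (spec$family == "rbf" && is.null(spec$sigma)) {
    stop("rbf kernel_spec has unresolved sigma; call resolve_sigma() first",
         call. = FALSE)
  }
  spec$sigma
}

#' Evaluate a kernel between two vectors
#'
#' Scalar form of the similarity functions in [kernel_spec()]. All families
#' are symmetric in `(x, r)`.
#'
#' @param spec A [kernel_spec()] (RBF bandwidth must be concrete).
#' @param x,r Numeric vectors of equal length. Cosine families require both
#'   to be nonzero.
#' @return A single numeric similarity value.
#' @export
#' @examples
#' kernel_value(kernel_spec("manhattan"), c(1, 2), c(0, 0))      # 3
#' kernel_value(kernel_spec("rbf", 2), c(1, 1), c(1, 1))         # 1
kernel_value <- function(spec, x, r) {
  if (length(x) != length(r)) {
    stop("x and r must have equal length", call. = FALSE)
  }
  switch(spec$family,
    rbf = exp(-sum((x - r)^2) / (2 * kernel_sigma(spec)^2)),
    euclidean_sq = sum((x - r)^2),
    manhattan = sum(abs(x - r)),
    cosine_printed = {
      nx <- sum(x^2); nr <- sum(r^2)
      if (nx == 0 || nr == 0) {
        stop("cosine similarity undefined for a zero vector", call. = FALSE)
      }
      sum(x * r) / (nx * nr)
    },
    cosine_standard = {
      nx <- sqrt(sum(x^2)); nr <- sqrt(sum(r^2))
      if (nx == 0 || nr == 0) {
        stop("cosine similarity undefined for a zero vector", call. = FALSE)
      }
      sum(x * r) / (nx * nr)
    }
  )
}

#' Draw a reference set from the rows of a matrix
#'
#' Samples `n_refs` distinct row indices uniformly without replacement.
#' Reference rows are stored by value so a fitted encoder survives
#' serialization independently of the training data.
#'
#' @param X Numeric matrix whose rows are candidate reference points.
#' @param n_refs Number of reference points, `1 <= n_refs <= nrow(X)`.
#' @param seed Integer seed.
#' @return Object of class `reference_set` with fields `points`
#'   (`n_refs x p`), `source_indices`, `seed`.
#' @export
select_references <- function(X, n_refs, seed = 1L) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (length(n_refs) != 1 || is.na(n_refs) || n_refs < 1 || n_refs > n) {
    stop(sprintf("`n_refs` must be in [1, %d]", n), call. = FALSE)
  }
  n_refs <- as.integer(n_refs)
  idx <- with_seed(seed, sample.int(n, n_refs, replace = FALSE))
  structure(
    list(points = X[idx, , drop = FALSE], source_indices = idx,
         seed = as.integer(seed)),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d points x %d dims, seed %d\n",
              nrow(x$points), ncol(x$points), x$seed))
  invisible(x)
}

#' Reduced (rectangular) kernel matrix against a reference set
#'
#' Entry `(i, j)` is `kernel_value(spec, X[i, ], refs$points[j, ])`: each row
#' is the similarity profile of one sample against the `n_refs` reference
#' points. With the full training set as references and a Mercer kernel this
#' is the ordinary square kernel matrix.
#'
#' @param spec A [kernel_spec()] with concrete parameters.
#' @param X Numeric matrix `N x p`.
#' @param refs A [select_references()] object with matching column count.
#' @return Numeric matrix `N x n_refs`.
#' @export
reduced_kernel_matrix <- function(spec, X, refs) {
  X <- as_feature_matrix(X)
  R <- refs$points
  if (ncol(X) != ncol(R)) {
    stop("X and reference points must share column count", call. = FALSE)
  }
  switch(spec$family,
    rbf = {
      d2 <- pairwise_sqdist(X, R)
      exp(-d2 / (2 * kernel_sigma(spec)^2))
    },
    euclidean_sq = pairwise_sqdist(X, R),
    manhattan = {
      out <- matrix(0, nrow(X), nrow(R))
      for (j in seq_len(nrow(R))) {
        out[, j] <- rowSums(abs(sweep(X, 2L, R[j, ], "-")))
      }
      out
    },
    cosine_printed = {
      nx <- rowSums(X^2); nr <- rowSums(R^2)
      check_nonzero_norms(nx, nr)
      tcrossprod(X, R) / outer(nx, nr)
    },
    cosine_standard = {
      nx <- sqrt(rowSums(X^2)); nr <- sqrt(rowSums(R^2))
      check_nonzero_norms(nx, nr)
      tcrossprod(X, R) / outer(nx, nr)
    }
  )
}

check_nonzero_norms <- function(nx, nr) {
  if (any(nx == 0) || any(nr == 0)) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  invisible(NULL)
}

# ||x_i - r_j||^2 via the expansion ||x||^2 + ||r||^2 - 2 x.r, clipped at 0
# against negative round-off.
pairwise_sqdist <- function(X, R) {
  d2 <- outer(rowSums(X^2), rowSums(R^2), "+") - 2 * tcrossprod(X, R)
  d2[d2 < 0] <- 0
  d2
}

#' The default four-kernel bank
#'
#' RBF, squared Euclidean distance, Manhattan distance and (printed-form)
#' cosine similarity, in that order — the kernel bank the multi-kernel models
#' fuse by default.
#'
#' @param sigma RBF bandwidth; `NULL` for the median heuristic at fit time.
#' @return A list of four [kernel_spec()] objects.
#' @export
default_kernels <- function(sigma = NULL) {
  list(
    kernel_spec("rbf", sigma),
    kernel_spec("euclidean_sq"),
    kernel_spec("manhattan"),
    kernel_spec("cosine_printed")
  )
}

# Map CLI-style names to kernel_spec objects ("rbf,euclid,manhattan,cosine").
parse_kernel_names <- function(names, sigma = NULL) {
  lapply(strsplit(names, ",")[[1]], function(nm) {
    nm <- trimws(nm)
    family <- switch(nm,
      rbf = "rbf",
      euclid = , euclidean = , euclidean_sq = "euclidean_sq",
      manhattan = "manhattan",
      cosine = , cosine_printed = "cosine_printed",
      cosine_standard = "cosine_standard",
      stop("unknown kernel name: ", nm, call. = FALSE)
    )
    kernel_spec(family, if (family == "rbf") sigma else NULL)
  })
}
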