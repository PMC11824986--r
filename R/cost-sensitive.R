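#' @title Cost matrices, minimum-risk decisions and evaluation metrics
#' @description
#' The decision layer: convert raw classifier scores to posterior
#' probabilities with a sigmoid followed by row normalization, then pick the
#' class with the lowest posterior-weighted expected misclassification cost
#' under an `m x m` cost matrix `c[i, j]` (cost of predicting class `j` when
#' the truth is class `i`). Also houses cost-weighting schemes for weighted
#' ELM baselines and the evaluation metrics: accuracy, total
#' misclassification cost `Tc` and relative performance.
#' @name cost_sensitive
NULL

#' Construct a misclassification cost matrix
#'
#' `costs[i, j]` is the cost of classifying true class `i` as class `j`;
#' the diagonal is zero.
#'
#' @param costs Square numeric matrix, nonnegative and finite, zero diagonal,
#'   at least one positive off-diagonal entry.
#' @param class_order Class labels in matrix order (defaults to existing
#'   dimnames or `c1..cm`).
#' @return An object of class `cost_matrix`.
#' @export
cost_matrix <- function(costs, class_order = NULL) {
  costs <- as.matrix(costs)
  if (nrow(costs) != ncol(costs)) stop("cost matrix must be square", call. = FALSE)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("costs must be finite and nonnegative", call. = FALSE)
  }
  if (all(costs[row(costs) != col(costs)] == 0)) {
    stop("at least one off-diagonal cost must be positive", call. = FALSE)
  }
  if (is.null(class_order)) {
    class_order <- if (!is.null(rownames(costs))) rownames(costs) else
      paste0("c", seq_len(nrow(costs)))
  }
  class_order <- as.character(class_order)
  if (length(class_order) != nrow(costs)) {
    stop("class_order length must match the matrix dimension", call. = FALSE)
  }
  dimnames(costs) <- list(class_order, class_order)
  structure(list(costs = costs, class_order = class_order),
            class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> %d classes\n", length(x$class_order)))
  print(x$costs)
  invisible(x)
}

#' Generate a cost matrix from one of four synthetic families
#'
#' All families put zero on the diagonal and are deterministic given `seed`:
#' \describe{
#'   \item{`uniform_range`}{off-diagonal integers uniform on `[1, max_cost]`
#'     (default 20), the random regime used for model ablations.}
#'   \item{`type_a`}{off-diagonal integers uniform on `[1, max_cost]`
#'     (default 10).}
#'   \item{`type_b`}{row severity: each true class `i` draws one severity
#'     `s_i` uniform on `[1, max_cost]` and `c[i, j] = s_i` for all
#'     `j != i` — misclassifying class `i` costs the same wherever it lands.}
#'   \item{`type_c`}{imbalance-linked: `c[i, j]` proportional to
#'     `1 / frequency(class i)`, rescaled so the maximum off-diagonal entry
#'     equals `max_cost` — rarer classes are costlier to miss. Requires
#'     `class_freq`.}
#' }
#' The three structured families are synthetic stand-ins named after a
#' three-way severity taxonomy; they are this package's own constructions.
#'
#' @param m Number of classes (>= 2).
#' @param family `"uniform_range"`, `"type_a"`, `"type_b"` or `"type_c"`.
#' @param max_cost Maximum cost value (default 20 for `uniform_range`, 10
#'   for the typed families).
#' @param seed Integer seed.
#' @param class_order Optional class labels.
#' @param class_freq Class frequencies (counts or proportions) for
#'   `type_c`.
#' @return A [cost_matrix()].
#' @export
#' @examples
#' make_cost_matrix(3, "uniform_range", seed = 1)
#' make_cost_matrix(2, "type_b", seed = 1)
make_cost_matrix <- function(m, family = c("uniform_range", "type_a", "type_b",
                                           "type_c"),
                             max_cost = NULL, seed = 1L, class_order = NULL,
                             class_freq = NULL) {
  family <- match.arg(family)
  if (length(m) != 1 || is.na(m) || m < 2) {
    stop("`m` must be an integer >= 2", call. = FALSE)
  }
  m <- as.integer(m)
  if (is.null(max_cost)) {
    max_cost <- if (family == "uniform_range") 20 else 10
  }
  if (max_cost < 1) stop("`max_cost` must be >= 1", call. = FALSE)
  off <- row(diag(m)) != col(diag(m))
  costs <- matrix(0, m, m)
  if (family %in% c("uniform_range", "type_a")) {
    costs[off] <- with_seed(seed,
      sample.int(as.integer(max_cost), sum(off), replace = TRUE))
  } else if (family == "type_b") {
    s <- with_seed(seed, sample.int(as.integer(max_cost), m, replace = TRUE))
    costs[off] <- s[row(costs)[off]]
  } else {
    if (is.null(class_freq)) {
      stop("`class_freq` is required for the type_c family", call. = FALSE)
    }
    if (length(class_freq) != m || any(class_freq <= 0)) {
      stop("`class_freq` must be positive with one entry per class",
           call. = FALSE)
    }
    raw <- 1 / (class_freq / sum(class_freq))
    costs[off] <- raw[row(costs)[off]]
    costs <- costs * (max_cost / max(costs[off]))
  }
  cost_matrix(costs, class_order %||% paste0("c", seq_len(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert classifier scores to posterior probabilities
#'
#' Applies the sigmoid `1 / (1 + exp(-f_i(x)))` to each per-class score, then
#' normalizes each row to sum to 1 (the raw sigmoids need not). Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` before normalization so downstream
#' risks stay finite.
#'
#' @param scores Numeric matrix `N x m` of raw classifier outputs (a vector
#'   is treated as one row).
#' @return Numeric matrix `N x m`; every row sums to 1.
#' @export
#' @examples
#' scores_to_posteriors(rbind(c(0, 0, 0)))      # uniform 1/3
#' scores_to_posteriors(rbind(c(10, -10)))      # ~ (1, 0)
scores_to_posteriors <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  P <- sigmoid(scores)
  P[P < 1e-12] <- 1e-12
  P[P > 1 - 1e-12] <- 1 - 1e-12
  P / rowSums(P)
}

#' Minimum-risk class decisions
#'
#' For each row of posteriors, computes the expected cost of predicting each
#' class `j`, `risk_j = sum_i P(i | x) * c[i, j]`, and returns the class with
#' the smallest risk. Ties break to the lowest class index. With 0-1 costs
#' this reduces to the argmax of the posteriors.
#'
#' @param posteriors Numeric matrix `N x m` of row-normalized posteriors
#'   (columns in the cost matrix's class order; a vector is one row).
#' @param cost A [cost_matrix()] with matching dimension.
#' @return Character vector of length `N` of decided class labels.
#' @export
#' @examples
#' cm <- cost_matrix(matrix(c(0, 10, 1, 0), 2, 2))
#' min_risk_decide(rbind(c(0.7, 0.3)), cm)  # picks the costly-to-miss class
min_risk_decide <- function(posteriors, cost) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1)
  m <- length(cost$class_order)
  if (ncol(posteriors) != m) {
    stop("posterior width must equal the cost-matrix dimension", call. = FALSE)
  }
  risks <- posteriors %*% cost$costs
  cost$class_order[max.col(-risks, ties.method = "first")]
}

#' Per-sample weights for cost-weighted ELM fits
#'
#' Four weighting schemes from the cost-sensitive ELM literature, each
#' producing one positive weight per training sample from its true class:
#' \describe{
#'   \item{`class_balance`}{`w_i = N_min / N_{y_i}`: inverse class-size
#'     weighting against imbalance; 1 for the smallest class.}
#'   \item{`row_sum`}{`w_i = sum_j c[y_i, j]`: the total misclassification
#'     cost of the sample's true class (the weight used by [fit_celm()]).}
#'   \item{`per_sample_cost`}{the row-sum weight rescaled to mean 1, a
#'     scale-free variant.}
#'   \item{`helm`}{`w_i = 1 / (p_i + (N_{y_i} - p_i) N_{y_i} / max_c N_c)`
#'     with `p_i = N - N_{y_i}`: a hierarchical-ELM class weighting that
#'     mildly up-weights minority classes.}
#' }
#'
#' @param labels True class label per sample.
#' @param cost A [cost_matrix()] (required for the cost-based schemes; its
#'   `class_order` must cover the labels).
#' @param scheme One of `"class_balance"`, `"row_sum"`, `"per_sample_cost"`,
#'   `"helm"`.
#' @return Object of class `cost_weights`: list with `scheme` and positive
#'   numeric `weights` of length `N`.
#' @export
compute_cost_weights <- function(labels, cost = NULL,
                                 scheme = c("class_balance", "row_sum",
                                            "per_sample_cost", "helm")) {
  scheme <- match.arg(scheme)
  if (length(labels) == 0) stop("labels must be nonempty", call. = FALSE)
  y <- as.character(labels)
  if (scheme %in% c("row_sum", "per_sample_cost")) {
    if (is.null(cost)) stop("`cost` is required for this scheme", call. = FALSE)
    if (!all(y %in% cost$class_order)) {
      stop("labels outside the cost matrix class order", call. = FALSE)
    }
    k <- rowSums(cost$costs)
    w <- k[match(y, cost$class_order)]
    if (any(w <= 0)) {
      stop("every class present must have positive row-sum cost", call. = FALSE)
    }
    if (scheme == "per_sample_cost") w <- w / mean(w)
  } else {
    counts <- table(y)
    if (scheme == "class_balance") {
      w <- as.numeric(min(counts)) / as.numeric(counts[y])
    } else {
      N <- length(y)
      n_i <- as.numeric(counts[y])
      p_i <- N - n_i
      w <- 1 / (p_i + (n_i - p_i) * n_i / max(counts))
    }
  }
  structure(list(scheme = scheme, weights = unname(w)), class = "cost_weights")
}

#' Fit a cost-weighted ELM classifier (CELM baseline)
#'
#' An ELM classifier whose ridge solve weights each sample's squared error by
#' the total misclassification cost of its true class (the row sum of the
#' cost matrix), so costly-to-miss classes dominate the fit:
#' `beta = (I/C + H' D H)^{-1} H' D T` with `D = diag(w)`.
#'
#' @inheritParams fit_mkp_elm
#' @param cost A [cost_matrix()] covering every class present.
#' @param L Hidden nodes.
#' @param C Ridge regularization.
#' @param seed Integer seed.
#' @return An `elm_classifier`.
#' @export
fit_celm <- function(data, cost, label = "label", labels = NULL, L = 1000,
                     C = 100, seed = 1L) {
  parts <- split_data_labels(data, label, labels)
  w <- compute_cost_weights(parts$y, cost, "row_sum")$weights
  fit_elm_classifier(parts$X, parts$y, L = L, C = C, seed = seed,
                     sample_weights = w)
}

#' Evaluate predictions under a cost matrix
#'
#' Builds the `m x m` confusion table (true class in rows, predicted in
#' columns) and computes accuracy `acc = 1 - sum(err_i) / N` and total
#' misclassification cost `Tc = sum_ij err_ij * c[i, j]`.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels of the same length.
#' @param cost Optional [cost_matrix()]; without it only accuracy is
#'   computed. All labels must appear in its class order.
#' @return Object of class `evaluation_report` with fields `confusion`,
#'   `acc`, `total_cost`, `n`. Use [glance()] / [tidy()] for tibble views.
#' @export
#' @examples
#' cm <- make_cost_matrix(2, "type_a", seed = 3)
#' evaluate_predictions(c("c1", "c1", "c2"), c("c1", "c2", "c2"), cm)
evaluate_predictions <- function(truth, estimate, cost = NULL) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  truth <- as.character(truth); estimate <- as.character(estimate)
  classes <- if (!is.null(cost)) cost$class_order else
    sort(unique(c(truth, estimate)))
  if (!all(c(truth, estimate) %in% classes)) {
    stop("labels outside the cost matrix class order", call. = FALSE)
  }
  confusion <- table(factor(truth, classes), factor(estimate, classes))
  confusion <- matrix(as.integer(confusion), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  acc <- sum(diag(confusion)) / length(truth)
  total_cost <- if (!is.null(cost)) sum(confusion * cost$costs) else NA_real_
  structure(
    list(confusion = confusion, acc = acc, total_cost = total_cost,
         n = length(truth)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, acc = %.4f%s\n", x$n, x$acc,
              if (is.na(x$total_cost)) "" else
                sprintf(", total cost = %.4g", x$total_cost)))
  print(x$confusion)
  invisible(x)
}

#' Relative performance of competing methods
#'
#' Divides each method's total misclassification cost by the largest cost in
#' the comparison, so the worst method scores exactly 1 and better methods
#' score in (0, 1).
#'
#' @param total_costs Named or unnamed numeric vector of per-method total
#'   costs, all nonnegative with a positive maximum.
#' @return Numeric vector of the same length and names; maximum exactly 1.
#' @export
#' @examples
#' relative_performance(c(ours = 50, baseline = 100))
relative_performance <- function(total_costs) {
  if (length(total_costs) == 0) stop("need at least one cost", call. = FALSE)
  if (any(!is.finite(total_costs)) || any(total_costs < 0)) {
    stop("costs must be finite and nonnegative", call. = FALSE)
  }
  mx <- max(total_costs)
  if (mx <= 0) stop("all costs are zero; relative performance undefined",
                    call. = FALSE)
  total_costs / mx
}
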