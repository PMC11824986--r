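#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a multi-kernel ELM
#'
#' One row per encoder in the stack: its position, kernel family, resolved
#' RBF bandwidth (if any), random-layer width and reference count.
#'
#' @param x A fitted `mk_elm`.
#' @param ... Unused.
#' @return A tibble with columns `encoder`, `kernel`, `sigma`, `l1`,
#'   `n_refs`, `regularization`.
#' @method tidy mk_elm
#' @export
tidy.mk_elm <- function(x, ...) {
  tibble::tibble(
    encoder = seq_along(x$encoders),
    kernel = vapply(x$encoders, function(e) e$kernel$family, character(1)),
    sigma = vapply(x$encoders, function(e) {
      if (identical(e$kernel$family, "rbf")) e$kernel$sigma else NA_real_
    }, numeric(1)),
    l1 = vapply(x$encoders, function(e) {
      if (is.null(e$random_layer)) NA_integer_ else
        nrow(e$random_layer$weights)
    }, integer(1)),
    n_refs = vapply(x$encoders, function(e) nrow(e$references$points),
                    integer(1)),
    regularization = vapply(x$encoders, function(e) e$regularization,
                            numeric(1))
  )
}

#' Glance at a multi-kernel ELM
#'
#' @param x A fitted `mk_elm`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, kernel count, sizing ratios,
#'   classifier width, regularization, class count and seed.
#' @method glance mk_elm
#' @export
glance.mk_elm <- function(x, ...) {
  tibble::tibble(
    architecture = x$architecture,
    n_kernels = length(x$encoders),
    r1 = x$sizing$r1, r2 = x$sizing$r2,
    l1 = x$sizing$L1, n_refs = x$sizing$n_refs,
    hidden_nodes = x$L, regularization = x$C,
    n_classes = length(x$classifier$classes),
    seed = x$seed
  )
}

#' Tidy an evaluation report
#'
#' Long-format confusion table: one row per (truth, predicted) cell with its
#' count.
#'
#' @param x An [evaluate_predictions()] report.
#' @param ... Unused.
#' @return A tibble with columns `truth`, `predicted`, `count`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    truth = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    count = as.integer(cm)
  )
}

#' Glance at an evaluation report
#'
#' @param x An [evaluate_predictions()] report.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `acc`, `total_cost`.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(n = x$n, acc = x$acc, total_cost = x$total_cost)
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object An [evaluate_predictions()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("acc = %.3f%s", object$acc,
                      if (is.na(object$total_cost)) "" else
                        sprintf(", total cost = %.4g", object$total_cost)),
      x = "predicted class", y = "true class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ablation result
#'
#' For an [ablate_r2()] result, accuracy and total cost against the
#' compression ratio; for an [ablate_kernels()] result, performance against
#' the number of fused kernels.
#'
#' @param object A tibble of class `costelm_ablation`.
#' @param metric `"total_cost"` (default) or `"acc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot costelm_ablation
#' @export
autoplot.costelm_ablation <- function(object, metric = c("total_cost", "acc"),
                                      ...) {
  metric <- match.arg(metric)
  xvar <- if ("r2" %in% names(object)) "r2" else "n_kernels"
  df <- dplyr::summarise(
    dplyr::group_by(object, dplyr::across(dplyr::all_of(xvar))),
    value = mean(.data[[metric]]), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = sprintf("mean %s", metric)) +
    ggplot2::theme_minimal()
}
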