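fit_one_arch <- function(architecture, train, label, kernels, r1, r2, L, C,
                         seed) {
  fitter <- if (architecture == "mkp") fit_mkp_elm else fit_mkr_elm
  fitter(train, label = label, kernels = kernels, r1 = r1, r2 = r2, L = L,
         C = C, seed = seed)
}

eval_fit <- function(model, test, label, cost, min_risk = TRUE) {
  pred <- predict(model, test, type = "class",
                  cost = if (min_risk) cost else NULL)
  evaluate_predictions(test[[label]], pred$.pred_class, cost)
}

#' Sweep the reference-set compression ratio
#'
#' Refits and evaluates a multi-kernel model over a grid of compression
#' ratios `r2 = n_refs / N` (default 0.01 to 0.2 in steps of 0.01), each at
#' one or more seeds, on a fixed train/test split per seed.
#'
#' @param data Data frame with features and a label column.
#' @param cost A [cost_matrix()] used for minimum-risk decisions and cost
#'   accounting.
#' @param label Label column name.
#' @param r2_grid Numeric vector of compression ratios to sweep.
#' @param architecture `"mkp"` or `"mkr"`.
#' @param kernels Kernel bank (default all four).
#' @param r1,L,C Model hyperparameters as in [fit_mkp_elm()].
#' @param train_fraction Train share of each split.
#' @param seeds Integer vector; one fit+evaluation per (r2, seed).
#' @return A tibble of class `costelm_ablation` with columns `r2`, `seed`,
#'   `acc`, `total_cost`.
#' @export
ablate_r2 <- function(data, cost, label = "label",
                      r2_grid = seq(0.01, 0.2, by = 0.01),
                      architecture = c("mkp", "mkr"),
                      kernels = default_kernels(), r1 = 10, L = 1000, C = 100,
                      train_fraction = 0.6, seeds = 1:5) {
  architecture <- match.arg(architecture)
  grid <- tidyr::expand_grid(r2 = r2_grid, seed = as.integer(seeds))
  res <- purrr::pmap_dfr(grid, function(r2, seed) {
    parts <- split_train_test(data, train_fraction, seed, label)
    model <- fit_one_arch(architecture, parts$train, label, kernels, r1, r2,
                          L, C, seed)
    rep <- eval_fit(model, parts$test, label, cost)
    tibble::tibble(r2 = r2, seed = seed, acc = rep$acc,
                   total_cost = rep$total_cost)
  })
  class(res) <- c("costelm_ablation", class(res))
  res
}

#' Sweep all kernel combinations
#'
#' Fits and evaluates the model for every non-empty subset of the kernel
#' bank (15 subsets for the default four kernels), each at one or more
#' seeds — the exhaustive combination study behind the "more kernels help"
#' comparison.
#'
#' @inheritParams ablate_r2
#' @param r2 Compression ratio used for every fit.
#' @return A tibble of class `costelm_ablation` with columns `combo`
#'   (kernel families joined by `+`), `n_kernels`, `seed`, `acc`,
#'   `total_cost`.
#' @export
ablate_kernels <- function(data, cost, label = "label",
                           architecture = c("mkp", "mkr"),
                           kernels = default_kernels(), r1 = 10, r2 = 0.05,
                           L = 1000, C = 100, train_fraction = 0.6,
                           seeds = 1:5) {
  architecture <- match.arg(architecture)
  k <- length(kernels)
  subsets <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(k, sz, simplify = FALSE)
  }), recursive = FALSE)
  grid <- tidyr::expand_grid(subset_id = seq_along(subsets),
                             seed = as.integer(seeds))
  res <- purrr::pmap_dfr(grid, function(subset_id, seed) {
    idx <- subsets[[subset_id]]
    parts <- split_train_test(data, train_fraction, seed, label)
    model <- fit_one_arch(architecture, parts$train, label, kernels[idx], r1,
                          r2, L, C, seed)
    rep <- eval_fit(model, parts$test, label, cost)
    tibble::tibble(
      combo = paste(vapply(kernels[idx], function(kk) kk$family, ""),
                    collapse = "+"),
      n_kernels = length(idx), seed = seed, acc = rep$acc,
      total_cost = rep$total_cost
    )
  })
  class(res) <- c("costelm_ablation", class(res))
  res
}
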