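test_that("scores_to_posteriors applies sigmoid then row normalization", {
  expect_close(scores_to_posteriors(c(0, 0, 0)), rbind(rep(1 / 3, 3)), 1e-12)
  p <- scores_to_posteriors(c(10, -10))
  manual <- oracle_sigmoid(c(10, -10))
  expect_close(p, rbind(manual / sum(manual)), 1e-9)
  expect_gt(p[1], 0.9999)
  S <- rmat(50, 4, seed = 1) * 10
  expect_close(rowSums(scores_to_posteriors(S)), rep(1, 50), 1e-9)
  expect_error(scores_to_posteriors(c(1, NA)), "finite")
})

test_that("min_risk_decide picks the minimum expected cost, ties to lowest index", {
  cm01 <- cost_matrix(matrix(c(0, 1, 1, 0), 2, 2), c("c1", "c2"))
  expect_identical(min_risk_decide(c(0.9, 0.1), cm01), "c1")
  # a 10x costlier second class flips the decision despite lower posterior
  cm <- cost_matrix(rbind(c(0, 1), c(10, 0)), c("c1", "c2"))
  risks <- c(0.7 * 0 + 0.3 * 10, 0.7 * 1 + 0.3 * 0)
  expect_identical(risks, c(3.0, 0.7))
  expect_identical(min_risk_decide(c(0.7, 0.3), cm), "c2")
  # uniform posteriors + symmetric costs: tie broken to the first class
  expect_identical(min_risk_decide(c(0.5, 0.5), cm01), "c1")
  expect_error(min_risk_decide(c(0.2, 0.3, 0.5), cm01), "dimension")
})

test_that("0-1 costs reduce minimum-risk to argmax on random posteriors", {
  for (seed in 1:50) {
    m <- 2 + seed %% 5
    post <- withr::with_seed(seed, {
      p <- matrix(runif(10 * m), 10, m); p / rowSums(p)
    })
    cm <- cost_matrix(1 - diag(m), paste0("c", 1:m))
    expect_identical(min_risk_decide(post, cm),
                     paste0("c", max.col(post, ties.method = "first")))
  }
})

test_that("decisions are risk-optimal and scale-invariant", {
  for (seed in 1:30) {
    m <- 2 + seed %% 5
    post <- withr::with_seed(seed, { p <- matrix(runif(5 * m), 5, m); p / rowSums(p) })
    costs <- withr::with_seed(seed + 99, matrix(sample(0:9, m * m, TRUE), m))
    diag(costs) <- 0
    if (all(costs == 0)) costs[1, 2] <- 1
    cm <- cost_matrix(costs, paste0("c", 1:m))
    dec <- min_risk_decide(post, cm)
    for (i in 1:5) {
      expect_identical(dec[i], paste0("c", oracle_min_risk(post[i, ], costs)))
    }
    cm_scaled <- cost_matrix(costs * 7.3, paste0("c", 1:m))
    expect_identical(min_risk_decide(post, cm_scaled), dec)
  }
})

test_that("cost-matrix families satisfy their constructions", {
  u <- make_cost_matrix(2, "uniform_range", seed = 1)
  off <- u$costs[row(u$costs) != col(u$costs)]
  expect_true(all(off >= 1 & off <= 20 & off == round(off)))
  expect_true(all(diag(u$costs) == 0))

  a <- make_cost_matrix(3, "type_a", seed = 2)
  offa <- a$costs[row(a$costs) != col(a$costs)]
  expect_length(offa, 6)
  expect_true(all(offa >= 1 & offa <= 10))

  b <- make_cost_matrix(4, "type_b", seed = 3)
  for (i in 1:4) {
    rowvals <- b$costs[i, -i]
    expect_true(all(rowvals == rowvals[1]))  # one severity per true class
  }

  cc <- make_cost_matrix(3, "type_c", seed = 4, class_freq = c(70, 20, 10))
  expect_equal(max(cc$costs), 10)
  # rarer classes are costlier to misclassify
  expect_true(cc$costs[3, 1] > cc$costs[2, 1])
  expect_true(cc$costs[2, 1] > cc$costs[1, 2])
  expect_error(make_cost_matrix(3, "type_c", seed = 1), "class_freq")
  expect_error(make_cost_matrix(1, "type_a"), "m")

  expect_identical(make_cost_matrix(3, "type_a", seed = 5)$costs,
                   make_cost_matrix(3, "type_a", seed = 5)$costs)
})

test_that("cost matrices round-trip through delimited text", {
  cm <- make_cost_matrix(3, "uniform_range", seed = 6,
                         class_order = c("lo", "mid", "hi"))
  path <- tempfile(fileext = ".csv")
  write_cost_matrix(cm, path)
  back <- read_cost_matrix(path)
  expect_identical(back$class_order, cm$class_order)
  expect_equal(back$costs, cm$costs)
})

test_that("weighting schemes match their defining formulas", {
  balanced <- rep(c("a", "b"), each = 10)
  expect_true(all(compute_cost_weights(balanced,
                                       scheme = "class_balance")$weights == 1))
  y <- rep(c("a", "b"), c(90, 10))
  w <- compute_cost_weights(y, scheme = "class_balance")$weights
  expect_equal(unique(w[y == "a"]), 10 / 90, tolerance = 1e-12)
  expect_equal(unique(w[y == "b"]), 1)

  cm <- cost_matrix(rbind(c(0, 1), c(10, 0)), c("a", "b"))
  wr <- compute_cost_weights(c("a", "b", "b"), cm, "row_sum")$weights
  expect_identical(wr, c(1, 10, 10))
  wp <- compute_cost_weights(c("a", "b", "b"), cm, "per_sample_cost")$weights
  expect_equal(mean(wp), 1)
  expect_equal(wp / wp[1], wr / wr[1])

  wh <- compute_cost_weights(y, scheme = "helm")$weights
  expect_true(all(wh > 0))
  # minority class gets at least the majority weight
  expect_gte(unique(wh[y == "b"]), unique(wh[y == "a"]))
})

test_that("fit_celm reduces to the unweighted fit under equal weights", {
  d <- generate_classification_data(n_samples = 40, n_features = 3,
                                    n_classes = 2, seed = 1)
  # symmetric cost matrix -> equal row sums -> weights all equal
  cm <- cost_matrix(rbind(c(0, 5), c(5, 0)), levels(d$label))
  celm <- fit_celm(d, cm, L = 15, C = 10, seed = 3)
  plain <- fit_elm_classifier(d[paste0("x", 1:3)], d$label, L = 15, C = 10,
                              seed = 3)
  # equal weights w scale the objective; with weight w the effective C is w*C
  w <- 5
  rescaled <- fit_elm_classifier(d[paste0("x", 1:3)], d$label, L = 15,
                                 C = w * 10, seed = 3)
  expect_close(celm$beta$coefficients, rescaled$beta$coefficients, 1e-8)
  expect_false(isTRUE(all.equal(celm$beta$coefficients,
                                plain$beta$coefficients, tolerance = 1e-8)))
})

test_that("fit_celm matches the weighted least-squares oracle", {
  d <- generate_classification_data(n_samples = 20, n_features = 5,
                                    n_classes = 2, seed = 2)
  cm <- cost_matrix(rbind(c(0, 2), c(9, 0)), levels(d$label))
  celm <- fit_celm(d, cm, L = 8, C = 4, seed = 5)
  X <- as.matrix(d[paste0("x", 1:5)])
  H <- random_map(celm$hidden_layer, X)
  T <- matrix(-1, 20, 2); T[cbind(1:20, as.integer(d$label))] <- 1
  w <- ifelse(d$label == levels(d$label)[1], 2, 9)
  # brute-force: minimize sum_i w_i ||h_i B - t_i||^2 + ||B||^2 / C
  obj <- function(b) {
    B <- matrix(b, 8, 2)
    sum(w * rowSums((H %*% B - T)^2)) + sum(B^2) / 4
  }
  fit <- optim(rep(0, 16), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_close(celm$beta$coefficients, matrix(fit$par, 8, 2), 1e-5)
})

test_that("up-weighting a class never hurts its training recall", {
  wins <- 0
  for (seed in 1:10) {
    d <- generate_classification_data(n_samples = 80, n_features = 3,
                                      n_classes = 2, cluster_separation = 1.5,
                                      noise_sd = 1.2, seed = seed)
    X <- d[paste0("x", 1:3)]
    plain <- fit_elm_classifier(X, d$label, L = 30, C = 10, seed = seed)
    upw <- ifelse(d$label == "c2", 20, 1)
    heavy <- fit_elm_classifier(X, d$label, L = 30, C = 10, seed = seed,
                                sample_weights = upw)
    rec <- function(m) mean(predict(m, X)[d$label == "c2"] == "c2")
    expect_gte(rec(heavy) + 1e-12, rec(plain))
  }
})

test_that("evaluate_predictions tallies the printed metric definitions", {
  cm <- cost_matrix(rbind(c(0, 3), c(7, 0)), c("a", "b"))
  truth <- c(rep("a", 5), rep("b", 5))
  est <- truth
  perfect <- evaluate_predictions(truth, est, cm)
  expect_identical(perfect$acc, 1)
  expect_identical(perfect$total_cost, 0)
  est[1] <- "b"   # one a->b error, cost 3
  est[6] <- "a"   # one b->a error, cost 7
  rep2 <- evaluate_predictions(truth, est, cm)
  expect_identical(rep2$acc, 0.8)
  expect_identical(rep2$total_cost, 10)
  expect_identical(sum(rep2$confusion), 10L)
  expect_error(evaluate_predictions(truth, rep("z", 10), cm), "class order")
  g <- glance(rep2)
  expect_identical(g$acc, 0.8)
  t <- tidy(rep2)
  expect_identical(sum(t$count), 10L)
})

test_that("relative performance is anchored at the worst method", {
  expect_identical(relative_performance(c(50, 100)), c(0.5, 1.0))
  expect_identical(relative_performance(42), 1)
  r <- relative_performance(c(a = 10, b = 80, c = 40))
  expect_identical(max(r), 1)
  expect_identical(names(r), c("a", "b", "c"))
  expect_error(relative_performance(c(0, 0)), "zero")
  expect_error(relative_performance(numeric(0)), "at least one")
})
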