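linear_fixture <- function(n = 800, p = 6, seed = 5, noise = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- 3 * x[, 1] - 2 * x[, 2] + 0.5 * x[, 3] + rnorm(n, 0, noise)
    tibble::as_tibble(x) |> dplyr::mutate(y = y)
  })
}

test_that("recoverable planted signals reach high test R-squared", {
  dat <- linear_fixture()
  ms <- train_models(dat, "y", seed = 1)
  expect_gte(ms$gradient_boosted_trees$r2_test, 0.95)
  expect_gte(ms$random_forest$r2_test, 0.8)
  expect_lte(ms$gradient_boosted_trees$r2_test, 1)
})

test_that("permuted targets carry no predictable signal", {
  dat <- linear_fixture()
  dat$y <- withr::with_seed(99, sample(dat$y))
  ms <- train_models(dat, "y", families = "gradient_boosted_trees", seed = 1)
  expect_lte(ms$gradient_boosted_trees$r2_test, 0.1)
})

test_that("the split is 70/30 by rows, disjoint and exhaustive", {
  dat <- linear_fixture(n = 100)
  ms <- train_models(dat, "y", families = "gradient_boosted_trees", seed = 2)
  m <- ms$gradient_boosted_trees
  expect_equal(length(m$train_idx), 70)
  expect_equal(anyDuplicated(m$train_idx), 0)
  expect_setequal(c(m$train_idx, setdiff(seq_len(100), m$train_idx)), 1:100)
  expect_error(train_models(dat[1:10, ], "y"), "at least 20")
})

test_that("Shapley attribution ranks a single planted driver first", {
  withr::with_seed(3, {
    x <- matrix(rnorm(400 * 6), 400,
                dimnames = list(NULL, paste0("f", 1:6)))
    dat <- tibble::as_tibble(x) |> dplyr::mutate(y = 4 * f4)
  })
  ms <- train_models(dat, "y", seed = 4)
  for (m in ms) {
    rk <- shapley_rank(m)
    expect_equal(rk$feature[1], "f4")
  }
  # additivity: contributions plus baseline reconstruct predictions
  m <- ms$gradient_boosted_trees
  shap <- attr(shapley_rank(m), "shap")
  pred <- predict(m$booster, m$x)
  expect_lt(max(abs(rowSums(shap) - pred)) / max(abs(pred)), 1e-5)
})

test_that("a constant target yields zero attributions", {
  withr::with_seed(6, {
    dat <- tibble::as_tibble(matrix(rnorm(200 * 4), 200,
                                    dimnames = list(NULL, paste0("f", 1:4))))
    dat$y <- 5
  })
  ms <- train_models(dat, "y", families = "gradient_boosted_trees", seed = 1)
  rk <- shapley_rank(ms$gradient_boosted_trees)
  expect_true(all(rk$mean_abs_shap < 1e-8))
})

test_that("shapley_rank rejects non-tree models", {
  expect_error(shapley_rank(lm(y ~ f1, data = linear_fixture())), "unsupported")
})

test_that("feature selection rules behave as documented", {
  rk <- tibble::tibble(feature = c("a", "b", "c", "d"),
                       mean_abs_shap = c(5, 3, 1, 0.1), rank = 1:4)
  expect_equal(select_features(rk, list(type = "top_n", n = 1)), "a")
  expect_equal(select_features(rk, list(type = "cumulative", fraction = 1)),
               c("a", "b", "c", "d"))
  expect_equal(select_features(rk, list(type = "cumulative", fraction = 0.5)),
               "a")
  expect_identical(select_features(rk), select_features(rk))
  expect_error(select_features(rk, list(type = "nope")), "unknown")
})

test_that("driver matching maps surrogates through the correlation cluster", {
  withr::with_seed(31, {
    z <- rnorm(200); w <- rnorm(200)
    desc <- tibble::tibble(design_id = sprintf("D%03d", 1:200),
                           drv1 = z, drv1_proxy = z + rnorm(200, 0, 0.1),
                           drv2 = w, other = rnorm(200))
  })
  rk <- tibble::tibble(feature = c("drv1_proxy", "drv2", "other"),
                       mean_abs_shap = c(3, 2, 1), rank = 1:3)
  mm <- match_drivers(rk, desc, drivers = c("drv1", "drv2"), top_n = 3)
  expect_equal(mm$driver[1], "drv1")
  expect_equal(mm$driver[2], "drv2")
  expect_true(is.na(mm$driver[3]))
})

test_that("the top/bottom composite contrast has exact group sizes and calibrated nulls", {
  withr::with_seed(8, {
    n <- 120
    summ <- tibble::tibble(design_id = sprintf("D%03d", 1:n),
                           attach_mean = runif(n, 0.5, 5),
                           ratio = exp(rnorm(n, 0, 0.3)))
    summ$composite <- log(summ$ratio) * summ$attach_mean
    desc <- tibble::tibble(design_id = summ$design_id,
                           null1 = rnorm(n), null2 = rnorm(n),
                           shifted = rnorm(n) + 3 * (rank(summ$composite) > n / 2))
  })
  ct <- topk_contrast(summ, desc, k = 40)
  expect_equal(attr(ct, "k"), 40)
  expect_true(all(ct$p_adjusted >= ct$p_value - 1e-15))
  expect_lt(ct$p_adjusted[ct$descriptor == "shifted"], 0.05)
  expect_gt(min(ct$p_adjusted[ct$descriptor != "shifted"]), 0.05)
  # duplicated descriptor values across the two poles: identical group
  # multisets by construction, nothing can be significant
  withr::with_seed(12, {
    v <- rnorm(40)
    dup <- tibble::tibble(design_id = sprintf("E%03d", 1:80),
                          attach_mean = 1,
                          ratio = exp(c(runif(40, 0.5, 1), -runif(40, 0.5, 1))),
                          composite = log(ratio))
    desc_dup <- tibble::tibble(design_id = dup$design_id, v = c(v, v))
  })
  ct0 <- topk_contrast(dup, desc_dup, k = 40)
  expect_gt(min(ct0$p_adjusted), 0.5)
  expect_error(topk_contrast(summ[1:50, ], desc, k = 40), "at least")
})

test_that("tidy and glance follow broom conventions", {
  dat <- linear_fixture(n = 120)
  ms <- train_models(dat, "y", families = "gradient_boosted_trees", seed = 3)
  td <- tidy(ms$gradient_boosted_trees)
  expect_named(td, c("feature", "mean_abs_shap", "rank"))
  gl <- glance(ms$gradient_boosted_trees)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r2_train", "r2_test", "split_fraction") %in% names(gl)))
})
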