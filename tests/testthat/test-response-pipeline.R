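# a small hand-checkable screen: 2 donors x (1 design duplicated + 2 flats)
toy_screen <- function() {
  tibble::tribble(
    ~donor, ~chip, ~design_id, ~is_flat, ~cell_count, ~mean_m1, ~mean_m2,
    "d1", 1L, "FLAT", TRUE,  4, 10, 10,
    "d1", 1L, "FLAT", TRUE,  8, 10, 10,
    "d1", 1L, "D1",   FALSE, 18, 10, 20,
    "d1", 1L, "D1",   FALSE, 24, 10, 20,
    "d2", 1L, "FLAT", TRUE,  10, 20, 10,
    "d2", 1L, "FLAT", TRUE,  10, 20, 10,
    "d2", 1L, "D1",   FALSE, 40, 20, 10,
    "d2", 1L, "D1",   FALSE, 20, 20, 10)
}

test_that("normalization and aggregation match hand arithmetic", {
  s <- normalize_and_aggregate(toy_screen())
  d1 <- s[s$design_id == "D1", ]
  # donor d1: flat mean 6 -> replicates (3, 4) -> 3.5; donor d2: flat 10 ->
  # (4, 2) -> 3; cross-donor mean 3.25, sd = sd(c(3.5, 3))
  expect_equal(d1$attach_mean, mean(c(3.5, 3)))
  expect_equal(d1$attach_sd, sd(c(3.5, 3)))
  expect_equal(d1$attach_snr, mean(c(3.5, 3)) / sd(c(3.5, 3)))
  # markers: d1 ratio (20/10)/(10/10) = 2; d2 (10/20)/(10/20)... m1_n = 1,
  # m2_n = 1 -> ratio contributions (2, 1) on the normalized scale
  expect_equal(d1$ratio, mean(c(2, 1)) / mean(c(1, 1)))
  # flat units normalize to exactly 1 for every donor
  fl <- s[s$design_id == "FLAT", ]
  expect_equal(fl$attach_mean, 1)
  expect_equal(fl$attach_sd, 0)
  expect_equal(fl$attach_snr, Inf)
})

test_that("normalizing an already flat-normalized table is a no-op", {
  s <- toy_screen()
  n1 <- normalize_and_aggregate(s)
  # rebuild a screen whose raw values are the normalized ones
  norm_tbl <- s |>
    dplyr::group_by(donor, chip) |>
    dplyr::mutate(cell_count = cell_count / mean(cell_count[is_flat]),
                  mean_m1 = mean_m1 / mean(mean_m1[is_flat]),
                  mean_m2 = mean_m2 / mean(mean_m2[is_flat])) |>
    dplyr::ungroup()
  n2 <- normalize_and_aggregate(norm_tbl)
  expect_equal(n1$attach_mean, n2$attach_mean)
  expect_equal(n1$ratio, n2$ratio)
})

test_that("missing flats raise an error", {
  s <- toy_screen()[!toy_screen()$is_flat, ]
  expect_error(normalize_and_aggregate(s), "flat")
})

test_that("the SNR filter keeps designs at or above the threshold", {
  summ <- tibble::tibble(design_id = c("a", "b", "c"),
                         attach_mean = c(1, 1, 1),
                         attach_sd = c(1 / 1.9, 1 / 2.0, 1 / 2.1),
                         attach_snr = c(1.9, 2.0, 2.1),
                         m1_norm = 1, m2_norm = 1, ratio = 1, composite = 0)
  kept <- snr_filter(summ, threshold = 2)
  expect_equal(kept$design_id, c("b", "c"))
  expect_equal(nrow(snr_filter(summ, threshold = 0)), 3)
  flagged <- snr_filter(summ, threshold = 2, keep_all = TRUE)
  expect_equal(nrow(flagged), 3)                       # conservation
  expect_equal(sum(flagged$retained), 2)
  expect_true(all(nzchar(flagged$filter_reason)))
  # identical replicates across donors: infinite SNR, always retained
  summ$attach_snr[1] <- Inf
  expect_true("a" %in% snr_filter(summ, threshold = 2)$design_id)
})

test_that("the composite variable behaves like log-ratio times attachment", {
  s <- tibble::tibble(ratio = c(1, exp(1), 0.5), attach_mean = c(5, 10, 4))
  cv <- composite_variable(s)
  expect_equal(cv[1], 0)
  expect_equal(cv[2], 10)
  # swapping markers flips the sign at equal attachment
  s2 <- tibble::tibble(ratio = 1 / s$ratio, attach_mean = s$attach_mean)
  expect_equal(composite_variable(s2), -cv)
})

test_that("k-means attachment classes recover planted groups", {
  withr::with_seed(3, {
    x <- c(rnorm(30, 1, 0.05), rnorm(25, 5, 0.1), rnorm(20, 20, 0.4))
    truth <- rep(c("low", "medium", "high"), c(30, 25, 20))
    cl <- cluster_attachment(x, k = 3, seed = 1)
    expect_equal(ari(cl, truth), 1)
    # labels ordered by descending cluster mean
    expect_true(mean(x[cl == "high"]) > mean(x[cl == "medium"]))
    expect_true(mean(x[cl == "medium"]) > mean(x[cl == "low"]))
    expect_identical(cl, cluster_attachment(x, k = 3, seed = 1))
  })
  expect_equal(as.character(sort(cluster_attachment(c(1, 5, 9), k = 3, seed = 1))),
               c("high", "medium", "low"))
  expect_error(cluster_attachment(rep(1, 5), k = 3, seed = 1), "distinct")
})

test_that("hierarchical phenotype classes follow the cluster-mean ratio order", {
  withr::with_seed(9, {
    summ <- tibble::tibble(
      ratio = c(rnorm(30, 2.0, 0.05), rnorm(30, 1.2, 0.05), rnorm(30, 0.6, 0.05)),
      attach_mean = c(rnorm(30, 8, 0.3), rnorm(30, 3, 0.3), rnorm(30, 1, 0.1)))
    truth <- rep(c("M2_biased", "M0", "M1_biased"), each = 30)
    cl <- cluster_phenotype(summ)
    expect_gte(ari(cl, truth), 0.9)
    means <- tapply(summ$ratio, cl, mean)
    expect_true(means[["M2_biased"]] > means[["M0"]])
    expect_true(means[["M0"]] > means[["M1_biased"]])
  })
  degenerate <- tibble::tibble(ratio = rep(1, 10), attach_mean = rep(2, 10))
  expect_error(cluster_phenotype(degenerate), "degenerate")
})

test_that("rank consistency is 1 for duplicated donors and rank-invariant", {
  withr::with_seed(13, {
    base <- tibble::tibble(donor = "d1", chip = 1L,
                           design_id = sprintf("D%03d", 1:40), is_flat = FALSE,
                           cell_count = rpois(40, 20),
                           mean_m1 = 10, mean_m2 = 10)
    dup <- dplyr::mutate(base, donor = "d2")
    rc <- rank_and_consistency(dplyr::bind_rows(base, dup))
    expect_equal(rc$pairwise$rho, 1)
    expect_equal(rc$mean_correlation, 1)
    # a monotone transform of the counts preserves the rank correlation
    mono <- dplyr::mutate(base, donor = "d3", cell_count = cell_count^2 + 1)
    rc2 <- rank_and_consistency(dplyr::bind_rows(base, mono))
    expect_equal(rc2$mean_correlation, 1)
  })
})

test_that("independent donors decorrelate at large design counts", {
  withr::with_seed(17, {
    tabs <- purrr::map(1:4, function(d) {
      tibble::tibble(donor = paste0("d", d), chip = 1L,
                     design_id = sprintf("D%03d", 1:500), is_flat = FALSE,
                     cell_count = runif(500, 0, 100), mean_m1 = 1, mean_m2 = 1)
    })
    rc <- rank_and_consistency(dplyr::bind_rows(tabs))
    expect_lt(abs(rc$mean_correlation), 0.1)
  })
})
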