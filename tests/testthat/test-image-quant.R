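make_frame <- function(n_cells, seed = 1, ...) {
  simulate_unit_frame(n_cells, mean_m1 = 40, mean_m2 = 90, seed = seed, ...)
}

test_that("illumination correction preserves uniform frames and flattens gradients", {
  u <- matrix(50, 120, 120)
  fr <- topo_frame(u, u, u, u)
  cor_fr <- correct_illumination(fr)
  expect_lt(max(abs(cor_fr$channels$nuclei - u)) / 50, 0.001)

  # planted multiplicative gradient (0.5x .. 1.5x): the corrected background
  # should be nearly constant again
  g <- matrix(rep(seq(0.5, 1.5, length.out = 120), each = 120), 120, 120)
  fr2 <- topo_frame(50 * g, u, u, u)
  cor2 <- correct_illumination(fr2)$channels$nuclei
  inner <- cor2[20:100, 20:100]      # away from the smoothing boundary
  expect_lt(sd(inner) / mean(inner), 0.02)
})

test_that("the robust-background threshold equals the trimmed-moment formula", {
  v <- c(1, 2, 2, 3, 3, 3, 4, 4, 5, 100)   # fixed printed array
  thr <- topomacro:::robust_background_threshold(v, trim = 0.1, k = 2)
  q <- quantile(v, c(0.1, 0.9), names = FALSE)
  mid <- v[v >= q[1] & v <= q[2]]
  expect_equal(thr, mean(mid) + 2 * sd(mid))
})

test_that("planted nuclei are detected and pure noise yields none", {
  sim <- make_frame(12, seed = 31)
  fr <- correct_illumination(sim$frame, channels = c("nuclei", "membrane"))
  labs <- detect_nuclei(fr$channels$nuclei, scale = 1)
  expect_equal(max(labs), 12)

  withr::with_seed(4, {
    noise <- matrix(abs(rnorm(150 * 150, 10, 1)), 150, 150)
  })
  expect_equal(max(detect_nuclei(noise, scale = 1)), 0)
})

test_that("cell demarcation yields one disjoint region per seed with good overlap", {
  sim <- make_frame(10, seed = 17)
  fr <- correct_illumination(sim$frame, channels = c("nuclei", "membrane"))
  nl <- detect_nuclei(fr$channels$nuclei, scale = 1)
  cl <- segment_cells(fr$channels$membrane, nl)
  expect_equal(sort(unique(cl[cl > 0])), sort(unique(nl[nl > 0])))
  # regions partition the mask: labels are single-valued per pixel by
  # construction; check per-cell overlap against the planted masks
  truth <- sim$truth
  jacc <- vapply(sort(unique(cl[cl > 0])), function(id) {
    seg <- cl == id
    ids <- table(truth[seg & truth > 0])
    tid <- as.integer(names(ids)[which.max(ids)])
    tr <- truth == tid
    sum(seg & tr) / sum(seg | tr)
  }, numeric(1))
  expect_true(all(jacc >= 0.8))
})

test_that("edge cells are excluded and uniform marker means recovered exactly", {
  sim <- make_frame(8, seed = 23)
  cells <- quantify_frame(sim$frame, correct = FALSE)
  expect_equal(nrow(cells), 8)
  expect_false(any(cells$touches_edge))
  # marker channels are planted as exact uniform fills
  expect_true(all(abs(cells$mean_m1 - 40) / 40 < 0.05))
  expect_true(all(abs(cells$mean_m2 - 90) / 90 < 0.05))

  # a cell planted across the frame border must be flagged, interior ones not
  n <- 100
  ii <- row(matrix(0, n, n)); jj <- col(matrix(0, n, n))
  disk <- function(ci, cj, r) (ii - ci)^2 + (jj - cj)^2 <= r^2
  blob <- function(ci, cj) 200 * exp(-((ii - ci)^2 + (jj - cj)^2) / (2 * 2.5^2))
  mem <- matrix(5, n, n) + 60 * (disk(4, 50, 8) | disk(50, 50, 8))
  nuc <- matrix(10, n, n) + blob(4, 50) + blob(50, 50)
  mk <- matrix(0, n, n); mk[disk(4, 50, 8) | disk(50, 50, 8)] <- 70
  fr <- topo_frame(nuc, mem, mk, mk)
  cells2 <- quantify_frame(fr, correct = FALSE)
  expect_equal(nrow(cells2), 2)
  expect_equal(sort(cells2$touches_edge), c(FALSE, TRUE))
  expect_equal(sum(!cells2$touches_edge), 1)
})

test_that("counting is accurate across plating densities", {
  for (n in c(5, 40, 90)) {
    sim <- make_frame(n, seed = 100 + n)
    cells <- quantify_frame(sim$frame)
    got <- sum(!cells$touches_edge)
    expect_lte(abs(got - n) / n, 0.05)
  }
})

test_that("marker means are invariant to multiplicative channel rescaling", {
  sim <- make_frame(6, seed = 41)
  fr <- sim$frame
  fr2 <- fr
  fr2$channels$m1 <- fr$channels$m1 * 3
  c1 <- quantify_frame(fr, correct = FALSE)
  c2 <- quantify_frame(fr2, correct = FALSE)
  expect_equal(c2$mean_m1, 3 * c1$mean_m1, tolerance = 1e-12)
  expect_equal(c2$mean_m2, c1$mean_m2, tolerance = 1e-12)
})

test_that("the focus score separates sharp from blurred frames", {
  sim <- make_frame(10, seed = 51)
  sharp <- sim$frame$channels$nuclei
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(sharp), sigma = 6))
  expect_gt(focus_score(sharp), 3 * focus_score(blurred))
  fr_blur <- sim$frame
  fr_blur$channels$nuclei <- blurred
  expect_warning(
    cells <- quantify_frame(fr_blur, min_focus = focus_score(sharp) / 2),
    "focus")
  expect_equal(nrow(cells), 0)
})
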