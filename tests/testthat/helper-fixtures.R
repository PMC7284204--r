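# small deterministic fixtures shared across test files

tiny_library <- function(n = 12, seed = 42, ...) {
  generate_library(n, seed = seed, config = topo_config(...))
}

# one-row design with explicit primitives (positions in um)
manual_design <- function(primitives, block_size = 29, id = "DX") {
  tibble::tibble(design_id = id, block_size = block_size, height = 10,
                 is_flat = nrow(primitives) == 0, primitives = list(primitives))
}

circle_prim <- function(d, x, y) {
  tibble::tibble(shape = "circle", size_a = d, size_b = NA_real_,
                 x = x, y = y, rotation = 0)
}

rect_prim <- function(w, h, x, y, rot = 0) {
  tibble::tibble(shape = "rectangle", size_a = w, size_b = h,
                 x = x, y = y, rotation = rot)
}

flat_design <- function(block_size = 29) {
  manual_design(circle_prim(5, 10, 10)[0, ], block_size, id = "FLAT_D")
}

# brute-force oracle for the inscribed-circle sequence: the distance of every
# free pixel to the nearest obstacle (or virtual border ring) is computed by
# direct minimization over obstacle coordinates -- independent of the
# transform used by the implementation
oracle_circles <- function(free, stop_diameter) {
  nr <- nrow(free); nc <- ncol(free)
  out <- NULL
  obstacle <- free == 0
  ii <- row(free); jj <- col(free)
  # min squared distance of every "from" point to the point set, by direct
  # minimization (chunked |a - b|^2 = |a|^2 + |b|^2 - 2 a.b expansion)
  min_dsq <- function(from, pts) {
    best <- rep(Inf, nrow(from))
    f2 <- rowSums(from^2)
    step <- 1000
    for (s in seq(1, nrow(pts), by = step)) {
      blk <- pts[s:min(nrow(pts), s + step - 1), , drop = FALSE]
      d <- outer(f2, rowSums(blk^2), "+") - 2 * from %*% t(blk)
      for (j in seq_len(ncol(d))) best <- pmin(best, d[, j])
    }
    round(best)  # squared integer distances; kill float round-off
  }
  repeat {
    obs <- which(obstacle, arr.ind = TRUE)
    ring <- rbind(cbind(0, 0:(nc + 1)), cbind(nr + 1, 0:(nc + 1)),
                  cbind(1:nr, 0), cbind(1:nr, nc + 1))
    pts <- rbind(obs, ring)
    fr <- which(!obstacle, arr.ind = TRUE)
    if (nrow(fr) == 0) break
    dsq <- min_dsq(fr, pts)
    best <- max(dsq)
    diam <- 2 * sqrt(best)
    if (diam < stop_diameter) break
    cand <- fr[dsq == best, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    ctr <- cand[1, ]
    out <- rbind(out, c(ctr[1], ctr[2], diam))
    obstacle[(ii - ctr[1])^2 + (jj - ctr[2])^2 < best] <- TRUE
  }
  out
}

# independent reference for the inscribed-circle sequence built on
# EBImage::distmap (a different exact Euclidean distance-transform
# implementation) with the greedy loop re-written in R
reference_circles <- function(free, stop_diameter) {
  nr <- nrow(free); nc <- ncol(free)
  obstacle <- free == 0
  ii <- row(free); jj <- col(free)
  out <- NULL
  repeat {
    pad <- matrix(0, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- 1 - obstacle
    d <- as.matrix(EBImage::distmap(pad))[2:(nr + 1), 2:(nc + 1)]
    d[obstacle] <- 0
    best_sq <- round(max(d)^2)      # squared distances are integers
    diam <- 2 * sqrt(best_sq)
    if (best_sq == 0 || diam < stop_diameter) break
    cand <- which(round(d^2) == best_sq & !obstacle, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    ctr <- cand[1, ]
    out <- rbind(out, c(ctr[1], ctr[2], diam))
    obstacle[(ii - ctr[1])^2 + (jj - ctr[2])^2 < best_sq] <- TRUE
  }
  out
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}
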