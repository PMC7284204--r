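#' Per-feature shape descriptors of a binary design raster
#'
#' Each 8-connected foreground component is one pillar ("feature"). Area is
#' the pixel count, perimeter the length of the smoothed Moore contour
#' (circular moving average over `smooth_window` contour points; raw chain
#' codes systematically overestimate smooth boundaries), form factor
#' 4*pi*A/P^2, eccentricity from the central second moments, solidity the
#' ratio of area to convex-hull area, and the Feret diameters the extremes of
#' the hull's caliper widths. All measurements are converted to micrometers
#' via the raster's scale.
#'
#' @param raster binary matrix from [render_design()] or [tile_unit()].
#' @param scale pixels per micrometer; taken from the raster attribute when
#'   absent.
#' @param smooth_window contour smoothing window (odd, default 5).
#' @return tibble with one row per feature: `feature_id`, `area`,
#'   `perimeter`, `form_factor`, `eccentricity`, `solidity`, `min_feret`,
#'   `max_feret` (um / um^2).
#' @export
compute_feature_descriptors <- function(raster, scale = NULL, smooth_window = 5) {
  if (is.null(scale)) scale <- attr(raster, "scale")
  stopifnot(!is.null(scale), scale > 0)
  m <- matrix(as.integer(raster != 0), nrow(raster), ncol(raster))
  if (!any(m == 1L)) {
    return(tibble::tibble(feature_id = integer(), area = numeric(),
                          perimeter = numeric(), form_factor = numeric(),
                          eccentricity = numeric(), solidity = numeric(),
                          min_feret = numeric(), max_feret = numeric()))
  }
  lab <- label_components8(m)
  contours <- EBImage::ocontour(lab)
  n_feat <- max(lab)
  px <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  purrr::map_dfr(seq_len(n_feat), function(f) {
    pts <- px[labs == f, , drop = FALSE]
    a_px <- nrow(pts)
    per_px <- contour_length(contours[[f]], smooth_window)
    if (per_px < 4) per_px <- 4 * sqrt(a_px)  # sub-resolution speck guard
    area <- a_px / scale^2
    perimeter <- per_px / scale
    hull <- hull_points(pts)
    # hull area in pixel units with a Pick-style boundary correction (the
    # hull of pixel centers misses the outer half-pixel band)
    hull_area_px <- polygon_area(hull) + polygon_perimeter(hull) / 2 + 1
    tibble::tibble(
      feature_id = f,
      area = area,
      perimeter = perimeter,
      form_factor = 4 * pi * area / perimeter^2,
      eccentricity = moment_eccentricity(pts),
      solidity = min(1, a_px / max(hull_area_px, a_px)),
      min_feret = feret_min(hull) / scale,
      max_feret = feret_max(hull) / scale)
  })
}

# length of the closed contour after circular moving-average smoothing
contour_length <- function(xy, k = 5) {
  n <- nrow(xy)
  if (n < 3) return(0)
  if (n >= k + 2) {
    sm <- xy * 0
    h <- k %/% 2
    for (o in -h:h) {
      idx <- ((seq_len(n) - 1 + o) %% n) + 1
      sm <- sm + xy[idx, , drop = FALSE]
    }
    xy <- sm / k
  }
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - xy)^2)))
}

# eccentricity from central second moments of the pixel centers
moment_eccentricity <- function(pts) {
  if (nrow(pts) < 2) return(0)
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  # 1/12 term: second moment of a unit square pixel about its center
  mxx <- mean(x^2) + 1 / 12
  myy <- mean(y^2) + 1 / 12
  mxy <- mean(x * y)
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  if (l1 <= 0) return(0)
  sqrt(pmax(0, 1 - l2 / l1))
}

# convex hull of pixel centers, closed polygon (matrix of x=row, y=col)
hull_points <- function(pts) {
  if (nrow(pts) <= 2) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

polygon_perimeter <- function(hull) {
  n <- nrow(hull)
  if (n < 2) return(0)
  nxt <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - hull)^2)))
}

polygon_area <- function(hull) {
  n <- nrow(hull)
  if (n < 3) return(0)
  x <- hull[, 1]; y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

feret_max <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(1)
  d <- as.matrix(dist(hull))
  max(d) + 1  # +1 px: Feret calipers touch the outer pixel edges
}

feret_min <- function(hull) {
  n <- nrow(hull)
  if (n < 3) return(1)
  widths <- purrr::map_dbl(seq_len(n), function(i) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1 else i + 1, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) return(NA_real_)
    # distance of every hull point from the edge's supporting line
    max(abs((hull[, 1] - p1[1]) * e[2] - (hull[, 2] - p1[2]) * e[1]) / len)
  })
  min(widths, na.rm = TRUE) + 1
}

#' Maximum-inscribed-circle spacing of a unit raster
#'
#' Quantifies the open space between pillars. The binary raster is inverted
#' (background becomes the region of interest), downscaled by block averaging
#' (a downscaled pixel is foreground when at least half of its block is), and
#' then the largest circle that fits in the remaining free region is found
#' via an exact Euclidean distance transform, recorded, and its interior
#' removed; the loop stops when the next diameter falls below
#' `stop_diameter_px`. The frame border bounds the circles; recorded circles
#' never overlap (tangency allowed). Ties for the largest circle are broken
#' by the smallest (row, col) center.
#'
#' @param unit_raster binary matrix (tiled design; see [tile_unit()]).
#' @param stop_diameter_px stop threshold in working-image pixels (default 3).
#' @param downscale integer downscale factor applied before the search
#'   (default 5).
#' @param scale pixels per micrometer of `unit_raster` (attribute fallback);
#'   used to report diameters in micrometers.
#' @return tibble of class `topo_circles`: `row`, `col` (working-image pixel
#'   centers), `diameter_px` (working image), `diameter_um`; attributes
#'   `working_scale` (px/um after downscaling), `stop_diameter_px`, `working_dim`.
#' @export
max_inscribed_circles <- function(unit_raster, stop_diameter_px = 3,
                                  downscale = 5, scale = NULL) {
  if (is.null(scale)) scale <- attr(unit_raster, "scale")
  stopifnot(!is.null(scale), scale > 0, downscale >= 1)
  inv <- matrix(as.integer(unit_raster == 0), nrow(unit_raster), ncol(unit_raster))
  work <- downscale_binary(inv, downscale)
  res <- max_inscribed_circles_cpp(work, stop_diameter_px)
  wscale <- scale / downscale
  out <- tibble::tibble(row = as.integer(res[, "row"]),
                        col = as.integer(res[, "col"]),
                        diameter_px = res[, "diameter"],
                        diameter_um = res[, "diameter"] / wscale)
  attr(out, "working_scale") <- wscale
  attr(out, "stop_diameter_px") <- stop_diameter_px
  attr(out, "working_dim") <- dim(work)
  class(out) <- c("topo_circles", class(out))
  out
}

# block-mean downscale of a binary matrix; >= 0.5 -> foreground
downscale_binary <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- rep(seq_len(nr %/% f), each = f)
  ci <- rep(seq_len(nc %/% f), each = f)
  s <- rowsum(t(rowsum(m, ri)), ci)  # column sums within blocks, transposed
  matrix(as.integer(t(s) >= f * f / 2), nr %/% f, nc %/% f)
}
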