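#' Rasterize a design into a binary image
#'
#' Foreground pixels (value 1) are exactly those whose centers fall inside a
#' primitive; overlapping primitives are unioned. Pixels are indexed from the
#' top-left corner, x rightward (columns), y downward (rows); the center of
#' pixel (i, j) sits at ((j - 0.5)/scale, (i - 0.5)/scale) micrometers.
#'
#' @param design a one-row `topo_library` tibble (or a row subset of one).
#' @param scale pixels per micrometer (default 10, i.e. 10 px = 1 um).
#' @return integer matrix (0 background / 1 pillar) with attributes `scale`
#'   and `design_id`.
#' @export
render_design <- function(design, scale = 10) {
  stopifnot(scale > 0, nrow(design) == 1)
  n <- as.integer(round(design$block_size * scale))
  img <- matrix(0L, n, n)
  prim <- design$primitives[[1]]
  for (k in seq_len(nrow(prim))) {
    img <- rasterize_primitive(img, prim[k, ], scale)
  }
  attr(img, "scale") <- scale
  attr(img, "design_id") <- design$design_id
  img
}

# paint one primitive onto img (in place logically); bounding-box restricted
rasterize_primitive <- function(img, p, scale) {
  n_r <- nrow(img); n_c <- ncol(img)
  cr <- primitive_circumradius(p$shape, p$size_a, p$size_b)
  j0 <- max(1L, floor((p$x - cr) * scale)); j1 <- min(n_c, ceiling((p$x + cr) * scale) + 1L)
  i0 <- max(1L, floor((p$y - cr) * scale)); i1 <- min(n_r, ceiling((p$y + cr) * scale) + 1L)
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  px <- (jj - 0.5) / scale   # x coordinate of pixel centers (um)
  py <- (ii - 0.5) / scale   # y coordinate
  dx <- outer(rep(1, length(ii)), px - p$x)
  dy <- outer(py - p$y, rep(1, length(jj)))
  inside <- switch(
    p$shape,
    circle = (dx^2 + dy^2) <= (p$size_a / 2)^2,
    rectangle = {
      th <- p$rotation * pi / 180
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      (abs(u) <= p$size_a / 2) & (abs(v) <= p$size_b / 2)
    },
    triangle = {
      # equilateral triangle inscribed in the circumscribing circle
      R <- p$size_a / 2
      ang <- (p$rotation + c(90, 210, 330)) * pi / 180
      vx <- R * cos(ang); vy <- R * sin(ang)
      s1 <- (vx[2] - vx[1]) * (dy - vy[1]) - (vy[2] - vy[1]) * (dx - vx[1])
      s2 <- (vx[3] - vx[2]) * (dy - vy[2]) - (vy[3] - vy[2]) * (dx - vx[2])
      s3 <- (vx[1] - vx[3]) * (dy - vy[3]) - (vy[1] - vy[3]) * (dx - vx[3])
      (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
    },
    stop("unknown primitive shape: ", p$shape))
  sub <- img[ii, jj, drop = FALSE]
  sub[inside] <- 1L
  img[ii, jj] <- sub
  img
}

#' Tile a feature-block raster into a periodic unit raster
#'
#' The block raster is repeated periodically and cropped (never stretched) to
#' the requested unit size.
#'
#' @param design a one-row `topo_library` tibble.
#' @param unit_size_um unit edge length in micrometers (>= block size;
#'   standard patterned interior is 290 um).
#' @param scale pixels per micrometer.
#' @return integer matrix with attributes `scale` and `design_id`.
#' @export
tile_unit <- function(design, unit_size_um = 290, scale = 10) {
  stopifnot(unit_size_um >= design$block_size[1])
  block <- render_design(design, scale)
  n_unit <- as.integer(round(unit_size_um * scale))
  reps <- ceiling(n_unit / nrow(block))
  idx <- rep(seq_len(nrow(block)), reps)[seq_len(n_unit)]
  out <- block[idx, idx, drop = FALSE]
  attr(out, "scale") <- scale
  attr(out, "design_id") <- design$design_id
  out
}

#' Write / read a binary design raster as PNG
#'
#' Foreground is stored as 255, background as 0, one 8-bit channel.
#'
#' @param raster integer/logical matrix.
#' @param path file path (`<design_id>.png` by convention).
#' @param scale pixels per micrometer recorded on read.
#' @return `write_design_raster` returns `path` invisibly; `read_design_raster`
#'   an integer 0/1 matrix with a `scale` attribute.
#' @export
write_design_raster <- function(raster, path) {
  png::writePNG(matrix(as.numeric(raster != 0), nrow(raster), ncol(raster)), path)
  invisible(path)
}

#' @rdname write_design_raster
#' @export
read_design_raster <- function(path, scale = 10) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  attr(out, "scale") <- scale
  out
}
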