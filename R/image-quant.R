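#' Construct a multi-channel fluorescence frame
#'
#' @param nuclei,membrane,m1,m2 numeric intensity matrices of identical
#'   dimension (nuclei = DNA stain, membrane = plasma-membrane stain, m1 =
#'   pro-inflammatory marker such as calprotectin, m2 = anti-inflammatory
#'   marker such as mannose receptor).
#' @param scale pixels per micrometer.
#' @param unit_ref optional list identifying the source unit (chip, row, col).
#' @return list of class `topo_frame`.
#' @export
topo_frame <- function(nuclei, membrane, m1, m2, scale = 1, unit_ref = NULL) {
  chans <- list(nuclei = nuclei, membrane = membrane, m1 = m1, m2 = m2)
  dims <- unique(purrr::map(chans, dim))
  if (length(dims) != 1) stop("all channels must share the same dimensions")
  if (any(purrr::map_lgl(chans, function(ch) any(ch < 0)))) {
    stop("intensities must be non-negative")
  }
  structure(list(channels = chans, scale = scale, unit_ref = unit_ref),
            class = "topo_frame")
}

#' Correct slowly varying illumination
#'
#' Estimates a multiplicative background field per channel with a
#' large-kernel Gaussian smooth (sigma = image edge / 8 by default), divides
#' it out, and rescales so the channel mean is preserved.
#'
#' @param frame a `topo_frame`.
#' @param sigma smoothing sigma in pixels (default `nrow/8`).
#' @param eps floor applied to the normalized background estimate.
#' @param channels which channels to correct (default all; sparse marker
#'   channels are poor subjects for self-estimated flat fields).
#' @return the corrected `topo_frame`.
#' @export
correct_illumination <- function(frame, sigma = NULL, eps = 1e-3,
                                 channels = names(frame$channels)) {
  stopifnot(inherits(frame, "topo_frame"))
  frame$channels[channels] <- purrr::map(frame$channels[channels], function(ch) {
    if (all(ch == 0)) return(ch)
    s <- if (is.null(sigma)) nrow(ch) / 8 else sigma
    bg <- as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = s,
                                   radius = 2 * ceiling(s) + 1))
    b <- bg / mean(bg)
    if (any(b < eps)) {
      warning("background estimate near zero; flooring", call. = FALSE)
      b <- pmax(b, eps)
    }
    out <- ch / b
    out * (mean(ch) / mean(out))
  })
  frame
}

# robust-background global threshold: trim the brightest/dimmest fractions,
# then mean + k * sd of what remains
robust_background_threshold <- function(v, trim = 0.05, k = 2) {
  q <- quantile(v, c(trim, 1 - trim), names = FALSE)
  mid <- v[v >= q[1] & v <= q[2]]
  if (length(mid) < 2 || sd(mid) == 0) return(max(v) + 1e-9)
  mean(mid) + k * sd(mid)
}

#' Detect nuclei by robust-background thresholding
#'
#' Global threshold = trimmed mean + k * trimmed SD of the channel (the
#' brightest and dimmest `trim` fractions excluded), 8-connected components,
#' size-filtered.
#'
#' @param nuclei_channel intensity matrix (illumination-corrected).
#' @param scale pixels per micrometer.
#' @param trim trimmed fraction on each side (default 0.05).
#' @param k SD multiplier (default 2).
#' @param size_range_um2 nucleus area bounds in um^2 (default c(20, 400)).
#' @return integer label matrix (0 = background), relabeled consecutively.
#' @export
detect_nuclei <- function(nuclei_channel, scale = 1, trim = 0.05, k = 2,
                          size_range_um2 = c(20, 400)) {
  thr <- robust_background_threshold(as.numeric(nuclei_channel), trim, k)
  mask <- matrix(as.integer(nuclei_channel > thr), nrow(nuclei_channel),
                 ncol(nuclei_channel))
  lab <- label_components8(mask)
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab)) / scale^2
  keep <- which(sizes >= size_range_um2[1] & sizes <= size_range_um2[2])
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Demarcate cells around nuclear seeds
#'
#' Propagates each nuclear seed through the membrane channel (CellProfiler
#' style seeded propagation, the watershed-family method used for cell
#' demarcation in high-content screens), restricted to an above-background
#' mask. Every seed yields exactly one region; regions are disjoint.
#'
#' @param membrane_channel intensity matrix.
#' @param nuclei_labels label matrix from [detect_nuclei()].
#' @param bg_k MAD multiplier for the background mask threshold (default 3).
#'   The mask uses median + k * MAD, which stays anchored to the background
#'   even when cells cover a large fraction of the frame.
#' @param lambda regularization of the propagation metric (default 1e-4).
#' @return integer label matrix; labels match the seed labels.
#' @export
segment_cells <- function(membrane_channel, nuclei_labels, bg_k = 3,
                          lambda = 1e-4) {
  stopifnot(all(dim(membrane_channel) == dim(nuclei_labels)))
  if (max(nuclei_labels) == 0) return(matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels)))
  v <- as.numeric(membrane_channel)
  thr <- median(v) + bg_k * stats::mad(v)
  mask <- membrane_channel > thr
  orphan <- setdiff(unique(nuclei_labels[nuclei_labels > 0]),
                    unique(nuclei_labels[nuclei_labels > 0 & mask]))
  if (length(orphan) > 0) {
    warning("seed(s) outside the background mask; their cell equals the seed region",
            call. = FALSE)
  }
  mask <- mask | nuclei_labels > 0
  seg <- EBImage::propagate(EBImage::Image(membrane_channel),
                            seeds = nuclei_labels, mask = mask, lambda = lambda)
  seg <- matrix(as.integer(round(as.matrix(seg))),
                nrow(nuclei_labels), ncol(nuclei_labels))
  # keep, per cell, only the connected component containing its seed: stray
  # above-threshold noise islands must not count as cell area
  comp <- label_components8(matrix(as.integer(seg > 0), nrow(seg), ncol(seg)))
  seed_comp <- unique(comp[nuclei_labels > 0 & comp > 0])
  seg[!(comp %in% seed_comp)] <- 0L
  seg
}

#' Quantify cells and flag frame-edge contact
#'
#' Computes per-cell area and mean marker intensities; cells with any pixel
#' on the one-pixel frame border are flagged (`touches_edge`) and should be
#' excluded from attachment counts downstream.
#'
#' @param cell_labels label matrix from [segment_cells()].
#' @param frame the source `topo_frame`.
#' @param nuclei_labels optional nucleus label matrix for centroids.
#' @return tibble with `cell_id`, `nucleus_row`, `nucleus_col`, `cell_area`
#'   (um^2), `mean_m1`, `mean_m2`, `touches_edge`.
#' @export
filter_and_quantify <- function(cell_labels, frame, nuclei_labels = NULL) {
  stopifnot(inherits(frame, "topo_frame"))
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (length(ids) == 0) {
    return(tibble::tibble(cell_id = integer(), nucleus_row = numeric(),
                          nucleus_col = numeric(), cell_area = numeric(),
                          mean_m1 = numeric(), mean_m2 = numeric(),
                          touches_edge = logical()))
  }
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE
  m1 <- frame$channels$m1
  m2 <- frame$channels$m2
  cen_src <- if (is.null(nuclei_labels)) cell_labels else nuclei_labels
  purrr::map_dfr(ids, function(id) {
    px <- cell_labels == id
    cpx <- which(cen_src == id, arr.ind = TRUE)
    if (nrow(cpx) == 0) cpx <- which(px, arr.ind = TRUE)
    tibble::tibble(
      cell_id = as.integer(id),
      nucleus_row = mean(cpx[, 1]),
      nucleus_col = mean(cpx[, 2]),
      cell_area = sum(px) / frame$scale^2,
      mean_m1 = mean(m1[px]),
      mean_m2 = mean(m2[px]),
      touches_edge = any(px & border))
  })
}

#' Variance-of-Laplacian focus score
#'
#' A standard sharpness measure: the variance of the 4-neighbor Laplacian of
#' the (mean-normalized) channel. Out-of-focus frames score low.
#'
#' @param channel intensity matrix.
#' @return a single non-negative number.
#' @export
focus_score <- function(channel) {
  m <- channel / max(mean(channel), .Machine$double.eps)
  nr <- nrow(m); nc <- ncol(m)
  core <- m[2:(nr - 1), 2:(nc - 1)]
  lap <- m[1:(nr - 2), 2:(nc - 1)] + m[3:nr, 2:(nc - 1)] +
    m[2:(nr - 1), 1:(nc - 2)] + m[2:(nr - 1), 3:nc] - 4 * core
  stats::var(as.numeric(lap))
}

#' Count and phenotype cells in one frame
#'
#' Convenience wrapper: illumination correction, optional focus screening,
#' nucleus detection, cell demarcation, edge filtering and marker
#' quantification in one call.
#'
#' @param frame a `topo_frame`.
#' @param correct apply [correct_illumination()] first (default TRUE).
#' @param min_focus optional [focus_score()] threshold on the nuclei channel;
#'   frames scoring below it are rejected (empty result, with a warning).
#'   `NULL` (default) disables focus screening.
#' @param ... passed to [detect_nuclei()].
#' @return tibble as [filter_and_quantify()], all cells flagged; attachment
#'   count = `sum(!touches_edge)`.
#' @export
quantify_frame <- function(frame, correct = TRUE, min_focus = NULL, ...) {
  if (!is.null(min_focus) && focus_score(frame$channels$nuclei) < min_focus) {
    warning("frame rejected: focus score below threshold", call. = FALSE)
    return(filter_and_quantify(matrix(0L, 1, 1),
                               topo_frame(matrix(0, 1, 1), matrix(0, 1, 1),
                                          matrix(0, 1, 1), matrix(0, 1, 1))))
  }
  if (correct) frame <- correct_illumination(frame,
                                             channels = c("nuclei", "membrane"))
  nl <- detect_nuclei(frame$channels$nuclei, scale = frame$scale, ...)
  cl <- segment_cells(frame$channels$membrane, nl)
  filter_and_quantify(cl, frame, nl)
}
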