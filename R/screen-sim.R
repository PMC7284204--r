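#' Parameters of the planted structure-function response model
#'
#' The generator plants the screen's reported regime: flat surfaces attach a
#' baseline of ~6 cells per unit; attachment is unimodal in the effective
#' pillar diameter with a peak near 5 um and a smooth cutoff above 10 um,
#' scaled by pillar density; the expected M2/M1 marker ratio decreases with
#' the smallest pillar area and increases with pillar density, spanning
#' roughly 0.41-2.13 with flat surfaces at 1.2.
#'
#' @param peak_diameter attachment-optimal effective pillar diameter (um).
#' @param cutoff_diameter diameter above which attachment is suppressed (um).
#' @param attach_width Gaussian width of the attachment bump (um).
#' @param cutoff_width logistic width of the suppression (um).
#' @param spacing_half inscribed-circle spacing (um, largest circle) at the
#'   midpoint of the density modulation; denser patterns (smaller spacing)
#'   attach more.
#' @param spacing_width logistic width of the density modulation (um).
#' @param density_floor lower bound of the density modulation factor.
#' @param flat_baseline expected cells/unit on flat controls.
#' @param max_attachment asymptotic expected cells/unit at the optimum.
#' @param flat_ratio expected M2/M1 ratio of flat controls.
#' @param ratio_lo,ratio_hi clip bounds of the expected ratio.
#' @param area_coef,spacing_coef phenotype coefficients: the expected ratio
#'   falls with `log(Pattern_Area_min + area_offset)` and with the log
#'   spacing (so it rises with pillar density).
#' @param area_offset damping offset (um^2) on the minimum pattern area.
#' @param area_ref,spacing_ref centering constants (um^2, um): a design at
#'   both references has the flat ratio.
#' @param donor_sd,replicate_sd lognormal SDs of the donor and replicate
#'   attachment effects.
#' @param marker_donor_sd,marker_sd lognormal SDs of per-donor-channel and
#'   per-unit marker noise.
#' @param count_dispersion negative-binomial size of the attachment counts
#'   (`Inf` = deterministic rounding).
#' @param marker_base base marker intensity (arbitrary units).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(peak_diameter = 5, cutoff_diameter = 10,
                          attach_width = 3, cutoff_width = 1,
                          spacing_half = 26, spacing_width = 5,
                          density_floor = 0.6,
                          flat_baseline = 6, max_attachment = 240,
                          flat_ratio = 1.2, ratio_lo = 0.41, ratio_hi = 2.13,
                          area_coef = 1.4, spacing_coef = 1.4,
                          area_offset = 80, area_ref = 180, spacing_ref = 22,
                          donor_sd = 0.25, replicate_sd = 0.10,
                          marker_donor_sd = 0.20, marker_sd = 0.10,
                          count_dispersion = 10, marker_base = 100) {
  stopifnot(ratio_lo < 1, 1 < ratio_hi, cutoff_diameter >= peak_diameter,
            donor_sd >= 0, replicate_sd >= 0, marker_sd >= 0,
            marker_donor_sd >= 0)
  structure(as.list(environment()), class = "screen_params")
}

effective_diameter <- function(area_mean) sqrt(4 * area_mean / pi)

#' Planted expected attachment per unit
#'
#' Unimodal in the effective pillar diameter `sqrt(4 * Pattern_Area_mean /
#' pi)` (Gaussian bump at `peak_diameter`, logistic suppression above
#' `cutoff_diameter`), modulated by pillar density measured through the
#' inscribed-circle spacing (denser patterns attach more). Flat designs
#' return the flat baseline.
#'
#' @param descriptors `topo_descriptors` tibble (needs `Pattern_Area_mean`,
#'   `Inscribed_Circle_Diameter_max` and `Pillar_Count`).
#' @param params a [screen_params()].
#' @return numeric vector of expected cells/unit.
#' @export
attachment_response <- function(descriptors, params = screen_params()) {
  d <- effective_diameter(descriptors$Pattern_Area_mean)
  spacing <- descriptors$Inscribed_Circle_Diameter_max
  g <- exp(-(d - params$peak_diameter)^2 / (2 * params$attach_width^2)) *
    stats::plogis((params$cutoff_diameter - d) / params$cutoff_width)
  h <- params$density_floor + (1 - params$density_floor) *
    stats::plogis((params$spacing_half - spacing) / params$spacing_width)
  mu <- params$flat_baseline +
    (params$max_attachment - params$flat_baseline) * g * h
  mu[descriptors$Pillar_Count == 0] <- params$flat_baseline
  mu
}

#' Planted expected M2/M1 ratio per unit
#'
#' Decreasing in the smallest pattern area and increasing in pillar density
#' (i.e. decreasing in the inscribed-circle spacing), clipped to
#' `[ratio_lo, ratio_hi]`; flat designs return `flat_ratio`.
#'
#' @inheritParams attachment_response
#' @return numeric vector of expected (unnormalized) M2/M1 ratios.
#' @export
phenotype_response <- function(descriptors, params = screen_params()) {
  a_min <- pmax(descriptors$Pattern_Area_min, 0)
  spacing <- pmax(descriptors$Inscribed_Circle_Diameter_max, 1e-6)
  r <- params$flat_ratio -
    params$area_coef * (log(a_min + params$area_offset) -
                          log(params$area_ref + params$area_offset)) -
    params$spacing_coef * (log(spacing) - log(params$spacing_ref))
  r <- pmin(params$ratio_hi, pmax(params$ratio_lo, r))
  r[descriptors$Pillar_Count == 0] <- params$flat_ratio
  r
}

#' Simulate a multi-donor TopoChip screen
#'
#' For each donor: a multiplicative lognormal donor effect on attachment and
#' on each marker channel; per unit slot a lognormal replicate effect;
#' attachment counts negative-binomial around the scaled expectation; marker
#' means lognormal around the phenotype expectation decomposed into M1 and
#' M2 components (`m1 = base / sqrt(ratio)`, `m2 = base * sqrt(ratio)`).
#' Fully reproducible from `seed`.
#'
#' @param layout a `topo_layout`.
#' @param descriptors a `topo_descriptors` matrix covering the layout's
#'   designs (flat units take the flat response by definition).
#' @param params a [screen_params()].
#' @param n_donors number of donors (default 5).
#' @param seed integer seed.
#' @return tibble of class `topo_screen`: `donor`, `chip`, `row`, `col`,
#'   `design_id`, `is_flat`, `cell_count`, `mean_m1`, `mean_m2`.
#' @export
simulate_screen <- function(layout, descriptors, params = screen_params(),
                            n_donors = 5, seed = 1) {
  ids <- setdiff(unique(layout$design_id), "FLAT")
  if (!all(ids %in% descriptors$design_id)) {
    stop("descriptor matrix does not cover every design in the layout")
  }
  desc <- descriptors[match(ids, descriptors$design_id), ]
  mu_attach <- setNames(attachment_response(desc, params), ids)
  ratio <- setNames(phenotype_response(desc, params), ids)
  mu_attach <- c(mu_attach, FLAT = params$flat_baseline)
  ratio <- c(ratio, FLAT = params$flat_ratio)
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(seq_len(n_donors), function(don) {
      d_att <- rlnorm(1, 0, params$donor_sd)
      d_m1 <- rlnorm(1, 0, params$marker_donor_sd)
      d_m2 <- rlnorm(1, 0, params$marker_donor_sd)
      n_slot <- nrow(layout)
      rep_eff <- if (params$replicate_sd > 0) {
        rlnorm(n_slot, 0, params$replicate_sd)
      } else rep(1, n_slot)
      mu <- mu_attach[layout$design_id] * d_att * rep_eff
      counts <- if (is.finite(params$count_dispersion)) {
        rnbinom(n_slot, mu = mu, size = params$count_dispersion)
      } else round(mu)
      r <- ratio[layout$design_id]
      noise1 <- if (params$marker_sd > 0) rlnorm(n_slot, 0, params$marker_sd) else 1
      noise2 <- if (params$marker_sd > 0) rlnorm(n_slot, 0, params$marker_sd) else 1
      tibble::tibble(donor = sprintf("donor%02d", don), chip = 1L,
                     row = layout$row, col = layout$col,
                     design_id = layout$design_id, is_flat = layout$is_flat,
                     cell_count = unname(as.numeric(counts)),
                     mean_m1 = unname(params$marker_base / sqrt(r) * d_m1 * noise1),
                     mean_m2 = unname(params$marker_base * sqrt(r) * d_m2 * noise2))
    })
    scr <- dplyr::bind_rows(rows)
    class(scr) <- c("topo_screen", class(scr))
    scr
  })
}

#' Simulate one fluorescence frame with ground truth
#'
#' Plants `cell_count` non-overlapping cells: a Gaussian nuclear blob, a
#' filled membrane disk with a brighter rim, and uniform marker fills equal
#' to `mean_m1` / `mean_m2` inside the cell footprint. Gaussian noise is
#' added to the nuclei and membrane channels (marker channels stay exact so
#' planted means are recoverable); an optional multiplicative illumination
#' gradient can be planted.
#'
#' @param cell_count number of cells to plant.
#' @param mean_m1,mean_m2 planted marker intensities.
#' @param field_um field of view edge (default 280 um).
#' @param scale pixels per micrometer (default 1).
#' @param cell_radius_um cell disk radius (default 8 um).
#' @param noise_sd Gaussian noise SD on nuclei/membrane channels.
#' @param gradient if `TRUE`, multiply all channels by a planted linear
#'   illumination gradient (0.5x to 1.5x, left to right).
#' @param margin_um keep-out border so planted cells never touch the frame
#'   edge; set to 0 to allow edge cells.
#' @param seed integer seed.
#' @return list with `frame` (a [topo_frame()]) and `truth` (label matrix of
#'   planted cell masks).
#' @export
simulate_unit_frame <- function(cell_count, mean_m1 = 100, mean_m2 = 100,
                                field_um = 280, scale = 1, cell_radius_um = 8,
                                noise_sd = 4, gradient = FALSE,
                                margin_um = 2, seed = 1) {
  n <- as.integer(round(field_um * scale))
  r <- cell_radius_um * scale
  withr::with_seed(as.integer(seed), {
    centers <- matrix(numeric(0), 0, 2)
    lim <- c(1 + r + margin_um * scale, n - r - margin_um * scale)
    if (lim[2] <= lim[1] && cell_count > 0) stop("field too small for the cell radius")
    # feasibility: hard disks of separation s in a span^2 box (loose bound)
    span <- lim[2] - lim[1]
    s_min <- 2 * r + 2
    if (cell_count > 0.7 * (span / s_min + 1)^2) {
      stop("requested cell count exceeds packable density", call. = FALSE)
    }
    attempts <- 0
    while (nrow(centers) < cell_count) {
      cand <- runif(2, lim[1], lim[2])
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))) > s_min) {
        centers <- rbind(centers, cand)
      }
      attempts <- attempts + 1
      if (attempts > 2000 * max(1, cell_count)) {
        stop("requested cell count exceeds packable density", call. = FALSE)
      }
    }
    ii <- row(matrix(0, n, n)); jj <- col(matrix(0, n, n))
    nuc <- matrix(10, n, n); mem <- matrix(5, n, n)
    m1 <- matrix(0, n, n); m2 <- matrix(0, n, n)
    truth <- matrix(0L, n, n)
    for (k in seq_len(nrow(centers))) {
      d2 <- (ii - centers[k, 1])^2 + (jj - centers[k, 2])^2
      disk <- d2 <= r^2
      truth[disk] <- k
      nuc <- nuc + 200 * exp(-d2 / (2 * (0.35 * r)^2))
      mem[disk] <- mem[disk] + 60
      rim <- d2 <= r^2 & d2 >= (0.8 * r)^2
      mem[rim] <- mem[rim] + 40
      m1[disk] <- mean_m1
      m2[disk] <- mean_m2
    }
    if (noise_sd > 0) {
      nuc <- pmax(nuc + matrix(rnorm(n * n, 0, noise_sd), n, n), 0)
      mem <- pmax(mem + matrix(rnorm(n * n, 0, noise_sd), n, n), 0)
    }
    if (gradient) {
      g <- matrix(rep(seq(0.5, 1.5, length.out = n), each = n), n, n)
      nuc <- nuc * g; mem <- mem * g
    }
    list(frame = topo_frame(nuc, mem, m1, m2, scale = scale),
         truth = truth)
  })
}
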