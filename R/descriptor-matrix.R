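shape_fields <- c(area = "Pattern_Area", perimeter = "Perimeter",
                  form_factor = "Form_Factor", eccentricity = "Eccentricity",
                  solidity = "Solidity", min_feret = "Min_Feret",
                  max_feret = "Max_Feret")

#' Summarize one design into a named descriptor vector
#'
#' Aggregates the per-feature shape records (mean, median, min, max and the
#' configured quantiles), the design construction parameters, pillar count
#' and coverage, and the inscribed-circle spacing summaries into one named
#' row. Flat designs get zeros for all pattern descriptors and the
#' frame-limited (maximal) spacing descriptors.
#'
#' @param design one-row `topo_library` tibble.
#' @param shape_records output of [compute_feature_descriptors()] for the
#'   design's block raster.
#' @param circle_set output of [max_inscribed_circles()] for the design's
#'   tiled raster.
#' @param quantiles quantile probabilities summarized per shape field
#'   (default 25th and 75th percentiles).
#' @return one-row tibble: `design_id` plus named descriptors.
#' @export
summarize_design <- function(design, shape_records, circle_set,
                             quantiles = c(0.25, 0.75)) {
  stats_of <- function(v) {
    if (length(v) == 0) v <- 0
    qs <- quantile(v, quantiles, names = FALSE)
    c(mean = mean(v), median = median(v), min = min(v), max = max(v),
      setNames(qs, paste0("q", round(100 * quantiles))))
  }
  out <- list(design_id = design$design_id)
  for (f in names(shape_fields)) {
    s <- stats_of(shape_records[[f]])
    names(s) <- paste(shape_fields[[f]], names(s), sep = "_")
    out <- c(out, as.list(s))
  }
  prim <- design$primitives[[1]]
  block_area <- design$block_size^2
  out$Pillar_Count <- nrow(shape_records)
  out$Pillar_Density <- nrow(shape_records) / block_area * 1000  # per 1000 um^2
  out$Pattern_Coverage <- sum(shape_records$area) / block_area
  out$Primitive_Count <- nrow(prim)
  sizes <- if (nrow(prim) > 0) prim$size_a else 0
  out$Primitive_Size_mean <- mean(sizes)
  out$Primitive_Size_min <- min(sizes)
  out$Primitive_Size_max <- max(sizes)
  for (sh in c("circle", "triangle", "rectangle")) {
    out[[paste0("Fraction_", tools::toTitleCase(sh))]] <-
      if (nrow(prim) > 0) mean(prim$shape == sh) else 0
  }
  d_um <- circle_set$diameter_um
  cs <- stats_of(d_um)
  names(cs) <- paste0("Inscribed_Circle_Diameter_", names(cs))
  out <- c(out, as.list(cs))
  out$Inscribed_Circle_Count <- nrow(circle_set)
  wdim <- attr(circle_set, "working_dim")
  wa <- if (is.null(wdim)) NA_real_ else prod(wdim) / attr(circle_set, "working_scale")^2
  out$Inscribed_Circle_Area_Fraction <-
    if (is.na(wa) || wa == 0) 0 else sum(pi * (d_um / 2)^2) / wa
  tibble::as_tibble(out)
}

#' Compute the descriptor matrix for a design library
#'
#' Renders every design, extracts per-feature shape descriptors from the
#' block raster and inscribed-circle spacing descriptors from a periodic
#' tiling, and summarizes them into one row per design. The spacing window is
#' `spacing_tiles` x `spacing_tiles` feature blocks: the pattern is periodic,
#' so a small window carries the same spacing structure as the full unit at a
#' fraction of the cost (window size is configurable).
#'
#' @param library a `topo_library`.
#' @param scale raster scale in px/um (default 10).
#' @param spacing_tiles number of block repeats per side for the spacing
#'   raster (default 2).
#' @param downscale,stop_diameter_px see [max_inscribed_circles()].
#' @param quantiles see [summarize_design()].
#' @return tibble of class `topo_descriptors`, one row per design, first
#'   column `design_id`; attribute `manifest` is a tibble naming each
#'   descriptor, its unit and its definition.
#' @export
compute_descriptor_matrix <- function(library, scale = 10, spacing_tiles = 2,
                                      downscale = 5, stop_diameter_px = 3,
                                      quantiles = c(0.25, 0.75)) {
  rows <- purrr::map(seq_len(nrow(library)), function(i) {
    design <- library[i, ]
    block <- render_design(design, scale)
    shp <- compute_feature_descriptors(block, scale)
    unit <- tile_unit(design, design$block_size * spacing_tiles, scale)
    circ <- max_inscribed_circles(unit, stop_diameter_px, downscale, scale)
    summarize_design(design, shp, circ, quantiles)
  })
  mat <- dplyr::bind_rows(rows)
  attr(mat, "manifest") <- descriptor_manifest(names(mat)[-1])
  class(mat) <- c("topo_descriptors", class(mat))
  mat
}

descriptor_manifest <- function(descriptors) {
  unit_of <- function(n) {
    if (grepl("^Pattern_Area|Area_Fraction|Coverage", n)) return("um^2 or fraction")
    if (grepl("Perimeter|Feret|Diameter|Size", n)) return("um")
    if (grepl("Density", n)) return("1 / 1000 um^2")
    "dimensionless"
  }
  tibble::tibble(
    descriptor = descriptors,
    unit = vapply(descriptors, unit_of, character(1)),
    definition = dplyr::case_when(
      grepl("^Pattern_Area", descriptors) ~ "summary of per-pillar top areas",
      grepl("^Perimeter", descriptors) ~ "summary of per-pillar smoothed contour lengths",
      grepl("^Form_Factor", descriptors) ~ "summary of per-pillar 4*pi*A/P^2",
      grepl("^Eccentricity", descriptors) ~ "summary of per-pillar moment eccentricities",
      grepl("^Solidity", descriptors) ~ "summary of per-pillar area / convex hull area",
      grepl("^Min_Feret|^Max_Feret", descriptors) ~ "summary of per-pillar caliper widths",
      grepl("^Inscribed_Circle_Diameter", descriptors) ~ "summary of inscribed-circle diameters (spacing)",
      descriptors == "Inscribed_Circle_Count" ~ "number of inscribed circles in the spacing window",
      descriptors == "Inscribed_Circle_Area_Fraction" ~ "fraction of the spacing window covered by circles",
      descriptors == "Pillar_Count" ~ "8-connected foreground components per block",
      descriptors == "Pillar_Density" ~ "pillars per 1000 um^2",
      descriptors == "Pattern_Coverage" ~ "foreground fraction of the block",
      grepl("^Primitive_", descriptors) ~ "design construction parameter",
      grepl("^Fraction_", descriptors) ~ "fraction of primitives of this shape",
      TRUE ~ "descriptor"))
}

#' Prune collinear descriptors by pairwise Pearson correlation
#'
#' Greedy removal: while any retained pair has |r| at or above the threshold,
#' drop from the worst pair the descriptor with the larger mean absolute
#' correlation to all other retained descriptors (ties broken by keeping the
#' earlier column in manifest order). Constant columns are removed first
#' (their correlation is undefined).
#'
#' @param matrix a `topo_descriptors` tibble (or any numeric data frame; a
#'   `design_id` column is ignored).
#' @param threshold pairwise |Pearson r| threshold in (0, 1] (default 0.85).
#' @return character vector of retained descriptor names, with attributes
#'   `dropped` (named character vector of reasons) in drop order.
#' @export
prune_by_correlation <- function(matrix, threshold = 0.85) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold <= 1)) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  num <- dplyr::select(tibble::as_tibble(matrix), dplyr::where(is.numeric))
  if (nrow(num) < 2) stop("need at least two designs to estimate correlations")
  dropped <- character()
  const <- names(num)[vapply(num, function(v) sd(v) == 0 || !all(is.finite(v)),
                             logical(1))]
  for (nm in const) dropped[nm] <- "constant or non-finite column"
  keep <- setdiff(names(num), const)
  cm <- abs(cor(num[keep]))
  diag(cm) <- 0
  while (length(keep) > 1 && max(cm) >= threshold) {
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    i <- worst[1]; j <- worst[2]
    mi <- mean(cm[i, ]); mj <- mean(cm[j, ])
    # drop the member with the larger mean |r|; on a tie keep the earlier
    # (manifest-order) column
    drop_idx <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    dropped[keep[drop_idx]] <-
      sprintf("|r| = %.3f with %s", max(cm), keep[if (drop_idx == i) j else i])
    keep <- keep[-drop_idx]
    cm <- cm[-drop_idx, -drop_idx, drop = FALSE]
  }
  structure(keep, dropped = dropped)
}
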