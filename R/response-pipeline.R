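#' Flat-normalize, average replicates and aggregate across donors
#'
#' Per donor and chip, cell counts and marker means are divided by that
#' donor/chip's mean over flat control units; duplicate units (and chips) are
#' then averaged per design within donor; finally mean, SD and SNR
#' (mean / SD) are computed across donors, along with the flat-normalized
#' marker ratio and the composite variable `log(ratio) * attachment`.
#'
#' @param screen_table a `topo_screen` tibble (columns `donor`, `chip`,
#'   `design_id`, `is_flat`, `cell_count`, `mean_m1`, `mean_m2`).
#' @param marker_floor_q marker means are floored at this quantile of the
#'   positive values before ratios are formed (guards log of zero;
#'   default 0.01).
#' @return tibble of class `topo_summary`: `design_id`, `attach_mean`,
#'   `attach_sd`, `attach_snr`, `m1_norm`, `m2_norm`, `ratio`, `composite`,
#'   `n_donors`.
#' @export
normalize_and_aggregate <- function(screen_table, marker_floor_q = 0.01) {
  stopifnot(all(c("donor", "design_id", "is_flat", "cell_count",
                  "mean_m1", "mean_m2") %in% names(screen_table)))
  if (!"chip" %in% names(screen_table)) screen_table$chip <- 1L
  if (!any(screen_table$is_flat)) stop("screen table contains no flat control units")
  floor_pos <- function(v) {
    pos <- v[v > 0]
    if (length(pos) == 0) stop("all marker means are non-positive")
    pmax(v, quantile(pos, marker_floor_q, names = FALSE))
  }
  screen_table$mean_m1 <- floor_pos(screen_table$mean_m1)
  screen_table$mean_m2 <- floor_pos(screen_table$mean_m2)
  normed <- screen_table |>
    dplyr::group_by(.data$donor, .data$chip) |>
    dplyr::group_modify(function(df, key) {
      fl <- df[df$is_flat, ]
      if (nrow(fl) == 0) stop("a donor/chip is missing flat control units")
      f_count <- mean(fl$cell_count)
      if (f_count == 0) {
        warning("flat attachment mean is zero for a donor/chip; excluding it",
                call. = FALSE)
        return(df[0, ])
      }
      df$count_n <- df$cell_count / f_count
      df$m1_n <- df$mean_m1 / mean(fl$mean_m1)
      df$m2_n <- df$mean_m2 / mean(fl$mean_m2)
      df
    }) |>
    dplyr::ungroup()
  per_donor <- normed |>
    dplyr::group_by(.data$donor, .data$design_id) |>
    dplyr::summarise(count_n = mean(.data$count_n), m1_n = mean(.data$m1_n),
                     m2_n = mean(.data$m2_n), .groups = "drop")
  out <- per_donor |>
    dplyr::group_by(.data$design_id) |>
    dplyr::summarise(
      attach_mean = mean(.data$count_n),
      attach_sd = sd(.data$count_n),
      attach_snr = ifelse(sd(.data$count_n) > 0,
                          mean(.data$count_n) / sd(.data$count_n), Inf),
      m1_norm = mean(.data$m1_n),
      m2_norm = mean(.data$m2_n),
      n_donors = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(ratio = .data$m2_norm / .data$m1_norm,
                  composite = log(.data$ratio) * .data$attach_mean)
  class(out) <- c("topo_summary", class(out))
  out
}

#' Exclude designs with a low signal-to-noise ratio
#'
#' A design is retained when its cross-donor SNR (mean / SD of the
#' flat-normalized attachment) is at or above the threshold. An optional
#' low-attachment override retains bottom-decile attachment designs whose SD
#' is small in absolute terms (off by default).
#'
#' @param summaries a `topo_summary`.
#' @param threshold SNR threshold (default 2).
#' @param keep_all return all rows flagged instead of the retained subset.
#' @param low_attach_override retain lowest-decile attachment designs when
#'   `attach_sd < 0.5 * sd_ref` (default off).
#' @param sd_ref reference SD for the override (default the median
#'   `attach_sd`).
#' @return retained `topo_summary` rows (or all rows with `retained` and
#'   `filter_reason` columns when `keep_all = TRUE`).
#' @export
snr_filter <- function(summaries, threshold = 2, keep_all = FALSE,
                       low_attach_override = FALSE, sd_ref = NULL) {
  retained <- summaries$attach_snr >= threshold
  reason <- ifelse(retained, "snr_ok",
                   sprintf("snr %.3f < %.3f", summaries$attach_snr, threshold))
  if (low_attach_override && any(!retained)) {
    dec <- quantile(summaries$attach_mean, 0.1, names = FALSE)
    if (is.null(sd_ref)) sd_ref <- median(summaries$attach_sd)
    ov <- !retained & summaries$attach_mean <= dec &
      summaries$attach_sd < 0.5 * sd_ref
    reason[ov] <- "low-attachment override (small absolute SD)"
    retained <- retained | ov
  }
  out <- summaries
  out$retained <- retained
  out$filter_reason <- reason
  if (keep_all) out else dplyr::filter(out, .data$retained)
}

#' Composite attachment-polarization variable
#'
#' Natural log of the flat-normalized M2/M1 ratio times the mean attachment:
#' zero when the markers balance, large positive for abundant M2-biased
#' responses, large negative for abundant M1-biased ones.
#'
#' @param summary a `topo_summary` (or any tibble with `ratio` and
#'   `attach_mean`).
#' @return numeric vector.
#' @export
composite_variable <- function(summary) {
  stopifnot(all(summary$ratio > 0))
  log(summary$ratio) * summary$attach_mean
}

#' Cluster attachment into high / medium / low classes
#'
#' k-means (Euclidean, k-means++-style multi-start via `nstart`) on the mean
#' attachment, clusters relabeled by descending cluster mean.
#'
#' @param attach_means numeric vector.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param nstart random restarts (default 10).
#' @return factor with levels `high`, `medium`, `low` (descending attachment;
#'   for k != 3, `class1` ... `classk`).
#' @export
cluster_attachment <- function(attach_means, k = 3, seed = 1, nstart = 10) {
  ux <- unique(attach_means)
  if (length(ux) < k) {
    stop("fewer distinct attachment values than clusters", call. = FALSE)
  }
  km <- if (length(ux) == k) {
    # every distinct value is its own cluster
    list(cluster = match(attach_means, ux), centers = matrix(ux))
  } else {
    withr::with_seed(as.integer(seed),
                     kmeans(matrix(attach_means), centers = k, nstart = nstart))
  }
  ord <- order(km$centers, decreasing = TRUE)
  lev <- if (k == 3) c("high", "medium", "low") else paste0("class", seq_len(k))
  factor(lev[match(km$cluster, ord)], levels = lev)
}

#' Cluster phenotype into M2-biased / M0 / M1-biased classes
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) on the
#' standardized (ratio, attachment) plane; the three clusters are labeled by
#' descending cluster-mean ratio.
#'
#' @param summaries a `topo_summary`.
#' @param k number of clusters (default 3).
#' @return factor with levels `M2_biased`, `M0`, `M1_biased`.
#' @export
cluster_phenotype <- function(summaries, k = 3) {
  x <- cbind(summaries$ratio, summaries$attach_mean)
  if (any(apply(x, 2, sd) == 0)) {
    stop("degenerate variance: ratio or attachment is constant; ",
         "phenotype clustering needs spread in both", call. = FALSE)
  }
  xs <- scale(x)
  hc <- hclust(dist(xs), method = "ward.D2")
  cl <- cutree(hc, k = k)
  mean_ratio <- tapply(summaries$ratio, cl, mean)
  ord <- order(mean_ratio, decreasing = TRUE)
  lev <- if (k == 3) c("M2_biased", "M0", "M1_biased") else paste0("pheno", seq_len(k))
  factor(lev[match(cl, ord)], levels = lev)
}

#' Per-donor attachment rank order and cross-donor consistency
#'
#' Ranks designs by mean attachment within each donor and computes the
#' Spearman rank correlation for every donor pair.
#'
#' @param screen_table a `topo_screen`.
#' @return list of class `topo_consistency`: `ranks` (tibble donor x design
#'   mean count and rank), `pairwise` (tibble `donor_a`, `donor_b`, `rho`)
#'   and `mean_correlation`.
#' @export
rank_and_consistency <- function(screen_table) {
  per <- screen_table |>
    dplyr::filter(!.data$is_flat) |>
    dplyr::group_by(.data$donor, .data$design_id) |>
    dplyr::summarise(mean_count = mean(.data$cell_count), .groups = "drop") |>
    dplyr::group_by(.data$donor) |>
    dplyr::mutate(rank = rank(-.data$mean_count, ties.method = "average")) |>
    dplyr::ungroup()
  donors <- unique(per$donor)
  if (length(donors) < 2) stop("need at least two donors")
  wide <- tidyr::pivot_wider(per[, c("donor", "design_id", "mean_count")],
                             names_from = "donor", values_from = "mean_count")
  pairs <- utils::combn(donors, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(donor_a = a, donor_b = b,
                   rho = cor(wide[[a]], wide[[b]], method = "spearman",
                             use = "complete.obs"))
  })
  structure(list(ranks = per, pairwise = pw,
                 mean_correlation = mean(pw$rho)),
            class = "topo_consistency")
}
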