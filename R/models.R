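default_hyper <- function(family) {
  if (family == "gradient_boosted_trees") {
    list(nrounds = 500, eta = 0.05, max_depth = 6, subsample = 0.8,
         colsample_bytree = 0.8)
  } else {
    # random forest via the boosting machinery: one round of many parallel
    # deep trees with row and per-split column subsampling
    list(nrounds = 1, num_parallel_tree = 500, eta = 1, max_depth = 20,
         subsample = 0.632, colsample_bynode = 1 / 3)
  }
}

#' Fit descriptor-to-response regression models
#'
#' Fits the requested tree-ensemble families (gradient-boosted trees and a
#' random forest, both through xgboost so that exact TreeSHAP attributions
#' are available) on a random 70/30 train/test split and reports train and
#' test R-squared.
#'
#' @param data tibble containing the target column and the feature columns
#'   (retained, SNR-filtered units joined to the pruned descriptor matrix).
#' @param target name of the target column (e.g. `"attach_mean"` or
#'   `"composite"`).
#' @param features character vector of feature column names (default: all
#'   numeric columns except the target and `design_id`).
#' @param families model families to fit.
#' @param split training fraction (default 0.70).
#' @param seed integer seed (controls the split and the fits).
#' @param hyper optional named list overriding the per-family defaults
#'   (500 trees; depth 6 / learning rate 0.05 for boosting, deep trees with
#'   bagging and per-split feature subsampling for the forest).
#' @return named list of `topo_model` objects (one per family), class
#'   `topo_model_set`.
#' @export
train_models <- function(data, target,
                         features = NULL,
                         families = c("gradient_boosted_trees", "random_forest"),
                         split = 0.7, seed = 1, hyper = list()) {
  families <- match.arg(families, c("gradient_boosted_trees", "random_forest"),
                        several.ok = TRUE)
  if (nrow(data) < 20) stop("insufficient data: need at least 20 rows", call. = FALSE)
  if (is.null(features)) {
    features <- setdiff(names(dplyr::select(data, dplyr::where(is.numeric))),
                        target)
  }
  stopifnot(target %in% names(data), all(features %in% names(data)))
  x <- as.matrix(data[, features])
  y <- data[[target]]
  keep <- complete.cases(x) & is.finite(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(x)
  idx_train <- withr::with_seed(as.integer(seed),
                                sample(n, size = round(split * n)))
  fits <- purrr::map(families, function(fam) {
    hp <- utils::modifyList(default_hyper(fam), hyper)
    nrounds <- hp$nrounds
    hp$nrounds <- NULL
    dtrain <- xgboost::xgb.DMatrix(x[idx_train, , drop = FALSE],
                                   label = y[idx_train])
    booster <- xgboost::xgb.train(
      params = c(hp, list(objective = "reg:squarederror", nthread = 1,
                          seed = as.integer(seed))),
      data = dtrain, nrounds = nrounds, verbose = 0)
    r2 <- function(obs, pred) {
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    }
    pred_train <- predict(booster, x[idx_train, , drop = FALSE])
    pred_test <- predict(booster, x[-idx_train, , drop = FALSE])
    structure(
      list(booster = booster, family = fam, target = target,
           features = features, x = x, y = y, train_idx = idx_train,
           split_fraction = split, seed = as.integer(seed),
           hyperparameters = c(hp, list(nrounds = nrounds)),
           r2_train = r2(y[idx_train], pred_train),
           r2_test = r2(y[-idx_train], pred_test)),
      class = "topo_model")
  })
  structure(setNames(fits, families), class = "topo_model_set")
}

#' @export
print.topo_model <- function(x, ...) {
  cat("<topo_model> ", x$family, " on '", x$target, "': ",
      length(x$features), " features, n = ", length(x$y),
      sprintf("; R2 train %.3f / test %.3f\n", x$r2_train, x$r2_test), sep = "")
  invisible(x)
}

#' Shapley-value feature ranking of a fitted tree-ensemble model
#'
#' Computes exact per-sample TreeSHAP attributions (additive decomposition
#' of each prediction into per-feature contributions plus a baseline),
#' checks that attributions reconstruct the predictions, and ranks features
#' by mean absolute attribution. Ties are broken by feature (manifest)
#' order.
#'
#' @param model a `topo_model`.
#' @param newdata optional feature matrix (defaults to the model's full
#'   design matrix).
#' @param tol additivity tolerance relative to the prediction scale
#'   (default 1e-5; tree ensembles score in single precision, which bounds
#'   the achievable reconstruction accuracy).
#' @return tibble: `feature`, `mean_abs_shap`, `rank`; attribute `shap` holds
#'   the per-sample attribution matrix.
#' @export
shapley_rank <- function(model, newdata = NULL, tol = 1e-5) {
  if (!inherits(model, "topo_model")) {
    stop("unsupported model: Shapley attribution requires a tree-ensemble topo_model",
         call. = FALSE)
  }
  x <- if (is.null(newdata)) model$x else as.matrix(newdata[, model$features])
  contrib <- predict(model$booster, x, predcontrib = TRUE)
  pred <- predict(model$booster, x)
  recon <- rowSums(contrib)
  # relative to the prediction scale: tree ensembles score in single
  # precision, so per-sample ratios near zero-crossings are not meaningful
  rel_err <- max(abs(recon - pred)) / max(1, max(abs(pred)))
  if (rel_err > tol) {
    stop("Shapley additivity check failed", call. = FALSE)
  }
  phi <- contrib[, model$features, drop = FALSE]
  mas <- colMeans(abs(phi))
  ord <- order(-mas, seq_along(mas))
  out <- tibble::tibble(feature = model$features[ord],
                        mean_abs_shap = unname(mas[ord]),
                        rank = seq_along(ord))
  attr(out, "shap") <- contrib
  out
}

#' Select features from a Shapley ranking
#'
#' @param ranking tibble from [shapley_rank()].
#' @param rule list: `list(type = "top_n", n = 20)` keeps the `n` best-ranked
#'   features; `list(type = "cumulative", fraction = f)` keeps the smallest
#'   prefix whose attributions account for at least fraction `f` of the total
#'   mean absolute attribution.
#' @return character vector of selected feature names.
#' @export
select_features <- function(ranking, rule = list(type = "top_n", n = 20)) {
  sel <- switch(
    rule$type,
    top_n = head(ranking$feature, rule$n),
    cumulative = {
      cs <- cumsum(ranking$mean_abs_shap) / sum(ranking$mean_abs_shap)
      ranking$feature[seq_len(which(cs >= rule$fraction)[1])]
    },
    stop("unknown selection rule: ", rule$type))
  if (length(sel) == 0 || all(is.na(sel))) stop("empty feature selection", call. = FALSE)
  sel
}

#' Map ranked features to planted driver descriptors
#'
#' Correlation pruning can replace a driver descriptor with a tightly
#' correlated surrogate from the same cluster (that is what pruning is for).
#' This helper maps each of the top-ranked features back to the driver it
#' tracks: a feature represents a driver when their |Pearson r| across the
#' descriptor matrix is at least `threshold` (default: the pruning
#' threshold) and that driver is its best match.
#'
#' @param ranking tibble from [shapley_rank()].
#' @param descriptors the full (unpruned) `topo_descriptors` matrix.
#' @param drivers character vector of planted driver descriptor names.
#' @param top_n how many top-ranked features to map (default 3).
#' @param threshold minimum |r| for a feature to count as a driver proxy.
#' @return tibble: `feature`, `rank`, `driver` (NA when no driver reaches the
#'   threshold), `abs_cor`.
#' @export
match_drivers <- function(ranking, descriptors, drivers, top_n = 3,
                          threshold = 0.85) {
  top <- head(ranking, top_n)
  purrr::map_dfr(seq_len(nrow(top)), function(i) {
    f <- top$feature[i]
    cors <- vapply(drivers, function(d) {
      suppressWarnings(abs(cor(descriptors[[f]], descriptors[[d]])))
    }, numeric(1))
    best <- which.max(cors)
    hit <- is.finite(cors[best]) && cors[best] >= threshold
    tibble::tibble(feature = f, rank = top$rank[i],
                   driver = if (hit) drivers[best] else NA_character_,
                   abs_cor = unname(cors[best]))
  })
}

#' Contrast descriptors between the top-k and bottom-k composite units
#'
#' Ranks retained units by the composite variable, takes the k most M2-biased
#' (top) and k most M1-biased (bottom) units, and tests every descriptor with
#' a two-sample Wilcoxon rank-sum test, Benjamini-Hochberg adjusted.
#'
#' @param summaries a `topo_summary` (retained units, with `composite`).
#' @param descriptor_matrix a `topo_descriptors`.
#' @param k group size (default 50).
#' @return tibble of class `topo_contrast`: `descriptor`, `mean_top`,
#'   `mean_bottom`, `statistic`, `p_value`, `p_adjusted`; attributes `k` and
#'   `adjust_method`.
#' @export
topk_contrast <- function(summaries, descriptor_matrix, k = 50) {
  joined <- dplyr::inner_join(summaries, descriptor_matrix, by = "design_id")
  if (nrow(joined) < 2 * k) {
    stop("need at least 2k = ", 2 * k, " retained units", call. = FALSE)
  }
  joined <- dplyr::arrange(joined, dplyr::desc(.data$composite))
  top <- joined[seq_len(k), ]
  bottom <- joined[seq(nrow(joined) - k + 1, nrow(joined)), ]
  descs <- setdiff(names(descriptor_matrix), "design_id")
  out <- purrr::map_dfr(descs, function(d) {
    a <- top[[d]]; b <- bottom[[d]]
    if (sd(c(a, b)) == 0) {
      return(tibble::tibble(descriptor = d, mean_top = mean(a),
                            mean_bottom = mean(b), statistic = NA_real_,
                            p_value = 1))
    }
    w <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(descriptor = d, mean_top = mean(a), mean_bottom = mean(b),
                   statistic = unname(w$statistic), p_value = w$p.value)
  })
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  attr(out, "k") <- k
  attr(out, "adjust_method") <- "BH"
  class(out) <- c("topo_contrast", class(out))
  out
}

#' Tidy a fitted topography model
#'
#' Returns the Shapley feature ranking as a tibble (broom convention).
#'
#' @param x a `topo_model`.
#' @param ... unused.
#' @return tibble with `feature`, `mean_abs_shap`, `rank`.
#' @method tidy topo_model
#' @export
tidy.topo_model <- function(x, ...) {
  r <- shapley_rank(x)
  attr(r, "shap") <- NULL
  r
}

#' Glance at a fitted topography model
#'
#' @param x a `topo_model`.
#' @param ... unused.
#' @return one-row tibble: family, target, nobs, n features, split fraction,
#'   seed, train and test R-squared.
#' @method glance topo_model
#' @export
glance.topo_model <- function(x, ...) {
  tibble::tibble(family = x$family, target = x$target, nobs = length(x$y),
                 n_features = length(x$features),
                 split_fraction = x$split_fraction, seed = x$seed,
                 r2_train = x$r2_train, r2_test = x$r2_test)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
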