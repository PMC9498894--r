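#' Spearman rank-order correlation
#'
#' Pearson correlation of average ranks (ties receive their average rank);
#' the model-performance metric used on held-out folds.
#'
#' @param y,y_hat numeric vectors of equal length `n >= 2`; neither may be
#'   constant.
#' @return a number in `[-1, 1]`.
#' @export
spearman_cor <- function(y, y_hat) {
  if (length(y) != length(y_hat)) mc_stop("lengths differ", "motifconv_dim_error")
  if (length(y) < 2L) mc_stop("need at least two observations", "motifconv_data_error")
  ry <- rank(y, ties.method = "average")
  rh <- rank(y_hat, ties.method = "average")
  if (stats::sd(ry) == 0 || stats::sd(rh) == 0) {
    mc_stop("correlation undefined: one of the vectors is constant",
            "motifconv_numeric_error")
  }
  stats::cor(ry, rh)
}

#' Partition a dataset into cross-validation folds
#'
#' Ids are shuffled once with `seed` and split into `k` contiguous blocks.
#' Fold f uses block f as its test set (so the k test sets partition the
#' data, ~10% each at k = 10); one tenth of the remaining ids (in shuffled
#' order) forms the validation set (~9% overall) and the rest the training
#' set (~81%). Splits are deterministic for a fixed seed.
#'
#' @param data an [mpra_dataset()].
#' @param k number of folds (>= 2, <= dataset size).
#' @param seed integer shuffle seed.
#' @return a list of `k` `fold_split` objects with `fold_index` (0-based),
#'   `train_ids`, `validation_ids`, `test_ids`.
#' @export
make_folds <- function(data, k = 10L, seed = 1L) {
  stopifnot(inherits(data, "mpra_dataset"))
  if (!is_count(k, 2L)) mc_stop("k must be a count >= 2", "motifconv_config_error")
  if (k > data$n) mc_stop("k exceeds the dataset size", "motifconv_config_error")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ids <- sample(data$ids)
  blocks <- split(ids, cut(seq_along(ids), breaks = k, labels = FALSE))
  lapply(seq_len(k), function(f) {
    test <- blocks[[f]]
    rest <- ids[!ids %in% test]              # shuffled order preserved
    n_val <- max(1L, floor(length(rest) / 10))
    structure(list(fold_index = f - 1L,
                   train_ids = rest[-seq_len(n_val)],
                   validation_ids = rest[seq_len(n_val)],
                   test_ids = test),
              class = "fold_split")
  })
}

#' k-fold cross-validation of a model configuration
#'
#' Trains one model per fold on the training ids (early stopping on the
#' validation ids) and scores Spearman correlation on the fold's held-out
#' test set. Per-fold training seeds are derived deterministically from
#' `seed` plus the fold index so runs are reproducible.
#'
#' @param data an [mpra_dataset()].
#' @param config a [model_config()] or [conventional_cnn_config()].
#' @param k number of folds (default 10).
#' @param seed master seed for fold assignment and per-fold training.
#' @return an object of class `cv_result` with `per_fold_spearman`,
#'   `mean_spearman`, `config`, `folds`.
#' @export
cross_validate <- function(data, config, k = 10L, seed = 1L) {
  folds <- make_folds(data, k, seed)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    cfg <- config
    cfg$seed <- as.integer((seed + 7919L * f) %% .Machine$integer.max)
    model <- if (inherits(cfg, "cnn_config")) build_conventional_cnn(cfg)
             else build_multinom_cnn(cfg)
    fit <- tryCatch(
      train_model(model, subset_dataset(data, fold$train_ids),
                  subset_dataset(data, fold$validation_ids)),
      error = function(e) {
        mc_stop(sprintf("fold %d: %s", fold$fold_index, conditionMessage(e)),
                "motifconv_cv_error")
      })
    test <- subset_dataset(data, fold$test_ids)
    per_fold[f] <- spearman_cor(test$activities, predict(fit, test))
  }
  structure(list(per_fold_spearman = per_fold,
                 mean_spearman = mean(per_fold),
                 k = k, seed = seed, config = config, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean Spearman %.4f (per fold: %s)\n",
              x$k, x$mean_spearman, paste(sprintf("%.3f", x$per_fold_spearman),
                                          collapse = ", ")))
  invisible(x)
}

n_model_parameters <- function(config) {
  if (inherits(config, "cnn_config")) {
    in_ch <- 4L
    total <- 0
    for (l in seq_along(config$conv_filters)) {
      total <- total + config$conv_lengths[l] * in_ch * config$conv_filters[l] +
        config$conv_filters[l]
      in_ch <- config$conv_filters[l]
    }
    nf <- in_ch
  } else {
    total <- config$filter_length * 4L * config$n_filters
    nf <- config$n_filters
  }
  total + if (config$n_dense_layers == 1L) nf + 1L else {
    nf * config$dense_hidden_units + config$dense_hidden_units +
      config$dense_hidden_units + 1L
  }
}

#' Grid search over model configurations
#'
#' Runs [cross_validate()] for every configuration and ranks them by mean
#' Spearman correlation, descending. Ties are broken in favor of the model
#' with fewer parameters, then by grid order.
#'
#' @param data an [mpra_dataset()].
#' @param grid non-empty list of configurations.
#' @inheritParams cross_validate
#' @return a list of `cv_result` objects, best first, with a `rank` field.
#' @export
hyperparameter_search <- function(data, grid, k = 10L, seed = 1L) {
  if (!is.list(grid) || length(grid) < 1L ||
      !all(vapply(grid, inherits, TRUE, "model_config"))) {
    mc_stop("grid must be a non-empty list of model configurations",
            "motifconv_config_error")
  }
  results <- lapply(grid, function(cfg) cross_validate(data, cfg, k = k, seed = seed))
  means <- vapply(results, `[[`, 0, "mean_spearman")
  sizes <- vapply(grid, n_model_parameters, 0)
  ord <- order(-means, sizes, seq_along(grid))
  results <- results[ord]
  for (i in seq_along(results)) results[[i]]$rank <- i
  results
}

#' Write a cross-validation report
#'
#' Tab-delimited text: one row per fold plus a `mean` row.
#'
#' @param result a `cv_result`.
#' @param path output path.
#' @export
write_cv_report <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  df <- data.frame(fold = c(seq_len(result$k) - 1L, NA),
                   label = c(rep("fold", result$k), "mean"),
                   spearman = c(result$per_fold_spearman, result$mean_spearman))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
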