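#' Classification metrics for a scored segment set
#'
#' Precision, recall and F1 at a decision threshold on the abnormal-class
#' score, and the threshold-free AUC computed as the Mann-Whitney rank
#' statistic (probability that a random abnormal segment outscores a
#' random normal one, ties counted half).
#'
#' @param y_true 0/1 labels.
#' @param y_score abnormal-class scores in [0, 1].
#' @param threshold decision threshold for the thresholded metrics.
#' @return one-row data.frame: `precision`, `recall`, `f1`, `auc`, `n`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y <- as.integer(y_true)
  stopifnot(length(y) == length(y_score), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  r <- rank(y_score)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  data.frame(precision = precision, recall = recall, f1 = f1, auc = auc,
             n = length(y))
}

#' Stratified driver-level fold assignment
#'
#' Assigns each driver to one of `k` folds, stratified by label so both
#' classes appear in every fold. Folds partition drivers, never
#' segments: no driver's data can reach both sides of a split.
#'
#' @param driver_labels named 0/1 vector, one entry per driver.
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @return named integer vector of fold ids per driver.
#' @export
make_folds <- function(driver_labels, k = 5L, seed = 1L) {
  tab <- table(driver_labels)
  if (length(tab) < 2 || any(tab < k))
    stop("infeasible split: need at least ", k, " drivers per class",
         call. = FALSE)
  set.seed(seed)
  fold <- integer(length(driver_labels))
  names(fold) <- names(driver_labels)
  for (cls in names(tab)) {
    ids <- names(driver_labels)[driver_labels == as.integer(cls)]
    ids <- sample(ids)
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

.model_for_approach <- function(approach, ds, node_dims = NULL) {
  p <- ncol(ds$x_naive)
  nspec <- if (is.null(node_dims)) naive_stream_spec(input_dim = p)
    else naive_stream_spec(input_dim = p, hidden_dims = node_dims)
  gspec <- if (is.null(node_dims)) grid_stream_spec(extent = ds$extent)
    else grid_stream_spec(extent = ds$extent, fc_dims = node_dims)
  cspec <- if (is.null(node_dims)) combined_spec()
    else combined_spec(fc_dims = node_dims)
  switch(approach,
         naive = build_naive_stream(nspec),
         grid = build_grid_stream(gspec),
         combined = build_combined(nspec, gspec, cspec),
         stop("unknown approach: ", approach, call. = FALSE))
}

.train_data <- function(approach, ds, scaler = NULL) {
  xn <- ds$x_naive
  if (!is.null(scaler) && approach %in% c("naive", "combined"))
    xn <- sweep(sweep(xn, 2, scaler$mu), 2, scaler$sd, "/")
  list(x_naive = if (approach %in% c("naive", "combined")) xn,
       x_grid = if (approach %in% c("grid", "combined")) ds$x_grid,
       y = ds$y)
}

# Column scaler fitted on the training fold only; constant columns are
# left unscaled.
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

#' Driver-grouped k-fold cross-validation
#'
#' Splits the cohort into `k` folds at the driver level (stratified by
#' label), trains the requested approach on each training portion —
#' rotation-augmented unless disabled — and scores the held-out drivers'
#' segments. Segment-level ("leaky") splitting is available behind
#' `group_by = "segment"` for comparison; with stride-1 windows it leaks
#' near-duplicate segments across the split and inflates scores.
#'
#' @param ds a `dg_dataset`.
#' @param approach `"combined"`, `"naive"` or `"grid"`.
#' @param k number of folds.
#' @param seed seed for fold assignment; per-fold training seeds derive
#'   from it.
#' @param cfg a [training_config()]; its `seed` is re-derived per fold.
#' @param augment rotation-augment the training folds. Augmentation is
#'   applied at the dataset level — every approach trains on the same
#'   expanded segment set (tabular direction means co-rotated with the
#'   grids) — so that approach comparisons share identical training
#'   data.
#' @param group_by `"driver"` (default) or `"segment"`.
#' @param node_dims optional hidden-layer width vector overriding the
#'   architecture defaults (experiment sweeps).
#' @return list: `folds` (per-fold metric rows), `summary` (mean and sd
#'   per metric), `pooled` (metrics over all held-out segments),
#'   `predictions` (`y`, `score`, `fold`, `driver_id`).
#' @export
cross_validate <- function(ds, approach = c("combined", "naive", "grid"),
                           k = 5L, seed = 1L, cfg = training_config(),
                           augment = TRUE,
                           group_by = c("driver", "segment"),
                           node_dims = NULL) {
  approach <- match.arg(approach)
  group_by <- match.arg(group_by)

  if (group_by == "driver") {
    dl <- tapply(ds$y, ds$driver_id, function(v) v[1])
    fold_of_driver <- make_folds(dl, k, seed)
    fold <- fold_of_driver[ds$driver_id]
  } else {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(k), length(ds$y)))
  }

  rows <- list(); preds <- list()
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    train_ds <- subset_dataset(ds, tr)
    if (augment) train_ds <- augment_dataset(train_ds)
    scaler <- .fit_scaler(train_ds$x_naive)
    model <- .model_for_approach(approach, ds, node_dims)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 101L * f
    model <- train_model(model, .train_data(approach, train_ds, scaler),
                         fold_cfg)
    p <- predict_proba(model,
                       .train_data(approach, subset_dataset(ds, te), scaler))
    score <- p[, "p_abnormal"]
    m <- compute_metrics(ds$y[te], score)
    m$fold <- f
    rows[[f]] <- m
    preds[[f]] <- data.frame(y = ds$y[te], score = score, fold = f,
                             driver_id = ds$driver_id[te],
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, rows)
  predictions <- do.call(rbind, preds)
  pooled <- compute_metrics(predictions$y, predictions$score)
  metric_cols <- c("precision", "recall", "f1", "auc")
  summary <- data.frame(metric = metric_cols,
                        mean = colMeans(folds[metric_cols]),
                        sd = apply(folds[metric_cols], 2, stats::sd),
                        row.names = NULL)
  list(folds = folds, summary = summary, pooled = pooled,
       predictions = predictions, approach = approach, k = k)
}

#' Default experiment grid: data size, width, depth
#'
#' Four configurations pairing growing corpus fractions with widening,
#' deepening layer stacks; the depth entry truncates the node triple to
#' the first `hidden_layers` widths.
#'
#' @return data.frame with `name`, `data_fraction`, `nodes` (comma
#'   string), `hidden_layers`.
#' @export
default_experiment_grid <- function() {
  data.frame(name = paste0("exp", 1:4),
             data_fraction = c(1 / 6, 1 / 3, 1 / 2, 1),
             nodes = c("64,32,16", "96,48,24", "128,64,32", "128,64,32"),
             hidden_layers = c(1L, 2L, 3L, 3L),
             stringsAsFactors = FALSE)
}

#' Run the factor sweep over approaches and experiment configurations
#'
#' For every configuration row, subsamples the corpus to the requested
#' fraction (per driver, so every driver stays represented), truncates
#' the node widths to the requested depth, and cross-validates each
#' approach. Emits one metric row per (configuration, approach) pair —
#' the tables behind the data-size / width / depth comparison plots.
#'
#' @param ds a `dg_dataset`.
#' @param grid configuration data.frame as [default_experiment_grid()].
#' @param approaches subset of `c("naive", "grid", "combined")`.
#' @param k folds.
#' @param seed master seed (subsampling and CV derive from it).
#' @param cfg a [training_config()].
#' @param augment rotation-augment training folds.
#' @return data.frame: one row per configuration x approach with the
#'   fold-mean precision, recall, F1 and AUC.
#' @export
run_factor_sweep <- function(ds, grid = default_experiment_grid(),
                             approaches = c("naive", "grid", "combined"),
                             k = 5L, seed = 1L, cfg = training_config(),
                             augment = TRUE) {
  out <- list()
  for (i in seq_len(nrow(grid))) {
    frac <- grid$data_fraction[i]
    dims <- as.integer(strsplit(grid$nodes[i], ",")[[1]])
    dims <- dims[seq_len(grid$hidden_layers[i])]
    set.seed(seed + i)
    keep <- unlist(lapply(split(seq_along(ds$y), ds$driver_id),
                          function(ii) {
                            m <- max(1L, floor(length(ii) * frac))
                            sort(sample(ii, m))
                          }), use.names = FALSE)
    sub <- subset_dataset(ds, sort(keep))
    for (ap in approaches) {
      cv <- cross_validate(sub, ap, k = k, seed = seed + i, cfg = cfg,
                           augment = augment, node_dims = dims)
      mu <- stats::setNames(cv$summary$mean, cv$summary$metric)
      out[[length(out) + 1L]] <-
        data.frame(name = grid$name[i], approach = ap,
                   data_fraction = frac, nodes = grid$nodes[i],
                   hidden_layers = grid$hidden_layers[i],
                   precision = mu[["precision"]], recall = mu[["recall"]],
                   f1 = mu[["f1"]], auc = mu[["auc"]],
                   n_segments = length(sub$y),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate, featurize, gridify and cross-validate in one call
#'
#' End-to-end convenience wrapper: simulates a labeled cohort, derives
#' the telemetry features, builds the segment dataset and runs
#' driver-grouped cross-validation for one approach.
#'
#' @param sim_cfg a [simulation_config()].
#' @param approach model to evaluate.
#' @param window,cell_km,extent,stride pipeline parameters (see
#'   [build_segment_dataset()]).
#' @param k folds.
#' @param cfg a [training_config()].
#' @param augment rotation-augment training folds.
#' @param normal,abnormal phenotype parameters.
#' @return the [cross_validate()] result, with the dataset attached as
#'   `$dataset`.
#' @export
evaluate_cohort <- function(sim_cfg = simulation_config(),
                            approach = "combined",
                            window = 30L, cell_km = 0.1, extent = 5L,
                            stride = 10L, k = 5L,
                            cfg = training_config(epochs = 25L),
                            augment = TRUE,
                            normal = normal_phenotype(),
                            abnormal = abnormal_phenotype()) {
  cohort <- simulate_cohort(sim_cfg, normal, abnormal)
  feats <- featurize_cohort(cohort$telemetry)
  ds <- build_segment_dataset(feats, cohort$labels, window = window,
                              cell_km = cell_km, extent = extent,
                              stride = stride)
  cv <- cross_validate(ds, approach, k = k, seed = sim_cfg$seed, cfg = cfg,
                       augment = augment)
  cv$dataset <- ds
  cv
}
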