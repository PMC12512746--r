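#' Candidate settings grid for the boosted model
#'
#' Every combination of the supplied values is a candidate; the tuning
#' routine fits each one and keeps the setting with the lowest
#' cross-validated RMSE. The defaults span shallow to moderately interacting
#' trees with the usual stochastic-boosting ranges.
#'
#' @param interaction_depth Maximum tree depth values.
#' @param shrinkage Learning-rate values.
#' @param bag_fraction Row-subsampling fractions per tree.
#' @param n_trees Maximum boosting iterations (the best iteration within this
#'   cap is selected by cross-validation).
#' @return A tibble, one row per candidate setting.
#' @export
settings_grid <- function(interaction_depth = c(1L, 3L, 5L),
                          shrinkage = c(0.01, 0.1),
                          bag_fraction = c(0.5, 0.75),
                          n_trees = 2000L) {
  tidyr::expand_grid(
    interaction_depth = as.integer(interaction_depth),
    shrinkage = shrinkage,
    bag_fraction = bag_fraction,
    n_trees = as.integer(n_trees)
  )
}

#' Split a design table into training and testing subsets
#'
#' Random, disjoint, exhaustive split at `train_fraction` (default 75%
#' training / 25% testing), reproducible from `seed`.
#'
#' @param data Design tibble (one row per observation).
#' @param train_fraction Fraction of rows assigned to training.
#' @param seed Integer seed; recorded in the result.
#' @return A list with `train`, `test` and `seed`.
#' @export
split_design <- function(data, train_fraction = 0.75, seed = 1L) {
  n <- nrow(data)
  if (n < 8) abort("fewer than 8 rows: a train/test split is meaningless")
  stopifnot(train_fraction > 0, train_fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n, size = round(n * train_fraction))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE],
       seed = seed)
}

# one-hot design matrix with a map from dummy columns back to base predictors
build_design_matrix <- function(data, response) {
  check_columns(data, response, "design table")
  predictors <- setdiff(names(data), c(response, "station_id", "tag_id"))
  df <- as.data.frame(data[, predictors, drop = FALSE])
  for (p in predictors) if (is.character(df[[p]]) || is.factor(df[[p]])) {
    df[[p]] <- factor(df[[p]])
    # a factor observed at a single level carries no signal and breaks
    # contrasts; keep the predictor (zero importance) but drop the column
    if (nlevels(droplevels(df[[p]])) < 2) df[[p]] <- NULL
  }
  mm <- model.matrix(~ . , data = df)
  assign_idx <- attr(mm, "assign")
  mm <- mm[, assign_idx != 0, drop = FALSE]
  feature_map <- stats::setNames(predictors[assign_idx[assign_idx != 0]],
                                 colnames(mm))
  list(x = mm, y = data[[response]], feature_map = feature_map,
       predictors = predictors)
}

xgb_params <- function(settings, seed) {
  xgboost::xgb.params(
    objective = "reg:squarederror",
    max_depth = settings$interaction_depth,
    eta = settings$shrinkage,
    subsample = settings$bag_fraction,
    nthread = 1,
    seed = seed
  )
}

xgb_matrix <- function(x, y = NULL) {
  if (is.null(y)) xgboost::xgb.DMatrix(x, nthread = 1) else
    xgboost::xgb.DMatrix(x, label = y, nthread = 1)
}

#' Grid-tune the boosted habitat model
#'
#' Fits a stochastic gradient-boosted regression-tree model at every grid
#' point and selects the setting with the lowest cross-validated RMSE (the
#' best iteration within each setting's `n_trees` cap is used, with early
#' stopping). Deterministic given `seed`.
#'
#' @param train Training design tibble.
#' @param response Name of the response column (default `"degree"`).
#' @param grid Settings grid from [settings_grid()].
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return The best setting as a one-row tibble with `n_trees` replaced by
#'   the best iteration and an attached `cv_rmse` column; the full grid with
#'   scores is in attribute `cv_results`.
#' @export
tune_boosted_model <- function(train, response = "degree",
                               grid = settings_grid(), cv_folds = 5L,
                               seed = 1L) {
  stopifnot(nrow(grid) >= 1)
  dm <- build_design_matrix(train, response)
  if (var(dm$y) == 0) abort("response has zero variance; nothing to model")
  dtrain <- xgb_matrix(dm$x, dm$y)
  scores <- purrr::map(seq_len(nrow(grid)), function(k) {
    s <- grid[k, ]
    set.seed(seed)  # fold assignment
    cv <- xgboost::xgb.cv(
      params = xgb_params(s, seed),
      data = dtrain,
      nrounds = s$n_trees, nfold = cv_folds,
      early_stopping_rounds = 25, verbose = 0
    )
    best_it <- which.min(cv$evaluation_log$test_rmse_mean)
    mutate(s,
           best_iteration = as.integer(best_it),
           cv_rmse = cv$evaluation_log$test_rmse_mean[best_it])
  })
  scores <- bind_rows(scores)
  best <- scores %>% arrange(.data$cv_rmse) %>% slice(1) %>%
    mutate(n_trees = .data$best_iteration) %>%
    select(-"best_iteration")
  attr(best, "cv_results") <- scores
  best
}

#' Fit the boosted habitat-preference model and attribute importance
#'
#' Fits a gradient-boosted regression-tree model of node degree on habitat
#' covariates at the given settings and computes each predictor's relative
#' influence: the model's total loss reduction attributed across predictors
#' (dummy columns of a categorical predictor are pooled), normalised to sum
#' to 100.
#'
#' @inheritParams tune_boosted_model
#' @param data Design tibble to fit on.
#' @param settings A one-row settings tibble (e.g. from
#'   [tune_boosted_model()]).
#' @return A `habitat_gbm` object: the fitted booster, `importance` tibble
#'   (`predictor`, `relative_influence`, descending), `r2_train` (squared
#'   Pearson correlation of fitted vs observed), `settings`, `seed` and the
#'   design contract needed to predict on new data.
#' @export
fit_boosted_model <- function(data, settings, response = "degree", seed = 1L) {
  dm <- build_design_matrix(data, response)
  booster <- xgboost::xgb.train(
    params = xgb_params(settings, seed),
    data = xgb_matrix(dm$x, dm$y),
    nrounds = settings$n_trees, verbose = 0
  )
  imp_raw <- xgboost::xgb.importance(model = booster)
  gains <- stats::setNames(numeric(length(dm$predictors)), dm$predictors)
  if (!is.null(imp_raw) && nrow(imp_raw) > 0) {
    base <- dm$feature_map[imp_raw$Feature]
    agg <- tapply(imp_raw$Gain, base, sum)
    gains[names(agg)] <- agg
  }
  importance <- tibble(
    predictor = names(gains),
    relative_influence = if (sum(gains) > 0) 100 * gains / sum(gains) else
      rep(100 / length(gains), length(gains))
  ) %>% arrange(dplyr::desc(.data$relative_influence))
  fitted <- stats::predict(booster, xgb_matrix(dm$x))
  structure(
    list(booster = booster, importance = importance,
         r2_train = if (sd(fitted) > 0) cor(fitted, dm$y)^2 else NA_real_,
         settings = settings, seed = seed, response = response,
         feature_names = colnames(dm$x), predictors = dm$predictors,
         rho_test = NA_real_),
    class = "habitat_gbm"
  )
}

# predict on a raw design tibble, reproducing the training dummy layout
predict_habitat_gbm <- function(fit, newdata) {
  dm <- build_design_matrix(newdata, fit$response)
  x <- matrix(0, nrow(dm$x), length(fit$feature_names),
              dimnames = list(NULL, fit$feature_names))
  shared <- intersect(colnames(dm$x), fit$feature_names)
  x[, shared] <- dm$x[, shared]
  stats::predict(fit$booster, xgb_matrix(x))
}

#' @export
predict.habitat_gbm <- function(object, newdata, ...) {
  predict_habitat_gbm(object, newdata)
}

#' Evaluate the fitted model on the held-out subset
#'
#' Spearman rank correlation between model predictions and observed response
#' on the testing subset — the model-accuracy check of the analysis protocol.
#'
#' @param fit A `habitat_gbm`.
#' @param test Held-out design tibble.
#' @return The Spearman correlation (`rho_test`), or `NA` with a warning when
#'   predictions are constant (correlation undefined).
#' @export
evaluate_holdout <- function(fit, test) {
  stopifnot(nrow(test) > 0)
  pred <- predict_habitat_gbm(fit, test)
  obs <- test[[fit$response]]
  if (sd(pred) == 0 || sd(obs) == 0) {
    warn("constant predictions or observations: Spearman correlation undefined")
    return(NA_real_)
  }
  suppressWarnings(cor(pred, obs, method = "spearman"))
}

#' Full habitat-preference modelling protocol
#'
#' Runs the complete protocol on one design table: 75/25 train/test split,
#' grid tuning by cross-validated RMSE, final fit with relative-influence
#' attribution, and Spearman evaluation on the hold-out.
#'
#' @inheritParams tune_boosted_model
#' @param data Full design tibble.
#' @param train_fraction Training fraction (default 0.75).
#' @return A `habitat_gbm` with `rho_test` filled in and the split recorded.
#' @export
fit_habitat_model <- function(data, response = "degree", train_fraction = 0.75,
                              grid = settings_grid(), cv_folds = 5L, seed = 1L) {
  sp <- split_design(data, train_fraction, seed)
  best <- tune_boosted_model(sp$train, response, grid, cv_folds, seed)
  fit <- fit_boosted_model(sp$train, best, response, seed)
  fit$rho_test <- evaluate_holdout(fit, sp$test)
  fit$split_seed <- seed
  fit
}

#' @export
print.habitat_gbm <- function(x, ...) {
  cat("<habitat_gbm>", x$response, "~", paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  depth %d, shrinkage %g, bag %g, trees %d | R2(train) %.3f, rho(test) %.3f\n",
              x$settings$interaction_depth, x$settings$shrinkage,
              x$settings$bag_fraction, x$settings$n_trees,
              x$r2_train, x$rho_test))
  top <- head(x$importance, 3)
  cat("  top influence:", paste(sprintf("%s (%.1f%%)", top$predictor,
                                        top$relative_influence), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the habitat-model design table from pipeline outputs
#'
#' Builds one design row per (individual network, diel period, node): the
#' response is the node's degree in that individual's period-specific
#' network, and predictors are the station's habitat covariates plus the
#' individual's sex and the period (`tod`). Individuals whose overall network
#' spans fewer than `min_individual_nodes` receivers are excluded upstream of
#' this table, so their rows never exist.
#'
#' With `stack_by_period = FALSE` the response is instead the node's degree
#' in the individual's full network (one row per individual and node, no
#' `tod` predictor) — the alternative when diel structure is not of
#' interest.
#'
#' @param detections Filtered, period-annotated detections.
#' @param tags Tag table.
#' @param covariates Station covariates from [assemble_node_covariates()].
#' @param min_individual_nodes Node rule for individual networks (default 3).
#' @param species Optional species filter.
#' @param stack_by_period One row per period per node (default) or per node.
#' @return A design tibble ready for [fit_habitat_model()].
#' @export
assemble_design <- function(detections, tags, covariates,
                            min_individual_nodes = 3L, species = NULL,
                            stack_by_period = TRUE) {
  det <- detections
  if (!"species" %in% names(det)) {
    det <- left_join(det, select(tags, "tag_id", "species", "sex"), by = "tag_id")
  }
  if (!is.null(species)) det <- filter(det, .data$species %in% !!species)
  ev <- extract_movement_events(det)
  qualifying <- det %>%
    group_by(.data$tag_id) %>%
    summarise(n_nodes = dplyr::n_distinct(.data$station_id), .groups = "drop") %>%
    filter(.data$n_nodes >= min_individual_nodes) %>%
    pull("tag_id")
  rows <- purrr::map(qualifying, function(tg) {
    if (stack_by_period) {
      purrr::map(PERIOD_LEVELS, function(p) {
        net <- build_network(ev, tag_id = tg, period = p)
        if (nrow(net$nodes) == 0) return(NULL)
        dc <- degree_centrality(net)
        mutate(dc, tag_id = tg, tod = p,
               sex = tags$sex[match(tg, tags$tag_id)] %||% "U")
      })
    } else {
      net <- build_network(ev, tag_id = tg)
      if (nrow(net$nodes) == 0) return(list(NULL))
      list(mutate(degree_centrality(net), tag_id = tg,
                  sex = tags$sex[match(tg, tags$tag_id)] %||% "U"))
    }
  })
  design <- bind_rows(purrr::flatten(rows))
  if (nrow(design) == 0) return(design)
  design %>%
    left_join(select(covariates, -any_of("coverage")), by = "station_id") %>%
    select("tag_id", "station_id", "degree", any_of("tod"), "sex",
           dplyr::everything())
}
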