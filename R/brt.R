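#' Boosted-regression-tree hyperparameters
#'
#' Defaults are the settings used for nightly migration-intensity models:
#' Gaussian (squared-error) boosting, 10-fold cross-validation, tree
#' complexity (interaction depth) 10, learning rate 0.001, bag fraction 0.5
#' and trees grown and evaluated in steps of 25, with held-out deviance
#' deciding the ensemble size.
#'
#' @param cv_folds number of cross-validation folds
#' @param interaction_depth splits per tree (a tree has depth + 1 leaves)
#' @param learning_rate shrinkage applied to every tree
#' @param bag_fraction stochastic subsample share per tree
#' @param step_size trees added per selection step
#' @param max_trees hard cap on ensemble size scanned by the selection
#' @param min_obs_node minimum observations per terminal node
#' @param plateau_steps stop scanning after this many consecutive steps
#'   without a new held-out deviance minimum
#' @return list of class `brt_hyperparams`
#' @export
brt_hyperparams <- function(cv_folds = 10, interaction_depth = 10,
                            learning_rate = 0.001, bag_fraction = 0.5,
                            step_size = 25, max_trees = 5000,
                            min_obs_node = 10, plateau_steps = 3) {
  stopifnot(cv_folds >= 2, interaction_depth >= 1, learning_rate > 0,
            bag_fraction > 0, bag_fraction <= 1, step_size >= 1,
            max_trees >= step_size)
  structure(list(cv_folds = cv_folds, interaction_depth = interaction_depth,
                 learning_rate = learning_rate, bag_fraction = bag_fraction,
                 step_size = step_size, max_trees = max_trees,
                 min_obs_node = min_obs_node, plateau_steps = plateau_steps),
            class = "brt_hyperparams")
}

#' Fit a boosted regression tree with cross-validated tree selection
#'
#' Squared-error gradient boosting of depth-limited trees (the tree engine
#' is xgboost, constrained to `interaction_depth + 1` leaves, shrinkage
#' `learning_rate`, stochastic bagging `bag_fraction`, no regularisation).
#' Ensemble size is chosen the stagewise way: trees are considered in steps
#' of `step_size`; for every step the mean held-out squared-error deviance
#' across `cv_folds` folds is computed, the scan walks forward until the
#' deviance has failed to reach a new minimum for `plateau_steps`
#' consecutive steps, and the minimising step is selected. The final model
#' is refit on all rows with the selected tree count. The whole procedure
#' is deterministic for a given `seed`.
#'
#' Rows with missing covariate values are kept; a tree split on a variable
#' missing for a row routes that row along a learned default branch.
#' Categorical covariates (character or factor) are ordinally encoded.
#'
#' @param data modelling data.frame
#' @param response name of the (finite, numeric) response column
#' @param covariates names of predictor columns
#' @param hyperparams a [brt_hyperparams()]
#' @param seed integer seed controlling fold assignment and bagging
#' @return object of class `brt_model`: the fitted booster plus
#'   `n_trees_selected`, `cv_deviance_trace` (data.frame step/trees/mean
#'   held-out deviance), `cv_correlation` (Pearson r between out-of-fold
#'   predictions at the selected size and the response),
#'   `train_deviance_trace`, fold assignments and encodings
#' @export
fit_brt <- function(data, response, covariates,
                    hyperparams = brt_hyperparams(), seed = 1L) {
  stopifnot(inherits(hyperparams, "brt_hyperparams"),
            response %in% names(data), all(covariates %in% names(data)))
  hp <- hyperparams
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite response values in rows: ",
         paste(head(bad, 10), collapse = ", "))
  n <- length(y)
  if (n < 2 * hp$cv_folds)
    stop("need at least ", 2 * hp$cv_folds, " rows for ", hp$cv_folds,
         "-fold cross-validation (got ", n, ")")

  enc <- encode_covariates(data, covariates)
  x <- enc$matrix

  ## degenerate constant response: no tree can improve, predict the constant
  if (var(y) == 0) {
    return(structure(list(
      booster = NULL, constant = y[1], encodings = enc$encodings,
      covariates = covariates, response = response, hyperparams = hp,
      n_trees_selected = 0L, cv_deviance_trace = NULL,
      cv_correlation = NA_real_, train_deviance_trace = NULL,
      folds = NULL, seed = as.integer(seed), train_matrix = x, y = y),
      class = "brt_model"))
  }

  folds <- with_seed(derive_seed(seed, "brt-folds"),
                     sample(rep_len(seq_len(hp$cv_folds), n)))
  xparams <- brt_xgb_params(hp, seed, base_score = mean(y))

  nsteps_max <- floor(hp$max_trees / hp$step_size)
  fold_dev <- matrix(NA_real_, hp$cv_folds, nsteps_max)
  fold_models <- vector("list", hp$cv_folds)
  for (k in seq_len(hp$cv_folds)) {
    tr <- folds != k
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                   nthread = 1)
    dtest <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr],
                                  nthread = 1)
    bst <- xgboost::xgb.train(xparams, dtrain,
                              nrounds = nsteps_max * hp$step_size,
                              evals = list(test = dtest), verbose = 0)
    rmse <- attributes(bst)$evaluation_log$test_rmse
    fold_dev[k, ] <- rmse[seq_len(nsteps_max) * hp$step_size]^2
    fold_models[[k]] <- bst
  }
  cv_dev <- colMeans(fold_dev)

  ## forward stagewise scan with a plateau stop
  best <- Inf; best_step <- 0L; stale <- 0L; scanned <- 0L
  for (j in seq_len(nsteps_max)) {
    scanned <- j
    if (cv_dev[j] < best) {
      best <- cv_dev[j]; best_step <- j; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= hp$plateau_steps) break
    }
  }
  if (scanned == nsteps_max && best_step == nsteps_max)
    warning("held-out deviance still improving at max_trees = ",
            hp$max_trees, "; consider raising it")
  n_sel <- best_step * hp$step_size

  ## out-of-fold predictions at the selected size
  oof <- numeric(n)
  for (k in seq_len(hp$cv_folds)) {
    te <- folds == k
    oof[te] <- predict(fold_models[[k]], x[te, , drop = FALSE],
                       iterationrange = c(1, n_sel))
  }
  cv_correlation <- cor(oof, y)

  ## refit on all rows with the selected tree count
  dall <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  final <- xgboost::xgb.train(brt_xgb_params(hp, seed + 1L,
                                             base_score = mean(y)),
                              dall, nrounds = n_sel,
                              evals = list(train = dall), verbose = 0)
  train_rmse <- attributes(final)$evaluation_log$train_rmse
  steps <- seq_len(floor(n_sel / hp$step_size))

  structure(list(
    booster = final, constant = NULL, encodings = enc$encodings,
    covariates = covariates, response = response, hyperparams = hp,
    n_trees_selected = n_sel,
    cv_deviance_trace = data.frame(
      step = seq_len(scanned), n_trees = seq_len(scanned) * hp$step_size,
      cv_deviance = cv_dev[seq_len(scanned)]),
    cv_correlation = cv_correlation,
    oof_predictions = oof,
    train_deviance_trace = data.frame(
      step = steps, n_trees = steps * hp$step_size,
      train_deviance = train_rmse[steps * hp$step_size]^2),
    folds = folds, seed = as.integer(seed),
    train_matrix = x, y = y),
    class = "brt_model")
}

brt_xgb_params <- function(hp, seed, base_score) {
  xgboost::xgb.params(
    objective = "reg:squarederror",
    eta = hp$learning_rate,
    subsample = hp$bag_fraction,
    max_depth = 0, max_leaves = hp$interaction_depth + 1,
    grow_policy = "lossguide", tree_method = "hist",
    min_child_weight = hp$min_obs_node,
    reg_lambda = 0, reg_alpha = 0,
    colsample_bytree = 1, nthread = 1,
    seed = derive_seed(seed, "brt-bag"),
    base_score = base_score)
}

# ordinal encoding for character/factor covariates; numeric passed through
encode_covariates <- function(data, covariates, encodings = NULL) {
  cols <- list(); enc <- encodings %||% list()
  for (cv in covariates) {
    col <- data[[cv]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      lev <- if (!is.null(enc[[cv]])) enc[[cv]] else sort(unique(as.character(col)))
      enc[[cv]] <- lev
      cols[[cv]] <- as.numeric(match(as.character(col), lev)) - 1
    } else {
      cols[[cv]] <- as.numeric(col)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  list(matrix = m, encodings = enc)
}

#' @export
print.brt_model <- function(x, ...) {
  cat("brt_model:", x$n_trees_selected, "trees",
      sprintf("(lr %.4g, depth %d, bag %.2f, %d-fold CV)",
              x$hyperparams$learning_rate, x$hyperparams$interaction_depth,
              x$hyperparams$bag_fraction, x$hyperparams$cv_folds), "\n")
  if (!is.null(x$cv_correlation) && is.finite(x$cv_correlation))
    cat("cross-validation correlation:", round(x$cv_correlation, 3), "\n")
  invisible(x)
}

#' @export
predict.brt_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    x <- object$train_matrix
  } else if (is.matrix(newdata)) {
    x <- newdata
  } else {
    x <- encode_covariates(newdata, object$covariates,
                           object$encodings)$matrix
  }
  if (!is.null(object$constant)) return(rep(object$constant, nrow(x)))
  predict(object$booster, x)
}

#' Relative importance of covariates in a boosted model
#'
#' For every variable, the squared-error improvements of all splits on it
#' are summed over all trees and the totals are scaled so that the sum over
#' variables is 100. A variable never selected for splitting scores 0; a
#' model with no splits at all (e.g. fitted to a constant response) yields
#' an all-zero table with a warning.
#'
#' @param model a fitted [fit_brt()] model
#' @return data.frame (`covariate`, `relative_importance`, `rank`) sorted
#'   by rank; importances are non-negative and sum to 100
#' @export
relative_importance <- function(model) {
  stopifnot(inherits(model, "brt_model"))
  gains <- setNames(numeric(length(model$covariates)), model$covariates)
  if (is.null(model$booster) || model$n_trees_selected == 0L) {
    warning("model has no splits: all importances are zero")
  } else {
    tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
    sp <- tt[tt$Feature != "Leaf", , drop = FALSE]
    if (nrow(sp) == 0L) {
      warning("model has no splits: all importances are zero")
    } else {
      agg <- tapply(sp$Gain, sp$Feature, sum)
      gains[names(agg)] <- agg
      gains <- 100 * gains / sum(gains)
    }
  }
  ord <- order(-gains, seq_along(gains))
  out <- data.frame(covariate = names(gains)[ord],
                    relative_importance = as.numeric(gains[ord]),
                    rank = seq_along(gains), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Marginal (partial-dependence) response curve
#'
#' Average model prediction over the training rows with one covariate set
#' to each grid value — the marginal response of (log-scale) migration
#' traffic rate to that covariate. `transform = "response"` back-transforms
#' with `exp(x) - 1` to the MTR scale.
#'
#' @param model a fitted [fit_brt()] model
#' @param covariate covariate name
#' @param grid grid values (default: 50 points spanning the observed range;
#'   for categorical covariates, the observed levels)
#' @param n_grid grid resolution when `grid` is NULL
#' @param transform `"log"` (model scale, default) or `"response"`
#' @return data.frame (`covariate`, `value`, `response`) with attribute
#'   `extrapolated` flagging grid points outside the observed range
#' @export
marginal_response <- function(model, covariate, grid = NULL, n_grid = 50,
                              transform = c("log", "response")) {
  stopifnot(inherits(model, "brt_model"),
            covariate %in% model$covariates)
  transform <- match.arg(transform)
  x <- model$train_matrix
  obs <- x[, covariate]
  lev <- model$encodings[[covariate]]
  if (is.null(grid)) {
    grid_num <- if (!is.null(lev)) seq_along(lev) - 1
    else seq(min(obs, na.rm = TRUE), max(obs, na.rm = TRUE),
             length.out = n_grid)
  } else {
    grid_num <- if (!is.null(lev)) match(as.character(grid), lev) - 1
    else as.numeric(grid)
  }
  resp <- vapply(grid_num, function(g) {
    xg <- x
    xg[, covariate] <- g
    mean(predict(model, xg))
  }, numeric(1))
  if (transform == "response") resp <- exp(resp) - 1
  value <- if (!is.null(lev)) lev[grid_num + 1] else grid_num
  out <- data.frame(covariate = covariate, value = value, response = resp,
                    stringsAsFactors = FALSE)
  attr(out, "extrapolated") <-
    grid_num < min(obs, na.rm = TRUE) | grid_num > max(obs, na.rm = TRUE)
  out
}

#' The 15 standard modelling covariates
#'
#' Ten weather covariates (night means at 500 m above the radar, plus
#' night-over-night deltas), three geographic covariates, the ordinal date
#' and the radar-type corrective variable.
#'
#' @return character vector of column names
#' @export
brt_covariates <- function() {
  c("temperature", "u", "v", "relative_humidity", "vertical_velocity",
    "cloud_cover", "wind_speed", "d_temperature", "d_u", "d_v",
    "latitude", "longitude", "elevation", "ordinal_date", "radar_type")
}

#' Merge covariates and MTR into the modelling table
#'
#' One row per site-night: the 15 covariates joined with the night's
#' directional MTR, plus the model response `log_mtr = log(directional
#' MTR + 1)` (the +1 keeps zero nights finite and the log meets the
#' Gaussian error assumption).
#'
#' @param covariates covariate table ([season_covariates()] output)
#' @param mtr nightly MTR table ([mtr_profile()] rows)
#' @return merged data.frame with `log_mtr`
#' @export
modelling_table <- function(covariates, mtr) {
  m <- merge(covariates,
             mtr[c("site_id", "night_id", "n_echoes", "nightly_mtr",
                   "directional_proportion", "directional_mtr")],
             by = c("site_id", "night_id"), all.x = TRUE)
  m <- m[order(m$site_id, m$night_id), , drop = FALSE]
  m$directional_mtr[is.na(m$directional_mtr)] <- 0
  m$log_mtr <- log(m$directional_mtr + 1)
  rownames(m) <- NULL
  m
}
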