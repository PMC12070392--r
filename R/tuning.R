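#' Cross-validation configuration
#'
#' Settings for repeated k-fold cross-validation over a penalty grid. The
#' default — 5 folds repeated 10 times — trains on 80% of the samples of
#' each condition and evaluates the relative reconstruction error on the
#' held-out 20%.
#'
#' @param n_folds Folds per repeat (>= 2; default 5).
#' @param n_repeats Repeats (default 10).
#' @param lambda1_grid,lambda2_grid Sorted positive penalty grids.
#' @param search_mode `"grid2d"` (full grid) or `"sequential"` (choose
#'   lambda1 first with lambda2 fixed at its grid minimum, then scan
#'   lambda2 at the chosen lambda1).
#' @param seed Master seed for fold assignment.
#' @return A list of class `ddn_cv_config`.
#' @export
cv_config <- function(n_folds = 5, n_repeats = 10,
                      lambda1_grid, lambda2_grid,
                      search_mode = c("grid2d", "sequential"),
                      seed = 1L) {
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  if (missing(lambda1_grid) || length(lambda1_grid) == 0 ||
      missing(lambda2_grid) || length(lambda2_grid) == 0)
    stop("lambda grids must be nonempty")
  if (any(lambda1_grid < 0) || any(lambda2_grid < 0))
    stop("lambda grids must be nonnegative")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 lambda1_grid = sort(unique(as.numeric(lambda1_grid))),
                 lambda2_grid = sort(unique(as.numeric(lambda2_grid))),
                 search_mode = match.arg(search_mode),
                 seed = as.integer(seed)),
            class = "ddn_cv_config")
}

# OLS re-estimation on the selected support, no intercept, rank-safe.
ols_refit <- function(x, y, support) {
  if (length(support) == 0) return(numeric(0))
  fit <- stats::lm.fit(x[, support, drop = FALSE], y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

#' Relative reconstruction error of a penalty pair
#'
#' The cross-validation criterion: fit the fused-Lasso model on the
#' training split, binarize each node's selected predictor set, re-fit
#' plain least squares on the selected predictors (removing the shrinkage
#' bias of lambda1), and predict each node of the test split from its
#' selected predictors. The error for node i under condition c is
#' `var(x_est - x_truth) / var(x_truth)` on the test samples; the returned
#' value averages over all nodes and both conditions. A node with an empty
#' selected set predicts 0, contributing error 1.
#'
#' Test data are standardized with the training-split parameters (no
#' leakage); the model is fit on the standardized training split.
#'
#' @param train,test [ddn_data] objects over the same features (raw;
#'   standardization is handled internally).
#' @param spec A [ddn_spec] carrying the allowed structure.
#' @param lambda1,lambda2 Scalar penalties applied uniformly.
#' @param tol,max_sweeps Solver controls.
#' @param warm Optional warm-start fit.
#' @return Scalar mean relative error (attribute `"fit"` carries the
#'   training fit for warm starting).
#' @export
cv_relative_error <- function(train, test, spec, lambda1, lambda2,
                              tol = 1e-6, max_sweeps = 100000L,
                              warm = NULL) {
  stopifnot(inherits(train, "ddn_data"), inherits(test, "ddn_data"))
  if (!identical(train$feature_ids, test$feature_ids))
    stop("train and test must share the same features")
  par1 <- standardize_params(train$x1)
  par2 <- standardize_params(train$x2)
  if (any(par1$scale == 0) || any(par2$scale == 0))
    stop("zero-variance feature in a training split")
  tr <- train
  tr$x1 <- sweep(sweep(train$x1, 2, par1$center, "-"), 2, par1$scale, "/")
  tr$x2 <- sweep(sweep(train$x2, 2, par2$center, "-"), 2, par2$scale, "/")
  tr$standardized <- TRUE
  te1 <- apply_standardization(test$x1, par1)
  te2 <- apply_standardization(test$x2, par2)

  fit <- ddn_fit(tr, set_penalties(spec, lambda1, lambda2),
                 tol = tol, max_sweeps = max_sweeps, beta_init = warm)
  errs <- c()
  for (cnd in 1:2) {
    beta <- if (cnd == 1) fit$beta1 else fit$beta2
    xtr <- if (cnd == 1) tr$x1 else tr$x2
    xte <- if (cnd == 1) te1 else te2
    for (i in seq_len(train$p)) {
      truthv <- xte[, i]
      if (stats::var(truthv) == 0) {
        warning("zero-variance test node skipped: ",
                train$feature_ids[i], " (condition ", cnd, ")")
        next
      }
      support <- which(beta[i, ] != 0)
      est <- if (length(support) == 0) rep(0, nrow(xte))
             else xte[, support, drop = FALSE] %*%
                  ols_refit(xtr, xtr[, i], support)
      errs <- c(errs, stats::var(as.numeric(est) - truthv) /
                        stats::var(truthv))
    }
  }
  structure(mean(errs), fit = fit)
}

# Fold assignment per condition: seeded permutation cut into k balanced
# folds.
fold_ids <- function(n, k, seed) {
  if (floor(n / k) < 2) stop("fold size below 2; reduce n_folds")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Repeated cross-validation over a penalty grid
#'
#' For each repeat, partitions the samples of each condition into
#' `n_folds` folds (seeded, per condition); every fold serves once as the
#' test split while the remaining folds train the model. The per-cell
#' error surface is the mean of [cv_relative_error()] over all
#' `n_repeats * n_folds` splits, with a standard error per cell. Two
#' selections are returned: the minimum-error pair, and the
#' one-standard-error pair — the most-penalized pair (largest lambda1,
#' then largest lambda2, among pairs componentwise >= the minimizer) whose
#' error is within one standard error of the minimum.
#'
#' Averaging order is fixed: nodes and conditions inside
#' [cv_relative_error()], then folds, then repeats.
#'
#' @param data A [ddn_data] (raw or standardized; splits are
#'   re-standardized per fold).
#' @param spec A [ddn_spec].
#' @param config A [cv_config()].
#' @param tol,max_sweeps Solver controls.
#' @return An object of class `ddn_cv`: matrices `error_surface` and
#'   `error_se` (lambda1 in rows, lambda2 in columns; `NA` for cells not
#'   visited in sequential mode), `chosen_min` and `chosen_1se` (named
#'   numeric pairs), the config, and `errors` (per-split error array).
#' @export
run_cv <- function(data, spec, config, tol = 1e-6, max_sweeps = 100000L) {
  stopifnot(inherits(data, "ddn_data"), inherits(spec, "ddn_spec"),
            inherits(config, "ddn_cv_config"))
  check_spec_data(spec, data)
  l1s <- config$lambda1_grid; l2s <- config$lambda2_grid
  cells <- if (config$search_mode == "grid2d") {
    expand.grid(i = seq_along(l1s), j = seq_along(l2s))
  } else {
    data.frame(i = seq_along(l1s), j = 1L)   # lambda1 scan at min lambda2
  }
  n_splits <- config$n_repeats * config$n_folds
  err <- array(NA_real_, c(length(l1s), length(l2s), n_splits))
  seeds <- derive_seeds(config$seed, 2L * config$n_repeats)

  split_errors <- function(cells, err) {
    s <- 0L
    for (r in seq_len(config$n_repeats)) {
      f1 <- fold_ids(data$n1, config$n_folds, seeds[2 * r - 1])
      f2 <- fold_ids(data$n2, config$n_folds, seeds[2 * r])
      for (k in seq_len(config$n_folds)) {
        s <- s + 1L
        train <- ddn_data(data$x1[f1 != k, , drop = FALSE],
                          data$x2[f2 != k, , drop = FALSE],
                          data$feature_ids)
        test <- ddn_data(data$x1[f1 == k, , drop = FALSE],
                         data$x2[f2 == k, , drop = FALSE],
                         data$feature_ids)
        # warm start along descending lambda1 within each lambda2 column
        for (j in unique(cells$j)) {
          warm <- NULL
          for (i in rev(sort(unique(cells$i[cells$j == j])))) {
            e <- cv_relative_error(train, test, spec, l1s[i], l2s[j],
                                   tol = tol, max_sweeps = max_sweeps,
                                   warm = warm)
            warm <- attr(e, "fit")
            err[i, j, s] <- as.numeric(e)
          }
        }
      }
    }
    err
  }
  err <- split_errors(cells, err)
  surf <- apply(err, c(1, 2), mean)
  se <- apply(err, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else stats::sd(v) / sqrt(sum(!is.na(v))))

  pick <- function(surf, se, rows, cols) {
    sub <- surf[rows, cols, drop = FALSE]
    best <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)
    # ties toward larger penalties
    best <- best[order(-best[, 1], -best[, 2]), , drop = FALSE][1, ]
    imin <- unname(rows[best[1]]); jmin <- unname(cols[best[2]])
    thr <- surf[imin, jmin] + se[imin, jmin]
    ok <- which(!is.na(surf) & surf <= thr, arr.ind = TRUE)
    ok <- ok[ok[, 1] >= imin & ok[, 2] >= jmin &
               ok[, 1] %in% rows & ok[, 2] %in% cols, , drop = FALSE]
    ok <- ok[order(-ok[, 1], -ok[, 2]), , drop = FALSE]
    list(min = c(i = imin, j = jmin),
         ose = c(i = unname(ok[1, 1]), j = unname(ok[1, 2])))
  }

  if (config$search_mode == "grid2d") {
    sel <- pick(surf, se, seq_along(l1s), seq_along(l2s))
  } else {
    # stage 1: lambda1 at the smallest lambda2
    s1 <- pick(surf, se, seq_along(l1s), 1L)
    i_min <- s1$min[["i"]]; i_1se <- s1$ose[["i"]]
    # stage 2: lambda2 scan at each chosen lambda1
    scan2 <- function(i) {
      cells2 <- data.frame(i = i, j = seq_along(l2s))
      err <<- split_errors(cells2, err)
      invisible(NULL)
    }
    scan2(i_min)
    if (i_1se != i_min) scan2(i_1se)
    surf <- apply(err, c(1, 2), mean)
    se <- apply(err, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else stats::sd(v) / sqrt(sum(!is.na(v))))
    s2min <- pick(surf, se, i_min, seq_along(l2s))
    # keep the 1-SE pair componentwise >= the minimum-error pair
    s2ose <- pick(surf, se, i_1se,
                  seq.int(s2min$min[["j"]], length(l2s)))
    sel <- list(min = c(i = i_min, j = s2min$min[["j"]]),
                ose = c(i = i_1se, j = s2ose$ose[["j"]]))
  }
  out <- list(error_surface = surf, error_se = se,
              chosen_min = c(lambda1 = l1s[sel$min[["i"]]],
                             lambda2 = l2s[sel$min[["j"]]]),
              chosen_1se = c(lambda1 = l1s[sel$ose[["i"]]],
                             lambda2 = l2s[sel$ose[["j"]]]),
              errors = err, config = config,
              lambda1_grid = l1s, lambda2_grid = l2s)
  class(out) <- "ddn_cv"
  out
}

#' @export
print.ddn_cv <- function(x, ...) {
  cat(sprintf(
    "Repeated CV (%d-fold x %d, %s search)\n  min error %.4f at lambda1=%.4g lambda2=%.4g\n  1-SE pair at lambda1=%.4g lambda2=%.4g\n",
    x$config$n_folds, x$config$n_repeats, x$config$search_mode,
    min(x$error_surface, na.rm = TRUE),
    x$chosen_min["lambda1"], x$chosen_min["lambda2"],
    x$chosen_1se["lambda1"], x$chosen_1se["lambda2"]))
  invisible(x)
}
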