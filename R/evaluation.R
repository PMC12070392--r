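#' Candidate pair universe of a specification
#'
#' The set of unordered node pairs over which edge recovery is scored: all
#' pairs with at least one allowed predictor direction, optionally
#' restricted to pairs whose endpoints both lie in the given layers. Pairs
#' excluded by constraints are not counted as true negatives, which would
#' otherwise inflate specificity.
#'
#' @param spec A [ddn_spec].
#' @param annotation Optional [layer_annotation()] (required if `layers`
#'   is given).
#' @param layers Optional layer names restricting the universe.
#' @return Two-column edge index matrix.
#' @export
pair_universe <- function(spec, annotation = NULL, layers = NULL) {
  cand <- spec$allowed | t(spec$allowed)
  if (!is.null(layers)) {
    if (is.null(annotation)) stop("layer restriction needs an annotation")
    keep <- annotation$layer %in% layers
    cand[!keep, ] <- FALSE
    cand[, !keep] <- FALSE
  }
  idx <- which(upper.tri(cand) & cand, arr.ind = TRUE)
  as_edge_matrix(idx)
}

confusion <- function(pred_keys, true_keys, universe_keys) {
  pred <- intersect(pred_keys, universe_keys)
  truth <- intersect(true_keys, universe_keys)
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  tn <- length(universe_keys) - tp - fp - fn
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1,
       fpr = if (fp + tn == 0) 0 else fp / (fp + tn),
       tpr = recall)
}

#' Score inferred networks against ground truth
#'
#' Compares the predicted common and differential edge sets with the true
#' ones inside a fixed candidate universe. The common network is scored as
#' predicted-common vs the intersection of the two condition truth graphs;
#' the differential network as predicted-differential vs their symmetric
#' difference. By default differential edges are compared at the pair
#' level, ignoring which condition they belong to; `strict_condition =
#' TRUE` additionally requires the predicted condition label to match the
#' condition in which the true edge is present.
#'
#' @param predicted A `ddn_networks` from [extract_networks()].
#' @param truth Either a `ddn_scenario` or a list with edge matrices
#'   `common` and `differential` (and, for strict mode, `cond1`/`cond2`).
#' @param universe Two-column edge matrix of candidate pairs (e.g.
#'   [pair_universe()]). Must be nonempty; truth and predictions are
#'   restricted to it.
#' @param strict_condition Match differential condition labels
#'   (default `FALSE`).
#' @return An object of class `ddn_eval`: per-network confusion counts and
#'   precision/recall/F1 (`common`, `differential`), plus `f1_common`,
#'   `f1_differential`, `f1_average` and `candidate_universe_size`.
#' @export
score_networks <- function(predicted, truth, universe,
                           strict_condition = FALSE) {
  uni <- edge_keys(universe)
  if (length(uni) == 0) stop("empty candidate universe")
  if (inherits(truth, "ddn_scenario"))
    truth <- list(common = truth$common_edges,
                  differential = truth$differential_edges,
                  cond1 = truth$cond1_edges, cond2 = truth$cond2_edges)
  pred <- network_edge_sets(predicted)
  common <- confusion(edge_keys(pred$common), edge_keys(truth$common), uni)
  if (!strict_condition) {
    differential <- confusion(edge_keys(pred$differential),
                              edge_keys(truth$differential), uni)
  } else {
    # label-aware: an edge only in condition c must be predicted in c
    tagged <- function(e1, e2) c(paste0("1:", edge_keys(e1)),
                                 paste0("2:", edge_keys(e2)))
    true_d1 <- keys_to_edges(setdiff(edge_keys(truth$cond1),
                                     edge_keys(truth$cond2)))
    true_d2 <- keys_to_edges(setdiff(edge_keys(truth$cond2),
                                     edge_keys(truth$cond1)))
    uni_t <- c(paste0("1:", uni), paste0("2:", uni))
    differential <- confusion(
      tagged(pred$differential_by_cond$cond1,
             pred$differential_by_cond$cond2),
      tagged(true_d1, true_d2), uni_t)
  }
  out <- list(common = common, differential = differential,
              f1_common = common$f1,
              f1_differential = differential$f1,
              f1_average = (common$f1 + differential$f1) / 2,
              candidate_universe_size = length(uni),
              strict_condition = strict_condition)
  class(out) <- "ddn_eval"
  out
}

#' @export
print.ddn_eval <- function(x, ...) {
  cat(sprintf(
    "Edge recovery over %d candidate pairs\n  common:       P=%.3f R=%.3f F1=%.3f\n  differential: P=%.3f R=%.3f F1=%.3f\n  average F1:   %.3f\n",
    x$candidate_universe_size,
    x$common$precision, x$common$recall, x$f1_common,
    x$differential$precision, x$differential$recall, x$f1_differential,
    x$f1_average))
  invisible(x)
}

#' Normalized partial area under an ROC curve
#'
#' Integrates the ROC curve by the trapezoid rule over the false positive
#' rate interval `[0, fpr_cutoff]` (with `(0, 0)` prepended and linear
#' interpolation at the cutoff) and divides by the cutoff, so a perfect
#' classifier scores 1 and a random one (TPR = FPR) scores `fpr_cutoff/2`.
#' If the curve ends before the cutoff the last TPR is carried forward.
#'
#' @param fpr,tpr Numeric vectors of operating points (any order;
#'   duplicated points are harmless).
#' @param fpr_cutoff Cutoff in (0, 1] (default 0.1).
#' @return Normalized partial AUC in \[0, 1\].
#' @export
pauc <- function(fpr, tpr, fpr_cutoff = 0.1) {
  if (fpr_cutoff <= 0 || fpr_cutoff > 1)
    stop("fpr_cutoff must be in (0, 1]")
  if (length(fpr) != length(tpr)) stop("fpr and tpr lengths differ")
  o <- order(fpr, tpr)
  x <- c(0, fpr[o]); y <- c(0, tpr[o])
  if (max(x) < fpr_cutoff) { x <- c(x, fpr_cutoff); y <- c(y, y[length(y)]) }
  area <- 0
  for (k in seq_len(length(x) - 1)) {
    x0 <- x[k]; x1 <- x[k + 1]
    if (x0 >= fpr_cutoff) break
    y0 <- y[k]; y1 <- y[k + 1]
    if (x1 > fpr_cutoff) {  # interpolate at the cutoff
      y1 <- y0 + (y1 - y0) * (fpr_cutoff - x0) / (x1 - x0)
      x1 <- fpr_cutoff
    }
    area <- area + 0.5 * (y0 + y1) * (x1 - x0)
  }
  area / fpr_cutoff
}

#' Hyperparameter sweep with per-lambda1 best-lambda2 selection
#'
#' Fits the model at every `(lambda1, lambda2)` grid pair (warm-started
#' along descending lambda1 within each lambda2), scores each fit against
#' the truth, and for each lambda1 reports the lambda2 maximizing the
#' selected F1 (ties broken toward larger lambda2, the sparser
#' difference). The common-network `(FPR, TPR)` of the selected pair gives
#' one operating point of the partial ROC curve.
#'
#' @inheritParams ddn_fit
#' @param truth A `ddn_scenario` or truth list (see [score_networks()]).
#' @param lambda1_grid,lambda2_grid Positive penalty grids (see
#'   [default_lambda_grids()] for the 640-combination default).
#' @param universe Candidate pair universe for scoring.
#' @param select Which F1 drives the per-lambda1 choice: `"differential"`,
#'   `"common"` or `"average"`.
#' @param strict_condition Passed to [score_networks()].
#' @return Data frame, one row per lambda1: `lambda1`, `lambda2` (the
#'   selected one), `f1_common`, `f1_differential`, `f1_average`,
#'   `fpr_common`, `tpr_common`.
#' @export
sweep_lambdas <- function(data, spec, truth, lambda1_grid, lambda2_grid,
                          universe, select = c("differential", "common",
                                               "average"),
                          strict_condition = FALSE,
                          tol = 1e-6, max_sweeps = 100000L) {
  select <- match.arg(select)
  if (length(lambda1_grid) == 0 || length(lambda2_grid) == 0)
    stop("lambda grids must be nonempty")
  if (!data$standardized) data <- standardize(data)
  l1s <- sort(unique(lambda1_grid), decreasing = TRUE)
  l2s <- sort(unique(lambda2_grid))
  key <- switch(select, differential = "f1_differential",
                common = "f1_common", average = "f1_average")
  rows <- vector("list", length(l1s))
  scores <- array(list(), c(length(l1s), length(l2s)))
  for (j in seq_along(l2s)) {
    warm <- NULL
    for (i in seq_along(l1s)) {
      sp <- set_penalties(spec, l1s[i], l2s[j])
      fit <- ddn_fit(data, sp, tol = tol, max_sweeps = max_sweeps,
                     beta_init = warm)
      warm <- fit
      net <- extract_networks(fit)
      scores[[i, j]] <- score_networks(net, truth, universe,
                                       strict_condition)
    }
  }
  out <- lapply(seq_along(l1s), function(i) {
    f1s <- vapply(seq_along(l2s), function(j) scores[[i, j]][[key]],
                  numeric(1))
    best <- max(which(f1s == max(f1s)))      # tie -> larger lambda2
    sc <- scores[[i, best]]
    data.frame(lambda1 = l1s[i], lambda2 = l2s[best],
               f1_common = sc$f1_common,
               f1_differential = sc$f1_differential,
               f1_average = sc$f1_average,
               fpr_common = sc$common$fpr,
               tpr_common = sc$common$tpr)
  })
  res <- do.call(rbind, out)
  res[order(res$lambda1), , drop = FALSE]
}

#' Default penalty grids
#'
#' The default sweep evaluates 640 penalty combinations, factorized as 32
#' log-spaced lambda1 values in \[0.02, 1\] times 20 log-spaced lambda2
#' values in \[0.001, 0.5\].
#'
#' @param n_lambda1,n_lambda2 Grid sizes (default 32 and 20).
#' @param lambda1_range,lambda2_range Ranges.
#' @return List with numeric vectors `lambda1` and `lambda2`.
#' @export
default_lambda_grids <- function(n_lambda1 = 32, n_lambda2 = 20,
                                 lambda1_range = c(0.02, 1),
                                 lambda2_range = c(0.001, 0.5)) {
  lg <- function(r, n) exp(seq(log(r[1]), log(r[2]), length.out = n))
  list(lambda1 = lg(lambda1_range, n_lambda1),
       lambda2 = lg(lambda2_range, n_lambda2))
}
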