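#' Two-condition dataset
#'
#' Bundles the paired data matrices of the two biological conditions. Both
#' matrices are samples x features with an identical feature set in
#' identical order. Columns with zero variance in either condition are
#' rejected: on standardized data they carry no usable signal and break the
#' unit-variance convention the solver relies on.
#'
#' @param x1,x2 Numeric matrices, samples in rows and features in columns
#'   (N1 x p and N2 x p). All entries must be finite.
#' @param feature_ids Character vector of p unique feature identifiers.
#'   Defaults to the common column names of `x1`/`x2`.
#' @param standardized Logical; mark the data as already standardized
#'   (mean 0, unit population variance per column per condition). Checked.
#' @return An object of class `ddn_data`: a list with elements `x1`, `x2`,
#'   `feature_ids`, `n1`, `n2`, `p` and a `standardized` flag.
#' @seealso [standardize()]
#' @export
ddn_data <- function(x1, x2, feature_ids = NULL, standardized = FALSE) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (!is.numeric(x1) || !is.numeric(x2))
    stop("data matrices must be numeric")
  if (ncol(x1) != ncol(x2))
    stop("conditions have different feature counts: ",
         ncol(x1), " vs ", ncol(x2))
  if (is.null(feature_ids)) feature_ids <- colnames(x1)
  if (is.null(feature_ids))
    feature_ids <- paste0("V", seq_len(ncol(x1)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(x1))
    stop("feature_ids length does not match feature count")
  if (anyDuplicated(feature_ids))
    stop("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (!is.null(colnames(x2)) && !is.null(colnames(x1)) &&
      !identical(colnames(x1), colnames(x2)))
    stop("feature ordering differs between conditions")
  for (cnd in 1:2) {
    x <- if (cnd == 1) x1 else x2
    if (any(!is.finite(x)))
      stop("non-finite entries in condition ", cnd,
           "; impute or filter upstream")
    v <- apply(x, 2, function(col) sum((col - mean(col))^2))
    if (any(v == 0))
      stop("zero-variance feature(s) in condition ", cnd, ": ",
           paste(feature_ids[v == 0], collapse = ", "))
  }
  colnames(x1) <- colnames(x2) <- feature_ids
  obj <- list(x1 = x1, x2 = x2, feature_ids = feature_ids,
              n1 = nrow(x1), n2 = nrow(x2), p = ncol(x1),
              standardized = isTRUE(standardized))
  class(obj) <- "ddn_data"
  if (obj$standardized) check_standardized(obj)
  obj
}

check_standardized <- function(data, tol = 1e-8) {
  for (cnd in 1:2) {
    x <- if (cnd == 1) data$x1 else data$x2
    m <- colMeans(x)
    s <- colMeans(x^2) - m^2
    if (max(abs(m)) > tol || max(abs(s - 1)) > tol)
      stop("data marked standardized but columns are not ",
           "mean-0 / unit-variance")
  }
  invisible(TRUE)
}

#' Standardize a two-condition dataset
#'
#' Centers every feature and scales it to unit variance separately within
#' each condition. The variance divisor is the sample count N (population
#' convention), so that `(1/Nc) * ||column||^2 = 1` exactly; this makes the
#' quadratic coefficient of the solver's reduced per-pair objective exactly
#' one, which the closed-form coordinate update assumes. The operation is
#' idempotent.
#'
#' @param data A [ddn_data] object.
#' @param ... Unused.
#' @return A standardized `ddn_data` object (`standardized = TRUE`).
#' @export
standardize <- function(data, ...) UseMethod("standardize")

#' @rdname standardize
#' @export
standardize.ddn_data <- function(data, ...) {
  data$x1 <- standardize_matrix(data$x1, data$feature_ids, "condition 1")
  data$x2 <- standardize_matrix(data$x2, data$feature_ids, "condition 2")
  data$standardized <- TRUE
  data
}

# Center and scale columns with the population (divisor-N) convention.
standardize_matrix <- function(x, ids = colnames(x), label = "data") {
  m <- colMeans(x)
  x <- sweep(x, 2, m, "-")
  s <- sqrt(colMeans(x^2))
  if (any(s == 0))
    stop("zero-variance feature(s) in ", label, ": ",
         paste(ids[s == 0], collapse = ", "))
  sweep(x, 2, s, "/")
}

# Standardization parameters of a matrix, for train->test transfer in CV.
standardize_params <- function(x) {
  m <- colMeans(x)
  list(center = m, scale = sqrt(colMeans(sweep(x, 2, m, "-")^2)))
}

apply_standardization <- function(x, par) {
  sweep(sweep(x, 2, par$center, "-"), 2, par$scale, "/")
}

#' @export
print.ddn_data <- function(x, ...) {
  cat("Two-condition dataset: p =", x$p, "features;",
      "N1 =", x$n1, ", N2 =", x$n2, "samples;",
      if (x$standardized) "standardized" else "raw", "\n")
  invisible(x)
}
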