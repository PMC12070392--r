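#' Allowed-predictor structure and per-edge penalties
#'
#' A dependency specification fixes, for every node i, the set of nodes
#' allowed as predictors of i (the allowed set A(i)), together with per-edge
#' sparsity penalties lambda1(i, j) and per-edge cross-condition similarity
#' penalties lambda2(i, j). Entry `allowed[i, j]` is `TRUE` iff node j may
#' predict node i; the matrix need not be symmetric, which encodes
#' directional regulator-to-effector priors. The diagonal is always
#' `FALSE`: self-regulation is not modeled.
#'
#' @param allowed A p x p logical matrix, or a single integer p (meaning
#'   all-allowed off-diagonal, the unconstrained behavior).
#' @param lambda1,lambda2 Nonnegative penalties; scalars are expanded to
#'   p x p matrices. Entries where `allowed` is `FALSE` are ignored by the
#'   solver.
#' @param feature_ids Optional feature identifiers (length p).
#' @return An object of class `ddn_spec` with elements `allowed`,
#'   `lambda1`, `lambda2`, `p`, `feature_ids`.
#' @export
ddn_spec <- function(allowed, lambda1 = 0, lambda2 = 0, feature_ids = NULL) {
  if (is.numeric(allowed) && length(allowed) == 1) {
    p <- as.integer(allowed)
    allowed <- matrix(TRUE, p, p)
  }
  allowed <- as.matrix(allowed)
  if (!is.logical(allowed)) storage.mode(allowed) <- "logical"
  p <- nrow(allowed)
  if (ncol(allowed) != p) stop("allowed must be square")
  diag(allowed) <- FALSE
  expand <- function(lam, name) {
    if (length(lam) == 1) lam <- matrix(as.numeric(lam), p, p)
    lam <- as.matrix(lam)
    if (!all(dim(lam) == c(p, p)))
      stop(name, " must be a scalar or a ", p, " x ", p, " matrix")
    if (any(!is.finite(lam)) || any(lam < 0))
      stop(name, " entries must be finite and nonnegative")
    unname(lam)
  }
  if (is.null(feature_ids)) feature_ids <- rownames(allowed)
  obj <- list(allowed = unname(allowed),
              lambda1 = expand(lambda1, "lambda1"),
              lambda2 = expand(lambda2, "lambda2"),
              p = p,
              feature_ids = if (is.null(feature_ids)) NULL
                            else as.character(feature_ids))
  class(obj) <- "ddn_spec"
  obj
}

#' Set uniform penalties on an existing specification
#'
#' Convenience for hyperparameter sweeps: returns the same allowed
#' structure with scalar penalties `lambda1`, `lambda2` applied everywhere.
#'
#' @param spec A [ddn_spec].
#' @param lambda1,lambda2 Nonnegative scalars.
#' @return A `ddn_spec`.
#' @export
set_penalties <- function(spec, lambda1, lambda2) {
  stopifnot(inherits(spec, "ddn_spec"))
  ddn_spec(spec$allowed, lambda1, lambda2, spec$feature_ids)
}

#' @export
print.ddn_spec <- function(x, ...) {
  cat("Dependency spec: p =", x$p, "nodes;",
      sum(x$allowed), "allowed directed predictor slots\n")
  invisible(x)
}

check_spec_data <- function(spec, data) {
  if (spec$p != data$p)
    stop("spec has p = ", spec$p, " but data has p = ", data$p)
  invisible(TRUE)
}
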