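#' Closed-form minimizer of the reduced per-pair objective
#'
#' At each block coordinate descent step the objective restricted to one
#' coefficient pair (a, b) — the same candidate edge under the two
#' conditions — reduces (constants dropped, unit-variance standardization)
#' to
#' \deqn{g(a,b) = a^2 - 2\rho_1 a + b^2 - 2\rho_2 b +
#'   \lambda_1(|a|+|b|) + \lambda_2|a-b|,}
#' where \eqn{\rho_c = (1/N_c)\langle x_j^{(c)}, y_{res}^{(c)}\rangle} is
#' the per-condition inner product of the predictor with the current
#' partial residual. `pairwise_update()` returns the exact global minimizer
#' by closed-form case analysis: the strictly convex piecewise-quadratic
#' objective attains its unique minimum at the stationary point of one of
#' the finitely many sign-pattern regions (origin; fused a = b; one
#' coefficient zero; interior orthants), all of which have closed forms.
#' Ties between regions resolve toward the sparser, then the fused,
#' solution.
#'
#' @param rho1,rho2 Finite per-condition inner products.
#' @param lambda1 Nonnegative sparsity penalty for this edge.
#' @param lambda2 Nonnegative cross-condition similarity penalty.
#' @return Numeric vector `c(a, b)`, the minimizer.
#' @examples
#' pairwise_update(1, -0.4, 0.2, 0)   # separable soft-thresholding
#' pairwise_update(1, 0.5, 0, 1)      # fused: both (rho1 + rho2) / 2
#' @export
pairwise_update <- function(rho1, rho2, lambda1, lambda2) {
  if (!all(is.finite(c(rho1, rho2, lambda1, lambda2))))
    stop("pairwise_update inputs must be finite")
  if (lambda1 < 0 || lambda2 < 0)
    stop("penalties must be nonnegative")
  ddn_pairwise_update_cpp(rho1, rho2, lambda1, lambda2)
}

#' Solve the fused-Lasso regression for a single node
#'
#' Runs cyclic block coordinate descent for node `node`: its observations
#' under each condition are regressed on its allowed predictors A(node),
#' with per-edge L1 penalties on both conditions' coefficients and on their
#' difference. Predictors are visited in ascending index order; each visit
#' applies the exact closed-form [pairwise_update()]. A sweep ends after
#' all of A(node) is visited; iteration stops when the mean absolute
#' coefficient change over the `2 * |A(node)|` coefficients in a sweep
#' drops below `tol`, or at `max_sweeps` (then `converged = FALSE`).
#'
#' @param data A standardized [ddn_data].
#' @param node Node index in `1:p`.
#' @param spec A [ddn_spec] with matching p.
#' @param beta_init Optional warm start: list of two numeric vectors of
#'   length p (condition-1 and condition-2 coefficients).
#' @param tol Convergence threshold on the mean absolute per-sweep change
#'   (default 1e-6).
#' @param max_sweeps Sweep cap (default 100000).
#' @return List with `beta1`, `beta2` (length-p vectors, zero outside
#'   A(node)), `sweeps`, `converged`.
#' @export
solve_node <- function(data, node, spec, beta_init = NULL,
                       tol = 1e-6, max_sweeps = 100000L) {
  stopifnot(inherits(data, "ddn_data"), inherits(spec, "ddn_spec"))
  check_spec_data(spec, data)
  if (!data$standardized)
    stop("dataset must be standardized (see standardize())")
  node <- as.integer(node)
  if (node < 1 || node > data$p) stop("node index out of range")
  active <- which(spec$allowed[node, ])
  b1 <- numeric(length(active)); b2 <- numeric(length(active))
  if (!is.null(beta_init)) {
    b1 <- beta_init[[1]][active]
    b2 <- beta_init[[2]][active]
  }
  res <- ddn_solve_node_cpp(data$x1, data$x2,
                            data$x1[, node], data$x2[, node],
                            active - 1L,
                            spec$lambda1[node, active],
                            spec$lambda2[node, active],
                            b1, b2, tol, as.integer(max_sweeps))
  beta1 <- numeric(data$p); beta2 <- numeric(data$p)
  beta1[active] <- res$beta1
  beta2[active] <- res$beta2
  list(beta1 = beta1, beta2 = beta2,
       sweeps = res$sweeps, converged = res$converged)
}

#' Fit the joint two-condition network model
#'
#' Solves the per-node fused-Lasso regression independently for every node
#' (the node problems are embarrassingly parallel) and assembles the
#' coefficient matrices. Results are identical for any worker count.
#'
#' @inheritParams solve_node
#' @param n_workers Number of forked workers (`parallel::mclapply`); the
#'   node problems are independent so the result does not depend on this.
#' @param beta_init Optional warm start: list with p x p matrices `beta1`,
#'   `beta2` (e.g. a previous fit at a larger lambda1).
#' @return An object of class `ddn_fit`: p x p coefficient matrices
#'   `beta1`, `beta2` (row i = regression of node i; entries outside the
#'   allowed structure are zero), integer vector `sweeps`, logical vector
#'   `converged`, and the `spec` used.
#' @export
ddn_fit <- function(data, spec, tol = 1e-6, max_sweeps = 100000L,
                    n_workers = 1L, beta_init = NULL) {
  stopifnot(inherits(data, "ddn_data"), inherits(spec, "ddn_spec"))
  check_spec_data(spec, data)
  if (!data$standardized)
    stop("dataset must be standardized (see standardize())")
  p <- data$p
  one <- function(i) {
    init <- if (is.null(beta_init)) NULL
            else list(beta_init$beta1[i, ], beta_init$beta2[i, ])
    solve_node(data, i, spec, beta_init = init,
               tol = tol, max_sweeps = max_sweeps)
  }
  fits <- if (n_workers > 1L)
    parallel::mclapply(seq_len(p), one, mc.cores = n_workers)
  else lapply(seq_len(p), one)
  beta1 <- do.call(rbind, lapply(fits, `[[`, "beta1"))
  beta2 <- do.call(rbind, lapply(fits, `[[`, "beta2"))
  dimnames(beta1) <- dimnames(beta2) <-
    list(data$feature_ids, data$feature_ids)
  out <- list(beta1 = beta1, beta2 = beta2,
              sweeps = vapply(fits, `[[`, integer(1), "sweeps"),
              converged = vapply(fits, `[[`, logical(1), "converged"),
              spec = spec, feature_ids = data$feature_ids)
  class(out) <- "ddn_fit"
  out
}

#' Per-node objective value
#'
#' Value of the node-wise convex objective (data term with 1/Nc scaling,
#' per-edge L1 sparsity, per-edge fused difference penalty) at given
#' coefficient vectors. Used to verify descent and optimality.
#'
#' @inheritParams solve_node
#' @param beta1,beta2 Length-p coefficient vectors for `node`.
#' @return Scalar objective value.
#' @export
node_objective <- function(data, node, spec, beta1, beta2) {
  a <- which(spec$allowed[node, ])
  y1 <- data$x1[, node]; y2 <- data$x2[, node]
  r1 <- y1 - data$x1[, a, drop = FALSE] %*% beta1[a]
  r2 <- y2 - data$x2[, a, drop = FALSE] %*% beta2[a]
  sum(r1^2) / data$n1 + sum(r2^2) / data$n2 +
    sum(spec$lambda1[node, a] * (abs(beta1[a]) + abs(beta2[a]))) +
    sum(spec$lambda2[node, a] * abs(beta1[a] - beta2[a]))
}

#' @export
print.ddn_fit <- function(x, ...) {
  cat("Two-condition fused-Lasso fit: p =", nrow(x$beta1), "nodes;",
      sum(x$beta1 != 0), "/", sum(x$beta2 != 0),
      "nonzero coefficients (cond1/cond2);",
      sum(!x$converged), "node(s) not converged\n")
  invisible(x)
}
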