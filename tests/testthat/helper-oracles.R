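# Independent numerical oracles used to certify the closed-form solver.
# These deliberately avoid the package's candidate-enumeration code path.

# Reduced per-pair objective (constants dropped).
pair_objective <- function(a, b, rho1, rho2, lam1, lam2) {
  a^2 - 2 * rho1 * a + b^2 - 2 * rho2 * b +
    lam1 * (abs(a) + abs(b)) + lam2 * abs(a - b)
}

# 2-D grid search with successive window refinement. Returns the best
# objective value found (and the argmin). Final step size <= 1e-5.
oracle_pair_grid <- function(rho1, rho2, lam1, lam2,
                             half_width = 3.5, coarse_step = 0.05,
                             stages = 4) {
  ctr <- c(0, 0)
  hw <- half_width
  step <- coarse_step
  best <- c(0, 0)
  for (s in seq_len(stages)) {
    as <- seq(ctr[1] - hw, ctr[1] + hw, by = step)
    bs <- seq(ctr[2] - hw, ctr[2] + hw, by = step)
    # include the axes and the diagonal kinks exactly
    as <- sort(unique(c(as, 0)))
    bs <- sort(unique(c(bs, 0, as[which.min(abs(as))])))
    # full objective on the grid, vectorized over b for each a
    val <- matrix(NA_real_, length(as), length(bs))
    fb <- bs^2 - 2 * rho2 * bs + lam1 * abs(bs)
    for (i in seq_along(as)) {
      val[i, ] <- (as[i]^2 - 2 * rho1 * as[i] + lam1 * abs(as[i])) +
        fb + lam2 * abs(as[i] - bs)
    }
    k <- arrayInd(which.min(val), dim(val))
    best <- c(as[k[1]], bs[k[2]])
    ctr <- best
    hw <- 2 * step
    step <- step / 10
  }
  list(par = best,
       value = pair_objective(best[1], best[2], rho1, rho2, lam1, lam2))
}

# Proximal operator of t * (lam1 (|a|+|b|) + lam2 |a-b|) by the fused-Lasso
# prox decomposition (fuse first, then soft-threshold). Independent of the
# closed-form case enumeration in the package.
prox_fused_pair <- function(u, v, t_lam1, t_lam2) {
  if (abs(u - v) <= 2 * t_lam2) {
    a <- b <- (u + v) / 2
  } else {
    s <- sign(u - v)
    a <- u - t_lam2 * s
    b <- v + t_lam2 * s
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  c(soft(a, t_lam1), soft(b, t_lam1))
}

# Per-node objective of the full fused-Lasso regression (matches the
# package's model: 1/Nc data scaling, per-edge penalties over the allowed
# set).
node_objective_oracle <- function(x1, x2, y1, y2, b1, b2, lam1, lam2) {
  sum((y1 - x1 %*% b1)^2) / nrow(x1) + sum((y2 - x2 %*% b2)^2) / nrow(x2) +
    sum(lam1 * (abs(b1) + abs(b2))) + sum(lam2 * abs(b1 - b2))
}

# Generic convex solver for one node: proximal gradient (ISTA) on the
# smooth data term with the fuse-then-shrink prox, run to a 1e-10 change.
# x1/x2: standardized design matrices restricted to the allowed set;
# lam1/lam2: per-predictor penalty vectors.
oracle_node_ista <- function(x1, x2, y1, y2, lam1, lam2,
                             tol = 1e-10, max_iter = 500000) {
  k <- ncol(x1)
  if (k == 0) return(list(b1 = numeric(0), b2 = numeric(0)))
  n1 <- nrow(x1); n2 <- nrow(x2)
  L <- 2 * max(max(eigen(crossprod(x1) / n1, symmetric = TRUE,
                         only.values = TRUE)$values),
               max(eigen(crossprod(x2) / n2, symmetric = TRUE,
                         only.values = TRUE)$values))
  t_step <- 1 / L
  b1 <- numeric(k); b2 <- numeric(k)
  for (it in seq_len(max_iter)) {
    g1 <- -2 * crossprod(x1, y1 - x1 %*% b1) / n1
    g2 <- -2 * crossprod(x2, y2 - x2 %*% b2) / n2
    u <- b1 - t_step * g1
    v <- b2 - t_step * g2
    nb1 <- numeric(k); nb2 <- numeric(k)
    for (j in seq_len(k)) {
      pr <- prox_fused_pair(u[j], v[j], t_step * lam1[j], t_step * lam2[j])
      nb1[j] <- pr[1]; nb2[j] <- pr[2]
    }
    delta <- max(abs(c(nb1 - b1, nb2 - b2)))
    b1 <- nb1; b2 <- nb2
    if (delta < tol) break
  }
  list(b1 = b1, b2 = b2, iterations = it)
}

# Brute-force confusion counts over an explicit pair universe.
brute_confusion <- function(pred_edges, true_edges, universe) {
  key <- function(e) if (nrow(e) == 0) character(0) else
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
  uk <- key(universe); pk <- key(pred_edges); tk <- key(true_edges)
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (u in uk) {
    p <- u %in% pk; t <- u %in% tk
    if (p && t) tp <- tp + 1L
    else if (p) fp <- fp + 1L
    else if (t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
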