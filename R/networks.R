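#' Extract common and differential networks from a fit
#'
#' Symmetrizes the coefficient matrices into per-condition weighted
#' adjacencies and splits the edge union into the common network (edges
#' present under both conditions) and the differential network (edges
#' present under exactly one condition, labeled with that condition).
#'
#' Symmetrization uses the OR rule: in a condition, edge \{i, j\} exists if
#' `|beta[i, j]| > weight_threshold` or `|beta[j, i]| > weight_threshold`
#' among the directions where estimation was allowed; its weight is the
#' mean of the allowed `|beta|` values for the pair (a single value when
#' only one direction is allowed, as under directional constraints).
#'
#' @param fit A `ddn_fit` from [ddn_fit()], or a list with p x p matrices
#'   `beta1`, `beta2`.
#' @param spec The [ddn_spec] used for the fit (defaults to the one stored
#'   in `fit`).
#' @param weight_threshold Nonnegative magnitude threshold for calling an
#'   edge (default 0: any nonzero coefficient, since the L1 penalty already
#'   produces exact zeros).
#' @return An object of class `ddn_networks`: symmetric nonnegative weight
#'   matrices `adjacency1`, `adjacency2`; data frame `common_edges`
#'   (`node_a`, `node_b`, `weight1`, `weight2`); data frame
#'   `differential_edges` (`node_a`, `node_b`, `condition`, `weight`);
#'   `feature_ids`. Edge endpoints satisfy index(node_a) < index(node_b).
#' @export
extract_networks <- function(fit, spec = fit$spec, weight_threshold = 0) {
  stopifnot(inherits(spec, "ddn_spec"))
  if (weight_threshold < 0) stop("weight_threshold must be nonnegative")
  b1 <- as.matrix(fit$beta1); b2 <- as.matrix(fit$beta2)
  p <- spec$p
  if (!all(dim(b1) == c(p, p)) || !all(dim(b2) == c(p, p)))
    stop("coefficient matrices do not match spec dimension")
  ids <- fit$feature_ids %||% spec$feature_ids %||% paste0("V", seq_len(p))

  symmetrize <- function(b) {
    adj <- matrix(0, p, p)
    present <- matrix(FALSE, p, p)
    # row i of allowed marks estimated entries beta[i, j]
    est <- spec$allowed
    absb <- abs(b) * est
    nall <- est + t(est)                        # 0, 1 or 2 directions
    wsum <- absb + t(absb)
    on <- (absb > weight_threshold) | t(absb > weight_threshold)
    adj[nall > 0] <- wsum[nall > 0] / nall[nall > 0]
    adj[!on] <- 0
    present <- on
    diag(adj) <- 0; diag(present) <- FALSE
    list(adj = adj, present = present)
  }
  s1 <- symmetrize(b1); s2 <- symmetrize(b2)

  ut <- upper.tri(s1$present)
  idx <- which(ut & (s1$present | s2$present), arr.ind = TRUE)
  in1 <- s1$present[idx]; in2 <- s2$present[idx]
  both <- in1 & in2
  common <- data.frame(node_a = ids[idx[both, 1]],
                       node_b = ids[idx[both, 2]],
                       weight1 = s1$adj[idx[both, , drop = FALSE]],
                       weight2 = s2$adj[idx[both, , drop = FALSE]],
                       stringsAsFactors = FALSE)
  only1 <- in1 & !in2; only2 <- in2 & !in1
  differential <- rbind(
    data.frame(node_a = ids[idx[only1, 1]], node_b = ids[idx[only1, 2]],
               condition = rep("cond1", sum(only1)),
               weight = s1$adj[idx[only1, , drop = FALSE]],
               stringsAsFactors = FALSE),
    data.frame(node_a = ids[idx[only2, 1]], node_b = ids[idx[only2, 2]],
               condition = rep("cond2", sum(only2)),
               weight = s2$adj[idx[only2, , drop = FALSE]],
               stringsAsFactors = FALSE))
  rownames(common) <- rownames(differential) <- NULL
  dimnames(s1$adj) <- dimnames(s2$adj) <- list(ids, ids)
  out <- list(adjacency1 = s1$adj, adjacency2 = s2$adj,
              common_edges = common,
              differential_edges = differential,
              feature_ids = ids,
              weight_threshold = weight_threshold)
  class(out) <- "ddn_networks"
  out
}

# Edge index matrices (i < j) for scoring.
network_edge_sets <- function(net) {
  idx <- function(df) {
    if (nrow(df) == 0) return(as_edge_matrix(NULL))
    as_edge_matrix(cbind(match(df$node_a, net$feature_ids),
                         match(df$node_b, net$feature_ids)))
  }
  list(common = idx(net$common_edges),
       differential = idx(net$differential_edges),
       differential_by_cond = lapply(
         split(net$differential_edges,
               factor(net$differential_edges$condition,
                      levels = c("cond1", "cond2"))),
         idx))
}

#' @export
print.ddn_networks <- function(x, ...) {
  cat("Networks over", length(x$feature_ids), "nodes:",
      nrow(x$common_edges), "common edges;",
      nrow(x$differential_edges), "differential edges\n")
  invisible(x)
}
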