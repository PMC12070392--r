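#' Generate a multi-layer scale-free network template
#'
#' Builds the ground-truth template graph of the simulation study: a
#' scale-free (preferential attachment) graph on the first layer (the mRNA
#' layer), plus regulator layers (e.g. TF proteins, miRNAs) whose nodes
#' each connect to a fixed number of distinct first-layer nodes chosen
#' uniformly at random. Optionally every layer gets its own scale-free
#' intra-layer wiring.
#'
#' @param n_per_layer Named integer vector of layer sizes; the first layer
#'   is the regulated (mRNA) layer. Default `c(mRNA = 50, TF_protein = 50,
#'   miRNA = 50)`.
#' @param m_attach Edges added per node in preferential attachment
#'   (default 1, giving a tree with `n - 1` edges on the first layer).
#' @param regulator_out_degree Number of distinct first-layer targets per
#'   regulator node (default 5). 0 leaves regulators isolated.
#' @param intra_all_layers If `TRUE`, regulator layers also receive their
#'   own preferential-attachment intra-layer edges (default `FALSE`: only
#'   the first layer has intra-layer structure).
#' @param seed Integer seed; the template is deterministic given it.
#' @return List with `edges` (two-column integer matrix, i < j, global
#'   node indices) and `annotation` (a [layer_annotation()]; ids are
#'   `<layer>_<k>`).
#' @export
generate_template <- function(n_per_layer = c(mRNA = 50, TF_protein = 50,
                                              miRNA = 50),
                              m_attach = 1, regulator_out_degree = 5,
                              intra_all_layers = FALSE, seed = 1L) {
  if (any(n_per_layer <= 0)) stop("layer sizes must be positive")
  if (is.null(names(n_per_layer)))
    names(n_per_layer) <- c("mRNA", "TF_protein", "miRNA",
                            paste0("layer", seq_along(n_per_layer)))[
                              seq_along(n_per_layer)]
  n1 <- n_per_layer[[1]]
  if (regulator_out_degree > n1)
    stop("regulator_out_degree exceeds first-layer size")
  offsets <- cumsum(c(0, n_per_layer))[seq_along(n_per_layer)]
  ids <- unlist(lapply(seq_along(n_per_layer), function(l)
    paste0(names(n_per_layer)[l], "_", seq_len(n_per_layer[[l]]))))
  ann <- layer_annotation(ids, rep(names(n_per_layer), n_per_layer))

  seeds <- derive_seeds(seed, length(n_per_layer) + 1L)
  pa_edges <- function(n, sd) {
    if (n < 2) return(matrix(integer(0), ncol = 2))
    g <- with_seed(sd, igraph::sample_pa(n, m = m_attach, directed = FALSE))
    igraph::as_edgelist(g, names = FALSE)
  }
  edges <- pa_edges(n1, seeds[1])
  if (intra_all_layers && length(n_per_layer) > 1) {
    for (l in 2:length(n_per_layer)) {
      e <- pa_edges(n_per_layer[[l]], seeds[l])
      if (nrow(e)) edges <- rbind(edges, e + offsets[l])
    }
  }
  if (regulator_out_degree > 0 && length(n_per_layer) > 1) {
    regs <- setdiff(seq_along(ids), seq_len(n1))
    tgt <- with_seed(seeds[length(seeds)],
                     lapply(regs, function(r)
                       sample(seq_len(n1), regulator_out_degree)))
    edges <- rbind(edges,
                   cbind(rep(regs, each = regulator_out_degree),
                         unlist(tgt)))
  }
  list(edges = as_edge_matrix(edges), annotation = ann)
}

#' Remove edges independently per condition
#'
#' Derives the two condition-specific truth graphs from the template by
#' removing, independently per condition, `round(removal_fraction * m)`
#' edges uniformly without replacement. Edges kept in both conditions form
#' the true common network; edges kept in exactly one form the true
#' differential network.
#'
#' @param template_edges Two-column edge matrix.
#' @param removal_fraction Fraction in \[0, 1) of edges removed per
#'   condition (default 0.25).
#' @param seed Integer seed (two independent sub-draws, one per condition).
#' @return List with `cond1_edges`, `cond2_edges` (edge matrices).
#' @export
rewire_conditions <- function(template_edges, removal_fraction = 0.25,
                              seed = 1L) {
  if (removal_fraction < 0 || removal_fraction >= 1)
    stop("removal_fraction must be in [0, 1)")
  e <- as_edge_matrix(template_edges)
  m <- nrow(e)
  k <- round(removal_fraction * m)
  seeds <- derive_seeds(seed, 2L)
  keep <- function(sd) {
    if (k == 0) return(e)
    drop <- with_seed(sd, sample.int(m, k))
    e[-drop, , drop = FALSE]
  }
  list(cond1_edges = keep(seeds[1]), cond2_edges = keep(seeds[2]))
}

#' Build a precision matrix with a given edge support
#'
#' Realizes a Gaussian graphical model on a fixed graph: off-diagonal
#' entries at edge positions are drawn uniformly from `weight_range` with
#' random sign, the diagonal is set to the absolute row sum plus
#' `diagonal_boost` (strict diagonal dominance, hence positive definite),
#' and the matrix is rescaled to unit diagonal so the implied partial
#' correlations stay bounded.
#'
#' @param edges Two-column edge matrix (may be empty).
#' @param p Node count.
#' @param weight_range Magnitude range `(lo, hi)` with `lo > 0`
#'   (default `c(0.2, 0.5)`).
#' @param sign_mix Probability that an entry is negative (default 0.5).
#' @param diagonal_boost Added to the dominant diagonal before rescaling
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A p x p symmetric positive-definite precision matrix with unit
#'   diagonal and off-diagonal support exactly the edge set.
#' @export
build_precision <- function(edges, p, weight_range = c(0.2, 0.5),
                            sign_mix = 0.5, diagonal_boost = 0.1,
                            seed = 1L) {
  if (weight_range[1] <= 0) stop("weight_range lower bound must be > 0")
  e <- as_edge_matrix(edges)
  if (nrow(e) > 0 && max(e) > p) stop("edges exceed node count")
  omega <- diag(p)
  if (nrow(e) > 0) {
    w <- with_seed(seed, {
      mag <- runif(nrow(e), weight_range[1], weight_range[2])
      sgn <- ifelse(runif(nrow(e)) < sign_mix, -1, 1)
      mag * sgn
    })
    omega[e] <- w
    omega[e[, c(2, 1), drop = FALSE]] <- w
    diag(omega) <- rowSums(abs(omega)) - 1 + diagonal_boost
    d <- sqrt(diag(omega))
    omega <- omega / outer(d, d)
  }
  omega
}

#' Sample from a Gaussian graphical model
#'
#' Draws i.i.d. zero-mean multivariate normal samples whose covariance is
#' the inverse of `precision`, via the Cholesky factor of the precision
#' matrix (no explicit inversion).
#'
#' @param precision Symmetric positive-definite p x p matrix.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return An `n_samples` x p matrix.
#' @export
sample_ggm <- function(precision, n_samples, seed = 1L) {
  p <- nrow(precision)
  R <- tryCatch(chol(precision),
                error = function(e) stop("precision matrix is not ",
                                         "positive definite"))
  z <- with_seed(seed, matrix(rnorm(n_samples * p), n_samples, p))
  # cov(R^{-1} z) = R^{-1} R^{-T} = precision^{-1}
  t(backsolve(R, t(z)))
}

#' Simulate a full two-condition multi-omics scenario
#'
#' End-to-end generator reproducing the simulation design: a scale-free
#' multi-layer template, independent 25% edge removal per condition,
#' precision matrices on each condition's graph, and Gaussian samples. All
#' randomness flows from `seed` through documented sub-seeds, so identical
#' seeds give identical scenarios.
#'
#' @inheritParams generate_template
#' @inheritParams rewire_conditions
#' @inheritParams build_precision
#' @param n_samples Samples per condition (default 200).
#' @param seed Master seed.
#' @return An object of class `ddn_scenario`: `template_edges`,
#'   `cond1_edges`, `cond2_edges`, `common_edges`, `differential_edges`
#'   (truth edge matrices; differential = symmetric difference),
#'   `precision1`, `precision2`, `annotation`, `samples1`, `samples2`
#'   (n x p matrices with feature-id column names), `seed`, and the
#'   generator parameters.
#' @export
simulate_scenario <- function(n_per_layer = c(mRNA = 50, TF_protein = 50,
                                              miRNA = 50),
                              regulator_out_degree = 5,
                              removal_fraction = 0.25,
                              n_samples = 200,
                              weight_range = c(0.2, 0.5),
                              sign_mix = 0.5, diagonal_boost = 0.1,
                              m_attach = 1, intra_all_layers = FALSE,
                              seed = 1L) {
  seeds <- derive_seeds(seed, 6L)
  tmpl <- generate_template(n_per_layer, m_attach, regulator_out_degree,
                            intra_all_layers, seed = seeds[1])
  p <- nrow(tmpl$annotation)
  rw <- rewire_conditions(tmpl$edges, removal_fraction, seed = seeds[2])
  prec1 <- build_precision(rw$cond1_edges, p, weight_range, sign_mix,
                           diagonal_boost, seed = seeds[3])
  prec2 <- build_precision(rw$cond2_edges, p, weight_range, sign_mix,
                           diagonal_boost, seed = seeds[4])
  x1 <- sample_ggm(prec1, n_samples, seed = seeds[5])
  x2 <- sample_ggm(prec2, n_samples, seed = seeds[6])
  colnames(x1) <- colnames(x2) <- tmpl$annotation$feature_id
  k1 <- edge_keys(rw$cond1_edges); k2 <- edge_keys(rw$cond2_edges)
  out <- list(template_edges = tmpl$edges,
              cond1_edges = rw$cond1_edges,
              cond2_edges = rw$cond2_edges,
              common_edges = keys_to_edges(intersect(k1, k2)),
              differential_edges = keys_to_edges(
                union(setdiff(k1, k2), setdiff(k2, k1))),
              precision1 = prec1, precision2 = prec2,
              annotation = tmpl$annotation,
              samples1 = x1, samples2 = x2,
              params = list(n_per_layer = n_per_layer,
                            regulator_out_degree = regulator_out_degree,
                            removal_fraction = removal_fraction,
                            n_samples = n_samples,
                            weight_range = weight_range,
                            sign_mix = sign_mix,
                            diagonal_boost = diagonal_boost,
                            m_attach = m_attach,
                            intra_all_layers = intra_all_layers),
              seed = seed)
  class(out) <- "ddn_scenario"
  out
}

#' Dataset view of a scenario
#'
#' Extracts the paired sample matrices of a simulated scenario as a
#' [ddn_data], optionally restricted to a subset of layers (e.g. the mRNA
#' layer only, for layer-combination experiments).
#'
#' @param scenario A `ddn_scenario`.
#' @param layers Optional character vector of layer names to keep.
#' @return A raw (unstandardized) `ddn_data`.
#' @export
scenario_dataset <- function(scenario, layers = NULL) {
  keep <- if (is.null(layers)) seq_len(nrow(scenario$annotation))
          else which(scenario$annotation$layer %in% layers)
  if (length(keep) == 0) stop("no features in requested layers")
  ddn_data(scenario$samples1[, keep, drop = FALSE],
           scenario$samples2[, keep, drop = FALSE],
           feature_ids = scenario$annotation$feature_id[keep])
}

#' Layer interaction rules matching the simulation design
#'
#' The constraint set a practitioner would pair with the generator's
#' topology: intra-layer edges allowed on the first (mRNA) layer, each
#' regulator layer allowed only as a directed predictor of the first
#' layer, and all other layer pairs disallowed.
#'
#' @param scenario A `ddn_scenario` (or a [layer_annotation()]).
#' @return An [interaction_rules()] data frame.
#' @export
scenario_rules <- function(scenario) {
  ann <- if (inherits(scenario, "ddn_scenario")) scenario$annotation
         else scenario
  layers <- unique(ann$layer)
  first <- layers[1]
  regs <- setdiff(layers, first)
  rules <- interaction_rules(first, first, directed = FALSE, allowed = TRUE)
  for (r in regs) {
    rules <- rbind(rules,
                   interaction_rules(r, first, directed = TRUE,
                                     allowed = TRUE),
                   interaction_rules(r, r, directed = FALSE,
                                     allowed = FALSE))
    for (r2 in setdiff(regs, r))
      rules <- rbind(rules, interaction_rules(r, r2, directed = FALSE,
                                              allowed = FALSE))
  }
  class(rules) <- c("ddn_rules", "data.frame")
  rules
}

#' Truth edges of a scenario restricted to layers
#'
#' @param scenario A `ddn_scenario`.
#' @param which One of `"common"`, `"differential"`, `"template"`,
#'   `"cond1"`, `"cond2"`.
#' @param layers Optional layer names; edges with both endpoints inside
#'   are kept.
#' @return Edge index matrix (indices refer to the full scenario node set).
#' @export
scenario_truth <- function(scenario,
                           which = c("common", "differential", "template",
                                     "cond1", "cond2"),
                           layers = NULL) {
  type <- match.arg(which)
  e <- switch(type,
              common = scenario$common_edges,
              differential = scenario$differential_edges,
              template = scenario$template_edges,
              cond1 = scenario$cond1_edges,
              cond2 = scenario$cond2_edges)
  if (!is.null(layers)) {
    keep <- which(scenario$annotation$layer %in% layers)
    e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  }
  e
}

#' @export
print.ddn_scenario <- function(x, ...) {
  cat("Simulated scenario:", nrow(x$annotation), "nodes in",
      length(unique(x$annotation$layer)), "layers;",
      nrow(x$template_edges), "template edges;",
      nrow(x$common_edges), "true common /",
      nrow(x$differential_edges), "true differential edges;",
      nrow(x$samples1), "samples per condition (seed", x$seed, ")\n")
  invisible(x)
}
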