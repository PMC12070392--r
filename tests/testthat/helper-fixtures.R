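# Small in-code fixtures shared across tests.

# Canonical "i|j" keys (i < j) for unordered edge sets.
edge_keys_test <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0) return(character(0))
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|"))
}

random_dataset <- function(p, n = 50, seed = 1, standardized = TRUE) {
  d <- with(list(), {
    set.seed(seed)
    ddn_data(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p), n, p),
             feature_ids = paste0("f", seq_len(p)))
  })
  if (standardized) standardize(d) else d
}

random_spec <- function(p, density = 0.7, lam_range = c(0.05, 0.5),
                        lam2_range = c(0, 0.3), seed = 1) {
  set.seed(seed)
  allowed <- matrix(runif(p * p) < density, p, p)
  diag(allowed) <- FALSE
  ddn_spec(allowed,
           matrix(runif(p * p, lam_range[1], lam_range[2]), p, p),
           matrix(runif(p * p, lam2_range[1], lam2_range[2]), p, p))
}

# TF/target two-layer toy annotation: nodes 1..3 TFs, 4..6 targets, with
# the regulatory rules "edges among TFs, TF -> target, none among targets".
toy_tf_annotation <- function() {
  layer_annotation(paste0("g", 1:6), rep(c("TF", "target"), each = 3))
}

toy_tf_rules <- function() {
  interaction_rules(source_layer = c("TF", "TF", "target"),
                    target_layer = c("TF", "target", "target"),
                    directed = c(FALSE, TRUE, FALSE),
                    allowed = c(TRUE, TRUE, FALSE))
}

small_scenario <- function(seed = 1, n_samples = 100) {
  simulate_scenario(n_per_layer = c(mRNA = 10, TF_protein = 6, miRNA = 6),
                    regulator_out_degree = 3, n_samples = n_samples,
                    seed = seed)
}
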