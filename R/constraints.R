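#' Layer annotation
#'
#' Assigns every feature to exactly one omics layer (e.g. `"mRNA"`,
#' `"TF_protein"`, `"miRNA"`).
#'
#' @param feature_ids Ordered character vector of unique feature ids.
#' @param layers Character vector of nonempty layer names, one per feature.
#' @return An object of class `ddn_layers`: data frame with columns
#'   `feature_id`, `layer`.
#' @export
layer_annotation <- function(feature_ids, layers) {
  feature_ids <- as.character(feature_ids)
  layers <- as.character(layers)
  if (length(layers) == 1) layers <- rep(layers, length(feature_ids))
  if (length(feature_ids) != length(layers))
    stop("feature_ids and layers must have equal length")
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids")
  if (any(is.na(layers) | layers == "")) stop("layer names must be nonempty")
  ann <- data.frame(feature_id = feature_ids, layer = layers,
                    stringsAsFactors = FALSE)
  class(ann) <- c("ddn_layers", "data.frame")
  ann
}

#' Layer-pair interaction rules
#'
#' One rule per row: whether predictors from `source_layer` may act on
#' nodes of `target_layer`. A directed allowed rule (`directed = TRUE`,
#' `allowed = TRUE`) encodes a regulator-to-effector prior: source
#' features become allowed predictors of target features while the reverse
#' direction is disallowed (unless a later rule or override re-permits it).
#' Undirected rules set or clear both directions.
#'
#' @param source_layer,target_layer Layer names.
#' @param directed,allowed Logical vectors (recycled).
#' @return Data frame of class `ddn_rules`.
#' @export
interaction_rules <- function(source_layer, target_layer,
                              directed = FALSE, allowed = TRUE) {
  r <- data.frame(source_layer = as.character(source_layer),
                  target_layer = as.character(target_layer),
                  directed = as.logical(directed),
                  allowed = as.logical(allowed),
                  stringsAsFactors = FALSE)
  class(r) <- c("ddn_rules", "data.frame")
  r
}

#' Build a dependency specification from layers, rules and overrides
#'
#' Constructs the allowed-predictor structure in three precedence tiers:
#' the default (all pairs allowed, no self-regulation), then layer-pair
#' rules applied in listed order, then per-edge overrides (highest
#' precedence). Directed semantics follow the regulator-to-effector
#' convention: a directed allowed relation u -> v makes u an allowed
#' predictor of v and removes v from the allowed predictors of u.
#'
#' Penalty matrices are filled from a scalar default and optional per
#' layer-pair values, keyed by (node layer, predictor layer).
#'
#' @param annotation A [layer_annotation()].
#' @param rules Optional [interaction_rules()] data frame.
#' @param edge_overrides Optional data frame with columns `from`, `to`
#'   (feature ids), `directed`, `allowed`; a directed allowed row makes
#'   `from` an allowed predictor of `to` and disallows the reverse.
#'   Duplicate rows for the same ordered feature pair with conflicting
#'   `allowed` are an error.
#' @param lambda1_rules,lambda2_rules Optional data frames with columns
#'   `node_layer`, `predictor_layer`, `value` setting per layer-pair
#'   penalties.
#' @param default_lambda1,default_lambda2 Scalar penalty defaults.
#' @return A [ddn_spec] with `feature_ids` from the annotation.
#' @examples
#' ann <- layer_annotation(paste0("g", 1:6),
#'                         rep(c("TF", "target"), each = 3))
#' rules <- interaction_rules(
#'   source_layer = c("TF", "TF", "target"),
#'   target_layer = c("TF", "target", "target"),
#'   directed = c(FALSE, TRUE, FALSE),
#'   allowed = c(TRUE, TRUE, FALSE))
#' spec <- build_spec(ann, rules)
#' which(spec$allowed[1, ])  # TFs predicted only by the other TFs
#' @export
build_spec <- function(annotation, rules = NULL, edge_overrides = NULL,
                       lambda1_rules = NULL, lambda2_rules = NULL,
                       default_lambda1 = 0, default_lambda2 = 0) {
  stopifnot(inherits(annotation, "data.frame"))
  ids <- annotation$feature_id
  lay <- annotation$layer
  p <- length(ids)
  layer_rows <- split(seq_len(p), lay)
  known <- names(layer_rows)

  allowed <- matrix(TRUE, p, p)
  diag(allowed) <- FALSE

  if (!is.null(rules) && nrow(rules) > 0) {
    bad <- setdiff(unique(c(rules$source_layer, rules$target_layer)), known)
    if (length(bad))
      stop("rules reference unknown layer(s): ", paste(bad, collapse = ", "))
    for (k in seq_len(nrow(rules))) {
      src <- layer_rows[[rules$source_layer[k]]]
      tgt <- layer_rows[[rules$target_layer[k]]]
      if (isTRUE(rules$directed[k]) && isTRUE(rules$allowed[k])) {
        allowed[tgt, src] <- TRUE     # source may predict target
        allowed[src, tgt] <- FALSE    # reverse direction disallowed
      } else {
        allowed[tgt, src] <- rules$allowed[k]
        allowed[src, tgt] <- rules$allowed[k]
      }
    }
    diag(allowed) <- FALSE
  }

  if (!is.null(edge_overrides) && nrow(edge_overrides) > 0) {
    ov <- edge_overrides
    iu <- match(ov$from, ids); iv <- match(ov$to, ids)
    if (anyNA(iu) || anyNA(iv))
      stop("edge overrides reference unknown feature id(s): ",
           paste(unique(c(ov$from[is.na(iu)], ov$to[is.na(iv)])),
                 collapse = ", "))
    key <- paste(ov$from, ov$to, ov$directed)
    if (anyDuplicated(key)) {
      dups <- key[duplicated(key)]
      conflict <- vapply(unique(dups), function(kk)
        length(unique(ov$allowed[key == kk])) > 1, logical(1))
      if (any(conflict))
        stop("conflicting duplicate overrides for pair(s): ",
             paste(unique(dups)[conflict], collapse = "; "))
    }
    for (k in seq_len(nrow(ov))) {
      if (isTRUE(ov$directed[k]) && isTRUE(ov$allowed[k])) {
        allowed[iv[k], iu[k]] <- TRUE
        allowed[iu[k], iv[k]] <- FALSE
      } else {
        allowed[iv[k], iu[k]] <- ov$allowed[k]
        allowed[iu[k], iv[k]] <- ov$allowed[k]
      }
    }
    diag(allowed) <- FALSE
  }

  fill_lambda <- function(default, lrules, name) {
    lam <- matrix(as.numeric(default), p, p)
    if (!is.null(lrules) && nrow(lrules) > 0) {
      bad <- setdiff(unique(c(lrules$node_layer, lrules$predictor_layer)),
                     known)
      if (length(bad))
        stop(name, " rules reference unknown layer(s): ",
             paste(bad, collapse = ", "))
      for (k in seq_len(nrow(lrules)))
        lam[layer_rows[[lrules$node_layer[k]]],
            layer_rows[[lrules$predictor_layer[k]]]] <- lrules$value[k]
    }
    lam
  }
  ddn_spec(allowed,
           fill_lambda(default_lambda1, lambda1_rules, "lambda1"),
           fill_lambda(default_lambda2, lambda2_rules, "lambda2"),
           feature_ids = ids)
}

#' Mask a fraction of non-true candidate edges
#'
#' Emulates prior-knowledge constraints of adjustable strength: a given
#' fraction of the currently allowed candidate pairs that are *not* true
#' edges is disallowed (both directions together); true edges are never
#' masked. Sampling is a fixed seeded permutation of the maskable pairs,
#' so masks are nested across fractions: the pairs masked at 20% are a
#' subset of those masked at 50% under the same seed.
#'
#' @param spec A [ddn_spec].
#' @param truth_edges True edge set (two-column matrix or data frame of
#'   node indices, unordered pairs).
#' @param mask_fraction Fraction in \[0, 1\] of maskable pairs to disallow.
#' @param seed Integer seed for the permutation.
#' @return A `ddn_spec` with the masked structure.
#' @export
mask_non_edges <- function(spec, truth_edges, mask_fraction, seed = 1L) {
  stopifnot(inherits(spec, "ddn_spec"))
  if (mask_fraction < 0 || mask_fraction > 1)
    stop("mask_fraction must be in [0, 1]")
  truth <- as_edge_matrix(truth_edges)
  if (nrow(truth) > 0 && max(truth) > spec$p)
    stop("truth edges exceed node count")
  cand <- spec$allowed | t(spec$allowed)
  ut <- which(upper.tri(cand) & cand, arr.ind = TRUE)
  keys <- paste(ut[, 1], ut[, 2], sep = "|")
  maskable <- !(keys %in% edge_keys(truth))
  pool <- ut[maskable, , drop = FALSE]
  n_mask <- round(mask_fraction * nrow(pool))
  if (n_mask > 0) {
    perm <- with_seed(seed, sample.int(nrow(pool)))
    drop <- pool[perm[seq_len(n_mask)], , drop = FALSE]
    allowed <- spec$allowed
    allowed[drop] <- FALSE
    allowed[drop[, c(2, 1), drop = FALSE]] <- FALSE
    spec <- ddn_spec(allowed, spec$lambda1, spec$lambda2, spec$feature_ids)
  }
  spec
}
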