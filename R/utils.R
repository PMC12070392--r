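# Internal helpers: seeded evaluation and edge-set bookkeeping.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive k reproducible sub-seeds from one master seed (documented
# substream scheme: the first k draws of sample.int under the master seed).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Edges are stored as integer matrices with two columns (i, j), i < j.
as_edge_matrix <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  e <- as.matrix(edges[, 1:2, drop = FALSE])
  storage.mode(e) <- "integer"
  flip <- e[, 1] > e[, 2]
  e[flip, ] <- e[flip, c(2, 1), drop = FALSE]
  if (any(e[, 1] == e[, 2])) stop("self-edges are not allowed")
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("i", "j"))
  e
}

edge_keys <- function(edges) {
  e <- as_edge_matrix(edges)
  if (nrow(e) == 0) return(character(0))
  paste(e[, 1], e[, 2], sep = "|")
}

keys_to_edges <- function(keys) {
  if (length(keys) == 0)
    return(as_edge_matrix(NULL))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  as_edge_matrix(cbind(as.integer(parts[, 1]), as.integer(parts[, 2])))
}

# All unordered pairs among node indices `idx` (within a p-node graph).
all_pairs <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 2) return(as_edge_matrix(NULL))
  cmb <- t(utils::combn(idx, 2))
  as_edge_matrix(cmb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
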