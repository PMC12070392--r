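test_that("standardization centers and scales with the population divisor", {
  d <- ddn_data(matrix(c(1, 2, 3, -1, 0, 4), 3),
                matrix(c(0, 1, 5, 2, 2.5, 3), 3))
  s <- standardize(d)
  # hand-computed: mean 2, population SD sqrt(2/3)
  expect_equal(s$x1[, 1], c(-sqrt(1.5), 0, sqrt(1.5)))
  for (x in list(s$x1, s$x2)) {
    expect_true(max(abs(colMeans(x))) < 1e-10)
    expect_equal(colSums(x^2) / nrow(x), rep(1, ncol(x)),
                 ignore_attr = TRUE)
  }
  # idempotent
  s2 <- standardize(s)
  expect_equal(s2$x1, s$x1, tolerance = 1e-12)
  expect_equal(s2$x2, s$x2, tolerance = 1e-12)
})

test_that("degenerate data are rejected with the offending feature named", {
  x_ok <- matrix(rnorm(9), 3)
  x_const <- cbind(rnorm(3), 5, rnorm(3))
  expect_error(ddn_data(x_const, x_ok, paste0("g", 1:3)), "g2")
  expect_error(ddn_data(x_ok, x_ok * c(1, NA, 1)), "finite|impute")
  expect_error(ddn_data(x_ok, matrix(rnorm(8), 2)), "feature count")
})

test_that("pairwise update reproduces hand-derived closed forms", {
  expect_equal(pairwise_update(0, 0, 0.7, 0.3), c(0, 0))
  # lambda2 = 0 separates into two scalar soft-thresholding problems
  expect_equal(pairwise_update(1, -0.4, 0.2, 0), c(0.9, -0.3))
  # large lambda2 fuses the pair at the average
  expect_equal(pairwise_update(1, 0.5, 0, 1), c(0.75, 0.75))
  expect_error(pairwise_update(1, 1, -0.1, 0), "nonnegative")
  expect_error(pairwise_update(Inf, 0, 0, 0), "finite")
})

test_that("pairwise update matches the grid+refine oracle and the prox
           decomposition on random tuples", {
  set.seed(101)
  for (k in 1:300) {
    r1 <- runif(1, -3, 3); r2 <- runif(1, -3, 3)
    l1 <- runif(1, 0, 2); l2 <- runif(1, 0, 2)
    ab <- pairwise_update(r1, r2, l1, l2)
    # never worse than the numerical grid optimum
    orc <- oracle_pair_grid(r1, r2, l1, l2)
    expect_lte(pair_objective(ab[1], ab[2], r1, r2, l1, l2),
               orc$value + 1e-6)
    # independent fuse-then-soft-threshold prox derivation agrees exactly
    expect_equal(ab, prox_fused_pair(r1, r2, l1 / 2, l2 / 2),
                 tolerance = 1e-12)
  }
})

test_that("solve_node handles empty and fully-shrunk problems", {
  d <- random_dataset(5, seed = 3)
  spec <- ddn_spec(matrix(FALSE, 5, 5), 0.1, 0.1)
  res <- solve_node(d, 2, spec)
  expect_equal(res$beta1, rep(0, 5))
  expect_true(res$converged)
  expect_equal(res$sweeps, 0)
  # penalty above the data-derived bound: all-zero after one sweep
  spec2 <- ddn_spec(5, lambda1 = 0, lambda2 = 0)
  rho_max <- max(abs(crossprod(d$x1) / d$n1), abs(crossprod(d$x2) / d$n2)
                 * upper.tri(diag(5)))
  spec2 <- ddn_spec(5, lambda1 = 2 * rho_max, lambda2 = 0)
  res2 <- solve_node(d, 1, spec2)
  expect_equal(res2$beta1, rep(0, 5))
  expect_equal(res2$beta2, rep(0, 5))
  expect_equal(res2$sweeps, 1)
  expect_true(res2$converged)
  # unstandardized data are rejected
  raw <- random_dataset(5, seed = 3, standardized = FALSE)
  expect_error(solve_node(raw, 1, spec2), "standardize")
})

test_that("BCD solution matches the proximal-gradient oracle per node", {
  set.seed(11)
  for (rep in 1:6) {
    p <- sample(4:10, 1)
    d <- random_dataset(p, n = 50, seed = 100 + rep)
    spec <- random_spec(p, seed = 200 + rep)
    fit <- ddn_fit(d, spec, tol = 1e-9)
    for (i in seq_len(p)) {
      a <- which(spec$allowed[i, ])
      if (!length(a)) next
      orc <- oracle_node_ista(d$x1[, a, drop = FALSE],
                              d$x2[, a, drop = FALSE],
                              d$x1[, i], d$x2[, i],
                              spec$lambda1[i, a], spec$lambda2[i, a])
      expect_lt(max(abs(c(fit$beta1[i, a] - orc$b1,
                          fit$beta2[i, a] - orc$b2))), 1e-4)
    }
  }
})

test_that("with all predictors allowed the fit reduces to the
           unconstrained two-condition formulation", {
  p <- 6
  d <- random_dataset(p, n = 50, seed = 5)
  spec <- ddn_spec(p, lambda1 = 0.3, lambda2 = 0.1)
  fit <- ddn_fit(d, spec, tol = 1e-9)
  for (i in seq_len(p)) {
    a <- setdiff(seq_len(p), i)
    orc <- oracle_node_ista(d$x1[, a], d$x2[, a], d$x1[, i], d$x2[, i],
                            rep(0.3, p - 1), rep(0.1, p - 1))
    expect_lt(max(abs(c(fit$beta1[i, a] - orc$b1,
                        fit$beta2[i, a] - orc$b2))), 1e-4)
  }
})

test_that("the per-node objective never increases across BCD sweeps", {
  d <- random_dataset(8, n = 40, seed = 9)
  spec <- random_spec(8, seed = 9)
  for (i in c(1, 4, 8)) {
    objs <- vapply(1:12, function(k) {
      r <- solve_node(d, i, spec, max_sweeps = k)
      node_objective(d, i, spec, r$beta1, r$beta2)
    }, numeric(1))
    expect_true(all(diff(objs) <= 1e-12))
  }
})

test_that("directional constraints confine the coefficient support", {
  # two-layer toy: 3 TFs predicted only by TFs, targets only by TFs
  d <- random_dataset(6, n = 30, seed = 21)
  spec <- build_spec(toy_tf_annotation(), toy_tf_rules(),
                     default_lambda1 = 0.05, default_lambda2 = 0.01)
  fit <- ddn_fit(d, spec)
  for (b in list(fit$beta1, fit$beta2)) {
    expect_true(all(b[, 4:6] == 0))          # targets never predict
    for (i in 1:3) expect_true(all(b[i, setdiff(1:6, 1:3)] == 0))
    expect_true(all(diag(b) == 0))
  }
  # huge lambda1 empties everything
  fit0 <- ddn_fit(d, set_penalties(spec, 10, 0))
  expect_true(all(fit0$beta1 == 0) && all(fit0$beta2 == 0))
})

test_that("fit is bit-identical across worker counts", {
  d <- random_dataset(20, n = 40, seed = 31)
  spec <- random_spec(20, seed = 31)
  f1 <- ddn_fit(d, spec, n_workers = 1)
  f4 <- ddn_fit(d, spec, n_workers = 4)
  expect_identical(f1$beta1, f4$beta1)
  expect_identical(f1$beta2, f4$beta2)
})

test_that("feature permutation only permutes the fitted model", {
  p <- 7
  d <- random_dataset(p, n = 40, seed = 41)
  spec <- random_spec(p, seed = 41)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  dp <- ddn_data(d$x1[, perm], d$x2[, perm], d$feature_ids[perm],
                 standardized = TRUE)
  specp <- ddn_spec(spec$allowed[perm, perm], spec$lambda1[perm, perm],
                    spec$lambda2[perm, perm])
  fit <- ddn_fit(d, spec, tol = 1e-9)
  fitp <- ddn_fit(dp, specp, tol = 1e-9)
  expect_equal(fitp$beta1, fit$beta1[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(fitp$beta2, fit$beta2[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-6)
  # edge sets permute consistently
  net <- extract_networks(fit)
  netp <- extract_networks(fitp)
  canon <- function(df) {
    k <- apply(df, 1, function(r) paste(sort(r[1:2]), collapse = "~"))
    sort(k)
  }
  expect_equal(canon(net$common_edges[, 1:2]),
               canon(netp$common_edges[, 1:2]))
  expect_equal(canon(net$differential_edges[, 1:2]),
               canon(netp$differential_edges[, 1:2]))
})

test_that("network extraction applies the OR rule with mean weights", {
  spec <- ddn_spec(3, 0.1, 0.1)
  b1 <- matrix(0, 3, 3); b2 <- matrix(0, 3, 3)
  b1[1, 2] <- 0.5                     # one direction only
  net <- extract_networks(list(beta1 = b1, beta2 = b2,
                               feature_ids = c("a", "b", "c")), spec)
  expect_equal(nrow(net$common_edges), 0)
  expect_equal(net$differential_edges$condition, "cond1")
  expect_equal(net$differential_edges$weight, 0.25)  # mean of 0.5 and 0
  expect_equal(net$adjacency1["a", "b"], 0.25)
  expect_true(isSymmetric(net$adjacency1))
  # equal coefficient matrices -> no differential edges
  b2[1, 2] <- 0.5
  net2 <- extract_networks(list(beta1 = b1, beta2 = b2,
                                feature_ids = c("a", "b", "c")), spec)
  expect_equal(nrow(net2$differential_edges), 0)
  expect_equal(nrow(net2$common_edges), 1)
  # all-zero solution -> empty everything
  net0 <- extract_networks(list(beta1 = b1 * 0, beta2 = b2 * 0,
                                feature_ids = c("a", "b", "c")), spec)
  expect_equal(nrow(net0$common_edges) + nrow(net0$differential_edges), 0)
  expect_true(all(net0$adjacency1 == 0))
})

test_that("large lambda2 forces exact cross-condition equality", {
  d <- random_dataset(8, n = 60, seed = 55)
  spec <- ddn_spec(8, lambda1 = 0.1, lambda2 = 10)
  fit <- ddn_fit(d, spec)
  expect_identical(fit$beta1, fit$beta2)
  expect_equal(nrow(extract_networks(fit)$differential_edges), 0)
})
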