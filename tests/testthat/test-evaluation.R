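toy_networks <- function(common, differential, p = 8) {
  ids <- paste0("g", seq_len(p))
  mk <- function(e) if (NROW(e) == 0)
    data.frame(node_a = character(0), node_b = character(0),
               stringsAsFactors = FALSE)
  else data.frame(node_a = ids[e[, 1]], node_b = ids[e[, 2]],
                  stringsAsFactors = FALSE)
  d <- mk(differential)
  d$condition <- rep("cond1", nrow(d))
  list(feature_ids = ids, common_edges = mk(common),
       differential_edges = d)
}

test_that("exact recovery and the harmonic-mean formula score correctly", {
  uni <- t(combn(8, 2))
  truth <- list(common = cbind(1:3, 4:6), differential = cbind(7, 8))
  perfect <- score_networks(toy_networks(truth$common,
                                         truth$differential),
                            truth, uni)
  expect_equal(perfect$f1_common, 1)
  expect_equal(perfect$f1_differential, 1)
  expect_equal(perfect$f1_average, 1)
  expect_equal(perfect$candidate_universe_size, 28)
  # precision 1/2, recall 1 -> F1 = 2/3
  pred <- toy_networks(rbind(truth$common, cbind(c(1, 2, 3), c(5, 6, 7))),
                       NULL)
  half <- score_networks(pred, list(common = truth$common,
                                    differential = NULL), uni)
  expect_equal(half$common$precision, 0.5)
  expect_equal(half$common$recall, 1)
  expect_equal(half$f1_common, 2 / 3)
  # empty prediction against nonempty truth
  none <- score_networks(toy_networks(NULL, NULL), truth, uni)
  expect_equal(none$f1_common, 0)
  expect_equal(none$common$recall, 0)
  expect_error(score_networks(pred, truth, NULL), "empty")
})

test_that("confusion counts equal a brute-force loop over the universe", {
  set.seed(61)
  for (rep in 1:5) {
    p <- 9
    uni <- t(combn(p, 2))
    pick <- function(k) uni[sample(nrow(uni), k), , drop = FALSE]
    truth <- list(common = pick(6), differential = pick(4))
    pred <- toy_networks(pick(5), pick(3), p)
    sc <- score_networks(pred, truth, uni)
    ids <- paste0("g", seq_len(p))
    as_idx <- function(df) cbind(match(df$node_a, ids),
                                 match(df$node_b, ids))
    bc <- brute_confusion(as_idx(pred$common_edges), truth$common, uni)
    expect_equal(c(tp = sc$common$tp, fp = sc$common$fp,
                   fn = sc$common$fn, tn = sc$common$tn), bc)
    bd <- brute_confusion(as_idx(pred$differential_edges),
                          truth$differential, uni)
    expect_equal(sc$differential$tp, unname(bd["tp"]))
    expect_equal(sc$differential$tn, unname(bd["tn"]))
    # counts always sum to the universe size
    with(sc$common, expect_equal(tp + fp + fn + tn, 36))
  }
})

test_that("restricting the universe never adds errors from outside it", {
  sc <- small_scenario(seed = 44)
  spec <- build_spec(sc$annotation, scenario_rules(sc),
                     default_lambda1 = 0.2, default_lambda2 = 0.05)
  fit <- ddn_fit(standardize(scenario_dataset(sc)), spec)
  net <- extract_networks(fit)
  uni_all <- pair_universe(spec, sc$annotation)
  uni_m <- pair_universe(spec, sc$annotation, "mRNA")
  expect_true(all(edge_keys_test(uni_m) %in% edge_keys_test(uni_all)))
  s_all <- score_networks(net, sc, uni_all)
  truth_m <- list(common = scenario_truth(sc, "common", "mRNA"),
                  differential = scenario_truth(sc, "differential",
                                                "mRNA"))
  s_m <- score_networks(net, truth_m, uni_m)
  expect_lte(s_m$common$fp + s_m$common$fn,
             s_all$common$fp + s_all$common$fn)
  expect_lte(s_m$candidate_universe_size, s_all$candidate_universe_size)
})

test_that("strict differential scoring also checks the condition label", {
  uni <- t(combn(4, 2))
  truth <- list(common = NULL, differential = cbind(1, 2),
                cond1 = cbind(1, 2), cond2 = matrix(integer(0), 0, 2))
  right <- toy_networks(NULL, cbind(1, 2), 4)   # predicted in cond1
  wrong <- right
  wrong$differential_edges$condition <- "cond2"
  expect_equal(score_networks(right, truth, uni,
                              strict_condition = TRUE)$differential$tp, 1)
  expect_equal(score_networks(wrong, truth, uni,
                              strict_condition = TRUE)$differential$tp, 0)
  # pair-level default ignores the label
  expect_equal(score_networks(wrong, truth, uni)$differential$tp, 1)
})

test_that("normalized pAUC follows trapezoid geometry", {
  # random classifier TPR = FPR: area c^2/2, normalized to c/2
  g <- seq(0, 1, by = 0.01)
  expect_equal(pauc(g, g, 0.1), 0.05)
  # perfect step at FPR 0
  expect_equal(pauc(0, 1, 0.1), 1)
  # two-point hand trapezoid: 0.5*0.05*0.6 + 0.5*0.05*(0.6+0.8) = 0.05
  expect_equal(pauc(c(0.05, 0.1), c(0.6, 0.8), 0.1), 0.5)
  # invariant to duplicated points
  expect_equal(pauc(c(0.05, 0.05, 0.1), c(0.6, 0.6, 0.8), 0.1), 0.5)
  # monotone under pointwise TPR increase
  set.seed(71)
  f <- sort(runif(20, 0, 0.3)); t1 <- sort(runif(20))
  t2 <- pmin(t1 + runif(20, 0, 0.2), 1)
  expect_gte(pauc(f, t2, 0.1), pauc(f, t1, 0.1))
  # curve ending before the cutoff carries the last TPR forward
  expect_equal(pauc(0.02, 1, 0.1), 0.9)
  expect_error(pauc(0.1, 0.5, 0), "cutoff")
})

test_that("lambda sweep selects per-lambda1 best lambda2 and ties to
           score_networks", {
  sc <- small_scenario(seed = 52)
  data <- standardize(scenario_dataset(sc))
  spec <- build_spec(sc$annotation, scenario_rules(sc))
  uni <- pair_universe(spec, sc$annotation)
  # 1x1 grid equals a direct fit + score
  tab <- sweep_lambdas(data, spec, sc, 0.3, 0.05, uni)
  fit <- ddn_fit(data, set_penalties(spec, 0.3, 0.05))
  ref <- score_networks(extract_networks(fit), sc, uni)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$f1_common, ref$f1_common)
  expect_equal(tab$f1_differential, ref$f1_differential)
  expect_equal(tab$fpr_common, ref$common$fpr)
  # a lambda1 too large for any edge gives the all-zero row
  tab0 <- sweep_lambdas(data, spec, sc, 10, c(0.01, 0.1), uni)
  expect_equal(tab0$tpr_common, 0)
  expect_equal(tab0$fpr_common, 0)
  expect_equal(tab0$f1_average, 0)
  # reported row is the best lambda2 for the selected metric
  tab2 <- sweep_lambdas(data, spec, sc, c(0.2, 0.4), c(0.01, 0.05, 0.2),
                        uni, select = "common")
  for (r in seq_len(nrow(tab2))) {
    all_f1 <- vapply(c(0.01, 0.05, 0.2), function(l2) {
      f <- ddn_fit(data, set_penalties(spec, tab2$lambda1[r], l2))
      score_networks(extract_networks(f), sc, uni)$f1_common
    }, numeric(1))
    expect_equal(tab2$f1_common[r], max(all_f1))
  }
})
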