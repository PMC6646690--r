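test_that("label_edges labels predictions against validated pairs", {
  ldn <- make_ldn(c("D1", "D1"), c("L1", "L2"), c(0.5, 0.2))
  truth <- data.frame(disease_id = "D1", lncrna_id = "L1")
  lab <- label_edges(ldn, truth)
  expect_equal(lab$score, c(0.5, 0.2))
  expect_equal(lab$label, c(1L, 0L))

  # a validated pair that was never predicted contributes nothing
  truth2 <- rbind(truth, data.frame(disease_id = "D9", lncrna_id = "L9"))
  expect_message(lab2 <- label_edges(ldn, truth2), "unscored positive")
  expect_equal(lab2, lab)

  # group restriction can empty the evaluation set
  groups <- data.frame(disease_id = "D1", group = "cancer")
  expect_error(label_edges(ldn, truth, group = "cardio", groups = groups),
               "no predicted edges")
  expect_error(label_edges(ldn, truth, group = "cancer"), "groups table")
  lab3 <- label_edges(ldn, truth, group = "cancer", groups = groups)
  expect_equal(lab3, lab)

  # all-positive or all-negative labellings are undefined
  expect_error(label_edges(ldn, data.frame(disease_id = "DX",
                                           lncrna_id = "LX")),
               "no positives")
  both <- data.frame(disease_id = c("D1", "D1"), lncrna_id = c("L1", "L2"))
  expect_error(label_edges(ldn, both), "no negatives")
})

test_that("roc_auc matches hand-worked cases and is a proper curve", {
  perfect <- data.frame(score = c(0.9, 0.8, 0.2, 0.1),
                        label = c(1, 1, 0, 0))
  expect_equal(roc_auc(perfect)$auc, 1)

  mixed <- data.frame(score = c(0.8, 0.3, 0.5, 0.1),
                      label = c(1, 1, 0, 0))
  expect_equal(roc_auc(mixed)$auc, 0.75)  # 3 of 4 pairs concordant

  tied <- data.frame(score = rep(0.4, 6), label = c(1, 0, 1, 0, 0, 1))
  expect_equal(roc_auc(tied)$auc, 0.5)

  roc <- roc_auc(mixed)
  expect_equal(roc$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_error(roc_auc(data.frame(score = 1, label = 1)), "positive")
})

test_that("roc_auc equals brute-force pairwise counting and is rank-invariant", {
  withr::local_seed(88)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    # coarse scores so ties occur often
    score <- round(rnorm(n), sample(0:2, 1))
    label <- rbinom(n, 1, 0.4)
    if (sum(label) == 0 || sum(label) == n) next
    lab <- data.frame(score = score, label = label)
    expect_equal(roc_auc(lab)$auc, auc_brute_force(score, label),
                 tolerance = 1e-12)
    # AUC is invariant under strictly monotone transforms of the scores
    lab2 <- data.frame(score = exp(2 * score) + 1, label = label)
    expect_equal(roc_auc(lab2)$auc, roc_auc(lab)$auc, tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(17)
  score <- c(rnorm(60, 1), rnorm(90))
  label <- c(rep(1, 60), rep(0, 90))
  ours <- roc_auc(data.frame(score = score, label = label))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("label shuffling preserves the unlabelled bipartite structure", {
  withr::local_seed(12)
  bench <- generate_benchmark(small_synth_config())
  ldn <- predict_all(bench$network)
  shuf <- shuffle_labels(ldn, rng_seed = 99)
  # weights stay attached to graph positions: multisets unchanged
  expect_identical(sort(shuf$edges$weight), sort(ldn$edges$weight))
  expect_identical(sort(as.integer(table(shuf$edges$disease_id))),
                   sort(as.integer(table(ldn$edges$disease_id))))
  expect_identical(sort(as.integer(table(shuf$edges$lncrna_id))),
                   sort(as.integer(table(ldn$edges$lncrna_id))))
  expect_setequal(unique(shuf$edges$disease_id), unique(ldn$edges$disease_id))
  # reproducible byte-for-byte for a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_ldn(shuffle_labels(ldn, rng_seed = 99), f1)
  write_ldn(shuf, f2)
  expect_identical(readLines(f1), readLines(f2))

  # explicit identity permutations leave the network unchanged
  lncs <- sort(unique(ldn$edges$lncrna_id))
  diseases <- sort(unique(ldn$edges$disease_id))
  ident <- shuffle_labels(ldn, rng_seed = 1,
                          lnc_perm = setNames(lncs, lncs),
                          disease_perm = setNames(diseases, diseases))
  expect_equal(ident$edges, ldn$edges)
})

test_that("shuffled predictions score near chance across many seeds", {
  withr::local_seed(30)
  bench <- generate_benchmark(small_synth_config())
  ldn <- predict_all(bench$network)
  aucs <- vapply(1:200, function(s) {
    roc_auc(label_edges(shuffle_labels(ldn, rng_seed = s),
                        bench$truth))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("rank_sum reproduces exact small-sample enumeration", {
  rs <- rank_sum(c(1, 2), c(3, 4))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 1 / 3, tolerance = 1e-12)  # 2/C(4,2)
  expect_equal(rs$method, "exact")

  same <- rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  big <- rank_sum(rnorm(100), rnorm(100))
  expect_equal(big$method, "normal-approximation")
  expect_error(rank_sum(numeric(0), 1), "non-empty")
})

test_that("ground truth and group files are normalized on read", {
  truth_path <- write_tsv_lines(c("# disease\tlncrna", "d1\t malat1",
                                  "D1\tMALAT1", "D2\tH19"))
  truth <- suppressMessages(read_ground_truth(truth_path))
  expect_equal(nrow(truth), 2)
  expect_setequal(truth$lncrna_id, c("MALAT1", "H19"))
  groups_path <- write_tsv_lines(c("D1\tcancer", "D2\tcardio"))
  groups <- read_disease_groups(groups_path)
  expect_equal(groups$group, c("cancer", "cardio"))
})
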