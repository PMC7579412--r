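test_that("pearson correlation matches the closed-form computation", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  x <- c(0, 1, 2, 4)
  y <- c(1, 0, 3, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("filtered pearson removes the largest-error entries", {
  x <- 1:10
  expect_equal(filtered_pearson(x, x), 1.0)
  # 10 collinear points plus one gross outlier: dropping 10% restores 1
  x11 <- c(1:10, 11)
  y11 <- c(1:10, -40)
  expect_equal(filtered_pearson(x11, y11, drop_fraction = 0.10), 1.0)
  expect_gte(filtered_pearson(x11, y11), pearson_r(x11, y11))
})

test_that("predictive index equals brute force on random small instances", {
  expect_equal(predictive_index(c(0, 1, 3), c(0, 2, 1)), 1 / 3)
  expect_equal(predictive_index(c(0, 1, 3), c(0, 1, 3)), 1.0)
  expect_equal(predictive_index(c(0, 1, 3), -c(0, 1, 3)), -1.0)
  expect_true(is.na(predictive_index(c(2, 2, 2), c(1, 2, 3))))
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    e <- round(runif(n, -3, 3), 2)
    p <- round(runif(n, -3, 3), 2)
    # ties in predictions must score 0, so inject some
    p[sample(n, 2)] <- p[1]
    expect_equal(predictive_index(e, p), pi_bruteforce(e, p))
  }
})

test_that("pearson and PI are invariant under positive affine rescaling", {
  set.seed(23)
  e <- rnorm(40)
  p <- e + rnorm(40, 0, 0.7)
  expect_equal(pearson_r(e, 2.5 * p + 3), pearson_r(e, p))
  expect_equal(predictive_index(e, 2.5 * p + 3), predictive_index(e, p))
  # and under joint permutation of the pairs
  perm <- sample(40)
  expect_equal(pearson_r(e[perm], p[perm]), pearson_r(e, p))
  expect_equal(predictive_index(e[perm], p[perm]), predictive_index(e, p))
  expect_equal(mcc(classify_ddg(e[perm]), classify_ddg(p[perm])),
               mcc(classify_ddg(e), classify_ddg(p)))
})

test_that("multiclass MCC matches direct confusion-matrix evaluation", {
  expect_equal(mcc(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1.0)
  # a hand-built 3x3 confusion matrix
  cm <- matrix(c(10, 2, 1,
                 3, 8, 2,
                 0, 4, 9), nrow = 3, byrow = TRUE)
  truth <- rep(0:2, times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(i) rep(0:2, times = cm[i, ])))
  expect_equal(mcc(truth, pred), mcc_from_confusion(cm))
  # degenerate marginals are NA, not zero
  expect_true(is.na(mcc(c(1, 1, 1), c(1, 1, 1))))
})

test_that("binary-mode MCC reduces to the classical two-class formula", {
  set.seed(31)
  truth <- sample(0:2, 60, replace = TRUE)
  pred <- sample(0:2, 60, replace = TRUE)
  expect_equal(mcc(truth, pred, mode = "binary"),
               mcc_binary_classic(as.integer(truth == 2),
                                  as.integer(pred == 2)))
})

test_that("MCC of predictions independent of truth is near zero", {
  set.seed(41)
  vals <- numeric(200)
  truth <- rep(0:2, length.out = 300)
  for (k in seq_along(vals)) {
    vals[k] <- mcc(truth, sample(truth))
  }
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("classification tables count ordinal errors per category", {
  rec <- mutation_table(pdb_id = "1AAA", chain = "A",
                        position = as.character(1:4),
                        wt_aa = c("A", "A", "A", "A"),
                        mut_aa = c("V", "G", "L", "I"),
                        ddg_exp = c(2, 2, 2, -2))
  set <- benchmark_set(rec)
  # known errors 0, 0, 1, 2
  preds <- data.frame(record_id = rec$record_id,
                      ddg_pred = c(2, 2, 0, 2))
  tab <- classification_table(set, preds)
  hh <- tab[tab$category == "Hydrophobic to hydrophobic", ]
  expect_equal(hh$n_entries, 4)
  expect_equal(hh$pct_same_class, 50)
  expect_equal(hh$pct_off_by_one, 25)
  expect_equal(hh$pct_off_by_two, 25)
  expect_equal(hh$pct_same_class + hh$pct_off_by_one + hh$pct_off_by_two,
               100)
  # perfect predictions are 100/0/0 in every category
  perfect <- classification_table(set, data.frame(
    record_id = rec$record_id, ddg_pred = rec$ddg_exp))
  expect_true(all(perfect$pct_same_class == 100))
  # unmatched record ids are a join error listing the id
  expect_error(classification_table(set, preds[-1, ]),
               rec$record_id[1])
})

test_that("evaluation summarises replicates as mean and sd", {
  rec <- gen_mutation_table(synthetic_spec(n_records = 120, seed = 14))
  set <- benchmark_set(rec)
  # single replicate: all sd columns zero
  p1 <- gen_predictions(rec, noise_sd = 0.8, seed = 2)
  ev1 <- evaluate_predictions(set, p1)
  expect_true(all(ev1$summary$pearson_r_sd[
    !is.na(ev1$summary$pearson_r_sd)] == 0))
  # three identical replicates: mean equals each, sd zero
  p3 <- do.call(rbind, lapply(1:3, function(r) transform(p1, replicate = r)))
  ev3 <- evaluate_predictions(set, p3)
  everything3 <- ev3$summary[ev3$summary$category == "Everything", ]
  everything1 <- ev1$summary[ev1$summary$category == "Everything", ]
  expect_equal(everything3$pearson_r, everything1$pearson_r)
  expect_equal(everything3$pearson_r_sd, 0)
  # distinct replicates: mean/sd match direct arithmetic
  pd <- gen_predictions(rec, noise_sd = 0.8, seed = 7, n_replicates = 3)
  evd <- evaluate_predictions(set, pd)
  per <- evd$per_replicate
  r_each <- vapply(1:3, function(r) {
    sub <- per[per$replicate == r & per$category == "Everything", ]
    sub$pearson_r
  }, numeric(1))
  ev_row <- evd$summary[evd$summary$category == "Everything", ]
  expect_equal(ev_row$pearson_r, mean(r_each))
  expect_equal(ev_row$pearson_r_sd, sd(r_each))
  # global error counts are consistent with the Everything row
  n <- nrow(rec)
  expect_equal(evd$error_counts$mean_off_by_two / n * 100,
               ev_row$pct_off_by_two, tolerance = 1e-8)
})

test_that("noisy predictions recover the attenuation law", {
  rec <- gen_mutation_table(synthetic_spec(n_records = 2000, seed = 19))
  sigma_exp <- sd(rec$ddg_exp)
  preds <- gen_predictions(rec, slope = 1, noise_sd = sigma_exp, seed = 3)
  r <- pearson_r(rec$ddg_exp, preds$ddg_pred)
  target <- 1 / sqrt(2)
  se <- (1 - target^2) / sqrt(2000)
  expect_lt(abs(r - target), 3 * se)
})
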