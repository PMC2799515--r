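test_that("co-membership scores follow the inner-product identities", {
  one_hot_same <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(co_membership(one_hot_same)[1, 2], 1)
  one_hot_diff <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(co_membership(one_hot_diff)[1, 2], 0)
  G <- 8
  unif <- matrix(1 / G, 3, G)
  cm <- co_membership(unif)
  expect_equal(cm[1, 2], 1 / G)
  expect_true(all(is.na(diag(cm))))
  set.seed(1)
  tau <- matrix(rexp(40), 5, 8); tau <- tau / rowSums(tau)
  cm2 <- co_membership(tau)
  expect_equal(cm2, t(cm2))
  expect_true(all(cm2 >= 0 & cm2 <= 1, na.rm = TRUE))
})

test_that("PR curves hit the standard anchor points", {
  label <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- pr_curve(c(1, 1, 0, 0), label)
  expect_true(any(perfect$precision == 1 & perfect$recall == 1))
  expect_equal(f1_max(perfect), 1)

  inverted <- pr_curve(c(0, 0, 1, 1), label)
  tail_row <- inverted[nrow(inverted), ]
  expect_equal(tail_row$recall, 1)
  expect_equal(tail_row$precision, 0.5)  # base rate at full recall

  # recall is non-decreasing as the threshold drops
  set.seed(2)
  sc <- runif(60); lb <- runif(60) < 0.3
  pr <- pr_curve(sc, lb)
  expect_true(all(diff(pr$recall) >= 0))
  expect_error(pr_curve(sc, rep(FALSE, 60)), "no positive")
})

test_that("tied scores are processed as a block", {
  # all scores equal: single curve point at the base rate
  pr <- pr_curve(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$precision, 1 / 3)
  expect_equal(pr$recall, 1)
})

test_that("max-F1 reduces to harmonic-mean arithmetic and is rank-invariant", {
  one_point <- structure(data.frame(threshold = 1, tp = 1, fp = 1,
                                    precision = 0.5, recall = 1),
                         class = c("dyhm_pr", "data.frame"))
  expect_equal(f1_max(one_point), 2 / 3)
  other <- structure(data.frame(threshold = 1, tp = 1, fp = 0,
                                precision = 1, recall = 0.5),
                     class = c("dyhm_pr", "data.frame"))
  expect_equal(f1_max(other), 2 / 3)

  set.seed(3)
  sc <- runif(80); lb <- runif(80) < 0.25
  f_raw <- f1_max(pr_curve(sc, lb))
  f_mono <- f1_max(pr_curve(qlogis(sc / 1.0001 + 1e-9), lb))  # strictly monotone
  expect_equal(f_raw, f_mono)
})

test_that("random scores give PR area near the positive base rate", {
  set.seed(4)
  areas <- replicate(100, {
    lb <- sample(rep(c(TRUE, FALSE), c(50, 150)))
    pr_area(pr_curve(runif(200), lb))
  })
  expect_lt(abs(mean(areas) - 0.25), 0.02)
})

test_that("pooled PR differs from curve averaging when replicates are unbalanced", {
  # replicate 1: one positive ranked first among 2 pairs
  r1 <- list(score = c(0.9, 0.1), label = c(TRUE, FALSE))
  # replicate 2: larger, with poor ranking
  r2 <- list(score = c(0.8, 0.7, 0.6, 0.5), label = c(FALSE, FALSE, FALSE, TRUE))
  pooled <- aggregate_pr(list(r1, r2))
  expect_identical(aggregate_pr(list(r1)), pr_curve(r1$score, r1$label))
  # two identical replicates leave precision/recall unchanged
  twice <- aggregate_pr(list(r1, r1))
  once <- pr_curve(r1$score, r1$label)
  expect_equal(twice$precision, once$precision)
  expect_equal(twice$recall, once$recall)
  # pooled full-recall precision = 2/6; per-replicate average = (1/2 + 1/4)/2
  pool_final <- pooled[nrow(pooled), ]
  expect_equal(pool_final$precision, 2 / 6)
  avg <- mean(c(1 / 2, 1 / 4))
  expect_false(isTRUE(all.equal(pool_final$precision, avg)))
})

test_that("per-snapshot F1 helper scores a fit against planted truth", {
  sim <- generate_dynamic(pswitch = 0, T = 3, pwithin = 1, pbetween = 0, seed = 5)
  fit <- fit_dynamic(sim$series, depth = 3, lambda = 1, seed = 5)
  f1 <- f1_per_snapshot(fit, sim$truth)
  expect_length(f1, 3)
  expect_true(all(f1 > 0.99))  # disjoint cliques are trivially recovered
})
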