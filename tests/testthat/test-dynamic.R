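test_that("coupled assignment update reproduces its limiting cases", {
  f <- c(0.3, -1.2, 0.8)
  # lambda = 0: identical to the static softmax update
  expect_equal(coupled_assignment_update(f, list(c(0.2, 0.3, 0.5)), lambda = 0),
               update_assignment(f))
  expect_equal(coupled_assignment_update(f, list(), lambda = 5),
               update_assignment(f))

  # huge lambda, one neighbor: the neighbor's membership
  out <- coupled_assignment_update(c(0, 0), list(c(0.9, 0.1)), lambda = 1e6)
  expect_equal(out, c(0.9, 0.1), tolerance = 1e-4)

  # huge lambda, two opposing neighbors: normalized geometric mean
  out2 <- coupled_assignment_update(c(0, 0),
                                    list(c(0.8, 0.2), c(0.2, 0.8)),
                                    lambda = 1e6)
  expect_equal(out2, c(0.5, 0.5), tolerance = 1e-4)
  expect_error(coupled_assignment_update(f, list(), lambda = -1), "non-negative")
})

test_that("identical snapshots under any lambda match the static clustering", {
  sn <- two_cliques_snapshot(5)
  series <- snapshot_series(list(sn, sn, sn))
  for (l in c(0.5, 4)) {
    fit <- fit_dynamic(series, depth = 1, lambda = l, seed = 3)
    for (t in 1:3) {
      cm <- co_membership(fit$tau[[t]])
      expect_gt(min(cm[1:5, 1:5], na.rm = TRUE), 0.95)
      expect_lt(max(cm[1:5, 6:10]), 0.05)
    }
    # membership identical across snapshots at the symmetric fixed point
    expect_equal(fit$tau[[1]], fit$tau[[2]], tolerance = 1e-3)
  }
})

test_that("lambda = 0 with per-snapshot parameters is bit-identical to static fits", {
  sim <- generate_dynamic(pswitch = 0.1, T = 4, seed = 8)
  fit <- fit_dynamic(sim$series, depth = 2, lambda = 0, seed = 8,
                     share_params = FALSE)
  for (t in 1:4) {
    ref <- fit_static(sim$series$snapshots[[t]], depth = 2,
                      seed = dyhm:::derive_seed(8, t))
    expect_identical(fit$tau[[t]], ref$tau)
    expect_identical(fit$elbo[t], ref$elbo)
  }
})

test_that("huge lambda forces memberships constant across coupled snapshots", {
  sim <- generate_dynamic(pswitch = 0.2, T = 4, seed = 13)
  fit <- fit_dynamic(sim$series, depth = 2, lambda = 1e6, seed = 13)
  for (k in seq_len(nrow(sim$series$neighbors))) {
    t1 <- sim$series$neighbors[k, 1]; t2 <- sim$series$neighbors[k, 2]
    expect_lt(max(abs(fit$tau[[t1]] - fit$tau[[t2]])), 1e-3)
  }
})

test_that("pswitch = 0 data with strong smoothing recovers the planted groups", {
  sim <- generate_dynamic(pswitch = 0, T = 6, pwithin = 0.9, pbetween = 0.05,
                          seed = 4)
  fit <- fit_dynamic(sim$series, depth = 3, lambda = 4, seed = 4)
  f1 <- f1_per_snapshot(fit, sim$truth)
  expect_gte(mean(f1), 0.95)
  # memberships essentially constant in time
  expect_lt(max(abs(fit$tau[[1]] - fit$tau[[6]])), 0.05)
})

test_that("the dynamic objective trace is (approximately) non-increasing", {
  # The coupled update treats neighboring snapshots' memberships
  # asynchronously, so strict descent is not guaranteed; increases, when
  # they occur, must stay negligible relative to the objective scale.
  sim <- generate_dynamic(pswitch = 0.05, T = 6, seed = 2)
  for (l in c(0.25, 1)) {
    fit <- fit_dynamic(sim$series, depth = 3, lambda = l, seed = 2)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) < 1e-3 * (1 + abs(tr[-1]))))
  }
})

test_that("transition counting matches hand-tracked label moves", {
  make_fit <- function(taus) {
    structure(list(tau = taus, depth = 2L, elbo = 0, elbo_beta = 0,
                   series = snapshot_series(replicate(length(taus),
                     snapshot(cbind("v001", "v002")), simplify = FALSE))),
              class = c("dyhm_dynamic", "dyhm"))
  }
  const_tau <- function() {
    m <- matrix(1e-12, 4, 4)
    m[cbind(1:4, c(1, 1, 2, 3))] <- 1
    m <- m / rowSums(m)
    rownames(m) <- sprintf("v%03d", 1:4)
    m
  }
  # time-constant memberships: no transitions at all
  const_fit <- make_fit(list(const_tau(), const_tau(), const_tau()))
  tt0 <- count_transitions(const_fit)
  expect_equal(tt0$m, 0L)
  expect_equal(tt0$W, 0L)
  expect_equal(tt0$V, 8L)   # 4 vertices over 2 couplings
  expect_equal(tt0$M, 12L)  # G = 4 leaves

  # a single forced move: one vertex goes leaf 1 -> 2 across one coupling
  taus <- list(const_tau(), const_tau())
  taus[[2]][1, ] <- c(1e-12, 1, 1e-12, 1e-12) / sum(c(1e-12, 1, 1e-12, 1e-12))
  tt1 <- count_transitions(make_fit(taus))
  expect_equal(tt1$m, 1L)
  expect_equal(tt1$W, 1L)
  expect_equal(tt1$transitions$from, 1L)
  expect_equal(tt1$transitions$to, 2L)

  # all-to-all shuffling cannot exceed G(G-1) distinct transitions
  set.seed(14)
  shuffled <- lapply(1:6, function(t) {
    m <- matrix(1e-12, 12, 4)
    m[cbind(1:12, sample.int(4, 12, TRUE))] <- 1
    m <- m / rowSums(m)
    rownames(m) <- sprintf("v%03d", 1:12)
    m
  })
  tts <- count_transitions(make_fit(shuffled))
  expect_lte(tts$m, 12L)
})

test_that("penalized likelihood applies the binomial-coefficient penalty", {
  # log C(56, 5) = log 3,819,816 (Beta-binomial transition marginal)
  expect_equal(lchoose(56, 5), log(3819816))
  # symmetry of the coefficient: m = M and m = 0 are unpenalized
  expect_equal(lchoose(56, 56), 0)
  expect_gt(lchoose(56, 28), lchoose(56, 5))

  # a time-constant fit pays no penalty: score equals its bound
  sim <- generate_dynamic(pswitch = 0, T = 3, pwithin = 1, pbetween = 0,
                          seed = 6)
  fit <- fit_dynamic(sim$series, depth = 3, lambda = 4, seed = 6)
  tt <- count_transitions(fit)
  expect_equal(penalized_likelihood(fit),
               sum(fit$elbo) + fit$elbo_beta - lchoose(tt$M, tt$m))
  expect_equal(tt$m, 0L)  # disjoint constant cliques: nothing moves
})

test_that("lambda selection scores the whole grid and breaks ties toward smoothness", {
  # identical snapshots: scores tie across the upper grid; larger lambda wins
  sn <- two_cliques_snapshot(4)
  series <- snapshot_series(list(sn, sn, sn))
  sel <- select_lambda(series, depth = 1, grid = c(0.5, 1, 2), seed = 1)
  expect_equal(sel$scores$lambda, c(0.5, 1, 2))
  expect_true(all(is.finite(sel$scores$penalized)))
  scores <- sel$scores$penalized
  ties <- which(scores >= max(scores) - 1e-9)
  expect_equal(sel$lambda, sel$scores$lambda[max(ties)])
  # the returned fit is the fit at the selected lambda
  expect_equal(sel$fit$lambda, sel$lambda)
  expect_error(select_lambda(series, depth = 1, grid = numeric(0)), "empty")
})
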