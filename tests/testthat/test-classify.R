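test_that("class covariances are trace-normalized within-class means", {
  data <- array(0, c(4, 2, 1000))
  withr::with_seed(1, {
    base <- matrix(rnorm(2 * 1000), 2)
    for (i in 1:2) data[i, , ] <- base            # identical MA trials
    for (i in 3:4) data[i, , ] <- matrix(rnorm(2 * 1000), 2)
  })
  ep <- make_epochs(data, c("MA", "MA", "LC", "LC"), fs = 100, t0 = -2)
  cc <- class_covariances(ep, window = c(0, 8))
  expect_equal(cc$classes[1], "MA")
  expect_equal(sum(diag(cc$cov1)), 1, tolerance = 1e-12)
  expect_equal(sum(diag(cc$cov2)), 1, tolerance = 1e-12)
  # identical trials: class covariance equals the single-trial normalized one
  tsel <- ep$times >= 0 & ep$times < 8
  filt <- earbci:::butter_design(1, 49, 100, 4)
  xf <- rbind(earbci:::zero_phase(data[1, 1, ], filt)[tsel],
              earbci:::zero_phase(data[1, 2, ], filt)[tsel])
  c1 <- tcrossprod(xf) / sum(tsel)
  expect_equal(cc$cov1, c1 / sum(diag(c1)), tolerance = 1e-10)
  expect_error(class_covariances(ep, labels = rep("MA", 4)), "two classes")
})

test_that("CSP solves the generalized eigenproblem with whitening and pairing", {
  # equal class covariances: all eigenvalues 1/2
  c0 <- random_spd(6, seed = 4)
  c0 <- c0 / sum(diag(c0))
  eq <- csp_fit(c0, c0, n_keep = 2, ridge = 0)
  expect_equal(eq$eigenvalues, rep(0.5, 6), tolerance = 1e-8)

  # hand case: diagonal covariances -> axis-aligned filters, lambda 2/3, 1/3
  d1 <- diag(c(2, 1)) / 3
  d2 <- diag(c(1, 2)) / 3
  hand <- csp_fit(d1, d2, n_keep = 1, ridge = 0)
  expect_equal(hand$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-9)
  w1 <- hand$filters[, 1]
  expect_lt(abs(abs(w1[1] / sqrt(sum(w1^2))) - 1), 1e-8)

  # whitening property and eigenvalue pairing on random SPD pairs
  for (s in 1:5) {
    c1 <- random_spd(6, seed = 100 + s)
    c2 <- random_spd(6, seed = 200 + s)
    mdl <- csp_fit(c1, c2, n_keep = 2, ridge = 0)
    wtw <- t(mdl$filters) %*% (c1 + c2) %*% mdl$filters
    expect_equal(wtw, diag(nrow(wtw)), tolerance = 1e-6)
    swapped <- csp_fit(c2, c1, n_keep = 2, ridge = 0)
    expect_equal(mdl$eigenvalues + rev(swapped$eigenvalues),
                 rep(1, 6), tolerance = 1e-8)
    expect_true(all(diff(mdl$eigenvalues) <= 1e-12))
    expect_true(all(mdl$eigenvalues >= -1e-9 & mdl$eigenvalues <= 1 + 1e-9))
  }
  expect_error(csp_fit(random_spd(4, 1), random_spd(6, 2)), "dimension")
  expect_error(csp_fit(d1, d2, n_keep = 2), "rank")
})

test_that("multi-band CSP features count, scale shift and fit/apply consistency", {
  ep <- gaussian_epochs(12, ns = 800)
  f <- multiband_csp_features(ep)
  expect_equal(dim(f), c(24, 20))            # 5 bands x (2 + 2) components

  models <- attr(f, "csp_models")
  f_apply <- multiband_csp_features(ep, models = models)
  expect_equal(unclass(f_apply)[, ], unclass(f)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  # scaling a trial by k shifts every log-variance feature by 2 log k
  ep2 <- ep
  ep2$data[3, , ] <- ep2$data[3, , ] * 5
  f2 <- multiband_csp_features(ep2, models = models)
  expect_equal(f2[3, ] - f[3, ], rep(2 * log(5), 20), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(f2[-3, ], f[-3, ], ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Ledoit-Wolf intensity approaches its limits", {
  withr::with_seed(5, {
    # truth equal to the nu*I target: full shrinkage is optimal
    big <- matrix(rnorm(10000 * 4), 10000, 4)
    expect_equal(ledoit_wolf_gamma(big), 1)
    # strongly structured covariance: almost no shrinkage; the frozen value
    # was cross-checked against an independent shrinkage implementation
    z <- matrix(rnorm(2000), 2000, 1)
    corr <- z %*% matrix(1, 1, 6) + 0.3 * matrix(rnorm(2000 * 6), 2000, 6)
    g <- ledoit_wolf_gamma(scale(corr, scale = FALSE))
    expect_equal(g, 0.0013923594, tolerance = 1e-6)
    expect_lt(g, 0.01)
    # two samples in twenty dimensions: strong shrinkage
    tiny <- matrix(rnorm(2 * 20), 2, 20)
    expect_gt(ledoit_wolf_gamma(tiny), 0.3)
  })
  expect_equal(ledoit_wolf_gamma(matrix(0, 5, 3)), 1)
  expect_error(ledoit_wolf_gamma(matrix(1, 1, 3)), "observations")
})

test_that("shrinkage LDA recovers the Bayes rule and degenerates gracefully", {
  withr::with_seed(6, {
    # far-separated clouds: perfect training accuracy
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
    y <- rep(c("MA", "LC"), each = 20)
    mdl <- slda_fit(x, y)
    expect_equal(mean(slda_predict(mdl, x) == y), 1)
    expect_true(mdl$gamma >= 0 && mdl$gamma <= 1)

    # gamma = 1 equals the nearest-class-mean rule
    m1 <- slda_fit(x, y, gamma = 1)
    mu <- rbind(colMeans(x[1:20, ]), colMeans(x[21:40, ]))
    near <- apply(x, 1, function(r) {
      c("MA", "LC")[which.min(c(sum((r - mu[1, ])^2), sum((r - mu[2, ])^2)))]
    })
    expect_equal(slda_predict(m1, x), near)

    # Bayes direction recovery within 5 degrees at n = 5000, known Sigma
    sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
    ch <- chol(sigma)
    n <- 5000
    x1 <- matrix(rnorm(n * 2), n) %*% ch
    x2 <- sweep(matrix(rnorm(n * 2), n) %*% ch, 2, c(-1, 0.5), `+`)
    xx <- rbind(x1, x2)
    yy <- rep(c("MA", "LC"), each = n)
    fit <- slda_fit(xx, yy)
    bayes <- solve(sigma, c(0, 0) - c(-1, 0.5))
    ang <- acos(sum(fit$w * bayes) /
                  sqrt(sum(fit$w^2) * sum(bayes^2))) * 180 / pi
    expect_lt(ang, 5)
  })
  expect_error(slda_fit(matrix(rnorm(10), 5), rep("MA", 5)), "two classes")
})

test_that("repeated stratified cross-validation counts folds and finds separable structure", {
  ep <- gaussian_epochs(20, scale_ma = 3, ns = 800, seed = 7)
  cv <- cross_validate(ep, k = 10, reps = 10, seed = 1)
  expect_equal(nrow(cv$folds), 100)
  expect_equal(cv$mean, mean(cv$folds$accuracy))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 100))
  expect_gt(cv$mean, 95)
  expect_identical(cross_validate(ep, k = 5, reps = 2, seed = 3)$folds,
                   cross_validate(ep, k = 5, reps = 2, seed = 3)$folds)
  expect_error(cross_validate(ep, k = 30), "stratified")
})

test_that("label shuffling on separable data drops accuracy to chance", {
  ep <- gaussian_epochs(30, scale_ma = 3, ns = 600, seed = 8)
  shuffled <- withr::with_seed(9, sample(ep$labels))
  cv <- cross_validate(ep, labels = shuffled, k = 10, reps = 3, seed = 10)
  n <- length(shuffled)
  ci <- 100 * qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_gte(cv$mean, ci[1])
  expect_lte(cv$mean, ci[2])
})

test_that("accuracies are invariant to channel reordering", {
  ep <- gaussian_epochs(12, scale_ma = 2, ns = 600, seed = 11)
  perm <- c(4, 2, 6, 1, 3, 5)
  ep_perm <- ep
  ep_perm$data <- ep$data[, perm, ]
  ep_perm$channels <- ep$channels[perm]
  cv1 <- cross_validate(ep, k = 6, reps = 2, seed = 12)
  cv2 <- cross_validate(ep_perm, k = 6, reps = 2, seed = 12)
  expect_equal(cv1$folds$accuracy, cv2$folds$accuracy, tolerance = 1e-8)
})
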