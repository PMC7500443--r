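test_that("trial covariance is symmetric, trace-normalized and concentrates", {
  set.seed(1)
  ## white-noise epoch, many samples: off-diagonals vanish
  X <- matrix(rnorm(8 * 1e5), 8)
  C <- trial_covariance(X)
  expect_equal(sum(diag(C)), 1, tolerance = 1e-12)
  expect_equal(C, t(C))
  expect_lt(max(abs(C[upper.tri(C)])), 0.02)
  ## single active channel
  X1 <- matrix(0, 4, 100); X1[2, ] <- rnorm(100)
  C1 <- trial_covariance(X1)
  expect_equal(C1[2, 2], 1)
  expect_equal(sum(abs(C1)) - C1[2, 2], 0)
  expect_error(trial_covariance(matrix(0, 4, 100)), "zero-variance")
})

test_that("csp_fit solves the diagonal case analytically", {
  C_pre <- diag(c(2, 1)) / 3
  C_post <- diag(c(1, 2)) / 3
  fit <- csp_fit(C_pre, C_post, gamma = 0)
  expect_equal(fit$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-9)
  w1 <- fit$W[, 1] / max(abs(fit$W[, 1]))
  expect_equal(abs(w1), c(1, 0), tolerance = 1e-9)
  ## Rayleigh pre/post ratio of the top filter
  w <- fit$W[, 1]
  expect_equal(drop(w %*% C_pre %*% w / (w %*% C_post %*% w)), 2,
               tolerance = 1e-9)
  ## swapping inputs reverses the filter order (up to sign)
  fit_sw <- csp_fit(C_post, C_pre, gamma = 0)
  agree <- abs(sum(fit_sw$W[, 2] * fit$W[, 1])) /
    sqrt(sum(fit_sw$W[, 2]^2) * sum(fit$W[, 1]^2))
  expect_equal(agree, 1, tolerance = 1e-9)
})

test_that("csp filters satisfy the generalized eigen relation and optimality", {
  set.seed(2)
  for (rep in 1:3) {
    A <- matrix(rnorm(24 * 8), 24); B <- matrix(rnorm(24 * 8), 24)
    C_pre <- crossprod(A) / 24; C_pre <- C_pre / sum(diag(C_pre))
    C_post <- crossprod(B) / 24; C_post <- C_post / sum(diag(C_post))
    fit <- csp_fit(C_pre, C_post, gamma = 0)   # inputs already PD
    comp <- C_pre + C_post
    ## residual of the generalized eigenproblem for every unit-norm filter
    for (j in seq_len(8)) {
      w <- fit$W[, j] / sqrt(sum(fit$W[, j]^2))
      r <- C_pre %*% w - fit$eigenvalues[j] * comp %*% w
      expect_lt(max(abs(r)), 1e-8)
    }
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    expect_true(all(fit$eigenvalues >= -1e-12 & fit$eigenvalues <= 1 + 1e-12))
    ## random-search Rayleigh oracle: 1e5 unit vectors cannot beat the filter
    V <- matrix(rnorm(8 * 1e5), 8)
    num <- colSums(V * (C_pre %*% V))
    den <- colSums(V * (C_post %*% V))
    w <- fit$W[, 1]
    best_rand <- max(num / den)
    expect_gte(drop(w %*% C_pre %*% w / (w %*% C_post %*% w)),
               best_rand * (1 - 1e-9))
    ## activation patterns invert the filters: A^T W = I
    expect_equal(crossprod(fit$patterns, fit$W), diag(8), tolerance = 1e-8)
  }
  expect_error(csp_fit(diag(2) * 0, diag(2) * 0, gamma = 0),
               "positive definite")
})

test_that("leave-one-trial-out equals a from-scratch refit oracle, byte for byte", {
  set.seed(3)
  p <- rnorm(6); p <- p / sqrt(sum(p^2))
  pre <- as_epochs(source_epochs(20, p, amp = 1), "pre")
  post <- as_epochs(source_epochs(20, p, amp = 0.6), "post")
  comp <- loto_components(pre, post)
  ## naive oracle: for each fold, recompute covariances from scratch and
  ## refit; identical fold bookkeeping must give identical bytes
  n <- 20
  for (i in c(1, 7, 20)) {
    keep <- setdiff(1:n, i)
    Cp <- 0; Cq <- 0
    for (j in keep) {
      Xp <- pre$data[j, , ]; Xq <- post$data[j, , ]
      Cpj <- tcrossprod(Xp) / ncol(Xp); Cp <- Cp + Cpj / sum(diag(Cpj))
      Cqj <- tcrossprod(Xq) / ncol(Xq); Cq <- Cq + Cqj / sum(diag(Cqj))
    }
    fit <- csp_fit(Cp / (n - 1), Cq / (n - 1))
    w <- fit$W[, 1]
    got <- comp$filters$csp_pre[i, ]
    ## sign alignment may flip the stored filter; compare up to sign
    if (sum(w * got) < 0) w <- -w
    expect_identical(got, w)
  }
})

test_that("mutating one trial only changes that trial's components", {
  set.seed(4)
  p <- rnorm(5); p <- p / sqrt(sum(p^2))
  pre_a <- source_epochs(12, p, amp = 1)
  post_a <- source_epochs(12, p, amp = 0.6)
  comp_a <- loto_components(as_epochs(pre_a, "pre"), as_epochs(post_a, "post"))
  pre_b <- pre_a
  pre_b[5, , ] <- pre_b[5, , ] + matrix(rnorm(5 * 250), 5)
  comp_b <- loto_components(as_epochs(pre_b, "pre"), as_epochs(post_a, "post"))
  ## trial 5's own filter is fit WITHOUT trial 5: identical filter, but its
  ## pre component reflects the mutated data
  expect_identical(comp_a$filters$csp_pre[5, ], comp_b$filters$csp_pre[5, ])
  expect_false(identical(comp_a$csp_pre$pre[5, ], comp_b$csp_pre$pre[5, ]))
  ## every other trial's filter and components change only through the
  ## refit; their post components (unchanged data) may shift, but trial 5 is
  ## the only one whose own input changed -- verify exclusion both ways
  same_input <- setdiff(1:12, 5)
  changed_filters <- vapply(same_input, function(i) {
    !isTRUE(all.equal(comp_a$filters$csp_pre[i, ], comp_b$filters$csp_pre[i, ]))
  }, logical(1))
  expect_true(all(changed_filters))   # all other folds saw the mutation
  expect_error(loto_components(as_epochs(pre_a[1:2, , ]),
                               as_epochs(post_a[1:2, , ])), "3 trials")
})

test_that("identical trials give identical fold filters", {
  set.seed(5)
  X <- matrix(rnorm(4 * 250), 4)
  Y <- matrix(rnorm(4 * 250), 4)
  pre <- array(0, c(6, 4, 250)); post <- array(0, c(6, 4, 250))
  for (i in 1:6) { pre[i, , ] <- X; post[i, , ] <- Y }
  comp <- loto_components(as_epochs(pre, "pre"), as_epochs(post, "post"))
  W <- comp$filters$csp_pre
  for (i in 2:6) {
    cosang <- sum(W[1, ] * W[i, ]) / sqrt(sum(W[1, ]^2) * sum(W[i, ]^2))
    expect_lt(acos(min(abs(cosang), 1)), 1e-6)
  }
})

test_that("component alpha power reduces to the channel power for a delta filter", {
  ## construct a world where the CSP solution IS a delta filter on channel 3:
  ## channel 3 carries all the pre/post contrast, other channels white noise
  set.seed(6)
  nch <- 5; n <- 12
  pre <- array(rnorm(n * nch * 250, sd = 0.1), c(n, nch, 250))
  post <- pre
  for (i in 1:n) {
    s <- sin(2 * pi * 10 * (1:250) / 500 + runif(1, 0, 2 * pi))
    pre[i, 3, ] <- pre[i, 3, ] + 3 * s
    post[i, 3, ] <- post[i, 3, ] + 0.5 * s
  }
  comp <- loto_components(as_epochs(pre, "pre"), as_epochs(post, "post"))
  ## filters concentrate on channel 3
  w_norm <- abs(comp$filters$csp_pre) /
    sqrt(rowSums(comp$filters$csp_pre^2))
  expect_true(all(w_norm[, 3] > 0.99))
  pp <- component_alpha_power(comp, 10, 500)
  expect_true(all(pp$alpha_power >= 0))
  ## power values scale with the squared channel-3 weight: ratios match the
  ## directly computed channel-3 window power ratios
  w3 <- comp$filters$csp_pre[, 3]
  direct_pre <- window_alpha_power(pre[1, 3, ], 10, 500)
  got_pre <- pp$alpha_power[pp$source == "CSPpre" & pp$window == "pre"][1]
  expect_equal(got_pre / w3[1]^2, direct_pre, tolerance = 0.05)
})

test_that("filter scale invariance: scaling epochs leaves power ratios unchanged", {
  set.seed(7)
  p <- rnorm(6); p <- p / sqrt(sum(p^2))
  pre <- source_epochs(10, p, amp = 1)
  post <- source_epochs(10, p, amp = 0.6)
  c1 <- loto_components(as_epochs(pre, "pre"), as_epochs(post, "post"))
  c2 <- loto_components(as_epochs(pre * 3.7, "pre"),
                        as_epochs(post * 3.7, "post"))
  p1 <- component_alpha_power(c1, 10, 500)
  p2 <- component_alpha_power(c2, 10, 500)
  r1 <- p1$alpha_power[p1$window == "post"] / p1$alpha_power[p1$window == "pre"]
  r2 <- p2$alpha_power[p2$window == "post"] / p2$alpha_power[p2$window == "pre"]
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("ground-truth pattern is recovered from 31-channel mixtures", {
  ## single suppressed source at SNR >= 0 dB; cosine similarity of the
  ## CSP(pre) pattern with the true mixing pattern across subjects
  layout <- build_montage()
  set.seed(8)
  sims <- replicate(12, {
    p <- alpha_source_pattern(layout, jitter_sd = 0.1)
    pre <- as_epochs(source_epochs(24, p, amp = 12, noise_sd = 1), "pre")
    post <- as_epochs(source_epochs(24, p, amp = 7, noise_sd = 1), "post")
    comp <- loto_components(pre, post)
    abs(sum(comp$patterns$csp_pre * p)) /
      sqrt(sum(comp$patterns$csp_pre^2) * sum(p^2))
  })
  expect_gte(median(sims), 0.9)
})

test_that("group-average pattern is sign-aligned and localizes posteriorly", {
  layout <- build_montage()
  ## single subject: identity
  set.seed(9)
  v <- rnorm(31)
  expect_equal(average_pattern(matrix(v, 1), layout)$weight, v)
  ## flipping one subject's sign leaves the aligned average unchanged
  P <- t(replicate(6, v + rnorm(31, sd = 0.1)))
  avg1 <- average_pattern(P, layout)
  P_flip <- P; P_flip[3, ] <- -P_flip[3, ]
  avg2 <- average_pattern(P_flip, layout)
  expect_equal(avg1$weight, avg2$weight)
  ## cohort with a posterior generator: absolute maximum inside the POC set
  pats <- t(replicate(10, {
    p <- alpha_source_pattern(layout, jitter_sd = 0.15)
    p * sample(c(-1, 1), 1)
  }))
  avg <- average_pattern(pats, layout)
  expect_true(avg$label[which.max(abs(avg$weight))] %in% poc_channels())
})
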