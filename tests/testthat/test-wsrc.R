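test_that("gaussian_similarity has the closed-form values", {
  a <- rnorm(10)
  expect_equal(gaussian_similarity(a, a, 1.5), 1.0)
  b <- a + c(sqrt(2) * 1.5, rep(0, 9))  # ||a-b||^2 = 2 sigma^2
  expect_equal(gaussian_similarity(a, b, 1.5), exp(-1))
  set.seed(420)
  x <- rnorm(7); y <- rnorm(7); s <- runif(1, 0.5, 3)
  expect_equal(gaussian_similarity(x, y, s),
               exp(-sum((x - y)^2) / (2 * s^2)))
  expect_error(gaussian_similarity(rnorm(3), rnorm(4), 1), "mismatch")
})

test_that("wsrc_dictionary normalises columns and keeps the originals' norms", {
  set.seed(421)
  X <- matrix(rnorm(12 * 6), 12, 6) * 5
  d <- wsrc_dictionary(X, rep(0:1, 3))
  expect_equal(sqrt(colSums(d$columns^2)), rep(1, 6), tolerance = 1e-10)
  expect_equal(sweep(d$columns, 2, d$column_norms, "*"), X)
  expect_error(wsrc_dictionary(cbind(X, 0), rep(0:1, length.out = 7)),
               "zero column")
})

test_that("weight_matrix is extremal at an exact dictionary match", {
  set.seed(422)
  X <- matrix(rnorm(8 * 5), 8, 5)
  d <- wsrc_dictionary(X, c(0, 0, 1, 1, 1))
  y <- d$columns[, 3]
  w_lit <- weight_matrix(y, d, wsrc_config(weight_mode = "literal"))
  expect_equal(w_lit[3], 1.0)
  expect_equal(which.max(w_lit), 3L)
  w_inv <- weight_matrix(y, d, wsrc_config(weight_mode = "inverse"))
  expect_equal(w_inv[3], 1.0)
  expect_equal(which.min(w_inv), 3L)
  # elementwise oracle
  cfg <- wsrc_config(sigma = 2.2)
  w <- weight_matrix(y, d, cfg)
  expect_equal(w, vapply(seq_len(5), function(j)
    gaussian_similarity(y, d$columns[, j], 2.2), numeric(1)))
})

test_that("solve_weighted_l1 handles analytic special cases", {
  y <- c(0.6, 0.8, 0)
  a <- solve_weighted_l1(y, matrix(y, ncol = 1), w = 3, epsilon = 1e-9)
  expect_equal(as.numeric(a), 1, tolerance = 1e-6)
  # orthogonal columns force the indicator solution
  X <- diag(3)
  a2 <- solve_weighted_l1(c(1, 0, 0), X, w = rep(1, 3), epsilon = 0.005)
  expect_equal(as.numeric(a2), c(0.995, 0, 0), tolerance = 1e-4)
  # query already inside the ball
  a3 <- solve_weighted_l1(c(1e-4, 0), diag(2), w = c(1, 1), epsilon = 0.005)
  expect_equal(as.numeric(a3), c(0, 0))
})

test_that("solve_weighted_l1 reports infeasible instances", {
  # single off-axis column cannot reach y
  expect_error(
    solve_weighted_l1(c(0, 1, 0), matrix(c(1, 0, 0), ncol = 1), 1, 0.1),
    "infeasible")
  # two coplanar columns, query out of plane
  X <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_error(solve_weighted_l1(c(0, 0, 1), X, c(1, 1), 0.1), "infeasible")
})

test_that("solutions are feasible and near-optimal on random instances", {
  eps <- 0.005
  for (i in 1:12) {
    inst <- random_l1_instance(d = 10, n = 20, seed = 430 + i)
    a <- solve_weighted_l1(inst$y, inst$X, inst$w, eps)
    res <- sqrt(sum((inst$y - inst$X %*% as.numeric(a))^2))
    expect_lte(res, eps + 10 * 1e-6)
    expect_equal(attr(a, "objective"), sum(inst$w * abs(a)))
  }
})

test_that("classification recovers an exact training column", {
  set.seed(440)
  X <- qr.Q(qr(matrix(rnorm(36), 6, 6)))  # orthogonal columns
  labels <- c(1, 1, 1, 0, 0, 0)
  d <- wsrc_dictionary(X, labels)
  s <- wsrc_classify(X[, 2], d)
  expect_identical(s$label, 1L)
  # the solver stops at the epsilon boundary, so the class-1 residual is ~eps
  expect_lt(s$residuals[["1"]], 2 * 0.005)
  expect_gt(s$residuals[["0"]], 0.9)
  expect_gt(s$score, 0)
})

test_that("ties go to the non-interacting class and score sign matches label", {
  # perfectly symmetric construction: residuals equal by symmetry
  X <- cbind(c(1, 0), c(0, 1))
  d <- wsrc_dictionary(X, c(0, 1))
  y <- c(1, 1) / sqrt(2)
  s <- wsrc_classify(y, d)
  expect_equal(unname(diff(s$residuals)), 0, tolerance = 1e-6)
  expect_identical(s$label, 0L)
  set.seed(441)
  for (i in 1:10) {
    inst <- random_l1_instance(8, 16, seed = 450 + i)
    d <- wsrc_dictionary(inst$X, rep(0:1, 8))
    s <- wsrc_classify(inst$y, d)
    expect_identical(s$label == 1L, s$score > 0)
  }
})

test_that("huge sigma reduces both weight modes to unweighted SRC", {
  inst <- random_l1_instance(10, 20, seed = 460)
  d <- wsrc_dictionary(inst$X, rep(0:1, 10))
  s_lit <- wsrc_classify(inst$y, d, wsrc_config(sigma = 1e6))
  s_inv <- wsrc_classify(inst$y, d,
                         wsrc_config(sigma = 1e6, weight_mode = "inverse"))
  s_unw <- solve_weighted_l1(inst$y / sqrt(sum(inst$y^2)), d$columns,
                             rep(1, 20), 0.005)
  expect_equal(s_lit$alpha, s_inv$alpha, tolerance = 1e-4)
  expect_equal(s_lit$alpha, as.numeric(s_unw), tolerance = 1e-4)
})

test_that("well-separated Gaussian classes are classified accurately", {
  set.seed(470)
  dims <- 60
  # class means of norm 2, orthogonal to each other (cluster separation well
  # above the within-class spread of ~0.2*sqrt(60))
  mu1 <- rnorm(dims); mu1 <- 2 * mu1 / sqrt(sum(mu1^2))
  mu0 <- rnorm(dims); mu0 <- mu0 - sum(mu0 * mu1) * mu1 / 4
  mu0 <- 2 * mu0 / sqrt(sum(mu0^2))
  draw <- function(n, mu) t(replicate(n, mu + 0.2 * rnorm(dims)))
  Xtr <- rbind(draw(50, mu1), draw(50, mu0))
  ytr <- rep(c(1, 0), each = 50)
  Xte <- rbind(draw(25, mu1), draw(25, mu0))
  yte <- rep(c(1, 0), each = 25)
  d <- wsrc_dictionary(t(Xtr), ytr)
  for (mode in c("literal", "inverse")) {
    cfg <- wsrc_config(weight_mode = mode)
    pred <- vapply(seq_len(nrow(Xte)), function(i)
      wsrc_classify(Xte[i, ], d, cfg)$label, integer(1))
    expect_gte(mean(pred == yte), 0.95)
  }
})
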