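test_that("kernel matrices match elementwise brute force", {
  A <- withr::with_seed(1, matrix(rnorm(10), 5, 2))
  B <- withr::with_seed(2, matrix(rnorm(6), 3, 2))
  h <- 1.7
  K <- kernel_matrix(A, B, rbf_kernel(h))
  for (i in 1:5) {
    for (j in 1:3) {
      expect_equal(K[i, j], exp(-h * sum((A[i, ] - B[j, ])^2)))
    }
  }
  expect_equal(diag(kernel_matrix(A, kernel = rbf_kernel(h))), rep(1, 5))
  expect_equal(kernel_matrix(A, B, linear_kernel()), tcrossprod(A, B))
  # h -> 0 flattens the RBF kernel toward 1
  expect_true(all(abs(kernel_matrix(A, B, rbf_kernel(1e-10)) - 1) < 1e-8))
  expect_error(kernel_matrix(A, matrix(0, 2, 3)), "dimensionality")
})

test_that("two-point problem recovers the maximal-margin closed form", {
  X <- rbind(c(0, 0), c(2, 0))
  y <- c(-1, 1)
  K <- kernel_matrix(X, kernel = linear_kernel())
  sol <- solve_weighted_dual(K, y, weights = c(1, 1), C = 1e6)
  # stationarity: w = alpha (x2 - x1) and w . (x2 - x1) = 2 at the margins,
  # so alpha = 2 / ||x1 - x2||^2 = 1/2 here
  expect_equal(sol$alpha, rep(1 / 2, 2), tolerance = 1e-6)
  # boundary passes through the midpoint
  f_mid <- sum(sol$alpha * y * (X %*% c(1, 0))) + sol$b
  expect_equal(f_mid, 0, tolerance = 1e-6)
  expect_equal(sum(y * sol$alpha), 0, tolerance = 1e-6)
})

test_that("dual objective matches an independent dense-QP solver", {
  for (s in 1:30) {
    d <- random_dataset(300 + s, n_pos = 4, n_neg = 4, sd = 0.8)
    X <- as.matrix(d[, c("x1", "x2")])
    y <- as.numeric(d$label)
    K <- kernel_matrix(X, kernel = rbf_kernel(1))
    w <- withr::with_seed(s, runif(8, 0.2, 1))
    C <- 10
    sol <- solve_weighted_dual(K, y, w, C, tol = 1e-8)
    H <- (y %o% y) * K + diag(1e-10, 8)
    qp <- kernlab::ipop(c = rep(-1, 8), H = H, A = matrix(y, 1),
                        b = 0, l = rep(0, 8), u = w * C, r = 0,
                        sigf = 9, maxiter = 100)
    obj_qp <- dual_objective(kernlab::primal(qp), K, y)
    expect_equal(sol$objective, obj_qp, tolerance = 1e-6)
    expect_gte(sol$objective, obj_qp - 1e-6 * max(1, abs(obj_qp)))
  }
})

test_that("solutions satisfy the KKT conditions", {
  eps <- 1e-4
  for (s in 1:25) {
    d <- random_dataset(500 + s, n_pos = 6, n_neg = 12, sd = 0.7)
    X <- as.matrix(d[, c("x1", "x2")])
    y <- as.numeric(d$label)
    K <- kernel_matrix(X, kernel = rbf_kernel(2))
    w <- withr::with_seed(s, runif(18, 0.1, 1))
    C <- 5
    sol <- solve_weighted_dual(K, y, w, C, tol = 1e-7)
    f <- as.numeric(K %*% (sol$alpha * y)) + sol$b
    m <- y * f
    ub <- w * C
    at_zero <- sol$alpha < 1e-8 * C
    at_up <- sol$alpha > ub - 1e-8 * C
    free <- !at_zero & !at_up
    expect_true(all(m[at_zero] >= 1 - eps))
    expect_true(all(abs(m[free] - 1) <= eps))
    expect_true(all(m[at_up] <= 1 + eps))
    expect_lt(abs(sum(y * sol$alpha)), 1e-6)
  }
})

test_that("solver dominates random feasible points", {
  d <- random_dataset(901, n_pos = 4, n_neg = 4)
  X <- as.matrix(d[, c("x1", "x2")])
  y <- as.numeric(d$label)
  K <- kernel_matrix(X, kernel = rbf_kernel(1))
  C <- 3
  w <- rep(1, 8)
  sol <- solve_weighted_dual(K, y, w, C)
  withr::with_seed(77, {
    for (i in 1:1000) {
      a <- runif(8, 0, C)
      # project onto the equality constraint along y
      a <- pmin(pmax(a - y * sum(y * a) / 8, 0), C)
      if (abs(sum(y * a)) > 1e-10) next
      expect_lte(dual_objective(a, K, y), sol$objective + 1e-8)
    }
  })
})

test_that("unit weights reproduce a reference standard SVM", {
  d <- random_dataset(42, n_pos = 15, n_neg = 30, sd = 0.6)
  X <- as.matrix(d[, c("x1", "x2")])
  h <- 2
  C <- 10
  fit <- rifsvm(d, scheme = "unit", C = C, kernel = rbf_kernel(h),
                tol = 1e-8)
  ref <- e1071::svm(X, factor(d$label), scale = FALSE, kernel = "radial",
                    gamma = h, cost = C, tolerance = 1e-8)
  f_ref <- attr(predict(ref, X, decision.values = TRUE), "decision.values")
  # e1071 orients its decision values by first-class convention
  sgn <- if (colnames(f_ref)[1] == "1/-1" || colnames(f_ref)[1] == "1/ -1") 1 else -1
  expect_equal(decision_values(fit, d), sgn * as.numeric(f_ref),
               tolerance = 1e-4)
})

test_that("zero weight is equivalent to deleting the instance", {
  d <- random_dataset(13, n_pos = 8, n_neg = 16)
  w <- rep(1, nrow(d))
  w[3] <- 0
  fit_w <- rifsvm(d, scheme = "unit", C = 5, kernel = rbf_kernel(1),
                  weights = w, tol = 1e-8)
  fit_d <- rifsvm(d[-3, ], scheme = "unit", C = 5, kernel = rbf_kernel(1),
                  tol = 1e-8)
  probe <- random_dataset(14, n_pos = 5, n_neg = 5)
  expect_equal(decision_values(fit_w, probe), decision_values(fit_d, probe),
               tolerance = 1e-6)
})

test_that("inactive box bounds make the solution C-invariant", {
  d <- separated_clusters(6, n_pos = 10, n_neg = 15)
  fit1 <- rifsvm(d, scheme = "unit", C = 100, kernel = rbf_kernel(0.1),
                 tol = 1e-8)
  expect_true(all(fit1$alpha < fit1$weights * fit1$C - 1e-6))  # interior
  fit2 <- rifsvm(d, scheme = "unit", C = 200, kernel = rbf_kernel(0.1),
                 tol = 1e-8)
  probe <- separated_clusters(7)
  expect_equal(decision_values(fit1, probe), decision_values(fit2, probe),
               tolerance = 1e-5)
})

test_that("unit scheme equals the rif path with weights forced to one", {
  d <- random_dataset(19, n_pos = 10, n_neg = 20)
  f_unit <- rifsvm(d, scheme = "unit", C = 2, kernel = rbf_kernel(1))
  f_forced <- rifsvm(d, scheme = "rif", C = 2, kernel = rbf_kernel(1),
                     weights = rep(1, nrow(d)))
  expect_equal(f_unit$alpha, f_forced$alpha)
  expect_equal(f_unit$b, f_forced$b)
})

test_that("translating the data shifts the linear-kernel bias accordingly", {
  d <- random_dataset(23, n_pos = 8, n_neg = 16, sd = 0.4)
  fit <- rifsvm(d, scheme = "unit", C = 10, kernel = linear_kernel(),
                tol = 1e-8)
  shift <- c(2, -1)
  d2 <- d
  d2$x1 <- d$x1 + shift[1]
  d2$x2 <- d$x2 + shift[2]
  fit2 <- rifsvm(d2, scheme = "unit", C = 10, kernel = linear_kernel(),
                 tol = 1e-8)
  w_vec <- colSums(fit$sv_coef * fit$sv_x)
  expect_equal(fit2$b, fit$b - sum(w_vec * shift), tolerance = 1e-4)
})

test_that("cost-sensitive and imbalance-scaled forms coincide", {
  # multiplying majority weights by IR under one C equals using the raw
  # scores with per-class costs C- = IR * C, C+ = C: the upper bounds are
  # identical, hence so is the dual
  d <- random_dataset(29, n_pos = 8, n_neg = 24)
  w <- rif_weights(d)
  ir <- attr(w, "ir")
  C <- 4
  ub_scaled <- w$weight * C
  raw <- ifelse(w$label == -1, w$score, w$weight)
  ub_cost <- raw * ifelse(w$label == -1, ir * C, C)
  expect_equal(ub_scaled, ub_cost)
})

test_that("fitted model accessors are coherent", {
  d <- random_dataset(3, n_pos = 10, n_neg = 20)
  fit <- rifsvm(d, "rif", C = 5, kernel = rbf_kernel(2))
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(d))
  expect_equal(sum(td$support), length(fit$support))
  gl <- glance(fit)
  expect_equal(gl$n_sv, length(fit$support))
  expect_equal(gl$ir, 0.5)
  # free support vectors sit on their margin
  f <- decision_values(fit, d)
  expect_true(all(abs(d$label[fit$free] * f[fit$free] - 1) < 1e-4))
  # far from all support points the RBF decision value decays to the bias
  far <- matrix(c(1e3, 1e3), 1)
  expect_equal(decision_values(fit, far), fit$b, tolerance = 1e-8)
})

test_that("models survive a JSON round trip", {
  d <- random_dataset(55, n_pos = 10, n_neg = 20)
  fit <- rifsvm(d, "rif", C = 5, kernel = rbf_kernel(2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  probe <- random_dataset(56, n_pos = 5, n_neg = 5)
  expect_equal(decision_values(back, probe), decision_values(fit, probe),
               tolerance = 1e-12)
  expect_equal(predict(back, probe), predict(fit, probe))
})
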