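test_that("exponential-decay membership hits its anchor values", {
  expect_equal(exp_decay_membership(0, 2), 1)
  expect_equal(exp_decay_membership(3, 3), 2 / (1 + exp(1)))
  expect_equal(exp_decay_membership(c(1, 2), 0), c(1, 1))  # degenerate D
})

test_that("intuitionistic score follows its two branches", {
  expect_equal(rif_score(1, 0), 1)
  expect_equal(rif_score(0.2, 0.3), 0)
  expect_equal(rif_score(0.6, 0.2), 0.8 / 1.2)
})

test_that("RIF memberships match a hand-scripted evaluation", {
  d <- random_dataset(21, n_pos = 10, n_neg = 20)
  prof <- density_profile(d)
  w <- rif_weights(d, profile = prof)
  neg <- w$label == -1
  pos <- !neg
  # independent one-line evaluations of the decay formulas
  dw <- prof$d_within[neg]
  db <- prof$d_between[neg]
  mu_neg <- 2 / (1 + exp(dw / max(dw)))
  rho_neg <- 2 / (1 + exp(db / max(db)))
  expect_equal(w$mu[neg], mu_neg)
  expect_equal(w$rho[neg], rho_neg)
  expect_equal(w$nu[neg], (1 - mu_neg) * rho_neg)
  expect_equal(w$weight[neg], attr(w, "ir") * rif_score(mu_neg, w$nu[neg]))
  dp <- prof$d_within[pos]
  expect_equal(w$weight[pos], 2 / (1 + exp(dp / max(dp))))
  expect_equal(attr(w, "ir"), 0.5)
})

test_that("RIF invariants hold across random datasets", {
  lo <- 2 / (1 + exp(1))
  for (s in 1:100) {
    n_pos <- sample(5:15, 1)
    d <- random_dataset(1000 + s, n_pos = n_pos,
                        n_neg = n_pos + sample(5:25, 1),
                        sd = runif(1, 0.2, 1))
    w <- rif_weights(d)
    neg <- w$label == -1
    expect_true(all(w$mu[neg] >= lo - 1e-12 & w$mu[neg] <= 1))
    expect_true(all(w$mu + w$nu <= 1 + 1e-12))
    expect_true(all(w$nu[neg] <= 1 - w$mu[neg] + 1e-12))
    expect_true(all(w$weight >= 0 & w$weight <= 1))
    expect_true(all(w$weight[neg] <= attr(w, "ir") + 1e-12))
    # under the default normalizer mu > nu, so the score stays positive
    expect_true(all(w$score[neg] > 0))
  }
})

test_that("a majority point inside the minority cluster is most penalized", {
  d <- separated_clusters(2, n_pos = 15, n_neg = 40)
  intruder <- tibble::tibble(x1 = 5, x2 = 5, label = -1L)  # minority center
  d <- dplyr::bind_rows(d, intruder)
  w <- rif_weights(d)
  neg <- which(w$label == -1)
  expect_equal(which.max(w$nu[neg]), length(neg))
})

test_that("mirror-symmetric balanced classes get mirror-equal weights", {
  # minority weights (within-class decay) must equal what the majority
  # membership formula yields on the mirrored class
  pos <- withr::with_seed(31, matrix(rnorm(40, sd = 0.3), ncol = 2))
  d <- tibble::tibble(x1 = c(pos[, 1], -pos[, 1] + 4),
                      x2 = c(pos[, 2], -pos[, 2] + 4),
                      label = c(rep(1L, 20), rep(-1L, 20)))
  w <- rif_weights(d)
  expect_equal(sort(w$weight[w$label == 1]), sort(w$mu[w$label == -1]))
})

test_that("membership never rises with within-class distance", {
  d <- random_dataset(77, n_pos = 12, n_neg = 30)
  prof <- density_profile(d)
  w <- rif_weights(d, profile = prof)
  neg <- w$label == -1
  ord <- order(prof$d_within[neg])
  expect_true(all(diff(w$mu[neg][ord]) <= 1e-12))
  ord_b <- order(prof$d_between[neg])
  expect_true(all(diff(w$rho[neg][ord_b]) <= 1e-12))
})

test_that("kernel-centroid membership has its forced anchor values", {
  d <- random_dataset(9, n_pos = 8, n_neg = 16)
  delta <- 1e-4
  mu <- if_membership(d, rbf_kernel(1), delta = delta)
  cd <- kernel_center_distances(d, rbf_kernel(1))
  # the instance attaining the class radius is pinned at delta / (R + delta)
  for (cl in c(1, -1)) {
    rows <- which(d$label == cl)
    R <- if (cl == 1) cd$radius[["pos"]] else cd$radius[["neg"]]
    expect_equal(min(mu[rows]), delta / (R + delta))
  }
  expect_true(all(mu > 0 & mu <= 1))
})

test_that("linear-kernel center distance is the Euclidean distance", {
  d <- random_dataset(14, n_pos = 6, n_neg = 9)
  X <- as.matrix(d[, c("x1", "x2")])
  cd <- kernel_center_distances(d, linear_kernel())
  for (cl in c(1, -1)) {
    rows <- which(d$label == cl)
    ctr <- colMeans(X[rows, ])
    expect_equal(cd$dist[rows],
                 apply(X[rows, ], 1, function(x) sqrt(sum((x - ctr)^2))))
  }
})

test_that("centroid-scheme affinity counts neighbors in the beta1 ball", {
  # geometry: one positive surrounded only by m negatives within the ball
  d <- tibble::tibble(
    x1 = c(0, 0.01, -0.01, 0.01, 5, 5.01, 6),
    x2 = c(0, 0.01, 0.01, -0.01, 5, 5.01, 6),
    label = c(1L, -1L, -1L, -1L, 1L, 1L, 1L))
  w <- if_weights(d, linear_kernel(), beta1 = 0.1)
  expect_equal(w$rho[1], 3 / 4)  # m / (m + 1) with m = 3
  # isolated instance: self-only ball
  expect_equal(w$rho[7], 0)
  expect_equal(w$nu[7], 0)
  expect_equal(w$score[7], w$mu[7])  # nu = 0 branch of the score
})

test_that("centroid-scheme affinity matches a brute-force double loop", {
  d <- random_dataset(41, n_pos = 10, n_neg = 15, sd = 0.8)
  X <- as.matrix(d[, c("x1", "x2")])
  kern <- rbf_kernel(2)
  w <- if_weights(d, kern, beta1 = 0.5)
  K <- kernel_matrix(X, kernel = kern)
  rho <- vapply(seq_len(nrow(d)), function(i) {
    dk <- vapply(seq_len(nrow(d)), function(j) {
      sqrt(max(K[i, i] + K[j, j] - 2 * K[i, j], 0))
    }, numeric(1))
    inside <- dk <= 0.5
    sum(inside & d$label != d$label[i]) / sum(inside)
  }, numeric(1))
  expect_equal(w$rho, rho)
})

test_that("baseline score function follows its three branches", {
  d <- tibble::tibble(mu = c(0.7, 0.1, 0.5), nu = c(0, 0.2, 0.25))
  s <- ifelse(d$nu == 0, d$mu, rif_score(d$mu, d$nu))
  expect_equal(s, c(0.7, 0, 0.75 / 1.25))
})

test_that("classic membership functions hit their anchors", {
  d <- c(0, 1, 2)
  expect_equal(classic_membership(d, "linear", delta = 1e-4)[1], 1)
  expect_equal(classic_membership(d, "exponential", beta = 0), rep(1, 3))
  expect_equal(classic_membership(d, "gaussian", mu = 2, sigma = 1)[3], 1)
  expect_error(classic_membership(d, "gaussian", sigma = 0), "positive")
})
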