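test_that("RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(0), c(0), 1), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))
  set.seed(20)
  u <- rnorm(5); v <- rnorm(5)
  expect_equal(rbf_kernel(u, v, 0.3), rbf_kernel(v, u, 0.3))
  expect_equal(rbf_kernel(u, v, 0.3), exp(-0.3 * sum((u - v)^2)))
  K <- rbf_kernel(matrix(rnorm(12), 4, 3), matrix(rnorm(6), 2, 3), 0.5)
  expect_equal(dim(K), c(4L, 2L))
  expect_true(all(K > 0 & K <= 1))
  expect_error(rbf_kernel(u, v, -1), "positive")
  expect_error(rbf_kernel(u, v[1:3], 1), "length")
})

test_that("the two-point problem is solved analytically", {
  # X = {0, 1}, y = {-1, +1}: maximising 2a - a^2 (1 - e^-1) gives
  # a = 1 / (1 - e^-1) for both points and a symmetric hyperplane (b = 0).
  m <- svc_binary(matrix(c(0, 1)), c(-1, 1), C = 1e6, gamma = 1, tol = 1e-8)
  a_star <- 1 / (1 - exp(-1))
  expect_equal(m$alpha, c(a_star, a_star), tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  expect_equal(decision_values(m, 0.5), 0, tolerance = 1e-10)
  # kernel decay: far queries approach the bias
  expect_equal(decision_values(m, 1e4), m$bias, tolerance = 1e-12)
  # duplicating every sample leaves the decision function unchanged
  m2 <- svc_binary(matrix(c(0, 1, 0, 1)), c(-1, 1, -1, 1),
    C = 1e6, gamma = 1, tol = 1e-8
  )
  xs <- matrix(seq(-1, 2, by = 0.25))
  expect_equal(decision_values(m2, xs), decision_values(m, xs), tolerance = 1e-6)
})

test_that("SMO agrees with the dense-QP oracle on random fixtures", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  n_checked_dec <- 0
  for (rep in 1:22) {
    n <- sample(8:25, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.5, 1, 10, 100), 1)
    g <- sample(c(0.1, 0.5, 1), 1)
    m <- svc_binary(X, y, C = C, gamma = g, tol = 1e-8)
    oracle <- qp_oracle(rbf_kernel(X, X, g), y, C)
    expect_lt(abs(m$objective - oracle$objective), 1e-6)
    # KKT feasibility of the trained machine
    expect_true(all(m$alpha >= 0 & m$alpha <= C + 1e-12))
    expect_lt(abs(m$sum_alpha_y), 1e-8)
    expect_lte(m$kkt_gap, 1e-8)
    if (abs(oracle$b_gap) < 1e-6) {
      Xq <- matrix(rnorm(5 * p), 5, p)
      d_or <- as.numeric(
        rbf_kernel(Xq, X, g) %*% (oracle$alpha * y) + oracle$b
      )
      expect_lt(max(abs(d_or - decision_values(m, Xq))), 1e-5)
      n_checked_dec <- n_checked_dec + 1
    }
    # free support vectors sit on the margin: y * f(x) = 1
    free <- m$alpha > 1e-6 * C & m$alpha < C * (1 - 1e-6)
    if (any(free)) {
      yf <- (decision_values(m, m$support_vectors) *
        sign(m$dual_coef))[free]
      expect_equal(yf, rep(1, sum(free)), tolerance = 1e-6)
    }
  }
  expect_gt(n_checked_dec, 10)
})

test_that("degenerate arguments are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(svc_binary(X, rep(1, 5), 1, 1), "both classes")
  expect_error(svc_binary(X, c(1, 1, 1, -1, 0), 1, 1), "-1 / \\+1")
  expect_error(svc_binary(X, c(1, 1, 1, -1, -1), -1, 1), "positive")
  m <- svc_binary(X, c(1, 1, 1, -1, -1), 1, 1)
  expect_error(decision_values(m, matrix(0, 1, 3)), "dimension")
})

test_that("training accuracy is non-decreasing in C at fixed gamma", {
  set.seed(22)
  X <- rbind(
    matrix(rnorm(20, 0, 1.2), 10, 2),
    matrix(rnorm(20, 1.5, 1.2), 10, 2)
  )
  labels <- rep(1:2, each = 10)
  acc <- vapply(10^(-2:4), function(C) {
    m <- rbf_svc(X, labels, C = C, gamma = 0.5)
    mean(predict(m, X) == labels)
  }, numeric(1))
  expect_true(all(diff(acc) >= -1e-12))
})

test_that("decision values are invariant under input scaling with gamma/s^2", {
  set.seed(23)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(-1, 1), 6)
  s <- 3.7
  m1 <- svc_binary(X, y, C = 10, gamma = 0.4, tol = 1e-8)
  m2 <- svc_binary(X * s, y, C = 10, gamma = 0.4 / s^2, tol = 1e-8)
  Xq <- matrix(rnorm(10), 5, 2)
  expect_equal(
    decision_values(m1, Xq), decision_values(m2, Xq * s),
    tolerance = 1e-8
  )
})

test_that("one-vs-one multiclass trains a machine per pair and votes", {
  fx <- separated_classes()
  model <- rbf_svc(fx$X, fx$labels, C = 10, gamma = 1)
  expect_length(model$machines, 3L) # 3 * 2 / 2 pairs
  expect_equal(predict(model, fx$X), fx$labels) # 100% training accuracy

  # sample order does not change predictions
  set.seed(24)
  perm <- sample(nrow(fx$X))
  expect_equal(predict(model, fx$X[perm, ]), fx$labels[perm])

  # two classes reduce to the single binary machine
  two <- fx$labels <= 2
  mc2 <- rbf_svc(fx$X[two, ], fx$labels[two], C = 10, gamma = 1)
  bin <- svc_binary(fx$X[two, ], ifelse(fx$labels[two] == 1, 1, -1),
    C = 10, gamma = 1
  )
  f2 <- decision_values(mc2$machines[[1]], fx$X[two, ])
  expect_equal(f2, decision_values(bin, fx$X[two, ]), tolerance = 1e-10)
  expect_equal(predict(mc2, fx$X[two, ]), fx$labels[two])

  expect_error(rbf_svc(fx$X, rep(1, nrow(fx$X)), 1, 1), "two classes")
  expect_error(predict(model, matrix(0, 1, 5)), "dimension")
})

test_that("vote ties fall back to decision strength then smallest label", {
  # three unit-variance classes at the corners of an equilateral triangle:
  # a query at the centroid receives one vote per class
  centers <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  X <- centers[rep(1:3, each = 2), ] + 0.01 * matrix(rnorm(12), 6, 2)
  labels <- rep(1:3, each = 2)
  model <- rbf_svc(X, labels, C = 100, gamma = 0.5)
  centroid <- colMeans(centers)
  pred <- predict(model, centroid)
  expect_true(pred %in% 1:3) # tie resolved deterministically
  expect_identical(pred, predict(model, centroid)) # and reproducibly
})

test_that("grid search scans the decade grid and reports both accuracies", {
  expect_equal(nrow(svc_grid()), 289L) # 17 x 17 cells
  expect_equal(sort(unique(svc_grid()$C)), 10^(-8:8))

  fx <- separated_classes(n_per = 6)
  sp <- split_4_1_1(fx$labels, fx$X)
  gs <- svc_grid_search(
    fx$X[sp$train, ], fx$labels[sp$train],
    fx$X[sp$validation, ], fx$labels[sp$validation],
    grid = svc_grid(-2, 2)
  )
  expect_equal(nrow(gs$results), 25L)
  expect_equal(gs$best$val_accuracy, 1) # a perfect cell exists and is found
  # single-cell grid returns that cell
  one <- svc_grid_search(
    fx$X[sp$train, ], fx$labels[sp$train],
    fx$X[sp$validation, ], fx$labels[sp$validation],
    grid = data.frame(C = 1, gamma = 0.5)
  )
  expect_equal(one$best$C, 1)
  expect_equal(one$best$gamma, 0.5)
  expect_error(
    svc_grid_search(fx$X, fx$labels, fx$X, fx$labels,
      grid = data.frame(C = numeric(), gamma = numeric())
    ),
    "at least one cell"
  )
})

test_that("classifiers survive a flat-text round-trip", {
  fx <- separated_classes(n_per = 5)
  model <- rbf_svc(fx$X, fx$labels, C = 10, gamma = 0.7)
  tmp <- withr::local_tempfile()
  write_svc(model, tmp)
  back <- read_svc(tmp)
  set.seed(25)
  Xq <- matrix(rnorm(20), 10, 2)
  expect_identical(predict(back, Xq), predict(model, Xq))
  for (k in 1:3) {
    expect_equal(
      decision_values(back$machines[[k]], Xq),
      decision_values(model$machines[[k]], Xq)
    )
  }
})
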