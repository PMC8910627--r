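test_that("design rows evaluate the polynomial bases at scaled time", {
  with_int <- model_config(degree = 2, random_intercept = TRUE)
  dr <- design_row(with_int, "2001/02")
  expect_equal(unname(dr$fixed), c(0, 0))
  expect_equal(unname(dr$random), c(1, 0, 0))

  dr <- design_row(model_config(degree = 1, random_intercept = TRUE), "1985/86")
  expect_equal(unname(dr$fixed), -1)
  expect_equal(unname(dr$random), c(1, -1))

  dr <- design_row(model_config(degree = 3, random_intercept = TRUE), "2021/22")
  expect_equal(unname(dr$fixed), c(1.25, 1.5625, 1.953125))
  expect_equal(unname(dr$random), c(1, 1.25, 1.5625, 1.953125))

  # default basis carries no random intercept: same powers as the fixed part
  dr <- design_row(model_config(degree = 3), "2021/22")
  expect_equal(unname(dr$random), c(1.25, 1.5625, 1.953125))
  expect_error(design_row(model_config(), "199x/xx"), "unknown wave")
})

test_that("log-likelihood matches per-cell Gaussian evaluation", {
  cfg <- model_config(degree = 1, random_intercept = TRUE)

  # single cell, zero residual, unit precision
  vals <- matrix(12, 1, 1, dimnames = list("A", "2001/02"))
  pan <- prevalence_panel(vals)
  st <- list(alpha = 12, beta = 0, z = 1L, phi = matrix(0, 1, 2),
             tau_b = c(1, 1), tau_eps = 1, c = 1)
  expect_equal(log_likelihood(st, pan, cfg), -0.5 * log(2 * pi))
  st2 <- st; st2$tau_eps <- 2
  expect_equal(log_likelihood(st2, pan, cfg),
               -0.5 * log(2 * pi) + 0.5 * log(2), tolerance = 1e-12)

  # 3 countries x 2 waves vs a hand-summed oracle over the 6 cells
  pan <- toy_panel()
  st <- list(alpha = 11, beta = 2, z = c(1L, 1L, 2L),
             phi = matrix(c(0.5, 1, -0.3, 0.2), 2, 2, byrow = TRUE),
             tau_b = c(1, 1), tau_eps = 0.5, c = 1)
  u <- scaled_time(cfg$time_mapping, pan$waves)
  oracle <- 0
  for (i in 1:3) for (j in 1:2) {
    mu <- st$alpha + u[j] * st$beta +
      sum(c(1, u[j]) * st$phi[st$z[i], ])
    oracle <- oracle + dnorm(pan$values[i, j], mu, sqrt(1 / st$tau_eps),
                             log = TRUE)
  }
  expect_equal(log_likelihood(st, pan, cfg), oracle, tolerance = 1e-10)
})

test_that("new-cluster marginal likelihood agrees with the direct multivariate normal", {
  # evidence formula used by the CRP kernel vs dense-covariance evaluation
  set.seed(5)
  for (rep in 1:5) {
    m <- sample(2:6, 1); q <- sample(1:4, 1)
    Z <- matrix(rnorm(m * q), m, q)
    r <- rnorm(m, sd = 3)
    tau_eps <- runif(1, 0.05, 2)
    tau_b <- runif(q, 0.05, 2)
    S <- diag(m) / tau_eps + Z %*% diag(1 / tau_b, q) %*% t(Z)
    direct <- -0.5 * (m * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                        drop(t(r) %*% solve(S, r)))
    expect_equal(dpgrowth:::cpp_log_marginal(r, Z, tau_eps, tau_b), direct,
                 tolerance = 1e-8)
  }
})

test_that("CRP assignment updates match exact partition enumeration on a toy panel", {
  pan <- toy_panel()
  cfg <- model_config(degree = 1, random_intercept = TRUE, n_iter = 10,
                      burn_in = 1)
  frozen <- list(alpha = 12, beta = 0.5, tau_eps = 0.25,
                 tau_b = c(0.05, 0.05), c = 1.0)
  co_exact <- enumerate_coclustering(pan, cfg, frozen$alpha, frozen$beta,
                                     frozen$tau_eps, frozen$tau_b, frozen$c)

  s <- init_state(pan, cfg)
  s[names(frozen)] <- frozen
  set.seed(99)
  n_sweep <- 15000; burn <- 1000
  co <- matrix(0, 3, 3)
  for (it in seq_len(n_sweep)) {
    s <- update_assignments(s, pan, cfg)
    s <- update_cluster_effects(s, pan, cfg)
    s[names(frozen)] <- frozen
    if (it > burn) co <- co + outer(s$z, s$z, `==`)
  }
  co <- co / (n_sweep - burn)
  # binomial MC error with autocorrelation margin: 3 x ~0.008
  expect_lt(max(abs(co - co_exact)), 0.025)
})

test_that("identical series co-cluster almost surely when noise is negligible", {
  vals <- matrix(c(15, 18, 15, 18), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("1997/98", "2005/06")))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, random_intercept = TRUE, n_iter = 10,
                      burn_in = 1)
  s <- init_state(pan, cfg)
  s$alpha <- 15; s$beta <- 0; s$tau_eps <- 1e6; s$tau_b <- c(0.1, 0.1)
  s$c <- 0.01
  set.seed(4)
  together <- 0
  for (it in 1:500) {
    s <- update_assignments(s, pan, cfg)
    s <- update_cluster_effects(s, pan, cfg)
    s$tau_eps <- 1e6; s$tau_b <- c(0.1, 0.1); s$c <- 0.01
    together <- together + (s$z[1] == s$z[2])
  }
  expect_gte(together / 500, 0.99)
})

test_that("a single series always forms exactly one cluster", {
  vals <- matrix(c(10, 12, 14), 1, 3,
                 dimnames = list("A", c("1997/98", "2005/06", "2013/14")))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, n_iter = 10, burn_in = 1)
  s <- init_state(pan, cfg)
  set.seed(1)
  for (it in 1:50) {
    s <- update_assignments(s, pan, cfg)
    expect_identical(s$z, 1L)
    expect_identical(nrow(s$phi), 1L)
    s <- update_cluster_effects(s, pan, cfg)
  }
})

test_that("cluster-effect updates follow scalar Gaussian conjugacy", {
  # one member, one observation at u = 0, random intercept: the intercept
  # coordinate has posterior mean tau_eps * r / (tau_eps + tau_b)
  vals <- matrix(20, 1, 1, dimnames = list("A", "2001/02"))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, random_intercept = TRUE, n_iter = 10,
                      burn_in = 1)
  st <- list(alpha = 14, beta = 0, z = 1L, phi = matrix(0, 1, 2),
             tau_b = c(0.5, 0.5), tau_eps = 2, c = 1)
  r <- 20 - 14
  set.seed(8)
  draws <- replicate(4000, update_cluster_effects(st, pan, cfg)$phi[1, 1])
  expect_equal(mean(draws), st$tau_eps * r / (st$tau_eps + st$tau_b[1]),
               tolerance = 0.05)
  expect_equal(sd(draws), sqrt(1 / (st$tau_eps + st$tau_b[1])),
               tolerance = 0.05)

  # tau_b -> infinity pins the effect at zero
  st$tau_b <- c(1e12, 1e12)
  expect_lt(abs(update_cluster_effects(st, pan, cfg)$phi[1, 1]), 1e-4)
})

test_that("fixed-effect updates match the generalized least-squares closed form", {
  vals <- matrix(c(10, 14, 18, 30, 26, 22), 2, 3, byrow = TRUE,
                 dimnames = list(c("A", "B"),
                                 c("1993/94", "2001/02", "2009/10")))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, random_intercept = TRUE,
                      prior_sd_fixed = 1e6, n_iter = 10, burn_in = 1)
  st <- list(alpha = 0, beta = 0, z = c(1L, 2L),
             phi = matrix(c(1, 0.5, -1, 0.2), 2, 2, byrow = TRUE),
             tau_b = c(1, 1), tau_eps = 1e8, c = 1)
  # with huge tau_eps the draw collapses onto the normal-equations solution
  u <- scaled_time(cfg$time_mapping, pan$waves)
  W <- cbind(1, rep(u, 2))
  y_adj <- c(vals[1, ] - cbind(1, u) %*% st$phi[1, ],
             vals[2, ] - cbind(1, u) %*% st$phi[2, ])
  ls_fit <- solve(crossprod(W), crossprod(W, y_adj))
  set.seed(2)
  upd <- update_fixed_effects(st, pan, cfg)
  expect_equal(upd$alpha, ls_fit[1], tolerance = 1e-3)
  expect_equal(upd$beta, ls_fit[2], tolerance = 1e-3)
})

test_that("precision updates draw from the correct Gamma full conditionals", {
  # perfect fit, two observations: tau_eps ~ Gamma(0.1 + 1, 0.1), mean 11
  vals <- matrix(c(10, 12), 1, 2, dimnames = list("A", c("1997/98", "2005/06")))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, random_intercept = TRUE, n_iter = 10,
                      burn_in = 1)
  u <- scaled_time(cfg$time_mapping, pan$waves)
  # choose state reproducing y exactly: y = alpha + beta u + phi . (1, u)
  beta <- (12 - 10) / (u[2] - u[1])
  alpha <- 10 - beta * u[1]
  st <- list(alpha = alpha, beta = beta, z = 1L, phi = matrix(0, 1, 2),
             tau_b = c(1, 1), tau_eps = 1, c = 1)
  set.seed(31)
  draws <- replicate(4000, update_precisions(st, pan, cfg)$tau_eps)
  expect_equal(mean(draws), 1.1 / 0.1, tolerance = 0.1 * 11)
  # long-run mean at nonzero residuals matches the conditional mean
  st$alpha <- alpha + 1
  ssr <- sum((vals - (st$alpha + beta * u)) ^ 2)
  draws <- replicate(4000, update_precisions(st, pan, cfg)$tau_eps)
  expect_equal(mean(draws), (0.1 + 1) / (0.1 + ssr / 2), tolerance = 0.05)
})

test_that("shared and per-dimension base-measure precisions are both available", {
  pan <- toy_panel()
  st <- list(alpha = 10, beta = 1, z = c(1L, 1L, 2L),
             phi = matrix(c(5, 0.1, -5, -0.1), 2, 2, byrow = TRUE),
             tau_b = c(1, 1), tau_eps = 1, c = 1)
  set.seed(6)
  shared <- replicate(500, {
    s <- update_precisions(st, pan, model_config(
      degree = 1, random_intercept = TRUE, n_iter = 10, burn_in = 1,
      shared_tau_b = TRUE))
    s$tau_b
  })
  expect_true(all(shared[1, ] == shared[2, ]))
  perdim <- update_precisions(st, pan, model_config(
    degree = 1, random_intercept = TRUE, n_iter = 10, burn_in = 1,
    shared_tau_b = FALSE))
  expect_false(perdim$tau_b[1] == perdim$tau_b[2])
  # shared tau pools all phi entries: conditional Gamma(0.1 + Kq/2, 0.1 + ss/2)
  ss <- sum(st$phi ^ 2)
  expect_equal(mean(shared[1, ]), (0.1 + 2) / (0.1 + ss / 2), tolerance = 0.1)
})

test_that("concentration updates target the Escobar-West posterior", {
  # chain of two-step updates vs 1-D quadrature of
  # p(c | K, n) propto c^(a-1) e^(-c) c^K Gamma(c) / Gamma(c + n)
  a <- 2; K <- 4L; n <- 30L
  log_post <- function(c) (a - 1) * log(c) - c + K * log(c) +
    lgamma(c) - lgamma(c + n)
  grid <- seq(0.001, 30, length.out = 20000)
  w <- exp(log_post(grid) - max(log_post(grid)))
  mean_exact <- sum(grid * w) / sum(w)

  st <- list(alpha = 0, beta = 0, z = 1L, phi = matrix(0, K, 1),
             tau_b = 1, tau_eps = 1, c = 1)
  cfg <- model_config(degree = 1, a = a, n_iter = 10, burn_in = 1)
  set.seed(12)
  cc <- numeric(20000)
  s <- st
  for (it in seq_along(cc)) {
    s <- update_concentration(s, n, cfg)
    cc[it] <- s$c
  }
  cc <- cc[-(1:500)]
  se <- sd(cc) / sqrt(length(cc) / 10)  # conservative autocorrelation margin
  expect_lt(abs(mean(cc) - mean_exact), 3 * se + 0.02)

  # n = 1, K = 1: posterior mean must exceed the prior mean a
  s1 <- st; s1$phi <- matrix(0, 1, 1)
  set.seed(13)
  cc1 <- replicate(5000, {
    s1 <<- update_concentration(s1, 1L, cfg)
    s1$c
  })
  expect_gt(mean(cc1), a)
})

test_that("prior expected cluster count follows the CRP formula", {
  expect_equal(prior_expected_clusters(0.7, 1), 1)
  expect_equal(prior_expected_clusters(1, 40), sum(1 / (1:40)),
               tolerance = 1e-12)
  expect_equal(prior_expected_clusters(1, 40), 4.2785, tolerance = 1e-4)
  expect_gt(prior_expected_clusters(1e6, 40), 39.9)  # c -> Inf: all singletons
  cs <- c(0.1, 0.5, 1, 2, 5, 20)
  expect_true(all(diff(sapply(cs, prior_expected_clusters, n = 40)) > 0))
})

test_that("the sampler is deterministic given a seed and keeps states consistent", {
  gen <- generate_panel(n_series = 6, seed = 2, sigma_eps = 2)
  cfg <- quick_config(seed = 77)
  d1 <- run_mcmc(gen$panel, cfg)
  d2 <- run_mcmc(gen$panel, cfg)
  expect_identical(d1$alpha, d2$alpha)
  expect_identical(d1$z, d2$z)
  expect_identical(d1$b, d2$b)
  d3 <- run_mcmc(gen$panel, quick_config(seed = 78))
  expect_false(identical(d1$alpha, d3$alpha))

  expect_length(d1$alpha, (cfg$n_iter - cfg$burn_in) / cfg$thin)
  # labels are consecutive from 1 in order of first appearance, K matches
  for (s in c(1L, nrow(d1$z))) {
    z <- d1$z[s, ]
    expect_identical(sort(unique(z)), seq_len(d1$K[s]))
    expect_identical(unique(z), seq_len(d1$K[s]))  # first-appearance order
  }
  expect_true(all(is.finite(d1$loglik)))
})

test_that("a tiny concentration keeps exchangeable noise in one cluster", {
  set.seed(9)
  vals <- matrix(rnorm(5 * 4, 20, 1), 5, 4,
                 dimnames = list(paste0("S", 1:5),
                                 c("1997/98", "2001/02", "2005/06", "2009/10")))
  pan <- prevalence_panel(vals)
  cfg <- model_config(degree = 1, n_iter = 10, burn_in = 1)
  s <- init_state(pan, cfg)
  s$alpha <- 20; s$tau_eps <- 1
  set.seed(10)
  k1 <- 0
  for (it in 1:400) {
    s <- update_assignments(s, pan, cfg)
    s <- update_cluster_effects(s, pan, cfg)
    s$c <- 1e-4; s$tau_eps <- 1
    k1 <- k1 + (nrow(s$phi) == 1L)
  }
  expect_gte(k1 / 400, 0.95)
})
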