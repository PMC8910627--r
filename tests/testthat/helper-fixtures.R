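# shared fixtures and small oracles used across test files

boys_path <- function() system.file("extdata", "hbsc_boys.csv", package = "dpgrowth")
girls_path <- function() system.file("extdata", "hbsc_girls.csv", package = "dpgrowth")

load_boys <- function() load_prevalence_table(boys_path(), "boys")
load_girls <- function() load_prevalence_table(girls_path(), "girls")

# small fully-observed panel with known values
toy_panel <- function(vals = matrix(c(10, 11, 10.5, 11.5, 20, 19), 3, 2,
                                    byrow = TRUE),
                      waves = c("1997/98", "2005/06"),
                      countries = c("A", "B", "C")) {
  dimnames(vals) <- list(countries, waves)
  prevalence_panel(vals, gender = "toy")
}

# quick config for sampler tests
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_iter = 1500, burn_in = 500, thin = 5, seed = 1L)
  defaults[names(args)] <- args
  do.call(model_config, defaults)
}

# hand-built dp_draws object for summary-level tests: z is draws x series,
# b_list a list of (series x q) random-effect matrices per draw
fake_draws <- function(z, countries, b_list = NULL, alpha = NULL,
                       beta = NULL, config = model_config(random_intercept = TRUE)) {
  S <- nrow(z)
  q <- length(if (config$random_intercept) 0:config$degree else 1:config$degree)
  if (is.null(b_list))
    b_list <- replicate(S, matrix(0, length(countries), q), simplify = FALSE)
  b <- array(0, dim = c(length(countries), q, S),
             dimnames = list(countries, NULL, NULL))
  for (s in seq_len(S)) b[, , s] <- b_list[[s]]
  colnames(z) <- countries
  structure(list(alpha = if (is.null(alpha)) rep(0, S) else alpha,
                 beta = if (is.null(beta)) matrix(0, S, config$degree) else beta,
                 z = z, b = b,
                 tau_b = matrix(1, S, q), tau_eps = rep(1, S),
                 c = rep(1, S), K = apply(z, 1L, function(r) length(unique(r))),
                 loglik = rep(0, S), config = config, countries = countries,
                 waves = hbsc_wave_labels(), gender = "fake"),
            class = "dp_draws")
}

# exact posterior over set partitions of a small panel with everything but
# the partition frozen: returns co-clustering probabilities (enumeration)
enumerate_coclustering <- function(panel, config, alpha, beta, tau_eps, tau_b, conc) {
  n <- length(panel$countries)
  u <- scaled_time(config$time_mapping, panel$waves)
  Z <- outer(u, if (config$random_intercept) 0:config$degree else
    seq_len(config$degree), `^`)
  Xb <- as.vector(outer(u, seq_len(config$degree), `^`) %*% beta)
  resid <- sweep(panel$values, 2L, alpha + Xb)

  log_marg_block <- function(rows) {
    r <- as.vector(t(resid[rows, , drop = FALSE]))
    Zs <- do.call(rbind, rep(list(Z), length(rows)))
    keep <- !is.na(r)
    r <- r[keep]; Zs <- Zs[keep, , drop = FALSE]
    S <- diag(length(r)) / tau_eps + Zs %*% diag(1 / tau_b, ncol(Zs)) %*% t(Zs)
    -0.5 * (length(r) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
              drop(t(r) %*% solve(S, r)))
  }
  parts <- set_partitions(n)
  crp_lp <- function(p)
    sum(log(conc) + lfactorial(lengths(p) - 1)) - sum(log(conc + 0:(n - 1)))
  lp <- vapply(parts, function(p) crp_lp(p) + sum(vapply(p, log_marg_block,
                                                         numeric(1))),
               numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  co <- matrix(0, n, n)
  for (k in seq_along(parts))
    for (blk in parts[[k]]) co[blk, blk] <- co[blk, blk] + post[k]
  co
}

# all set partitions of 1..n (n small), as lists of index blocks
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (j in seq_along(p)) {
      q <- p; q[[j]] <- c(q[[j]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# integrated autocorrelation time (initial positive-sequence truncation),
# used to put honest standard errors on MCMC averages
iact <- function(x, lag_max = 200) {
  ac <- stats::acf(x, lag.max = min(lag_max, length(x) - 1), plot = FALSE)$acf
  1 + 2 * sum(pmax(ac[-1], 0))
}

# Geweke-style joint-distribution check: alternate (parameters | data) Gibbs
# sweeps with (data | parameters) resimulation; the parameter marginals must
# then match plain prior sampling. Moderate priors keep the compared moments
# finite and well estimated. Returns z-scores per monitored statistic.
geweke_run <- function(M = 8000, seed = 1, burn = 1000) {
  waves <- c("2001/02", "2009/10", "2017/18")
  n <- 5L
  cfg <- model_config(degree = 1, a = 1, gamma_shape = 2, gamma_rate = 2,
                      prior_sd_fixed = 2, n_iter = 10, burn_in = 1)
  u <- scaled_time(cfg$time_mapping, waves)
  forward_state <- function() {
    conc <- rgamma(1, cfg$a, 1)
    z <- rcrp(n, conc); K <- max(z)
    tb <- rgamma(1, cfg$gamma_shape, cfg$gamma_rate)
    te <- rgamma(1, cfg$gamma_shape, cfg$gamma_rate)
    list(alpha = rnorm(1, 0, cfg$prior_sd_fixed),
         beta = rnorm(1, 0, cfg$prior_sd_fixed),
         z = as.integer(z), phi = matrix(rnorm(K, 0, 1 / sqrt(tb)), K, 1),
         tau_b = tb, tau_eps = te, c = conc)
  }
  sim_data <- function(st) {
    mu <- outer(rep(st$alpha, n), st$beta * u, `+`) +
      st$phi[st$z, 1] %o% u
    vals <- mu + matrix(rnorm(n * 3, 0, 1 / sqrt(st$tau_eps)), n, 3)
    dimnames(vals) <- list(paste0("S", 1:n), waves)
    prevalence_panel(vals, gender = "geweke", range_check = FALSE)
  }
  stats_of <- function(st) c(alpha = st$alpha, beta = st$beta,
                             tau_eps = st$tau_eps, K = nrow(st$phi),
                             c = st$c)
  set.seed(seed)
  fwd <- t(replicate(M, stats_of(forward_state())))
  st <- forward_state()
  chain <- matrix(NA_real_, M, ncol(fwd), dimnames = list(NULL, colnames(fwd)))
  for (it in seq_len(M)) {
    pan <- sim_data(st)
    st <- update_assignments(st, pan, cfg)
    st <- update_cluster_effects(st, pan, cfg)
    st <- update_fixed_effects(st, pan, cfg)
    st <- update_precisions(st, pan, cfg)
    st <- update_concentration(st, n, cfg)
    chain[it, ] <- stats_of(st)
  }
  chain <- chain[-seq_len(burn), , drop = FALSE]
  z <- vapply(colnames(fwd), function(v) {
    se_f <- sd(fwd[, v]) / sqrt(M)
    se_c <- sd(chain[, v]) * sqrt(iact(chain[, v]) / nrow(chain))
    (mean(fwd[, v]) - mean(chain[, v])) / sqrt(se_f^2 + se_c^2)
  }, numeric(1))
  list(z = z, fwd = colMeans(fwd), chain = colMeans(chain))
}

# CRP forward sampler: partition labels for n series given concentration c
rcrp <- function(n, conc) {
  z <- integer(n); z[1L] <- 1L; K <- 1L
  for (i in 2:n) {
    counts <- tabulate(z[1:(i - 1L)], K)
    probs <- c(counts, conc) / (i - 1 + conc)
    pick <- sample.int(K + 1L, 1L, prob = probs)
    if (pick > K) K <- K + 1L
    z[i] <- pick
  }
  z
}
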