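hbsc_wave_labels <- function() {
  c("1985/86", "1989/90", "1993/94", "1997/98", "2001/02", "2005/06",
    "2009/10", "2013/14", "2017/18")
}

#' Missingness mask shaped like a staggered-entry survey
#'
#' Emulates the participation pattern of a multi-wave survey in which
#' countries join at different waves and are then observed from their entry
#' wave onward, optionally with sporadic interior gaps. Every series is
#' guaranteed at least three observed waves, mirroring the inclusion rule of
#' the shipped panels.
#'
#' @param n_series number of series.
#' @param waves character vector of wave labels.
#' @param entry_dist probability vector over entry waves (length
#'   `length(waves)`); mass on entries leaving fewer than three observable
#'   waves is an error. Default: uniform over admissible entry waves.
#' @param gap_prob probability that a post-entry, non-final wave is skipped
#'   (gaps are suppressed when they would leave fewer than three
#'   observations). Default 0.
#' @param seed integer seed.
#' @return logical matrix (`n_series` by `length(waves)`), `TRUE` where
#'   observed.
#' @export
hbsc_like_mask <- function(n_series, waves = hbsc_wave_labels(),
                           entry_dist = NULL, gap_prob = 0, seed = 1L) {
  W <- length(waves)
  stopifnot(W >= 3L, n_series >= 1L)
  last_ok <- W - 2L  # entering later leaves < 3 waves
  if (is.null(entry_dist)) entry_dist <- rep(1 / last_ok, last_ok)
  if (length(entry_dist) < W) entry_dist <- c(entry_dist, rep(0, W - length(entry_dist)))
  if (any(entry_dist[(last_ok + 1L):W] > 0))
    stop("entry-wave distribution allows fewer than three observed waves")
  set.seed(seed)
  entries <- sample.int(W, n_series, replace = TRUE, prob = entry_dist)
  mask <- outer(entries, seq_len(W), `<=`)
  if (gap_prob > 0) {
    for (i in seq_len(n_series)) {
      interior <- which(mask[i, ])
      interior <- interior[interior > entries[i] & interior < W]
      for (j in interior) {
        if (sum(mask[i, ]) <= 3L) break
        if (stats::runif(1) < gap_prob) mask[i, j] <- FALSE
      }
    }
  }
  dimnames(mask) <- list(sprintf("S%02d", seq_len(n_series)), waves)
  mask
}

#' Generate a synthetic prevalence panel with known truth
#'
#' Simulates the generative model exactly: a global polynomial trend, a
#' latent partition of the series into clusters each carrying one
#' random-effect polynomial, and additive Gaussian observation noise, with
#' optional survey-like missingness. The defaults mimic the study geometry:
#' 40 series over the nine survey waves, a cubic rise-then-fall global trend
#' around 35%, three level-separated clusters (shifts +15, 0, -15) and noise
#' of 3 percentage points, all comfortably inside the [0, 100] percent scale.
#'
#' @param n_series number of series (default 40).
#' @param waves wave labels (default the nine survey waves).
#' @param degree polynomial degree (default 3).
#' @param true_partition integer vector of cluster ids (length `n_series`),
#'   or a single integer K for a balanced assignment. Default 3.
#' @param phi_spec either a K by (degree + 1) matrix of cluster
#'   random-effect vectors, or `list(sd = s)` to draw them from
#'   N(0, s^2) per coordinate. Default: three level shifts +15, 0, -15.
#' @param alpha global intercept (default 35).
#' @param beta fixed polynomial coefficients, length `degree`
#'   (default c(-4, -8, 4): rises to a peak near the centring year, then
#'   declines).
#' @param sigma_eps observation noise standard deviation in percentage
#'   points (default 3).
#' @param missing_pattern `"none"`, `"hbsc"` (staggered entry via
#'   [hbsc_like_mask()]), or a numeric p for independent missingness with
#'   probability p (each series keeps at least one observation).
#' @param clip logical; clip cells to [0, 100] (default `FALSE`, with a
#'   warning if values fall outside).
#' @param seed integer seed; same seed, same panel and truth.
#' @param mapping a [time_mapping()] for the wave labels.
#' @return list with `panel` (a [prevalence_panel()]) and `truth` (list:
#'   `partition`, `alpha`, `beta`, `phi`, `sigma_eps`, `mask`, `trajectory`
#'   noiseless matrix, `seed`).
#' @export
generate_panel <- function(n_series = 40, waves = hbsc_wave_labels(),
                           degree = 3, true_partition = 3, phi_spec = NULL,
                           alpha = 35, beta = c(-4, -8, 4), sigma_eps = 3,
                           missing_pattern = "hbsc", clip = FALSE, seed = 1L,
                           mapping = time_mapping()) {
  W <- length(waves)
  if (length(true_partition) == 1L)
    true_partition <- rep_len(seq_len(true_partition), n_series)
  stopifnot(length(true_partition) == n_series, length(beta) == degree,
            sigma_eps >= 0)
  K <- max(true_partition)
  q <- degree + 1L
  set.seed(seed)
  if (is.null(phi_spec)) {
    levels3 <- c(15, 0, -15)
    phi_spec <- matrix(0, K, q)
    phi_spec[, 1L] <- levels3[((seq_len(K) - 1L) %% 3L) + 1L]
  } else if (is.list(phi_spec)) {
    phi_spec <- matrix(stats::rnorm(K * q, 0, phi_spec$sd), K, q)
  }
  if (!all(dim(phi_spec) == c(K, q)))
    stop("phi_spec must be a ", K, " x ", q, " matrix")

  u <- scaled_time(mapping, waves)
  X <- outer(u, seq_len(degree), `^`)
  Z <- outer(u, 0:degree, `^`)
  traj <- matrix(alpha + X %*% beta, n_series, W, byrow = TRUE) +
    phi_spec[true_partition, , drop = FALSE] %*% t(Z)
  vals <- traj + matrix(stats::rnorm(n_series * W, 0, sigma_eps), n_series, W)

  mask <- if (identical(missing_pattern, "none")) {
    matrix(TRUE, n_series, W)
  } else if (identical(missing_pattern, "hbsc")) {
    hbsc_like_mask(n_series, waves, seed = seed + 1L)
  } else if (is.numeric(missing_pattern)) {
    m <- matrix(stats::runif(n_series * W) >= missing_pattern, n_series, W)
    for (i in seq_len(n_series))  # never leave a series empty
      if (!any(m[i, ])) m[i, sample.int(W, 1L)] <- TRUE
    m
  } else stop("unknown missing_pattern")

  out_of_range <- any(vals < 0 | vals > 100)
  if (out_of_range) {
    if (clip) {
      warning("clipping synthetic cells to [0, 100]")
      vals <- pmin(pmax(vals, 0), 100)
    }
  }
  vals[!mask] <- NA_real_
  dimnames(vals) <- list(sprintf("S%02d", seq_len(n_series)), waves)
  dimnames(traj) <- dimnames(vals)
  panel <- prevalence_panel(vals, gender = "synthetic", range_check = clip)
  truth <- list(partition = true_partition, alpha = alpha, beta = beta,
                phi = phi_spec, sigma_eps = sigma_eps, mask = mask,
                trajectory = traj, seed = seed)
  list(panel = panel, truth = truth)
}
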