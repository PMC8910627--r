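#' Posterior co-clustering (similarity) matrix
#'
#' Entry (i, j) is the fraction of retained draws in which series i and j
#' carry the same cluster label. Symmetric with unit diagonal; invariant to
#' relabelling of clusters within draws.
#'
#' @param draws a `dp_draws` object from [run_mcmc()].
#' @return numeric matrix (countries by countries) with entries in [0, 1].
#' @export
cosim_matrix <- function(draws) {
  z <- draws$z
  S <- nrow(z)
  stopifnot(S >= 1L)
  n <- ncol(z)
  sim <- matrix(0, n, n, dimnames = list(draws$countries, draws$countries))
  for (s in seq_len(S)) {
    zs <- z[s, ]
    sim <- sim + outer(zs, zs, `==`)
  }
  sim / S
}

# sum over pairs i<j of (1[zi==zj] - sim_ij)^2 -- Dahl's least-squares score
partition_score <- function(z, sim) {
  d <- outer(z, z, `==`) - sim
  sum(d[upper.tri(d)]^2)
}

#' Point-estimate partition
#'
#' Selects, among the sampled partitions, the one whose implied co-clustering
#' pattern is closest in least squares to the posterior similarity matrix
#' (Dahl's criterion); ties go to the earliest draw. Labels are renumbered
#' consecutively in order of first appearance along the country list.
#'
#' @param draws a `dp_draws` object.
#' @param similarity optional precomputed [cosim_matrix()]; computed if
#'   missing.
#' @return An object of class `dp_partition`: a list with `labels` (named
#'   integer vector), `k` (number of clusters), `score` (least-squares
#'   distance), `draw_index` (which retained draw was selected) and
#'   `similarity`.
#' @export
point_partition <- function(draws, similarity = NULL) {
  if (is.null(similarity)) similarity <- cosim_matrix(draws)
  z <- draws$z
  scores <- apply(z, 1L, partition_score, sim = similarity)
  best <- which.min(scores)  # which.min takes the earliest minimiser
  labels <- canonical_labels(z[best, ])
  names(labels) <- draws$countries
  structure(list(labels = labels, k = max(labels), score = scores[best],
                 draw_index = best, similarity = similarity),
            class = "dp_partition")
}

canonical_labels <- function(z) {
  as.integer(factor(z, levels = unique(z)))
}

#' @export
print.dp_partition <- function(x, ...) {
  cat(sprintf("dp_partition: %d clusters over %d series (draw %d, score %.3f)\n",
              x$k, length(x$labels), x$draw_index, x$score))
  for (k in seq_len(x$k))
    cat(sprintf("  cluster %d (%d): %s\n", k, sum(x$labels == k),
                paste(names(x$labels)[x$labels == k], collapse = " ")))
  invisible(x)
}

#' Posterior distribution of the number of clusters
#'
#' @param draws a `dp_draws` object.
#' @return named numeric vector: relative frequency of each observed K,
#'   summing to 1.
#' @export
k_distribution <- function(draws) {
  stopifnot(length(draws$K) >= 1L)
  tab <- table(draws$K)
  stats::setNames(as.numeric(tab) / length(draws$K), names(tab))
}

#' Export a partition summary to CSV
#'
#' Writes the similarity matrix (countries as header row and column) and the
#' point partition as a two-column country/cluster mapping.
#'
#' @param partition a `dp_partition` from [point_partition()].
#' @param sim_path,labels_path output CSV paths; `NULL` skips that file.
#' @return invisibly, the paths written.
#' @export
write_partition <- function(partition, sim_path = NULL, labels_path = NULL) {
  stopifnot(inherits(partition, "dp_partition"))
  if (!is.null(sim_path))
    utils::write.csv(partition$similarity, sim_path, row.names = TRUE)
  if (!is.null(labels_path))
    utils::write.csv(data.frame(country = names(partition$labels),
                                cluster = unname(partition$labels)),
                     labels_path, row.names = FALSE)
  invisible(c(sim_path, labels_path))
}
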