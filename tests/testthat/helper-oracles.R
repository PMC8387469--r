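# Independent oracles and fixture builders used across test files.

# Brute-force bout partition: walk the stream press by press, cutting at
# every gap >= threshold, with no vectorized shortcuts.  Independent of
# partition_bouts().
brute_force_partition <- function(times, gap_threshold = 5, min_bout_size = 2) {
  runs <- list()
  cur <- numeric(0)
  for (t in times) {
    if (length(cur) == 0L) {
      cur <- t
    } else if (t - cur[length(cur)] >= gap_threshold) {
      runs[[length(runs) + 1L]] <- cur
      cur <- t
    } else {
      cur <- c(cur, t)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  sizes <- vapply(runs, length, 1L)
  list(bouts = runs[sizes >= min_bout_size],
       solitary = unlist(runs[sizes < min_bout_size]) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form two-sample Welch t statistic.
welch_t_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

# Closed-form one-way ANOVA F from textbook sums of squares.
oneway_f_oracle <- function(values, groups) {
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  k <- length(unique(groups)); n <- length(values)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# Pearson r by the product-moment formula.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# region_density matrix from a plain matrix.
make_density <- function(m, groups = rep("a", ncol(m))) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("an%d", seq_len(ncol(m)))
  structure(m, groups = groups, zscored = FALSE,
            class = c("region_density", "matrix", "array"))
}

# Region features with two planted covariance blocks: regions within a block
# share a latent animal profile (pairwise correlation ~ rho), blocks are
# independent.
make_block_features <- function(n_regions = 10, n_animals = 20, rho = 0.9) {
  blocks <- rep(1:2, each = n_regions / 2)
  g <- matrix(stats::rnorm(2 * n_animals), 2)
  feats <- sqrt(rho) * g[blocks, ] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_regions * n_animals), n_regions)
  list(features = feats + 10, blocks = blocks)
}

# Well-separated random 3-D points inside [margin, limit-margin]^3.
place_separated <- function(n, min_dist, limit, margin = 60) {
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3, margin, limit - margin), 1)
    if (!nrow(pts) ||
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 3, byrow = TRUE))^2))) >
          min_dist)
      pts <- rbind(pts, cand)
  }
  data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
}
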