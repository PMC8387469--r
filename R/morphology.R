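# Grayscale morphology and separable filtering on 3-D volumes.
# Implemented directly because the cell-detection recipe needs an even-sized
# (8x8) in-plane structuring element and a seeded watershed that floods down
# to a fixed intensity threshold; the generic immersion watersheds in image
# packages have different semantics.

# Shift a 3-D array by `s` voxels along `axis`, filling with `fill`.
shift_array <- function(a, s, axis, fill) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  src <- max(1, 1 - s):min(n, n - s)
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- src + s
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Running min/max over a window of `size` voxels along `axis`.
# Even sizes use the asymmetric offset split floor((size-1)/2) forward /
# the rest backward when `forward = TRUE`, and the reflected split otherwise,
# so that erosion and dilation are adjoint and opening(x) <= x holds.
minmax_filter_axis <- function(a, size, axis, op = c("min", "max"),
                               forward = TRUE) {
  op <- match.arg(op)
  lo <- -floor((size - 1) / 2)
  hi <- ceiling((size - 1) / 2)
  offsets <- if (forward) lo:hi else (-hi):(-lo)
  fill <- if (op == "min") Inf else -Inf
  f <- if (op == "min") pmin else pmax
  out <- NULL
  for (s in offsets) {
    sh <- shift_array(a, s, axis, fill)
    out <- if (is.null(out)) sh else f(out, sh)
  }
  out
}

# In-plane (axes 1 and 2) grayscale opening with a size x size flat box.
opening_inplane <- function(vol, size) {
  er <- minmax_filter_axis(vol, size, 1L, "min", forward = TRUE)
  er <- minmax_filter_axis(er, size, 2L, "min", forward = TRUE)
  di <- minmax_filter_axis(er, size, 1L, "max", forward = FALSE)
  minmax_filter_axis(di, size, 2L, "max", forward = FALSE)
}

# Separable 3-D Gaussian blur via banded kernel matrices and BLAS.
gaussian_blur_3d <- function(vol, sigma) {
  d <- dim(vol)
  blur_axis <- function(a, axis) {
    n <- dim(a)[axis]
    x <- seq_len(n)
    K <- exp(-outer(x, x, `-`)^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, dp[1])
    aperm(array(m, dp), order(perm))
  }
  for (ax in 1:3) vol <- blur_axis(vol, ax)
  vol
}

# Difference-of-Gaussians enhancement: blur(sigma_narrow) - blur(sigma_wide).
dog_filter <- function(vol, kernel_size) {
  s1 <- kernel_size / 4
  s2 <- kernel_size / 2
  gaussian_blur_3d(vol, s1) - gaussian_blur_3d(vol, s2)
}

# 26-connected neighbor linear-index offsets for a volume of dims d.
neighbor_offsets_26 <- function(d) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  list(di = g$di, dj = g$dj, dk = g$dk,
       lin = g$di + g$dj * d[1] + g$dk * d[1] * d[2])
}

# Local maxima of `score` restricted to linear indices `cand`.
# Plateaus are broken deterministically: a voxel must be strictly greater
# than neighbors that precede it in lexicographic (linear-index) order and
# at least equal to the rest.  Out-of-volume neighbors count as -Inf.
local_maxima_3d <- function(score, cand) {
  d <- dim(score)
  nb <- neighbor_offsets_26(d)
  ijk <- arrayInd(cand, d)
  ok <- rep(TRUE, length(cand))
  v <- score[cand]
  for (m in seq_along(nb$lin)) {
    i <- ijk[, 1] + nb$di[m]; j <- ijk[, 2] + nb$dj[m]; k <- ijk[, 3] + nb$dk[m]
    inb <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    nv <- rep(-Inf, length(cand))
    nv[inb] <- score[cand[inb] + nb$lin[m]]
    ok <- ok & (if (nb$lin[m] < 0) v > nv else v >= nv)
    if (!any(ok)) break
  }
  cand[ok]
}

# Seeded watershed: grow labels from `seeds` (linear indices) over the masked
# voxels `mask_idx` (suprathreshold set), iteratively assigning each
# unlabeled masked voxel the label of its brightest labeled 26-neighbor
# (ties by smaller label).  Flooding stops at the mask boundary, i.e. the
# intensity threshold.  Returns an integer vector of labels aligned with
# `mask_idx` (0 = unreached).
watershed_to_threshold <- function(intensity, mask_idx, seeds) {
  d <- dim(intensity)
  nb <- neighbor_offsets_26(d)
  lab_vol <- array(0L, d)
  lab_vol[seeds] <- seq_along(seeds)
  in_mask <- array(FALSE, d)
  in_mask[mask_idx] <- TRUE
  pending <- setdiff(mask_idx, seeds)
  repeat {
    if (!length(pending)) break
    ijk <- arrayInd(pending, d)
    best_lab <- integer(length(pending))
    best_int <- rep(-Inf, length(pending))
    for (m in seq_along(nb$lin)) {
      i <- ijk[, 1] + nb$di[m]; j <- ijk[, 2] + nb$dj[m]; k <- ijk[, 3] + nb$dk[m]
      p <- which(i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3])
      if (!length(p)) next
      nidx <- pending[p] + nb$lin[m]
      nlab <- lab_vol[nidx]
      has <- nlab > 0L
      if (!any(has)) next
      p <- p[has]; nlab <- nlab[has]; nint <- intensity[nidx[has]]
      better <- nint > best_int[p] |
        (nint == best_int[p] & (best_lab[p] == 0L | nlab < best_lab[p]))
      p <- p[better]
      if (length(p)) {
        best_int[p] <- nint[better]
        best_lab[p] <- nlab[better]
      }
    }
    got <- best_lab > 0L
    if (!any(got)) break
    lab_vol[pending[got]] <- best_lab[got]
    pending <- pending[!got]
  }
  lab_vol[mask_idx]
}
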