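#' Cell-detection parameters
#'
#' The simplified whole-brain c-Fos detection recipe: background removal by
#' in-plane grayscale morphological opening (8 x 8 box) subtracted from the
#' volume; difference-of-Gaussians (DoG) enhancement with a 4 x 4 x 4 kernel;
#' candidate peaks = local maxima whose background-subtracted intensity is at
#' least `peak_threshold` (125); each peak painted outward by a seeded
#' watershed down to the threshold; surviving objects filtered to
#' `size_bounds` (8-200 contiguous voxels).
#'
#' The DoG output localizes peaks; the 125 threshold and the watershed floor
#' act on the background-subtracted intensities, where the original
#' amplitudes are preserved.
#'
#' @param opening_size in-plane box size in pixels (default 8).
#' @param dog_kernel DoG kernel size in voxels (default 4); the narrow and
#'   wide Gaussian SDs are `dog_kernel/4` and `dog_kernel/2`.
#' @param peak_threshold intensity threshold for peaks and watershed floor
#'   (default 125).
#' @param size_bounds c(min, max) object size in voxels (default c(8, 200)).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(opening_size = 8, dog_kernel = 4,
                             peak_threshold = 125, size_bounds = c(8, 200)) {
  stop_if_not_scalar_pos(opening_size, "opening_size")
  stop_if_not_scalar_pos(dog_kernel, "dog_kernel")
  stop_if_not_scalar_pos(peak_threshold, "peak_threshold")
  if (length(size_bounds) != 2L || size_bounds[1] < 1 ||
      size_bounds[1] >= size_bounds[2])
    stop("`size_bounds` must be c(min, max) with 1 <= min < max", call. = FALSE)
  structure(list(opening_size = as.integer(opening_size),
                 dog_kernel = dog_kernel, peak_threshold = peak_threshold,
                 size_bounds = size_bounds),
            class = "detection_params")
}

#' Detect cells in a 3-D volume
#'
#' Runs the recipe described in [detection_params()] and returns one record
#' per surviving object.
#'
#' @param volume 3-D numeric array of nonnegative intensities.
#' @param params a [detection_params()] object.
#' @param voxel_size_um voxel edge length used to report micrometre
#'   coordinates (default 1; voxel `i` is centred at `(i-0.5)*voxel_size_um`).
#' @return data.frame with columns `x_um`, `y_um`, `z_um` (centroid),
#'   `intensity` (peak background-subtracted intensity), `size_voxels`.
#' @export
detect_cells <- function(volume, params = detection_params(),
                         voxel_size_um = 1) {
  stopifnot(inherits(params, "detection_params"))
  d <- dim(volume)
  if (length(d) != 3L) stop("`volume` must be a 3-D array", call. = FALSE)
  if (any(volume < 0)) stop("intensities must be nonnegative", call. = FALSE)

  bg <- opening_inplane(volume, params$opening_size)
  sub <- volume - bg
  sub[sub < 0] <- 0
  dog <- dog_filter(sub, params$dog_kernel)

  mask_idx <- which(sub >= params$peak_threshold)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0), size_voxels = integer(0))
  if (!length(mask_idx)) return(empty)
  seeds <- local_maxima_3d(dog, mask_idx)
  if (!length(seeds)) return(empty)

  labels <- watershed_to_threshold(sub, mask_idx, seeds)
  keep <- labels > 0L
  if (!any(keep)) return(empty)
  idx <- mask_idx[keep]
  lab <- labels[keep]
  sizes <- tabulate(lab)
  ok_lab <- which(sizes >= params$size_bounds[1] & sizes <= params$size_bounds[2])
  if (!length(ok_lab)) return(empty)

  ijk <- arrayInd(idx, d)
  out <- lapply(ok_lab, function(l) {
    sel <- lab == l
    ctr <- colMeans(ijk[sel, , drop = FALSE])
    data.frame(x_um = (ctr[1] - 0.5) * voxel_size_um,
               y_um = (ctr[2] - 0.5) * voxel_size_um,
               z_um = (ctr[3] - 0.5) * voxel_size_um,
               intensity = max(sub[idx[sel]]),
               size_voxels = sizes[l])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Striatal subregion binning scheme
#'
#' Atlas-free partition of the (pre-aligned) striatal volume into four
#' subregions by thresholding first the anterior/posterior (AP) coordinate,
#' then the medial/lateral (ML) coordinate.  ML is taken as absolute distance
#' from the midline, pooling hemispheres.  Bins are half-open: a coordinate
#' exactly on a boundary falls on the posterior/medial side.
#'
#' Axis convention for clouds: `x_um` = ML (signed, midline at `midline_x`),
#' `y_um` = AP (larger = more anterior), `z_um` = DV.
#'
#' @param ap_boundary AP split, micrometres.
#' @param ml_boundary ML split, micrometres from midline (> 0).
#' @param striatal_bounds 3x2 matrix of (min, max) bounds in (|ML|, AP, DV)
#'   space; cells outside are labeled `"other"`.
#' @param midline_x the midline's x coordinate (default 0).
#' @param bin_volumes named numeric vector of bin volumes in mm^3 for the
#'   four labels; default computed from the bounds (x 2 for the two pooled
#'   hemispheres).
#' @return an object of class `subregion_scheme` with `region_labels`
#'   `c("aDMS", "aDLS", "pDMS", "pDLS")`.
#' @export
subregion_scheme <- function(ap_boundary, ml_boundary, striatal_bounds,
                             midline_x = 0, bin_volumes = NULL) {
  striatal_bounds <- matrix(as.numeric(striatal_bounds), 3, 2)
  if (any(striatal_bounds[, 2] <= striatal_bounds[, 1]))
    stop("striatal_bounds must have max > min on every axis", call. = FALSE)
  if (ap_boundary <= striatal_bounds[2, 1] || ap_boundary >= striatal_bounds[2, 2])
    stop("`ap_boundary` must lie inside the AP bounds", call. = FALSE)
  if (ml_boundary <= striatal_bounds[1, 1] || ml_boundary >= striatal_bounds[1, 2])
    stop("`ml_boundary` must lie inside the |ML| bounds", call. = FALSE)
  labels <- c("aDMS", "aDLS", "pDMS", "pDLS")
  if (is.null(bin_volumes)) {
    ml_ext <- c(med = ml_boundary - striatal_bounds[1, 1],
                lat = striatal_bounds[1, 2] - ml_boundary)
    ap_ext <- c(post = ap_boundary - striatal_bounds[2, 1],
                ant = striatal_bounds[2, 2] - ap_boundary)
    dv_ext <- striatal_bounds[3, 2] - striatal_bounds[3, 1]
    # x2: |ML| bins pool the two hemispheres
    bin_volumes <- 2 * c(aDMS = ml_ext["med"] * ap_ext["ant"],
                         aDLS = ml_ext["lat"] * ap_ext["ant"],
                         pDMS = ml_ext["med"] * ap_ext["post"],
                         pDLS = ml_ext["lat"] * ap_ext["post"]) * dv_ext / 1e9
    names(bin_volumes) <- labels
  }
  if (!setequal(names(bin_volumes), labels) || any(bin_volumes <= 0))
    stop("`bin_volumes` must be positive and named by the four region labels",
         call. = FALSE)
  structure(list(ap_boundary = ap_boundary, ml_boundary = ml_boundary,
                 striatal_bounds = striatal_bounds, midline_x = midline_x,
                 region_labels = labels,
                 bin_volumes = bin_volumes[labels]),
            class = "subregion_scheme")
}

#' Assign striatal subregion labels to a cell cloud
#'
#' @param cloud data.frame with columns `x_um`, `y_um`, `z_um`.
#' @param scheme a [subregion_scheme()].
#' @return the cloud with an added `region` column (one of the four labels or
#'   `"other"`).  Rows with missing coordinates are rejected.
#' @export
assign_subregions <- function(cloud, scheme) {
  stopifnot(inherits(scheme, "subregion_scheme"))
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(cloud)))
    stop("cloud must have x_um, y_um, z_um columns", call. = FALSE)
  bad <- which(!stats::complete.cases(cloud[need]))
  if (length(bad))
    stop("missing coordinates in cloud rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ml <- abs(cloud$x_um - scheme$midline_x)
  ap <- cloud$y_um
  dv <- cloud$z_um
  b <- scheme$striatal_bounds
  inside <- ml >= b[1, 1] & ml < b[1, 2] &
            ap >= b[2, 1] & ap < b[2, 2] &
            dv >= b[3, 1] & dv < b[3, 2]
  anterior <- ap > scheme$ap_boundary     # == boundary -> posterior
  lateral <- ml > scheme$ml_boundary      # == boundary -> medial
  region <- ifelse(!inside, "other",
            ifelse(anterior & lateral, "aDLS",
            ifelse(anterior & !lateral, "aDMS",
            ifelse(lateral, "pDLS", "pDMS"))))
  cloud$region <- region
  cloud
}

#' Region x animal density matrix
#'
#' Cell counts per subregion per animal divided by the region's bin volume.
#'
#' @param labeled_clouds named list of per-animal clouds (as from
#'   [assign_subregions()]); names are animal ids.
#' @param scheme a [subregion_scheme()], or NULL when `volumes` is given.
#' @param groups character vector of group labels, one per animal (recycled
#'   from each cloud's `group` column when absent).
#' @param volumes optional named vector of region volumes (mm^3) overriding
#'   the scheme's.
#' @return an object of class `region_density`: a region x animal numeric
#'   matrix with attributes `groups` (per animal) and `zscored = FALSE`.
#' @export
density_matrix <- function(labeled_clouds, scheme = NULL, groups = NULL,
                           volumes = NULL) {
  if (!length(labeled_clouds)) stop("need at least one animal", call. = FALSE)
  volumes <- volumes %||% scheme$bin_volumes
  if (is.null(volumes)) stop("provide a scheme or explicit `volumes`", call. = FALSE)
  if (any(volumes <= 0)) stop("region volumes must be positive", call. = FALSE)
  regions <- names(volumes)
  ids <- names(labeled_clouds) %||% sprintf("animal%d", seq_along(labeled_clouds))
  mat <- sapply(labeled_clouds, function(cl) {
    cnt <- table(factor(cl$region, levels = regions))
    as.numeric(cnt) / volumes
  })
  mat <- matrix(mat, nrow = length(regions),
                dimnames = list(regions, ids))
  if (is.null(groups)) {
    groups <- vapply(labeled_clouds, function(cl)
      if ("group" %in% names(cl) && nrow(cl)) as.character(cl$group[1])
      else NA_character_, "")
  }
  structure(mat, groups = unname(groups), zscored = FALSE,
            class = c("region_density", "matrix", "array"))
}

#' Z-score a density matrix
#'
#' Default (`by = "animal"`): each animal's region vector (a column) is
#' centred and scaled to mean 0, SD 1, expressing each region's density
#' relative to that animal's overall activation profile.  `by = "region"`
#' scales each region across animals instead.  Zero-variance vectors map to
#' zeros rather than NaN.
#'
#' @param mat a `region_density` matrix.
#' @param by `"animal"` (default) or `"region"`.
#' @return the z-scored `region_density` matrix (`zscored = TRUE`).
#' @export
zscore_densities <- function(mat, by = c("animal", "region")) {
  stopifnot(inherits(mat, "region_density"))
  by <- match.arg(by)
  z1 <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  out <- if (by == "animal") apply(mat, 2, z1) else t(apply(mat, 1, z1))
  dimnames(out) <- dimnames(mat)
  structure(out, groups = attr(mat, "groups"), zscored = TRUE,
            class = class(mat))
}

#' KNN clustering of regions by density covariance
#'
#' Each region's feature vector is its density profile across animals
#' (within-group mode, optionally restricted to one group) or, in
#' group-difference mode, its densities across all animals after subtracting,
#' for each animal, the region's mean density in the *other* group.  Distance
#' is correlation distance `1 - cor`; each region is linked to its k nearest
#' neighbors and clusters are the connected components of the symmetrized
#' graph.  By default the graph is symmetrized by union (an edge exists when
#' either endpoint lists the other among its k neighbors), the behaviour of
#' treating a k-neighbors graph as undirected, as standard KNN tooling does.
#' `symmetrize = "mutual"` keeps only reciprocated edges; note that on
#' tightly covarying blocks a mutual graph regularly isolates single regions
#' whose reciprocations fall just outside k, splitting true blocks.  A 2-D
#' stochastic-neighbor embedding ([tsne_embed()]) with a fixed seed
#' accompanies the clusters.
#'
#' @param mat a `region_density` matrix (raw or z-scored).
#' @param k neighbors per region (>= 1, < number of regions).
#' @param mode `"within-group"` (default) or `"group-difference"`.
#' @param symmetrize `"union"` (default) or `"mutual"`.
#' @param group for within-group mode, which group's animals to use (default
#'   all columns).
#' @param perplexity t-SNE perplexity (default `max(1, (n_regions - 1)/3)`).
#' @param seed integer seed for the embedding (default 1).
#' @param embed compute the 2-D embedding (default TRUE; skip when only the
#'   cluster memberships are needed).
#' @return list with `features`, `distance` (dist matrix), `neighbors`
#'   (region x k matrix of neighbor names), `adjacency` (symmetrized KNN
#'   logical matrix), `clusters` (named integer membership), `embedding`
#'   (region x 2 coordinates, or NULL when `embed = FALSE`).
#' @export
region_knn_clusters <- function(mat, k, mode = c("within-group", "group-difference"),
                                symmetrize = c("union", "mutual"),
                                group = NULL, perplexity = NULL, seed = 1,
                                embed = TRUE) {
  stopifnot(inherits(mat, "region_density"))
  mode <- match.arg(mode)
  symmetrize <- match.arg(symmetrize)
  groups <- attr(mat, "groups")
  nr <- nrow(mat)
  if (k < 1 || k >= nr)
    stop("`k` must satisfy 1 <= k < number of regions", call. = FALSE)

  if (mode == "within-group") {
    feats <- if (is.null(group)) mat else {
      if (!group %in% groups) stop("unknown group: ", group, call. = FALSE)
      mat[, groups == group, drop = FALSE]
    }
    feats <- unclass(feats)
  } else {
    if (is.null(groups) || length(unique(stats::na.omit(groups))) != 2L)
      stop("group-difference mode needs exactly two groups", call. = FALSE)
    gl <- unique(stats::na.omit(groups))
    m <- unclass(mat)
    other_mean <- cbind(rowMeans(m[, groups == gl[2], drop = FALSE]),
                        rowMeans(m[, groups == gl[1], drop = FALSE]))
    feats <- m
    for (j in seq_len(ncol(m)))
      feats[, j] <- m[, j] - other_mean[, match(groups[j], gl)]
  }
  if (ncol(feats) < 2L) stop("need at least 2 animals for covariance features",
                             call. = FALSE)

  cm <- suppressWarnings(stats::cor(t(feats)))
  cm[!is.finite(cm)] <- 0          # zero-variance feature rows
  diag(cm) <- 1
  D <- 1 - cm

  # k nearest neighbors excluding self; distances tied with the k-th
  # neighbor are all included, so degenerate all-equal profiles connect fully
  adj <- matrix(FALSE, nr, nr, dimnames = list(rownames(mat), rownames(mat)))
  neighbors <- matrix("", nr, k, dimnames = list(rownames(mat), NULL))
  for (i in seq_len(nr)) {
    d_i <- D[i, -i]
    dk <- sort(d_i)[k]
    nb <- setdiff(which(D[i, ] <= dk + 1e-12), i)
    adj[i, nb] <- TRUE
    ord <- order(D[i, ], seq_len(nr))
    neighbors[i, ] <- rownames(mat)[ord[ord != i][seq_len(k)]]
  }
  sym <- if (symmetrize == "mutual") adj & t(adj) else adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
  comp <- igraph::components(g)$membership
  emb <- NULL
  if (embed) {
    emb <- tsne_embed(D, perplexity = perplexity %||% max(1, (nr - 1) / 3),
                      seed = seed)
    rownames(emb) <- rownames(mat)
  }
  list(features = feats, distance = stats::as.dist(D), neighbors = neighbors,
       adjacency = sym, clusters = comp, embedding = emb)
}

#' Per-region group contrast of cell densities
#'
#' Two-way (region x group) analysis of variance with interaction on the
#' stacked densities of two groups, followed — when the interaction is
#' significant at `alpha` — by per-region Welch t contrasts with Holm
#' adjustment across regions.
#'
#' @param mat_a,mat_b `region_density` matrices with identical region sets
#'   and >= 2 animals each.
#' @param alpha gating level for the post-hoc contrasts (default 0.05).
#' @return list with `anova` (data.frame of effect, df, F, p), `contrasts`
#'   (data.frame region, mean_a, mean_b, diff, t, df, p, p_adj; NULL when the
#'   interaction gate fails), and `gated` (logical).
#' @export
group_density_difference <- function(mat_a, mat_b, alpha = 0.05) {
  stopifnot(inherits(mat_a, "region_density"), inherits(mat_b, "region_density"))
  if (!identical(rownames(mat_a), rownames(mat_b)))
    stop("matrices must share an identical region set", call. = FALSE)
  if (ncol(mat_a) < 2L || ncol(mat_b) < 2L)
    stop("need at least 2 animals per group", call. = FALSE)
  regions <- rownames(mat_a)
  long <- rbind(
    data.frame(density = as.vector(unclass(mat_a)),
               region = rep(regions, ncol(mat_a)), group = "A"),
    data.frame(density = as.vector(unclass(mat_b)),
               region = rep(regions, ncol(mat_b)), group = "B"))
  long$region <- factor(long$region, levels = regions)
  long$group <- factor(long$group)
  an <- two_way_anova_table(long$density, long$region, long$group)
  inter <- an[an$effect == "region:group", ]
  gated <- is.finite(inter$p) && inter$p < alpha
  contrasts <- NULL
  if (gated) {
    rows <- lapply(regions, function(rg) {
      a <- unclass(mat_a)[rg, ]; b <- unclass(mat_b)[rg, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        data.frame(region = rg, mean_a = mean(a), mean_b = mean(b),
                   diff = mean(a) - mean(b), t = 0,
                   df = length(a) + length(b) - 2, p = 1)
      } else {
        tt <- stats::t.test(a, b)
        data.frame(region = rg, mean_a = mean(a), mean_b = mean(b),
                   diff = mean(a) - mean(b), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
      }
    })
    contrasts <- do.call(rbind, rows)
    contrasts$p_adj <- stats::p.adjust(contrasts$p, method = "holm")
  }
  list(anova = an, contrasts = contrasts, gated = gated)
}
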