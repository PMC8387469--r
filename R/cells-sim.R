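#' Parameters for synthetic 3-D cell clouds
#'
#' Emulates whole-brain detected-cell coordinate tables in a common
#' pre-aligned reference frame: per animal and per named region, the cell
#' count is Poisson with mean `rate * region_volume_mm3` and positions are
#' uniform inside the region's axis-aligned sub-box.  Clouds can be rendered
#' as voxel volumes ([render_cell_volume()]) with one Gaussian blob per cell,
#' providing ground truth for the cell detector.
#'
#' @param bounding_box 3x2 matrix of (min, max) extents in micrometres, rows
#'   = (x, y, z).
#' @param region_partition named list of 3x2 sub-box matrices; sub-boxes must
#'   be pairwise disjoint and tile the bounding box.
#' @param per_region_rate region x group matrix (cells per mm^3); dimnames
#'   name the regions and groups.
#' @param n_animals_per_group animals per group.
#' @param blob_peak rendered peak intensity per cell.
#' @param blob_sigma rendered Gaussian width, micrometres.
#' @param seed optional integer seed.
#' @return an object of class `cloud_sim_params`.
#' @export
cloud_sim_params <- function(bounding_box, region_partition, per_region_rate,
                             n_animals_per_group = 4, blob_peak = 200,
                             blob_sigma = 10, seed = NULL) {
  bounding_box <- matrix(as.numeric(bounding_box), 3, 2)
  if (any(bounding_box[, 2] <= bounding_box[, 1]))
    stop("bounding_box must have max > min on every axis", call. = FALSE)
  region_partition <- lapply(region_partition, function(b) matrix(as.numeric(b), 3, 2))
  vol_um3 <- function(b) prod(b[, 2] - b[, 1])
  # containment
  for (nm in names(region_partition)) {
    b <- region_partition[[nm]]
    if (any(b[, 1] < bounding_box[, 1] - 1e-9) ||
        any(b[, 2] > bounding_box[, 2] + 1e-9))
      stop(sprintf("region '%s' leaves the bounding box", nm), call. = FALSE)
  }
  # pairwise disjoint (interiors)
  nms <- names(region_partition)
  for (i in seq_along(nms)) for (j in seq_len(i - 1L)) {
    a <- region_partition[[i]]; b <- region_partition[[j]]
    if (all(a[, 1] < b[, 2] - 1e-9) && all(b[, 1] < a[, 2] - 1e-9))
      stop(sprintf("regions '%s' and '%s' overlap", nms[i], nms[j]), call. = FALSE)
  }
  if (abs(sum(vapply(region_partition, vol_um3, 1)) - vol_um3(bounding_box)) >
      1e-6 * vol_um3(bounding_box))
    stop("region_partition must tile the bounding box", call. = FALSE)
  per_region_rate <- as.matrix(per_region_rate)
  if (is.null(rownames(per_region_rate)) ||
      !setequal(rownames(per_region_rate), names(region_partition)))
    stop("`per_region_rate` rows must be named by the partition's regions", call. = FALSE)
  if (any(per_region_rate < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(list(bounding_box = bounding_box,
                 region_partition = region_partition,
                 per_region_rate = per_region_rate,
                 n_animals_per_group = as.integer(n_animals_per_group),
                 blob_peak = blob_peak, blob_sigma = blob_sigma, seed = seed),
            class = "cloud_sim_params")
}

#' Simulate per-animal 3-D cell clouds
#'
#' @param params a [cloud_sim_params()] object.
#' @return list with `clouds` (one data.frame per animal: animal_id, group,
#'   region (ground truth), x_um, y_um, z_um, intensity, size_voxels) and
#'   `params`.
#' @export
simulate_cell_cloud <- function(params) {
  stopifnot(inherits(params, "cloud_sim_params"))
  with_seed(params$seed, {
    groups <- colnames(params$per_region_rate) %||%
      paste0("g", seq_len(ncol(params$per_region_rate)))
    clouds <- list()
    for (gi in seq_along(groups)) {
      for (ai in seq_len(params$n_animals_per_group)) {
        id <- sprintf("%s_a%d", groups[gi], ai)
        rows <- lapply(names(params$region_partition), function(rg) {
          b <- params$region_partition[[rg]]
          vol_mm3 <- prod(b[, 2] - b[, 1]) / 1e9
          n <- stats::rpois(1L, params$per_region_rate[rg, gi] * vol_mm3)
          if (n == 0L) return(NULL)
          data.frame(animal_id = id, group = groups[gi], region = rg,
                     x_um = stats::runif(n, b[1, 1], b[1, 2]),
                     y_um = stats::runif(n, b[2, 1], b[2, 2]),
                     z_um = stats::runif(n, b[3, 1], b[3, 2]),
                     intensity = params$blob_peak,
                     size_voxels = NA_real_)
        })
        cl <- do.call(rbind, rows)
        if (is.null(cl))
          cl <- data.frame(animal_id = character(0), group = character(0),
                           region = character(0), x_um = numeric(0),
                           y_um = numeric(0), z_um = numeric(0),
                           intensity = numeric(0), size_voxels = numeric(0))
        clouds[[id]] <- cl
      }
    }
    list(clouds = clouds, params = params)
  })
}

#' Render a cell cloud as a voxel volume
#'
#' Places one isotropic Gaussian blob (peak `blob_peak`, SD `blob_sigma` um)
#' per cell on a zero background; voxel `i` along an axis is centred at
#' `(i - 0.5) * voxel_size_um`.  Optional additive white noise.
#'
#' @param cloud a per-animal cloud data.frame (columns x_um, y_um, z_um).
#' @param dim_vox integer c(nx, ny, nz) volume dimensions.
#' @param voxel_size_um voxel edge length, micrometres.
#' @param blob_peak,blob_sigma blob parameters (defaults 200 and 10 um).
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param seed optional integer seed for the noise.
#' @return 3-D numeric array.
#' @export
render_cell_volume <- function(cloud, dim_vox, voxel_size_um = 5,
                               blob_peak = 200, blob_sigma = 10,
                               noise_sd = 0, seed = NULL) {
  dim_vox <- as.integer(dim_vox)
  stopifnot(length(dim_vox) == 3L, all(dim_vox > 0))
  with_seed(seed, {
    vol <- array(0, dim_vox)
    if (nrow(cloud)) {
      reach <- ceiling(4 * blob_sigma / voxel_size_um)
      for (r in seq_len(nrow(cloud))) {
        p <- c(cloud$x_um[r], cloud$y_um[r], cloud$z_um[r])
        ctr_vox <- p / voxel_size_um + 0.5   # voxel-index coordinate of the cell
        lo <- pmax(1L, floor(ctr_vox - reach))
        hi <- pmin(dim_vox, ceiling(ctr_vox + reach))
        if (any(lo > hi)) next
        ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
        dx2 <- ((ix - 0.5) * voxel_size_um - p[1])^2
        dy2 <- ((iy - 0.5) * voxel_size_um - p[2])^2
        dz2 <- ((iz - 0.5) * voxel_size_um - p[3])^2
        blob <- blob_peak * exp(-(outer(outer(dx2, dy2, `+`), dz2, `+`)) /
                                  (2 * blob_sigma^2))
        vol[ix, iy, iz] <- vol[ix, iy, iz] + blob
      }
    }
    if (noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(dim_vox), 0, noise_sd), dim_vox)
    vol
  })
}
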