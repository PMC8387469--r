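scheme_demo <- function() {
  subregion_scheme(ap_boundary = 1000, ml_boundary = 2000,
                   striatal_bounds = matrix(c(1000, 3000, 0, 2000, 0, 2000),
                                            3, 2, byrow = TRUE))
}

test_that("detection recipe accepts valid blobs and rejects the gates", {
  set.seed(14)
  dimv <- c(72, 72, 72); vs <- 5
  pts <- place_separated(5, 90, dimv[1] * vs)
  vol <- render_cell_volume(pts, dimv, vs, blob_peak = 210, blob_sigma = 12)
  det <- detect_cells(vol, detection_params(), voxel_size_um = vs)
  expect_equal(nrow(det), 5)
  expect_true(all(det$size_voxels >= 8 & det$size_voxels <= 200))
  # detected centroids land on the planted cells
  d <- as.matrix(dist(rbind(as.matrix(pts), as.matrix(det[, 1:3]))))
  d <- d[1:5, 5 + seq_len(nrow(det)), drop = FALSE]
  expect_lt(max(apply(d, 1, min)), vs)
  # peak 100 < threshold 125: rejected
  vol_low <- render_cell_volume(pts[1, ], dimv, vs, blob_peak = 100,
                                blob_sigma = 12)
  expect_equal(nrow(detect_cells(vol_low, detection_params(), vs)), 0)
  # oversize object (> 200 contiguous suprathreshold voxels): rejected
  vol_big <- render_cell_volume(pts[1, ], dimv, vs, blob_peak = 3000,
                                blob_sigma = 40)
  sub_check <- sum(vol_big >= 125)
  expect_gt(sub_check, 200)
  expect_equal(nrow(detect_cells(vol_big, detection_params(), vs)), 0)
  expect_error(detect_cells(matrix(1, 3, 3)), "3-D")
})

test_that("detection tolerates a smooth additive background", {
  set.seed(15)
  dimv <- c(64, 64, 48); vs <- 5
  pts <- place_separated(4, 90, 240, margin = 50)
  pts$z_um <- pmin(pts$z_um, 190)
  vol <- render_cell_volume(pts, dimv, vs, blob_peak = 210, blob_sigma = 12)
  ramp <- array(rep(seq(0, 60, length.out = dimv[1]), times = dimv[2] * dimv[3]),
                dimv)
  det0 <- detect_cells(vol, detection_params(), vs)
  det1 <- detect_cells(vol + ramp, detection_params(), vs)
  expect_equal(nrow(det1), nrow(det0))
})

test_that("subregion assignment follows the AP-then-ML half-open rule", {
  sch <- scheme_demo()
  cl <- data.frame(x_um = c(2500, 1500, 2500, 1500, 2500, 500, -2500),
                   y_um = c(1500, 1500, 500, 500, 1000, 1500, 1500),
                   z_um = 1000)
  lab <- assign_subregions(cl, sch)$region
  expect_equal(lab[1:4], c("aDLS", "aDMS", "pDLS", "pDMS"))
  # exactly on the AP boundary -> posterior
  expect_equal(lab[5], "pDLS")
  # outside the |ML| bounds -> other
  expect_equal(lab[6], "other")
  # hemisphere pooling via |ML|
  expect_equal(lab[7], "aDLS")
  expect_error(assign_subregions(data.frame(x_um = 1, y_um = NA, z_um = 1), sch),
               "missing coordinates")
})

test_that("assignment conserves cell counts", {
  set.seed(16)
  sch <- scheme_demo()
  cl <- data.frame(x_um = runif(500, -4000, 4000), y_um = runif(500, -500, 2500),
                   z_um = runif(500, -100, 2100))
  lab <- assign_subregions(cl, sch)
  expect_equal(sum(table(lab$region)), 500)
  expect_true(all(lab$region %in% c(sch$region_labels, "other")))
})

test_that("densities are counts over volume and scale linearly", {
  sch <- scheme_demo()
  cl <- data.frame(x_um = rep(2500, 10), y_um = rep(1500, 10), z_um = 1000)
  lab <- assign_subregions(cl, sch)
  dm <- density_matrix(list(a1 = lab), volumes = c(aDLS = 2, aDMS = 1,
                                                   pDMS = 1, pDLS = 1))
  expect_equal(unclass(dm)["aDLS", "a1"], 5)
  expect_equal(sum(unclass(dm)[c("aDMS", "pDMS", "pDLS"), ]), 0)
  # doubling the cloud doubles every density
  dm2 <- density_matrix(list(a1 = rbind(lab, lab)),
                        volumes = c(aDLS = 2, aDMS = 1, pDMS = 1, pDLS = 1))
  expect_equal(unclass(dm2), 2 * unclass(dm))
  expect_error(density_matrix(list(a1 = lab), volumes = c(aDLS = 0)),
               "positive")
})

test_that("z-scoring centers each animal's region profile", {
  set.seed(17)
  m <- make_density(matrix(rpois(40, 50), 8, 5))
  z <- zscore_densities(m)
  expect_true(isTRUE(attr(z, "zscored")))
  expect_true(all(abs(colMeans(unclass(z))) < 1e-12))
  expect_true(all(abs(apply(unclass(z), 2, sd) - 1) < 1e-12))
  # constant profile -> zeros, not NaN
  mc <- make_density(matrix(5, 4, 3))
  expect_true(all(zscore_densities(mc) == 0))
  # alternative axis
  zr <- zscore_densities(m, by = "region")
  expect_true(all(abs(rowMeans(unclass(zr))) < 1e-12))
})

test_that("KNN components recover planted covariance blocks", {
  set.seed(18)
  bl <- make_block_features(n_regions = 10, n_animals = 20, rho = 0.9)
  m <- make_density(bl$features)
  res <- region_knn_clusters(m, k = 3, embed = FALSE)
  expect_equal(length(unique(res$clusters)), 2)
  expect_true(all(tapply(res$clusters, bl$blocks, function(v)
    length(unique(v))) == 1))
})

test_that("clustering degenerate cases behave as documented", {
  m <- make_density(matrix(rep(c(1, 2, 3, 4), 2), 2, 4, byrow = TRUE))
  res <- region_knn_clusters(m, k = 1, embed = FALSE)
  expect_equal(length(unique(res$clusters)), 1)
  # identical feature vectors: all distances 0, one component
  m2 <- make_density(matrix(rep(c(5, 1, 2, 6), each = 6), 6, 4, byrow = FALSE))
  res2 <- region_knn_clusters(m2, k = 2, embed = FALSE)
  expect_equal(length(unique(res2$clusters)), 1)
  expect_error(region_knn_clusters(m, k = 2), "k")
})

test_that("the embedding is reproducible under a fixed seed", {
  set.seed(19)
  m <- make_density(matrix(rnorm(60, 10), 6, 10))
  a <- region_knn_clusters(m, k = 2, seed = 5)$embedding
  b <- region_knn_clusters(m, k = 2, seed = 5)$embedding
  expect_identical(a, b)
  expect_equal(dim(a), c(6L, 2L))
})

test_that("group-difference features subtract the other group's mean", {
  set.seed(20)
  m <- make_density(matrix(rnorm(48, 100, 5), 4, 12),
                    groups = rep(c("tr", "yk"), each = 6))
  res <- region_knn_clusters(m, k = 1, mode = "group-difference",
                             embed = FALSE)
  gm_tr <- rowMeans(unclass(m)[, 1:6])
  gm_yk <- rowMeans(unclass(m)[, 7:12])
  expect_equal(res$features[, 1], unclass(m)[, 1] - gm_yk)
  expect_equal(res$features[, 7], unclass(m)[, 7] - gm_tr)
})

test_that("group contrast flags only the planted region", {
  set.seed(22)
  A <- matrix(rnorm(30, 100, 5), 5, 6)
  A[2, ] <- A[2, ] + 3 * 5   # +3 SD elevation in one region
  B <- matrix(rnorm(30, 100, 5), 5, 6)
  res <- group_density_difference(make_density(A), make_density(B))
  expect_true(res$gated)
  sig <- res$contrasts$region[res$contrasts$p_adj < 0.05]
  expect_identical(sig, "r2")
  # all-constant input: F = 0 for group and interaction
  C <- make_density(matrix(7, 4, 4))
  res0 <- group_density_difference(C, C)
  expect_equal(res0$anova$F[res0$anova$effect == "group"], 0)
  expect_equal(res0$anova$F[res0$anova$effect == "region:group"], 0)
  expect_false(res0$gated)
  expect_error(group_density_difference(make_density(A[, 1, drop = FALSE]),
                                        make_density(B)), "2 animals")
})
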