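test_that("soma sampling respects the volume and the depth profile", {
  expect_equal(nrow(sample_somata(n = 0, seed = 1)), 0)
  som <- sample_somata(n = 374, seed = 2)
  expect_equal(nrow(som), 374)
  expect_true(all(som$x >= 0 & som$x <= 354 & som$y >= 0 & som$y <= 354 &
                    som$z >= 0 & som$z <= 140))

  # uniform profile: depth histogram passes a chi-square GOF test
  uni <- depth_density_profile(edges = seq(0, 140, 35), density = rep(1, 4))
  z <- sample_somata(uni, n = 10000, seed = 3)$z
  counts <- table(cut(z, seq(0, 140, 35)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  expect_error(depth_density_profile(density = c(0, 0, 0, 0)),
               class = "ngf_error_config")
})

test_that("nearest-neighbor distances match the exhaustive oracle", {
  two <- data.frame(x = c(0, 3), y = c(0, 4), z = c(0, 0))
  expect_equal(nn_distances(two), c(5, 5))

  lat <- expand.grid(x = seq(0, 20, 10), y = seq(0, 20, 10),
                     z = seq(0, 20, 10))
  expect_true(all(nn_distances(lat) == 10))

  set.seed(4)
  pts <- data.frame(x = runif(50, 0, 30), y = runif(50, 0, 30),
                    z = runif(50, 0, 30))
  oracle <- vapply(seq_len(50), function(i) {
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2 +
                (pts$z - pts$z[i])^2)
    min(d[-i])
  }, numeric(1))
  expect_equal(unname(nn_distances(pts)), oracle)

  expect_error(nn_distances(two[1, ]), class = "ngf_error_stats")
})

test_that("coverage map equals the brute-force per-voxel oracle", {
  set.seed(9)
  boutons <- tibble::tibble(cell = rep(1:5, each = 4),
                            x = runif(20, 1, 11), y = runif(20, 1, 11),
                            z = runif(20, 1, 11))
  dims <- c(12, 12, 12)
  cov <- build_coverage(boutons, radius = 1.5, voxel_size = 1, dims = dims)
  oracle <- coverage_oracle(boutons, dims, 1.5, 1)
  oracle_nz <- oracle[oracle$boutons > 0, ]
  merged <- merge(as.data.frame(cov)[c("ix", "iy", "iz", "boutons",
                                       "sources")],
                  oracle_nz, by = c("ix", "iy", "iz"), all = TRUE)
  expect_false(any(is.na(merged)))
  expect_equal(merged$boutons.x, merged$boutons.y)
  expect_equal(merged$sources.x, merged$sources.y)
})

test_that("single-bouton coverage is exactly the within-radius voxels", {
  b <- tibble::tibble(cell = 1, x = 5.2, y = 5.2, z = 5.2)
  cov <- build_coverage(b, radius = 1.5, voxel_size = 1, dims = c(10, 10, 10))
  expect_true(all(cov$boutons == 1))
  ctr <- cbind(cov$ix + 0.5, cov$iy + 0.5, cov$iz + 0.5)
  d <- sqrt(rowSums((ctr - matrix(c(5.2, 5.2, 5.2), nrow(cov), 3,
                                  byrow = TRUE))^2))
  expect_true(all(d <= 1.5))
  # count of covered voxels equals the oracle count
  oracle <- coverage_oracle(b, c(10, 10, 10), 1.5, 1)
  expect_equal(nrow(cov), sum(oracle$boutons > 0))

  # two boutons of one cell covering a voxel: 2 boutons, 1 source
  b2 <- tibble::tibble(cell = c(1, 1), x = c(5, 5.4), y = 5, z = 5)
  cov2 <- build_coverage(b2, radius = 1.5, voxel_size = 1,
                         dims = c(10, 10, 10))
  vox <- cov2[cov2$ix == 4 & cov2$iy == 4 & cov2$iz == 4, ]
  expect_equal(vox$boutons, 2)
  expect_equal(vox$sources, 1)
})

test_that("coverage counts grow monotonically with radius", {
  set.seed(12)
  boutons <- tibble::tibble(cell = rep(1:4, each = 6),
                            x = runif(24, 0, 15), y = runif(24, 0, 15),
                            z = runif(24, 0, 15))
  tot <- vapply(c(0.5, 1, 1.5, 2.5), function(r)
    sum(build_coverage(boutons, radius = r, voxel_size = 1,
                       dims = c(15, 15, 15))$boutons), numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("source multiplicity: normalization, single cell, subsampling", {
  set.seed(5)
  boutons <- tibble::tibble(cell = rep(1:5, each = 5),
                            x = runif(25, 2, 18), y = runif(25, 2, 18),
                            z = runif(25, 2, 18))
  cov <- build_coverage(boutons, radius = 1.5, voxel_size = 1,
                        dims = c(20, 20, 20))
  mult <- source_multiplicity(cov)
  expect_equal(sum(mult$percent), 100, tolerance = 1e-6)
  # matches exhaustive enumeration (non-edge voxels)
  oracle <- coverage_oracle(boutons, c(20, 20, 20), 1.5, 1)
  inner <- oracle$boutons > 0 &
    oracle$ix >= 1.5 - 0.5 & oracle$ix + 0.5 <= 20 - 1.5 &
    oracle$iy >= 1.5 - 0.5 & oracle$iy + 0.5 <= 20 - 1.5 &
    oracle$iz >= 1.5 - 0.5 & oracle$iz + 0.5 <= 20 - 1.5
  tab <- table(cut(oracle$sources[inner],
                   c(0.5, 1.5, 2.5, 3.5, Inf),
                   labels = c("1", "2", "3", ">=4")))
  expect_equal(mult$n_voxels, as.integer(tab))

  # single-cell population: 100% single source
  b1 <- boutons[boutons$cell == 1, ]
  m1 <- source_multiplicity(build_coverage(b1, radius = 1.5,
                                           voxel_size = 1,
                                           dims = c(20, 20, 20)))
  expect_equal(m1$percent[m1$sources == "1"], 100)

  # lowering active_fraction shifts mass toward single sources (over seeds)
  p1_full <- mult$percent[mult$sources == "1"]
  p1_sub <- mean(vapply(1:10, function(s)
    source_multiplicity(cov, active_fraction = 0.5, seed = s)$percent[1],
    numeric(1)))
  expect_gte(p1_sub, p1_full)
  expect_error(source_multiplicity(cov, active_fraction = 0),
               class = "ngf_error_config")
})

test_that("population layout combines arbors and bouton clouds", {
  som <- sample_somata(dims = c(60, 60, 50), n = 4, seed = 3)
  lay <- population_layout(som,
                           growth_params(total_length_mean = 600,
                                         total_length_sd = 100,
                                         n_branch_mean = 5,
                                         n_branch_sd = 1),
                           seed = 8, dims = c(60, 60, 50))
  expect_s3_class(lay, "population_layout")
  expect_setequal(unique(lay$boutons$cell), som$cell)
  # deterministic under the same seed
  lay2 <- population_layout(som,
                            growth_params(total_length_mean = 600,
                                          total_length_sd = 100,
                                          n_branch_mean = 5,
                                          n_branch_sd = 1),
                            seed = 8, dims = c(60, 60, 50))
  expect_identical(lay$boutons, lay2$boutons)
})
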