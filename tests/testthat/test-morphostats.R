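test_that("kNN mean distance reproduces hand-computed values on the unit tetrahedron", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  res <- knn_mean_distance(pts, k = 3)
  expect_equal(res$mean_knn_distance_um[1], 1.0, tolerance = 1e-12)
  # the off-origin points each see distances (1, sqrt(2), sqrt(2))
  expect_equal(res$mean_knn_distance_um[2], (1 + 2 * sqrt(2)) / 3,
               tolerance = 1e-12)
  expect_equal(res$mean_knn_distance_um[2], 1.27614, tolerance = 1e-5)
  expect_true(all(res$defined))
})

test_that("too few points flags every result as undefined", {
  pts <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))
  res <- knn_mean_distance(pts, k = 3)
  expect_true(all(is.na(res$mean_knn_distance_um)))
  expect_false(any(res$defined))
  expect_error(knn_mean_distance(pts, k = 0), "k must be")
})

test_that("kNN agrees with the brute-force oracle on 100 random point sets", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(5:60, 1)                # small n keeps the oracle quick here
    xyz <- matrix(runif(3 * n, 0, 10), ncol = 3)
    k <- sample(1:4, 1)
    expect_equal(knn_mean_distance(xyz, k)$mean_knn_distance_um,
                 knn_oracle(xyz, k), tolerance = 1e-12)
  }
})

test_that("kNN distances are invariant under rigid motions and permutation", {
  set.seed(31)
  xyz <- matrix(runif(90, 0, 5), ncol = 3)
  base <- knn_mean_distance(xyz, 3)$mean_knn_distance_um
  shifted <- knn_mean_distance(xyz + rep(c(10, -4, 2), each = 30), 3)
  expect_equal(shifted$mean_knn_distance_um, base, tolerance = 1e-9)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    rotated <- knn_mean_distance(xyz %*% Q, 3)
    expect_equal(rotated$mean_knn_distance_um, base, tolerance = 1e-9)
  }
  perm <- sample(nrow(xyz))
  permuted <- knn_mean_distance(xyz[perm, ], 3)
  expect_equal(permuted$mean_knn_distance_um[order(perm)][seq_len(5)],
               base[seq_len(5)], tolerance = 1e-12)
})

test_that("density is count over volume and reproduces the count", {
  expect_identical(puncta_density(50, 250), 0.2)
  expect_identical(puncta_density(0, 10), 0)
  expect_error(puncta_density(5, 0), "> 0")
  set.seed(8)
  for (i in 1:20) {
    n <- sample.int(500, 1); v <- runif(1, 1, 400)
    expect_equal(puncta_density(n, v) * v, n, tolerance = 1e-9)
  }
})

test_that("image summaries handle regular and degenerate tables", {
  roi <- list(role = "somatodendritic", volume_um3 = 100)
  tab <- data.frame(cx_um = 1:3, cy_um = 1:3, cz_um = 1:3,
                    volume_um3 = c(0.01, 0.02, 0.03))
  s <- summarize_image(tab, roi, k = 3, case_id = "c", image_id = "i")
  expect_equal(s$mean_volume_um3, 0.02)
  expect_equal(s$median_volume_um3, 0.02)
  expect_equal(s$density_per_um3 * s$roi_volume_um3, s$n_puncta,
               tolerance = 1e-9)
  expect_true(is.na(s$mean_knn_um))        # 3 points cannot have 3 neighbours

  one <- summarize_image(tab[1, ], roi, 3)
  expect_true(is.na(one$sd_volume_um3))
  expect_equal(one$q1_volume_um3, 0.01)
  expect_equal(one$q3_volume_um3, 0.01)

  none <- summarize_image(tab[0, ], roi, 3)
  expect_identical(none$n_puncta, 0L)
  expect_identical(none$density_per_um3, 0)
  expect_true(is.na(none$mean_volume_um3))
})

test_that("case summaries average images with equal weight", {
  roi <- list(role = "somatodendritic", volume_um3 = 100)
  mk <- function(vols, id) summarize_image(
    data.frame(cx_um = seq_along(vols), cy_um = 0, cz_um = 0, volume_um3 = vols),
    roi, 3, case_id = "c1", image_id = id)
  imgs <- rbind(mk(rep(0.01, 4), "a"), mk(rep(0.03, 2), "b"))
  cs <- summarize_case(imgs)
  expect_equal(cs$mean_volume_um3_mean, 0.02)   # unweighted despite 4 vs 2 puncta
  expect_identical(cs$n_images, 2L)

  single <- summarize_case(imgs[1, ])
  expect_equal(single$mean_volume_um3_mean, 0.01)
  expect_true(is.na(single$mean_volume_um3_sd))

  identical2 <- summarize_case(rbind(mk(rep(0.02, 3), "a"), mk(rep(0.02, 3), "b")))
  expect_equal(identical2$mean_volume_um3_sd, 0)

  bad <- imgs; bad$case_id <- c("c1", "c2")
  expect_error(summarize_case(bad), "mixed case ids")
})

test_that("spatial export is long-format, bit-exact and propagates NA", {
  set.seed(4)
  tab <- data.frame(cx_um = runif(20), cy_um = runif(20), cz_um = runif(20),
                    volume_um3 = rlnorm(20, log(0.008), 0.5))
  out <- export_spatial(tab, "volume_um3")
  expect_identical(nrow(out), 20L)
  expect_identical(out$volume_um3, tab$volume_um3)

  tab3 <- add_neighbor_stats(tab[1:3, ], k = 3)
  out3 <- export_spatial(tab3, "mean_knn_distance_um")
  expect_true(all(is.na(out3$mean_knn_distance_um)))

  expect_error(export_spatial(tab, "no_such_metric"), "unknown metric")

  path <- tempfile(fileext = ".csv")
  export_spatial(tab, "volume_um3", path)
  expect_equal(read.csv(path)$volume_um3, tab$volume_um3, tolerance = 1e-12)
})
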