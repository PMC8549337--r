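# Threshold segmentation and volumetry.

test_that("a homogeneous block segments to its exact voxel count", {
  hu <- array(0, c(5, 5, 5))
  hu[2:4, 2:4, 2:4] <- 200
  m <- segment_marker(hu, c(2.5, 2.5, 2.5), segmentation_params(140),
                      spacing = c(1, 1, 1))
  expect_true(is_visible(m))
  expect_identical(m$volume_ul, 27)
  expect_equal(m$peak_hu, 200)
  # a threshold above every voxel yields the distinguished not-visible result
  m2 <- segment_marker(hu, c(2.5, 2.5, 2.5), segmentation_params(250),
                       spacing = c(1, 1, 1))
  expect_false(is_visible(m2))
  expect_s3_class(m2, "marker_not_visible")
})

test_that("seeds outside the grid are an error, not a result", {
  hu <- array(200, c(4, 4, 4))
  expect_error(segment_marker(hu, c(10, 1, 1), spacing = c(1, 1, 1)),
               "outside the grid")
})

test_that("seeded segmentation matches the brute-force flood-fill oracle", {
  set.seed(404)
  for (rep in 1:25) {
    d <- sample(6:12, 3, replace = TRUE)
    hu <- array(ifelse(stats::runif(prod(d)) < 0.45, 200, 0), d)
    seed_ijk <- sapply(d, function(n) sample.int(n, 1))
    hu[seed_ijk[1], seed_ijk[2], seed_ijk[3]] <- 200
    for (conn in c(6, 18, 26)) {
      m <- segment_marker(hu, seed_ijk - 0.5,
                          segmentation_params(140, conn, roi_radius = 100),
                          spacing = c(1, 1, 1))
      expect_identical(sort(m$voxel_idx),
                       oracle_component(hu >= 140, seed_ijk, conn))
    }
  }
})

test_that("raising the threshold never grows a segmented marker", {
  sc <- build_scene(scene_config(list(marker_spec(20)), seed = 21))
  vol <- acquire_ct(sc, default_protocols()[["70"]], seed = 3)
  seedp <- unlist(sc$markers[1, c("x", "y", "z")])
  vols <- sapply(c(140, 200, 300, 450), function(thr) {
    m <- segment_marker(vol, seedp, segmentation_params(thr))
    if (is_visible(m)) m$volume_ul else 0
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("segmentation is equivariant under whole-voxel shifts", {
  hu <- array(0, c(12, 12, 12))
  hu[3:5, 4:6, 2:4] <- 300
  shift <- c(4L, 2L, 5L)
  hu2 <- array(0, dim(hu))
  hu2[3:5 + shift[1], 4:6 + shift[2], 2:4 + shift[3]] <- 300
  p <- segmentation_params(140, roi_radius = 100)
  m1 <- segment_marker(hu, c(3.5, 4.5, 2.5), p, spacing = c(1, 1, 1))
  m2 <- segment_marker(hu2, c(3.5, 4.5, 2.5) + shift, p, spacing = c(1, 1, 1))
  expect_identical(m1$volume_ul, m2$volume_ul)
  expect_identical(sweep(m1$voxels, 2, shift, "+"), m2$voxels)
})

test_that("unseeded detection finds each disjoint component exactly once", {
  hu <- array(0, c(10, 10, 5))
  hu[2:4, 2:3, 2:3] <- 200
  hu[7:8, 7:8, 2:3] <- 300
  det <- detect_markers(hu, segmentation_params(140), min_volume_ul = 1,
                        spacing = c(1, 1, 1))
  expect_length(det, 2L)
  expect_equal(sapply(det, `[[`, "volume_ul"), c(12, 8))  # sorted decreasing
  # two blocks separated by a single sub-threshold plane stay separate
  hu2 <- array(0, c(9, 5, 5))
  hu2[2:4, 2:4, 2:4] <- 200
  hu2[6:8, 2:4, 2:4] <- 200
  expect_length(detect_markers(hu2, segmentation_params(140, 26),
                               spacing = c(1, 1, 1)), 2L)
  # an empty volume gives an empty list
  expect_length(detect_markers(array(0, c(5, 5, 5)),
                               spacing = c(1, 1, 1)), 0L)
})

test_that("diagonal contact merges components under 26- but not 6-connectivity", {
  hu <- array(0, c(6, 6, 6))
  hu[2:3, 2:3, 2:3] <- 200
  hu[4:5, 4:5, 4:5] <- 200   # touches only at the corner voxel diagonal
  expect_length(detect_markers(hu, segmentation_params(140, 26),
                               spacing = c(1, 1, 1)), 1L)
  expect_length(detect_markers(hu, segmentation_params(140, 6),
                               spacing = c(1, 1, 1)), 2L)
})

test_that("suggest_lower_level matches its degenerate closed forms", {
  expect_identical(suggest_lower_level(array(50, c(8, 8, 8))), 51L)
  expect_identical(suggest_lower_level(array(-1000, c(8, 8, 8))), -999L)
  # noisy soft tissue at the worst default noise level stays below 140:
  # 50 + 3.09 * 8 < 140 (99.9% normal quantile)
  set.seed(77)
  noisy <- array(stats::rnorm(40^3, 50, 8), c(40, 40, 40))
  expect_lte(suggest_lower_level(noisy), 140L)
  expect_error(suggest_lower_level(array(numeric(0), c(0, 0, 0))), "empty")
})

test_that("suggested level excludes soft tissue on an acquired phantom", {
  sc <- build_scene(scene_config(list(marker_spec(10)), seed = 31))
  for (kv in c("70", "120")) {
    vol <- acquire_ct(sc, default_protocols()[[kv]], seed = 13)
    expect_lte(suggest_lower_level(vol), 140L)
  }
})

test_that("segmentation params are validated", {
  expect_error(segmentation_params(connectivity = 10), "connectivity")
  expect_error(segmentation_params(roi_radius = -1))
})
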