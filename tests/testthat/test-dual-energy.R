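# Mixed-energy images, two-material decomposition and VNC-based
# classification of hyperdense objects.

test_that("mixing is the voxelwise weighted sum", {
  a <- array(100, c(4, 4, 4)); b <- array(0, c(4, 4, 4))
  expect_equal(mix_images(a, a, 0.6), a)              # identical inputs
  expect_equal(unique(as.vector(mix_images(a, b, 0.6))), 60)
  expect_identical(mix_images(a, b, 1), a)            # boundary weight
  expect_error(mix_images(a, array(0, c(4, 4, 5))), "share a grid")
})

test_that("mixing commutes with the noise-free forward model", {
  sc <- flat_scene(list(marker_spec(10)), seed = 3)
  pa <- ideal_protocol(80); pb <- ideal_protocol(150, tin_filter = TRUE)
  a <- acquire_ct(sc, pa, 1); b <- acquire_ct(sc, pb, 1)
  w <- 0.6
  mixed <- mix_images(a, b, w)
  # linearity: the mix of two lookups is the lookup of the mixed tables
  lut <- w * a$hu + (1 - w) * b$hu
  expect_equal(mixed, lut)
})

test_that("decomposition inverts the forward model exactly without noise", {
  conc <- 25
  sc <- flat_scene(list(marker_spec(10, iodine_concentration = conc)),
                   seed = 5)
  a <- acquire_ct(sc, ideal_protocol(80), 1)
  b <- acquire_ct(sc, ideal_protocol(150, tin_filter = TRUE), 1)
  dect <- decompose_dect(a, b)
  idx <- sc$marker_voxels[[1]]
  expect_lte(max(abs(dect$iodine_map[idx] - conc)) / conc, 1e-9)
  expect_true(all(dect$iodine_map[-idx] == 0))
  # VNC restores the soft-tissue baseline inside the marker
  expect_equal(unique(round(dect$vnc[idx], 9)), 50)
  # a scene with no iodine: map is zero and VNC equals the mixed image
  sc0 <- flat_scene(list(), seed = 6)
  a0 <- acquire_ct(sc0, ideal_protocol(80), 1)
  b0 <- acquire_ct(sc0, ideal_protocol(150, tin_filter = TRUE), 1)
  d0 <- decompose_dect(a0, b0)
  expect_true(all(d0$iodine_map == 0))
  expect_equal(d0$vnc, d0$mixed)
})

test_that("a singular iodine vector is rejected", {
  a <- array(0, c(3, 3, 3))
  expect_error(decompose_dect(a, a, iodine_vector = c(20, 20)), "singular")
  expect_error(decompose_dect(a, a, iodine_vector = c(10, 20)), "exceed")
})

test_that("titanium keeps its attenuation in the VNC image", {
  sc <- flat_scene(list(), seed = 7, dim = c(30, 30, 20))
  sc$label[15, 15, 10] <- mat_code("titanium_clip")
  a <- acquire_ct(sc, ideal_protocol(80), 1)
  b <- acquire_ct(sc, ideal_protocol(150, tin_filter = TRUE), 1)
  d <- decompose_dect(a, b)
  expect_equal(d$iodine_map[15, 15, 10], 0)         # equal HU in both tubes
  expect_equal(d$vnc[15, 15, 10], d$mixed[15, 15, 10])
  expect_gte(d$vnc[15, 15, 10], 1000)
})

test_that("markers vanish in VNC while clips and calcifications persist", {
  sc <- build_scene(scene_config(
    lapply(c(10, 20, 30), marker_spec), seed = 17, include_bone = FALSE,
    confounders = list(confounder_spec("titanium_clip", 20),
                       confounder_spec("calcification", 25))))
  a <- acquire_ct(sc, ideal_protocol(80), 1)
  b <- acquire_ct(sc, ideal_protocol(150, tin_filter = TRUE), 1)
  dect <- decompose_dect(a, b)
  mixed_vol <- structure(list(hu = dect$mixed, spacing = sc$spacing),
                         class = "ct_volume")
  det <- detect_markers(mixed_vol, segmentation_params(140),
                        min_volume_ul = 2)
  expect_length(det, 5L)
  cls <- classify_hyperdense(dect, det)
  expect_equal(sum(cls$label == "iodine_marker"), 3L)
  expect_true(all(cls$vnc_retention[cls$label == "iodine_marker"] < 0.05))
  expect_true(all(cls$vnc_retention[cls$label != "iodine_marker"] > 0.7))
  # degenerate threshold: everything counts as an iodine marker
  cls1 <- classify_hyperdense(dect, det, retention_threshold = 1.0)
  expect_true(all(cls1$label == "iodine_marker"))
})

test_that("classification separates markers from confounders under noise", {
  p <- default_protocols()
  sc <- build_scene(scene_config(
    lapply(rep(c(10, 20, 30), length.out = 20), marker_spec), seed = 23,
    include_bone = FALSE,
    confounders = c(lapply(1:3, function(i) confounder_spec("titanium_clip", 15)),
                    lapply(1:2, function(i) confounder_spec("calcification", 25)))))
  acq <- acquire_dect(sc, p[["80"]], p[["150Sn"]], seed = 29)
  dect <- decompose_dect(acq$a, acq$b)
  mixed_vol <- structure(list(hu = dect$mixed, spacing = sc$spacing),
                         class = "ct_volume")
  det <- detect_markers(mixed_vol, segmentation_params(140), min_volume_ul = 2)
  expect_length(det, 25L)
  cls <- classify_hyperdense(dect, det)
  # perfect separation at the default retention threshold
  truth_marker <- sapply(det, function(m) {
    d2 <- (sc$markers$x - m$centroid[1])^2 + (sc$markers$y - m$centroid[2])^2
    min(d2) < (sc$config$marker_pitch / 2)^2
  })
  expect_identical(cls$label == "iodine_marker", truth_marker)
  expect_equal(sum(cls$label == "iodine_marker"), 20L)
})

test_that("slab averaging preserves means and grid shape", {
  arr <- array(stats::rnorm(10 * 10 * 9), c(10, 10, 9))
  out <- slab_average(arr, c(1, 1, 1), 3)
  expect_identical(dim(out), dim(arr))
  expect_equal(mean(out), mean(arr))
  expect_equal(out[, , 1], (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3)
  expect_equal(out[, , 1], out[, , 2])
})
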