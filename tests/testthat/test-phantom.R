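# Phantom scenes and the CT forward model.

test_that("scenes place the requested markers as disjoint iodine deposits", {
  cfg <- scene_config(lapply(rep(c(10, 20, 30), 3), marker_spec), seed = 7)
  sc <- build_scene(cfg)
  expect_equal(nrow(sc$markers), 9L)
  vox <- unlist(sc$marker_voxels)
  expect_false(anyDuplicated(vox) > 0)           # disjoint components
  expect_identical(sort(which(sc$iodine > 0)), sort(as.integer(vox)))
})

test_that("a marker-free scene has an identically zero iodine grid", {
  sc <- build_scene(scene_config(list(), seed = 3))
  expect_true(all(sc$iodine == 0))
})

test_that("rasterised marker volumes match the nominal volume", {
  # voxel-count oracle: 10 ul at 0.4 x 0.4 x 0.6 mm -> ~104 voxels of 0.096 ul
  sc <- build_scene(scene_config(list(marker_spec(10, shape = "rounded")),
                                 seed = 11))
  n_vox <- length(sc$marker_voxels[[1]])
  expect_true(n_vox * 0.096 >= 9.5 && n_vox * 0.096 <= 10.5)
  # within 5% before blur for every volume/shape over several seeds
  for (seed in 1:4) {
    sc <- build_scene(scene_config(lapply(c(10, 20, 30), marker_spec),
                                   seed = seed))
    expect_true(all(abs(sc$markers$raster_ul - sc$markers$nominal_ul) /
                      sc$markers$nominal_ul <= 0.05))
    # unit identity: voxel count x voxel volume is the stored volume exactly
    expect_equal(lengths(sc$marker_voxels) * prod(sc$spacing),
                 sc$markers$raster_ul)
  }
})

test_that("marker geometry follows the shape rules", {
  expect_s3_class(marker_spec(10), "marker_spec")
  expect_identical(marker_spec(10)$shape, "rounded")
  expect_identical(marker_spec(30)$shape, "multilobular")
  expect_error(marker_spec(10, shape = "rounded", n_lobes = 2), "one lobe")
  expect_error(marker_spec(30, shape = "multilobular", n_lobes = 5), "2-4")
})

test_that("overlapping or out-of-grid markers are rejected", {
  two_close <- list(marker_spec(30, center = c(10, 10, 6)),
                    marker_spec(30, center = c(10.5, 10, 6)))
  expect_error(build_scene(scene_config(two_close, seed = 1,
                                        air_thickness = 0,
                                        flap_thickness = 0,
                                        include_bone = FALSE,
                                        dim = c(50, 50, 20))),
               "overlap")
  outside <- list(marker_spec(10, center = c(0.2, 10, 6)))
  expect_error(build_scene(scene_config(outside, seed = 1,
                                        dim = c(50, 50, 20))),
               "outside the grid")
})

test_that("noise-free blur-free acquisition is an exact HU lookup", {
  sc <- flat_scene(list(), seed = 2)
  vol <- acquire_ct(sc, ideal_protocol(120), seed = 1)
  expect_true(all(vol$hu == 50))               # soft tissue everywhere
  # marker voxel closed form at 70 kV: HU = 50 + c * 38
  sc <- flat_scene(list(marker_spec(10, iodine_concentration = 25)), seed = 2)
  vol <- acquire_ct(sc, ideal_protocol(70), seed = 1)
  expect_equal(unique(vol$hu[sc$marker_voxels[[1]]]), 50 + 25 * 38)
})

test_that("acquisition is bit-identical for a fixed seed", {
  sc <- build_scene(scene_config(list(marker_spec(10)), seed = 4))
  p <- default_protocols()[["100"]]
  expect_identical(acquire_ct(sc, p, seed = 9)$hu,
                   acquire_ct(sc, p, seed = 9)$hu)
  d1 <- acquire_dect(sc, default_protocols()[["80"]],
                     default_protocols()[["150Sn"]], seed = 5)
  d2 <- acquire_dect(sc, default_protocols()[["80"]],
                     default_protocols()[["150Sn"]], seed = 5)
  expect_identical(d1$a$hu, d2$a$hu)
  expect_identical(d1$b$hu, d2$b$hu)
  # A and B use independent noise streams
  expect_false(identical(d1$a$hu - mean(d1$a$hu), d1$b$hu - mean(d1$b$hu)))
})

test_that("iodine contrast decreases with energy and so does marker HU", {
  contrast <- default_iodine_contrast()
  expect_true(all(diff(unname(contrast)) < 0))
  sc <- flat_scene(list(marker_spec(10)), seed = 6)
  mean_hu <- sapply(c("70", "100", "120"), function(kv)
    mean(acquire_ct(sc, ideal_protocol(as.numeric(kv)),
                    seed = 1)$hu[sc$marker_voxels[[1]]]))
  expect_true(all(diff(mean_hu) < 0))
})

test_that("material table satisfies its invariants", {
  tab <- default_material_table()
  expect_true(all(tab$air <= -900))
  expect_true(all(tab$bone > tab$soft_tissue))
  expect_true(all(vapply(tab, function(x) all(is.finite(x)), logical(1))))
})

test_that("dual-energy acquisition honours the closed-form contrast", {
  conc <- 25
  sc <- flat_scene(list(marker_spec(10, iodine_concentration = conc)),
                   seed = 8)
  a <- acquire_ct(sc, ideal_protocol(80), seed = 1)
  b <- acquire_ct(sc, ideal_protocol(150, tin_filter = TRUE), seed = 1)
  idx <- sc$marker_voxels[[1]]
  ivec <- default_iodine_contrast()
  expect_equal(unique(a$hu[idx] - b$hu[idx]),
               conc * (ivec[["80"]] - ivec[["150Sn"]]))
  # titanium clip is hyperdense in both tubes
  scc <- flat_scene(list(), seed = 9, dim = c(40, 40, 20))
  scc$label[20, 20, 10] <- mat_code("titanium_clip")
  ta <- acquire_ct(scc, ideal_protocol(80), seed = 1)
  tb <- acquire_ct(scc, ideal_protocol(150, tin_filter = TRUE), seed = 1)
  expect_gte(ta$hu[20, 20, 10], 1000)
  expect_gte(tb$hu[20, 20, 10], 1000)
})

test_that("acquire_dect validates the tube ordering", {
  sc <- flat_scene(list(), seed = 1)
  p80 <- default_protocols()[["80"]]
  p150 <- default_protocols()[["150Sn"]]
  expect_error(acquire_dect(sc, p150, p80, seed = 1), "low-energy")
})

test_that("unknown energies are rejected by the material lookup", {
  sc <- flat_scene(list(), seed = 1)
  bad <- acquisition_protocol(95, iodine_hu_per_unit = 30)
  expect_error(acquire_ct(sc, bad, seed = 1), "no entry")
})
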