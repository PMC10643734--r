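test_that("CT normalisation divides by 1000 HU and clamps", {
  v <- spine_volume(array(c(1000, 0, 2500, -1024, 40, 700), c(6, 1, 1)))
  out <- normalize_ct(v)
  expect_equal(as.vector(out$data),
               c(1, 0, 1, -1, 0.04, 0.7))
  bad <- spine_volume(array(c(1, NA, Inf, 0), c(4, 1, 1)))
  expect_error(normalize_ct(bad), "2 non-finite")
})

test_that("MR normalisation maps [0, max] affinely onto [-1, 1]", {
  v <- spine_volume(array(c(0, 50, 100), c(3, 1, 1)))
  expect_equal(as.vector(normalize_mr(v)$data), c(-1, 0, 1))
  # uniform positive volume maps to all ones
  u <- spine_volume(array(7, c(2, 2, 2)))
  expect_true(all(normalize_mr(u)$data == 1))
  expect_error(normalize_mr(spine_volume(array(0, c(2, 2, 2)))), "degenerate")
})

test_that("round trip: normalize_ct of 1000*x is the identity on [-1,1]", {
  x <- array(runif(60, -1, 1), c(5, 4, 3))
  expect_equal(normalize_ct(1000 * x), x, tolerance = 1e-12)
})

test_that("jitter is mean-anchored, seeded, bounded and has identity at 0", {
  x <- array(runif(200, -1, 1), c(10, 10, 2))
  expect_identical(jitter_mr(x, strength = 0), x)
  expect_identical(jitter_mr(x, seed = 5), jitter_mr(x, seed = 5))
  expect_error(jitter_mr(x, strength = -1), "strength")
  for (s in 1:100) {
    out <- jitter_mr(x, 0.2, seed = s)
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("resampling rules follow the 2D and 3D training regimes", {
  cs <- tiny_phantom(seed = 2)  # 1 x 1 x 3 mm by default
  same <- resample_pair(cs, "sagittal_2d")
  expect_identical(dim(same$mr$data), dim(cs$mr$data))  # already in-plane 1mm
  iso <- resample_pair(cs, "isotropic_3d")
  d0 <- dim(cs$mr$data); d1 <- dim(iso$mr$data)
  expect_equal(d1[1:2], d0[1:2])
  expect_lte(abs(d1[3] - 3 * d0[3]), 1)   # through-plane count triples
  expect_equal(iso$mr$spacing, c(1, 1, 1))
  # coarser in-plane input doubles its in-plane counts
  cs2 <- cs
  for (f in c("mr", "ct")) cs2[[f]]$spacing <- c(2, 2, 3)
  cs2$mask$spacing <- c(2, 2, 3)
  sag <- resample_pair(cs2, "sagittal_2d")
  expect_lte(max(abs(dim(sag$mr$data)[1:2] - 2 * d0[1:2])), 1)
})

test_that("elastic augmentation emits 10 consistent copies across seeds", {
  cs <- tiny_phantom(seed = 13)
  lab0 <- unique(as.vector(cs$mask$data))
  for (s in 1:20) {
    aug <- elastic_augment(cs, copies = 10, seed = s)
    expect_length(aug, 10)
    labs <- unique(unlist(lapply(aug, function(a) unique(as.vector(a$mask$data)))))
    expect_true(all(labs %in% lab0))
  }
})

test_that("a zero-amplitude deformation is the identity", {
  cs <- tiny_phantom(seed = 14)
  aug <- elastic_augment(cs, copies = 1, sd_mm = 0, seed = 1)[[1]]
  expect_equal(aug$mr$data, cs$mr$data, tolerance = 1e-12)
  expect_identical(aug$mask$data, cs$mask$data)
})

test_that("image and mask receive the identical displacement field", {
  # encode the mask into an image; after deformation the nearest-neighbour
  # image of the label field must equal the deformed mask wherever the field
  # lands on-grid -> compare label centroids instead (2-voxel tolerance)
  cs <- tiny_phantom(seed = 15)
  aug <- elastic_augment(cs, copies = 1, sd_mm = 4, seed = 9)[[1]]
  for (lab in c(1L, 6L)) {
    c0 <- colMeans(which(cs$mask$data == lab, arr.ind = TRUE))
    c1 <- colMeans(which(aug$mask$data == lab, arr.ind = TRUE))
    expect_true(all(abs(c1 - c0) <= 4 / cs$mask$spacing + 2))
  }
  # CT bone stays where the deformed mask says bone is
  bone <- aug$mask$data > 0
  expect_gt(mean(aug$ct$data[bone] > 300), 0.9)
})

test_that("2D datasets emit only segmented slices with exact crops", {
  cs <- normalized_phantom(seed = 16)
  n_seg_slices <- sum(apply(cs$mask$data, 3, function(sl) any(sl != 0)))
  recs <- make_2d_dataset(list(cs), crop_size = 32, mode = "train", seed = 2)
  expect_length(recs, n_seg_slices)
  for (r in recs) {
    expect_identical(dim(r$mr), c(32L, 32L))
    expect_gt(sum(r$mask != 0), 0)
    expect_true(all(r$mr >= -1 & r$mr <= 1))
    expect_true(all(r$ct >= -1 & r$ct <= 1))
  }
  # evaluation crops are deterministic
  e1 <- make_2d_dataset(list(cs), crop_size = 32, mode = "eval")
  e2 <- make_2d_dataset(list(cs), crop_size = 32, mode = "eval")
  expect_identical(e1, e2)
  # padding path: crop larger than the volume
  big <- make_2d_dataset(list(cs), crop_size = 128, mode = "eval")
  expect_identical(dim(big[[1]]$mr), c(128L, 128L))
})

test_that("3D patches carry correct position ramps and reject empty masks", {
  cs <- normalized_phantom(seed = 17)
  iso <- resample_pair(cs, "isotropic_3d")
  ps <- c(32L, 32L, 16L)
  recs <- make_3d_patches(list(iso), patch_shape = ps, n_per_case = 3, seed = 4)
  expect_length(recs, 3)
  d <- dim(iso$mr$data)
  for (r in recs) {
    expect_gt(sum(r$mask != 0), 0)
    o <- r$provenance$offset
    for (ax in 1:3) {
      expected <- (o[ax] - 1 + seq_len(ps[ax]) - 1) / (d[ax] - 1)
      got <- switch(ax, r$ramps[, 1, 1, 1], r$ramps[1, , 1, 2],
                    r$ramps[1, 1, , 3])
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # a patch spanning a full axis has a ramp covering [0, 1]
  full <- make_3d_patches(list(iso), patch_shape = c(dim(iso$mr$data)[1], 32, 16),
                          n_per_case = 1, seed = 5)
  expect_equal(range(full[[1]]$ramps[, 1, 1, 1]), c(0, 1))
  # determinism
  again <- make_3d_patches(list(iso), patch_shape = ps, n_per_case = 3, seed = 4)
  expect_identical(recs, again)
})
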