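make_block <- function(coords, series) {
  structure(list(coords = coords, series = series, region_code = 1L),
            class = "voxel_block")
}

test_that("extract_region_voxels returns the labeled voxels", {
  net <- default_network()
  d <- generate_participant(net, ground_truth(net, "FM", "Pain"),
                            build_paradigm("Pain"), noise_sd = 0.05, seed = 3)
  rn <- render_nifti(d, voxels_per_subregion = 2)
  code <- rn$region_codes[["C6RD"]]
  blk <- extract_region_voxels(rn$image, rn$labels, code)
  expect_identical(nrow(blk$coords), 10L)           # 2 voxels x 5 subregions
  expect_identical(nrow(blk$series), nrow(blk$coords))
  expect_true(all(blk$coords >= 0))                 # 0-based convention
  expect_error(extract_region_voxels(rn$image, rn$labels, 0), "absent")
  expect_error(extract_region_voxels(rn$image,
                                     rn$labels[1, , , drop = FALSE], 1),
               "grid")
})

test_that("k-means parcellation balances collinear voxels optimally", {
  # 50 equispaced collinear voxels, k = 5: the optimal partition is five
  # contiguous runs of 10 (brute-force 1-D optimum)
  coords <- cbind(0:49, 0, 0)
  blk <- make_block(coords, matrix(rnorm(50 * 8), 50))
  asg <- kmeans_subregions(blk, k = 5, seed = 2)
  expect_identical(sort(tabulate(asg$labels, 5)), rep(10L, 5))
  for (cl in 1:5) {
    idx <- which(asg$labels == cl)
    expect_identical(idx, seq(min(idx), max(idx)))  # contiguous
  }
})

test_that("k-means handles edge cases and enforces balance", {
  coords <- cbind(0:3, 0, 0)
  blk <- make_block(coords, matrix(0, 4, 5))
  one <- kmeans_subregions(blk, k = 1)
  expect_identical(one$labels, rep(1L, 4))
  expect_error(kmeans_subregions(blk, k = 5), "fewer voxels")

  # lopsided cloud: balancing must cap the largest cluster
  set.seed(1)
  pts <- rbind(matrix(rnorm(120, 0, 0.2), ncol = 3),
               matrix(rnorm(30, 5, 0.2), ncol = 3))
  blk2 <- make_block(pts, matrix(rnorm(50 * 6), 50))
  asg2 <- kmeans_subregions(blk2, k = 5, seed = 3, balance_tol = 0.25)
  sizes <- tabulate(asg2$labels, 5)
  expect_identical(sum(sizes), 50L)                 # partition property
  expect_true(max(sizes) <= (1 + 0.25) * 50 / 5)
  expect_true(all(sizes > 0))
  # deterministic given seed
  asg3 <- kmeans_subregions(blk2, k = 5, seed = 3, balance_tol = 0.25)
  expect_identical(asg2$labels, asg3$labels)
})

test_that("sub-region time-courses recombine to the region mean", {
  set.seed(8)
  series <- matrix(rnorm(30 * 12), 30)
  blk <- make_block(cbind(0:29, 0, 0), series)
  asg <- kmeans_subregions(blk, k = 5, seed = 1)
  tc <- subregion_timecourses(blk, asg)
  expect_identical(nrow(tc), 5L)
  expect_true(all(abs(rowMeans(tc)) < 1e-12))
  # size-weighted recombination equals the centered whole-region mean
  sizes <- tabulate(asg$labels, 5)
  recomb <- colSums(tc * sizes) / sum(sizes)
  whole <- colMeans(series); whole <- whole - mean(whole)
  expect_equal(recomb, whole, tolerance = 1e-12)

  # identical voxels: every cluster mean equals the common centered series
  common <- rnorm(12)
  blk2 <- make_block(cbind(0:9, 0, 0),
                     matrix(rep(common, each = 10), 10))
  asg2 <- kmeans_subregions(blk2, k = 2, seed = 1)
  tc2 <- subregion_timecourses(blk2, asg2)
  expect_equal(tc2[1, ], common - mean(common), tolerance = 1e-12)
  expect_equal(tc2[2, ], common - mean(common), tolerance = 1e-12)
})

test_that("render -> extract -> parcellate round trip recovers signals", {
  net <- default_network()
  d <- generate_participant(net, ground_truth(net, "FM", "Pain"),
                            build_paradigm("Pain"), noise_sd = 0.05, seed = 4)
  rn <- render_nifti(d, voxels_per_subregion = 3, voxel_noise_sd = 0.02)
  subtc <- extract_all_subregions(rn$image, rn$labels, rn$region_codes,
                                  k = 5, seed = 1)
  # for each region, some recovered cluster tracks the ground-truth
  # signal series closely
  for (r in c("C6RD", "LC", "Thalamus")) {
    truth <- d$region_series[r, ]
    best <- max(abs(cor(t(subtc[r, , ]), truth)))
    expect_gt(best, 0.95)
  }
})

test_that("NIfTI round trip matches the nibabel reference", {
  set.seed(21)
  arr <- array(rnorm(4 * 3 * 2 * 6), c(4, 3, 2, 6))
  lab <- array(sample.int(3, 24, replace = TRUE), c(4, 3, 2))
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "a.nii.gz"); fl <- file.path(td, "lab.nii")
  write_nifti(arr, fa)
  write_nifti(lab, fl)
  # self round trip (float32 storage)
  expect_equal(read_nifti(fa), arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.vector(read_nifti(fl)), as.vector(lab))
  # independent reader: nibabel
  py <- sprintf(paste0(
    "import nibabel, numpy, json; ",
    "a = nibabel.load('%s').get_fdata(); ",
    "b = nibabel.load('%s').get_fdata(); ",
    "print(json.dumps({'shape': list(a.shape), 'sum': float(a.sum()), ",
    "'lab_max': float(b.max()), 'first': float(a.flat[0])}))"), fa, fl)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  ref <- jsonlite::fromJSON(out[length(out)])
  expect_identical(ref$shape, dim(arr))
  expect_equal(ref$sum, sum(arr), tolerance = 1e-4)
  expect_equal(ref$first, arr[1, 1, 1, 1], tolerance = 1e-6)
  expect_equal(ref$lab_max, max(lab))
})
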