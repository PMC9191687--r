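test_that("CLAHE returns a bounded, shape-preserving enhancement", {
  set.seed(1)
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 5L)
  out <- apply_clahe(ph$flair)
  expect_identical(dim(out$data), dim(ph$flair$data))
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 1)
})

test_that("CLAHE leaves a constant volume unchanged and rejects non-finite input", {
  v <- raw_volume(array(5, c(8, 8, 4)))
  expect_identical(apply_clahe(v)$data, v$data)
  bad <- array(1, c(4, 4, 4))
  bad[c(2, 7)] <- NA
  expect_error(apply_clahe(raw_volume(bad)), "2 non-finite")
})

test_that("each CLAHE tile independently spans the output range", {
  # two vertical tiles: left half holds intensities 0..127, right 128..255
  sl <- matrix(rep(0:255, each = 64), nrow = 256, ncol = 64, byrow = FALSE)
  vol <- raw_volume(array(rep(sl, 3), c(256, 64, 3)))
  out <- apply_clahe(vol, preprocess_config(clahe_tile_grid = 2))$data[, , 2]
  left <- out[1:128, ]
  right <- out[129:256, ]
  expect_lt(min(left), 0.05)
  expect_gt(max(left), 0.9)
  expect_lt(min(right), 0.1)
  expect_gt(max(right), 0.95)
})

test_that("global CLAHE agrees with a histogram-equalization oracle in rank and increases entropy", {
  set.seed(7)
  x <- matrix(runif(64 * 64)^2, 64, 64)
  vol <- raw_volume(array(x, c(64, 64, 1)))
  # high clip limit ~ plain equalization; single tile avoids interpolation
  out <- apply_clahe(vol, preprocess_config(clahe_clip_limit = 1,
                                            clahe_tile_grid = 1))$data[, , 1]
  ref <- oracle_hist_eq(x / max(x))
  expect_gt(cor(as.vector(out), as.vector(ref), method = "spearman"), 0.999)
  # monotone: ranking preserved within the single tile
  expect_true(all(diff(out[order(x)]) >= -1e-9))
  ent <- function(v) {
    h <- tabulate(pmin(floor(v * 64) + 1, 64), nbins = 64)
    p <- h[h > 0] / sum(h)
    -sum(p * log(p))
  }
  expect_gte(ent(out / max(out)), ent(x / max(x)) - 1e-9)
})

test_that("Laplacian stencils match direct evaluation", {
  z <- array(0, c(7, 7, 7))
  z[4, 4, 4] <- 1
  e <- laplacian_edges(raw_volume(z))$data
  expect_equal(e[4, 4, 4], -6)
  expect_equal(e[3, 4, 4], 1)
  expect_equal(e[4, 5, 4], 1)
  expect_equal(e[4, 4, 3], 1)
  expect_equal(sum(e != 0), 7)
  # constant -> zero; linear ramp -> zero in the interior
  expect_true(all(laplacian_edges(raw_volume(array(3, c(5, 5, 5))))$data == 0))
  ramp <- array(rep(1:6, times = 25), c(6, 5, 5))
  er <- laplacian_edges(raw_volume(ramp))$data
  expect_true(all(abs(er[2:5, 2:4, 2:4]) < 1e-12))
  # slice2d uses the 4-neighbour stencil per axial slice
  e2 <- laplacian_edges(raw_volume(z),
                        preprocess_config(laplacian_mode = "slice2d"))$data
  expect_equal(e2[4, 4, 4], -4)
  expect_equal(e2[4, 4, 3], 0)
})

test_that("Laplacian is linear in its input", {
  set.seed(11)
  v <- array(rnorm(6^3), c(6, 6, 6))
  a <- 3.7
  e1 <- laplacian_edges(raw_volume(a * v))$data
  e2 <- a * laplacian_edges(raw_volume(v))$data
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("z-score normalization standardizes the region and is idempotent", {
  v <- array(0, c(4, 4, 4))
  v[1] <- 1
  v[2] <- 3
  out <- zscore_normalize(raw_volume(v))
  expect_equal(out$data[1:2], c(-1, 1))
  expect_true(all(out$data[3:64] == 0))

  set.seed(3)
  r <- array(rnorm(8^3, 10, 2), c(8, 8, 8))
  cfg <- preprocess_config(normalize_region = "all")
  n1 <- zscore_normalize(raw_volume(r), cfg)
  expect_lt(abs(mean(n1$data)), 1e-6)
  expect_lt(abs(sqrt(mean((n1$data - mean(n1$data))^2)) - 1), 1e-6)
  n2 <- zscore_normalize(n1, cfg)
  expect_lt(max(abs(n2$data - n1$data)), 1e-6)

  expect_error(zscore_normalize(raw_volume(array(7, c(3, 3, 3))),
                                preprocess_config(normalize_region = "all")),
               "zero variance")
})

test_that("build_volume4d composes the channels and preserves shape", {
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 9L)
  cfg <- preprocess_config()
  v4 <- build_volume4d(ph$flair, cfg)
  expect_identical(dim(v4$channels), c(2L, dim(ph$flair$data)))
  enh <- apply_clahe(ph$flair, cfg)
  expect_equal(v4$channels[1, , , ], zscore_normalize(enh, cfg)$data)
  expect_equal(v4$channels[2, , , ], laplacian_edges(enh, cfg)$data)
  # channel 0 invariant: zero mean / unit variance over the region
  reg <- v4$channels[1, , , ][enh$data != 0]
  expect_lt(abs(mean(reg)), 1e-4)
  expect_lt(abs(sqrt(mean((reg - mean(reg))^2)) - 1), 1e-4)
})

test_that("NIfTI write/read round-trips data and affine", {
  dir <- withr::local_tempdir()
  m <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  p1 <- file.path(dir, "mask.nii.gz")
  write_nifti(lesion_mask(m), p1)
  expect_identical(read_nifti(p1)$data, m * 1)

  ph <- test_phantom(shape = 16L, n_lesions = 0L, seed = 2L)
  p2 <- file.path(dir, "phantom.nii.gz")
  aff <- diag(c(0.8, 1, 1.2, 1))
  v <- raw_volume(ph$flair$data, spacing = c(0.8, 1, 1.2), affine = aff)
  write_nifti(v, p2)
  back <- read_nifti(p2)
  expect_lt(max(abs(back$data - v$data)), 1e-6)
  expect_equal(unclass(back$affine)[1:3, 1:3], aff[1:3, 1:3],
               ignore_attr = TRUE, tolerance = 1e-6)

  expect_error(read_nifti(file.path(dir, "absent.nii.gz")), "no such file")
  p3 <- file.path(dir, "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), p3)
  expect_error(read_nifti(p3), "3D")
})
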