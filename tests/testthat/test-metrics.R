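test_that("18-connectivity joins faces and edges but not corners", {
  fx <- make_worked_masks()
  expect_identical(attr(connected_components_18(fx$face_touch$gt),
                        "n_components"), 1L)
  expect_identical(attr(connected_components_18(fx$corner_touch$gt),
                        "n_components"), 2L)
  # the same corner pair is a single component under 26-connectivity
  lab26 <- flood_fill_label(fx$corner_touch$gt$data, offsets_26)
  expect_identical(attr(lab26, "n_components"), 1L)
  empty <- lesion_mask(array(0L, c(5, 5, 5)))
  expect_identical(attr(connected_components_18(empty), "n_components"), 0L)
  expect_error(lesion_mask(array(2, c(2, 2, 2))), "binary")
})

test_that("voxel metrics match hand arithmetic", {
  fx <- make_worked_masks()
  expect_equal(dsc(fx$identical$pred, fx$identical$gt), 1)
  expect_equal(avd(fx$identical$pred, fx$identical$gt), 0)
  expect_equal(dsc(fx$disjoint$pred, fx$disjoint$gt), 0)
  expect_equal(dsc(fx$volume_60_80_100$pred, fx$volume_60_80_100$gt),
               2 * 60 / 180)
  expect_equal(avd(fx$volume_60_80_100$pred, fx$volume_60_80_100$gt), 0.2)
  # AVD is symmetric in |pred| vs |gt| around the gt volume
  expect_equal(avd(fx$volume_60_80_100$gt, fx$volume_60_80_100$pred),
               20 / 80)
  expect_equal(dsc(lesion_mask(array(0L, c(3, 3, 3))),
                   lesion_mask(array(0L, c(3, 3, 3)))), 1)
  expect_error(avd(fx$identical$pred, lesion_mask(array(0L, c(20, 20, 20)))),
               "empty ground-truth")
})

test_that("lesion-wise rates follow the component-overlap definitions", {
  fx <- make_worked_masks()
  w <- fx$three_of_four_plus2
  expect_equal(ltpr(w$pred, w$gt), 0.75)
  expect_equal(lfpr(w$pred, w$gt), 0.4)
  rep <- evaluate_pair(w$pred, w$gt)
  expect_identical(rep$n_components_gt, 4L)
  expect_identical(rep$n_components_pred, 5L)
  ov <- attr(rep, "per_component_overlaps")
  expect_identical(sum(ov$overlap > 0), 3L)
  # conventions for empty masks
  empty <- lesion_mask(array(0L, c(20, 20, 20)))
  expect_equal(ltpr(empty, w$gt), 0)
  expect_equal(lfpr(empty, w$gt), 0)
  expect_equal(ltpr(w$pred, empty), 1)
  expect_equal(lfpr(w$pred, empty), 1)
})

test_that("metrics agree with flood-fill + overlap oracles on random masks", {
  set.seed(41)
  for (i in 1:200) {
    pred <- random_mask()
    gt <- random_mask()
    lab <- connected_components_18(lesion_mask(gt))
    oracle_lab <- flood_fill_label(gt, offsets_18)
    expect_identical(attr(lab, "n_components"),
                     attr(oracle_lab, "n_components"))
    orc <- oracle_lesion_rates(pred, gt)
    expect_equal(ltpr(lesion_mask(pred), lesion_mask(gt)), orc$ltpr)
    expect_equal(lfpr(lesion_mask(pred), lesion_mask(gt)), orc$lfpr)
    expect_equal(dsc(lesion_mask(pred), lesion_mask(gt)),
                 2 * sum(pred * gt) / (sum(pred) + sum(gt)))
  }
  # component membership, not just counts: label partitions must coincide
  set.seed(42)
  m <- random_mask(p = 0.15)
  lab <- connected_components_18(lesion_mask(m))
  oracle_lab <- flood_fill_label(m, offsets_18)
  for (k in seq_len(attr(lab, "n_components"))) {
    members <- which(lab == k)
    expect_identical(length(unique(oracle_lab[members])), 1L)
  }
})

test_that("DSC and AVD are symmetric; lesion-wise rates are not", {
  set.seed(43)
  a <- random_mask(p = 0.1)
  b <- random_mask(p = 0.1)
  expect_equal(dsc(lesion_mask(a), lesion_mask(b)),
               dsc(lesion_mask(b), lesion_mask(a)))
  fx <- make_worked_masks()$three_of_four_plus2
  expect_false(isTRUE(all.equal(ltpr(fx$pred, fx$gt), ltpr(fx$gt, fx$pred))))
  expect_false(isTRUE(all.equal(lfpr(fx$pred, fx$gt), lfpr(fx$gt, fx$pred))))
})

test_that("dilating a correct prediction keeps LTPR at 1 and creates no FP components", {
  ph <- test_phantom(shape = 32L, n_lesions = 2L, seed = 44L)
  dil <- scavox:::dilate6(ph$truth$data == 1L, 1L)
  dil_mask <- lesion_mask(array(as.integer(dil), dim(ph$truth$data)))
  expect_equal(ltpr(dil_mask, ph$truth), 1)
  expect_equal(lfpr(dil_mask, ph$truth), 0)
})

test_that("two-rater evaluation localises a one-voxel disagreement and round-trips CSV", {
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 45L)
  pred <- ph$truth
  r1 <- ph$truth$data
  r2 <- r1
  flip <- which(scavox:::dilate6(r1 == 1L, 1L) & r1 == 0L)[1]
  r2[flip] <- 1L
  out <- evaluate_two_raters(pred, lesion_mask(r1), lesion_mask(r2))
  expect_identical(out$rater, c("rater1", "rater2", "mean"))
  expect_equal(out$dsc[1], 1)
  expect_lt(out$dsc[2], 1)
  expect_equal(out$dsc[3], mean(out$dsc[1:2]))
  # only the flipped voxel separates the reports
  expect_equal(out$avd[2], 1 / sum(r2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(out, path)
  back <- read_metrics_csv(path)
  expect_equal(back$dsc, out$dsc, tolerance = 1e-12)
  expect_identical(back$rater, out$rater)
})
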