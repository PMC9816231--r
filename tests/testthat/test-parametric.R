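mk_dyn <- function(frame_values, dims = c(3, 3, 3),
                   schedule = default_schedule()) {
  arr <- array(rep(frame_values, each = prod(dims)),
               c(dims, length(frame_values)))
  dynamic_image(arr, c(1, 1, 1), schedule)
}

test_that("summation images are duration-weighted frame means", {
  sch <- frame_schedule(c(0, 20, 25, 30), c(20, 25, 30, 40))
  dyn <- mk_dyn(c(9, 3, 3, 6), schedule = sch)
  expect_equal(unique(as.vector(summation_image(dyn, c(20, 40)))),
               (5 * 3 + 5 * 3 + 10 * 6) / 20)
  # constant across frames stays constant
  dyn2 <- mk_dyn(c(4, 4, 4, 4), schedule = sch)
  expect_equal(unique(as.vector(summation_image(dyn2, c(0, 40)))), 4)
  # two equal-duration frames valued 2 and 4 average to 3
  sch3 <- frame_schedule(c(0, 5), c(5, 10))
  expect_equal(unique(as.vector(summation_image(mk_dyn(c(2, 4),
                                                       schedule = sch3),
                                                c(0, 10)))), 3)
  # frames of durations 5 and 10 valued 3 and 6 give (5*3 + 10*6) / 15
  sch4 <- frame_schedule(c(0, 5), c(5, 15))
  expect_equal(unique(as.vector(summation_image(mk_dyn(c(3, 6),
                                                       schedule = sch4),
                                                c(0, 15)))), 5)
})

test_that("misaligned summation windows name the offending boundary", {
  dyn <- mk_dyn(rep(1, 10))
  expect_error(summation_image(dyn, c(20, 37)), "37",
               class = "fetrad_alignment_error")
})

test_that("background mean averages the masked voxels and must be positive", {
  vol <- array(2, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  expect_equal(background_mean(vol, mask), 2)
  vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3
  expect_equal(background_mean(vol, mask), 2)
  expect_error(background_mean(vol, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(background_mean(vol * 0, mask),
               class = "fetrad_normalization_error")
})

test_that("background mean on a phantom matches direct index arithmetic", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(20, 20, 20), seed = 3,
                                      tumor_radius = 6))
  s <- summation_image(ph$image, c(20, 40))
  expect_equal(background_mean(s, ph$background_mask),
               sum(s * ph$background_mask) / sum(ph$background_mask))
})

test_that("TBR images divide by the background mean and ignore global scale", {
  s <- array(c(3.2, 1, 2, 4), c(2, 2, 1))
  tbr <- tbr_image(s, 2.0)
  expect_equal(tbr$data[1, 1, 1], 1.6)
  expect_equal(tbr_image(s, 1)$data, s)
  expect_error(tbr_image(s, 0), class = "fetrad_normalization_error")
  # global rescaling of activity cancels in the ratio
  k <- 17.3
  expect_equal(tbr_image(k * s, background_mean(k * s, array(TRUE, dim(s))))$data,
               tbr_image(s, background_mean(s, array(TRUE, dim(s))))$data)
})

test_that("time-to-peak groups follow the minute intervals", {
  expect_equal(ttp_group(c(0.5, 4.9, 5, 9.9, 10, 15, 19.9, 20, 29, 30, 40)),
               c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L, 6L, 6L))
})

test_that("TAC classification matches the stated rules", {
  sch <- default_schedule()
  # early peak, washout tail -> group of the peak-frame midpoint
  tac <- simulate_tac(kinetic_phenotype(1, 7, 0.5, 1), sch)
  expect_equal(classify_ttp(tac, sch), 2L)
  # strictly increasing TAC -> positive late slope -> group 6
  expect_equal(classify_ttp(seq_len(nrow(sch)), sch), 6L)
  # maximum only in an excluded early frame: earliest maximal kept frame wins
  tac3 <- c(10, 9, 1, 5, 4.5, 4, 3, 2, 1, 0.5)
  expect_equal(classify_ttp(tac3, sch), oracle_classify(tac3, sch))
  expect_equal(classify_ttp(tac3, sch), 1L)  # frame 3-4, midpoint 3.5
  # every frame excluded is a degenerate schedule
  sch2 <- frame_schedule(c(0, 1), c(1, 2))
  expect_error(classify_ttp(c(1, 2), sch2),
               class = "fetrad_degenerate_schedule")
})

test_that("random TACs always land in exactly one group and match the oracle", {
  sch <- default_schedule()
  set.seed(42)
  for (i in 1:200) {
    tac <- runif(nrow(sch))
    g <- classify_ttp(tac, sch)
    expect_true(g %in% 1:6)
    expect_equal(g, oracle_classify(tac, sch))
  }
})

test_that("TTP maps equal per-voxel classification and ignore voxel scaling", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(10, 10, 10), seed = 4,
                                      tumor_radius = 4, noise_sd = 0.1))
  dyn <- ph$image
  ttp <- ttp_image(dyn)
  d <- dim(dyn$data)
  for (v in sample(prod(d[1:3]), 25)) {
    p <- arrayInd(v, d[1:3])
    expect_equal(ttp$data[p[1], p[2], p[3]],
                 as.numeric(classify_ttp(dyn$data[p[1], p[2], p[3], ],
                                         dyn$schedule)))
  }
  # positive per-voxel rescaling leaves the map unchanged
  scale <- array(runif(prod(d[1:3]), 0.5, 3), d[1:3])
  arr2 <- dyn$data * as.vector(scale)
  dyn2 <- dynamic_image(arr2, dyn$voxel_size, dyn$schedule)
  expect_equal(ttp_image(dyn2)$data, ttp$data)
  # masked maps carry the documented fill value outside
  ttpm <- ttp_image(dyn, ph$tumor_mask)
  expect_true(all(is.na(ttpm$data[!ph$tumor_mask])))
  expect_equal(ttpm$data[ph$tumor_mask], ttp$data[ph$tumor_mask])
})

test_that("segmentation thresholds at 1.6 inclusively and keeps one component", {
  arr <- array(1, c(10, 10, 10))
  arr[3:5, 3:5, 3:5] <- 2                     # main lesion
  arr[9, 9, 9] <- 1.6                         # isolated boundary-value speck
  tbr <- parametric_image(arr, "TBR", c(1, 1, 1))
  seg <- segment_tumor(tbr)
  expect_equal(sum(seg), 27)
  expect_false(seg[9, 9, 9])
  segall <- segment_tumor(tbr, largest_component = FALSE)
  expect_true(segall[9, 9, 9])                # threshold is inclusive
  empty <- segment_tumor(parametric_image(arr * 0 + 1, "TBR", c(1, 1, 1)))
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty), 0)
})

test_that("a suprathreshold sphere segments to the analytic sphere", {
  gs <- c(24, 24, 24)
  sph <- sphere_mask(gs, c(1, 1, 1), c(11, 11, 11), 6)
  arr <- array(1, gs); arr[sph] <- 2
  seg <- segment_tumor(parametric_image(arr, "TBR", c(1, 1, 1)))
  expect_equal(seg & TRUE, sph, ignore_attr = TRUE)
})
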