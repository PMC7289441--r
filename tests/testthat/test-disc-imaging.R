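test_that("maximum-intensity projection is the pixelwise max over z", {
  one <- array(matrix(1:4, 2, 2), dim = c(2, 2, 1))
  expect_equal(max_intensity_projection(one), matrix(1:4, 2, 2))

  two <- array(c(1, 3, 2, 4, 4, 2, 3, 1), dim = c(2, 2, 2))
  expect_equal(max_intensity_projection(two), matrix(c(4, 3, 3, 4), 2, 2))

  set.seed(1)
  arr <- array(runif(6 * 6 * 5), dim = c(6, 6, 5))
  mip <- max_intensity_projection(arr)
  for (z in 1:5) expect_true(all(mip >= arr[, , z]))

  expect_error(max_intensity_projection(matrix(1, 2, 2)),
               class = "coprecip_contract_error")
})

test_that("disc segmentation recovers a known pixel count and rejects blank images", {
  img <- matrix(5, 150, 150)
  rr <- row(img); cc <- col(img)
  d2 <- (rr - 75.5)^2 + (cc - 75.5)^2
  ord <- order(d2)
  img[ord[1:10000]] <- 200  # exactly 10,000 foreground pixels
  seg <- segment_disc(img, pixel_size = 0.5)
  expect_equal(sum(seg$mask), 10000)
  expect_equal(seg$disc_area_um2, 2500)

  expect_error(segment_disc(matrix(7, 20, 20), 0.5),
               class = "coprecip_no_disc_error")
})

test_that("only the largest connected component is retained and holes are filled", {
  img <- matrix(0, 60, 60)
  img[10:30, 10:30] <- 100   # 441 px blob
  img[45:50, 45:50] <- 100   # 36 px blob
  seg <- segment_disc(img, 1)
  expect_equal(sum(seg$mask), 441)
  expect_true(all(seg$mask[10:30, 10:30]))
  expect_false(any(seg$mask[45:50, 45:50]))

  holed <- matrix(0, 60, 60)
  holed[10:40, 10:40] <- 100
  holed[20:25, 20:25] <- 0   # interior hole
  seg2 <- segment_disc(holed, 1)
  expect_equal(sum(seg2$mask), 31 * 31)
})

test_that("elav_fraction handles full, empty and planted-fraction signals", {
  mask <- matrix(FALSE, 40, 40); mask[10:30, 10:30] <- TRUE
  full <- matrix(0, 40, 40); full[mask] <- 150
  expect_equal(elav_fraction(full, mask), 100)

  expect_equal(elav_fraction(matrix(0, 40, 40), mask), 0)

  out <- generate_disc_image(disc_sim_config(elav_fraction_of_disc = 0.4,
                                             noise_sd = 0, seed = 8))
  mips <- max_intensity_projection(out$stack)
  seg <- segment_disc(mips$dapi, out$stack$pixel_size)
  got <- elav_fraction(mips$elav, seg$mask)
  expect_equal(got, 40, tolerance = 2 / 40)

  expect_error(elav_fraction(full, matrix(FALSE, 40, 40)),
               class = "coprecip_contract_error")
})

test_that("basal fluorescence is a median robust to sparse bright foci", {
  mask <- matrix(TRUE, 50, 50)
  expect_equal(estimate_basal_fluorescence(matrix(100, 50, 50), mask), 100)

  img <- matrix(100, 50, 50)
  img[1:10, 1:10] <- 1e5  # 4% of pixels are bright foci
  expect_lt(abs(estimate_basal_fluorescence(img, mask) - 100) / 100, 0.05)
})

test_that("the median basal estimate is unbiased under Gaussian noise (Monte Carlo)", {
  set.seed(501)
  mask <- matrix(TRUE, 40, 40)
  est <- replicate(200, {
    img <- matrix(100 + rnorm(1600, 0, 10), 40, 40)
    estimate_basal_fluorescence(img, mask)
  })
  expect_lt(abs(mean(est) - 100), 1)
})

test_that("focus calling applies the inclusive 3x threshold and the strict 1-60 um2 gate", {
  mask <- matrix(TRUE, 80, 80)
  ps <- 1  # 1 um/px: pixel counts are areas in um2
  img <- matrix(100, 80, 80)
  expect_equal(nrow(call_caspase_foci(img, mask, 100, ps)), 0L)

  # planted areas 5, 30 and 70 um2; the 70 is rejected by the upper gate
  img[2:6, 2] <- 500                    # 5 px
  img[20:25, 20:24] <- 500              # 30 px
  img[50:56, 50:59] <- 500              # 70 px
  foci <- call_caspase_foci(img, mask, 100, ps)
  expect_equal(sort(foci$area_um2), c(5, 30))
  expect_equal(foci$mean_fluorescence, c(500, 500))

  # exactly 3.0x basal is called ("starting from 3 times")
  img2 <- matrix(100, 80, 80)
  img2[10:12, 10:12] <- 300
  foci2 <- call_caspase_foci(img2, mask, 100, ps)
  expect_equal(nrow(foci2), 1L)
  expect_equal(foci2$area_um2, 9)

  # boundary areas: exactly 1 um2 and exactly 60 um2 are rejected
  img3 <- matrix(100, 80, 80)
  img3[5, 5] <- 500                      # 1 px = 1 um2
  img3[30:35, 30:39] <- 500              # 60 px = 60 um2
  expect_equal(nrow(call_caspase_foci(img3, mask, 100, ps)), 0L)
})

test_that("focus components are labeled with 8-connectivity", {
  mask <- matrix(TRUE, 20, 20)
  img <- matrix(100, 20, 20)
  # two 2x1 bars touching only diagonally: one focus under 8-connectivity
  img[5:6, 5] <- 500
  img[7:8, 6] <- 500
  foci <- call_caspase_foci(img, mask, 100, 1)
  expect_equal(nrow(foci), 1L)
  expect_equal(foci$area_um2, 4)
})

test_that("area outputs scale exactly with pixel_size^2", {
  out <- generate_disc_image(disc_sim_config(noise_sd = 0, seed = 12))
  mips <- max_intensity_projection(out$stack)
  seg1 <- segment_disc(mips$dapi, 0.325)
  seg2 <- segment_disc(mips$dapi, 0.65)
  expect_equal(seg2$disc_area_um2, 4 * seg1$disc_area_um2)

  basal <- estimate_basal_fluorescence(mips$caspase, seg1$mask)
  f1 <- call_caspase_foci(mips$caspase, seg1$mask, basal, 0.325,
                          area_gate = c(0, Inf))
  f2 <- call_caspase_foci(mips$caspase, seg1$mask, basal, 0.65,
                          area_gate = c(0, Inf))
  expect_equal(f2$area_um2, 4 * f1$area_um2)
})

test_that("end-to-end quantification recovers planted truth on a noise-free stack", {
  out <- generate_disc_image(disc_sim_config(noise_sd = 0, seed = 31))
  q <- quantify_disc(out$stack, disc_id = "d31")
  gl <- glance(q)
  expect_equal(gl$n_foci, nrow(out$truth$foci))
  expect_lt(abs(gl$disc_area_um2 - out$truth$disc_area_um2) /
              out$truth$disc_area_um2, 0.02)
  expect_lt(abs(gl$elav_fraction_pct - out$truth$elav_fraction_pct), 2)
  expect_equal(sort(tidy(q)$area_um2), sort(out$truth$foci$area_um2),
               tolerance = 1e-8)
  expect_s3_class(autoplot(q), "ggplot")
})

test_that("disc-size classification uses mean +/- 2 sample SDs of controls", {
  ctrl <- c(90, 95, 100, 105, 110)
  res <- classify_disc_sizes(rep(mean(ctrl), 10), ctrl)
  expect_equal(unlist(res[1, c("frac_below", "frac_within", "frac_above")],
                      use.names = FALSE), c(0, 1, 0))

  m <- mean(ctrl); s <- sd(ctrl)
  res2 <- classify_disc_sizes(m + 3 * s, ctrl)
  expect_equal(res2$frac_above, 1)
  expect_equal(res2$frac_below + res2$frac_within, 0)

  expect_equal(res$lower, m - 2 * s)
  expect_equal(res$upper, m + 2 * s)
  expect_error(classify_disc_sizes(c(1, 2), 100),
               class = "coprecip_contract_error")

  set.seed(88)
  big <- classify_disc_sizes(rnorm(20000, 100, 10), rnorm(20000, 100, 10))
  expect_equal(big$frac_below + big$frac_above, 0.0455, tolerance = 0.15)
  expect_equal(big$frac_below + big$frac_within + big$frac_above, 1)
})
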