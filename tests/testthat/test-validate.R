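test_that("FSC has the defining fixed points and null distribution", {
  set.seed(31)
  v <- array(rnorm(32^3), c(32, 32, 32))
  f <- fsc(v, v, pixel_size = 2)
  expect_true(all(abs(f$value[!f$zero_power] - 1) < 1e-12))
  fneg <- fsc(v, -v, pixel_size = 2)
  expect_true(all(abs(fneg$value[!fneg$zero_power] + 1) < 1e-12))
  expect_equal(f$resolution, 1 / f$freq)
  # two independent white-noise volumes: each shell within +-4/sqrt(n)
  w <- array(rnorm(32^3), c(32, 32, 32))
  fn <- fsc(v, w)
  expect_true(all(abs(fn$value) < 4 / sqrt(fn$n_voxels)))
  expect_error(fsc(v, w[1:16, 1:16, 1:16]), "shapes")
})

test_that("R^2 modulation is radial, centre-zero and inversion covariant", {
  sr <- small_recon()
  vr <- sr$rec$map_real
  m <- r2_modulate(vr)
  ct <- 17
  expect_identical(m[ct, ct, ct], 0)
  # single off-centre voxels scale by their squared radius
  probe <- array(0, c(32, 32, 32))
  probe[ct + 5, ct, ct] <- 2
  probe[ct, ct - 3, ct] <- 1
  pm <- r2_modulate(probe)
  expect_equal(pm[ct + 5, ct, ct], 2 * 25)
  expect_equal(pm[ct, ct - 3, ct], 1 * 9)
  # commutes with inversion, voxel-exact
  expect_identical(r2_modulate(invert_volume(vr)$density),
                   mirror3(r2_modulate(vr)))
  expect_error(r2_modulate(sr$rec$map_imag), "real-component")
})

test_that("Wiener filter attenuates shells by snr/(snr+1)", {
  # a map living on a single shell
  box <- 32
  s <- ewaldhand:::shell_index_grid(box)
  g <- array(0 + 0i, c(box, box, box))
  g[s == 6] <- 1 + 0i
  v <- ewaldhand:::ifft_centered_real(g)
  snr <- rep(1e12, 16)
  expect_equal(wiener_filter(v, snr), v, tolerance = 1e-9)
  snr1 <- rep(0, 16); snr1[6] <- 1
  f <- wiener_filter(v, snr1)
  expect_equal(f, v / 2, tolerance = 1e-12)          # snr 1 halves
  snr0 <- rep(0, 16)
  expect_lt(max(abs(wiener_filter(v, snr0))), 1e-12)  # snr 0 zeroes
  expect_error(wiener_filter(v, c(-1, snr[-1])), "non-negative")
})

test_that("I-R FSC mirror identity is exact and the self-test saturates", {
  sr <- small_recon()
  cur <- irfsc(sr$rec$map_real, sr$rec$map_imag)
  # the inverted-solution curve is the bit-exact negation
  expect_identical(cur$irfsc_inverted$value, -cur$irfsc_as_given$value)
  # degenerate self-test: imag map equal to the modulated real map
  self <- irfsc(sr$rec$map_real, r2_modulate(sr$rec$map_real))
  ok <- !self$irfsc_as_given$zero_power
  expect_true(all(abs(self$irfsc_as_given$value[ok] - 1) < 1e-9))
  expect_true(all(abs(self$irfsc_inverted$value[ok] + 1) < 1e-9))
})

test_that("predicted I-R FSC behaves like a geometric mean of normalized SNRs", {
  f <- seq(0, 0.95, length.out = 16)
  wr <- rep(0.5, 16)
  p <- predicted_irfsc(f, wr)
  expect_equal(p$value[1], 0)                    # no half-map signal
  expect_true(all(predicted_irfsc(f, rep(0, 16))$value == 0))  # planar limit
  # monotone in each argument
  expect_true(all(diff(p$value) > 0))
  p2 <- predicted_irfsc(f, wr * 2)
  expect_true(all(p2$value[-1] > p$value[-1]))
  p3 <- predicted_irfsc(f, wr, compensation = 2)
  expect_true(all(p3$value[-1] > p$value[-1]))
  # FSC = 1 capped, flagged
  pc <- predicted_irfsc(c(1, f[-1]), wr)
  expect_true(pc$capped[1])
  expect_lt(pc$value[1], 1 + 1e-9)
  expect_error(predicted_irfsc(c(2, f[-1]), wr), "outside")
})

test_that("verdict follows the score sign and mirrors exactly", {
  n <- rep(400, 16)
  dk <- 1 / 64
  curve <- structure(data.frame(shell = 1:16, freq = (1:16) * dk,
                                resolution = 1 / ((1:16) * dk),
                                value = rep(0.3, 16), n_voxels = n * 2,
                                zero_power = FALSE),
                     class = c("fsc_curve", "data.frame"))
  rep_pos <- handedness_verdict(curve, n_eff = n)
  expect_equal(rep_pos$verdict, "as_given")
  neg <- curve; neg$value <- -curve$value
  rep_neg <- handedness_verdict(neg, n_eff = n)
  expect_equal(rep_neg$verdict, "inverted")
  expect_equal(rep_neg$z_score, -rep_pos$z_score)
  expect_identical(rep_pos$irfsc_inverted$value, -rep_pos$irfsc_as_given$value)
  # weak curve: indeterminate; flagged against an above-noise prediction
  weak <- curve; weak$value <- rep(0.001, 16)
  pred <- curve; pred$value <- rep(0.5, 16)
  rep_weak <- handedness_verdict(weak, n_eff = n, predicted = pred)
  expect_equal(rep_weak$verdict, "indeterminate")
  expect_equal(rep_weak$validation_flag, "inconsistent-with-prediction")
})

test_that("verdict is invariant under map scaling and R^2 modulation", {
  sr <- small_recon()
  base <- handedness_from_maps(sr$rec$map_real$density,
                               sr$rec$map_imag$density, pixel_size = 3)
  scaled <- handedness_from_maps(sr$rec$map_real$density * 7,
                                 sr$rec$map_imag$density * 0.03,
                                 pixel_size = 3)
  expect_equal(scaled$z_score, base$z_score, tolerance = 1e-9)
  expect_equal(scaled$verdict, base$verdict)
})

test_that("white-noise map pairs are indeterminate in >= 99% of trials", {
  set.seed(77)
  n_ind <- 0L
  trials <- 200L
  for (i in seq_len(trials)) {
    a <- array(rnorm(24^3), c(24, 24, 24))
    b <- array(rnorm(24^3), c(24, 24, 24))
    r <- handedness_from_maps(a, b)
    n_ind <- n_ind + (r$verdict == "indeterminate")
  }
  expect_gte(n_ind / trials, 0.99)
})

test_that("pipeline handedness report is self-consistent", {
  sr <- small_recon()
  rep <- handedness(sr$rec)
  expect_s3_class(rep, "handedness_report")
  expect_equal(rep$verdict, "as_given")
  expect_identical(rep$irfsc_inverted$value, -rep$irfsc_as_given$value)
  expect_true(all(rep$predicted_irfsc$value >= 0))
  expect_equal(length(rep$n_eff), 16)
  # x-flipped images (detector-hand violation with stale metadata) must
  # never look like a confident correct solution
  ds <- sr$ds
  rec_x <- reconstruct_components(images = ds$images[c(1, 32:2), , ],
                                  poses = ds$poses, defoci = ds$defoci,
                                  optics = ds$optics)
  expect_false(handedness(rec_x)$verdict == "as_given")
})
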