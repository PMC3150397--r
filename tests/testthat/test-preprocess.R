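test_that("lowess normalization leaves balanced channels untouched and removes planted bias", {
  ## balanced channels: fit of zeros is zero
  des <- toy_design()
  cy <- matrix(2^runif(100 * 6, 8, 12), nrow = 100)
  sp <- toy_spots(des, cy, cy)
  out <- normalize_subarray_lowess(sp, min_spots = 50)
  expect_equal(log2(out$cy5 / out$cy3), rep(0, nrow(out)), tolerance = 1e-10)

  ## planted smooth dye bias 0.5*sin(A) + noise: per-A-decile |mean M| < 0.05
  set.seed(81)
  n <- 2000
  a <- runif(n, 8, 13)
  m <- 0.5 * sin(a) + rnorm(n, 0, 0.05)
  sp1 <- data.frame(array_id = "A1", subarray_id = 1L,
                    probe_id = sprintf("P%04d", 1:n), genbank_id = "",
                    symbol = "", cy3 = 2^(a - m / 2), cy5 = 2^(a + m / 2),
                    control_flag = FALSE, stringsAsFactors = FALSE)
  out1 <- normalize_subarray_lowess(sp1, span = 0.4, iterations = 3)
  m_out <- log2(out1$cy5 / out1$cy3)
  dec <- cut(a, quantile(a, 0:10 / 10), include.lowest = TRUE, labels = FALSE)
  expect_true(all(abs(tapply(m_out, dec, mean)) < 0.05))
  ## A is preserved by the back-computation
  expect_equal(0.5 * log2(out1$cy5 * out1$cy3), a, tolerance = 1e-10)

  ## independent local-regression oracle: residuals from limma's loess fit
  ## agree with ours at the decile level
  fit <- limma::loessFit(m, a, span = 0.4, iterations = 3)
  m_limma <- m - fit$fitted
  expect_true(all(abs(tapply(m_out - m_limma, dec, mean)) < 0.02))
})

test_that("undersized subarrays are left unnormalized with a warning", {
  des <- toy_design()[1, , drop = FALSE]
  cy3 <- matrix(2^runif(10, 8, 12), nrow = 10)
  sp <- toy_spots(des, cy3, cy3 * 2)
  expect_warning(out <- normalize_subarray_lowess(sp, min_spots = 50),
                 "unnormalized")
  expect_equal(out$cy3, sp$cy3)
  expect_equal(out$cy5, sp$cy5)
})

test_that("median scaling hits the target exactly and handles degenerate arrays", {
  des <- toy_design()[1, , drop = FALSE]
  ## pooled median 500 -> every intensity doubled
  sp <- toy_spots(des, matrix(c(100, 500, 900), 3), matrix(c(300, 500, 700), 3))
  out <- scale_to_global_median(sp, target = 1000)
  expect_equal(median(c(out$cy3, out$cy5)), 1000)
  expect_equal(out$cy3, sp$cy3 * 2)
  ## already at target -> unchanged
  out2 <- scale_to_global_median(out, target = 1000)
  expect_equal(out2$cy3, out$cy3)
  ## constant array -> every value becomes the target
  spc <- toy_spots(des, matrix(rep(7, 5), 5), matrix(rep(7, 5), 5))
  outc <- scale_to_global_median(spc, target = 1000)
  expect_true(all(outc$cy3 == 1000 & outc$cy5 == 1000))
  ## all-zero array is an error
  sp0 <- toy_spots(des, matrix(0, 3), matrix(0, 3))
  expect_error(scale_to_global_median(sp0), "median")
})

test_that("the intensity floor thresholds each channel at the boundary", {
  des <- toy_design()[1, , drop = FALSE]
  sp <- toy_spots(des, matrix(c(150, 200, 1000), 3), matrix(c(199.9, 201, 50), 3))
  out <- apply_intensity_floor(sp, floor = 200)
  expect_equal(out$cy3, c(200, 200, 1000))
  expect_equal(out$cy5, c(200, 201, 200))
  expect_gte(min(c(out$cy3, out$cy5)), 200)
  expect_error(apply_intensity_floor(sp, floor = -1), "nonnegative")
})

test_that("low-intensity exclusion needs both channels low in more than half the arrays", {
  des <- toy_design()
  ## probe k has both channels at 100 in exactly k of the 6 arrays (k = 0..6);
  ## probe "H" keeps one channel high everywhere
  cy3 <- matrix(1000, nrow = 8, ncol = 6)
  cy5 <- matrix(1000, nrow = 8, ncol = 6)
  for (k in 1:6) {
    cy3[k + 1, seq_len(k)] <- 100
    cy5[k + 1, seq_len(k)] <- 100
  }
  cy5[8, ] <- 100  # one channel low everywhere, the other high
  sp <- toy_spots(des, cy3, cy5,
                  probe_ids = c(sprintf("K%d", 0:6), "H"))
  mask <- filter_low_intensity_spots(sp, des, floor = 200)
  excl <- setNames(mask$excluded, mask$probe_id)
  expect_false(excl[["K3"]])  # 3 of 6: retained
  expect_true(excl[["K4"]])   # 4 of 6: excluded
  expect_equal(unname(excl[sprintf("K%d", 0:6)]),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_false(excl[["H"]])   # the rule requires both channels
})

test_that("exclusion is monotone in the floor", {
  des <- toy_design()
  set.seed(12)
  cy3 <- matrix(2^runif(50 * 6, 6, 11), nrow = 50)
  cy5 <- matrix(2^runif(50 * 6, 6, 11), nrow = 50)
  sp <- toy_spots(des, cy3, cy5)
  floors <- c(100, 200, 400, 800)
  prev <- rep(FALSE, 50)
  for (f in floors) {
    mask <- filter_low_intensity_spots(sp, des, floor = f)
    cur <- mask$excluded[match(sprintf("P%03d", 1:50), mask$probe_id)]
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("log ratios resolve the dye orientation", {
  des <- toy_design()[1:2, ]  # rep 1 stim_cy3, rep 2 stim_cy5
  sp <- toy_spots(des, cy3 = matrix(c(2000, 1000), 1), cy5 = matrix(c(1000, 2000), 1))
  r <- compute_log_ratios(sp, des)
  expect_equal(r$M, c(1, 1))  # identical M from both orientations
  ## stim == vehicle -> 0
  spe <- toy_spots(des, matrix(c(500, 500), 1), matrix(c(500, 500), 1))
  expect_equal(compute_log_ratios(spe, des)$M, c(0, 0))
  ## orientation invariance: swap channels and flip the orientation label
  des_flip <- des
  des_flip$dye_orientation <- rev(des$dye_orientation)
  sp_flip <- sp
  sp_flip$cy3 <- sp$cy5; sp_flip$cy5 <- sp$cy3
  expect_equal(compute_log_ratios(sp_flip, des_flip)$M, r$M)
  ## missing orientation errors
  des_bad <- des; des_bad$dye_orientation <- NA
  expect_error(compute_log_ratios(sp, des_bad), "dye_orientation")
})

test_that("dye-swap discordance excludes opposite effects at the inclusive boundary", {
  m <- rbind(c(0.6, -0.6, 0.6, -0.6, 0.6, -0.6),   # opposite: excluded
             c(0.6, 0.2, 0.6, 0.2, 0.6, 0.2),      # same sign: retained
             c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5),   # boundary: excluded
             c(0.49, -0.49, 0.49, -0.49, 0.49, -0.49))  # just inside: retained
  r <- toy_ratios(m)
  out <- filter_dye_swap_discordant(r, threshold = 0.5)
  expect_setequal(out$excluded$probe_id, c("P001", "P003"))
  expect_setequal(unique(out$ratios$probe_id), c("P002", "P004"))
})

test_that("a single-replicate condition passes through the discordance filter with a warning", {
  m <- rbind(c(0.6, NA, 0.6, NA, 0.6, NA))
  r <- toy_ratios(m)
  r <- r[r$replicate == 1, ]
  expect_warning(out <- filter_dye_swap_discordant(r), "single replicate")
  expect_equal(nrow(out$excluded), 0)
  expect_equal(nrow(out$ratios), 3)
})

test_that("replicate averaging uses survivors and tracks completeness", {
  m <- rbind(c(0.8, 0.4, 0.8, 0.4, 0.8, 0.4))
  avg <- average_replicates(toy_ratios(m))
  expect_equal(avg$M, rep(0.6, 3))
  expect_true(all(avg$complete))

  ## one replicate missing at 16 h: its value is the surviving replicate
  r <- toy_ratios(m)
  r <- r[!(r$time_h == 16 & r$replicate == 2), ]
  avg1 <- average_replicates(r)
  expect_equal(avg1$M[avg1$time_h == 16], 0.8)
  expect_equal(avg1$n_rep[avg1$time_h == 16], 1)
  expect_true(all(avg1$complete))

  ## a whole time point missing makes the profile incomplete
  r2 <- toy_ratios(m)
  r2 <- r2[r2$time_h != 16, ]
  avg2 <- average_replicates(r2)
  expect_false(any(avg2$complete))
})

test_that("the full cascade on a null simulation leaves no systematic ratio", {
  cfg <- simulation_config(n_probes = 500, frac_responsive = 0,
                           dye_bias_amplitude = 0, noise_sd = 0.2,
                           frac_low_intensity = 0, spot_dropout_rate = 0,
                           seed = 23)
  e <- generate_experiment(cfg)
  pre <- preprocess_experiment(e$spots, e$design)
  ## per-probe mean M across the six arrays of each condition stays within
  ## 3 * noise_sd / sqrt(6) of zero for almost all probes, and globally
  avg <- pre$averaged
  cond_mean <- tapply(avg$M, paste(avg$probe_id, avg$cell_line, avg$treatment),
                      mean)
  expect_lt(abs(mean(cond_mean)), 0.02)
  expect_gt(mean(abs(cond_mean) < 3 * 0.2 / sqrt(6)), 0.99)
})

test_that("pooled condition matrices have six ordered columns", {
  m <- rbind(c(1, 2, 3, 4, 5, 6), c(-1, -2, -3, -4, -5, -6))
  x <- pool_condition_ratios(toy_ratios(m), "PC346C", "R1881")
  expect_equal(dim(x), c(2, 6))
  expect_equal(colnames(x), c("t4_r1", "t4_r2", "t8_r1", "t8_r2", "t16_r1", "t16_r2"))
  expect_equal(unname(x["P001", ]), c(1, 2, 3, 4, 5, 6))
})
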