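test_that("configuration is validated", {
  expect_error(simulation_config(n_probes = -5), "integer")
  expect_error(simulation_config(n_probes = 10.5), "integer")
  expect_error(simulation_config(frac_responsive = 1.2), "fraction")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(ar_response_multiplier = c(PC346C = 1)),
               "missing cell line")
  expect_error(simulation_config(
    ar_response_multiplier = c(PC346C = 1, PC346DCC = 0.5,
                               PC346Flu1 = 2.5, PC346Flu2 = 1)),
    "vestigial")
})

test_that("the design has one dye-swapped pair per condition and time, DCC R1881 only", {
  des <- panel_design()
  expect_equal(nrow(des), 7 * 3 * 2)
  expect_false(any(des$cell_line == "PC346DCC" & des$treatment == "OHF"))
  key <- paste(des$cell_line, des$treatment, des$time_h)
  orient <- tapply(des$dye_orientation, key, function(o) sort(o))
  expect_true(all(vapply(orient, function(o)
    identical(o, c("stim_cy3", "stim_cy5")), logical(1))))
  expect_false(anyDuplicated(
    des[, c("cell_line", "treatment", "time_h", "replicate")]) > 0)
})

test_that("the same seed reproduces the experiment exactly", {
  cfg <- simulation_config(n_probes = 200, seed = 42)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$spots, e2$spots)
  expect_identical(e1$truth, e2$truth)
  d <- withr::local_tempdir()
  write_experiment(e1, file.path(d, "a"))
  write_experiment(e2, file.path(d, "b"))
  for (f in c("spots.tsv", "design.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d, "a", f)),
                     readLines(file.path(d, "b", f)))
  back <- read_experiment(file.path(d, "a"))
  expect_equal(nrow(back$spots), nrow(e1$spots))
})

test_that("zero noise, zero bias and no responsive probes give M = 0 on every spot", {
  cfg <- simulation_config(n_probes = 100, frac_responsive = 0, noise_sd = 0,
                           dye_bias_amplitude = 0, frac_low_intensity = 0,
                           spot_dropout_rate = 0, seed = 7)
  e <- generate_experiment(cfg)
  expect_equal(log2(e$spots$cy5 / e$spots$cy3), rep(0, nrow(e$spots)))
})

test_that("truth marks responsive probes with a nonzero effect and nulls all-zero", {
  cfg <- simulation_config(n_probes = 300, frac_responsive = 0.1, seed = 3)
  e <- generate_experiment(cfg)
  eff_by_probe <- tapply(abs(e$truth$true_effect), e$truth$probe_id, max)
  n_resp <- sum(eff_by_probe > 0)
  expect_equal(n_resp, 30)
  ## the vestigial-AR line never responds
  dcc <- e$truth[e$truth$cell_line == "PC346DCC", ]
  expect_true(all(dcc$true_effect == 0))
})

test_that("the pipeline recovers the planted mean ratio of responsive probes", {
  ## moderate noise, unit effect in every responsive line: the averaged
  ## profile of responsive probes should estimate 1.0 closely
  cfg <- simulation_config(n_probes = 2000, base_effect = 1.0,
                           ar_response_multiplier = c(PC346C = 1, PC346DCC = 0,
                                                      PC346Flu1 = 1, PC346Flu2 = 1),
                           noise_sd = 0.1, frac_low_intensity = 0,
                           spot_dropout_rate = 0, frac_down = 0, seed = 11)
  e <- generate_experiment(cfg)
  pre <- preprocess_experiment(e$spots, e$design)
  resp <- unique(e$truth$probe_id[e$truth$true_effect != 0 &
                                    e$truth$cell_line == "PC346C" &
                                    e$truth$treatment == "R1881"])
  a <- pre$averaged[pre$averaged$cell_line == "PC346C" &
                      pre$averaged$treatment == "R1881" &
                      pre$averaged$probe_id %in% resp, ]
  expect_equal(mean(a$M), 1.0, tolerance = 0.05)
})

test_that("with zero noise and bias, planted effects at the threshold are all recalled", {
  cfg <- simulation_config(n_probes = 400, base_effect = 0.5,
                           ar_response_multiplier = c(PC346C = 1, PC346DCC = 0,
                                                      PC346Flu1 = 1, PC346Flu2 = 1),
                           flut_agonism = c(PC346C = 0, PC346DCC = 0,
                                            PC346Flu1 = 0, PC346Flu2 = 1),
                           noise_sd = 0, dye_bias_amplitude = 0,
                           frac_low_intensity = 0, spot_dropout_rate = 0,
                           ## keep all spots clear of the intensity floor:
                           ## flooring compresses fold changes by design, and
                           ## this invariant presumes undistorted effects
                           a_base_range = c(10.5, 13.5),
                           seed = 5)
  e <- generate_experiment(cfg)
  pre <- preprocess_experiment(e$spots, e$design)
  sig <- call_signature(pre$averaged, threshold = 0.5)
  rec <- evaluate_against_truth(sig, e$truth)
  expect_equal(rec$overall$recall, 1)
  expect_equal(rec$overall$fdp, 0)
})

test_that("the marginal M of null probes is symmetric about zero", {
  cfg <- simulation_config(n_probes = 2000, frac_responsive = 0.05,
                           dye_bias_amplitude = 0, frac_low_intensity = 0,
                           spot_dropout_rate = 0, seed = 19)
  e <- generate_experiment(cfg)
  null_probes <- unique(e$truth$probe_id[
    !e$truth$probe_id %in% e$truth$probe_id[e$truth$true_effect != 0]])
  arrays <- e$design$array_id[e$design$cell_line == "PC346C" &
                                e$design$treatment == "R1881"]
  sp <- e$spots[e$spots$array_id %in% arrays &
                  e$spots$probe_id %in% null_probes, ]
  m <- log2(sp$cy5 / sp$cy3)
  expect_gte(length(m), 1e4)
  ks <- suppressWarnings(stats::ks.test(m, -m))
  expect_gt(ks$p.value, 0.01)
})

test_that("recovery metrics follow the confusion-matrix arithmetic", {
  truth <- data.frame(probe_id = sprintf("P%02d", 1:10),
                      cell_line = "PC346C", treatment = "R1881",
                      true_effect = c(rep(1, 4), rep(0, 6)),
                      stringsAsFactors = FALSE)
  empty <- data.frame(probe_id = character(0), cell_line = character(0),
                      treatment = character(0), stringsAsFactors = FALSE)
  r0 <- evaluate_against_truth(empty, truth)
  expect_equal(r0$overall$recall, 0)
  expect_equal(r0$overall$fdp, 0)

  perfect <- data.frame(probe_id = sprintf("P%02d", 1:4),
                        cell_line = "PC346C", treatment = "R1881",
                        stringsAsFactors = FALSE)
  r1 <- evaluate_against_truth(perfect, truth)
  expect_equal(r1$overall$precision, 1)
  expect_equal(r1$overall$recall, 1)

  mixed <- data.frame(probe_id = sprintf("P%02d", c(1:3, 10)),
                      cell_line = "PC346C", treatment = "R1881",
                      stringsAsFactors = FALSE)
  r2 <- evaluate_against_truth(mixed, truth)
  expect_equal(r2$overall$fdp, 0.25)

  bad <- data.frame(probe_id = "NOPE", cell_line = "PC346C",
                    treatment = "R1881", stringsAsFactors = FALSE)
  expect_error(evaluate_against_truth(bad, truth), "NOPE")
})
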