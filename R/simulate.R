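## Spot-level simulator for the two-color androgen-response design.

#' @keywords internal
.arsig_cell_lines <- c("PC346C", "PC346DCC", "PC346Flu1", "PC346Flu2")
#' @keywords internal
.arsig_treatments <- c("R1881", "OHF")
#' @keywords internal
.arsig_times <- c(4, 8, 16)

#' Simulation configuration for a two-color androgen-response experiment
#'
#' Defines the study conditions emulated by [generate_experiment()]: a panel
#' of four PC346 prostate cancer lines with distinct AR states (wild-type,
#' vestigial, overexpressed, T877A-mutant), stimulated with 1 nM R1881 or
#' 1 uM hydroxyflutamide versus vehicle at 4, 8 and 16 h, hybridized in two
#' biological replicates with swapped dye orientation. The vestigial-AR line
#' (PC346DCC) receives the R1881 arm only and must have zero response
#' multipliers in both arms.
#'
#' @param n_probes number of non-control probes per array.
#' @param n_subarrays number of print-tip subarrays the probes are split into.
#' @param frac_responsive fraction of probes with a planted androgen response.
#' @param base_effect planted effect size in 2log units before per-line scaling.
#' @param ar_response_multiplier named nonnegative scalars (one per cell line)
#'   scaling `base_effect` in the R1881 arm. Defaults encode a moderate
#'   wild-type response, no response in the vestigial-AR line, an amplified
#'   response under AR overexpression and a wild-type-like response in the
#'   T877A mutant.
#' @param flut_agonism named nonnegative scalars scaling `base_effect` in the
#'   hydroxyflutamide arm; nonzero only for the T877A mutant, whose broadened
#'   ligand specificity turns the antagonist into a (weaker) agonist.
#' @param dye_bias_amplitude amplitude (2log units) of the smooth
#'   intensity-dependent dye bias, a scaled sinusoid in A so that lowess
#'   removal is exercisable.
#' @param noise_sd standard deviation (2log units) of per-spot noise on M.
#' @param frac_low_intensity fraction of probes censored to low intensity
#'   (both channels below the floor) on every array.
#' @param spot_dropout_rate per-spot probability of an additional low-intensity
#'   dropout, so the low-intensity exclusion rule has both pass and fail cases.
#' @param frac_down fraction of responsive genes that are repressed rather
#'   than induced.
#' @param time_multiplier named multipliers (names `"4"`, `"8"`, `"16"`)
#'   applied to the planted effect at each time point; all 1 by default
#'   (kinetic effects negligible), override for kinetics tests.
#' @param a_base_range range (log2) of per-probe baseline abundance. The
#'   default keeps regular probes clear of the intensity floor after median
#'   scaling, so censoring is governed by `frac_low_intensity`; note that
#'   spots whose lower channel grazes the floor have their fold change
#'   compressed by flooring (by design).
#' @param n_controls number of control spots (landmarks, buffer, alien
#'   oligos) per array; flagged and excluded from normalization fits.
#' @param seed integer seed; the same configuration yields byte-identical
#'   output.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [generate_experiment()]
#' @export
simulation_config <- function(n_probes = 2000,
                              n_subarrays = 4,
                              frac_responsive = 0.05,
                              base_effect = 1.0,
                              ar_response_multiplier = c(PC346C = 1, PC346DCC = 0,
                                                         PC346Flu1 = 2.5, PC346Flu2 = 1),
                              flut_agonism = c(PC346C = 0, PC346DCC = 0,
                                               PC346Flu1 = 0, PC346Flu2 = 0.6),
                              dye_bias_amplitude = 0.3,
                              noise_sd = 0.25,
                              frac_low_intensity = 0.02,
                              spot_dropout_rate = 0.01,
                              frac_down = 0.3,
                              time_multiplier = c(`4` = 1, `8` = 1, `16` = 1),
                              a_base_range = c(9.3, 13.5),
                              n_controls = 50,
                              seed = 1L) {
  check_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != as.integer(x))
      stop(sprintf("'%s' must be a single non-negative integer >= %d", nm, min))
  }
  check_frac <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", nm))
  }
  check_count(n_probes, "n_probes")
  check_count(n_subarrays, "n_subarrays")
  check_count(n_controls, "n_controls", min = 0)
  check_frac(frac_responsive, "frac_responsive")
  check_frac(frac_low_intensity, "frac_low_intensity")
  check_frac(spot_dropout_rate, "spot_dropout_rate")
  check_frac(frac_down, "frac_down")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (dye_bias_amplitude < 0) stop("'dye_bias_amplitude' must be >= 0")
  for (nm in c("ar_response_multiplier", "flut_agonism")) {
    m <- get(nm)
    missing_lines <- setdiff(.arsig_cell_lines, names(m))
    if (length(missing_lines))
      stop(sprintf("'%s' is missing cell line(s): %s", nm,
                   paste(missing_lines, collapse = ", ")))
    if (any(m < 0)) stop(sprintf("'%s' must be nonnegative", nm))
  }
  if (ar_response_multiplier[["PC346DCC"]] != 0 || flut_agonism[["PC346DCC"]] != 0)
    stop("response multipliers for the vestigial-AR line PC346DCC must be 0")
  if (!all(c("4", "8", "16") %in% names(time_multiplier)))
    stop("'time_multiplier' must be named with times \"4\", \"8\", \"16\"")
  if (length(a_base_range) != 2 || diff(a_base_range) <= 0)
    stop("'a_base_range' must be an increasing (lo, hi) pair")
  cfg <- list(n_probes = as.integer(n_probes), n_subarrays = as.integer(n_subarrays),
              frac_responsive = frac_responsive, base_effect = base_effect,
              ar_response_multiplier = ar_response_multiplier[.arsig_cell_lines],
              flut_agonism = flut_agonism[.arsig_cell_lines],
              dye_bias_amplitude = dye_bias_amplitude, noise_sd = noise_sd,
              frac_low_intensity = frac_low_intensity,
              spot_dropout_rate = spot_dropout_rate, frac_down = frac_down,
              time_multiplier = time_multiplier[c("4", "8", "16")],
              a_base_range = as.numeric(a_base_range),
              n_controls = as.integer(n_controls), seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Hybridization design for the PC346 panel
#'
#' One co-hybridized array per (cell line, treatment, time, replicate);
#' replicate 2 has the swapped dye orientation, and the vestigial-AR line
#' PC346DCC is stimulated with R1881 only.
#'
#' @return data.frame with columns `array_id`, `cell_line`, `treatment`,
#'   `time_h`, `replicate`, `dye_orientation` (`"stim_cy3"` or `"stim_cy5"`).
#' @export
panel_design <- function() {
  conds <- expand.grid(treatment = .arsig_treatments,
                       cell_line = .arsig_cell_lines,
                       stringsAsFactors = FALSE)
  conds <- conds[!(conds$cell_line == "PC346DCC" & conds$treatment == "OHF"), ]
  des <- merge(conds,
               expand.grid(time_h = .arsig_times, replicate = 1:2),
               by = NULL)
  des <- des[order(des$cell_line, des$treatment, des$time_h, des$replicate), ]
  des$dye_orientation <- ifelse(des$replicate == 1, "stim_cy3", "stim_cy5")
  des$array_id <- sprintf("A%02d", seq_len(nrow(des)))
  rownames(des) <- NULL
  des[, c("array_id", "cell_line", "treatment", "time_h", "replicate",
          "dye_orientation")]
}

#' Generate a spot-level two-color androgen-response experiment
#'
#' Simulates one array per design row. Channel intensities are
#' `2^(A +/- M/2)` where `M = effect * orientation + dye_bias(A) + noise`,
#' truncated at zero; the dye bias is a smooth sinusoid in A; a configurable
#' probe subset is censored to low intensity in both channels on every array,
#' and additional per-spot dropouts occur at `spot_dropout_rate`.
#'
#' @param config a [simulation_config()].
#' @return list with elements
#'   * `spots`: data.frame of spot rows (`array_id`, `subarray_id`,
#'     `probe_id`, `genbank_id`, `symbol`, `cy3`, `cy5`, `control_flag`),
#'   * `design`: the hybridization design (see [panel_design()]),
#'   * `truth`: truth table, one row per (probe, cell line, treatment) with
#'     the planted `true_effect` in 2log units (responsive probes have at
#'     least one nonzero entry, non-responsive probes are all zero),
#'   * `manifest`: list of run metadata (seed, parameters).
#' @export
generate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_probes
  design <- panel_design()

  ## probe annotation: three two-probe genes exercise symbol-level collapse
  sym_idx <- seq_len(n)
  if (n >= 6) sym_idx[c(2, 4, 6)] <- c(1, 3, 5)
  probe_id <- sprintf("P%05d", seq_len(n))
  genbank_id <- sprintf("SYN%05d", seq_len(n))
  symbol <- sprintf("SGENE%04d", sym_idx)

  n_resp <- round(config$frac_responsive * n)
  responsive <- seq_len(n) <= n_resp
  ## direction assigned per symbol so duplicate probes of a gene agree
  sym_sign <- ifelse(runif(n) < config$frac_down, -1, 1)
  eff_sign <- sym_sign[sym_idx]

  ## per-condition planted effects
  conds <- unique(design[, c("cell_line", "treatment")])
  truth <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    cl <- conds$cell_line[i]; trt <- conds$treatment[i]
    mult <- if (trt == "R1881") config$ar_response_multiplier[[cl]]
            else config$flut_agonism[[cl]]
    data.frame(probe_id = probe_id, cell_line = cl, treatment = trt,
               true_effect = ifelse(responsive, eff_sign * config$base_effect * mult, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  ## baseline abundance per probe (log2). The default range is kept clear of
  ## the intensity floor after median scaling (floor/median = 0.2, i.e. 2.32
  ## log2 units below the range midpoint), so that censoring is governed by
  ## frac_low_intensity rather than by the tail of the abundance distribution.
  a_base <- runif(n, config$a_base_range[1], config$a_base_range[2])
  n_low <- round(config$frac_low_intensity * n)
  low_idx <- if (n_low > 0) sample.int(n, n_low) else integer(0)
  a_base[low_idx] <- runif(n_low, 4, 6.3)

  subarray_id <- rep(seq_len(config$n_subarrays), each = ceiling(n / config$n_subarrays))[seq_len(n)]

  nc <- config$n_controls
  ctrl_probe <- if (nc > 0) sprintf("CTRL%03d", seq_len(nc)) else character(0)
  ctrl_a <- if (nc > 0) runif(nc, 7, 14) else numeric(0)
  ctrl_sub <- if (nc > 0) rep(seq_len(config$n_subarrays), length.out = nc) else integer(0)

  truth_key <- paste(truth$cell_line, truth$treatment)
  eff_lookup <- split(truth$true_effect, truth_key)

  spots <- do.call(rbind, lapply(seq_len(nrow(design)), function(r) {
    cl <- design$cell_line[r]; trt <- design$treatment[r]
    tm <- as.character(design$time_h[r])
    orient <- if (design$dye_orientation[r] == "stim_cy5") 1 else -1
    eff <- eff_lookup[[paste(cl, trt)]] * config$time_multiplier[[tm]]

    a <- c(a_base, ctrl_a) + rnorm(n + nc, 0, 0.1)
    bias <- config$dye_bias_amplitude * sin(a)
    ## M on the channel scale (log2 cy5/cy3); stim in cy5 => +effect
    m <- c(eff, rep(0, nc)) * orient + bias + rnorm(n + nc, 0, config$noise_sd)
    ## per-spot dropouts: both channels pushed below the floor
    drop <- runif(n + nc) < config$spot_dropout_rate
    a[drop] <- runif(sum(drop), 4, 6.3)
    cy5 <- pmax(2^(a + m / 2), 0)
    cy3 <- pmax(2^(a - m / 2), 0)
    data.frame(array_id = design$array_id[r],
               subarray_id = c(subarray_id, ctrl_sub),
               probe_id = c(probe_id, ctrl_probe),
               genbank_id = c(genbank_id, rep("", nc)),
               symbol = c(symbol, rep("", nc)),
               cy3 = cy3, cy5 = cy5,
               control_flag = c(rep(FALSE, n), rep(TRUE, nc)),
               stringsAsFactors = FALSE)
  }))
  rownames(spots) <- NULL

  manifest <- list(seed = config$seed,
                   n_probes = n, n_arrays = nrow(design),
                   n_responsive = n_resp, n_low_intensity = n_low,
                   parameters = unclass(config))
  list(spots = spots, design = design, truth = truth, manifest = manifest)
}

#' Write a simulated experiment to disk
#'
#' Writes the spot table, design table and truth table as TSV and the run
#' manifest as JSON.
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv <- function(x, f)
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(experiment$spots, "spots.tsv")
  write_tsv(experiment$design, "design.tsv")
  write_tsv(experiment$truth, "truth.tsv")
  jsonlite::write_json(experiment$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated experiment back from disk
#'
#' @param dir directory written by [write_experiment()].
#' @return list with `spots`, `design`, `truth` data.frames.
#' @export
read_experiment <- function(dir) {
  read_tsv <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  list(spots = read_tsv("spots.tsv"), design = read_tsv("design.tsv"),
       truth = read_tsv("truth.tsv"))
}

#' Simulate pooled per-gene log-ratio vectors
#'
#' Direct simulation at the pooled-ratio level (the six values of one
#' condition: three time points times two replicates), bypassing the spot
#' level, for SAM calibration studies.
#'
#' @param n_genes number of genes.
#' @param n_responsive number of genes with a planted effect.
#' @param effect planted mean 2log ratio for responsive genes.
#' @param noise_sd per-value noise standard deviation (2log units).
#' @param n_values values per gene (default 6).
#' @param seed integer seed.
#' @return list with `x` (genes x values matrix, rownames `G1...`) and
#'   `responsive` (logical vector of planted truth).
#' @export
simulate_gene_ratios <- function(n_genes = 2000, n_responsive = 100,
                                 effect = 1.0, noise_sd = 0.25,
                                 n_values = 6, seed = 1L) {
  stopifnot(n_responsive <= n_genes)
  set.seed(seed)
  mu <- c(rep(effect, n_responsive), rep(0, n_genes - n_responsive))
  x <- matrix(rnorm(n_genes * n_values, mean = mu, sd = noise_sd),
              nrow = n_genes, ncol = n_values)
  rownames(x) <- sprintf("G%05d", seq_len(n_genes))
  list(x = x, responsive = seq_len(n_genes) <= n_responsive)
}

#' Score a called signature against planted truth
#'
#' @param signature data.frame of signature entries with columns `probe_id`,
#'   `cell_line`, `treatment` (e.g. from [call_signature()], optionally
#'   pre-filtered on a q-value cutoff).
#' @param truth truth table from [generate_experiment()].
#' @return object of class `recovery_report`: list with `per_condition`
#'   (data.frame of TP/FP/FN, precision, recall, FDP per cell line x
#'   treatment) and `overall` (probe-level: a probe counts as called if it
#'   qualifies in any condition, as truly responsive if any condition has a
#'   nonzero planted effect). FDP is FP/(FP+TP), defined 0 when nothing is
#'   called.
#' @export
evaluate_against_truth <- function(signature, truth) {
  stopifnot(is.data.frame(truth),
            all(c("probe_id", "cell_line", "treatment", "true_effect") %in% names(truth)))
  if (nrow(signature) > 0) {
    unknown <- setdiff(unique(signature$probe_id), unique(truth$probe_id))
    if (length(unknown))
      stop("signature contains probe ids absent from the truth table: ",
           paste(utils::head(unknown, 5), collapse = ", "),
           if (length(unknown) > 5) ", ..." else "")
  }
  prf <- function(tp, fp, fn) {
    c(tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      fdp = if (tp + fp > 0) fp / (tp + fp) else 0)
  }
  conds <- unique(truth[, c("cell_line", "treatment")])
  per_cond <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    cl <- conds$cell_line[i]; trt <- conds$treatment[i]
    tr <- truth[truth$cell_line == cl & truth$treatment == trt, ]
    called <- if (nrow(signature)) signature$probe_id[
      signature$cell_line == cl & signature$treatment == trt] else character(0)
    pos <- tr$probe_id[tr$true_effect != 0]
    m <- prf(length(intersect(called, pos)),
             length(setdiff(called, pos)),
             length(setdiff(pos, called)))
    data.frame(cell_line = cl, treatment = trt, t(m), stringsAsFactors = FALSE)
  }))
  called_any <- unique(signature$probe_id)
  pos_any <- unique(truth$probe_id[truth$true_effect != 0])
  overall <- prf(length(intersect(called_any, pos_any)),
                 length(setdiff(called_any, pos_any)),
                 length(setdiff(pos_any, called_any)))
  out <- list(per_condition = per_cond, overall = as.list(overall))
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery against planted truth\n")
  cat(sprintf("  overall: precision %.3f, recall %.3f, FDP %.3f (%d TP, %d FP, %d FN)\n",
              x$overall$precision, x$overall$recall, x$overall$fdp,
              x$overall$tp, x$overall$fp, x$overall$fn))
  print(x$per_condition, digits = 3)
  invisible(x)
}
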