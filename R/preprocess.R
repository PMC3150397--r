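## Normalization and QC cascade: per-subarray lowess -> global median scaling
## -> intensity floor -> low-intensity exclusion -> log ratios -> dye-swap
## discordance filter -> replicate averaging.

spot_ma <- function(spots) {
  list(m = log2(spots$cy5 / spots$cy3),
       a = 0.5 * log2(spots$cy5 * spots$cy3))
}

#' Lowess-normalize spot log-ratios within each subarray
#'
#' Removes the intensity-dependent dye bias: within each (array, subarray)
#' block the channel log-ratio M = log2(cy5/cy3) is replaced by its residual
#' from a locally weighted regression of M on A = mean log2 intensity, fitted
#' on non-control spots. Channel intensities are back-computed so that A is
#' preserved exactly.
#'
#' @param spots spot table (columns `array_id`, `subarray_id`, `probe_id`,
#'   `cy3`, `cy5`, and optionally `control_flag`).
#' @param span lowess span (fraction of points in each local fit).
#' @param iterations number of robustifying iterations.
#' @param min_spots minimum non-control spots required to fit a subarray;
#'   smaller subarrays are returned unchanged with a warning.
#' @return the spot table with normalized `cy3`/`cy5`.
#' @export
normalize_subarray_lowess <- function(spots, span = 0.4, iterations = 3,
                                      min_spots = 50) {
  ctrl <- if ("control_flag" %in% names(spots)) spots$control_flag else
    rep(FALSE, nrow(spots))
  ma <- spot_ma(spots)
  m <- ma$m; a <- ma$a
  grp <- interaction(spots$array_id, spots$subarray_id, drop = TRUE)
  for (idx in split(seq_len(nrow(spots)), grp)) {
    ok <- is.finite(m[idx]) & is.finite(a[idx])
    fit_idx <- idx[ok & !ctrl[idx]]
    if (length(fit_idx) < min_spots || length(unique(a[fit_idx])) < 2) {
      warning(sprintf("subarray %s/%s has fewer than %d usable spots; left unnormalized",
                      spots$array_id[idx[1]], spots$subarray_id[idx[1]], min_spots))
      next
    }
    lo <- lowess(a[fit_idx], m[fit_idx], f = span, iter = iterations)
    fitted <- approx(lo$x, lo$y, xout = a[idx], rule = 2, ties = mean)$y
    use <- idx[ok]
    m[use] <- m[use] - fitted[ok]
  }
  fin <- is.finite(m) & is.finite(a)
  spots$cy5[fin] <- 2^(a[fin] + m[fin] / 2)
  spots$cy3[fin] <- 2^(a[fin] - m[fin] / 2)
  spots
}

#' Scale each array so the pooled global median intensity hits a target
#'
#' Both channels of all spots on an array are multiplied by one scalar so
#' that the pooled (Cy3 and Cy5 together) median over non-control spots
#' equals `target`.
#'
#' @param spots spot table.
#' @param target target median intensity (default 1000).
#' @return the scaled spot table.
#' @export
scale_to_global_median <- function(spots, target = 1000) {
  if (nrow(spots) == 0) stop("empty spot table")
  ctrl <- if ("control_flag" %in% names(spots)) spots$control_flag else
    rep(FALSE, nrow(spots))
  for (idx in split(seq_len(nrow(spots)), spots$array_id)) {
    use <- idx[!ctrl[idx]]
    if (!length(use)) use <- idx
    med <- median(c(spots$cy3[use], spots$cy5[use]))
    if (!is.finite(med) || med <= 0)
      stop(sprintf("array %s has non-positive median intensity; cannot scale",
                   spots$array_id[idx[1]]))
    sc <- target / med
    spots$cy3[idx] <- spots$cy3[idx] * sc
    spots$cy5[idx] <- spots$cy5[idx] * sc
  }
  spots
}

#' Threshold channel intensities at a floor
#'
#' Each channel value below `floor` is replaced by `floor`; this stabilizes
#' fold changes in the low-intensity range against outliers.
#'
#' @param spots spot table.
#' @param floor intensity floor (default 200).
#' @return the floored spot table.
#' @export
apply_intensity_floor <- function(spots, floor = 200) {
  if (floor < 0) stop("'floor' must be nonnegative")
  spots$cy3 <- pmax(spots$cy3, floor)
  spots$cy5 <- pmax(spots$cy5, floor)
  spots
}

#' Flag probes with too many low-intensity arrays in a time-course
#'
#' Within each time-course (the six arrays of one cell line x treatment:
#' three time points times two replicates), a probe is excluded when the
#' number of arrays where *both* channels sit at or below the floor exceeds
#' `max_below` (more than half of the arrays). A value at the floor counts
#' as below, so the rule can be applied after flooring.
#'
#' @param spots spot table covering one or more time-courses.
#' @param design hybridization design (see [panel_design()]).
#' @param floor intensity floor (default 200).
#' @param max_below largest tolerated count of both-channels-low arrays;
#'   default `floor(n_arrays / 2)` (3 of 6). Time-courses with other than six
#'   arrays scale it proportionally, with a warning.
#' @return data.frame with one row per (probe, cell line, treatment):
#'   `n_below`, `n_arrays`, `excluded`.
#' @export
filter_low_intensity_spots <- function(spots, design, floor = 200,
                                       max_below = NULL) {
  sp <- spots[!(if ("control_flag" %in% names(spots)) spots$control_flag
                else FALSE), , drop = FALSE]
  di <- match(sp$array_id, design$array_id)
  if (anyNA(di)) stop("spot table contains arrays absent from the design")
  cl <- design$cell_line[di]; trt <- design$treatment[di]
  below <- as.integer(sp$cy3 <= floor & sp$cy5 <= floor)
  key <- paste(sp$probe_id, cl, trt, sep = "\r")
  n_below <- rowsum(below, key)
  n_arr <- rowsum(rep(1L, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(n_below), "\r", fixed = TRUE))
  out <- data.frame(probe_id = parts[, 1], cell_line = parts[, 2],
                    treatment = parts[, 3], n_below = n_below[, 1],
                    n_arrays = n_arr[, 1], stringsAsFactors = FALSE)
  if (is.null(max_below)) {
    mb <- floor(out$n_arrays / 2)
    if (any(out$n_arrays != 6))
      warning("time-course(s) with != 6 arrays; exclusion threshold scaled to >50%")
  } else {
    mb <- rep(max_below, nrow(out))
  }
  out$excluded <- out$n_below > mb
  rownames(out) <- NULL
  out[order(out$cell_line, out$treatment, out$probe_id), ]
}

#' Compute stimulated/vehicle log ratios per spot
#'
#' Resolves which channel carries the stimulated sample from the design's
#' dye orientation and computes `M = log2(stim/vehicle)` and
#' `A = 0.5 * log2(stim * vehicle)`; M is therefore invariant to the dye
#' orientation. Control spots are dropped.
#'
#' @param spots floored, normalized spot table.
#' @param design hybridization design with `dye_orientation`.
#' @return data.frame with columns `probe_id`, `genbank_id`, `symbol`,
#'   `cell_line`, `treatment`, `time_h`, `replicate`, `M`, `A`.
#' @export
compute_log_ratios <- function(spots, design) {
  if (!"dye_orientation" %in% names(design) ||
      anyNA(design$dye_orientation) ||
      !all(design$dye_orientation %in% c("stim_cy3", "stim_cy5")))
    stop("design must give a dye_orientation of 'stim_cy3' or 'stim_cy5' for every array")
  sp <- spots[!(if ("control_flag" %in% names(spots)) spots$control_flag
                else FALSE), , drop = FALSE]
  di <- match(sp$array_id, design$array_id)
  if (anyNA(di)) stop("spot table contains arrays absent from the design")
  stim_cy3 <- design$dye_orientation[di] == "stim_cy3"
  stim <- ifelse(stim_cy3, sp$cy3, sp$cy5)
  veh <- ifelse(stim_cy3, sp$cy5, sp$cy3)
  data.frame(probe_id = sp$probe_id,
             genbank_id = if ("genbank_id" %in% names(sp)) sp$genbank_id else "",
             symbol = if ("symbol" %in% names(sp)) sp$symbol else "",
             cell_line = design$cell_line[di], treatment = design$treatment[di],
             time_h = design$time_h[di], replicate = design$replicate[di],
             M = log2(stim / veh), A = 0.5 * log2(stim * veh),
             stringsAsFactors = FALSE)
}

#' Exclude probes with opposite effects in the dye-swap replicates
#'
#' For each (probe, cell line, treatment), the replicate mean M over the
#' three time points is computed per replicate; the probe is excluded for
#' that condition when one replicate mean is at or above `+threshold` and
#' the other at or below `-threshold` (both bounds inclusive), i.e. the two
#' dye orientations report opposite effects.
#'
#' @param ratios log-ratio table from [compute_log_ratios()].
#' @param threshold discordance threshold in 2log units (default 0.5).
#' @return list with `ratios` (rows of discordant (probe, condition) pairs
#'   removed) and `excluded` (data.frame of removed pairs with the two
#'   replicate means).
#' @export
filter_dye_swap_discordant <- function(ratios, threshold = 0.5) {
  key_cond <- paste(ratios$cell_line, ratios$treatment, sep = "\r")
  single <- tapply(ratios$replicate, key_cond, function(r) length(unique(r)) < 2)
  if (any(single)) {
    warning("condition(s) with a single replicate: no discordance filtering applied there")
  }
  key <- paste(ratios$probe_id, key_cond, ratios$replicate, sep = "\r")
  msum <- rowsum(ratios$M, key)
  mn <- rowsum(rep(1L, length(key)), key)
  rmean <- msum[, 1] / mn[, 1]
  parts <- do.call(rbind, strsplit(names(rmean), "\r", fixed = TRUE))
  pm <- data.frame(probe_id = parts[, 1], cell_line = parts[, 2],
                   treatment = parts[, 3], replicate = as.integer(parts[, 4]),
                   rep_mean = rmean, stringsAsFactors = FALSE)
  ## pair the two replicates of each (probe, condition)
  pkey <- paste(pm$probe_id, pm$cell_line, pm$treatment, sep = "\r")
  r1 <- pm[pm$replicate == 1, ]; r2 <- pm[pm$replicate == 2, ]
  i2 <- match(paste(r1$probe_id, r1$cell_line, r1$treatment, sep = "\r"),
              paste(r2$probe_id, r2$cell_line, r2$treatment, sep = "\r"))
  m1 <- r1$rep_mean; m2 <- r2$rep_mean[i2]
  ## inclusive bounds, with 1e-9 slack against floating-point rounding
  th <- threshold - 1e-9
  disc <- !is.na(m2) &
    ((m1 >= th & m2 <= -th) | (m1 <= -th & m2 >= th))
  excluded <- data.frame(probe_id = r1$probe_id[disc],
                         cell_line = r1$cell_line[disc],
                         treatment = r1$treatment[disc],
                         rep_mean_1 = m1[disc], rep_mean_2 = m2[disc],
                         stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  if (nrow(excluded)) {
    bad <- paste(excluded$probe_id, excluded$cell_line, excluded$treatment, sep = "\r")
    keep <- !(paste(ratios$probe_id, key_cond, sep = "\r") %in% bad)
    ratios <- ratios[keep, , drop = FALSE]
  }
  list(ratios = ratios, excluded = excluded)
}

#' Average the dye-swap replicates per time point
#'
#' Per (probe, condition, time point), M is the mean of the surviving
#' replicate values; when one replicate is missing after QC the surviving
#' replicate is used. A profile is complete (`complete = TRUE`) only when
#' all three time points carry a value.
#'
#' @param ratios log-ratio table, typically after
#'   [filter_dye_swap_discordant()].
#' @return data.frame with one row per (probe, condition, time point):
#'   `M` (replicate mean), `n_rep`, and `complete` (all three time points
#'   present for that probe and condition).
#' @export
average_replicates <- function(ratios) {
  key <- paste(ratios$probe_id, ratios$cell_line, ratios$treatment,
               ratios$time_h, sep = "\r")
  msum <- rowsum(ratios$M, key)
  mn <- rowsum(rep(1L, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(msum), "\r", fixed = TRUE))
  out <- data.frame(probe_id = parts[, 1], cell_line = parts[, 2],
                    treatment = parts[, 3], time_h = as.numeric(parts[, 4]),
                    M = msum[, 1] / mn[, 1], n_rep = mn[, 1],
                    stringsAsFactors = FALSE)
  anno <- unique(ratios[, intersect(c("probe_id", "genbank_id", "symbol"),
                                    names(ratios)), drop = FALSE])
  anno <- anno[!duplicated(anno$probe_id), , drop = FALSE]
  ai <- match(out$probe_id, anno$probe_id)
  if ("genbank_id" %in% names(anno)) out$genbank_id <- anno$genbank_id[ai]
  if ("symbol" %in% names(anno)) out$symbol <- anno$symbol[ai]
  ckey <- paste(out$probe_id, out$cell_line, out$treatment, sep = "\r")
  ntp <- rowsum(rep(1L, nrow(out)), ckey)
  out$complete <- ntp[match(ckey, rownames(ntp)), 1] == 3
  rownames(out) <- NULL
  out[order(out$cell_line, out$treatment, out$probe_id, out$time_h), ]
}

#' Pool the per-condition ratio values into a genes x values matrix
#'
#' Collects, for one cell line and treatment, the (up to) six 2log ratios
#' per probe (three time points times two replicates) as one row, in column
#' order t4/rep1, t4/rep2, t8/rep1, t8/rep2, t16/rep1, t16/rep2. Missing
#' values are NA.
#'
#' @param ratios log-ratio table (post-QC, pre-averaging).
#' @param cell_line,treatment condition selector.
#' @return numeric matrix, rownames = probe ids.
#' @export
pool_condition_ratios <- function(ratios, cell_line, treatment) {
  r <- ratios[ratios$cell_line == cell_line & ratios$treatment == treatment, ]
  probes <- sort(unique(r$probe_id))
  times <- sort(unique(r$time_h))
  reps <- sort(unique(r$replicate))
  cols <- expand.grid(replicate = reps, time_h = times)
  x <- matrix(NA_real_, nrow = length(probes), ncol = nrow(cols),
              dimnames = list(probes, sprintf("t%g_r%d", cols$time_h, cols$replicate)))
  ci <- match(paste(r$time_h, r$replicate),
              paste(cols$time_h, cols$replicate))
  x[cbind(match(r$probe_id, probes), ci)] <- r$M
  x
}

#' Run the full normalization and QC cascade
#'
#' Applies, in order: per-subarray lowess normalization, global median
#' scaling, intensity flooring, the low-intensity time-course exclusion,
#' log-ratio computation, the dye-swap discordance filter and replicate
#' averaging.
#'
#' @param spots raw spot table.
#' @param design hybridization design.
#' @param span,iterations,min_spots lowess parameters
#'   (see [normalize_subarray_lowess()]).
#' @param floor intensity floor (default 200).
#' @param median_target per-array pooled median target (default 1000).
#' @param max_below low-intensity exclusion threshold
#'   (see [filter_low_intensity_spots()]).
#' @param discordance_threshold dye-swap discordance threshold (default 0.5).
#' @return list with `averaged` (replicate-averaged profiles), `ratios`
#'   (post-QC per-replicate ratios, input to SAM pooling), `low_intensity`
#'   (the exclusion table), `discordant` (excluded discordant pairs) and
#'   `qc` (exclusion tallies).
#' @export
preprocess_experiment <- function(spots, design, span = 0.4, iterations = 3,
                                  min_spots = 50, floor = 200,
                                  median_target = 1000, max_below = NULL,
                                  discordance_threshold = 0.5) {
  sp <- normalize_subarray_lowess(spots, span = span, iterations = iterations,
                                  min_spots = min_spots)
  sp <- scale_to_global_median(sp, target = median_target)
  sp <- apply_intensity_floor(sp, floor = floor)
  low <- filter_low_intensity_spots(sp, design, floor = floor,
                                    max_below = max_below)
  ratios <- compute_log_ratios(sp, design)
  excl <- low[low$excluded, c("probe_id", "cell_line", "treatment")]
  if (nrow(excl)) {
    bad <- paste(excl$probe_id, excl$cell_line, excl$treatment, sep = "\r")
    keep <- !(paste(ratios$probe_id, ratios$cell_line, ratios$treatment,
                    sep = "\r") %in% bad)
    ratios <- ratios[keep, , drop = FALSE]
  }
  ds <- filter_dye_swap_discordant(ratios, threshold = discordance_threshold)
  averaged <- average_replicates(ds$ratios)
  list(averaged = averaged, ratios = ds$ratios, low_intensity = low,
       discordant = ds$excluded,
       qc = list(n_spots = nrow(spots),
                 n_low_excluded = sum(low$excluded),
                 n_discordant_excluded = nrow(ds$excluded)))
}

#' Write per-condition ratio matrices to TSV
#'
#' One file per (cell line, treatment): probes x time points of averaged
#' 2log ratios.
#'
#' @param averaged output of [average_replicates()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_ratio_matrices <- function(averaged, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  conds <- unique(averaged[, c("cell_line", "treatment")])
  paths <- character(0)
  for (i in seq_len(nrow(conds))) {
    a <- averaged[averaged$cell_line == conds$cell_line[i] &
                  averaged$treatment == conds$treatment[i], ]
    wide <- stats::reshape(a[, c("probe_id", "time_h", "M")],
                           idvar = "probe_id", timevar = "time_h",
                           direction = "wide")
    names(wide) <- sub("^M\\.", "M_t", names(wide))
    p <- file.path(dir, sprintf("ratios_%s_%s.tsv",
                                conds$cell_line[i], conds$treatment[i]))
    write.table(wide, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
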