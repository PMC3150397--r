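## qPCR quantification: standard curves, Ct -> quantity, reference-gene
## normalization with a calibrator, and ordered-group comparisons.

#' Fit a qPCR standard curve
#'
#' Least-squares line of threshold cycle (Ct) on log10 input quantity from a
#' serial dilution series. The amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle, slope about
#' -3.32); a warning is issued when it falls outside [0.8, 1.1].
#'
#' @param log10_quantity numeric vector of log10 input quantities.
#' @param ct matching Ct values (cycles).
#' @return object of class `standard_curve`: `slope`, `intercept` (Ct at
#'   unit quantity), `r2`, `efficiency`, and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(log10_quantity, ct) {
  if (length(log10_quantity) != length(ct))
    stop("'log10_quantity' and 'ct' must have equal length")
  if (length(unique(log10_quantity)) < 3)
    stop("need at least 3 distinct dilution points")
  fit <- lm(ct ~ log10_quantity)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  efficiency <- 10^(-1 / slope) - 1
  if (slope >= 0)
    warning("standard curve slope is nonnegative: curve is not usable for quantification")
  else if (efficiency < 0.8 || efficiency > 1.1)
    warning(sprintf("amplification efficiency %.2f outside [0.8, 1.1]", efficiency))
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency = efficiency, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Ct = %.3f %+.3f * log10(quantity)\n", x$intercept, x$slope))
  cat(sprintf("  r2 = %.4f, efficiency = %.3f\n", x$r2, x$efficiency))
  invisible(x)
}

#' Convert Ct values to quantities via a standard curve
#'
#' `quantity = 10^((ct - intercept) / slope)`; the inverse of the fitted
#' line, so points on the curve recover their input quantity exactly.
#'
#' @param ct numeric vector of threshold cycles; replicate wells should be
#'   averaged on the quantity scale afterwards (see [collapse_wells()]).
#' @param curve a `standard_curve`.
#' @return quantities in the arbitrary units of the dilution series.
#' @export
quantify_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("standard curve slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}

#' Average replicate wells on the quantity scale
#'
#' @param quantities numeric vector.
#' @param sample_id,gene grouping keys.
#' @return data.frame `sample_id`, `gene`, `quantity` (mean over wells).
#' @export
collapse_wells <- function(quantities, sample_id, gene) {
  key <- paste(sample_id, gene, sep = "\r")
  qs <- rowsum(quantities, key)
  qn <- rowsum(rep(1L, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(qs), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], gene = parts[, 2],
                    quantity = qs[, 1] / qn[, 1], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalize a target quantity against endogenous reference genes
#'
#' `single_ref` mode divides the target quantity by the reference quantity
#' (normalized gene expression relative to a housekeeping gene).
#' `dual_ref_calibrated` mode divides by the average of two endogenous
#' references and expresses the result relative to a calibrator sample:
#' `(target / mean(refs)) / calibrator_value`, where `calibrator_value` is
#' the same target/mean(refs) ratio computed on the calibrator.
#'
#' @param target_qty target-gene quantity (vectorized).
#' @param reference_qtys a numeric vector (single reference) or a matrix /
#'   data.frame with one column per reference gene.
#' @param mode `"single_ref"` or `"dual_ref_calibrated"`.
#' @param calibrator_value the normalized ratio of the calibrator sample
#'   (required in dual mode).
#' @param ref_average `"arithmetic"` (default) or `"geometric"` mean of the
#'   references.
#' @return normalized expression (unitless).
#' @export
normalize_expression <- function(target_qty, reference_qtys,
                                 mode = c("single_ref", "dual_ref_calibrated"),
                                 calibrator_value = NULL,
                                 ref_average = c("arithmetic", "geometric")) {
  mode <- match.arg(mode)
  ref_average <- match.arg(ref_average)
  refs <- as.matrix(reference_qtys)
  if (any(!is.finite(refs)) || any(refs <= 0))
    stop("reference quantities must be positive (offending row(s): ",
         paste(utils::head(which(apply(refs, 1, function(r) any(!is.finite(r) | r <= 0))), 5),
               collapse = ", "), ")")
  ref <- if (ref_average == "arithmetic") rowMeans(refs)
         else exp(rowMeans(log(refs)))
  nge <- target_qty / ref
  if (mode == "single_ref") return(nge)
  if (is.null(calibrator_value) || !is.finite(calibrator_value) ||
      calibrator_value <= 0)
    stop("dual_ref_calibrated mode needs a positive 'calibrator_value'")
  nge / calibrator_value
}

## two-sided Mann-Whitney; exact for small groups, normal approximation
## with tie correction otherwise
mwu_p <- function(x, y, exact_max = 8) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

## linear-contrast trend test across ordered groups (ANOVA partition):
## equally spaced centered scores on the group means, within-group MSE
## error, two-sided t.
linear_trend_p <- function(values, groups, levels) {
  g <- factor(groups, levels = levels)
  keep <- !is.na(g) & !is.na(values)
  g <- droplevels(g[keep]); values <- values[keep]
  k <- nlevels(g)
  if (k < 2) return(NA_real_)
  scores <- seq_len(k) - (k + 1) / 2
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  L <- sum(scores * means)
  N <- length(values)
  df <- N - k
  if (df <= 0) return(NA_real_)
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df
  se <- sqrt(mse * sum(scores^2 / ns))
  if (se == 0) return(if (L == 0) 1 else 0)
  2 * pt(-abs(L / se), df)
}

## Jonckheere-Terpstra trend test, normal approximation (two-sided)
jonckheere_p <- function(values, groups, levels) {
  g <- factor(groups, levels = levels)
  keep <- !is.na(g) & !is.na(values)
  g <- droplevels(g[keep]); values <- values[keep]
  k <- nlevels(g)
  if (k < 2) return(NA_real_)
  vs <- split(values, g)
  J <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    for (v in vs[[i]]) J <- J + sum(vs[[j]] > v) + 0.5 * sum(vs[[j]] == v)
  }
  ns <- lengths(vs); N <- sum(ns)
  mu <- (N^2 - sum(ns^2)) / 4
  sig <- sqrt((N^2 * (2 * N + 3) - sum(ns^2 * (2 * ns + 3))) / 72)
  if (sig == 0) return(NA_real_)
  2 * pnorm(-abs((J - mu) / sig))
}

#' Compare normalized expression across ordered sample groups
#'
#' Pairwise two-sided Mann-Whitney tests between consecutive (and optionally
#' all) group pairs, exact for small groups (both n <= 8, no ties) and
#' normal-approximated with tie correction otherwise, plus an across-groups
#' linear-trend test (significance of the linear contrast of group means
#' with equally spaced scores, ANOVA error term, two-sided). A
#' nonparametric Jonckheere-Terpstra trend alternative is available via
#' `trend = "jonckheere"`. Groups with fewer than two observations are
#' skipped with a warning. No multiple-testing correction is applied.
#'
#' @param values normalized expression values.
#' @param groups group membership of each value.
#' @param group_order the ordered group levels (disease progression order).
#' @param pairs `"consecutive"` (default) or `"all"` pairwise comparisons.
#' @param trend `"linear"` (default) or `"jonckheere"`.
#' @return list of class `group_comparison`: `pairwise` (data.frame of
#'   group pairs and Mann-Whitney p-values), `trend_p`, `trend_method`,
#'   `group_order`.
#' @export
compare_groups <- function(values, groups, group_order = sort(unique(groups)),
                           pairs = c("consecutive", "all"),
                           trend = c("linear", "jonckheere")) {
  pairs <- match.arg(pairs)
  trend <- match.arg(trend)
  g <- factor(groups, levels = group_order)
  if (any(is.na(g))) stop("groups contain levels absent from 'group_order'")
  ns <- table(g)
  usable <- names(ns)[ns >= 2]
  if (length(usable) < length(group_order))
    warning("group(s) with fewer than 2 observations skipped: ",
            paste(setdiff(group_order, usable), collapse = ", "))
  idx <- match(usable, group_order)
  pair_idx <- if (pairs == "consecutive") {
    if (length(idx) >= 2) cbind(idx[-length(idx)], idx[-1]) else
      matrix(integer(0), ncol = 2)
  } else {
    t(utils::combn(idx, 2))
  }
  pw <- do.call(rbind, lapply(seq_len(nrow(pair_idx)), function(r) {
    ga <- group_order[pair_idx[r, 1]]; gb <- group_order[pair_idx[r, 2]]
    data.frame(group_a = ga, group_b = gb,
               p_mwu = mwu_p(values[g == ga], values[g == gb]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw))
    pw <- data.frame(group_a = character(0), group_b = character(0),
                     p_mwu = numeric(0), stringsAsFactors = FALSE)
  tp <- if (trend == "linear") linear_trend_p(values, groups, group_order)
        else jonckheere_p(values, groups, group_order)
  structure(list(pairwise = pw, trend_p = tp, trend_method = trend,
                 group_order = group_order),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Ordered-group expression comparison (",
      paste(x$group_order, collapse = " -> "), ")\n", sep = "")
  print(x$pairwise, digits = 4)
  cat(sprintf("Trend (%s) p = %.4g\n", x$trend_method, x$trend_p))
  invisible(x)
}
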