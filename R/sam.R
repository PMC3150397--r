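## One-class Significance Analysis of Microarrays (SAM) on pooled log ratios.
##
## Each gene contributes one vector of treated/control 2log ratios (the three
## time points x two replicates of one condition, pooled). The statistic is
## d = mean(x) / (s + s0) with s the standard error of the mean and s0 a
## small exchangeability ("fudge") factor chosen to stabilize low-variance
## genes. The null distribution comes from sign-flip permutations of each
## gene's vector, which is the natural null for paired log ratios.

row_moments <- function(x) {
  fin <- is.finite(x)
  k <- rowSums(fin)
  x0 <- x; x0[!fin] <- 0
  m <- rowSums(x0) / k
  ss <- rowSums(x0^2)
  v <- pmax(ss - k * m^2, 0) / pmax(k - 1, 1)
  list(k = k, mean = m, ss = ss, se = sqrt(v) / sqrt(k), fin = fin, x0 = x0)
}

## Tusher-style s0: candidate percentiles of s; pick the one minimizing the
## coefficient of variation of the windowed median absolute deviation of d.
choose_s0 <- function(m, s, percentiles = seq(0, 100, 5)) {
  cand <- quantile(s, percentiles / 100, names = FALSE, type = 7)
  n_win <- max(2L, min(100L, floor(length(s) / 10)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- m / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

#' Compute one-class SAM d-statistics
#'
#' @param x numeric matrix, genes in rows, pooled 2log ratio values in
#'   columns (NAs allowed; at least two finite values per gene).
#' @param s0 the exchangeability factor. `NULL` (default) selects it from
#'   candidate percentiles of the per-gene standard errors by minimizing the
#'   coefficient of variation of the windowed median absolute d.
#' @param s0_percentiles candidate percentiles (of the s distribution) for
#'   the automatic s0 search.
#' @return list of class `sam_stats`: `d`, `mean`, `se` (per gene) and the
#'   `s0` used.
#' @export
sam_statistics <- function(x, s0 = NULL, s0_percentiles = seq(0, 100, 5)) {
  x <- as.matrix(x)
  mo <- row_moments(x)
  if (any(mo$k < 2))
    stop("every gene needs at least 2 finite values")
  if (is.null(s0)) s0 <- choose_s0(mo$mean, mo$se, s0_percentiles)
  if (s0 < 0) stop("'s0' must be nonnegative")
  if (s0 == 0 && any(mo$se == 0))
    stop("gene(s) with zero variance and s0 = 0: d is undefined; supply s0 > 0")
  d <- mo$mean / (mo$se + s0)
  structure(list(d = setNames(d, rownames(x)), mean = mo$mean, se = mo$se,
                 s0 = s0),
            class = "sam_stats")
}

sign_matrix <- function(p, n_permutations, seed = NULL) {
  if (identical(n_permutations, "exhaustive") || (is.numeric(n_permutations) &&
      n_permutations >= 2^p)) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), p)))
  } else {
    if (!is.numeric(n_permutations) || n_permutations < 10)
      stop("'n_permutations' must be \"exhaustive\" or a number >= 10")
    if (!is.null(seed)) set.seed(seed)
    matrix(sample(c(-1, 1), p * n_permutations, replace = TRUE),
           nrow = n_permutations, ncol = p)
  }
}

#' One-class SAM with sign-flip permutation FDR and q-values
#'
#' Computes d-statistics, generates a permutation null by flipping the signs
#' of each gene's values (exhaustive over all 2^p sign vectors when p <= 6,
#' otherwise sampled), and for a grid of thresholds delta applies the
#' quantile-quantile cutting rule: the observed order statistics d_(i) are
#' compared with their permutation expectations, and genes beyond the first
#' crossing of |d_(i) - dbar_i| >= delta are called. The false discovery
#' rate at each delta is `pi0 * median permuted call count / observed call
#' count`; a gene's q-value is the smallest FDR at which it is called,
#' clipped to [0, 1] and made monotone in |d|. pi0 is estimated as
#' `min(1, 2 * fraction of observed d inside the permuted quartiles)`.
#'
#' @param x genes x values matrix of pooled 2log ratios.
#' @param s0,s0_percentiles passed to [sam_statistics()].
#' @param n_permutations `"exhaustive"` (default; always used when the
#'   number of values is <= 6) or a count of sampled sign vectors (>= 10).
#' @param fdr_target FDR cutoff used to flag significant genes (default 0.05).
#' @param n_delta size of the delta grid.
#' @param seed seed for sampled permutations.
#' @return object of class `sam_fit`: per-gene `d`, `se`, `q`,
#'   `significant` (q <= `fdr_target`), the `s0` and `pi0` used, and
#'   `delta_table` (delta, cutlow, cutup, genes called, median false calls,
#'   FDR).
#' @export
sam_one_class <- function(x, s0 = NULL, s0_percentiles = seq(0, 100, 5),
                          n_permutations = "exhaustive", fdr_target = 0.05,
                          n_delta = 60, seed = NULL) {
  x <- as.matrix(x)
  st <- sam_statistics(x, s0 = s0, s0_percentiles = s0_percentiles)
  mo <- row_moments(x)
  sgn <- sign_matrix(ncol(x), n_permutations, seed = seed)
  B <- nrow(sgn)
  n <- nrow(x)

  ## permuted d: flipped mean from x0 %*% sgn'; sum of squares is invariant
  mperm <- (mo$x0 %*% t(sgn)) / mo$k
  vperm <- pmax(mo$ss - mo$k * mperm^2, 0) / pmax(mo$k - 1, 1)
  seperm <- sqrt(vperm) / sqrt(mo$k)
  dperm <- mperm / (seperm + st$s0)

  d <- st$d
  ord <- order(d)
  do <- d[ord]
  dbar <- rowMeans(apply(dperm, 2, sort))
  diff <- do - dbar

  qq <- quantile(dperm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, 2 * mean(d >= qq[1] & d <= qq[2]))

  deltas <- seq(0, max(abs(diff)) + 1e-9, length.out = n_delta)
  delta_table <- do.call(rbind, lapply(deltas, function(delta) {
    up <- which(diff >= delta & do > 0)
    cutup <- if (length(up)) min(do[up]) else Inf
    lo <- which(diff <= -delta & do < 0)
    cutlow <- if (length(lo)) max(do[lo]) else -Inf
    called <- sum(d >= cutup) + sum(d <= cutlow)
    false_b <- colSums(dperm >= cutup) + colSums(dperm <= cutlow)
    med_false <- median(false_b)
    fdr <- if (called == 0) 0 else min(1, pi0 * med_false / called)
    data.frame(delta = delta, cutlow = cutlow, cutup = cutup,
               called = called, median_false = med_false, fdr = fdr)
  }))

  ## per-gene q: smallest FDR among deltas at which the gene is called
  q <- rep(1, n)
  for (i in seq_len(nrow(delta_table))) {
    called_i <- d >= delta_table$cutup[i] | d <= delta_table$cutlow[i]
    q[called_i] <- pmin(q[called_i], delta_table$fdr[i])
  }
  ## monotone in extremity within each tail: a gene never has larger q than
  ## a less extreme gene on the same side. (The two tails are monotonized
  ## separately because the cutting rule is asymmetric: with all signal in
  ## one tail the other tail is never called and must keep q = 1.)
  for (side in c(1, -1)) {
    idx <- which(sign(d) == side)
    if (!length(idx)) next
    o <- idx[order(-abs(d[idx]))]
    q[o] <- rev(cummin(rev(q[o])))
  }
  q <- pmin(pmax(q, 0), 1)
  names(q) <- names(d)

  structure(list(d = d, se = st$se, mean = st$mean, s0 = st$s0, pi0 = pi0,
                 q = q, significant = q <= fdr_target,
                 fdr_target = fdr_target, delta_table = delta_table,
                 n_permutations = B),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("One-class SAM fit\n")
  cat(sprintf("  %d genes, %d sign-flip permutations\n",
              length(x$d), x$n_permutations))
  cat(sprintf("  s0 = %.4g, pi0 = %.3f\n", x$s0, x$pi0))
  cat(sprintf("  %d genes significant at q <= %.3g\n",
              sum(x$significant), x$fdr_target))
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  print(object)
  cat("\nDelta table (head):\n")
  print(utils::head(object$delta_table), digits = 4)
  invisible(object)
}

#' Run one-class SAM for every condition of a preprocessed experiment
#'
#' @param ratios post-QC per-replicate ratio table (the `ratios` element of
#'   [preprocess_experiment()]).
#' @param ... passed to [sam_one_class()].
#' @return named list of `sam_fit` objects, one per `"cell_line|treatment"`.
#' @export
sam_by_condition <- function(ratios, ...) {
  conds <- unique(ratios[, c("cell_line", "treatment")])
  fits <- lapply(seq_len(nrow(conds)), function(i) {
    x <- pool_condition_ratios(ratios, conds$cell_line[i], conds$treatment[i])
    x <- x[rowSums(is.finite(x)) >= 2, , drop = FALSE]
    sam_one_class(x, ...)
  })
  names(fits) <- paste(conds$cell_line, conds$treatment, sep = "|")
  fits
}
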