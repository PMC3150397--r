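## Fold-change signature calling on replicate-averaged ratio profiles.

#' Call the (anti)androgen-regulated signature by the fold-change rule
#'
#' A probe enters the signature when, for at least one (cell line,
#' treatment), its three per-time-point averaged 2log ratios share a sign
#' and all have absolute value at or above `threshold` (0.5 by default,
#' i.e. fold change >= 1.42 or <= 0.71). Each qualifying condition is
#' annotated with the direction and the mean of the three time-point
#' averages. Conditions with incomplete profiles (fewer than three time
#' points after QC) are skipped.
#'
#' @param averaged replicate-averaged profiles from [average_replicates()].
#' @param threshold absolute 2log ratio threshold (default 0.5), inclusive.
#' @return data.frame of signature entries, one row per qualifying
#'   (probe, cell line, treatment): `probe_id`, `genbank_id`, `symbol`,
#'   `cell_line`, `treatment`, `direction` (`"up"`/`"down"`), `mean_ratio`.
#' @export
call_signature <- function(averaged, threshold = 0.5) {
  key <- paste(averaged$probe_id, averaged$cell_line, averaged$treatment,
               sep = "\r")
  ntp <- rowsum(rep(1L, nrow(averaged)), key)
  ## boundary is inclusive; the 1e-9 slack keeps it inclusive when the
  ## log2 round trip lands half an ulp under a representable threshold
  nmin <- rowsum(as.integer(abs(averaged$M) >= threshold - 1e-9), key)
  npos <- rowsum(as.integer(averaged$M > 0), key)
  nneg <- rowsum(as.integer(averaged$M < 0), key)
  msum <- rowsum(averaged$M, key)
  complete <- ntp[, 1] == 3
  qual <- complete & nmin[, 1] == 3 & (npos[, 1] == 3 | nneg[, 1] == 3)
  parts <- do.call(rbind, strsplit(rownames(ntp)[qual], "\r", fixed = TRUE))
  if (!length(parts))
    return(data.frame(probe_id = character(0), genbank_id = character(0),
                      symbol = character(0), cell_line = character(0),
                      treatment = character(0), direction = character(0),
                      mean_ratio = numeric(0), stringsAsFactors = FALSE))
  mr <- msum[qual, 1] / ntp[qual, 1]
  out <- data.frame(probe_id = parts[, 1], cell_line = parts[, 2],
                    treatment = parts[, 3],
                    direction = ifelse(mr > 0, "up", "down"),
                    mean_ratio = mr, stringsAsFactors = FALSE)
  anno <- averaged[!duplicated(averaged$probe_id),
                   intersect(c("probe_id", "genbank_id", "symbol"),
                             names(averaged)), drop = FALSE]
  ai <- match(out$probe_id, anno$probe_id)
  out$genbank_id <- if ("genbank_id" %in% names(anno)) anno$genbank_id[ai] else ""
  out$symbol <- if ("symbol" %in% names(anno)) anno$symbol[ai] else ""
  rownames(out) <- NULL
  out[order(out$cell_line, out$treatment, out$probe_id),
      c("probe_id", "genbank_id", "symbol", "cell_line", "treatment",
        "direction", "mean_ratio")]
}

gene_label <- function(entries) {
  sym <- if ("symbol" %in% names(entries)) entries$symbol else ""
  gb <- if ("genbank_id" %in% names(entries)) entries$genbank_id else ""
  ifelse(is.na(sym) | sym == "", gb, sym)
}

#' Count signature genes per condition and direction
#'
#' Probes collapsing to one gene symbol are counted once; probes without a
#' symbol are counted by accession.
#'
#' @param entries signature entries (see [call_signature()] or
#'   [load_signature_fixture()]).
#' @return data.frame with `cell_line`, `treatment`, `direction`, `n_genes`.
#' @export
summarize_signature_counts <- function(entries) {
  if (nrow(entries) == 0)
    return(data.frame(cell_line = character(0), treatment = character(0),
                      direction = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  gene <- gene_label(entries)
  key <- paste(entries$cell_line, entries$treatment, entries$direction,
               sep = "\r")
  counts <- tapply(gene, key, function(g) length(unique(g)))
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  out <- data.frame(cell_line = parts[, 1], treatment = parts[, 2],
                    direction = parts[, 3], n_genes = as.integer(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cell_line, out$treatment, out$direction), ]
}

#' Attach SAM q-values to signature entries
#'
#' Joins each entry's qualifying condition to the matching one-class SAM
#' fit (by probe id and condition); entries without SAM coverage carry NA.
#' q-values above 1 in externally supplied results are clipped to 1, with
#' the original kept in `sam_q_original`.
#'
#' @param entries signature entries.
#' @param sam_fits named list of `sam_fit` objects keyed
#'   `"cell_line|treatment"` (see [sam_by_condition()]).
#' @param fdr_target cutoff for the `sam_significant` flag (default 0.05).
#' @return the entries with `sam_q`, `sam_q_original` and `sam_significant`
#'   columns.
#' @export
annotate_signature_with_q <- function(entries, sam_fits, fdr_target = 0.05) {
  q <- rep(NA_real_, nrow(entries))
  if (length(sam_fits)) {
    keys <- paste(entries$cell_line, entries$treatment, sep = "|")
    for (k in unique(keys)) {
      fit <- sam_fits[[k]]
      if (is.null(fit)) next
      sel <- which(keys == k)
      q[sel] <- fit$q[match(entries$probe_id[sel], names(fit$q))]
    }
  }
  entries$sam_q_original <- q
  entries$sam_q <- pmin(pmax(q, 0), 1)
  entries$sam_significant <- !is.na(entries$sam_q) & entries$sam_q <= fdr_target
  entries
}

#' Write signature entries as TSV
#'
#' Columns mirror the published gene-list layout: accession, symbol,
#' cytoband, cell line, treatment, direction, mean 2log ratio, SAM q-value.
#'
#' @param entries signature entries.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(entries, path) {
  cols <- intersect(c("genbank_id", "symbol", "cytoband", "cell_line",
                      "treatment", "direction", "mean_ratio", "sam_q"),
                    names(entries))
  write.table(entries[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load the packaged reference signature tables
#'
#' The package ships a curated reference table of the androgen- and
#' hydroxyflutamide-regulated gene lists of the PC346 panel (accession,
#' symbol, cytoband, qualifying cell line, mean 2log ratio and SAM q-value
#' per condition), used as a test fixture and worked-example input.
#' Reported q-values occasionally exceed 1 in the source lists; the numeric
#' `sam_q` column is clipped to [0, 1] and the verbatim string is kept in
#' `sam_q_original`.
#'
#' @param path fixture path; defaults to the packaged file.
#' @return data.frame of signature entries (one row per probe x qualifying
#'   condition) with columns `genbank_id`, `symbol`, `cytoband`,
#'   `cell_line`, `treatment`, `direction`, `mean_ratio`, `sam_q`,
#'   `sam_q_original`.
#' @export
load_signature_fixture <- function(path = system.file("extdata",
                                                      "signature_tables.tsv",
                                                      package = "arsig")) {
  if (!nzchar(path) || !file.exists(path))
    stop("signature fixture not found")
  fx <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("genbank_id", "symbol", "cytoband", "cell_line", "treatment",
              "direction", "mean_ratio", "sam_q")
  missing_cols <- setdiff(needed, names(fx))
  if (length(missing_cols))
    stop("malformed signature fixture: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(fx) == 0) stop("signature fixture is empty")
  mr <- suppressWarnings(as.numeric(fx$mean_ratio))
  if (anyNA(mr))
    stop("malformed signature fixture: non-numeric mean_ratio at line(s) ",
         paste(which(is.na(mr)) + 1, collapse = ", "))
  fx$mean_ratio <- mr
  fx$sam_q_original <- fx$sam_q
  fx$sam_q <- pmin(pmax(suppressWarnings(as.numeric(fx$sam_q)), 0), 1)
  bad_dir <- which(!(fx$direction %in% c("up", "down")) |
                     sign(fx$mean_ratio) != ifelse(fx$direction == "up", 1, -1))
  if (length(bad_dir))
    stop("malformed signature fixture: direction/ratio mismatch at line(s) ",
         paste(bad_dir + 1, collapse = ", "))
  fx$probe_id <- fx$genbank_id
  fx
}
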