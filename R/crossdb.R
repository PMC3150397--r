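## Cross-study concordance: harmonize external gene-level study tables,
## apply presence filters, cluster the signed concordance matrix and assign
## progression clusters.

.crossdb_classes <- c("androgen_response", "tumor_vs_normal",
                      "met_vs_primary", "resistant_or_recurrent")

#' Harmonize gene identifiers across study tables
#'
#' Upper-cases and whitespace-strips symbols, applies a user-supplied alias
#' map, and averages duplicate symbols within one study (with a warning).
#' Rows without a resolvable symbol are kept under their accession.
#'
#' @param tables data.frame with columns `study_id`, `symbol`, `value`
#'   (signed 2log units or direction -1/0/+1), and optionally
#'   `comparison_class`.
#' @param alias_map named character vector mapping old symbols to canonical
#'   ones (e.g. `c(MTP18 = "MTFP1")`).
#' @return the harmonized table (one row per study x symbol).
#' @export
harmonize_identifiers <- function(tables, alias_map = NULL) {
  sym <- toupper(trimws(tables$symbol))
  if (!is.null(alias_map)) {
    names(alias_map) <- toupper(trimws(names(alias_map)))
    hit <- sym %in% names(alias_map)
    sym[hit] <- toupper(trimws(alias_map[sym[hit]]))
  }
  tables$symbol <- sym
  key <- paste(tables$study_id, tables$symbol, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate symbol(s) within one study: values averaged")
    vsum <- rowsum(tables$value, key)
    vn <- rowsum(rep(1L, length(key)), key)
    first <- tables[!duplicated(key), , drop = FALSE]
    first <- first[match(rownames(vsum), paste(first$study_id, first$symbol,
                                               sep = "\r")), ]
    first$value <- vsum[, 1] / vn[, 1]
    tables <- first
    rownames(tables) <- NULL
  }
  tables
}

#' Retain genes present in at least a minimum number of studies
#'
#' @param genes character vector of candidate gene symbols.
#' @param tables harmonized study tables.
#' @param min_present minimum number of studies with a non-missing value.
#' @return the retained gene symbols (in input order).
#' @export
presence_filter <- function(genes, tables, min_present) {
  n_studies <- length(unique(tables$study_id))
  if (min_present > n_studies)
    stop(sprintf("min_present (%d) exceeds the number of studies (%d)",
                 min_present, n_studies))
  ok <- tables[!is.na(tables$value), ]
  n_present <- tapply(ok$study_id, ok$symbol, function(s) length(unique(s)))
  genes[genes %in% names(n_present)[n_present >= min_present] | min_present == 0]
}

#' Build a genes x studies concordance matrix
#'
#' @param genes gene symbols (rows).
#' @param tables harmonized study tables.
#' @return numeric matrix (NA = missing), columns ordered by study id.
#' @export
concordance_matrix <- function(genes, tables) {
  studies <- sort(unique(tables$study_id))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(studies),
              dimnames = list(genes, studies))
  ri <- match(tables$symbol, genes)
  ci <- match(tables$study_id, studies)
  keep <- !is.na(ri)
  m[cbind(ri[keep], ci[keep])] <- tables$value[keep]
  m
}

#' Hierarchically cluster a concordance matrix
#'
#' Agglomerative clustering with distance `1 - centered Pearson correlation`
#' computed over pairwise-complete columns, average linkage. Rows with all
#' values missing are dropped first; pairs whose correlation is undefined
#' (zero variance or fewer than two shared columns) get the maximum
#' distance 2, with a warning. Leaf order is deterministic (ties broken by
#' input order).
#'
#' @param mat numeric matrix (genes x study columns), NAs allowed.
#' @return list of class `concordance_clust`: `hclust` (the tree), `dist`
#'   (the distance matrix) and `leaf_order` (labels in dendrogram order).
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  keep <- rowSums(is.finite(mat)) > 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) stop("need at least 2 rows with data to cluster")
  cc <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  if (anyNA(cc[upper.tri(cc)]))
    warning("undefined correlation(s) (zero variance or insufficient overlap): distance set to 2")
  cc[!is.finite(cc)] <- -1
  d <- as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, dist = d, leaf_order = hc$labels[hc$order]),
            class = "concordance_clust")
}

#' @export
print.concordance_clust <- function(x, ...) {
  cat(sprintf("Concordance clustering of %d genes (1 - centered Pearson, average linkage)\n",
              length(x$leaf_order)))
  cat("Leaf order:", paste(utils::head(x$leaf_order, 10), collapse = ", "),
      if (length(x$leaf_order) > 10) "..." else "", "\n")
  invisible(x)
}

#' Export a concordance dendrogram as Newick
#'
#' @param clust a `concordance_clust` from [hierarchical_cluster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Export a clustered matrix in CDT-like tab-delimited layout
#'
#' Rows are written in dendrogram leaf order with a gene-id column, so the
#' file can be inspected in heat-map viewers.
#'
#' @param mat the matrix handed to [hierarchical_cluster()].
#' @param clust the resulting `concordance_clust`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cdt_matrix <- function(mat, clust, path) {
  ord <- clust$leaf_order
  out <- data.frame(GID = ord, NAME = ord,
                    mat[ord, , drop = FALSE], check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

consensus_direction <- function(values, zero_band = 0.1) {
  v <- values[!is.na(values)]
  s <- sign(v) * (abs(v) >= zero_band)
  n_up <- sum(s > 0); n_down <- sum(s < 0)
  if (n_up > n_down) "up" else if (n_down > n_up) "down" else NA_character_
}

#' Assign a progression cluster to one gene
#'
#' The four clusters combine the androgen response direction with the
#' consensus metastasis-versus-primary direction (strict sign majority over
#' non-missing studies; absolute values below `zero_band` count as no
#' direction): androgen-repressed genes up-regulated during progression are
#' cluster 1, repressed/down cluster 2, induced/down cluster 3 and
#' induced/up cluster 4. A sign tie or no data leaves the gene unassigned.
#'
#' @param androgen_dir `"up"` or `"down"` (from the signature).
#' @param met_values numeric vector of signed met-vs-primary values across
#'   studies (NA = missing).
#' @param zero_band absolute values below this count as no direction
#'   (default 0.1).
#' @return integer 1-4, or NA for unassigned.
#' @export
assign_progression_cluster <- function(androgen_dir, met_values,
                                       zero_band = 0.1) {
  stopifnot(androgen_dir %in% c("up", "down"))
  met <- consensus_direction(met_values, zero_band)
  if (is.na(met)) return(NA_integer_)
  if (androgen_dir == "down" && met == "up") 1L
  else if (androgen_dir == "down" && met == "down") 2L
  else if (androgen_dir == "up" && met == "down") 3L
  else 4L
}

#' Assign progression clusters for a set of genes
#'
#' @param directions data.frame with `symbol` and `direction` (androgen
#'   response, `"up"`/`"down"`).
#' @param met_tables harmonized study tables restricted to the
#'   metastasis-versus-primary comparison class (or any tables whose
#'   consensus should define progression).
#' @param zero_band see [assign_progression_cluster()].
#' @return data.frame with `symbol`, `direction`, `cluster` (1-4 or NA).
#' @export
assign_progression_clusters <- function(directions, met_tables,
                                        zero_band = 0.1) {
  mat <- concordance_matrix(directions$symbol, met_tables)
  cl <- vapply(seq_len(nrow(directions)), function(i) {
    assign_progression_cluster(directions$direction[i], mat[i, ], zero_band)
  }, integer(1))
  data.frame(symbol = directions$symbol, direction = directions$direction,
             cluster = cl, stringsAsFactors = FALSE)
}

#' Simulate a pack of external study tables with tunable concordance
#'
#' Emulates published gene-level comparison tables (androgen response in
#' other model systems; tumor-versus-normal, metastasis-versus-primary and
#' recurrent/resistant clinical comparisons) for a given signature: each
#' study reports, per gene, a signed value agreeing with the gene's
#' direction with probability `concordance`, and is missing at random with
#' probability `missing_rate`.
#'
#' @param directions data.frame with `symbol` and `direction` of the
#'   signature genes; for the clinical classes the sign is additionally
#'   flipped for androgen-induced genes with probability
#'   `progression_flip`, emulating selective pathway down-regulation during
#'   progression.
#' @param n_androgen,n_tumor,n_met,n_recurrent number of studies per
#'   comparison class.
#' @param concordance probability that a study's sign agrees.
#' @param missing_rate probability of a missing value.
#' @param progression_flip probability that a clinical study reverses an
#'   androgen-induced gene (default 0, i.e. fully concordant progression).
#' @param seed integer seed.
#' @return data.frame with `study_id`, `comparison_class`, `symbol`,
#'   `value`.
#' @export
simulate_study_pack <- function(directions, n_androgen = 5, n_tumor = 2,
                                n_met = 3, n_recurrent = 2,
                                concordance = 0.85, missing_rate = 0.2,
                                progression_flip = 0, seed = 1L) {
  set.seed(seed)
  studies <- data.frame(
    study_id = c(sprintf("AR%02d", seq_len(n_androgen)),
                 sprintf("TN%02d", seq_len(n_tumor)),
                 sprintf("MP%02d", seq_len(n_met)),
                 sprintf("RR%02d", seq_len(n_recurrent))),
    comparison_class = rep(.crossdb_classes,
                           c(n_androgen, n_tumor, n_met, n_recurrent)),
    stringsAsFactors = FALSE)
  base_sign <- ifelse(directions$direction == "up", 1, -1)
  out <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    sgn <- base_sign
    if (studies$comparison_class[i] != "androgen_response" &&
        progression_flip > 0) {
      flip <- runif(length(sgn)) < progression_flip & base_sign > 0
      sgn[flip] <- -sgn[flip]
    }
    agree <- ifelse(runif(length(sgn)) < concordance, 1, -1)
    val <- sgn * agree * abs(rnorm(length(sgn), 1, 0.4))
    val[runif(length(val)) < missing_rate] <- NA
    data.frame(study_id = studies$study_id[i],
               comparison_class = studies$comparison_class[i],
               symbol = directions$symbol, value = val,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
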