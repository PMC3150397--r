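# Small in-code fixtures shared across test files.

# Six-array time-course (one cell line x treatment), dye-swapped replicates.
toy_design <- function(cell_line = "PC346C", treatment = "R1881") {
  data.frame(array_id = sprintf("T%02d", 1:6),
             cell_line = cell_line, treatment = treatment,
             time_h = rep(c(4, 8, 16), each = 2), replicate = rep(1:2, 3),
             dye_orientation = rep(c("stim_cy3", "stim_cy5"), 3),
             stringsAsFactors = FALSE)
}

# Spot table from channel matrices (probes x arrays).
toy_spots <- function(design, cy3, cy5, probe_ids = sprintf("P%03d", seq_len(nrow(cy3)))) {
  do.call(rbind, lapply(seq_len(nrow(design)), function(j) {
    data.frame(array_id = design$array_id[j], subarray_id = 1L,
               probe_id = probe_ids, genbank_id = probe_ids,
               symbol = probe_ids, cy3 = cy3[, j], cy5 = cy5[, j],
               control_flag = FALSE, stringsAsFactors = FALSE)
  }))
}

# Ratio table from a probes x 6 matrix of M values (columns follow
# toy_design order: t4r1, t4r2, t8r1, t8r2, t16r1, t16r2).
toy_ratios <- function(m, design = toy_design(),
                       probe_ids = sprintf("P%03d", seq_len(nrow(m)))) {
  do.call(rbind, lapply(seq_len(nrow(design)), function(j) {
    data.frame(probe_id = probe_ids, genbank_id = probe_ids,
               symbol = probe_ids, cell_line = design$cell_line[j],
               treatment = design$treatment[j], time_h = design$time_h[j],
               replicate = design$replicate[j], M = m[, j], A = 10,
               stringsAsFactors = FALSE)
  }))
}

# Averaged-profile table from a probes x 3 matrix (times 4, 8, 16 h).
toy_averaged <- function(m, cell_line = "PC346C", treatment = "R1881",
                         probe_ids = sprintf("P%03d", seq_len(nrow(m)))) {
  do.call(rbind, lapply(1:3, function(t) {
    data.frame(probe_id = probe_ids, genbank_id = probe_ids,
               symbol = probe_ids, cell_line = cell_line,
               treatment = treatment, time_h = c(4, 8, 16)[t],
               M = m[, t], n_rep = 2L, complete = TRUE,
               stringsAsFactors = FALSE)
  }))
}

# Independent brute-force UPGMA on a distance matrix: returns merge heights
# and member sets at each step, recomputing all pairwise cluster distances
# (mean of original pairwise distances) from scratch each iteration.
brute_force_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  steps <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    steps[[length(steps) + 1]] <- list(height = best[1],
                                       members = sort(c(clusters[[i]], clusters[[j]])))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  steps
}

# Member sets at each hclust merge step.
hclust_member_sets <- function(hc) {
  n <- length(hc$height)
  members <- vector("list", n)
  for (k in seq_len(n)) {
    grab <- function(v) {
      unlist(lapply(v, function(x) if (x < 0) -x else members[[x]]))
    }
    members[[k]] <- sort(grab(hc$merge[k, ]))
  }
  members
}
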