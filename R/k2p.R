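PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence has a gap (`-`) or an `N` are excluded
#' pairwise. With transition proportion `P` and transversion proportion
#' `Q` over the compared sites, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`
#' in substitutions per site. When an argument of a logarithm is
#' non-positive the pair is saturated and the distance is undefined
#' (an error, not `NaN`).
#'
#' @param seq_a,seq_b aligned sequences (equal-length character strings
#'   over A, C, G, T, `-`, N; case-insensitive).
#' @return object of class `pairwise_divergence`: list with `P`, `Q`,
#'   `n_sites` (compared sites), and `d`.
#' @examples
#' k2p_distance("ACGT", "ACGT")$d   # 0
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop_hostspec("sequences differ in length (not aligned)",
                  "hostspec_alignment_error")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0)
    stop_hostspec("no overlapping ungapped sites", "hostspec_no_overlap_error")
  diff <- a != b
  same_class <- (a %in% PURINES) == (b %in% PURINES)
  ts <- sum(diff & same_class)   # purine<->purine or pyrimidine<->pyrimidine
  tv <- sum(diff & !same_class)
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop_hostspec(sprintf(
      "saturated pair (P = %.3f, Q = %.3f): K2P distance undefined", P, Q),
      "hostspec_saturation_error")
  structure(list(P = P, Q = Q, n_sites = n,
                 d = -0.5 * log(arg1) - 0.25 * log(arg2)),
            class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat(sprintf(
    "K2P divergence: d = %.4f (P = %.4f, Q = %.4f over %d sites)\n",
    x$d, x$P, x$Q, x$n_sites))
  invisible(x)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Pairwise (not complete) deletion of gap/N sites, the standard choice
#' for barcoding distances. Distances are proportions (substitutions per
#' site); multiply by 100 only for display.
#'
#' @param seqs named character vector of aligned sequences (as returned
#'   by [read_fasta()]).
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- k2p_distance(seqs[[i]], seqs[[j]])$d
      m[i, j] <- d
      m[j, i] <- d
    }
  m
}

#' Gene-flow call from a K2P distance
#'
#' Two populations on different hosts are treated as connected by ongoing
#' gene flow when their distance is at or below the threshold (inclusive;
#' default 5%), otherwise as genetically isolated.
#'
#' @param d K2P distance, a proportion >= 0.
#' @param threshold proportion (default 0.05).
#' @return `"ongoing_gene_flow"` or `"isolated"` (vectorised over `d`).
#' @export
gene_flow_call <- function(d, threshold = 0.05) {
  if (any(d < 0)) stop_hostspec("distance must be >= 0",
                                "hostspec_validation_error")
  ifelse(d <= threshold, "ongoing_gene_flow", "isolated")
}

#' Barcode-gap OTU delimitation by threshold sweep
#'
#' For each candidate threshold, labels are clustered by single linkage
#' (transitive closure of "distance <= threshold"); the partition
#' maximising the barcode gap -- smallest between-cluster distance minus
#' largest within-cluster distance -- is returned. The gap is undefined
#' for the all-singleton and the single-cluster partitions, which are
#' only returned when no candidate yields a defined gap. Ties are broken
#' towards the smallest threshold. This is a deliberately simple
#' gap-maximising sweep, not a probability-scored partitioner.
#'
#' @param matrix symmetric K2P distance matrix with labelled rows.
#' @param threshold_grid numeric vector of candidate thresholds
#'   (proportions).
#' @return object of class `delimitation_partition`: list with
#'   `clusters` (list of label vectors), `threshold_used`, `gap_width`
#'   (`NA` when undefined).
#' @export
delimit_otus <- function(matrix,
                         threshold_grid = seq(0.005, 0.15, by = 0.005)) {
  if (!length(threshold_grid))
    stop_hostspec("empty threshold grid", "hostspec_validation_error")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop_hostspec("distance matrix must be symmetric",
                  "hostspec_validation_error")
  labels <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  n <- nrow(matrix)
  if (n == 1)
    return(structure(list(clusters = list(labels),
                          threshold_used = threshold_grid[1],
                          gap_width = NA_real_),
                     class = "delimitation_partition"))

  threshold_grid <- sort(threshold_grid)
  best <- NULL
  for (thr in threshold_grid) {
    memb <- single_linkage_components(matrix, thr)
    gw <- barcode_gap(matrix, memb)
    if (!is.na(gw) && (is.null(best) || gw > best$gap_width + 1e-12)) {
      best <- list(memb = memb, gap_width = gw, thr = thr)
    }
  }
  if (is.null(best)) {  # degenerate: no partition has both terms defined
    memb <- single_linkage_components(matrix, threshold_grid[1])
    best <- list(memb = memb, gap_width = NA_real_, thr = threshold_grid[1])
  }
  clusters <- split(labels, best$memb)
  names(clusters) <- NULL
  structure(list(clusters = clusters, threshold_used = best$thr,
                 gap_width = best$gap_width),
            class = "delimitation_partition")
}

## connected components of the graph with edges d <= thr
single_linkage_components <- function(m, thr) {
  n <- nrow(m)
  memb <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && m[i, j] <= thr && memb[j] != memb[i]) {
        memb[memb == memb[j]] <- memb[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(memb, unique(memb))
}

barcode_gap <- function(m, memb) {
  same <- outer(memb, memb, "==")
  ut <- upper.tri(m)
  within <- m[ut & same]
  between <- m[ut & !same]
  if (!length(within) || !length(between)) return(NA_real_)
  min(between) - max(within)
}

#' @export
print.delimitation_partition <- function(x, ...) {
  cat(sprintf("OTU delimitation: %d cluster(s), threshold %.3f, gap width %s\n",
              length(x$clusters), x$threshold_used,
              ifelse(is.na(x$gap_width), "undefined",
                     sprintf("%.4f", x$gap_width))))
  for (i in seq_along(x$clusters))
    cat(sprintf("  OTU %d: %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Write a square distance matrix as TSV
#'
#' Labels in the first row and first column.
#'
#' @param m labelled symmetric matrix.
#' @param path output file.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
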