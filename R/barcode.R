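#' Construct a barcode count table
#'
#' @param counts non-negative integer matrix, barcodes x samples, with row
#'   and column names.
#' @param roles character vector, one per sample: `"baseline"` for the
#'   pre-treatment aliquots, any other label for condition x replicate
#'   samples (replicates of a condition share a label).
#' @param truth optional list of planted expanded barcode indices (kept by
#'   the synthetic generator for validation).
#' @return An object of class `barcode_table`.
#' @export
barcode_table <- function(counts, roles, truth = NULL) {
  counts <- as.matrix(counts)
  if (length(roles) != ncol(counts))
    stop_config("one role per sample column required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("bc%05d", seq_len(nrow(counts)))
  structure(counts, roles = as.character(roles), truth = truth,
            class = c("barcode_table", class(counts)))
}

#' @export
print.barcode_table <- function(x, ...) {
  r <- attr(x, "roles")
  cat(sprintf("barcode_table: %d barcodes x %d samples (%d baseline)\n",
              nrow(x), ncol(x), sum(r == "baseline")))
  cat("  samples:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample barcode frequencies
#'
#' Counts divided by the sample total, computed before any filtering; each
#' column sums to 1.
#'
#' @param table a [barcode_table()].
#' @return Numeric matrix of frequencies.
#' @export
barcode_frequencies <- function(table) {
  stopifnot(inherits(table, "barcode_table"))
  totals <- colSums(table)
  if (any(totals == 0)) stop_config("sample with zero total reads")
  f <- sweep(unclass(table), 2, totals, "/")
  stopifnot(all(abs(colSums(f) - 1) < 1e-9))
  f
}

#' Baseline-derived enrichment threshold
#'
#' The frequency vectors of the baseline samples are averaged element-wise
#' and the threshold is the largest entry of the averaged vector -- the
#' frequency of the most abundant clone before selection. A clone must
#' exceed this to count as positively selected.
#'
#' @param table a [barcode_table()] with >= 1 baseline sample.
#' @return Threshold frequency (> 0).
#' @export
enrichment_threshold <- function(table) {
  roles <- attr(table, "roles")
  if (!any(roles == "baseline"))
    stop_config("table has no baseline samples")
  f <- barcode_frequencies(table)
  avg <- rowMeans(f[, roles == "baseline", drop = FALSE])
  max(avg)
}

#' Call enriched barcodes
#'
#' Flags, per non-baseline sample, the barcodes whose frequency strictly
#' exceeds the baseline-derived threshold ("exceeding" is read strictly: a
#' barcode at exactly the threshold is not called).
#'
#' @param table a [barcode_table()].
#' @param threshold enrichment threshold, normally from
#'   [enrichment_threshold()].
#' @return An object of class `enrichment_result`: list with `threshold`,
#'   `enriched` (named list of barcode ids per non-baseline sample) and
#'   `union` (ids enriched in at least one sample).
#' @export
call_enriched <- function(table, threshold = enrichment_threshold(table)) {
  stopifnot(inherits(table, "barcode_table"), threshold > 0)
  roles <- attr(table, "roles")
  f <- barcode_frequencies(table)
  sel <- which(roles != "baseline")
  enriched <- lapply(sel, function(j) rownames(table)[f[, j] > threshold])
  names(enriched) <- colnames(table)[sel]
  structure(list(threshold = threshold, enriched = enriched,
                 union = sort(unique(unlist(enriched)))),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: threshold %.4g; %d barcodes enriched in >= 1 sample\n",
    x$threshold, length(x$union)))
  for (s in names(x$enriched))
    cat(sprintf("  %s: %d\n", s, length(x$enriched[[s]])))
  invisible(x)
}

#' Shannon diversity of clone frequencies
#'
#' H = -sum f_i ln f_i in nats; zero-frequency clones contribute nothing.
#' H is maximal, ln(k), for k equally frequent clones, and 0 for a
#' monoclonal sample; clonal selection drives it down.
#'
#' @param f frequencies (or counts, which are normalized first).
#' @return Diversity in nats.
#' @export
shannon_diversity <- function(f) {
  stopifnot(all(f >= 0), sum(f) > 0)
  f <- f / sum(f)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Spearman correlation of samples over enriched barcodes
#'
#' Pairwise Spearman rank correlation of per-sample frequencies restricted
#' to the union of enriched barcodes. Replicates of the same condition
#' correlating more strongly than samples of different conditions is the
#' signature of selection acting on clones that pre-existed treatment.
#'
#' @param result an [call_enriched()] result with non-empty union.
#' @param table the [barcode_table()] it was computed from.
#' @return Symmetric correlation matrix over all samples (unit diagonal).
#' @export
replicate_correlation <- function(result, table) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(table, "barcode_table"))
  if (!length(result$union)) stop_config("no enriched barcodes")
  if (length(result$union) < 3)
    warning("fewer than 3 enriched barcodes: correlations are underpowered")
  f <- barcode_frequencies(table)[result$union, , drop = FALSE]
  cor(f, method = "spearman")
}

#' Hierarchical clustering of enriched barcodes and samples
#'
#' Agglomerative clustering (complete linkage, Euclidean distance on log10
#' pseudo-frequencies) of the enriched barcodes (rows) and of the samples
#' (columns), emitting the orderings used for heatmap display.
#'
#' @param result an [call_enriched()] result with non-empty union.
#' @param table the [barcode_table()] it was computed from.
#' @param pseudocount added to counts before log-frequency transformation.
#' @return An object of class `barcode_clustering`: list with `log_freq`
#'   matrix, `row_hclust`/`col_hclust` (NULL for a single row/column) and
#'   `row_order`/`col_order`.
#' @export
cluster_enriched <- function(result, table, pseudocount = 0.5) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(table, "barcode_table"))
  if (!length(result$union)) stop_config("no enriched barcodes")
  counts <- unclass(table)[result$union, , drop = FALSE]
  totals <- colSums(unclass(table))
  lf <- log10(sweep(counts + pseudocount, 2, totals, "/"))
  row_h <- if (nrow(lf) > 1) hclust(dist(lf), method = "complete") else NULL
  col_h <- if (ncol(lf) > 1) hclust(dist(t(lf)), method = "complete") else NULL
  structure(list(log_freq = lf,
                 row_hclust = row_h, col_hclust = col_h,
                 row_order = if (is.null(row_h)) 1L else row_h$order,
                 col_order = if (is.null(col_h)) 1L else col_h$order),
            class = "barcode_clustering")
}

#' @export
print.barcode_clustering <- function(x, ...) {
  cat(sprintf("barcode_clustering: %d barcodes x %d samples\n",
              nrow(x$log_freq), ncol(x$log_freq)))
  invisible(x)
}

#' Full clone-tracing analysis of a barcode table
#'
#' Convenience wrapper running threshold derivation, enrichment calling,
#' per-sample Shannon diversity, Spearman correlation and clustering.
#'
#' @param table a [barcode_table()].
#' @return List with `threshold`, `enrichment`, `diversity` (named vector,
#'   nats), `correlation` and `clustering` (NULL when nothing is enriched).
#' @export
analyze_barcodes <- function(table) {
  stopifnot(inherits(table, "barcode_table"))
  thr <- enrichment_threshold(table)
  enr <- call_enriched(table, thr)
  f <- barcode_frequencies(table)
  div <- apply(f, 2, shannon_diversity)
  if (length(enr$union)) {
    corr <- replicate_correlation(enr, table)
    clus <- cluster_enriched(enr, table)
  } else corr <- clus <- NULL
  list(threshold = thr, enrichment = enr, diversity = div,
       correlation = corr, clustering = clus)
}
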