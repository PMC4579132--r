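#' Clamp expression values into a box
#'
#' Bounds every value into `[lo, hi]`, the usual conditioning for
#' oligonucleotide-array intensities: very low values are noise-dominated and
#' very high values saturate the scanner. The conventional box for this kind
#' of data is 20 to 16,000 units.
#'
#' @param data Expression data (matrix or data frame; see
#'   [as_expression_matrix()]). `NA` entries pass through untouched.
#' @param lo,hi Box bounds, `lo < hi`.
#' @return Data of the same type as the input (tibble for data-frame input,
#'   matrix otherwise) with values clamped; shapes and identifiers unchanged.
#' @examples
#' bound_expression(matrix(c(5, 500, 20000), 1), lo = 20, hi = 16000)
#' @export
bound_expression <- function(data, lo = 20, hi = 16000) {
  if (lo >= hi) abort("`lo` must be strictly less than `hi`.")
  m <- as_expression_matrix(data, allow_na = TRUE)
  m[] <- pmin(pmax(m, lo), hi)
  if (is.data.frame(data)) expression_tbl(m) else m
}

#' Ratio/variation gene filter
#'
#' Keeps the genes whose expression actually moves across samples: a gene
#' survives iff its max/min ratio is at least `ratio_min` AND its absolute
#' variation (max minus min) is at least `variation_min`, both computed
#' across samples. Genes failing either threshold (flat or near-flat
#' profiles) are excluded. The matrix must be bounded below zero-free first
#' (see [bound_expression()]) so the ratio is well defined.
#'
#' @param data Expression data with strictly positive values.
#' @param ratio_min Minimum max/min ratio (default 5).
#' @param variation_min Minimum max - min variation (default 500).
#' @return A list with `data` (the filtered expression, same type as the
#'   input, gene order preserved and surviving values untouched) and
#'   `report`, a tibble with one row per input gene: `gene_id`, `max`,
#'   `min`, `ratio`, `variation`, `kept`. The report carries attributes
#'   `n_before` and `n_after`.
#' @export
filter_genes <- function(data, ratio_min = 5, variation_min = 500) {
  m <- as_expression_matrix(data)
  if (any(apply(m, 2, min) <= 0)) {
    abort("a gene has a zero (or negative) minimum; bound the matrix first so ratios are defined.")
  }
  mx <- apply(m, 2, max)
  mn <- apply(m, 2, min)
  report <- tibble(
    gene_id = colnames(m),
    max = unname(mx), min = unname(mn),
    ratio = unname(mx / mn),
    variation = unname(mx - mn),
    kept = unname(mx / mn >= ratio_min & mx - mn >= variation_min)
  )
  attr(report, "n_before") <- ncol(m)
  attr(report, "n_after") <- sum(report$kept)
  kept <- m[, report$kept, drop = FALSE]
  list(data = if (is.data.frame(data)) expression_tbl(kept) else kept,
       report = report)
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Replaces each missing entry by the average of the corresponding values of
#' the k genes nearest to the gene in question. Gene-to-gene distance is
#' Euclidean over the entries co-observed between the two genes, normalized
#' by the co-observed count (i.e. root mean squared difference), so genes
#' with different missingness patterns are comparable. A missing entry at
#' (sample i, gene g) is filled with the mean over the k nearest genes that
#' are observed at sample i; if fewer than k such genes exist, all available
#' ones are used.
#'
#' @param data Expression data possibly containing `NA` entries.
#' @param k Number of neighbouring genes to average (default 5).
#' @return Data of the same type as the input with no missing values;
#'   observed entries are untouched.
#' @export
knn_impute <- function(data, k = 5) {
  stopifnot(k >= 1)
  m <- as_expression_matrix(data, allow_na = TRUE)
  if (!anyNA(m)) {
    return(if (is.data.frame(data)) expression_tbl(m) else m)
  }
  if (any(colSums(!is.na(m)) == 0)) {
    abort("a gene has no observed values; it cannot be imputed from neighbours.")
  }
  out <- m
  need <- which(colSums(is.na(m)) > 0)
  for (g in need) {
    d <- gene_distances(m, g)
    miss_rows <- which(is.na(m[, g]))
    for (i in miss_rows) {
      cand <- which(!is.na(m[i, ]) & is.finite(d))
      if (length(cand) == 0) {
        abort("no gene shares observed entries with the gene being imputed.")
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, g] <- mean(m[i, nb])
    }
  }
  if (is.data.frame(data)) expression_tbl(out) else out
}

# RMS distance from gene g to every other gene over co-observed samples;
# Inf where no sample is co-observed (and to itself).
gene_distances <- function(m, g) {
  x <- m[, g]
  obs_x <- !is.na(x)
  d <- rep(Inf, ncol(m))
  for (h in seq_len(ncol(m))) {
    if (h == g) next
    both <- obs_x & !is.na(m[, h])
    n_co <- sum(both)
    if (n_co > 0) d[h] <- sqrt(sum((x[both] - m[both, h])^2) / n_co)
  }
  d
}
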