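#' Coerce expression data to a samples-by-genes matrix
#'
#' User-facing functions accept expression data either as a numeric matrix
#' (rows = samples, columns = genes) or as a data frame with a `sample_id`
#' column and one numeric column per gene. Non-numeric columns other than
#' `sample_id` (e.g. class annotations carried alongside) are dropped.
#'
#' @param data A numeric matrix or a data frame as described above.
#' @param allow_na Keep `NA` entries (the imputation path) instead of
#'   rejecting them.
#' @return A numeric matrix with `sample_id` rownames and gene colnames.
#' @examples
#' as_expression_matrix(generate_toy(seed = 1))[1:3, ]
#' @export
as_expression_matrix <- function(data, allow_na = FALSE) {
  if (is.data.frame(data)) {
    df <- as.data.frame(data)
    ids <- if ("sample_id" %in% names(df)) as.character(df$sample_id)
           else sprintf("sample_%d", seq_len(nrow(df)))
    num <- vapply(df, is.numeric, logical(1))
    num["sample_id"] <- FALSE
    if (!any(num)) abort("no numeric gene columns found in `data`.")
    m <- as.matrix(df[, num, drop = FALSE])
    rownames(m) <- ids
  } else if (is.matrix(data) && is.numeric(data)) {
    m <- data
    if (is.null(rownames(m))) rownames(m) <- sprintf("sample_%d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("gene_%d", seq_len(ncol(m)))
  } else {
    abort("`data` must be a numeric matrix or a data frame.")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate sample identifiers in `data`.")
  if (any(is.infinite(m))) abort("`data` contains non-finite values.")
  if (!allow_na && anyNA(m)) {
    abort("`data` contains missing values; impute first (see `knn_impute()`).")
  }
  if (any(m < 0, na.rm = TRUE)) abort("`data` contains negative values; expression input must be non-negative.")
  m
}

#' Convert a samples-by-genes matrix back to a tibble
#'
#' @param m A numeric matrix with sample rownames.
#' @return A tibble with a `sample_id` column followed by one column per gene.
#' @export
expression_tbl <- function(m) {
  stopifnot(is.matrix(m))
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

# Validates label input against the samples of `m` and returns the internal
# representation: integer assignment (NA = unlabeled) plus the ordered class
# vector. `labels` may be a vector aligned with rows of `m` (character/factor,
# NA or "UNLABELED" meaning unlabeled) or a data frame with columns
# sample_id/class covering a subset of samples.
resolve_labels <- function(m, labels, classes = NULL) {
  n <- nrow(m)
  if (is.null(labels)) {
    lab <- rep(NA_character_, n)
  } else if (is.data.frame(labels)) {
    if (!all(c("sample_id", "class") %in% names(labels))) {
      abort("label data frame needs `sample_id` and `class` columns.")
    }
    unknown <- setdiff(as.character(labels$sample_id), rownames(m))
    if (length(unknown) > 0) {
      abort(paste0("label file refers to unknown sample(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    dup <- labels[duplicated(labels$sample_id) | duplicated(labels$sample_id, fromLast = TRUE), ]
    if (nrow(dup) > 0 && any(tapply(as.character(dup$class), as.character(dup$sample_id),
                                    function(x) length(unique(x))) > 1)) {
      abort("a sample is listed with two different classes.")
    }
    lab <- rep(NA_character_, n)
    lab[match(as.character(labels$sample_id), rownames(m))] <- as.character(labels$class)
  } else {
    if (length(labels) != n) abort("`labels` must have one entry per sample.")
    lab <- as.character(labels)
  }
  lab[!is.na(lab) & toupper(lab) == "UNLABELED"] <- NA_character_
  if (is.null(classes)) {
    classes <- unique(lab[!is.na(lab)])   # first-appearance order
  } else if (!all(lab[!is.na(lab)] %in% classes)) {
    abort("`labels` contains classes not present in `classes`.")
  }
  list(assignment = match(lab, classes), classes = classes)
}

# One-hot indicator for the labeled block: d x r.
indicator_matrix <- function(assignment, r) {
  lab <- which(!is.na(assignment))
  Q <- matrix(0, length(lab), r)
  Q[cbind(seq_along(lab), assignment[lab])] <- 1
  Q
}
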