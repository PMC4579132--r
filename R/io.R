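#' Read an expression matrix from genes-in-rows TSV
#'
#' On disk the community convention is genes in rows: first column gene IDs,
#' header row of sample IDs, tab-separated, token `NA` (case-insensitive) or
#' an empty field marking a missing value. Internally the package works
#' samples-in-rows, so the reader owns the transpose — cell (gene g, sample
#' s) on disk becomes entry (s, g) in memory.
#'
#' @param path Path to the TSV file.
#' @return A numeric samples-by-genes matrix with sample rownames and gene
#'   colnames; `NA`s preserved for the imputation path.
#' @seealso [write_expression()], [knn_impute()]
#' @export
read_expression <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(readr::col_character(), .default = readr::col_double()),
    na = c("NA", "na", "Na", "nA", ""), progress = FALSE,
    name_repair = "minimal"
  ))
  if (ncol(df) < 2) abort("expression TSV needs a gene-ID column plus at least one sample.")
  probs <- readr::problems(df)
  if (nrow(probs) > 0) abort(paste0("malformed expression TSV: ", path))
  gene_ids <- as.character(df[[1]])
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) abort("duplicate sample IDs in header.")
  if (anyDuplicated(gene_ids)) abort("duplicate gene IDs in first column.")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(m) <- list(samples, gene_ids)
  if (any(m < 0, na.rm = TRUE)) abort("negative expression value on disk.")
  m
}

#' Write an expression matrix as genes-in-rows TSV
#'
#' @param data Expression data (matrix or data frame; see
#'   [as_expression_matrix()]).
#' @param path Output path. Values are written at 10 significant digits;
#'   missing entries as `NA`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  m <- as_expression_matrix(data, allow_na = TRUE)
  disk <- t(m)
  lines <- c(
    paste(c("gene_id", rownames(m)), collapse = "\t"),
    vapply(seq_len(nrow(disk)), function(i) {
      paste(c(rownames(disk)[i], format_num(disk[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 10, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Read a partial label table
#'
#' Two-column TSV (`sample_id`, `class`), no header required to match —
#' a header line `sample_id<TAB>class` is accepted and skipped. Samples
#' absent from the file, or labeled with the sentinel `UNLABELED`
#' (case-insensitive), are unlabeled. Class order is first-appearance order
#' in the file.
#'
#' @param path Path to the labels TSV.
#' @param sample_ids Optional character vector of valid sample IDs; listed
#'   samples must belong to it.
#' @return A tibble with columns `sample_id` and `class` (`NA` for the
#'   sentinel), carrying attribute `classes` with the class order.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- readr::read_tsv(path, col_names = c("sample_id", "class"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) > 0 && identical(tolower(unlist(df[1, ])), c("sample_id", "class"))) {
    df <- df[-1, , drop = FALSE]
  }
  df$class[!is.na(df$class) & toupper(df$class) == "UNLABELED"] <- NA_character_
  if (!is.null(sample_ids)) {
    unknown <- setdiff(df$sample_id, sample_ids)
    if (length(unknown) > 0) {
      abort(paste0("label file refers to unknown sample(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if (anyDuplicated(df$sample_id)) {
    conf <- tapply(df$class, df$sample_id, function(x) length(unique(x)))
    if (any(conf > 1)) abort("a sample is listed twice with different classes.")
    df <- df[!duplicated(df$sample_id), , drop = FALSE]
  }
  attr(df, "classes") <- unique(df$class[!is.na(df$class)])
  df
}

#' Write a label table
#'
#' @param labels A data frame with `sample_id` and `class` columns; `NA`
#'   classes are written as the sentinel `UNLABELED`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  cls <- ifelse(is.na(labels$class), "UNLABELED", as.character(labels$class))
  writeLines(paste(labels$sample_id, cls, sep = "\t"), path)
  invisible(path)
}
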