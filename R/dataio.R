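#' Read a gene-expression matrix from TSV/CSV
#'
#' Reads a normalized expression matrix (TPM/FPKM-like, nonnegative) with
#' gene identifiers in the first column and sample identifiers in the header
#' row. Genes are rows, samples are columns, everywhere in this package.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter. `NULL` (default) auto-detects from the
#'   file extension: `.tsv`/`.txt` read as tab, `.csv` as comma.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, validated by [validate_expression_matrix()].
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delimiter <- delimiter %||% detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty expression matrix in ", path)
  gene_ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop("non-numeric cell at row ", if (is.na(bad)) "?" else bad,
           ", column '", colnames(body)[j], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- gene_ids
  validate_expression_matrix(m)
}

#' Write an expression matrix as a delimited text file
#'
#' Inverse of [read_expression_matrix()]: header row of sample ids preceded
#' by a `gene_id` field, first column the gene ids.
#'
#' @param m Expression (or log-expression) matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @export
write_expression_matrix <- function(m, path, delimiter = NULL) {
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

detect_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric, nonnegative, unique gene and
#' sample ids, non-empty.
#'
#' @param m Matrix to validate.
#' @return The matrix, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene ids (rownames) and sample ids (colnames)")
  dup_g <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_g)) stop("duplicate gene id: ", dup_g[1L])
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s)) stop("duplicate sample id: ", dup_s[1L])
  if (anyNA(m) || any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value ", m[bad[1L], bad[2L]], " at gene '",
         rownames(m)[bad[1L]], "', sample '", colnames(m)[bad[2L]], "'")
  }
  m
}

#' Read a sample-metadata table
#'
#' Expects a delimited table with at least `sample_id` and `group` columns
#' (`group` in `normal`/`AML`); `patient_id` and `tissue` are optional.
#'
#' @param path Path to a TSV/CSV metadata table.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @return A `data.frame` with columns `sample_id`, `group`, `patient_id`,
#'   `tissue` (missing optional columns filled with `NA`).
#' @export
read_sample_table <- function(path, delimiter = NULL) {
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param meta A candidate metadata `data.frame`.
#' @export
validate_sample_table <- function(meta) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  bad <- setdiff(unique(meta$group), c("normal", "AML"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (is.null(meta$patient_id)) meta$patient_id <- NA_character_
  if (is.null(meta$tissue)) meta$tissue <- NA_character_
  meta$patient_id <- as.character(meta$patient_id)
  meta[, c("sample_id", "group", "patient_id", "tissue")]
}

#' Average duplicate samples of the same patient
#'
#' Samples sharing a `patient_id` are collapsed to a single column holding
#' their arithmetic mean; the collapsed column is labelled with the patient
#' id. Samples without a patient id (or with a unique one) pass through
#' unchanged. Column order follows the first occurrence of each output
#' sample. A patient whose samples carry different group labels is an error
#' (the collapsed sample's label would be ambiguous).
#'
#' @param m Expression matrix (genes x samples).
#' @param meta Sample table covering every column of `m`.
#' @return A list with `matrix` (collapsed expression matrix) and `meta`
#'   (matching collapsed sample table).
#' @export
collapse_duplicate_samples <- function(m, meta) {
  meta <- validate_sample_table(meta)
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  key <- ifelse(is.na(meta$patient_id) | meta$patient_id == "",
                meta$sample_id, meta$patient_id)
  keys <- unique(key)
  out <- matrix(0, nrow(m), length(keys),
                dimnames = list(rownames(m), keys))
  grp <- character(length(keys))
  for (i in seq_along(keys)) {
    idx <- which(key == keys[i])
    g <- unique(meta$group[idx])
    if (length(g) > 1L)
      stop("patient '", keys[i], "' has samples in different groups: ",
           paste(g, collapse = ", "))
    out[, i] <- rowMeans(m[, idx, drop = FALSE])
    grp[i] <- g
  }
  list(matrix = out,
       meta = data.frame(sample_id = keys, group = grp,
                         patient_id = keys, tissue = NA_character_,
                         stringsAsFactors = FALSE))
}

#' Natural-log transform with a pseudocount
#'
#' Returns `ln(x + pseudocount)` elementwise. The pseudocount is recorded as
#' an attribute so [exp_transform()] can invert the map exactly.
#'
#' @param m Nonnegative expression matrix.
#' @param pseudocount Positive value added before taking logs (default 1,
#'   which maps zeros to zero).
#' @return The log matrix with attribute `pseudocount`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  L <- log(m + pseudocount)
  attr(L, "pseudocount") <- pseudocount
  L
}

#' @rdname log_transform
#' @param L A log matrix produced by [log_transform()].
#' @export
exp_transform <- function(L, pseudocount = NULL) {
  pseudocount <- pseudocount %||% attr(L, "pseudocount")
  if (is.null(pseudocount)) stop("no pseudocount recorded on this matrix")
  m <- exp(L) - pseudocount
  attr(m, "pseudocount") <- NULL
  m
}

#' Write a run manifest
#'
#' Records the configuration of an analysis run (pseudocount, seeds,
#' thresholds, package version) as structured JSON next to the result
#' tables.
#'
#' @param path Output path for the manifest.
#' @param ... Named configuration entries to record.
#' @export
write_run_manifest <- function(path, ...) {
  manifest <- c(list(package = "passfec",
                     version = as.character(utils::packageVersion("passfec")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
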