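normalize_group <- function(g) {
  key <- gsub("[-_ ]", "", tolower(trimws(as.character(g))))
  out <- rep(NA_character_, length(key))
  out[key == "copd"] <- "copd"
  out[key == "noncopd"] <- "non_copd"
  if (anyNA(out)) {
    stop("unrecognized group label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "),
         " (expected COPD / non-COPD)")
  }
  out
}

#' Construct a per-cohort expression dataset
#'
#' Container for one cohort: a gene x sample matrix with COPD / non-COPD
#' group labels, a compartment label (whole lung tissue or small airway
#' epithelial cells) and a scale flag.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). All values must be finite; non-negative when
#'   `scale = "linear"`.
#' @param groups Per-sample labels, any spelling of COPD / non-COPD
#'   (case-insensitive, hyphen/underscore/space tolerant). Each group needs
#'   at least 2 samples.
#' @param dataset_id Cohort identifier (e.g. a GSE-style accession or a
#'   synthetic id).
#' @param compartment `"lung"` or `"saec"`.
#' @param scale `"log2"` or `"linear"`.
#' @param linear Optional linear-scale copy of `values` (kept internally when
#'   [ensure_log2()] transforms linear data, so ratio statistics can use
#'   exact linear means).
#' @return An `expression_dataset` (a list).
#' @export
expression_dataset <- function(values, groups, dataset_id,
                               compartment = c("lung", "saec"),
                               scale = c("log2", "linear"),
                               linear = NULL) {
  compartment <- match.arg(compartment)
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids after collapse")
  if (!all(is.finite(values))) stop("non-finite expression values")
  if (scale == "linear" && any(values < 0)) {
    stop("negative values are not allowed on the linear scale")
  }
  groups <- normalize_group(groups)
  if (length(groups) != ncol(values)) {
    stop("groups length must equal the number of samples")
  }
  cnt <- table(factor(groups, levels = c("non_copd", "copd")))
  if (any(cnt < 2L)) {
    stop("each group needs >= 2 samples (got non_copd=", cnt[["non_copd"]],
         ", copd=", cnt[["copd"]], ")")
  }
  structure(
    list(dataset_id = as.character(dataset_id), compartment = compartment,
         values = values, groups = groups, scale = scale, linear = linear),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset %s (%s, %s scale): %d genes x %d samples (%d non-COPD, %d COPD)\n",
    x$dataset_id, x$compartment, x$scale, nrow(x$values), ncol(x$values),
    sum(x$groups == "non_copd"), sum(x$groups == "copd")))
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has a header row of sample ids and gene symbols in the
#' first column; the metadata file maps `sample_id` to `group` (COPD /
#' non-COPD). Duplicate gene rows (multiple probes per symbol) are collapsed
#' to the row with the highest mean expression, a standard microarray
#' convention. Samples absent from the metadata are dropped with a warning
#' (or rejected when `strict = TRUE`).
#'
#' @param matrix_path Path to the genes x samples TSV.
#' @param metadata_path Path to the `sample_id<TAB>group` TSV.
#' @param dataset_id,compartment Passed to [expression_dataset()].
#' @param scale `"auto"` (matrix maximum > 50 implies linear, else log2),
#'   `"linear"` or `"log2"`.
#' @param strict If `TRUE`, a matrix sample with no metadata is an error.
#' @return An `expression_dataset`.
#' @export
read_expression_matrix <- function(matrix_path, metadata_path, dataset_id,
                                   compartment = c("lung", "saec"),
                                   scale = c("auto", "linear", "log2"),
                                   strict = FALSE) {
  compartment <- match.arg(compartment)
  scale <- match.arg(scale)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs a gene column and >= 1 sample")
  genes <- toupper(trimws(raw[[1L]]))
  sample_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s' (value '%s')",
                   genes[bad[1L]], sample_ids[j], col[bad[1L]]))
    }
    vals[, j] <- v
  }
  # collapse duplicate symbols: keep the row with the highest mean expression
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    ord <- order(factor(genes, levels = unique(genes)), -means)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)  # preserve first-occurrence gene order
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata needs columns sample_id and group")
  }
  grp <- stats::setNames(meta$group, meta$sample_id)
  missing_meta <- setdiff(sample_ids, names(grp))
  if (length(missing_meta)) {
    if (strict) {
      stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
    }
    warning("dropping ", length(missing_meta),
            " sample(s) without metadata: ",
            paste(missing_meta, collapse = ", "))
    vals <- vals[, setdiff(sample_ids, missing_meta), drop = FALSE]
  }
  groups <- unname(grp[colnames(vals)])
  if (scale == "auto") scale <- if (max(vals) > 50) "linear" else "log2"
  expression_dataset(vals, groups, dataset_id, compartment, scale)
}

#' Normalize an expression dataset to the log2 scale
#'
#' Linear-scale values become `log2(x + pseudocount)` and the linear copy is
#' retained internally for ratio statistics computed on linear means. A
#' dataset already on the log2 scale is returned unchanged, so the operation
#' is idempotent.
#'
#' @param ds An `expression_dataset`.
#' @param pseudocount Added before the log transform of linear data.
#' @return The dataset on the log2 scale.
#' @export
ensure_log2 <- function(ds, pseudocount = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale == "log2") return(ds)
  if (any(ds$values < 0)) stop("negative values cannot be log2 transformed")
  ds$linear <- ds$values
  ds$values <- log2(ds$values + pseudocount)
  ds$scale <- "log2"
  ds
}

# linear-scale view of the dataset: the retained linear copy when one exists,
# otherwise the back-transform of the log2 values
linear_values <- function(ds) {
  if (!is.null(ds$linear)) return(ds$linear)
  if (ds$scale == "linear") return(ds$values)
  2^ds$values
}

#' Write an expression dataset back to matrix + metadata TSV files
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param ds An `expression_dataset`.
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, `c(matrix_path, metadata_path)`.
#' @export
write_expression_dataset <- function(ds, matrix_path, metadata_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  chr <- matrix(sprintf("%.17g", ds$values), nrow(ds$values))
  out <- cbind(gene = rownames(ds$values), as.data.frame(chr))
  colnames(out) <- c("gene", colnames(ds$values))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(
    sample_id = colnames(ds$values),
    group = ifelse(ds$groups == "copd", "COPD", "non-COPD"),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}
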