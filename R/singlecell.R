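#' Construct a cell x gene expression table with population labels
#'
#' @param values Non-negative numeric matrix, cells in rows (rownames = cell
#'   ids), genes in columns (colnames = gene symbols). Counts or normalized
#'   values; only the positive support matters downstream.
#' @param populations Per-cell population label (e.g. `MCC`, `NDC`,
#'   `EC_other`, `non_epithelial`); non-empty strings, length `nrow(values)`.
#' @return A `cell_expression_table` (a list).
#' @export
cell_expression_table <- function(values, populations) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry cell rownames and gene colnames")
  }
  if (any(values < 0) || !all(is.finite(values))) {
    stop("expression values must be finite and non-negative")
  }
  populations <- as.character(populations)
  if (length(populations) != nrow(values)) {
    stop("populations must label every cell")
  }
  if (any(is.na(populations) | !nzchar(populations))) {
    stop("population labels must be non-empty strings")
  }
  structure(list(values = values, populations = populations),
            class = "cell_expression_table")
}

#' @export
print.cell_expression_table <- function(x, ...) {
  tab <- table(x$populations)
  cat(sprintf("cell_expression_table: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Fraction of cells expressing a gene, overall and per population
#'
#' A cell "expresses" the gene when its value exceeds `min_value`
#' (default 0, i.e. any positive signal counts).
#'
#' @param tab A `cell_expression_table`.
#' @param gene Gene symbol present in the table.
#' @param min_value Expression threshold; strictly-greater comparison.
#' @return List with `frac_overall` and `frac_by_population` (named numeric).
#' @export
fraction_expressing <- function(tab, gene, min_value = 0) {
  stopifnot(inherits(tab, "cell_expression_table"), length(gene) == 1L)
  if (!gene %in% colnames(tab$values)) {
    stop("gene not present in table: ", gene)
  }
  expr <- tab$values[, gene] > min_value
  by_pop <- tapply(expr, tab$populations, mean)
  list(
    frac_overall = mean(expr),
    frac_by_population = stats::setNames(as.numeric(by_pop), names(by_pop))
  )
}

#' Bin a fraction of expressing cells into low / intermediate / high
#'
#' `"+"` (low) below 25%, `"++"` (intermediate) from 25% to 50% inclusive,
#' `"+++"` (high) above 50%. The closed 25-50% interval takes both
#' boundaries, its neighbours being open-ended.
#'
#' @param frac Numeric vector of fractions in `[0, 1]`.
#' @return Character vector of bins.
#' @examples
#' bin_fraction(c(0.24, 0.25, 0.5, 0.51))
#' @export
bin_fraction <- function(frac) {
  stopifnot(is.numeric(frac))
  if (anyNA(frac) || any(frac < 0) || any(frac > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  ifelse(frac < 0.25, "+", ifelse(frac <= 0.50, "++", "+++"))
}

#' Principal expressing cell population
#'
#' The population with the highest fraction of expressing cells is reported
#' as principal when its fraction is at least `dominance_ratio` times the
#' pooled fraction of expressing cells across all other populations;
#' otherwise expression is called broad (`"All"`). `EC_other` is reported
#' under the published label `"EC"`.
#'
#' @param frac_by_population Named numeric vector of per-population
#'   fractions (>= 2 populations).
#' @param dominance_ratio Dominance threshold (default 1.5).
#' @param weights Optional named population sizes used to pool the
#'   non-leading fractions; equal weights when omitted.
#' @return A population label or `"All"`.
#' @export
principal_population <- function(frac_by_population, dominance_ratio = 1.5,
                                 weights = NULL) {
  f <- frac_by_population
  stopifnot(is.numeric(f), length(f) >= 2L, !is.null(names(f)))
  if (anyNA(f) || any(f < 0) || any(f > 1)) stop("fractions must lie in [0, 1]")
  if (all(f == 0)) {
    warning("all population fractions are zero; principal population undefined")
    return("All")
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(f)), names(f))
  }
  weights <- weights[names(f)]
  top <- which.max(f)
  pooled <- sum(f[-top] * weights[-top]) / sum(weights[-top])
  if (f[top] >= dominance_ratio * pooled) {
    lab <- names(f)[top]
    if (lab == "EC_other") "EC" else lab
  } else {
    "All"
  }
}

#' Annotate genes with single-cell expression summaries
#'
#' For each requested gene: overall and per-population fractions of
#' expressing cells, the low/intermediate/high bin of the overall fraction,
#' and the principal expressing population.
#'
#' @param tab A `cell_expression_table`.
#' @param genes Genes to annotate (default: every gene in the table).
#' @param min_value Expression threshold, see [fraction_expressing()].
#' @param dominance_ratio See [principal_population()].
#' @return `data.frame` with columns `gene`, `frac_overall`, one
#'   `frac_<population>` column per population, `bin`, `principal`.
#' @export
annotate_single_cell <- function(tab, genes = NULL, min_value = 0,
                                 dominance_ratio = 1.5) {
  stopifnot(inherits(tab, "cell_expression_table"))
  genes <- genes %||% colnames(tab$values)
  missing <- setdiff(genes, colnames(tab$values))
  if (length(missing)) {
    stop("gene(s) absent from table: ", paste(missing, collapse = ", "))
  }
  pops <- sort_c(unique(tab$populations))
  sizes <- stats::setNames(
    vapply(pops, function(p) sum(tab$populations == p), numeric(1)), pops)
  rows <- lapply(genes, function(g) {
    fr <- fraction_expressing(tab, g, min_value = min_value)
    by_pop <- fr$frac_by_population[pops]
    row <- data.frame(gene = g, frac_overall = fr$frac_overall,
                      stringsAsFactors = FALSE)
    for (p in pops) row[[paste0("frac_", p)]] <- unname(by_pop[p])
    row$bin <- bin_fraction(fr$frac_overall)
    row$principal <- principal_population(by_pop, dominance_ratio,
                                          weights = sizes)
    row
  })
  do.call(rbind, rows)
}
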