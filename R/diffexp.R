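#' Two-group t test (Welch or Student), computed from first principles
#'
#' Two-sided two-sample t test of `mean(x) - mean(y)`. The Welch variant uses
#' the Welch-Satterthwaite degrees of freedom; the Student variant pools the
#' variances. Degenerate inputs follow fixed conventions: two constant groups
#' with equal values give `t = 0, p = 1`; two constant groups with unequal
#' values give `p = 0` with a warning.
#'
#' @param x,y Numeric sample vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return List with elements `t`, `df`, `p`.
#' @examples
#' two_group_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
two_group_t_test <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations")
  }
  res <- .row_t(matrix(x, nrow = 1L), matrix(y, nrow = 1L), variant)
  list(t = res$t, df = res$df, p = res$p)
}

# vectorized core: one test per row of the two matrices
.row_t <- function(xmat, ymat, variant = "welch") {
  nx <- ncol(xmat)
  ny <- ncol(ymat)
  mx <- rowMeans(xmat)
  my <- rowMeans(ymat)
  vx <- rowSums((xmat - mx)^2) / (nx - 1L)
  vy <- rowSums((ymat - my)^2) / (ny - 1L)
  if (variant == "welch") {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  } else {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep(nx + ny - 2L, length(mx))
  }
  t <- (mx - my) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (mx == my)
    t[eq] <- 0
    df[eq] <- nx + ny - 2L
    p[eq] <- 1
    ne <- degen & (mx != my)
    if (any(ne)) {
      warning(sum(ne), " test(s) with zero variance and unequal means; p set to 0")
      t[ne] <- sign(mx[ne] - my[ne]) * Inf
      df[ne] <- nx + ny - 2L
      p[ne] <- 0
    }
  }
  data.frame(t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Computes q-values by the step-up rule
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, and returns them in the
#' input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `pvals`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (length(pvals) == 0L) return(numeric())
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  # guard the q >= p invariant against 1-ulp rounding in p * m / j
  pmax(out, pvals)
}

#' Per-dataset COPD vs non-COPD differential expression over a geneset
#'
#' Tests every gene in the intersection of the geneset and the dataset's gene
#' list on the log2 scale (COPD minus non-COPD), applies the
#' Benjamini-Hochberg adjustment over exactly that tested set, and reports
#' both the log2 fold change and the dot-plot log10 ratio
#' `log10(mean_linear(non-COPD) / mean_linear(COPD))`, which runs in the
#' opposite orientation.
#'
#' @param ds An `expression_dataset`; linear-scale data are log2 transformed
#'   first via [ensure_log2()].
#' @param geneset A non-empty `gene_set`.
#' @param alpha Significance threshold (default 0.05).
#' @param sig_rule `"raw_p"` (default; significant iff `p < alpha`) or
#'   `"fdr_q"` (significant iff `q < alpha`).
#' @param variant t-test variant, see [two_group_t_test()].
#' @return A `dataset_de_result`: list with `dataset_id`, `compartment`,
#'   `table` (one row per tested gene: `gene`, `log2fc`, `log10_ratio`, `t`,
#'   `df`, `p`, `q`, `significant`, `n_copd`, `n_noncopd`), `n_tested`,
#'   `n_significant`, `alpha`, `sig_rule`.
#' @export
run_diffexp <- function(ds, geneset, alpha = 0.05,
                        sig_rule = c("raw_p", "fdr_q"),
                        variant = c("welch", "student")) {
  sig_rule <- match.arg(sig_rule)
  variant <- match.arg(variant)
  stopifnot(inherits(ds, "expression_dataset"), inherits(geneset, "gene_set"))
  if (nrow(geneset) == 0L) stop("geneset is empty")
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  ds <- ensure_log2(ds)
  genes <- sort_c(intersect(rownames(ds$values), geneset$symbol))
  if (length(genes) == 0L) {
    stop("no geneset gene is present in dataset ", ds$dataset_id)
  }
  is_copd <- ds$groups == "copd"
  xmat <- ds$values[genes, is_copd, drop = FALSE]
  ymat <- ds$values[genes, !is_copd, drop = FALSE]
  tt <- .row_t(xmat, ymat, variant)
  lin <- linear_values(ds)[genes, , drop = FALSE]
  mean_lin_copd <- rowMeans(lin[, is_copd, drop = FALSE])
  mean_lin_non <- rowMeans(lin[, !is_copd, drop = FALSE])
  log10_ratio <- log10(mean_lin_non / mean_lin_copd)
  q <- bh_fdr(tt$p)
  significant <- if (sig_rule == "raw_p") tt$p < alpha else q < alpha
  tab <- data.frame(
    gene = genes,
    log2fc = rowMeans(xmat) - rowMeans(ymat),
    log10_ratio = log10_ratio,
    t = tt$t, df = tt$df, p = tt$p, q = q,
    significant = significant,
    n_copd = sum(is_copd), n_noncopd = sum(!is_copd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(dataset_id = ds$dataset_id, compartment = ds$compartment,
         table = tab, n_tested = nrow(tab),
         n_significant = sum(tab$significant),
         alpha = alpha, sig_rule = sig_rule),
    class = "dataset_de_result"
  )
}

#' @export
print.dataset_de_result <- function(x, ...) {
  cat(sprintf(
    "dataset_de_result %s (%s): %d/%d genes significant (%s < %g)\n",
    x$dataset_id, x$compartment, x$n_significant, x$n_tested,
    if (x$sig_rule == "raw_p") "p" else "q", x$alpha))
  invisible(x)
}

#' Genes called significant in a differential-expression result
#'
#' @param de A `dataset_de_result`.
#' @return Character vector of significant gene symbols, sorted.
#' @export
significant_genes <- function(de) {
  stopifnot(inherits(de, "dataset_de_result"))
  sort_c(de$table$gene[de$table$significant])
}

#' Named list of significant-gene sets from several DE results
#'
#' @param de_list List of `dataset_de_result` objects.
#' @return Named list (dataset_id -> character vector) suitable for
#'   [tier_summary()].
#' @export
significance_sets <- function(de_list) {
  stats::setNames(lapply(de_list, significant_genes),
                  vapply(de_list, function(d) d$dataset_id, character(1)))
}

#' Write a per-dataset differential expression table as TSV
#'
#' @param de A `dataset_de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "dataset_de_result"))
  utils::write.table(de$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
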