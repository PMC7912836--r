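#' Percentage of a geneset, half-up rounded
#'
#' @param count Number of genes (0 <= count <= geneset_size).
#' @param geneset_size Size of the reference geneset (> 0).
#' @param decimals Decimal places of the half-up rounding (0 or 1 in the
#'   study's printed formats; up to 6 accepted).
#' @return `100 * count / geneset_size`, rounded half-up.
#' @examples
#' percent_of_geneset(100, 350)      # 29
#' percent_of_geneset(10, 399, 1)    # 2.5
#' @export
percent_of_geneset <- function(count, geneset_size, decimals = 0) {
  stopifnot(length(count) == 1L, length(geneset_size) == 1L,
            is.numeric(count), is.numeric(geneset_size))
  if (geneset_size <= 0) stop("geneset_size must be positive")
  if (count < 0 || count > geneset_size) {
    stop("count must lie between 0 and geneset_size")
  }
  if (!decimals %in% 0:6) stop("decimals must be between 0 and 6")
  round_half_up(100 * count / geneset_size, decimals)
}

#' Cross-dataset concordance tiers and Venn partition
#'
#' Combines per-dataset significant-gene sets of one compartment into (i) a
#' per-gene membership map, (ii) tier counts (number of genes significant in
#' at least k datasets, k = 1..n), (iii) the Venn partition (number of genes
#' significant in exactly each non-empty subset of datasets) and, when the
#' compartment geneset size is supplied, (iv) tier percentages of the
#' geneset.
#'
#' @param sig_sets Named list: dataset_id -> character vector of significant
#'   genes (see [significance_sets()]).
#' @param geneset_size Optional size of the compartment geneset, the
#'   denominator for percentages.
#' @param compartment Optional compartment label carried in the result.
#' @param decimals Decimal places for the percentages.
#' @return A `tier_summary`: list with `compartment`, `dataset_ids`,
#'   `membership` (gene -> sorted dataset ids), `tier_counts` (named by k),
#'   `venn` (named by "&"-joined sorted dataset-id tuples), `geneset_size`,
#'   `percentages`.
#' @examples
#' tier_summary(list(D1 = c("A", "B", "C"), D2 = c("B", "C"), D3 = "C"))
#' @export
tier_summary <- function(sig_sets, geneset_size = NULL, compartment = NULL,
                         decimals = 0) {
  stopifnot(is.list(sig_sets), length(sig_sets) >= 1L)
  ids <- names(sig_sets)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("sig_sets must be uniquely named by dataset id")
  }
  genes <- sort_c(unique(unlist(sig_sets, use.names = FALSE)))
  membership <- lapply(genes, function(g) {
    sort_c(ids[vapply(sig_sets, function(s) g %in% s, logical(1))])
  })
  names(membership) <- genes
  counts <- lengths(membership)
  n <- length(ids)
  tier_counts <- stats::setNames(
    vapply(seq_len(n), function(k) sum(counts >= k), integer(1)),
    as.character(seq_len(n))
  )
  venn <- stats::setNames(integer(), character())
  if (length(membership)) {
    keys <- vapply(membership, paste, character(1), collapse = "&")
    venn_tab <- table(keys)
    venn <- stats::setNames(as.integer(venn_tab), names(venn_tab))
    venn <- venn[sort_c(names(venn))]
  }
  percentages <- NULL
  if (!is.null(geneset_size)) {
    percentages <- stats::setNames(
      vapply(tier_counts, percent_of_geneset, numeric(1),
             geneset_size = geneset_size, decimals = decimals),
      names(tier_counts)
    )
  }
  structure(
    list(compartment = compartment, dataset_ids = ids,
         membership = membership, tier_counts = tier_counts, venn = venn,
         geneset_size = geneset_size, percentages = percentages),
    class = "tier_summary"
  )
}

#' @export
print.tier_summary <- function(x, ...) {
  cat(sprintf("tier_summary (%s): %d datasets, %d genes significant somewhere\n",
              x$compartment %||% "unspecified compartment",
              length(x$dataset_ids), length(x$membership)))
  for (k in names(x$tier_counts)) {
    cat(sprintf("  >= %s dataset(s): %d%s\n", k, x$tier_counts[[k]],
                if (!is.null(x$percentages)) {
                  sprintf(" (%s%% of geneset)", x$percentages[[k]])
                } else ""))
  }
  invisible(x)
}

#' Genes significant in at least `min_datasets` datasets of a tier summary
#'
#' @param ts A `tier_summary`.
#' @param min_datasets Tier threshold k.
#' @return Sorted character vector of gene symbols.
#' @export
tier_genes <- function(ts, min_datasets = 1L) {
  stopifnot(inherits(ts, "tier_summary"), min_datasets >= 1L)
  sort_c(names(ts$membership)[lengths(ts$membership) >= min_datasets])
}

#' Cross-compartment concordant hits
#'
#' Genes significant in at least `lung_min` whole-lung datasets AND at least
#' `saec_min` SAEC datasets, together with the union of genes deregulated
#' anywhere and the ciliopathy-flagged subsets of both.
#'
#' @param lung,saec `tier_summary` objects for the two compartments.
#' @param lung_min,saec_min Per-compartment tier thresholds (defaults 2
#'   and 1).
#' @param geneset Optional `gene_set` supplying the `is_ciliopathy` flags.
#' @return A `cross_compartment_result`: list with `hits`,
#'   `ciliopathy_hits`, `union_deregulated`, `ciliopathy_union` (the last two
#'   over genes significant in >= 1 dataset of either compartment).
#' @export
cross_compartment_hits <- function(lung, saec, lung_min = 2L, saec_min = 1L,
                                   geneset = NULL) {
  stopifnot(inherits(lung, "tier_summary"), inherits(saec, "tier_summary"),
            lung_min >= 1L, saec_min >= 1L)
  if (!is.null(lung$compartment) && lung$compartment != "lung") {
    stop("first tier summary must be the lung compartment")
  }
  if (!is.null(saec$compartment) && saec$compartment != "saec") {
    stop("second tier summary must be the saec compartment")
  }
  hits <- sort_c(intersect(tier_genes(lung, lung_min),
                           tier_genes(saec, saec_min)))
  union_dereg <- sort_c(union(tier_genes(lung, 1L), tier_genes(saec, 1L)))
  cilio <- character()
  if (!is.null(geneset)) {
    stopifnot(inherits(geneset, "gene_set"))
    cilio <- geneset$symbol[geneset$is_ciliopathy]
  }
  structure(
    list(hits = hits,
         ciliopathy_hits = sort_c(intersect(hits, cilio)),
         union_deregulated = union_dereg,
         ciliopathy_union = sort_c(intersect(union_dereg, cilio)),
         lung_min = lung_min, saec_min = saec_min),
    class = "cross_compartment_result"
  )
}

#' @export
print.cross_compartment_result <- function(x, ...) {
  cat(sprintf(
    "cross_compartment_result: %d hits (>= %d lung & >= %d SAEC datasets), %d ciliopathy-flagged\n",
    length(x$hits), x$lung_min, x$saec_min, length(x$ciliopathy_hits)))
  invisible(x)
}

#' Table of the main commonly deregulated genes across compartments
#'
#' Lists every gene significant in at least `lung_min` lung datasets or at
#' least `saec_min` SAEC datasets, with one log2 fold-change column per
#' dataset (blank unless the gene was significant there, mirroring the
#' published table layout) and a `fully_concordant` flag for genes
#' significant in every dataset of their compartment.
#'
#' @param lung,saec `tier_summary` objects.
#' @param de_list List of `dataset_de_result` covering all datasets named in
#'   the two summaries.
#' @param lung_min,saec_min Inclusion thresholds (defaults 3 and 2).
#' @return `data.frame` with columns `gene`, `compartment`, one numeric
#'   column per dataset id, and `fully_concordant`; rows ordered lung genes
#'   first, lexicographic within compartment.
#' @export
common_gene_table <- function(lung, saec, de_list, lung_min = 3L,
                              saec_min = 2L) {
  stopifnot(inherits(lung, "tier_summary"), inherits(saec, "tier_summary"))
  de_ids <- vapply(de_list, function(d) d$dataset_id, character(1))
  all_ids <- c(lung$dataset_ids, saec$dataset_ids)
  missing <- setdiff(all_ids, de_ids)
  if (length(missing)) {
    stop("DE results missing for dataset(s): ", paste(missing, collapse = ", "))
  }
  lung_genes <- tier_genes(lung, lung_min)
  saec_genes <- tier_genes(saec, saec_min)
  genes <- c(lung_genes, sort_c(setdiff(saec_genes, lung_genes)))
  comp <- ifelse(genes %in% lung_genes & genes %in% saec_genes, "lung;saec",
                 ifelse(genes %in% lung_genes, "lung", "saec"))
  out <- data.frame(gene = genes, compartment = comp,
                    stringsAsFactors = FALSE)
  for (id in all_ids) {
    de <- de_list[[match(id, de_ids)]]
    fc <- stats::setNames(de$table$log2fc, de$table$gene)
    sig <- stats::setNames(de$table$significant, de$table$gene)
    col <- rep(NA_real_, length(genes))
    hit <- genes %in% names(fc)
    show <- hit & !is.na(sig[genes]) & sig[genes]
    col[show] <- fc[genes[show]]
    out[[id]] <- col
  }
  full <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    in_lung <- g %in% lung_genes &&
      length(lung$membership[[g]]) == length(lung$dataset_ids)
    in_saec <- g %in% saec_genes &&
      length(saec$membership[[g]]) == length(saec$dataset_ids)
    full[i] <- in_lung || in_saec
  }
  out$fully_concordant <- full
  out
}

#' Write tier-summary outputs
#'
#' `write_tier_table()` emits one row per deregulated gene (`gene`,
#' `compartment`, `n_datasets`, `datasets`); `write_venn_json()` emits the
#' Venn region counts keyed by "&"-joined sorted dataset-id tuples.
#'
#' @param ts A `tier_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tier_table <- function(ts, path) {
  stopifnot(inherits(ts, "tier_summary"))
  out <- data.frame(
    gene = names(ts$membership) %||% character(),
    compartment = rep(ts$compartment %||% NA_character_,
                      length(ts$membership)),
    n_datasets = unname(lengths(ts$membership)),
    datasets = vapply(ts$membership, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tier_table
#' @export
write_venn_json <- function(ts, path) {
  stopifnot(inherits(ts, "tier_summary"))
  jsonlite::write_json(as.list(ts$venn), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
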