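#' Write a simulated study to disk as pipeline-ready files
#'
#' Emits the labelled geneset source TSV, one matrix + metadata TSV pair per
#' cohort, a truth JSON, and a `manifest.yaml` that [run_pipeline()] can
#' consume directly.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param alpha,sig_rule Analysis settings recorded in the manifest.
#' @return Path to the manifest file, invisibly.
#' @export
write_study <- function(study, dir, alpha = 0.05, sig_rule = "raw_p") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src_rows <- do.call(rbind, lapply(names(study$source_lists), function(lab) {
    x <- study$source_lists[[lab]]
    data.frame(source = lab, symbol = x$symbol, accession = x$accession,
               name = x$name, stringsAsFactors = FALSE)
  }))
  src_path <- file.path(dir, "geneset_sources.tsv")
  utils::write.table(src_rows, src_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  datasets <- c(study$lung$datasets, study$saec$datasets)
  entries <- lapply(datasets, function(ds) {
    m <- paste0(ds$dataset_id, "_matrix.tsv")
    md <- paste0(ds$dataset_id, "_metadata.tsv")
    write_expression_dataset(ds, file.path(dir, m), file.path(dir, md))
    list(dataset_id = ds$dataset_id, compartment = ds$compartment,
         matrix = m, metadata = md, scale = ds$scale)
  })
  jsonlite::write_json(
    list(lung_de_genes = study$lung$truth$de_genes,
         saec_de_genes = study$saec$truth$de_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest <- list(
    geneset = list(sources = "geneset_sources.tsv",
                   ciliopathy_sources = as.list(study$ciliopathy_sources)),
    datasets = entries,
    alpha = alpha,
    sig_rule = sig_rule
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

stage_call <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    try(file.create(file.path(out_dir, "FAILED")), silent = TRUE)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full curation / validation / DE / concordance pipeline
#'
#' Orchestrates geneset curation, dataset loading and validation,
#' per-dataset differential expression, per-compartment concordance tiers
#' and Venn partitions, cross-compartment hit calling, the common-gene
#' table, and (when single-cell inputs are configured) single-cell
#' annotation. All stage outputs are written under `out_dir` together with a
#' machine-readable `report.json`; reruns with identical inputs produce
#' byte-identical reports. A failing stage aborts with a stage-labelled
#' error and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config Path to a manifest YAML (as produced by [write_study()]) or
#'   an equivalent list. Recognized fields: `geneset` (`sources` TSV path
#'   and `ciliopathy_sources`), `datasets` (list of `dataset_id`,
#'   `compartment`, `matrix`, `metadata`, optional `scale`), `alpha`,
#'   `sig_rule`, `lung_min`/`saec_min` (common-table thresholds, defaults 3
#'   and 2), `cross_lung_min`/`cross_saec_min` (defaults 2 and 1),
#'   `lung_decimals`/`saec_decimals` (tier percentage formats, defaults 0
#'   and 1), optional `singlecell` (`matrix` and `cells` TSV paths).
#' @param out_dir Output directory; may also be given as `config$out_dir`.
#' @return The report, invisibly (also serialized to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rel <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  alpha <- config$alpha %||% 0.05
  sig_rule <- config$sig_rule %||% "raw_p"

  gs <- stage_call("curate", out_dir, {
    g <- config$geneset
    if (is.null(g)) stop("manifest has no geneset entry")
    sl <- read_source_lists(rel(g$sources))
    out <- merge_gene_sources(
      sl, ciliopathy_sources = unlist(g$ciliopathy_sources %||%
                                        "uniprot_ciliopathy"))
    write_geneset(out, file.path(out_dir, "geneset_merged.tsv"))
    jsonlite::write_json(geneset_summary(out),
                         file.path(out_dir, "geneset_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out
  })

  datasets <- stage_call("validate", out_dir, {
    if (length(config$datasets) == 0L) stop("manifest lists no datasets")
    lapply(config$datasets, function(e) {
      read_expression_matrix(rel(e$matrix), rel(e$metadata), e$dataset_id,
                             e$compartment, scale = e$scale %||% "auto")
    })
  })

  de_list <- stage_call("diffexp", out_dir, {
    lapply(datasets, function(ds) {
      de <- run_diffexp(ds, gs, alpha = alpha, sig_rule = sig_rule)
      write_de_table(de, file.path(out_dir,
                                   paste0("de_", ds$dataset_id, ".tsv")))
      de
    })
  })

  comps <- vapply(datasets, function(d) d$compartment, character(1))
  tiers <- list()
  comp_gs <- list()
  report_comp <- list()
  for (cp in c("lung", "saec")) {
    idx <- which(comps == cp)
    if (!length(idx)) next
    cg <- compartment_geneset(gs, datasets[idx])
    dec <- config[[paste0(cp, "_decimals")]] %||%
      (if (cp == "lung") 0L else 1L)
    ts <- stage_call("concord", out_dir, {
      tier_summary(significance_sets(de_list[idx]), geneset_size = nrow(cg),
                   compartment = cp, decimals = dec)
    })
    write_tier_table(ts, file.path(out_dir, paste0("tiers_", cp, ".tsv")))
    write_venn_json(ts, file.path(out_dir, paste0("venn_", cp, ".json")))
    tiers[[cp]] <- ts
    comp_gs[[cp]] <- cg
    report_comp[[cp]] <- list(
      geneset_size = nrow(cg),
      tier_counts = as.list(ts$tier_counts),
      percentages = as.list(ts$percentages),
      venn = as.list(ts$venn)
    )
  }

  cross <- NULL
  common <- NULL
  if (!is.null(tiers$lung) && !is.null(tiers$saec)) {
    cross <- stage_call("concord", out_dir, {
      cross_compartment_hits(tiers$lung, tiers$saec,
                             lung_min = config$cross_lung_min %||% 2L,
                             saec_min = config$cross_saec_min %||% 1L,
                             geneset = gs)
    })
    utils::write.table(
      data.frame(gene = cross$hits,
                 is_ciliopathy = as.integer(cross$hits %in%
                                              cross$ciliopathy_hits)),
      file.path(out_dir, "cross_compartment_hits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    common <- stage_call("concord", out_dir, {
      common_gene_table(tiers$lung, tiers$saec, de_list,
                        lung_min = config$lung_min %||% 3L,
                        saec_min = config$saec_min %||% 2L)
    })
    utils::write.table(common, file.path(out_dir, "common_gene_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sc_annot <- NULL
  if (!is.null(config$singlecell)) {
    sc_annot <- stage_call("scbin", out_dir, {
      sc <- config$singlecell
      mat <- as.matrix(utils::read.delim(rel(sc$matrix), row.names = 1,
                                         check.names = FALSE))
      cells <- utils::read.delim(rel(sc$cells), stringsAsFactors = FALSE)
      tab <- cell_expression_table(mat, cells$population[
        match(rownames(mat), cells$cell_id)])
      ann <- annotate_single_cell(tab, genes = intersect(colnames(mat),
                                                         gs$symbol))
      utils::write.table(ann, file.path(out_dir, "singlecell_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ann
    })
  }

  sig6 <- function(x) signif(x, 6)
  n_cilio <- sum(gs$is_ciliopathy)
  report <- list(
    schema_version = "1.0",
    alpha = alpha,
    sig_rule = sig_rule,
    geneset = geneset_summary(gs),
    datasets = lapply(de_list, function(de) {
      list(dataset_id = de$dataset_id, compartment = de$compartment,
           n_tested = de$n_tested, n_significant = de$n_significant,
           pct_significant = percent_of_geneset(de$n_significant,
                                                de$n_tested, 1))
    }),
    compartments = report_comp,
    cross_compartment = if (!is.null(cross)) list(
      n_hits = length(cross$hits),
      hits = cross$hits,
      n_ciliopathy_hits = length(cross$ciliopathy_hits),
      pct_ciliopathy_hits = if (n_cilio > 0) {
        percent_of_geneset(length(cross$ciliopathy_hits), n_cilio, 0)
      },
      n_union_deregulated = length(cross$union_deregulated),
      n_ciliopathy_union = length(cross$ciliopathy_union),
      pct_ciliopathy_union = if (n_cilio > 0) {
        percent_of_geneset(length(cross$ciliopathy_union), n_cilio, 0)
      }
    ),
    common_gene_table_rows = if (!is.null(common)) nrow(common),
    singlecell = if (!is.null(sc_annot)) list(
      n_genes = nrow(sc_annot),
      bins = as.list(table(sc_annot$bin))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 6)
  invisible(report)
}
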