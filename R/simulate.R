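#' Configuration for the synthetic multi-cohort study generator
#'
#' Encodes the emulated study design: 4 whole-lung cohorts totalling 238
#' non-COPD and 391 COPD subjects, 3 SAEC cohorts totalling 300 non-COPD and
#' 117 COPD subjects, and a 495-gene cilia geneset of which 189 genes are
#' ciliopathy-flagged. Effects are planted on a random subset of genes with
#' per-dataset activity (concordance) probability `rho`, and genes drop out
#' of individual datasets with probability `dropout` to emulate platform
#' coverage differences.
#'
#' @param seed Integer seed governing every draw.
#' @param lung_datasets,saec_datasets Lists of `c(n_noncopd, n_copd)` per
#'   cohort; defaults split the compartment totals evenly.
#' @param n_genes,n_ciliopathy,n_cilia Geneset structure: total unique
#'   genes, ciliopathy-flagged genes, and cilia-list size (the overlap
#'   `n_cilia + n_ciliopathy - n_genes` must be non-negative).
#' @param frac_de Fraction of genes planted differential.
#' @param delta Planted effect size, log2 units.
#' @param sigma_range Per-gene noise s.d. drawn uniformly from this interval.
#' @param baseline_mean,baseline_sd Log2 baseline expression distribution.
#' @param rho Probability that a planted gene is active in a given dataset.
#' @param dropout Per-gene per-dataset probability of absence.
#' @return A `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       lung_datasets = list(c(60, 98), c(60, 98),
                                            c(59, 98), c(59, 97)),
                       saec_datasets = list(c(100, 39), c(100, 39),
                                            c(100, 39)),
                       n_genes = 495L, n_ciliopathy = 189L, n_cilia = 447L,
                       frac_de = 0.25, delta = 0.4,
                       sigma_range = c(0.3, 1.0),
                       baseline_mean = 7, baseline_sd = 2,
                       rho = 0.5, dropout = 0.1) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    length(lung_datasets) >= 1L, length(saec_datasets) >= 1L,
    all(vapply(c(lung_datasets, saec_datasets), length, integer(1)) == 2L),
    n_ciliopathy <= n_genes, n_cilia <= n_genes,
    n_cilia + n_ciliopathy >= n_genes,
    frac_de >= 0, frac_de <= 1, rho >= 0, rho <= 1,
    dropout >= 0, dropout <= 1,
    length(sigma_range) == 2L, all(sigma_range > 0),
    sigma_range[1] <= sigma_range[2], baseline_sd >= 0, delta >= 0
  )
  sizes <- unlist(c(lung_datasets, saec_datasets))
  if (any(sizes < 2L)) stop("every simulated group needs >= 2 samples")
  structure(
    list(seed = as.integer(seed), lung_datasets = lung_datasets,
         saec_datasets = saec_datasets, n_genes = as.integer(n_genes),
         n_ciliopathy = as.integer(n_ciliopathy),
         n_cilia = as.integer(n_cilia), frac_de = frac_de, delta = delta,
         sigma_range = sigma_range, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, rho = rho, dropout = dropout),
    class = "sim_config"
  )
}

sim_gene_universe <- function(n_genes) sprintf("GENE%04d", seq_len(n_genes))

#' Generate synthetic labelled source lists for the geneset curation stage
#'
#' Builds per-source gene lists over a synthetic gene universe so that the
#' merged geneset has exactly `n_genes` unique symbols of which
#' `n_ciliopathy` are ciliopathy-flagged and `n_cilia` appear in the cilia
#' list (overlap by inclusion-exclusion). The UniProt ciliopathy query
#' contributes 90% of the ciliopathy genes (171 of 189 at the default
#' sizes); the synthetic 100,000 Genomes list completes the remainder and is
#' therefore ciliopathy-labelled too. The four compiled libraries resample
#' cilia-list genes to give records multi-source provenance.
#'
#' @param n_genes,n_ciliopathy,n_cilia Geneset structure, as in
#'   [sim_config()].
#' @param seed Integer seed.
#' @return List with `source_lists` (named list of `data.frame`s for
#'   [merge_gene_sources()]) and `ciliopathy_sources` (the labels to flag).
#' @export
simulate_source_lists <- function(n_genes = 495L, n_ciliopathy = 189L,
                                  n_cilia = 447L, seed = 1L) {
  stopifnot(n_ciliopathy <= n_genes, n_cilia <= n_genes,
            n_cilia + n_ciliopathy >= n_genes, n_ciliopathy >= 1L)
  genes <- sim_gene_universe(n_genes)
  acc <- sprintf("Q%05d", seq_len(n_genes))
  nm <- paste("synthetic cilia protein", seq_len(n_genes))
  set.seed(seed)
  cilio_idx <- sort(sample.int(n_genes, n_ciliopathy))
  overlap_n <- n_cilia + n_ciliopathy - n_genes
  non_cilio <- setdiff(seq_len(n_genes), cilio_idx)
  cilia_idx <- sort(c(non_cilio, sample(cilio_idx, overlap_n)))
  n_uniprot_cilio <- min(n_ciliopathy, round(0.905 * n_ciliopathy))
  up_cilio_idx <- sort(sample(cilio_idx, n_uniprot_cilio))
  rest_cilio <- setdiff(cilio_idx, up_cilio_idx)
  g100k_idx <- sort(c(rest_cilio,
                      sample(up_cilio_idx,
                             min(length(up_cilio_idx),
                                 ceiling(0.15 * n_ciliopathy)))))
  make <- function(idx) data.frame(symbol = genes[idx], accession = acc[idx],
                                   name = nm[idx], stringsAsFactors = FALSE)
  lib <- function(frac) sort(sample(cilia_idx,
                                    max(1L, round(frac * length(cilia_idx)))))
  source_lists <- list(
    uniprot_cilia = make(cilia_idx),
    uniprot_ciliopathy = make(up_cilio_idx),
    genomes100k = make(g100k_idx),
    centrosomedb = make(lib(0.25)),
    cildb = make(lib(0.45)),
    syscilia = make(lib(0.35)),
    ciliacarta = make(lib(0.40))
  )
  list(source_lists = source_lists,
       ciliopathy_sources = c("uniprot_ciliopathy", "genomes100k"))
}

# gene-level truth shared by both compartments: seeded only by config$seed so
# the two compartments plant the same genes with the same directions
sim_gene_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  sigma <- stats::runif(n, config$sigma_range[1], config$sigma_range[2])
  n_de <- round(config$frac_de * n)
  de_idx <- sort(sample.int(n, n_de))
  dirs <- sample(c(-1, 1), n_de, replace = TRUE)
  list(mu = mu, sigma = sigma, de_idx = de_idx, dirs = dirs)
}

#' Simulate one compartment of the study
#'
#' Draws the compartment's cohorts from the shared gene-level model: per gene
#' a log2 baseline `mu_g ~ N(baseline_mean, baseline_sd)` and noise s.d.
#' `sigma_g ~ U(sigma_range)`; a planted gene that is active in a dataset
#' (probability `rho`) shifts its COPD samples by `direction_g * delta`;
#' each gene independently drops out of each dataset with probability
#' `dropout`. Fully reproducible from `config$seed` (gene-level draws use the
#' seed itself, dataset-level draws a compartment-offset seed, so both
#' compartments share planted genes and directions).
#'
#' @param config A [sim_config()].
#' @param compartment `"lung"` or `"saec"`.
#' @return List with `datasets` (list of `expression_dataset`, log2 scale)
#'   and `truth`: `de_genes` (sorted planted symbols), `directions` (named
#'   +1/-1), `active` (planted-gene x dataset logical matrix), `detected`
#'   (all-gene x dataset logical matrix of non-dropout).
#' @export
simulate_compartment <- function(config, compartment = c("lung", "saec")) {
  stopifnot(inherits(config, "sim_config"))
  compartment <- match.arg(compartment)
  genes <- sim_gene_universe(config$n_genes)
  gt <- sim_gene_truth(config)
  specs <- config[[paste0(compartment, "_datasets")]]
  ids <- sprintf("%s%d", toupper(compartment), seq_along(specs))
  set.seed(config$seed + if (compartment == "lung") 1L else 2L)
  n_de <- length(gt$de_idx)
  active <- matrix(FALSE, n_de, length(specs),
                   dimnames = list(genes[gt$de_idx], ids))
  detected <- matrix(FALSE, config$n_genes, length(specs),
                     dimnames = list(genes, ids))
  datasets <- vector("list", length(specs))
  for (d in seq_along(specs)) {
    n0 <- specs[[d]][1]
    n1 <- specs[[d]][2]
    active[, d] <- stats::rbinom(n_de, 1L, config$rho) == 1L
    detected[, d] <- stats::runif(config$n_genes) >= config$dropout
    eff <- numeric(config$n_genes)
    eff[gt$de_idx[active[, d]]] <- gt$dirs[active[, d]] * config$delta
    nsamp <- n0 + n1
    vals <- gt$mu + matrix(stats::rnorm(config$n_genes * nsamp),
                           config$n_genes, nsamp) * gt$sigma
    copd_cols <- seq.int(n0 + 1L, nsamp)
    vals[, copd_cols] <- vals[, copd_cols] + eff
    dimnames(vals) <- list(genes, sprintf("%s_S%03d", ids[d], seq_len(nsamp)))
    groups <- c(rep("non_copd", n0), rep("copd", n1))
    datasets[[d]] <- expression_dataset(
      vals[detected[, d], , drop = FALSE], groups, ids[d], compartment,
      scale = "log2"
    )
  }
  list(
    datasets = datasets,
    truth = list(
      de_genes = genes[gt$de_idx],
      directions = stats::setNames(gt$dirs, genes[gt$de_idx]),
      active = active,
      detected = detected
    )
  )
}

#' Simulate the full seven-cohort study plus its curated geneset
#'
#' @param config A [sim_config()].
#' @return List with `geneset` (merged `gene_set`), `source_lists` (the
#'   labelled inputs it was merged from), `ciliopathy_sources`, `lung` and
#'   `saec` (each the output of [simulate_compartment()]).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sl <- simulate_source_lists(config$n_genes, config$n_ciliopathy,
                              config$n_cilia, seed = config$seed)
  geneset <- merge_gene_sources(sl$source_lists, sl$ciliopathy_sources)
  list(
    geneset = geneset,
    source_lists = sl$source_lists,
    ciliopathy_sources = sl$ciliopathy_sources,
    lung = simulate_compartment(config, "lung"),
    saec = simulate_compartment(config, "saec")
  )
}

#' Simulate a cell x gene single-cell expression table
#'
#' Each cell/gene value is `Bernoulli(expr_prob) * (1 + Poisson(1))`, so the
#' fraction of positive cells per population equals the planted probability
#' in expectation.
#'
#' @param seed Integer seed.
#' @param n_cells_per_population Named integer vector, population -> number
#'   of cells (each >= 1).
#' @param expr_prob Numeric matrix of expression probabilities, genes in
#'   rows (rownames = symbols), populations in columns (colnames matching
#'   `names(n_cells_per_population)`).
#' @return A `cell_expression_table`.
#' @export
simulate_single_cell <- function(seed, n_cells_per_population, expr_prob) {
  stopifnot(is.numeric(n_cells_per_population),
            !is.null(names(n_cells_per_population)),
            is.matrix(expr_prob), !is.null(rownames(expr_prob)),
            !is.null(colnames(expr_prob)),
            all(expr_prob >= 0), all(expr_prob <= 1))
  if (any(n_cells_per_population < 1L)) {
    stop("every population needs at least one cell")
  }
  pops <- names(n_cells_per_population)
  if (!all(pops %in% colnames(expr_prob))) {
    stop("expr_prob must have one column per population")
  }
  genes <- rownames(expr_prob)
  set.seed(seed)
  blocks <- lapply(pops, function(p) {
    nc <- n_cells_per_population[[p]]
    ng <- length(genes)
    bern <- matrix(stats::rbinom(nc * ng, 1L, rep(expr_prob[, p], each = nc)),
                   nc, ng)
    bern * (1L + matrix(stats::rpois(nc * ng, 1), nc, ng))
  })
  values <- do.call(rbind, blocks)
  rownames(values) <- sprintf("CELL%05d", seq_len(nrow(values)))
  colnames(values) <- genes
  populations <- rep(pops, times = n_cells_per_population[pops])
  cell_expression_table(values, populations)
}
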