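# brute-force Benjamini-Hochberg step-up: explicit double loop over the
# sorted p-values, independent of the vectorized implementation
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[o][i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# step-up significance calls: reject the k smallest p-values where k is the
# largest index with p_(k) <= k * alpha / m
bf_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# brute-force tier and Venn counts from an incidence matrix
bf_tiers <- function(sig_sets) {
  genes <- sort(unique(unlist(sig_sets)), method = "radix")
  ids <- names(sig_sets)
  inc <- vapply(sig_sets, function(s) genes %in% s,
                logical(length(genes)))
  inc <- matrix(inc, nrow = length(genes), dimnames = list(genes, ids))
  counts <- rowSums(inc)
  tier <- vapply(seq_along(ids), function(k) sum(counts >= k), integer(1))
  keys <- apply(inc, 1, function(r) {
    paste(sort(ids[r], method = "radix"), collapse = "&")
  })
  venn <- table(keys)
  list(tier_counts = tier,
       venn = stats::setNames(as.integer(venn), names(venn)))
}

# random labelled source lists over a small symbol alphabet
random_source_lists <- function(n_sources = 3, pool = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- sample(CILIA_SOURCES, n_sources)
  syms <- sprintf("SYM%02d", seq_len(pool))
  out <- lapply(labs, function(l) {
    s <- sample(syms, sample(1:pool, 1), replace = TRUE)
    data.frame(symbol = s, accession = paste0("A", match(s, syms)),
               name = paste("protein", s), stringsAsFactors = FALSE)
  })
  stats::setNames(out, labs)
}

# gene_set over plain symbols, for tests that need a geneset without curation
simple_geneset <- function(symbols, ciliopathy = character()) {
  lists <- list(uniprot_cilia = data.frame(
    symbol = symbols, accession = paste0("Q", seq_along(symbols)),
    name = symbols, stringsAsFactors = FALSE))
  if (length(ciliopathy)) {
    lists$uniprot_ciliopathy <- data.frame(
      symbol = ciliopathy, accession = paste0("Q", match(ciliopathy, symbols)),
      name = ciliopathy, stringsAsFactors = FALSE)
  }
  merge_gene_sources(lists)
}

# hand-constructed DE result, for concordance tests that exercise the table
# layout without rerunning the statistics
make_de <- function(id, compartment, genes, sig_genes,
                    log2fc = seq_along(genes) / 10) {
  tab <- data.frame(
    gene = genes, log2fc = log2fc, log10_ratio = -log2fc / 4,
    t = log2fc * 3, df = 20, p = ifelse(genes %in% sig_genes, 0.01, 0.5),
    q = ifelse(genes %in% sig_genes, 0.04, 0.8),
    significant = genes %in% sig_genes, n_copd = 10, n_noncopd = 10,
    stringsAsFactors = FALSE
  )
  structure(list(dataset_id = id, compartment = compartment, table = tab,
                 n_tested = nrow(tab), n_significant = sum(tab$significant),
                 alpha = 0.05, sig_rule = "raw_p"),
            class = "dataset_de_result")
}

# small expression dataset with planted group difference on chosen genes
toy_dataset <- function(genes, n0 = 10, n1 = 10, shift = numeric(length(genes)),
                        sigma = 0.5, id = "D1", compartment = "lung",
                        seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(length(genes) * (n0 + n1), 7, sigma),
                 length(genes), n0 + n1,
                 dimnames = list(genes, sprintf("S%02d", seq_len(n0 + n1))))
  vals[, seq.int(n0 + 1, n0 + n1)] <- vals[, seq.int(n0 + 1, n0 + n1)] + shift
  expression_dataset(vals, c(rep("non_copd", n0), rep("copd", n1)),
                     id, compartment, scale = "log2")
}
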