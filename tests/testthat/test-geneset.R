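test_that("merging source lists deduplicates by symbol and unions provenance", {
  expect_equal(nrow(merge_gene_sources(list())), 0L)

  gs <- merge_gene_sources(list(
    uniprot_cilia = data.frame(symbol = c("A", "B"), accession = c("Q1", "Q2"),
                               name = c("a", "b")),
    uniprot_ciliopathy = data.frame(symbol = c("B", "C"),
                                    accession = c("Q2", "Q3"),
                                    name = c("b", "c"))
  ))
  expect_equal(nrow(gs), 3L)
  expect_equal(gs$symbol, c("A", "B", "C"))
  expect_equal(gs$sources[[match("B", gs$symbol)]],
               c("uniprot_cilia", "uniprot_ciliopathy"))
  expect_equal(gs$is_ciliopathy, c(FALSE, TRUE, TRUE))
})

test_that("symbols are normalized and malformed entries handled", {
  expect_warning(
    gs <- merge_gene_sources(list(
      uniprot_cilia = data.frame(symbol = c(" foxj1 ", "NEK6", ""),
                                 accession = c("Q92949", "Q9HC98", "Q0"),
                                 name = c("f", "n", "x"))
    )),
    "empty symbol"
  )
  expect_equal(gs$symbol, c("FOXJ1", "NEK6"))

  expect_warning(
    gs2 <- merge_gene_sources(list(
      uniprot_cilia = data.frame(symbol = "A", accession = "Q1", name = "a"),
      cildb = data.frame(symbol = "A", accession = "Q9", name = "a")
    )),
    "conflicting accessions"
  )
  expect_equal(gs2$uniprot_id, "Q1")

  expect_error(merge_gene_sources(list(notasource = data.frame(symbol = "A"))),
               "unrecognized source")
})

test_that("study-scale synthetic fixture merges to 495 unique entries, 189 ciliopathy", {
  sl <- simulate_source_lists(495, 189, 447, seed = 42)
  gs <- merge_gene_sources(sl$source_lists, sl$ciliopathy_sources)
  expect_equal(nrow(gs), 495L)
  expect_equal(sum(gs$is_ciliopathy), 189L)
  # inclusion-exclusion: the cilia list and the ciliopathy set share 141 genes
  cilio_syms <- unique(c(sl$source_lists$uniprot_ciliopathy$symbol,
                         sl$source_lists$genomes100k$symbol))
  expect_length(cilio_syms, 189L)
  expect_length(sl$source_lists$uniprot_cilia$symbol, 447L)
  expect_length(intersect(sl$source_lists$uniprot_cilia$symbol, cilio_syms),
                141L)
  # brute-force recount of unique normalized symbols across all lists
  all_syms <- unlist(lapply(sl$source_lists, function(x)
    toupper(trimws(x$symbol))))
  expect_equal(length(unique(all_syms)), 495L)
})

test_that("merge is idempotent and its size equals the brute-force symbol union", {
  for (s in 1:25) {
    lists <- random_source_lists(n_sources = sample(1:4, 1), seed = s)
    gs <- merge_gene_sources(lists)
    union_size <- length(unique(toupper(trimws(
      unlist(lapply(lists, `[[`, "symbol"))))))
    expect_equal(nrow(gs), union_size)
    gs2 <- merge_gene_sources(as_source_lists(gs),
                              ciliopathy_sources = "uniprot_ciliopathy")
    expect_equal(gs2$symbol, gs$symbol)
    expect_equal(gs2$sources, gs$sources)
    expect_equal(gs2$is_ciliopathy, gs$is_ciliopathy)
  }
})

test_that("compartment geneset is the detected subset and grows monotonically", {
  gs <- simple_geneset(c("A", "B", "C"))
  mk <- function(genes, id) toy_dataset(genes, n0 = 2, n1 = 2, id = id)
  d1 <- mk(c("A"), "D1")
  d2 <- mk(c("B"), "D2")
  d3 <- mk(c("A", "B", "C", "D"), "D3")
  expect_equal(compartment_geneset(gs, list(d1, d2))$symbol, c("A", "B"))
  expect_equal(compartment_geneset(gs, list(d3))$symbol, c("A", "B", "C"))
  # subset of gs, and adding a dataset never shrinks the result
  one <- compartment_geneset(gs, list(d1))$symbol
  two <- compartment_geneset(gs, list(d1, d2))$symbol
  expect_true(all(one %in% gs$symbol))
  expect_true(all(one %in% two))
  d_saec <- toy_dataset("A", n0 = 2, n1 = 2, id = "S1", compartment = "saec")
  expect_error(compartment_geneset(gs, list(d1, d_saec)), "compartments")
})

test_that("compartment geneset under dropout matches the brute-force union", {
  cfg <- sim_config(seed = 11, n_genes = 80, n_ciliopathy = 30, n_cilia = 70,
                    lung_datasets = rep(list(c(5, 5)), 4), dropout = 0.1)
  sim <- simulate_compartment(cfg, "lung")
  gs <- simple_geneset(sprintf("GENE%04d", 1:80))
  cg <- compartment_geneset(gs, sim$datasets)
  expected <- sort(unique(unlist(lapply(sim$datasets, function(d)
    rownames(d$values)))), method = "radix")
  expect_equal(cg$symbol, expected)
  expect_equal(nrow(cg), sum(rowSums(sim$truth$detected) >= 1))
})

test_that("genesets survive a TSV round trip and summarize correctly", {
  sl <- simulate_source_lists(40, 15, 35, seed = 3)
  gs <- merge_gene_sources(sl$source_lists, sl$ciliopathy_sources)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_geneset(gs, path)
  gs2 <- read_geneset(path)
  expect_equal(gs2$symbol, gs$symbol)
  expect_equal(gs2$sources, gs$sources)
  expect_equal(gs2$is_ciliopathy, gs$is_ciliopathy)

  smry <- geneset_summary(gs)
  expect_equal(smry$total, 40L)
  expect_equal(smry$n_ciliopathy, 15L)
  expect_equal(smry$per_source_counts$uniprot_cilia, 35L)

  # source-list TSV round trip
  src_path <- withr::local_tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(names(sl$source_lists), function(l)
    cbind(source = l, sl$source_lists[[l]])))
  write.table(rows, src_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_source_lists(src_path)
  expect_equal(sort(names(back)), sort(names(sl$source_lists)))
  expect_equal(back$uniprot_cilia$symbol, sl$source_lists$uniprot_cilia$symbol)
})

test_that("the packaged synthetic example source file curates cleanly", {
  path <- system.file("extdata", "synthetic_geneset_sources.tsv",
                      package = "cilicopd")
  sl <- read_source_lists(path)
  gs <- merge_gene_sources(sl, ciliopathy_sources = c("uniprot_ciliopathy",
                                                      "genomes100k"))
  expect_equal(nrow(gs), 12L)
  expect_equal(sum(gs$is_ciliopathy), 5L)
  expect_true(all(unlist(gs$sources) %in% CILIA_SOURCES))
})
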