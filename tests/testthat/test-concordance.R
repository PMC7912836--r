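test_that("tier counts and Venn partition match hand-worked examples", {
  one <- tier_summary(list(D1 = c("A", "B")))
  expect_equal(unname(one$tier_counts), 2L)

  ts <- tier_summary(list(S1 = c("A", "B", "C"), S2 = c("B", "C"), S3 = "C"))
  expect_equal(unname(ts$tier_counts), c(3L, 2L, 1L))
  expect_equal(ts$venn[["S1"]], 1L)
  expect_equal(ts$venn[["S1&S2"]], 1L)
  expect_equal(ts$venn[["S1&S2&S3"]], 1L)
  expect_equal(ts$membership$B, c("S1", "S2"))
})

test_that("tier/Venn computation equals brute-force enumeration on random instances", {
  set.seed(77)
  for (i in 1:30) {
    n_ds <- sample(1:6, 1)
    pool <- sprintf("G%03d", seq_len(sample(5:200, 1)))
    sig_sets <- stats::setNames(
      lapply(seq_len(n_ds), function(j)
        sample(pool, sample(0:length(pool), 1))),
      paste0("DS", seq_len(n_ds)))
    ts <- tier_summary(sig_sets)
    bf <- bf_tiers(sig_sets)
    expect_equal(unname(ts$tier_counts), bf$tier_counts)
    expect_equal(ts$venn, bf$venn[sort(names(bf$venn), method = "radix")])
    # venn regions partition the tier-1 genes; region count bounded by 2^n - 1
    expect_equal(sum(ts$venn), unname(ts$tier_counts[["1"]]))
    expect_lte(length(ts$venn), 2^n_ds - 1)
    expect_false(is.unsorted(rev(ts$tier_counts)))
  }
})

test_that("percentage of geneset uses half-up rounding at the published formats", {
  expect_equal(percent_of_geneset(100, 350, 0), 29)
  expect_equal(percent_of_geneset(10, 399, 1), 2.5)
  expect_equal(percent_of_geneset(0, 350, 0), 0)
  expect_equal(percent_of_geneset(1, 8, 0), 13)   # 12.5 rounds half-up
  expect_error(percent_of_geneset(1, 0), "positive")
  expect_error(percent_of_geneset(5, 4), "between 0")
})

test_that("cross-compartment hits apply both tier thresholds", {
  lung <- tier_summary(list(L1 = c("A", "B"), L2 = "A"), compartment = "lung")
  saec_empty <- tier_summary(list(S1 = character()), compartment = "saec")
  expect_equal(cross_compartment_hits(lung, saec_empty)$hits, character())

  saec <- tier_summary(list(S1 = c("A", "B"), S2 = "B"), compartment = "saec")
  res <- cross_compartment_hits(lung, saec, lung_min = 2, saec_min = 1)
  expect_equal(res$hits, "A")
  expect_equal(res$union_deregulated, c("A", "B"))

  gs <- simple_geneset(c("A", "B"), ciliopathy = "A")
  res2 <- cross_compartment_hits(lung, saec, geneset = gs)
  expect_equal(res2$ciliopathy_hits, "A")
  expect_equal(res2$ciliopathy_union, "A")
  expect_true(all(res2$ciliopathy_hits %in% res2$hits))
  expect_true(all(res2$hits %in% res2$union_deregulated))

  expect_error(cross_compartment_hits(saec, lung), "lung compartment")
})

test_that("raising a cross-compartment threshold never grows the hit set", {
  set.seed(31)
  pool <- sprintf("G%02d", 1:40)
  lung <- tier_summary(stats::setNames(
    lapply(1:4, function(i) sample(pool, 15)), paste0("L", 1:4)),
    compartment = "lung")
  saec <- tier_summary(stats::setNames(
    lapply(1:3, function(i) sample(pool, 15)), paste0("S", 1:3)),
    compartment = "saec")
  prev <- NULL
  for (lm in 1:4) {
    cur <- cross_compartment_hits(lung, saec, lung_min = lm)$hits
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_true(all(cross_compartment_hits(lung, saec, saec_min = 2)$hits %in%
                    cross_compartment_hits(lung, saec, saec_min = 1)$hits))
})

test_that("common-gene table mirrors the published layout", {
  lung_ids <- paste0("L", 1:4)
  saec_ids <- paste0("S", 1:3)
  # gene ALL4 significant in all lung datasets, PART in 3, SA in 2 SAEC
  lung_sets <- list(L1 = c("ALL4", "PART"), L2 = c("ALL4", "PART"),
                    L3 = c("ALL4", "PART"), L4 = "ALL4")
  saec_sets <- list(S1 = "SA", S2 = "SA", S3 = character())
  lung <- tier_summary(lung_sets, compartment = "lung")
  saec <- tier_summary(saec_sets, compartment = "saec")
  genes <- c("ALL4", "PART", "SA")
  de_list <- c(
    lapply(lung_ids, function(id)
      make_de(id, "lung", genes, lung_sets[[id]])),
    lapply(saec_ids, function(id)
      make_de(id, "saec", genes, saec_sets[[id]]))
  )
  tab <- common_gene_table(lung, saec, de_list)
  expect_equal(tab$gene, c("ALL4", "PART", "SA"))
  expect_equal(tab$compartment, c("lung", "lung", "saec"))
  expect_equal(tab$fully_concordant, c(TRUE, FALSE, FALSE))
  expect_true(is.na(tab$L4[tab$gene == "PART"]))   # blank where not significant
  expect_false(is.na(tab$L1[tab$gene == "PART"]))
  expect_true(all(is.na(tab[tab$gene == "SA", paste0("L", 1:4)])))

  empty <- common_gene_table(
    tier_summary(stats::setNames(rep(list(character()), 4), lung_ids),
                 compartment = "lung"),
    tier_summary(stats::setNames(rep(list(character()), 3), saec_ids),
                 compartment = "saec"),
    de_list)
  expect_equal(nrow(empty), 0L)
})

test_that("a gene planted active in every lung dataset is flagged fully concordant", {
  cfg <- sim_config(seed = 5, n_genes = 60, n_ciliopathy = 25, n_cilia = 55,
                    lung_datasets = rep(list(c(20, 20)), 4),
                    saec_datasets = rep(list(c(20, 20)), 3),
                    frac_de = 0.2, delta = 2, sigma_range = c(0.25, 0.25),
                    rho = 1, dropout = 0)
  st <- simulate_study(cfg)
  de_lung <- lapply(st$lung$datasets, run_diffexp, geneset = st$geneset)
  de_saec <- lapply(st$saec$datasets, run_diffexp, geneset = st$geneset)
  lung <- tier_summary(significance_sets(de_lung), compartment = "lung")
  saec <- tier_summary(significance_sets(de_saec), compartment = "saec")
  tab <- common_gene_table(lung, saec, c(de_lung, de_saec))
  planted <- st$lung$truth$de_genes
  lung_rows <- tab[tab$gene %in% planted & grepl("lung", tab$compartment), ]
  expect_gt(nrow(lung_rows), 0)
  expect_true(all(lung_rows$fully_concordant))
})
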