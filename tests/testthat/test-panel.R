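test_that("initial variant filters use inclusive gates and drop indels", {
  vs <- make_variants(6)
  vs$phred_quality <- c(19.9, 20, 30, 30, 30, 30)
  vs$alt_freq <- c(0.5, 0.5, 0.199, 0.20, 0.5, 0.5)
  vs$alt_read_count <- c(5, 5, 5, 2, 1, 5)
  vs$is_indel <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  kept <- filter_variants(vs)$variant_id
  expect_setequal(kept, vs$variant_id[c(2, 4)])
})

test_that("proximity filter removes both members of a close pair, <= 60 bp", {
  vs <- make_variants(5, pos = c(100L, 150L, 300L, 900L, 961L))
  kept <- proximity_filter(vs)$variant_id
  # 100/150 are 50 apart (both out); 900/961 are 61 apart (both kept)
  expect_setequal(kept, vs$variant_id[3:5])
  # distance exactly 60 still removes
  vs2 <- make_variants(2, pos = c(100L, 160L))
  expect_equal(nrow(proximity_filter(vs2)), 0)
  # a singleton chromosome survives
  expect_equal(nrow(proximity_filter(make_variants(1))), 1)
})

test_that("context variants trigger removal without being candidates", {
  vs <- make_variants(1, pos = 500L)
  ctx <- tibble::tibble(chrom = "1", pos = 540L)
  expect_equal(nrow(proximity_filter(vs, context = ctx)), 0)
  ctx_far <- tibble::tibble(chrom = "2", pos = 540L)
  expect_equal(nrow(proximity_filter(vs, context = ctx_far)), 1)
})

test_that("merging keeps the intersection and reports allele conflicts", {
  ds1 <- make_variants(3, pos = c(100L, 200L, 300L))
  ds2 <- make_variants(3, pos = c(200L, 300L, 400L))
  ds2$allele_alt[ds2$pos == 300] <- "G" # conflicting alt at shared site
  out <- merge_datasets(ds1, ds2)
  expect_equal(out$merged$pos, 200)
  expect_equal(out$merged$source, "both")
  expect_equal(out$conflicts$pos, 300)
  # disjoint sets merge to nothing
  expect_equal(nrow(merge_datasets(make_variants(2, pos = c(1L, 50000L)),
                                   make_variants(2, pos = c(9L, 70000L)))$merged), 0)
})

test_that("gene/QTL-region overlap is 1-based inclusive", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "1",
                          start = c(100L, 100L, 50L), end = c(200L, 200L, 400L))
  regions <- tibble::tibble(trait = "yield", chrom = "1",
                            start = c(150L, 201L), end = c(300L, 300L))
  expect_setequal(genes_in_qtl_regions(genes, regions[1, ]), c("g1", "g2", "g3"))
  regions2 <- tibble::tibble(trait = "t", chrom = "1", start = 201L, end = 300L)
  genes2 <- genes[genes$gene_id == "g1", ]
  expect_length(genes_in_qtl_regions(genes2, regions2), 0)
})

test_that("term enrichment matches the closed-form hypergeometric tail", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    terms = c(rep(list("T1"), 10), rep(list("T2"), 90))
  )
  qtl <- sprintf("g%03d", 1:10) # all ten T1 carriers drawn
  te <- term_enrichment(qtl, genes)
  expect_equal(te$p[te$term == "T1"], 1 / choose(100, 10))
  # a term carried by every gene is never enriched
  genes2 <- tibble::tibble(gene_id = genes$gene_id, terms = list("ALL"))
  te2 <- term_enrichment(qtl, genes2)
  expect_equal(te2$p, 1)
  expect_error(term_enrichment(character(), genes), "empty")
})

test_that("one SNP per gene follows the stated priority ladder", {
  base <- make_variants(2, gene = "gene1")
  # unique-flank synonymous beats non-unique missense
  v <- base
  v$flank_unique <- c(TRUE, FALSE)
  v$effect <- c("synonymous", "missense")
  expect_equal(select_one_per_gene(v, "gene1")$variant_id, v$variant_id[1])
  # missense breaks the tie when flanks agree
  v2 <- base
  v2$effect <- c("synonymous", "missense")
  expect_equal(select_one_per_gene(v2, "gene1")$variant_id, v2$variant_id[2])
  # single-bead-type alleles (A/C) beat A/T when all else equal
  v3 <- base
  v3$allele_alt <- c("T", "C")
  expect_equal(select_one_per_gene(v3, "gene1")$variant_id, v3$variant_id[2])
  # higher ADT last; deterministic position tie-break at the end
  v4 <- base
  v4$adt_score <- c(0.99, 0.95)
  expect_equal(select_one_per_gene(v4, "gene1")$variant_id, v4$variant_id[1])
})

test_that("the ADT gate is strictly greater than 0.9", {
  v <- make_variants(2, gene = "gene1")
  v$adt_score <- c(0.90, 0.901)
  out <- select_one_per_gene(v, "gene1")
  expect_equal(out$variant_id, v$variant_id[2])
  v$adt_score <- c(0.90, 0.90)
  expect_equal(nrow(select_one_per_gene(v, "gene1")), 0)
})

test_that("selection returns at most one variant per gene", {
  set.seed(8)
  v <- make_variants(60)
  v$gene_id <- sample(sprintf("gene%02d", 1:15), 60, TRUE)
  v$adt_score <- runif(60, 0.85, 1)
  out <- select_one_per_gene(v, unique(v$gene_id))
  expect_lte(max(table(out$gene_id)), 1)
})

test_that("anchor quotas follow largest-remainder apportionment and sum to target", {
  genes <- c(`1` = 100, `2` = 250, `3` = 650)
  pool <- dplyr::bind_rows(lapply(names(genes), function(ch)
    make_variants(700, chrom = ch)))
  out <- allocate_anchors(pool, genes, target = 1000, seed = 1)
  expect_equal(out$quota$quota, c(100, 250, 650))
  expect_equal(nrow(out$selected), 1000)
  expect_equal(sum(out$quota$quota), 1000)
})

test_that("anchor allocation is reproducible under a fixed seed", {
  genes <- c(`1` = 10, `2` = 30)
  pool <- dplyr::bind_rows(make_variants(50, chrom = "1"),
                           make_variants(50, chrom = "2"))
  a <- allocate_anchors(pool, genes, target = 20, seed = 99)
  b <- allocate_anchors(pool, genes, target = 20, seed = 99)
  expect_identical(a$selected$variant_id, b$selected$variant_id)
  c_ <- allocate_anchors(pool, genes, target = 20, seed = 100)
  expect_false(identical(a$selected$variant_id, c_$selected$variant_id))
})

test_that("underfilled chromosomes draw from the fill pool and report shortfall", {
  genes <- c(`1` = 50, `2` = 50)
  pool <- make_variants(3, chrom = "1")
  fills <- make_variants(30, chrom = "2")
  fills$variant_id <- sprintf("fill%02d", 1:30)
  out <- allocate_anchors(pool, genes, target = 10, seed = 3,
                          fill_pool = fills)
  expect_equal(sum(out$selected$chrom == "2"), 5)
  expect_equal(out$shortfall$chrom, "1")
  expect_equal(out$shortfall$missing, 2)
})

test_that("bead accounting charges 2 for A/T and C/G, 1 otherwise", {
  v <- make_variants(4)
  v$allele_ref <- c("A", "A", "C", "T")
  v$allele_alt <- c("C", "T", "G", "G")
  expect_equal(bead_usage(v), 1 + 2 + 2 + 1)
  vi <- v
  vi$is_indel[1] <- TRUE
  expect_error(bead_usage(vi), "SNV")
})

test_that("13,530 SNPs with 1,470 two-bead sites consume 15,000 bead types", {
  n <- 13530
  n_double <- 1470
  v <- make_variants(n)
  v$allele_ref <- c(rep("A", n_double), rep("A", n - n_double))
  v$allele_alt <- c(rep("T", n_double), rep("G", n - n_double))
  expect_equal(bead_usage(v), 15000)
})

test_that("gap filling takes the largest gap's midpoint-nearest pool variant", {
  sel <- make_variants(2, pos = c(100L, 900L))
  pool <- make_variants(2, pos = c(450L, 880L))
  pool$variant_id <- c("p450", "p880")
  out <- fill_gaps(sel, pool, c(`1` = 1000), bead_budget = 3)
  expect_equal(out$audit$variant_id[1], "p450")
  # brute-force check: of all gaps (1-100, 100-900, 900-1000) the largest is
  # 100-900 with midpoint 500; 450 is nearer than 880
  expect_equal(out$audit$gap_start[1], 100)
  expect_equal(out$audit$gap_end[1], 900)
})

test_that("gap filling never increases the maximum gap and respects the budget", {
  set.seed(13)
  sel <- make_variants(10, pos = sort(sample.int(1e6, 10)))
  pool <- make_variants(40, pos = sort(sample.int(1e6, 40)) + 3L)
  pool$variant_id <- sprintf("pool%02d", 1:40)
  lens <- c(`1` = 1e6)
  max_gap <- function(s) max(diff(c(1, sort(s$pos), 1e6)))
  before <- max_gap(sel)
  out <- fill_gaps(sel, pool, lens, bead_budget = 20)
  expect_lte(max_gap(out$selected), before)
  expect_lte(bead_usage(out$selected), 20)
  # empty pool and consumed budget leave the selection unchanged
  expect_equal(nrow(fill_gaps(sel, pool[0, ], lens)$selected), 10)
  expect_equal(nrow(fill_gaps(sel, pool, lens,
                              bead_budget = bead_usage(sel))$selected), 10)
})

test_that("panel summary reports per-scaffold gap statistics and roll-ups", {
  v <- dplyr::bind_rows(
    make_variants(3, chrom = "1", pos = c(100L, 200L, 400L)),
    make_variants(1, chrom = "11", pos = 5000L)
  )
  v$gene_id <- c("g1", NA, "g2", NA)
  s <- panel_summary(v)
  r1 <- s[s$chrom == "1", ]
  expect_equal(r1$mean_gap, 150)
  expect_equal(r1$max_gap, 200)
  expect_equal(r1$min_gap, 100)
  expect_true(is.na(s$mean_gap[s$chrom == "11"])) # single marker: undefined
  expect_equal(s$n_snps[s$chrom == "all"], 4)
  expect_equal(s$n_snps[s$chrom == "LG 1-10"], 3)
  expect_equal(s$n_snps[s$chrom == "all"],
               sum(s$n_snps[!s$chrom %in% c("all", "LG 1-10")]))
})
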