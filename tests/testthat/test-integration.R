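de_lnc <- function(chrom = "chr1", start = 5000, end = 8000, strand = "+",
                   id = "L1", is_de = TRUE) {
  data.frame(lnc_id = id, chrom = chrom, start = start, end = end,
             strand = strand, length = end - start, log2fc = 3,
             adj_p = 0.01, is_de = is_de)
}

sdmc_at <- function(chrom, pos, id = sprintf("cg%02d", seq_along(pos))) {
  data.frame(probe_id = id, chrom = chrom, pos = pos)
}

test_that("gene models derive the TSS from the strand", {
  bed <- genomic_intervals(c("chr1", "chr1"), c(5000, 5000), c(8000, 8000),
                           strand = c("+", "-"), name = c("gp", "gm"))
  g <- gene_models(bed)
  expect_equal(g$tss, c(5000, 7999))
  expect_equal(g$prom_start, c(4000, 6999))
  expect_equal(g$prom_end, c(6001, 9000))
  dot <- genomic_intervals("chr1", 5000, 8000, strand = ".", name = "gd")
  expect_warning(gd <- gene_models(dot), "treated as '\\+'")
  expect_equal(gd$tss, 5000)
})

test_that("SDMC-lncRNA pairing distinguishes promoter and body regions", {
  lnc <- de_lnc()  # body [5000, 8000) +, promoter [4000, 6001)
  expect_equal(map_sdmc_to_lncrna(sdmc_at("chr1", 4500), lnc)$region, "promoter")
  expect_equal(map_sdmc_to_lncrna(sdmc_at("chr1", 7000), lnc)$region, "body")
  expect_equal(nrow(map_sdmc_to_lncrna(sdmc_at("chr2", 7000), lnc)), 0)
  # a locus inside both regions yields one pair, promoter wins
  both <- map_sdmc_to_lncrna(sdmc_at("chr1", 5500), lnc)
  expect_equal(nrow(both), 1)
  expect_equal(both$region, "promoter")
})

test_that("non-DE lncRNAs never produce pairs", {
  lnc <- de_lnc(is_de = FALSE)
  expect_equal(nrow(map_sdmc_to_lncrna(sdmc_at("chr1", 4500), lnc)), 0)
})

test_that("methylation target sets use promoter-or-body containment", {
  bed <- genomic_intervals(c("chr1", "chr1"), c(5000, 50000), c(8000, 60000),
                           strand = "+", name = c("g1", "g2"))
  g <- gene_models(bed)
  expect_equal(target_genes_of_methylation(sdmc_at("chr1", 4500), g), "g1")
  expect_equal(target_genes_of_methylation(
    sdmc_at("chr1", c(7000, 7001, 7002, 7003, 7004)), g), "g1")
  expect_equal(target_genes_of_methylation(sdmc_at("chr1", 7000), g,
                                           mode = "promoter_only"),
               character())
})

test_that("lncRNA target sets use promoter-body overlap of DE lncRNAs", {
  bed <- genomic_intervals("chr1", 5000, 8000, strand = "+", name = "g1")
  g <- gene_models(bed)  # promoter [4000, 6001)
  expect_equal(target_genes_of_lncrna(de_lnc(start = 5900, end = 9000), g), "g1")
  expect_equal(target_genes_of_lncrna(de_lnc(start = 5900, end = 9000,
                                             is_de = FALSE), g),
               character())
  expect_equal(target_genes_of_lncrna(de_lnc(start = 6001, end = 9000), g),
               character())
})

test_that("target assignments match brute-force scans on random fixtures", {
  set.seed(41)
  bed <- rand_intervals(60)
  bed$name <- sprintf("g%03d", seq_len(60))
  bed$strand <- sample(c("+", "-"), 60, replace = TRUE)
  g <- gene_models(bed)
  lo <- rand_loci(300)
  lo$probe_id <- sprintf("cg%03d", seq_len(300))

  prom <- genomic_intervals(g$chrom, g$prom_start, g$prom_end)
  body <- genomic_intervals(g$chrom, g$start, g$end)
  want <- union(bf_loci_in(lo, prom)$interval, bf_loci_in(lo, body)$interval)
  expect_setequal(target_genes_of_methylation(lo, g),
                  g$gene_id[unique(want)])

  lnc <- rand_intervals(80)
  lnc <- data.frame(lnc_id = sprintf("L%03d", seq_len(80)), lnc,
                    length = lnc$end - lnc$start, log2fc = 3, adj_p = 0.01,
                    is_de = sample(c(TRUE, FALSE), 80, replace = TRUE))
  want <- bf_overlap_pairs(prom, lnc[lnc$is_de, ])$query
  expect_setequal(target_genes_of_lncrna(lnc, g), g$gene_id[unique(want)])
})

test_that("target intersection and hypergeometric enrichment are exact", {
  res <- intersect_targets(paste0("g", 1:5), paste0("g", 3:6),
                           universe_size = 10)
  expect_equal(res$common_targets, c("g3", "g4", "g5"))
  expect_equal(res$n_common, 3)
  expect_equal(res$overlap_p, 55 / 210)

  disj <- intersect_targets(c("a", "b"), c("c"), universe_size = 10)
  expect_equal(disj$n_common, 0)
  expect_equal(disj$overlap_p, 1)

  all_in <- intersect_targets(paste0("g", 1:4), paste0("g", 1:4),
                              universe_size = 4)
  expect_equal(all_in$n_common, 4)
  expect_equal(all_in$overlap_p, 1)

  expect_error(intersect_targets(paste0("g", 1:5), paste0("g", 6:8), 7),
               "universe_size")
})

test_that("common targets are always a subset of both target sets", {
  set.seed(43)
  for (rep in 1:10) {
    a <- sample(paste0("g", 1:30), sample(5:20, 1))
    b <- sample(paste0("g", 1:30), sample(5:20, 1))
    res <- intersect_targets(a, b, 30)
    expect_true(all(res$common_targets %in% a))
    expect_true(all(res$common_targets %in% b))
  }
})
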