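# Small desk-scale configuration used throughout this file.
small_cfg <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_probes = 400, n_pairs = 6, n_lnc = 150,
         n_genes = 60, n_patients = 120, genome_length = 6e5,
         frac_sdmc = 0.05, frac_de_lnc = 0.1,
         frac_crosstalk_genes = 0.05, n_snp = 200),
    list(...))
  do.call(sim_config, args)
}

test_that("planted probe count is deterministic and zero when disabled", {
  cfg <- sim_config(n_probes = 1000, frac_sdmc = 0.05, n_pairs = 4)
  met <- gen_methylation(cfg)
  expect_equal(nrow(met$truth), 50)
  cfg0 <- sim_config(n_probes = 500, frac_sdmc = 0, n_pairs = 4)
  expect_equal(nrow(gen_methylation(cfg0)$truth), 0)
})

test_that("generated betas are valid and planted shifts have the stated size", {
  cfg <- small_cfg()
  met <- gen_methylation(cfg)
  expect_true(all(met$beta$beta >= 0 & met$beta$beta <= 1))
  db <- compute_delta_beta(met$beta)
  planted <- met$truth$probe_id[!met$truth$clipped]
  signs <- ifelse(met$truth$direction[!met$truth$clipped] == "hyper", 1, -1)
  # group means of 6 noisy samples: planted effect recovered within noise
  expect_equal(unname(db[planted]), signs * cfg$planted_dbeta,
               tolerance = 0.2)
  expect_lt(max(abs(db[setdiff(names(db), met$truth$probe_id)])), 0.2)
})

test_that("the same seed regenerates byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(small_cfg(seed = 9), d1)
  simulate_bundle(small_cfg(seed = 9), d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("crosstalk layout plants recoverable promoter SDMCs and lncRNAs", {
  lg <- gen_lnc_and_genes(small_cfg(seed = 13))
  g <- gene_models(lg$genes)
  truth <- lg$truth
  expect_equal(length(truth$crosstalk_genes), 3)  # 5% of 60 genes

  # each planted SDMC locus sits in its own gene's promoter
  i <- match(truth$promoter_sdmc$gene_id, g$gene_id)
  expect_true(all(g$prom_start[i] <= truth$promoter_sdmc$pos &
                  truth$promoter_sdmc$pos < g$prom_end[i]))

  # DE lncRNAs pass the filter exactly; non-DE violate >= 1 threshold
  filt <- filter_lncrna(lg$lnc)
  expect_setequal(filt$lnc_id[filt$is_de], truth$de_lnc_ids)

  # integration on the planted loci recovers exactly the crosstalk set
  sdmc <- data.frame(probe_id = paste0("cg", seq_len(nrow(truth$promoter_sdmc))),
                     truth$promoter_sdmc[c("chrom", "pos")])
  res <- integrate_crosstalk(sdmc, filt, g)
  expect_setequal(res$lnc_targets, truth$crosstalk_genes)
  expect_setequal(res$common_targets, truth$crosstalk_genes)
})

test_that("disabling crosstalk empties the planted gene set", {
  lg <- gen_lnc_and_genes(small_cfg(frac_crosstalk_genes = 0))
  expect_equal(length(lg$truth$crosstalk_genes), 0)
  expect_setequal(target_genes_of_lncrna(filter_lncrna(lg$lnc),
                                         gene_models(lg$genes)),
                  character())
})

test_that("gene layout overflow is an error", {
  expect_error(gen_lnc_and_genes(sim_config(n_genes = 1000, genome_length = 1e6)),
               "layout overflow")
})

test_that("survival cohorts honour censoring and the altered fraction", {
  cfg <- small_cfg()
  cfg$n_patients <- 1000
  sv <- gen_survival(cfg, altered_fraction = 0.05)
  clin <- sv$clinical
  expect_true(all(clin$time_months > 0))
  # empirical censoring near the 20% target
  expect_equal(mean(clin$event == 0), cfg$censor_frac, tolerance = 0.35)
  # re-computed z-scores reproduce the intended altered fraction
  frac <- mean(classify_altered(zscore(clin$GENE_DRIVER)))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)

  cfg$censor_frac <- 0
  sv0 <- gen_survival(cfg, altered_fraction = 0.05)
  expect_true(all(sv0$clinical$event == 1))
})

test_that("all emitted files re-parse through the package readers cleanly", {
  d <- withr::local_tempdir()
  simulate_bundle(small_cfg(seed = 17), d)
  expect_no_warning({
    m <- read_beta_matrix(file.path(d, "beta.tsv"), file.path(d, "samples.tsv"))
    man <- read_probe_manifest(file.path(d, "probes.tsv"))
    lnc <- read_lnc_table(file.path(d, "lncrna.tsv"))
    genes <- read_bed(file.path(d, "genes.bed"))
    for (f in c("snp.bed", "cpg_island.bed", "enhancer.bed", "dhs.bed"))
      read_bed(file.path(d, f))
    read_clinical(file.path(d, "clinical.tsv"))
  })
  expect_equal(nrow(m$beta), 400)
  expect_equal(nrow(man), 400)
  expect_equal(nrow(lnc), 150)
  expect_equal(nrow(genes), 60)
})
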