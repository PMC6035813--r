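# Synthetic input bundles with planted effects. Every generator draws
# from its own RNG stream (cfg$seed plus a fixed per-file offset), so
# regenerating one output never perturbs the others.

#' Simulation configuration
#'
#' Defaults are desk-scale versions of a paired 450K + lncRNA study:
#' 10,000 probes over 12 tumor/paratumor pairs, 2,500 lncRNA
#' candidates, 1,000 genes (roughly a 50-fold shrink of genome scale),
#' with a planted differential fraction of 1.3% echoing the rate of
#' significant CpGs seen in paired carcinoma profiling. Planted SDMCs
#' shift the tumor group mean by 0.35 on the beta scale under
#' per-sample Gaussian noise of sd 0.05.
#'
#' @param seed Base RNG seed.
#' @param n_probes,n_pairs,n_lnc,n_genes,n_patients Problem sizes.
#' @param frac_sdmc Fraction of probes planted differential.
#' @param planted_dbeta Planted effect size on the beta scale.
#' @param beta_noise_sd Per-sample Gaussian noise sd on the beta scale.
#' @param frac_de_lnc Fraction of lncRNA candidates planted DE.
#' @param planted_lfc Planted |log2 fold change| for DE lncRNAs.
#' @param frac_crosstalk_genes Fraction of genes given both a promoter
#'   SDMC and an overlapping DE lncRNA.
#' @param hazard_ratio Altered vs not-altered hazard ratio.
#' @param censor_frac Expected censoring fraction.
#' @param genome_length Length in bp of each synthetic chromosome.
#' @param island_coverage,enhancer_coverage,dhs_coverage Approximate
#'   genome fraction covered by each feature track.
#' @param n_snp Number of synthetic point SNPs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_probes = 10000, n_pairs = 12,
                       n_lnc = 2500, n_genes = 1000, n_patients = 500,
                       frac_sdmc = 0.013, planted_dbeta = 0.35,
                       beta_noise_sd = 0.05, frac_de_lnc = 0.012,
                       planted_lfc = 3.5, frac_crosstalk_genes = 0.02,
                       hazard_ratio = 2.5, censor_frac = 0.2,
                       genome_length = 1e7, island_coverage = 0.02,
                       enhancer_coverage = 0.05, dhs_coverage = 0.04,
                       n_snp = 2000) {
  cfg <- list(seed = seed, n_probes = n_probes, n_pairs = n_pairs,
              n_lnc = n_lnc, n_genes = n_genes, n_patients = n_patients,
              frac_sdmc = frac_sdmc, planted_dbeta = planted_dbeta,
              beta_noise_sd = beta_noise_sd, frac_de_lnc = frac_de_lnc,
              planted_lfc = planted_lfc,
              frac_crosstalk_genes = frac_crosstalk_genes,
              hazard_ratio = hazard_ratio, censor_frac = censor_frac,
              genome_length = genome_length,
              island_coverage = island_coverage,
              enhancer_coverage = enhancer_coverage,
              dhs_coverage = dhs_coverage, n_snp = n_snp)
  fracs <- c(frac_sdmc, frac_de_lnc, frac_crosstalk_genes, censor_frac,
             island_coverage, enhancer_coverage, dhs_coverage)
  stopifnot(all(fracs >= 0 & fracs <= 1), hazard_ratio > 0,
            planted_dbeta > 0, beta_noise_sd >= 0,
            all(c(n_probes, n_pairs, n_lnc, n_genes, n_patients) >= 1))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate gene models, lncRNA candidates and annotation tracks
#'
#' Gene bodies are laid out non-overlapping, one per fixed-width slot
#' of `chr1`, with wide margins so that no promoter or planted lncRNA
#' can reach a neighbouring slot. Crosstalk genes receive (a) one
#' planted SDMC position inside their promoter and (b) one DE lncRNA
#' whose body overlaps their promoter. All other lncRNA candidates
#' live on the gene-free `chr2`, so by construction the set of genes
#' cis-targeted by DE lncRNAs equals the planted crosstalk set
#' exactly. Non-DE candidates violate at least one DE threshold
#' (short length, weak fold change, or large adjusted p). Feature
#' tracks (CpG islands, enhancers, DHS, point SNPs) are placed
#' uniformly at the configured coverage.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (BED6-style table), `lnc` (candidate
#'   table), `tracks` (named list of interval tables) and `truth`
#'   (crosstalk gene ids, planted promoter SDMC loci, DE lncRNA ids).
#' @export
gen_lnc_and_genes <- function(cfg) {
  set.seed(cfg$seed + 2)
  slot <- floor(cfg$genome_length / cfg$n_genes)
  if (slot < 8000)
    stop("gene layout overflow: ", cfg$n_genes, " genes do not fit ",
         cfg$genome_length, " bp (need >= 8 kb per gene)")
  glen <- sample(1000:3000, cfg$n_genes, replace = TRUE)
  gstart <- (seq_len(cfg$n_genes) - 1) * slot + 1100
  gend <- gstart + glen
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- genomic_intervals("chr1", gstart, gend, strand = strand,
                             name = sprintf("GENE%04d", seq_len(cfg$n_genes)))
  tss <- ifelse(strand == "+", gstart, gend - 1)

  n_ct <- round(cfg$frac_crosstalk_genes * cfg$n_genes)
  ct_idx <- sort(sample(cfg$n_genes, n_ct))
  # planted promoter SDMC: within 900 bp of the TSS
  sdmc_pos <- tss[ct_idx] + sample(-900:900, n_ct, replace = TRUE)
  sdmc_pos <- pmax(sdmc_pos, 0)
  # crosstalk lncRNA: body starts at the TSS, so it overlaps the promoter
  ct_len <- sample(500:3000, n_ct, replace = TRUE)
  n_de <- max(round(cfg$frac_de_lnc * cfg$n_lnc), n_ct)
  if (n_de > cfg$n_lnc) stop("frac_crosstalk_genes implies more DE lncRNAs ",
                             "than n_lnc candidates")
  n_other <- cfg$n_lnc - n_ct
  n_de_other <- n_de - n_ct
  mode <- sample(3, n_other, replace = TRUE)  # non-DE violation mode
  other_len <- ifelse(seq_len(n_other) <= n_de_other,
                      sample(200:5000, n_other, replace = TRUE),
                      ifelse(mode == 1, sample(50:199, n_other, replace = TRUE),
                             sample(200:5000, n_other, replace = TRUE)))
  other_start <- sample.int(cfg$genome_length - 6000, n_other, replace = TRUE)
  lnc <- data.frame(
    lnc_id = sprintf("LNC%05d", seq_len(cfg$n_lnc)),
    chrom = c(rep("chr1", n_ct), rep("chr2", n_other)),
    start = c(tss[ct_idx], other_start),
    end = c(tss[ct_idx] + ct_len, other_start + other_len),
    strand = sample(c("+", "-"), cfg$n_lnc, replace = TRUE),
    stringsAsFactors = FALSE)
  lnc$length <- lnc$end - lnc$start
  de <- seq_len(cfg$n_lnc) <= n_ct |
    (seq_len(cfg$n_lnc) > n_ct & seq_len(cfg$n_lnc) <= n_ct + n_de_other)
  sign <- sample(c(-1, 1), cfg$n_lnc, replace = TRUE)
  lnc$log2fc <- ifelse(de, sign * cfg$planted_lfc, sign * stats::runif(cfg$n_lnc, 0, 1.9))
  lnc$adj_p <- ifelse(de, stats::runif(cfg$n_lnc, 0, 0.05),
                      stats::runif(cfg$n_lnc, 0, 1))
  other_rows <- which(!de)
  m3 <- other_rows[mode[match(other_rows, n_ct + seq_len(n_other))] == 3]
  lnc$log2fc[m3] <- sample(c(-1, 1), length(m3), replace = TRUE) * cfg$planted_lfc
  lnc$adj_p[m3] <- stats::runif(length(m3), 0.06, 1)

  tracks <- list(
    snp = {
      pos <- sample.int(cfg$genome_length - 1, cfg$n_snp, replace = TRUE)
      genomic_intervals(sample(c("chr1", "chr2"), cfg$n_snp, replace = TRUE),
                        pos, pos + 1)
    },
    cpg_island = random_track(cfg$island_coverage, 500, 2000, cfg$genome_length),
    enhancer = random_track(cfg$enhancer_coverage, 200, 2000, cfg$genome_length),
    dhs = random_track(cfg$dhs_coverage, 150, 1000, cfg$genome_length))

  truth <- list(
    crosstalk_genes = genes$name[ct_idx],
    promoter_sdmc = data.frame(chrom = rep("chr1", n_ct), pos = sdmc_pos,
                               gene_id = genes$name[ct_idx],
                               stringsAsFactors = FALSE),
    de_lnc_ids = lnc$lnc_id[de],
    crosstalk_lnc_ids = lnc$lnc_id[seq_len(n_ct)])
  list(genes = genes, lnc = lnc, tracks = tracks, truth = truth)
}

# Uniformly placed intervals on chr1+chr2 at roughly the given coverage.
random_track <- function(coverage, min_w, max_w, genome_length) {
  mean_w <- (min_w + max_w) / 2
  n <- max(round(coverage * 2 * genome_length / mean_w), 1)
  w <- sample(min_w:max_w, n, replace = TRUE)
  start <- sample.int(genome_length - max_w, n, replace = TRUE)
  genomic_intervals(sample(c("chr1", "chr2"), n, replace = TRUE),
                    start, start + w)
}

#' Generate a paired beta-value matrix with planted SDMCs
#'
#' Null probes share one baseline beta ~ Uniform(0.1, 0.9) in both
#' groups; planted probes shift the tumor mean by `planted_dbeta` in a
#' direction chosen to stay inside \[0, 1\] (random where both fit;
#' clipping, if forced, is recorded in the truth table). Per-sample
#' Gaussian noise of sd `beta_noise_sd` is added and clipped to
#' \[0, 1\]. Optional `planted_loci` pins the first planted probes to
#' given coordinates (used to put SDMCs inside crosstalk promoters);
#' all other probes get uniform positions on `chr1`.
#'
#' @param cfg A [sim_config()].
#' @param planted_loci Optional data frame (`chrom`, `pos`) of
#'   coordinates for planted probes.
#' @return List with `beta` (a [beta_matrix()]), `manifest` (probe
#'   coordinates, 0-based) and `truth` (planted probe ids, directions,
#'   baselines, clipping flags).
#' @export
gen_methylation <- function(cfg, planted_loci = NULL) {
  set.seed(cfg$seed + 1)
  n <- cfg$n_probes
  k_pin <- if (is.null(planted_loci)) 0 else nrow(planted_loci)
  n_planted <- max(round(cfg$frac_sdmc * n), k_pin)
  if (n_planted > n) stop("frac_sdmc implies more planted probes than n_probes")
  probe_id <- sprintf("cg%06d", seq_len(n))
  planted_idx <- sort(sample(n, n_planted))

  chrom <- rep("chr1", n)
  pos <- sample.int(cfg$genome_length, n, replace = TRUE) - 1
  if (k_pin > 0) {
    chrom[planted_idx[seq_len(k_pin)]] <- planted_loci$chrom
    pos[planted_idx[seq_len(k_pin)]] <- planted_loci$pos
  }

  baseline <- stats::runif(n, 0.1, 0.9)
  dir <- rep(NA_character_, n)
  shift <- rep(0, n)
  if (n_planted > 0) {
    b <- baseline[planted_idx]
    up_ok <- b + cfg$planted_dbeta <= 1
    dn_ok <- b - cfg$planted_dbeta >= 0
    s <- ifelse(up_ok & dn_ok, sample(c(1, -1), n_planted, replace = TRUE),
                ifelse(up_ok, 1, -1))
    dir[planted_idx] <- ifelse(s > 0, "hyper", "hypo")
    shift[planted_idx] <- s * cfg$planted_dbeta
  }
  tumor_mean <- baseline + shift
  clipped <- tumor_mean < 0 | tumor_mean > 1
  tumor_mean <- pmin(pmax(tumor_mean, 0), 1)

  np <- cfg$n_pairs
  noise <- function(mu) pmin(pmax(
    matrix(stats::rnorm(n * np, rep(mu, np), cfg$beta_noise_sd), n, np), 0), 1)
  beta <- cbind(noise(tumor_mean), noise(baseline))
  rownames(beta) <- probe_id
  colnames(beta) <- c(sprintf("T%02d", seq_len(np)), sprintf("N%02d", seq_len(np)))
  samples <- data.frame(
    sample_id = colnames(beta),
    group = rep(c("tumor", "paratumor"), each = np),
    pair_id = rep(sprintf("P%02d", seq_len(np)), 2),
    stringsAsFactors = FALSE)

  list(beta = beta_matrix(beta, samples),
       manifest = data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                             strand = "+", stringsAsFactors = FALSE),
       truth = data.frame(probe_id = probe_id[planted_idx],
                          direction = dir[planted_idx],
                          baseline = baseline[planted_idx],
                          clipped = clipped[planted_idx],
                          stringsAsFactors = FALSE))
}

#' Generate a survival cohort with expression-altered patients
#'
#' Each patient is altered with probability `altered_fraction`; the
#' driver gene's expression is drawn from the matching tail (altered:
#' |z| >= 1.96) or centre of a standard normal, so that re-computed
#' cohort z-scores reproduce the intended status up to boundary noise.
#' Survival times are exponential with the hazard multiplied by
#' `cfg$hazard_ratio` for altered patients; censoring is independent
#' Uniform(0, c) with c solved so the expected censoring fraction is
#' `cfg$censor_frac`. `n_null_genes` additional genes carry expression
#' unrelated to survival.
#'
#' @param cfg A [sim_config()].
#' @param altered_fraction Target altered fraction in (0, 1); the
#'   default 0.05 matches the mass beyond |z| = 1.96.
#' @param median_survival Baseline (not-altered) median survival in
#'   months.
#' @param n_null_genes Number of survival-neutral extra genes.
#' @return List with `clinical` (patient table) and `truth` (intended
#'   altered status per patient).
#' @export
gen_survival <- function(cfg, altered_fraction = 0.05,
                         median_survival = 30, n_null_genes = 3) {
  stopifnot(altered_fraction > 0, altered_fraction < 1)
  set.seed(cfg$seed + 3)
  n <- cfg$n_patients
  altered <- stats::runif(n) < altered_fraction
  expr <- tail_or_centre_normal(altered, 1.96)

  lam0 <- log(2) / median_survival
  lam <- lam0 * ifelse(altered, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = lam)
  if (cfg$censor_frac > 0) {
    cmax <- censor_horizon(cfg$censor_frac, lam0, cfg$hazard_ratio,
                           altered_fraction)
    t_cens <- stats::runif(n, 0, cmax)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  clinical <- data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
                         time_months = time, event = event,
                         GENE_DRIVER = expr, stringsAsFactors = FALSE)
  for (g in seq_len(n_null_genes))
    clinical[[sprintf("GENE_NULL%d", g)]] <- stats::rnorm(n)
  list(clinical = clinical,
       truth = data.frame(patient_id = clinical$patient_id,
                          altered = altered, stringsAsFactors = FALSE))
}

# Standard-normal draws from the two-sided tail (|z| >= z0) for altered
# patients and from the centre (|z| < z0) otherwise, by inverse CDF.
tail_or_centre_normal <- function(altered, z0) {
  n <- length(altered)
  u <- stats::runif(n)
  p0 <- stats::pnorm(-z0)                       # one-tail mass
  z <- numeric(n)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  z[altered] <- sgn[altered] * -stats::qnorm(u[altered] * p0)
  z[!altered] <- stats::qnorm(p0 + u[!altered] * (1 - 2 * p0))
  z
}

# Horizon c of Uniform(0, c) censoring hitting the target expected
# censoring fraction under the exponential mixture.
censor_horizon <- function(target, lam0, hr, altered_fraction) {
  pc <- function(c) {
    f <- function(l) (1 - exp(-l * c)) / (l * c)
    altered_fraction * f(lam0 * hr) + (1 - altered_fraction) * f(lam0) - target
  }
  stats::uniroot(pc, c(1e-6, 1e6))$root
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate and write a complete input bundle
#'
#' Generates coordinated methylation, lncRNA/gene, annotation-track
#' and clinical inputs (planted promoter SDMC positions from the gene
#' layout are pinned into the methylation manifest) and writes them in
#' the pipeline's own file dialects, together with truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with all generated objects, truth tables
#'   and file paths.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lg <- gen_lnc_and_genes(cfg)
  met <- gen_methylation(cfg, planted_loci = lg$truth$promoter_sdmc)
  surv <- gen_survival(cfg)

  p <- function(f) file.path(dir, f)
  beta_df <- data.frame(probe_id = rownames(met$beta$beta), met$beta$beta,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(beta_df, p("beta.tsv"))
  write_tsv(met$beta$samples, p("samples.tsv"))
  man_out <- met$manifest
  man_out$pos <- man_out$pos + 1  # manifest dialect is 1-based
  write_tsv(man_out, p("probes.tsv"))
  write_tsv(lg$lnc, p("lncrna.tsv"))
  write_bed(lg$genes, p("genes.bed"))
  for (nm in names(lg$tracks)) write_bed(lg$tracks[[nm]], p(paste0(nm, ".bed")))
  write_tsv(surv$clinical, p("clinical.tsv"))
  write_tsv(met$truth, p("truth_sdmc.tsv"))
  write_tsv(data.frame(gene_id = lg$truth$crosstalk_genes), p("truth_crosstalk.tsv"))
  write_tsv(data.frame(lnc_id = lg$truth$de_lnc_ids), p("truth_de_lnc.tsv"))
  write_tsv(surv$truth, p("truth_survival.tsv"))

  invisible(list(cfg = cfg, dir = dir, methylation = met, lnc_genes = lg,
                 survival = surv))
}
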