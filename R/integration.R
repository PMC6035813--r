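# Coordinate-based integration of differential methylation and
# differential lncRNA expression: methylation-lncRNA pairs, target-gene
# sets from each signal, and their intersection.

#' Build gene models with strand-aware TSS and promoter
#'
#' The TSS is the 5' end of the gene body: `start` on the plus strand,
#' `end - 1` on the minus strand. Strand `"."` is treated as `"+"`
#' with a warning. The promoter is TSS +/- `flank` bp (see
#' [promoter_of()]).
#'
#' @param bed BED6-style interval table with columns `chrom`, `start`,
#'   `end`, `name` (gene id), `strand`.
#' @param flank Promoter flank in bp (default 1000).
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `prom_start`, `prom_end`.
#' @export
gene_models <- function(bed, flank = 1000) {
  validate_intervals(bed)
  if (is.null(bed$name)) stop("gene models need a name column (gene id)")
  strand <- bed$strand
  if (any(strand == ".")) {
    warning(sum(strand == "."), " gene(s) with strand '.'; treated as '+'")
    strand[strand == "."] <- "+"
  }
  tss <- ifelse(strand == "+", bed$start, bed$end - 1)
  prom <- promoter_of(bed$chrom, tss, strand, flank = flank)
  data.frame(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, strand = strand, tss = tss,
             prom_start = prom$start, prom_end = prom$end,
             stringsAsFactors = FALSE)
}

# Promoters of DE lncRNAs from their strand-aware TSS; "." assumed "+".
lnc_promoters <- function(lnc, flank = 1000) {
  strand <- lnc$strand
  if (any(is.na(strand) | strand == ".")) {
    warning(sum(is.na(strand) | strand == "."),
            " lncRNA(s) without strand; '+' assumed")
    strand[is.na(strand) | strand == "."] <- "+"
  }
  tss <- ifelse(strand == "+", lnc$start, lnc$end - 1)
  promoter_of(lnc$chrom, tss, strand, flank = flank)
}

#' Map SDMC loci onto differentially expressed lncRNAs
#'
#' Pairs every SDMC locus with every DE lncRNA whose promoter
#' (strand-aware TSS +/- `flank` bp) or body contains it. A locus in
#' both regions of the same lncRNA yields a single pair with
#' `region = "promoter"` (promoter takes precedence).
#'
#' @param sdmc Locus table of SDMCs with `probe_id`, `chrom`, `pos`.
#' @param lnc lncRNA records (only rows with `is_de` are used).
#' @param flank Promoter flank in bp (default 1000).
#' @return Data frame with columns `probe_id`, `lnc_id`, `region`.
#' @export
map_sdmc_to_lncrna <- function(sdmc, lnc, flank = 1000) {
  lnc <- lnc[which(lnc$is_de), , drop = FALSE]
  empty <- data.frame(probe_id = character(), lnc_id = character(),
                      region = character(), stringsAsFactors = FALSE)
  if (nrow(lnc) == 0 || nrow(sdmc) == 0) return(empty)
  lo <- loci(sdmc$chrom, sdmc$pos, id = sdmc$probe_id)
  prom <- lnc_promoters(lnc, flank = flank)
  in_prom <- loci_in_intervals(lo, prom)
  in_body <- loci_in_intervals(lo, lnc)
  pairs <- rbind(
    data.frame(probe_id = sdmc$probe_id[in_prom$locus],
               lnc_id = lnc$lnc_id[in_prom$interval],
               region = rep("promoter", nrow(in_prom)),
               stringsAsFactors = FALSE),
    data.frame(probe_id = sdmc$probe_id[in_body$locus],
               lnc_id = lnc$lnc_id[in_body$interval],
               region = rep("body", nrow(in_body)),
               stringsAsFactors = FALSE))
  # promoter precedence, one pair per probe-lnc
  pairs <- pairs[order(pairs$probe_id, pairs$lnc_id,
                       pairs$region != "promoter"), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[c("probe_id", "lnc_id")]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Genes targeted by differential methylation
#'
#' A gene is targeted when at least one SDMC locus falls in its
#' promoter or (by default) its body.
#'
#' @param sdmc Locus table of SDMCs (`chrom`, `pos`).
#' @param genes Gene models from [gene_models()].
#' @param mode `"promoter_or_body"` (default) or `"promoter_only"`.
#' @return Character vector (set) of targeted gene ids.
#' @export
target_genes_of_methylation <- function(sdmc, genes,
                                        mode = c("promoter_or_body",
                                                 "promoter_only")) {
  mode <- match.arg(mode)
  if (nrow(sdmc) == 0 || nrow(genes) == 0) return(character())
  lo <- loci(sdmc$chrom, sdmc$pos)
  prom <- genomic_intervals(genes$chrom, genes$prom_start, genes$prom_end)
  hit <- unique(loci_in_intervals(lo, prom)$interval)
  if (mode == "promoter_or_body") {
    body <- genomic_intervals(genes$chrom, genes$start, genes$end)
    hit <- union(hit, unique(loci_in_intervals(lo, body)$interval))
  }
  sort(unique(genes$gene_id[hit]))
}

#' Genes cis-targeted by differentially expressed lncRNAs
#'
#' A gene is a lncRNA target when its promoter overlaps the body of at
#' least one DE lncRNA (strand-agnostic overlap).
#'
#' @param lnc lncRNA records (only rows with `is_de` are used).
#' @param genes Gene models from [gene_models()].
#' @return Character vector (set) of targeted gene ids.
#' @export
target_genes_of_lncrna <- function(lnc, genes) {
  lnc <- lnc[which(lnc$is_de), , drop = FALSE]
  if (nrow(lnc) == 0 || nrow(genes) == 0) return(character())
  prom <- genomic_intervals(genes$chrom, genes$prom_start, genes$prom_end)
  hit <- unique(overlap_pairs(prom, lnc)$query)
  sort(unique(genes$gene_id[hit]))
}

#' Intersect the two target-gene sets with enrichment p
#'
#' Exact set intersection plus the upper-tail hypergeometric
#' probability of observing at least that overlap when drawing
#' `|lnc_targets|` genes from a universe containing `|met_targets|`
#' methylation targets.
#'
#' @param met_targets,lnc_targets Character vectors of gene ids.
#' @param universe_size Number of genes in the universe; must be at
#'   least the size of the union (defaults sensibly to the number of
#'   supplied gene models upstream).
#' @return List with `common_targets`, `n_met`, `n_lnc`, `n_common`,
#'   `universe_size` and `overlap_p`.
#' @export
intersect_targets <- function(met_targets, lnc_targets, universe_size) {
  met_targets <- unique(met_targets)
  lnc_targets <- unique(lnc_targets)
  n_union <- length(union(met_targets, lnc_targets))
  if (universe_size < n_union)
    stop("universe_size (", universe_size, ") smaller than target union (",
         n_union, ")")
  common <- sort(intersect(met_targets, lnc_targets))
  k <- length(common)
  # P(X >= k), X ~ Hypergeometric(universe, |met|, draws = |lnc|)
  p <- stats::phyper(k - 1, length(met_targets),
                     universe_size - length(met_targets),
                     length(lnc_targets), lower.tail = FALSE)
  list(common_targets = common, n_met = length(met_targets),
       n_lnc = length(lnc_targets), n_common = k,
       universe_size = universe_size, overlap_p = p)
}

#' Full integration stage
#'
#' Runs [map_sdmc_to_lncrna()], both target-gene assignments and
#' [intersect_targets()] on SDMC loci, DE lncRNAs and gene models.
#'
#' @param sdmc SDMC locus table (`probe_id`, `chrom`, `pos`).
#' @param lnc lncRNA records with `is_de`.
#' @param genes Gene models from [gene_models()].
#' @param universe_size Gene universe for the enrichment p; defaults to
#'   the number of supplied gene models.
#' @param met_mode Methylation target rule, see
#'   [target_genes_of_methylation()].
#' @return List with `met_lnc_pairs`, `met_targets`, `lnc_targets`,
#'   and the fields of [intersect_targets()].
#' @export
integrate_crosstalk <- function(sdmc, lnc, genes,
                                universe_size = nrow(genes),
                                met_mode = "promoter_or_body") {
  pairs <- map_sdmc_to_lncrna(sdmc, lnc)
  met <- target_genes_of_methylation(sdmc, genes, mode = met_mode)
  lnct <- target_genes_of_lncrna(lnc, genes)
  res <- intersect_targets(met, lnct, universe_size)
  c(list(met_lnc_pairs = pairs, met_targets = met, lnc_targets = lnct), res)
}
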