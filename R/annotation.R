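# Annotation of significant CpG sites against genomic feature tracks
# (SNP, CpG island/shore, enhancer, DNase hypersensitive sites).

#' Expand CpG islands by their shores
#'
#' Shores are the `shore_width` bp flanks on both sides of each island;
#' the combined island/shore track is the union of each island with its
#' shores, merged wherever the expanded intervals touch or overlap and
#' clipped at the chromosome start.
#'
#' @param islands Interval table of CpG islands.
#' @param shore_width Shore width in bp (default 2000, the
#'   field-standard shore definition).
#' @return Interval table of merged island-plus-shore regions.
#' @export
expand_shores <- function(islands, shore_width = 2000) {
  stopifnot(shore_width >= 0)
  if (nrow(islands) == 0) return(islands)
  ex <- islands
  ex$start <- pmax(ex$start - shore_width, 0)
  ex$end <- ex$end + shore_width
  merged <- GenomicRanges::reduce(iv_to_granges(ex), ignore.strand = TRUE)
  granges_to_iv(merged)
}

#' Annotate loci against feature tracks
#'
#' For each locus, a membership flag per track (by containment); per
#' track, a summary with hit count and fraction. Tracks are not
#' mutually exclusive: a locus inside several tracks counts in each.
#' Loci without coordinates are excluded from the totals.
#'
#' @param lo Locus table (e.g. SDMC records with `chrom`, `pos`, and
#'   optionally `probe_id`).
#' @param tracks Named list of interval tables, e.g.
#'   `list(snp = ..., cpg_island_shore = ..., enhancer = ..., dhs = ...)`.
#' @return List with `summary` (data frame: `category`, `n_hit`,
#'   `n_total`, `fraction`) and `flags` (one logical column per track,
#'   one row per usable locus).
#' @export
annotate_loci <- function(lo, tracks) {
  stopifnot(is.list(tracks), length(tracks) > 0, !is.null(names(tracks)))
  usable <- !is.na(lo$chrom) & !is.na(lo$pos)
  if (any(!usable))
    warning(sum(!usable), " loci without coordinates excluded from annotation")
  lo <- lo[usable, , drop = FALSE]
  n_total <- nrow(lo)
  flags <- data.frame(row.names = seq_len(n_total))
  if (!is.null(lo$probe_id)) flags$probe_id <- lo$probe_id
  for (nm in names(tracks)) {
    hit <- rep(FALSE, n_total)
    if (n_total > 0 && nrow(tracks[[nm]]) > 0) {
      pairs <- loci_in_intervals(lo, tracks[[nm]])
      hit[unique(pairs$locus)] <- TRUE
    }
    flags[[nm]] <- hit
  }
  n_hit <- vapply(names(tracks), function(nm) sum(flags[[nm]]), 0L)
  summary <- data.frame(category = names(tracks), n_hit = n_hit,
                        n_total = n_total,
                        fraction = if (n_total > 0) n_hit / n_total else 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, flags = flags)
}

#' Read SNP positions as width-1 intervals
#'
#' Point variants in a BED file (or any BED intervals) become the
#' track used for exact locus containment.
#'
#' @param path BED file path.
#' @return Interval table.
#' @export
read_snp_track <- function(path) read_bed(path)
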