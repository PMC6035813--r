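# Genomic interval model: 0-based half-open coordinates throughout
# (BED convention). 1-based inputs are converted at the reader boundary.

#' Construct a table of genomic intervals
#'
#' Intervals use 0-based half-open coordinates: `start` is the first base
#' covered, `end` is one past the last. Strand is `"+"`, `"-"` or `"."`.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions (integer-like, >= 0).
#' @param end Exclusive end positions (> start).
#' @param strand Strand symbols, recycled; one of `"+"`, `"-"`, `"."`.
#' @param name Optional feature names.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `name` if given), validated.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  if (length(chrom) == 0 || length(start) == 0) n <- 0
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), n)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval with empty chromosome name")
  if (any(df$start < 0)) stop("interval start < 0")
  if (any(df$end <= df$start)) stop("interval with end <= start")
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Construct a table of loci (single-base positions)
#'
#' @param chrom Chromosome names.
#' @param pos 0-based positions (>= 0).
#' @param id Optional identifiers.
#' @return A `data.frame` with columns `chrom`, `pos` (and `id`).
#' @export
loci <- function(chrom, pos, id = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- as.character(id)
  if (any(df$pos < 0)) stop("locus position < 0")
  df
}

#' Test whether pairs of intervals overlap
#'
#' Element-wise on two interval tables of equal length (or length one,
#' recycled). Strand is ignored; half-open semantics, so abutting
#' intervals do not overlap.
#'
#' @param a,b Interval tables as from [genomic_intervals()].
#' @return Logical vector.
#' @export
iv_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Test whether intervals contain loci
#'
#' Element-wise: `start <= pos < end` on the same chromosome.
#'
#' @param iv Interval table.
#' @param lo Locus table as from [loci()].
#' @return Logical vector.
#' @export
iv_contains <- function(iv, lo) {
  iv$chrom == lo$chrom & iv$start <= lo$pos & lo$pos < iv$end
}

#' Promoter window around a transcription start site
#'
#' The promoter is the TSS plus `flank` bp on both sides, inclusive on
#' both flanks (so 2 * flank + 1 positions), clipped at the chromosome
#' start. The window is symmetric; strand only determines which gene
#' coordinate is the TSS (done upstream) and is carried through.
#'
#' @param chrom Chromosome of each TSS.
#' @param pos 0-based TSS position.
#' @param strand Strand symbol, carried into the result.
#' @param flank Flank size in bp (default 1000, i.e. TSS +/- 1 kb).
#' @return Interval table of promoter windows.
#' @export
promoter_of <- function(chrom, pos, strand = "+", flank = 1000) {
  stopifnot(flank > 0)
  genomic_intervals(chrom,
                    start = pmax(pos - flank, 0),
                    end = pos + flank + 1,
                    strand = strand)
}

# GRanges bridges. GRanges is 1-based closed, so [start, end) maps to
# start+1 .. end; a locus at pos maps to the single base pos+1.
iv_to_granges <- function(df) {
  strand <- if (is.null(df$strand)) "*" else ifelse(df$strand == ".", "*", df$strand)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         strand = strand)
}

loci_to_granges <- function(lo) {
  GenomicRanges::GRanges(lo$chrom, IRanges::IRanges(lo$pos + 1, lo$pos + 1))
}

granges_to_iv <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1,
                    GenomicRanges::end(gr),
                    strand = ifelse(s == "*", ".", s))
}

# findOverlaps on a shared seqlevel set (disjoint chromosome sets are
# an expected no-hit case, not worth a warning).
find_hits <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
}

#' Batch overlap query between two interval sets
#'
#' Indexed overlap join (interval-tree backed). Strand is ignored.
#'
#' @param query,subject Interval tables.
#' @return A `data.frame` with columns `query` and `subject`, the row
#'   indices of each overlapping pair.
#' @export
overlap_pairs <- function(query, subject) {
  hits <- find_hits(iv_to_granges(query), iv_to_granges(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Batch containment query of loci in intervals
#'
#' @param lo Locus table.
#' @param iv Interval table.
#' @return A `data.frame` with columns `locus` and `interval`, row
#'   indices of each (locus contained in interval) pair.
#' @export
loci_in_intervals <- function(lo, iv) {
  hits <- find_hits(loci_to_granges(lo), iv_to_granges(iv))
  data.frame(locus = S4Vectors::queryHits(hits),
             interval = S4Vectors::subjectHits(hits))
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open. Columns beyond the sixth are
#' ignored; four- and five-column files are accepted (name, score).
#' Malformed lines raise an error naming the line number.
#'
#' @param path File path.
#' @return Interval table with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand` (absent strand becomes `"."`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lnum[which(nf < 3)[1]], ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("BED line ", lnum[which(bad)[1]], ": non-numeric coordinates")
  bad <- start < 0 | end <= start
  if (any(bad))
    stop("BED line ", lnum[which(bad)[1]], ": invalid interval [",
         start[which(bad)[1]], ", ", end[which(bad)[1]], ")")
  df <- data.frame(chrom = vapply(fields, `[`, "", 1), start = start,
                   end = end, stringsAsFactors = FALSE)
  if (any(nf >= 4)) df$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  if (any(nf >= 5)) df$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")))
  if (any(nf >= 6)) {
    df$strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", "")
    bad <- !df$strand %in% c("+", "-", ".")
    if (any(bad))
      stop("BED line ", lnum[which(bad)[1]], ": invalid strand '",
           df$strand[which(bad)[1]], "'")
  } else {
    df$strand <- "."
  }
  validate_intervals(df)
  df
}

#' Write an interval table as BED
#'
#' Writes BED6 when `name`/`score`/`strand` are present, BED3 otherwise.
#'
#' @param iv Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  out <- data.frame(chrom = iv$chrom,
                    start = format(iv$start, scientific = FALSE, trim = TRUE),
                    end = format(iv$end, scientific = FALSE, trim = TRUE))
  if (!is.null(iv$strand) || !is.null(iv$name)) {
    out$name <- if (is.null(iv$name)) "." else iv$name
    out$score <- if (is.null(iv$score)) 0 else iv$score
    out$strand <- if (is.null(iv$strand)) "." else iv$strand
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
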