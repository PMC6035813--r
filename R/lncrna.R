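# Differential-expression filtering of lncRNA candidates.

#' Filter lncRNA candidates to significant differentially expressed set
#'
#' A candidate is differentially expressed (DE) when its length is at
#' least `min_len` bp (the lncRNA length definition), its log2 fold
#' change passes `min_abs_lfc` and its adjusted p-value is at most
#' `max_adjp`; all bounds inclusive. By default the fold-change
#' threshold is applied to |log2FC| so that down-regulated lncRNAs are
#' retained; `signed = TRUE` keeps only log2FC >= `min_abs_lfc`.
#' Records with a missing length, fold change or adjusted p are never
#' DE and are flagged.
#'
#' @param records Data frame with columns `length`, `log2fc`, `adj_p`
#'   (other columns carried through).
#' @param min_len Minimum transcript length in bp (default 200).
#' @param min_abs_lfc Fold-change threshold on the log2 scale (default 2).
#' @param max_adjp Adjusted p-value ceiling (default 0.05).
#' @param signed If `TRUE`, require signed log2FC >= threshold instead
#'   of |log2FC| >= threshold.
#' @return `records` with logical columns `is_de` and `flagged` added.
#' @export
filter_lncrna <- function(records, min_len = 200, min_abs_lfc = 2.0,
                          max_adjp = 0.05, signed = FALSE) {
  stopifnot(all(c("length", "log2fc", "adj_p") %in% names(records)))
  lfc <- if (signed) records$log2fc else abs(records$log2fc)
  records$flagged <- is.na(records$length) | is.na(records$log2fc) |
    is.na(records$adj_p)
  records$is_de <- !records$flagged & records$length >= min_len &
    lfc >= min_abs_lfc & records$adj_p <= max_adjp
  records
}

#' Read a lncRNA candidate table
#'
#' TSV with columns `lnc_id`, `chrom`, `start`, `end`, `strand`,
#' `length`, `log2fc`, `adj_p`; coordinates 0-based half-open.
#'
#' @param path File path.
#' @return Data frame of lncRNA records.
#' @export
read_lnc_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lnc_id", "chrom", "start", "end", "strand", "length",
            "log2fc", "adj_p")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("lncRNA table is missing columns: ", paste(miss, collapse = ", "))
  validate_intervals(tab)
  bad <- which(!is.na(tab$adj_p) & (tab$adj_p < 0 | tab$adj_p > 1))
  if (length(bad))
    stop("lncRNA table: adj_p out of [0, 1] at row ", bad[1])
  tab
}
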