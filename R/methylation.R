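# Paired differential methylation on 450K-style beta values.
# Beta = methylated / (methylated + unmethylated) signal, in [0, 1].

#' Construct a paired beta-value matrix
#'
#' Holds probe x sample methylation beta values plus the sample sheet
#' linking each tumor sample to its paratumor pair.
#'
#' @param beta Numeric matrix (probes x samples), values in \[0, 1\] or
#'   `NA`; rownames are probe ids, colnames sample ids.
#' @param samples Data frame with columns `sample_id`, `group` (one of
#'   `"tumor"`, `"paratumor"`) and `pair_id` (patient identifier); each
#'   `pair_id` must occur exactly once per group.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, samples) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) stop("beta matrix needs probe ids as rownames")
  if (is.null(colnames(beta))) stop("beta matrix needs sample ids as colnames")
  stopifnot(all(c("sample_id", "group", "pair_id") %in% names(samples)))
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("sample sheet is missing entries for some beta-matrix columns")
  if (!all(samples$group %in% c("tumor", "paratumor")))
    stop("group must be 'tumor' or 'paratumor'")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  for (g in c("tumor", "paratumor")) {
    pid <- samples$pair_id[samples$group == g]
    if (anyDuplicated(pid)) stop("pair_id duplicated within group '", g, "'")
  }
  n_complete <- length(intersect(samples$pair_id[samples$group == "tumor"],
                                 samples$pair_id[samples$group == "paratumor"]))
  if (n_complete < 2) stop("need at least 2 complete tumor/paratumor pairs")
  structure(list(beta = beta, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples (",
      sum(x$samples$group == "tumor"), "tumor /",
      sum(x$samples$group == "paratumor"), "paratumor )\n")
  invisible(x)
}

# Matrices of tumor and paratumor betas, columns aligned by pair_id.
paired_betas <- function(m) {
  tum <- m$samples[m$samples$group == "tumor", ]
  par <- m$samples[m$samples$group == "paratumor", ]
  common <- intersect(tum$pair_id, par$pair_id)
  list(tumor = m$beta[, tum$sample_id[match(common, tum$pair_id)], drop = FALSE],
       paratumor = m$beta[, par$sample_id[match(common, par$pair_id)], drop = FALSE],
       pair_id = common)
}

#' Per-probe methylation difference (delta beta)
#'
#' Mean beta over tumor samples minus mean over paratumor samples,
#' skipping missing values. Probes with fewer than 2 non-missing values
#' in either group get `NA`.
#'
#' @param m A [beta_matrix()].
#' @return Named numeric vector of delta-beta values in \[-1, 1\].
#' @export
compute_delta_beta <- function(m) {
  tum <- m$beta[, m$samples$group == "tumor", drop = FALSE]
  par <- m$beta[, m$samples$group == "paratumor", drop = FALSE]
  d <- rowMeans(tum, na.rm = TRUE) - rowMeans(par, na.rm = TRUE)
  low <- rowSums(!is.na(tum)) < 2 | rowSums(!is.na(par)) < 2
  d[low] <- NA_real_
  d
}

# Exact two-sided signed-rank p for differences with no zeros and no
# tied absolute values; matches stats::wilcox.test(exact = TRUE).
signed_rank_exact_p <- function(w, n) {
  if (w > n * (n + 1) / 4) p <- stats::psignrank(w - 1, n, lower.tail = FALSE)
  else p <- stats::psignrank(w, n)
  min(2 * p, 1)
}

# Exact two-sided p by full sign-flip enumeration (handles midranks
# from tied absolute differences); 2^n null values, so small n only.
signed_rank_enum_p <- function(r, w, n) {
  masks <- 0:(2^n - 1)
  signs <- outer(masks, 0:(n - 1), function(i, j) bitwAnd(i, 2^j) > 0)
  wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(wall >= w), mean(wall <= w)))
}

paired_p_one <- function(d, method) {
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  if (all(d == 0)) return(1)
  if (method == "ttest") {
    if (stats::sd(d) == 0) return(0)  # constant nonzero shift: degenerate
    return(stats::t.test(d)$p.value)
  }
  dz <- d[d != 0]  # zero differences dropped (Wilcoxon's treatment)
  if (length(dz) < 1) return(1)
  n <- length(dz)
  r <- rank(abs(dz))
  if (n <= 200 && !anyDuplicated(r))
    return(signed_rank_exact_p(sum(r[dz > 0]), n))
  if (n <= 14)
    return(signed_rank_enum_p(r, sum(r[dz > 0]), n))
  suppressWarnings(stats::wilcox.test(dz)$p.value)
}

#' Paired test per probe
#'
#' Two-sided test on per-patient (tumor - paratumor) beta differences.
#' Pairs with a missing member are dropped per probe; probes with fewer
#' than 2 usable pairs get `NA`. The default Wilcoxon signed-rank test
#' drops zero differences first and uses the exact signed-rank null
#' when absolute differences are untied, full sign-flip enumeration
#' when they are tied at up to 14 pairs, and the normal approximation
#' with continuity correction beyond that; `"ttest"` selects the
#' paired t-test. Probes whose differences are all exactly
#' zero get p = 1 (the null holds exactly).
#'
#' @param m A [beta_matrix()].
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @return Named numeric vector of two-sided p-values.
#' @export
paired_test <- function(m, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  pb <- paired_betas(m)
  diffs <- pb$tumor - pb$paratumor
  apply(diffs, 1, paired_p_one, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Missing entries pass
#' through; the number of tests m is the number of non-missing
#' p-values. Values outside \[0, 1\] raise an error naming the index.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p-value out of [0, 1] at index ", bad[1], ": ", p[bad[1]])
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call significantly differentially methylated CpGs (SDMCs)
#'
#' A probe is an SDMC when `|delta_beta| >= dbeta_min` and
#' `adj_p <= adjp_max`, both bounds inclusive. Direction is `hyper`
#' for positive delta beta, `hypo` for negative. Probes with missing
#' delta beta or adjusted p are never SDMCs and are flagged.
#'
#' @param records Data frame with columns `delta_beta` and `adj_p`
#'   (other columns are carried through).
#' @param dbeta_min Minimum absolute methylation difference (default 0.25).
#' @param adjp_max Maximum adjusted p-value (default 0.05).
#' @return `records` with columns `direction`, `is_sdmc`, `flagged` added.
#' @export
call_sdmc <- function(records, dbeta_min = 0.25, adjp_max = 0.05) {
  stopifnot(all(c("delta_beta", "adj_p") %in% names(records)))
  db <- records$delta_beta
  records$direction <- ifelse(is.na(db), NA_character_,
                              ifelse(db > 0, "hyper",
                                     ifelse(db < 0, "hypo", NA_character_)))
  records$flagged <- is.na(db) | is.na(records$adj_p)
  records$is_sdmc <- !records$flagged &
    abs(db) >= dbeta_min & records$adj_p <= adjp_max
  records
}

#' Paired differential-methylation analysis
#'
#' Runs [compute_delta_beta()], [paired_test()], [adjust_bh()] and
#' [call_sdmc()] and joins probe coordinates from the manifest.
#'
#' @param m A [beta_matrix()].
#' @param manifest Probe manifest as from [read_probe_manifest()], with
#'   columns `probe_id`, `chrom`, `pos` (0-based); may be `NULL`.
#' @param method Paired test, see [paired_test()].
#' @param dbeta_min,adjp_max SDMC thresholds, see [call_sdmc()].
#' @return Data frame of per-probe records: `probe_id`, `chrom`, `pos`,
#'   `delta_beta`, `p_value`, `adj_p`, `direction`, `is_sdmc`, `flagged`.
#' @export
diff_methylation <- function(m, manifest = NULL,
                             method = c("wilcoxon", "ttest"),
                             dbeta_min = 0.25, adjp_max = 0.05) {
  db <- compute_delta_beta(m)
  p <- paired_test(m, method)
  rec <- data.frame(probe_id = rownames(m$beta), delta_beta = db,
                    p_value = p, adj_p = adjust_bh(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(manifest)) {
    i <- match(rec$probe_id, manifest$probe_id)
    rec$chrom <- manifest$chrom[i]
    rec$pos <- manifest$pos[i]
    rec <- rec[, c("probe_id", "chrom", "pos", "delta_beta", "p_value", "adj_p")]
  }
  call_sdmc(rec, dbeta_min = dbeta_min, adjp_max = adjp_max)
}

#' Read a beta-value matrix and sample sheet
#'
#' The beta TSV has a header row of sample ids and probe ids in the
#' first column; the sample sheet TSV has columns `sample_id`, `group`,
#' `pair_id`.
#'
#' @param beta_path,samples_path File paths.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(beta_path, samples_path) {
  tab <- utils::read.delim(beta_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab[[1]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  beta_matrix(beta, samples)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based, converted to
#' the package's 0-based convention on read) and optionally `strand`.
#'
#' @param path File path.
#' @return Data frame with 0-based `pos`.
#' @export
read_probe_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(man)))
  man$pos <- man$pos - 1
  if (any(man$pos < 0)) stop("probe manifest: position < 1 (expected 1-based)")
  man
}
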