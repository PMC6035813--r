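# z-score alteration calling and Kaplan-Meier / log-rank association
# of candidate-gene expression with clinical outcome.

#' z-score normalize one gene's expression across a cohort
#'
#' `(x - mean) / sd` with the sample standard deviation (n - 1
#' denominator), computed over the non-missing values of the whole
#' supplied cohort. Missing values pass through.
#'
#' @param x Numeric expression values, one per patient.
#' @param gene Gene name used in error messages.
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(x, gene = "gene") {
  ok <- !is.na(x)
  if (sum(ok) < 2)
    stop("zscore(", gene, "): need at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0)
    stop("zscore(", gene, "): zero standard deviation")
  (x - mean(x[ok])) / s
}

#' Classify patients as expression-altered
#'
#' Altered when `|z| >= thresh`, pooling high and low outliers
#' (two-sided, inclusive). Missing z-scores give `NA` and are excluded
#' downstream.
#'
#' @param z z-scores from [zscore()].
#' @param thresh Threshold (default 1.96, the two-sided 5% normal
#'   quantile).
#' @return Logical vector (`TRUE` = altered), `NA` where z is missing.
#' @export
classify_altered <- function(z, thresh = 1.96) {
  abs(z) >= thresh
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival S(t) drops by the factor (1 - d_i / n_i) at each distinct
#' time with at least one event; times with only censorings shrink the
#' risk set without a factor. Events precede censorings at tied times.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @return Data frame with one row per distinct event time: `time`,
#'   `at_risk`, `events`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("km_estimate: no patients")
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], at_risk = fit$n.risk[keep],
             events = fit$n.event[keep], survival = fit$surv[keep])
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group A are
#' compared with their hypergeometric expectation given the pooled
#' risk set; the statistic is (sum O - sum E)^2 / sum V, referred to a
#' chi-square distribution with 1 df. Zero total variance (e.g. no
#' usable event times) gives p = 1 with a warning.
#'
#' @param time Follow-up times for both groups combined.
#' @param event Event indicators.
#' @param group Two-level grouping vector (factor, logical or
#'   character).
#' @return List with `chi_square`, `p_value`, `n` (per-group sizes),
#'   `observed` and `expected` (per-group event counts).
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("logrank: need exactly 2 non-empty groups")
  if (sum(event) < 1) stop("logrank: need at least one event overall")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- sd$chisq
  if (!is.finite(chisq)) {
    warning("logrank: zero variance; p set to 1")
    chisq <- 0
  }
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = sd$n, observed = sd$obs, expected = sd$exp)
}

#' Survival association of candidate genes
#'
#' For each gene: z-score the cohort's expression, call altered status
#' at `|z| >= z_thresh`, and compare altered vs not-altered survival
#' with the log-rank test. Patients with missing expression for a gene
#' are excluded for that gene. Genes where either arm is empty get
#' `NA` results.
#'
#' @param clinical Data frame with columns `patient_id`, `time_months`,
#'   `event` and one numeric column per gene.
#' @param genes Gene column names to test; defaults to all columns
#'   after the three clinical ones.
#' @param z_thresh Alteration threshold (default 1.96).
#' @return Data frame with one row per gene: `gene`, `n_altered`,
#'   `n_not_altered`, `chi_square`, `p_value`.
#' @export
survival_association <- function(clinical, genes = NULL, z_thresh = 1.96) {
  need <- c("patient_id", "time_months", "event")
  stopifnot(all(need %in% names(clinical)))
  if (is.null(genes)) genes <- setdiff(names(clinical), need)
  rows <- lapply(genes, function(g) {
    z <- zscore(clinical[[g]], gene = g)
    altered <- classify_altered(z, thresh = z_thresh)
    ok <- !is.na(altered)
    na_row <- data.frame(gene = g, n_altered = sum(altered[ok]),
                         n_not_altered = sum(!altered[ok]),
                         chi_square = NA_real_, p_value = NA_real_,
                         stringsAsFactors = FALSE)
    if (length(unique(altered[ok])) != 2) return(na_row)
    lr <- logrank(clinical$time_months[ok], clinical$event[ok], altered[ok])
    na_row$chi_square <- lr$chi_square
    na_row$p_value <- lr$p_value
    na_row
  })
  do.call(rbind, rows)
}

#' Read a clinical table
#'
#' TSV with columns `patient_id`, `time_months`, `event` (0/1) and one
#' column per gene.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("clinical table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$time_months <= 0)) stop("clinical table: time_months must be > 0")
  if (!all(tab$event %in% c(0, 1))) stop("clinical table: event must be 0/1")
  tab
}
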