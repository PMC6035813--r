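# Pipeline orchestration: diffmeth -> difflnc -> annotate -> integrate
# (-> survival when a clinical table is supplied). Every stage is
# file-in / file-out, so stages rerun individually are byte-identical
# to a full run.

#' Build a pipeline configuration
#'
#' Paths default to the file names written by [simulate_bundle()].
#' Thresholds default to the pipeline's standard values: SDMC at
#' |delta beta| >= 0.25 and adjusted p <= 0.05; DE lncRNA at length >=
#' 200 bp, |log2FC| >= 2, adjusted p <= 0.05; promoter = TSS +/- 1000
#' bp; CpG shores +/- 2000 bp; alteration at |z| >= 1.96.
#'
#' @param input_dir Directory holding the input files.
#' @param out_dir Output directory.
#' @param ... Overrides for any config entry (paths or thresholds).
#' @return A named list (`pipeline_config`).
#' @export
pipeline_config <- function(input_dir, out_dir, ...) {
  p <- function(f) file.path(input_dir, f)
  cfg <- list(
    beta_path = p("beta.tsv"), samples_path = p("samples.tsv"),
    manifest_path = p("probes.tsv"), lnc_path = p("lncrna.tsv"),
    genes_path = p("genes.bed"),
    track_paths = c(snp = p("snp.bed"), cpg_island = p("cpg_island.bed"),
                    enhancer = p("enhancer.bed"), dhs = p("dhs.bed")),
    clinical_path = if (file.exists(p("clinical.tsv"))) p("clinical.tsv") else NULL,
    out_dir = out_dir,
    dbeta_min = 0.25, adjp_max = 0.05, test_method = "wilcoxon",
    min_len = 200, min_abs_lfc = 2.0, lnc_adjp_max = 0.05,
    promoter_flank = 1000, shore_width = 2000, z_thresh = 1.96,
    met_mode = "promoter_or_body")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds `input_dir`, `out_dir` and optional overrides for
#' any [pipeline_config()] entry.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$input_dir), !is.null(y$out_dir))
  extra <- y[setdiff(names(y), c("input_dir", "out_dir"))]
  if (!is.null(extra$track_paths)) extra$track_paths <- unlist(extra$track_paths)
  do.call(pipeline_config, c(list(input_dir = y$input_dir,
                                  out_dir = y$out_dir), extra))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, cfg, body) {
  t0 <- Sys.time()
  res <- tryCatch(body(), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  stage_log(stage, "done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  res
}

#' Run the crosstalk pipeline
#'
#' Executes the requested stages in order diffmeth, difflnc, annotate,
#' integrate, survival; each stage reads its inputs (including
#' upstream stage outputs) from disk and writes its results under
#' `cfg$out_dir`, so any subset reproduces exactly what a full run
#' writes. A JSON run report with the headline counts and the
#' resolved configuration are written alongside.
#'
#' @param cfg A [pipeline_config()] list.
#' @param stages Character vector of stages to run.
#' @return The run report, invisibly (a named list).
#' @export
run_pipeline <- function(cfg, stages = c("diffmeth", "difflnc", "annotate",
                                         "integrate", "survival")) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(cfg$out_dir, f)
  report <- list()

  if ("diffmeth" %in% stages) {
    report <- c(report, run_stage("diffmeth", cfg, function() {
      m <- read_beta_matrix(cfg$beta_path, cfg$samples_path)
      man <- read_probe_manifest(cfg$manifest_path)
      dm <- diff_methylation(m, man, method = cfg$test_method,
                             dbeta_min = cfg$dbeta_min,
                             adjp_max = cfg$adjp_max)
      write_tsv(dm, o("dm_results.tsv"))
      stage_log("diffmeth", "%d probes, %d SDMCs", nrow(dm), sum(dm$is_sdmc))
      list(n_probes = nrow(dm), n_sdmc = sum(dm$is_sdmc),
           n_hyper = sum(dm$is_sdmc & dm$direction == "hyper"),
           n_hypo = sum(dm$is_sdmc & dm$direction == "hypo"))
    }))
  }

  if ("difflnc" %in% stages) {
    report <- c(report, run_stage("difflnc", cfg, function() {
      lnc <- filter_lncrna(read_lnc_table(cfg$lnc_path),
                           min_len = cfg$min_len,
                           min_abs_lfc = cfg$min_abs_lfc,
                           max_adjp = cfg$lnc_adjp_max)
      write_tsv(lnc, o("lnc_results.tsv"))
      stage_log("difflnc", "%d candidates, %d DE", nrow(lnc), sum(lnc$is_de))
      list(n_lnc = nrow(lnc), n_de_lnc = sum(lnc$is_de))
    }))
  }

  if ("annotate" %in% stages) {
    report <- c(report, run_stage("annotate", cfg, function() {
      dm <- utils::read.delim(o("dm_results.tsv"), stringsAsFactors = FALSE)
      sdmc <- dm[dm$is_sdmc, , drop = FALSE]
      tracks <- lapply(cfg$track_paths, read_bed)
      if ("cpg_island" %in% names(tracks)) {
        tracks$cpg_island_shore <- expand_shores(tracks$cpg_island,
                                                 shore_width = cfg$shore_width)
      }
      ann <- annotate_loci(sdmc, tracks)
      write_tsv(ann$summary, o("annotation_summary.tsv"))
      write_tsv(ann$flags, o("annotation_flags.tsv"))
      list(annotation = stats::setNames(as.list(ann$summary$fraction),
                                        paste0("frac_", ann$summary$category)))
    }))
  }

  if ("integrate" %in% stages) {
    report <- c(report, run_stage("integrate", cfg, function() {
      dm <- utils::read.delim(o("dm_results.tsv"), stringsAsFactors = FALSE)
      sdmc <- dm[dm$is_sdmc, , drop = FALSE]
      lnc <- utils::read.delim(o("lnc_results.tsv"), stringsAsFactors = FALSE)
      genes <- gene_models(read_bed(cfg$genes_path),
                           flank = cfg$promoter_flank)
      res <- integrate_crosstalk(sdmc, lnc, genes, met_mode = cfg$met_mode)
      write_tsv(res$met_lnc_pairs, o("met_lnc_pairs.tsv"))
      writeLines(res$met_targets, o("met_targets.txt"))
      writeLines(res$lnc_targets, o("lnc_targets.txt"))
      writeLines(res$common_targets, o("common_targets.txt"))
      stage_log("integrate", "%d met targets, %d lnc targets, %d common",
                res$n_met, res$n_lnc, res$n_common)
      list(n_met_targets = res$n_met, n_lnc_targets = res$n_lnc,
           n_common = res$n_common, overlap_p = res$overlap_p,
           n_met_lnc_pairs = nrow(res$met_lnc_pairs))
    }))
  }

  if ("survival" %in% stages && !is.null(cfg$clinical_path)) {
    report <- c(report, run_stage("survival", cfg, function() {
      clin <- read_clinical(cfg$clinical_path)
      sa <- survival_association(clin, z_thresh = cfg$z_thresh)
      write_tsv(sa, o("survival_results.tsv"))
      curves <- do.call(rbind, lapply(sa$gene, function(g) {
        altered <- classify_altered(zscore(clin[[g]], g), cfg$z_thresh)
        do.call(rbind, lapply(c(TRUE, FALSE), function(a) {
          i <- which(altered == a)
          if (length(i) == 0) return(NULL)
          km <- km_estimate(clin$time_months[i], clin$event[i])
          if (nrow(km) == 0) return(NULL)
          cbind(gene = g, arm = if (a) "altered" else "not_altered", km)
        }))
      }))
      if (is.null(curves))
        curves <- data.frame(gene = character(), arm = character(),
                             time = numeric(), at_risk = integer(),
                             events = integer(), survival = numeric())
      write_tsv(curves, o("km_curves.tsv"))
      list(survival = stats::setNames(as.list(sa$p_value),
                                      paste0("logrank_p_", sa$gene)))
    }))
  }

  jsonlite::write_json(report, o("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], o("config_resolved.yaml"))
  invisible(report)
}
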