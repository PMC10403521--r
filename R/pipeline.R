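#' Run the full interaction-scan pipeline
#'
#' Binds the stages end to end: read inputs (or accept in-memory objects),
#' variant QC, the single-variant scan, the two-step screen and fixed
#' thresholds, inflation diagnostics, stratified odds-ratio tables for
#' declared hits, and optional meta-analysis and rare-variant passes. Each
#' stage failure aborts with the stage name and a machine-readable code
#' (`gxe_pipeline_error` condition with a `stage` field).
#'
#' @param config named list (or path to a flat key-value file read by
#'   [read_config()]). Recognised entries:
#'   * `vcf`, `pheno`: input paths (alternatively pass `cohort` and
#'     `dosage` objects directly);
#'   * `exposure`: exposure column name in the phenotype file
#'     (default `"diabetes"`);
#'   * `covariate_set`: 1 (age, sex, study/platform, pc1-pc3) or 2 (set 1
#'     plus `bmi`);
#'   * `tests`: character vector for [scan_variants()];
#'   * `B`, `alpha`: two-step screen parameters (defaults 5, 0.05);
#'   * `n_families`: number of primary test families sharing alpha
#'     (default 3);
#'   * `known_loci`: optional path to a headerless `chr bp` file of known
#'     susceptibility anchors for presentation pruning;
#'   * `sets`: optional gene-set mapping path triggering the rare-variant
#'     pass (with `rare_vcf` for the rare dosages);
#'   * `run_meta`: logical, per-study exposure meta-analysis;
#'   * `out_dir`: when set, results are written there as TSV/text.
#' @param cohort,dosage optional in-memory inputs overriding `vcf`/`pheno`.
#' @return list with `scan`, `qc_report`, `screen` (two-step output),
#'   `thresholds` (per-family and genome-wide), `inflation`, `hits`
#'   (variants significant on the primary 3-d.f. rule with their stratified
#'   OR tables), `meta`, `rare`, `log` (character vector of stage events).
#' @export
run_pipeline <- function(config, cohort = NULL, dosage = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- function(key, default = NULL) config[[key]] %||% default
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("gxe_pipeline_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }

  note("pipeline start")
  if (is.null(cohort)) {
    cohort <- stage("read_pheno",
                    read_phenotype_table(cfg("pheno"),
                                         exposure = cfg("exposure", "diabetes")))
  }
  if (is.null(dosage)) {
    dosage <- stage("read_vcf", read_dosage_vcf(cfg("vcf")))
  }
  covset <- cfg("covariate_set", 1)
  covariates <- intersect(c("age", "sex", "study", "platform",
                            "pc1", "pc2", "pc3",
                            if (covset >= 2) "bmi"),
                          names(cohort))
  note("covariate set ", covset, ": ", paste(covariates, collapse = ", "))

  qc <- stage("qc", qc_filter_variants(dosage, qc_thresholds(),
                                       status = cohort$status[
                                         match(colnames(dosage$dosage),
                                               cohort$subject_id)]))
  note("qc: ", nrow(qc$dosage$dosage), " of ", nrow(dosage$dosage),
       " variants retained")

  scan <- stage("scan", scan_variants(cohort, qc$dosage,
                                      covariates = covariates,
                                      tests = cfg("tests",
                                                  c("dg", "eg", "gxe", "2df",
                                                    "3df", "edge"))))
  note("scan: ", nrow(scan), " variants tested")

  thresholds <- apply_fwer_split(cfg("n_families", 3), cfg("alpha", 0.05))
  screen <- stage("two_step",
                  two_step_screen(scan, B = cfg("B", 5),
                                  alpha = thresholds$per_family,
                                  dosage = qc$dosage))
  infl <- stage("inflation",
                inflation_report(scan$p_gxe,
                                 n_cases = sum(cohort$status == 1),
                                 n_controls = sum(cohort$status == 0)))
  note(sprintf("inflation: lambda %.3f, lambda_1000 %.3f",
               infl$lambda, infl$lambda_1000))

  pruned <- NULL
  if (!is.null(cfg("known_loci"))) {
    known <- utils::read.table(cfg("known_loci"), header = FALSE,
                               col.names = c("chr", "bp"),
                               colClasses = c("character", "integer"))
    ctrl <- cohort$subject_id[cohort$status == 0]
    ref <- dosage
    ref$dosage <- ref$dosage[, intersect(colnames(ref$dosage), ctrl),
                             drop = FALSE]
    pruned <- stage("prune", prune_known_loci(scan, known, ref))
    note("prune: ", nrow(pruned), " variants survive known-locus removal")
  }

  # primary declaration: 3-d.f. p below the genome-wide threshold shared
  # across the test families
  primary_thr <- thresholds$genome_wide / cfg("n_families", 3)
  hit_ids <- scan$id[!is.na(scan$p_3df) & scan$p_3df < primary_thr]
  hit_ids <- union(hit_ids, screen$significant)
  hits <- lapply(hit_ids, function(vid) {
    g <- qc$dosage$dosage[match(vid, qc$dosage$info$id), ]
    stage("stratified", stratified_ors(cohort, g, covariates = covariates))
  })
  names(hits) <- hit_ids
  note(length(hits), " variant(s) declared for stratified follow-up")

  meta <- NULL
  if (isTRUE(cfg("run_meta", FALSE)) && "study" %in% names(cohort)) {
    est <- stage("meta", per_study_estimates(cohort))
    meta <- if (nrow(est) >= 2) list(estimates = est, pooled = hk_meta(est),
                                     funnel = funnel_points(est))
    else list(estimates = est, pooled = NULL, funnel = funnel_points(est))
    note("meta: ", nrow(est), " studies pooled")
  }

  rare <- NULL
  if (!is.null(cfg("sets"))) {
    rare_dos <- if (!is.null(cfg("rare_vcf"))) {
      stage("read_rare_vcf", read_dosage_vcf(cfg("rare_vcf")))
    } else dosage
    rare <- stage("rare", rare_scan(cohort, rare_dos, cfg("sets"),
                                    covariates = covariates))
    note("rare: ", nrow(rare), " sets tested")
  }

  out <- list(scan = scan, qc_report = qc$report, screen = screen,
              thresholds = thresholds, inflation = infl, pruned = pruned,
              hits = hits, meta = meta, rare = rare, log = log)
  if (!is.null(cfg("out_dir"))) {
    dir.create(cfg("out_dir"), showWarnings = FALSE, recursive = TRUE)
    od <- cfg("out_dir")
    write_scan(scan, file.path(od, "scan.tsv"))
    utils::write.table(qc$report, file.path(od, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(screen$table, file.path(od, "two_step.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("lambda = %.6f", infl$lambda),
                 sprintf("lambda_1000 = %.6f", infl$lambda_1000),
                 sprintf("n_cases = %d", infl$n_cases),
                 sprintf("n_controls = %d", infl$n_controls)),
               file.path(od, "inflation.txt"))
    utils::write.table(infl$qq_points, file.path(od, "qq_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rare)) {
      utils::write.table(rare, file.path(od, "rare_sets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(meta)) {
      write_study_estimates(meta$estimates,
                            file.path(od, "study_estimates.tsv"))
    }
    writeLines(log, file.path(od, "run_log.txt"))
  }
  out
}
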