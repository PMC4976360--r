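#' Run the full sex-locus analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> discover -> classify ->
#' scan -> report with fixed seeds, writing plain-text TSV outputs and a
#' run log. The default design mirrors a two-stage study: sex-linked
#' loci are discovered by strict segregation in a named subset of
#' samples, all remaining samples are genetically sexed against the
#' discovered panel, and the exact association scan runs on the full
#' cohort.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results: `matrix`, `truth` (when simulated),
#'   `filter_report` (when filtering was requested), `discovery`
#'   (passing-locus tibble), `orientation` (pass counts under both
#'   orientations), `classification` (a [classify_cohort()] object),
#'   `scan`, `regions`, `summary`, and `files` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("sexscan pipeline ", as.character(utils::packageVersion("sexscan"))),
    paste0("seed: ", config$seed)
  )
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }

  # --- input ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_cohort(cfg)
    })
    g <- sim$matrix
    truth <- sim$truth
  } else {
    g <- stage("read", read_vcf(config$vcf, read_sample_meta(config$meta)))
  }

  # --- optional site filtering --------------------------------------
  filt_report <- NULL
  if (config$apply_filters) {
    g_filt <- stage("filter", suppressWarnings(filter_sites(g)))
    filt_report <- filter_report(g_filt)
    readr::write_tsv(filt_report, file.path(out_dir, "filter_report.tsv"),
                     progress = FALSE)
    g_scan <- g_filt
  } else {
    g_scan <- g
  }

  # --- discovery on the designated subset ---------------------------
  ids <- g$samples$sample_id
  disc_ids <- config$discovery_samples
  if (is.null(disc_ids)) disc_ids <- ids
  stopifnot(all(disc_ids %in% ids))
  g_disc <- g[, ids %in% disc_ids]
  discovery <- stage("discover", find_sex_linked(g_disc, config$criterion))
  orientation <- stage("orientation", orientation_sweep(g_disc, config$criterion))
  readr::write_tsv(discovery, file.path(out_dir, "discovery.tsv"),
                   progress = FALSE)

  # --- classification of the remaining samples ----------------------
  # disjoint by construction: everyone not used for discovery is classified
  class_ids <- setdiff(ids, disc_ids)
  if (length(class_ids) == 0) class_ids <- ids  # no held-out set: classify all
  classification <- stage("classify", {
    if (nrow(discovery) == 0) NULL
    else classify_cohort(g[, ids %in% class_ids], discovery)
  })
  if (!is.null(classification)) {
    readr::write_tsv(tidy(classification),
                     file.path(out_dir, "sex_calls.tsv"), progress = FALSE)
    readr::write_tsv(classification$confusion,
                     file.path(out_dir, "confusion.tsv"), progress = FALSE)
  }

  # --- genome scan and region calling -------------------------------
  scan <- stage("scan", scan_sex_association(g_scan))
  regions <- stage("regions", call_regions(scan,
                                           sd_multiplier = config$sd_multiplier,
                                           merge_gap_bp = config$merge_gap_bp))
  summary <- summarize_regions(regions)
  readr::write_tsv(
    scan[, c("chrom", "pos", "ref", "alt", "tested", "log_p", "neglog10_p")],
    file.path(out_dir, "scan.tsv"), progress = FALSE
  )
  readr::write_tsv(summary$regions, file.path(out_dir, "regions.tsv"),
                   progress = FALSE)

  log_lines <- c(log_lines, sprintf("total sex-linked loci in regions: %d",
                                    summary$total_sex_linked))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  list(
    matrix = g, truth = truth, filter_report = filt_report,
    discovery = discovery, orientation = orientation,
    classification = classification, scan = scan, regions = regions,
    summary = summary,
    files = list.files(out_dir, full.names = TRUE)
  )
}

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()]) or both `vcf` and `meta` paths must
#' be given. `discovery_samples` names the subset used for segregation
#' discovery; the remaining samples are classified against the
#' discovered panel (all samples when no subset is named).
#'
#' @param sim A [sim_config()], or `NULL` to read `vcf` + `meta`.
#' @param vcf,meta Input VCF and sample-metadata TSV paths.
#' @param discovery_samples Character vector of sample ids, or `NULL`.
#' @param criterion A [segregation_criterion()].
#' @param apply_filters Run [filter_sites()] before the scan.
#' @param sd_multiplier,merge_gap_bp Region-calling parameters, see
#'   [call_regions()].
#' @param out_dir Output directory for the TSV reports and run log.
#' @param seed Integer seed governing every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), vcf = NULL, meta = NULL,
                            discovery_samples = NULL,
                            criterion = segregation_criterion(),
                            apply_filters = FALSE,
                            sd_multiplier = 6, merge_gap_bp = 1e6,
                            out_dir = tempfile("sexscan_run_"),
                            seed = 1L) {
  if (is.null(sim) && (is.null(vcf) || is.null(meta))) {
    stop("either a simulation config or vcf + meta paths are required",
         call. = FALSE)
  }
  if (!is.null(vcf)) stopifnot(file.exists(vcf), file.exists(meta))
  structure(
    list(sim = sim, vcf = vcf, meta = meta,
         discovery_samples = discovery_samples, criterion = criterion,
         apply_filters = apply_filters, sd_multiplier = sd_multiplier,
         merge_gap_bp = merge_gap_bp, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}
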