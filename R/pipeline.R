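#' Default pipeline configuration
#'
#' A nested list describing a full run: data source (simulate with a
#' [simConfig()], or `counts`/`samples` input paths), DE thresholds, bootstrap
#' overlap parameters, peak-integration settings and stage toggles. The fully
#' resolved configuration (defaults merged in) is persisted next to the
#' outputs by [runPipeline()]. One global seed spawns deterministic per-stage
#' child seeds so stages can be rerun in isolation.
#'
#' @param seed Global seed.
#' @param outdir Output directory.
#' @return A nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L, outdir = "paraloverlap-run") {
  list(
    version = 1L,
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(enabled = TRUE, params = list()),
    input = list(counts = NULL, samples = NULL, aliases = NULL),
    de = list(enabled = TRUE, min_total = 10, alpha = 0.05,
              lfc_cutoff = 0.58, shrink_disp = 0.3, shrink_lfc = FALSE),
    overlap = list(enabled = TRUE, n_boot = 100L, min_unique = 3L,
                   max_pairs = 10000L, alternative = "two.sided",
                   n_boot_cor = 100L),
    peaks = list(enabled = TRUE, peaks = NULL, tss = NULL, marks = NULL,
                 max_dist = 1000000, promoter_halfwidth = 5000,
                 fdr_cut = 0.05, sim_params = list()))
}

# deep-merge user values over defaults
.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[nm] <- list(user[[nm]])  # keeps explicit NULLs in place
  }
  defaults
}

#' Read / validate a pipeline configuration
#'
#' `readRunConfig` loads a YAML file and merges it over
#' [defaultRunConfig()]; `validateRunConfig` checks parameter domains and
#' that referenced input files exist, failing with the offending field named
#' before any computation starts.
#'
#' @param path Path to a YAML configuration.
#' @return The resolved configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- .mergeConfig(defaultRunConfig(), user)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config A configuration list.
#' @export
validateRunConfig <- function(config) {
  .assertScalarNumber(config$seed, "seed", min = 0, max = 2^31 - 1)
  .assertScalarNumber(config$de$alpha, "de$alpha", min = 0, max = 1)
  .assertScalarNumber(config$de$lfc_cutoff, "de$lfc_cutoff", min = 0)
  .assertScalarNumber(config$de$min_total, "de$min_total", min = 0)
  .assertScalarNumber(config$overlap$n_boot, "overlap$n_boot", min = 2)
  .assertScalarNumber(config$overlap$min_unique, "overlap$min_unique",
                      min = 1)
  if (!config$overlap$alternative %in% c("two.sided", "greater", "less"))
    stop("invalid configuration: `overlap$alternative` must be two.sided, ",
         "greater or less", call. = FALSE)
  .assertScalarNumber(config$peaks$max_dist, "peaks$max_dist", min = 0)
  if (isTRUE(config$simulate$enabled)) {
    sim <- do.call(simConfig, config$simulate$params)
    if (config$overlap$min_unique > sim$n_reps)
      stop("invalid configuration: `min_unique` (", config$overlap$min_unique,
           ") exceeds n_reps (", sim$n_reps, ")", call. = FALSE)
  } else {
    for (f in c("counts", "samples")) {
      p <- config$input[[f]]
      if (is.null(p) || !file.exists(p))
        stop("invalid configuration: input$", f, " missing or not found",
             call. = FALSE)
    }
  }
  if (isTRUE(config$peaks$enabled) && !isTRUE(config$simulate$enabled)) {
    for (f in c("peaks", "tss")) {
      p <- config$peaks[[f]]
      if (is.null(p) || !file.exists(p))
        stop("invalid configuration: peaks$", f, " missing or not found",
             call. = FALSE)
    }
  }
  config
}

# format one direction's row for table1
.fmtCI <- function(ci) sprintf("[%.3f-%.3f]", ci[1], ci[2])
.capitalise <- function(x) paste0(toupper(substr(x, 1, 1)),
                                  substr(x, 2, nchar(x)))

#' Render the observed/expected overlap summary table
#'
#' Produces the machine twin of the bootstrap-overlap summary: rows Up, Down
#' and All with the observed Jaccard index and its interval, each paralog's
#' expected Jaccard with basic bootstrap interval and Z-test p-value, and
#' the observed/expected ratio as a one-decimal percentage. Directions with
#' empty DEG sets in every replicate render as `NA`, not 0.
#'
#' @param x An [OverlapAnalysis-class], or a report list from
#'   [runPipeline()].
#' @param path Optional TSV output path.
#' @return data.frame with the table rows.
#' @export
renderTable1 <- function(x, path = NULL) {
  if (methods::is(x, "OverlapAnalysis")) {
    dirs <- c("up", "down", "all")
    rows <- lapply(dirs, function(d) {
      empty <- !is.finite(x@expected1[d]) || !is.finite(x@expected2[d]) ||
        (x@expected1[d] == 0 && x@expected2[d] == 0 && x@observed[d] == 0)
      if (empty) {
        return(data.frame(
          direction = .capitalise(d), observed_j = NA_real_,
          observed_ci = "NA", expected_j_tf1 = NA_real_, ci_tf1 = "NA",
          p_tf1 = NA_real_, expected_j_tf2 = NA_real_, ci_tf2 = "NA",
          p_tf2 = NA_real_, oe_ratio = "NA"))
      }
      data.frame(
        direction = .capitalise(d),
        observed_j = round(x@observed[d], 3),
        observed_ci = .fmtCI(x@ciObserved[d, ]),
        expected_j_tf1 = round(x@expected1[d], 3),
        ci_tf1 = .fmtCI(x@ci1[d, ]),
        p_tf1 = signif(x@p1[d], 3),
        expected_j_tf2 = round(x@expected2[d], 3),
        ci_tf2 = .fmtCI(x@ci2[d, ]),
        p_tf2 = signif(x@p2[d], 3),
        oe_ratio = if (is.finite(x@oeRatio[d]))
          sprintf("%.1f%%", x@oeRatio[d]) else "NA")
    })
    tab <- do.call(rbind, rows)
  } else if (is.list(x) && !is.null(x$table1)) {
    tab <- as.data.frame(x$table1)
  } else stop("cannot render: need an OverlapAnalysis or a report list",
              call. = FALSE)
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

# serialise an OverlapAnalysis for the JSON report
.overlapReportList <- function(ov) {
  dirs <- c("up", "down", "all")
  per_dir <- lapply(dirs, function(d) list(
    observed_j = unname(ov@observed[d]),
    observed_ci = unname(ov@ciObserved[d, ]),
    expected_j_tf1 = unname(ov@expected1[d]),
    ci_tf1 = unname(ov@ci1[d, ]),
    z_tf1 = unname(ov@z1[d]), p_tf1 = unname(ov@p1[d]),
    expected_j_tf2 = unname(ov@expected2[d]),
    ci_tf2 = unname(ov@ci2[d, ]),
    z_tf2 = unname(ov@z2[d]), p_tf2 = unname(ov@p2[d]),
    oe_ratio_pct = unname(ov@oeRatio[d])))
  names(per_dir) <- dirs
  list(directions = per_dir,
       correlation = ov@correlation[c("pearson_r", "r_squared", "ci",
                                      "n_genes", "n_boot")],
       deg_counts = list(
         TF1 = list(up = length(upGenes(ov@degs$TF1)),
                    down = length(downGenes(ov@degs$TF1))),
         TF2 = list(up = length(upGenes(ov@degs$TF2)),
                    down = length(downGenes(ov@degs$TF2)))),
       universe_size = universeSize(ov@degs$TF1),
       params = ov@params)
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in order — simulate (or load counts), DE for
#' both paralogs, bootstrap overlap analysis, peak integration — writing all
#' exchange files plus an aggregated `report.json` and `table1.tsv` into the
#' output directory. The resolved configuration is persisted as
#' `resolved_config.yaml`. Identical configuration and seed give
#' byte-identical reports. Failure of the (optional) peak stage does not
#' discard earlier outputs.
#'
#' @param config A configuration list ([defaultRunConfig()]-shaped) or a
#'   path to a YAML file.
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- validateRunConfig(.mergeConfig(defaultRunConfig(), config))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_out <- config
  cfg_out$simulate$params <- unclass(do.call(simConfig,
                                             config$simulate$params))
  yaml::write_yaml(cfg_out, file.path(outdir, "resolved_config.yaml"))
  report <- list(schema_version = 1L, seed = config$seed,
                 package_version = as.character(packageVersion("paraloverlap")))

  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    simp <- config$simulate$params
    simp$seed <- .deriveSeed(config$seed, "simulate")
    sim <- simulateCounts(do.call(simConfig, simp))
    pcs <- sim$counts; truth <- sim$truth
    writeCountMatrix(pcs, file.path(outdir, "counts.tsv"),
                     file.path(outdir, "samples.csv"))
    writeTruth(truth, file.path(outdir, "truth.tsv"))
    report$simulate <- list(seed = simp$seed, n_genes = nrow(pcs),
                            n_samples = ncol(pcs))
  } else {
    pcs <- readCountMatrix(config$input$counts, config$input$samples,
                           aliases = unlist(config$input$aliases))
  }

  res1 <- res2 <- NULL
  if (isTRUE(config$de$enabled)) {
    de <- config$de
    xf <- filterLowCounts(pcs, de$min_total)
    res1 <- runCombinedContrast(xf, "TF1", min_total = 0,
                                shrink_disp = de$shrink_disp,
                                shrink_lfc = de$shrink_lfc)
    res2 <- runCombinedContrast(xf, "TF2", min_total = 0,
                                shrink_disp = de$shrink_disp,
                                shrink_lfc = de$shrink_lfc)
    deg1 <- callDEGs(res1, de$alpha, de$lfc_cutoff)
    deg2 <- callDEGs(res2, de$alpha, de$lfc_cutoff)
    writeDEResult(res1, file.path(outdir, "de_TF1.tsv"))
    writeDEResult(res2, file.path(outdir, "de_TF2.tsv"))
    writeDEGSet(deg1, file.path(outdir, "degs_TF1.json"))
    writeDEGSet(deg2, file.path(outdir, "degs_TF2.json"))
    report$de <- list(
      n_tested = sum(res1$tested), n_filtered = nrow(pcs) - nrow(xf),
      TF1 = list(up = length(upGenes(deg1)), down = length(downGenes(deg1))),
      TF2 = list(up = length(upGenes(deg2)), down = length(downGenes(deg2))))
  }

  ov <- NULL
  if (isTRUE(config$overlap$enabled)) {
    op <- config$overlap
    ov <- degOverlapAnalysis(
      pcs, B = op$n_boot, min_unique = op$min_unique,
      alpha = config$de$alpha, lfc_cutoff = config$de$lfc_cutoff,
      min_total = config$de$min_total, max_pairs = op$max_pairs,
      alternative = op$alternative, shrink_disp = config$de$shrink_disp,
      n_boot_cor = op$n_boot_cor, seed = .deriveSeed(config$seed, "overlap"))
    report$overlap <- .overlapReportList(ov)
    tab <- renderTable1(ov, file.path(outdir, "table1.tsv"))
    report$table1 <- tab
  }

  if (isTRUE(config$peaks$enabled)) {
    pk_result <- tryCatch({
      pk <- config$peaks
      if (isTRUE(config$simulate$enabled)) {
        ps <- simulatePeaks(truth, do.call(peakSimConfig, pk$sim_params),
                            seed = .deriveSeed(config$seed, "peaks"))
        peaks <- ps$peaks; tss <- ps$tss
        writePeaks(peaks, file.path(outdir, "peaks.narrowPeak"),
                   format = "narrowPeak")
        writeTSS(tss, file.path(outdir, "tss.bed"))
      } else {
        peaks <- readPeaks(pk$peaks)
        tss <- readTSS(pk$tss)
      }
      if (!is.null(pk$marks)) {
        marks <- readPeaks(pk$marks)
        peaks <- filterActivePeaks(peaks, marks)
      }
      ann <- tssDistanceAnnotation(peaks, tss, pk$promoter_halfwidth)
      links <- linkPeaksToGenes(peaks, tss, pk$max_dist,
                                pk$promoter_halfwidth)
      write.table(links, file.path(outdir, "links.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      out <- list(n_peaks = length(peaks),
                  promoter_fraction = ann$promoter_fraction,
                  n_links = nrow(links))
      if (!is.null(res1)) {
        deg1 <- callDEGs(res1, config$de$alpha, config$de$lfc_cutoff)
        direct <- classifyDirectTargets(links, deg1)
        fn <- predictTFFunction(links, res1, fdr_cut = pk$fdr_cut)
        jsonlite::write_json(
          list(activating_p = fn$activating_p,
               repressive_p = fn$repressive_p),
          file.path(outdir, "function_prediction.json"), auto_unbox = TRUE,
          digits = 10)
        out$n_up_direct <- direct$n_up_direct
        out$n_down_direct <- direct$n_down_direct
        out$activating_p <- fn$activating_p
        out$repressive_p <- fn$repressive_p
      }
      out
    }, error = function(e) {
      warning("peak stage failed (earlier outputs kept): ",
              conditionMessage(e))
      list(error = conditionMessage(e))
    })
    report$peaks <- pk_result
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
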