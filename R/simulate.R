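#' Simulation configuration for the paired CRISPR perturbation design
#'
#' Collects and validates all parameters of the negative-binomial count
#' simulator. Defaults describe a desk-scale experiment with the structure of
#' the six-condition design: two paralogous TFs, each perturbed by
#' CRISPR-activation (OE) and CRISPR knockout (KO), with non-targeting
#' controls per system, six replicates per condition, stress responses shared
#' within a CRISPR system, and NB counts with a 1/mu dispersion trend.
#'
#' @param n_genes Number of genes (including the two TF genes themselves).
#' @param n_reps Replicates per condition (>= 3 so the constrained bootstrap
#'   is satisfiable).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of the
#'   log-normal per-gene baseline expression.
#' @param dispersion_a0,dispersion_a1 Dispersion trend
#'   \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#' @param libsize_sd Log-normal sd of per-sample size factors (renormalised to
#'   geometric mean 1).
#' @param n_targets_tf1,n_targets_tf2 Number of direct targets per TF.
#' @param shared_fraction Fraction of the smaller target set shared by both
#'   TFs; exactly `round(shared_fraction * min(n_targets))` genes are targets
#'   of both, with the same signed effect for both TFs.
#' @param frac_down Fraction of targets that are downregulated.
#' @param effect_log2fc_mean,effect_log2fc_sd Target effect magnitudes are
#'   `|N(mean, sd)|` in log2 units, applied on the OE side.
#' @param ko_oe_ratio KO-side effect magnitude relative to the OE side
#'   (mirrored sign); the default 0.5 reflects the weaker knockout response.
#' @param stress_fraction,stress_log2fc_sd Fraction of genes responding to
#'   each CRISPR system itself and the sd of those log2 responses; a stress
#'   response is identical in targeting and control conditions of its system,
#'   which is exactly what the combined contrast cancels.
#' @param tf_oe_log2fc Named numeric (TF1, TF2): log2FC of each TF gene under
#'   its own OE (defaults 4.2 and 5.2).
#' @param tf_ko_fraction_remaining Named numeric: residual TF expression under
#'   KO (defaults 0.35 and 0.47, i.e. 65% / 53% knockdown).
#' @param seed Integer RNG seed.
#' @return A validated list of class `simConfig`.
#' @examples
#' cfg <- simConfig(n_genes = 500, seed = 7)
#' @export
simConfig <- function(n_genes = 2000L, n_reps = 6L,
                      baseline_log_mean = 4, baseline_log_sd = 1.5,
                      dispersion_a0 = 0.05, dispersion_a1 = 2,
                      libsize_sd = 0.2,
                      n_targets_tf1 = 150L, n_targets_tf2 = 100L,
                      shared_fraction = 0.15, frac_down = 0.3,
                      effect_log2fc_mean = 2, effect_log2fc_sd = 0.5,
                      ko_oe_ratio = 0.5,
                      stress_fraction = 0.1, stress_log2fc_sd = 1,
                      tf_oe_log2fc = c(TF1 = 4.2, TF2 = 5.2),
                      tf_ko_fraction_remaining = c(TF1 = 0.35, TF2 = 0.47),
                      seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
    libsize_sd = libsize_sd,
    n_targets_tf1 = as.integer(n_targets_tf1),
    n_targets_tf2 = as.integer(n_targets_tf2),
    shared_fraction = shared_fraction, frac_down = frac_down,
    effect_log2fc_mean = effect_log2fc_mean,
    effect_log2fc_sd = effect_log2fc_sd,
    ko_oe_ratio = ko_oe_ratio,
    stress_fraction = stress_fraction,
    stress_log2fc_sd = stress_log2fc_sd,
    tf_oe_log2fc = tf_oe_log2fc,
    tf_ko_fraction_remaining = tf_ko_fraction_remaining,
    seed = as.integer(seed))
  .assertScalarNumber(cfg$n_genes, "n_genes", min = 10)
  .assertScalarNumber(cfg$n_reps, "n_reps", min = 3)
  .assertScalarNumber(cfg$baseline_log_sd, "baseline_log_sd", min = 0)
  .assertScalarNumber(cfg$dispersion_a0, "dispersion_a0", min = 0)
  .assertScalarNumber(cfg$dispersion_a1, "dispersion_a1", min = 0)
  .assertScalarNumber(cfg$libsize_sd, "libsize_sd", min = 0)
  .assertScalarNumber(cfg$shared_fraction, "shared_fraction", min = 0, max = 1)
  .assertScalarNumber(cfg$frac_down, "frac_down", min = 0, max = 1)
  .assertScalarNumber(cfg$effect_log2fc_sd, "effect_log2fc_sd", min = 0)
  .assertScalarNumber(cfg$ko_oe_ratio, "ko_oe_ratio", min = 0)
  .assertScalarNumber(cfg$stress_fraction, "stress_fraction", min = 0, max = 1)
  .assertScalarNumber(cfg$stress_log2fc_sd, "stress_log2fc_sd", min = 0)
  if (length(cfg$tf_oe_log2fc) != 2L)
    stop("invalid configuration: `tf_oe_log2fc` must have two entries",
         call. = FALSE)
  if (length(cfg$tf_ko_fraction_remaining) != 2L ||
      any(cfg$tf_ko_fraction_remaining <= 0))
    stop("invalid configuration: `tf_ko_fraction_remaining` must be two ",
         "positive fractions", call. = FALSE)
  if (cfg$n_targets_tf1 < 0 || cfg$n_targets_tf2 < 0)
    stop("invalid configuration: `n_targets_tf1`/`n_targets_tf2` must be >= 0",
         call. = FALSE)
  if (cfg$n_targets_tf1 + cfg$n_targets_tf2 > cfg$n_genes - 2L)
    stop("invalid configuration: `n_targets_tf1` + `n_targets_tf2` exceeds ",
         "the number of non-TF genes", call. = FALSE)
  class(cfg) <- "simConfig"
  cfg
}

# per-gene x per-condition true log2 offsets used to scale NB means,
# including stress and the TF genes' own perturbation responses
.deltaMatrix <- function(truth) {
  conds <- conditionLevels()
  d <- matrix(0, nrow(truth), length(conds),
              dimnames = list(truth$gene_id, conds))
  d[, .OE_SYSTEM] <- d[, .OE_SYSTEM] + truth$stress_oe_lfc
  d[, .KO_SYSTEM] <- d[, .KO_SYSTEM] + truth$stress_ko_lfc
  d[, "TF1-OE"] <- d[, "TF1-OE"] + truth$lfc_tf1_oe
  d[, "TF1-KO"] <- d[, "TF1-KO"] + truth$lfc_tf1_ko
  d[, "TF2-OE"] <- d[, "TF2-OE"] + truth$lfc_tf2_oe
  d[, "TF2-KO"] <- d[, "TF2-KO"] + truth$lfc_tf2_ko
  d
}

#' Simulate counts for the six-condition paired CRISPR design
#'
#' Draws gamma-Poisson (negative binomial) counts
#' \eqn{counts_{gs} \sim NB(sf_s\,\mu_g\,2^{\Delta_{g,cond(s)}},\ \alpha(\mu_g))}
#' with variance \eqn{\mu + \alpha\mu^2}. The log2 offset \eqn{\Delta}
#' combines (i) target effects — `+effect` in the matching TF's OE condition,
#' `-ko_oe_ratio * effect` in its KO condition; (ii) stress effects drawn once
#' per gene per CRISPR system and applied identically in targeting and
#' control conditions of that system; (iii) the TF genes' own responses
#' (`tf_oe_log2fc` under OE, `log2(tf_ko_fraction_remaining)` under KO).
#' Identical configurations (including the seed) give identical output.
#'
#' @param config A [simConfig()].
#' @return List with elements `counts` (a [ParalogCountSet-class]) and
#'   `truth` (data.frame: per-gene roles, signed effects, stress log2FCs and
#'   true per-condition log2FC relative to the matched control).
#' @examples
#' sim <- simulateCounts(simConfig(n_genes = 300, seed = 3))
#' sim$counts
#' @export
simulateCounts <- function(config = simConfig()) {
  if (!inherits(config, "simConfig")) config <- do.call(simConfig, config)
  set.seed(config$seed)
  g <- config$n_genes
  ids <- c("TF1", "TF2", sprintf("G%05d", seq_len(g - 2L)))
  mu <- exp(rnorm(g, config$baseline_log_mean, config$baseline_log_sd))
  names(mu) <- ids

  # target assignment: shared genes first (same signed effect for both TFs)
  pool <- ids[-(1:2)]
  n_sh <- round(config$shared_fraction *
                  min(config$n_targets_tf1, config$n_targets_tf2))
  pick <- sample(pool, config$n_targets_tf1 + config$n_targets_tf2 - n_sh)
  sh <- pick[seq_len(n_sh)]
  t1 <- c(sh, pick[seq_len(config$n_targets_tf1 - n_sh) + n_sh])
  t2 <- c(sh, pick[seq_len(config$n_targets_tf2 - n_sh) +
                     config$n_targets_tf1])
  role_of <- function(n) ifelse(runif(n) < config$frac_down,
                                "down-target", "up-target")
  eff_of <- function(role) {
    mag <- abs(rnorm(length(role), config$effect_log2fc_mean,
                     config$effect_log2fc_sd))
    ifelse(role == "down-target", -mag, mag)
  }
  role_sh <- role_of(n_sh); eff_sh <- eff_of(role_sh)
  role_t1x <- role_of(length(t1) - n_sh); eff_t1x <- eff_of(role_t1x)
  role_t2x <- role_of(length(t2) - n_sh); eff_t2x <- eff_of(role_t2x)

  truth <- data.frame(
    gene_id = ids,
    tf1_role = "none", tf2_role = "none",
    tf1_effect = 0, tf2_effect = 0,
    stress_oe_lfc = 0, stress_ko_lfc = 0,
    stringsAsFactors = FALSE)
  rownames(truth) <- ids
  truth[t1, "tf1_role"] <- c(role_sh, role_t1x)
  truth[t1, "tf1_effect"] <- c(eff_sh, eff_t1x)
  truth[t2, "tf2_role"] <- c(role_sh, role_t2x)
  truth[t2, "tf2_effect"] <- c(eff_sh, eff_t2x)

  # stress responders per CRISPR system (TF genes excluded to keep their
  # matched-control log2FCs at the configured values)
  nonTF <- ids[-(1:2)]
  s_oe <- nonTF[runif(length(nonTF)) < config$stress_fraction]
  s_ko <- nonTF[runif(length(nonTF)) < config$stress_fraction]
  truth[s_oe, "stress_oe_lfc"] <- rnorm(length(s_oe), 0,
                                        config$stress_log2fc_sd)
  truth[s_ko, "stress_ko_lfc"] <- rnorm(length(s_ko), 0,
                                        config$stress_log2fc_sd)

  # true per-condition log2FC relative to the matched control (stress cancels
  # there by construction)
  truth$lfc_tf1_oe <- ifelse(truth$tf1_role == "none", 0, truth$tf1_effect)
  truth$lfc_tf1_ko <- -config$ko_oe_ratio * truth$lfc_tf1_oe
  truth$lfc_tf2_oe <- ifelse(truth$tf2_role == "none", 0, truth$tf2_effect)
  truth$lfc_tf2_ko <- -config$ko_oe_ratio * truth$lfc_tf2_oe
  truth["TF1", c("lfc_tf1_oe", "lfc_tf1_ko")] <-
    c(config$tf_oe_log2fc[[1]], log2(config$tf_ko_fraction_remaining[[1]]))
  truth["TF2", c("lfc_tf2_oe", "lfc_tf2_ko")] <-
    c(config$tf_oe_log2fc[[2]], log2(config$tf_ko_fraction_remaining[[2]]))
  truth$combined_tf1 <- truth$lfc_tf1_oe - truth$lfc_tf1_ko
  truth$combined_tf2 <- truth$lfc_tf2_oe - truth$lfc_tf2_ko

  delta <- .deltaMatrix(truth)
  conds <- rep(conditionLevels(), each = config$n_reps)
  sample_ids <- paste0(conds, "_r", rep(seq_len(config$n_reps),
                                        times = length(conditionLevels())))
  sf <- rlnorm(length(conds), 0, config$libsize_sd)
  sf <- sf / exp(mean(log(sf)))
  alpha <- config$dispersion_a0 + config$dispersion_a1 / mu
  size <- 1 / pmax(alpha, 1e-10)

  counts <- matrix(0, g, length(conds), dimnames = list(ids, sample_ids))
  for (s in seq_along(conds)) {
    m <- sf[s] * mu * 2^delta[, conds[s]]
    counts[, s] <- if (all(alpha == 0)) rpois(g, m) else
      rnbinom(g, mu = m, size = size)
  }
  attr(truth, "config") <- config
  attr(truth, "size_factors") <- setNames(sf, sample_ids)
  attr(truth, "baseline_mu") <- mu
  list(counts = ParalogCountSet(counts, setNames(conds, sample_ids)),
       truth = truth)
}

#' Configuration for the synthetic peak/TSS generator
#'
#' @param tss_spacing Distance in bp between consecutive TSSs on a synthetic
#'   chromosome.
#' @param genes_per_chrom Genes placed per synthetic chromosome.
#' @param peak_fraction Fraction of direct-target genes receiving a binding
#'   peak.
#' @param peak_dist_max Peak-to-TSS distances are uniform on
#'   `[0, peak_dist_max]` with random sign.
#' @param background_rate Probability that a non-target gene receives a
#'   background peak.
#' @param peak_width Width of every peak in bp (summit at the centre).
#' @param offset Coordinate of the first TSS on each chromosome.
#' @return A validated list of class `peakSimConfig`.
#' @export
peakSimConfig <- function(tss_spacing = 100000L, genes_per_chrom = 500L,
                          peak_fraction = 0.9, peak_dist_max = 100000L,
                          background_rate = 0.1, peak_width = 200L,
                          offset = 1000000L) {
  cfg <- list(tss_spacing = as.integer(tss_spacing),
              genes_per_chrom = as.integer(genes_per_chrom),
              peak_fraction = peak_fraction,
              peak_dist_max = as.integer(peak_dist_max),
              background_rate = background_rate,
              peak_width = as.integer(peak_width),
              offset = as.integer(offset))
  .assertScalarNumber(cfg$tss_spacing, "tss_spacing", min = 1)
  .assertScalarNumber(cfg$peak_fraction, "peak_fraction", min = 0, max = 1)
  .assertScalarNumber(cfg$background_rate, "background_rate", min = 0, max = 1)
  .assertScalarNumber(cfg$peak_dist_max, "peak_dist_max", min = 0)
  if (cfg$peak_width < 1 || cfg$peak_width >= cfg$tss_spacing)
    stop("invalid configuration: `peak_width` must be in [1, tss_spacing)",
         call. = FALSE)
  if (cfg$offset <= cfg$peak_dist_max + cfg$peak_width)
    stop("invalid configuration: `offset` too small to place peaks at ",
         "negative distances", call. = FALSE)
  class(cfg) <- "peakSimConfig"
  cfg
}

#' Simulate TF binding peaks and a TSS table for simulated genes
#'
#' Places one TSS per gene on synthetic chromosomes at regular spacing
#' (alternating strand), gives a configurable fraction of direct-target genes
#' a binding peak at a uniform distance from their TSS, and sprinkles
#' background peaks over non-target genes at a lower rate. All intervals use
#' 1-based closed coordinates in the returned `GRanges` (the BED writers emit
#' 0-based half-open).
#'
#' @param truth Truth data.frame from [simulateCounts()] (or any data.frame
#'   with `gene_id`, `tf1_role`, `tf2_role`).
#' @param config A [peakSimConfig()].
#' @param seed Integer RNG seed.
#' @return List with `peaks` (GRanges with `name`, `score`, `summit_offset`),
#'   `tss` (GRanges of width 1 with `gene_id`), and `proximal_peaks`
#'   (the generator's own count of peaks whose summit lies within +-5 kb of
#'   any TSS, computed arithmetically from the regular TSS grid).
#' @export
simulatePeaks <- function(truth, config = peakSimConfig(), seed = 1L) {
  if (!inherits(config, "peakSimConfig"))
    config <- do.call(peakSimConfig, config)
  set.seed(seed)
  ids <- truth$gene_id
  n <- length(ids)
  chrom_i <- (seq_len(n) - 1L) %/% config$genes_per_chrom
  chrom <- paste0("chrS", chrom_i + 1L)
  pos_i <- (seq_len(n) - 1L) %% config$genes_per_chrom
  tss_pos <- config$offset + pos_i * config$tss_spacing
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  tss <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(tss_pos, width = 1L),
                                strand = strand)
  S4Vectors::mcols(tss)$gene_id <- ids
  names(tss) <- ids

  is_target <- truth$tf1_role != "none" | truth$tf2_role != "none"
  take_t <- is_target & runif(n) < config$peak_fraction
  take_b <- !is_target & runif(n) < config$background_rate
  take <- take_t | take_b
  dist <- round(runif(sum(take), 0, config$peak_dist_max)) *
    sample(c(-1L, 1L), sum(take), replace = TRUE)
  summit <- tss_pos[take] + dist
  half <- config$peak_width %/% 2L
  pk_start <- summit - half
  pk_end <- pk_start + config$peak_width - 1L
  peaks <- GenomicRanges::GRanges(chrom[take],
                                  IRanges::IRanges(pk_start, pk_end),
                                  strand = "*")
  S4Vectors::mcols(peaks)$name <- sprintf("peak%05d", seq_len(sum(take)))
  S4Vectors::mcols(peaks)$score <- round(runif(sum(take), 10, 1000))
  S4Vectors::mcols(peaks)$summit_offset <- summit - pk_start
  S4Vectors::mcols(peaks)$source_gene <- ids[take]

  # distance of each summit to the nearest TSS on the regular grid of its
  # chromosome (independent of any interval-scan machinery)
  rel <- summit - config$offset
  n_on_chrom <- ifelse(chrom_i[take] <
                         max(chrom_i), config$genes_per_chrom,
                       n - max(chrom_i) * config$genes_per_chrom)
  k <- pmin(pmax(round(rel / config$tss_spacing), 0), n_on_chrom - 1L)
  grid_dist <- abs(rel - k * config$tss_spacing)
  proximal <- sum(grid_dist <= 5000L)

  list(peaks = peaks, tss = tss, proximal_peaks = proximal)
}

#' Write simulated data in the pipeline's plain-text exchange formats
#'
#' `writeCountMatrix` writes `counts.tsv` (gene rows, sample columns, header,
#' tab-separated) and `samples.csv` (`sample_id,condition`);
#' `writeTruth` writes the ground-truth table as TSV.
#'
#' @param x A [ParalogCountSet-class].
#' @param counts_tsv,samples_csv,path Output paths.
#' @return Invisibly, the output path(s).
#' @export
writeCountMatrix <- function(x, counts_tsv, samples_csv) {
  m <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, counts_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample_id = colnames(x),
                   condition = as.character(sampleConditions(x)))
  write.table(ss, samples_csv, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(counts_tsv, samples_csv))
}

#' @rdname writeCountMatrix
#' @param truth Truth data.frame from [simulateCounts()].
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix and sample sheet into a ParalogCountSet
#'
#' @param counts_tsv TSV with a `gene_id` column and one column per sample.
#' @param samples_csv CSV with columns `sample_id,condition`.
#' @param aliases Optional named character vector mapping non-standard
#'   condition labels to [conditionLevels()].
#' @return A [ParalogCountSet-class].
#' @export
readCountMatrix <- function(counts_tsv, samples_csv, aliases = NULL) {
  df <- read.delim(counts_tsv, check.names = FALSE)
  if (!"gene_id" %in% colnames(df))
    stop("counts file must have a 'gene_id' column", call. = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  ss <- read.csv(samples_csv)
  if (!all(c("sample_id", "condition") %in% colnames(ss)))
    stop("sample sheet must have columns 'sample_id' and 'condition'",
         call. = FALSE)
  cond <- as.character(ss$condition)
  if (!is.null(aliases)) {
    hit <- cond %in% names(aliases)
    cond[hit] <- aliases[cond[hit]]
  }
  miss <- setdiff(colnames(m), ss$sample_id)
  if (length(miss))
    stop("samples missing from sample sheet: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ParalogCountSet(m, setNames(cond, ss$sample_id))
}
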