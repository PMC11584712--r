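#' Filter genes by total count
#'
#' Keeps genes with at least `min_total` counts summed over all samples
#' (inclusive threshold), preserving gene order and the sample sheet.
#'
#' @param x A [ParalogCountSet-class].
#' @param min_total Minimum total count (default 10).
#' @return The filtered `ParalogCountSet`; a warning (not an error) if no
#'   gene passes.
#' @examples
#' sim <- simulateCounts(simConfig(n_genes = 200, seed = 1))
#' filterLowCounts(sim$counts)
#' @export
filterLowCounts <- function(x, min_total = 10) {
  stopifnot(min_total >= 0)
  keep <- rowSums(SummarizedExperiment::assay(x, "counts")) >= min_total
  if (!any(keep)) warning("no gene passes the count filter")
  x[keep, ]
}

#' Median-of-ratios size factors
#'
#' The standard normalisation for NB count models: per sample, the median
#' over reference genes of the ratio of its count to the gene's geometric
#' mean across samples. Genes containing any zero are excluded from the
#' reference; with `fallback = TRUE` a pseudo-reference (counts + 0.5) is used
#' when no gene is all-positive.
#'
#' @param x A [ParalogCountSet-class] or count matrix.
#' @param fallback Use the pseudo-reference when no all-positive gene exists.
#' @return Named positive numeric vector of size factors (one per sample).
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3)
#' medianRatioSizeFactors(m)  # ~ (1/sqrt(2), sqrt(2))
#' @export
medianRatioSizeFactors <- function(x, fallback = FALSE) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  logm <- log(m)
  ref <- rowMeans(logm)
  ok <- is.finite(ref)
  if (!any(ok)) {
    if (!fallback)
      stop("no gene with all-positive counts; rerun with fallback = TRUE ",
           "to use a pseudo-reference", call. = FALSE)
    logm <- log(m + 0.5)
    ref <- rowMeans(logm)
    ok <- rep(TRUE, nrow(m))
  }
  ratios <- exp(logm[ok, , drop = FALSE] - ref[ok])
  setNames(apply(ratios, 2, median), colnames(m))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per-gene NB dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha\mu^2})
#' estimated by moments on size-factor-normalised counts within each
#' condition, pooled across conditions, and optionally shrunk toward a fitted
#' mean-dispersion trend \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#'
#' @param x A [ParalogCountSet-class] or count matrix.
#' @param sf Size factors (defaults to [medianRatioSizeFactors()]).
#' @param conditions Condition labels per sample (taken from `x` when it is a
#'   `ParalogCountSet`).
#' @param shrink Weight of the trend value in the final estimate (0 = raw
#'   moments, 1 = trend only).
#' @param alpha_floor Lower bound applied to all estimates.
#' @return Named numeric vector of dispersions (one per gene), with the
#'   fitted trend coefficients in attribute `"trend"`.
#' @export
momentDispersions <- function(x, sf = NULL, conditions = NULL, shrink = 0.3,
                              alpha_floor = 1e-8) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  if (is.null(conditions) && methods::is(x, "ParalogCountSet"))
    conditions <- as.character(sampleConditions(x))
  if (is.null(sf)) sf <- medianRatioSizeFactors(m)
  q <- sweep(m, 2, sf, "/")
  num <- den <- numeric(nrow(m))
  for (cond in unique(conditions)) {
    j <- which(conditions == cond)
    if (length(j) < 2) next
    qc <- q[, j, drop = FALSE]
    mc <- rowMeans(qc)
    vc <- rowSums((qc - mc)^2) / (length(j) - 1)
    w <- mean(1 / sf[j])  # Var(y/s) = mu/s + alpha mu^2 for NB y
    num <- num + (length(j) - 1) * (vc - mc * w)
    den <- den + (length(j) - 1) * mc^2
  }
  raw <- ifelse(den > 0, num / den, 0)
  mu_bar <- rowMeans(q)
  trend <- c(a0 = 0, a1 = 0)
  if (shrink > 0) {
    use <- which(raw > 0 & raw < 10 & mu_bar > 1)
    if (length(use) >= 20) {
      fit <- tryCatch(
        MASS::rlm(raw[use] ~ I(1 / mu_bar[use]), maxit = 50),
        error = function(e) lm(raw[use] ~ I(1 / mu_bar[use])))
      trend <- pmax(coef(fit), 0)
      names(trend) <- c("a0", "a1")
    } else shrink <- 0
  }
  tv <- trend[["a0"]] + trend[["a1"]] / pmax(mu_bar, 1e-8)
  out <- pmax((1 - shrink) * pmax(raw, 0) + shrink * tv, alpha_floor)
  names(out) <- rownames(m)
  attr(out, "trend") <- trend
  out
}

#' Fit the six-condition cell-means NB GLM
#'
#' Maximum-likelihood fit of a negative-binomial log-link model with one mean
#' parameter per condition and a `log(sf)` offset, at fixed per-gene
#' dispersion. With cell-means coding the likelihood separates by condition,
#' so each per-gene, per-condition log-mean is found by a Newton iteration on
#' the score \eqn{\sum_s (y_s - s_s m)/(1 + \alpha s_s m) = 0}, vectorised
#' across genes. Coefficients are reported in log2 units; their variances come
#' from the observed information \eqn{I = \sum_s \mu_s/(1+\alpha\mu_s)}
#' (diagonal across conditions), stabilised by a small ridge so all-zero
#' conditions yield a floored coefficient with a large variance rather than a
#' failure.
#'
#' @param x A [ParalogCountSet-class] or count matrix.
#' @param sf Size factors.
#' @param conditions Condition labels per sample.
#' @param dispersions Per-gene dispersion vector.
#' @param tol Convergence tolerance on the log-mean update (default 1e-8).
#' @param maxit Maximum Newton iterations (default 100).
#' @param ridge Ridge added to the information (default 1e-8).
#' @param zero_pseudo Pseudo-count total used to floor the mean of an
#'   all-zero condition (default 0.5).
#' @return List with matrices `log2means` and `log2vars`
#'   (genes x conditions), plus `baseMean` (mean normalised count) and
#'   `iterations`.
#' @export
fitConditionMeans <- function(x, sf = NULL, conditions = NULL,
                              dispersions = NULL, tol = 1e-8, maxit = 100,
                              ridge = 1e-8, zero_pseudo = 0.5) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  if (is.null(conditions) && methods::is(x, "ParalogCountSet"))
    conditions <- as.character(sampleConditions(x))
  if (is.null(sf)) sf <- medianRatioSizeFactors(m)
  if (is.null(dispersions))
    dispersions <- momentDispersions(m, sf, conditions)
  conds <- unique(conditions)
  g <- nrow(m)
  l2m <- l2v <- matrix(NA_real_, g, length(conds),
                       dimnames = list(rownames(m), conds))
  iters <- 0L
  for (cond in conds) {
    j <- which(conditions == cond)
    y <- m[, j, drop = FALSE]
    s <- sf[j]
    a <- dispersions
    zero <- rowSums(y) == 0
    mm <- rowMeans(sweep(y, 2, s, "/"))
    mm[zero] <- zero_pseudo / sum(s)
    beta <- log(mm)
    active <- !zero
    for (it in seq_len(maxit)) {
      if (!any(active)) break
      mcur <- exp(beta[active])
      M <- mcur %o% s                       # genes x samples means
      A <- a[active]
      denom <- 1 + A * M
      f <- rowSums((y[active, , drop = FALSE] - M) / denom)
      fp_m <- -rowSums(sweep(1 + A * y[active, , drop = FALSE], 2, s, "*") /
                         denom^2)           # df/dm
      step <- f / (fp_m * mcur)             # Newton step on log scale
      step[!is.finite(step)] <- 0
      step <- pmax(pmin(-step, 5), -5)      # guard huge steps
      beta[active] <- beta[active] + step
      conv <- abs(step) < tol
      idx <- which(active)
      active[idx[conv]] <- FALSE
      iters <- it
      if (!any(active)) break
    }
    mhat <- exp(beta)
    mu_s <- mhat %o% s
    info <- rowSums(mu_s / (1 + dispersions * mu_s)) + ridge
    l2m[, cond] <- beta / log(2)
    l2v[, cond] <- 1 / (info * log(2)^2)
  }
  list(log2means = l2m, log2vars = l2v,
       baseMean = rowMeans(sweep(m, 2, sf, "/")), iterations = iters)
}

#' Wald statistics for the combined OE/KO contrast
#'
#' Applies the contrast weights of [contrastWeights()] to a fitted
#' cell-means model: `log2fc = c'beta`, `se = sqrt(c' Sigma c)` (the
#' covariance is diagonal across conditions), Wald `z = log2fc/se` and a
#' two-sided normal p-value. Genes with a singular (non-finite) variance get
#' `NA` statistics.
#'
#' @param fit Result of [fitConditionMeans()].
#' @param tf `"TF1"` or `"TF2"`.
#' @return data.frame with `log2fc`, `se`, `wald_z`, `pvalue`.
#' @export
combinedContrast <- function(fit, tf = c("TF1", "TF2")) {
  tf <- match.arg(tf)
  cc <- .contrastConditions(tf)
  miss <- setdiff(cc, colnames(fit$log2means))
  if (length(miss))
    stop("fit does not cover contrast condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  w <- c(1, -1, -1, 1)
  lfc <- as.vector(fit$log2means[, cc, drop = FALSE] %*% w)
  v <- as.vector(fit$log2vars[, cc, drop = FALSE] %*% w^2)
  se <- sqrt(v)
  bad <- !is.finite(lfc) | !is.finite(se) | se <= 0
  lfc[bad] <- NA_real_; se[bad] <- NA_real_
  z <- lfc / se
  data.frame(log2fc = lfc, se = se, wald_z = z,
             pvalue = 2 * pnorm(-abs(z)),
             row.names = rownames(fit$log2means))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (via
#' [stats::p.adjust()]); `NA`/`NaN` inputs propagate and are excluded from
#' the number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

# lean internal chain on a plain matrix: size factors -> dispersions -> fit
# -> contrast -> BH; used by runCombinedContrast and the bootstrap loop
.deChain <- function(m, conds, tf, shrink_disp = 0.3, sf = NULL) {
  if (is.null(sf)) sf <- medianRatioSizeFactors(m)
  disp <- momentDispersions(m, sf, conds, shrink = shrink_disp)
  fit <- fitConditionMeans(m, sf, conds, disp)
  ct <- combinedContrast(fit, tf)
  ct$padj <- bhAdjust(ct$pvalue)
  ct$baseMean <- fit$baseMean
  attr(ct, "dispersion_trend") <- attr(disp, "trend")
  ct
}

#' Run the combined-contrast differential expression analysis
#'
#' The full engine for one paralog: count filter, median-of-ratios size
#' factors, moment dispersions with trend shrinkage, cell-means NB fit,
#' combined Wald contrast and BH adjustment. Genes failing the count filter
#' are reported with `tested = FALSE` and `NA` statistics.
#'
#' @param x A [ParalogCountSet-class] (unfiltered is fine).
#' @param tf `"TF1"` or `"TF2"`.
#' @param min_total Count-filter threshold (inclusive, default 10).
#' @param shrink_disp Dispersion trend-shrinkage weight.
#' @param shrink_lfc If `TRUE`, adds a `log2FoldChangeShrunk` column with a
#'   normal-prior posterior-mean shrinkage of the MLE log2FC (prior variance
#'   by moments). DEG calling always uses the MLE column.
#' @param sf Optional precomputed size factors.
#' @return A [ContrastResult-class] covering all genes of `x`.
#' @examples
#' sim <- simulateCounts(simConfig(n_genes = 300, seed = 2))
#' res <- runCombinedContrast(sim$counts, "TF1")
#' head(as.data.frame(res))
#' @export
runCombinedContrast <- function(x, tf = c("TF1", "TF2"), min_total = 10,
                                shrink_disp = 0.3, shrink_lfc = FALSE,
                                sf = NULL) {
  tf <- match.arg(tf)
  m <- SummarizedExperiment::assay(x, "counts")
  keep <- rowSums(m) >= min_total
  conds <- as.character(sampleConditions(x))
  ct <- .deChain(m[keep, , drop = FALSE], conds, tf,
                 shrink_disp = shrink_disp, sf = sf)
  n <- nrow(x)
  fill <- function(v) { out <- rep(NA_real_, n); out[keep] <- v; out }
  res <- S4Vectors::DataFrame(
    baseMean = fill(ct$baseMean), log2FoldChange = fill(ct$log2fc),
    lfcSE = fill(ct$se), stat = fill(ct$wald_z), pvalue = fill(ct$pvalue),
    padj = fill(ct$padj), tested = keep, row.names = rownames(x))
  if (shrink_lfc) {
    lfc <- res$log2FoldChange; se2 <- res$lfcSE^2
    ok <- !is.na(lfc)
    tau2 <- max(var(lfc[ok]) - mean(se2[ok]), 0)
    res$log2FoldChangeShrunk <- ifelse(ok, lfc * tau2 / (tau2 + se2),
                                       NA_real_)
  }
  out <- methods::new("ContrastResult", res)
  S4Vectors::metadata(out) <- list(tf = tf, weights = contrastWeights(tf),
                                   min_total = min_total,
                                   dispersion_trend = attr(ct,
                                                           "dispersion_trend"))
  out
}

#' Call differentially expressed gene sets
#'
#' Strict thresholds, matching the printed cutoffs: up = `padj < alpha` and
#' `log2fc > lfc_cutoff`; down analogously with `log2fc < -lfc_cutoff`.
#'
#' @param res A [ContrastResult-class].
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cutoff Absolute log2FC threshold (default 0.58).
#' @return A [DEGSet-class].
#' @export
callDEGs <- function(res, alpha = 0.05, lfc_cutoff = 0.58) {
  tf <- S4Vectors::metadata(res)$tf
  if (is.null(tf)) tf <- "TF1"
  ok <- res$tested & !is.na(res$padj)
  up <- rownames(res)[ok & res$padj < alpha & res$log2FoldChange > lfc_cutoff]
  dn <- rownames(res)[ok & res$padj < alpha &
                        res$log2FoldChange < -lfc_cutoff]
  DEGSet(tf, up, dn, universeSize = sum(res$tested), alpha = alpha,
         lfcCutoff = lfc_cutoff)
}

#' Write a ContrastResult / DEGSet to the exchange formats
#'
#' `writeDEResult` writes `de_<tf>.tsv` with columns `gene_id, base_mean,
#' log2fc, se, wald_z, pvalue, padj, tested`; `writeDEGSet` writes a JSON
#' listing the up/down sets, thresholds and universe size.
#'
#' @param res A [ContrastResult-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeDEResult <- function(res, path) {
  df <- data.frame(gene_id = rownames(res), base_mean = res$baseMean,
                   log2fc = res$log2FoldChange, se = res$lfcSE,
                   wald_z = res$stat, pvalue = res$pvalue, padj = res$padj,
                   tested = res$tested)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @param degs A [DEGSet-class].
#' @export
writeDEGSet <- function(degs, path) {
  jsonlite::write_json(
    list(tf = degs@tf, up = degs@up, down = degs@down,
         universe_size = degs@universeSize,
         thresholds = list(alpha_fdr = degs@alpha,
                           min_abs_log2fc = degs@lfcCutoff)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
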