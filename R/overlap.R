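#' Jaccard index of two gene sets
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}; returns 0 when both sets are empty
#' (documented convention).
#'
#' @param a,b Character vectors (treated as sets).
#' @return Numeric in `[0, 1]`.
#' @examples
#' jaccardIndex(letters[1:4], letters[3:6])  # 2/6
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Fisher exact test for gene-set overlap
#'
#' Builds the 2x2 table (both, A-only, B-only, neither) over a tested-gene
#' universe and reports the exact two-sided p-value, the conditional-MLE odds
#' ratio with exact confidence interval (the [stats::fisher.test()]
#' convention) and, for reference, the sample odds ratio `ad/bc` (0 or `Inf`
#' on degenerate margins).
#'
#' @param nA,nB Set sizes.
#' @param n_intersect Intersection size.
#' @param universe_size Number of genes in the tested universe.
#' @param conf_level Confidence level for the exact CI.
#' @return List with `nA`, `nB`, `n_intersect`, `n_union`, `universe_size`,
#'   `jaccard`, `odds_ratio` (conditional MLE), `or_ci`, `sample_or`,
#'   `pvalue`, and the underlying `table`.
#' @examples
#' fisherOverlap(155, 54, 14, 19689)
#' @export
fisherOverlap <- function(nA, nB, n_intersect, universe_size,
                          conf_level = 0.95) {
  if (n_intersect > min(nA, nB))
    stop("n_intersect exceeds a set size", call. = FALSE)
  if (nA + nB - n_intersect > universe_size)
    stop("union exceeds the universe", call. = FALSE)
  k <- n_intersect
  b <- nA - k; cc <- nB - k
  d <- universe_size - (nA + nB - k)
  tab <- matrix(c(k, b, cc, d), 2, 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  ft <- fisher.test(tab, conf.level = conf_level)
  sample_or <- if (b * cc == 0) {
    if (k * d == 0) NaN else Inf
  } else (k * d) / (b * cc)
  u <- nA + nB - k
  list(nA = nA, nB = nB, n_intersect = k, n_union = u,
       universe_size = universe_size,
       jaccard = if (u == 0) 0 else k / u,
       odds_ratio = unname(ft$estimate), or_ci = as.numeric(ft$conf.int),
       sample_or = sample_or, pvalue = ft$p.value, table = tab)
}

#' Constrained bootstrap resampling indices
#'
#' Draws, for each condition, `size` indices with replacement; draws with
#' fewer than `min_unique` distinct indices are rejected and redrawn (the
#' constraint that a bootstrapped condition contains at least three unique
#' samples). Rejections are counted.
#'
#' @param condition_sizes Named integer vector of samples per condition.
#' @param min_unique Minimum distinct indices per condition (default 3).
#' @return List with `indices` (list of integer vectors per condition) and
#'   `rejections` (total redraws).
#' @examples
#' set.seed(1)
#' bootstrapResampleIndices(c(`ctrl-OE` = 6, `TF1-OE` = 6))
#' @export
bootstrapResampleIndices <- function(condition_sizes, min_unique = 3) {
  if (any(condition_sizes < min_unique))
    stop("invalid configuration: `min_unique` (", min_unique,
         ") exceeds a condition size", call. = FALSE)
  rejections <- 0L
  idx <- lapply(condition_sizes, function(n) {
    repeat {
      draw <- sample.int(n, n, replace = TRUE)
      if (length(unique(draw)) >= min_unique) return(draw)
      rejections <<- rejections + 1L
    }
  })
  list(indices = idx, rejections = rejections)
}

#' Bootstrap DEG sets for one paralog
#'
#' For each of `B` replicates: resample samples with replacement within each
#' of the six conditions (constrained to `min_unique` distinct samples per
#' condition), rerun the full differential-expression chain (size factors,
#' dispersions, NB fit, combined contrast, BH) and call DEGs at the main
#' thresholds.
#'
#' @param x A filtered [ParalogCountSet-class].
#' @param tf `"TF1"` or `"TF2"`.
#' @param B Number of bootstrap replicates (default 100).
#' @param min_unique Constraint on distinct samples per condition.
#' @param alpha,lfc_cutoff DEG thresholds.
#' @param shrink_disp Dispersion shrinkage weight passed through.
#' @param seed Integer seed; fixed seed gives identical DEG sets.
#' @return List of [DEGSet-class] of length `B`, with per-replicate rejection
#'   counts in attribute `"rejections"` and the number of failed replicates in
#'   attribute `"failed"`.
#' @export
bootstrapDEGSets <- function(x, tf = c("TF1", "TF2"), B = 100,
                             min_unique = 3, alpha = 0.05,
                             lfc_cutoff = 0.58, shrink_disp = 0.3,
                             seed = 1L) {
  tf <- match.arg(tf)
  set.seed(seed)
  conds <- as.character(sampleConditions(x))
  m <- SummarizedExperiment::assay(x, "counts")
  cond_idx <- split(seq_along(conds), conds)
  sizes <- vapply(cond_idx, length, integer(1))
  out <- vector("list", B)
  rejections <- integer(B)
  failed <- 0L
  for (b in seq_len(B)) {
    rs <- bootstrapResampleIndices(sizes, min_unique)
    rejections[b] <- rs$rejections
    take <- unlist(lapply(names(cond_idx),
                          function(cn) cond_idx[[cn]][rs$indices[[cn]]]),
                   use.names = FALSE)
    ct <- tryCatch(
      .deChain(m[, take, drop = FALSE], conds[take], tf,
               shrink_disp = shrink_disp),
      error = function(e) NULL)
    if (is.null(ct)) { failed <- failed + 1L; next }
    ok <- !is.na(ct$padj)
    up <- rownames(ct)[ok & ct$padj < alpha & ct$log2fc > lfc_cutoff]
    dn <- rownames(ct)[ok & ct$padj < alpha & ct$log2fc < -lfc_cutoff]
    out[[b]] <- DEGSet(tf, up, dn, universeSize = nrow(ct), alpha = alpha,
                       lfcCutoff = lfc_cutoff)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (failed > 0)
    warning(failed, " bootstrap replicate(s) failed and were excluded")
  attr(out, "rejections") <- rejections
  attr(out, "failed") <- failed
  out
}

# extract up / down / all gene sets from a list of DEGSet
.extractSets <- function(sets, which = c("all", "up", "down")) {
  which <- match.arg(which)
  lapply(sets, function(s) {
    if (methods::is(s, "DEGSet")) {
      switch(which, up = upGenes(s), down = downGenes(s), all = degGenes(s))
    } else as.character(s)
  })
}

#' Pairwise Jaccard indices across bootstrap DEG sets
#'
#' `pairwiseJaccard` computes J over all unordered pairs of one list of sets
#' (the within-paralog expected-overlap distribution);
#' `crossPairwiseJaccard` pairs every set of the first list with every set of
#' the second (the cross-paralog distribution). Pair counts above `max_pairs`
#' are reduced by seeded subsampling.
#'
#' @param sets,sets1,sets2 Lists of [DEGSet-class] objects or character
#'   vectors.
#' @param which `"all"` (union of up and down per replicate), `"up"` or
#'   `"down"`.
#' @param max_pairs Cap on the number of pairs (default 10000).
#' @param seed Seed for the subsampling of pairs.
#' @return Numeric vector of Jaccard indices.
#' @export
pairwiseJaccard <- function(sets, which = c("all", "up", "down"),
                            max_pairs = 10000, seed = 1L) {
  gs <- .extractSets(sets, match.arg(which))
  if (length(gs) < 2) stop("need at least two sets", call. = FALSE)
  pairs <- combn(length(gs), 2)
  if (ncol(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  vapply(seq_len(ncol(pairs)),
         function(i) jaccardIndex(gs[[pairs[1, i]]], gs[[pairs[2, i]]]),
         numeric(1))
}

#' @rdname pairwiseJaccard
#' @export
crossPairwiseJaccard <- function(sets1, sets2, which = c("all", "up", "down"),
                                 max_pairs = 10000, seed = 1L) {
  which <- match.arg(which)
  g1 <- .extractSets(sets1, which)
  g2 <- .extractSets(sets2, which)
  pairs <- expand.grid(i = seq_along(g1), j = seq_along(g2))
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), ]
  }
  vapply(seq_len(nrow(pairs)),
         function(k) jaccardIndex(g1[[pairs$i[k]]], g2[[pairs$j[k]]]),
         numeric(1))
}

#' Basic bootstrap confidence interval
#'
#' The reflection interval \eqn{(2\hat\theta - q_{1-\alpha/2},\
#' 2\hat\theta - q_{\alpha/2})} built from empirical quantiles of the
#' bootstrap distribution. For the expected-overlap application there is no
#' single full-data statistic to reflect around, so the default centre is the
#' mean of the values (configurable).
#'
#' @param values Numeric vector of bootstrap statistics (>= 2 finite values).
#' @param alpha 1 - confidence level (default 0.05).
#' @param center Reflection centre \eqn{\hat\theta} (default `mean(values)`).
#' @param clip Optional `c(lo, hi)` to clip the interval (use `c(0, 1)` for
#'   Jaccard quantities); `NULL` for no clipping.
#' @return Numeric `c(low, high)`.
#' @examples
#' basicBootstrapCI(seq(0.1, 1, by = 0.1), center = 0.55)
#' @export
basicBootstrapCI <- function(values, alpha = 0.05, center = mean(values),
                             clip = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    if (length(values) == 1) return(c(values, values))
    stop("need at least two finite values", call. = FALSE)
  }
  q <- quantile(values, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci <- c(2 * center - q[2], 2 * center - q[1])
  if (!is.null(clip)) ci <- pmin(pmax(ci, clip[1]), clip[2])
  ci
}

#' One-sample Z test of observed vs. bootstrap-expected overlap
#'
#' Compares the observed cross-paralog Jaccard index with the within-paralog
#' bootstrap distribution via the normal approximation of the bootstrap
#' variance: \eqn{z = (\bar J - J_{obs}) / sd(J)} with the sample sd
#' (ddof = 1).
#'
#' @param observed_j Observed Jaccard index.
#' @param within_tf_j Numeric vector of within-paralog bootstrap J values.
#' @param alternative `"two.sided"` (default), `"greater"` (expected exceeds
#'   observed) or `"less"`.
#' @return List with `z`, `pvalue`, `mean`, `sd`, `alternative`.
#' @examples
#' zTestOverlap(0.072, rnorm(100, 0.5, 0.1))
#' @export
zTestOverlap <- function(observed_j, within_tf_j,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  within_tf_j <- within_tf_j[is.finite(within_tf_j)]
  if (length(within_tf_j) < 2)
    stop("need at least two bootstrap values", call. = FALSE)
  s <- sd(within_tf_j)
  if (s == 0) {
    warning("zero bootstrap spread; p-value undefined")
    return(list(z = NA_real_, pvalue = NA_real_, mean = mean(within_tf_j),
                sd = 0, alternative = alternative))
  }
  z <- (mean(within_tf_j) - observed_j) / s
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(z = z, pvalue = p, mean = mean(within_tf_j), sd = s,
       alternative = alternative)
}

#' Observed/expected overlap ratio
#'
#' The observed Jaccard index divided by the mean of the two paralogs'
#' expected (within-paralog bootstrap) Jaccard indices, in percent.
#'
#' @param observed_j Observed Jaccard index.
#' @param expected_j_tf1,expected_j_tf2 Expected J per paralog.
#' @return Percentage (not rounded; render with one decimal for reporting).
#' @examples
#' oeRatio(0.072, 0.511, 0.493)  # 14.34 -> prints 14.3%
#' @export
oeRatio <- function(observed_j, expected_j_tf1, expected_j_tf2) {
  e <- mean(c(expected_j_tf1, expected_j_tf2))
  if (!is.finite(e) || e <= 0)
    stop("expected Jaccard mean must be positive", call. = FALSE)
  100 * observed_j / e
}

#' Pearson correlation between the Wald Z-scores of the two paralogs
#'
#' Correlation of per-gene Wald statistics over the genes tested in both
#' analyses, with a percentile bootstrap confidence interval obtained by
#' resampling genes with replacement.
#'
#' @param res1,res2 [ContrastResult-class] objects for the two paralogs.
#' @param n_boot Bootstrap resamples for the CI (default 100).
#' @param conf_level Confidence level.
#' @param seed Integer seed.
#' @return List with `pearson_r`, `r_squared`, `ci`, `n_genes`, `n_boot`.
#' @export
zscoreCorrelation <- function(res1, res2, n_boot = 100, conf_level = 0.95,
                              seed = 1L) {
  shared <- intersect(rownames(res1)[res1$tested & !is.na(res1$stat)],
                      rownames(res2)[res2$tested & !is.na(res2$stat)])
  if (length(shared) < 3)
    stop("fewer than 3 genes tested in both analyses", call. = FALSE)
  z1 <- res1[shared, "stat"]; z2 <- res2[shared, "stat"]
  r <- cor(z1, z2)
  set.seed(seed)
  rb <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(shared), replace = TRUE)
    cor(z1[i], z2[i])
  }, numeric(1))
  a <- (1 - conf_level) / 2
  list(pearson_r = r, r_squared = r^2,
       ci = quantile(rb, c(a, 1 - a), names = FALSE),
       n_genes = length(shared), n_boot = n_boot)
}

#' Filter CRISPR off-target candidates against both paralogs' DEG sets
#'
#' Keeps candidate sites with CFD score strictly above `cfd_min` and exonic
#' or intronic location, then classifies each kept gene:
#' `possible_guide_specific_offtarget` if differentially expressed for exactly
#' one paralog, `shared_effect_not_offtarget` if DE for both (a gene affected
#' by both paralogs cannot be the off-target of one guide sequence),
#' `no_expression_effect` otherwise.
#'
#' @param candidates data.frame with columns `gene_id`, `guide_id`, `cfd`
#'   (in `[0, 1]`) and `context` (one of exon, intron, intergenic, promoter,
#'   other).
#' @param deg_tf1,deg_tf2 [DEGSet-class] objects.
#' @param cfd_min CFD threshold (strict `>`, default 0.1).
#' @return The kept rows with an added `verdict` column; dropped rows are
#'   reported in attribute `"n_dropped"`.
#' @export
offtargetFilter <- function(candidates, deg_tf1, deg_tf2, cfd_min = 0.1) {
  need <- c("gene_id", "guide_id", "cfd", "context")
  miss <- setdiff(need, colnames(candidates))
  if (length(miss))
    stop("candidate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  valid <- c("exon", "intron", "intergenic", "promoter", "other")
  bad <- which(!candidates$context %in% valid)
  if (length(bad))
    stop("unknown context label in candidate row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(candidates$cfd < 0 | candidates$cfd > 1))
    stop("CFD scores must be in [0, 1]", call. = FALSE)
  keep <- candidates$cfd > cfd_min & candidates$context %in% c("exon", "intron")
  out <- candidates[keep, , drop = FALSE]
  de1 <- out$gene_id %in% degGenes(deg_tf1)
  de2 <- out$gene_id %in% degGenes(deg_tf2)
  out$verdict <- ifelse(de1 & de2, "shared_effect_not_offtarget",
                        ifelse(de1 | de2, "possible_guide_specific_offtarget",
                               "no_expression_effect"))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Observed vs. bootstrap-expected DEG-set overlap analysis
#'
#' The full overlap workflow for a six-condition count set: DE and DEG
#' calling for both paralogs, the observed cross-paralog Jaccard per
#' direction, per-paralog constrained-bootstrap DEG sets, within-paralog
#' pairwise Jaccard distributions (the expected overlap under the
#' shared-targets null) with basic bootstrap intervals, one-sample Z tests,
#' observed/expected ratios, the cross-paralog pairwise distribution (source
#' of the observed-J interval) and the Wald Z-score correlation.
#'
#' @param x A [ParalogCountSet-class].
#' @param B Bootstrap replicates per paralog (default 100).
#' @param min_unique Constraint on distinct samples per condition (default 3).
#' @param alpha,lfc_cutoff DEG thresholds (defaults 0.05 / 0.58).
#' @param min_total Count-filter threshold.
#' @param max_pairs Cap on pairwise comparisons.
#' @param alternative Sidedness of the Z tests.
#' @param shrink_disp Dispersion shrinkage weight.
#' @param n_boot_cor Bootstrap resamples for the correlation CI.
#' @param seed Global seed (per-stage child seeds are derived from it).
#' @return An [OverlapAnalysis-class] object.
#' @examples
#' \donttest{
#' sim <- simulateCounts(simConfig(n_genes = 400, seed = 5))
#' ov <- degOverlapAnalysis(sim$counts, B = 10, seed = 5)
#' renderTable1(ov)
#' }
#' @export
degOverlapAnalysis <- function(x, B = 100, min_unique = 3, alpha = 0.05,
                               lfc_cutoff = 0.58, min_total = 10,
                               max_pairs = 10000,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               shrink_disp = 0.3, n_boot_cor = 100,
                               seed = 1L) {
  alternative <- match.arg(alternative)
  xf <- filterLowCounts(x, min_total)
  res1 <- runCombinedContrast(xf, "TF1", min_total = 0,
                              shrink_disp = shrink_disp)
  res2 <- runCombinedContrast(xf, "TF2", min_total = 0,
                              shrink_disp = shrink_disp)
  deg1 <- callDEGs(res1, alpha, lfc_cutoff)
  deg2 <- callDEGs(res2, alpha, lfc_cutoff)
  boot1 <- bootstrapDEGSets(xf, "TF1", B = B, min_unique = min_unique,
                            alpha = alpha, lfc_cutoff = lfc_cutoff,
                            shrink_disp = shrink_disp,
                            seed = .deriveSeed(seed, "boot-TF1"))
  boot2 <- bootstrapDEGSets(xf, "TF2", B = B, min_unique = min_unique,
                            alpha = alpha, lfc_cutoff = lfc_cutoff,
                            shrink_disp = shrink_disp,
                            seed = .deriveSeed(seed, "boot-TF2"))
  dirs <- c("up", "down", "all")
  observed <- e1 <- e2 <- z1 <- z2 <- p1 <- p2 <- oe <-
    setNames(rep(NA_real_, 3), dirs)
  ci1 <- ci2 <- ciO <- matrix(NA_real_, 3, 2,
                              dimnames = list(dirs, c("low", "high")))
  jW1 <- jW2 <- jX <- setNames(vector("list", 3), dirs)
  for (d in dirs) {
    sets <- .extractSets(list(deg1, deg2), d)
    observed[d] <- jaccardIndex(sets[[1]], sets[[2]])
    jW1[[d]] <- pairwiseJaccard(boot1, d, max_pairs,
                                seed = .deriveSeed(seed, paste0("pw1-", d)))
    jW2[[d]] <- pairwiseJaccard(boot2, d, max_pairs,
                                seed = .deriveSeed(seed, paste0("pw2-", d)))
    jX[[d]] <- crossPairwiseJaccard(boot1, boot2, d, max_pairs,
                                    seed = .deriveSeed(seed,
                                                       paste0("pwx-", d)))
    e1[d] <- mean(jW1[[d]]); e2[d] <- mean(jW2[[d]])
    ci1[d, ] <- basicBootstrapCI(jW1[[d]], clip = c(0, 1))
    ci2[d, ] <- basicBootstrapCI(jW2[[d]], clip = c(0, 1))
    ciO[d, ] <- basicBootstrapCI(jX[[d]], clip = c(0, 1))
    if (sd(jW1[[d]]) > 0) {
      t1 <- zTestOverlap(observed[d], jW1[[d]], alternative)
      z1[d] <- t1$z; p1[d] <- t1$pvalue
    }
    if (sd(jW2[[d]]) > 0) {
      t2 <- zTestOverlap(observed[d], jW2[[d]], alternative)
      z2[d] <- t2$z; p2[d] <- t2$pvalue
    }
    if (is.finite(e1[d]) && is.finite(e2[d]) && (e1[d] + e2[d]) > 0)
      oe[d] <- oeRatio(observed[d], e1[d], e2[d])
  }
  corr <- tryCatch(
    zscoreCorrelation(res1, res2, n_boot = n_boot_cor,
                      seed = .deriveSeed(seed, "zcor")),
    error = function(e) list(pearson_r = NA_real_, r_squared = NA_real_,
                             ci = c(NA_real_, NA_real_), n_genes = 0,
                             n_boot = n_boot_cor))
  methods::new("OverlapAnalysis",
               observed = observed, expected1 = e1, expected2 = e2,
               ci1 = ci1, ci2 = ci2, ciObserved = ciO,
               z1 = z1, z2 = z2, p1 = p1, p2 = p2, oeRatio = oe,
               jWithin1 = jW1, jWithin2 = jW2, jCross = jX,
               degs = list(TF1 = deg1, TF2 = deg2), correlation = corr,
               params = list(B = B, min_unique = min_unique, alpha = alpha,
                             lfc_cutoff = lfc_cutoff, min_total = min_total,
                             max_pairs = max_pairs,
                             alternative = alternative, seed = seed,
                             boot_sizes = c(length(boot1), length(boot2))))
}
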