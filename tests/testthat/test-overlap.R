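test_that("Jaccard index matches definition, conventions and brute force", {
  expect_equal(jaccardIndex(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccardIndex(letters[1:3], letters[4:6]), 0)
  expect_equal(jaccardIndex(character(), character()), 0)
  set.seed(3)
  for (i in 1:100) {
    a <- sample(letters, sample.int(20, 1))
    b <- sample(letters, sample.int(20, 1))
    brute <- sum(unique(a) %in% unique(b)) /
      length(unique(c(a, b)))
    expect_equal(jaccardIndex(a, b), brute)
  }
})

test_that("published DEG-set sizes yield consistent Jaccard and odds ratio", {
  # enumeration oracle: the intersection consistent with BOTH the published
  # J (0.072) and OR (48.3) at universe 19,689 is unique
  consistent <- Filter(function(k) {
    j <- k / (155 + 54 - k)
    or <- (k * (19689 - (155 + 54 - k))) / ((155 - k) * (54 - k))
    round(j, 3) == 0.072 && abs(or - 48.3) < 1
  }, 0:54)
  expect_equal(consistent, 14)
  ft <- fisherOverlap(155, 54, 14, 19689)
  expect_equal(ft$jaccard, 14 / 195, tolerance = 1e-12)
  expect_equal(round(ft$jaccard, 3), 0.072)
  expect_equal(ft$sample_or, 48.39, tolerance = 0.01)
  expect_lt(ft$pvalue, 1e-10)
  ft2 <- fisherOverlap(34, 65, 11, 19689)
  expect_equal(ft2$sample_or, 173.6, tolerance = 0.1)
})

test_that("Fisher overlap matches brute-force hypergeometric enumeration", {
  expect_equal(fisherOverlap(10, 12, 0, 500)$sample_or, 0)
  expect_error(fisherOverlap(5, 5, 6, 100), "exceeds")
  expect_error(fisherOverlap(90, 90, 0, 100), "universe")
  set.seed(8)
  for (i in 1:100) {
    N <- sample(50:400, 1)
    nA <- sample.int(N %/% 3, 1); nB <- sample.int(N %/% 3, 1)
    k <- sample.int(min(nA, nB), 1)
    ft <- fisherOverlap(nA, nB, k, N)
    expect_equal(ft$pvalue, bruteFisherP(nA, nB, k, N), tolerance = 1e-8)
    expect_equal(ft$n_union, nA + nB - k)
    expect_true(ft$jaccard >= 0 && ft$jaccard <= 1)
  }
})

test_that("constrained resampling always yields enough unique samples", {
  set.seed(5)
  sizes <- c(`TF1-OE` = 6, `ctrl-OE` = 6)
  for (i in 1:2000) {
    rs <- bootstrapResampleIndices(sizes, min_unique = 3)
    expect_true(all(vapply(rs$indices,
                           function(ix) length(unique(ix)) >= 3,
                           logical(1))))
  }
  # plain bootstrap: no rejections possible
  set.seed(5)
  rs1 <- bootstrapResampleIndices(sizes, min_unique = 1)
  expect_equal(rs1$rejections, 0L)
  # determinism under a fixed seed
  set.seed(99); a <- bootstrapResampleIndices(sizes)
  set.seed(99); b <- bootstrapResampleIndices(sizes)
  expect_identical(a, b)
  expect_error(bootstrapResampleIndices(c(x = 2), min_unique = 3),
               "min_unique")
})

test_that("pairwise Jaccard values equal hand computation", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"), c("x", "y"))
  expect_equal(pairwiseJaccard(sets, "all"),
               c(2 / 4, 0, 0))
  same <- replicate(4, c("g1", "g2"), simplify = FALSE)
  expect_true(all(pairwiseJaccard(same, "all") == 1))
  x <- crossPairwiseJaccard(sets[1:2], sets[3], "all")
  expect_equal(x, c(0, 0))
  capped <- pairwiseJaccard(randomSets(30), "all", max_pairs = 50, seed = 2)
  expect_length(capped, 50)
})

test_that("basic bootstrap interval follows the reflection formula", {
  expect_equal(basicBootstrapCI(rep(0.4, 10)), c(0.4, 0.4))
  v <- seq(0.1, 1, by = 0.1)
  expect_equal(basicBootstrapCI(v, center = 0.55),
               bruteBasicCI(v, center = 0.55))
  # symmetric values: basic equals percentile
  set.seed(10)
  sym <- 0.5 + c(-1, 1) * rep(runif(200), each = 2)
  expect_equal(basicBootstrapCI(sym),
               unname(quantile(sym, c(0.025, 0.975))), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:100) {
    vals <- runif(sample(5:60, 1))
    expect_equal(basicBootstrapCI(vals), bruteBasicCI(vals))
  }
  # clipping for Jaccard-scale quantities
  ci <- basicBootstrapCI(c(0.01, 0.02, 0.9), clip = c(0, 1))
  expect_true(all(ci >= 0 & ci <= 1))
  expect_error(basicBootstrapCI(0.5[0]), "two")
})

test_that("one-sample Z test matches normal-CDF arithmetic", {
  vals <- c(0.4, 0.5, 0.6)
  z0 <- zTestOverlap(0.5, vals)
  expect_equal(z0$z, 0); expect_equal(z0$pvalue, 1)
  # closed-form check at mean 0.5, sd 0.1
  set.seed(1)
  v <- rnorm(200, 0.5, 0.1)
  v <- (v - mean(v)) / sd(v) * 0.1 + 0.5  # exact moments
  zt <- zTestOverlap(0.072, v)
  expect_equal(zt$z, 4.28, tolerance = 1e-10)
  expect_equal(zt$pvalue, 2 * pnorm(-4.28), tolerance = 1e-10)
  expect_equal(zt$pvalue, 1.87e-5, tolerance = 0.01)
  zg <- zTestOverlap(0.072, v, alternative = "greater")
  expect_equal(zg$pvalue, zt$pvalue / 2)
  expect_warning(z_flat <- zTestOverlap(0.3, rep(0.5, 5)), "spread")
  expect_true(is.na(z_flat$pvalue))
})

test_that("observed/expected ratio reproduces the published summary cells", {
  tab <- read.delim(system.file("extdata", "meis_jaccard_table.tsv",
                                package = "paraloverlap"),
                    comment.char = "#")
  oe <- mapply(oeRatio, tab$observed_j, tab$expected_j_tf1,
               tab$expected_j_tf2)
  expect_equal(round(oe, 1), c(14.3, 47.6, 23.5))
  expect_equal(oeRatio(0.3, 0.3, 0.3), 100)
  expect_error(oeRatio(0.1, 0, 0), "positive")
})

test_that("Z-score correlation behaves at its fixed points and under the null", {
  sim <- simulateCounts(simConfig(n_genes = 200, n_targets_tf1 = 20,
                                  n_targets_tf2 = 20, seed = 23))
  res <- runCombinedContrast(sim$counts, "TF1")
  self <- zscoreCorrelation(res, res, n_boot = 20)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$r_squared, 1)
  neg_df <- S4Vectors::DataFrame(as.data.frame(res))
  neg_df$stat <- -neg_df$stat
  neg <- new("ContrastResult", neg_df)
  S4Vectors::metadata(neg) <- list(tf = "TF2")
  expect_equal(zscoreCorrelation(res, neg, n_boot = 20)$pearson_r, -1)
  # independent z-vectors: negligible correlation
  set.seed(42)
  fake <- function(z) {
    df <- S4Vectors::DataFrame(
      baseMean = 1, log2FoldChange = z, lfcSE = 1, stat = z,
      pvalue = 2 * pnorm(-abs(z)), padj = NA_real_,
      tested = TRUE, row.names = sprintf("g%04d", seq_along(z)))
    df$padj <- bhAdjust(df$pvalue)
    out <- new("ContrastResult", df)
    S4Vectors::metadata(out) <- list(tf = "TF1")
    out
  }
  for (i in 1:5) {
    r <- zscoreCorrelation(fake(rnorm(5000)), fake(rnorm(5000)),
                           n_boot = 10, seed = i)
    expect_lt(abs(r$pearson_r), 0.05)
  }
  tiny <- fake(rnorm(2))
  expect_error(zscoreCorrelation(tiny, tiny), "3 genes")
})

test_that("off-target filter applies CFD/context rules and DEG verdicts", {
  deg1 <- DEGSet("TF1", up = c("SMOC1", "ONLY1"), down = character(), 100)
  deg2 <- DEGSet("TF2", up = "SMOC1", down = character(), 100)
  cand <- data.frame(
    gene_id = c("LOWCFD", "INTERG", "SMOC1", "ONLY1", "NOEFF"),
    guide_id = paste0("g", 1:5),
    cfd = c(0.05, 0.2, 0.2, 0.9, 0.4),
    context = c("intron", "intergenic", "intron", "exon", "exon"))
  out <- offtargetFilter(cand, deg1, deg2)
  expect_setequal(out$gene_id, c("SMOC1", "ONLY1", "NOEFF"))
  expect_equal(out$verdict[out$gene_id == "SMOC1"],
               "shared_effect_not_offtarget")
  expect_equal(out$verdict[out$gene_id == "ONLY1"],
               "possible_guide_specific_offtarget")
  expect_equal(out$verdict[out$gene_id == "NOEFF"], "no_expression_effect")
  expect_equal(attr(out, "n_dropped"), 2L)
  bad <- cand; bad$context[3] <- "weird"
  expect_error(offtargetFilter(bad, deg1, deg2), "row\\(s\\) 3")
  # boundary: cfd exactly at the threshold is dropped (strict >)
  edge <- data.frame(gene_id = "E", guide_id = "g", cfd = 0.1,
                     context = "exon")
  expect_equal(nrow(offtargetFilter(edge, deg1, deg2)), 0)
})

test_that("bootstrap DEG sets are reproducible and null-calibrated", {
  sim <- simulateCounts(simConfig(n_genes = 300, seed = 55))
  xf <- filterLowCounts(sim$counts)
  b1 <- bootstrapDEGSets(xf, "TF1", B = 2, seed = 123)
  b2 <- bootstrapDEGSets(xf, "TF1", B = 2, seed = 123)
  expect_identical(lapply(b1, degGenes), lapply(b2, degGenes))
  # no targets, no stress: DEG sets should be (nearly) empty
  null_cfg <- simConfig(n_genes = 400, n_targets_tf1 = 0, n_targets_tf2 = 0,
                        stress_fraction = 0,
                        tf_oe_log2fc = c(TF1 = 0, TF2 = 0),
                        tf_ko_fraction_remaining = c(TF1 = 1, TF2 = 1),
                        seed = 66)
  nsim <- simulateCounts(null_cfg)
  # full-data analysis of pure noise calls (essentially) nothing
  null_deg <- callDEGs(runCombinedContrast(nsim$counts, "TF1"))
  expect_lte(length(degGenes(null_deg)), 2)
  # bootstrap replicates add resampling churn (a documented property of the
  # bootstrap null); the called fraction must still stay small
  nb <- bootstrapDEGSets(filterLowCounts(nsim$counts), "TF1", B = 8,
                         seed = 9)
  sizes <- vapply(nb, function(s) length(degGenes(s)), integer(1))
  expect_lte(median(sizes) / universeSize(nb[[1]]), 0.05)
})

test_that("overlap analysis separates shared from disjoint architectures", {
  # disjoint targets: strong divergence signal
  div_cfg <- simConfig(n_genes = 500, n_targets_tf1 = 60, n_targets_tf2 = 60,
                       shared_fraction = 0, seed = 71)
  ov <- degOverlapAnalysis(simulateCounts(div_cfg)$counts, B = 12, seed = 71)
  expect_lt(ov@p1[["all"]], 0.01)
  expect_lt(ov@oeRatio[["all"]], 30)
  # under a fully shared architecture the two paralogs' within-TF J
  # distributions and the cross-TF distribution sit at comparable levels
  # (pairwise J values are heavily dependent, so location ratios rather
  # than a rank test are the meaningful comparison)
  sh_cfg <- simConfig(n_genes = 500, n_targets_tf1 = 60, n_targets_tf2 = 60,
                      shared_fraction = 1, seed = 72)
  ov2 <- degOverlapAnalysis(simulateCounts(sh_cfg)$counts, B = 12, seed = 72)
  r12 <- mean(ov2@jWithin1[["all"]]) / mean(ov2@jWithin2[["all"]])
  expect_gt(r12, 0.8); expect_lt(r12, 1.25)
  rx <- mean(ov2@jCross[["all"]]) /
    mean(c(ov2@jWithin1[["all"]], ov2@jWithin2[["all"]]))
  expect_gt(rx, 0.6); expect_lt(rx, 1.1)
  expect_gt(ov2@observed[["all"]], 0.5)
})
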