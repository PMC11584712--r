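test_that("BED and narrowPeak readers honour coordinates and report errors", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t100\t200"), bed)
  gr <- readPeaks(bed)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
  expect_equal(GenomicRanges::start(gr), 101)  # 0-based half-open in, 1-based out
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(as.character(GenomicRanges::strand(gr)), "*")

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr2\t1000\t1200\tpk1\t80\t.\t5.5\t3.2\t2.1\t50", np)
  pk <- readPeaks(np)
  # absolute summit in the input's 0-based frame is start + offset = 1050
  expect_equal((GenomicRanges::start(pk) - 1) + pk$summit_offset, 1050)
  expect_equal(pk$signalValue, 5.5)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), bad)
  expect_error(readPeaks(bad), "line\\(s\\) 2")
  mixed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t2", "chr1\t1\t2\tx"), mixed)
  expect_error(readPeaks(mixed), "column count")
})

test_that("peak and TSS writers round-trip through the readers", {
  sim <- simulateCounts(simConfig(n_genes = 200, n_targets_tf1 = 30,
                                  n_targets_tf2 = 20, seed = 14))
  ps <- simulatePeaks(sim$truth, seed = 14)
  f_np <- tempfile(fileext = ".narrowPeak")
  writePeaks(ps$peaks, f_np, format = "narrowPeak")
  back <- readPeaks(f_np)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ps$peaks))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ps$peaks))
  expect_equal(back$summit_offset, ps$peaks$summit_offset)

  f_tss <- tempfile(fileext = ".bed")
  writeTSS(ps$tss, f_tss)
  tss_back <- readTSS(f_tss)
  expect_equal(GenomicRanges::start(tss_back), GenomicRanges::start(ps$tss))
  expect_equal(tss_back$gene_id, ps$tss$gene_id)
  expect_equal(as.character(GenomicRanges::strand(tss_back)),
               as.character(GenomicRanges::strand(ps$tss)))

  # duplicate TSS entries collapse to the first, with a message
  dup <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101\tgA\t0\t+", "chr1\t900\t901\tgA\t0\t+",
               "chr1\t500\t501\tgB\t0\t-"), dup)
  expect_message(tss2 <- readTSS(dup), "multiple TSS")
  expect_equal(length(tss2), 2)
  expect_equal(GenomicRanges::start(tss2[tss2$gene_id == "gA"]), 101)
})

test_that("TSS distance annotation applies the inclusive 5 kb boundary", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50000, width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- "g1"
  mk_peak <- function(mid) {  # odd width: midpoint is exactly `mid`
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(mid - 50, mid + 50))
    S4Vectors::mcols(gr)$name <- "p"
    gr
  }
  at0 <- tssDistanceAnnotation(mk_peak(50000), tss)
  expect_equal(at0$annotation$distance, 0)
  expect_true(at0$annotation$within_promoter)
  at_edge <- tssDistanceAnnotation(mk_peak(55000), tss)
  expect_equal(at_edge$annotation$distance, 5000)
  expect_true(at_edge$annotation$within_promoter)
  at_out <- tssDistanceAnnotation(mk_peak(55001), tss)
  expect_false(at_out$annotation$within_promoter)
  # minus-strand gene flips the distance sign
  tss_m <- tss; GenomicRanges::strand(tss_m) <- "-"
  at_m <- tssDistanceAnnotation(mk_peak(55000), tss_m)
  expect_equal(at_m$annotation$distance, -5000)
  expect_error(tssDistanceAnnotation(mk_peak(1000), tss[0]), "empty")
})

test_that("promoter fraction equals a brute-force all-pairs scan", {
  sim <- simulateCounts(simConfig(n_genes = 1000, seed = 33))
  ps <- simulatePeaks(sim$truth, peakSimConfig(background_rate = 0.4),
                      seed = 33)
  ann <- tssDistanceAnnotation(ps$peaks, ps$tss)
  summit <- GenomicRanges::start(ps$peaks) + ps$peaks$summit_offset
  pk_chr <- as.character(GenomicRanges::seqnames(ps$peaks))
  tss_pos <- GenomicRanges::start(ps$tss)
  tss_chr <- as.character(GenomicRanges::seqnames(ps$tss))
  brute <- mean(vapply(seq_along(summit), function(i) {
    d <- abs(tss_pos[tss_chr == pk_chr[i]] - summit[i])
    length(d) > 0 && min(d) <= 5000
  }, logical(1)))
  expect_equal(ann$promoter_fraction, brute)
  # permutation invariance
  perm <- sample(length(ps$peaks))
  ann_p <- tssDistanceAnnotation(ps$peaks[perm], ps$tss)
  expect_equal(ann_p$promoter_fraction, ann$promoter_fraction)
})

test_that("peak-gene linking applies the inclusive 1 Mb window", {
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(2000000, width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- "g1"
  peak_at <- function(mid) {  # odd width: midpoint is exactly `mid`
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(mid - 10, mid + 10))
    S4Vectors::mcols(gr)$name <- "p"
    gr
  }
  expect_equal(nrow(linkPeaksToGenes(peak_at(2000000 + 999999), tss)), 1)
  expect_equal(nrow(linkPeaksToGenes(peak_at(2000000 + 1000000), tss)), 1)
  expect_equal(nrow(linkPeaksToGenes(peak_at(2000000 + 1000001), tss)), 0)
  one <- linkPeaksToGenes(peak_at(2000000), tss)
  expect_equal(nrow(one), 1)
  expect_true(one$within_promoter)
})

test_that("link table equals a brute-force double loop on random fixtures", {
  set.seed(44)
  n_pk <- 300; n_g <- 80
  pk_chr <- sample(c("chr1", "chr2"), n_pk, replace = TRUE)
  mid <- sample.int(5000000, n_pk) + 30L
  # odd widths keep the midpoint unambiguous for the brute-force oracle
  peaks <- GenomicRanges::GRanges(pk_chr, IRanges::IRanges(mid - 25, mid + 25))
  S4Vectors::mcols(peaks)$name <- sprintf("p%03d", seq_len(n_pk))
  g_chr <- sample(c("chr1", "chr2"), n_g, replace = TRUE)
  g_pos <- sample.int(5000000, n_g)
  g_str <- sample(c("+", "-"), n_g, replace = TRUE)
  tss <- GenomicRanges::GRanges(g_chr, IRanges::IRanges(g_pos, width = 1),
                                strand = g_str)
  S4Vectors::mcols(tss)$gene_id <- sprintf("g%02d", seq_len(n_g))
  links <- linkPeaksToGenes(peaks, tss, max_dist = 300000)
  brute <- bruteLinks(pk_chr, mid, g_chr, g_pos, g_str,
                      tss$gene_id, 300000)
  key <- function(g, p, d) paste(g, p, d)
  expect_setequal(key(links$gene_id, links$peak_id, links$distance),
                  key(brute$gene, sprintf("p%03d", brute$peak),
                      brute$distance))
})

test_that("histone-mark filtering uses half-open overlap semantics", {
  mk <- function(s, e) GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(s + 1, e))
  peak <- mk(100, 200)
  expect_length(filterActivePeaks(peak, mk(150, 160)), 1)
  expect_length(filterActivePeaks(peak, mk(200, 300)), 0)
  expect_length(filterActivePeaks(peak, mk(199, 300)), 1)
  set.seed(9)
  s <- sort(sample.int(100000, 60)); peaks <- mk(s, s + 500)
  ms <- sort(sample.int(100000, 40)); marks <- mk(ms, ms + 300)
  kept <- filterActivePeaks(peaks, marks)
  brute <- peaks[vapply(seq_along(peaks), function(i) {
    any(pmin(GenomicRanges::end(peaks)[i], GenomicRanges::end(marks)) -
          pmax(GenomicRanges::start(peaks)[i],
               GenomicRanges::start(marks)) + 1 >= 1)
  }, logical(1))]
  expect_equal(GenomicRanges::start(kept), GenomicRanges::start(brute))
})

test_that("direct-target classification counts DEGs with linked peaks", {
  links <- data.frame(gene_id = c("u1", "u1", "d1"),
                      peak_id = c("p1", "p2", "p3"),
                      distance = c(0L, 100L, -50L),
                      within_promoter = TRUE)
  degs <- DEGSet("TF1", up = c("u1", "u2"), down = c("d1", "d2"), 100)
  out <- classifyDirectTargets(links, degs)
  expect_equal(out$n_up_direct, 1)
  expect_equal(out$n_down_direct, 1)
  expect_false(out$table$direct[out$table$gene_id == "u2"])
  expect_equal(out$table$n_linked_peaks[out$table$gene_id == "u1"], 2)
})

test_that("every peaked target is direct when the generator places peaks", {
  sim <- simulateCounts(simConfig(n_genes = 300, seed = 61))
  ps <- simulatePeaks(sim$truth,
                      peakSimConfig(peak_fraction = 1, background_rate = 0,
                                    peak_dist_max = 1000), seed = 61)
  links <- linkPeaksToGenes(ps$peaks, ps$tss)
  tr <- sim$truth
  targets <- tr$gene_id[tr$tf1_role != "none" | tr$tf2_role != "none"]
  degs <- DEGSet("TF1", up = targets, down = character(), length(tr$gene_id))
  out <- classifyDirectTargets(links, degs)
  expect_true(all(out$table$direct))
})

test_that("regulatory potential uses the distance-decay weight", {
  links <- data.frame(gene_id = "g1", peak_id = "p1", distance = 0L,
                      within_promoter = TRUE)
  df <- S4Vectors::DataFrame(
    baseMean = 1, log2FoldChange = c(2, rep(0, 19)), lfcSE = 0.1,
    stat = c(20, rep(0, 19)), pvalue = c(1e-9, rep(0.9, 19)),
    padj = c(1e-8, rep(0.95, 19)), tested = TRUE,
    row.names = c("g1", sprintf("n%02d", 1:19)))
  de <- new("ContrastResult", df)
  suppressWarnings(fn <- predictTFFunction(links, de))
  expect_equal(fn$scores$score[fn$scores$gene_id == "g1"], exp(-0.5),
               tolerance = 1e-12)
  expect_equal(fn$scores$score[fn$scores$gene_id == "n01"], 0)
})

test_that("activating function is detected when up-targets carry peaks", {
  cfg <- simConfig(n_genes = 500, n_targets_tf1 = 80, n_targets_tf2 = 0,
                   shared_fraction = 0, frac_down = 0, seed = 81)
  sim <- simulateCounts(cfg)
  # peaks only on (up-regulated) targets, promoter-proximal
  ps <- simulatePeaks(sim$truth,
                      peakSimConfig(peak_fraction = 1, background_rate = 0,
                                    peak_dist_max = 2000), seed = 81)
  links <- linkPeaksToGenes(ps$peaks, ps$tss)
  res <- runCombinedContrast(sim$counts, "TF1")
  fn <- suppressWarnings(predictTFFunction(links, res))
  expect_lt(fn$activating_p, 0.01)
  if (!is.na(fn$repressive_p)) expect_gt(fn$repressive_p, 0.1)
})
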