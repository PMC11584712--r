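#' Read peak files (BED / narrowPeak) into a GRanges
#'
#' Dialect is auto-detected from the column count of the first data line:
#' 3-6 columns are parsed as BED (via `rtracklayer`), 10 columns as ENCODE
#' narrowPeak (BED6+4 with a summit offset in the last column). Input
#' coordinates are 0-based half-open; the returned `GRanges` uses the usual
#' 1-based closed convention. `track`/`browser`/`#` lines are skipped;
#' malformed lines are reported with their line numbers.
#'
#' @param path Path to a BED3/BED6 or narrowPeak file.
#' @return A `GRanges`; narrowPeak input carries metadata columns `name`,
#'   `score`, `signalValue`, `pValue`, `qValue` and `summit_offset`
#'   (offset of the summit from the interval start, or `NA` if -1).
#' @export
readPeaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  data_idx <- which(!skip)
  if (!length(data_idx)) stop("no data lines in ", path, call. = FALSE)
  nfield <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  ncol1 <- nfield[1]
  if (any(nfield != ncol1))
    stop("inconsistent column count at line(s) ",
         paste(head(data_idx[nfield != ncol1], 5), collapse = ", "),
         " of ", path, call. = FALSE)
  if (!(ncol1 %in% c(3:6, 10)))
    stop("unsupported column count (", ncol1, ") in ", path,
         "; expected BED3-BED6 or 10-column narrowPeak", call. = FALSE)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(starts) | !is.finite(ends) | starts < 0 |
                 starts >= ends)
  if (length(bad))
    stop("malformed interval (need 0 <= start < end) at line(s) ",
         paste(head(data_idx[bad], 5), collapse = ", "), " of ", path,
         call. = FALSE)
  if (ncol1 <= 6) {
    gr <- rtracklayer::import(path, format = "BED")
    return(gr)
  }
  # narrowPeak: BED6+4 (signalValue, pValue, qValue, summit offset)
  chrom <- vapply(fields, `[`, "", 1L)
  name <- vapply(fields, `[`, "", 4L)
  score <- as.numeric(vapply(fields, `[`, "", 5L))
  strand <- vapply(fields, `[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  summit <- as.integer(vapply(fields, `[`, "", 10L))
  widths <- ends - starts
  bad_summit <- which(summit >= widths)
  if (length(bad_summit))
    stop("summit offset outside the peak at line(s) ",
         paste(head(data_idx[bad_summit], 5), collapse = ", "), " of ", path,
         call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts + 1, ends),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = score,
    signalValue = as.numeric(vapply(fields, `[`, "", 7L)),
    pValue = as.numeric(vapply(fields, `[`, "", 8L)),
    qValue = as.numeric(vapply(fields, `[`, "", 9L)),
    summit_offset = ifelse(summit < 0, NA_integer_, summit))
  names(gr) <- name
  gr
}

#' Read a TSS table (BED6, name = gene id) into a GRanges of width 1
#'
#' The BED interval's start (0-based) is taken as the TSS coordinate. Genes
#' listed more than once collapse to their first entry by default (logged via
#' a message); with `collapse = FALSE` all entries are kept and downstream
#' distance operations use the minimum over a gene's TSSs.
#'
#' @param path Path to a BED6 file whose name column holds gene ids.
#' @param collapse Keep only the first TSS per gene (default `TRUE`).
#' @return A `GRanges` of width-1 positions with metadata column `gene_id`.
#' @export
readTSS <- function(path, collapse = TRUE) {
  gr <- readPeaks(path)
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("TSS file must be BED6 with gene ids in the name column",
         call. = FALSE)
  tss <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(GenomicRanges::start(gr), width = 1L),
    strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(tss)$gene_id <- gr$name
  if (collapse && anyDuplicated(gr$name)) {
    dup <- unique(gr$name[duplicated(gr$name)])
    message(length(dup), " gene(s) with multiple TSS entries; first kept")
    tss <- tss[!duplicated(tss$gene_id)]
  }
  if (collapse) names(tss) <- tss$gene_id
  tss
}

#' Write peaks / TSS tables as BED or narrowPeak
#'
#' Emits 0-based half-open coordinates. `writePeaks` writes BED6 or, with
#' `format = "narrowPeak"`, BED6+4 using the `signalValue`, `pValue`,
#' `qValue` and `summit_offset` metadata columns (defaults 0, -1, -1, -1
#' when absent). `writeTSS` writes the width-1 TSS positions as BED6 with the
#' gene id in the name column.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return Invisibly, `path`.
#' @export
writePeaks <- function(gr, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(gr)
  nm <- if (!is.null(mc$name)) mc$name else paste0("peak", seq_along(gr))
  sc <- if (!is.null(mc$score)) mc$score else 0
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = sc, strand = st)
  if (format == "narrowPeak") {
    df$signalValue <- if (!is.null(mc$signalValue)) mc$signalValue else 0
    df$pValue <- if (!is.null(mc$pValue)) mc$pValue else -1
    df$qValue <- if (!is.null(mc$qValue)) mc$qValue else -1
    df$peak <- if (!is.null(mc$summit_offset))
      ifelse(is.na(mc$summit_offset), -1L, mc$summit_offset) else -1L
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePeaks
#' @export
writeTSS <- function(gr, path) {
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::start(gr),
                   name = gr$gene_id, score = 0, strand = st)
  df$end <- df$start + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# reference point of each peak: absolute summit when present, else midpoint
.peakPoints <- function(peaks) {
  mc <- S4Vectors::mcols(peaks)
  pt <- IRanges::mid(IRanges::ranges(peaks))
  if (!is.null(mc$summit_offset)) {
    has <- !is.na(mc$summit_offset)
    pt[has] <- GenomicRanges::start(peaks)[has] + mc$summit_offset[has]
  }
  pt
}

#' Annotate peaks with the distance to the nearest TSS
#'
#' Distance is measured from the peak summit (when a `summit_offset`
#' metadata column is present) or midpoint to the nearest TSS on the same
#' chromosome. The promoter fraction is the share of peaks within
#' `promoter_halfwidth` of a TSS (inclusive at the boundary); peaks on
#' chromosomes without any TSS are excluded from the fraction's denominator
#' (reported via a message).
#'
#' @param peaks `GRanges` of peaks.
#' @param tss `GRanges` of width-1 TSS positions with `gene_id`.
#' @param promoter_halfwidth Promoter window half-width in bp (default 5000).
#' @return List with `annotation` (data.frame: peak name, nearest gene,
#'   signed distance, `within_promoter`), `promoter_fraction` and
#'   `n_excluded` (peaks on TSS-less chromosomes). The distance sign is
#'   (peak point - TSS) times the gene's strand sign.
#' @export
tssDistanceAnnotation <- function(peaks, tss, promoter_halfwidth = 5000) {
  if (!length(tss)) stop("empty TSS table", call. = FALSE)
  pk_chr <- as.character(GenomicRanges::seqnames(peaks))
  tss_chr <- as.character(GenomicRanges::seqnames(tss))
  unmatched <- setdiff(unique(pk_chr), unique(tss_chr))
  if (length(unmatched))
    message("peak chromosome(s) without TSS: ",
            paste(unmatched, collapse = ", "))
  pts <- .peakPoints(peaks)
  pt_gr <- GenomicRanges::GRanges(pk_chr, IRanges::IRanges(pts, width = 1L))
  hit <- GenomicRanges::nearest(pt_gr, tss, ignore.strand = TRUE)
  ok <- !is.na(hit)
  tss_pos <- GenomicRanges::start(tss)
  tss_strand <- as.character(GenomicRanges::strand(tss))
  sign_of <- ifelse(tss_strand == "-", -1L, 1L)
  dist <- rep(NA_integer_, length(peaks))
  gene <- rep(NA_character_, length(peaks))
  dist[ok] <- (pts[ok] - tss_pos[hit[ok]]) * sign_of[hit[ok]]
  gene[ok] <- tss$gene_id[hit[ok]]
  nm <- if (!is.null(peaks$name)) peaks$name else paste0("peak",
                                                         seq_along(peaks))
  ann <- data.frame(peak = nm, nearest_gene = gene, distance = dist,
                    within_promoter = !is.na(dist) &
                      abs(dist) <= promoter_halfwidth)
  frac <- if (any(ok)) mean(ann$within_promoter[ok]) else NA_real_
  list(annotation = ann, promoter_fraction = frac, n_excluded = sum(!ok))
}

#' Link peaks to genes within a TSS window
#'
#' Associates every peak with every gene whose TSS lies within `max_dist`
#' (inclusive) of the peak's summit/midpoint — the window-based peak-gene
#' assignment used by binding-and-expression integration, default 1 Mb. A
#' peak may link to many genes and vice versa.
#'
#' @param peaks `GRanges` of peaks.
#' @param tss `GRanges` of width-1 TSS positions with `gene_id`.
#' @param max_dist Maximum absolute TSS distance in bp (default 1e6).
#' @param promoter_halfwidth Promoter window half-width for the
#'   `within_promoter` flag.
#' @return data.frame (the link table) with columns `gene_id`, `peak_id`,
#'   `distance` (signed, strand-aware), `within_promoter`.
#' @export
linkPeaksToGenes <- function(peaks, tss, max_dist = 1000000,
                             promoter_halfwidth = 5000) {
  pts <- .peakPoints(peaks)
  pt_gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(peaks)),
    IRanges::IRanges(pts, width = 1L))
  win <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(tss)),
    IRanges::IRanges(pmax(GenomicRanges::start(tss) - max_dist, 0L),
                     GenomicRanges::start(tss) + max_dist))
  hits <- GenomicRanges::findOverlaps(pt_gr, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  tss_strand <- as.character(GenomicRanges::strand(tss))
  sign_of <- ifelse(tss_strand == "-", -1L, 1L)
  dist <- (pts[qi] - GenomicRanges::start(tss)[si]) * sign_of[si]
  keep <- abs(dist) <= max_dist
  nm <- if (!is.null(peaks$name)) peaks$name else paste0("peak",
                                                         seq_along(peaks))
  data.frame(gene_id = tss$gene_id[si][keep], peak_id = nm[qi][keep],
             distance = as.integer(dist[keep]),
             within_promoter = abs(dist[keep]) <= promoter_halfwidth)
}

#' Retain peaks overlapping active histone marks
#'
#' Keeps peaks with at least 1 bp overlap with any mark interval (e.g.
#' H3K27ac marking active enhancers). Half-open input semantics are honoured:
#' BED intervals `[100,200)` and `[200,300)` do not overlap.
#'
#' @param peaks,marks `GRanges` (as returned by [readPeaks()]).
#' @return The retained subset of `peaks`.
#' @export
filterActivePeaks <- function(peaks, marks) {
  hits <- GenomicRanges::findOverlaps(peaks, marks, minoverlap = 1L,
                                      ignore.strand = TRUE)
  peaks[unique(S4Vectors::queryHits(hits))]
}

#' Classify DEGs as direct or indirect targets
#'
#' A differentially expressed gene with at least one linked binding peak is
#' a putative direct target; DEGs without any linked peak are indirect.
#'
#' @param links Link table from [linkPeaksToGenes()].
#' @param degs A [DEGSet-class].
#' @return List with `n_up_direct`, `n_down_direct` and `table` (per-DEG
#'   data.frame with direction, number of linked peaks and `direct` flag).
#' @export
classifyDirectTargets <- function(links, degs) {
  genes <- c(upGenes(degs), downGenes(degs))
  dir <- c(rep("up", length(upGenes(degs))),
           rep("down", length(downGenes(degs))))
  n_peaks <- vapply(genes,
                    function(g) sum(links$gene_id == g), integer(1))
  tab <- data.frame(gene_id = genes, direction = dir,
                    n_linked_peaks = n_peaks, direct = n_peaks > 0,
                    row.names = NULL)
  list(n_up_direct = sum(tab$direct & tab$direction == "up"),
       n_down_direct = sum(tab$direct & tab$direction == "down"),
       table = tab)
}

#' Regulatory potential and activating/repressive function prediction
#'
#' Scores every gene by a distance-decayed sum over its linked peaks,
#' \eqn{S_g = \sum_k e^{-(0.5 + 4\Delta_k)}} with
#' \eqn{\Delta_k = |d_k| / 100{,}000} (a peak at the TSS contributes
#' \eqn{e^{-0.5} \approx 0.607}), then compares the score distributions of
#' upregulated vs. non-DE genes (activating test) and downregulated vs.
#' non-DE genes (repressive test) with one-sided two-sample
#' Kolmogorov-Smirnov tests: a small p-value says that DE stratum carries
#' systematically higher regulatory potential than non-DE genes.
#'
#' @param links Link table from [linkPeaksToGenes()].
#' @param de A [ContrastResult-class].
#' @param fdr_cut FDR threshold defining the DE strata (default 0.05; no
#'   fold-change cutoff, to keep test power).
#' @param min_stratum Minimum genes per stratum; below it the test is
#'   skipped with a warning (default 5).
#' @return List with `activating_p`, `repressive_p` and `scores` (per-gene
#'   data.frame: regulatory potential and stratum).
#' @export
predictTFFunction <- function(links, de, fdr_cut = 0.05, min_stratum = 5) {
  genes <- rownames(de)[de$tested]
  w <- exp(-(0.5 + 4 * abs(links$distance) / 1e5))
  s <- tapply(w, links$gene_id, sum)
  scores <- setNames(rep(0, length(genes)), genes)
  hit <- intersect(names(s), genes)
  scores[hit] <- s[hit]
  padj <- de[genes, "padj"]; lfc <- de[genes, "log2FoldChange"]
  stratum <- rep("nonDE", length(genes))
  stratum[!is.na(padj) & padj < fdr_cut & lfc > 0] <- "up"
  stratum[!is.na(padj) & padj < fdr_cut & lfc < 0] <- "down"
  ks_p <- function(x, y) {
    if (length(x) < min_stratum || length(y) < min_stratum) {
      warning("stratum below ", min_stratum, " genes; test skipped")
      return(NA_real_)
    }
    # alternative = "less": ECDF of x below that of y, i.e. x stochastically
    # larger -- DE genes carry higher regulatory potential
    suppressWarnings(ks.test(x, y, alternative = "less")$p.value)
  }
  non <- scores[stratum == "nonDE"]
  list(activating_p = ks_p(scores[stratum == "up"], non),
       repressive_p = ks_p(scores[stratum == "down"], non),
       scores = data.frame(gene_id = genes, score = unname(scores),
                           stratum = stratum))
}
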