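#' ParalogCountSet: counts from a paired CRISPR KO/OE perturbation design
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' gene x sample integer count matrix (assay `"counts"`) and a `condition`
#' column in `colData` with values from [conditionLevels()].
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @export
setClass("ParalogCountSet", contains = "SummarizedExperiment")

setValidity("ParalogCountSet", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)))
      msgs <- c(msgs, "counts must be finite")
    else if (any(m < 0))
      msgs <- c(msgs, "counts must be non-negative")
    else if (any(abs(m - round(m)) > 1e-8))
      msgs <- c(msgs, "counts must be integers")
  }
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'condition' column")
  else {
    cond <- as.character(SummarizedExperiment::colData(object)$condition)
    bad <- setdiff(unique(cond), conditionLevels())
    if (length(bad))
      msgs <- c(msgs, paste0("unknown condition label(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene identifiers (rownames) must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParalogCountSet
#'
#' @param counts Gene x sample matrix of non-negative integer counts with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param conditions Character or factor of length `ncol(counts)` with values
#'   from [conditionLevels()], or a named vector matched to `colnames(counts)`.
#' @return A [ParalogCountSet-class] object.
#' @examples
#' m <- matrix(rpois(60, 10), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' pcs <- ParalogCountSet(m, rep(conditionLevels(), each = 1))
#' @export
ParalogCountSet <- function(counts, conditions) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (!is.null(names(conditions)))
    conditions <- conditions[colnames(counts)]
  if (length(conditions) != ncol(counts))
    stop("`conditions` must have one entry per sample", call. = FALSE)
  cond <- factor(as.character(conditions), levels = conditionLevels())
  if (anyNA(cond))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(as.character(conditions)), conditionLevels()),
               collapse = ", "), call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = cond,
                                   row.names = colnames(counts)))
  methods::new("ParalogCountSet", se)
}

#' @describeIn ParalogCountSet-class Condition label of each sample.
#' @param x,object A `ParalogCountSet`.
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname ParalogCountSet-class
#' @export
setMethod("sampleConditions", "ParalogCountSet", function(x) {
  SummarizedExperiment::colData(x)$condition
})

setMethod("show", "ParalogCountSet", function(object) {
  cat("ParalogCountSet with", nrow(object), "genes and",
      ncol(object), "samples\n")
  tab <- table(droplevels(sampleConditions(object)))
  cat("  conditions:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' ContrastResult: per-gene combined-contrast differential expression
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene and columns
#' `baseMean`, `log2FoldChange`, `lfcSE`, `stat` (Wald Z), `pvalue`, `padj`
#' (Benjamini-Hochberg) and `tested` (passed the minimum-count filter;
#' untested genes carry `NA` statistics). Metadata records the paralog label
#' and the contrast weights.
#'
#' @export
setClass("ContrastResult", contains = "DFrame")

setValidity("ContrastResult", function(object) {
  need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue", "padj",
            "tested")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  p <- object$pvalue; q <- object$padj
  ok <- !is.na(p) & !is.na(q)
  if (any(q[ok] + 1e-12 < p[ok]))
    return("padj must be >= pvalue for tested genes")
  if (any(!is.na(p) & !object$tested))
    return("untested genes must carry NA p-values")
  TRUE
})

setMethod("show", "ContrastResult", function(object) {
  tf <- S4Vectors::metadata(object)$tf
  cat("ContrastResult", if (!is.null(tf)) paste0("(", tf, ")"),
      "with", nrow(object), "genes,", sum(object$tested), "tested\n")
  methods::callNextMethod()
})

#' DEGSet: up/down differentially expressed gene sets for one paralog
#'
#' @slot tf Paralog label (`"TF1"` or `"TF2"`).
#' @slot up Character vector of upregulated gene ids (UreG).
#' @slot down Character vector of downregulated gene ids (DreG).
#' @slot universeSize Number of tested genes.
#' @slot alpha FDR threshold used (strict `<`).
#' @slot lfcCutoff Absolute log2 fold-change threshold used (strict `>`).
#' @export
setClass("DEGSet", representation(
  tf = "character", up = "character", down = "character",
  universeSize = "integer", alpha = "numeric", lfcCutoff = "numeric"))

setValidity("DEGSet", function(object) {
  msgs <- character()
  if (length(intersect(object@up, object@down)))
    msgs <- c(msgs, "up and down sets must be disjoint")
  if (length(object@up) + length(object@down) > object@universeSize)
    msgs <- c(msgs, "more DEGs than tested genes")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DEGSet-class
#' @param tf,up,down,universeSize,alpha,lfcCutoff See slots.
#' @export
DEGSet <- function(tf, up, down, universeSize, alpha = 0.05,
                   lfcCutoff = 0.58) {
  methods::new("DEGSet", tf = as.character(tf),
               up = as.character(up), down = as.character(down),
               universeSize = as.integer(universeSize),
               alpha = alpha, lfcCutoff = lfcCutoff)
}

#' @describeIn DEGSet-class Upregulated gene ids.
#' @param x A `DEGSet`.
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))
#' @rdname DEGSet-class
#' @export
setMethod("upGenes", "DEGSet", function(x) x@up)

#' @describeIn DEGSet-class Downregulated gene ids.
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))
#' @rdname DEGSet-class
#' @export
setMethod("downGenes", "DEGSet", function(x) x@down)

#' @describeIn DEGSet-class Union of up- and downregulated gene ids.
#' @export
setGeneric("degGenes", function(x) standardGeneric("degGenes"))
#' @rdname DEGSet-class
#' @export
setMethod("degGenes", "DEGSet", function(x) union(x@up, x@down))

#' @describeIn DEGSet-class Number of tested genes.
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
#' @rdname DEGSet-class
#' @export
setMethod("universeSize", "DEGSet", function(x) x@universeSize)

setMethod("show", "DEGSet", function(object) {
  cat("DEGSet for ", object@tf, ": ", length(object@up), " up, ",
      length(object@down), " down (universe ", object@universeSize,
      ", padj < ", object@alpha, ", |log2FC| > ", object@lfcCutoff, ")\n",
      sep = "")
})

#' OverlapAnalysis: observed vs. bootstrap-expected DEG-set overlap
#'
#' Result container of [degOverlapAnalysis()]. For each direction
#' (`up`, `down`, `all`) it stores the observed cross-paralog Jaccard index,
#' the within-paralog pairwise bootstrap Jaccard distributions (the expected
#' overlap under the shared-targets null), basic bootstrap confidence
#' intervals, one-sample Z tests and the observed/expected ratio.
#'
#' @slot observed Named numeric: observed Jaccard per direction.
#' @slot expected1,expected2 Named numeric: mean within-paralog bootstrap J.
#' @slot ci1,ci2,ciObserved 3 x 2 matrices of basic bootstrap intervals.
#' @slot z1,z2,p1,p2 Named numeric: Z statistics / p-values per paralog.
#' @slot oeRatio Named numeric: observed/expected ratio in percent.
#' @slot jWithin1,jWithin2,jCross Lists of pairwise Jaccard vectors.
#' @slot degs List of the two full-data [DEGSet-class] objects.
#' @slot correlation List from [zscoreCorrelation()].
#' @slot params List of analysis parameters (B, min_unique, seed, ...).
#' @export
setClass("OverlapAnalysis", representation(
  observed = "numeric", expected1 = "numeric", expected2 = "numeric",
  ci1 = "matrix", ci2 = "matrix", ciObserved = "matrix",
  z1 = "numeric", z2 = "numeric", p1 = "numeric", p2 = "numeric",
  oeRatio = "numeric", jWithin1 = "list", jWithin2 = "list",
  jCross = "list", degs = "list", correlation = "list", params = "list"))

setMethod("show", "OverlapAnalysis", function(object) {
  cat("OverlapAnalysis (B =", object@params$B, "bootstrap replicates)\n")
  print(renderTable1(object))
})
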