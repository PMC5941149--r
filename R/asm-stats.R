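# Assembly and annotation summary statistics.

#' Nx length and Lx count of a length set
#'
#' With the lengths sorted descending and `T` the filtered total, the Nx
#' is the length at which the cumulative sum first reaches `x`% of `T`,
#' and Lx is the number of sequences up to and including that one. This
#' is the usual contiguity statistic: N50 is the shortest sequence among
#' those covering half the assembly.
#'
#' @param lengths Integer/numeric vector of sequence lengths (bp).
#' @param x Percentage in (0, 100); 50 gives N50/L50.
#' @param min_length Drop sequences shorter than this before computing.
#' @return `list(nx = , lx = )`.
#' @examples
#' nxLx(c(10, 9, 8, 7, 6, 5), 50)  # N50 = 8, L50 = 3
#' @export
nxLx <- function(lengths, x, min_length = 0) {
  if (x <= 0 || x >= 100) stop("'x' must be in (0, 100)", call. = FALSE)
  lengths <- lengths[lengths >= min_length]
  if (!length(lengths)) stop("no sequences pass min_length", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(as.numeric(s)) >= x / 100 * sum(as.numeric(s)))[1L]
  list(nx = s[i], lx = i)
}

#' Count sequences at least a threshold long
#'
#' @param lengths Sequence lengths (bp).
#' @param threshold Minimum length in bp; the boundary is inclusive.
#' @return Integer count.
#' @export
countAtLeast <- function(lengths, threshold) {
  if (threshold < 0) stop("'threshold' must be >= 0", call. = FALSE)
  sum(lengths >= threshold)
}

#' Base composition and GC content
#'
#' Fractions of A, C, G, T are computed over unambiguous bases only;
#' `gc = (G + C) / (A + C + G + T)`. The count of N bases is reported
#' separately, along with the alternative GC convention that divides by
#' all bases including ambiguity codes.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector of
#'   nucleotide sequences).
#' @return `list(base_fractions = named numeric, gc = , n_count = ,
#'   gc_with_ambiguous = )`.
#' @export
baseComposition <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  af <- colSums(Biostrings::alphabetFrequency(seqs))
  acgt <- af[c("A", "C", "G", "T")]
  total <- sum(acgt)
  if (total == 0) stop("no unambiguous bases", call. = FALSE)
  n_count <- as.integer(af[["N"]])
  list(base_fractions = acgt / total,
       gc = unname((acgt[["G"]] + acgt[["C"]]) / total),
       n_count = n_count,
       gc_with_ambiguous = unname((acgt[["G"]] + acgt[["C"]]) /
                                    sum(Biostrings::width(seqs))))
}

#' Annotation acceptance rule
#'
#' The BLASTP acceptance rule used to call a predicted protein
#' "annotated": identity at least 30%, alignment length at least 80 bp,
#' and e-value at most 1e-5, all boundaries inclusive.
#'
#' @param identity Fractional identity in \[0, 1\].
#' @param aln_len Alignment length in bp.
#' @param evalue BLAST e-value.
#' @return Logical vector.
#' @export
acceptAnnotation <- function(identity, aln_len, evalue) {
  if (any(identity < 0 | identity > 1))
    stop("'identity' must be a fraction in [0, 1]", call. = FALSE)
  identity >= 0.30 & aln_len >= 80 & evalue <= 1e-5
}

#' Exact per-base coverage summary from aligned intervals
#'
#' Depth at every base is obtained by interval stacking (via
#' [IRanges::coverage()]); the summary reports the mean depth, type-1
#' (order statistic) quantiles, and a depth histogram. Mass is conserved:
#' the sum of depth over bases equals the sum of interval lengths.
#'
#' @param starts,ends 0-based half-open interval coordinates (internal
#'   convention), or an [IRanges::IRanges] in `starts`.
#' @param seq_len Sequence length in bp.
#' @param probs Quantile probabilities.
#' @return `list(mean_depth, depth_quantiles, histogram)`; the histogram
#'   is a named vector depth -> base count.
#' @export
perBaseCoverage <- function(starts, ends = NULL, seq_len,
                            probs = c(.05, .25, .5, .75, .95)) {
  if (methods::is(starts, "IRanges")) {
    ir <- starts
  } else {
    if (length(starts) != length(ends))
      stop("starts/ends length mismatch", call. = FALSE)
    if (length(starts) && (any(starts < 0) || any(ends > seq_len) ||
                           any(starts >= ends)))
      stop("interval out of bounds [0, seq_len)", call. = FALSE)
    ir <- IRanges::IRanges(start = starts + 1L, end = ends)  # to 1-based
  }
  if (length(ir) && (min(IRanges::start(ir)) < 1 ||
                     max(IRanges::end(ir)) > seq_len))
    stop("interval out of bounds [0, seq_len)", call. = FALSE)
  cov <- IRanges::coverage(ir, width = seq_len)
  depth <- rep(S4Vectors::runValue(cov), S4Vectors::runLength(cov))
  hist <- table(depth)
  list(mean_depth = mean(depth),
       depth_quantiles = stats::quantile(depth, probs = probs, type = 1),
       histogram = stats::setNames(as.integer(hist), names(hist)))
}

#' Pooled gene-element length statistics
#'
#' Gene span is the distance from the start of the first exon to the end
#' of the last; introns are the gaps between consecutive exons. Means are
#' pooled across all genes / exons / introns (not averaged per gene
#' first). Coordinates are 0-based half-open.
#'
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`.
#' @param cds Optional `data.frame` with the same columns restricted to
#'   coding intervals; enables the mean CDS length per gene.
#' @return `list(n_genes, mean_span, mean_exon, mean_intron, mean_cds)`;
#'   `mean_intron` is `NA` when every gene is single-exon, `mean_cds`
#'   `NA` when `cds` is missing.
#' @export
geneModelStats <- function(exons, cds = NULL) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(exons$start >= exons$end))
    stop("exon with start >= end", call. = FALSE)
  by_gene <- split(exons[c("start", "end")], exons$gene_id)
  spans <- vapply(by_gene, function(g) max(g$end) - min(g$start), 0)
  introns <- unlist(lapply(by_gene, function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping exons within a gene", call. = FALSE)
    if (nrow(g) < 2) numeric(0) else g$start[-1] - g$end[-nrow(g)]
  }), use.names = FALSE)
  mean_cds <- NA_real_
  if (!is.null(cds)) {
    cds_by_gene <- split(cds$end - cds$start, cds$gene_id)
    mean_cds <- mean(vapply(cds_by_gene, sum, 0))
  }
  list(n_genes = length(by_gene),
       mean_span = mean(spans),
       mean_exon = mean(exons$end - exons$start),
       mean_intron = if (length(introns)) mean(introns) else NA_real_,
       mean_cds = mean_cds)
}

# ---- AssemblyReport --------------------------------------------------------

#' Assembly summary report
#'
#' Container for whole-assembly summary statistics: total/max/mean
#' length, N-base count, Nx/Lx at 50 and 75, counts above standard size
#' thresholds, and base composition with GC under both the
#' unambiguous-base (headline) and all-base conventions.
#'
#' @slot total_length,max_length,mean_length,n_count Numbers of bp.
#' @slot nx,lx Named numeric vectors over x = 50, 75.
#' @slot counts_ge Named integer vector threshold (bp) -> count.
#' @slot gc,gc_with_ambiguous GC fractions under the two conventions.
#' @slot base_fractions Named fractions of A, C, G, T.
#' @slot n_sequences Number of sequences after the length filter.
#' @slot min_length The length filter applied.
#' @export
setClass("AssemblyReport",
         representation(total_length = "numeric", max_length = "numeric",
                        mean_length = "numeric", n_count = "numeric",
                        nx = "numeric", lx = "numeric",
                        counts_ge = "integer", gc = "numeric",
                        gc_with_ambiguous = "numeric",
                        base_fractions = "numeric",
                        n_sequences = "integer", min_length = "numeric"))

setValidity("AssemblyReport", function(object) {
  if (length(object@nx) >= 2 && object@nx[["50"]] < object@nx[["75"]])
    return("N50 must be >= N75")
  if (length(object@lx) >= 2 && object@lx[["50"]] > object@lx[["75"]])
    return("L50 must be <= L75")
  if (is.unsorted(rev(object@counts_ge)))
    return("counts_ge must be non-increasing in threshold")
  if (abs(sum(object@base_fractions) - 1) > 1e-9)
    return("base fractions must sum to 1")
  TRUE
})

#' @export
setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport (", object@n_sequences, " sequences >= ",
      object@min_length, " bp)\n", sep = "")
  cat(sprintf("  total %s bp, max %s bp, mean %.0f bp, Ns %s\n",
              format(object@total_length, big.mark = ","),
              format(object@max_length, big.mark = ","),
              object@mean_length,
              format(object@n_count, big.mark = ",")))
  cat(sprintf("  N50 %s (L50 %d), N75 %s (L75 %d)\n",
              format(object@nx[["50"]], big.mark = ","),
              as.integer(object@lx[["50"]]),
              format(object@nx[["75"]], big.mark = ","),
              as.integer(object@lx[["75"]])))
  cat(sprintf("  GC %.2f%% (unambiguous) / %.2f%% (all bases)\n",
              100 * object@gc, 100 * object@gc_with_ambiguous))
  invisible(object)
})

#' Compute an assembly summary report
#'
#' @param seqs A [Biostrings::DNAStringSet] of scaffolds or contigs.
#' @param min_length Length filter in bp applied before all statistics
#'   (contig tables conventionally use 300, scaffold tables 1000).
#' @param thresholds Size thresholds (bp) for the "counts at least"
#'   rows.
#' @return An [AssemblyReport-class] object.
#' @export
assemblyReport <- function(seqs, min_length = 0,
                           thresholds = c(300, 1000, 5000, 10000)) {
  keep <- Biostrings::width(seqs) >= min_length
  seqs <- seqs[keep]
  if (!length(seqs)) stop("no sequences pass min_length", call. = FALSE)
  lens <- Biostrings::width(seqs)
  comp <- baseComposition(seqs)
  n50 <- nxLx(lens, 50); n75 <- nxLx(lens, 75)
  methods::new("AssemblyReport",
    total_length = sum(as.numeric(lens)), max_length = max(lens),
    mean_length = mean(lens), n_count = comp$n_count,
    nx = c("50" = n50$nx, "75" = n75$nx),
    lx = c("50" = n50$lx, "75" = n75$lx),
    counts_ge = stats::setNames(
      vapply(thresholds, function(t) countAtLeast(lens, t), 0L),
      as.character(thresholds)),
    gc = comp$gc, gc_with_ambiguous = comp$gc_with_ambiguous,
    base_fractions = comp$base_fractions,
    n_sequences = length(seqs), min_length = as.numeric(min_length))
}
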