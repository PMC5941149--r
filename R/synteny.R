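# Whole-genome alignment block filtering, orientation classification and
# per-chromosome summaries.

#' Read a show-coords-like alignment block table
#'
#' Tab-separated, one block per line, with the MUMmer show-coords column
#' layout `S1 E1 S2 E2 LEN1 LEN2 %IDY REF QRY` (as from
#' `show-coords -T -H`): reference (chromosome) coordinates first, then
#' query (scaffold) coordinates, both 1-based inclusive. Descending
#' query coordinates encode reverse orientation and are preserved.
#'
#' @param path Path to the table (optionally gzipped).
#' @return `data.frame` of blocks with columns `query_id`, `q_start`,
#'   `q_end`, `subject_id`, `s_start`, `s_end`, `identity`,
#'   `aligned_length`.
#' @export
readCoords <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 9L)
    stop("expected >= 9 columns (S1 E1 S2 E2 LEN1 LEN2 %IDY REF QRY)",
         call. = FALSE)
  data.frame(query_id = as.character(df[[9L]]),
             q_start = as.integer(df[[3L]]), q_end = as.integer(df[[4L]]),
             subject_id = as.character(df[[8L]]),
             s_start = as.integer(df[[1L]]), s_end = as.integer(df[[2L]]),
             identity = as.numeric(df[[7L]]),
             aligned_length = as.integer(df[[5L]]),
             stringsAsFactors = FALSE)
}

#' Classify alignment block orientation
#'
#' A block is `forward` when query and subject coordinates increase
#' together and `reverse` when one axis descends — the reverse-complement
#' alignments that mark inversions.
#'
#' @param blocks Block `data.frame` with `q_start`, `q_end`, `s_start`,
#'   `s_end` columns.
#' @return `blocks` with an added `orientation` factor
#'   (`forward`/`reverse`).
#' @export
classifyOrientation <- function(blocks) {
  dq <- blocks$q_end - blocks$q_start
  ds <- blocks$s_end - blocks$s_start
  if (any(dq == 0) || any(ds == 0))
    stop("zero-length block on one axis", call. = FALSE)
  blocks$orientation <- factor(ifelse(sign(dq) == sign(ds),
                                      "forward", "reverse"),
                               levels = c("forward", "reverse"))
  blocks
}

#' Dot-plot block filter
#'
#' Keeps blocks at least `min_aln` bp long whose scaffold's total
#' aligned span on the chromosome reaches `min_fraction` of the
#' chromosome (both boundaries inclusive, per "at least"). The span
#' predicate is recomputed from the blocks that pass the length filter,
#' so the filter is stable under upstream subsetting. `fraction_of`
#' selects the denominator: the chromosome's full length (default) or
#' its aligned portion.
#'
#' @param blocks Block `data.frame` (see [readCoords()]).
#' @param chrom_lengths Named vector subject_id -> chromosome length.
#' @param min_aln Minimum block alignment length in bp.
#' @param min_fraction Minimum scaffold aligned span as a fraction of
#'   the denominator.
#' @param fraction_of `"chromosome"` or `"aligned"`.
#' @return Filtered block `data.frame`.
#' @export
dotplotFilter <- function(blocks, chrom_lengths, min_aln = 3000,
                          min_fraction = 0.0025,
                          fraction_of = c("chromosome", "aligned")) {
  fraction_of <- match.arg(fraction_of)
  unknown <- setdiff(blocks$subject_id, names(chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome: ", unknown[1L], call. = FALSE)
  long <- blocks[blocks$aligned_length >= min_aln, , drop = FALSE]
  if (!nrow(long)) return(long)
  key <- paste(long$query_id, long$subject_id, sep = "\r")
  span <- tapply(long$aligned_length, key, sum)
  denom <- if (fraction_of == "chromosome")
    chrom_lengths[long$subject_id]
  else {
    per_chrom <- tapply(long$aligned_length, long$subject_id, sum)
    per_chrom[long$subject_id]
  }
  keep <- as.numeric(span[key]) >= min_fraction * as.numeric(denom)
  out <- long[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chord-diagram block filter
#'
#' Keeps blocks from scaffolds with total length strictly greater than
#' `min_scaffold` and alignment length strictly greater than `min_aln`
#' (both strict, per "greater than").
#'
#' @param blocks Block `data.frame`.
#' @param scaffold_lengths Named vector query_id -> scaffold length.
#' @param min_scaffold Scaffold length threshold in bp (strict).
#' @param min_aln Alignment length threshold in bp (strict).
#' @return Filtered block `data.frame`.
#' @export
chordFilter <- function(blocks, scaffold_lengths, min_scaffold = 500000,
                        min_aln = 10000) {
  unknown <- setdiff(blocks$query_id, names(scaffold_lengths))
  if (length(unknown))
    stop("unknown scaffold: ", unknown[1L], call. = FALSE)
  keep <- scaffold_lengths[blocks$query_id] > min_scaffold &
    blocks$aligned_length > min_aln
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome alignment summary and overall coverage
#'
#' Per-chromosome identity is the alignment-length-weighted mean of
#' block identities; covered bp is the union (overlaps merged) of
#' subject intervals, so it never exceeds the chromosome length. Overall
#' coverage is total merged covered bp over total chromosome length.
#'
#' @param blocks Block `data.frame` with `identity` and subject
#'   coordinates.
#' @param chrom_lengths Named vector subject_id -> chromosome length;
#'   chromosomes without blocks report zero coverage.
#' @return `list(per_chromosome = data.frame(subject_id,
#'   weighted_identity, covered_bp, coverage_fraction),
#'   overall_coverage = fraction)`.
#' @export
chromosomeSummary <- function(blocks, chrom_lengths) {
  ids <- names(chrom_lengths)
  rows <- lapply(ids, function(chr) {
    b <- blocks[blocks$subject_id == chr, , drop = FALSE]
    if (!nrow(b))
      return(data.frame(subject_id = chr, weighted_identity = NA_real_,
                        covered_bp = 0L, coverage_fraction = 0,
                        stringsAsFactors = FALSE))
    ir <- IRanges::IRanges(start = pmin(b$s_start, b$s_end),
                           end = pmax(b$s_start, b$s_end))
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    data.frame(subject_id = chr,
               weighted_identity = sum(b$identity * b$aligned_length) /
                 sum(b$aligned_length),
               covered_bp = covered,
               coverage_fraction = covered / chrom_lengths[[chr]],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_chromosome = per,
       overall_coverage = sum(per$covered_bp) /
         sum(as.numeric(chrom_lengths)))
}
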