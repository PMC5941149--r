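# Multi-stage contamination screen over best-hit BLAST tables.

#' Cascade filter over taxonomic read hits
#'
#' Applies the screening cascade to a best-hit-per-read table, in fixed
#' order: (1) keep hits with alignment length >= `min_aln` bp; (2) drop
#' hits matching an avian species (the assembly's own clade); (3) drop
#' hits whose species has fewer than `min_species_count` surviving reads
#' (strict: a species at exactly the threshold is kept). Species tallies
#' are computed after the avian drop; the pre-avian tallies are attached
#' for logging.
#'
#' @param hits `data.frame` with columns `read_id`, `species`,
#'   `is_avian`, `alignment_length` (and usually `scaffold_id`), one row
#'   per read.
#' @param min_aln Minimum alignment length in bp (inclusive).
#' @param min_species_count Minimum surviving reads per species; species
#'   below this are treated as spurious.
#' @return The surviving subset of `hits`, with attributes
#'   `stage_counts` (named read counts: input, after each stage) and
#'   `species_counts` / `species_counts_pre_avian` (per-species tallies).
#' @export
cascadeFilter <- function(hits, min_aln = 100, min_species_count = 50) {
  stopifnot(all(c("read_id", "species", "is_avian",
                  "alignment_length") %in% names(hits)))
  if (anyDuplicated(hits$read_id))
    stop("'hits' must contain one best hit per read", call. = FALSE)
  n0 <- nrow(hits)
  s1 <- hits[hits$alignment_length >= min_aln, , drop = FALSE]
  pre_avian <- table(s1$species)
  s2 <- s1[!s1$is_avian, , drop = FALSE]
  tab <- table(s2$species)
  keep_sp <- names(tab)[tab >= min_species_count]
  s3 <- s2[s2$species %in% keep_sp, , drop = FALSE]
  rownames(s3) <- NULL
  attr(s3, "stage_counts") <- c(input = n0, min_aln = nrow(s1),
                                non_avian = nrow(s2),
                                species_count = nrow(s3))
  attr(s3, "species_counts_pre_avian") <-
    stats::setNames(as.integer(pre_avian), names(pre_avian))
  attr(s3, "species_counts") <- stats::setNames(as.integer(tab), names(tab))
  s3
}

#' Call contaminated scaffolds from surviving hits
#'
#' A scaffold is flagged for removal when strictly more than `min_reads`
#' surviving reads land on it (a scaffold at exactly the threshold is
#' kept).
#'
#' @param hits Surviving hits from [cascadeFilter()], carrying
#'   `scaffold_id`.
#' @param min_reads Read-count cutoff per scaffold (strict `>`).
#' @param scaffold_ids Optional scaffold universe so that scaffolds with
#'   zero surviving reads appear in the output with
#'   `supporting_reads = 0`.
#' @return `data.frame` with columns `scaffold_id`, `supporting_reads`,
#'   `removed`, and a list-column `species_breakdown` of per-species
#'   read counts.
#' @export
callScaffolds <- function(hits, min_reads = 20, scaffold_ids = NULL) {
  stopifnot("scaffold_id" %in% names(hits))
  hits <- hits[!is.na(hits$scaffold_id), , drop = FALSE]
  ids <- unique(c(scaffold_ids, hits$scaffold_id))
  counts <- table(factor(hits$scaffold_id, levels = ids))
  breakdown <- lapply(ids, function(sid) {
    tb <- table(hits$species[hits$scaffold_id == sid])
    stats::setNames(as.integer(tb), names(tb))
  })
  out <- data.frame(scaffold_id = ids,
                    supporting_reads = as.integer(counts),
                    removed = as.integer(counts) > min_reads,
                    stringsAsFactors = FALSE)
  out$species_breakdown <- breakdown
  rownames(out) <- NULL
  out
}

#' Contamination screen report
#'
#' Summary of a screening run: scaffolds and bases removed, plus the
#' per-stage read counts of the cascade.
#'
#' @slot n_scaffolds_removed Count of removed scaffolds.
#' @slot bp_removed Total bp of removed scaffolds.
#' @slot stage_counts Named read counts through the cascade.
#' @export
setClass("ScreenReport",
         representation(n_scaffolds_removed = "integer",
                        bp_removed = "numeric",
                        stage_counts = "integer"))

setValidity("ScreenReport", function(object) {
  sc <- object@stage_counts
  if (length(sc) > 1 && is.unsorted(rev(sc)))
    return("stage counts must be non-increasing through the cascade")
  TRUE
})

#' @export
setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport: %d scaffold(s) removed, %s bp\n",
              object@n_scaffolds_removed,
              format(object@bp_removed, big.mark = ",")))
  if (length(object@stage_counts))
    cat("  reads through cascade:",
        paste(sprintf("%s=%d", names(object@stage_counts),
                      object@stage_counts), collapse = " -> "), "\n")
  invisible(object)
})

#' Remove called scaffolds from an assembly
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param calls Output of [callScaffolds()].
#' @param stage_counts Optional named per-stage read counts (as attached
#'   by [cascadeFilter()]) to embed in the report.
#' @return `list(assembly = cleaned DNAStringSet,
#'   report = ScreenReport)`.
#' @export
applyRemoval <- function(assembly, calls, stage_counts = integer(0)) {
  drop_ids <- calls$scaffold_id[calls$removed]
  unknown <- setdiff(drop_ids, names(assembly))
  if (length(unknown))
    stop("call references unknown scaffold: ", unknown[1L], call. = FALSE)
  keep <- !(names(assembly) %in% drop_ids)
  report <- methods::new("ScreenReport",
    n_scaffolds_removed = length(drop_ids),
    bp_removed = sum(as.numeric(Biostrings::width(assembly)[!keep])),
    stage_counts = stats::setNames(as.integer(stage_counts),
                                   names(stage_counts)))
  list(assembly = assembly[keep], report = report)
}

#' Run the full contamination screen
#'
#' Convenience wrapper chaining [cascadeFilter()], [callScaffolds()] and
#' [applyRemoval()].
#'
#' @inheritParams cascadeFilter
#' @inheritParams callScaffolds
#' @param assembly A named [Biostrings::DNAStringSet].
#' @return `list(assembly, report, calls, surviving_hits)`.
#' @export
screenContamination <- function(assembly, hits, min_aln = 100,
                                min_species_count = 50, min_reads = 20) {
  surv <- cascadeFilter(hits, min_aln = min_aln,
                        min_species_count = min_species_count)
  calls <- callScaffolds(surv, min_reads = min_reads,
                         scaffold_ids = names(assembly))
  res <- applyRemoval(assembly, calls,
                      stage_counts = attr(surv, "stage_counts"))
  c(res, list(calls = calls, surviving_hits = surv))
}
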