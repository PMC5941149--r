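# Gene-family size matrices, single-copy orthologs, and supermatrix
# concatenation.

#' Gene-family size matrix
#'
#' Counts genes per cluster per species; species absent from a cluster
#' count zero. Rows are clusters, columns the declared species order.
#'
#' @param clusters An [OrthoClusters-class] object.
#' @param species_list Species columns (defaults to the declared
#'   species).
#' @return Integer matrix, `length(clusters)` x
#'   `length(species_list)`.
#' @export
familyMatrix <- function(clusters, species_list = speciesNames(clusters)) {
  if (!length(species_list)) stop("empty species list", call. = FALSE)
  cl <- clusterList(clusters)
  m <- matrix(0L, nrow = length(cl), ncol = length(species_list),
              dimnames = list(names(cl), species_list))
  for (cid in names(cl)) {
    cnt <- lengths(cl[[cid]])
    present <- intersect(names(cnt), species_list)
    m[cid, present] <- as.integer(cnt[present])
  }
  m
}

#' Single-copy ortholog clusters
#'
#' Clusters in which every species of `species_list` has exactly one
#' gene — the unit of phylogenomic supermatrices.
#'
#' @inheritParams familyMatrix
#' @return Character vector of cluster ids.
#' @export
singleCopy <- function(clusters, species_list = speciesNames(clusters)) {
  m <- familyMatrix(clusters, species_list)
  rownames(m)[rowSums(m == 1L) == ncol(m)]
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Every gene alignment must contain all species, with equal sequence
#' lengths within a gene. Genes are concatenated in the same fixed order
#' for every species (defaulting to lexicographic gene id, which is
#' deterministic); the partition table records each gene's coordinates
#' in 1-based inclusive output convention.
#'
#' @param gene_alignments Named list gene -> named character vector (or
#'   `XStringSet`) species -> aligned sequence.
#' @param species_order Species order of the output.
#' @param gene_order Gene concatenation order; default sorted gene ids.
#' @return `list(alignment = named character vector per species,
#'   partitions = data.frame(gene, start, end))`.
#' @export
concatenateAlignments <- function(gene_alignments,
                                  species_order = NULL,
                                  gene_order = sort(names(gene_alignments))) {
  if (!length(gene_alignments)) stop("no gene alignments", call. = FALSE)
  gene_alignments <- lapply(gene_alignments, function(x)
    if (is.character(x)) x else stats::setNames(as.character(x), names(x)))
  if (is.null(species_order))
    species_order <- names(gene_alignments[[1L]])
  if (!setequal(gene_order, names(gene_alignments)))
    stop("gene_order must be a permutation of the alignment names",
         call. = FALSE)
  for (g in gene_order) {
    aln <- gene_alignments[[g]]
    missing <- setdiff(species_order, names(aln))
    if (length(missing))
      stop("gene ", g, " lacks species ", missing[1L], call. = FALSE)
    if (length(unique(nchar(aln[species_order]))) != 1L)
      stop("length mismatch within gene ", g, call. = FALSE)
  }
  lens <- vapply(gene_alignments[gene_order],
                 function(a) nchar(a[[1L]]), 0)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  alignment <- vapply(species_order, function(sp)
    paste(vapply(gene_order, function(g)
      gene_alignments[[g]][[sp]], ""), collapse = ""), "")
  list(alignment = alignment,
       partitions = data.frame(gene = gene_order,
                               start = as.integer(starts),
                               end = as.integer(ends),
                               stringsAsFactors = FALSE,
                               row.names = NULL))
}

#' Write a family-size matrix as a CAFE-style table
#'
#' Tab-separated with Description and ID columns followed by one column
#' per species.
#'
#' @param m Matrix from [familyMatrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFamilyMatrix <- function(m, path) {
  df <- data.frame(Description = rep("(null)", nrow(m)),
                   ID = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a supermatrix as FASTA plus a RAxML-style partition file
#'
#' @param sm Output of [concatenateAlignments()].
#' @param fasta_path,partition_path Output paths.
#' @param type Partition data type tag (`"DNA"` or `"WAG"` etc.).
#' @return `fasta_path`, invisibly.
#' @export
writeSupermatrix <- function(sm, fasta_path, partition_path,
                             type = "DNA") {
  writeFasta(sm$alignment, fasta_path)
  writeLines(sprintf("%s, %s = %d-%d", type, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end),
             partition_path)
  invisible(fasta_path)
}
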