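#' Read a FASTA file into a validated string set
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces a
#' declared alphabet, uppercases residues, and reports format problems by
#' record name. Sequence ids are the first whitespace-delimited token of
#' the header; the remainder is kept in the `description` metadata column.
#' Gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param alphabet `"nucleotide"` (IUPAC DNA codes) or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] with
#'   one element per record, in file order, with a `description` column in
#'   its metadata.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence ", ids[which(empty)[1L]], call. = FALSE)
  valid <- if (alphabet == "nucleotide") "ACGTNRYSWKMBDHV" else
    "ACDEFGHIKLMNPQRSTVWYBXZJUO*"
  bad <- grepl(sprintf("[^%s]", valid), seqs)
  if (any(bad))
    stop(sprintf("record %s contains residues outside the %s alphabet",
                 ids[which(bad)[1L]], alphabet), call. = FALSE)
  out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences as FASTA
#'
#' Sequences are wrapped at 60 columns, the biologist-facing convention
#' used throughout the package's outputs.
#'
#' @param x A named `XStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line width in residues.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named", call. = FALSE)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a taxon table
#'
#' Three-column whitespace/tab-separated text mapping NCBI-style taxids to
#' species labels and an avian flag. Avian status comes from this
#' caller-supplied table rather than a live taxonomy service, keeping the
#' screen fully offline.
#'
#' @param path Path to a TSV with columns taxid, species, is_avian
#'   (logical or 0/1). A header line is optional.
#' @return `data.frame` with columns `taxid` (character), `species`,
#'   `is_avian` (logical).
#' @export
readTaxonTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#",
                          col.names = c("taxid", "species", "is_avian"))
  if (is.character(df$is_avian))
    df$is_avian <- df$is_avian %in% c("1", "TRUE", "true", "T", "yes")
  df$taxid <- as.character(df$taxid)
  df$is_avian <- as.logical(df$is_avian)
  if (anyDuplicated(df$taxid))
    stop("duplicated taxid in taxon table", call. = FALSE)
  df
}

#' Read BLAST tabular hits (outfmt 6 + staxids) as best-hit-per-read
#'
#' Parses the 13-column tabular dialect produced by
#' `-outfmt "6 std staxids"`: the 12 standard columns plus a staxids
#' column. One hit is kept per read: lowest e-value, ties broken by
#' highest bitscore, then first occurrence in the file. Multi-taxid cells
#' (`"562;563"`) resolve to the first listed taxid. Taxids missing from
#' `taxon_table` are retained with species `"unknown"` and
#' `is_avian = FALSE`, with a warning.
#'
#' @param path Path to the tabular file (optionally gzipped).
#' @param taxon_table A `data.frame` as returned by [readTaxonTable()].
#' @param read_map Optional `data.frame` (or path to a two-column TSV) of
#'   `read_id`, `scaffold_id` giving each read's assembly placement; when
#'   supplied, a `scaffold_id` column is joined onto the hits.
#' @return `data.frame` with one row per distinct read:
#'   `read_id`, `species`, `is_avian`, `alignment_length`, `evalue`,
#'   `bitscore`, and `scaffold_id` when a read map was given.
#' @export
readBlastTab <- function(path, taxon_table, read_map = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 13L)
    stop("expected >= 13 tab-separated columns (outfmt 6 std staxids), got ",
         ncol(df), call. = FALSE)
  hits <- data.frame(read_id = as.character(df[[1L]]),
                     alignment_length = as.integer(df[[4L]]),
                     evalue = as.numeric(df[[11L]]),
                     bitscore = as.numeric(df[[12L]]),
                     staxid = sub(";.*$", "", as.character(df[[13L]])),
                     stringsAsFactors = FALSE)
  # best hit per read: e-value asc, bitscore desc, file order
  ord <- order(hits$read_id, hits$evalue, -hits$bitscore,
               seq_len(nrow(hits)))
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_id), , drop = FALSE]
  hits <- hits[order(match(hits$read_id, unique(df[[1L]]))), , drop = FALSE]
  idx <- match(hits$staxid, taxon_table$taxid)
  unknown <- is.na(idx)
  if (any(unknown))
    warning(sum(unknown), " hit(s) with taxid absent from the taxon table; ",
            "kept as species 'unknown', non-avian", call. = FALSE)
  hits$species <- ifelse(unknown, "unknown", taxon_table$species[idx])
  hits$is_avian <- ifelse(unknown, FALSE, taxon_table$is_avian[idx])
  hits$staxid <- NULL
  rownames(hits) <- NULL
  if (!is.null(read_map)) {
    if (is.character(read_map)) read_map <- readReadMap(read_map)
    hits$scaffold_id <- read_map$scaffold_id[
      match(hits$read_id, read_map$read_id)]
  }
  hits[, c("read_id", "species", "is_avian", "alignment_length",
           "evalue", "bitscore",
           if (!is.null(read_map)) "scaffold_id")]
}

#' Read a two-column read-to-scaffold map
#'
#' @param path TSV with columns read_id, scaffold_id (no header).
#' @return `data.frame` with columns `read_id`, `scaffold_id`.
#' @export
readReadMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("read_id", "scaffold_id"))
  df$read_id <- as.character(df$read_id)
  df$scaffold_id <- as.character(df$scaffold_id)
  df
}

#' Read a two-column gene-to-category annotation map
#'
#' @param path TSV with columns gene_id, category_id (no header); a gene
#'   may appear on several lines, one per category.
#' @return `data.frame` with columns `gene_id`, `category_id`.
#' @export
readGeneCategories <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("gene_id", "category_id"))
  df$gene_id <- as.character(df$gene_id)
  df$category_id <- as.character(df$category_id)
  unique(df)
}

# ---- OrthoClusters ---------------------------------------------------------

#' Ortholog cluster container
#'
#' Holds OrthoMCL-style gene clusters: a mapping from cluster id to
#' per-species gene lists over a declared species set. Validity enforces
#' that every gene id appears in at most one cluster and that only
#' declared species occur.
#'
#' @slot clusters Named list; each element is a named list
#'   species -> character vector of gene ids.
#' @slot species Character vector of declared species labels.
#' @export
setClass("OrthoClusters",
         representation(clusters = "list", species = "character"))

setValidity("OrthoClusters", function(object) {
  cl <- object@clusters
  if (length(cl) && is.null(names(cl))) return("clusters must be named")
  sp <- unique(unlist(lapply(cl, names)))
  if (length(setdiff(sp, object@species)))
    return(paste("undeclared species:",
                 paste(setdiff(sp, object@species), collapse = ", ")))
  genes <- unlist(lapply(cl, function(x)
    paste(rep(names(x), lengths(x)), unlist(x), sep = "|")),
    use.names = FALSE)
  if (anyDuplicated(genes))
    return(paste("gene assigned to more than one cluster:",
                 genes[duplicated(genes)][1L]))
  TRUE
})

#' @describeIn OrthoClusters Number of clusters.
#' @param x,object An `OrthoClusters`.
#' @export
setMethod("length", "OrthoClusters", function(x) length(x@clusters))

#' @describeIn OrthoClusters Cluster ids.
#' @export
setMethod("names", "OrthoClusters", function(x) names(x@clusters))

#' @export
setMethod("show", "OrthoClusters", function(object) {
  cat(sprintf("OrthoClusters: %d clusters over %d species (%s)\n",
              length(object@clusters), length(object@species),
              paste(object@species, collapse = ", ")))
})

#' Accessors for OrthoClusters
#'
#' `clusterList()` returns the cluster -> (species -> genes) list;
#' `speciesNames()` the declared species labels.
#' @param x An `OrthoClusters`.
#' @return A list, respectively a character vector.
#' @export
clusterList <- function(x) x@clusters

#' @rdname clusterList
#' @export
speciesNames <- function(x) x@species

#' Construct an OrthoClusters object
#'
#' @param clusters Named list cluster_id -> (species -> gene id vector).
#' @param species Declared species labels.
#' @return An [OrthoClusters-class] object.
#' @export
OrthoClusters <- function(clusters, species) {
  methods::new("OrthoClusters", clusters = clusters,
               species = as.character(species))
}

#' Read an OrthoMCL groups file
#'
#' Each line is `cluster_id: sp|gene sp|gene ...`. Species prefixes must
#' belong to `species_list`; a gene id occurring in more than one cluster
#' is an integrity error.
#'
#' @param path Path to the groups file (optionally gzipped).
#' @param species_list Declared species labels.
#' @return An [OrthoClusters-class] object; per-species gene lists keep
#'   file order.
#' @export
readClusters <- function(path, species_list) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(trimws(lines))]
  clusters <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed cluster line: ", ln, call. = FALSE)
    cid <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = ":")),
                     "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    sp <- sub("\\|.*$", "", toks)
    gene <- sub("^[^|]*\\|", "", toks)
    bad <- setdiff(sp, species_list)
    if (length(bad))
      stop("unknown species prefix '", bad[1L], "' in cluster ", cid,
           call. = FALSE)
    clusters[[cid]] <- split(gene, factor(sp, levels = unique(sp)))
  }
  OrthoClusters(clusters, species_list)
}
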