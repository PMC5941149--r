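# Pairwise codon-evolution statistics: Nei-Gojobori (1986) site and
# difference counting with Jukes-Cantor correction, LRT post-processing,
# and the consensus amino-acid substitution scanner.

.GC <- Biostrings::GENETIC_CODE
.BASES <- c("A", "C", "G", "T")

.codonAA <- function(codon) {
  aa <- .GC[codon]
  ifelse(is.na(aa), "X", aa)
}

.isStop <- function(codon) !is.na(.GC[codon]) & .GC[codon] == "*"

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' Each of the nine single-base mutants of the codon is classified under
#' the standard genetic code; the synonymous site count is the sum over
#' positions of the fraction of synonymous alternatives, so that
#' synonymous + nonsynonymous sites = 3 for every sense codon. Mutations
#' creating a stop codon count as nonsynonymous.
#'
#' @param codon A 3-letter string over A, C, G, T; not a stop codon.
#' @return `c(syn = , nonsyn = )`, summing to 3.
#' @examples
#' ng86Sites("TTT")  # 1/3 synonymous
#' ng86Sites("GGG")  # fourfold-degenerate third position: 1 synonymous
#' @export
ng86Sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("codon must be 3 bases over A, C, G, T", call. = FALSE)
  if (.isStop(codon)) stop("stop codon has no defined sites", call. = FALSE)
  aa <- .GC[[codon]]
  pos <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (i in 1:3) {
    for (b in setdiff(.BASES, pos[i])) {
      mut <- pos; mut[i] <- b
      mut_aa <- .GC[[paste(mut, collapse = "")]]
      if (mut_aa != "*" && mut_aa == aa) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Average (syn, nonsyn) differences between two codons over all minimal
# single-step pathways, excluding pathways that traverse a stop codon
# (standard NG86 practice). If every pathway is blocked by a stop, all
# pathways are used with stop-traversing steps counted nonsynonymous, so
# that syn + nonsyn always equals the number of differing positions.
.pathwayDiffs <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(diff_pos) else {
    idx <- if (d == 2L) list(1:2, 2:1) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(i) diff_pos[i])
  }
  walk <- function(order, allow_stop) {
    cur <- a; syn <- 0; nonsyn <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (.GC[[to]] == "*" && !identical(to, codon_b) && !allow_stop)
        return(NULL)
      if (.GC[[to]] != "*" && .GC[[from]] != "*" &&
          .GC[[to]] == .GC[[from]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(perms, walk, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

#' Per-column pairwise identity statistics
#'
#' Nucleotide identity is computed over alignment columns where both
#' sequences are non-gap; amino-acid statistics are computed over codon
#' columns free of gaps in both sequences, translated under the standard
#' genetic code.
#'
#' @param seq_a,seq_b Aligned nucleotide sequences of equal length
#'   (characters, `-` for gaps).
#' @return `list(aligned_bases, nt_identity, aligned_aa, aa_identity,
#'   aa_substitutions)`; identities are percentages.
#' @export
pairwiseIdentityStats <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  a <- strsplit(seq_a, "")[[1L]]; b <- strsplit(seq_b, "")[[1L]]
  both <- a != "-" & b != "-"
  aligned_bases <- sum(both)
  nt_identity <- if (aligned_bases) 100 * sum(a[both] == b[both]) /
    aligned_bases else NA_real_
  n_cod <- floor(length(a) / 3)
  aa_a <- character(0); aa_b <- character(0)
  if (n_cod > 0) {
    cs <- 3 * (seq_len(n_cod) - 1) + 1
    cod_a <- substring(seq_a, cs, cs + 2)
    cod_b <- substring(seq_b, cs, cs + 2)
    ok <- !grepl("-", cod_a) & !grepl("-", cod_b)
    aa_a <- .codonAA(cod_a[ok]); aa_b <- .codonAA(cod_b[ok])
  }
  aligned_aa <- length(aa_a)
  list(aligned_bases = aligned_bases,
       nt_identity = nt_identity,
       aligned_aa = aligned_aa,
       aa_identity = if (aligned_aa) 100 * sum(aa_a == aa_b) / aligned_aa
                     else NA_real_,
       aa_substitutions = sum(aa_a != aa_b))
}

#' Codon pair statistics container
#'
#' Per-gene-pair codon statistics: alignment identity at nucleotide and
#' amino-acid level, NG86 synonymous/nonsynonymous site and difference
#' counts, proportions, Jukes-Cantor-corrected distances and their ratio
#' omega = dN/dS. `omega_defined` is `FALSE` when dS is zero or a
#' proportion is saturated (p >= 3/4), in which case `omega` is `NA`.
#'
#' @slot gene_id Identifier of the pair.
#' @slot aligned_bases,aligned_aa,aa_substitutions Integer counts.
#' @slot nt_identity,aa_identity Percent identities.
#' @slot n_codons Codon columns compared (gap-free, unambiguous, sense).
#' @slot N,S,Nd,Sd,pN,pS,dN,dS,omega NG86 quantities.
#' @slot omega_defined Whether omega is reportable.
#' @export
setClass("CodonPairStats",
         representation(gene_id = "character", aligned_bases = "integer",
                        nt_identity = "numeric", aligned_aa = "integer",
                        aa_identity = "numeric", aa_substitutions = "integer",
                        n_codons = "integer", N = "numeric", S = "numeric",
                        Nd = "numeric", Sd = "numeric", pN = "numeric",
                        pS = "numeric", dN = "numeric", dS = "numeric",
                        omega = "numeric", omega_defined = "logical"))

setValidity("CodonPairStats", function(object) {
  if (abs(object@N + object@S - 3 * object@n_codons) > 1e-6)
    return("N + S must equal 3 x compared codons")
  if (object@Nd < 0 || object@Sd < 0) return("negative difference counts")
  TRUE
})

#' @export
setMethod("show", "CodonPairStats", function(object) {
  cat(sprintf("CodonPairStats %s: %d codons, nt id %.2f%%, aa id %s\n",
              object@gene_id, object@n_codons, object@nt_identity,
              ifelse(is.na(object@aa_identity), "NA",
                     sprintf("%.2f%%", object@aa_identity))))
  cat(sprintf("  N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%.4f dS=%.4f omega=%s\n",
              object@N, object@S, object@Nd, object@Sd, object@dN,
              object@dS,
              if (object@omega_defined) sprintf("%.4f", object@omega)
              else "undefined"))
  invisible(object)
})

#' dN/dS ratio of a codon pair
#' @param x A [CodonPairStats-class] object.
#' @return The omega value (`NA` when undefined).
#' @export
omegaRatio <- function(x) x@omega

.jc <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3) + 0  # +0 avoids IEEE negative zero at p = 0
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged with equal weight over all
#' minimal substitution pathways for multi-difference codons, excluding
#' pathways through stop codons), then applies the Jukes-Cantor
#' correction `d = -(3/4) log(1 - (4/3) p)` to each proportion. Codon
#' columns containing a gap in either sequence are removed pairwise
#' first; codons with ambiguity codes or stops are skipped with a
#' warning.
#'
#' @param seq_a,seq_b Aligned codon sequences of equal length (character
#'   or `DNAString`); length must be divisible by 3.
#' @param gene_id Label for the pair.
#' @return A [CodonPairStats-class] object.
#' @examples
#' ng86Dnds(paste0(strrep("TTT", 9), "GGG"), paste0(strrep("TTT", 9), "GGA"))
#' @export
ng86Dnds <- function(seq_a, seq_b, gene_id = "pair") {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(seq_a) %% 3 != 0)
    stop("aligned length must be divisible by 3", call. = FALSE)
  ident <- pairwiseIdentityStats(seq_a, seq_b)
  cs <- 3 * (seq_len(nchar(seq_a) / 3) - 1) + 1
  cod_a <- substring(seq_a, cs, cs + 2)
  cod_b <- substring(seq_b, cs, cs + 2)
  gapless <- !grepl("-", cod_a) & !grepl("-", cod_b)
  cod_a <- cod_a[gapless]; cod_b <- cod_b[gapless]
  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  stops <- clean & (.isStop(cod_a) | .isStop(cod_b))
  usable <- clean & !stops
  if (any(!usable))
    warning(sum(!usable), " codon column(s) skipped (ambiguous or stop)",
            call. = FALSE)
  cod_a <- cod_a[usable]; cod_b <- cod_b[usable]
  n_cod <- length(cod_a)
  if (n_cod == 0L) stop("no comparable codons", call. = FALSE)
  sites_a <- vapply(cod_a, ng86Sites, c(syn = 0, nonsyn = 0))
  sites_b <- vapply(cod_b, ng86Sites, c(syn = 0, nonsyn = 0))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- 3 * n_cod - S
  diffs <- mapply(function(x, y) .pathwayDiffs(x, y), cod_a, cod_b)
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- .jc(pS); dN <- .jc(pN)
  omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
  methods::new("CodonPairStats",
    gene_id = gene_id,
    aligned_bases = as.integer(ident$aligned_bases),
    nt_identity = ident$nt_identity,
    aligned_aa = as.integer(ident$aligned_aa),
    aa_identity = ident$aa_identity,
    aa_substitutions = as.integer(ident$aa_substitutions),
    n_codons = as.integer(n_cod), N = N, S = S, Nd = Nd, Sd = Sd,
    pN = ifelse(is.na(pN), NA_real_, pN), pS = ifelse(is.na(pS), NA_real_, pS),
    dN = ifelse(is.na(dN), NA_real_, dN), dS = ifelse(is.na(dS), NA_real_, dS),
    omega = if (omega_defined) dN / dS else NA_real_,
    omega_defined = omega_defined)
}

#' Tabulate codon pair statistics
#'
#' Collapses a list of [CodonPairStats-class] objects into one
#' data.frame row per gene, in the column order used for reporting
#' MHC-style gene tables: aligned bases, nucleotide identity, aligned
#' amino acids, amino-acid identity, substitutions, dN/dS.
#'
#' @param stats A list of `CodonPairStats`.
#' @return A `data.frame`.
#' @export
codonPairTable <- function(stats) {
  if (methods::is(stats, "CodonPairStats")) stats <- list(stats)
  do.call(rbind, lapply(stats, function(s) data.frame(
    gene = s@gene_id, aligned_bases = s@aligned_bases,
    nt_identity = s@nt_identity, aligned_aa = s@aligned_aa,
    aa_identity = s@aa_identity, aa_substitutions = s@aa_substitutions,
    dN = s@dN, dS = s@dS, dnds = s@omega,
    stringsAsFactors = FALSE)))
}

# ---- branch-site LRT post-processing --------------------------------------

#' Branch-site likelihood ratio test from model log-likelihoods
#'
#' Computes `stat = max(0, 2 (lnL_alt - lnL_null))` and its upper-tail
#' chi-square probability with one degree of freedom (the conservative
#' convention for the branch-site test). Negative differences — optimizer
#' noise — are clamped to zero with a warning. Setting `mixture = TRUE`
#' uses the 50:50 point-mass/chi-square(1) mixture null instead.
#'
#' @param lnl_null,lnl_alt Finite log-likelihoods of the null
#'   (omega fixed at 1) and alternative models; vectorized.
#' @param gene_id Optional gene labels.
#' @param mixture Use the mixture null distribution.
#' @return `data.frame` with columns `gene_id`, `lrt_stat`, `df`, `p`.
#' @export
branchSiteLRT <- function(lnl_null, lnl_alt, gene_id = NULL,
                          mixture = FALSE) {
  if (any(!is.finite(lnl_null)) || any(!is.finite(lnl_alt)))
    stop("log-likelihoods must be finite", call. = FALSE)
  stat <- 2 * (lnl_alt - lnl_null)
  if (any(stat < 0))
    warning(sum(stat < 0), " test(s) with lnL_alt < lnL_null clamped to 0",
            call. = FALSE)
  stat <- pmax(0, stat)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- ifelse(stat == 0, 1, 0.5 * p)
  data.frame(gene_id = if (is.null(gene_id))
    paste0("g", seq_along(stat)) else as.character(gene_id),
    lrt_stat = stat, df = 1, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank, capped at
#' 1, returned in input order.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bhFdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Positively selected gene calls from per-gene log-likelihoods
#'
#' Runs the branch-site LRT per gene and adjusts with
#' Benjamini-Hochberg; genes with `q < fdr_cutoff` are flagged.
#'
#' @param lnl `data.frame` with columns `gene_id`, `lnl_null`,
#'   `lnl_alt`.
#' @param fdr_cutoff FDR threshold for the `selected` flag.
#' @param mixture Passed to [branchSiteLRT()].
#' @return `data.frame` with `gene_id`, `lrt_stat`, `df`, `p`, `q`,
#'   `selected`.
#' @export
selectionTests <- function(lnl, fdr_cutoff = 0.05, mixture = FALSE) {
  stopifnot(all(c("gene_id", "lnl_null", "lnl_alt") %in% names(lnl)))
  out <- branchSiteLRT(lnl$lnl_null, lnl$lnl_alt, lnl$gene_id,
                       mixture = mixture)
  out$q <- bhFdr(out$p)
  out$selected <- out$q < fdr_cutoff
  out
}

# ---- consensus amino-acid substitution scan -------------------------------

#' Scan a protein alignment for focal-specific consensus substitutions
#'
#' For each alignment column where at least `min_support` of the
#' non-focal sequences share a single residue and the focal sequence
#' carries a different, non-gap residue, a substitution is reported.
#' Positions are 1-based indices in the ungapped focal sequence (the
#' convention in which a hemoglobin change is quoted as, say, position
#' 78). With the default `min_support = 1` a substitution requires every
#' non-focal sequence to agree on the consensus residue.
#'
#' @param msa A named [Biostrings::AAStringSet] (or named character
#'   vector) of aligned protein sequences of equal length.
#' @param focal_id Name of the focal sequence.
#' @param min_support Minimum fraction of non-focal sequences carrying
#'   the consensus residue.
#' @return `data.frame` with columns `position`, `consensus_residue`,
#'   `focal_residue`, `support`.
#' @export
consensusSubstitutions <- function(msa, focal_id, min_support = 1.0) {
  if (!is.character(msa))
    msa <- stats::setNames(as.character(msa), names(msa))
  if (is.null(names(msa))) stop("'msa' must be named", call. = FALSE)
  if (!focal_id %in% names(msa))
    stop("focal sequence '", focal_id, "' absent from alignment",
         call. = FALSE)
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(mat) <- names(msa)
  focal <- mat[focal_id, ]
  others <- mat[setdiff(rownames(mat), focal_id), , drop = FALSE]
  pos_ungapped <- cumsum(focal != "-")
  out <- list()
  for (j in seq_len(ncol(mat))) {
    if (focal[j] == "-") next
    col <- others[, j]
    tab <- table(col[col != "-"])
    if (!length(tab)) next
    consensus <- names(tab)[which.max(tab)]
    support <- sum(col == consensus) / length(col)
    if (support >= min_support && focal[j] != consensus)
      out[[length(out) + 1L]] <- data.frame(
        position = pos_ungapped[j], consensus_residue = consensus,
        focal_residue = focal[j], support = support,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(0),
                      consensus_residue = character(0),
                      focal_residue = character(0), support = numeric(0)))
  do.call(rbind, out)
}
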