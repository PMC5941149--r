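# Seeded synthetic-data generators. Each generator draws from its own
# RNG stream derived from the master seed by a fixed label, so adding a
# generator never perturbs existing fixtures. Truth tables are returned
# alongside every dataset and are meant for tests only, never as
# pipeline inputs.

#' Simulate an assembly of random scaffolds
#'
#' Scaffold lengths are log-normal (the long-tailed distribution typical
#' of short-read assemblies); bases are drawn i.i.d. at the target GC,
#' split evenly between G/C and between A/T.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param meanlog,sdlog Log-normal parameters of scaffold length in bp.
#' @param gc Target GC fraction.
#' @param min_length Floor on simulated lengths in bp.
#' @param seed Master seed (mandatory).
#' @return `list(sequences = named DNAStringSet,
#'   truth = data.frame(scaffold_id, length))`.
#' @export
simAssembly <- function(n_scaffolds = 50, meanlog = log(20000),
                        sdlog = 1, gc = 0.42, min_length = 500,
                        seed) {
  withSeed(subSeed(seed, "assembly"), {
    if (n_scaffolds == 0)
      return(list(sequences = Biostrings::DNAStringSet(),
                  truth = data.frame(scaffold_id = character(0),
                                     length = integer(0))))
    lens <- pmax(min_length,
                 as.integer(round(stats::rlnorm(n_scaffolds, meanlog,
                                                sdlog))))
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), "")
    ids <- sprintf("scaffold%03d", seq_len(n_scaffolds))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    list(sequences = out,
         truth = data.frame(scaffold_id = ids, length = lens,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate contamination read hits for an assembly
#'
#' Plants `n_contaminants` scaffolds with abundant reads from a
#' non-avian contaminant species: each planted scaffold receives at
#' least twice the scaffold read-count threshold in screen-eligible
#' reads (long alignments), and the species total comfortably exceeds
#' twice the per-species threshold. Clean scaffolds receive only noise:
#' short-alignment reads, avian-matching reads, and a few reads from a
#' rare species below the species threshold — all of which the cascade
#' must discard.
#'
#' @param assembly Output of [simAssembly()] (or a named
#'   `DNAStringSet` in `$sequences`).
#' @param n_contaminants Number of planted contaminated scaffolds.
#' @param reads_per_contaminant Screen-eligible reads per planted
#'   scaffold (default 60 = 3x the scaffold cutoff of 20; with two or
#'   more planted scaffolds the species total also clears 2x the
#'   species cutoff of 50).
#' @param noise_reads Number of noise reads spread over clean scaffolds.
#' @param seed Master seed.
#' @return `list(hits = best-hit data.frame (read_id, species,
#'   is_avian, alignment_length, evalue, scaffold_id),
#'   truth = character vector of planted scaffold ids)`.
#' @export
simContamination <- function(assembly, n_contaminants = 2,
                             reads_per_contaminant = 60,
                             noise_reads = 30, seed) {
  seqs <- assembly$sequences
  if (n_contaminants > length(seqs))
    stop("more contaminants than scaffolds", call. = FALSE)
  withSeed(subSeed(seed, "contamination"), {
    ids <- names(seqs)
    planted <- if (n_contaminants > 0) sample(ids, n_contaminants)
               else character(0)
    clean <- setdiff(ids, planted)
    rows <- list()
    rid <- 0L
    mk <- function(n, species, avian, aln, scaffolds) {
      if (n == 0) return(NULL)
      rid <<- rid + n
      data.frame(read_id = sprintf("read%06d", (rid - n + 1L):rid),
                 species = species, is_avian = avian,
                 alignment_length = aln,
                 evalue = 10^-stats::runif(n, 20, 60),
                 scaffold_id = scaffolds, stringsAsFactors = FALSE)
    }
    # planted signal: long-alignment reads from one abundant contaminant
    for (sid in planted)
      rows[[length(rows) + 1L]] <-
        mk(reads_per_contaminant, "Escherichia coli", FALSE,
           sample(100:151, reads_per_contaminant, replace = TRUE), sid)
    if (length(clean) && noise_reads > 0) {
      third <- function(k) sample(clean, k, replace = TRUE)
      n1 <- ceiling(noise_reads / 3)
      n2 <- ceiling(noise_reads / 3)
      n3 <- noise_reads - n1 - n2
      # short alignments (fail stage 1)
      rows[[length(rows) + 1L]] <-
        mk(n1, "Escherichia coli", FALSE,
           sample(30:99, n1, replace = TRUE), third(n1))
      # avian self-hits (fail stage 2)
      rows[[length(rows) + 1L]] <-
        mk(n2, "Gallus gallus", TRUE,
           sample(100:151, n2, replace = TRUE), third(n2))
      # rare species below the per-species cutoff (fail stage 3)
      if (n3 > 0)
        rows[[length(rows) + 1L]] <-
          mk(n3, "Bacillus subtilis", FALSE,
             sample(100:151, n3, replace = TRUE), third(n3))
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- data.frame(read_id = character(0), species = character(0),
                         is_avian = logical(0),
                         alignment_length = integer(0),
                         evalue = numeric(0), scaffold_id = character(0))
    rownames(hits) <- NULL
    list(hits = hits, truth = planted)
  })
}

# codon neighbours and NG86-consistent rates, precomputed once per call
.codonNeighbours <- function(omega, kappa) {
  codons <- names(.GC)[.GC != "*"]
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  lapply(stats::setNames(codons, codons), function(cod) {
    pos <- strsplit(cod, "")[[1L]]
    to <- character(0); rate <- numeric(0)
    for (i in 1:3) for (b in setdiff(.BASES, pos[i])) {
      mut <- pos; mut[i] <- b
      mcod <- paste(mut, collapse = "")
      if (.GC[[mcod]] == "*") next
      r <- 1 / 3
      if (transitions[[pos[i]]] == b) r <- r * kappa
      if (.GC[[mcod]] != .GC[[cod]]) r <- r * omega
      to <- c(to, mcod); rate <- c(rate, r)
    }
    list(to = to, rate = rate, total = sum(rate))
  })
}

# evolve one codon along time t by Gillespie event sampling
.evolveCodon <- function(cod, t, nb) {
  repeat {
    entry <- nb[[cod]]
    if (entry$total <= 0) return(cod)
    wait <- stats::rexp(1, entry$total)
    if (wait > t) return(cod)
    t <- t - wait
    cod <- sample(entry$to, 1L, prob = entry$rate)
  }
}

#' Simulate an aligned codon sequence pair at known omega
#'
#' An ancestor is drawn uniformly over sense codons and each lineage
#' evolves independently for time `t` under a continuous-time codon
#' process: each position mutates to each alternative base at rate 1/3,
#' multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes; mutations to stop codons are rejected. Under
#' this scaling the per-synonymous-site rate is 1 and the
#' per-nonsynonymous-site rate is `omega`, so the NG86 estimator
#' recovers `omega` directly (with `kappa = 1`, the NG86 assumption).
#'
#' @param n_codons Number of codons.
#' @param t Branch length per lineage (expected substitutions per
#'   synonymous site).
#' @param omega True dN/dS of the generating process.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Master seed.
#' @return `list(seq_a, seq_b = codon sequence strings, omega = true
#'   value)`.
#' @export
simCodonPair <- function(n_codons = 2000, t = 0.2, omega = 1,
                         kappa = 1, seed) {
  if (n_codons < 1) stop("'n_codons' must be >= 1", call. = FALSE)
  if (t < 0) stop("'t' must be >= 0", call. = FALSE)
  nb <- .codonNeighbours(omega, kappa)
  sense <- names(nb)
  withSeed(subSeed(seed, "codons"), {
    anc <- sample(sense, n_codons, replace = TRUE)
    a <- vapply(anc, .evolveCodon, "", t = t, nb = nb)
    b <- vapply(anc, .evolveCodon, "", t = t, nb = nb)
    list(seq_a = paste(a, collapse = ""),
         seq_b = paste(b, collapse = ""), omega = omega)
  })
}

#' Simulate a gene universe with one planted enriched category
#'
#' Genes are annotated into categories of fixed size drawn uniformly
#' from the universe. The selected set is drawn without replacement with
#' sampling weight `odds` for members of the planted category and 1
#' otherwise; `odds = 1` yields a null dataset with no enrichment
#' anywhere.
#'
#' @param n_genes Universe size.
#' @param n_categories Number of categories.
#' @param category_size Genes per category (40 is a typical mid-size
#'   functional term).
#' @param n_selected Selected set size.
#' @param odds Inclusion odds multiplier for the planted category.
#' @param seed Master seed.
#' @return `list(universe, annotation = data.frame(gene_id,
#'   category_id), selected, truth = planted category id or NA for a
#'   null dataset)`.
#' @export
simEnrichment <- function(n_genes = 1000, n_categories = 40,
                          category_size = 40, n_selected = 100,
                          odds = 10, seed) {
  if (n_selected > n_genes)
    stop("selected set larger than universe", call. = FALSE)
  withSeed(subSeed(seed, "enrichment"), {
    universe <- sprintf("gene%05d", seq_len(n_genes))
    cats <- sprintf("CAT%03d", seq_len(n_categories))
    annotation <- do.call(rbind, lapply(cats, function(cc)
      data.frame(gene_id = sample(universe, category_size),
                 category_id = cc, stringsAsFactors = FALSE)))
    planted <- if (odds > 1) cats[1L] else NA_character_
    w <- rep(1, n_genes)
    if (!is.na(planted)) {
      members <- annotation$gene_id[annotation$category_id == planted]
      w[universe %in% members] <- odds
    }
    selected <- sample(universe, n_selected, prob = w)
    if (n_selected == 0) selected <- character(0)
    list(universe = universe, annotation = annotation,
         selected = selected, truth = planted)
  })
}

#' Simulate synteny blocks with planted inversions
#'
#' Collinear blocks are laid along a virtual chromosome with identities
#' drawn uniformly in `identity_range`; planted inversions have their
#' subject coordinates flipped (descending), i.e. reverse-complement
#' alignments.
#'
#' @param n_blocks Number of blocks.
#' @param n_inversions Number of planted inverted blocks.
#' @param block_length Mean block length in bp.
#' @param gap Gap between consecutive blocks in bp.
#' @param identity_range Uniform range of block identities (percent).
#' @param seed Master seed.
#' @return `list(blocks = data.frame(block_id, query_id, q_start,
#'   q_end, subject_id, s_start, s_end, identity, aligned_length),
#'   truth = inverted block ids, chrom_lengths = named vector)`.
#' @export
simSynteny <- function(n_blocks = 100, n_inversions = 3,
                       block_length = 20000, gap = 5000,
                       identity_range = c(86, 90), seed) {
  if (n_inversions > n_blocks)
    stop("more inversions than blocks", call. = FALSE)
  withSeed(subSeed(seed, "synteny"), {
    lens <- pmax(1000L, as.integer(round(stats::rlnorm(
      n_blocks, log(block_length), 0.4))))
    s_start <- cumsum(c(1L, (lens + gap)[-n_blocks]))
    s_end <- s_start + lens - 1L
    inverted <- if (n_inversions > 0)
      sort(sample(seq_len(n_blocks), n_inversions)) else integer(0)
    blocks <- data.frame(
      block_id = sprintf("block%03d", seq_len(n_blocks)),
      query_id = sprintf("scaffold%03d", seq_len(n_blocks)),
      q_start = 1L, q_end = lens,
      subject_id = "chr1", s_start = s_start, s_end = s_end,
      identity = stats::runif(n_blocks, identity_range[1L],
                              identity_range[2L]),
      aligned_length = lens, stringsAsFactors = FALSE)
    flip <- seq_len(n_blocks) %in% inverted
    tmp <- blocks$s_start[flip]
    blocks$s_start[flip] <- blocks$s_end[flip]
    blocks$s_end[flip] <- tmp
    list(blocks = blocks, truth = blocks$block_id[inverted],
         chrom_lengths = c(chr1 = max(s_end) + gap))
  })
}
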