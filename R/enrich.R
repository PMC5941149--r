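# Hypergeometric category enrichment with a permutation empirical p,
# exact-enumeration oracle, Bonferroni variant, and slim rollup.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` category genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` belong to the
#' category. Delegates to [stats::phyper()], which works in log space.
#'
#' @param N Universe size.
#' @param K Category size within the universe.
#' @param n Number drawn (the selected set size).
#' @param k Observed overlap.
#' @return The tail probability; vectorized over `k`.
#' @examples
#' hypergeomTail(10, 4, 5, 3)  # 66/252
#' @export
hypergeomTail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N) || any(k < 0) || any(k > n))
    stop("impossible hypergeometric configuration", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Per-category overlap table for one selected set.
.categoryCounts <- function(annotation, selected, universe) {
  stopifnot(all(c("gene_id", "category_id") %in% names(annotation)))
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  cats <- sort(unique(annotation$category_id))
  K <- vapply(cats, function(cc)
    length(unique(annotation$gene_id[annotation$category_id == cc])), 0L)
  k <- vapply(cats, function(cc)
    length(intersect(selected,
                     annotation$gene_id[annotation$category_id == cc])), 0L)
  data.frame(category_id = cats, k = k, K = K,
             n = length(selected), N = length(universe),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric enrichment over all categories
#'
#' @param annotation `data.frame` with columns `gene_id`,
#'   `category_id` (one row per gene-category membership).
#' @param selected Character vector of selected genes (e.g. PSGs); must
#'   be a subset of `universe`.
#' @param universe Character vector of background genes.
#' @return `data.frame` with columns `category_id`, `k`, `K`, `n`, `N`,
#'   `p_hyper`.
#' @export
enrichmentTest <- function(annotation, selected, universe) {
  selected <- unique(selected); universe <- unique(universe)
  if (length(setdiff(selected, universe)))
    stop("'selected' must be a subset of 'universe'", call. = FALSE)
  out <- .categoryCounts(annotation, selected, universe)
  out$p_hyper <- hypergeomTail(out$N, out$K, out$n, out$k)
  out
}

#' Empirical permutation p-values for category enrichment
#'
#' The observed hypergeometric tail probability of each category is
#' ranked within a null distribution obtained by drawing `B` random gene
#' sets of the same size as the selected set, uniformly without
#' replacement from the universe. The empirical p uses the add-one
#' correction `p_emp = (1 + #{draws with p_hyper <= observed}) / (B + 1)`
#' so it is never exactly zero and has resolution `1/(B+1)`; ties count
#' against significance. The seed fully determines the output.
#'
#' @inheritParams enrichmentTest
#' @param B Number of null draws (the study-scale default is 100,000).
#' @param seed RNG seed (required; the draw stream is local and does not
#'   disturb the session RNG).
#' @param adjust Multiple-testing adjustment applied to `p_hyper` for
#'   the `p_adj` column: `"BH"` or `"bonferroni"`.
#' @return The [enrichmentTest()] table with added `p_emp` and `p_adj`.
#' @export
empiricalP <- function(annotation, selected, universe, B = 100000L,
                       seed, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  obs <- enrichmentTest(annotation, selected, universe)
  universe <- unique(universe)
  n <- length(unique(selected))
  if (n > length(universe))
    stop("selected set larger than universe", call. = FALSE)
  # gene x category membership over the universe
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  memb <- matrix(FALSE, nrow = length(universe), ncol = nrow(obs),
                 dimnames = list(universe, obs$category_id))
  memb[cbind(match(ann$gene_id, universe),
             match(ann$category_id, obs$category_id))] <- TRUE
  exceed <- integer(nrow(obs))
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(length(universe), n)
      kb <- colSums(memb[idx, , drop = FALSE])
      pb <- hypergeomTail(obs$N[1L], obs$K, n, kb)
      exceed <- exceed + (pb <= obs$p_hyper)
    }
  })
  obs$p_emp <- (1 + exceed) / (B + 1)
  obs$p_adj <- if (adjust == "BH") bhFdr(obs$p_hyper) else
    bonferroniAdjust(obs$p_hyper)
  obs
}

#' Exact permutation p-values by full subset enumeration
#'
#' Enumerates every subset of the universe with the selected set's size
#' and reports, per category, the exact fraction of subsets whose
#' hypergeometric tail probability is at most the observed one. Feasible
#' only for small problems; the Monte-Carlo [empiricalP()] converges to
#' this quantity.
#'
#' @inheritParams enrichmentTest
#' @param max_space Refuse enumeration beyond this many subsets.
#' @return `data.frame` with `category_id`, `p_hyper`, `p_exact`.
#' @export
exactPermutationP <- function(annotation, selected, universe,
                              max_space = 1e6) {
  obs <- enrichmentTest(annotation, selected, universe)
  universe <- unique(universe)
  n <- length(unique(selected))
  if (choose(length(universe), n) > max_space)
    stop("subset space too large to enumerate; use empiricalP()",
         call. = FALSE)
  subsets <- utils::combn(universe, n, simplify = FALSE)
  cat_genes <- lapply(obs$category_id, function(cc)
    unique(annotation$gene_id[annotation$category_id == cc &
                                annotation$gene_id %in% universe]))
  p_exact <- vapply(seq_len(nrow(obs)), function(i) {
    ks <- vapply(subsets, function(s)
      length(intersect(s, cat_genes[[i]])), 0L)
    ps <- hypergeomTail(obs$N[1L], obs$K[i], n, ks)
    mean(ps <= obs$p_hyper[i])
  }, 0)
  data.frame(category_id = obs$category_id, p_hyper = obs$p_hyper,
             p_exact = p_exact, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; the convention used for KEGG pathway
#' enrichment.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param m Number of tests (defaults to `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, pvalues * m)
}

#' Roll enriched categories up into slim categories
#'
#' Annotates each result row with its slim category (categories missing
#' from the map fall into `"unclassified"`) and tabulates, per slim, the
#' number of categories significant at `alpha` on the chosen column.
#'
#' @param results An enrichment table (from [empiricalP()] or
#'   [enrichmentTest()]).
#' @param slim_map Named character vector or two-column `data.frame`
#'   mapping category_id -> slim_id.
#' @param alpha Significance threshold.
#' @param p_column Which p-value column to threshold.
#' @return `list(results = annotated table, slim_summary = data.frame
#'   with slim_id, n_categories, n_significant)`.
#' @export
slimRollup <- function(results, slim_map, alpha = 0.05,
                       p_column = "p_hyper") {
  if (is.data.frame(slim_map))
    slim_map <- stats::setNames(as.character(slim_map[[2L]]),
                                as.character(slim_map[[1L]]))
  slim <- slim_map[results$category_id]
  slim[is.na(slim)] <- "unclassified"
  results$slim_id <- unname(slim)
  sig <- results[[p_column]] <= alpha
  agg <- lapply(split(seq_len(nrow(results)), results$slim_id),
                function(i) c(n_categories = length(i),
                              n_significant = sum(sig[i])))
  slim_summary <- data.frame(slim_id = names(agg),
                             do.call(rbind, agg),
                             stringsAsFactors = FALSE, row.names = NULL)
  list(results = results, slim_summary = slim_summary)
}
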