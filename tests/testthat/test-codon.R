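sense_codons <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"]

test_that("NG86 site counts: worked codons and syn+nonsyn = 3 on all 61", {
  expect_equal(ng86Sites("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_equal(ng86Sites("GGG"), c(syn = 1, nonsyn = 2))
  expect_equal(ng86Sites("ATG"), c(syn = 0, nonsyn = 3))
  for (cod in sense_codons) {
    got <- ng86Sites(cod)
    expect_equal(sum(got), 3)
    expect_equal(unname(got), oracle_sites(cod))
  }
  expect_error(ng86Sites("TAA"), "stop")
  expect_error(ng86Sites("AXG"), "A, C, G, T")
})

test_that("pairwise identity statistics count aligned columns only", {
  same <- pairwiseIdentityStats("ACGT", "ACGT")
  expect_equal(same$nt_identity, 100)
  one_off <- pairwiseIdentityStats("ACGT", "ACGA")
  expect_equal(one_off$aligned_bases, 4)
  expect_equal(one_off$nt_identity, 75)
  gapped <- pairwiseIdentityStats("AC-T", "ACGT")
  expect_equal(gapped$aligned_bases, 3)
  expect_equal(gapped$nt_identity, 100)
  # amino-acid layer: 2 codons, one silent difference, one replacement
  aa <- pairwiseIdentityStats("TTTGGG", "TTCAGG")
  expect_equal(aa$aligned_aa, 2)
  expect_equal(aa$aa_identity, 50)
  expect_equal(aa$aa_substitutions, 1)
  expect_error(pairwiseIdentityStats("ACG", "AC"), "equal length")
})

test_that("NG86 dN/dS reproduces the hand-computed single-difference pair", {
  s <- ng86Dnds(paste0(strrep("TTT", 9), "GGG"),
                paste0(strrep("TTT", 9), "GGA"))
  expect_equal(s@Sd, 1)
  expect_equal(s@Nd, 0)
  expect_equal(s@S, 4)
  expect_equal(s@pS, 0.25)
  expect_equal(s@dS, -0.75 * log(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(round(s@dS, 4), 0.3041)
  expect_equal(s@dN, 0)
  expect_true(s@omega_defined)
  expect_equal(s@omega, 0)
})

test_that("identical sequences give zero distances and undefined omega", {
  s <- ng86Dnds("TTTGGGAAA", "TTTGGGAAA")
  expect_equal(s@Nd + s@Sd, 0)
  expect_equal(s@dN, 0)
  expect_equal(s@dS, 0)
  expect_false(s@omega_defined)
  expect_true(is.na(s@omega))
})

test_that("NG86 counting matches the pathway-enumeration oracle", {
  set.seed(71)
  for (i in 1:150) {
    n_cod <- sample(1:3, 1)
    a <- sample(sense_codons, n_cod, replace = TRUE)
    # mutate up to 2 positions per codon, rejecting stops
    b <- vapply(a, function(cod) {
      repeat {
        v <- strsplit(cod, "")[[1]]
        for (p in sample(1:3, sample(0:2, 1)))
          v[p] <- sample(c("A", "C", "G", "T"), 1)
        out <- paste(v, collapse = "")
        if (Biostrings::GENETIC_CODE[[out]] != "*") return(out)
      }
    }, "")
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    got <- ng86Dnds(sa, sb)
    exp <- oracle_ng86(sa, sb)
    expect_equal(got@S, exp$S)
    expect_equal(got@N, exp$N)
    expect_equal(got@Sd, exp$Sd)
    expect_equal(got@Nd, exp$Nd)
    expect_equal(got@Nd + got@Sd,
                 sum(mapply(function(x, y)
                   sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
                   a, b)))  # pathway averaging conserves total differences
    if (!is.na(exp$dS)) expect_equal(got@dS, exp$dS)
    if (!is.na(exp$dN)) expect_equal(got@dN, exp$dN)
  }
})

test_that("gap codons are removed pairwise; ambiguity is skipped with warning", {
  s <- ng86Dnds("TTT---GGG", "TTTAAAGGA")
  expect_equal(s@n_codons, 2L)
  expect_warning(ng86Dnds("TTTNNN", "TTTAAA"), "skipped")
  expect_error(ng86Dnds("---", "AAA"), "no comparable codons")
  expect_error(ng86Dnds("ACGT", "ACGT"), "divisible by 3")
})

test_that("simulated pairs recover omega within 15% (median of replicates)", {
  for (true_omega in c(0.2, 1, 2)) {
    est <- vapply(1:10, function(r) {
      p <- simCodonPair(n_codons = 1200, t = 0.05, omega = true_omega,
                        kappa = 1, seed = 1000 * true_omega + r)
      omegaRatio(ng86Dnds(p$seq_a, p$seq_b))
    }, 0)
    expect_lt(abs(stats::median(est) - true_omega) / true_omega, 0.15)
  }
})

test_that("branch-site LRT clamps at zero and matches the chi-square tail", {
  flat <- branchSiteLRT(-100, -100)
  expect_equal(flat$lrt_stat, 0)
  expect_equal(flat$p, 1)
  crit <- branchSiteLRT(-100, -100 + 1.92073)
  expect_equal(crit$lrt_stat, 3.84146, tolerance = 1e-5)
  expect_equal(crit$p, 0.05, tolerance = 1e-3)
  expect_warning(neg <- branchSiteLRT(-100, -100.3), "clamped")
  expect_equal(neg$lrt_stat, 0)
  # p monotone decreasing in the statistic
  stats_in <- seq(0, 20, by = 0.5)
  p <- branchSiteLRT(rep(0, length(stats_in)), stats_in / 2)$p
  expect_true(all(diff(p) < 0))
  # mixture null halves positive-stat p-values
  mix <- branchSiteLRT(-100, -98, mixture = TRUE)
  expect_equal(mix$p, 0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_error(branchSiteLRT(NaN, 0), "finite")
})

test_that("BH adjustment equals the exhaustive step-up closed form", {
  expect_equal(bhFdr(c(0.005, 0.02, 0.03, 0.05)),
               c(0.02, 0.04, 0.04, 0.05))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  set.seed(5)
  for (i in 1:300) {
    p <- runif(sample(1:25, 1))
    q <- bhFdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
  }
  expect_error(bhFdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("selectionTests flags genes below the FDR cutoff", {
  lnl <- data.frame(gene_id = c("psg", "null1", "null2", "null3"),
                    lnl_null = rep(-500, 4),
                    lnl_alt = c(-488, -499.9, -499.8, -500))
  res <- suppressWarnings(selectionTests(lnl))
  expect_true(res$selected[res$gene_id == "psg"])
  expect_false(any(res$selected[res$gene_id != "psg"]))
  expect_true(all(res$q >= res$p))
})

test_that("consensus substitution scan reports ungapped focal positions", {
  msa <- c(f = "MKT-AW", s1 = "MKAQAW", s2 = "MKAQAW", s3 = "MKAQAW",
           s4 = "MKAQAW", s5 = "MKAQAW")
  out <- consensusSubstitutions(msa, "f")
  expect_identical(nrow(out), 1L)
  expect_identical(out$position, 3L)   # gap column does not advance focal
  expect_identical(out$consensus_residue, "A")
  expect_identical(out$focal_residue, "T")
  expect_equal(out$support, 1)

  # focal equals consensus everywhere: empty result
  expect_identical(nrow(consensusSubstitutions(
    c(f = "MKA", s1 = "MKA", s2 = "MKA"), "f")), 0L)

  # focal gap column yields no record even when others agree
  gap <- c(f = "M-A", s1 = "MTA", s2 = "MTA")
  expect_identical(nrow(consensusSubstitutions(gap, "f")), 0L)

  # support below threshold suppresses the call; lowering it recovers
  split_col <- c(f = "T", s1 = "A", s2 = "A", s3 = "A", s4 = "G")
  expect_identical(nrow(consensusSubstitutions(split_col, "f")), 0L)
  relaxed <- consensusSubstitutions(split_col, "f", min_support = 0.75)
  expect_identical(relaxed$consensus_residue, "A")
  expect_equal(relaxed$support, 0.75)

  expect_error(consensusSubstitutions(msa, "absent"), "absent")
})

test_that("an alanine-for-threonine change at a known site is recovered", {
  # six aligned globin-like fragments; the focal bird alone carries T at
  # the column that is position 78 of its ungapped sequence
  set.seed(78)
  len <- 120
  base <- paste(sample(c("A", "V", "L", "G", "S", "K", "H", "E"),
                       len, replace = TRUE), collapse = "")
  focal <- base
  substr(focal, 78, 78) <- "T"
  substr(base, 78, 78) <- "A"
  msa <- c(mikado = focal, sp1 = base, sp2 = base, sp3 = base,
           sp4 = base, sp5 = base)
  out <- consensusSubstitutions(msa, "mikado")
  expect_identical(out$position, 78L)
  expect_identical(out$consensus_residue, "A")
  expect_identical(out$focal_residue, "T")
})
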