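mk_hits <- function(n, species, avian = FALSE, aln = 120,
                    scaffold = "s1", prefix = species) {
  if (n == 0) return(NULL)
  data.frame(read_id = paste0(gsub("\\s", "", prefix), seq_len(n)),
             species = species, is_avian = avian,
             alignment_length = aln, scaffold_id = scaffold,
             stringsAsFactors = FALSE)
}

test_that("cascade applies length, avian, and species-count rules in order", {
  hits <- rbind(mk_hits(60, "Escherichia coli", scaffold = "s1"),
                mk_hits(10, "Bacillus subtilis", scaffold = "s2"),
                mk_hits(15, "Gallus gallus", avian = TRUE, scaffold = "s3"),
                mk_hits(5, "Escherichia coli", aln = 99, scaffold = "s1",
                        prefix = "short"))
  surv <- cascadeFilter(hits)
  expect_identical(sort(unique(surv$species)), "Escherichia coli")
  expect_identical(nrow(surv), 60L)
  sc <- attr(surv, "stage_counts")
  expect_identical(unname(sc), c(90L, 85L, 70L, 60L))
  expect_false(is.unsorted(rev(sc)))
})

test_that("cascade boundaries: >=100 bp kept, species at exactly 50 kept", {
  at_boundary <- rbind(mk_hits(50, "Escherichia coli", aln = 100),
                       mk_hits(49, "Bacillus subtilis", aln = 100))
  surv <- cascadeFilter(at_boundary)
  expect_identical(unique(surv$species), "Escherichia coli")
  expect_identical(nrow(surv), 50L)
  # 99 bp fails stage 1 even for an abundant species
  surv2 <- cascadeFilter(mk_hits(60, "Escherichia coli", aln = 99))
  expect_identical(nrow(surv2), 0L)
})

test_that("scaffold calls use a strict > threshold", {
  hits <- rbind(mk_hits(25, "Escherichia coli", scaffold = "sA"),
                mk_hits(20, "Escherichia coli", scaffold = "sB",
                        prefix = "ecB"),
                mk_hits(21, "Escherichia coli", scaffold = "sC",
                        prefix = "ecC"))
  calls <- callScaffolds(hits, scaffold_ids = c("sA", "sB", "sC", "sD"))
  removed <- calls$scaffold_id[calls$removed]
  expect_identical(sort(removed), c("sA", "sC"))
  expect_identical(calls$supporting_reads[calls$scaffold_id == "sD"], 0L)
  expect_false(calls$removed[calls$scaffold_id == "sD"])
  bd <- calls$species_breakdown[[which(calls$scaffold_id == "sA")]]
  expect_identical(unname(bd), 25L)
})

test_that("applyRemoval drops called scaffolds and accounts bases", {
  asm <- Biostrings::DNAStringSet(c(s1 = "ACGT", s2 = strrep("A", 200),
                                    s3 = "GGG"))
  calls <- data.frame(scaffold_id = c("s1", "s2", "s3"),
                      supporting_reads = c(0L, 25L, 0L),
                      removed = c(FALSE, TRUE, FALSE))
  res <- applyRemoval(asm, calls)
  expect_identical(names(res$assembly), c("s1", "s3"))
  expect_identical(res$report@n_scaffolds_removed, 1L)
  expect_equal(res$report@bp_removed, 200)
  # no calls: identity
  none <- applyRemoval(asm, calls[calls$removed == FALSE, ])
  expect_identical(names(none$assembly), names(asm))
  expect_equal(none$report@bp_removed, 0)
  calls$scaffold_id[2] <- "nope"
  expect_error(applyRemoval(asm, calls), "unknown scaffold")
})

test_that("planted contaminants are recovered with no false positives", {
  for (seed in c(1, 7, 23)) {
    asm <- simAssembly(n_scaffolds = 50, seed = seed)
    ct <- simContamination(asm, n_contaminants = 2, seed = seed)
    res <- screenContamination(asm$sequences, ct$hits)
    removed <- res$calls$scaffold_id[res$calls$removed]
    expect_setequal(removed, ct$truth)            # recall 1, FPR 0
    expect_equal(res$report@bp_removed,
                 sum(asm$truth$length[asm$truth$scaffold_id %in% ct$truth]))
  }
})

test_that("screen is idempotent on its own cleaned output", {
  asm <- simAssembly(n_scaffolds = 40, seed = 9)
  ct <- simContamination(asm, n_contaminants = 3, seed = 9)
  first <- screenContamination(asm$sequences, ct$hits)
  kept_hits <- ct$hits[ct$hits$scaffold_id %in% names(first$assembly), ]
  second <- screenContamination(first$assembly, kept_hits)
  expect_identical(second$report@n_scaffolds_removed, 0L)
  expect_identical(names(second$assembly), names(first$assembly))
})

test_that("raising any threshold never enlarges the removed set", {
  asm <- simAssembly(n_scaffolds = 50, seed = 31)
  ct <- simContamination(asm, n_contaminants = 3, seed = 31)
  base <- screenContamination(asm$sequences, ct$hits)
  base_removed <- base$calls$scaffold_id[base$calls$removed]
  grid <- expand.grid(min_aln = c(100, 120, 140),
                      min_species = c(50, 80, 130),
                      min_reads = c(20, 40, 70))
  for (i in seq_len(nrow(grid))) {
    res <- screenContamination(asm$sequences, ct$hits,
                               min_aln = grid$min_aln[i],
                               min_species_count = grid$min_species[i],
                               min_reads = grid$min_reads[i])
    removed <- res$calls$scaffold_id[res$calls$removed]
    expect_true(all(removed %in% base_removed))
  }
})

test_that("calls are invariant under permutation of input hit rows", {
  asm <- simAssembly(n_scaffolds = 30, seed = 13)
  ct <- simContamination(asm, n_contaminants = 2, seed = 13)
  a <- screenContamination(asm$sequences, ct$hits)
  perm <- ct$hits[sample(nrow(ct$hits)), ]
  b <- screenContamination(asm$sequences, perm)
  ord <- function(calls) calls[order(calls$scaffold_id),
                               c("scaffold_id", "supporting_reads", "removed")]
  expect_equal(ord(a$calls), ord(b$calls), ignore_attr = TRUE)
})

test_that("duplicate read ids are rejected (input must be best-hit)", {
  dup <- rbind(mk_hits(2, "Escherichia coli"), mk_hits(2, "Escherichia coli"))
  expect_error(cascadeFilter(dup), "best hit")
})
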