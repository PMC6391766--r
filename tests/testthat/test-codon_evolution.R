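# Nei-Gojobori site counting, pathway averaging and Ks/Ka estimation.

test_that("syn_nonsyn_sites matches enumeration on worked examples", {
  expect_equal(syn_nonsyn_sites("ATG")$s, 0)
  expect_equal(syn_nonsyn_sites("ATG")$n, 3)
  expect_equal(syn_nonsyn_sites("TTT")$s, 1 / 3)
  expect_equal(syn_nonsyn_sites("TTT")$n, 8 / 3)
  expect_equal(syn_nonsyn_sites("GGG")$s, 1)
  expect_equal(syn_nonsyn_sites("GGG")$n, 2)
})

test_that("syn_nonsyn_sites rejects stops and ambiguity", {
  expect_error(syn_nonsyn_sites("TAA"), "stop")
  expect_error(syn_nonsyn_sites("TGA"), "stop")
  expect_error(syn_nonsyn_sites("ANG"), "non-ACGT")
  expect_error(syn_nonsyn_sites("AT-"), "non-ACGT")
})

test_that("kappa weighting: s non-decreasing in kappa for transition-only syn codons", {
  # two-fold degenerate third positions have their synonymous change as a
  # transition (e.g. TTT<->TTC, GAT<->GAC)
  for (codon in c("TTT", "GAT", "AAA", "TGT")) {
    s_vals <- vapply(c(0.5, 1, 2, 4, 8),
                     function(k) syn_nonsyn_sites(codon, kappa = k)$s,
                     numeric(1))
    expect_true(all(diff(s_vals) >= -1e-12), info = codon)
  }
  # kappa = 1 reduces to the unweighted count
  expect_equal(syn_nonsyn_sites("CTT", kappa = 1)$s,
               unname(oracle_site_counts("CTT")["s"]))
})

test_that("pathway_differences matches enumeration on worked examples", {
  expect_equal(pathway_differences("GTT", "GTT")[c("sd", "nd")],
               list(sd = 0, nd = 0))
  expect_equal(pathway_differences("GTT", "GTA")[c("sd", "nd")],
               list(sd = 1, nd = 0))
  expect_equal(pathway_differences("TTT", "GTA")[c("sd", "nd")],
               list(sd = 0.5, nd = 1.5))
  expect_error(pathway_differences("TAA", "TTT"), "stop")
})

test_that("pathway_differences equals brute-force enumeration on random pairs", {
  withr::with_seed(11, {
    pairs <- cbind(sample(SENSE, 150, replace = TRUE),
                   sample(SENSE, 150, replace = TRUE))
  })
  for (r in seq_len(nrow(pairs))) {
    got <- pathway_differences(pairs[r, 1], pairs[r, 2])
    want <- oracle_pathway(pairs[r, 1], pairs[r, 2])
    expect_equal(got$sd, unname(want["sd"]), info = paste(pairs[r, ], collapse = "/"))
    expect_equal(got$nd, unname(want["nd"]), info = paste(pairs[r, ], collapse = "/"))
    if (!got$all_paths_blocked)
      expect_equal(got$sd + got$nd, got$n_diff)
  }
})

test_that("jukes_cantor_correct behaves over its domain", {
  expect_equal(jukes_cantor_correct(0), 0)
  expect_equal(jukes_cantor_correct(0.06), 0.06254, tolerance = 1e-5 / 0.06254)
  expect_error(jukes_cantor_correct(0.75), class = "mybevol_saturation_error")
  expect_error(jukes_cantor_correct(0.9), class = "mybevol_saturation_error")
  # monotone and >= p
  p <- seq(0.01, 0.7, by = 0.01)
  d <- vapply(p, jukes_cantor_correct, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("codon_alignment validates its invariants", {
  expect_error(codon_alignment("ACGT", "ACG"), "equal length")
  expect_error(codon_alignment("ACGT", "ACGT"), "divisible by 3")
  expect_error(codon_alignment("ACGTAX", "ACGTAA"), "A/C/G/T/N")
  expect_error(codon_alignment("---", "AAA"), "no ungapped")
  expect_error(codon_alignment("TAA", "TAA"), "no ungapped")  # stop-only
  aln <- codon_alignment("ATGAAA", "ATGAAG", labels = c("x", "y"))
  expect_s3_class(aln, "codon_alignment")
})

test_that("estimate_ks_ka on identical sequences gives zero distances", {
  seq <- strrep("ATGAAACCCGGGTTTCTT", 17)  # 102 codons, >=100, no stops
  aln <- codon_alignment(substr(seq, 1, 300), substr(seq, 1, 300))
  r <- estimate_ks_ka(aln)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$codons_used, 100)
  expect_equal(r$S + r$N, 3 * r$codons_used)
})

test_that("two-codon worked example exercises the saturation path", {
  aln <- codon_alignment("TTTGTT", "TTCGTA")
  expect_warning(r <- estimate_ks_ka(aln), "saturated")
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 4 / 3)  # mean of per-sequence totals (both are 4/3)
  expect_equal(r$pS, 1.5)
  expect_true(is.na(r$Ks))
  expect_true("ks_saturated" %in% r$flags)
  expect_equal(r$Ka, 0)  # partial result available
})

test_that("gap/ambiguity/stop codon columns are dropped per column", {
  # 4 codons; column 2 gapped, column 3 has N, column 4 stop in seq_b
  aln <- codon_alignment("CCCAAAGGGTGT", "CCC---GGNTGA")
  r <- suppressWarnings(estimate_ks_ka(aln))
  expect_equal(r$codons_used, 1)
  expect_equal(r$dropped_columns, 3)
  expect_equal(r$Ks, 0)
  # a lone retained Met codon has no synonymous sites: Ks undefined, flagged
  aln2 <- codon_alignment("ATG", "ATG")
  r2 <- estimate_ks_ka(aln2)
  expect_true(is.na(r2$Ks))
  expect_true("no_synonymous_sites" %in% r2$flags)
})

test_that("simulated pairs: Sd recovered exactly, Ks matches planted bookkeeping", {
  for (seed in 1:5) {
    sim <- simulate_cds_pair(600, true_ks = 0.12, seed = seed)
    r <- estimate_ks_ka(sim$alignment)
    expect_identical(r$Sd, as.numeric(sim$truth$sd_planted))
    expect_identical(r$Nd, 0)
    # site-preserving planting keeps S at the ancestor's total
    expect_equal(r$S, sim$truth$s_ancestor)
    expect_equal(r$Ks, jukes_cantor_correct(sim$truth$sd_planted / r$S))
  }
})

test_that("estimator recovery: mean over replicates within 3 SE of truth", {
  # scaled-down version of the 100-replicate recovery property (runtime);
  # planting is exact so the only variation is integer rounding of counts
  for (true_ks in c(0.02, 0.15, 0.3)) {
    est <- vapply(1:40, function(s)
      estimate_ks_ka(simulate_cds_pair(1000, true_ks, seed = s)$alignment)$Ks,
      numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - true_ks), 3 * se + 1e-12)
  }
})

test_that("pairwise_ks_matrix is symmetric, zero-diagonal, NA for failed pairs", {
  seqs <- c(a = "ATGAAACCC", b = "ATGAAACCC", c = "ATGAAACCG")
  m <- pairwise_ks_matrix(seqs)
  expect_equal(m$ks["a", "b"], 0)
  expect_equal(diag(m$ks), c(a = 0, b = 0, c = 0))
  expect_equal(m$ks, t(m$ks))
  # saturated pair yields NA, not an error
  seqs2 <- c(x = "TTTGTTAAACCC", y = "TTCGTAAAGCCA", z = "TTTGTTAAACCC")
  m2 <- pairwise_ks_matrix(seqs2)
  expect_true(is.na(m2$ks["x", "y"]))
  expect_equal(m2$ks["x", "z"], 0)
})

test_that("family simulator Ks entries track 2kT within sampling error", {
  fam <- simulate_gene_family("((A:10,B:10):10,C:20);", n_codons = 2000,
                              rate = 3.2e-9, seed = 4)
  m <- pairwise_ks_matrix(fam$sequences)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expected <- fam$expected_ks[pair[1], pair[2]]
    got <- m$ks[pair[1], pair[2]]
    expect_lt(abs(got - expected) / expected, 0.25)
  }
})
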