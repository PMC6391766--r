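# 2^-ddCt relative expression, ANOVA letter groups, exact U tests.

make_ct <- function(df, n_tech = 3) {
  # expand per-bio-rep mean Cts into identical technical replicates
  out <- do.call(rbind, lapply(seq_len(n_tech), function(tr) {
    d <- df
    d$tech_rep <- tr
    d
  }))
  out
}

test_that("identical Ct everywhere gives fold 1 for every group", {
  grid <- expand.grid(genotype = c("BW", "PLP"), tissue = "lemma",
                      gene = c("ubiquitin", "myb"), bio_rep = 1:3,
                      stringsAsFactors = FALSE)
  grid$ct <- 20
  rec <- make_ct(grid)
  res <- relative_expression(rec, "ubiquitin", "BW")
  expect_true(all(abs(res$summary$fold_change - 1) < 1e-12))
  expect_true(all(abs(res$replicates$fold - 1) < 1e-12))
})

test_that("a 3-cycle dCt advantage gives fold 8", {
  grid <- expand.grid(genotype = c("cal", "high"), tissue = "t",
                      gene = c("ubiquitin", "g"), bio_rep = 1:3,
                      stringsAsFactors = FALSE)
  grid$ct <- ifelse(grid$gene == "ubiquitin", 18,
                    ifelse(grid$genotype == "cal", 25, 22))
  res <- relative_expression(make_ct(grid), "ubiquitin", "cal")
  s <- res$summary
  expect_equal(s$fold_change[s$genotype == "high"], 8)
  expect_equal(s$fold_change[s$genotype == "cal"], 1)
})

test_that("folds are invariant to adding a constant to all Ct values", {
  sim <- simulate_ct_table(
    data.frame(genotype = c("BW", "PLP"), tissue = "lemma",
               gene = "myb", fold = c(1, 5)), seed = 2)
  r1 <- relative_expression(sim$records, "ubiquitin", "BW")
  shifted <- sim$records
  shifted$ct <- shifted$ct + 3.7
  r2 <- relative_expression(shifted, "ubiquitin", "BW")
  expect_equal(r1$summary$fold_change, r2$summary$fold_change)
})

test_that("calibrator normalisation: calibrator mean fold is exactly 1", {
  sim <- simulate_ct_table(
    data.frame(genotype = c("BW", "BA"), tissue = "aleurone",
               gene = "myb", fold = c(1, 8)), sd_ct = 0.3, seed = 6)
  res <- relative_expression(sim$records, "ubiquitin", "BW")
  cal <- res$summary[res$summary$genotype == "BW", ]
  expect_equal(cal$fold_change, 1, tolerance = 1e-9)
})

test_that("missing reference and absent calibrator are handled", {
  grid <- expand.grid(genotype = c("a", "b"), tissue = "t",
                      gene = c("ubiquitin", "g"), bio_rep = 1:2,
                      stringsAsFactors = FALSE)
  grid$ct <- 20
  rec <- make_ct(grid)
  expect_error(relative_expression(rec, "ubiquitin", "zz"), "calibrator")
  expect_error(relative_expression(rec, "nope", "a"), "reference gene")
  # drop a sample's reference measurements -> warning, sample dropped
  rec2 <- rec[!(rec$genotype == "b" & rec$gene == "ubiquitin" &
                  rec$bio_rep == 2), ]
  expect_warning(res <- relative_expression(rec2, "ubiquitin", "a"),
                 "dropped")
  expect_equal(sum(res$replicates$genotype == "b"), 1L)
})

test_that("anova_letter_groups separates clear groups and not identical ones", {
  withr::with_seed(14, {
    same <- lapply(1:3, function(i) rnorm(5, 10, 1))
    names(same) <- c("g1", "g2", "g3")
  })
  expect_equal(unname(anova_letter_groups(same)), rep("a", 3))
  far <- list(lo = c(1, 1.01, 0.99), mid = c(100, 100.5, 99.5),
              hi = c(10000, 10010, 9990))
  expect_equal(sort(unname(anova_letter_groups(far))), c("a", "b", "c"))
  two <- list(a = c(1, 1.001, 0.999), b = c(5, 5.001, 4.999))
  expect_equal(sort(unname(anova_letter_groups(two))), c("a", "b"))
})

test_that("anova_letter_groups degenerate inputs", {
  expect_equal(unname(anova_letter_groups(list(a = c(2, 2), b = c(2, 2)))),
               c("a", "a"))
  # zero variance but different means: groups must not share a letter
  lets <- anova_letter_groups(list(a = c(1, 1), b = c(2, 2)))
  expect_false(lets[["a"]] == lets[["b"]])
  expect_error(anova_letter_groups(list(a = 1:3)), "two groups")
  expect_error(anova_letter_groups(list(a = 1, b = 1:2)), "at least two values")
})

test_that("letters share only between non-separated neighbours", {
  withr::with_seed(123, {
    groups <- list(lo = rnorm(4, 0, 0.2), mid = rnorm(4, 1.2, 0.2),
                   hi = rnorm(4, 15, 0.2))
  })
  lets <- anova_letter_groups(groups)
  shared <- intersect(strsplit(lets[["lo"]], "")[[1]],
                      strsplit(lets[["hi"]], "")[[1]])
  expect_length(shared, 0)
})

test_that("utest_compare: identical samples and full separation", {
  r <- suppressWarnings(utest_compare(c(3, 3, 3, 3), c(3, 3, 3, 3)))
  expect_equal(r$p, 1)
  expect_equal(r$tier, "")
  r2 <- suppressWarnings(utest_compare(1:4, 5:8))
  expect_equal(r2$p, 2 / 70)
  expect_equal(r2$tier, "**")
  expect_equal(r2$method, "exact")
  r3 <- utest_compare(1:9, 11:19)
  expect_equal(r3$p, 2 / 48620)
  expect_equal(r3$tier, "*")
})

test_that("utest warns when the strict tier is unreachable, or on tiny n", {
  expect_warning(utest_compare(1:4, 5:8), "unattainable")
  expect_warning(r <- utest_compare(1, c(2, 3)), "fewer than 2")
  expect_true(is.na(r$p))
})

test_that("exact U p-values match full enumeration for n <= 6 per side", {
  withr::with_seed(99, {
    for (i in 1:20) {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      a <- sample(1:8, n1, replace = TRUE)  # ties included
      b <- sample(1:8, n2, replace = TRUE)
      got <- suppressWarnings(utest_compare(a, b))
      expect_equal(got$p, oracle_u_p(a, b),
                   info = paste(c(a, "|", b), collapse = " "))
      # no-ties case agrees with wilcox.test's exact two-sided p
      a2 <- sample(seq(1, 400, by = 2), n1)
      b2 <- sample(seq(2, 400, by = 2), n2)
      got2 <- suppressWarnings(utest_compare(a2, b2))
      ref <- stats::wilcox.test(a2, b2, exact = TRUE)$p.value
      expect_equal(got2$p, ref, tolerance = 1e-12)
    }
  })
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  withr::with_seed(7, {
    a <- rnorm(30)
    b <- rnorm(30, 1)
  })
  r <- utest_compare(a, b)
  expect_equal(r$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(r$p, ref, tolerance = 1e-6)
})

test_that("planted fold changes are recovered within 10% (expectation)", {
  folds <- data.frame(
    genotype = c("BW", "PLP", "BW", "BA", "BW", "PLP2"),
    tissue = c("lemma", "lemma", "aleurone", "aleurone", "lemma2", "lemma2"),
    gene = c("mybA", "mybA", "mybB", "mybB", "mybC", "mybC"),
    fold = c(1, 7, 1, 8, 1, 1.5))
  est <- sapply(1:5, function(s) {
    sim <- simulate_ct_table(folds, sd_ct = 0.15, seed = 100 + s)
    res <- relative_expression(sim$records, "ubiquitin", "BW")
    s <- res$summary
    c(s$fold_change[s$genotype == "PLP"], s$fold_change[s$genotype == "BA"],
      s$fold_change[s$genotype == "PLP2"])
  })
  recovered <- rowMeans(est)
  expect_equal(recovered[1], 7, tolerance = 0.1)
  expect_equal(recovered[2], 8, tolerance = 0.1)
  expect_equal(recovered[3], 1.5, tolerance = 0.1)
})
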