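# Global alignment, indel/SNP calling and IUPAC motif scanning.

test_that("global_align handles identity and simple gaps", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$aligned_a, "ACGT")
  expect_equal(al$aligned_b, "ACGT")
  expect_equal(al$score, 8)
  al2 <- global_align("ACGT", "AGT")
  expect_equal(al2$aligned_a, "ACGT")
  expect_equal(al2$aligned_b, "A-GT")
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment score equals exhaustive search on short pairs", {
  withr::with_seed(8, {
    for (i in 1:40) {
      a <- random_seq(sample(1:6, 1))
      b <- random_seq(sample(1:6, 1))
      got <- global_align(a, b)$score
      expect_equal(got, oracle_align_score(a, b), info = paste(a, b))
    }
  })
})

test_that("call_indels recovers a planted 17-bp insertion as one event", {
  pr <- simulate_promoters(seed = 7)
  al <- global_align(pr$reference, pr$variant)
  calls <- call_indels(al$aligned_a, al$aligned_b, reference = "a")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "insertion")
  expect_equal(calls$length, 17L)
  expect_equal(calls$sequence, "CAGCAGAGCACTAGCTC")
  expect_equal(calls$position, pr$truth$indel$position)
})

test_that("call_indels base cases and planted deletion", {
  expect_equal(nrow(call_indels("ACGT", "ACGT")), 0L)
  withr::with_seed(12, ref <- random_seq(80))
  qry <- paste0(substr(ref, 1, 40), substr(ref, 44, 80))  # 3-bp deletion
  al <- global_align(ref, qry)
  calls <- call_indels(al$aligned_a, al$aligned_b, reference = "a")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "deletion")
  expect_equal(calls$length, 3L)
  # left-normalised position: applying the call reconstructs the query
  rebuilt <- paste0(substr(ref, 1, calls$position),
                    substr(ref, calls$position + calls$length + 1, nchar(ref)))
  expect_equal(rebuilt, qry)
})

test_that("indel conservation: applying calls to reference rebuilds query", {
  apply_calls <- function(ref, calls) {
    # apply right-to-left so positions stay valid
    calls <- calls[order(-calls$position), , drop = FALSE]
    out <- ref
    for (r in seq_len(nrow(calls))) {
      p <- calls$position[r]
      if (calls$kind[r] == "insertion") {
        out <- paste0(substr(out, 1, p), calls$sequence[r],
                      substr(out, p + 1, nchar(out)))
      } else {
        out <- paste0(substr(out, 1, p),
                      substr(out, p + calls$length[r] + 1, nchar(out)))
      }
    }
    out
  }
  withr::with_seed(19, {
    for (i in 1:10) {
      ref <- random_seq(150)
      # one insertion and one deletion at well-separated sites
      qry <- paste0(substr(ref, 1, 30), "TTAACCGG", substr(ref, 31, 100),
                    substr(ref, 106, 150))
      al <- global_align(ref, qry)
      calls <- call_indels(al$aligned_a, al$aligned_b, reference = "a")
      expect_equal(apply_calls(ref, calls), qry)
    }
  })
})

test_that("call_snps reports substitutions in reference coordinates", {
  snps <- call_snps("ACGTACGT", "ACGAACGT")
  expect_equal(snps$position, 4L)
  expect_equal(snps$ref, "T")
  expect_equal(snps$alt, "A")
  expect_equal(nrow(call_snps("AC-T", "ACGT")), 0L)
})

test_that("motif library validation rejects bad patterns", {
  expect_error(motif_library("x", "CAXXTG"), "invalid IUPAC")
  expect_error(motif_library("x", "CAT"), "at least 4")
  lib <- default_motif_library()
  expect_s3_class(lib, "motif_library")
  expect_true(all(nchar(lib$pattern) >= 4))
})

test_that("scan_motifs finds the palindromic E-box on both strands", {
  lib <- motif_library("EBOX", "CANNTG")
  hits <- scan_motifs(c(s = "AAACACGTGAAA"), lib)
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$start), 4L)
  expect_equal(unique(hits$end), 9L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$match), "CACGTG")
  # dedupe option collapses the palindromic duplicate
  expect_equal(nrow(scan_motifs(c(s = "AAACACGTGAAA"), lib,
                                dedupe_palindromes = TRUE)), 1L)
})

test_that("empty library and N handling", {
  lib0 <- motif_library(character(0), character(0))
  expect_equal(nrow(scan_motifs(c(s = "ACGTACGT"), lib0)), 0L)
  # N in sequence never matches a non-N pattern code
  lib <- motif_library("m", "CAGT")
  expect_equal(nrow(scan_motifs(c(s = "CANT"), lib)), 0L)
  # pattern N matches sequence N
  libn <- motif_library("m", "CANT")
  expect_equal(nrow(scan_motifs(c(s = "CANT"), libn)), 1L)
  expect_error(scan_motifs(c(s = "ACGQ"), lib), "outside")
})

test_that("scanner equals the naive sliding-window matcher on random input", {
  lib <- default_motif_library()
  withr::with_seed(42, {
    for (i in 1:6) {
      s <- random_seq(800)
      hits <- scan_motifs(c(x = s), lib)
      for (r in seq_len(nrow(lib))) {
        want <- oracle_scan(s, lib$pattern[r], lib$both_strands[r])
        got <- hits[hits$motif == lib$name[r], , drop = FALSE]
        key_want <- sort(paste(want$start, want$strand))
        key_got <- sort(paste(got$start, got$strand))
        expect_equal(key_got, key_want, info = lib$name[r])
      }
    }
  })
})

test_that("strand symmetry: scanning the reverse complement swaps strands", {
  lib <- motif_library("MYB", "CNGTTR")
  withr::with_seed(55, s <- random_seq(600))
  n <- nchar(s)
  fwd <- scan_motifs(c(x = s), lib)
  rev <- scan_motifs(c(x = reverse_complement(s)), lib)
  # reflect rev hits back into forward coordinates and flip strands
  reflected <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                          strand = ifelse(rev$strand == "+", "-", "+"))
  expect_equal(sort(paste(fwd$start, fwd$strand)),
               sort(paste(reflected$start, reflected$strand)))
})

test_that("reverse_complement round trips and maps degenerate codes", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("CANNTG"), "CANNTG")
  expect_equal(reverse_complement("CNGTTR"), "YAACNG")
  withr::with_seed(3, s <- random_seq(50))
  expect_equal(reverse_complement(reverse_complement(s)), s)
})
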