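# Synthetic-data generators with ground-truth manifests: clock-evolved CDS
# pairs and families, motif/indel-bearing promoters, replicated Ct tables.
# A single seeded stream per generator call makes outputs byte-identical
# across runs and platforms.

SENSE_CODONS <- names(.codon_aa)[.codon_aa != "*"]

# single-base neighbours of each sense codon, split by synonymy
.codon_neighbours <- function(codon) {
  aa <- .aa(codon)
  syn <- character(0)
  nonsyn <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- .mutate(codon, pos, b)
      if (.is_stop(alt)) next
      if (.aa(alt) == aa) syn <- c(syn, alt) else nonsyn <- c(nonsyn, alt)
    }
  }
  list(syn = syn, nonsyn = nonsyn)
}

.NEIGHBOUR_TAB <- lapply(stats::setNames(SENSE_CODONS, SENSE_CODONS),
                         .codon_neighbours)

.SYN_SITES_K1 <- vapply(stats::setNames(SENSE_CODONS, SENSE_CODONS),
                        function(cd) syn_nonsyn_sites(cd, 1)$s, numeric(1))

# inverse of the Jukes-Cantor correction: distance -> expected p
.jc_inverse <- function(d) 3 / 4 * (1 - exp(-4 * d / 3))

#' Simulate a diverged in-frame CDS pair with known substitution counts
#'
#' Draws an ancestor uniformly over sense codons, then plants single-base
#' synonymous (and, if `true_ka > 0`, nonsynonymous) substitutions on
#' distinct codons, split randomly between the two descendant sequences, so
#' that the planted difference counts match the proportions implied by the
#' requested distances (Jukes-Cantor inverted). Synonymous changes are chosen
#' among neighbours that preserve the codon's synonymous-site count, so both
#' descendants keep exactly the ancestor's site totals and the analytic
#' expectation `Ks = JC(sd_planted / S)` is exact, not approximate. The truth
#' manifest records the realised counts, which downstream tests treat as the
#' oracle.
#'
#' @param n_codons Number of codons (>= 10).
#' @param true_ks,true_ka Target synonymous / nonsynonymous distances.
#' @param kappa Transition/transversion weighting used for site bookkeeping.
#' @param seed Integer RNG seed.
#' @return List with `alignment` (a [codon_alignment]) and `truth`
#'   (planted counts and targets).
#' @export
simulate_cds_pair <- function(n_codons, true_ks, true_ka = 0, kappa = 1,
                              seed = 1) {
  stopifnot(n_codons >= 10, true_ks >= 0, true_ka >= 0)
  withr::with_seed(seed, {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    s_anc <- sum(.SYN_SITES_K1[anc])
    n_anc <- 3 * n_codons - s_anc
    # stochastic rounding keeps the planted counts unbiased in expectation
    # (deterministic rounding would bias small targets at fixed n_codons)
    stoch_round <- function(x) floor(x) + (stats::runif(1) < x - floor(x))
    n_syn <- stoch_round(.jc_inverse(true_ks) * s_anc)
    n_nonsyn <- stoch_round(.jc_inverse(true_ka) * n_anc)
    # synonymous neighbours that leave the codon's site count unchanged
    syn_keep <- lapply(anc, function(cd) {
      s <- .NEIGHBOUR_TAB[[cd]]$syn
      s[abs(.SYN_SITES_K1[s] - .SYN_SITES_K1[[cd]]) < 1e-12]
    })
    syn_ok <- which(lengths(syn_keep) > 0)
    nonsyn_ok <- which(vapply(.NEIGHBOUR_TAB[anc], function(x)
      length(x$nonsyn) > 0, logical(1)))
    if (n_syn > length(syn_ok) || n_syn + n_nonsyn > n_codons)
      stop("requested true_ks/true_ka unattainable at this n_codons ",
           "(saturation)", call. = FALSE)
    syn_idx <- if (n_syn > 0) sample(syn_ok, n_syn) else integer(0)
    nonsyn_pool <- setdiff(nonsyn_ok, syn_idx)
    if (n_nonsyn > length(nonsyn_pool))
      stop("requested true_ka unattainable at this n_codons", call. = FALSE)
    nonsyn_idx <- if (n_nonsyn > 0) sample(nonsyn_pool, n_nonsyn) else integer(0)

    seq_a <- anc
    seq_b <- anc
    apply_change <- function(idx, choices) {
      for (i in idx) {
        opts <- choices[[i]]
        alt <- opts[sample.int(length(opts), 1)]
        if (stats::runif(1) < 0.5) seq_a[i] <<- alt else seq_b[i] <<- alt
      }
    }
    apply_change(syn_idx, syn_keep)
    apply_change(nonsyn_idx, lapply(.NEIGHBOUR_TAB[anc], `[[`, "nonsyn"))

    aln <- codon_alignment(paste(seq_a, collapse = ""),
                           paste(seq_b, collapse = ""),
                           labels = c("sim_a", "sim_b"))
    list(alignment = aln,
         truth = list(n_codons = n_codons, true_ks = true_ks,
                      true_ka = true_ka, sd_planted = n_syn,
                      nd_planted = n_nonsyn, s_ancestor = s_anc,
                      n_ancestor = n_anc, seed = seed))
  })
}

# evolve a codon vector along one branch: events arrive at rate
# `rate` per synonymous site per year (nonsynonymous at ka_ks_ratio * rate
# per nonsynonymous site); each event substitutes one base in one codon
.evolve_branch <- function(codons, t_years, rate, ka_ks_ratio) {
  s_sites <- .SYN_SITES_K1[codons]
  n_ev_syn <- stats::rpois(1, rate * t_years * sum(s_sites))
  for (e in seq_len(n_ev_syn)) {
    i <- sample.int(length(codons), 1, prob = s_sites)
    syn <- .NEIGHBOUR_TAB[[codons[i]]]$syn
    if (length(syn) == 0L) next
    codons[i] <- syn[sample.int(length(syn), 1)]
    s_sites[i] <- .SYN_SITES_K1[codons[i]]
  }
  if (ka_ks_ratio > 0) {
    n_sites <- 3 - s_sites
    n_ev_non <- stats::rpois(1, ka_ks_ratio * rate * t_years * sum(n_sites))
    for (e in seq_len(n_ev_non)) {
      i <- sample.int(length(codons), 1, prob = n_sites)
      ns <- .NEIGHBOUR_TAB[[codons[i]]]$nonsyn
      if (length(ns) == 0L) next
      codons[i] <- ns[sample.int(length(ns), 1)]
      s_sites[i] <- .SYN_SITES_K1[codons[i]]
      n_sites[i] <- 3 - s_sites[i]
    }
  }
  codons
}

#' Simulate a gene family evolving under a strict molecular clock
#'
#' Evolves coding sequences along an ultrametric family tree (branch lengths
#' in MYA) at `rate` substitutions per synonymous site per year;
#' nonsynonymous changes occur at `ka_ks_ratio * rate` (default 0:
#' synonymous-only, mirroring gene families in which only synonymous
#' variation is observed). The truth manifest holds the pairwise divergence
#' times, from which the expected Ks of any pair is `2 * rate * T`.
#'
#' @param tree An `ape::phylo` object or Newick string; branch lengths in
#'   million years; must be ultrametric for the truth times to be exact.
#' @param n_codons Codons per sequence (default 1000).
#' @param rate Clock rate, substitutions per synonymous site per year
#'   (default 3.2e-9).
#' @param ka_ks_ratio Ratio of nonsynonymous to synonymous rate (default 0).
#' @param seed Integer RNG seed.
#' @return List with `sequences` (named character vector of ungapped CDS),
#'   `times_mya` (symmetric matrix of pairwise divergence times),
#'   `expected_ks` (matrix `2 * rate * T`), `tree` and `config`.
#' @export
simulate_gene_family <- function(tree, n_codons = 1000, rate = 3.2e-9,
                                 ka_ks_ratio = 0, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            n_codons >= 10, rate > 0)
  withr::with_seed(seed, {
    root <- length(tree$tip.label) + 1L
    seqs <- vector("list", max(tree$edge))
    seqs[[root]] <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    # preorder: parents before children
    ord <- order(tree$edge[, 1])
    for (e in ord) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t_years <- tree$edge.length[e] * 1e6
      seqs[[child]] <- .evolve_branch(seqs[[parent]], t_years, rate,
                                      ka_ks_ratio)
    }
    tips <- seq_along(tree$tip.label)
    sequences <- vapply(seqs[tips], paste, character(1), collapse = "")
    names(sequences) <- tree$tip.label
    times_mya <- stats::cophenetic(tree) / 2
    times_mya <- times_mya[tree$tip.label, tree$tip.label]
    list(sequences = sequences, times_mya = times_mya,
         expected_ks = 2 * rate * times_mya * 1e6, tree = tree,
         config = list(n_codons = n_codons, rate = rate,
                       ka_ks_ratio = ka_ks_ratio, seed = seed))
  })
}

# draw a concrete instance of an IUPAC pattern
.instantiate_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

.default_plants <- function(length) {
  data.frame(
    name = c("MYC_EBOX", "MYC_EBOX", "MYB_CORE", "MYB_CORE", "GBOX"),
    pattern = c("CANNTG", "CANNTG", "CNGTTR", "CNGTTR", "CACGTG"),
    position = pmin(c(40L, 160L, 280L, 400L, 520L), length - 8L),
    stringsAsFactors = FALSE)
}

#' Simulate promoter haplotypes with planted motifs and indels
#'
#' Builds a reference promoter (random background or poly-A) with concrete
#' motif instances planted at recorded positions, plus a variant haplotype
#' carrying a recorded insertion (by default the 17-bp CAGCAGAGCACTAGCTC
#' event) and optionally random SNPs. The truth manifest is sufficient to
#' verify scanner and indel-caller output.
#'
#' @param length Promoter length in bp (default 600, roughly the stretch
#'   upstream of the start codon that promoter scans cover).
#' @param plant_motifs Data frame with columns name, pattern, position
#'   (1-based start); defaults to a small Myc/Myb/G-box set. Use a
#'   zero-row data frame to plant nothing.
#' @param insertion List with `sequence` and `position` (insertion goes after
#'   this reference base; 0 for a leading insertion), or `NULL` for none.
#' @param n_snps Number of random substitutions planted in the variant.
#' @param background `"random"` (uniform A/C/G/T) or `"polyA"`.
#' @param seed Integer RNG seed.
#' @return List with `reference`, `variant` and `truth` (planted motif table
#'   with start/end, indel record, SNP table).
#' @export
simulate_promoters <- function(length = 600,
                               plant_motifs = NULL,
                               insertion = list(
                                 sequence = "CAGCAGAGCACTAGCTC",
                                 position = 300L),
                               n_snps = 0, background = c("random", "polyA"),
                               seed = 1) {
  background <- match.arg(background)
  if (is.null(plant_motifs)) plant_motifs <- .default_plants(length)
  withr::with_seed(seed, {
    ref <- if (background == "random")
      sample(BASES, length, replace = TRUE) else rep("A", length)

    if (nrow(plant_motifs) > 0) {
      starts <- as.integer(plant_motifs$position)
      ends <- starts + nchar(plant_motifs$pattern) - 1L
      if (any(starts < 1L) || any(ends > length))
        stop("planted motif extends outside the promoter", call. = FALSE)
      ord <- order(starts)
      if (any(starts[ord][-1] <= ends[ord][-nrow(plant_motifs)]))
        stop("overlapping motif plant requests", call. = FALSE)
      plant_motifs$instance <- vapply(plant_motifs$pattern,
                                      .instantiate_pattern, character(1))
      for (r in seq_len(nrow(plant_motifs))) {
        ref[starts[r]:ends[r]] <- strsplit(plant_motifs$instance[r], "")[[1]]
      }
      plant_motifs$start <- starts
      plant_motifs$end <- ends
    }
    ins_pos <- NULL
    if (!is.null(insertion)) {
      ins_pos <- as.integer(insertion$position)
      stopifnot(ins_pos >= 0L, ins_pos <= length)
      # keep the insertion context unambiguous so the planted event has a
      # unique alignment placement: flanking bases must not extend the insert
      ins <- strsplit(toupper(insertion$sequence), "")[[1]]
      fix_flank <- function(at, clash) {
        if (at >= 1L && at <= length && ref[at] == clash)
          ref[at] <<- setdiff(BASES, clash)[1]
      }
      fix_flank(ins_pos, ins[length(ins)])
      fix_flank(ins_pos + 1L, ins[1])
    }
    ref_str <- paste(ref, collapse = "")

    var <- ref
    snps <- data.frame(position = integer(0), ref = character(0),
                       alt = character(0), stringsAsFactors = FALSE)
    if (n_snps > 0) {
      protected <- c(ins_pos, if (!is.null(ins_pos)) ins_pos + 1L)
      if (nrow(plant_motifs) > 0)
        protected <- c(protected,
                       unlist(mapply(seq, plant_motifs$start, plant_motifs$end,
                                     SIMPLIFY = FALSE)))
      pool <- setdiff(seq_len(length), protected)
      pos <- sort(sample(pool, min(n_snps, length(pool))))
      for (p in pos) {
        alt <- sample(setdiff(BASES, var[p]), 1)
        snps <- rbind(snps, data.frame(position = p, ref = var[p], alt = alt,
                                       stringsAsFactors = FALSE))
        var[p] <- alt
      }
    }
    indel_truth <- NULL
    var_str <- paste(var, collapse = "")
    if (!is.null(insertion)) {
      var_str <- paste0(substr(var_str, 1, ins_pos),
                        toupper(insertion$sequence),
                        substr(var_str, ins_pos + 1L, length))
      indel_truth <- data.frame(position = ins_pos, kind = "insertion",
                                length = nchar(insertion$sequence),
                                sequence = toupper(insertion$sequence),
                                stringsAsFactors = FALSE)
    }
    list(reference = ref_str, variant = var_str,
         truth = list(motifs = plant_motifs, indel = indel_truth,
                      snps = snps, seed = seed))
  })
}

#' Simulate a replicated qPCR Ct table with known fold changes
#'
#' Reference-gene Ct values are `baseline_ref + noise`; target-gene Ct values
#' are `baseline_target - log2(fold) + noise`, so the expected ddCt against
#' the calibrator genotype (whose fold is 1 by construction) is
#' `-log2(fold)`. Gaussian noise of `sd_ct` cycles is added independently to
#' every technical measurement.
#'
#' @param true_folds Data frame with columns genotype, tissue, gene, fold;
#'   must include the calibrator genotype rows (fold 1) for every
#'   tissue/gene combination present.
#' @param reference_gene Reference gene name (default "ubiquitin").
#' @param n_bio,n_tech Biological / technical replicate counts (default 3
#'   and 3, the standard qPCR design).
#' @param sd_ct Technical noise SD in cycles (default 0.15).
#' @param baseline_ref,baseline_target Mean Ct of reference and of an
#'   unregulated target (defaults 18 and 24).
#' @param seed Integer RNG seed.
#' @return List with `records` (Ct table data frame) and `truth`
#'   (`true_folds` plus the design parameters).
#' @export
simulate_ct_table <- function(true_folds, reference_gene = "ubiquitin",
                              n_bio = 3, n_tech = 3, sd_ct = 0.15,
                              baseline_ref = 18, baseline_target = 24,
                              seed = 1) {
  stopifnot(all(c("genotype", "tissue", "gene", "fold") %in% names(true_folds)),
            all(true_folds$fold > 0), n_bio >= 1, n_tech >= 1, sd_ct >= 0)
  withr::with_seed(seed, {
    rows <- list()
    emit <- function(genotype, tissue, gene, mean_ct) {
      for (b in seq_len(n_bio)) {
        for (tr in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <<- data.frame(
            genotype = genotype, tissue = tissue, gene = gene,
            bio_rep = b, tech_rep = tr,
            ct = mean_ct + stats::rnorm(1, 0, sd_ct),
            stringsAsFactors = FALSE)
        }
      }
    }
    combos <- unique(true_folds[, c("genotype", "tissue")])
    for (r in seq_len(nrow(combos))) {
      emit(combos$genotype[r], combos$tissue[r], reference_gene, baseline_ref)
    }
    for (r in seq_len(nrow(true_folds))) {
      emit(true_folds$genotype[r], true_folds$tissue[r], true_folds$gene[r],
           baseline_target - log2(true_folds$fold[r]))
    }
    records <- do.call(rbind, rows)
    list(records = records,
         truth = list(true_folds = true_folds, n_bio = n_bio, n_tech = n_tech,
                      sd_ct = sd_ct, reference_gene = reference_gene,
                      seed = seed))
  })
}
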