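# End-to-end orchestration: Ks matrix -> clock dating -> NJ tree ->
# promoter characterisation -> qPCR expression, written as a TSV/Newick
# report bundle with a run log.

#' Assemble a pipeline configuration
#'
#' Defaults mirror the analysis conventions of the gene-family study this
#' package emulates: calibration time 10 MYA, 1000 bootstrap replicates,
#' kappa 1, ANOVA alpha 0.05 and U-test tiers at 0.005 / 0.05.
#'
#' @param cds Named character vector of aligned CDS, or path to a FASTA file.
#' @param calibration_pairs List of 2-element character vectors naming the
#'   taxon pairs whose mean Ks calibrates the clock.
#' @param t_cal_mya Calibration divergence time in MYA (default 10).
#' @param groups Optional named character vector mapping taxon -> group
#'   label; cross-group Ks ranges are dated per group pair.
#' @param kappa Transition/transversion weighting for site counting.
#' @param bootstrap_B,bootstrap_seed NJ bootstrap replicate count and seed.
#' @param tree_model Distance model for the tree, `"jc"` or `"p"`.
#' @param promoters Named character vector of promoter sequences (or FASTA
#'   path); first record is the reference unless `promoter_reference` names
#'   one.
#' @param promoter_reference Label of the reference promoter.
#' @param motif_library A [motif_library] or TSV path (default: bundled).
#' @param ct_records Ct data frame or TSV path.
#' @param reference_gene,calibrator_genotype qPCR normalisation settings.
#' @param alpha ANOVA significance level.
#' @param out_dir Output directory for the report bundle.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cds = NULL, calibration_pairs = NULL,
                            t_cal_mya = 10, groups = NULL, kappa = 1,
                            bootstrap_B = 1000, bootstrap_seed = 1378,
                            tree_model = "jc",
                            promoters = NULL, promoter_reference = NULL,
                            motif_library = NULL,
                            ct_records = NULL, reference_gene = "ubiquitin",
                            calibrator_genotype = NULL, alpha = 0.05,
                            out_dir = tempfile("mybevol_run_")) {
  if (bootstrap_B < 1) stop("bootstrap_B must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full comparative-evolution pipeline
#'
#' Executes, for whichever inputs the configuration provides: (1) all-vs-all
#' Ks/Ka estimation, (2) clock calibration on the designated pairs and dating
#' of every pair plus cross-group ranges, (3) NJ tree with bootstrap
#' supports, (4) promoter motif scanning and indel/SNP calling against the
#' reference promoter, (5) relative-expression summaries with ANOVA letters
#' and pairwise U-tests against the calibrator genotype. Outputs are
#' deterministic TSV/Newick files plus `run_log.txt`.
#'
#' @param config A [pipeline_config].
#' @return List with the in-memory results (`ks`, `calibration`, `dating`,
#'   `tree`, `promoter`, `expression`) and `files`, the paths written.
#' @export
run_paper_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$cds) && is.null(config$promoters) &&
      is.null(config$ct_records))
    stop("configuration provides no inputs (cds, promoters or ct_records)",
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  files <- character(0)
  log_lines <- c(sprintf("mybevol %s run | config %s",
                         as.character(utils::packageVersion("mybevol")), hash),
                 sprintf("kappa=%g bootstrap_B=%d bootstrap_seed=%d t_cal_mya=%g",
                         config$kappa, as.integer(config$bootstrap_B),
                         as.integer(config$bootstrap_seed), config$t_cal_mya))
  out <- list()

  if (!is.null(config$cds)) {
    seqs <- if (is.character(config$cds) && length(config$cds) == 1L &&
                file.exists(config$cds)) read_sequences(config$cds) else config$cds

    km <- .stage("ks_matrix", pairwise_ks_matrix(seqs, kappa = config$kappa))
    out$ks <- km
    labs <- rownames(km$ks)
    pair_rows <- do.call(rbind, lapply(km$results, function(r) data.frame(
      pair = paste(r$labels, collapse = "|"), codons_used = r$codons_used,
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, pS = r$pS, pN = r$pN,
      Ks = r$Ks, Ka = r$Ka,
      flags = if (length(r$flags)) paste(r$flags, collapse = ",") else NA,
      stringsAsFactors = FALSE)))
    f <- file.path(config$out_dir, "ks_matrix.tsv")
    .write_report_tsv(pair_rows, f, hash)
    files <- c(files, f)
    dropped <- sum(vapply(km$results, `[[`, numeric(1), "dropped_columns"))
    log_lines <- c(log_lines, sprintf("ks: %d pairs, %d dropped codon columns",
                                      length(km$results), dropped))

    if (!is.null(config$calibration_pairs)) {
      calib <- .stage("calibration", {
        cal_ks <- vapply(config$calibration_pairs, function(p) {
          v <- km$ks[p[1], p[2]]
          if (is.na(v)) stop("calibration pair ", paste(p, collapse = "/"),
                             " has no Ks estimate", call. = FALSE)
          v
        }, numeric(1))
        calibrate_rate(cal_ks, config$t_cal_mya * 1e6)
      })
      out$calibration <- calib
      log_lines <- c(log_lines, sprintf("calibration: k = %.6g subst/site/yr",
                                        calib$k))

      idx <- which(upper.tri(km$ks), arr.ind = TRUE)
      dating <- data.frame(
        taxon_a = labs[idx[, 1]], taxon_b = labs[idx[, 2]],
        ks = km$ks[idx], stringsAsFactors = FALSE)
      dating <- dating[!is.na(dating$ks), , drop = FALSE]
      dating$t_mya <- round(vapply(dating$ks, function(ks)
        divergence_time(ks, calib)$t_mya, numeric(1)), 1)
      ranges <- NULL
      if (!is.null(config$groups)) {
        g <- config$groups
        dating$group_a <- unname(g[dating$taxon_a])
        dating$group_b <- unname(g[dating$taxon_b])
        cross <- dating[!is.na(dating$group_a) & !is.na(dating$group_b) &
                          dating$group_a != dating$group_b, , drop = FALSE]
        if (nrow(cross) > 0) {
          key <- apply(cbind(cross$group_a, cross$group_b), 1L,
                       function(x) paste(sort(x), collapse = "|"))
          ranges <- do.call(rbind, lapply(split(cross, key), function(d) {
            rg <- divergence_range(d$ks, calib)
            data.frame(groups = paste(sort(c(d$group_a[1], d$group_b[1])),
                                      collapse = "|"),
                       n_pairs = nrow(d), t_min_mya = rg$t_min_mya,
                       t_max_mya = rg$t_max_mya, stringsAsFactors = FALSE)
          }))
          rownames(ranges) <- NULL
        }
      }
      out$dating <- list(per_pair = dating, ranges = ranges, calibration = calib)
      f <- file.path(config$out_dir, "dating.tsv")
      .write_report_tsv(dating, f, hash)
      files <- c(files, f)
      if (!is.null(ranges)) {
        f <- file.path(config$out_dir, "dating_ranges.tsv")
        .write_report_tsv(ranges, f, hash)
        files <- c(files, f)
      }
    }

    if (length(seqs) >= 3L) {
      tree <- .stage("tree", bootstrap_tree(
        seqs, B = config$bootstrap_B, seed = config$bootstrap_seed,
        model = config$tree_model))
      out$tree <- tree
      f <- file.path(config$out_dir, "tree.nwk")
      write_newick(tree, f)
      files <- c(files, f)
      f <- file.path(config$out_dir, "supports.tsv")
      .write_report_tsv(attr(tree, "supports"), f, hash)
      files <- c(files, f)
      log_lines <- c(log_lines, sprintf("tree: %d taxa, %d bootstrap replicates (%d failed)",
                                        length(seqs), as.integer(config$bootstrap_B),
                                        attr(tree, "boot_failed")))
    }
  }

  if (!is.null(config$promoters)) {
    proms <- if (is.character(config$promoters) &&
                 length(config$promoters) == 1L &&
                 file.exists(config$promoters))
      read_sequences(config$promoters) else config$promoters
    lib <- config$motif_library
    if (is.null(lib)) lib <- default_motif_library()
    if (is.character(lib)) lib <- read_motif_library(lib)
    ref_label <- config$promoter_reference
    if (is.null(ref_label)) ref_label <- names(proms)[1]

    hits <- .stage("promoter_scan",
                   scan_motifs(gsub("-", "", proms), library = lib))
    indels <- list()
    snps <- list()
    for (lab in setdiff(names(proms), ref_label)) {
      aln <- .stage("promoter_align",
                    global_align(gsub("-", "", proms[[ref_label]]),
                                 gsub("-", "", proms[[lab]])))
      ind <- call_indels(aln$aligned_a, aln$aligned_b, reference = "a")
      if (nrow(ind) > 0) {
        ind$reference <- ref_label
        ind$query <- lab
        indels[[lab]] <- ind
      }
      sn <- call_snps(aln$aligned_a, aln$aligned_b, reference = "a")
      if (nrow(sn) > 0) {
        sn$reference <- ref_label
        sn$query <- lab
        snps[[lab]] <- sn
      }
    }
    indels <- if (length(indels)) do.call(rbind, indels) else
      data.frame(reference = character(0), query = character(0),
                 position = integer(0), kind = character(0),
                 length = integer(0), sequence = character(0))
    snps <- if (length(snps)) do.call(rbind, snps) else
      data.frame(position = integer(0), ref = character(0),
                 alt = character(0), reference = character(0),
                 query = character(0))
    out$promoter <- list(hits = hits, indels = indels, snps = snps)
    f <- file.path(config$out_dir, "promoter_hits.tsv")
    .write_report_tsv(hits, f, hash)
    files <- c(files, f)
    f <- file.path(config$out_dir, "indels.tsv")
    .write_report_tsv(indels, f, hash)
    files <- c(files, f)
    log_lines <- c(log_lines, sprintf(
      "promoters: %d sequences, %d motif hits, %d indels, %d SNPs",
      length(proms), nrow(hits), nrow(indels), nrow(snps)))
  }

  if (!is.null(config$ct_records)) {
    records <- if (is.character(config$ct_records))
      read_ct_table(config$ct_records) else config$ct_records
    calibrator <- config$calibrator_genotype
    if (is.null(calibrator)) calibrator <- records$genotype[1]
    expr <- .stage("expression", relative_expression(
      records, reference_gene = config$reference_gene,
      calibrator_genotype = calibrator))
    summ <- expr$summary
    summ$letters <- NA_character_
    summ$u_p <- NA_real_
    summ$u_tier <- NA_character_
    for (gene in unique(summ$gene)) {
      for (tis in unique(summ$tissue[summ$gene == gene])) {
        sel <- expr$replicates$gene == gene & expr$replicates$tissue == tis
        reps <- expr$replicates[sel, , drop = FALSE]
        grps <- split(reps$fold, reps$genotype)
        if (length(grps) >= 2L && all(lengths(grps) >= 2L)) {
          lets <- anova_letter_groups(grps, alpha = config$alpha)
          for (g in names(lets)) {
            summ$letters[summ$gene == gene & summ$tissue == tis &
                           summ$genotype == g] <- lets[[g]]
          }
          for (g in setdiff(names(grps), calibrator)) {
            if (!calibrator %in% names(grps)) next
            ut <- suppressWarnings(utest_compare(grps[[g]], grps[[calibrator]]))
            row <- summ$gene == gene & summ$tissue == tis & summ$genotype == g
            summ$u_p[row] <- ut$p
            summ$u_tier[row] <- ut$tier
          }
        }
      }
    }
    out$expression <- list(summary = summ, replicates = expr$replicates)
    f <- file.path(config$out_dir, "expression.tsv")
    .write_report_tsv(summ, f, hash)
    files <- c(files, f)
    log_lines <- c(log_lines, sprintf("expression: %d groups summarised",
                                      nrow(summ)))
  }

  log_file <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_file)
  files <- c(files, log_file)
  out$files <- files
  out$config_hash <- hash
  invisible(out)
}
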