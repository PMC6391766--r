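# Relative expression from qPCR Ct tables (2^-ddCt), one-way ANOVA with a
# compact letter display, and exact Mann-Whitney U comparisons.

.required_ct_cols <- c("genotype", "tissue", "gene", "bio_rep", "tech_rep", "ct")

#' Read a Ct table from a tab-separated file
#'
#' Expected columns: genotype, tissue, gene, bio_rep, tech_rep, ct.
#' Ct values must lie in (0, 45).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_ct_table(tab)
}

#' @rdname read_ct_table
#' @param records Data frame of Ct records to validate.
#' @export
validate_ct_table <- function(records) {
  missing <- setdiff(.required_ct_cols, names(records))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$ct) | records$ct <= 0 | records$ct >= 45))
    stop("Ct values must be finite and in (0, 45)", call. = FALSE)
  records
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are collapsed by the arithmetic mean of Ct per
#' biological replicate. Per biological replicate,
#' `dCt = Ct(target) - Ct(reference)`; `ddCt = dCt - mean dCt(calibrator)`,
#' where the calibrator is the designated genotype within the same tissue
#' (or a single pinned tissue via `calibrator_tissue`); the per-replicate
#' fold is `efficiency^-ddCt`. The group-level `fold_change` is
#' `efficiency^-mean(ddCt)`, so the calibrator group's own fold_change is
#' exactly 1; `fold_mean`/`fold_se` are the arithmetic mean and standard
#' error of the per-replicate folds (figure-style error bars).
#'
#' @param records Ct data frame (columns genotype, tissue, gene, bio_rep,
#'   tech_rep, ct).
#' @param reference_gene Name of the reference (housekeeping) gene, e.g.
#'   ubiquitin.
#' @param calibrator_genotype Genotype used as calibrator.
#' @param calibrator_tissue Optional: calibrate every tissue against this one
#'   tissue of the calibrator genotype; default calibrates within tissue.
#' @param efficiency Amplification efficiency (default 2 = perfect doubling).
#' @return List with `summary` (one row per genotype/tissue/gene:
#'   `fold_change`, `fold_mean`, `fold_se`, `n_bio`) and `replicates`
#'   (per-biological-replicate dCt, ddCt and fold).
#' @export
relative_expression <- function(records, reference_gene,
                                calibrator_genotype,
                                calibrator_tissue = NULL,
                                efficiency = 2) {
  records <- validate_ct_table(records)
  if (!reference_gene %in% records$gene)
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)
  if (!calibrator_genotype %in% records$genotype)
    stop("calibrator genotype '", calibrator_genotype,
         "' absent from Ct table", call. = FALSE)

  # collapse technical replicates
  coll <- stats::aggregate(ct ~ genotype + tissue + gene + bio_rep,
                           data = records, FUN = mean)
  ref <- coll[coll$gene == reference_gene, ]
  tgt <- coll[coll$gene != reference_gene, ]
  names(ref)[names(ref) == "ct"] <- "ct_ref"
  merged <- merge(tgt, ref[, c("genotype", "tissue", "bio_rep", "ct_ref")],
                  by = c("genotype", "tissue", "bio_rep"), all.x = TRUE)
  dropped <- is.na(merged$ct_ref)
  if (any(dropped)) {
    warning(sum(dropped), " sample(s) dropped: missing reference-gene Ct",
            call. = FALSE)
    merged <- merged[!dropped, , drop = FALSE]
  }
  merged$dct <- merged$ct - merged$ct_ref

  cal_dct <- function(gene, tissue) {
    tis <- if (is.null(calibrator_tissue)) tissue else calibrator_tissue
    v <- merged$dct[merged$gene == gene & merged$tissue == tis &
                      merged$genotype == calibrator_genotype]
    if (length(v) == 0L)
      stop(sprintf("no calibrator (%s, tissue %s) measurements for gene %s",
                   calibrator_genotype, tis, gene), call. = FALSE)
    mean(v)
  }
  merged$ddct <- merged$dct - mapply(cal_dct, merged$gene, merged$tissue)
  merged$fold <- efficiency^(-merged$ddct)

  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  summ <- do.call(rbind, lapply(
    split(merged, merged[, c("genotype", "tissue", "gene")], drop = TRUE),
    function(g) data.frame(
      genotype = g$genotype[1], tissue = g$tissue[1], gene = g$gene[1],
      n_bio = nrow(g), fold_change = efficiency^(-mean(g$ddct)),
      fold_mean = mean(g$fold), fold_se = se(g$fold),
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  summ <- summ[order(summ$gene, summ$tissue, summ$genotype), , drop = FALSE]
  list(summary = summ,
       replicates = merged[order(merged$gene, merged$tissue, merged$genotype,
                                 merged$bio_rep), , drop = FALSE])
}

# pairwise non-significance matrix -> compact letter display (sweep method)
.cld_from_nonsig <- function(means, nonsig) {
  ord <- order(means)
  g <- length(means)
  runs <- list()
  for (a in seq_len(g)) {
    b <- a
    while (b < g && all(nonsig[ord[a:(b + 1)], ord[a:(b + 1)]]))
      b <- b + 1L
    runs[[a]] <- ord[a:b]
  }
  # drop runs contained in an earlier/longer run
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]]) &&
          length(runs[[i]]) < length(runs[[j]])) keep[i] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  letters_out <- rep("", g)
  for (k in seq_along(runs)) {
    lab <- letters[(k - 1L) %% 26L + 1L]
    for (m in runs[[k]]) letters_out[m] <- paste0(letters_out[m], lab)
  }
  letters_out
}

#' One-way ANOVA with compact letter display
#'
#' Runs a one-way ANOVA over the groups; if significant at `alpha`, all-pairs
#' Tukey HSD decides which pairs differ and a compact letter display is
#' built (groups sharing a letter are not significantly different). If the
#' ANOVA is not significant every group is labelled "a".
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   values (>= 2 groups of >= 2 values).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
anova_letter_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two values", call. = FALSE)
  labs <- names(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    grp = factor(rep(labs, vapply(groups, length, integer(1))), levels = labs))
  means <- vapply(groups, mean, numeric(1))
  rss <- sum((df$value - stats::ave(df$value, df$grp))^2)
  if (rss < 1e-300) {
    # degenerate: zero within-group variance
    if (max(means) - min(means) < 1e-12)
      return(stats::setNames(rep("a", length(labs)), labs))
    nonsig <- outer(means, means, function(x, y) abs(x - y) < 1e-12)
    return(stats::setNames(.cld_from_nonsig(means, nonsig), labs))
  }
  fit <- stats::aov(value ~ grp, data = df)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (!is.finite(p_anova) || p_anova > alpha)
    return(stats::setNames(rep("a", length(labs)), labs))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  nonsig <- matrix(TRUE, length(labs), length(labs),
                   dimnames = list(labs, labs))
  comps <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_len(nrow(tk))) {
    p <- tk[r, "p adj"]
    a <- comps[[r]][1]
    b <- comps[[r]][2]
    sig <- is.finite(p) && p <= alpha
    nonsig[a, b] <- nonsig[b, a] <- !sig
  }
  stats::setNames(.cld_from_nonsig(means, nonsig), labs)
}

#' Exact two-sided Mann-Whitney U comparison with significance tiers
#'
#' Computes the Mann-Whitney U statistic on midranks. While
#' `choose(n1 + n2, n1)` is small enough to enumerate (covers all designs up
#' to 9 vs 9 and beyond), the two-sided p-value is the exact probability,
#' over all assignments of the pooled values to the two groups, of a U at
#' least as far from its null mean `n1*n2/2` as observed. Larger designs use
#' the tie-corrected normal approximation with continuity correction.
#' Significance tiers follow the two-level convention `"*"` for p <= 0.005
#' and `"**"` for 0.005 < p <= 0.05.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 values each for a defined
#'   p; singletons yield `NA` with a warning).
#' @param enumeration_limit Enumerate exactly while `choose(n1+n2, n1)` does
#'   not exceed this (default 2e5).
#' @return List with `u`, `p`, `tier`, `method` and `min_p` (smallest
#'   attainable two-sided p at this design, exact method only).
#' @export
utest_compare <- function(sample_a, sample_b, enumeration_limit = 2e5) {
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  if (n1 == 0L || n2 == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (n1 < 2L || n2 < 2L) {
    warning("fewer than 2 values on one side; p undefined", call. = FALSE)
    return(list(u = NA_real_, p = NA_real_, tier = "", method = "undefined",
                min_p = NA_real_))
  }
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  if (choose(n, n1) <= enumeration_limit) {
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    min_p <- min(vapply(unique(abs(u_all - mu)), function(dev)
      mean(abs(u_all - mu) >= dev - 1e-9), numeric(1)))
    method <- "exact"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    min_p <- NA_real_
    method <- "normal_approx"
  }
  tier <- if (is.na(p)) "" else if (p <= 0.005) "*"
          else if (p <= 0.05) "**" else ""
  if (method == "exact" && min_p > 0.005)
    warning(sprintf(
      "tier '*' (p <= 0.005) is unattainable at n = %d vs %d (min p = %.4g)",
      n1, n2, min_p), call. = FALSE)
  list(u = u, p = p, tier = tier, method = method, min_p = min_p)
}
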