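# Nei-Gojobori style counting of synonymous/nonsynonymous sites and
# differences on in-frame codon alignments, with Jukes-Cantor correction.

BASES <- c("A", "C", "G", "T")

# standard nuclear genetic code, indexed by codon string; "*" marks stops
.codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
})

.aa <- function(codon) unname(.codon_aa[codon])

.is_stop <- function(codon) identical(.aa(codon), "*")

.is_transition <- function(b1, b2) {
  purines <- c("A", "G")
  (b1 %in% purines) == (b2 %in% purines)
}

.validate_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop(sprintf("%s must be a single 3-letter string", arg), call. = FALSE)
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% BASES))
    stop(sprintf("%s '%s' contains a non-ACGT (gap or ambiguous) base", arg, codon),
         call. = FALSE)
  if (.is_stop(codon))
    stop(sprintf("%s '%s' is a stop codon", arg, codon), call. = FALSE)
  codon
}

.mutate <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

#' Synonymous and nonsynonymous site counts for one codon
#'
#' Counts the fractional number of synonymous (`s`) and nonsynonymous (`n`)
#' sites of a sense codon under the (modified) Nei-Gojobori convention. Each
#' codon position contributes the weighted fraction of its three possible
#' single-base substitutions that are synonymous, with transitions weighted by
#' `kappa` and transversions by 1; substitutions creating stop codons are
#' excluded from both numerator and denominator. With `kappa = 1` this reduces
#' to the original (unweighted) Nei-Gojobori count. `s + n = 3` always.
#'
#' @param codon Single 3-letter string over A/C/G/T; must not be a stop codon.
#' @param kappa Transition/transversion rate ratio used for weighting
#'   (default 1, i.e. unmodified Nei-Gojobori).
#' @return A list with components `s`, `n` (fractional site counts,
#'   `s + n == 3`) and `kappa`.
#' @examples
#' syn_nonsyn_sites("GGG")   # fourfold degenerate third position: s = 1
#' syn_nonsyn_sites("ATG")   # Met has no synonymous neighbours: s = 0
#' @export
syn_nonsyn_sites <- function(codon, kappa = 1) {
  codon <- .validate_codon(codon)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a positive scalar", call. = FALSE)
  aa <- .aa(codon)
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    num <- 0
    den <- 0
    for (b in setdiff(BASES, ref)) {
      alt <- .mutate(codon, pos, b)
      if (.is_stop(alt)) next
      w <- if (.is_transition(ref, b)) kappa else 1
      den <- den + w
      if (.aa(alt) == aa) num <- num + w
    }
    if (den > 0) s <- s + num / den
  }
  list(s = s, n = 3 - s, kappa = kappa)
}

# permutations of positions, used for pathway averaging (at most 3! = 6)
.perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Pathway-averaged synonymous/nonsynonymous difference counts
#'
#' For two sense codons, counts synonymous (`sd`) and nonsynonymous (`nd`)
#' differences averaged with equal weight over all single-step mutational
#' pathways between them (Nei-Gojobori convention). Pathways passing through a
#' stop codon are excluded. If every pathway passes through a stop, both counts
#' are `NA` and `all_paths_blocked` is `TRUE`; callers drop such codon pairs.
#'
#' @param codon_a,codon_b Sense codons (3-letter A/C/G/T strings).
#' @return List with `sd`, `nd` (sum equals the number of differing positions
#'   when any pathway is viable), `n_diff`, and `all_paths_blocked`.
#' @export
pathway_differences <- function(codon_a, codon_b) {
  codon_a <- .validate_codon(codon_a, "codon_a")
  codon_b <- .validate_codon(codon_b, "codon_b")
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(ca != cb)
  nd <- length(diff_pos)
  if (nd == 0L)
    return(list(sd = 0, nd = 0, n_diff = 0L, all_paths_blocked = FALSE))
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (path in .perms(diff_pos)) {
    cur <- codon_a
    sd_p <- 0L
    nd_p <- 0L
    ok <- TRUE
    for (pos in path) {
      nxt <- .mutate(cur, pos, cb[pos])
      if (.is_stop(nxt)) { ok <- FALSE; break }
      if (.aa(nxt) == .aa(cur)) sd_p <- sd_p + 1L else nd_p <- nd_p + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd_p
      nd_tot <- nd_tot + nd_p
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L)
    return(list(sd = NA_real_, nd = NA_real_, n_diff = nd, all_paths_blocked = TRUE))
  list(sd = sd_tot / n_valid, nd = nd_tot / n_valid, n_diff = nd,
       all_paths_blocked = FALSE)
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts a proportion of observed differences per site into an estimated
#' number of substitutions per site: `-(3/4) * log(1 - 4p/3)`.
#'
#' @param p Proportion of differences per site, `0 <= p < 3/4`.
#' @return Corrected distance (substitutions per site), always `>= p`.
#' @export
jukes_cantor_correct <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop("p must be a single non-negative number", call. = FALSE)
  if (p >= 3 / 4)
    stop(saturation_error(p))
  -(3 / 4) * log(1 - 4 * p / 3)
}

saturation_error <- function(p) {
  structure(
    class = c("mybevol_saturation_error", "error", "condition"),
    list(message = sprintf(
      "proportion of differences p = %.4g is at or beyond the Jukes-Cantor saturation limit 3/4", p),
      call = NULL, p = p))
}

#' In-frame pairwise codon alignment
#'
#' Container for a pair of aligned coding sequences (gap character `-`).
#' Lengths must be equal and divisible by 3; at least one codon column free of
#' gaps, ambiguity and stop codons must remain after masking.
#'
#' @param seq_a,seq_b Aligned nucleotide strings (A/C/G/T/N/-, case-insensitive).
#' @param labels Character vector of length 2 naming the two sequences.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq_a, seq_b, labels = c("seq_a", "seq_b")) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L,
            length(labels) == 2L)
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be divisible by 3", call. = FALSE)
  bad <- grepl("[^ACGTN-]", c(seq_a, seq_b))
  if (any(bad))
    stop("sequences may contain only A/C/G/T/N/-", call. = FALSE)
  aln <- structure(list(seq_a = seq_a, seq_b = seq_b,
                        labels = as.character(labels)),
                   class = "codon_alignment")
  if (nrow(.retained_codons(aln)) == 0L)
    stop("no ungapped, stop-free codon columns remain after masking",
         call. = FALSE)
  aln
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %s vs %s, %d columns (%d codons)\n",
              x$labels[1], x$labels[2], nchar(x$seq_a), nchar(x$seq_a) %/% 3L))
  invisible(x)
}

# codon columns retained under the complete-deletion-per-column policy:
# any column with a gap, an N, or a stop codon in either sequence is dropped
.retained_codons <- function(aln) {
  n_cod <- nchar(aln$seq_a) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  ca <- substring(aln$seq_a, starts, starts + 2L)
  cb <- substring(aln$seq_b, starts, starts + 2L)
  clean <- function(x) !grepl("[^ACGT]", x)
  keep <- clean(ca) & clean(cb)
  keep[keep] <- !vapply(ca[keep], .is_stop, logical(1)) &
    !vapply(cb[keep], .is_stop, logical(1))
  data.frame(index = which(keep), codon_a = ca[keep], codon_b = cb[keep],
             stringsAsFactors = FALSE)
}

#' Nei-Gojobori Ks/Ka estimate for a codon alignment
#'
#' Codon columns containing a gap, an ambiguous base or a stop codon in either
#' sequence are dropped (complete deletion per column), as are the rare pairs
#' whose every mutational pathway crosses a stop codon. `S` and `N` are the
#' arithmetic means of the two sequences' site totals over retained columns;
#' `Sd`/`Nd` are pathway-averaged difference counts; `Ks`/`Ka` apply the
#' Jukes-Cantor correction to `pS = Sd/S` and `pN = Nd/N`. On saturation
#' (`pS` or `pN >= 3/4`) the corresponding distance is `NA`, a flag is set and
#' a warning raised, leaving the partial result available.
#'
#' @param aln A [codon_alignment].
#' @param kappa Transition/transversion weighting for site counting (default 1).
#' @return Object of class `ks_ka_result` with fields `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `codons_used`, `dropped_columns`,
#'   `blocked_pairs` and `flags`.
#' @export
estimate_ks_ka <- function(aln, kappa = 1) {
  stopifnot(inherits(aln, "codon_alignment"))
  cod <- .retained_codons(aln)
  n_total <- nchar(aln$seq_a) %/% 3L
  if (nrow(cod) == 0L)
    stop("no retained codon columns in alignment", call. = FALSE)

  # per-codon site counts, memoised over the <=61 sense codons present
  uniq <- unique(c(cod$codon_a, cod$codon_b))
  site_tab <- vapply(uniq, function(cd) syn_nonsyn_sites(cd, kappa)$s,
                     numeric(1))
  s_a <- site_tab[cod$codon_a]
  s_b <- site_tab[cod$codon_b]

  Sd <- 0
  Nd <- 0
  blocked <- 0L
  keep <- rep(TRUE, nrow(cod))
  pair_key <- paste(cod$codon_a, cod$codon_b)
  for (key in unique(pair_key[cod$codon_a != cod$codon_b])) {
    idx <- which(pair_key == key)
    pd <- pathway_differences(cod$codon_a[idx[1]], cod$codon_b[idx[1]])
    if (pd$all_paths_blocked) {
      blocked <- blocked + length(idx)
      keep[idx] <- FALSE
    } else {
      Sd <- Sd + pd$sd * length(idx)
      Nd <- Nd + pd$nd * length(idx)
    }
  }
  codons_used <- sum(keep)
  if (codons_used == 0L)
    stop("no retained codon columns in alignment", call. = FALSE)
  S <- (sum(s_a[keep]) + sum(s_b[keep])) / 2
  N <- 3 * codons_used - S
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  flags <- character(0)
  if (blocked > 0L) flags <- c(flags, "blocked_pathway_codons_dropped")
  if (S == 0) flags <- c(flags, "no_synonymous_sites")
  if (N == 0) flags <- c(flags, "no_nonsynonymous_sites")

  jc_or_na <- function(p, what) {
    if (is.nan(p)) return(NA_real_)
    if (p >= 3 / 4) {
      warning(sprintf("%s saturated (p = %.4g >= 3/4); distance set to NA",
                      what, p), call. = FALSE)
      NA_real_
    } else jukes_cantor_correct(p)
  }
  Ks <- jc_or_na(pS, "pS")
  Ka <- jc_or_na(pN, "pN")
  if (is.na(Ks)) flags <- c(flags, "ks_saturated")
  if (is.na(Ka)) flags <- c(flags, "ka_saturated")

  structure(list(
    labels = aln$labels, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    Ks = Ks, Ka = Ka, codons_used = codons_used, kappa = kappa,
    dropped_columns = n_total - nrow(cod), blocked_pairs = blocked,
    flags = flags), class = "ks_ka_result")
}

#' @export
print.ks_ka_result <- function(x, ...) {
  cat(sprintf("ks_ka_result %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  codons used: %d (dropped columns: %d)\n",
              x$codons_used, x$dropped_columns))
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.4f  pN = %.4f  Ks = %s  Ka = %s\n", x$pS, x$pN,
              format(x$Ks, digits = 4), format(x$Ka, digits = 4)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' All-vs-all Ks matrix over a set of aligned coding sequences
#'
#' Applies [estimate_ks_ka] to every pair of sequences from a multiple codon
#' alignment. Pairs that fail (saturation, no retained columns) yield `NA`
#' entries rather than errors; the matrix is symmetric with a zero diagonal.
#'
#' @param seqs Named character vector of aligned CDS (equal lengths, gap `-`).
#' @param kappa Transition/transversion weighting (default 1).
#' @return List with `ks` and `ka` symmetric matrices and `results`, a list of
#'   per-pair `ks_ka_result` objects keyed `"a|b"`.
#' @export
pairwise_ks_matrix <- function(seqs, kappa = 1) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names", call. = FALSE)
  labs <- names(seqs)
  n <- length(seqs)
  ks <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  ka <- ks
  diag(ks) <- 0
  diag(ka) <- 0
  results <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      res <- tryCatch({
        aln <- codon_alignment(seqs[[i]], seqs[[j]], labels = labs[c(i, j)])
        suppressWarnings(estimate_ks_ka(aln, kappa = kappa))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        ks[i, j] <- ks[j, i] <- res$Ks
        ka[i, j] <- ka[j, i] <- res$Ka
        results[[paste(labs[i], labs[j], sep = "|")]] <- res
      }
    }
  }
  list(ks = ks, ka = ka, results = results)
}
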