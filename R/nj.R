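# Neighbor-Joining tree construction with bootstrap support.
#
# The agglomeration is authored here (rather than delegated) because the
# deterministic Q-tie-breaking and the negative-branch clamping policy are
# part of the module contract; trees are returned as ape "phylo" objects.

#' Jukes-Cantor nucleotide distance between two aligned sequences
#'
#' Pairwise deletion: only columns where both sequences have an unambiguous
#' A/C/G/T base are compared. `p = mismatches / comparable sites`, corrected
#' as `-(3/4) log(1 - 4p/3)`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @param model `"jc"` (default) or `"p"` for the uncorrected p-distance.
#' @return Single numeric distance (substitutions/site).
#' @export
jc_distance <- function(seq_a, seq_b, model = c("jc", "p")) {
  model <- match.arg(model)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned to equal length", call. = FALSE)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% BASES & b %in% BASES
  n_comp <- sum(ok)
  if (n_comp == 0L)
    stop("no comparable (ungapped, unambiguous) sites between sequences",
         call. = FALSE)
  p <- sum(a[ok] != b[ok]) / n_comp
  if (model == "p") return(p)
  jukes_cantor_correct(p)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' @param seqs Named character vector of aligned sequences.
#' @inheritParams jc_distance
#' @return Symmetric numeric matrix with taxon labels.
#' @export
alignment_distances <- function(seqs, model = c("jc", "p")) {
  model <- match.arg(model)
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- jc_distance(seqs[[i]], seqs[[j]], model = model)
    }
  }
  d
}

.check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < 3L)
    stop("at least 3 taxa are required", call. = FALSE)
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  d
}

.fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion. Ties in Q are broken by the
#' lowest (i, j) pair in current label order, so results are deterministic
#' across platforms. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch of the same join (preserving the
#' joined pair's distance); clamping is flagged via `attr(tree, "clamped")`.
#' Additive matrices are recovered exactly.
#'
#' @param dm Symmetric distance matrix with a zero diagonal (labels in
#'   dimnames) or the list produced by [alignment_distances].
#' @return Unrooted `ape::phylo` tree (basal trifurcation).
#' @export
build_nj <- function(dm) {
  d <- .check_dist_matrix(dm)
  labs <- rownames(d)
  frag <- labs
  clamped <- FALSE
  degenerate <- all(d == 0)

  clamp_pair <- function(v) {
    if (v[1] < 0) { v[2] <- v[2] + v[1]; v[1] <- 0; clamped <<- TRUE }
    if (v[2] < 0) { v[1] <- v[1] + v[2]; v[2] <- 0; clamped <<- TRUE }
    pmax(v, 0)
  }

  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_)
    best_q <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    v <- clamp_pair(c(vi, vj))
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], .fmt_len(v[1]),
                        frag[j], .fmt_len(v[2]))
    others <- setdiff(seq_len(n), c(i, j))
    d_new <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, d_new), c(d_new, 0))
    frag <- c(frag[others], new_frag)
    rownames(d) <- colnames(d) <- frag
  }

  # final three nodes: central node via the three-point formulas
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- d[1, 2] - v1
  v3 <- d[1, 3] - v1
  v <- pmax(c(v1, v2, v3), 0)
  if (any(c(v1, v2, v3) < 0)) clamped <- TRUE
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], .fmt_len(v[1]), frag[2], .fmt_len(v[2]),
                    frag[3], .fmt_len(v[3]))
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  attr(tree, "degenerate") <- degenerate
  tree
}

# canonical bipartition keys for the internal edges of an unrooted phylo;
# each non-root internal node's clade is one side, canonicalised to the side
# not containing the alphabetically first tip label
.bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  n_tip <- length(tips)
  keys <- character(0)
  nodes <- integer(0)
  for (idx in seq_along(pp)) {
    node <- n_tip + idx
    clade <- tips[pp[[idx]]]
    if (length(clade) >= n_tip - 1L || length(clade) <= 1L) next
    if (ref %in% clade) clade <- setdiff(tips, clade)
    if (length(clade) <= 1L) next
    keys <- c(keys, paste(sort(clade), collapse = "|"))
    nodes <- c(nodes, node)
  }
  stats::setNames(keys, nodes)
}

#' Neighbor-Joining tree with bootstrap branch supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `B` times, rebuilds the tree per
#' replicate and records, for each internal edge of the point tree, the
#' percentage of replicates containing the same bipartition (branch lengths
#' ignored). Deterministic given `seed`. Replicates whose distance matrix is
#' undefined (saturation, empty overlap) count as not containing any edge.
#'
#' @param seqs Named character vector: the multiple alignment.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed (default 1378).
#' @inheritParams jc_distance
#' @return `phylo` tree; internal-node labels carry integer supports (root
#'   label empty). `attr(tree, "boot_failed")` counts skipped replicates.
#' @export
bootstrap_tree <- function(seqs, B = 1000, seed = 1378, model = c("jc", "p")) {
  model <- match.arg(model)
  if (!is.numeric(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  B <- as.integer(B)
  point <- build_nj(alignment_distances(seqs, model = model))
  bip <- .bipartitions(point)
  counts <- stats::setNames(rep(0L, length(bip)), bip)

  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- names(seqs)
  n_col <- ncol(mat)
  failed <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(n_col, n_col, replace = TRUE)
      rs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      tr <- tryCatch(build_nj(alignment_distances(rs, model = model)),
                     error = function(e) NULL)
      if (is.null(tr)) { failed <- failed + 1L; next }
      hit <- bip %in% .bipartitions(tr)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- round(100 * counts / B)
  n_tip <- length(point$tip.label)
  n_node <- point$Nnode
  labels <- rep("", n_node)
  node_ids <- as.integer(names(bip))
  labels[node_ids - n_tip] <- as.character(as.integer(support))
  point$node.label <- labels
  attr(point, "supports") <- data.frame(
    bipartition = unname(bip), support = unname(support),
    stringsAsFactors = FALSE)
  attr(point, "boot_failed") <- failed
  attr(point, "B") <- B
  attr(point, "seed") <- seed
  point
}

#' Serialise a tree to Newick text
#'
#' Branch lengths are written in full precision; bootstrap supports (if
#' present as node labels) appear as integer internal-node labels. A
#' parse-serialise round trip preserves topology, lengths and supports.
#'
#' @param tree An `ape::phylo` object.
#' @param file Optional path; when given the Newick string is also written.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
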