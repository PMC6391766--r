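# Independent brute-force oracles used across the suite. These deliberately
# re-derive everything from first principles (Biostrings' genetic code and
# plain enumeration) rather than calling package internals.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")
SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

oracle_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      out <- c(out, alt)
    }
  }
  out
}

# per-codon synonymous sites by enumeration of the 9 single-base neighbours,
# kappa = 1, stop-creating substitutions excluded from both counts
oracle_site_counts <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    tot <- 0
    for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (ORACLE_CODE[[alt]] == "*") next
      tot <- tot + 1
      if (ORACLE_CODE[[alt]] == aa) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# pathway differences by explicit enumeration of position permutations
oracle_pathway <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(diffs) == 1) list(diffs) else {
    m <- NULL
    if (length(diffs) == 2) m <- list(diffs, rev(diffs))
    if (length(diffs) == 3) {
      m <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        m[[length(m) + 1]] <- diffs[c(i, j, setdiff(1:3, c(i, j)))]
      }
    }
    m
  }
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0
  for (p in perms) {
    cur <- a; sd_p <- 0; nd_p <- 0; ok <- TRUE
    for (pos in p) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (ORACLE_CODE[[nxt]] == "*") { ok <- FALSE; break }
      if (ORACLE_CODE[[nxt]] == ORACLE_CODE[[cur]]) sd_p <- sd_p + 1
      else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd_p; nd_tot <- nd_tot + nd_p; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
}

# exhaustive global-alignment score: best over all gap placements, scoring a
# gap run of length L as gap_open + L * gap_extend
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  n <- nchar(a); m <- nchar(b)
  best <- -Inf
  walk <- function(i, j, cols_a, cols_b) {
    if (i == n && j == m) {
      sc <- 0
      in_gap <- 0
      for (k in seq_along(cols_a)) {
        ca <- cols_a[k]; cb <- cols_b[k]
        if (ca == "-" || cb == "-") {
          gap_id <- if (ca == "-") 1 else 2
          sc <- sc + gap_extend + if (in_gap != gap_id) gap_open else 0
          in_gap <- gap_id
        } else {
          sc <- sc + if (ca == cb) match else mismatch
          in_gap <- 0
        }
      }
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < n && j < m)
      walk(i + 1, j + 1, c(cols_a, substr(a, i + 1, i + 1)),
           c(cols_b, substr(b, j + 1, j + 1)))
    if (i < n)
      walk(i + 1, j, c(cols_a, substr(a, i + 1, i + 1)), c(cols_b, "-"))
    if (j < m)
      walk(i, j + 1, c(cols_a, "-"), c(cols_b, substr(b, j + 1, j + 1)))
  }
  walk(0, 0, character(0), character(0))
  best
}

# naive sliding-window IUPAC matcher over both strands
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T", "N"))

oracle_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  hits <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0))
  for (strand in if (both_strands) c("+", "-") else "+") {
    pat <- if (strand == "+") pattern else oracle_revcomp(pattern)
    pchars <- strsplit(pat, "")[[1]]
    w <- length(pchars)
    for (i in seq_len(max(0, length(chars) - w + 1))) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!chars[i + j - 1] %in% ORACLE_IUPAC[[pchars[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- rbind(hits, data.frame(start = i, end = i + w - 1,
                                             strand = strand))
    }
  }
  hits
}

# same sliding-window semantics as oracle_scan, vectorised across window
# starts so 5-kb inputs stay fast; each window still tests every pattern
# position against the IUPAC base set
oracle_scan_fast <- function(seq, pattern, both_strands = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- data.frame(start = integer(0), strand = character(0))
  for (strand in if (both_strands) c("+", "-") else "+") {
    pat <- if (strand == "+") pattern else oracle_revcomp(pattern)
    pchars <- strsplit(pat, "")[[1]]
    w <- length(pchars)
    if (n < w) next
    ok <- rep(TRUE, n - w + 1)
    for (j in seq_len(w)) {
      ok <- ok & chars[j:(n - w + j)] %in% ORACLE_IUPAC[[pchars[j]]]
    }
    starts <- which(ok)
    if (length(starts))
      out <- rbind(out, data.frame(start = starts, strand = strand))
  }
  out
}

# exact two-sided U-test p by enumeration of group assignments
oracle_u_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sel <- utils::combn(n1 + n2, n1)
  u_all <- apply(sel, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# ---- unrooted topology enumeration + least-squares fit (NJ oracle) ----

# trees as edge matrices over node ids; tips 1..n, internals n+1, n+2, ...
oracle_topologies <- function(n) {
  trees <- list(rbind(c(1, n + 1), c(2, n + 1), c(3, n + 1)))
  n_internal <- 1
  for (t in seq(4, n)) {
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        newnode <- n + n_internal + 1
        nt <- rbind(tr[-e, , drop = FALSE],
                    c(tr[e, 1], newnode), c(tr[e, 2], newnode),
                    c(t, newnode))
        new_trees[[length(new_trees) + 1]] <- nt
      }
    }
    trees <- new_trees
    n_internal <- n_internal + 1
  }
  trees
}

# tip-to-tip edge paths by BFS; returns indicator matrix (pairs x edges)
oracle_path_matrix <- function(edges, n) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  for (p in seq_len(ncol(pairs))) {
    from <- pairs[1, p]; to <- pairs[2, p]
    # DFS path
    path_edges <- NULL
    dfs <- function(node, prev, used) {
      if (node == to) { path_edges <<- used; return(TRUE) }
      if (!is.null(adj[[node]]))
        for (r in seq_len(nrow(adj[[node]]))) {
          nxt <- adj[[node]][r, 1]; ed <- adj[[node]][r, 2]
          if (nxt != prev && dfs(nxt, node, c(used, ed))) return(TRUE)
        }
      FALSE
    }
    dfs(from, 0, integer(0))
    A[p, path_edges] <- 1
  }
  A
}

# bipartition keys of a topology (edge matrix form)
oracle_bipartitions <- function(edges, n) {
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 1] <= n || edges[e, 2] <= n) next  # pendant edge
    # tips on one side of this internal edge
    reach <- function(start, banned_edge) {
      seen <- start
      repeat {
        grow <- unique(c(seen, unlist(lapply(seq_len(nrow(edges)), function(k) {
          if (k == banned_edge) return(NULL)
          if (edges[k, 1] %in% seen) return(edges[k, 2])
          if (edges[k, 2] %in% seen) return(edges[k, 1])
          NULL
        }))))
        if (length(grow) == length(seen)) break
        seen <- grow
      }
      seen
    }
    side <- sort(intersect(reach(edges[e, 1], e), seq_len(n)))
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    if (length(side) > 1 && length(side) < n - 1)
      keys <- c(keys, paste(side, collapse = "|"))
  }
  sort(unique(keys))
}

# best topology by least squares over all unrooted topologies
oracle_ls_topology <- function(d) {
  n <- nrow(d)
  dv <- d[t(utils::combn(n, 2))]
  best_rss <- Inf
  best <- NULL
  for (tr in oracle_topologies(n)) {
    A <- oracle_path_matrix(tr, n)
    fit <- stats::lm.fit(A, dv)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- tr }
  }
  list(edges = best, rss = best_rss,
       bipartitions = oracle_bipartitions(best, n))
}

# bipartition keys of an ape phylo, tips mapped to integer order of `labels`
phylo_bipartitions <- function(tree, labels) {
  n <- length(labels)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (idx in seq_along(pp)) {
    side <- sort(match(tree$tip.label[pp[[idx]]], labels))
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    if (length(side) > 1 && length(side) < n - 1)
      keys <- c(keys, paste(side, collapse = "|"))
  }
  sort(unique(keys))
}

# random unrooted binary tree with given tip labels and uniform lengths
random_additive_matrix <- function(n, min_len = 0.05, max_len = 1) {
  topo <- oracle_topologies(n)
  tr <- topo[[sample.int(length(topo), 1)]]
  lens <- stats::runif(nrow(tr), min_len, max_len)
  A <- oracle_path_matrix(tr, n)
  dv <- as.numeric(A %*% lens)
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- 0
  pairs <- utils::combn(n, 2)
  for (p in seq_len(ncol(pairs))) {
    d[pairs[1, p], pairs[2, p]] <- dv[p]
    d[pairs[2, p], pairs[1, p]] <- dv[p]
  }
  labs <- paste0("t", seq_len(n))
  dimnames(d) <- list(labs, labs)
  list(d = d, edges = tr, lengths = lens,
       bipartitions = oracle_bipartitions(tr, n))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# perturb a sequence at n_changes random positions (keeps divergence far
# from Jukes-Cantor saturation, unlike independent random draws)
mutate_seq <- function(s, n_changes) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(length(chars), n_changes)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
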