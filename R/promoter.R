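# Promoter characterisation: global alignment, indel/SNP calling, and IUPAC
# cis-element scanning.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Reverse complement of a (possibly degenerate) nucleotide string
#' @param x Character vector of sequences over the IUPAC alphabet.
#' @return Reverse complement(s), degeneracy codes mapped to their complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Optimal global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment; a gap run of length L scores
#' `gap_open + L * gap_extend`. Tie-breaking in the traceback is
#' deterministic: diagonal, then up (gap in `seq_b`), then left (gap in
#' `seq_a`). The defaults favour one long indel over scattered gaps, which is
#' what is needed to recover a contiguous promoter insertion as a single
#' event.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (scores, not
#'   costs; gap parameters are negative).
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @export
global_align <- function(seq_a, seq_b, match = 2, mismatch = -3,
                         gap_open = -5, gap_extend = -2) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  .align_affine_cpp(toupper(seq_a), toupper(seq_b), match, mismatch,
                    gap_open, gap_extend)
}

#' Call indels from an aligned sequence pair
#'
#' Maximal runs of gap characters in the reference are reported as insertions
#' (sequence taken from the query); runs in the query as deletions. Positions
#' are 1-based reference coordinates of the base preceding the event (0 for
#' events before the first reference base). When the flanking context makes a
#' gap placement ambiguous (the event sits in a repeat), calls are
#' left-normalised: the event is slid toward the 5' end as far as the
#' context allows, so output is deterministic regardless of where the
#' aligner placed the gap. Applying the calls to the reference reconstructs
#' the query when the alignment contains no substitutions.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings (as produced by
#'   [global_align]).
#' @param reference Which input is the reference: `"a"` (default) or `"b"`.
#' @return Data frame with columns `reference`, `query`, `position`, `kind`
#'   (`"insertion"`/`"deletion"`), `length` and `sequence`; zero rows for a
#'   gapless alignment.
#' @export
call_indels <- function(aligned_a, aligned_b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned strings must have equal length", call. = FALSE)
  ref <- if (reference == "a") aligned_a else aligned_b
  qry <- if (reference == "a") aligned_b else aligned_a
  r <- strsplit(toupper(ref), "")[[1]]
  q <- strsplit(toupper(qry), "")[[1]]
  ref_pos <- cumsum(r != "-")  # reference coordinate at/before each column

  calls <- list()
  state <- ifelse(r == "-", "ins", ifelse(q == "-", "del", "aln"))
  rl <- rle(state)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (k in seq_along(rl$values)) {
    if (rl$values[k] == "aln") next
    cols <- starts[k]:ends[k]
    kind <- if (rl$values[k] == "ins") "insertion" else "deletion"
    seq <- paste(if (kind == "insertion") q[cols] else r[cols], collapse = "")
    pos <- if (starts[k] == 1L) 0L else ref_pos[starts[k] - 1L]
    # left-normalise: rotate the event 5'-ward while the preceding reference
    # base equals the event's last base
    ref_seq <- r[r != "-"]
    ev <- strsplit(seq, "")[[1]]
    len <- length(ev)
    repeat {
      if (pos < 1L) break
      prev <- ref_seq[pos]
      ok <- if (kind == "insertion") identical(prev, ev[len])
            else identical(prev, ref_seq[pos + len])
      if (!ok) break
      pos <- pos - 1L
      ev <- c(prev, ev[-len])
    }
    if (kind == "deletion") ev <- ref_seq[(pos + 1L):(pos + len)]
    seq <- paste(ev, collapse = "")
    calls[[length(calls) + 1L]] <- data.frame(
      reference = reference, query = setdiff(c("a", "b"), reference),
      position = pos, kind = kind, length = length(cols), sequence = seq,
      stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L)
    return(data.frame(reference = character(0), query = character(0),
                      position = integer(0), kind = character(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Call single-nucleotide substitutions from an aligned pair
#'
#' @inheritParams call_indels
#' @return Data frame with `position` (1-based on the reference), `ref` and
#'   `alt` bases; gap and N columns are skipped.
#' @export
call_snps <- function(aligned_a, aligned_b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  ref <- if (reference == "a") aligned_a else aligned_b
  qry <- if (reference == "a") aligned_b else aligned_a
  r <- strsplit(toupper(ref), "")[[1]]
  q <- strsplit(toupper(qry), "")[[1]]
  ref_pos <- cumsum(r != "-")
  idx <- which(r %in% BASES & q %in% BASES & r != q)
  data.frame(position = ref_pos[idx], ref = r[idx], alt = q[idx],
             stringsAsFactors = FALSE)
}

.validate_pattern <- function(pattern, name = pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop(sprintf("motif '%s': invalid IUPAC code(s) %s", name,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  if (length(chars) < 4L)
    stop(sprintf("motif '%s': pattern must be at least 4 bases", name),
         call. = FALSE)
  paste(chars, collapse = "")
}

#' Motif library constructor / loader
#'
#' A motif library is a data frame with columns `name`, `pattern` (IUPAC
#' degenerate string, length >= 4) and `both_strands` (logical). Patterns are
#' validated at load time.
#'
#' @param name,pattern,both_strands Vectors defining the motifs.
#' @return Validated data frame of class `motif_library`.
#' @export
motif_library <- function(name, pattern, both_strands = TRUE) {
  stopifnot(length(name) == length(pattern))
  both_strands <- if (length(name)) rep_len(as.logical(both_strands),
                                            length(name)) else logical(0)
  pattern <- as.character(mapply(.validate_pattern, pattern, name))
  structure(data.frame(name = as.character(name),
                       pattern = unname(pattern),
                       both_strands = both_strands,
                       stringsAsFactors = FALSE),
            class = c("motif_library", "data.frame"))
}

#' Read a motif library from a tab-separated file
#'
#' Expected columns: name, pattern, both_strands (TRUE/FALSE); a header line
#' is required.
#'
#' @param path Path to the TSV file.
#' @return A [motif_library].
#' @export
read_motif_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("name", "pattern", "both_strands")
  if (!all(required %in% names(tab)))
    stop("motif library must have columns name, pattern, both_strands",
         call. = FALSE)
  motif_library(tab$name, tab$pattern, tab$both_strands)
}

#' Bundled default cis-element library
#'
#' A small curated stand-in for a full plant cis-element database: the Myc
#' E-box (CANNTG), the Myb core (CNGTTR), MYBPLANT (MACCWAMC), the
#' light-responsive G-box (CACGTG) and the GT-1 consensus (GRWAAW). Real
#' analyses should supply their own library TSV.
#'
#' @return A [motif_library] of five motifs scanned on both strands.
#' @export
default_motif_library <- function() {
  motif_library(
    name = c("MYC_EBOX", "MYB_CORE", "MYBPLANT", "GBOX", "GT1_CONSENSUS"),
    pattern = c("CANNTG", "CNGTTR", "MACCWAMC", "CACGTG", "GRWAAW"),
    both_strands = TRUE)
}

# IUPAC pattern -> regex character classes; pattern N matches sequence N,
# every other code matches only its concrete bases (so sequence N never
# matches a non-N code)
.iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (ch == "N") bases <- c(bases, "N")
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

.scan_one_strand <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts[starts > 0L]
}

#' Scan sequences for IUPAC motif occurrences
#'
#' Every matching position is reported, overlapping hits included. Minus
#' strand hits are found by matching the reverse complement of the pattern
#' against the forward sequence; their coordinates stay on the forward strand
#' and `match` holds the forward-strand subsequence (reverse-complement it to
#' read the motif). Palindromic motifs are reported on both strands;
#' deduplication is off by default.
#'
#' @param seqs Named character vector of sequences over A/C/G/T/N (a single
#'   unnamed sequence is labelled `"seq1"`).
#' @param library A [motif_library] (or data frame with the same columns).
#' @param dedupe_palindromes Drop minus-strand hits whose coordinates
#'   duplicate a plus-strand hit of the same motif (default `FALSE`).
#' @return Data frame of hits: `motif`, `seq`, `start`, `end` (1-based
#'   inclusive, forward strand), `strand`, `match`.
#' @export
scan_motifs <- function(seqs, library = default_motif_library(),
                        dedupe_palindromes = FALSE) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (!all(c("name", "pattern", "both_strands") %in% names(library)))
    stop("library must have columns name, pattern, both_strands", call. = FALSE)
  hits <- list()
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    if (grepl("[^ACGTN]", s))
      stop(sprintf("sequence '%s' contains characters outside A/C/G/T/N", sid),
           call. = FALSE)
    for (r in seq_len(nrow(library))) {
      pat <- library$pattern[r]
      w <- nchar(pat)
      strands <- if (isTRUE(library$both_strands[r])) c("+", "-") else "+"
      for (strand in strands) {
        regex <- .iupac_regex(if (strand == "+") pat else reverse_complement(pat))
        starts <- .scan_one_strand(s, regex)
        if (length(starts) == 0L) next
        hits[[length(hits) + 1L]] <- data.frame(
          motif = library$name[r], seq = sid, start = starts,
          end = starts + w - 1L, strand = strand,
          match = substring(s, starts, starts + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(0), seq = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  if (dedupe_palindromes) {
    key <- paste(out$motif, out$seq, out$start, out$end)
    drop <- out$strand == "-" & key %in% key[out$strand == "+"]
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$seq, out$start, out$motif, out$strand), , drop = FALSE]
}
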