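# FASTA and TSV input/output. Parsing is delegated to Biostrings; the
# validation layer (duplicate labels, per-position alphabet errors) is ours.

#' Read labelled sequences from a FASTA file
#'
#' Record order and labels are preserved; sequences are uppercased and
#' validated against the A/C/G/T/N/- alphabet. A write/read round trip is the
#' identity.
#'
#' @param path Path to a (possibly gapped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  labels <- sub("\\s.*$", "", names(set))
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L)
    stop("duplicate sequence label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[[i]])
    if (bad > 0L)
      stop(sprintf(
        "record '%s': invalid character '%s' at position %d",
        labels[i], substr(seqs[[i]], bad, bad), bad), call. = FALSE)
  }
  stats::setNames(unname(seqs), labels)
}

#' Write labelled sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# short config hash (rolling polynomial over the deparsed object, mod a
# Mersenne prime) for report headers; only needs to be stable, not crypto
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# TSV writer with a standard header comment (version + config hash);
# missing values rendered as "."
.write_report_tsv <- function(df, path, config_hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# mybevol %s | config %s | coordinates 1-based inclusive",
    as.character(utils::packageVersion("mybevol")), config_hash), con)
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
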