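# Sequence file I/O, centralised on Biostrings.

#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the first non-empty character (`>` FASTA, `@`
#' FASTQ); plain or gzip-compressed files are accepted.
#'
#' @param path File path.
#' @param as Return type: `"character"` (named vector, default) or
#'   `"DNAStringSet"` / `"AAStringSet"` / `"BStringSet"`.
#' @return Sequences, named by record id.
#' @export
read_seq_file <- function(path, as = "character") {
  con <- gzfile(path, "r")
  first <- ""
  while (!nzchar(first)) first <- trimws(readLines(con, n = 1))
  close(con)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  names(set) <- sub("\\s.*$", "", names(set))
  switch(as,
         character = stats::setNames(as.character(set), names(set)),
         DNAStringSet = Biostrings::DNAStringSet(set),
         AAStringSet = Biostrings::AAStringSet(set),
         BStringSet = set,
         stop("unknown return type: ", as))
}

#' Write sequences as FASTA / FASTQ
#'
#' @param seqs Named character vector (or XStringSet).
#' @param path Output path.
#' @param width Line wrap for FASTA (default 80).
#' @param qualities Per-read quality strings for FASTQ (default constant
#'   "I", i.e. Q40).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- unlist(lapply(seq_along(seqs), function(i) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs[[i]])
    c(paste0(">", names(seqs)[i]), strsplit(body, "\n")[[1]])
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  if (is.null(qualities))
    qualities <- vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1))
  out <- as.vector(rbind(paste0("@", names(seqs)), seqs, "+", qualities))
  writeLines(out, path)
  invisible(path)
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
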