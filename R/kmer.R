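#' K-mer multiplicity spectrum
#'
#' Histogram of canonical k-mer multiplicities over a read set, plus the
#' read metadata needed for depth estimation: the k-mer length K, the read
#' length L and the total sequenced bases.
#'
#' @param counts Named numeric vector: multiplicity m -> number of distinct
#'   k-mers seen m times.
#' @param K,L K-mer and read length (bases), `K <= L`.
#' @param total_read_bases Total bases in the read set.
#' @return Object of class `kmer_spectrum` with elements `K`, `L`,
#'   `counts`, `total_kmer_instances`, `total_read_bases`.
#' @export
kmer_spectrum <- function(counts, K, L, total_read_bases = NA_real_) {
  m <- as.numeric(names(counts))
  if (any(is.na(m)) || any(m < 1)) stop("multiplicities must be >= 1")
  if (K > L) stop("K must not exceed the read length L")
  counts <- as.numeric(counts)
  names(counts) <- m
  structure(list(K = as.integer(K), L = as.numeric(L), counts = counts,
                 total_kmer_instances = sum(m * counts),
                 total_read_bases = as.numeric(total_read_bases)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("K-mer spectrum: K =", x$K, ", L =", x$L, ",",
      format(sum(x$counts), big.mark = ","), "distinct k-mers,",
      format(x$total_kmer_instances, big.mark = ","), "instances\n")
  invisible(x)
}

#' Count canonical k-mers in a read set
#'
#' Counts all length-K substrings of the reads, collapsing each k-mer with
#' its reverse complement (reads are unstranded); k-mers containing
#' non-ACGT symbols are skipped.  Odd K is recommended (a canonical k-mer
#' cannot be its own reverse complement).
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA/FASTQ file path (plain or
#'   gzipped).
#' @param K K-mer length, `1 <= K <= 31` and at most the shortest read.
#' @return A [kmer_spectrum()].
#' @examples
#' sp <- count_kmers(c("AAAA", "TTTT"), K = 4)  # one canonical 4-mer, m = 2
#' @export
count_kmers <- function(reads, K) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_seq_file(reads)
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (length(reads) == 0) stop("empty read set")
  lens <- nchar(reads)
  if (K > min(lens)) stop("K exceeds the shortest read length")
  res <- .kmer_spectrum_cpp(reads, as.integer(K))
  counts <- stats::setNames(res$count, res$multiplicity)
  counts <- counts[order(as.numeric(names(counts)))]
  kmer_spectrum(counts, K = K, L = mean(lens),
                total_read_bases = sum(lens))
}

#' Locate the main peak and the error valley of a spectrum
#'
#' The valley is the smallest multiplicity (>= 2) at which the histogram
#' turns from falling to rising, separating the low-multiplicity error mass
#' from the main coverage peak; for a unimodal (rising-then-falling)
#' spectrum the valley is 0.  M is the multiplicity with the highest count
#' above the valley.
#'
#' @param spectrum A [kmer_spectrum()].
#' @return List with `M` (peak multiplicity, the discrete argmax),
#'   `valley`, and `M_refined` (continuous peak position from quadratic
#'   interpolation through the mode and its neighbours; equals `M` when
#'   interpolation is not applicable).
#' @export
find_peak <- function(spectrum) {
  cts <- spectrum$counts
  if (length(cts) == 0) stop("empty spectrum")
  mx <- max(as.numeric(names(cts)))
  dense <- numeric(mx)
  dense[as.numeric(names(cts))] <- cts
  if (mx < 2)   # unit-coverage spectrum
    return(list(M = 1, valley = 0, M_refined = 1, interpolated = FALSE))
  valley <- 0
  if (dense[1] > dense[2]) {
    # descending from an error peak: first local minimum
    for (m in 2:(mx - 1)) {
      if (dense[m] <= dense[m - 1] && dense[m] <= dense[m + 1]) {
        valley <- m
        break
      }
    }
    if (valley == 0) stop("spectrum too shallow: no mode above the valley")
  }
  region <- (valley + 1):mx
  M <- region[which.max(dense[region])]
  if (dense[M] == 0) stop("spectrum too shallow: no mode above the valley")
  # continuous peak refinement: vertex of the parabola through the mode and
  # its neighbours (the discrete argmax is biased by up to half a unit,
  # which alone is a ~2-5% genome-size error at 25-30x)
  M_refined <- M
  interpolated <- FALSE
  if (M - 1 > valley && M + 1 <= mx) {
    c1 <- dense[M - 1]; c2 <- dense[M]; c3 <- dense[M + 1]
    den <- c1 - 2 * c2 + c3
    if (den < 0) {
      off <- 0.5 * (c1 - c3) / den
      if (abs(off) <= 0.5) {
        M_refined <- M + off
        interpolated <- TRUE
      }
    }
  }
  list(M = M, valley = valley, M_refined = M_refined,
       interpolated = interpolated)
}

#' Invert the peak formula to the sequencing depth
#'
#' The k-mer coverage peak M relates to the base sequencing depth N through
#' `M = N * (L - K + 1) / L`: a read of length L contributes `L - K + 1`
#' k-mers, so k-mer coverage is depressed relative to base coverage by that
#' factor.  This inverts the relation: `N = M * L / (L - K + 1)`.
#'
#' @param M Peak k-mer multiplicity (> 0).
#' @param L Read length.
#' @param K K-mer length, `1 <= K <= L`.
#' @return Base sequencing depth N.
#' @examples
#' depth_from_peak(M = 42, L = 100, K = 17)  # 50
#' @export
depth_from_peak <- function(M, L, K) {
  if (K > L) stop("K must not exceed L")
  if (K < 1 || M <= 0) stop("require K >= 1 and M > 0")
  M * L / (L - K + 1)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Haploid/homozygous model: genome size G = (k-mer instances above the
#' error valley) / M, with M the coverage peak.  As a cross-check, when the
#' total read bases are known, `G_bases = total_read_bases / N` is also
#' reported (N from [depth_from_peak()]); the two agree closely on
#' error-free data.
#'
#' @param spectrum A [kmer_spectrum()].
#' @return Object of class `depth_model`: list with `M`, `N`, `G`,
#'   `G_bases`, `valley`, `K`, `L`.
#' @export
estimate_genome_size <- function(spectrum) {
  pk <- find_peak(spectrum)
  if (pk$valley >= pk$M) stop("valley at or above the peak")
  # For Poisson-distributed multiplicities the continuous spectrum peak
  # lies half a unit below the mean k-mer coverage (the Poisson mode in
  # interpolated position is lambda - 1/2), so the mean coverage is the
  # interpolated vertex + 0.5.  Without interpolation fall back on the
  # discrete argmax.
  M <- if (pk$interpolated) pk$M_refined + 0.5 else pk$M
  N <- depth_from_peak(M, spectrum$L, spectrum$K)
  m <- as.numeric(names(spectrum$counts))
  keep <- m > pk$valley
  G <- sum(m[keep] * spectrum$counts[keep]) / M
  structure(list(M = M, N = N, G = G,
                 G_bases = spectrum$total_read_bases / N,
                 valley = pk$valley, K = spectrum$K, L = spectrum$L),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf(
    "Depth model: M = %.2f, N = %.2fx, valley = %s\n  G = %s bp (spectrum), %s bp (bases/N)\n",
    x$M, x$N, x$valley, format(round(x$G), big.mark = ","),
    if (is.na(x$G_bases)) "NA" else format(round(x$G_bases),
                                           big.mark = ",")))
  invisible(x)
}

#' Read / write a spectrum as two-column TSV
#'
#' Jellyfish `histo` layout: multiplicity, count; no header.
#'
#' @param path File path.
#' @param spectrum A [kmer_spectrum()].
#' @param K,L,total_read_bases Metadata to attach on read (not stored in
#'   the histo format).
#' @return `read_spectrum` returns a [kmer_spectrum()].
#' @export
read_spectrum <- function(path, K, L, total_read_bases = NA_real_) {
  df <- utils::read.table(path, col.names = c("multiplicity", "count"))
  kmer_spectrum(stats::setNames(df$count, df$multiplicity), K, L,
                total_read_bases)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(as.numeric(names(spectrum$counts)), spectrum$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
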