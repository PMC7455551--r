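# Reciprocal-best-hit orthology at desk scale: an in-repo Smith-Waterman
# with BLOSUM62 defaults stands in for BLAST; significance is a
# Karlin-Altschul-style extreme-value estimate calibrated on shuffled
# decoys.  The published screening threshold "<10 x 10^-5" is read as
# E < 1e-5; both the value and its interpretation are arguments, not
# constants.

#' BLOSUM62 substitution matrix
#'
#' Fetched from Biostrings; rows/columns cover the 20 amino acids plus
#' B, Z, X and `*`.
#'
#' @return Numeric matrix with dimnames.
#' @export
default_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under an affine gap scheme (a gap of
#' length g costs `gap_open + g * gap_extend`).  Symmetric in its two
#' arguments for a symmetric substitution matrix.  Sequences must use
#' residues present in the substitution matrix alphabet; anything else is
#' rejected.
#'
#' @param a,b Protein (or nucleotide) sequences, non-empty strings.
#' @param submat Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (positive costs; defaults 11
#'   and 1).
#' @return Numeric score (>= 0).
#' @examples
#' local_align_score("HEAGAWGHEE", "PAWHEAE")
#' @export
local_align_score <- function(a, b, submat = default_blosum62(),
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .sw_score_cpp(a, b, submat, rownames(submat), gap_open, gap_extend)$score
}

#' All-vs-all local alignment scores between two protein sets
#'
#' @param set_a,set_b Named character vectors of sequences.
#' @inheritParams local_align_score
#' @return List of matrices `score`, `coverage_a` (aligned span / length of
#'   the `set_a` sequence), `coverage_b`; rows index `set_a`, columns
#'   `set_b`.
#' @export
align_all_pairs <- function(set_a, set_b, submat = default_blosum62(),
                            gap_open = 11, gap_extend = 1) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  res <- .sw_all_pairs_cpp(set_a, set_b, submat, rownames(submat),
                           gap_open, gap_extend)
  for (k in seq_along(res))
    dimnames(res[[k]]) <- list(names(set_a), names(set_b))
  res
}

# best column index per row with coverage-then-id tie-break
#' @noRd
best_hit_idx <- function(score, coverage) {
  vapply(seq_len(nrow(score)), function(i) {
    s <- score[i, ]
    cand <- which(s == max(s))
    if (length(cand) > 1) {
      cv <- coverage[i, cand]
      cand <- cand[cv == max(cv)]
      if (length(cand) > 1)
        cand <- cand[order(colnames(score)[cand])][1]
    }
    cand[1]
  }, integer(1))
}

#' Reciprocal best hits between two protein sets
#'
#' `(a, b)` is an ortholog call when `b` is `a`'s best hit in set B and `a`
#' is `b`'s best hit in set A, and both alignments pass the score
#' threshold.  Ties between equal best scores break by higher query
#' coverage, then lexicographic subject id; applied tie-breaks are recorded
#' in the `tie_broken` column.
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @param threshold Minimum alignment score (default 0 = no filter).
#' @inheritParams local_align_score
#' @param scores Optional precomputed result of [align_all_pairs()].
#' @return data.frame `id_a`, `id_b`, `score`, `coverage_a`, `coverage_b`,
#'   `tie_broken`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, threshold = 0,
                                 submat = default_blosum62(),
                                 gap_open = 11, gap_extend = 1,
                                 scores = NULL) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  if (is.null(scores))
    scores <- align_all_pairs(set_a, set_b, submat, gap_open, gap_extend)
  sc <- scores$score
  ba <- best_hit_idx(sc, scores$coverage_a)                 # a -> b
  bb <- best_hit_idx(t(sc), t(scores$coverage_b))           # b -> a
  rows <- list()
  for (i in seq_along(ba)) {
    j <- ba[i]
    if (bb[j] != i) next
    if (sc[i, j] < threshold) next
    tie <- sum(sc[i, ] == sc[i, j]) > 1 || sum(sc[, j] == sc[i, j]) > 1
    rows[[length(rows) + 1]] <- data.frame(
      id_a = rownames(sc)[i], id_b = colnames(sc)[j], score = sc[i, j],
      coverage_a = scores$coverage_a[i, j],
      coverage_b = scores$coverage_b[i, j], tie_broken = tie)
  }
  if (!length(rows))
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0), tie_broken = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate an extreme-value significance model on shuffled decoys
#'
#' Scores of composition-preserving shuffles against a query set follow a
#' Gumbel law; the location/scale are fit by the method of moments
#' (`lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda`).  The
#' E-value of a score S over `n_comparisons` searches is
#' `n_comparisons * exp(-lambda * (S - mu))`.
#'
#' @param decoy_scores Numeric vector of alignment scores between unrelated
#'   (shuffled) sequences.
#' @return List with `lambda`, `mu`, `n` (class `sw_calibration`).
#' @export
calibrate_significance <- function(decoy_scores) {
  if (length(decoy_scores) < 10)
    stop("need >= 10 decoy scores for calibration")
  lambda <- pi / (stats::sd(decoy_scores) * sqrt(6))
  mu <- mean(decoy_scores) - 0.5772156649 / lambda
  structure(list(lambda = lambda, mu = mu, n = length(decoy_scores)),
            class = "sw_calibration")
}

#' @rdname calibrate_significance
#' @param score Alignment score(s).
#' @param calibration Result of `calibrate_significance`.
#' @param n_comparisons Search-space size (number of pairwise comparisons).
#' @return `evalue` returns the expected number of chance hits at or above
#'   `score`.
#' @export
evalue <- function(score, calibration, n_comparisons = 1) {
  n_comparisons * exp(-calibration$lambda * (score - calibration$mu))
}

#' Inventory a proteome against a curated query panel
#'
#' Counts how many panel proteins have a reciprocal-best-hit partner in the
#' proteome (`total_count`), and how many of those belong to the designated
#' core subset (`core_count`).  Invariant to panel order and to decoy
#' proteins in the proteome.
#'
#' @param proteome,panel Named character vectors of protein sequences.
#' @param core_ids Subset of panel ids designating the core members.
#' @param threshold Minimum alignment score for a hit.
#' @inheritParams local_align_score
#' @return List with `core_count`, `total_count`, and the underlying
#'   `rbh` table.
#' @export
panel_inventory <- function(proteome, panel, core_ids, threshold = 0,
                            submat = default_blosum62(),
                            gap_open = 11, gap_extend = 1) {
  if (!all(core_ids %in% names(panel)))
    stop("core_ids must be a subset of panel ids")
  rbh <- reciprocal_best_hits(panel, proteome, threshold = threshold,
                              submat = submat, gap_open = gap_open,
                              gap_extend = gap_extend)
  found <- rbh$id_a
  list(core_count = length(intersect(found, core_ids)),
       total_count = length(found), rbh = rbh)
}

#' Flagellate-capability call from flagellar protein counts
#'
#' Fixed empirical thresholds: flagellate species carry >= 40 core and
#' >= 192 total flagellar-protein homologues, while non-flagellate species
#' carry <= 26 core and <= 140 total; anything between is indeterminate.
#'
#' @param core_count,total_count Non-negative integers, `core_count <=
#'   total_count`.
#' @return Object of class `flagellar_call`: list with the two counts and
#'   `call` in `{flagellate-capable, non-flagellate, indeterminate}`.
#' @examples
#' flagellate_call(50, 217)$call   # "flagellate-capable"
#' @export
flagellate_call <- function(core_count, total_count) {
  if (core_count < 0 || total_count < 0) stop("counts must be >= 0")
  if (core_count > total_count)
    stop("core_count cannot exceed total_count")
  call <- if (core_count >= 40 && total_count >= 192) "flagellate-capable"
          else if (core_count <= 26 && total_count <= 140) "non-flagellate"
          else "indeterminate"
  structure(list(core_count = core_count, total_count = total_count,
                 call = call), class = "flagellar_call")
}

#' @export
print.flagellar_call <- function(x, ...) {
  cat(sprintf("%s (core %d, total %d)\n", x$call, x$core_count,
              x$total_count))
  invisible(x)
}

#' Screen candidate genes by similarity and annotation consistency
#'
#' A candidate is accepted when (1) it has a threshold-passing alignment to
#' some query and (2) its functional annotation contains every required
#' keyword of that query (case-insensitive token match); a missing or blank
#' annotation is inconsistent by definition.
#'
#' @param proteome Named character vector of candidate sequences.
#' @param queries Named character vector of query sequences.
#' @param annotations Named character vector: candidate id -> annotation
#'   text (ids absent from it are treated as unannotated).
#' @param keywords Named list: query id -> character vector of required
#'   keywords.
#' @param threshold Minimum alignment score.
#' @inheritParams local_align_score
#' @return data.frame `id`, `accepted`, `query` (best passing query or
#'   NA), `reason` (`""`, `"no-hit"`, or `"annotation-inconsistent"`).
#' @export
candidate_gene_screen <- function(proteome, queries, annotations, keywords,
                                  threshold, submat = default_blosum62(),
                                  gap_open = 11, gap_extend = 1) {
  scores <- align_all_pairs(proteome, queries, submat, gap_open,
                            gap_extend)$score
  tokenize <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    tolower(strsplit(x, "[^A-Za-z0-9]+")[[1]])
  }
  out <- lapply(names(proteome), function(id) {
    ann <- if (id %in% names(annotations)) annotations[[id]] else NA
    toks <- tokenize(ann)
    passing <- names(queries)[scores[id, ] >= threshold]
    if (!length(passing))
      return(data.frame(id = id, accepted = FALSE, query = NA,
                        reason = "no-hit"))
    # prefer the highest-scoring query whose keywords all match
    passing <- passing[order(-scores[id, passing])]
    for (q in passing) {
      need <- tolower(keywords[[q]])
      if (length(need) && all(need %in% toks))
        return(data.frame(id = id, accepted = TRUE, query = q,
                          reason = ""))
    }
    data.frame(id = id, accepted = FALSE, query = passing[1],
               reason = "annotation-inconsistent")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
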