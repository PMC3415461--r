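#' Alignment scoring schemes
#'
#' `nt_scoring()` builds a nucleotide scheme (default match +2, mismatch -3,
#' gap open -5, gap extend -2; `N` scores as a mismatch against everything,
#' including itself). `aa_scoring()` builds a protein scheme (default
#' BLOSUM62, gap open -11, gap extend -1). Gap penalties follow the
#' open-plus-per-residue convention: a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match,mismatch nucleotide match/mismatch scores (`match > mismatch`).
#' @param gap_open,gap_extend gap penalties, non-positive.
#' @param matrix name of a protein substitution matrix (e.g. `"BLOSUM62"`).
#' @return A list of class `aln_scoring`.
#' @export
nt_scoring <- function(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2) {
  if (match <= mismatch) abort("match score must exceed mismatch score")
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be <= 0")
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch  # N is a universal mismatch
  m[, "N"] <- mismatch
  structure(list(kind = "nucleotide", match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 substitution_matrix = m),
            class = "aln_scoring")
}

#' @rdname nt_scoring
#' @export
aa_scoring <- function(matrix = "BLOSUM62", gap_open = -11, gap_extend = -1) {
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be <= 0")
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  structure(list(kind = "protein", match = NA, mismatch = NA,
                 gap_open = gap_open, gap_extend = gap_extend,
                 substitution_matrix = get(matrix, envir = e)),
            class = "aln_scoring")
}

# Biostrings uses positive gap costs; first gap residue costs opening+extension,
# which matches the open-plus-per-residue convention used here.
aln_engine <- function(a, b, scoring, type) {
  ctor <- if (scoring$kind == "protein") Biostrings::AAString else Biostrings::DNAString
  Biostrings::pairwiseAlignment(
    pattern = ctor(a), subject = ctor(b), type = type,
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
}

# columns of two gapped strings -> run-length op string over {M,I,D}
# M: both residues; I: insertion in query (gap in target); D: gap in query
ops_from_gapped <- function(q_gapped, t_gapped) {
  qc <- strsplit(q_gapped, "")[[1]]
  tc <- strsplit(t_gapped, "")[[1]]
  op <- ifelse(qc == "-", "D", ifelse(tc == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

expand_ops <- function(op_string) {
  m <- stringr::str_match_all(op_string, "(\\d+)([MID])")[[1]]
  if (nrow(m) == 0) abort(sprintf("malformed op string: '%s'", op_string))
  rep(m[, 3], as.integer(m[, 2]))
}

#' Construct a pairwise alignment object directly
#'
#' Mostly useful for tests and for feeding externally produced alignments to
#' [map_region()]. `n_columns` is derived from `op_string`.
#'
#' @param op_string run-length operation string over M (aligned column),
#'   I (insertion in query), D (deletion from query), e.g. `"5M2D3M"`.
#' @param query_span,target_span 1-based inclusive spans on the ungapped
#'   sequences, as length-2 integer vectors.
#' @param n_identical number of identical aligned columns.
#' @param score alignment score.
#' @param query_id,target_id sequence labels.
#' @param q_aln,t_aln optional gapped alignment row strings.
#' @return An object of class `pw_alignment`.
#' @export
new_pw_alignment <- function(op_string, query_span, target_span, n_identical,
                             score = NA_real_, query_id = "query",
                             target_id = "target", q_aln = NULL, t_aln = NULL) {
  ops <- expand_ops(op_string)
  n_columns <- length(ops)
  q_len <- sum(ops != "D")
  t_len <- sum(ops != "I")
  if (q_len != query_span[2] - query_span[1] + 1) {
    abort("op_string inconsistent with query_span")
  }
  if (t_len != target_span[2] - target_span[1] + 1) {
    abort("op_string inconsistent with target_span")
  }
  if (n_identical < 0 || n_identical > n_columns) {
    abort("n_identical outside [0, n_columns]")
  }
  structure(list(query_id = query_id, target_id = target_id,
                 op_string = op_string,
                 query_span = as.integer(query_span),
                 target_span = as.integer(target_span),
                 n_identical = as.integer(n_identical),
                 n_columns = as.integer(n_columns),
                 score = score, q_aln = q_aln, t_aln = t_aln),
            class = "pw_alignment")
}

wrap_biostrings_aln <- function(aln, query_id, target_id, kind) {
  qg <- as.character(Biostrings::pattern(aln))
  tg <- as.character(Biostrings::subject(aln))
  if (nchar(qg) == 0) return(NULL)
  qc <- strsplit(qg, "")[[1]]
  tc <- strsplit(tg, "")[[1]]
  ident <- qc == tc & qc != "-"
  if (kind == "nucleotide") ident <- ident & qc != "N"
  new_pw_alignment(
    op_string = ops_from_gapped(qg, tg),
    query_span = c(Biostrings::start(Biostrings::pattern(aln)),
                   Biostrings::end(Biostrings::pattern(aln))),
    target_span = c(Biostrings::start(Biostrings::subject(aln)),
                    Biostrings::end(Biostrings::subject(aln))),
    n_identical = sum(ident),
    score = Biostrings::score(aln),
    query_id = query_id, target_id = target_id,
    q_aln = qg, t_aln = tg
  )
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (terminal gaps penalised). Deterministic:
#' the engine's traceback rule is fixed.
#'
#' @param a,b non-empty sequences (query and target).
#' @param scoring an `aln_scoring` scheme; default [nt_scoring()].
#' @param query_id,target_id labels carried into the result.
#' @return A `pw_alignment` object.
#' @export
#' @examples
#' aln <- align_global("ACGT", "ACGA")
#' pw_identity(aln)
align_global <- function(a, b, scoring = nt_scoring(),
                         query_id = "query", target_id = "target") {
  if (nchar(a) == 0 || nchar(b) == 0) abort("cannot align an empty sequence")
  wrap_biostrings_aln(aln_engine(a, b, scoring, "global"),
                      query_id, target_id, scoring$kind)
}

#' Best local pairwise alignment
#'
#' Smith-Waterman with affine gaps. Returns `NULL` when no positive-scoring
#' local alignment exists.
#'
#' @inheritParams align_global
#' @return A `pw_alignment` object, or `NULL`.
#' @export
align_local <- function(a, b, scoring = nt_scoring(),
                        query_id = "query", target_id = "target") {
  if (nchar(a) == 0 || nchar(b) == 0) abort("cannot align an empty sequence")
  aln <- aln_engine(a, b, scoring, "local")
  if (Biostrings::score(aln) <= 0) return(NULL)
  wrap_biostrings_aln(aln, query_id, target_id, scoring$kind)
}

#' Optimal global alignment scores for paired sequence vectors
#'
#' Vectorised over `a` and `b` (element i of `a` against element i of `b`)
#' through the same engine and scoring as [align_global()], returning scores
#' only. Useful when thousands of small alignments are needed.
#'
#' @param a,b character vectors of equal length.
#' @param scoring an `aln_scoring` scheme; default [nt_scoring()].
#' @return Numeric vector of optimal global scores.
#' @export
align_global_scores <- function(a, b, scoring = nt_scoring()) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  if (any(nchar(c(a, b)) == 0)) abort("cannot align an empty sequence")
  ctor <- if (scoring$kind == "protein") Biostrings::AAStringSet else Biostrings::DNAStringSet
  Biostrings::pairwiseAlignment(
    pattern = ctor(a), subject = ctor(b), type = "global",
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    scoreOnly = TRUE
  )
}

#' Fraction of identical aligned columns
#'
#' @param aln a `pw_alignment`.
#' @return Identity on `[0, 1]` over all alignment columns (internal gaps
#'   count as non-identical).
#' @export
pw_identity <- function(aln) aln$n_identical / aln$n_columns

#' Percent identity and percent aligned of a pairwise alignment
#'
#' `pct_identity` is 100 x identical columns / alignment columns (gap columns
#' included). `pct_aligned` is 100 x gap-free columns / the denominator
#' sequence length — by default the longer of the two sequences.
#'
#' @param aln a `pw_alignment`.
#' @param len_a,len_b full (unaligned) lengths of the two sequences.
#' @param denominator `"max"` (longer sequence, default) or `"query"`.
#' @return A one-row tibble with `pct_identity` and `pct_aligned`.
#' @export
alignment_stats <- function(aln, len_a, len_b, denominator = c("max", "query")) {
  denominator <- match.arg(denominator)
  if (aln$n_columns == 0) abort("zero-length alignment")
  n_m <- sum(expand_ops(aln$op_string) == "M")
  denom <- if (denominator == "max") max(len_a, len_b) else len_a
  tibble(pct_identity = 100 * aln$n_identical / aln$n_columns,
         pct_aligned = 100 * n_m / denom)
}

#' Project a query interval through an alignment onto the target
#'
#' Each query position inside the interval that sits in an aligned (M) column
#' projects to its target position; the result is the bounding target interval
#' of the projected positions plus the fraction of interval positions that
#' project. An interval entirely opposite target gaps yields an empty
#' (NA) interval with fraction 0 and `projected = FALSE`.
#'
#' @param aln a `pw_alignment`.
#' @param qstart,qend 1-based inclusive interval on the query; must lie within
#'   `aln$query_span`.
#' @return A one-row tibble: `target_start`, `target_end`, `mapped_fraction`,
#'   `projected`.
#' @export
map_region <- function(aln, qstart, qend) {
  if (qstart > qend) abort("qstart must be <= qend")
  if (qstart < aln$query_span[1] || qend > aln$query_span[2]) {
    abort(sprintf("interval %d..%d outside query span %d..%d",
                  qstart, qend, aln$query_span[1], aln$query_span[2]))
  }
  ops <- expand_ops(aln$op_string)
  qpos <- aln$query_span[1] - 1L
  tpos <- aln$target_span[1] - 1L
  hits <- integer(0)
  for (op in ops) {
    if (op == "M") {
      qpos <- qpos + 1L; tpos <- tpos + 1L
      if (qpos >= qstart && qpos <= qend) hits <- c(hits, tpos)
    } else if (op == "I") {
      qpos <- qpos + 1L
    } else {
      tpos <- tpos + 1L
    }
    if (qpos > qend) break
  }
  n_int <- qend - qstart + 1L
  if (length(hits) == 0) {
    return(tibble(target_start = NA_integer_, target_end = NA_integer_,
                  mapped_fraction = 0, projected = FALSE))
  }
  tibble(target_start = min(hits), target_end = max(hits),
         mapped_fraction = length(hits) / n_int, projected = TRUE)
}

#' @export
print.pw_alignment <- function(x, ...) {
  cat(sprintf("<pw_alignment> %s vs %s  score %.1f  identity %.1f%% (%d/%d)\n",
              x$query_id, x$target_id, x$score, 100 * pw_identity(x),
              x$n_identical, x$n_columns))
  cat(sprintf("  query %d..%d  target %d..%d  ops %s\n",
              x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2], x$op_string))
  invisible(x)
}

#' Tidy a pairwise alignment into its operation runs
#'
#' @param x a `pw_alignment`.
#' @param ... unused.
#' @return A tibble with one row per run: `op`, `length`.
#' @method tidy pw_alignment
#' @export
tidy.pw_alignment <- function(x, ...) {
  m <- stringr::str_match_all(x$op_string, "(\\d+)([MID])")[[1]]
  tibble(op = m[, 3], length = as.integer(m[, 2]))
}

#' One-row summary of a pairwise alignment
#'
#' @param x a `pw_alignment`.
#' @param ... unused.
#' @return A one-row tibble of score, identity and spans.
#' @method glance pw_alignment
#' @export
glance.pw_alignment <- function(x, ...) {
  tibble(score = x$score, n_identical = x$n_identical,
         n_columns = x$n_columns, identity = pw_identity(x),
         query_start = x$query_span[1], query_end = x$query_span[2],
         target_start = x$target_span[1], target_end = x$target_span[2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
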