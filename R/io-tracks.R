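#' Read a 5'-end count track from a 4-column TSV
#'
#' Expected columns (no header): contig, 1-based position, strand, count.
#' Duplicate (contig, strand, position) rows are summed with a warning.
#'
#' @param path path to the TSV.
#' @param replicate_id label stored in the `replicate` column.
#' @param genome optional genome tibble for bounds checking.
#' @return A tibble with columns `contig_id`, `position`, `strand`, `count`,
#'   `replicate`.
#' @export
read_count_track_tsv <- function(path, replicate_id = "rep1", genome = NULL) {
  if (!file.exists(path)) abort(sprintf("count track not found: %s", path))
  x <- readr::read_tsv(path, col_names = c("contig_id", "position", "strand", "count"),
                       col_types = "cicd", progress = FALSE)
  new_count_track(x, replicate_id, genome, src = path)
}

#' Read a 5'-end count track from a per-strand bedGraph pair
#'
#' bedGraph intervals are 0-based half-open; an interval `[s, e)` with value
#' `v` expands to 1-based positions `s+1 .. e`, each with count `v`. One file
#' per strand.
#'
#' @param plus_path,minus_path bedGraph files for the `+` and `-` strands.
#'   Either may be `NULL` if that strand has no signal.
#' @param replicate_id label stored in the `replicate` column.
#' @param genome optional genome tibble for bounds checking.
#' @return A count-track tibble as in [read_count_track_tsv()].
#' @export
read_count_track_bedgraph <- function(plus_path, minus_path,
                                      replicate_id = "rep1", genome = NULL) {
  one <- function(path, strand) {
    if (is.null(path)) {
      return(tibble(contig_id = character(), position = integer(),
                    strand = character(), count = numeric()))
    }
    if (!file.exists(path)) abort(sprintf("bedGraph not found: %s", path))
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0) {
      return(tibble(contig_id = character(), position = integer(),
                    strand = character(), count = numeric()))
    }
    # rtracklayer already converts to 1-based inclusive ranges
    w <- GenomicRanges::width(gr)
    tibble(
      contig_id = rep(as.character(GenomicRanges::seqnames(gr)), w),
      position = unlist(purrr::map2(GenomicRanges::start(gr),
                                    GenomicRanges::end(gr), seq)),
      strand = strand,
      count = rep(gr$score, w)
    )
  }
  x <- bind_rows(one(plus_path, "+"), one(minus_path, "-"))
  new_count_track(x, replicate_id, genome,
                  src = paste(c(plus_path, minus_path), collapse = " + "))
}

new_count_track <- function(x, replicate_id, genome, src = "count track") {
  if (nrow(x) == 0) {
    return(tibble(contig_id = character(), position = integer(),
                  strand = character(), count = integer(),
                  replicate = character()))
  }
  check_strand(x$strand)
  if (any(x$count < 0)) abort(sprintf("negative count(s) in %s", src))
  if (any(x$count != round(x$count))) {
    abort(sprintf("fractional count(s) in %s: counts must be integers", src))
  }
  if (any(x$count < 1)) abort(sprintf("zero count row(s) in %s", src))
  dup <- anyDuplicated(x[c("contig_id", "strand", "position")])
  if (dup) {
    warn(sprintf("duplicate positions in %s: counts summed", src))
    x <- x |>
      group_by(.data$contig_id, .data$strand, .data$position) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  if (!is.null(genome)) {
    lens <- genome$length[match(x$contig_id, genome$contig_id)]
    if (any(is.na(lens))) {
      abort(sprintf("track contig(s) absent from genome: %s",
                    paste(setdiff(x$contig_id, genome$contig_id), collapse = ", ")))
    }
    if (any(x$position < 1 | x$position > lens)) {
      abort(sprintf("track position(s) outside contig bounds in %s", src))
    }
  }
  x |>
    mutate(count = as.integer(.data$count), position = as.integer(.data$position),
           replicate = replicate_id) |>
    arrange(.data$contig_id, .data$strand, .data$position) |>
    select("contig_id", "position", "strand", "count", "replicate")
}

#' Write a count track as a 4-column TSV
#'
#' @param track count-track tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_track_tsv <- function(track, path) {
  readr::write_tsv(track[c("contig_id", "position", "strand", "count")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Write a count track as a per-strand bedGraph pair
#'
#' @param track count-track tibble.
#' @param plus_path,minus_path output paths for the two strands.
#' @return Invisibly, the two paths.
#' @export
write_count_track_bedgraph <- function(track, plus_path, minus_path) {
  one <- function(x, path) {
    gr <- GenomicRanges::GRanges(
      seqnames = x$contig_id,
      ranges = IRanges::IRanges(start = x$position, width = 1L),
      score = x$count
    )
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  one(filter(track, .data$strand == "+"), plus_path)
  one(filter(track, .data$strand == "-"), minus_path)
  invisible(c(plus_path, minus_path))
}
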