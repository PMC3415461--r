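#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct
#'   row_number n across all_of rename relocate pull slice first desc if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_chr map_int map_dbl map_lgl keep discard
#' @importFrom stats cor rnbinom rpois rgeom runif setNames
#' @importFrom utils head tail
NULL

# strand helpers -------------------------------------------------------------

check_strand <- function(strand, where = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("invalid %s value(s): %s (must be '+' or '-')",
                  where, paste(unique(strand[bad]), collapse = ", ")))
  }
  invisible(strand)
}

other_strand <- function(strand) ifelse(strand == "+", "-", "+")

#' Reverse complement of a nucleotide string
#'
#' Vectorised over its input. `N` is preserved as `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# logging: all pipeline messages go to stderr so tabular stdout stays clean
log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) inform(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
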