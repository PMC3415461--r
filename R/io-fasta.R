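#' Read a nucleotide FASTA file into a genome table
#'
#' One row per contig; residues are upper-cased and must be over `{A,C,G,T,N}`.
#' RNA alphabets (`U`) and any other character are rejected with the offending
#' character and record named.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `contig_id`, `seq`, `length`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), f)
#' read_genome_fasta(f)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  seqs <- unname(toupper(as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- stringr::str_locate(seqs[[i]], "[^ACGTN]")[1, "start"]
    if (!is.na(bad)) {
      ch <- substr(seqs[[i]], bad, bad)
      hint <- if (ch == "U") " (RNA alphabet not accepted; convert U to T)" else ""
      abort(sprintf(
        "non-nucleotide character '%s' at position %d of record '%s' in %s%s",
        ch, bad, ids[i], path, hint))
    }
  }
  tibble(contig_id = ids, seq = seqs, length = nchar(seqs))
}

#' Write a genome table to FASTA
#'
#' @param genome tibble with `contig_id` and `seq` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(setNames(genome$seq, genome$contig_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path path to an amino-acid FASTA file.
#' @return A tibble with columns `gene_id`, `protein`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  tibble(gene_id = sub("\\s.*$", "", names(set)),
         protein = unname(as.character(set)))
}

#' Write named sequences to FASTA
#'
#' @param ids,seqs character vectors of equal length.
#' @param path output path.
#' @param alphabet `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  ctor <- if (alphabet == "dna") Biostrings::DNAStringSet else Biostrings::AAStringSet
  Biostrings::writeXStringSet(ctor(setNames(seqs, ids)), path)
  invisible(path)
}

#' Extract a strand-aware region from a genome
#'
#' Coordinates are 1-based inclusive. On `+` the forward slice is returned; on
#' `-` its reverse complement. Out-of-bounds coordinates are an error — there
#' is no silent clipping.
#'
#' @param genome genome tibble from [read_genome_fasta()].
#' @param contig_id contig to slice.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A single nucleotide string.
#' @export
#' @examples
#' g <- tibble::tibble(contig_id = "c", seq = "ACGTACGT", length = 8L)
#' extract_region(g, "c", 2, 4, "+") # "CGT"
#' extract_region(g, "c", 2, 4, "-") # "ACG"
extract_region <- function(genome, contig_id, start, end, strand) {
  check_strand(strand)
  i <- match(contig_id, genome$contig_id)
  if (is.na(i)) abort(sprintf("contig '%s' not in genome", contig_id))
  len <- genome$length[i]
  if (start < 1 || end > len || start > end) {
    abort(sprintf("region %d..%d out of bounds for contig '%s' (length %d)",
                  start, end, contig_id, len))
  }
  s <- substr(genome$seq[i], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

contig_length <- function(genome, contig_id) {
  i <- match(contig_id, genome$contig_id)
  if (is.na(i)) abort(sprintf("contig '%s' not in genome", contig_id))
  genome$length[i]
}
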