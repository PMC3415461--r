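#' Read gene annotations from GFF3
#'
#' Keeps `CDS` features and small-RNA features (`ncRNA`, `sRNA`,
#' `small_regulatory_ncRNA`), mapping the latter to feature type `sRNA`.
#' Coordinates stay 1-based inclusive as in GFF3. Gene identifiers are taken
#' from the `ID` attribute, falling back to `locus_tag` then `Name`.
#'
#' @param path path to a GFF3 file.
#' @param genome optional genome tibble; when given, feature coordinates are
#'   cross-checked against contig bounds.
#' @return A tibble with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `feature_type`, and `protein` (NA unless supplied elsewhere).
#' @export
read_gene_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  srna_types <- c("ncRNA", "sRNA", "small_regulatory_ncRNA")
  keep <- type %in% c("CDS", srna_types)
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  feature_type = character(), protein = character()))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort(sprintf("feature(s) without strand ('.') in %s: %s", path,
                  paste(head(which(strand == "*"), 3), collapse = ", ")))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) ids <- dplyr::coalesce(ids, gr$locus_tag)
  if (!is.null(gr$Name)) ids <- dplyr::coalesce(ids, gr$Name)
  if (any(is.na(ids))) {
    abort(sprintf("feature(s) without ID/locus_tag/Name in %s", path))
  }
  out <- tibble(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    feature_type = ifelse(type == "CDS", "CDS", "sRNA"),
    protein = NA_character_
  )
  if (any(out$start > out$end)) abort("feature with start > end")
  if (!is.null(genome)) {
    missing <- setdiff(out$contig_id, genome$contig_id)
    if (length(missing) > 0) {
      abort(sprintf("annotation contig(s) absent from genome: %s",
                    paste(missing, collapse = ", ")))
    }
    lens <- genome$length[match(out$contig_id, genome$contig_id)]
    if (any(out$end > lens)) abort("feature extends beyond contig end")
  }
  out
}

#' Write gene annotations to GFF3
#'
#' @param genes gene tibble as from [read_gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "tsscompare"
  gr$type <- ifelse(genes$feature_type == "CDS", "CDS", "ncRNA")
  gr$phase <- ifelse(genes$feature_type == "CDS", 0L, NA_integer_)
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Translation start coordinate of each gene
#'
#' The translation start is the `start` coordinate on `+` and the `end`
#' coordinate on `-` (the 5' end of the feature in transcription direction).
#' For sRNA features the same rule gives the 5' end of the RNA.
#'
#' @param genes gene tibble.
#' @return Integer vector of translation starts, one per gene.
#' @export
translation_start <- function(genes) {
  check_strand(genes$strand)
  ifelse(genes$strand == "+", genes$start, genes$end)
}
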