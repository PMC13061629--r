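## Thin readers/writers for the plain-text formats the pipeline exchanges.

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (constant quality)
#' @param reads character vector of sequences.
#' @param path output file.
#' @param ids optional read names.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1L))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  ln[seq(2L, length(ln), by = 4L)]
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#' @param path file.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#' @param track data.frame with chrom, start, end, score.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "score")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write BED intervals
#' @param df data.frame with chrom, start, end (optional name, strand).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  if (!"name" %in% cols && "pirna_id" %in% names(df)) {
    df$name <- df$pirna_id
    cols <- c("chrom", "start", "end", "name",
              intersect(c("score", "strand"), names(df)))
  }
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simple GTF gene models (exon per transcript)
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param path output file.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tpiRslice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}
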