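#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; gzip-compressed files
#' are handled transparently.  Record names are truncated at the first
#' whitespace, as is conventional for sequence identifiers.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' @param seqs Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  names(out) <- names(seqs)
  out
}

#' Read a gene annotation table
#'
#' Expected columns: `element_id`, `gene_id`, `product`, `evalue` (TSV with
#' header).  Extra columns are kept.
#'
#' @param path Path to a TSV file.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element_id", "gene_id", "product", "evalue")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  }
  ann
}

#' Read paired reads from a two-column TSV
#'
#' @param path TSV with header columns `read1`, `read2` (one mate pair per
#'   row, plain sequence text).
#' @return data.frame with columns `read1`, `read2`.
#' @export
read_pairs_tsv <- function(path) {
  rp <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("read1", "read2") %in% names(rp))) {
    stop("read-pair table needs columns 'read1' and 'read2'")
  }
  rp
}

#' Read paired reads from two FASTQ files
#'
#' @param fq1,fq2 Paths to mate-1 and mate-2 FASTQ files (same order).
#' @return data.frame with columns `read1`, `read2`.
#' @export
read_pairs_fastq <- function(fq1, fq2) {
  r1 <- as.character(Biostrings::readDNAStringSet(fq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fq2, format = "fastq"))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  data.frame(read1 = unname(r1), read2 = unname(r2), stringsAsFactors = FALSE)
}

# Write a small TSV without quoting or row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
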