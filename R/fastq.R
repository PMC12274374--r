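## Paired FASTQ reading/writing (Phred+33). In-memory read pairs travel as a
## data frame with columns read_id, seq1, qual1, seq2, qual2.

#' Write paired reads to FASTQ
#'
#' @param reads data frame with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#' @param prefix output path prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written
#' @return character vector of the two paths, invisibly
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(s) <- reads$read_id
    q <- Biostrings::BStringSet(reads[[paste0("qual", m)]])
    Biostrings::writeXStringSet(s, paths[m], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read paired FASTQ files
#'
#' @param r1,r2 FASTQ paths for the two mates (matching record order)
#' @return data frame with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#' @export
read_fastq_pairs <- function(r1, r2) {
  one <- function(p) {
    x <- Biostrings::readQualityScaledDNAStringSet(p)
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  a <- one(r1); b <- one(r2)
  if (!identical(a$read_id, b$read_id))
    stop("R1/R2 record ids do not match")
  data.frame(read_id = a$read_id, seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
}
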