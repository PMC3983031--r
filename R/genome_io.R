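#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a validated genome object. Sequences are
#' uppercased; only the alphabet `A`, `C`, `G`, `T`, `N` is accepted —
#' IUPAC ambiguity codes other than `N` are rejected, as are duplicated
#' chromosome identifiers and empty files.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  gen <- Biostrings::readDNAStringSet(path)
  if (length(gen) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(gen) <- ids
  gen <- Biostrings::DNAStringSet(toupper(as.character(gen)))
  names(gen) <- ids
  validate_genome(gen)
  gen
}

validate_genome <- function(genome) {
  af <- Biostrings::alphabetFrequency(genome, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- colnames(af)[colSums(af) > 0 & !colnames(af) %in% allowed]
  if (length(bad) > 0L) {
    stop("disallowed character(s) in genome sequence: ",
         paste(bad, collapse = ", "), " (alphabet is A/C/G/T/N)")
  }
  invisible(genome)
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# fetch [start, end] (1-based inclusive) of chromosome `chrom`, plus strand
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop("interval [", start, ",", end, "] out of bounds for ", chrom)
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
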