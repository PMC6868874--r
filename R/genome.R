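#' Genome container with a CpG index
#'
#' A `Genome` holds uppercase contig sequences together with a per-contig
#' sorted vector of 0-based positions of the C of every CpG dinucleotide on
#' the forward strand. All coordinates in the package are 0-based half-open;
#' a CpG site is always addressed by its forward-strand C position, whichever
#' strand the evidence came from.
#'
#' @param sequences named character vector of nucleotide strings. Lowercase
#'   input is uppercased; non-ACGT characters are retained but never indexed
#'   as part of a CpG.
#' @return an object of class `Genome`: a list with `sequences` (named
#'   character vector) and `cpg_index` (named list of 0-based integer
#'   positions, strictly increasing per contig).
#' @export
Genome <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "") ||
      anyDuplicated(names(sequences))) {
    stop("contig names must be present and unique")
  }
  if (any(nchar(sequences) == 0L)) stop("empty contig sequence")
  sequences <- toupper(sequences)
  cpg_index <- lapply(sequences, function(s) {
    hits <- gregexpr("(?=CG)", s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
  })
  structure(list(sequences = sequences, cpg_index = cpg_index),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome: %d contig(s), %s bp, %s CpGs\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              format(sum(lengths(x$cpg_index)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of a Genome
#' @param genome a [Genome()]
#' @return named integer vector
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  vapply(genome$sequences, nchar, integer(1))
}

#' Extract a subsequence in 0-based half-open coordinates
#' @param genome a [Genome()]
#' @param contig contig name
#' @param start0,end0 0-based half-open interval
#' @return character scalar
#' @export
genome_subseq <- function(genome, contig, start0, end0) {
  s <- genome$sequences[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  stopifnot(start0 >= 0, end0 <= nchar(s), start0 < end0)
  substr(s, start0 + 1L, end0)
}

#' Reverse complement of a nucleotide string
#' @param x character vector of sequences (A/C/G/T/N, case-insensitive)
#' @return character vector
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
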