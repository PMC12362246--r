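#' Construct a codon alignment
#'
#' A codon alignment is a named character vector of equal-length,
#' in-frame aligned sequences over the alphabet `A,C,G,T,-,!`
#' (`!` marks an aligner-inferred frameshift accommodation; `-` is a
#' gap).  Any codon containing a gap (or any non-ACGT character, or a
#' stop triplet) is treated as missing data in the likelihood, not
#' dropped column-wise, so per-taxon information is preserved.
#'
#' @param sequences Named character vector (names are taxa).
#' @return An object of class `codon_alignment` with fields `taxa`,
#'   `sequences` and `length` (alignment length in nucleotides).
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("sequences must be named by taxon")
  if (anyDuplicated(names(sequences)))
    stop("duplicate taxon name in alignment: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  if (length(sequences) == 0L) stop("alignment has no sequences")
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("sequences have unequal lengths: ",
         paste(sort(unique(nchar(sequences))), collapse = ", "))
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not a multiple of 3")
  bad <- grepl("[^ACGT!-]", sequences)
  if (any(bad))
    stop("invalid characters in sequences of: ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(taxa = names(sequences),
                 sequences = sequences,
                 length = as.integer(len)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa,", x$length, "nt (",
      x$length %/% 3L, "codons )\n")
  invisible(x)
}

#' Read a codon alignment from FASTA
#'
#' Reads an in-frame codon FASTA alignment.  The `!` frameshift marks
#' that some codon-aware aligners insert are tolerated on read; with
#' `drop_frameshifted = TRUE` (the default) every sequence containing at
#' least one `!` is removed entirely, on the view that a sequence whose
#' reading frame needed repair should not enter a codon-model fit.
#'
#' @param path FASTA file.
#' @param drop_frameshifted Remove sequences containing `!`?
#' @return A [codon_alignment()].  Removed taxa are recorded in the
#'   `"dropped_frameshifted"` attribute.
#' @export
read_codon_fasta <- function(path, drop_frameshifted = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  dropped <- character(0)
  if (drop_frameshifted) {
    fs <- grepl("!", seqs, fixed = TRUE)
    if (any(fs)) {
      dropped <- names(seqs)[fs]
      .rs_log("dropping %d frameshift-containing sequence(s): %s",
              sum(fs), paste(dropped, collapse = ", "))
      seqs <- seqs[!fs]
      if (length(seqs) == 0L)
        stop("all sequences contained frameshift marks")
    }
  }
  aln <- codon_alignment(seqs)
  attr(aln, "dropped_frameshifted") <- dropped
  aln
}

#' Write a codon alignment to FASTA
#'
#' Canonical form: taxa in the alignment's order, sequence on a single
#' line, `\n` line endings, so write-read round trips are byte-stable.
#'
#' @param x A [codon_alignment()].
#' @param path Output file.
#' @export
write_codon_fasta <- function(x, path) {
  stopifnot(inherits(x, "codon_alignment"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (taxon in x$taxa)
    writeLines(c(paste0(">", taxon), x$sequences[[taxon]]), con, sep = "\n")
  invisible(path)
}

#' Integer codon states of an alignment
#'
#' Maps each codon to its 1-based index among the 61 sense codons;
#' codons containing a gap, an ambiguous character or encoding a stop
#' are `NA` (missing data).
#'
#' @param x A [codon_alignment()].
#' @return ntaxa x ncodon integer matrix with taxa as rownames.
#' @keywords internal
codon_states <- function(x) {
  stopifnot(inherits(x, "codon_alignment"))
  code <- genetic_code()
  ncod <- x$length %/% 3L
  out <- matrix(NA_integer_, length(x$taxa), ncod,
                dimnames = list(x$taxa, NULL))
  for (i in seq_along(x$taxa)) {
    s <- x$sequences[[i]]
    cods <- substring(s, seq(1L, x$length, 3L), seq(3L, x$length, 3L))
    out[i, ] <- match(cods, code$codons)
  }
  out
}

# Collapse alignment columns into unique site patterns with weights.
# Returns list(states = ntaxa x npat matrix, weights = integer).
.site_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = states[, first, drop = FALSE],
       weights = as.integer(tabulate(idx, nbins = sum(first))))
}
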