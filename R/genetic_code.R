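#' Sense-codon tables for the standard genetic code
#'
#' The codon model operates on the 61 sense codons of the standard
#' (bacterial/nuclear) genetic code; stop codons are excluded from the
#' state space.  The returned object caches everything the rate-matrix
#' builder needs: the codon strings, their amino-acid translation, and
#' the list of single-nucleotide codon pairs with their change position,
#' target nucleotide, transition/transversion status and
#' synonymous/nonsynonymous status.
#'
#' @return A list with elements `codons` (character, length 61),
#'   `aa` (amino acid per codon), and `pairs`, a data.frame of
#'   single-nucleotide-difference ordered codon pairs with columns
#'   `i`, `j` (1-based codon indices), `pos` (changed codon position,
#'   1-3), `target` (index of the target nucleotide in A,C,G,T),
#'   `transition` (logical) and `nonsyn` (logical).
#' @export
genetic_code <- function() {
  if (!is.null(.rs_cache$code)) return(.rs_cache$code)
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  gc_map <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc_map[match(all64, names(gc_map))])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  n <- length(sense)
  stopifnot(n == 61L)

  cmat <- do.call(rbind, strsplit(sense, ""))
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  ii <- jj <- pos <- tgt <- integer(0)
  ts <- ns <- logical(0)
  for (p in 1:3) {
    same <- outer(cmat[, (p %% 3) + 1], cmat[, (p %% 3) + 1], "==") &
      outer(cmat[, ((p + 1) %% 3) + 1], cmat[, ((p + 1) %% 3) + 1], "==")
    diffp <- outer(cmat[, p], cmat[, p], "!=")
    hit <- which(same & diffp, arr.ind = TRUE)
    ii <- c(ii, hit[, 1]); jj <- c(jj, hit[, 2])
    pos <- c(pos, rep.int(p, nrow(hit)))
    tgt <- c(tgt, match(cmat[hit[, 2], p], nt))
    ts <- c(ts, purine[cmat[hit[, 1], p]] == purine[cmat[hit[, 2], p]])
    ns <- c(ns, aa[hit[, 1]] != aa[hit[, 2]])
  }
  code <- list(codons = sense, aa = aa,
               pairs = data.frame(i = ii, j = jj, pos = pos, target = tgt,
                                  transition = ts, nonsyn = ns))
  .rs_cache$code <- code
  code
}

#' Position-specific nucleotide frequencies and F3x4 codon frequencies
#'
#' Computes the F3x4 equilibrium codon-frequency parameterization from a
#' codon alignment: nucleotide frequencies are counted separately at the
#' three codon positions (gap characters ignored), codon frequencies are
#' the product over positions, stop codons are removed and the vector is
#' renormalized.  A pseudocount keeps all four nucleotides at positive
#' frequency so the reversible-model similarity transform stays defined.
#'
#' @param x A [codon_alignment()].
#' @param pseudocount Count added to every (position, nucleotide) cell;
#'   default 0.5.
#' @return A list with `pos_freqs` (3 x 4 matrix over A,C,G,T rows
#'   summing to 1) and `pi` (length-61 F3x4 codon frequencies).
#' @export
f3x4_frequencies <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "codon_alignment"))
  nt <- c("A", "C", "G", "T")
  chars <- lapply(x$sequences, function(s) strsplit(s, "")[[1]])
  counts <- matrix(pseudocount, 3, 4, dimnames = list(NULL, nt))
  for (v in chars) {
    posidx <- rep_len(1:3, length(v))
    keep <- v %in% nt
    tab <- table(factor(posidx[keep], levels = 1:3),
                 factor(v[keep], levels = nt))
    counts <- counts + as.matrix(tab)
  }
  pos_freqs <- counts / rowSums(counts)
  f3x4_from_pos_freqs(pos_freqs)
}

#' Build F3x4 codon frequencies from position-specific nucleotide
#' frequencies
#'
#' @param pos_freqs 3 x 4 matrix of nucleotide frequencies (columns
#'   A,C,G,T) at codon positions 1-3; rows must each sum to 1.
#' @return A list with `pos_freqs` and the normalized sense-codon
#'   frequency vector `pi`.
#' @export
f3x4_from_pos_freqs <- function(pos_freqs) {
  stopifnot(is.matrix(pos_freqs), dim(pos_freqs) == c(3, 4),
            all(pos_freqs > 0),
            all(abs(rowSums(pos_freqs) - 1) < 1e-8))
  colnames(pos_freqs) <- c("A", "C", "G", "T")
  code <- genetic_code()
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  pi <- pos_freqs[1, cmat[, 1]] * pos_freqs[2, cmat[, 2]] *
    pos_freqs[3, cmat[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- code$codons
  list(pos_freqs = pos_freqs, pi = pi)
}
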