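#' Parameters of the MG94xHKY mixture codon model
#'
#' The substitution process acts on the 61 sense codons.  Single-
#' nucleotide exchanges occur at rate
#' \eqn{q_{ij} = \kappa^{1[ts]} \, \omega^{1[nonsyn]} \, f_p(b)}
#' where \eqn{\kappa} is the transition/transversion ratio,
#' \eqn{\omega} the nonsynonymous/synonymous rate ratio and
#' \eqn{f_p(b)} the F3x4 frequency of the target nucleotide \eqn{b} at
#' the changed codon position \eqn{p}; multi-nucleotide exchanges have
#' rate 0.  Sites are assigned one of several \eqn{\omega} categories
#' (probabilities `p`); on `test` branches category \eqn{c} evolves
#' under \eqn{\omega_c^k}, the relaxation/intensification coefficient
#' `k` being the quantity the branch test estimates.  Generators are
#' jointly rescaled so one unit of branch length is one expected
#' substitution per codon site under the reference-branch mixture.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Ascending vector of omega categories (>= 0).
#' @param p Category probabilities (same length, sums to 1).
#' @param k Relaxation coefficient applied on test branches (> 0).
#' @param freqs Result of [f3x4_frequencies()] or
#'   [f3x4_from_pos_freqs()]: list with `pos_freqs` and `pi`.
#' @return An object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega, p, k = 1, freqs) {
  stopifnot(kappa > 0, k > 0, all(omega >= 0), length(omega) == length(p),
            all(p >= 0), abs(sum(p) - 1) < 1e-8)
  if (is.unsorted(omega)) stop("omega categories must be ascending")
  stopifnot(is.list(freqs), !is.null(freqs$pi), !is.null(freqs$pos_freqs))
  if (abs(sum(freqs$pi) - 1) > 1e-12)
    freqs$pi <- freqs$pi / sum(freqs$pi)
  structure(list(kappa = kappa, omega = omega, p = p / sum(p), k = k,
                 freqs = freqs),
            class = "codon_model_params")
}

# Unscaled MG94xHKY generator for a single omega.
.mg94_q <- function(omega, kappa, pos_freqs) {
  code <- genetic_code()
  pr <- code$pairs
  rate <- ifelse(pr$transition, kappa, 1) *
    ifelse(pr$nonsyn, omega, 1) *
    pos_freqs[cbind(pr$pos, pr$target)]
  Q <- matrix(0, 61, 61, dimnames = list(code$codons, code$codons))
  Q[cbind(pr$i, pr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

# Total substitution rate (expected substitutions per codon per unit
# time) of generator Q at stationarity pi.
.q_rate <- function(Q, pi) -sum(pi * diag(Q))

# Reference-branch mixture scaling constant for a parameter set.
.mixture_rate <- function(params) {
  qs <- lapply(params$omega, .mg94_q, kappa = params$kappa,
               pos_freqs = params$freqs$pos_freqs)
  sum(params$p * vapply(qs, .q_rate, 0, pi = params$freqs$pi))
}

#' Build the scaled MG94xHKY generator for one effective omega
#'
#' Returns the 61 x 61 rate matrix for a single effective omega under
#' the model's shared scaling: the generator is divided by the
#' reference-branch mixture substitution rate, so branch lengths read
#' as expected substitutions per codon site on reference branches.
#'
#' @param params A [codon_model_params()].
#' @param omega Effective omega for this matrix (e.g. `omega_c` on a
#'   reference branch or `omega_c^k` on a test branch); >= 0.
#' @return Rate matrix with rows summing to 0; the stationary codon
#'   frequencies are attached as attribute `"pi"`.
#' @export
build_rate_matrix <- function(params, omega) {
  stopifnot(inherits(params, "codon_model_params"))
  if (omega < 0) stop("omega must be >= 0")
  Q <- .mg94_q(omega, params$kappa, params$freqs$pos_freqs) /
    .mixture_rate(params)
  attr(Q, "pi") <- params$freqs$pi
  Q
}

#' Transition probabilities of a reversible generator
#'
#' Computes `expm(Q t)` through the eigendecomposition of the
#' symmetrized reversible form \eqn{D^{1/2} Q D^{-1/2}}.
#'
#' @param Q Reversible generator with stationary distribution attached
#'   as attribute `"pi"` (as returned by [build_rate_matrix()]), or
#'   supplied via `pi`.
#' @param t Branch length (>= 0).
#' @param pi Stationary distribution; defaults to `attr(Q, "pi")`.
#' @return Stochastic matrix `exp(Q t)`.
#' @export
transition_probabilities <- function(Q, t, pi = attr(Q, "pi")) {
  if (t < 0) stop("branch length must be >= 0")
  if (is.null(pi)) stop("stationary distribution 'pi' required")
  es <- .eig_rev_cpp(unclass(Q)[, , drop = FALSE], pi)
  P <- .trans_prob_cpp(es$U, es$lambda, es$V, t)
  dimnames(P) <- dimnames(Q)
  P
}

# ---------------------------------------------------------------------
# Likelihood engine
# ---------------------------------------------------------------------

# Precompute everything that depends only on (alignment, tree):
# postorder edges, tip pattern states, pattern weights, edge tags.
.peel_data <- function(aln, tree) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "tagged_tree"))
  phy <- tree$phy
  tips <- phy$tip.label
  if (!all(tips %in% aln$taxa))
    stop("tree leaves missing from alignment: ",
         paste(setdiff(tips, aln$taxa), collapse = ", "))
  states <- codon_states(aln)[tips, , drop = FALSE]
  pat <- .site_patterns(states)
  po <- ape::reorder.phylo(phy, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  tipstate <- pat$states
  tipstate[is.na(tipstate)] <- 0L   # -> -1 after 0-base shift
  list(edge = po$edge,
       blen = phy$edge.length[ord],
       tags = tree$tags[ord],
       tipstate = tipstate - 1L,
       weights = pat$weights,
       n_node_total = length(tips) + phy$Nnode,
       ntip = length(tips))
}

# Per-pattern log-likelihood for each omega category (rows) given fixed
# branch lengths.  `scale` multiplies all branch lengths.
.mixture_site_loglik <- function(pd, params, scale = 1) {
  pi <- params$freqs$pi
  ncat <- length(params$omega)
  nedge <- nrow(pd$edge)
  Qs <- lapply(params$omega, function(w)
    .mg94_q(w, params$kappa, params$freqs$pos_freqs))
  rho <- sum(params$p * vapply(Qs, .q_rate, 0, pi = pi))
  Qs <- lapply(Qs, function(q) q / rho)
  esys <- matrix(rep(seq_len(ncat), each = nedge), nedge, ncat)
  if (params$k != 1 && any(pd$tags == "test")) {
    Qs <- c(Qs, lapply(params$omega^params$k, function(w)
      .mg94_q(w, params$kappa, params$freqs$pos_freqs) / rho))
    test_e <- pd$tags == "test"
    esys[test_e, ] <- matrix(rep(ncat + seq_len(ncat), each = sum(test_e)),
                             sum(test_e), ncat)
  }
  .class_loglik_cpp(pd$edge, pd$blen * scale, esys, Qs, pd$tipstate, pi,
                    pd$n_node_total)
}

.logsumexp_cols <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

#' Log-likelihood of a codon alignment on a tagged tree
#'
#' Felsenstein pruning over the rooted tree, summing per-site
#' likelihoods over the omega-category mixture.  On `test` branches
#' category \eqn{c} uses \eqn{\omega_c^k}; `reference` and `excluded`
#' branches use \eqn{\omega_c}.  Codons with gaps or ambiguity are
#' missing data (partial-likelihood vectors of ones).
#'
#' @param aln A [codon_alignment()]; its taxa must cover the tree
#'   leaves (extra taxa are ignored).
#' @param tree A [tagged_tree()].
#' @param params A [codon_model_params()].
#' @return The log-likelihood (scalar); per-pattern values and their
#'   multiplicities are attached as attributes `"pattern_loglik"` and
#'   `"pattern_weights"`.
#' @export
log_likelihood <- function(aln, tree, params) {
  stopifnot(inherits(params, "codon_model_params"))
  pd <- .peel_data(aln, tree)
  ll <- .mixture_site_loglik(pd, params)
  site <- .logsumexp_cols(ll + log(params$p))
  out <- sum(site * pd$weights)
  attr(out, "pattern_loglik") <- site
  attr(out, "pattern_weights") <- pd$weights
  out
}
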