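# ---------------------------------------------------------------------
# Per-branch MG94 fit and dN/dS
#
# Each branch carries its own omega and its own length t, measured in
# expected substitutions per codon site under that branch's own
# process; kappa and the F3x4 frequencies are shared.  This is the
# "local" codon-model convention, fitted by coordinate ascent.
# ---------------------------------------------------------------------

# synonymous / nonsynonymous flux of the neutral (omega = 1) process:
# flux_n(omega) = omega * A1 and flux_s = S1, both per codon per unit
# time of the unscaled generator.
.syn_nonsyn_flux <- function(kappa, freqs) {
  code <- genetic_code()
  pr <- code$pairs
  rate <- ifelse(pr$transition, kappa, 1) *
    freqs$pos_freqs[cbind(pr$pos, pr$target)] * freqs$pi[pr$i]
  c(A1 = sum(rate[pr$nonsyn]), S1 = sum(rate[!pr$nonsyn]))
}

#' Fit a single-omega-per-branch MG94 model
#'
#' Fits, by coordinate ascent, an MG94xHKY model in which every branch
#' has its own omega and its own length (expected substitutions per
#' codon site under that branch's own process), with a shared kappa and
#' F3x4 frequencies.  This is the genome-wide dN/dS workhorse applied
#' to the concatenated single-copy alignment.
#'
#' @param aln A [codon_alignment()] covering the tree leaves.
#' @param tree A [tagged_tree()] or rooted `ape::phylo`.
#' @param passes Coordinate-ascent sweeps over branches (default 2).
#' @param kappa_init,omega_init Starting values.
#' @return An object of class `mg94_fit`: data.frame `branches`
#'   (parent, child, label, t, omega), `kappa`, `lnl`, plus the
#'   frequency model.
#' @export
fit_mg94_branches <- function(aln, tree, passes = 2, kappa_init = 2,
                              omega_init = 0.3) {
  if (inherits(tree, "phylo")) tree <- tagged_tree(tree)
  stopifnot(inherits(tree, "tagged_tree"))
  pd <- .peel_data(aln, tree)
  freqs <- f3x4_frequencies(aln)
  nedge <- nrow(pd$edge)
  esys <- matrix(seq_len(nedge), nedge, 1)

  kappa <- kappa_init
  omega <- rep(omega_init, nedge)
  tlen <- pmax(pd$blen, 1e-4)

  flux <- .syn_nonsyn_flux(kappa, freqs)
  own_rate <- function(w, fl) w * fl[["A1"]] + fl[["S1"]]
  gens <- vector("list", nedge)
  rebuild <- function(e, kap, fl) {
    .eig_rev_cpp(.mg94_q(omega[e], kap, freqs$pos_freqs) /
                   own_rate(omega[e], fl), freqs$pi)
  }
  for (e in seq_len(nedge)) gens[[e]] <- rebuild(e, kappa, flux)

  lnl_of <- function() {
    ll <- .class_loglik_cpp(pd$edge, tlen, esys, gens, pd$tipstate,
                            freqs$pi, pd$n_node_total)
    sum(ll[1, ] * pd$weights)
  }
  lnl <- lnl_of()

  for (pass in seq_len(passes)) {
    # kappa, globally (all eigensystems rebuilt per evaluation)
    kobj <- function(lk) {
      kap <- exp(lk)
      fl <- .syn_nonsyn_flux(kap, freqs)
      for (e in seq_len(nedge)) gens[[e]] <<- rebuild(e, kap, fl)
      -lnl_of()
    }
    kf <- optimize(kobj, c(log(0.2), log(20)), tol = 1e-3)
    kappa <- exp(kf$minimum)
    flux <- .syn_nonsyn_flux(kappa, freqs)
    for (e in seq_len(nedge)) gens[[e]] <- rebuild(e, kappa, flux)

    # per-branch (t, omega)
    for (e in seq_len(nedge)) {
      eobj <- function(th) {
        if (any(abs(th) > 16)) return(1e10)
        omega[e] <<- exp(th[2])
        tlen[e] <<- exp(th[1])
        gens[[e]] <<- rebuild(e, kappa, flux)
        v <- -lnl_of()
        if (!is.finite(v)) 1e10 else v
      }
      ef <- optim(c(log(tlen[e]), log(omega[e])), eobj,
                  method = "Nelder-Mead",
                  control = list(maxit = 80, reltol = 1e-8))
      eobj(ef$par)   # leave state at the optimum
    }
    new_lnl <- lnl_of()
    if (new_lnl - lnl < 1e-4 && pass > 1) break
    lnl <- new_lnl
  }

  ntip <- pd$ntip
  labs <- c(tree$phy$tip.label,
            if (!is.null(tree$phy$node.label) &&
                any(nzchar(tree$phy$node.label)))
              tree$phy$node.label
            else paste0("node", seq_len(tree$phy$Nnode)))
  branches <- data.frame(parent = pd$edge[, 1], child = pd$edge[, 2],
                         label = labs[pd$edge[, 2]],
                         tag = pd$tags,
                         t = tlen, omega = omega)
  structure(list(branches = branches, kappa = kappa, lnl = lnl_of(),
                 freqs = freqs),
            class = "mg94_fit")
}

#' @export
print.mg94_fit <- function(x, ...) {
  cat(sprintf("mg94_fit: %d branches, kappa = %.2f, lnL = %.2f\n",
              nrow(x$branches), x$kappa, x$lnl))
  invisible(x)
}

#' Per-branch dN and dS from a per-branch MG94 fit
#'
#' Decomposes each branch's expected substitutions into nonsynonymous
#' and synonymous classes and divides by the corresponding site
#' fractions of the neutral (omega = 1) mutation process, so that
#' dN/dS equals the branch's fitted omega exactly.  Branches whose dS
#' falls below `mask_threshold` are flagged `masked`: at such shallow
#' synonymous divergence the ratio is numerically unreliable, and no
#' ratio is reported for them.
#'
#' @param fit An `mg94_fit` from [fit_mg94_branches()].
#' @param mask_threshold Mask branches with dS below this (default
#'   5e-5).
#' @return data.frame with parent, child, label, t, dN, dS, dnds,
#'   masked.
#' @export
branch_dnds <- function(fit, mask_threshold = 5e-5) {
  stopifnot(inherits(fit, "mg94_fit"))
  fl <- .syn_nonsyn_flux(fit$kappa, fit$freqs)
  A1 <- fl[["A1"]]; S1 <- fl[["S1"]]
  fN <- A1 / (A1 + S1)          # nonsynonymous site fraction, omega = 1
  fS <- S1 / (A1 + S1)
  b <- fit$branches
  en <- b$t * (b$omega * A1) / (b$omega * A1 + S1)  # expected nonsyn subs
  es <- b$t * S1 / (b$omega * A1 + S1)
  dn <- en / fN
  ds <- es / fS
  masked <- ds < mask_threshold
  data.frame(parent = b$parent, child = b$child, label = b$label,
             tag = b$tag, t = b$t, dN = dn, dS = ds,
             dnds = ifelse(masked, NA_real_, dn / ds),
             masked = masked)
}
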