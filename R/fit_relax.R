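# ---------------------------------------------------------------------
# Branch-partitioned relaxation test
#
# Two nested models are fitted to one orthogroup alignment on the
# tagged species tree:
#   null:        shared omega-category mixture, k fixed at 1
#   alternative: test branches evolve under omega_c^k, k free
# 2*(lnL_alt - lnL_null) is referred to chi^2 with 1 df.  k < 1 means
# the omega distribution is compressed toward 1 on the test branches
# (drift-affected); k > 1 means it is spread away from 1
# (selection-dominated).
# ---------------------------------------------------------------------

# objective helpers -----------------------------------------------------

.softmax <- function(y) {
  z <- exp(c(y, 0) - max(c(y, 0)))
  z / sum(z)
}

# theta -> (omega ascending, p) for ncat categories:
# omegas from exponentiated increments, probabilities via softmax.
.decode_mixture <- function(theta, ncat) {
  a <- theta[seq_len(ncat)]
  y <- theta[ncat + seq_len(ncat - 1)]
  if (any(abs(c(a, y)) > 30)) return(NULL)          # guard overflow
  list(omega = cumsum(exp(a)), p = .softmax(y))
}

.encode_mixture <- function(omega, p) {
  a <- log(pmax(diff(c(0, omega)), 1e-8))
  y <- log(pmax(p, 1e-12))
  c(a, y[-length(y)] - y[length(y)])
}

# mixture lnL at fixed branch lengths (scale nuisance multiplies them)
.mixture_lnl <- function(pd, freqs, kappa, omega, p, k, scale) {
  params <- codon_model_params(kappa, omega, p, k, freqs)
  ll <- .mixture_site_loglik(pd, params, scale = scale)
  sum(.logsumexp_cols(ll + log(params$p)) * pd$weights)
}

# Per-pattern, per-category log-likelihoods WITHOUT the mixture-rate
# normalization of the generators: the free branch scale absorbs the
# normalization constant exactly, which makes the category weights
# pure mixture weights (see .profile_weights).
.raw_ll_matrix <- function(pd, freqs, kappa, omega, k, s) {
  ncat <- length(omega)
  nedge <- nrow(pd$edge)
  Qs <- lapply(omega, function(w) .mg94_q(w, kappa, freqs$pos_freqs))
  esys <- matrix(rep(seq_len(ncat), each = nedge), nedge, ncat)
  if (k != 1 && any(pd$tags == "test")) {
    Qs <- c(Qs, lapply(omega^k, function(w)
      .mg94_q(w, kappa, freqs$pos_freqs)))
    te <- pd$tags == "test"
    esys[te, ] <- matrix(rep(ncat + seq_len(ncat), each = sum(te)),
                         sum(te), ncat)
  }
  .class_loglik_cpp(pd$edge, pd$blen * s, esys, Qs, pd$tipstate,
                    freqs$pi, pd$n_node_total)
}

# Profile the mixture weights out of the likelihood by EM on the
# per-category pattern likelihoods (concave in p; monotone updates).
.profile_weights <- function(ll, w, p0 = NULL, max_iter = 500,
                             tol = 1e-8) {
  ncat <- nrow(ll)
  if (ncat == 1L)
    return(list(lnl = sum(ll[1, ] * w), p = 1))
  shift <- ll[1, ]
  for (r in 2:ncat) shift <- pmax(shift, ll[r, ])
  A <- exp(sweep(ll, 2, shift))
  p <- if (is.null(p0) || length(p0) != ncat) rep(1 / ncat, ncat) else p0
  wsum <- sum(w)
  lnl_old <- -Inf
  for (i in seq_len(max_iter)) {
    mix <- colSums(A * p)
    lnl <- sum(w * (log(mix) + shift))
    if (lnl - lnl_old < tol && i > 3) break
    lnl_old <- lnl
    p <- as.vector((A * p) %*% (w / mix)) / wsum
  }
  list(lnl = lnl, p = p)
}

# Hybrid optimizer: Nelder-Mead to get near the optimum cheaply, then
# a quasi-Newton (finite-difference BFGS) polish, whose quadratic
# local convergence removes NM's slow tail.  Convergence is accepted
# when the quasi-Newton stage reports convergence or a short restart
# improves the log-likelihood by no more than `tol`.
.nm_converge <- function(par, obj, maxit = 400, tol = 0.01) {
  fit <- optim(par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
  pol <- tryCatch(
    optim(fit$par, obj, method = "BFGS",
          control = list(maxit = 25, reltol = 1e-9)),
    error = function(e) NULL)
  converged <- FALSE
  if (!is.null(pol) && pol$value <= fit$value + 1e-9) {
    converged <- pol$convergence == 0
    if (pol$value < fit$value) fit <- pol
  }
  if (!converged) {
    nxt <- tryCatch(
      optim(fit$par, obj, method = "Nelder-Mead",
            control = list(maxit = 150, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(nxt)) {
      converged <- fit$value - nxt$value <= tol
      if (nxt$value < fit$value) fit <- nxt
    }
  }
  fit$converged_stable <- converged
  fit
}

# Stage A: single-omega MG94 fit of (branch scale, kappa, omega).
.fit_scale_kappa_omega <- function(pd, freqs) {
  obj <- function(th) {
    if (any(abs(th) > 20)) return(1e10)
    v <- -.mixture_lnl(pd, freqs, exp(th[2]), exp(th[3]), 1, 1, exp(th[1]))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- optim(c(0, log(2), log(0.3)), obj, method = "Nelder-Mead",
               control = list(maxit = 180, reltol = 1e-8))
  list(scale = exp(fit$par[1]), kappa = exp(fit$par[2]),
       omega = exp(fit$par[3]), lnl = -fit$value)
}

#' Fit the branch-partitioned relaxation model to one alignment
#'
#' Fits the null (k = 1) and alternative (k free) omega-mixture models
#' from shared starting values and computes the likelihood-ratio test
#' of relaxation/intensification on the `test` branches.  Branch
#' lengths are taken from the tree up to a fitted global scale
#' (re-optimized under the mixture), and kappa is estimated once under
#' a single-omega fit; the alternative model is started from the null
#' solution with a deterministic k multistart.
#'
#' @param aln A [codon_alignment()] covering the tree leaves.
#' @param tree A [tagged_tree()] with at least one `test` and one
#'   `reference` branch.
#' @param ncat Number of omega categories (default 3).
#' @param k_starts Deterministic multistart values for k.
#' @param maxit Iteration cap for the final joint optimization.
#' @return An object of class `relax_fit` with elements `k_hat`,
#'   `lnl_null`, `lnl_alt`, `lrt`, `p_raw`, `p_corrected` (NA until a
#'   family-wise correction assigns it), `classification`
#'   (`"pending"` or `"failed"`), `converged`, the fitted mixtures,
#'   and bookkeeping fields (`n_test_taxa`, `n_ref_taxa`).
#' @export
fit_relax <- function(aln, tree, ncat = 3, k_starts = c(0.2, 1, 5),
                      maxit = 200) {
  stopifnot(inherits(tree, "tagged_tree"))
  if (!any(tree$tags == "test"))
    stop("tree has no test branches")
  if (!any(tree$tags == "reference"))
    stop("tree has no reference branches")

  ntip <- length(tree$phy$tip.label)
  term <- tree$phy$edge[, 2] <= ntip
  n_test_taxa <- sum(term & tree$tags == "test")
  n_ref_taxa <- sum(term & tree$tags == "reference")

  out <- structure(list(k_hat = NA_real_, lnl_null = NA_real_,
                        lnl_alt = NA_real_, lrt = NA_real_,
                        p_raw = NA_real_, p_corrected = NA_real_,
                        classification = "failed", converged = FALSE,
                        null = NULL, alt = NULL,
                        n_test_taxa = n_test_taxa,
                        n_ref_taxa = n_ref_taxa),
                   class = "relax_fit")

  res <- try({
    pd <- .peel_data(aln, tree)
    freqs <- f3x4_frequencies(aln)
    stage_a <- .fit_scale_kappa_omega(pd, freqs)
    kappa <- stage_a$kappa
    pw_env <- new.env(parent = emptyenv())  # warm start for the EM
    pw_env$p <- NULL

    # stage B parameterization: theta = (log omega increments, log raw
    # branch scale [, log k]); the mixture weights are profiled out by
    # EM on every evaluation (warm-started), so the outer problem has
    # ncat+1 (null) or ncat+2 (alternative) dimensions.
    lnl_profiled <- function(omega, k, s) {
      ll <- .raw_ll_matrix(pd, freqs, kappa, omega, k, s)
      em <- .profile_weights(ll, pd$weights, pw_env$p)
      pw_env$p <- em$p
      em
    }
    obj_at <- function(th, k_free) {
      if (any(abs(th) > 25)) return(1e10)
      omega <- cumsum(exp(th[seq_len(ncat)]))
      s <- exp(th[ncat + 1])
      k <- if (k_free) exp(th[ncat + 2]) else 1
      if (k_free && abs(th[ncat + 2]) > 6) return(1e10)
      v <- -lnl_profiled(omega, k, s)$lnl
      if (!is.finite(v)) 1e10 else v
    }
    nulobj <- function(th) obj_at(th, FALSE)
    altobj <- function(th) obj_at(th, TRUE)

    omega0 <- pmax(stage_a$omega, 1e-3) * c(0.25, 1, 2.5)[seq_len(ncat)]
    if (ncat != 3)
      omega0 <- pmax(stage_a$omega, 1e-3) *
        exp(seq(-1.2, 1, length.out = ncat))
    rho_a <- .q_rate(.mg94_q(stage_a$omega, kappa, freqs$pos_freqs),
                     freqs$pi)
    s0 <- stage_a$scale / rho_a
    th0 <- c(log(pmax(diff(c(0, omega0)), 1e-8)), log(s0))
    fit0 <- .nm_converge(th0, nulobj, maxit = maxit)

    # deterministic k multistart: score the probe points, refine the
    # best bracket in 1-D, then optimize jointly from there
    base <- fit0$par
    probe_val <- vapply(k_starts, function(ks)
      altobj(c(base, log(ks))), 0)
    ibest <- order(probe_val)[1]
    lo <- max(log(min(k_starts)) - 1.7, log(0.02))
    hi <- min(log(max(k_starts)) + 1.7, log(50))
    kb <- optimize(function(z) altobj(c(base, z)), c(lo, hi), tol = 0.02)
    start_k <- if (kb$objective < min(probe_val)) kb$minimum
      else log(k_starts[ibest])
    fit1 <- .nm_converge(c(base, start_k), altobj, maxit = maxit)
    # re-polish the null from the alternative's solution so both
    # hypotheses receive symmetric optimization effort
    fit0b <- .nm_converge(fit1$par[seq_len(ncat + 1)], nulobj,
                          maxit = 120)
    if (fit0b$value < fit0$value) fit0 <- fit0b

    lnl_null <- -fit0$value
    em0 <- lnl_profiled(cumsum(exp(fit0$par[seq_len(ncat)])), 1,
                        exp(fit0$par[ncat + 1]))
    lnl_alt <- max(-fit1$value, lnl_null)   # the alternative nests the null
    omega1 <- cumsum(exp(fit1$par[seq_len(ncat)]))
    s1 <- exp(fit1$par[ncat + 1])
    k_hat <- if (-fit1$value >= lnl_null) exp(fit1$par[ncat + 2]) else 1
    em1 <- lnl_profiled(omega1, k_hat, s1)

    lrt <- max(0, 2 * (lnl_alt - lnl_null))
    out$k_hat <- k_hat
    out$lnl_null <- lnl_null
    out$lnl_alt <- lnl_alt
    out$lrt <- lrt
    out$p_raw <- pchisq(lrt, df = 1, lower.tail = FALSE)
    omega_n <- cumsum(exp(fit0$par[seq_len(ncat)]))
    rho_n <- sum(em0$p * vapply(omega_n, function(w)
      .q_rate(.mg94_q(w, kappa, freqs$pos_freqs), freqs$pi), 0))
    rho_1 <- sum(em1$p * vapply(omega1, function(w)
      .q_rate(.mg94_q(w, kappa, freqs$pos_freqs), freqs$pi), 0))
    out$null <- list(kappa = kappa, omega = omega_n, p = em0$p,
                     scale = exp(fit0$par[ncat + 1]) * rho_n)
    out$alt <- list(kappa = kappa, omega = omega1, p = em1$p,
                    k = k_hat, scale = s1 * rho_1)
    out$converged <- is.finite(lnl_alt) && is.finite(lnl_null) &&
      fit1$converged_stable && fit0$converged_stable
    out$classification <- if (out$converged) "pending" else "failed"
    out
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out$classification <- "failed"
    attr(out, "error") <- as.character(res)
    return(out)
  }
  res
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf(
    "relax_fit: k = %.3f, lnL(null) = %.2f, lnL(alt) = %.2f, LRT = %.3f, p = %.3g [%s]\n",
    x$k_hat, x$lnl_null, x$lnl_alt, x$lrt, x$p_raw, x$classification))
  invisible(x)
}

#' Three-way classification of a relaxation test
#'
#' An orthogroup is `drift-affected` when the corrected p-value passes
#' the significance cutoff and the fitted k is below 1 (the omega
#' distribution is compressed toward neutrality on the test branches),
#' `selection-dominated` when significant with k above 1, and
#' `not-significant` otherwise.  Fits flagged as non-converged are
#' `failed` and take no label.
#'
#' @param fit A `relax_fit`, or a numeric k estimate.
#' @param p_corrected Multiplicity-corrected p-value for this fit.
#' @param alpha Significance cutoff (default 0.1); significance is
#'   `p_corrected <= alpha`.
#' @return One of `"drift-affected"`, `"selection-dominated"`,
#'   `"not-significant"`, `"failed"`.
#' @export
classify_relax <- function(fit, p_corrected, alpha = 0.1) {
  k <- if (inherits(fit, "relax_fit")) {
    if (!fit$converged) return("failed")
    fit$k_hat
  } else fit
  if (is.na(p_corrected) || is.na(k)) return("failed")
  if (p_corrected <= alpha && k < 1) "drift-affected"
  else if (p_corrected <= alpha && k > 1) "selection-dominated"
  else "not-significant"
}
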