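# Shared fixtures and independent oracles for the test suite.

default_freqs <- function() {
  pf <- matrix(c(0.30, 0.18, 0.26, 0.26,
                 0.29, 0.21, 0.19, 0.31,
                 0.27, 0.20, 0.22, 0.31), 3, 4, byrow = TRUE)
  f3x4_from_pos_freqs(pf / rowSums(pf))
}

default_params <- function(k = 1, ncat = 3) {
  omega <- c(0.08, 0.45, 1.3)[seq_len(ncat)]
  p <- c(0.5, 0.3, 0.2)[seq_len(ncat)]
  codon_model_params(kappa = 2.5, omega = omega, p = p / sum(p), k = k,
                     freqs = default_freqs())
}

random_codon_aln <- function(taxa, n_codons, seed = 1) {
  set.seed(seed)
  codons <- genetic_code()$codons
  codon_alignment(setNames(
    vapply(seq_along(taxa), function(i)
      paste(sample(codons, n_codons, TRUE), collapse = ""), ""),
    taxa))
}

# --- brute-force likelihood oracle -----------------------------------
# Sums the joint probability over ALL internal-node codon states; the
# transition matrices come from Matrix::expm, independent of the
# eigendecomposition route used by the pruning engine.
oracle_loglik <- function(aln, tree, params) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  root <- ntip + 1L
  states <- relaxscan:::codon_states(aln)[phy$tip.label, , drop = FALSE]
  pi <- params$freqs$pi
  rho <- relaxscan:::.mixture_rate(params)
  Pmat <- function(omega, t) {
    Q <- relaxscan:::.mg94_q(omega, params$kappa, params$freqs$pos_freqs) /
      rho
    as.matrix(Matrix::expm(Q * t))
  }
  ncat <- length(params$omega)
  combos <- as.matrix(expand.grid(rep(list(1:61), nint)))
  total <- numeric(ncol(states))
  for (c in seq_len(ncat)) {
    eP <- lapply(seq_len(nrow(phy$edge)), function(e) {
      om <- if (tree$tags[e] == "test") params$omega[c]^params$k
        else params$omega[c]
      Pmat(om, phy$edge.length[e])
    })
    for (s in seq_len(ncol(states))) {
      pr <- pi[combos[, root - ntip]]
      for (e in seq_len(nrow(phy$edge))) {
        u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
        su <- combos[, u - ntip]
        sv <- if (v <= ntip) rep(states[v, s], nrow(combos))
          else combos[, v - ntip]
        pr <- pr * eP[[e]][cbind(su, sv)]
      }
      total[s] <- total[s] + params$p[c] * sum(pr)
    }
  }
  sum(log(total))
}

# --- two-sided binomial oracle ---------------------------------------
# Plain enumeration with the minimum-likelihood convention.
oracle_binom <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# --- Dollo loss-count oracle -----------------------------------------
# Brute force over all subsets of edges carrying a loss: a leaf is
# absent iff some edge on its root path is in the subset.
oracle_dollo <- function(presence, phy) {
  tips <- phy$tip.label
  ntip <- length(tips)
  nedge <- nrow(phy$edge)
  path_edges <- lapply(seq_len(ntip), function(tip) {
    e <- integer(0)
    node <- tip
    while (TRUE) {
      row <- which(phy$edge[, 2] == node)
      if (!length(row)) break
      e <- c(e, row)
      node <- phy$edge[row, 1]
    }
    e
  })
  target <- !presence[tips]
  best <- Inf
  for (mask in 0:(2^nedge - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(nedge) - 1)) > 0)
    if (length(S) >= best) next
    absent <- vapply(path_edges, function(pe) any(pe %in% S), TRUE)
    if (all(absent == target)) best <- length(S)
  }
  best
}

# --- minimum vertex cover oracle -------------------------------------
oracle_min_cover <- function(pairs, nv) {
  if (nrow(pairs) == 0) return(0L)
  best <- nv
  for (mask in 0:(2^nv - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(nv) - 1)) > 0)
    if (length(S) >= best) next
    if (all(pairs[, 1] %in% S | pairs[, 2] %in% S)) best <- length(S)
  }
  best
}

# --- exact Mann-Whitney oracle (two-sided, no ties) ------------------
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  u_of <- function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# small tagged tree builders
tree3 <- function() read_tagged_newick("((A:0.2,B:0.3){test}:0.1,C:0.4);")
tree4_bal <- function()
  read_tagged_newick("((A:0.2,B:0.3){test}:0.15,(C:0.25,D:0.1):0.2);")
tree4_cat <- function()
  read_tagged_newick("(((A:0.2,B{test}:0.3):0.1,C:0.25):0.15,D:0.4);")
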