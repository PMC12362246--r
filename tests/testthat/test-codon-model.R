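test_that("MG94 rate matrix has generator structure and detailed balance", {
  par <- default_params()
  Q <- build_rate_matrix(par, 0.6)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  pi <- attr(Q, "pi")
  # reversibility: pi_i q_ij == pi_j q_ji
  F <- Q * pi
  expect_lt(max(abs(F - t(F))), 1e-14)

  # omega = 0 kills every nonsynonymous exchange
  Q0 <- build_rate_matrix(par, 0)
  code <- genetic_code()
  pr <- code$pairs
  expect_true(all(Q0[cbind(pr$i[pr$nonsyn], pr$j[pr$nonsyn])] == 0))
  expect_true(any(Q0[cbind(pr$i[!pr$nonsyn], pr$j[!pr$nonsyn])] > 0))

  # multi-nucleotide exchanges are forbidden
  allowed <- matrix(FALSE, 61, 61)
  allowed[cbind(pr$i, pr$j)] <- TRUE
  diag(allowed) <- TRUE
  expect_true(all(Q[!allowed] == 0))

  # the scaling convention: the reference mixture makes one expected
  # substitution per codon per unit branch length
  rate <- sum(par$p * vapply(par$omega, function(w)
    -sum(pi * diag(build_rate_matrix(par, w))), 0))
  expect_equal(rate, 1, tolerance = 1e-12)

  expect_error(build_rate_matrix(par, -0.1), ">= 0")
})

test_that("transition probabilities are stochastic and form a semigroup", {
  par <- default_params()
  Q <- build_rate_matrix(par, 0.4)
  expect_equal(transition_probabilities(Q, 0), diag(61),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (t in c(0.01, 1, 10)) {
    P <- transition_probabilities(Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
  }
  P1 <- transition_probabilities(Q, 0.7)
  P2 <- transition_probabilities(Q, 1.4)
  expect_lt(max(abs(P2 - P1 %*% P1)), 1e-8)
  expect_error(transition_probabilities(Q, -1), ">= 0")
})

test_that("pruning equals brute-force enumeration on small trees", {
  par <- default_params(k = 0.5)
  for (build in list(tree3, tree4_bal, tree4_cat)) {
    tre <- build()
    n_cod <- if (length(tre$phy$tip.label) == 3) 8 else 4
    aln <- random_codon_aln(tre$phy$tip.label, n_cod,
                            seed = n_cod)
    ll <- as.numeric(log_likelihood(aln, tre, par))
    expect_equal(ll, oracle_loglik(aln, tre, par), tolerance = 1e-8)
  }
})

test_that("identical taxa joined by zero-length branches give sum log pi", {
  par <- default_params()
  seqs <- paste(rep("ATGTTTAAA", 1), collapse = "")
  aln <- codon_alignment(c(A = seqs, B = seqs))
  tre <- read_tagged_newick("(A:0,B:0);")
  pi <- par$freqs$pi
  cods <- c("ATG", "TTT", "AAA")
  expect_equal(as.numeric(log_likelihood(aln, tre, par)),
               sum(log(pi[cods])), tolerance = 1e-10)
})

test_that("k = 1 collapses the test/reference partition", {
  par1 <- default_params(k = 1)
  tre_tagged <- tree4_bal()
  tre_plain <- tagged_tree(tre_tagged$phy)   # all reference
  aln <- random_codon_aln(tre_tagged$phy$tip.label, 20, seed = 3)
  expect_equal(as.numeric(log_likelihood(aln, tre_tagged, par1)),
               as.numeric(log_likelihood(aln, tre_plain, par1)),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to taxon order and root placement", {
  par <- default_params()
  phy <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.25,D:0.15):0.2);")
  aln <- random_codon_aln(c("A", "B", "C", "D"), 30, seed = 9)
  ll1 <- as.numeric(log_likelihood(aln, tagged_tree(phy), par))

  aln_perm <- codon_alignment(aln$sequences[c("D", "B", "A", "C")])
  expect_equal(as.numeric(log_likelihood(aln_perm, tagged_tree(phy), par)),
               ll1, tolerance = 1e-12)

  re <- ape::root(phy, outgroup = "C", resolve.root = TRUE)
  ll2 <- as.numeric(log_likelihood(aln, tagged_tree(re), par))
  expect_equal(ll2, ll1, tolerance = 1e-8)
})

test_that("gap codons act as missing data, not dropped columns", {
  par <- default_params()
  tre <- tree3()
  aln <- random_codon_aln(c("A", "B", "C"), 10, seed = 4)
  seqs <- aln$sequences
  # first codon of C masked: its tip contributes a vector of ones
  substr(seqs[["C"]], 1, 3) <- "---"
  ll_missing <- as.numeric(log_likelihood(codon_alignment(seqs), tre, par))
  # equivalent: site 1 likelihood computed on the tree pruned to A, B
  pat1 <- codon_alignment(vapply(aln$sequences[c("A", "B")],
                                 substr, "", 1, 3))
  rest <- codon_alignment(vapply(aln$sequences, substring, "", 4))
  sub <- prune_for_orthogroup(tagged_tree(tre$phy), c("A", "B"))
  expect_equal(ll_missing,
               as.numeric(log_likelihood(pat1, sub, par)) +
                 as.numeric(log_likelihood(rest, tre, par)),
               tolerance = 1e-8)
})

test_that("per-branch dN/dS reproduces omega and masks tiny dS", {
  aln <- random_codon_aln(c("A", "B", "C"), 40, seed = 12)
  fit <- fit_mg94_branches(aln, tree3()$phy, passes = 1)
  rates <- branch_dnds(fit)
  ok <- !rates$masked
  expect_true(any(ok))
  expect_equal(rates$dnds[ok], fit$branches$omega[ok], tolerance = 1e-9)

  # hand-built fit: neutral branch has dN/dS exactly 1; dS below the
  # mask threshold is flagged
  fake <- fit
  fake$branches$omega <- c(1, 1, 0.5, 0.5)
  fake$branches$t <- c(0.5, 1e-6, 0.5, 1e-6)
  r2 <- branch_dnds(fake, mask_threshold = 5e-5)
  expect_equal(r2$dnds[1], 1, tolerance = 1e-9)
  expect_true(r2$masked[2])
  expect_true(is.na(r2$dnds[2]))
  expect_false(r2$masked[1])
})

test_that("F3x4 frequencies are a valid simplex honoring stop exclusion", {
  aln <- random_codon_aln(c("A", "B"), 50, seed = 5)
  fr <- f3x4_frequencies(aln)
  expect_equal(sum(fr$pi), 1, tolerance = 1e-12)
  expect_equal(length(fr$pi), 61L)
  expect_true(all(fr$pi > 0))
  expect_equal(rowSums(fr$pos_freqs), rep(1, 3), ignore_attr = TRUE)
})
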