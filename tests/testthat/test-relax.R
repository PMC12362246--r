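test_that("relaxation fit recovers a planted k and respects nesting", {
  cfg <- sim_config(n_ingroup = 4, n_outgroup = 4, ingroup_scale = 0.5,
                    seed = 7)
  phy <- simulate_tree(cfg)
  tre <- label_branches(phy, ingroup_taxa(phy))
  par <- default_params(k = 0.2)
  aln <- simulate_codon_alignment(tre, par, 400, seed = 77)
  fit <- fit_relax(aln, tre)
  expect_true(fit$converged)
  expect_gte(fit$lnl_alt, fit$lnl_null - 1e-6)
  expect_gte(fit$lrt, 0)
  expect_lt(fit$k_hat, 1)
  expect_lt(fit$p_raw, 0.05)
})

test_that("tag placement among isomorphic branch sets leaves lnL unchanged", {
  # mirror-symmetric tree with identical data on both cherries: tagging
  # either cherry as test must give the same likelihood
  par <- default_params(k = 0.4)
  s1 <- random_codon_aln(c("A", "B"), 25, seed = 5)$sequences
  aln <- codon_alignment(c(A = s1[["A"]], B = s1[["B"]],
                           C = s1[["A"]], D = s1[["B"]]))
  t_left <- read_tagged_newick(
    "((A{test}:0.2,B{test}:0.3){test}:0.1,(C:0.2,D:0.3):0.1);")
  t_right <- read_tagged_newick(
    "((A:0.2,B:0.3):0.1,(C{test}:0.2,D{test}:0.3){test}:0.1);")
  expect_equal(as.numeric(log_likelihood(aln, t_left, par)),
               as.numeric(log_likelihood(aln, t_right, par)),
               tolerance = 1e-6)
})

test_that("fit_relax rejects trees without a test or reference partition", {
  aln <- random_codon_aln(c("A", "B", "C"), 10, seed = 1)
  plain <- tagged_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  expect_error(fit_relax(aln, plain), "no test branches")
})

test_that("three-way classification follows the corrected-p / k rule", {
  expect_equal(classify_relax(0.4, 0.05, alpha = 0.1), "drift-affected")
  expect_equal(classify_relax(2.0, 0.02, alpha = 0.1),
               "selection-dominated")
  expect_equal(classify_relax(0.4, 0.5, alpha = 0.1), "not-significant")
  # boundary: significance is p <= alpha
  expect_equal(classify_relax(0.4, 0.1, alpha = 0.1), "drift-affected")
  expect_equal(classify_relax(1.7, 0.30, alpha = 0.1), "not-significant")
  expect_equal(classify_relax(NA_real_, NA_real_), "failed")
})

test_that("single-category mixtures collapse to the plain codon model", {
  par1 <- codon_model_params(2.5, omega = 0.4, p = 1, k = 1,
                             freqs = default_freqs())
  tre <- tree3()
  aln <- random_codon_aln(tre$phy$tip.label, 15, seed = 8)
  pd <- relaxscan:::.peel_data(aln, tre)
  direct <- as.numeric(log_likelihood(aln, tre, par1))
  via_mix <- relaxscan:::.mixture_lnl(pd, par1$freqs, 2.5, 0.4, 1, 1, 1)
  expect_equal(via_mix, direct, tolerance = 1e-10)
  # and the raw (unnormalized) parameterization differs only by the
  # absorbed rate constant
  rho <- relaxscan:::.q_rate(
    relaxscan:::.mg94_q(0.4, 2.5, par1$freqs$pos_freqs), par1$freqs$pi)
  raw <- relaxscan:::.raw_ll_matrix(pd, par1$freqs, 2.5, 0.4, 1, 1 / rho)
  expect_equal(sum(raw[1, ] * pd$weights), direct, tolerance = 1e-8)
})

test_that("profiled mixture weights maximize the weight likelihood", {
  set.seed(2)
  ll <- matrix(log(matrix(runif(3 * 40, 0.1, 1), 3)), 3)
  w <- rep(1, 40)
  em <- relaxscan:::.profile_weights(ll, w)
  expect_equal(sum(em$p), 1, tolerance = 1e-12)
  lnl_at <- function(p) sum(w * log(colSums(exp(ll) * p)))
  expect_equal(em$lnl, lnl_at(em$p), tolerance = 1e-9)
  for (i in 1:20) {
    p_try <- as.vector(stats::rgamma(3, 1)); p_try <- p_try / sum(p_try)
    expect_lte(lnl_at(p_try), em$lnl + 1e-6)
  }
})
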