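test_that("simulated trees have a short-branched monophyletic ingroup", {
  cfg <- sim_config(seed = 9)
  phy <- simulate_tree(cfg)
  expect_equal(length(phy$tip.label), 20L)
  expect_true(ape::is.monophyletic(phy, ingroup_taxa(cfg)))
  expect_true(ape::is.rooted(phy))
  # determinism
  expect_identical(ape::write.tree(simulate_tree(cfg)),
                   ape::write.tree(phy))
  # ingroup branches shorter than outgroup on average
  tr <- label_branches(phy, ingroup_taxa(cfg))
  expect_lt(mean(tr$phy$edge.length[tr$tags == "test"]),
            mean(tr$phy$edge.length[tr$tags == "reference"]) * 0.6)
})

test_that("codon simulation follows the model it claims to follow", {
  par <- default_params()
  # zero branch lengths: all sequences identical to the root draw
  tre0 <- read_tagged_newick("((A:0,B:0):0,C:0);")
  a0 <- simulate_codon_alignment(tre0, par, 50, seed = 2)
  expect_equal(length(unique(a0$sequences)), 1L)

  # stationarity: codon frequencies over many sites match pi
  tre1 <- read_tagged_newick("(A:0.05,B:0.05);")
  a1 <- simulate_codon_alignment(tre1, par, 8000, seed = 5)
  states <- relaxscan:::codon_states(a1)
  pi <- par$freqs$pi
  obs <- tabulate(states, 61) / length(states)
  se <- sqrt(pi * (1 - pi) / length(states))
  expect_true(all(abs(obs - pi) < 4 * se + 1e-4))

  # saturation: at long branches pairwise identity approaches sum(pi^2);
  # the closed-form expectation sum_c p_c sum_i pi_i P_ii(2t) is the
  # oracle for the simulated value
  tre2 <- read_tagged_newick("(A:40,B:40);")
  a2 <- simulate_codon_alignment(tre2, par, 2000, seed = 6)
  st <- relaxscan:::codon_states(a2)
  ident <- mean(st[1, ] == st[2, ])
  theo <- sum(vapply(seq_along(par$omega), function(c)
    par$p[c] * sum(pi * diag(transition_probabilities(
      build_rate_matrix(par, par$omega[c]), 80))), 0))
  expect_lt(abs(theo - sum(pi^2)), 2e-3)          # saturated to pi
  expect_lt(abs(ident - theo), 3 * sqrt(theo * (1 - theo) / 2000) + 1e-3)

  # determinism under a fixed seed
  expect_identical(simulate_codon_alignment(tre1, par, 30, seed = 7),
                   simulate_codon_alignment(tre1, par, 30, seed = 7))
})

test_that("simulated genome tables satisfy the table invariants", {
  cfg <- sim_config(seed = 27)
  tabs <- simulate_genome_tables(cfg)
  loci <- tabs$loci
  expect_false(anyDuplicated(loci[c("genome", "locus")]) > 0)
  expect_true(all(loci$status %in% c("intact", "pseudogene")))
  expect_true(all(loci$length_bp > 0))
  # pseudogenes enter orthogroups only via hit assignment
  expect_true(all(is.na(loci$orthogroup[loci$status == "pseudogene"])))
  # every hit subject is a known intact locus
  expect_true(all(tabs$hits$subject %in%
                    loci$locus[loci$status == "intact"]))
  # byte-identical regeneration
  tabs2 <- simulate_genome_tables(cfg)
  expect_identical(tabs, tabs2)
  # the tables pass straight through the io layer
  f <- withr::local_tempfile()
  write_tsv(loci, f)
  expect_equal(nrow(read_locus_table(f)), nrow(loci))

  # ingroup pseudogene excess: ingroup genomes dominate pseudogene counts
  for (s in 1:8) {
    tt <- simulate_genome_tables(sim_config(seed = 100 + s))
    cnt <- table(factor(tt$loci$genome[tt$loci$status == "pseudogene"],
                        levels = tt$genomes$genome))
    ing <- grepl("^ING", names(cnt))
    expect_gt(mean(cnt[ing]), mean(cnt[!ing]))
  }
})

test_that("the full synthetic dataset is internally consistent", {
  cfg <- sim_config(n_ingroup = 4, n_outgroup = 6, n_orthogroups = 8,
                    codons_per_og = 60, seed = 33)
  dat <- simulate_dataset(cfg)
  expect_s3_class(dat$tree, "tagged_tree")
  for (og in names(dat$alignments)) {
    a <- dat$alignments[[og]]
    expect_true(all(a$taxa %in% dat$tree$phy$tip.label))
    # alignment taxa are exactly the single-intact-copy genomes
    sub <- dat$tables$loci[
      !is.na(dat$tables$loci$orthogroup) &
        dat$tables$loci$orthogroup == og &
        dat$tables$loci$status == "intact", ]
    single <- names(which(table(sub$genome) == 1))
    expect_setequal(a$taxa, single)
  }
  expect_true(all(lengths(dat$truth$k_ingroup) > 0))
})
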