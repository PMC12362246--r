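test_that("two-sided binomial test follows the minimum-likelihood rule", {
  expect_equal(binomial_two_sided(5, 10, 0.5), 1, tolerance = 1e-12)
  expect_equal(binomial_two_sided(0, 3, 0.5), 0.25, tolerance = 1e-12)
  # independent route: the classical exact test
  for (cse in list(c(3, 20, 0.3), c(0, 7, 0.2), c(12, 15, 0.5),
                   c(2, 30, 0.2), c(9, 12, 0.665))) {
    expect_equal(binomial_two_sided(cse[1], cse[2], cse[3]),
                 binom.test(cse[1], cse[2], cse[3])$p.value,
                 tolerance = 1e-12)
  }
  expect_error(binomial_two_sided(5, 4, 0.5), "k <= n")
  expect_error(binomial_two_sided(1, 4, 0), "p0")
})

test_that("two-sided binomial equals enumeration for small n", {
  for (p0 in c(0.1, 0.5, 0.665))
    for (n in 1:12)
      for (k in 0:n)
        expect_equal(binomial_two_sided(k, n, p0), oracle_binom(k, n, p0),
                     tolerance = 1e-12,
                     info = sprintf("k=%d n=%d p0=%g", k, n, p0))
})

test_that("Benjamini-Hochberg adjustment is a correct step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  p <- c(0.002, 0.9, 0.04, 0.3, 0.011)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(length(p))
  expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("category enrichment uses the empirical null correctly", {
  # single category spanning the whole table: k/n == p0 by construction
  res <- data.frame(orthogroup = sprintf("OG%02d", 1:40),
                    positive = rep(c(TRUE, FALSE), c(10, 30)))
  cats <- data.frame(orthogroup = res$orthogroup, category = "all")
  e <- enrich_categories(res, cats)
  expect_equal(e$p_raw, 1, tolerance = 1e-12)
  expect_equal(e$p0, 0.25)

  # empirical p0 recomputed after filtering: no stale totals
  filt <- res[1:20, ]  # 10/20 positive now
  e2 <- enrich_categories(filt, cats)
  expect_equal(e2$p0, 0.5)
  expect_equal(e2$n, 20L)

  # a category with no analyzed orthogroup is skipped
  cats2 <- rbind(cats, data.frame(orthogroup = "OG_unseen",
                                  category = "ghost"))
  expect_false("ghost" %in% enrich_categories(res, cats2)$category)
})

test_that("a planted category at 3x the base rate ranks first", {
  set.seed(101)
  p0 <- 0.1
  n_bg <- 540; n_pl <- 60
  ogs <- sprintf("OG%03d", seq_len(n_bg + n_pl))
  planted <- ogs[1:n_pl]
  pos <- c(runif(n_pl) < 3 * p0, runif(n_bg) < p0)
  res <- data.frame(orthogroup = ogs, positive = pos)
  cats <- rbind(
    data.frame(orthogroup = planted, category = "planted"),
    do.call(rbind, lapply(1:9, function(i)
      data.frame(orthogroup = sample(ogs[-(1:n_pl)], 60),
                 category = paste0("bg", i)))))
  e <- enrich_categories(res, cats, p0 = p0)
  expect_equal(e$category[1], "planted")
  expect_lt(e$p_adjusted[1], 0.1)
  expect_equal(e$direction[1], "over")

  # categories at exactly the null rate are never significant
  res_null <- data.frame(orthogroup = ogs,
                         positive = rep(c(TRUE, FALSE),
                                        c(60, n_bg + n_pl - 60)))
  cats_null <- do.call(rbind, lapply(1:8, function(i)
    data.frame(orthogroup = ogs[((i - 1) * 70 + 1):(i * 70)][1:60],
               category = paste0("c", i))))
  # build each category with exactly 6/60 positives
  cats_null <- do.call(rbind, lapply(1:8, function(i) {
    members <- c(ogs[((i - 1) * 7 + 1):((i - 1) * 7 + 6)],     # positives
                 ogs[(60 + (i - 1) * 54 + 1):(60 + i * 54)])   # negatives
    data.frame(orthogroup = members, category = paste0("c", i))
  }))
  e0 <- enrich_categories(res_null, cats_null, p0 = 0.1)
  expect_true(all(e0$p_adjusted > 0.1))
})

test_that("pseudogene enrichment input applies both filters", {
  loci <- do.call(rbind, lapply(sprintf("OG%d", 1:3), function(og) {
    genomes <- paste0("g", 1:7)
    data.frame(genome = genomes, locus = paste0(og, "_", genomes),
               orthogroup = og, status = "intact", length_bp = 900,
               gene_name = NA_character_, ko = NA_character_,
               pathways = if (og == "OG3") "" else "p1")
  }))
  loci$status[loci$orthogroup == "OG1" & loci$genome == "g1"] <- "pseudogene"
  # OG2 present in too few genomes
  loci <- loci[!(loci$orthogroup == "OG2" & loci$genome %in%
                   paste0("g", 4:7)), ]
  tab <- propagate_annotations(loci)
  inp <- pseudogene_enrichment_input(tab, ingroup = c("g1", "g2"),
                                     min_genomes = 6)
  expect_equal(inp$orthogroup, "OG1")   # OG2 too sparse, OG3 unannotated
  expect_true(inp$positive[1])
})
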