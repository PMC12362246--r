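make_loci <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(genome = r[[1]], locus = r[[2]], orthogroup = r[[3]],
               status = r[[4]], length_bp = 900,
               gene_name = if (length(r) > 4) r[[5]] else NA_character_,
               ko = NA_character_,
               pathways = if (length(r) > 5) r[[6]] else "")
  }))
}

test_that("annotation propagation is inclusive, conflict-aware, idempotent", {
  loci <- make_loci(
    list("g1", "l1", "OG1", "intact", "geneA", "p1"),
    list("g2", "l2", "OG1", "intact", NA, ""),
    list("g1", "l3", "OG2", "intact", "geneA", ""),
    list("g2", "l4", "OG2", "intact", "geneB", "p2"),
    list("g1", "l5", "OG3", "intact", NA, ""))
  tab <- propagate_annotations(loci)
  ann <- tab$annotations
  expect_equal(ann$gene_names[ann$orthogroup == "OG1"], "geneA")
  expect_false(ann$conflict[ann$orthogroup == "OG1"])
  expect_equal(ann$gene_names[ann$orthogroup == "OG2"], "geneA;geneB")
  expect_true(ann$conflict[ann$orthogroup == "OG2"])
  expect_equal(ann$gene_names[ann$orthogroup == "OG3"], "")
  expect_false(ann$conflict[ann$orthogroup == "OG3"])

  # idempotence: pushing propagated annotations back onto the loci and
  # re-propagating changes nothing
  loci2 <- loci
  loci2$gene_name <- NA_character_
  idx <- match(loci$orthogroup, ann$orthogroup)
  loci2$pathways <- ann$pathways[idx]
  first <- propagate_annotations(loci2)
  again_loci <- loci2
  again_loci$pathways <- first$annotations$pathways[
    match(loci2$orthogroup, first$annotations$orthogroup)]
  expect_equal(propagate_annotations(again_loci)$annotations,
               first$annotations)
})

test_that("pseudogene assignment follows lowest e-value with tie-breaks", {
  loci <- make_loci(
    list("g1", "s1", "OG1", "intact"),
    list("g1", "s2", "OG2", "intact"),
    list("g2", "s3", "OG3", "intact"))
  hits <- data.frame(
    query = c("q1", "q1", "q2", "q2", "q3", "q3"),
    subject = c("s1", "s2", "s1", "s2", "s2", "s3"),
    evalue = c(1e-50, 1e-10, 1e-20, 1e-20, 1e-30, 1e-30),
    bitscore = c(500, 100, 200, 300, 250, 250))
  asg <- assign_pseudogenes(hits, loci)
  expect_equal(asg$orthogroup[asg$query == "q1"], "OG1")  # lowest e-value
  expect_equal(asg$orthogroup[asg$query == "q2"], "OG2")  # bit-score tie-break
  expect_equal(asg$orthogroup[asg$query == "q3"], "OG2")  # lexicographic
  expect_equal(attr(assign_pseudogenes(hits[0, ], loci), "unassigned"),
               character(0))
  asg2 <- assign_pseudogenes(hits[hits$query != "q3", ], loci)
  expect_false("q3" %in% asg2$query)
})

test_that("core/pan genomes at both levels follow the definitions", {
  # geneA sits on OG1 (intact in g1-g3) and OG2 (intact in g4, g5):
  # neither orthogroup is core over {g1..g5} but geneA is
  loci <- make_loci(
    list("g1", "a1", "OG1", "intact", "geneA"),
    list("g2", "a2", "OG1", "intact", "geneA"),
    list("g3", "a3", "OG1", "intact", NA),
    list("g4", "a4", "OG2", "intact", "geneA"),
    list("g5", "a5", "OG2", "intact", NA),
    list("g4", "a6", "OG1", "pseudogene", NA),
    list("g1", "a7", "OG3", "intact", "geneB"),
    list("g2", "a8", "OG3", "intact", NA),
    list("g3", "a9", "OG3", "intact", NA),
    list("g4", "a10", "OG3", "intact", NA),
    list("g5", "a11", "OG3", "intact", NA))
  tab <- propagate_annotations(loci)
  gset <- paste0("g", 1:5)
  og_cp <- core_pan(tab, gset, level = "orthogroup")
  expect_equal(og_cp$core, "OG3")
  expect_setequal(og_cp$pan, c("OG1", "OG2", "OG3"))
  ann_cp <- core_pan(tab, gset, level = "annotation")
  expect_setequal(ann_cp$core, c("geneA", "geneB"))

  single <- core_pan(tab, "g1", level = "orthogroup")
  expect_equal(single$core, single$pan)
  expect_error(core_pan(tab, character(0)), "empty")
})

test_that("core/pan containment properties hold on a random fixture", {
  set.seed(31)
  rows <- list()
  for (og in sprintf("OG%02d", 1:12)) {
    gn <- if (runif(1) < 0.6) sample(sprintf("gene%02d", 1:6), 1) else NA
    for (g in paste0("g", 1:6))
      if (runif(1) < 0.8)
        rows[[length(rows) + 1]] <- list(g, paste0(og, g), og, "intact", gn)
  }
  tab <- propagate_annotations(do.call(make_loci, rows))
  gset <- paste0("g", 1:6)
  og_cp <- core_pan(tab, gset, "orthogroup")
  an_cp <- core_pan(tab, gset, "annotation")
  expect_true(all(og_cp$core %in% og_cp$pan))
  expect_true(all(an_cp$core %in% an_cp$pan))
  # annotations carried by a core orthogroup are in the annotation core
  ann <- tab$annotations
  core_og_genes <- unlist(relaxscan:::.split_pathways(
    ann$gene_names[ann$orthogroup %in% og_cp$core]))
  expect_true(all(core_og_genes %in% an_cp$core))
  # removing a genome never shrinks the core
  for (drop in gset) {
    cp5 <- core_pan(tab, setdiff(gset, drop), "orthogroup")
    expect_true(all(og_cp$core %in% cp5$core))
  }
})

test_that("relax eligibility drops multicopy genomes then applies 3+3", {
  loci <- do.call(make_loci, c(
    lapply(1:3, function(i) list(paste0("in", i), paste0("ia", i),
                                 "OG1", "intact")),
    list(list("in4", "ib1", "OG1", "intact"),
         list("in4", "ib2", "OG1", "intact")),
    lapply(1:3, function(i) list(paste0("out", i), paste0("oa", i),
                                 "OG1", "intact")),
    lapply(1:2, function(i) list(paste0("in", i), paste0("ic", i),
                                 "OG2", "intact")),
    lapply(1:5, function(i) list(paste0("out", i), paste0("oc", i),
                                 "OG2", "intact"))))
  ing <- paste0("in", 1:4); outg <- paste0("out", 1:5)
  tab <- propagate_annotations(loci)
  el <- relax_eligibility(tab, ing, outg)
  expect_true(el$eligible[el$orthogroup == "OG1"])
  expect_false("in4" %in% attr(el, "taxa")$OG1)  # doubled genome dropped
  expect_false(el$eligible[el$orthogroup == "OG2"])  # only 2 ingroup
  expect_error(relax_eligibility(tab, ing, c("in1", "out1")), "overlap")
})

test_that("single-copy orthogroups require exactly one intact locus everywhere", {
  loci <- make_loci(
    list("g1", "x1", "OG1", "intact"), list("g2", "x2", "OG1", "intact"),
    list("g3", "x3", "OG1", "intact"),
    list("g1", "y1", "OG2", "intact"), list("g3", "y3", "OG2", "intact"),
    list("g1", "z1", "OG3", "intact"), list("g2", "z2", "OG3", "intact"),
    list("g3", "z3", "OG3", "intact"), list("g2", "z4", "OG3", "pseudogene"))
  tab <- propagate_annotations(loci)
  expect_setequal(single_copy_set(tab), c("OG1", "OG3"))
  expect_equal(single_copy_set(tab, character(0)), character(0))
})

test_that("genome statistics and clade tests behave at the edges", {
  gen <- data.frame(genome = paste0("g", 1:8),
                    clade = rep(c("a", "b"), each = 4),
                    length_bp = c(1:4, 1:4) * 1e6,
                    gc = c(0.40, 0.41, 0.42, 0.43, 0.40, 0.41, 0.42, 0.43))
  loci <- do.call(make_loci, lapply(1:8, function(i)
    list(paste0("g", i), paste0("L", i), "OG1", "intact")))
  loci$length_bp <- gen$length_bp / 2000
  res <- genome_statistics(gen, loci, compare_clades = c("a", "b"))
  expect_equal(res$tests$p_value[res$tests$statistic == "gc"], 1)

  # perfectly collinear length vs intact count
  gen2 <- gen
  loci2 <- do.call(rbind, lapply(1:8, function(i) {
    n <- i  # i loci in genome i
    do.call(make_loci, lapply(seq_len(n), function(j)
      list(paste0("g", i), paste0("L", i, "_", j), "OG1", "intact")))
  }))
  gen2$length_bp <- 1e5 * vapply(1:8, function(i) i, 0)
  r2 <- genome_statistics(gen2, loci2)$r2
  expect_equal(r2, 1, tolerance = 1e-12)

  # 4-vs-4 exact Mann-Whitney against the enumeration oracle
  x <- c(0.40, 0.45, 0.47, 0.52); y <- c(0.41, 0.56, 0.58, 0.60)
  gen3 <- data.frame(genome = paste0("g", 1:8),
                     clade = rep(c("a", "b"), each = 4),
                     length_bp = 1e6, gc = c(x, y))
  res3 <- genome_statistics(gen3, loci, compare_clades = c("a", "b"))
  expect_equal(res3$tests$p_value[res3$tests$statistic == "gc"],
               oracle_mann_whitney(x, y), tolerance = 1e-12)
  expect_error(genome_statistics(gen3[c(1, 5:8), ], loci,
                                 compare_clades = c("a", "b")),
               "at least 2")
})
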