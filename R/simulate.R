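# ---------------------------------------------------------------------
# Synthetic data generator
#
# Emulates the derived data of a vertically inherited symbiont study:
# a species tree with a short-branched symbiont ingroup clade nested
# among free-living relatives, per-orthogroup codon alignments evolved
# under an omega mixture with ingroup relaxation k, and the
# locus/annotation/hit tables the genome-accounting steps consume
# (intact/pseudogene/absent statuses with an ingroup pseudogene
# excess, multicopy genes, pathway labels with planted enrichment).
# ---------------------------------------------------------------------

#' Configuration for the synthetic-data generator
#'
#' Defaults are desk-scale study conditions: an 8-genome symbiont
#' ingroup against 12 free-living genomes (split into "sister" and
#' "parent" clades), 60 orthogroups of 300 codons, ingroup relaxation
#' at k = 0.5, and a 10-fold ingroup excess in per-genome pseudogene
#' rates concentrated in a pseudogene-prone subset of orthogroups.
#'
#' @param n_ingroup,n_outgroup Genomes in the symbiont clade and the
#'   free-living set.
#' @param n_orthogroups,codons_per_og Scan size.
#' @param k_ingroup True relaxation coefficient on ingroup branches;
#'   scalar (recycled) or one value per orthogroup.
#' @param kappa Transition/transversion ratio of the simulation model.
#' @param outgroup_brlen Range (min, max) of free-living branch
#'   lengths, in expected substitutions per codon site.
#' @param ingroup_scale Multiplier shrinking ingroup branch lengths
#'   (short symbiont branches).
#' @param stem_length Ingroup stem branch length.
#' @param og_rate_sd Lognormal sd of the per-orthogroup rate
#'   multiplier.
#' @param prone_fraction Fraction of orthogroups able to pseudogenize.
#' @param pseudo_rate_ingroup,pseudo_rate_outgroup Per-genome
#'   pseudogene probability within a prone orthogroup.
#' @param absent_rate_ingroup,absent_rate_outgroup Per-genome absence
#'   probability (prone orthogroups only).
#' @param multicopy_rate Probability a genome carries two loci of an
#'   orthogroup.
#' @param unplaced_rate Fraction of extra loci not placed in any
#'   orthogroup.
#' @param n_pathways Number of background pathway labels.
#' @param pathway_fraction Fraction of orthogroups with a pathway
#'   annotation.
#' @param planted_pathway_size Orthogroups in the planted pathway.
#' @param planted_multiplier Multiplier on pseudogene-proneness inside
#'   the planted pathway (1 = no planting).
#' @param seed Global seed; per-orthogroup child seeds are derived
#'   from it by counter so subsets are independently reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ingroup = 8, n_outgroup = 12,
                       n_orthogroups = 60, codons_per_og = 300,
                       k_ingroup = 0.5, kappa = 2.5,
                       outgroup_brlen = c(0.05, 0.35),
                       ingroup_scale = 0.15, stem_length = 0.2,
                       og_rate_sd = 0.25,
                       prone_fraction = 0.15,
                       pseudo_rate_ingroup = 0.5,
                       pseudo_rate_outgroup = 0.05,
                       absent_rate_ingroup = 0.15,
                       absent_rate_outgroup = 0.03,
                       multicopy_rate = 0.03,
                       unplaced_rate = 0.02,
                       n_pathways = 8, pathway_fraction = 0.5,
                       planted_pathway_size = 14,
                       planted_multiplier = 3,
                       seed = 42) {
  cfg <- as.list(environment())
  stopifnot(n_ingroup >= 3, n_outgroup >= 3, n_orthogroups >= 1,
            codons_per_og >= 1, all(k_ingroup > 0), kappa > 0,
            prone_fraction >= 0, prone_fraction <= 1)
  cfg$k_ingroup <- rep_len(k_ingroup, n_orthogroups)
  structure(cfg, class = "sim_config")
}

# deterministic child seed from a global seed and a counter
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

# position-specific nucleotide frequencies of a moderately AT-rich
# bacterial genome; rows are codon positions, columns A,C,G,T
.default_pos_freqs <- function() {
  m <- matrix(c(0.30, 0.18, 0.26, 0.26,
                0.29, 0.21, 0.19, 0.31,
                0.27, 0.20, 0.22, 0.31), 3, 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m / rowSums(m)
}

.sub_newick <- function(phy) sub(";$", "", ape::write.tree(phy))

#' Simulate the species tree
#'
#' A random rooted tree in which the symbiont ingroup is a
#' monophyletic clade of short branches (lengths scaled by
#' `ingroup_scale`) nested on the "parent" side of the free-living
#' genomes, mirroring the shape of a symbiont/free-living phylogeny.
#'
#' @param cfg A [sim_config()].
#' @return A rooted `ape::phylo`; ingroup leaves are named `ING..`,
#'   free-living leaves `OUTP..` (parent clade) and `OUTS..` (sister
#'   clade).
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 1L))
  rb <- function(n) runif(n, cfg$outgroup_brlen[1], cfg$outgroup_brlen[2])
  n_sis <- max(1L, cfg$n_outgroup %/% 2L)
  n_par <- cfg$n_outgroup - n_sis

  ing <- ape::rtree(cfg$n_ingroup, br = rb,
                    tip.label = sprintf("ING%02d", seq_len(cfg$n_ingroup)))
  ing$edge.length <- ing$edge.length * cfg$ingroup_scale
  sis <- ape::rtree(n_sis, br = rb,
                    tip.label = sprintf("OUTS%02d", seq_len(n_sis)))
  par_ <- if (n_par > 1)
    ape::rtree(n_par, br = rb,
               tip.label = sprintf("OUTP%02d", seq_len(n_par)))
  else NULL

  if (is.null(par_)) {
    nwk <- sprintf("(%s:%.6f,(%s:%.6f,OUTP01:%.6f):%.6f);",
                   .sub_newick(sis), rb(1), .sub_newick(ing),
                   cfg$stem_length, rb(1), rb(1))
  } else {
    nwk <- sprintf("(%s:%.6f,(%s:%.6f,%s:%.6f):%.6f);",
                   .sub_newick(sis), rb(1), .sub_newick(ing),
                   cfg$stem_length, .sub_newick(par_), rb(1), rb(1))
  }
  ape::read.tree(text = nwk)
}

#' Taxa of the simulated ingroup
#' @param tree_or_cfg A [sim_config()] or a simulated tree.
#' @return Character vector of ingroup leaf names.
#' @export
ingroup_taxa <- function(tree_or_cfg) {
  if (inherits(tree_or_cfg, "sim_config"))
    return(sprintf("ING%02d", seq_len(tree_or_cfg$n_ingroup)))
  grep("^ING", if (inherits(tree_or_cfg, "tagged_tree"))
    tree_or_cfg$phy$tip.label else tree_or_cfg$tip.label, value = TRUE)
}

#' Simulate a codon alignment along a tagged tree
#'
#' Forward simulation under the MG94xHKY omega-mixture model: each
#' site draws one omega category, root codons are drawn from the F3x4
#' stationary distribution, and each branch evolves by the transition
#' matrix of its tag's generator (test branches use omega^k) under the
#' shared reference-mixture branch-length scaling.  Stop codons are
#' impossible by construction (they are outside the state space).
#'
#' @param tree A [tagged_tree()].
#' @param params A [codon_model_params()] (its `k` applies on `test`
#'   branches).
#' @param n_codons Alignment length in codons.
#' @param seed Optional seed applied before simulation.
#' @return A [codon_alignment()]; the per-site category draw is
#'   attached as attribute `"site_category"`.
#' @export
simulate_codon_alignment <- function(tree, params, n_codons, seed = NULL) {
  stopifnot(inherits(tree, "tagged_tree"),
            inherits(params, "codon_model_params"))
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::reorder.phylo(tree$phy, "cladewise")  # parents before children
  ord <- match(paste(phy$edge[, 1], phy$edge[, 2]),
               paste(tree$phy$edge[, 1], tree$phy$edge[, 2]))
  tags <- tree$tags[ord]
  pi <- params$freqs$pi
  ncat <- length(params$omega)
  rho <- .mixture_rate(params)
  ntip <- length(phy$tip.label)
  n_nodes <- ntip + phy$Nnode

  eig_ref <- lapply(params$omega, function(w)
    .eig_rev_cpp(.mg94_q(w, params$kappa, params$freqs$pos_freqs) / rho, pi))
  eig_test <- if (params$k != 1)
    lapply(params$omega^params$k, function(w)
      .eig_rev_cpp(.mg94_q(w, params$kappa, params$freqs$pos_freqs) / rho,
                   pi))
  else eig_ref

  cat_of_site <- sample.int(ncat, n_codons, replace = TRUE,
                            prob = params$p)
  states <- matrix(NA_integer_, n_nodes, n_codons)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)

  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    t_e <- phy$edge.length[e]
    esys <- if (tags[e] == "test") eig_test else eig_ref
    for (c in seq_len(ncat)) {
      idx <- which(cat_of_site == c)
      if (!length(idx)) next
      P <- .trans_prob_cpp(esys[[c]]$U, esys[[c]]$lambda, esys[[c]]$V, t_e)
      P <- P / rowSums(P)
      cur <- states[u, idx]
      for (s in unique(cur)) {
        here <- idx[cur == s]
        states[v, here] <- sample.int(61L, length(here), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  codons <- genetic_code()$codons
  seqs <- setNames(vapply(seq_len(ntip), function(i)
    paste(codons[states[i, ]], collapse = ""), ""), phy$tip.label)
  aln <- codon_alignment(seqs)
  attr(aln, "site_category") <- cat_of_site
  aln
}

#' Simulate the derived genome tables
#'
#' Generates the locus table (statuses intact/pseudogene per genome
#' and orthogroup, with multicopy and unplaced loci), the
#' pseudogene-vs-gene hit table, per-genome metadata (length, GC,
#' clade) and annotation labels (gene names, KOs, pathways including a
#' planted pathway whose orthogroups are pseudogene-prone at
#' `planted_multiplier` times the baseline rate).  Planted truths are
#' recorded in the `truth` element.
#'
#' @param cfg A [sim_config()].
#' @param tree Optional simulated tree (defaults to
#'   `simulate_tree(cfg)`); statuses are generated per genome
#'   independently, the tree fixes the genome set.
#' @return List with `loci`, `hits`, `genomes`, `truth`.
#' @export
simulate_genome_tables <- function(cfg, tree = simulate_tree(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 2L))
  genomes <- tree$tip.label
  ing <- grep("^ING", genomes, value = TRUE)
  outg <- setdiff(genomes, ing)
  n_og <- cfg$n_orthogroups
  ogs <- sprintf("OG%04d", seq_len(n_og))

  # pathway labels; the planted pathway goes on a fixed-size block
  pathways <- sprintf("path%02d", seq_len(cfg$n_pathways))
  planted <- "path_planted"
  planted_ogs <- ogs[seq_len(min(cfg$planted_pathway_size, n_og))]
  og_paths <- vector("list", n_og)
  names(og_paths) <- ogs
  for (i in seq_len(n_og)) {
    p <- character(0)
    if (ogs[i] %in% planted_ogs) p <- planted
    if (runif(1) < cfg$pathway_fraction)
      p <- c(p, sample(pathways, sample(1:2, 1)))
    og_paths[[i]] <- p
  }

  # pseudogene-prone orthogroups; proneness is multiplied inside the
  # planted pathway.  Counts are fixed (sampled without replacement)
  # rather than Bernoulli so the planted contrast is realized exactly,
  # not merely in expectation.
  prone <- rep(FALSE, n_og)
  in_planted <- ogs %in% planted_ogs
  n_pl <- sum(in_planted)
  n_bg_prone <- round(cfg$prone_fraction * (n_og - n_pl))
  n_pl_prone <- round(min(1, cfg$prone_fraction * cfg$planted_multiplier) *
                        n_pl)
  if (n_bg_prone > 0)
    prone[sample(which(!in_planted), n_bg_prone)] <- TRUE
  if (n_pl_prone > 0)
    prone[sample(which(in_planted), n_pl_prone)] <- TRUE

  gene_name <- ifelse(runif(n_og) < 0.45, sprintf("gene%03d", seq_len(n_og)),
                      NA_character_)
  ko <- ifelse(runif(n_og) < 0.45, sprintf("K%05d", seq_len(n_og)),
               NA_character_)

  rows <- vector("list", 0L)
  locus_counter <- 0L
  new_locus <- function(genome) {
    locus_counter <<- locus_counter + 1L
    sprintf("%s_L%05d", genome, locus_counter)
  }
  for (g in genomes) {
    is_ing <- g %in% ing
    pr_pseudo <- if (is_ing) cfg$pseudo_rate_ingroup else
      cfg$pseudo_rate_outgroup
    pr_absent <- if (is_ing) cfg$absent_rate_ingroup else
      cfg$absent_rate_outgroup
    for (i in seq_len(n_og)) {
      u <- runif(1)
      status <- "intact"
      if (prone[i]) {
        if (u < pr_absent) next
        if (u < pr_absent + pr_pseudo) status <- "pseudogene"
      }
      n_copies <- if (status == "intact" && runif(1) < cfg$multicopy_rate)
        2L else 1L
      for (cp in seq_len(n_copies)) {
        len <- round(rnorm(1, if (is_ing) 880 else 950, 120))
        if (status == "pseudogene") len <- round(len * runif(1, 0.3, 0.8))
        rows[[length(rows) + 1L]] <- data.frame(
          genome = g, locus = new_locus(g), orthogroup = ogs[i],
          status = status, length_bp = max(150, len),
          gene_name = gene_name[i], ko = ko[i],
          pathways = paste(og_paths[[i]], collapse = ";"))
      }
    }
    # unplaced loci
    n_unpl <- stats::rbinom(1, n_og, cfg$unplaced_rate)
    for (j in seq_len(n_unpl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, locus = new_locus(g), orthogroup = NA_character_,
        status = "intact", length_bp = max(150, round(rnorm(1, 600, 150))),
        gene_name = NA_character_, ko = NA_character_, pathways = "")
    }
  }
  loci <- do.call(rbind, rows)
  rownames(loci) <- NULL
  # pseudogenes carry no annotations of their own; they inherit them
  # only through orthogroup assignment
  ps <- loci$status == "pseudogene"
  loci$gene_name[ps] <- NA_character_
  loci$ko[ps] <- NA_character_
  loci$pathways[ps] <- ""
  # the locus table's orthogroup column reflects the upstream
  # clustering of intact genes; pseudogenes enter orthogroups only via
  # the similarity-hit assignment below
  truth_ps_og <- loci$orthogroup
  loci$orthogroup[ps] <- NA_character_

  # hit table: each pseudogene hits an intact locus of its true
  # orthogroup best, plus 0-2 weaker decoy hits elsewhere
  intact <- loci[loci$status == "intact" & !is.na(loci$orthogroup), ]
  hit_rows <- vector("list", 0L)
  for (r in which(ps)) {
    og <- truth_ps_og[r]
    subjects <- intact$locus[intact$orthogroup == og]
    if (!length(subjects)) next
    ev <- 10^runif(1, -80, -40)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query = loci$locus[r], subject = sample(subjects, 1),
      evalue = ev, bitscore = round(runif(1, 200, 600)))
    for (d in seq_len(sample(0:2, 1))) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query = loci$locus[r], subject = sample(intact$locus, 1),
        evalue = 10^runif(1, -20, -3), bitscore = round(runif(1, 30, 120)))
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(query = character(0), subject = character(0),
               evalue = numeric(0), bitscore = numeric(0))

  # genome length follows coding content through a clade-typical coding
  # density (symbionts lowest), so length and intact-gene count are
  # strongly collinear as in real genome panels
  clade <- ifelse(grepl("^ING", genomes), "symbiont",
                  ifelse(grepl("^OUTS", genomes), "sister", "parent"))
  coding <- vapply(genomes, function(g)
    sum(loci$length_bp[loci$genome == g & loci$status == "intact"]), 0)
  density <- ifelse(clade == "symbiont",
                    runif(length(genomes), 0.78, 0.82),
                    ifelse(clade == "sister",
                           runif(length(genomes), 0.86, 0.90),
                           runif(length(genomes), 0.85, 0.89)))
  gdf <- data.frame(
    genome = genomes, clade = clade,
    length_bp = round(coding / density),
    gc = ifelse(clade == "symbiont", runif(length(genomes), 0.380, 0.388),
                ifelse(clade == "sister", runif(length(genomes), 0.42, 0.46),
                       runif(length(genomes), 0.38, 0.41))))
  rownames(gdf) <- NULL

  truth <- list(prone = setNames(prone, ogs),
                planted_pathway = planted, planted_ogs = planted_ogs,
                og_pathways = og_paths,
                pseudo_rate = c(ingroup = cfg$pseudo_rate_ingroup,
                                outgroup = cfg$pseudo_rate_outgroup))
  list(loci = loci, hits = hits, genomes = gdf, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Tree, genome tables and one codon alignment per orthogroup.
#' Alignments cover the genomes holding exactly one intact locus of
#' the orthogroup and evolve under per-orthogroup omega mixtures with
#' the configured ingroup relaxation `k_ingroup[i]` on the symbiont
#' clade (stem excluded), plus a lognormal per-orthogroup rate
#' multiplier.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (a [tagged_tree()] labeled around the
#'   ingroup), `alignments` (named list of [codon_alignment()]),
#'   `tables` (see [simulate_genome_tables()]) and `truth` (planted
#'   per-orthogroup parameters).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  phy <- simulate_tree(cfg)
  tree <- label_branches(phy, ingroup_taxa(phy))
  tables <- simulate_genome_tables(cfg, phy)
  loci <- tables$loci

  set.seed(.child_seed(cfg$seed, 3L))
  ogs <- sprintf("OG%04d", seq_len(cfg$n_orthogroups))
  og_omega <- lapply(seq_along(ogs), function(i) {
    o1 <- runif(1, 0.02, 0.12)
    o2 <- runif(1, 0.2, 0.5)
    o3 <- runif(1, 0.9, 1.5)
    list(omega = c(o1, o2, o3),
         p = as.vector(stats::rgamma(3, c(5, 3.5, 1.5))))
  })
  og_rate <- rlnorm(length(ogs), 0, cfg$og_rate_sd)
  freqs <- f3x4_from_pos_freqs(.default_pos_freqs())

  alignments <- vector("list", length(ogs))
  names(alignments) <- ogs
  for (i in seq_along(ogs)) {
    tab <- loci[!is.na(loci$orthogroup) & loci$orthogroup == ogs[i] &
                  loci$status == "intact", ]
    cnt <- table(tab$genome)
    taxa <- names(cnt)[cnt == 1L]
    if (length(taxa) < 4L ||
        length(intersect(taxa, ingroup_taxa(phy))) < 2L ||
        length(setdiff(taxa, ingroup_taxa(phy))) < 2L)
      next
    sub <- prune_for_orthogroup(tree, taxa)
    sub$phy$edge.length <- sub$phy$edge.length * og_rate[i]
    p <- og_omega[[i]]$p / sum(og_omega[[i]]$p)
    params <- codon_model_params(cfg$kappa, og_omega[[i]]$omega, p,
                                 k = cfg$k_ingroup[i], freqs = freqs)
    alignments[[i]] <- simulate_codon_alignment(
      sub, params, cfg$codons_per_og, seed = .child_seed(cfg$seed, 100L + i))
  }
  alignments <- alignments[!vapply(alignments, is.null, TRUE)]

  truth <- tables$truth
  truth$k_ingroup <- setNames(cfg$k_ingroup, ogs)
  truth$og_rate <- setNames(og_rate, ogs)
  truth$og_omega <- setNames(og_omega, ogs)
  list(tree = tree, alignments = alignments, tables = tables,
       truth = truth)
}
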