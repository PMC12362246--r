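# ---------------------------------------------------------------------
# Pipeline orchestration
# ---------------------------------------------------------------------

#' Pipeline configuration
#'
#' Gathers the constants of the analysis: the significance cutoff for
#' the corrected per-orthogroup p-value (0.1), the minimum number of
#' single-copy ingroup and outgroup genomes for an orthogroup to be
#' testable (3 each), the dS threshold below which per-branch dN/dS is
#' masked as unreliable (5e-5), the pairwise-dS threshold used when
#' subsampling the genome set (0.01), and the omega-category count.
#'
#' @param ingroup,outgroup Disjoint taxon sets.
#' @param alpha Corrected-p significance cutoff.
#' @param min_ingroup,min_outgroup Eligibility thresholds.
#' @param ds_mask dS mask threshold for per-branch rates.
#' @param ds_subsample Pairwise dS threshold for subsampling.
#' @param ncat Omega categories in the mixture.
#' @param seed Seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ingroup, outgroup = character(0), alpha = 0.1,
                            min_ingroup = 3, min_outgroup = 3,
                            ds_mask = 5e-5, ds_subsample = 0.01,
                            ncat = 3, seed = 1) {
  stopifnot(alpha > 0, min_ingroup > 0, min_outgroup > 0, ds_mask > 0,
            ds_subsample > 0, ncat >= 1)
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup overlap")
  structure(list(ingroup = ingroup, outgroup = outgroup, alpha = alpha,
                 min_ingroup = min_ingroup, min_outgroup = min_outgroup,
                 ds_mask = ds_mask, ds_subsample = ds_subsample,
                 ncat = ncat, seed = seed),
            class = "pipeline_config")
}

#' Run the per-orthogroup relaxation scan
#'
#' Applies the eligibility filter, prunes the species tree to each
#' orthogroup's single-copy genomes, fits the relaxation test per
#' orthogroup, corrects the raw p-values across the converged fits
#' with Benjamini-Hochberg, and classifies.  Non-converged fits are
#' recorded as `failed` and excluded from the correction family.
#'
#' @param alignments Named list of [codon_alignment()] (names are
#'   orthogroup ids).
#' @param tree A [tagged_tree()] labeled around the config's ingroup.
#' @param table An `orthogroup_table` used for eligibility; `NULL`
#'   skips the table-based filter and tests every alignment with
#'   enough ingroup/outgroup taxa.
#' @param config A [pipeline_config()].
#' @return data.frame of class `relax_scan`: orthogroup, n_test_taxa,
#'   n_ref_taxa, k_hat, lnl_null, lnl_alt, lrt, p_raw, p_corrected,
#'   classification; the summary percentages are attached as attribute
#'   `"summary"` and the per-orthogroup disposition (classified /
#'   ineligible / failed) as `"manifest"`.
#' @export
run_orthogroup_scan <- function(alignments, tree, table = NULL, config) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(tree, "tagged_tree"))
  ogs <- names(alignments)
  if (is.null(ogs)) stop("alignments must be a named list")

  eligible_taxa <- list()
  for (og in ogs) {
    taxa <- intersect(alignments[[og]]$taxa, tree$phy$tip.label)
    n_in <- length(intersect(taxa, config$ingroup))
    n_out <- length(setdiff(taxa, config$ingroup))
    if (n_in >= config$min_ingroup && n_out >= config$min_outgroup)
      eligible_taxa[[og]] <- taxa
  }
  if (!is.null(table)) {
    el <- relax_eligibility(table, config$ingroup,
                            union(config$outgroup,
                                  setdiff(tree$phy$tip.label,
                                          c(config$ingroup,
                                            unlist(tree$exclude)))),
                            config$min_ingroup, config$min_outgroup)
    keep <- el$orthogroup[el$eligible]
    eligible_taxa <- eligible_taxa[intersect(names(eligible_taxa), keep)]
  }
  if (!length(eligible_taxa)) {
    warning("no eligible orthogroups")
    empty <- data.frame(orthogroup = character(0))
    attr(empty, "manifest") <-
      data.frame(orthogroup = ogs, disposition = "ineligible")
    return(empty)
  }

  rows <- vector("list", length(eligible_taxa))
  ord <- sort(names(eligible_taxa))
  for (i in seq_along(ord)) {
    og <- ord[i]
    sub <- prune_for_orthogroup(tree, eligible_taxa[[og]])
    fit <- fit_relax(alignments[[og]], sub, ncat = config$ncat)
    rows[[i]] <- data.frame(
      orthogroup = og, n_test_taxa = fit$n_test_taxa,
      n_ref_taxa = fit$n_ref_taxa, k_hat = fit$k_hat,
      lnl_null = fit$lnl_null, lnl_alt = fit$lnl_alt, lrt = fit$lrt,
      p_raw = fit$p_raw,
      converged = fit$converged)
  }
  res <- do.call(rbind, rows)
  res$p_corrected <- NA_real_
  conv <- res$converged
  res$p_corrected[conv] <- benjamini_hochberg(res$p_raw[conv])
  res$classification <- vapply(seq_len(nrow(res)), function(r) {
    if (!res$converged[r]) "failed"
    else classify_relax(res$k_hat[r], res$p_corrected[r], config$alpha)
  }, "")

  cls <- res$classification[res$classification != "failed"]
  summ <- c(drift_affected = mean(cls == "drift-affected") * 100,
            selection_dominated = mean(cls == "selection-dominated") * 100,
            not_significant = mean(cls == "not-significant") * 100)
  manifest <- data.frame(
    orthogroup = ogs,
    disposition = ifelse(!ogs %in% names(eligible_taxa), "ineligible",
                         ifelse(ogs %in% res$orthogroup[res$converged],
                                "classified", "failed")))
  res <- res[, c("orthogroup", "n_test_taxa", "n_ref_taxa", "k_hat",
                 "lnl_null", "lnl_alt", "lrt", "p_raw", "p_corrected",
                 "classification")]
  attr(res, "summary") <- summ
  attr(res, "manifest") <- manifest
  class(res) <- c("relax_scan", "data.frame")
  res
}

#' Concatenate single-copy orthogroup alignments
#'
#' Per-taxon concatenation in sorted orthogroup order.  Every
#' alignment must cover exactly the same taxon set (the single-copy
#' contract); alignments that dropped frameshift-containing sequences
#' violate it and should have been excluded beforehand.
#'
#' @param alignments Named list of [codon_alignment()].
#' @param ids Orthogroup ids to concatenate (default: all).
#' @return A [codon_alignment()].
#' @export
concatenate_single_copy <- function(alignments, ids = names(alignments)) {
  ids <- sort(ids)
  if (!length(ids)) stop("no orthogroups to concatenate")
  if (!all(ids %in% names(alignments)))
    stop("missing alignment(s): ",
         paste(setdiff(ids, names(alignments)), collapse = ", "))
  taxa <- sort(alignments[[ids[1]]]$taxa)
  parts <- lapply(ids, function(og) {
    a <- alignments[[og]]
    if (!setequal(a$taxa, taxa))
      stop("orthogroup ", og, " does not cover the single-copy taxon set")
    a$sequences[taxa]
  })
  codon_alignment(setNames(do.call(paste0, parts), taxa))
}

#' Subsample genomes so all pairwise distances exceed a threshold
#'
#' Removes a minimal set of genomes so that no retained pair has
#' synonymous divergence at or below the threshold.  Offending pairs
#' form a conflict graph whose minimum vertex cover is the removal
#' set; it is found exactly for up to 22 conflicted genomes
#' (lexicographically smallest among the minimum covers), with a
#' greedy most-conflicted-first fallback beyond that.
#'
#' @param ds Symmetric non-negative matrix of pairwise dS with genome
#'   dimnames.
#' @param threshold Retained pairs must have dS strictly above this.
#' @return Character vector of retained genomes; removed ones are in
#'   attribute `"removed"`.
#' @export
subsample_by_ds <- function(ds, threshold = 0.01) {
  stopifnot(is.matrix(ds), nrow(ds) == ncol(ds),
            !is.null(rownames(ds)), all(ds >= 0),
            isTRUE(all.equal(ds, t(ds), tolerance = 1e-8)))
  g <- rownames(ds)
  conflict <- ds <= threshold
  diag(conflict) <- FALSE
  pairs <- which(conflict & upper.tri(conflict), arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    out <- g
    attr(out, "removed") <- character(0)
    return(out)
  }
  verts <- sort(unique(c(pairs[, 1], pairs[, 2])))
  removed <- if (length(verts) <= 22L) {
    .min_vertex_cover(pairs, verts)
  } else {
    .greedy_vertex_cover(pairs, verts)
  }
  out <- setdiff(g, g[removed])
  attr(out, "removed") <- g[sort(removed)]
  out
}

# exact minimum vertex cover by increasing-size enumeration over the
# conflicted vertices; first (lexicographically smallest) cover wins
.min_vertex_cover <- function(pairs, verts) {
  for (size in 0:length(verts)) {
    combs <- utils::combn(verts, size)
    for (ci in seq_len(ncol(combs))) {
      cover <- combs[, ci]
      if (all(pairs[, 1] %in% cover | pairs[, 2] %in% cover))
        return(cover)
    }
  }
  verts
}

.greedy_vertex_cover <- function(pairs, verts) {
  removed <- integer(0)
  left <- pairs
  while (nrow(left)) {
    deg <- table(factor(c(left[, 1], left[, 2]), levels = verts))
    pick <- verts[which.max(deg)]   # ties: first = lexicographic
    removed <- c(removed, pick)
    left <- left[left[, 1] != pick & left[, 2] != pick, , drop = FALSE]
  }
  sort(removed)
}

#' Repeat the orthogroup scan with alternative ingroups
#'
#' For each named clade, relabels the tree with that clade as the test
#' ingroup while the focal symbiont clade is excluded from the
#' reference set, reruns the scan, and tabulates the three-way
#' percentages, giving a control for branch-length-driven bias:
#' clades without a planted signal should rarely be called.
#'
#' @param alignments Named list of [codon_alignment()].
#' @param tree A [tagged_tree()] (its ingroup is the focal clade).
#' @param clades Named list of leaf-name vectors (clades of >= 3
#'   leaves; smaller ones are skipped with a warning).
#' @param table Optional `orthogroup_table` for eligibility.
#' @param config A [pipeline_config()].
#' @return data.frame: clade, n_tested, pct drift/selection/ns.
#' @export
alternative_ingroup_scan <- function(alignments, tree, clades,
                                     table = NULL, config) {
  focal <- tree$ingroup
  out <- lapply(names(clades), function(nm) {
    cl <- clades[[nm]]
    if (length(cl) < 3) {
      warning("clade ", nm, " has fewer than 3 leaves; skipped")
      return(NULL)
    }
    excl <- if (setequal(cl, focal)) list() else list(focal)
    tr <- label_branches(tree$phy, cl, exclude = excl)
    cfg <- config
    cfg$ingroup <- cl
    cfg$outgroup <- setdiff(tree$phy$tip.label, c(cl, unlist(excl)))
    scan <- run_orthogroup_scan(alignments, tr, table, cfg)
    s <- attr(scan, "summary")
    data.frame(clade = nm, n_tested = nrow(scan),
               pct_drift_affected = s[["drift_affected"]],
               pct_selection_dominated = s[["selection_dominated"]],
               pct_not_significant = s[["not_significant"]])
  })
  do.call(rbind, out)
}

#' Run the full analysis end to end
#'
#' Orchestrates the whole pipeline on in-memory inputs (typically from
#' [simulate_dataset()] or from files read with the io functions):
#' orthogroup accounting with pseudogene assignment, the
#' per-orthogroup relaxation scan, the concatenated single-copy
#' genome-wide fit (per-branch dN/dS and genome-wide k), pathway /
#' multicopy / pseudogene enrichment, gene-loss mapping, genome
#' statistics, and a run manifest.  Deterministic given inputs and
#' config.
#'
#' @param data List with `tree`, `alignments`, `tables` (as produced
#'   by [simulate_dataset()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables
#'   are written there as TSV.
#' @param genomewide Also fit the concatenated single-copy model?
#'   (slowest step; default TRUE)
#' @return List of results tables.
#' @export
run_pipeline <- function(data, config, out_dir = NULL, genomewide = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  loci <- data$tables$loci
  hits <- data$tables$hits
  assignments <- assign_pseudogenes(hits, loci)
  loci2 <- apply_pseudogene_assignments(loci, assignments)
  table <- propagate_annotations(loci2)

  scan <- run_orthogroup_scan(data$alignments, data$tree, table, config)

  # pathway enrichment of drift-affected orthogroups among converged
  # results, two-sided against the genome-wide drift-affected fraction
  ann <- table$annotations
  cat_long <- do.call(rbind, lapply(seq_len(nrow(ann)), function(r) {
    pw <- .split_pathways(ann$pathways[r])[[1]]
    if (!length(pw)) return(NULL)
    data.frame(orthogroup = ann$orthogroup[r], category = pw)
  }))
  conv <- scan[scan$classification != "failed", , drop = FALSE]
  enr_drift <- NULL
  if (nrow(conv) && !is.null(cat_long) &&
      any(conv$classification == "drift-affected") &&
      !all(conv$classification == "drift-affected")) {
    enr_drift <- enrich_categories(
      data.frame(orthogroup = conv$orthogroup,
                 positive = conv$classification == "drift-affected"),
      cat_long)
  }
  # pseudogene-containing enrichment (table-level)
  ps_in <- pseudogene_enrichment_input(table, config$ingroup)
  enr_pseudo <- NULL
  if (nrow(ps_in) && mean(ps_in$positive) > 0 && mean(ps_in$positive) < 1)
    enr_pseudo <- enrich_categories(ps_in, cat_long)

  # gene loss for annotation-level genes absent/pseudogenic in the
  # ingroup but core to the outgroup
  out_core <- core_pan(table, intersect(table$genomes, config$outgroup),
                       level = "annotation")$core
  in_core <- core_pan(table, intersect(table$genomes, config$ingroup),
                      level = "annotation")$core
  lost <- setdiff(out_core, in_core)
  losses <- if (length(lost))
    gene_loss_events(table, lost, data$tree$phy) else NULL

  stats <- genome_statistics(data$tables$genomes, loci2,
                             compare_clades =
                               if (all(c("sister", "parent") %in%
                                       data$tables$genomes$clade))
                                 c("sister", "parent") else NULL)

  gw <- NULL
  if (genomewide) {
    sc <- single_copy_set(table)
    sc <- intersect(sc, names(data$alignments))
    sc <- sc[vapply(sc, function(og)
      setequal(data$alignments[[og]]$taxa, table$genomes), TRUE)]
    if (length(sc)) {
      concat <- concatenate_single_copy(data$alignments, sc)
      fitb <- fit_mg94_branches(concat, data$tree)
      rates <- branch_dnds(fitb, mask_threshold = config$ds_mask)
      gwfit <- fit_relax(concat, data$tree, ncat = config$ncat)
      gw <- list(n_single_copy = length(sc), branch_rates = rates,
                 k_genomewide = gwfit$k_hat, p_raw = gwfit$p_raw)
    }
  }

  out <- list(scan = scan, enrichment_drift = enr_drift,
              enrichment_pseudogene = enr_pseudo, gene_losses = losses,
              genome_stats = stats, genomewide = gw,
              orthogroup_table = table,
              manifest = attr(scan, "manifest"), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(scan), file.path(out_dir, "relax_scan.tsv"))
    if (!is.null(enr_drift))
      write_tsv(enr_drift, file.path(out_dir, "enrichment_drift.tsv"))
    if (!is.null(enr_pseudo))
      write_tsv(enr_pseudo, file.path(out_dir, "enrichment_pseudogene.tsv"))
    if (!is.null(losses))
      write_tsv(losses, file.path(out_dir, "gene_losses.tsv"))
    write_tsv(stats$stats, file.path(out_dir, "genome_stats.tsv"))
    if (!is.null(gw))
      write_tsv(gw$branch_rates, file.path(out_dir, "branch_dnds.tsv"))
    write_tsv(attr(scan, "manifest"), file.path(out_dir, "manifest.tsv"))
  }
  out
}
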