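# ---------------------------------------------------------------------
# Minimum gene-loss mapping (Dollo parsimony)
#
# Genes analyzed here are ancestrally present (they belong to the
# free-living core), so evolution is single-origin: the gene is
# present at the root and can only be lost, never regained.
# Pseudogenes count as absent.  Under losses-only evolution the
# minimum-loss reconstruction is unique: an internal node is present
# iff any leaf below it is present, and a loss is placed on every
# branch whose parent is present but whose subtree is entirely absent
# (the maximal absent clades).  This also realizes the rootward
# tie-break: one loss on a clade stem rather than several below it.
# ---------------------------------------------------------------------

#' Map minimum gene-loss events onto a rooted tree
#'
#' @param presence Named logical vector over all tree leaves
#'   (`TRUE` = intact).  Pseudogenes must already be coded `FALSE`.
#' @param phy Rooted `ape::phylo` (or [tagged_tree()]).
#' @return An object of class `loss_map`: `n_losses`, `branches`
#'   (data.frame parent, child, label for each loss branch), and the
#'   input `presence`.
#' @export
dollo_min_losses <- function(presence, phy) {
  if (inherits(phy, "tagged_tree")) phy <- phy$phy
  stopifnot(inherits(phy, "phylo"))
  tips <- phy$tip.label
  if (!setequal(names(presence), tips))
    stop("presence vector must cover exactly the tree leaves")
  presence <- as.logical(presence[tips])
  ntip <- length(tips)
  nn <- ntip + phy$Nnode

  # postorder sweep: node present iff any descendant leaf present
  state <- c(presence, rep(NA, phy$Nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    u <- po$edge[e, 1]; v <- po$edge[e, 2]
    if (is.na(state[u])) state[u] <- FALSE
    state[u] <- state[u] || state[v]
  }

  loss_edge <- state[phy$edge[, 1]] & !state[phy$edge[, 2]]
  labs <- c(tips, if (!is.null(phy$node.label) &&
                      any(nzchar(phy$node.label)))
    phy$node.label else paste0("node", seq_len(phy$Nnode)))
  branches <- data.frame(parent = phy$edge[loss_edge, 1],
                         child = phy$edge[loss_edge, 2],
                         label = labs[phy$edge[loss_edge, 2]])
  rownames(branches) <- NULL
  structure(list(n_losses = sum(loss_edge), branches = branches,
                 presence = setNames(presence, tips)),
            class = "loss_map")
}

#' @export
print.loss_map <- function(x, ...) {
  cat("loss_map:", x$n_losses, "loss event(s) on branch(es):",
      paste(x$branches$label, collapse = ", "), "\n")
  invisible(x)
}

#' Minimum loss events for a set of annotation-level genes
#'
#' Builds each gene's leaf presence vector from the orthogroup table
#' (an annotation is present in a genome if any orthogroup carrying it
#' has an intact locus there; pseudogenes are absent) and maps the
#' minimum loss events.  Branches can be translated to divergence-age
#' intervals through a user-supplied branch label -> age table; ages
#' are annotated, never computed.
#'
#' @param table An `orthogroup_table`.
#' @param genes Character vector of gene names / KOs.
#' @param phy Rooted tree over the table's genomes (or a subset).
#' @param branch_ages Optional data.frame with `label` and `age`
#'   columns.
#' @return data.frame gene, n_losses, branches (`;`-separated labels),
#'   ages (when supplied).
#' @export
gene_loss_events <- function(table, genes, phy, branch_ages = NULL) {
  if (inherits(phy, "tagged_tree")) phy <- phy$phy
  stopifnot(inherits(table, "orthogroup_table"))
  m <- .intact_matrix(table, intersect(table$genomes, phy$tip.label))
  ann <- table$annotations
  out <- lapply(genes, function(g) {
    carriers <- ann$orthogroup[
      vapply(seq_len(nrow(ann)), function(r)
        g %in% unlist(c(.split_pathways(ann$gene_names[r]),
                        .split_pathways(ann$kos[r]))), TRUE)]
    pres <- if (length(carriers))
      apply(m[carriers, phy$tip.label, drop = FALSE], 2, any)
    else setNames(rep(FALSE, length(phy$tip.label)), phy$tip.label)
    lm_ <- dollo_min_losses(pres, phy)
    ages <- ""
    if (!is.null(branch_ages) && nrow(lm_$branches)) {
      idx <- match(lm_$branches$label, branch_ages$label)
      ages <- paste(ifelse(is.na(idx), "", branch_ages$age[idx]),
                    collapse = ";")
    }
    data.frame(gene = g, n_losses = lm_$n_losses,
               branches = paste(lm_$branches$label, collapse = ";"),
               ages = ages)
  })
  do.call(rbind, out)
}
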