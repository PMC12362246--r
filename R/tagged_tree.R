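#' Rooted phylogeny with test/reference/excluded branch tags
#'
#' The branch-partitioned selection test needs every branch of a rooted
#' species tree assigned to exactly one of three groups: `test` (the
#' symbiont ingroup whose selective regime is being interrogated),
#' `reference` (the free-living background) or `excluded` (branches
#' contributing to neither side, e.g. the ingroup stem, along which the
#' transition to symbiosis happened at an unknown point).
#'
#' @param phy A rooted `ape::phylo` object.
#' @param tags Character vector of tags, one per row of `phy$edge`.
#'   Defaults to all-`"reference"`.
#' @param ingroup Taxa whose clade is tagged `test` (recorded so tags
#'   can be recomputed after pruning).
#' @param exclude List of character vectors; each element is a clade
#'   (or single leaf) whose branches, stem included, are excluded.
#' @return An object of class `tagged_tree`.
#' @export
tagged_tree <- function(phy, tags = NULL, ingroup = character(0),
                        exclude = list()) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf name: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (is.null(phy$edge.length)) {
    .rs_log("tree has no branch lengths; setting all to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    .rs_log("missing branch lengths set to 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (is.null(tags)) tags <- rep("reference", nrow(phy$edge))
  stopifnot(length(tags) == nrow(phy$edge))
  structure(list(phy = phy, tags = tags, ingroup = ingroup,
                 exclude = exclude),
            class = "tagged_tree")
}

#' @export
print.tagged_tree <- function(x, ...) {
  cat("tagged_tree:", length(x$phy$tip.label), "leaves;",
      sum(x$tags == "test"), "test /", sum(x$tags == "reference"),
      "reference /", sum(x$tags == "excluded"), "excluded branches\n")
  invisible(x)
}

# all nodes strictly below `node` (tips and internals)
.clade_desc <- function(phy, node) {
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  out <- kids
  while (length(kids)) {
    kids <- phy$edge[phy$edge[, 1] %in% kids, 2]
    out <- c(out, kids)
  }
  out
}

.clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  d <- .clade_desc(phy, node)
  phy$tip.label[d[d <= ntip]]
}

#' Partition the branches of a species tree around a focal ingroup
#'
#' Tags every terminal and internal branch inside the (monophyletic)
#' ingroup clade as `test`, the stem branch of that clade as
#' `excluded`, and everything else as `reference`.  Additional clades
#' may be excluded outright (stem and all internal/terminal branches),
#' which is how a focal symbiont clade is kept out of the reference set
#' when scanning alternative ingroups.
#'
#' @param phy A rooted `ape::phylo`, or a [tagged_tree()] whose tags are
#'   recomputed.
#' @param ingroup Character vector of ingroup leaf names (at least 2;
#'   a single leaf has no non-stem branch to test and is rejected).
#' @param exclude Optional list of character vectors of leaf names;
#'   each must form a clade (single leaves allowed).
#' @return A [tagged_tree()].
#' @export
label_branches <- function(phy, ingroup, exclude = list()) {
  if (inherits(phy, "tagged_tree")) phy <- phy$phy
  stopifnot(inherits(phy, "phylo"))
  tips <- phy$tip.label
  if (!all(ingroup %in% tips))
    stop("ingroup taxa absent from tree: ",
         paste(setdiff(ingroup, tips), collapse = ", "))
  if (length(ingroup) < 2L)
    stop("ingroup of a single leaf leaves no test branch ",
         "(its terminal branch is the clade stem)")
  if (length(ingroup) >= length(tips))
    stop("ingroup covers the whole tree; no reference branches remain")
  mrca <- ape::getMRCA(phy, ingroup)
  clade <- .clade_tips(phy, mrca)
  if (!setequal(clade, ingroup))
    stop("ingroup is not monophyletic; its clade also contains: ",
         paste(setdiff(clade, ingroup), collapse = ", "))
  tags <- rep("reference", nrow(phy$edge))
  inside <- .clade_desc(phy, mrca)
  tags[phy$edge[, 2] %in% inside] <- "test"
  tags[phy$edge[, 2] == mrca] <- "excluded"

  if (length(exclude)) {
    for (ex in exclude) {
      ex <- intersect(ex, tips)
      if (length(ex) == 0L) next
      if (length(ex) == 1L) {
        node <- match(ex, tips)
      } else {
        node <- ape::getMRCA(phy, ex)
        cl <- .clade_tips(phy, node)
        if (!setequal(cl, ex))
          stop("excluded set is not monophyletic: ",
               paste(ex, collapse = ", "))
      }
      sub <- if (length(ex) == 1L) integer(0) else .clade_desc(phy, node)
      tags[phy$edge[, 2] %in% c(node, sub)] <- "excluded"
    }
  }
  if (!any(tags == "reference"))
    stop("no reference branches remain after labeling")
  tagged_tree(phy, tags, ingroup = ingroup, exclude = exclude)
}

#' Prune a tagged tree to a subset of taxa
#'
#' Restricts the species tree to the taxa present in an orthogroup.
#' Degree-2 nodes created by the pruning are suppressed with their
#' branch lengths added, and branch tags are recomputed from the
#' retained ingroup/excluded taxa, so root-to-leaf path lengths of
#' retained leaves are preserved.
#'
#' @param tree A [tagged_tree()] carrying its ingroup.
#' @param taxa Leaves to keep (must include at least 2 ingroup and
#'   1 non-ingroup leaf).
#' @return A pruned [tagged_tree()].
#' @export
prune_for_orthogroup <- function(tree, taxa) {
  stopifnot(inherits(tree, "tagged_tree"))
  tips <- tree$phy$tip.label
  if (!all(taxa %in% tips))
    stop("taxa absent from tree: ",
         paste(setdiff(taxa, tips), collapse = ", "))
  if (setequal(taxa, tips)) return(tree)
  phy <- ape::keep.tip(tree$phy, taxa)
  ing <- intersect(tree$ingroup, taxa)
  if (length(ing) >= 2)
    label_branches(phy, ing, exclude = tree$exclude)
  else if (length(tree$ingroup) == 0)
    tagged_tree(phy)
  else
    stop("fewer than 2 ingroup taxa retained by the pruning")
}

.TAG_MARK <- "__TAG__"

#' Read a rooted Newick tree with optional branch tags
#'
#' Accepts HyPhy-style `{tag}` annotations after a leaf name or closing
#' parenthesis, and `#tag` suffixes on node labels; untagged branches
#' default to `reference`.  A basal trifurcation is resolved by
#' rerooting on its first child with a zero-length branch (harmless for
#' reversible models).  Missing branch lengths are set to 0.
#'
#' @param path Path to a Newick file, or a Newick string containing
#'   a semicolon.
#' @return A [tagged_tree()]; the ingroup is inferred as the set of
#'   leaves spanned by `test` tags, when present and monophyletic.
#' @export
read_tagged_newick <- function(path) {
  txt <- if (grepl("[();]", path) || !file.exists(path)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\{([^}{]+)\\}", paste0(.TAG_MARK, "\\1"), txt)
  txt <- gsub("#([A-Za-z0-9_.-]+)", paste0(.TAG_MARK, "\\1"), txt)
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("could not parse Newick input")
  if (anyDuplicated(sub(paste0(.TAG_MARK, ".*$"), "", phy$tip.label)))
    stop("duplicate leaf name in Newick input")

  if (!ape::is.rooted(phy)) {
    first_child <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2][1]
    out <- if (first_child <= length(phy$tip.label))
      phy$tip.label[first_child] else .clade_tips(phy, first_child)
    .rs_log("basal multifurcation: rerooting on first child (0-length branch)")
    phy <- ape::root(phy, outgroup = out, resolve.root = TRUE)
  }

  split_tag <- function(lab) {
    has <- grepl(.TAG_MARK, lab, fixed = TRUE)
    tag <- ifelse(has, sub(paste0("^.*", .TAG_MARK), "", lab), NA_character_)
    list(label = sub(paste0(.TAG_MARK, ".*$"), "", lab), tag = tag)
  }
  tl <- split_tag(phy$tip.label)
  phy$tip.label <- tl$label
  node_tag <- rep(NA_character_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    nl <- split_tag(phy$node.label)
    phy$node.label <- nl$label
    node_tag <- nl$tag
  }
  all_tag <- c(tl$tag, node_tag)
  tags <- all_tag[phy$edge[, 2]]
  tags[is.na(tags)] <- "reference"
  bad <- setdiff(unique(tags), c("test", "reference", "excluded"))
  if (length(bad))
    stop("unknown branch tag(s): ", paste(bad, collapse = ", "))

  ingroup <- character(0)
  if (any(tags == "test")) {
    test_children <- phy$edge[tags == "test", 2]
    ntip <- length(phy$tip.label)
    leaves <- unique(unlist(lapply(test_children, .clade_tips, phy = phy)))
    mrca <- if (length(leaves) > 1) ape::getMRCA(phy, leaves) else 0L
    if (mrca > 0 && setequal(.clade_tips(phy, mrca), leaves))
      ingroup <- leaves
  }
  tagged_tree(phy, tags, ingroup = ingroup)
}

#' Write a tagged tree as Newick with `{tag}` annotations
#'
#' Emits the HyPhy-style brace syntax for every branch whose tag is not
#' `reference`, so untagged round trips stay clean.
#'
#' @param tree A [tagged_tree()].
#' @param path Output file; if `NULL` the Newick string is returned.
#' @export
write_tagged_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "tagged_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  node_lab <- phy$node.label
  if (is.null(node_lab)) node_lab <- rep("", phy$Nnode)
  marked <- which(tree$tags != "reference")
  for (e in marked) {
    child <- phy$edge[e, 2]
    m <- paste0(.TAG_MARK, tree$tags[e])
    if (child <= ntip)
      phy$tip.label[child] <- paste0(phy$tip.label[child], m)
    else
      node_lab[child - ntip] <- paste0(node_lab[child - ntip], m)
  }
  if (any(nzchar(node_lab))) phy$node.label <- node_lab
  txt <- ape::write.tree(phy)
  txt <- gsub(paste0(.TAG_MARK, "([A-Za-z]+)"), "{\\1}", txt)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
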