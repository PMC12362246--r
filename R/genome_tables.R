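# ---------------------------------------------------------------------
# Orthogroup and annotation bookkeeping
# ---------------------------------------------------------------------

.split_pathways <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Read the locus table
#'
#' TSV with header; mandatory columns `genome`, `locus`, `orthogroup`
#' (empty = unplaced), `status` (`intact` or `pseudogene`); optional
#' `length_bp`, `gene_name`, `ko` and `pathways`
#' (semicolon-separated).  Unknown columns are preserved but ignored.
#'
#' @param path TSV file.
#' @return data.frame of locus records.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = c("NA", ""))
  need <- c("genome", "locus", "orthogroup", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("locus table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("genome", "locus")]))
    stop("duplicate (genome, locus) pair in locus table")
  bad <- setdiff(unique(df$status), c("intact", "pseudogene"))
  if (length(bad))
    stop("unknown locus status: ", paste(bad, collapse = ", "))
  if ("length_bp" %in% names(df)) df$length_bp <- as.numeric(df$length_bp)
  for (col in c("gene_name", "ko", "pathways"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$pathways[is.na(df$pathways)] <- ""
  df
}

#' Read the pseudogene-vs-gene hit table
#'
#' TSV with header; columns `query`, `subject`, `evalue`, `bitscore`.
#' When a locus table is supplied every subject must be a known locus.
#'
#' @param path TSV file.
#' @param loci Optional locus table for subject validation.
#' @return data.frame of hit records.
#' @export
read_hit_table <- function(path, loci = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c(query = "character",
                                  subject = "character"))
  need <- c("query", "subject", "evalue", "bitscore")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  df$evalue <- as.numeric(df$evalue)
  df$bitscore <- as.numeric(df$bitscore)
  if (any(df$evalue < 0) || any(df$bitscore < 0))
    stop("negative e-value or bit score")
  if (!is.null(loci)) {
    unknown <- setdiff(df$subject, loci$locus)
    if (length(unknown))
      stop("hit subject(s) not in locus table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  df
}

#' Write a table as canonical TSV
#'
#' Tab separators, `\n` endings, no quoting, no row names, so equal
#' tables serialize byte-identically.
#'
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "")
  invisible(path)
}

#' Aggregate loci into an orthogroup table with propagated annotations
#'
#' Counts intact and pseudogene loci per (genome, orthogroup) and
#' propagates annotations inclusively: every gene name, KO and pathway
#' assigned to at least one member locus is assigned to the whole
#' orthogroup.  When non-missing gene names of member loci disagree
#' the orthogroup's `conflict` flag is set (the disagreement is noted,
#' not resolved).  Propagation is idempotent.
#'
#' @param loci Locus table (see [read_locus_table()]).
#' @return An object of class `orthogroup_table`: `counts` (long
#'   data.frame: orthogroup, genome, n_intact, n_pseudo),
#'   `annotations` (orthogroup, gene_names, kos, pathways, conflict),
#'   `genomes`, `orthogroups`.
#' @export
propagate_annotations <- function(loci) {
  placed <- loci[!is.na(loci$orthogroup), , drop = FALSE]
  genomes <- sort(unique(loci$genome))
  ogs <- sort(unique(placed$orthogroup))

  key <- paste(placed$orthogroup, placed$genome, sep = "\t")
  n_int <- tapply(placed$status == "intact", key, sum)
  n_pse <- tapply(placed$status == "pseudogene", key, sum)
  kk <- strsplit(names(n_int), "\t", fixed = TRUE)
  counts <- data.frame(
    orthogroup = vapply(kk, `[`, "", 1L),
    genome = vapply(kk, `[`, "", 2L),
    n_intact = as.integer(n_int), n_pseudo = as.integer(n_pse))
  counts <- counts[order(counts$orthogroup, counts$genome), ]
  rownames(counts) <- NULL

  uniq_cat <- function(v) {
    v <- sort(unique(v[!is.na(v) & nzchar(v)]))
    paste(v, collapse = ";")
  }
  ann <- do.call(rbind, lapply(split(placed, placed$orthogroup), function(d) {
    gn <- unique(d$gene_name[!is.na(d$gene_name)])
    data.frame(orthogroup = d$orthogroup[1],
               gene_names = uniq_cat(d$gene_name),
               kos = uniq_cat(d$ko),
               pathways = uniq_cat(unlist(.split_pathways(d$pathways))),
               conflict = length(gn) > 1L)
  }))
  rownames(ann) <- NULL
  structure(list(counts = counts, annotations = ann,
                 genomes = genomes, orthogroups = ogs),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", length(x$orthogroups), "orthogroups x",
      length(x$genomes), "genomes;",
      sum(x$annotations$conflict), "annotation conflict(s)\n")
  invisible(x)
}

#' Assign pseudogenes to orthogroups by best similarity hit
#'
#' Each pseudogene query is assigned to the orthogroup containing the
#' intact locus with the lowest e-value hit; ties are broken by higher
#' bit score, then by lexicographically smallest orthogroup id, so the
#' assignment is deterministic.  Queries without hits stay unassigned.
#'
#' @param hits Hit table (see [read_hit_table()]).
#' @param loci Locus table; subjects must be intact loci with
#'   orthogroups.
#' @return data.frame query -> orthogroup (unassigned queries absent);
#'   attribute `"unassigned"` lists hit-less queries.
#' @export
assign_pseudogenes <- function(hits, loci) {
  og_of <- setNames(loci$orthogroup, loci$locus)
  unknown <- setdiff(hits$subject, loci$locus)
  if (length(unknown))
    stop("hit subject(s) not in locus table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  h <- hits
  h$orthogroup <- og_of[h$subject]
  h <- h[!is.na(h$orthogroup), , drop = FALSE]
  h <- h[order(h$query, h$evalue, -h$bitscore, h$orthogroup), ]
  best <- h[!duplicated(h$query), c("query", "orthogroup")]
  rownames(best) <- NULL
  attr(best, "unassigned") <- setdiff(unique(hits$query), best$query)
  best
}

#' Apply pseudogene orthogroup assignments to a locus table
#'
#' Fills the `orthogroup` column of assigned pseudogene loci so they
#' participate in pseudogene-aware accounting (annotations then reach
#' them through orthogroup-level propagation).
#'
#' @param loci Locus table.
#' @param assignments Result of [assign_pseudogenes()].
#' @return Updated locus table.
#' @export
apply_pseudogene_assignments <- function(loci, assignments) {
  idx <- match(loci$locus, assignments$query)
  take <- !is.na(idx) & loci$status == "pseudogene"
  loci$orthogroup[take] <- assignments$orthogroup[idx[take]]
  loci
}

# presence (>=1 intact locus) matrix: orthogroups x genomes
.intact_matrix <- function(table, genomes = table$genomes) {
  m <- matrix(FALSE, length(table$orthogroups), length(genomes),
              dimnames = list(table$orthogroups, genomes))
  cc <- table$counts
  cc <- cc[cc$genome %in% genomes & cc$n_intact > 0, , drop = FALSE]
  m[cbind(cc$orthogroup, cc$genome)] <- TRUE
  m
}

#' Core and pan genomes at orthogroup or annotation level
#'
#' The core genome is the set of units intact in every genome of the
#' set; the pan genome is the set intact in at least one.  At the
#' orthogroup level the unit is the orthogroup.  At the annotation
#' level the unit is a gene name or KO, and an annotation counts as
#' intact in a genome if any orthogroup carrying it has an intact
#' locus there, so no single orthogroup needs to be core for the
#' annotation to be core.
#'
#' @param table An `orthogroup_table`.
#' @param genomes Genome set (non-empty subset of the table's
#'   genomes).
#' @param level `"orthogroup"` or `"annotation"`.
#' @return list(core, pan) of sorted unit ids.
#' @export
core_pan <- function(table, genomes, level = c("orthogroup", "annotation")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "orthogroup_table"))
  if (length(genomes) == 0L) stop("empty genome set")
  if (!all(genomes %in% table$genomes))
    stop("unknown genome(s): ",
         paste(setdiff(genomes, table$genomes), collapse = ", "))
  m <- .intact_matrix(table, genomes)
  if (level == "orthogroup") {
    core <- rownames(m)[rowSums(m) == length(genomes)]
    pan <- rownames(m)[rowSums(m) > 0]
    return(list(core = sort(core), pan = sort(pan)))
  }
  ann <- table$annotations
  units <- sort(unique(unlist(c(.split_pathways(ann$gene_names),
                                .split_pathways(ann$kos)))))
  if (!length(units)) return(list(core = character(0), pan = character(0)))
  am <- matrix(FALSE, length(units), length(genomes),
               dimnames = list(units, genomes))
  for (r in seq_len(nrow(ann))) {
    u <- unlist(c(.split_pathways(ann$gene_names[r]),
                  .split_pathways(ann$kos[r])))
    if (!length(u)) next
    am[u, ] <- am[u, , drop = FALSE] | rep(m[ann$orthogroup[r], ],
                                           each = length(u))
  }
  list(core = sort(rownames(am)[rowSums(am) == length(genomes)]),
       pan = sort(rownames(am)[rowSums(am) > 0]))
}

#' Orthogroups eligible for the branch-partitioned selection test
#'
#' A genome contributing more than one locus (intact or pseudogene
#' members count by intact loci only; multiple intact copies are
#' paralogs) to an orthogroup is dropped from that orthogroup first;
#' the orthogroup is then eligible if at least `min_ingroup` ingroup
#' genomes and `min_outgroup` outgroup genomes remain with exactly one
#' intact locus each.
#'
#' @param table An `orthogroup_table`.
#' @param ingroup,outgroup Disjoint genome sets.
#' @param min_ingroup,min_outgroup Thresholds (default 3 each).
#' @return data.frame orthogroup, n_ingroup, n_outgroup, eligible;
#'   plus `taxa`, a named list of the retained single-copy genomes per
#'   eligible orthogroup.
#' @export
relax_eligibility <- function(table, ingroup, outgroup,
                              min_ingroup = 3, min_outgroup = 3) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup overlap")
  cc <- table$counts
  cc <- cc[cc$n_intact == 1L & cc$genome %in% c(ingroup, outgroup), ,
           drop = FALSE]
  res <- do.call(rbind, lapply(split(cc, cc$orthogroup), function(d) {
    data.frame(orthogroup = d$orthogroup[1],
               n_ingroup = sum(d$genome %in% ingroup),
               n_outgroup = sum(d$genome %in% outgroup))
  }))
  all_ogs <- data.frame(orthogroup = table$orthogroups)
  res <- merge(all_ogs, res, by = "orthogroup", all.x = TRUE)
  res$n_ingroup[is.na(res$n_ingroup)] <- 0L
  res$n_outgroup[is.na(res$n_outgroup)] <- 0L
  res$eligible <- res$n_ingroup >= min_ingroup &
    res$n_outgroup >= min_outgroup
  res <- res[order(res$orthogroup), ]
  rownames(res) <- NULL
  taxa <- lapply(split(cc$genome, cc$orthogroup), sort)
  attr(res, "taxa") <- taxa[res$orthogroup[res$eligible]]
  res
}

#' Single-copy orthogroups
#'
#' Orthogroups containing exactly one intact locus in every genome of
#' the set (pseudogene copies do not disqualify; the definition counts
#' intact loci only).
#'
#' @param table An `orthogroup_table`.
#' @param genomes Genome set (default: all genomes in the table).
#' @return Sorted character vector of orthogroup ids.
#' @export
single_copy_set <- function(table, genomes = table$genomes) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (!length(genomes)) return(character(0))
  cc <- table$counts
  cc <- cc[cc$genome %in% genomes, , drop = FALSE]
  ok <- vapply(split(cc, cc$orthogroup), function(d) {
    nrow(d[d$n_intact == 1L, ]) == length(genomes) &&
      all(d$n_intact <= 1L)
  }, TRUE)
  sort(names(ok)[ok])
}

#' Per-genome statistics and clade comparisons
#'
#' Computes per-genome summaries (intact genes, pseudogenes, mean
#' intact gene length, coding density, genes per Mbp) and, when clades
#' are given, two-sided Mann-Whitney-Wilcoxon tests between clade
#' pairs for each statistic (exact for group sizes up to 20, normal
#' approximation with tie correction otherwise) plus the least-squares
#' R^2 of intact gene count against genome length.
#'
#' @param genomes data.frame with `genome`, `length_bp`, `gc` and
#'   optionally `clade`.
#' @param loci Locus table.
#' @param compare_clades Character vector of length 2 naming the
#'   clades to test (requires a `clade` column; each clade needs at
#'   least 2 genomes).
#' @return list(stats, tests, r2); `tests` is NULL without clades.
#' @export
genome_statistics <- function(genomes, loci, compare_clades = NULL) {
  per <- lapply(split(loci, loci$genome), function(d) {
    ok <- d$status == "intact"
    data.frame(genome = d$genome[1],
               n_intact = sum(ok),
               n_pseudo = sum(d$status == "pseudogene"),
               mean_gene_length = mean(d$length_bp[ok]),
               coding_bp = sum(d$length_bp[ok]))
  })
  st <- merge(genomes, do.call(rbind, per), by = "genome", all.x = TRUE)
  for (col in c("n_intact", "n_pseudo", "coding_bp"))
    st[[col]][is.na(st[[col]])] <- 0
  st$coding_density <- pmin(1, st$coding_bp / st$length_bp)
  st$genes_per_mbp <- st$n_intact / (st$length_bp / 1e6)

  tests <- NULL
  if (!is.null(compare_clades)) {
    stopifnot(length(compare_clades) == 2, "clade" %in% names(st))
    a <- st[st$clade == compare_clades[1], ]
    b <- st[st$clade == compare_clades[2], ]
    if (nrow(a) < 2 || nrow(b) < 2)
      stop("each compared clade needs at least 2 genomes")
    vars <- c("gc", "length_bp", "n_intact", "n_pseudo",
              "mean_gene_length", "coding_density", "genes_per_mbp")
    tests <- do.call(rbind, lapply(vars, function(v) {
      if (length(unique(c(a[[v]], b[[v]]))) == 1L)
        return(data.frame(statistic = v, p_value = 1))
      exact <- nrow(a) <= 20 && nrow(b) <= 20 &&
        !anyDuplicated(c(a[[v]], b[[v]]))
      w <- suppressWarnings(
        wilcox.test(a[[v]], b[[v]], exact = exact))
      data.frame(statistic = v, p_value = w$p.value)
    }))
  }
  fit <- lm(n_intact ~ length_bp, data = st)
  list(stats = st[order(st$genome), ],
       tests = tests,
       r2 = summary(fit)$r.squared)
}
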