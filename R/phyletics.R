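#' Deduplicate system calls to unique TaxIDs
#'
#' Phyletic statistics count species-level TaxIDs, not assemblies: a
#' TaxID counts once per subtype no matter how many assemblies or
#' loci carry it, and may count for several distinct subtypes.
#'
#' @param calls data.frame with one row per locus: columns
#'   \code{locus_id}, \code{genome_id}, \code{subtype},
#'   \code{components} (comma-joined component names; optional).
#' @param genomes list of \linkS4class{GenomeRecord} keyed by genome
#'   id (source of each genome's taxid).
#' @return list with \code{subtypes} (unique taxid x subtype pairs),
#'   \code{components} (unique taxid x subtype x component triples)
#'   and \code{n_unmapped} (calls whose genome had no taxid mapping,
#'   excluded with a warning).
#' @export
dedupeTaxa <- function(calls, genomes) {
  if (nrow(calls) == 0L)
    return(list(subtypes = data.frame(taxid = integer(),
                                      subtype = character()),
                components = data.frame(taxid = integer(),
                                        subtype = character(),
                                        component = character()),
                n_unmapped = 0L))
  taxids <- unname(vapply(calls$genome_id, function(g)
    if (!is.null(genomes[[g]])) taxId(genomes[[g]]) else NA_integer_,
    integer(1)))
  unmapped <- is.na(taxids)
  if (any(unmapped))
    warning(sum(unmapped), " call(s) on genomes without taxonomy ",
            "mapping were excluded")
  calls <- calls[!unmapped, , drop = FALSE]
  taxids <- taxids[!unmapped]
  st <- unique(data.frame(taxid = taxids, subtype = calls$subtype,
                          stringsAsFactors = FALSE))
  st <- st[order(st$taxid, st$subtype), , drop = FALSE]
  comp_rows <- list()
  if (!is.null(calls$components)) {
    for (i in seq_len(nrow(calls))) {
      comps <- unlist(strsplit(calls$components[i], ","))
      comps <- comps[nzchar(comps)]
      if (length(comps))
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          taxid = taxids[i], subtype = calls$subtype[i],
          component = comps, stringsAsFactors = FALSE)
    }
  }
  co <- if (length(comp_rows)) unique(do.call(rbind, comp_rows)) else
    data.frame(taxid = integer(), subtype = character(),
               component = character())
  co <- co[order(co$taxid, co$subtype, co$component), , drop = FALSE]
  rownames(st) <- rownames(co) <- NULL
  list(subtypes = st, components = co, n_unmapped = sum(unmapped))
}

.group_of_taxid <- function(taxids, taxonomy, rank) {
  if (!rank %in% colnames(taxonomy))
    stop("rank '", rank, "' not present in the taxonomy table")
  g <- taxonomy[[rank]][match(taxids, taxonomy$taxid)]
  g[is.na(g) | !nzchar(g)] <- "unclassified"
  g
}

#' Build a phyletic presence/absence matrix of unique-TaxID counts
#'
#' @param summary result of \code{\link{dedupeTaxa}}.
#' @param taxonomy taxonomy data.frame
#'   (\code{\link{readTaxonomyTable}}).
#' @param rank lineage rank to group rows at (default
#'   \code{"phylum"}); TaxIDs without that rank are bucketed under
#'   \code{"unclassified"}.
#' @param axis \code{"subtype"} or \code{"component"} columns.
#' @return a \linkS4class{PhyleticMatrix}.
#' @export
presenceMatrix <- function(summary, taxonomy, rank = "phylum",
                           axis = c("subtype", "component")) {
  axis <- match.arg(axis)
  tab <- if (axis == "subtype") summary$subtypes else summary$components
  col_of <- if (axis == "subtype") tab$subtype else tab$component
  all_taxa <- unique(taxonomy$taxid)
  group_all <- .group_of_taxid(all_taxa, taxonomy, rank)
  group_taxa <- vapply(split(all_taxa, group_all), function(v)
    length(unique(v)), integer(1))
  groups <- sort(names(group_taxa))
  cols <- sort(unique(col_of))
  m <- matrix(0L, nrow = length(groups), ncol = length(cols),
              dimnames = list(groups, cols))
  if (nrow(tab)) {
    gvec <- .group_of_taxid(tab$taxid, taxonomy, rank)
    key <- paste(gvec, col_of, sep = "\r")
    for (kk in unique(key)) {
      sel <- key == kk
      parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
      m[parts[1], parts[2]] <- length(unique(tab$taxid[sel]))
    }
  }
  new("PhyleticMatrix", counts = m, rank = rank, axis = axis,
      groupTaxa = group_taxa[groups])
}

.DEFAULT_ANCHOR <- c("Type-1" = "BrxC", "Type-2" = "BrxC",
                     "Type-3" = "BrxC", "Type-4" = "BrxC",
                     "Type-5" = "BrxC", "Type-6" = "BrxC",
                     "Type-1 BR" = "DUF499_ATPase",
                     "Type-2 BR" = "DUF499_ATPase",
                     "Type-3 BR" = "DUF499_ATPase",
                     "BRC" = "HerA_FtsK")

#' Component retention among anchored taxa
#'
#' Retention of a component within a subtype is reported as in the
#' phyletic survey: the number of unique TaxIDs carrying the
#' component, divided by the number of unique TaxIDs carrying the
#' subtype's anchor component (e.g. BrxC for the Type-1 family).
#'
#' @param summary result of \code{\link{dedupeTaxa}}.
#' @param component component name.
#' @param subtype subtype whose taxa are considered.
#' @param anchor anchor component (defaults to the subtype's standard
#'   anchor).
#' @param digits optional rounding of the fraction.
#' @return list with \code{count} (anchored taxa carrying the
#'   component) and \code{fraction}; zero anchored taxa yields NA.
#' @export
retentionFraction <- function(summary, component, subtype, anchor = NULL,
                              digits = NULL) {
  if (is.null(anchor)) {
    anchor <- .DEFAULT_ANCHOR[subtype]
    if (is.na(anchor)) stop("no default anchor for subtype ", subtype)
  }
  co <- summary$components[summary$components$subtype == subtype, ,
                           drop = FALSE]
  anchored <- unique(co$taxid[co$component == anchor])
  if (length(anchored) == 0L)
    return(list(count = 0L, fraction = NA_real_))
  with_comp <- unique(co$taxid[co$component == component])
  count <- length(intersect(anchored, with_comp))
  frac <- count / length(anchored)
  if (!is.null(digits)) frac <- round(frac, digits)
  list(count = count, fraction = frac)
}

#' Render a phyletic matrix as a heatmap
#'
#' Thin wrapper over pheatmap mirroring the survey's group-by-subtype
#' count-scaled layout; requires the optional pheatmap package.
#'
#' @param pm a \linkS4class{PhyleticMatrix}.
#' @param file optional output file (png).
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @return the pheatmap object, invisibly.
#' @export
plotPhyleticHeatmap <- function(pm, file = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("the pheatmap package is required for plotting")
  p <- pheatmap::pheatmap(phyleticCounts(pm), cluster_rows = FALSE,
                          cluster_cols = FALSE, filename = file, ...)
  invisible(p)
}
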