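#' Neighborhood reconstruction parameters
#'
#' @param max_gap_nt maximum intergenic gap (nt) for two adjacent
#'   genes to be considered operonic; the proximity filter's default
#'   is 100 nt.
#' @param window_genes genes taken on each side of the anchor when a
#'   locus is extracted.
#' @param strand_mode \code{"same_strand_blocks"} (blocks break at
#'   strand switches; divergently oriented neighboring blocks may
#'   still join a locus) or \code{"any"}.
#' @param min_phyla distinct phyla required for cross-phyla support.
#' @return parameter list.
#' @export
neighborhoodParams <- function(max_gap_nt = 100L, window_genes = 10L,
                               strand_mode = c("same_strand_blocks", "any"),
                               min_phyla = 2L) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(max_gap_nt >= 0L, window_genes >= 1L, min_phyla >= 1L)
  list(max_gap_nt = as.integer(max_gap_nt),
       window_genes = as.integer(window_genes), strand_mode = strand_mode,
       min_phyla = as.integer(min_phyla))
}

#' Intergenic gap between two genes
#'
#' With 0-based half-open coordinates the gap is simply
#' \code{start2 - end1}: the number of bases strictly between the two
#' genes. Abutting genes give 0, overlapping genes a negative value.
#'
#' @param g1,g2 single-row gene entries (list or data.frame row with
#'   \code{start}, \code{end}, and optionally \code{genome_id}); g1
#'   must not start after g2.
#' @return integer gap in nt.
#' @export
intergenicGap <- function(g1, g2) {
  if (!is.null(g1$genome_id) && !is.null(g2$genome_id) &&
      g1$genome_id != g2$genome_id)
    stop("genes are on different genomes")
  stopifnot(g1$start <= g2$start)
  as.integer(g2$start - g1$end)
}

#' Partition a genome's genes into operon blocks
#'
#' A block is a maximal run of consecutive genes whose successive
#' intergenic gaps are at most \code{max_gap_nt} and (under
#' \code{same_strand_blocks}) that share a strand. Overlapping genes
#' (negative gap) always co-block. Every gene lands in exactly one
#' block.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param params \code{\link{neighborhoodParams}}.
#' @return list of blocks, each a list with \code{idx} (row indices
#'   into \code{genes(genome)}), \code{strand}, \code{span}.
#' @export
buildOperonBlocks <- function(genome, params = neighborhoodParams()) {
  g <- genes(genome)
  n <- nrow(g)
  if (n == 0L) return(list())
  st <- g$start; en <- g$end; sd <- g$strand
  breaks <- if (n > 1L) {
    gaps <- st[-1L] - en[-n]
    gaps > params$max_gap_nt |
      (params$strand_mode == "same_strand_blocks" & sd[-1L] != sd[-n])
  } else logical(0)
  block_id <- cumsum(c(1L, as.integer(breaks)))
  lapply(split(seq_len(n), block_id), function(idx) list(
    idx = idx, strand = sd[idx[1]],
    span = c(min(st[idx]), max(en[idx]))))
}

#' Extract the candidate defense locus around an anchor gene
#'
#' Takes the window of \code{window_genes} genes on each side of the
#' anchor, keeps the anchor's operon block, and grows the locus by
#' admitting neighboring blocks (within the window) whose nearest edge
#' is at most \code{max_gap_nt} from the locus span as it grows. This
#' admits divergently oriented adjacent blocks, as seen in real
#' neighborhoods, while still breaking the locus at any larger gap.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param anchor_gene_id gene id of the anchor.
#' @param params \code{\link{neighborhoodParams}}.
#' @return a \linkS4class{DefenseLocus}.
#' @export
extractLocus <- function(genome, anchor_gene_id,
                         params = neighborhoodParams()) {
  g <- genes(genome)
  gene_ids <- g$gene_id
  a <- match(anchor_gene_id, gene_ids)
  if (is.na(a)) stop("anchor gene '", anchor_gene_id, "' not found in ",
                     genomeId(genome))
  win <- seq(max(1L, a - params$window_genes),
             min(nrow(g), a + params$window_genes))
  blocks <- buildOperonBlocks(genome, params)
  in_win <- vapply(blocks, function(b) any(b$idx %in% win), logical(1))
  banchor <- which(vapply(blocks, function(b) a %in% b$idx, logical(1)))
  kept <- banchor
  span <- blocks[[banchor]]$span
  repeat {
    grew <- FALSE
    for (bi in which(in_win)) {
      if (bi %in% kept) next
      b <- blocks[[bi]]
      dist <- max(b$span[1] - span[2], span[1] - b$span[2])
      if (dist <= params$max_gap_nt) {
        kept <- c(kept, bi)
        span <- c(min(span[1], b$span[1]), max(span[2], b$span[2]))
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  kept <- sort(kept)
  idx <- integer(); block_col <- integer()
  for (k in seq_along(kept)) {
    bidx <- intersect(blocks[[kept[k]]]$idx, win)
    idx <- c(idx, bidx)
    block_col <- c(block_col, rep(k, length(bidx)))
  }
  o <- order(idx)
  idx <- idx[o]; block_col <- block_col[o]
  lg <- g[idx, , drop = FALSE]
  lg$block_id <- block_col
  new("DefenseLocus",
      locusId = paste0(genomeId(genome), ":", anchor_gene_id),
      genomeId = genomeId(genome), anchorGeneId = anchor_gene_id,
      genes = lg, span = c(min(lg$start), max(lg$end)),
      flags = character())
}

#' Flag loci whose composition is not conserved across phyla
#'
#' Groups component-annotated loci by their archetype key (the sorted
#' multiset of component names) and checks in how many distinct phyla
#' each archetype occurs. Archetypes below \code{min_phyla} are not
#' deleted: their loci are returned flagged \code{"phyla_support"},
#' matching the use of this criterion as a curation confidence filter.
#'
#' @param loci list of \linkS4class{DefenseLocus}.
#' @param components data.frame mapping \code{protein_id} to
#'   \code{component} (as from \code{\link{annotateProteins}}).
#' @param genomes list of GenomeRecord (for genome -> assembly
#'   lookup).
#' @param taxonomy taxonomy data.frame
#'   (\code{\link{readTaxonomyTable}}).
#' @param params \code{\link{neighborhoodParams}}.
#' @return list with \code{kept} and \code{flagged} lists of loci;
#'   flagged loci carry \code{"phyla_support"} (or
#'   \code{"no_taxonomy"}) in their flags.
#' @export
crossPhylaFilter <- function(loci, components, genomes, taxonomy,
                             params = neighborhoodParams()) {
  if (length(loci) == 0L) return(list(kept = list(), flagged = list()))
  phylum_of <- function(l) {
    rec <- genomes[[genomeId(l)]]
    if (is.null(rec)) return(NA_character_)
    row <- taxonomy[taxonomy$assembly_id == assemblyId(rec), , drop = FALSE]
    if (nrow(row) == 0L || is.null(row$phylum)) NA_character_
    else row$phylum[1]
  }
  key_of <- function(l) {
    ids <- genes(l)$gene_id
    comp <- components$component[match(ids, components$protein_id)]
    comp <- comp[!is.na(comp) & comp != "unknown"]
    paste(sort(comp), collapse = "+")
  }
  keys <- vapply(loci, key_of, character(1))
  phyla <- vapply(loci, phylum_of, character(1))
  support <- tapply(phyla, keys, function(p)
    length(unique(p[!is.na(p)])))
  kept <- list(); flagged <- list()
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    if (is.na(phyla[i])) {
      l@flags <- union(l@flags, "no_taxonomy")
      flagged[[length(flagged) + 1L]] <- l
    } else if (support[[keys[i]]] >= params$min_phyla) {
      kept[[length(kept) + 1L]] <- l
    } else {
      l@flags <- union(l@flags, "phyla_support")
      flagged[[length(flagged) + 1L]] <- l
    }
  }
  list(kept = kept, flagged = flagged)
}
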