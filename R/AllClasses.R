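#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GenomeRecord: one annotated replicon
#'
#' Holds the ordered gene table of a single replicon together with its
#' assembly, taxonomy and lineage metadata. Gene coordinates are stored
#' 0-based half-open on the genome-forward strand; the strand of
#' transcription is a separate column. Conversion from the 1-based
#' inclusive GenBank convention happens only at the I/O boundary.
#'
#' @slot genomeId single replicon identifier (LOCUS name).
#' @slot assemblyId assembly the replicon belongs to; several replicons
#'   may share an assembly.
#' @slot taxid positive integer NCBI-style species-level taxonomy id.
#' @slot lineage named character vector of rank = name pairs, ordered
#'   from superkingdom down to species.
#' @slot seqLength replicon length in bp.
#' @slot genes a \link[S4Vectors]{DataFrame} with columns
#'   \code{gene_id}, \code{start}, \code{end}, \code{strand},
#'   \code{translation}, \code{product}, sorted ascending by
#'   \code{start}.
#' @export
setClass("GenomeRecord", representation(
  genomeId = "character", assemblyId = "character", taxid = "integer",
  lineage = "character", seqLength = "integer", genes = "DataFrame"))

setValidity("GenomeRecord", function(object) {
  g <- object@genes
  msg <- character()
  need <- c("gene_id", "start", "end", "strand", "translation", "product")
  if (!all(need %in% colnames(g)))
    msg <- c(msg, paste("genes must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(g)) {
      if (is.unsorted(g$start)) msg <- c(msg, "genes must be sorted by start")
      if (any(g$start >= g$end)) msg <- c(msg, "gene start must be < end")
      if (any(g$start < 0L) || any(g$end > object@seqLength))
        msg <- c(msg, "gene coordinates must lie within [0, seqLength)")
      if (anyDuplicated(g$gene_id))
        msg <- c(msg, "gene_id must be unique within a genome")
      if (!all(g$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    }
  }
  if (length(object@taxid) != 1L || is.na(object@taxid) || object@taxid <= 0L)
    msg <- c(msg, "taxid must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' DefenseLocus: a reconstructed candidate defense neighborhood
#'
#' @slot locusId locus identifier (genomeId:anchor gene).
#' @slot genomeId replicon the locus lives on.
#' @slot anchorGeneId the gene the neighborhood was seeded from.
#' @slot genes DataFrame of member genes (gene table columns plus a
#'   \code{block_id} column giving the operon block of each gene).
#' @slot span integer length-2 vector, 0-based half-open hull of all
#'   member genes.
#' @slot flags character vector of curation flags (e.g.
#'   \code{"phyla_support"}, \code{"no_taxonomy"}).
#' @export
setClass("DefenseLocus", representation(
  locusId = "character", genomeId = "character", anchorGeneId = "character",
  genes = "DataFrame", span = "integer", flags = "character"))

setValidity("DefenseLocus", function(object) {
  g <- object@genes
  msg <- character()
  if (!"block_id" %in% colnames(g))
    msg <- c(msg, "locus genes need a block_id column")
  if (!(object@anchorGeneId %in% g$gene_id))
    msg <- c(msg, "anchor gene must be a member of the locus")
  if (length(object@span) != 2L || object@span[1] >= object@span[2])
    msg <- c(msg, "span must be an increasing length-2 integer vector")
  if (length(msg)) msg else TRUE
})

#' SystemCall: classification outcome for one locus
#'
#' @slot locusId locus identifier.
#' @slot system one of \code{"BREX"}, \code{"BR"}, \code{"BRC"},
#'   \code{"unassigned"}.
#' @slot subtype subtype label, or \code{"NA"} when unassigned.
#' @slot familyGroup \code{"Type-1-family"} for BREX Types 1/5/6
#'   (which form a single clade), else \code{"other"}.
#' @slot completeness \code{"complete"}, \code{"partial"} or
#'   \code{"discarded"}.
#' @slot componentsPresent component names observed in the locus.
#' @slot missingCore mandatory components of the matched subtype that
#'   were not observed.
#' @slot fusionFlags fusion flags aggregated over member proteins.
#' @export
setClass("SystemCall", representation(
  locusId = "character", system = "character", subtype = "character",
  familyGroup = "character", completeness = "character",
  componentsPresent = "character", missingCore = "character",
  fusionFlags = "character"))

setValidity("SystemCall", function(object) {
  msg <- character()
  if (!object@system %in% c("BREX", "BR", "BRC", "unassigned"))
    msg <- c(msg, "unknown system")
  if ((object@system == "unassigned") != (object@subtype == "NA"))
    msg <- c(msg, "subtype must be 'NA' iff system is unassigned")
  if (object@subtype %in% c("Type-5", "Type-6") &&
      object@familyGroup != "Type-1-family")
    msg <- c(msg, "Type-5/6 must carry family_group Type-1-family")
  if (length(msg)) msg else TRUE
})

#' PhyleticMatrix: taxonomic group x subtype/component unique-TaxID counts
#'
#' @slot counts integer matrix; rows are taxonomic groups at
#'   \code{rank}, columns are subtypes or components; each cell is the
#'   number of unique TaxIDs in that group with at least one qualifying
#'   call.
#' @slot rank the lineage rank the rows are grouped at.
#' @slot axis which quantity the columns enumerate
#'   (\code{"subtype"} or \code{"component"}).
#' @slot groupTaxa named integer vector: unique TaxIDs available per
#'   group (upper bound for every cell in that row).
#' @export
setClass("PhyleticMatrix", representation(
  counts = "matrix", rank = "character", axis = "character",
  groupTaxa = "integer"))

setValidity("PhyleticMatrix", function(object) {
  msg <- character()
  if (!is.integer(object@counts[1]) && length(object@counts))
    msg <- c(msg, "counts must be integer")
  if (nrow(object@counts) && !identical(rownames(object@counts),
                                        names(object@groupTaxa)))
    msg <- c(msg, "groupTaxa names must match matrix rows")
  if (nrow(object@counts) &&
      any(object@counts > object@groupTaxa[rownames(object@counts)]))
    msg <- c(msg, "a cell exceeds the number of unique TaxIDs in its group")
  if (length(msg)) msg else TRUE
})

#' EntropyProfile: per-column dual-alphabet Shannon entropy of an MSA
#'
#' @slot profile DataFrame with columns \code{column_index} (1-based
#'   alignment column), \code{H20} (bits, 20-letter alphabet),
#'   \code{H8} (bits, reduced 8-class chemical alphabet),
#'   \code{gap_fraction}, \code{n_effective} (non-gap, standard
#'   residues counted) and \code{gappy} (gap fraction above threshold).
#' @slot nRows number of sequences in the alignment.
#' @slot gapThreshold gap fraction above which a column is flagged.
#' @export
setClass("EntropyProfile", representation(
  profile = "DataFrame", nRows = "integer", gapThreshold = "numeric"))

setValidity("EntropyProfile", function(object) {
  p <- object@profile
  msg <- character()
  need <- c("column_index", "H20", "H8", "gap_fraction", "n_effective")
  if (!all(need %in% colnames(p)))
    msg <- c(msg, paste("profile needs columns:", paste(need, collapse = ", ")))
  else {
    h20 <- p$H20[!is.na(p$H20)]; h8 <- p$H8[!is.na(p$H8)]
    if (any(h20 < -1e-9) || any(h20 > log2(20) + 1e-9))
      msg <- c(msg, "H20 out of [0, log2(20)]")
    if (any(h8 < -1e-9) || any(h8 > 3 + 1e-9))
      msg <- c(msg, "H8 out of [0, 3]")
  }
  if (length(msg)) msg else TRUE
})
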