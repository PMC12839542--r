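#' @include AllClasses.R
NULL

#' Accessors for brexscan classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... ignored.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x, ...) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x, ...) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setGeneric("taxId", function(x, ...) standardGeneric("taxId"))
#' @rdname accessors
#' @export
setGeneric("lineage", function(x, ...) standardGeneric("lineage"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("locusId", function(x, ...) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setGeneric("anchorGeneId", function(x, ...) standardGeneric("anchorGeneId"))
#' @rdname accessors
#' @export
setGeneric("locusSpan", function(x, ...) standardGeneric("locusSpan"))
#' @rdname accessors
#' @export
setGeneric("locusFlags", function(x, ...) standardGeneric("locusFlags"))
#' @rdname accessors
#' @export
setGeneric("systemOf", function(x, ...) standardGeneric("systemOf"))
#' @rdname accessors
#' @export
setGeneric("subtypeOf", function(x, ...) standardGeneric("subtypeOf"))
#' @rdname accessors
#' @export
setGeneric("familyGroup", function(x, ...) standardGeneric("familyGroup"))
#' @rdname accessors
#' @export
setGeneric("completeness", function(x, ...) standardGeneric("completeness"))
#' @rdname accessors
#' @export
setGeneric("componentsPresent", function(x, ...)
  standardGeneric("componentsPresent"))
#' @rdname accessors
#' @export
setGeneric("fusionFlags", function(x, ...) standardGeneric("fusionFlags"))
#' @rdname accessors
#' @export
setGeneric("phyleticCounts", function(x, ...) standardGeneric("phyleticCounts"))
#' @rdname accessors
#' @export
setGeneric("entropyTable", function(x, ...) standardGeneric("entropyTable"))

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x, ...) x@genomeId)
#' @rdname accessors
#' @export
setMethod("assemblyId", "GenomeRecord", function(x, ...) x@assemblyId)
#' @rdname accessors
#' @export
setMethod("taxId", "GenomeRecord", function(x, ...) x@taxid)
#' @rdname accessors
#' @export
setMethod("lineage", "GenomeRecord", function(x, ...) x@lineage)
#' @rdname accessors
#' @export
setMethod("genes", "GenomeRecord", function(x, ...) x@genes)
#' @rdname accessors
#' @export
setMethod("length", "GenomeRecord", function(x) x@seqLength)

#' @rdname accessors
#' @export
setMethod("genomeId", "DefenseLocus", function(x, ...) x@genomeId)
#' @rdname accessors
#' @export
setMethod("genes", "DefenseLocus", function(x, ...) x@genes)
#' @rdname accessors
#' @export
setMethod("locusId", "DefenseLocus", function(x, ...) x@locusId)
#' @rdname accessors
#' @export
setMethod("anchorGeneId", "DefenseLocus", function(x, ...) x@anchorGeneId)
#' @rdname accessors
#' @export
setMethod("locusSpan", "DefenseLocus", function(x, ...) x@span)
#' @rdname accessors
#' @export
setMethod("locusFlags", "DefenseLocus", function(x, ...) x@flags)

#' @rdname accessors
#' @export
setMethod("locusId", "SystemCall", function(x, ...) x@locusId)
#' @rdname accessors
#' @export
setMethod("systemOf", "SystemCall", function(x, ...) x@system)
#' @rdname accessors
#' @export
setMethod("subtypeOf", "SystemCall", function(x, ...) x@subtype)
#' @rdname accessors
#' @export
setMethod("familyGroup", "SystemCall", function(x, ...) x@familyGroup)
#' @rdname accessors
#' @export
setMethod("completeness", "SystemCall", function(x, ...) x@completeness)
#' @rdname accessors
#' @export
setMethod("componentsPresent", "SystemCall", function(x, ...)
  x@componentsPresent)
#' @rdname accessors
#' @export
setMethod("fusionFlags", "SystemCall", function(x, ...) x@fusionFlags)

#' @rdname accessors
#' @export
setMethod("phyleticCounts", "PhyleticMatrix", function(x, ...) x@counts)
#' @rdname accessors
#' @export
setMethod("entropyTable", "EntropyProfile", function(x, ...) x@profile)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@genomeId,
      sprintf("(assembly %s, taxid %d)\n", object@assemblyId, object@taxid))
  cat(sprintf("  %d bp, %d genes; lineage: %s\n", object@seqLength,
              nrow(object@genes),
              paste(utils::tail(object@lineage, 2), collapse = " / ")))
})

setMethod("show", "DefenseLocus", function(object) {
  cat("DefenseLocus", object@locusId, "\n")
  cat(sprintf("  genome %s, span [%d, %d), %d genes in %d blocks",
              object@genomeId, object@span[1], object@span[2],
              nrow(object@genes), length(unique(object@genes$block_id))))
  if (length(object@flags)) cat("; flags:", paste(object@flags, collapse = ","))
  cat("\n")
})

setMethod("show", "SystemCall", function(object) {
  cat(sprintf("SystemCall %s: %s / %s (%s, %s)\n", object@locusId,
              object@system, object@subtype, object@familyGroup,
              object@completeness))
  cat("  components:", paste(object@componentsPresent, collapse = ", "), "\n")
  if (length(object@fusionFlags))
    cat("  fusions:", paste(object@fusionFlags, collapse = ", "), "\n")
})

setMethod("show", "PhyleticMatrix", function(object) {
  cat(sprintf("PhyleticMatrix (%s x %s): %d groups x %d columns\n",
              object@rank, object@axis, nrow(object@counts),
              ncol(object@counts)))
  print(object@counts)
})

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf("EntropyProfile: %d columns from %d sequences\n",
              nrow(object@profile), object@nRows))
  h <- object@profile$H20
  cat(sprintf("  H20 range [%.3f, %.3f] bits; %d gappy columns (> %.0f%% gaps)\n",
              suppressWarnings(min(h, na.rm = TRUE)),
              suppressWarnings(max(h, na.rm = TRUE)),
              sum(object@profile$gappy), 100 * object@gapThreshold))
})
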