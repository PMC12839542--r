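#' @include AllClasses.R
NULL

.STD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.GAP_CHARS <- c("-", ".")

#' Residue alphabet maps for entropy profiles
#'
#' Two maps ship with the package: \code{"identity20"} (each standard
#' residue its own class, M = 20) and \code{"chem8"}, a Murphy-style
#' 8-class chemical-property partition
#' \{LVIMC\}\{AG\}\{ST\}\{P\}\{FWY\}\{EDNQ\}\{KR\}\{H\}. A custom map
#' can be loaded from a two-column TSV (residue, class).
#'
#' @param name \code{"identity20"}, \code{"chem8"}, or a path to a
#'   map file.
#' @return list with \code{name}, \code{mapping} (named character:
#'   residue -> class) and \code{class_count}.
#' @export
alphabetMap <- function(name = c("identity20", "chem8")) {
  if (length(name) == 1L && file.exists(name)) {
    tab <- utils::read.delim(name, header = TRUE,
                             stringsAsFactors = FALSE)
    mapping <- setNames(as.character(tab[[2]]), toupper(tab[[1]]))
    miss <- setdiff(.STD_AA, names(mapping))
    if (length(miss))
      stop("alphabet map does not cover residues: ",
           paste(miss, collapse = ", "))
    return(list(name = basename(name), mapping = mapping[.STD_AA],
                class_count = length(unique(mapping))))
  }
  name <- match.arg(name)
  mapping <- if (name == "identity20") setNames(.STD_AA, .STD_AA) else {
    classes <- list(LVIMC = c("L", "V", "I", "M", "C"), AG = c("A", "G"),
                    ST = c("S", "T"), P = "P", FWY = c("F", "W", "Y"),
                    EDNQ = c("E", "D", "N", "Q"), KR = c("K", "R"),
                    H = "H")
    m <- unlist(lapply(names(classes), function(cl)
      setNames(rep(cl, length(classes[[cl]])), classes[[cl]])))
    m[.STD_AA]
  }
  list(name = name, mapping = mapping,
       class_count = length(unique(mapping)))
}

#' Reduce an alignment column to class counts
#'
#' Gaps are excluded from the counts; nonstandard residues
#' (B, Z, X, U, O, J and stops) are excluded too and tallied in the
#' \code{"n_nonstandard"} attribute.
#'
#' @param residues character vector of single residues (one alignment
#'   column).
#' @param map an \code{\link{alphabetMap}}.
#' @return named integer vector of class counts, with attributes
#'   \code{n_gap} and \code{n_nonstandard}.
#' @export
reduceAlphabet <- function(residues, map = alphabetMap("identity20")) {
  r <- toupper(residues)
  is_gap <- r %in% .GAP_CHARS
  cls <- map$mapping[r[!is_gap]]
  n_nonstd <- sum(is.na(cls))
  counts <- table(cls[!is.na(cls)])
  out <- setNames(as.integer(counts), names(counts))
  attr(out, "n_gap") <- sum(is_gap)
  attr(out, "n_nonstandard") <- n_nonstd
  out
}

#' Shannon entropy of a column's class counts
#'
#' H = -sum p_i log2 p_i with p_i the class fractions (0 log 0 = 0).
#' Under the 20-letter alphabet H ranges from 0 for a completely
#' conserved column to log2(20) = 4.32 bits when all twenty residues
#' are equally represented.
#'
#' @param counts integer vector of class counts.
#' @return entropy in bits; NA for an empty column.
#' @export
columnEntropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(NA_real_)
  p <- counts / sum(counts)
  # + 0 normalizes IEEE negative zero for fully conserved columns
  -sum(p * log2(p)) + 0
}

#' Dual-alphabet positional entropy profile of a protein alignment
#'
#' Computes per-column Shannon entropy under the full 20-letter
#' alphabet and the reduced 8-class chemical alphabet. Columns whose
#' gap fraction exceeds \code{gap_threshold} are flagged. The plotting
#' convention follows the dual-track bar layout: the 20-alphabet track
#' is signed positive and the 8-alphabet track negative
#' (\code{H8_signed}) so they sit above and below zero.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or an \code{AAMultipleAlignment}/\code{AAStringSet}.
#' @param maps list of two alphabet maps (20-letter first).
#' @param gap_threshold gap-fraction flag threshold (default 0.5).
#' @return an \linkS4class{EntropyProfile}.
#' @export
msaProfile <- function(alignment,
                       maps = list(alphabetMap("identity20"),
                                   alphabetMap("chem8")),
                       gap_threshold = 0.5) {
  if (is(alignment, "AAMultipleAlignment"))
    alignment <- as.character(alignment)
  if (is(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  stopifnot(length(alignment) >= 2L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    bad <- names(alignment)[lens != stats::median(lens)]
    stop("ragged alignment; offending rows: ",
         paste(bad, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ncol_aln <- ncol(mat)
  H20 <- H8 <- gapf <- neff <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    c20 <- reduceAlphabet(col, maps[[1]])
    c8 <- reduceAlphabet(col, maps[[2]])
    H20[j] <- columnEntropy(c20)
    H8[j] <- columnEntropy(c8)
    gapf[j] <- attr(c20, "n_gap") / length(col)
    neff[j] <- sum(c20)
  }
  prof <- S4Vectors::DataFrame(
    column_index = seq_len(ncol_aln), H20 = H20, H8 = H8,
    H8_signed = -H8, gap_fraction = gapf, n_effective = as.integer(neff),
    gappy = gapf > gap_threshold)
  new("EntropyProfile", profile = prof, nRows = length(alignment),
      gapThreshold = gap_threshold)
}
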