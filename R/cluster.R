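#' Clustering parameters
#'
#' Two modes mirror the two tools whose semantics they reproduce:
#' \code{"single_linkage"} (minimum alignment coverage L on both
#' sequences, valid 0.2-0.5, plus a score threshold S, valid 20-50)
#' and \code{"greedy_incremental"} (identity threshold c, valid
#' 0.4-0.9, word length n, valid 2-5). Following the original tool's
#' documented dual semantics, an S above 3 is a percent score density
#' (100 x identities / alignment columns) and an S of at most 3 is a
#' bit score density (half-bit substitution score / 2 / columns).
#'
#' @param mode clustering mode.
#' @param min_coverage L analog: aligned fraction required of each
#'   sequence (single linkage: both; greedy: the shorter one).
#' @param min_score_density S analog (single linkage only).
#' @param min_identity c analog (greedy only).
#' @param word_length k-mer length of the greedy-mode prefilter.
#' @return parameter list.
#' @export
clusterParams <- function(mode = c("single_linkage", "greedy_incremental"),
                          min_coverage = 0.5, min_score_density = 50,
                          min_identity = 0.9, word_length = 5L) {
  mode <- match.arg(mode)
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1, word_length >= 1L)
  list(mode = mode, min_coverage = min_coverage,
       min_score_density = min_score_density, min_identity = min_identity,
       word_length = as.integer(word_length))
}

#' Pairwise identity, coverage and score density of two proteins
#'
#' Global alignment with end-gap-free (overlap) semantics under
#' BLOSUM62 with gap open 11 / extend 1. Identity is matches divided
#' by alignment columns excluding terminal gaps; coverage of each
#' sequence is its aligned span over its length; score density is the
#' percent form (100 x matches / columns) alongside the raw-score
#' bits-per-column form, so either threshold semantics can be applied.
#'
#' @param a,b amino-acid sequences (non-empty character scalars).
#' @return list with \code{identity}, \code{coverage_a},
#'   \code{coverage_b}, \code{score_density} (percent form),
#'   \code{bit_density}, \code{columns}.
#' @export
pairwiseIdentity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  cols <- Biostrings::nchar(aln)  # alignment columns excluding end gaps
  if (cols == 0L)
    return(list(identity = 0, coverage_a = 0, coverage_b = 0,
                score_density = 0, bit_density = -Inf, columns = 0L))
  nm <- Biostrings::nmatch(aln)
  pa <- Biostrings::pattern(aln)
  sb <- Biostrings::subject(aln)
  span_a <- Biostrings::end(pa) - Biostrings::start(pa) + 1L
  span_b <- Biostrings::end(sb) - Biostrings::start(sb) + 1L
  list(identity = nm / cols,
       coverage_a = span_a / nchar(a),
       coverage_b = span_b / nchar(b),
       score_density = 100 * nm / cols,
       bit_density = (Biostrings::score(aln) / 2) / cols,
       columns = cols)
}

.representative <- function(ids, lens) {
  # longest member; ties broken by lexicographically smallest id
  o <- order(-lens, ids)
  ids[o[1]]
}

.cluster_set <- function(membership, seqs, params) {
  ids <- names(seqs)
  lens <- nchar(seqs)
  clusters <- lapply(split(ids, membership), function(m) {
    m <- sort(m)
    list(representative_id = .representative(m, lens[m]), member_ids = m)
  })
  reps <- vapply(clusters, `[[`, character(1), "representative_id")
  clusters <- clusters[order(reps)]
  names(clusters) <- NULL
  list(clusters = clusters, params = params)
}

#' Single-linkage clustering of protein sequences
#'
#' Draws an edge between two sequences when the alignment covers at
#' least \code{min_coverage} of BOTH and the score density meets
#' \code{min_score_density}; clusters are the connected components
#' (union-find). The partition is independent of input order.
#'
#' @param seqs named character vector of protein sequences.
#' @param params \code{\link{clusterParams}} with mode
#'   \code{"single_linkage"}.
#' @return a cluster set: list with \code{clusters} (each
#'   \code{representative_id} + sorted \code{member_ids}) and
#'   \code{params}.
#' @export
singleLinkageCluster <- function(seqs, params = clusterParams()) {
  stopifnot(params$mode == "single_linkage")
  ids <- names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  use_percent <- params$min_score_density > 3
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (find(i) == find(j)) next
    pw <- pairwiseIdentity(seqs[[i]], seqs[[j]])
    dens <- if (use_percent) pw$score_density else pw$bit_density
    if (pw$coverage_a >= params$min_coverage &&
        pw$coverage_b >= params$min_coverage &&
        dens >= params$min_score_density)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  membership <- setNames(match(comp, unique(comp)), ids)
  .cluster_set(membership, seqs, params)
}

.kmer_multiset <- function(seq, k) {
  if (nchar(seq) < k) return(table(character()))
  table(substring(seq, 1:(nchar(seq) - k + 1L), k:nchar(seq)))
}

.shared_kmers <- function(t1, t2) {
  common <- intersect(names(t1), names(t2))
  if (length(common) == 0L) return(0L)
  sum(pmin(as.integer(t1[common]), as.integer(t2[common])))
}

#' Greedy-incremental deduplication clustering
#'
#' Sequences are processed longest-first (ties by id order); each
#' sequence joins the first existing representative with identity at
#' least \code{min_identity} and coverage of the shorter sequence at
#' least \code{min_coverage}, else founds a new cluster. A shared
#' k-mer prefilter (word length \code{word_length}) skips candidate
#' representatives that provably cannot reach the identity threshold:
#' a pair at identity c over the shorter length m shares at least
#' m - k + 1 - k * floor((1 - c) * m) of its k-mers, so only pairs
#' below threshold are ever skipped.
#'
#' @param seqs named character vector of protein sequences.
#' @param params \code{\link{clusterParams}} with mode
#'   \code{"greedy_incremental"}.
#' @param use_prefilter disable to force full alignment against every
#'   representative (for equivalence checks).
#' @return a cluster set (see \code{\link{singleLinkageCluster}}).
#' @export
greedyDedupe <- function(seqs, params = clusterParams("greedy_incremental"),
                         use_prefilter = TRUE) {
  stopifnot(params$mode == "greedy_incremental")
  ids <- names(seqs)
  o <- order(-nchar(seqs), ids)
  k <- params$word_length
  rep_idx <- integer()
  rep_kmers <- list()
  membership <- setNames(integer(length(seqs)), ids)
  for (i in o) {
    s <- seqs[[i]]
    km <- if (use_prefilter) .kmer_multiset(s, k) else NULL
    assigned <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- seqs[[rep_idx[ci]]]
      m <- min(nchar(s), nchar(r))
      if (use_prefilter) {
        bound <- (m - k + 1L) - k * floor((1 - params$min_identity) * m)
        if (bound > 0L && .shared_kmers(km, rep_kmers[[ci]]) < bound) next
      }
      pw <- pairwiseIdentity(s, r)
      cov_short <- if (nchar(s) <= nchar(r)) pw$coverage_a else pw$coverage_b
      if (pw$identity >= params$min_identity &&
          cov_short >= params$min_coverage) {
        membership[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      rep_kmers[[length(rep_idx)]] <- if (use_prefilter) km else character()
      membership[i] <- length(rep_idx)
    }
  }
  .cluster_set(membership, seqs, params)
}

#' Write a cluster set as TSV (and its representatives as FASTA)
#'
#' @param cluster_set result of a clustering operation.
#' @param path output TSV path (columns cluster_id,
#'   representative_id, member_id).
#' @param seqs optional sequences; when given, representatives are
#'   written next to the TSV as \code{<path>_reps.fasta}.
#' @return invisible vector of files written.
#' @export
writeClusterTable <- function(cluster_set, path, seqs = NULL) {
  rows <- do.call(rbind, lapply(seq_along(cluster_set$clusters),
                                function(i) {
    cl <- cluster_set$clusters[[i]]
    data.frame(cluster_id = sprintf("C%04d", i),
               representative_id = cl$representative_id,
               member_id = cl$member_ids, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(cluster_id = character(),
                       representative_id = character(),
                       member_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- path
  if (!is.null(seqs)) {
    reps <- vapply(cluster_set$clusters, `[[`, character(1),
                   "representative_id")
    fa <- paste0(tools::file_path_sans_ext(path), "_reps.fasta")
    writeFastaAA(seqs[reps], fa)
    files <- c(files, fa)
  }
  invisible(files)
}
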