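#' Call domain signatures on a protein sequence (synthetic mode)
#'
#' Scans a protein for the registry's signature blocks with a
#' configurable mismatch tolerance and returns the non-overlapping,
#' best-scoring hit set (greedy highest-score-first selection). This is
#' the synthetic-mode annotator for generator-built proteins; for real
#' proteins, import externally computed hits with
#' \code{\link{readDomainTable}}.
#'
.SEED_K <- 8L

# seed index: every exact 8-mer of every signature, keyed for O(1)
# candidate lookup; cached per registry object
.seed_index <- local({
  cache <- NULL
  cache_key <- NULL
  function(registry) {
    key <- paste(attr(registry, "version"), nrow(registry),
                 registry$domain_name[1])
    if (!is.null(cache) && identical(key, cache_key)) return(cache)
    k <- .SEED_K
    rows <- lapply(seq_len(nrow(registry)), function(i) {
      s <- registry$signature[i]
      data.frame(kmer = substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)),
                 sig = i, offset = 0:(nchar(s) - k),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    env <- new.env(hash = TRUE, size = nrow(tab))
    for (r in seq_len(nrow(tab))) {
      e <- env[[tab$kmer[r]]]
      env[[tab$kmer[r]]] <- rbind(e, c(tab$sig[r], tab$offset[r]))
    }
    raws <- lapply(registry$signature, charToRaw)
    idx <- list(env = env, raws = raws,
                lens = nchar(registry$signature))
    cache <<- idx
    cache_key <<- key
    idx
  }
})

#' @param protein amino-acid sequence (character scalar).
#' @param registry domain registry data.frame.
#' @param max_mismatch_frac maximum fraction of mismatching positions
#'   tolerated within a signature block (default 0.1).
#' @details Matching is seed-and-verify: candidate placements are
#'   located through exact 8-mer seeds shared with a signature and
#'   verified by counting mismatches over the full block. At the
#'   default tolerance this finds every placement that retains at
#'   least one exact 8-mer (for i.i.d. substitution noise up to the
#'   tolerated 10 percent, the probability that a block has no seed
#'   is well below 1e-3).
#' @return data.frame with columns \code{domain_name}, \code{aa_start},
#'   \code{aa_end} (0-based half-open), \code{score} (matching
#'   positions), sorted by \code{aa_start}; empty when nothing matches.
#' @export
callDomains <- function(protein, registry = domainRegistry(),
                        max_mismatch_frac = 0.1) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  idx <- .seed_index(registry)
  n <- nchar(protein)
  k <- .SEED_K
  empty <- data.frame(domain_name = character(), aa_start = integer(),
                      aa_end = integer(), score = numeric())
  if (n < k) return(empty)
  praw <- charToRaw(protein)
  kmers <- substring(protein, 1:(n - k + 1L), k:n)
  cand <- list()
  hit_at <- which(vapply(kmers, function(x)
    !is.null(idx$env[[x]]), logical(1)))
  for (pos in hit_at) {
    e <- idx$env[[kmers[pos]]]
    for (r in seq_len(nrow(e)))
      cand[[length(cand) + 1L]] <- c(e[r, 1L], pos - e[r, 2L])
  }
  if (length(cand) == 0L) return(empty)
  cand <- unique(do.call(rbind, cand))
  hits <- list()
  for (r in seq_len(nrow(cand))) {
    si <- cand[r, 1L]; st <- cand[r, 2L]
    L <- idx$lens[si]
    if (st < 1L || st + L - 1L > n) next
    nmm <- sum(praw[st:(st + L - 1L)] != idx$raws[[si]])
    if (nmm > floor(max_mismatch_frac * L)) next
    hits[[length(hits) + 1L]] <- data.frame(
      domain_name = registry$domain_name[si], aa_start = st - 1L,
      aa_end = st + L - 1L, score = L - nmm, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  h <- unique(do.call(rbind, hits))
  # greedy non-overlapping selection, best score first
  h <- h[order(-h$score, h$aa_end - h$aa_start, h$aa_start,
               h$domain_name), , drop = FALSE]
  keep <- logical(nrow(h))
  occ_s <- integer(); occ_e <- integer()
  for (j in seq_len(nrow(h))) {
    if (!any(h$aa_start[j] < occ_e & h$aa_end[j] > occ_s)) {
      keep[j] <- TRUE
      occ_s <- c(occ_s, h$aa_start[j]); occ_e <- c(occ_e, h$aa_end[j])
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$aa_start), , drop = FALSE]
}

#' Compose a protein's ordered domain architecture from hits
#'
#' Sorts hits by start and resolves overlaps: the higher score wins;
#' ties go to the longer hit, then to the smaller start.
#'
#' @param protein_id protein identifier.
#' @param hits data.frame of hits for this protein (columns
#'   \code{domain_name}, \code{aa_start}, \code{aa_end}, \code{score}).
#' @param source \code{"signature"} or \code{"imported"}.
#' @return list with \code{protein_id}, \code{domains} (resolved,
#'   sorted data.frame) and \code{source}.
#' @export
composeArchitecture <- function(protein_id, hits, source = "signature") {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(protein_id = protein_id,
                domains = data.frame(domain_name = character(),
                                     aa_start = integer(),
                                     aa_end = integer(), score = numeric()),
                source = source))
  if (is.null(hits$score)) hits$score <- hits$aa_end - hits$aa_start
  h <- hits[order(-hits$score, -(hits$aa_end - hits$aa_start),
                  hits$aa_start), , drop = FALSE]
  keep <- logical(nrow(h))
  occ_s <- integer(); occ_e <- integer()
  for (j in seq_len(nrow(h))) {
    if (!any(h$aa_start[j] < occ_e & h$aa_end[j] > occ_s)) {
      keep[j] <- TRUE
      occ_s <- c(occ_s, h$aa_start[j]); occ_e <- c(occ_e, h$aa_end[j])
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$aa_start), , drop = FALSE]
  rownames(h) <- NULL
  list(protein_id = protein_id, domains = h, source = source)
}

.match_subsequence <- function(arch, mandatory) {
  # how many of `mandatory` (in order) can be matched left-to-right
  pos <- 1L
  matched <- 0L
  for (d in mandatory) {
    while (pos <= length(arch) && arch[pos] != d) pos <- pos + 1L
    if (pos > length(arch)) break
    matched <- matched + 1L
    pos <- pos + 1L
  }
  matched
}

#' Map a domain architecture to a canonical component call
#'
#' Walks the ordered rule table (most-specific first); the first rule
#' whose mandatory domains appear in order wins. Fusion flags are set
#' from the rule's optional-domain conditions. When no rule matches
#' fully, a second pass accepts the first rule with at least half of
#' its mandatory domains present in order (confidence
#' \code{"partial"}); otherwise the component is \code{"unknown"}.
#'
#' @param arch an architecture from \code{\link{composeArchitecture}}.
#' @param rules rule table (default \code{\link{componentRules}()}).
#' @return list with \code{protein_id}, \code{component},
#'   \code{fusion_flags} (character), \code{confidence}
#'   (\code{"exact"} or \code{"partial"}).
#' @export
callComponent <- function(arch, rules = componentRules()) {
  d <- arch$domains$domain_name
  result <- function(component, flags, confidence)
    list(protein_id = arch$protein_id, component = component,
         fusion_flags = flags, confidence = confidence)
  if (length(d)) {
    for (r in rules) {
      if (!is.null(r$predicate)) {
        if (!r$predicate(d)) next
      } else {
        if (.match_subsequence(d, r$mandatory) < length(r$mandatory)) next
        if (r$exclusive && !all(d %in% c(r$mandatory, r$optional))) next
      }
      flags <- character()
      for (fn in names(r$flags)) if (r$flags[[fn]](d)) flags <- c(flags, fn)
      return(result(r$component, flags, "exact"))
    }
    # partial pass: incomplete genes (contig edges) keep >= half the
    # mandatory domains of some multi-domain rule; the best-covered
    # rule wins so a degraded architecture is not captured by a
    # superset rule evaluated earlier
    best <- NULL; best_frac <- 0; best_n <- 0L
    for (r in rules) {
      n <- length(r$mandatory)
      if (n < 2L || !is.null(r$predicate)) next
      m <- .match_subsequence(d, r$mandatory)
      if (2L * m < n) next
      frac <- m / n
      if (frac > best_frac + 1e-12 ||
          (abs(frac - best_frac) < 1e-12 && m > best_n)) {
        best <- r; best_frac <- frac; best_n <- m
      }
    }
    if (!is.null(best))
      return(result(best$component, character(), "partial"))
  }
  result("unknown", character(), "exact")
}

#' Annotate a set of proteins into component calls
#'
#' Convenience wrapper: signature-match (or look up imported hits),
#' compose architectures and call components for many proteins at once.
#'
#' @param proteins named character vector of protein sequences.
#' @param registry domain registry.
#' @param imported optional imported domain-hit data.frame (from
#'   \code{\link{readDomainTable}}); when given, signature matching is
#'   skipped and hits are taken from the table.
#' @param max_mismatch_frac passed to \code{\link{callDomains}}.
#' @return data.frame with one row per protein: \code{protein_id},
#'   \code{component}, \code{fusion_flags} (comma-joined),
#'   \code{confidence}, \code{architecture} (comma-joined domains).
#' @export
annotateProteins <- function(proteins, registry = domainRegistry(),
                             imported = NULL, max_mismatch_frac = 0.1) {
  rules <- componentRules()
  rows <- lapply(names(proteins), function(pid) {
    hits <- if (is.null(imported))
      callDomains(proteins[[pid]], registry, max_mismatch_frac)
    else {
      m <- imported[imported$protein_id == pid, , drop = FALSE]
      data.frame(domain_name = m$domain_name, aa_start = m$aa_start,
                 aa_end = m$aa_end,
                 score = if (is.null(m$score)) m$aa_end - m$aa_start
                         else m$score)
    }
    arch <- composeArchitecture(pid, hits,
                                if (is.null(imported)) "signature"
                                else "imported")
    cc <- callComponent(arch, rules)
    data.frame(protein_id = pid, component = cc$component,
               fusion_flags = paste(cc$fusion_flags, collapse = ","),
               confidence = cc$confidence,
               architecture = paste(arch$domains$domain_name,
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
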