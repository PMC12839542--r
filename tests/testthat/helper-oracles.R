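# independent brute-force oracles the implementation is checked against

# operon blocks by direct scan over the sorted gene table
oracle_blocks <- function(genome, max_gap, same_strand = TRUE) {
  g <- as.data.frame(genes(genome))
  if (nrow(g) == 0L) return(list())
  blocks <- list(1L)
  for (i in seq_len(nrow(g))[-1]) {
    gap <- g$start[i] - g$end[i - 1L]
    new_block <- gap > max_gap ||
      (same_strand && g$strand[i] != g$strand[i - 1L])
    if (new_block) blocks[[length(blocks) + 1L]] <- i
    else blocks[[length(blocks)]] <- c(blocks[[length(blocks)]], i)
  }
  blocks
}

# connected components over an explicit all-pairs edge list (BFS)
oracle_single_linkage <- function(seqs, params) {
  ids <- names(seqs)
  n <- length(ids)
  adj <- lapply(seq_len(n), function(i) integer())
  use_percent <- params$min_score_density > 3
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pw <- pairwiseIdentity(seqs[[i]], seqs[[j]])
    dens <- if (use_percent) pw$score_density else pw$bit_density
    if (pw$coverage_a >= params$min_coverage &&
        pw$coverage_b >= params$min_coverage &&
        dens >= params$min_score_density) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE
        queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(ids[comp])
  }
  comps
}

# greedy incremental clustering without any prefilter
oracle_greedy <- function(seqs, params) {
  ids <- names(seqs)
  o <- order(-nchar(seqs), ids)
  reps <- integer(); members <- list()
  for (i in o) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      pw <- pairwiseIdentity(seqs[[i]], seqs[[reps[ci]]])
      cov_short <- if (nchar(seqs[[i]]) <= nchar(seqs[[reps[ci]]]))
        pw$coverage_a else pw$coverage_b
      if (pw$identity >= params$min_identity &&
          cov_short >= params$min_coverage) {
        members[[ci]] <- c(members[[ci]], ids[i]); placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i)
      members[[length(reps)]] <- ids[i] }
  }
  lapply(members, sort)
}

# canonical form of a partition for comparison
partition_of <- function(cluster_set)
  unname(lapply(cluster_set$clusters, function(cl) sort(cl$member_ids)))

sort_partition <- function(p) p[order(vapply(p, `[`, character(1), 1))]

# closed-form Shannon entropy used as the entropy oracle
oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# seeded family of related sequences: a base sequence plus mutated /
# truncated relatives, for clustering tests
random_protein <- function(len)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")

mutate_protein <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  at <- sample(seq_along(ch), n_sub)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in at) ch[i] <- sample(setdiff(aa, ch[i]), 1L)
  paste(ch, collapse = "")
}

random_seq_family <- function(n, seed) {
  set.seed(seed)
  seqs <- character(n)
  i <- 1L
  while (i <= n) {
    base <- random_protein(sample(60:120, 1L))
    fam <- sample(1:3, 1L)
    for (f in seq_len(min(fam, n - i + 1L))) {
      s <- mutate_protein(base, sample(0:12, 1L))
      if (runif(1) < 0.3)
        s <- substr(s, 1L, max(30L, nchar(s) - sample(5:30, 1L)))
      seqs[i] <- s
      i <- i + 1L
    }
  }
  setNames(seqs, sprintf("s%03d", seq_len(n)))
}

# expected effector inventory for a truth locus, derived from the
# fixed role ontology applied to the planted composition
expected_effector_roles <- function(truth_locus) {
  comp <- truth_locus$components
  flags <- unlist(strsplit(comp$flags, ","))
  flags <- flags[nzchar(flags)]
  sys <- truth_locus$system; sub <- truth_locus$subtype
  aux_set <- c("PDDExK_REase", "NERD", "Shedu_REase", "HNH", "ParB_HNH",
               "SRA_HNH", "HKD", "TOPRIM", "REase")
  backup_set <- c("HEPN", "MNT", "PIN", "Schlafen")
  rows <- list()
  add <- function(domain, role)
    rows[[length(rows) + 1L]] <<- paste(domain, role, sep = "|")
  if ((sys == "BREX" || sub == "Type-3 BR") && "PglZ" %in% comp$component)
    add("PglZ", "primary")
  if (sub == "Type-1 BR" && "helicase:REase_fused" %in% flags)
    add("REase", "primary")
  if (sub == "Type-2 BR" && "helicase:HKD_fused" %in% flags)
    add("HKD", "primary")
  for (i in seq_len(nrow(comp))) {
    fl <- unlist(strsplit(comp$flags[i], ","))
    if ("BrxL:HKD" %in% fl) add("HKD", "auxiliary")
    if ("helicase:REase_fused" %in% fl && sub != "Type-1 BR")
      add("REase", "auxiliary")
    if ("helicase:HKD_fused" %in% fl && sub != "Type-2 BR")
      add("HKD", "auxiliary")
    if ("DUF499:HEPN_fused" %in% fl) add("HEPN", "backup")
    if ("HEPN:MNT_fused" %in% fl) add("MNT", "backup")
    if (comp$component[i] == "PglW") add("NERD", "auxiliary")
  }
  old_at <- which(comp$component == "OLD_ABC")
  dyad_partner <- unique(c(old_at - 1L, old_at + 1L))
  for (i in seq_len(nrow(comp))) {
    cc <- comp$component[i]
    if (cc == "OLD_ABC") add("OLD_ABC", "backup")
    else if (cc %in% backup_set) add(cc, "backup")
    else if (cc %in% aux_set)
      add(cc, if (i %in% dyad_partner) "backup" else "auxiliary")
  }
  sort(as.character(unlist(rows)))
}
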