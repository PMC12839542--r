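test_that("pairwise scores behave on identity, containment and noise", {
  pw <- pairwiseIdentity("MKLVRTWY", "MKLVRTWY")
  expect_equal(pw$identity, 1)
  expect_equal(pw$coverage_a, 1)
  expect_equal(pw$coverage_b, 1)
  expect_equal(pw$score_density, 100)

  pw2 <- pairwiseIdentity("AAAA", "AAAATTTT")
  expect_equal(pw2$identity, 1)
  expect_equal(pw2$coverage_a, 1)
  expect_equal(pw2$coverage_b, 0.5)

  # unrelated random 100-mers: identity stays below 0.4 whenever the
  # aligned region is substantial, and no clustering edge ever forms
  # (very short opportunistic alignments can score higher but fail
  # the coverage requirement)
  set.seed(404)
  for (i in 1:30) {
    pw <- pairwiseIdentity(random_protein(100), random_protein(100))
    if (pw$columns >= 30) expect_lt(pw$identity, 0.4)
    expect_false(pw$coverage_a >= 0.5 && pw$coverage_b >= 0.5 &&
                   pw$score_density >= 50)
  }
  expect_error(pairwiseIdentity("", "MK"))
})

test_that("single linkage merges chains and matches brute force", {
  # chain A~B, B~C with A and C unrelated still forms one cluster
  set.seed(3)
  base <- random_protein(140)
  A <- substr(base, 1, 70)
  B <- base
  C <- substr(base, 71, 140)
  seqs <- c(A = A, B = B, C = C)
  params <- clusterParams(min_coverage = 0.5, min_score_density = 90)
  pwAC <- pairwiseIdentity(A, C)
  expect_true(pwAC$coverage_a < 0.5 || pwAC$score_density < 90)
  cs <- singleLinkageCluster(seqs, params)
  expect_length(cs$clusters, 1L)
  expect_setequal(cs$clusters[[1]]$member_ids, c("A", "B", "C"))
  expect_equal(cs$clusters[[1]]$representative_id, "B")

  # unrelated sequences stay singletons
  set.seed(5)
  lone <- setNames(vapply(1:4, function(i) random_protein(80),
                          character(1)), letters[1:4])
  cs2 <- singleLinkageCluster(lone, clusterParams(min_score_density = 50))
  expect_length(cs2$clusters, 4L)

  # oracle equivalence on seeded mixed families
  for (seed in c(11, 12, 13)) {
    fam <- random_seq_family(30, seed)
    mine <- sort_partition(partition_of(
      singleLinkageCluster(fam, clusterParams(min_coverage = 0.5,
                                              min_score_density = 70))))
    ref <- sort_partition(oracle_single_linkage(
      fam, clusterParams(min_coverage = 0.5, min_score_density = 70)))
    expect_identical(mine, ref)
  }
})

test_that("single linkage is invariant under input permutation", {
  fam <- random_seq_family(24, seed = 21)
  params <- clusterParams(min_coverage = 0.4, min_score_density = 60)
  ref <- singleLinkageCluster(fam, params)
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(length(fam))
    expect_identical(partition_of(singleLinkageCluster(fam[perm], params)),
                     partition_of(ref))
  }
})

test_that("greedy dedupe respects identity thresholds and the prefilter", {
  # duplicated sequences collapse to one cluster per distinct sequence
  set.seed(9)
  s <- random_protein(100)
  dup <- c(a = s, b = s, c = random_protein(100))
  gp <- clusterParams("greedy_incremental", min_identity = 0.9,
                      min_coverage = 0.5)
  cs <- greedyDedupe(dup, gp)
  expect_length(cs$clusters, 2L)

  # a 95%-identical pair merges at c = 0.9 but not at c = 0.97
  set.seed(10)
  base <- random_protein(100)
  pair <- c(p = base, q = mutate_protein(base, 5L))
  expect_length(greedyDedupe(pair, gp)$clusters, 1L)
  gp97 <- clusterParams("greedy_incremental", min_identity = 0.97,
                        min_coverage = 0.5)
  expect_length(greedyDedupe(pair, gp97)$clusters, 2L)

  # the k-mer prefilter never changes the outcome at c >= 0.7
  for (seed in c(31, 32)) {
    fam <- random_seq_family(25, seed)
    for (c_thr in c(0.7, 0.9)) {
      p <- clusterParams("greedy_incremental", min_identity = c_thr,
                         min_coverage = 0.5)
      expect_identical(partition_of(greedyDedupe(fam, p)),
                       partition_of(greedyDedupe(fam, p,
                                                 use_prefilter = FALSE)))
    }
  }
})

test_that("greedy mode matches the no-prefilter brute-force reference", {
  for (seed in c(41, 42, 43)) {
    fam <- random_seq_family(28, seed)
    p <- clusterParams("greedy_incremental", min_identity = 0.8,
                       min_coverage = 0.5)
    expect_identical(sort_partition(partition_of(greedyDedupe(fam, p))),
                     sort_partition(oracle_greedy(fam, p)))
  }
})

test_that("raising the identity threshold only refines clusters", {
  fam <- random_seq_family(24, seed = 51)
  parts <- lapply(c(0.5, 0.7, 0.9), function(c_thr)
    partition_of(greedyDedupe(fam, clusterParams("greedy_incremental",
                                                 min_identity = c_thr,
                                                 min_coverage = 0.4))))
  cluster_of <- function(part) {
    m <- character()
    for (i in seq_along(part)) m[part[[i]]] <- i
    m
  }
  for (k in 1:2) {
    lo <- cluster_of(parts[[k]]); hi <- cluster_of(parts[[k + 1]])
    # members together at the stricter threshold stay together at the
    # looser one
    for (cl in unique(hi)) {
      ids <- names(hi)[hi == cl]
      expect_length(unique(lo[ids]), 1L)
    }
  }
})

test_that("cluster tables and representative FASTA are written", {
  fam <- random_seq_family(8, seed = 61)
  cs <- greedyDedupe(fam, clusterParams("greedy_incremental"))
  f <- tempfile(fileext = ".tsv")
  files <- writeClusterTable(cs, f, seqs = fam)
  tab <- utils::read.delim(f)
  expect_equal(sort(tab$member_id), sort(names(fam)))
  reps <- readFastaAA(files[2])
  expect_setequal(names(reps),
                  vapply(cs$clusters, `[[`, character(1),
                         "representative_id"))
})
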