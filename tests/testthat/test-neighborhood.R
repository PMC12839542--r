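test_that("intergenic gap follows the half-open convention", {
  g1 <- list(start = 100L, end = 400L, genome_id = "X")
  g2 <- list(start = 449L, end = 900L, genome_id = "X")
  expect_equal(intergenicGap(g1, g2), 49L)
  expect_equal(intergenicGap(list(start = 100, end = 400),
                             list(start = 400, end = 600)), 0L)
  expect_equal(intergenicGap(list(start = 100, end = 400),
                             list(start = 390, end = 600)), -10L)
  expect_error(intergenicGap(g1, list(start = 500, end = 600,
                                      genome_id = "Y")),
               "different genomes")
})

test_that("operon blocks split at the gap threshold and strand switches", {
  gen <- make_genome(c(100L, 449L, 1100L), c(400L, 900L, 1500L))
  b <- buildOperonBlocks(gen, neighborhoodParams(max_gap_nt = 100L))
  expect_length(b, 2L)
  expect_equal(b[[1]]$idx, 1:2)   # gap 49 joins, gap 200 splits
  expect_equal(b[[2]]$idx, 3L)

  gen2 <- make_genome(c(0L, 110L, 220L), c(100L, 210L, 320L),
                      strands = c("+", "+", "-"))
  b2 <- buildOperonBlocks(gen2, neighborhoodParams())
  expect_length(b2, 2L)
  expect_equal(b2[[2]]$idx, 3L)
  # under strand_mode "any" the strand switch does not split
  b2a <- buildOperonBlocks(gen2, neighborhoodParams(strand_mode = "any"))
  expect_length(b2a, 1L)

  single <- make_genome(500L, 900L)
  expect_length(buildOperonBlocks(single, neighborhoodParams()), 1L)
  # overlapping genes always co-block
  ovl <- make_genome(c(0L, 90L), c(100L, 200L), strands = c("+", "+"))
  expect_length(buildOperonBlocks(ovl, neighborhoodParams(max_gap_nt = 0L)),
                1L)
})

test_that("block partition matches a brute-force scan on random layouts", {
  for (seed in 1:40) {
    gen <- random_layout(sample(2:25, 1L), seed)
    for (gap in c(0L, 50L, 100L, 300L)) {
      mine <- buildOperonBlocks(gen, neighborhoodParams(max_gap_nt = gap))
      ref <- oracle_blocks(gen, gap)
      expect_identical(unname(lapply(mine, `[[`, "idx")), ref)
      # partition property
      expect_identical(sort(unname(unlist(lapply(mine, `[[`, "idx")))),
                       seq_len(nrow(genes(gen))))
    }
    # monotonicity: a larger gap threshold never creates more blocks
    n50 <- length(buildOperonBlocks(gen, neighborhoodParams(max_gap_nt = 50L)))
    n200 <- length(buildOperonBlocks(gen,
                                     neighborhoodParams(max_gap_nt = 200L)))
    expect_gte(n50, n200)
  }
})

test_that("locus extraction keeps the anchor block and near blocks only", {
  gen <- make_genome(c(100L, 449L, 1100L), c(400L, 900L, 1500L))
  l <- extractLocus(gen, "g01", neighborhoodParams(max_gap_nt = 100L))
  expect_equal(genes(l)$gene_id, c("g01", "g02"))
  expect_equal(locusSpan(l), c(100L, 900L))
  expect_equal(anchorGeneId(l), "g01")
  expect_error(extractLocus(gen, "nope"), "not found")

  single <- make_genome(500L, 900L)
  ls <- extractLocus(single, "g01")
  expect_equal(nrow(genes(ls)), 1L)

  # a divergently oriented block within the gap joins the locus
  gen2 <- make_genome(c(0L, 150L, 320L), c(100L, 250L, 500L),
                      strands = c("+", "+", "-"))
  l2 <- extractLocus(gen2, "g01", neighborhoodParams(max_gap_nt = 100L))
  expect_equal(nrow(genes(l2)), 3L)
  expect_equal(length(unique(genes(l2)$block_id)), 2L)
})

test_that("recovered loci equal planted truth spans on noiseless genomes", {
  for (s in c("Type-1", "Type-4", "BRC")) {
    g <- synthGenome(paste0("NL", s), s, n_decoys = 12, seed = 101)
    anchor <- g$truth$components$gene_id[1]
    l <- extractLocus(g$record, anchor)
    expect_setequal(genes(l)$gene_id, g$truth$components$gene_id)
    expect_equal(unname(locusSpan(l)), unname(g$truth$span))
  }
  # widening the gap threshold never shrinks a locus
  g <- synthGenome("MONO", "Type-2", n_decoys = 10, seed = 55)
  a <- g$truth$components$gene_id[1]
  n_small <- nrow(genes(extractLocus(g$record, a,
                                     neighborhoodParams(max_gap_nt = 60L))))
  n_big <- nrow(genes(extractLocus(g$record, a,
                                   neighborhoodParams(max_gap_nt = 100L))))
  expect_lte(n_small, n_big)
})

test_that("cross-phyla support flags single-phylum archetypes", {
  mk <- function(id, phylum, taxid, subtype, seed) {
    synthGenome(id, subtype, n_decoys = 0, seed = seed, taxid = taxid,
                lineage = c(superkingdom = "Bacteria",
                            phylum = phylum, species = id),
                assemblyId = paste0("A_", id))
  }
  # same operon seed twice: identical Type-1 composition in two phyla
  gens <- list(mk("CPa", "PhyA", 1L, "Type-1", seed = 7),
               mk("CPb", "PhyB", 2L, "Type-1", seed = 7),
               mk("CPc", "PhyA", 3L, "Type-3 BR", seed = 8))
  records <- setNames(lapply(gens, `[[`, "record"),
                      vapply(gens, function(x) genomeId(x$record),
                             character(1)))
  taxonomy <- do.call(rbind, lapply(records, function(r) data.frame(
    assembly_id = assemblyId(r), taxid = taxId(r),
    phylum = lineage(r)["phylum"], stringsAsFactors = FALSE)))
  proteins <- do.call(c, unname(lapply(records, function(r)
    setNames(genes(r)$translation, genes(r)$gene_id))))
  ann <- annotateProteins(proteins)
  loci <- lapply(names(records), function(gid)
    extractLocus(records[[gid]],
                 gens[[which(names(records) == gid)]]$truth$components$gene_id[1]))
  res <- crossPhylaFilter(loci, ann, records, taxonomy)
  # identical Type-1 loci occur in two phyla: kept; the BR archetype
  # is single-phylum: flagged but retained
  kept_ids <- vapply(res$kept, genomeId, character(1))
  flag_ids <- vapply(res$flagged, genomeId, character(1))
  expect_setequal(kept_ids, c("CPa", "CPb"))
  expect_equal(flag_ids, "CPc")
  expect_true("phyla_support" %in% locusFlags(res$flagged[[1]]))
  # unknown genome -> no_taxonomy flag
  res2 <- crossPhylaFilter(loci[3], ann, list(), taxonomy)
  expect_true("no_taxonomy" %in% locusFlags(res2$flagged[[1]]))
})
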