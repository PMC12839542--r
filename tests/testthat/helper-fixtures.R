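# shared fixtures: tiny genomes and cohorts built in code

make_gene_table <- function(starts, ends, strands = NULL, ids = NULL,
                            translations = NULL) {
  n <- length(starts)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  if (is.null(translations)) translations <- strrep("M", 50)[rep(1, n)]
  data.frame(gene_id = ids, start = starts, end = ends, strand = strands,
             translation = translations, product = "test protein",
             stringsAsFactors = FALSE)
}

make_genome <- function(starts, ends, strands = NULL, ids = NULL,
                        genome_id = "T1", taxid = 101L,
                        lineage = c(superkingdom = "Bacteria",
                                    phylum = "PhylumA",
                                    species = "Testus examplei")) {
  g <- make_gene_table(starts, ends, strands, ids)
  GenomeRecord(genome_id, g, seqLength = max(ends) + 500L,
               taxid = taxid, lineage = lineage)
}

# random gene layout on one strand-of-choice for property tests
random_layout <- function(n_genes, seed) {
  set.seed(seed)
  pos <- 0L
  starts <- integer(n_genes); ends <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    pos <- pos + sample(0:250, 1L)
    len <- sample(90:900, 1L)
    starts[i] <- pos; ends[i] <- pos + len
    pos <- pos + len
  }
  make_genome(starts, ends,
              strands = sample(c("+", "-"), n_genes, replace = TRUE),
              genome_id = sprintf("R%05d", seed))
}

small_cohort <- function(per_subtype = 2L, subtypes = subtypeGrammars(),
                         seed = 77L, noise_rate = 0, ...) {
  synthCohort(cohortSpec(
    subtype_mix = setNames(rep(as.integer(per_subtype), length(subtypes)),
                           subtypes),
    noise_rate = noise_rate, seed = seed, ...))
}

truth_subtypes <- function(cohort) {
  setNames(vapply(cohort$truth$loci, function(x) x$subtype, character(1)),
           vapply(cohort$truth$loci, function(x) x$genome_id, character(1)))
}

# recovered subtype per genome from a scan bundle
recovered_subtypes <- function(bundle) {
  got <- vapply(bundle$calls, subtypeOf, character(1))
  setNames(got, vapply(bundle$loci[names(got)], genomeId, character(1)))
}
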