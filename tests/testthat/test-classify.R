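test_that("the decision list reproduces the described subtype calls", {
  sc <- classifyLocus(c("BrxC", "BrxX", "PglZ", "BrxA", "BrxB", "BrxL"))
  expect_equal(systemOf(sc), "BREX")
  expect_equal(subtypeOf(sc), "Type-1")
  expect_equal(familyGroup(sc), "Type-1-family")
  expect_equal(completeness(sc), "complete")

  sc2 <- classifyLocus(c("DUF499_ATPASE", "BR_MTase", "BR_helicase",
                         "PglZ", "iSTAND"))
  expect_equal(subtypeOf(sc2), "Type-3 BR")
  expect_equal(completeness(sc2), "complete")

  sc3 <- classifyLocus("BrxC")
  expect_equal(systemOf(sc3), "unassigned")
  expect_equal(subtypeOf(sc3), "NA")
  expect_equal(completeness(sc3), "discarded")

  sc4 <- classifyLocus(c("BrxC", "PglZ", "BrxP", "DUF4007", "BrxL",
                         "CysDesulf"))
  expect_equal(subtypeOf(sc4), "Type-4")
  expect_equal(familyGroup(sc4), "other")

  sc5 <- classifyLocus(c("PglZ:minimal", "DUF6079", "STAND_active",
                         "DUF4007", "HerA_FtsK", "GNAT", "TGT"))
  expect_equal(systemOf(sc5), "BRC")
  expect_equal(completeness(sc5), "complete")

  # Type-2 via the BrxD+BrxHI dyad without PglW
  sc6 <- classifyLocus(c("BrxC", "BrxX", "PglZ", "BrxD", "BrxHI"))
  expect_equal(subtypeOf(sc6), "Type-2")
  expect_equal(completeness(sc6), "partial")

  # Type-2 BR by HKD-fused helicase even without DUF3780
  sc7 <- classifyLocus(c("DUF499_ATPase", "BR_MTase", "BrxHII"),
                       flags = "helicase:HKD_fused")
  expect_equal(subtypeOf(sc7), "Type-2 BR")

  # Type-5/Type-6 inside the Type-1 family; BrxE wins when both marks
  sc8 <- classifyLocus(c("BrxC", "BrxX", "PglZ", "BrxA", "BrxB",
                         "BrxHII"))
  expect_equal(subtypeOf(sc8), "Type-5")
  expect_equal(familyGroup(sc8), "Type-1-family")
  sc9 <- classifyLocus(c("BrxC", "BrxX", "PglZ", "BrxA", "BrxB", "BrxE",
                         "BrxHII"))
  expect_equal(subtypeOf(sc9), "Type-6")
  expect_true("review:Type-6_with_extra_helicase" %in% fusionFlags(sc9))

  # Type-3 BREX both by BrxXI and by the BrxF+BrxHII route
  expect_equal(subtypeOf(classifyLocus(c("BrxC", "BrxXI", "PglZ"))),
               "Type-3")
  expect_equal(subtypeOf(classifyLocus(c("BrxF", "BrxHII", "PglZ",
                                         "BrxC"))), "Type-3")
})

test_that("every locus gets exactly one deterministic call", {
  set.seed(62)
  for (i in 1:50) {
    comps <- sample(c("BrxC", "BrxX", "BrxXI", "PglZ", "BrxA", "BrxB",
                      "BrxL", "PglW", "BrxD", "BrxHI", "BrxHII", "BrxP",
                      "DUF499_ATPase", "BR_MTase", "DUF3780", "HerA_FtsK",
                      "STAND_active", "GNAT", "TGT", "BrxE", "unknown"),
                    sample(1:8, 1))
    sc <- classifyLocus(comps)
    expect_s4_class(sc, "SystemCall")
    expect_identical(subtypeOf(classifyLocus(comps)), subtypeOf(sc))
    if (subtypeOf(sc) %in% c("Type-5", "Type-6"))
      expect_equal(familyGroup(sc), "Type-1-family")
  }
})

make_locus_fixture <- function(subtype, seed) {
  g <- synthGenome(paste0("EF", seed), subtype, n_decoys = 4, seed = seed)
  prot <- setNames(genes(g$record)$translation, genes(g$record)$gene_id)
  ann <- annotateProteins(prot)
  l <- extractLocus(g$record, g$truth$components$gene_id[1])
  ids <- genes(l)$gene_id
  sc <- classifyLocus(
    ann$component[match(ids, ann$protein_id)],
    unlist(strsplit(ann$fusion_flags[match(ids, ann$protein_id)], ",")),
    locus_id = locusId(l))
  list(genome = g, locus = l, ann = ann, call = sc)
}

test_that("effector roles follow the fixed ontology", {
  # a Type-1 locus with an HKD-bearing BrxL: primary PglZ, auxiliary
  # HKD carried as a core-component fusion
  found <- FALSE
  for (seed in 1:30) {
    fx <- make_locus_fixture("Type-1", seed)
    if (!any(grepl("BrxL:HKD", fx$ann$fusion_flags))) next
    inv <- catalogEffectors(fx$locus, fx$call, fx$ann, fx$genome$record)
    expect_equal(inv$effector_domain[inv$role == "primary"], "PglZ")
    hkd <- inv[inv$effector_domain == "HKD", ]
    expect_equal(hkd$role, "auxiliary")
    expect_equal(hkd$provenance, "core_component_fusion")
    found <- TRUE
    break
  }
  expect_true(found)

  # Type-1 BR with a HEPN-fused ATPase: primary REase, backup HEPN
  found <- FALSE
  for (seed in 1:40) {
    fx <- make_locus_fixture("Type-1 BR", seed + 100)
    fl <- unlist(strsplit(fx$ann$fusion_flags, ","))
    if (!("DUF499:HEPN_fused" %in% fl &&
          "helicase:REase_fused" %in% fl)) next
    inv <- catalogEffectors(fx$locus, fx$call, fx$ann, fx$genome$record)
    expect_equal(inv$effector_domain[inv$role == "primary"], "REase")
    expect_equal(inv$provenance[inv$role == "primary"],
                 "core_component_fusion")
    expect_true(any(inv$effector_domain == "HEPN" &
                      inv$role == "backup"))
    found <- TRUE
    break
  }
  expect_true(found)

  # an adjacent OLD_ABC + TOPRIM pair flanking a locus forms a backup
  # dyad with flanking provenance
  reg <- domainRegistry()
  sig <- function(d) paste0("M", reg$signature[match(d, reg$domain_name)])
  set.seed(7)
  core <- sampleOperon(operonGrammar("Type-3 BR"), offset = 1000L)
  extra <- data.frame(
    gene_id = c("old1", "top1"),
    start = max(core$genes$end) + c(80L, 500L),
    end = max(core$genes$end) + c(440L, 900L),
    strand = "+",
    translation = c(sig("OLD_ABC"), sig("TOPRIM")),
    product = "x", stringsAsFactors = FALSE)
  extra$end <- extra$start + 3L * nchar(extra$translation)
  extra$start[2] <- extra$end[1] + 60L
  extra$end[2] <- extra$start[2] + 3L * nchar(extra$translation[2])
  gen <- GenomeRecord("DY", rbind(core$genes, extra),
                      seqLength = max(extra$end) + 200L, taxid = 5L)
  prot <- setNames(genes(gen)$translation, genes(gen)$gene_id)
  ann <- annotateProteins(prot)
  l <- extractLocus(gen, core$truth$gene_id[1],
                    neighborhoodParams(window_genes = 4L))
  sc <- classifyLocus(ann$component[match(genes(l)$gene_id,
                                          ann$protein_id)],
                      locus_id = locusId(l))
  inv <- catalogEffectors(l, sc, ann, gen)
  dyad <- inv[inv$carrier_protein %in% c("old1", "top1"), ]
  expect_setequal(dyad$effector_domain, c("OLD_ABC", "TOPRIM"))
  expect_true(all(dyad$role == "backup"))
  expect_true(sum(inv$role == "primary") <= 1L)
})

test_that("cohort summaries count subtypes, retention and discards", {
  co <- small_cohort(2L, seed = 71)
  b <- runScan(runConfig(genomes = co$records, taxonomy = co$taxonomy))
  s <- summarizeCohort(b$calls, b$effectors)
  tt <- table(truth_subtypes(co))
  expect_equal(as.integer(s$subtype_counts[names(tt)]),
               as.integer(tt))
  ret <- s$component_retention
  expect_true(all(ret$fraction > 0 & ret$fraction <= 1))
  # BrxC is in every Type-1 locus
  expect_equal(ret$fraction[ret$subtype == "Type-1" &
                              ret$component == "BrxC"], 1)
  expect_true(all(c("primary", "auxiliary") %in%
                    names(s$effector_classes) |
                    sum(s$effector_classes) >= 0))
  # empty input gives a zeroed report
  s0 <- summarizeCohort(list())
  expect_equal(length(s0$subtype_counts), 0L)
  expect_equal(nrow(s0$discarded), 0L)
})

test_that("component dropout produces partial calls that are reported", {
  co <- small_cohort(4L, c("Type-1", "Type-2"), seed = 81,
                     dropout_rate = 0.25)
  b <- runScan(runConfig(genomes = co$records, taxonomy = co$taxonomy))
  s <- summarizeCohort(b$calls)
  cc <- s$completeness_counts
  expect_true(sum(cc) == length(b$calls))
  expect_true(any(names(cc) %in% c("partial", "discarded")) ||
                all(names(cc) == "complete"))
})
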