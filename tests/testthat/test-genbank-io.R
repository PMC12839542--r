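test_that("GenBank coordinates convert 1-based inclusive to 0-based half-open", {
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       TESTA 1000 bp    DNA     linear   BCT 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    '                     /db_xref="taxon:42"',
    "     CDS             101..400",
    '                     /locus_tag="gA"',
    '                     /translation="MKKLLVV"',
    "     CDS             complement(501..700)",
    '                     /locus_tag="gB"',
    '                     /translation="MAAAT"',
    "//"), gbk)
  recs <- readGenBank(gbk)
  g <- genes(recs[[1]])
  expect_equal(g$start, c(100L, 500L))
  expect_equal(g$end, c(400L, 700L))
  expect_equal(g$strand, c("+", "-"))
  expect_equal(taxId(recs[[1]]), 42L)
})

test_that("generator GenBank output round-trips the truth gene table", {
  g <- synthGenome("RT1", "Type-2", n_decoys = 4, seed = 5)
  f <- tempfile(fileext = ".gbk")
  writeGenBank(g$record, f)
  back <- readGenBank(f)[[1]]
  expect_identical(as.data.frame(genes(back)),
                   as.data.frame(genes(g$record)))
  expect_equal(length(back), length(g$record))
  expect_equal(taxId(back), taxId(g$record))
  expect_equal(assemblyId(back), assemblyId(g$record))
  expect_equal(unname(lineage(back)["phylum"]),
               unname(lineage(g$record)["phylum"]))
})

test_that("multi-record files, join collapse and missing translations", {
  g1 <- synthGenome("MRA", "Type-1", n_decoys = 2, seed = 1)$record
  g2 <- synthGenome("MRB", "Type-3", n_decoys = 2, seed = 2)$record
  f <- tempfile(fileext = ".gbk")
  writeGenBank(list(g1, g2), f)
  recs <- readGenBank(f)
  expect_length(recs, 2L)
  expect_setequal(names(recs), c("MRA", "MRB"))

  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       JOINY 5000 bp    DNA     linear   BCT 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(11..100,201..400)",
    '                     /locus_tag="gJ"',
    '                     /translation="MWWW"',
    "     CDS             601..700",
    '                     /locus_tag="gN"',
    "//"), gbk)
  expect_warning(expect_warning(recs <- readGenBank(gbk),
                                "collapsed to outer span"),
                 "lacks a translation")
  g <- genes(recs[[1]])
  expect_equal(nrow(g), 1L)           # the untranslated CDS was skipped
  expect_equal(c(g$start, g$end), c(10L, 400L))
  expect_equal(attr(recs, "skip_report")$reason, "no_translation")
})

test_that("FASTA read/write round-trips, upper-cases and rejects duplicates", {
  f <- tempfile(fileext = ".fasta")
  recs <- c(p1 = "MKLV", p2 = "mwtt", p3 = paste(rep("ACDE", 40),
                                                 collapse = ""))
  writeFastaAA(recs, f)
  back <- readFastaAA(f)
  expect_equal(names(back), names(recs))
  expect_equal(unname(back), unname(toupper(recs)))
  expect_equal(nchar(back[["p2"]]), 4L)

  # aligned FASTA with gaps round-trips; ragged rows are accepted here
  f2 <- tempfile(fileext = ".fasta")
  writeFastaAA(c(a = "MK-V", b = "MKL"), f2)
  expect_silent(ali <- readFastaAA(f2))
  expect_equal(unname(nchar(ali)), c(4L, 3L))
  expect_error(msaProfile(ali), "ragged")

  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "MK", ">x", "ML"), f3)
  expect_error(readFastaAA(f3), "duplicate")
  f4 <- tempfile(fileext = ".fasta")
  file.create(f4)
  expect_length(readFastaAA(f4), 0L)
})

test_that("domain tables convert coordinates and label unknown domains", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_name\taa_start\taa_end\tscore",
               "P1\tPglZ_core\t430\t720\t85.2",
               "P2\tFooBar\t10\t60\t12"), f)
  tab <- readDomainTable(f)
  expect_equal(tab$aa_start, c(429L, 9L))
  expect_equal(tab$aa_end, c(720L, 60L))
  expect_equal(tab$domain_name[2], "other:FooBar")

  f2 <- tempfile(fileext = ".tsv")
  writeLines("protein_id\tdomain_name\taa_start\taa_end\tscore", f2)
  expect_equal(nrow(readDomainTable(f2)), 0L)

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_name\taa_start", "P\tX\t5"), f3)
  expect_error(readDomainTable(f3), "missing columns")

  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_name\taa_start\taa_end\tscore",
               "P1\tHNH\t90\t30\t5"), f4)
  expect_error(readDomainTable(f4), "line")
})

test_that("result tables are written deterministically with JSON sidecars", {
  co <- small_cohort(1L, c("Type-1", "BRC"), seed = 9)
  b <- runScan(runConfig(genomes = co$records, taxonomy = co$taxonomy))
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  writeTables(b$calls, file.path(d1, "calls.tsv"), "calls")
  writeTables(b$calls, file.path(d2, "calls.tsv"), "calls")
  expect_identical(readLines(file.path(d1, "calls.tsv")),
                   readLines(file.path(d2, "calls.tsv")))
  expect_true(file.exists(file.path(d1, "calls.json")))
  js <- jsonlite::read_json(file.path(d1, "calls.json"),
                            simplifyVector = TRUE)
  tsv <- utils::read.delim(file.path(d1, "calls.tsv"))
  expect_equal(nrow(js), nrow(tsv))
  expect_equal(js$locus_id, tsv$locus_id)

  # empty inputs give header-only tables
  f <- tempfile(fileext = ".tsv")
  writeTables(list(), f, "loci")
  expect_equal(length(readLines(f)), 1L)
})
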