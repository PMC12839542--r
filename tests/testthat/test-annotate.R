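reg <- domainRegistry()

protein_for <- function(arch_key) {
  op <- NULL
  sig <- function(d) reg$signature[match(d, reg$domain_name)]
  doms <- brexscan:::.componentArchitectures()[[arch_key]]
  paste0("M", paste(sig(doms), collapse = "GSGSGSGS"))
}

test_that("signature matching recovers planted architectures in order", {
  p <- protein_for("BrxC")
  hits <- callDomains(p, reg)
  expect_equal(hits$domain_name,
               c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH",
                 "coiledcoil", "terminal_subdomain"))
  expect_true(all(diff(hits$aa_start) > 0))
  expect_true(all(hits$score == nchar(reg$signature[1])))

  # decoy: no hits at all
  set.seed(8)
  expect_equal(nrow(callDomains(random_protein(250), reg)), 0L)

  # 5% substitution noise keeps the hit list at default tolerance
  set.seed(12)
  noisy <- brexscan:::.mutate_protein(p, 0.05)
  hits2 <- callDomains(noisy, reg)
  expect_equal(hits2$domain_name, hits$domain_name)
  expect_equal(hits2$aa_start, hits$aa_start)
  expect_true(all(hits2$score < hits$score))
})

test_that("architecture composition resolves overlaps by score", {
  hits <- data.frame(domain_name = c("HNH", "PIN"),
                     aa_start = c(10L, 30L), aa_end = c(60L, 80L),
                     score = c(50, 30))
  arch <- composeArchitecture("P", hits)
  expect_equal(arch$domains$domain_name, "HNH")
  # tie on score: the longer hit wins
  hits2 <- data.frame(domain_name = c("HNH", "PIN"),
                      aa_start = c(10L, 5L), aa_end = c(60L, 90L),
                      score = c(40, 40))
  expect_equal(composeArchitecture("P", hits2)$domains$domain_name, "PIN")
  expect_equal(nrow(composeArchitecture("P", NULL)$domains), 0L)
  # imported table rows pass through sorted
  imp <- data.frame(domain_name = c("wHTH", "AAA_ATPase"),
                    aa_start = c(200L, 0L), aa_end = c(260L, 180L),
                    score = c(20, 90))
  expect_equal(composeArchitecture("P", imp, "imported")$domains$domain_name,
               c("AAA_ATPase", "wHTH"))
})

arch_of <- function(domains)
  list(protein_id = "P",
       domains = data.frame(domain_name = domains,
                            aa_start = seq(0, by = 100,
                                           length.out = length(domains)),
                            aa_end = seq(90, by = 100,
                                         length.out = length(domains)),
                            score = rep(100, length(domains))),
       source = "signature")

test_that("component rules map architectures to canonical calls", {
  cc <- callComponent(arch_of(c("SIGMA_HTH", "OB_fold", "MCM_ATPase",
                                "HKD")))
  expect_equal(cc$component, "BrxL")
  expect_true("BrxL:HKD" %in% cc$fusion_flags)

  cc2 <- callComponent(arch_of(c("NERD", "pseudokinase", "STY_kinase",
                                 "RNApolA_CTD", "wHTH", "wHTH", "wHTH",
                                 "iSTAND")))
  expect_equal(cc2$component, "PglW")

  # minimal BRC-style PglZ: core only, no linker, no C-terminal domain
  cc3 <- callComponent(arch_of("PglZ_core"))
  expect_equal(cc3$component, "PglZ")
  expect_true("PglZ:minimal" %in% cc3$fusion_flags)
  cc3b <- callComponent(arch_of(c("iSwi2Snf2", "PglZ_core")))
  expect_true("PglZ:minimal" %in% cc3b$fusion_flags)
  # the full-length form does not carry the minimal flag
  cc4 <- callComponent(arch_of(c("iSwi2Snf2", "HTH", "helical_linker",
                                 "PglZ_core", "beta_sandwich")))
  expect_equal(cc4$component, "PglZ")
  expect_false("PglZ:minimal" %in% cc4$fusion_flags)

  # BrxA/DUF4007: 2-3 HTH/wHTH and nothing else
  expect_equal(callComponent(arch_of(c("HTH", "wHTH")))$component, "BrxA")
  expect_equal(callComponent(arch_of(c("HTH", "wHTH", "wHTH")))$component,
               "BrxA")
  expect_equal(callComponent(arch_of(c("HTH", "wHTH", "wHTH",
                                       "HTH")))$component, "unknown")
  # standalone iSTAND vs active STAND are distinct registry domains
  expect_equal(callComponent(arch_of("iSTAND"))$component, "iSTAND")
  expect_equal(callComponent(arch_of("STAND_active"))$component,
               "STAND_active")
  expect_equal(callComponent(arch_of("AAA_ATPase"))$component, "BrxD")
  expect_equal(callComponent(arch_of(character()))$component, "unknown")
})

test_that("incomplete architectures fall back to partial confidence", {
  # BrxC missing one interior mandatory domain is still called BrxC
  cc <- callComponent(arch_of(c("AAA_ATPase", "wHTH", "wHTH")))
  expect_equal(cc$component, "BrxC")
  expect_equal(cc$confidence, "partial")
  # and is not captured by the DUF499 superset rule
  cc2 <- callComponent(arch_of(c("AAA_ATPase", "wHTH", "alphabeta_core")))
  expect_equal(cc2$component, "BrxC")
  expect_equal(cc2$confidence, "partial")
})

test_that("rule evaluation is total, deterministic and tier-stable", {
  archs <- lapply(names(brexscan:::.componentArchitectures()), function(k)
    arch_of(brexscan:::.componentArchitectures()[[k]]))
  rules <- componentRules()
  base <- vapply(archs, function(a) callComponent(a, rules)$component,
                 character(1))
  expect_false(any(is.na(base)))
  # permute rules within equal-specificity tiers: calls do not change
  nmand <- vapply(rules, function(r) length(r$mandatory), integer(1))
  set.seed(14)
  for (rep in 1:5) {
    perm <- unlist(lapply(split(seq_along(rules), nmand)[order(
      -as.integer(names(split(seq_along(rules), nmand))))], sample))
    shuffled <- rules[perm]
    got <- vapply(archs, function(a)
      callComponent(a, shuffled)$component, character(1))
    expect_identical(got, base)
  }
})

test_that("every grammar's planted components and flags are recovered", {
  set.seed(33)
  for (s in subtypeGrammars()) {
    for (rep in 1:3) {
      op <- sampleOperon(operonGrammar(s))
      ann <- annotateProteins(setNames(op$genes$translation,
                                       op$genes$gene_id))
      expect_identical(ann$component, op$truth$component,
                       label = paste(s, "components"))
      got_flags <- lapply(strsplit(ann$fusion_flags, ","),
                          function(x) sort(x[nzchar(x)]))
      want_flags <- lapply(strsplit(op$truth$flags, ","),
                           function(x) sort(x[nzchar(x)]))
      expect_identical(got_flags, want_flags, label = paste(s, "flags"))
      expect_true(all(ann$confidence == "exact"))
    }
  }
})

test_that("imported domain tables drive annotation in real mode", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_name\taa_start\taa_end\tscore",
               "P1\tSIGMA_HTH\t1\t80\t40",
               "P1\tOB_fold\t81\t180\t50",
               "P1\tMCM_ATPase\t181\t500\t90",
               "P1\tLonP\t501\t700\t60",
               "P2\tHerA_FtsK\t1\t400\t99"), f)
  imp <- readDomainTable(f)
  ann <- annotateProteins(c(P1 = "M", P2 = "M"), imported = imp)
  expect_equal(ann$component, c("BrxL", "HerA_FtsK"))
  expect_equal(ann$fusion_flags[1], "BrxL:LonP")
})
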