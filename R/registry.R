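#' The shipped domain registry
#'
#' Loads the versioned JSON registry of domain names used throughout
#' the package: the controlled vocabulary for component rules plus, for
#' synthetic mode, one unique amino-acid signature block (36 aa,
#' mutually distinguishable) per domain. The signatures are synthetic
#' constructs for planted-truth benchmarking; the signature matcher is
#' not claimed to detect real domains (real-mode annotation is
#' import-only via \code{\link{readDomainTable}}).
#'
#' @param path optional path to a user-edited registry JSON with the
#'   same shape as the shipped one.
#' @return data.frame with columns \code{domain_name},
#'   \code{signature}, \code{family_class}, \code{description}; the
#'   registry version is kept in the \code{"version"} attribute.
#' @export
domainRegistry <- local({
  cache <- NULL
  function(path = NULL) {
    if (is.null(path) && !is.null(cache)) return(cache)
    p <- if (is.null(path))
      system.file("extdata", "domain_registry.json", package = "brexscan")
    else path
    raw <- jsonlite::read_json(p, simplifyVector = TRUE)
    reg <- as.data.frame(raw$entries, stringsAsFactors = FALSE)
    if (anyDuplicated(reg$domain_name)) stop("duplicate registry domains")
    attr(reg, "version") <- raw$registry_version
    if (is.null(path)) cache <<- reg
    reg
  }
})

# Component rule table. Each rule: component name, mandatory domains
# (matched in order as a subsequence of the architecture), optional
# domains, fusion-flag conditions, and whether the rule is exclusive
# (no domains outside mandatory+optional allowed). Rules are evaluated
# most-specific first; the stored order within a specificity tier is a
# deterministic tie-break only (see componentRules()).
.rule <- function(component, mandatory, optional = character(),
                  flags = list(), exclusive = FALSE, predicate = NULL) {
  list(component = component, mandatory = mandatory, optional = optional,
       flags = flags, exclusive = exclusive, predicate = predicate)
}

#' The component rule table
#'
#' The ordered decision table mapping a protein's domain architecture
#' to a canonical component name. Mandatory domains must appear in
#' order (extra uncalled segments and lineage-specific insertions are
#' tolerated unless the rule is exclusive); optional domains set fusion
#' flags. Evaluation is most-specific (longest mandatory list) first.
#'
#' @return list of rule entries, already sorted for evaluation.
#' @export
componentRules <- function() {
  rules <- list(
    .rule("PglW", c("NERD", "pseudokinase", "STY_kinase", "RNApolA_CTD",
                    "wHTH", "wHTH", "wHTH", "iSTAND")),
    .rule("BR_MTase", c("DUF1156_helical", "N6_MTase", "TRD_insert", "HTH",
                        "wHTH", "HTH"),
          optional = c("Zn4C")),
    .rule("BrxXI", c("N6_MTase", "TRD_insert", "HTH", "wHTH", "HTH"),
          optional = c("Zn4C")),
    .rule("DUF499_ATPase", c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH",
                             "RRM"),
          optional = c("FnIII", "HEPN"),
          flags = list("DUF499:HEPN_fused" = function(d) d[1] == "HEPN",
                       "DUF499:FnIII" = function(d) "FnIII" %in% d)),
    .rule("BrxC", c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH"),
          optional = c("coiledcoil", "terminal_subdomain")),
    .rule("BrxHI", c("Ski2_helicase", "wHTH", "HAS_barrel", "Lhr_CTD")),
    .rule("BrxX", c("N_helical_bundle", "N6_MTase", "TRD_Cterm"),
          optional = c("wHTH", "coiledcoil_ext")),
    .rule("BrxL", c("SIGMA_HTH", "OB_fold", "MCM_ATPase"),
          optional = c("LonP", "HKD"),
          flags = list("BrxL:LonP" = function(d) "LonP" %in% d,
                       "BrxL:HKD" = function(d) "HKD" %in% d)),
    .rule("PglZ", c("helical_linker", "PglZ_core"),
          optional = c("iSTAND", "iSwi2Snf2", "HTH", "beta_sandwich", "wHTH"),
          flags = list("PglZ:iSTAND_fused" = function(d) "iSTAND" %in% d)),
    .rule("BrxHII", c("Swi2Snf2_helicase"),
          optional = c("TUDOR", "HKD", "iREase", "alphabeta_CTD", "REase"),
          flags = list("helicase:HKD_fused" = function(d) "HKD" %in% d,
                       "helicase:REase_fused" = function(d) "REase" %in% d)),
    .rule("BrxP", c("PAPS_reductase"),
          optional = c("DUF1795", "ferredoxin_4Fe4S", "HTH", "wHTH"),
          flags = list("BrxP:DUF4007_fused" =
                         function(d) sum(d %in% c("HTH", "wHTH")) >= 2)),
    .rule("DUF3780", c("DUF3780_core"),
          optional = c("ASCH_PUA", "RAMA"),
          flags = list("DUF3780:ASCH_PUA_fused" =
                         function(d) "ASCH_PUA" %in% d,
                       "DUF3780:RAMA_fused" = function(d) "RAMA" %in% d)),
    # minimal BRC-style PglZ: core +/- the inactive Swi2/Snf2 P-loop only
    .rule("PglZ", c("PglZ_core"), optional = c("iSwi2Snf2"),
          flags = list("PglZ:minimal" = function(d) TRUE), exclusive = TRUE),
    .rule("ZnHTH", c("zinc_finger", "HTH"), exclusive = TRUE),
    .rule("CysDesulf", c("cysteine_desulfurase")),
    .rule("HerA_FtsK", c("HerA_FtsK")),
    .rule("GNAT", c("GNAT")),
    .rule("TGT", c("TGT")),
    .rule("BrxE", c("BrxE_sig")),
    .rule("BrxD", c("AAA_ATPase"), exclusive = TRUE),
    .rule("iSTAND", c("iSTAND"), exclusive = TRUE),
    .rule("STAND_active", c("STAND_active"), exclusive = TRUE),
    # BrxA / DUF4007: 2-3 consecutive HTH/wHTH modules and nothing else
    .rule("BrxA", c("HTH"), exclusive = TRUE, predicate = function(d)
      length(d) >= 2 && length(d) <= 3 && all(d %in% c("HTH", "wHTH"))),
    # standalone effector proteins
    .rule("HEPN", c("HEPN"), optional = c("MNT"),
          flags = list("HEPN:MNT_fused" = function(d) "MNT" %in% d),
          exclusive = TRUE),
    .rule("PDDExK_REase", c("PDDExK_REase"), exclusive = TRUE),
    .rule("NERD", c("NERD"), exclusive = TRUE),
    .rule("Shedu_REase", c("Shedu_REase"), exclusive = TRUE),
    .rule("HNH", c("HNH"), exclusive = TRUE),
    .rule("ParB_HNH", c("ParB_HNH"), exclusive = TRUE),
    .rule("SRA_HNH", c("SRA_HNH"), exclusive = TRUE),
    .rule("HKD", c("HKD"), exclusive = TRUE),
    .rule("TOPRIM", c("TOPRIM"), exclusive = TRUE),
    .rule("OLD_ABC", c("OLD_ABC"), exclusive = TRUE),
    .rule("PIN", c("PIN"), exclusive = TRUE),
    .rule("Schlafen", c("Schlafen_kinase_wHTH"), exclusive = TRUE)
  )
  # most-specific first; stable within a tier
  nmand <- vapply(rules, function(r) length(r$mandatory), integer(1))
  rules[order(-nmand, seq_along(rules))]
}

# Domain composition used by the synthetic generator for each component
# variant. Names index into the grammar tables in synthdata.R.
.componentArchitectures <- function() list(
  BrxC = c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH", "coiledcoil",
           "terminal_subdomain"),
  BrxX = c("N_helical_bundle", "N6_MTase", "TRD_Cterm", "wHTH"),
  PglZ = c("iSwi2Snf2", "HTH", "helical_linker", "PglZ_core",
           "beta_sandwich"),
  PglZ_T2 = c("iSwi2Snf2", "HTH", "helical_linker", "PglZ_core", "wHTH"),
  PglZ_T3 = c("iSwi2Snf2", "HTH", "helical_linker", "PglZ_core"),
  PglZ_iSTAND = c("iSTAND", "iSwi2Snf2", "HTH", "helical_linker",
                  "PglZ_core"),
  PglZ_standalone = c("helical_linker", "PglZ_core"),
  PglZ_minimal = c("iSwi2Snf2", "PglZ_core"),
  BrxA = c("HTH", "wHTH"),
  BrxA3 = c("HTH", "wHTH", "wHTH"),
  BrxB = "iSTAND",
  BrxF = "iSTAND",
  iSTAND = "iSTAND",
  STAND_active = "STAND_active",
  BrxL = c("SIGMA_HTH", "OB_fold", "MCM_ATPase", "LonP"),
  BrxL_HKD = c("SIGMA_HTH", "OB_fold", "MCM_ATPase", "HKD"),
  BrxL_T4 = c("SIGMA_HTH", "OB_fold", "MCM_ATPase"),
  PglW = c("NERD", "pseudokinase", "STY_kinase", "RNApolA_CTD", "wHTH",
           "wHTH", "wHTH", "iSTAND"),
  BrxD = "AAA_ATPase",
  BrxHI = c("Ski2_helicase", "wHTH", "HAS_barrel", "Lhr_CTD"),
  BrxXI = c("N6_MTase", "TRD_insert", "Zn4C", "HTH", "wHTH", "HTH"),
  BrxHII = c("TUDOR", "Swi2Snf2_helicase", "iREase", "alphabeta_CTD"),
  BrxHII_REase = c("TUDOR", "Swi2Snf2_helicase", "iREase", "alphabeta_CTD",
                   "REase"),
  BR_helicase_REase = c("TUDOR", "Swi2Snf2_helicase", "iREase",
                        "alphabeta_CTD", "REase"),
  BR_helicase_HKD = c("HKD", "Swi2Snf2_helicase", "iREase", "alphabeta_CTD"),
  BR_MTase = c("DUF1156_helical", "N6_MTase", "TRD_insert", "Zn4C", "HTH",
               "wHTH", "HTH"),
  DUF499 = c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH", "RRM"),
  DUF499_HEPN = c("HEPN", "AAA_ATPase", "wHTH", "alphabeta_core", "wHTH",
                  "RRM"),
  DUF499_FnIII = c("AAA_ATPase", "wHTH", "alphabeta_core", "wHTH", "FnIII",
                   "FnIII", "RRM"),
  DUF3780 = "DUF3780_core",
  BrxP = c("PAPS_reductase", "DUF1795", "ferredoxin_4Fe4S"),
  BrxP_DUF4007 = c("PAPS_reductase", "DUF1795", "ferredoxin_4Fe4S", "HTH",
                   "wHTH", "wHTH"),
  CysDesulf = "cysteine_desulfurase",
  ZnHTH = c("zinc_finger", "HTH"),
  BrxE = "BrxE_sig",
  HerA_FtsK = "HerA_FtsK",
  GNAT = "GNAT",
  TGT = "TGT",
  HEPN = "HEPN",
  HEPN_MNT = c("HEPN", "MNT"),
  PDDExK_REase = "PDDExK_REase",
  Shedu_REase = "Shedu_REase",
  HNH = "HNH",
  ParB_HNH = "ParB_HNH",
  SRA_HNH = "SRA_HNH",
  TOPRIM = "TOPRIM",
  OLD_ABC = "OLD_ABC",
  PIN = "PIN",
  Schlafen = "Schlafen_kinase_wHTH"
)
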