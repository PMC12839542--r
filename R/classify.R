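#' @include AllClasses.R
NULL

# canonical spellings and accepted synonyms for component names
.COMPONENT_ALIASES <- c(
  duf4007 = "BrxA", brxa = "BrxA", brxb = "iSTAND", brxf = "iSTAND",
  brxb_istand = "iSTAND", istand = "iSTAND",
  duf499_atpase = "DUF499_ATPase", duf499 = "DUF499_ATPase",
  br_helicase = "BrxHII", brxhii = "BrxHII", br_mtase = "BR_MTase",
  brxc = "BrxC", "duf6079" = "BrxC", brxc_like = "BrxC",
  brxx = "BrxX", brxxi = "BrxXI", pglz = "PglZ", brxl = "BrxL",
  pglw = "PglW", brxd = "BrxD", brxhi = "BrxHI", brxp = "BrxP",
  cysdesulf = "CysDesulf", duf3780 = "DUF3780", brxe = "BrxE",
  hera_ftsk = "HerA_FtsK", gnat = "GNAT", tgt = "TGT",
  stand_active = "STAND_active", znhth = "ZnHTH",
  pddexk_rease = "PDDExK_REase", nerd = "NERD", shedu_rease = "Shedu_REase",
  hnh = "HNH", parb_hnh = "ParB_HNH", sra_hnh = "SRA_HNH", hkd = "HKD",
  toprim = "TOPRIM", old_abc = "OLD_ABC", hepn = "HEPN", mnt = "MNT",
  pin = "PIN", schlafen = "Schlafen", rease = "REase")

.normalize_components <- function(x) {
  # a trailing ":minimal"-style spelling such as "PglZ:minimal" keeps
  # its component part
  key <- sub(":.*$", "", x)
  key <- tolower(gsub("[^A-Za-z0-9_]", "", key))
  mapped <- .COMPONENT_ALIASES[key]
  out <- ifelse(is.na(mapped), x, mapped)
  unname(out)
}

.MANDATORY <- list(
  "Type-1" = c("BrxC", "BrxX", "PglZ", "BrxA", "iSTAND", "BrxL"),
  "Type-2" = c("BrxC", "BrxX", "PglZ", "PglW", "BrxD", "BrxHI"),
  "Type-3" = c("BrxC", "BrxXI", "PglZ", "BrxA", "iSTAND", "BrxHII"),
  "Type-4" = c("BrxC", "PglZ", "BrxP", "BrxL"),
  "Type-5" = c("BrxC", "BrxX", "PglZ", "BrxA", "iSTAND", "BrxHII"),
  "Type-6" = c("BrxC", "BrxX", "PglZ", "BrxA", "iSTAND", "BrxE"),
  "Type-1 BR" = c("DUF499_ATPase", "BR_MTase", "BrxHII"),
  "Type-2 BR" = c("DUF499_ATPase", "BR_MTase", "BrxHII", "DUF3780"),
  "Type-3 BR" = c("DUF499_ATPase", "BR_MTase", "BrxHII", "PglZ"),
  "BRC" = c("PglZ", "BrxC", "STAND_active", "BrxA", "HerA_FtsK"))

.ANCHORS <- list(BREX = c("BrxC", "PglZ"), BR = "DUF499_ATPase",
                 BRC = "HerA_FtsK")

#' Mandatory components per subtype
#'
#' The component sets a locus must carry to be scored
#' \code{"complete"} for its matched subtype.
#'
#' @return named list of character vectors.
#' @export
mandatoryComponents <- function() .MANDATORY

#' Classify a component-annotated locus into a system and subtype
#'
#' Applies the ordered decision list (first match wins): BRC by its
#' uniquely diagnostic HerA/FtsK + PglZ + BrxC-like trio; then the
#' DUF499-anchored BR family, split Type-3 (PglZ in locus), Type-2
#' (standalone DUF3780 or HKD-fused helicase) and Type-1; then BREX
#' Type-4 (PAPS-reductase replacing the methyltransferase), Type-2
#' (PglW or the BrxD+BrxHI dyad), Type-3 (BrxXI, or BrxF+BrxHII
#' without a Type-1 core), and the Type-1 family, inside which BrxE
#' marks Type-6 and an extra BrxHII-class helicase marks Type-5.
#' Types 1, 5 and 6 share the family group \code{"Type-1-family"}.
#'
#' @param components character vector of component names present in
#'   the locus (synonyms such as DUF4007, BrxB, BrxF, BR_helicase are
#'   normalized).
#' @param flags character vector of fusion flags present.
#' @param locus_id identifier stored in the call.
#' @return a \linkS4class{SystemCall}.
#' @export
classifyLocus <- function(components, flags = character(),
                          locus_id = "locus") {
  s <- unique(.normalize_components(components[components != "unknown"]))
  f <- unique(flags[nzchar(flags)])
  has <- function(...) all(c(...) %in% s)
  system <- "unassigned"; subtype <- "NA"
  if (has("HerA_FtsK", "PglZ") && ("BrxC" %in% s ||
                                   "DUF499_ATPase" %in% s)) {
    system <- "BRC"; subtype <- "BRC"
  } else if (has("DUF499_ATPase")) {
    system <- "BR"
    subtype <- if (has("PglZ")) "Type-3 BR"
    else if (has("DUF3780") || "helicase:HKD_fused" %in% f) "Type-2 BR"
    else "Type-1 BR"
  } else if (has("BrxP") && !any(c("BrxX", "BrxXI", "BR_MTase") %in% s)) {
    system <- "BREX"; subtype <- "Type-4"
  } else if (has("PglW") || has("BrxD", "BrxHI")) {
    system <- "BREX"; subtype <- "Type-2"
  } else if (has("BrxXI") ||
             (has("iSTAND", "BrxHII") && !"BrxX" %in% s)) {
    system <- "BREX"; subtype <- "Type-3"
  } else if (has("BrxC", "BrxX", "PglZ")) {
    system <- "BREX"
    subtype <- if ("BrxE" %in% s) "Type-6"
    else if ("BrxHII" %in% s) "Type-5"
    else "Type-1"
  }
  if (subtype == "Type-6" && "BrxHII" %in% s)
    f <- union(f, "review:Type-6_with_extra_helicase")
  fam <- if (subtype %in% c("Type-1", "Type-5", "Type-6")) "Type-1-family"
         else "other"
  if (system == "unassigned") {
    completeness <- "discarded"; missing <- character()
  } else {
    mand <- .MANDATORY[[subtype]]
    missing <- setdiff(mand, s)
    anchors <- .ANCHORS[[system]]
    completeness <- if (length(missing) == 0L) "complete"
    else if (length(s) >= 3L && any(anchors %in% s)) "partial"
    else "discarded"
  }
  new("SystemCall", locusId = locus_id, system = system, subtype = subtype,
      familyGroup = fam, completeness = completeness,
      componentsPresent = sort(s), missingCore = sort(missing),
      fusionFlags = sort(f))
}

.AUX_EFFECTORS <- c("PDDExK_REase", "NERD", "Shedu_REase", "HNH",
                    "ParB_HNH", "SRA_HNH", "HKD", "TOPRIM", "REase")
.BACKUP_EFFECTORS <- c("HEPN", "MNT", "PIN", "Schlafen")

#' Catalog primary, auxiliary and backup effectors of a locus
#'
#' Applies the fixed effector-role ontology: PglZ is the primary
#' effector of every BREX subtype and of Type-3 BR; the
#' helicase-fused REase and HKD-endoDNase are the primaries of Type-1
#' and Type-2 BR respectively. DNase-class domains (PD-(D/E)xK,
#' NERD, Shedu, HNH variants, HKD on BrxL, TOPRIM) are auxiliary
#' whether fused or standalone; RNase-class and abortive modules
#' (HEPN with or without MNT, PIN, Schlafen) and any OLD-ABC-paired
#' nuclease dyad are backup. Provenance distinguishes fusions within
#' core components, standalone genes inside the locus, and flanking
#' genes admitted by the neighborhood gap rule.
#'
#' @param locus a \linkS4class{DefenseLocus}.
#' @param call the locus's \linkS4class{SystemCall}.
#' @param annotations per-protein annotation data.frame
#'   (\code{\link{annotateProteins}}).
#' @param genome optional \linkS4class{GenomeRecord}; when given,
#'   genes within \code{max_gap_nt} of the locus span that are not
#'   members are considered flanking.
#' @param params \code{\link{neighborhoodParams}}.
#' @return data.frame: locus_id, effector_domain, carrier_protein,
#'   role, provenance.
#' @export
catalogEffectors <- function(locus, call, annotations, genome = NULL,
                             params = neighborhoodParams()) {
  members <- genes(locus)$gene_id
  ann <- annotations[match(members, annotations$protein_id), , drop = FALSE]
  ann <- ann[!is.na(ann$protein_id), , drop = FALSE]
  ann$component <- .normalize_components(ann$component)
  flank <- data.frame(protein_id = character(), component = character(),
                      fusion_flags = character())
  if (!is.null(genome)) {
    # flanking genes chain outward from the locus under the same gap
    # rule used for operon blocks
    g <- as.data.frame(genes(genome))
    g <- g[order(g$start), , drop = FALSE]
    at <- which(g$gene_id %in% members)
    near <- character()
    if (length(at)) {
      i <- min(at) - 1L
      right_edge <- locusSpan(locus)[1]
      while (i >= 1L && right_edge - g$end[i] <= params$max_gap_nt) {
        near <- c(near, g$gene_id[i])
        right_edge <- g$start[i]
        i <- i - 1L
      }
      i <- max(at) + 1L
      left_edge <- locusSpan(locus)[2]
      while (i <= nrow(g) && g$start[i] - left_edge <= params$max_gap_nt) {
        near <- c(near, g$gene_id[i])
        left_edge <- g$end[i]
        i <- i + 1L
      }
    }
    if (length(near)) {
      flank <- annotations[match(near, annotations$protein_id), ,
                           drop = FALSE]
      flank <- flank[!is.na(flank$protein_id), , drop = FALSE]
      flank$component <- .normalize_components(flank$component)
    }
  }
  rows <- list()
  add <- function(domain, carrier, role, provenance)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus_id = locusId(locus), effector_domain = domain,
      carrier_protein = carrier, role = role, provenance = provenance,
      stringsAsFactors = FALSE)
  flags_of <- function(a) unlist(strsplit(a$fusion_flags, ","))
  # --- primary, by system/subtype
  sys <- systemOf(call); sub <- subtypeOf(call)
  if ((sys == "BREX" || sub == "Type-3 BR") &&
      "PglZ" %in% ann$component) {
    carrier <- ann$protein_id[ann$component == "PglZ"][1]
    add("PglZ", carrier, "primary", "standalone_in_locus")
  } else if (sub == "Type-1 BR") {
    i <- which(vapply(seq_len(nrow(ann)), function(k)
      "helicase:REase_fused" %in% flags_of(ann[k, ]), logical(1)))
    if (length(i)) add("REase", ann$protein_id[i[1]], "primary",
                       "core_component_fusion")
  } else if (sub == "Type-2 BR") {
    i <- which(vapply(seq_len(nrow(ann)), function(k)
      "helicase:HKD_fused" %in% flags_of(ann[k, ]), logical(1)))
    if (length(i)) add("HKD", ann$protein_id[i[1]], "primary",
                       "core_component_fusion")
  }
  # --- effectors embedded in core components (fusion flags)
  for (k in seq_len(nrow(ann))) {
    fl <- flags_of(ann[k, ])
    pid <- ann$protein_id[k]
    if ("BrxL:HKD" %in% fl) add("HKD", pid, "auxiliary",
                                "core_component_fusion")
    if ("helicase:REase_fused" %in% fl && sub != "Type-1 BR")
      add("REase", pid, "auxiliary", "core_component_fusion")
    if ("helicase:HKD_fused" %in% fl && sub != "Type-2 BR")
      add("HKD", pid, "auxiliary", "core_component_fusion")
    if ("DUF499:HEPN_fused" %in% fl)
      add("HEPN", pid, "backup", "core_component_fusion")
    if ("HEPN:MNT_fused" %in% fl)
      add("MNT", pid, "backup", "core_component_fusion")
    if (ann$component[k] == "PglW")
      add("NERD", pid, "auxiliary", "core_component_fusion")
  }
  # --- standalone effector genes, inside the locus and flanking
  old_abc_ids <- character()
  standalone <- function(tbl, provenance) {
    for (k in seq_len(nrow(tbl))) {
      comp <- tbl$component[k]; pid <- tbl$protein_id[k]
      if (comp == "OLD_ABC") {
        old_abc_ids <<- c(old_abc_ids, pid)
        add("OLD_ABC", pid, "backup", provenance)
      } else if (comp %in% .BACKUP_EFFECTORS) {
        add(comp, pid, "backup", provenance)
      } else if (comp %in% .AUX_EFFECTORS) {
        add(comp, pid, "auxiliary", provenance)
      }
    }
  }
  standalone(ann, "standalone_in_locus")
  standalone(flank, "flanking")
  inv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), effector_domain = character(),
               carrier_protein = character(), role = character(),
               provenance = character())
  # --- OLD-ABC-paired nuclease dyads become backup modules
  if (length(old_abc_ids) && !is.null(genome)) {
    g <- genes(genome)
    ord <- g$gene_id[order(g$start)]
    for (oid in old_abc_ids) {
      at <- match(oid, ord)
      nb <- ord[c(at - 1L, at + 1L)]
      nb <- nb[!is.na(nb)]
      inv$role[inv$carrier_protein %in% nb & inv$role == "auxiliary" &
                 inv$provenance != "core_component_fusion"] <- "backup"
    }
  } else if (length(old_abc_ids)) {
    # without genome context, pair within the locus by gene order
    ord <- genes(locus)$gene_id
    for (oid in old_abc_ids) {
      at <- match(oid, ord)
      nb <- ord[c(at - 1L, at + 1L)]
      nb <- nb[!is.na(nb)]
      inv$role[inv$carrier_protein %in% nb & inv$role == "auxiliary" &
                 inv$provenance != "core_component_fusion"] <- "backup"
    }
  }
  stopifnot(sum(inv$role == "primary") <= 1L)
  rownames(inv) <- NULL
  inv
}

#' Summarize a cohort of system calls and effector inventories
#'
#' @param calls list of \linkS4class{SystemCall}.
#' @param inventories optional list/data.frame of effector
#'   inventories (rbound).
#' @return list with \code{subtype_counts},
#'   \code{completeness_counts}, \code{component_retention} (per
#'   subtype, fraction of loci carrying each component),
#'   \code{effector_classes}, and \code{discarded} (locus ids with
#'   reasons).
#' @export
summarizeCohort <- function(calls, inventories = NULL) {
  if (length(calls) == 0L)
    return(list(subtype_counts = table(character()),
                completeness_counts = table(character()),
                component_retention = data.frame(),
                effector_classes = table(character()),
                discarded = data.frame(locus_id = character(),
                                       reason = character())))
  subtypes <- vapply(calls, subtypeOf, character(1))
  compl <- vapply(calls, completeness, character(1))
  retention <- do.call(rbind, lapply(split(calls, subtypes), function(cs) {
    comps <- table(unlist(lapply(cs, componentsPresent)))
    data.frame(subtype = subtypeOf(cs[[1]]), component = names(comps),
               n_loci = length(cs), n_with = as.integer(comps),
               fraction = as.numeric(comps) / length(cs),
               stringsAsFactors = FALSE)
  }))
  rownames(retention) <- NULL
  eff <- if (is.null(inventories)) table(character()) else {
    inv <- if (is.data.frame(inventories)) inventories
           else do.call(rbind, inventories)
    table(inv$role)
  }
  disc <- vapply(calls, completeness, character(1)) == "discarded"
  discarded <- data.frame(
    locus_id = vapply(calls[disc], locusId, character(1)),
    reason = vapply(calls[disc], function(x)
      if (systemOf(x) == "unassigned") "no_system_match"
      else paste0("incomplete:", paste(x@missingCore, collapse = "/")),
      character(1)), stringsAsFactors = FALSE)
  list(subtype_counts = table(subtypes),
       completeness_counts = table(compl),
       component_retention = retention,
       effector_classes = eff, discarded = discarded)
}
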