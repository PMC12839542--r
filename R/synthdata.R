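#' @include registry.R
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.LINKER <- "GSGSGSGS"

# variant mixes reflect the per-component retention and fusion
# fractions reported for the mined genome set (e.g. the HKD-for-LonP
# substitution in roughly 35% of BrxL, HEPN fusions in 56% of Type-1
# BR ATPases); diagnostic core slots always have presence 1 so a
# planted locus is classifiable from composition alone
.slot <- function(component, presence = 1, variants = NULL, choice = NULL) {
  if (is.null(variants) && is.null(choice))
    variants <- list(list(arch = component, prob = 1, flags = character()))
  list(component = component, presence = presence, variants = variants,
       choice = choice)
}
.var <- function(arch, prob, flags = character())
  list(arch = arch, prob = prob, flags = flags)

.AUX_CHOICES <- c("HNH", "ParB_HNH", "SRA_HNH", "PDDExK_REase",
                  "Shedu_REase")
.BACKUP_CHOICES <- c("HEPN", "HEPN_MNT", "PIN", "Schlafen")

.aux_slot <- function(p = 0.25) list(component = NA_character_, presence = p,
                                     variants = NULL, choice = .AUX_CHOICES)
.backup_slot <- function(p = 0.2) list(component = NA_character_,
                                       presence = p, variants = NULL,
                                       choice = .BACKUP_CHOICES)
.dyad_slot <- function(p = 0.1) list(component = "OLD_ABC_dyad", presence = p,
                                     variants = NULL, choice = NULL)

.GRAMMARS <- local({
  g <- list()
  g[["Type-1"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"), .slot("BrxX"), .slot("PglZ", variants = list(.var("PglZ", 1))),
    .slot("BrxA", variants = list(.var("BrxA", 0.7), .var("BrxA3", 0.3))),
    .slot("iSTAND", variants = list(.var("BrxB", 1))),
    .slot("BrxL", variants = list(.var("BrxL", 0.646, "BrxL:LonP"),
                                  .var("BrxL_HKD", 0.354, "BrxL:HKD"))),
    .aux_slot(), .backup_slot(), .dyad_slot()))
  g[["Type-2"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"), .slot("BrxX"),
    .slot("PglZ", variants = list(.var("PglZ_T2", 1))),
    .slot("PglW"), .slot("BrxD"), .slot("BrxHI"),
    .aux_slot(), .backup_slot()))
  g[["Type-3"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"), .slot("BrxXI"),
    .slot("PglZ", variants = list(.var("PglZ_T3", 1))),
    .slot("BrxA", variants = list(.var("BrxA3", 1))),
    .slot("iSTAND", variants = list(.var("BrxF", 1))),
    .slot("BrxHII"), .aux_slot(), .backup_slot()))
  g[["Type-4"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"),
    .slot("PglZ", variants = list(
      .var("PglZ_iSTAND", 0.64, "PglZ:iSTAND_fused"),
      .var("PglZ_T3", 0.36))),
    .slot("BrxP", variants = list(
      .var("BrxP_DUF4007", 0.6, "BrxP:DUF4007_fused"), .var("BrxP", 0.4))),
    .slot("BrxA", presence = 0.4, variants = list(.var("BrxA3", 1))),
    .slot("BrxL", variants = list(.var("BrxL_T4", 1))),
    .slot("CysDesulf", presence = 0.56),
    .slot("ZnHTH", presence = 0.3), .aux_slot(0.15)))
  g[["Type-5"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"), .slot("BrxX"),
    .slot("PglZ", variants = list(.var("PglZ", 1))),
    .slot("BrxA", variants = list(.var("BrxA", 1))),
    .slot("iSTAND", variants = list(.var("BrxB", 1))),
    .slot("BrxHII", variants = list(
      .var("BrxHII", 0.75), .var("BrxHII_REase", 0.25,
                                 "helicase:REase_fused"))),
    .backup_slot(0.15)))
  g[["Type-6"]] <- list(system = "BREX", slots = list(
    .slot("BrxC"), .slot("BrxX"),
    .slot("PglZ", variants = list(.var("PglZ", 1))),
    .slot("BrxA", variants = list(.var("BrxA", 1))),
    .slot("iSTAND", variants = list(.var("BrxB", 1))),
    .slot("BrxE"), .slot("BrxHII", presence = 0.5), .backup_slot(0.15)))
  g[["Type-1 BR"]] <- list(system = "BR", slots = list(
    .slot("DUF499_ATPase", variants = list(
      .var("DUF499_HEPN", 0.56, "DUF499:HEPN_fused"), .var("DUF499", 0.44))),
    .slot("BR_MTase"),
    .slot("BrxHII", variants = list(
      .var("BR_helicase_REase", 0.79, "helicase:REase_fused"),
      .var("BrxHII", 0.21))),
    .aux_slot(0.25), .dyad_slot(0.1)))
  g[["Type-2 BR"]] <- list(system = "BR", slots = list(
    .slot("DUF499_ATPase", variants = list(
      .var("DUF499_FnIII", 0.53, "DUF499:FnIII"), .var("DUF499", 0.47))),
    .slot("BR_MTase"),
    .slot("BrxHII", variants = list(
      .var("BR_helicase_HKD", 0.83, "helicase:HKD_fused"),
      .var("BrxHII", 0.17))),
    .slot("DUF3780"), .aux_slot(0.2)))
  g[["Type-3 BR"]] <- list(system = "BR", slots = list(
    .slot("DUF499_ATPase", variants = list(.var("DUF499", 1))),
    .slot("BR_MTase"), .slot("BrxHII"),
    .slot("PglZ", variants = list(.var("PglZ_standalone", 1))),
    .slot("iSTAND", presence = 0.82,
          variants = list(.var("iSTAND", 1)))))
  g[["BRC"]] <- list(system = "BRC", slots = list(
    .slot("PglZ", variants = list(.var("PglZ_minimal", 1, "PglZ:minimal"))),
    .slot("BrxC"), .slot("STAND_active"),
    .slot("BrxA", variants = list(.var("BrxA3", 1))),
    .slot("HerA_FtsK"), .slot("GNAT", presence = 0.7),
    .slot("TGT", presence = 0.7)))
  for (s in names(g)) {
    g[[s]]$subtype <- s
    g[[s]]$strand_policy <- "same"
    g[[s]]$gap_distribution <- c(5L, 60L)
  }
  g
})

#' Subtype operon grammars
#'
#' \code{subtypeGrammars()} lists the ten shipped subtype labels;
#' \code{operonGrammar(subtype)} returns one grammar: the ordered
#' component slots with presence probabilities and fusion-variant
#' mixes, the strand policy and the intergenic gap range the
#' generator draws from.
#'
#' @param subtype one of the labels returned by
#'   \code{subtypeGrammars()}.
#' @return \code{operonGrammar}: a grammar list; \code{subtypeGrammars}:
#'   character vector of subtype labels.
#' @export
operonGrammar <- function(subtype) {
  if (!subtype %in% names(.GRAMMARS))
    stop("unknown subtype '", subtype, "'; valid subtypes: ",
         paste(names(.GRAMMARS), collapse = ", "))
  .GRAMMARS[[subtype]]
}

#' @rdname operonGrammar
#' @export
subtypeGrammars <- function() names(.GRAMMARS)

.build_protein <- function(arch_key, registry) {
  doms <- .componentArchitectures()[[arch_key]]
  if (is.null(doms)) stop("unknown architecture key ", arch_key)
  sigs <- registry$signature[match(doms, registry$domain_name)]
  if (anyNA(sigs)) stop("architecture ", arch_key, " uses unknown domains")
  paste0("M", paste(sigs, collapse = .LINKER))
}

.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    repl <- sample(.AA20, length(hit), replace = TRUE)
    same <- repl == ch[hit]
    while (any(same)) {
      repl[same] <- sample(.AA20, sum(same), replace = TRUE)
      same <- repl == ch[hit]
    }
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

.draw_gap <- function(range) {
  if (range[1] >= range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1L)
}

#' Sample one operon from a subtype grammar
#'
#' Realizes the grammar's component slots (presence draws, fusion
#' variant draws, auxiliary/backup effector draws), builds one
#' signature-block protein per realized gene and lays the genes
#' left-to-right with intergenic gaps drawn from the grammar's gap
#' distribution. Uses the session RNG; seed upstream for
#' reproducibility.
#'
#' @param grammar a grammar from \code{\link{operonGrammar}}.
#' @param offset genome coordinate (0-based) where the operon starts.
#' @param id_prefix prefix for generated gene ids.
#' @param noise_rate i.i.d. residue substitution rate applied to the
#'   translations (0 = noiseless, exactly recoverable).
#' @param dropout_rate probability that a non-diagnostic (presence
#'   < 1) realized component is dropped again, for robustness
#'   experiments.
#' @param registry domain registry.
#' @return list with \code{genes} (gene table rows) and \code{truth}
#'   (data.frame: gene_id, component, arch, domains, flags).
#' @export
sampleOperon <- function(grammar, offset = 0L, id_prefix = "g",
                         noise_rate = 0, dropout_rate = 0,
                         registry = domainRegistry()) {
  archs <- .componentArchitectures()
  picked <- list()
  for (slot in grammar$slots) {
    if (stats::runif(1) > slot$presence) next
    if (!is.null(slot$choice)) {
      key <- sample(slot$choice, 1L)
      comp <- switch(key, HEPN_MNT = "HEPN", key)
      picked[[length(picked) + 1L]] <- list(component = comp, arch = key,
                                            flags = if (key == "HEPN_MNT")
                                              "HEPN:MNT_fused"
                                            else character())
      next
    }
    if (identical(slot$component, "OLD_ABC_dyad")) {
      picked[[length(picked) + 1L]] <- list(component = "OLD_ABC",
                                            arch = "OLD_ABC",
                                            flags = character())
      picked[[length(picked) + 1L]] <- list(component = "TOPRIM",
                                            arch = "TOPRIM",
                                            flags = character())
      next
    }
    probs <- vapply(slot$variants, `[[`, numeric(1), "prob")
    v <- slot$variants[[sample(length(slot$variants), 1L, prob = probs)]]
    picked[[length(picked) + 1L]] <- list(component = slot$component,
                                          arch = v$arch, flags = v$flags)
  }
  # optional dropout of core slots for robustness experiments
  if (dropout_rate > 0 && length(picked) > 3L) {
    keep <- stats::runif(length(picked)) >= dropout_rate
    keep[1] <- TRUE
    picked <- picked[keep]
  }
  pos <- as.integer(offset)
  gene_rows <- list(); truth_rows <- list()
  for (i in seq_along(picked)) {
    p <- picked[[i]]
    translation <- .build_protein(p$arch, registry)
    noised <- .mutate_protein(translation, noise_rate)
    len_nt <- 3L * nchar(noised)
    gid <- sprintf("%s%02d", id_prefix, i)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, start = pos, end = pos + len_nt, strand = "+",
      translation = noised,
      product = paste0(p$component, " family protein"),
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      gene_id = gid, component = p$component, arch = p$arch,
      domains = paste(archs[[p$arch]], collapse = ","),
      flags = paste(p$flags, collapse = ","), stringsAsFactors = FALSE)
    pos <- pos + len_nt + .draw_gap(grammar$gap_distribution)
  }
  list(genes = do.call(rbind, gene_rows), truth = do.call(rbind, truth_rows))
}

.sig_kmers <- local({
  cache <- NULL
  function(registry) {
    if (!is.null(cache)) return(cache)
    km <- unlist(lapply(registry$signature, function(s)
      substring(s, 1:(nchar(s) - 11L), 12:nchar(s))))
    cache <<- unique(km)
    cache
  }
})

.decoy_protein <- function(len, registry) {
  sig_km <- .sig_kmers(registry)
  repeat {
    seq <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
    # by construction decoys share no 12-mer with any signature block
    km <- unique(substring(seq, 1:(len - 11L), 12:len))
    if (!any(km %in% sig_km)) return(seq)
  }
}

#' Generate one synthetic genome with a planted operon and decoys
#'
#' Plants one operon of the requested subtype, surrounded by decoy
#' genes that carry no registry signature. Planted loci are isolated
#' from decoys by five times the locus gap threshold so the truth
#' locus is unambiguous under any configured threshold up to that
#' margin.
#'
#' @param genome_id replicon id.
#' @param subtype subtype label (see \code{\link{subtypeGrammars}}),
#'   or \code{NA} for a decoy-only genome.
#' @param n_decoys number of decoy genes.
#' @param seed integer seed (fixed seed implies byte-identical
#'   output).
#' @param noise_rate,dropout_rate passed to \code{\link{sampleOperon}}.
#' @param gap_threshold locus gap threshold the isolation margin is
#'   derived from (margin = 5x this value).
#' @param assemblyId,taxid,lineage genome metadata.
#' @param registry domain registry.
#' @return list with the \code{record} (GenomeRecord) and \code{truth}
#'   (list: locus span, subtype, components, effectors).
#' @export
synthGenome <- function(genome_id, subtype, n_decoys = 10L, seed = 1L,
                        noise_rate = 0, dropout_rate = 0,
                        gap_threshold = 100L, assemblyId = genome_id,
                        taxid = 1L, lineage = character(),
                        registry = domainRegistry()) {
  set.seed(seed)
  isolation <- 5L * gap_threshold
  pos <- 200L
  gene_rows <- list(); truth <- NULL
  n_before <- if (n_decoys > 0L) sample(0:n_decoys, 1L) else 0L
  mk_decoys <- function(n, pos, tag) {
    rows <- list()
    for (i in seq_len(n)) {
      tr <- .decoy_protein(sample(150:300, 1L), registry)
      len <- 3L * nchar(tr)
      rows[[i]] <- data.frame(
        gene_id = sprintf("%s_%s%02d", genome_id, tag, i), start = pos,
        end = pos + len, strand = sample(c("+", "-"), 1L),
        translation = tr, product = "hypothetical protein",
        stringsAsFactors = FALSE)
      pos <- pos + len + sample(20:400, 1L)
    }
    list(rows = rows, pos = pos)
  }
  d1 <- mk_decoys(n_before, pos, "d")
  gene_rows <- d1$rows
  pos <- d1$pos + isolation
  if (!is.na(subtype)) {
    op <- sampleOperon(operonGrammar(subtype), offset = pos,
                       id_prefix = paste0(genome_id, "_p"),
                       noise_rate = noise_rate,
                       dropout_rate = dropout_rate, registry = registry)
    gene_rows <- c(gene_rows, list(op$genes))
    span <- c(min(op$genes$start), max(op$genes$end))
    truth <- list(subtype = subtype,
                  system = operonGrammar(subtype)$system,
                  span = span, components = op$truth)
    pos <- span[2] + isolation
  }
  d2 <- mk_decoys(n_decoys - n_before, pos, "e")
  gene_rows <- c(gene_rows, d2$rows)
  pos <- d2$pos
  genes <- do.call(rbind, gene_rows)
  rec <- GenomeRecord(genome_id, genes, seqLength = pos + 200L,
                      assemblyId = assemblyId, taxid = taxid,
                      lineage = lineage)
  list(record = rec, truth = truth)
}

#' Specification for a synthetic cohort
#'
#' @param subtype_mix named integer vector: loci to plant per subtype
#'   (defaults to 20 of each of the ten subtypes).
#' @param phyla phylum names to spread taxa over (each subtype is
#'   assigned round-robin so it occurs in at least two phyla when
#'   possible; a single-phylum request is recorded as a warning in the
#'   truth metadata).
#' @param assemblies_per_taxon integer range; extra assemblies of a
#'   taxon replicate its planted locus (exercising TaxID dedup).
#' @param decoy_genes_per_genome integer range.
#' @param noise_rate,dropout_rate per-residue substitution rate and
#'   component dropout rate.
#' @param seed cohort seed; all per-genome seeds derive from it.
#' @return a validated cohort spec list.
#' @export
cohortSpec <- function(subtype_mix = setNames(rep(20L, 10L),
                                              subtypeGrammars()),
                       phyla = c("Pseudomonadota", "Bacillota",
                                 "Actinomycetota", "Cyanobacteriota"),
                       assemblies_per_taxon = c(1L, 1L),
                       decoy_genes_per_genome = c(8L, 16L),
                       noise_rate = 0, dropout_rate = 0, seed = 1L) {
  bad <- setdiff(names(subtype_mix), subtypeGrammars())
  if (length(bad))
    stop("unknown subtype(s) ", paste(bad, collapse = ", "),
         "; valid subtypes: ", paste(subtypeGrammars(), collapse = ", "))
  stopifnot(all(subtype_mix >= 0), length(phyla) >= 1)
  list(subtype_mix = subtype_mix, phyla = phyla,
       assemblies_per_taxon = as.integer(assemblies_per_taxon),
       decoy_genes_per_genome = as.integer(decoy_genes_per_genome),
       noise_rate = noise_rate, dropout_rate = dropout_rate,
       seed = as.integer(seed))
}

.genome_seed <- function(cohort_seed, i)
  as.integer((as.numeric(cohort_seed) * 7919 + i * 104729) %% 2147483629)
# assemblies of one taxon replicate the same organism: they share the
# taxon's substream so their planted loci are identical

#' Generate a synthetic genome cohort with ground truth
#'
#' Realizes a \code{\link{cohortSpec}}: one taxon per planted locus,
#' lineages assigned so every subtype spans at least two phyla (when
#' the phylum list allows), optionally several assemblies per taxon, decoy
#' genes per genome, and a machine-readable truth table (planted loci,
#' component lists with fusion flags, effector roles, unique-TaxID
#' counts per subtype).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param dir optional output directory; when given, writes one
#'   GenBank file per genome, \code{taxonomy.tsv} and
#'   \code{truth.json}.
#' @return list with \code{records} (list of GenomeRecord),
#'   \code{taxonomy} (data.frame), \code{truth} (list with per-locus
#'   entries and per-subtype unique-TaxID counts).
#' @export
synthCohort <- function(spec = cohortSpec(), dir = NULL) {
  registry <- domainRegistry()
  subtypes <- rep(names(spec$subtype_mix), times = spec$subtype_mix)
  n <- length(subtypes)
  meta_warnings <- character()
  if (length(spec$phyla) < 2L)
    meta_warnings <- c(meta_warnings,
                       "single phylum requested: cross-phyla support cannot be demonstrated")
  records <- list(); tax_rows <- list(); loci_truth <- list()
  set.seed(spec$seed)
  phylum_of <- character(n)
  for (s in unique(subtypes)) {
    idx <- which(subtypes == s)
    phylum_of[idx] <- spec$phyla[((seq_along(idx) - 1L) %%
                                    length(spec$phyla)) + 1L]
  }
  asm_counts <- if (spec$assemblies_per_taxon[1] >=
                    spec$assemblies_per_taxon[2])
    rep(spec$assemblies_per_taxon[1], n)
  else sample(seq(spec$assemblies_per_taxon[1],
                  spec$assemblies_per_taxon[2]), n, replace = TRUE)
  decoys <- if (spec$decoy_genes_per_genome[1] >=
                spec$decoy_genes_per_genome[2])
    rep(spec$decoy_genes_per_genome[1], n)
  else sample(seq(spec$decoy_genes_per_genome[1],
                  spec$decoy_genes_per_genome[2]), n, replace = TRUE)
  for (i in seq_len(n)) {
    taxid <- 10000L + i
    lin <- c(superkingdom = "Bacteria", phylum = phylum_of[i],
             class = paste0(phylum_of[i], "ia"),
             order = paste0("Synthetales_", phylum_of[i]),
             family = paste0("Synthetaceae_", phylum_of[i]),
             genus = "Synthoba",
             species = sprintf("Synthoba simulata tx%05d", taxid))
    for (a in seq_len(asm_counts[i])) {
      gid <- sprintf("SYN%04d_%d", i, a)
      asm <- sprintf("GCA_%06d.%d", i, a)
      g <- synthGenome(gid, subtypes[i], n_decoys = decoys[i],
                       seed = .genome_seed(spec$seed, i),
                       noise_rate = spec$noise_rate,
                       dropout_rate = spec$dropout_rate,
                       assemblyId = asm, taxid = taxid, lineage = lin,
                       registry = registry)
      records[[gid]] <- g$record
      tax_rows[[length(tax_rows) + 1L]] <- data.frame(
        assembly_id = asm, taxid = taxid, t(lin),
        stringsAsFactors = FALSE)
      if (!is.null(g$truth))
        loci_truth[[length(loci_truth) + 1L]] <- c(
          list(genome_id = gid, assembly_id = asm, taxid = taxid,
               phylum = phylum_of[i]), g$truth)
    }
  }
  taxonomy <- do.call(rbind, tax_rows)
  taxa_per_subtype <- vapply(split(
    vapply(loci_truth, function(x) x$taxid, integer(1)),
    vapply(loci_truth, function(x) x$subtype, character(1))),
    function(v) length(unique(v)), integer(1))
  truth <- list(loci = loci_truth, n_loci = length(loci_truth),
                unique_taxa_per_subtype = as.list(taxa_per_subtype),
                warnings = meta_warnings, seed = spec$seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (gid in names(records))
      writeGenBank(records[[gid]], file.path(dir, paste0(gid, ".gbk")))
    utils::write.table(taxonomy, file.path(dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, taxonomy = taxonomy, truth = truth)
}

#' Generate a synthetic protein alignment with known column entropies
#'
#' Draws each alignment column i.i.d. from a user-specified residue
#' distribution and reports, per column, both the expected Shannon
#' entropy of the generating distribution and the plug-in entropy of
#' the realized counts (computed here by direct formula evaluation,
#' independently of the entropy module).
#'
#' @param n_rows number of sequences (>= 2).
#' @param column_spec list of named probability vectors over the 20
#'   standard residues plus \code{"-"} (gap); each must sum to 1.
#' @param seed integer seed.
#' @return list with \code{alignment} (named character vector of
#'   aligned rows) and \code{truth} (data.frame: column_index,
#'   expected_H, plugin_H, gap_fraction).
#' @export
synthMSA <- function(n_rows, column_spec, seed = 1L) {
  stopifnot(n_rows >= 2)
  set.seed(seed)
  plugin_entropy <- function(counts) {
    counts <- counts[counts > 0]
    if (length(counts) == 0L) return(NA_real_)
    p <- counts / sum(counts)
    -sum(p * log2(p)) + 0
  }
  cols <- matrix("", nrow = n_rows, ncol = length(column_spec))
  truth <- data.frame(column_index = seq_along(column_spec),
                      expected_H = NA_real_, plugin_H = NA_real_,
                      gap_fraction = NA_real_)
  for (j in seq_along(column_spec)) {
    p <- column_spec[[j]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("column ", j, " distribution does not sum to 1")
    residues <- names(p)
    draw <- sample(residues, n_rows, replace = TRUE, prob = p)
    cols[, j] <- draw
    pa <- p[residues != "-"]
    pa <- pa[pa > 0]
    truth$expected_H[j] <- -sum(pa * log2(pa))
    realized <- table(draw[draw != "-"])
    truth$plugin_H[j] <- plugin_entropy(as.integer(realized))
    truth$gap_fraction[j] <- mean(draw == "-")
  }
  alignment <- setNames(apply(cols, 1, paste, collapse = ""),
                        sprintf("seq%03d", seq_len(n_rows)))
  list(alignment = alignment, truth = truth)
}
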