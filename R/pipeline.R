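#' Configuration for a full scan run
#'
#' @param genomes list of \linkS4class{GenomeRecord} (alternative to
#'   \code{genomes_dir}).
#' @param genomes_dir directory of GenBank files (.gb/.gbk).
#' @param taxonomy taxonomy data.frame or path to a taxonomy TSV;
#'   when absent, the cross-phyla and phyletic stages are skipped
#'   with an explicit log line.
#' @param domain_table optional externally computed domain-hit table
#'   (data.frame or TSV path); replaces signature matching.
#' @param alignments optional named character vector of aligned FASTA
#'   paths for the entropy stage.
#' @param neighborhood \code{\link{neighborhoodParams}}.
#' @param cluster \code{\link{clusterParams}} for the pooling stage.
#' @param annotate_mode \code{"direct"} annotates every protein;
#'   \code{"cluster"} follows the cluster-then-annotate-then-map-back
#'   loop (each cluster's representative is annotated and the calls
#'   are mapped back to members).
#' @param max_mismatch_frac signature-matching tolerance.
#' @param entropy_gap_threshold gap flag threshold for entropy
#'   profiles.
#' @param output_dir optional directory for the output bundle.
#' @param seed integer seed recorded in the manifest and used for any
#'   randomized stage.
#' @return validated config list.
#' @export
runConfig <- function(genomes = NULL, genomes_dir = NULL, taxonomy = NULL,
                      domain_table = NULL, alignments = NULL,
                      neighborhood = neighborhoodParams(),
                      cluster = clusterParams("greedy_incremental"),
                      annotate_mode = c("direct", "cluster"),
                      max_mismatch_frac = 0.1,
                      entropy_gap_threshold = 0.5,
                      output_dir = NULL, seed = 1L) {
  annotate_mode <- match.arg(annotate_mode)
  if (is.null(genomes) && is.null(genomes_dir))
    stop("provide genomes or genomes_dir")
  if (!is.null(genomes_dir) && !dir.exists(genomes_dir))
    stop("genomes_dir does not exist: ", genomes_dir)
  if (is.character(taxonomy) && !file.exists(taxonomy))
    stop("taxonomy file does not exist: ", taxonomy)
  if (is.character(domain_table) && !file.exists(domain_table))
    stop("domain table does not exist: ", domain_table)
  for (a in alignments) if (!file.exists(a))
    stop("alignment file does not exist: ", a)
  list(genomes = genomes, genomes_dir = genomes_dir, taxonomy = taxonomy,
       domain_table = domain_table, alignments = alignments,
       neighborhood = neighborhood, cluster = cluster,
       annotate_mode = annotate_mode,
       max_mismatch_frac = max_mismatch_frac,
       entropy_gap_threshold = entropy_gap_threshold,
       output_dir = output_dir, seed = as.integer(seed))
}

.ANCHOR_COMPONENTS <- c("BrxC", "DUF499_ATPase", "PglZ", "HerA_FtsK")

#' Run the full scan pipeline
#'
#' Executes the stages in order: read genomes, annotate proteins
#' (signature matching, imported table, or cluster-and-map-back),
#' select anchor genes, extract loci, classify, catalog effectors,
#' flag cross-phyla support, and aggregate TaxID-deduplicated
#' phyletic matrices; optional alignments get entropy profiles. The
#' run manifest records package version, parameters, seed and
#' per-stage record counts; a rerun with identical inputs and config
#' produces identical tables.
#'
#' @param config a \code{\link{runConfig}}.
#' @return the output bundle: list with \code{genomes}, \code{loci},
#'   \code{annotations}, \code{calls}, \code{effectors},
#'   \code{flagged}, \code{phyletics}, \code{entropy},
#'   \code{manifest}, \code{log}.
#' @export
runScan <- function(config) {
  set.seed(config$seed)
  logln <- character()
  note <- function(...) logln <<- c(logln, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- read
  genomes <- stage("read", {
    if (!is.null(config$genomes)) config$genomes else {
      files <- sort(list.files(config$genomes_dir,
                               pattern = "\\.(gb|gbk|gbff)$",
                               full.names = TRUE))
      recs <- list()
      for (f in files) for (r in readGenBank(f)) recs[[genomeId(r)]] <- r
      recs
    }
  })
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, genomeId, character(1))
  taxonomy <- if (is.character(config$taxonomy))
    readTaxonomyTable(config$taxonomy) else config$taxonomy
  note("read: ", length(genomes), " genomes")
  # --- protein pool
  proteins <- stage("pool", {
    p <- do.call(c, unname(lapply(genomes, function(g)
      setNames(genes(g)$translation, genes(g)$gene_id))))
    if (anyDuplicated(names(p)))
      stop("gene ids are not unique across genomes")
    p
  })
  imported <- if (is.character(config$domain_table))
    readDomainTable(config$domain_table) else config$domain_table
  # --- annotate (optionally via clustering + map-back)
  annotations <- stage("annotate", {
    if (!is.null(imported)) {
      annotateProteins(proteins, imported = imported)
    } else if (config$annotate_mode == "cluster") {
      cs <- greedyDedupe(proteins, config$cluster)
      reps <- vapply(cs$clusters, `[[`, character(1), "representative_id")
      rep_ann <- annotateProteins(proteins[reps],
                                  max_mismatch_frac =
                                    config$max_mismatch_frac)
      rows <- lapply(cs$clusters, function(cl) {
        r <- rep_ann[rep_ann$protein_id == cl$representative_id, ]
        out <- r[rep(1L, length(cl$member_ids)), , drop = FALSE]
        out$protein_id <- cl$member_ids
        out
      })
      a <- do.call(rbind, rows)
      a <- a[match(names(proteins), a$protein_id), , drop = FALSE]
      rownames(a) <- NULL
      a
    } else {
      annotateProteins(proteins,
                       max_mismatch_frac = config$max_mismatch_frac)
    }
  })
  note("annotate: ", sum(annotations$component != "unknown"),
       " of ", nrow(annotations), " proteins assigned a component (",
       config$annotate_mode, if (!is.null(imported)) "/imported" else "",
       ")")
  # --- anchors and loci
  loci <- stage("loci", {
    out <- list()
    for (g in genomes) {
      ids <- genes(g)$gene_id
      comp <- annotations$component[match(ids, annotations$protein_id)]
      anchors <- ids[comp %in% .ANCHOR_COMPONENTS & !is.na(comp)]
      seen_spans <- character()
      for (a in anchors) {
        l <- extractLocus(g, a, config$neighborhood)
        key <- paste(locusSpan(l), collapse = "-")
        if (key %in% seen_spans) next
        seen_spans <- c(seen_spans, key)
        out[[locusId(l)]] <- l
      }
    }
    out
  })
  note("loci: ", length(loci), " candidate loci from ",
       length(genomes), " genomes")
  # --- classify + effectors
  calls <- stage("classify", lapply(loci, function(l) {
    ids <- genes(l)$gene_id
    ann <- annotations[match(ids, annotations$protein_id), , drop = FALSE]
    ann <- ann[!is.na(ann$protein_id), , drop = FALSE]
    classifyLocus(ann$component,
                  unlist(strsplit(ann$fusion_flags, ",")),
                  locus_id = locusId(l))
  }))
  effectors <- stage("effectors", {
    rows <- lapply(names(loci), function(lid)
      catalogEffectors(loci[[lid]], calls[[lid]], annotations,
                       genome = genomes[[genomeId(loci[[lid]])]],
                       params = config$neighborhood))
    do.call(rbind, rows)
  })
  note("classify: ",
       sum(vapply(calls, systemOf, character(1)) != "unassigned"),
       " assigned, ",
       sum(vapply(calls, completeness, character(1)) == "discarded"),
       " discarded")
  # --- cross-phyla flag + phyletics
  flagged <- list(); phyl <- NULL
  if (is.null(taxonomy)) {
    note("phyletics: skipped (no taxonomy table provided)")
  } else {
    cpf <- stage("cross_phyla",
                 crossPhylaFilter(loci, annotations, genomes, taxonomy,
                                  config$neighborhood))
    flagged <- cpf$flagged
    loci_flagged <- vapply(cpf$flagged, locusId, character(1))
    for (lid in loci_flagged) loci[[lid]] <- cpf$flagged[[
      which(loci_flagged == lid)[1]]]
    note("cross_phyla: ", length(cpf$kept), " kept, ",
         length(cpf$flagged), " flagged")
    assigned <- calls[vapply(calls, completeness, character(1)) !=
                        "discarded"]
    call_df <- data.frame(
      locus_id = vapply(assigned, locusId, character(1)),
      genome_id = vapply(assigned, function(sc)
        genomeId(loci[[locusId(sc)]]), character(1)),
      subtype = vapply(assigned, subtypeOf, character(1)),
      components = vapply(assigned, function(sc)
        paste(componentsPresent(sc), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    summary <- stage("phyletics", dedupeTaxa(call_df, genomes))
    phyl <- list(
      summary = summary,
      subtype_matrix = presenceMatrix(summary, taxonomy, "phylum",
                                      "subtype"),
      component_matrix = presenceMatrix(summary, taxonomy, "phylum",
                                        "component"))
    note("phyletics: ", nrow(summary$subtypes),
         " unique TaxID x subtype pairs")
  }
  # --- entropy stage
  entropy <- NULL
  if (length(config$alignments)) {
    entropy <- stage("entropy", lapply(config$alignments, function(a)
      msaProfile(readFastaAA(a),
                 gap_threshold = config$entropy_gap_threshold)))
    note("entropy: ", length(entropy), " alignment profile(s)")
  }
  n_genes <- sum(vapply(genomes, function(g) nrow(genes(g)), integer(1)))
  n_blocks_genes <- sum(vapply(genomes, function(g)
    length(unlist(lapply(buildOperonBlocks(g, config$neighborhood),
                         `[[`, "idx"))), integer(1)))
  manifest <- list(
    package = "brexscan",
    version = as.character(utils::packageVersion("brexscan")),
    seed = config$seed,
    parameters = list(neighborhood = config$neighborhood,
                      cluster = config$cluster[c("mode", "min_coverage",
                                                 "min_identity",
                                                 "word_length")],
                      annotate_mode = config$annotate_mode,
                      max_mismatch_frac = config$max_mismatch_frac),
    stage_counts = list(
      genomes = length(genomes), genes = n_genes,
      genes_in_blocks = n_blocks_genes,
      proteins_annotated = nrow(annotations), loci = length(loci),
      calls = length(calls),
      assigned = sum(vapply(calls, systemOf, character(1)) !=
                       "unassigned"),
      discarded = sum(vapply(calls, completeness, character(1)) ==
                        "discarded"),
      flagged = length(flagged)))
  bundle <- list(genomes = genomes, loci = loci,
                 annotations = annotations, calls = calls,
                 effectors = effectors, flagged = flagged,
                 phyletics = phyl, entropy = entropy,
                 manifest = manifest, log = logln)
  if (!is.null(config$output_dir)) writeBundle(bundle, config$output_dir)
  bundle
}

#' Write a scan bundle to disk
#'
#' @param bundle result of \code{\link{runScan}}.
#' @param dir output directory (created if needed).
#' @return invisible vector of files written.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    writeTables(bundle$loci, file.path(dir, "loci.tsv"), "loci"),
    writeTables(bundle$calls, file.path(dir, "calls.tsv"), "calls"),
    writeTables(bundle$effectors, file.path(dir, "effectors.tsv"),
                "table"))
  if (!is.null(bundle$phyletics)) {
    files <- c(files,
               writeTables(bundle$phyletics$subtype_matrix,
                           file.path(dir, "matrix_subtype.tsv"), "matrix"),
               writeTables(bundle$phyletics$component_matrix,
                           file.path(dir, "matrix_component.tsv"),
                           "matrix"))
  }
  if (!is.null(bundle$entropy))
    for (nm in names(bundle$entropy))
      files <- c(files, writeTables(
        bundle$entropy[[nm]],
        file.path(dir, paste0("entropy_",
                              tools::file_path_sans_ext(basename(nm)),
                              ".tsv")), "entropy"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(c(files, file.path(dir, c("manifest.json", "run.log"))))
}

#' Human-readable report of a scan bundle
#'
#' @param bundle result of \code{\link{runScan}} (possibly partial).
#' @param file optional file to write the report to.
#' @return character vector of report lines, invisibly; also printed.
#' @export
runReport <- function(bundle, file = NULL) {
  lines <- c("brexscan scan report", strrep("=", 20))
  if (is.null(bundle$calls) || length(bundle$calls) == 0L) {
    lines <- c(lines, "no system calls present (empty or failed scan)")
  } else {
    s <- summarizeCohort(bundle$calls,
                         inventories = bundle$effectors)
    lines <- c(lines, "", "System calls by subtype:")
    st <- s$subtype_counts
    lines <- c(lines, sprintf("  %-12s %d", names(st), as.integer(st)))
    cc <- s$completeness_counts
    lines <- c(lines, "", "Completeness:",
               sprintf("  %-12s %d", names(cc), as.integer(cc)))
    if (length(s$effector_classes)) {
      ec <- s$effector_classes
      lines <- c(lines, "", "Effector roles:",
                 sprintf("  %-12s %d", names(ec), as.integer(ec)))
    }
    if (nrow(s$discarded))
      lines <- c(lines, "", sprintf("Discarded loci (%d):",
                                    nrow(s$discarded)),
                 sprintf("  %s: %s", s$discarded$locus_id,
                         s$discarded$reason))
  }
  if (is.null(bundle$phyletics)) {
    lines <- c(lines, "", "Phyletic matrices: absent (no taxonomy)")
  } else {
    m <- phyleticCounts(bundle$phyletics$subtype_matrix)
    lines <- c(lines, "", sprintf(
      "Phyletic subtype matrix: %d groups x %d subtypes, %d TaxID hits",
      nrow(m), ncol(m), sum(m)))
  }
  lines <- c(lines, "", "Stage log:", paste0("  ", bundle$log))
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
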