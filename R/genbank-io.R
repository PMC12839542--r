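#' @include AllClasses.R
NULL

.RANKS <- c("superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

#' Construct a GenomeRecord
#'
#' @param genomeId replicon identifier.
#' @param genes data.frame or DataFrame with columns \code{gene_id},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{translation}, \code{product}. Rows are re-sorted by start.
#' @param seqLength replicon length in bp.
#' @param assemblyId assembly identifier (defaults to the genomeId).
#' @param taxid positive integer taxonomy id.
#' @param lineage named character vector of rank = name pairs.
#' @return a validated \linkS4class{GenomeRecord}.
#' @export
GenomeRecord <- function(genomeId, genes, seqLength,
                         assemblyId = genomeId, taxid = 1L,
                         lineage = character()) {
  g <- S4Vectors::DataFrame(as.data.frame(genes))
  if (nrow(g)) g <- g[order(g$start), , drop = FALSE]
  g$start <- as.integer(g$start); g$end <- as.integer(g$end)
  new("GenomeRecord", genomeId = as.character(genomeId),
      assemblyId = as.character(assemblyId), taxid = as.integer(taxid),
      lineage = lineage, seqLength = as.integer(seqLength), genes = g)
}

.collapse_location <- function(loc, locus) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- grepl("^(join|order)\\(", loc)
  if (joined) loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2L)
    stop("malformed CDS location in LOCUS ", locus, ": ", loc)
  nums <- as.numeric(nums)
  if (joined)
    warning("compound location collapsed to outer span in LOCUS ", locus)
  list(start1 = min(nums), end1 = max(nums), strand = strand)
}

.parse_qualifiers <- function(lines) {
  txt <- sub("^\\s+", "", lines)
  starts <- grep("^/", txt)
  quals <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(txt)
    piece <- paste(txt[from:to], collapse = "")
    m <- regmatches(piece, regexec('^/([A-Za-z_0-9]+)=?"?([^"]*)"?', piece))[[1]]
    if (length(m) == 3L) quals[[m[2]]] <- m[3]
  }
  quals
}

#' Read a GenBank flat file into GenomeRecord objects
#'
#' Parses the CDS features of each LOCUS entry. Coordinates are
#' converted from the GenBank 1-based inclusive convention to the
#' internal 0-based half-open convention; compound (join) locations are
#' collapsed to their outer span with a warning. CDS features without a
#' /translation qualifier are skipped with a warning and tallied in the
#' \code{"skip_report"} attribute of the result.
#'
#' @param path path to a GenBank flat file (one or more LOCUS entries).
#' @return a list of \linkS4class{GenomeRecord}, one per LOCUS entry,
#'   with a \code{data.frame} attribute \code{"skip_report"}.
#' @export
readGenBank <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  locus_at <- grep("^LOCUS ", lines)
  end_at <- grep("^//\\s*$", lines)
  if (length(locus_at) == 0L) stop("no LOCUS entry found in ", path)
  if (length(end_at) < length(locus_at))
    stop("malformed GenBank file: unterminated LOCUS entry near line ",
         locus_at[length(end_at) + 1L])
  skip <- data.frame(genome_id = character(), gene_index = integer(),
                     reason = character())
  out <- vector("list", length(locus_at))
  for (r in seq_along(locus_at)) {
    block <- lines[locus_at[r]:end_at[r]]
    lf <- strsplit(block[1], "\\s+")[[1]]
    locus <- lf[2]
    len <- suppressWarnings(as.integer(lf[3]))
    if (is.na(len)) stop("malformed LOCUS line for record ", locus)
    asm <- locus
    dbl <- grep("^DBLINK", block, value = TRUE)
    if (length(dbl)) {
      m <- regmatches(dbl[1], regexec("Assembly:\\s*(\\S+)", dbl[1]))[[1]]
      if (length(m) == 2L) asm <- m[2]
    }
    lin <- character()
    org_at <- grep("^  ORGANISM", block)
    if (length(org_at)) {
      species <- sub("^  ORGANISM\\s+", "", block[org_at[1]])
      i <- org_at[1] + 1L
      lin_txt <- character()
      while (i <= length(block) && grepl("^\\s{10,}", block[i]) &&
             !grepl("^FEATURES", block[i])) {
        lin_txt <- c(lin_txt, trimws(block[i])); i <- i + 1L
      }
      parts <- trimws(strsplit(sub("\\.$", "", paste(lin_txt, collapse = " ")),
                               ";")[[1]])
      parts <- parts[nzchar(parts)]
      lin <- c(parts, species)
      names(lin) <- .RANKS[seq_along(lin)]
    }
    feat_at <- grep("^FEATURES", block)
    taxid <- 1L
    gene_rows <- list()
    if (length(feat_at)) {
      fb <- block[(feat_at[1] + 1L):length(block)]
      is_key <- grepl("^ {5}\\S", fb)
      key_at <- which(is_key)
      for (k in seq_along(key_at)) {
        from <- key_at[k]
        to <- if (k < length(key_at)) key_at[k + 1L] - 1L else length(fb)
        fl <- fb[from:to]
        fl <- fl[!grepl("^(ORIGIN|//)", fl)]
        key <- strsplit(trimws(fl[1]), "\\s+")[[1]][1]
        loc <- sub("^\\s*\\S+\\s+", "", fl[1])
        j <- 2L
        while (j <= length(fl) && !grepl("^\\s+/", fl[j])) {
          loc <- paste0(loc, trimws(fl[j])); j <- j + 1L
        }
        quals <- if (j <= length(fl)) .parse_qualifiers(fl[j:length(fl)])
                 else list()
        if (key == "source") {
          if (!is.null(quals$db_xref) && grepl("^taxon:", quals$db_xref))
            taxid <- as.integer(sub("^taxon:", "", quals$db_xref))
          next
        }
        if (key != "CDS") next
        pl <- .collapse_location(loc, locus)
        gid <- quals$locus_tag
        if (is.null(gid)) gid <- quals$protein_id
        if (is.null(gid)) gid <- sprintf("%s_cds%03d", locus, k)
        if (is.null(quals$translation) || !nzchar(quals$translation)) {
          warning("CDS ", gid, " in LOCUS ", locus,
                  " lacks a translation; skipped")
          skip <- rbind(skip, data.frame(genome_id = locus, gene_index = k,
                                         reason = "no_translation"))
          next
        }
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, start = as.integer(pl$start1 - 1L),
          end = as.integer(pl$end1), strand = pl$strand,
          translation = toupper(quals$translation),
          product = if (is.null(quals$product)) "" else quals$product,
          stringsAsFactors = FALSE)
      }
    }
    g <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(gene_id = character(), start = integer(), end = integer(),
                 strand = character(), translation = character(),
                 product = character())
    out[[r]] <- GenomeRecord(locus, g, len, assemblyId = asm, taxid = taxid,
                             lineage = lin)
  }
  names(out) <- vapply(out, genomeId, character(1))
  attr(out, "skip_report") <- skip
  out
}

.wrap <- function(x, width = 58L) {
  if (nchar(x) <= width) return(x)
  substring(x, seq(1L, nchar(x), width),
            pmin(seq(width, nchar(x) + width - 1L, width), nchar(x)))
}

#' Write GenomeRecord objects as a GenBank flat file
#'
#' Emits one LOCUS entry per record with source and CDS features
#' (coordinates converted back to 1-based inclusive) and the lineage in
#' the ORGANISM block. The nucleotide ORIGIN section is omitted; the
#' protein translations carried by the CDS features are the sequence
#' payload the pipeline consumes.
#'
#' @param records a GenomeRecord or list of GenomeRecord.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(records, path) {
  if (is(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    g <- genes(rec)
    lin <- lineage(rec)
    species <- if (length(lin)) unname(lin[length(lin)]) else "synthetic organism"
    cat(sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2026\n",
                genomeId(rec), length(rec)), file = con)
    cat(sprintf("DEFINITION  synthetic replicon %s.\n", genomeId(rec)),
        file = con)
    cat(sprintf("ACCESSION   %s\n", genomeId(rec)), file = con)
    cat(sprintf("DBLINK      Assembly: %s\n", assemblyId(rec)), file = con)
    cat(sprintf("SOURCE      %s\n", species), file = con)
    cat(sprintf("  ORGANISM  %s\n", species), file = con)
    if (length(lin) > 1L)
      cat(sprintf("            %s.\n",
                  paste(lin[-length(lin)], collapse = "; ")), file = con)
    cat("FEATURES             Location/Qualifiers\n", file = con)
    cat(sprintf("     source          1..%d\n", length(rec)), file = con)
    cat(sprintf('                     /organism="%s"\n', species), file = con)
    cat(sprintf('                     /db_xref="taxon:%d"\n', taxId(rec)),
        file = con)
    if (nrow(g)) for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      cat(sprintf("     CDS             %s\n", loc), file = con)
      cat(sprintf('                     /locus_tag="%s"\n', g$gene_id[i]),
          file = con)
      cat(sprintf('                     /product="%s"\n', g$product[i]),
          file = con)
      tr <- .wrap(g$translation[i])
      cat(sprintf('                     /translation="%s', tr[1]), file = con)
      if (length(tr) > 1L)
        for (piece in tr[-1])
          cat(sprintf("\n                     %s", piece), file = con)
      cat('"\n', file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}

#' Read and write protein FASTA
#'
#' \code{readFastaAA} returns a named character vector of upper-cased
#' sequences (gap characters preserved, so aligned FASTA round-trips).
#' \code{writeFastaAA} writes a named character vector or AAStringSet.
#'
#' @param path file path.
#' @return \code{readFastaAA}: named character vector; an empty file
#'   yields an empty vector. Duplicate ids are an error.
#' @export
readFastaAA <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(setNames(character(), character()))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname readFastaAA
#' @param records named character vector (or AAStringSet) of sequences.
#' @param width line-wrap width.
#' @export
writeFastaAA <- function(records, path, width = 60L) {
  if (is(records, "XStringSet")) records <- setNames(as.character(records),
                                                     names(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(records)) {
    cat(">", id, "\n", sep = "", file = con)
    s <- records[[id]]
    for (piece in substring(s, seq(1L, max(nchar(s), 1L), width),
                            pmin(seq(width, nchar(s) + width - 1L, width),
                                 nchar(s))))
      cat(piece, "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read an externally produced per-protein domain-hit table
#'
#' The table is TSV with header columns \code{protein_id},
#' \code{domain_name}, \code{aa_start}, \code{aa_end}, \code{score} and
#' 1-based inclusive amino-acid coordinates; coordinates are converted
#' to 0-based half-open. Domain names outside the shipped registry are
#' retained but relabelled \code{"other:<name>"}. Rows with
#' \code{aa_start >= aa_end} are rejected with their line number.
#'
#' @param path TSV path.
#' @param registry a domain registry (see \code{\link{domainRegistry}}).
#' @return data.frame of domain hits (0-based half-open coordinates).
#' @export
readDomainTable <- function(path, registry = domainRegistry()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "aa_start", "aa_end", "score")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("domain table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(tab)
  bad <- which(tab$aa_start >= tab$aa_end)
  if (length(bad))
    stop("aa_start >= aa_end on data line(s): ", paste(bad, collapse = ", "))
  unknown <- !(tab$domain_name %in% registry$domain_name)
  tab$domain_name[unknown] <- paste0("other:", tab$domain_name[unknown])
  tab$aa_start <- as.integer(tab$aa_start - 1L)
  tab$aa_end <- as.integer(tab$aa_end)
  tab
}

#' Read an assembly -> TaxID -> lineage taxonomy table
#'
#' @param path TSV with columns \code{assembly_id}, \code{taxid} and
#'   the lineage ranks superkingdom..species.
#' @return data.frame.
#' @export
readTaxonomyTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assembly_id", "taxid")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("taxonomy table is missing columns: ", paste(miss, collapse = ", "))
  tab$taxid <- as.integer(tab$taxid)
  tab
}

.loci_table <- function(loci) {
  if (length(loci) == 0L)
    return(data.frame(locus_id = character(), genome_id = character(),
                      anchor_gene_id = character(), span_start = integer(),
                      span_end = integer(), n_genes = integer(),
                      n_blocks = integer(), member_genes = character(),
                      blocks = character(), flags = character()))
  do.call(rbind, lapply(loci, function(l) {
    g <- genes(l)
    data.frame(locus_id = locusId(l), genome_id = genomeId(l),
               anchor_gene_id = anchorGeneId(l),
               span_start = locusSpan(l)[1], span_end = locusSpan(l)[2],
               n_genes = nrow(g), n_blocks = length(unique(g$block_id)),
               member_genes = paste(g$gene_id, collapse = ","),
               blocks = paste(g$block_id, collapse = ","),
               flags = paste(locusFlags(l), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

.calls_table <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(locus_id = character(), system = character(),
                      subtype = character(), family_group = character(),
                      completeness = character(),
                      components_present = character(),
                      missing_core = character(), fusion_flags = character()))
  do.call(rbind, lapply(calls, function(sc) data.frame(
    locus_id = locusId(sc), system = systemOf(sc), subtype = subtypeOf(sc),
    family_group = familyGroup(sc), completeness = completeness(sc),
    components_present = paste(sort(componentsPresent(sc)), collapse = ","),
    missing_core = paste(sort(sc@missingCore), collapse = ","),
    fusion_flags = paste(sort(fusionFlags(sc)), collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Write result objects as TSV with a JSON sidecar
#'
#' Serializes the pipeline's result objects with deterministic column
#' and row order (rows sorted by their stable key). A \code{.json}
#' sidecar mirroring the TSV content is written next to every table.
#'
#' @param objects the object(s) to write: a list of DefenseLocus
#'   (\code{schema = "loci"}), a list of SystemCall (\code{"calls"}),
#'   a \linkS4class{PhyleticMatrix} (\code{"matrix"}; writes wide and
#'   long forms), an \linkS4class{EntropyProfile} (\code{"entropy"}),
#'   or a plain data.frame (\code{"table"}).
#' @param path output TSV path (the sidecar replaces the extension
#'   with \code{.json}).
#' @param schema one of \code{"loci"}, \code{"calls"}, \code{"matrix"},
#'   \code{"entropy"}, \code{"table"}.
#' @return invisible character vector of files written.
#' @export
writeTables <- function(objects, path,
                        schema = c("table", "loci", "calls", "matrix",
                                   "entropy")) {
  schema <- match.arg(schema)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  files <- c(path, json_path)
  tab <- switch(schema,
    loci = {
      t <- .loci_table(objects)
      t[order(t$locus_id), , drop = FALSE]
    },
    calls = {
      t <- .calls_table(objects)
      t[order(t$locus_id), , drop = FALSE]
    },
    matrix = {
      m <- phyleticCounts(objects)
      wide <- data.frame(group = rownames(m), as.data.frame(m),
                         check.names = FALSE)
      long <- data.frame(
        group = rep(rownames(m), times = ncol(m)),
        name = rep(colnames(m), each = nrow(m)),
        count = as.vector(m), stringsAsFactors = FALSE)
      long <- long[order(long$group, long$name), , drop = FALSE]
      long_path <- paste0(tools::file_path_sans_ext(path), "_long.tsv")
      utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, long_path)
      wide
    },
    entropy = as.data.frame(entropyTable(objects)),
    table = {
      t <- as.data.frame(objects)
      if (nrow(t)) t <- t[do.call(order, t[, 1, drop = FALSE]), , drop = FALSE]
      t
    })
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, json_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
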