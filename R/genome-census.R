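#' @include domain-locator.R
#' @importFrom GenomicRanges GRanges seqnames strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement translate getGeneticCode subseq
NULL

#' Construct a GenomeAnnotation
#'
#' @param genomeId Genome identifier.
#' @param replicons Named \code{DNAStringSet} (or named character vector) of
#'   replicon sequences.
#' @param genes \code{data.frame} with columns \code{geneId},
#'   \code{repliconId}, \code{start}, \code{end}, \code{strand},
#'   \code{product}, \code{proteinSequence} (1-based inclusive
#'   forward-strand coordinates).
#' @param topology Character vector ("circular"/"linear"), recycled across
#'   replicons.
#' @param roles Role labels ("chromosome", "chromid", "plasmid", "unknown"),
#'   recycled across replicons.
#' @return A [GenomeAnnotation-class].
#' @export
GenomeAnnotation <- function(genomeId, replicons, genes = NULL,
                             topology = "linear", roles = "unknown") {
  if (is.character(replicons)) replicons <- DNAStringSet(replicons)
  rid <- names(replicons)
  info <- S4Vectors::DataFrame(
    repliconId = rid,
    topology = rep_len(topology, length(rid)),
    role = rep_len(roles, length(rid)))
  if (is.null(genes) || nrow(genes) == 0L) {
    gr <- GRanges(seqnames = character(0), ranges = IRanges(),
                  strand = character(0))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = character(0), product = character(0),
      proteinSequence = character(0))
  } else {
    gr <- GRanges(seqnames = genes$repliconId,
                  ranges = IRanges(genes$start, genes$end),
                  strand = genes$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = genes$geneId, product = genes$product,
      proteinSequence = genes$proteinSequence)
  }
  new("GenomeAnnotation", genomeId = genomeId, replicons = replicons,
      repliconInfo = info, genes = gr)
}

## translate a CDS given forward-strand coordinates, bacterial code (table 11)
translateCds <- function(repliconSeq, start, end, strand) {
  nt <- subseq(repliconSeq, start, end)
  if (strand == "-") nt <- reverseComplement(nt)
  aa <- as.character(suppressWarnings(
    translate(nt, genetic.code = getGeneticCode("11"), if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Load an annotated genome
#'
#' Reads either a (multi-record) GenBank flat file or a GFF3 file plus
#' genomic FASTA into a [GenomeAnnotation-class]. One gene record is created
#' per CDS feature; the protein sequence is taken from the annotated
#' translation when present, otherwise translated from the genomic
#' coordinates with the bacterial genetic code (table 11), trimming the
#' terminal stop. A CDS whose length is not a multiple of three when
#' translation must be computed is skipped with a warning, as are CDS with
#' compound (join) locations.
#'
#' @param path GenBank file, or GFF3 file when \code{format = "gff3"}.
#' @param format \code{"genbank"} or \code{"gff3"}.
#' @param fasta Genomic FASTA path (required for GFF3 input).
#' @param genomeId Genome identifier (defaults to the file name).
#' @param topology Named character vector overriding per-replicon topology;
#'   for GenBank input the LOCUS line topology is used by default, for GFF3
#'   input the default is "linear".
#' @param roles Named character vector of replicon role labels
#'   ("chromosome", "chromid", "plasmid"); unlisted replicons get "unknown".
#' @return A [GenomeAnnotation-class].
#' @export
loadGenome <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                       genomeId = NULL, topology = NULL, roles = NULL) {
  format <- match.arg(format)
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "genbank") {
    parsed <- parseGenbank(path)
    seqs <- DNAStringSet(vapply(parsed, `[[`, character(1), "sequence"))
    names(seqs) <- vapply(parsed, `[[`, character(1), "name")
    topo <- vapply(parsed, `[[`, character(1), "topology")
    genes <- do.call(rbind, lapply(parsed, `[[`, "genes"))
  } else {
    if (is.null(fasta))
      stop("GFF3 input requires a genomic FASTA via the 'fasta' argument")
    seqs <- readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    gff <- rtracklayer::import(path)
    gff <- gff[gff$type == "CDS"]
    topo <- rep("linear", length(seqs))
    genes <- if (length(gff) == 0L) NULL else {
      ids <- if (!is.null(gff$locus_tag)) gff$locus_tag else gff$ID
      data.frame(geneId = as.character(ids),
                 repliconId = as.character(seqnames(gff)),
                 start = GenomicRanges::start(gff),
                 end = GenomicRanges::end(gff),
                 strand = as.character(strand(gff)),
                 product = if (!is.null(gff$product))
                   as.character(gff$product) else "",
                 proteinSequence = if (!is.null(gff$translation))
                   as.character(gff$translation) else NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  if (!is.null(topology)) {
    topo[match(names(topology), names(seqs), nomatch = 0L) != 0] <-
      topology[names(topology) %in% names(seqs)]
    idx <- match(names(topology), names(seqs))
    topo[idx[!is.na(idx)]] <- topology[!is.na(idx)]
  }
  roleVec <- rep("unknown", length(seqs))
  if (!is.null(roles)) {
    idx <- match(names(roles), names(seqs))
    roleVec[idx[!is.na(idx)]] <- roles[!is.na(idx)]
  }
  if (!is.null(genes) && nrow(genes)) {
    # fill in missing translations from the genomic sequence
    need <- which(is.na(genes$proteinSequence) | !nzchar(genes$proteinSequence))
    drop <- integer(0)
    for (i in need) {
      len <- genes$end[i] - genes$start[i] + 1L
      if (len %% 3L != 0L) {
        warning(sprintf("CDS '%s' length %d is not a multiple of 3; record skipped",
                        genes$geneId[i], len))
        drop <- c(drop, i)
        next
      }
      genes$proteinSequence[i] <- translateCds(
        seqs[[genes$repliconId[i]]], genes$start[i], genes$end[i],
        genes$strand[i])
    }
    if (length(drop)) genes <- genes[-drop, , drop = FALSE]
  }
  GenomeAnnotation(genomeId, seqs, genes,
                   topology = topo, roles = roleVec)
}

## minimal GenBank flat-file reader: LOCUS topology, CDS features with
## locus_tag/product/translation qualifiers, ORIGIN sequence
parseGenbank <- function(path) {
  lines <- readLines(path)
  recEnds <- grep("^//", lines)
  if (length(recEnds) == 0L)
    stop(sprintf("%s: no GenBank record terminator '//' found", path))
  recStarts <- c(1L, head(recEnds, -1L) + 1L)
  records <- Map(function(s, e) lines[s:(e - 1L)], recStarts, recEnds)
  lapply(records, parseGenbankRecord, path = path)
}

parseGenbankRecord <- function(rec, path) {
  locus <- grep("^LOCUS", rec, value = TRUE)
  if (length(locus) != 1L)
    stop(sprintf("%s: record without a single LOCUS line", path))
  lf <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  name <- lf[2L]
  topology <- if (any(tolower(lf) == "circular")) "circular" else "linear"

  featStart <- grep("^FEATURES", rec)
  originStart <- grep("^ORIGIN", rec)
  if (length(originStart) != 1L)
    stop(sprintf("%s record '%s': missing ORIGIN section", path, name))
  seqLines <- rec[(originStart + 1L):length(rec)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))

  genes <- NULL
  if (length(featStart) == 1L && featStart + 1L < originStart) {
    feat <- rec[(featStart + 1L):(originStart - 1L)]
    keyLines <- grep("^ {5}\\S", feat)
    cdsIdx <- keyLines[grepl("^ {5}CDS\\s", feat[keyLines])]
    rows <- list()
    for (j in seq_along(cdsIdx)) {
      i0 <- cdsIdx[j]
      i1 <- if (any(keyLines > i0)) min(keyLines[keyLines > i0]) - 1L
            else length(feat)
      block <- feat[i0:i1]
      loc <- trimws(sub("^ {5}CDS\\s+", "", block[1L]))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\(", "", sub("\\)$", "", loc))
      }
      if (grepl("join|order", loc)) {
        warning(sprintf("%s record '%s': compound CDS location '%s' skipped",
                        path, name, loc))
        next
      }
      m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
      if (length(m) != 3L)
        stop(sprintf("%s record '%s': cannot parse CDS location '%s'",
                     path, name, loc))
      quals <- parseQualifiers(block[-1L])
      gid <- quals[["locus_tag"]]
      if (is.null(gid)) gid <- quals[["gene"]]
      if (is.null(gid)) gid <- sprintf("%s_CDS%d", name, j)
      rows[[length(rows) + 1L]] <- data.frame(
        geneId = gid, repliconId = name,
        start = as.integer(m[2L]), end = as.integer(m[3L]), strand = strand,
        product = if (is.null(quals[["product"]])) "" else quals[["product"]],
        proteinSequence = if (is.null(quals[["translation"]])) NA_character_
                          else gsub("\\s", "", quals[["translation"]]),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) genes <- do.call(rbind, rows)
  }
  list(name = name, topology = topology, sequence = sequence, genes = genes)
}

## feature qualifier lines (continuations at column 22) -> named list
parseQualifiers <- function(lines) {
  txt <- trimws(lines)
  starts <- grepl("^/", txt)
  if (!any(starts)) return(list())
  grpIdx <- cumsum(starts)
  keep <- grpIdx > 0L
  joined <- vapply(split(txt[keep], grpIdx[keep]),
                   paste, character(1), collapse = "")
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

#' Write a GenomeAnnotation as a GenBank flat file
#'
#' Emits one record per replicon with CDS features (locus_tag, product,
#' translation) and the ORIGIN sequence; round-trips through [loadGenome()].
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param path Output path.
#' @export
writeGenbank <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- annotation@replicons
  info <- annotation@repliconInfo
  g <- annotation@genes
  for (i in seq_along(seqs)) {
    rid <- names(seqs)[i]
    L <- Biostrings::width(seqs)[i]
    topo <- info$topology[match(rid, info$repliconId)]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s BCT 01-JAN-2026",
                       rid, L, topo), con)
    writeLines(sprintf("DEFINITION  synthetic replicon %s.", rid), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    sel <- which(as.character(seqnames(g)) == rid)
    for (k in sel) {
      s <- GenomicRanges::start(g)[k]; e <- GenomicRanges::end(g)[k]
      loc <- sprintf("%d..%d", s, e)
      if (as.character(strand(g))[k] == "-")
        loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         g$geneId[k]), con)
      writeLines(sprintf("                     /product=\"%s\"",
                         g$product[k]), con)
      aa <- g$proteinSequence[k]
      chunks <- substring(aa, seq(1L, nchar(aa), 44L),
                          pmin(seq(1L, nchar(aa), 44L) + 43L, nchar(aa)))
      tlines <- sprintf("                     %s", chunks)
      tlines[1L] <- sprintf("                     /translation=\"%s", chunks[1L])
      tlines[length(tlines)] <- paste0(tlines[length(tlines)], "\"")
      writeLines(tlines, con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(as.character(seqs[[i]]))
    pos <- seq(1L, nchar(s), 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a GenomeAnnotation as GFF3 plus FASTA
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param gffPath Output GFF3 path.
#' @param fastaPath Output genomic FASTA path.
#' @export
writeGff3 <- function(annotation, gffPath, fastaPath) {
  g <- annotation@genes
  gr <- GRanges(seqnames = seqnames(g), ranges = IRanges::ranges(g),
                strand = strand(g))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep("CDS", length(g)),
    phase = rep(0L, length(g)),
    ID = g$geneId, locus_tag = g$geneId, product = g$product,
    translation = g$proteinSequence)
  rtracklayer::export(gr, gffPath, format = "gff3")
  writeXStringSet(annotation@replicons, fastaPath)
  invisible(c(gffPath, fastaPath))
}

#' Classify every protein of a genome
#'
#' For each gene, each of the three domain types is ABSENT when the hit table
#' has no hit of that type, and otherwise classified by the corresponding
#' activity-motif classifier applied to the hit's sub-sequence. A protein
#' with several same-type hits is called ACTIVE when any instance is ACTIVE.
#' Overlapping same-type hits are resolved with [resolveOverlaps()] first.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param hits Domain-hit \code{data.frame} whose \code{proteinId}s are gene
#'   ids of the annotation (unknown ids raise an error).
#' @param motifs Named list of patterns with elements \code{GGDEF},
#'   \code{EAL}, \code{PILZ}, as from [cdgMotifs()].
#' @return \code{data.frame} with one row per gene: \code{geneId};
#'   \code{ggdef}, \code{eal}, \code{pilz} (each \code{"ABSENT"},
#'   \code{"ACTIVE"} or \code{"DEGENERATE"}); \code{iSite} (logical;
#'   \code{FALSE} whenever ggdef is ABSENT); \code{architecture}.
#' @export
classifyProteome <- function(annotation, hits, motifs = cdgMotifs()) {
  g <- annotation@genes
  ids <- g$geneId
  unknown <- setdiff(unique(hits$proteinId), ids)
  if (length(unknown))
    stop(sprintf("hit table references unknown proteins: %s",
                 paste(unknown, collapse = ", ")))
  hits <- resolveOverlaps(hits)
  classifiers <- list(
    GGDEF = function(s) classifyGgdef(s, motifs[["GGDEF"]]),
    EAL = function(s) classifyEal(s, motifs[["EAL"]]),
    PILZ = function(s) classifyPilz(s, motifs[["PILZ"]]))
  out <- data.frame(geneId = ids, ggdef = "ABSENT", eal = "ABSENT",
                    pilz = "ABSENT", iSite = FALSE, architecture = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    ph <- hits[hits$proteinId == ids[i], , drop = FALSE]
    if (nrow(ph) == 0L) next
    aa <- g$proteinSequence[i]
    if (any(ph$end > nchar(aa)))
      stop(sprintf("hit coordinates exceed protein length for '%s'", ids[i]))
    out$architecture[i] <- architectureString(ph)
    for (type in c("GGDEF", "EAL", "PILZ")) {
      th <- ph[ph$domainType == type, , drop = FALSE]
      if (nrow(th) == 0L) next
      calls <- lapply(seq_len(nrow(th)), function(k) {
        sub <- substr(aa, th$start[k], th$end[k])
        if (nchar(sub) < 10L) return(NULL)  # too short to classify
        classifiers[[type]](sub)
      })
      calls <- Filter(Negate(is.null), calls)
      col <- c(GGDEF = "ggdef", EAL = "eal", PILZ = "pilz")[[type]]
      if (length(calls) == 0L) {
        out[[col]][i] <- "DEGENERATE"
        next
      }
      statuses <- vapply(calls, callStatus, character(1))
      out[[col]][i] <- if (any(statuses == "ACTIVE")) "ACTIVE" else "DEGENERATE"
      if (type == "GGDEF")
        out$iSite[i] <- any(vapply(calls, function(x)
          isTRUE(iSitePresent(x)), logical(1)))
    }
  }
  out
}

#' Build the per-genome signaling inventory
#'
#' Census categories follow the panel definition: DGC-only (GGDEF ACTIVE and
#' EAL not ACTIVE), PDE-only (EAL ACTIVE and GGDEF not ACTIVE), bifunctional
#' (both ACTIVE) and PilZ-like (PilZ ACTIVE, tallied independently, so it may
#' intersect the catalytic categories). Domain-presence totals
#' (\code{ggdef_total}, \code{eal_total}, \code{pilz_total}) count proteins
#' carrying the domain regardless of activity.
#'
#' @param calls \code{data.frame} from [classifyProteome()].
#' @param genomeId Genome identifier to record.
#' @return A [SignalingInventory-class].
#' @export
buildInventory <- function(calls, genomeId = "genome") {
  dgcOnly <- calls$geneId[calls$ggdef == "ACTIVE" & calls$eal != "ACTIVE"]
  pdeOnly <- calls$geneId[calls$eal == "ACTIVE" & calls$ggdef != "ACTIVE"]
  bifun <- calls$geneId[calls$ggdef == "ACTIVE" & calls$eal == "ACTIVE"]
  pilz <- calls$geneId[calls$pilz == "ACTIVE"]
  counts <- c(
    ggdef_total = sum(calls$ggdef != "ABSENT"),
    ggdef_active = sum(calls$ggdef == "ACTIVE"),
    eal_total = sum(calls$eal != "ABSENT"),
    eal_active = sum(calls$eal == "ACTIVE"),
    pilz_total = sum(calls$pilz != "ABSENT"),
    DGC_only = length(dgcOnly), PDE_only = length(pdeOnly),
    bifunctional = length(bifun), PilZ_like = length(pilz))
  new("SignalingInventory", genomeId = genomeId,
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      categoryGenes = list(DGC_only = dgcOnly, PDE_only = pdeOnly,
                           bifunctional = bifun, PilZ_like = pilz))
}

#' Summarize a panel of genomes
#'
#' Computes the per-category mean and sample standard deviation (n - 1
#' denominator) across genomes. Accepts either a list of
#' [SignalingInventory-class] objects or a plain numeric vector of counts
#' for a single category (e.g. total component counts read off a figure).
#' With a single genome the SD is reported as \code{NA}.
#'
#' @param inventories List of inventories, or a numeric vector.
#' @return \code{data.frame} with columns \code{category}, \code{mean},
#'   \code{sd}, \code{n}.
#' @examples
#' summarizePanel(c(25, 26, 35, 26, 28))  # mean 28.0
#' @export
summarizePanel <- function(inventories) {
  if (is.numeric(inventories)) {
    if (length(inventories) == 0L) stop("no counts supplied")
    return(data.frame(category = "components", mean = mean(inventories),
                      sd = if (length(inventories) > 1L) stats::sd(inventories)
                           else NA_real_,
                      n = length(inventories)))
  }
  if (!is.list(inventories) || length(inventories) == 0L)
    stop("need at least one inventory")
  stopifnot(all(vapply(inventories, is, logical(1), "SignalingInventory")))
  mat <- do.call(rbind, lapply(inventories, inventoryCounts))
  data.frame(category = colnames(mat),
             mean = colMeans(mat),
             sd = if (nrow(mat) > 1L) apply(mat, 2L, stats::sd) else NA_real_,
             n = nrow(mat), row.names = NULL)
}
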