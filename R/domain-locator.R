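#' @include motif-engine.R
NULL

## canonical empty hit table; all locator functions speak this schema
emptyHits <- function() {
  data.frame(proteinId = character(0), domainType = character(0),
             domainName = character(0), start = integer(0), end = integer(0),
             score = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Domain-name alias table
#'
#' Reads a two-column TSV mapping external domain names or accessions (CDD,
#' Pfam, ...) to the canonical types \code{GGDEF}, \code{EAL}, \code{PILZ}.
#' Matching downstream is case-insensitive; unmapped names are carried as
#' \code{OTHER}. With no argument the bundled table is returned.
#'
#' @param file Path to an alias TSV, or \code{NULL} for the bundled table.
#' @return \code{data.frame} with columns \code{alias}, \code{type}.
#' @export
domainAliases <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "domain_aliases.tsv", package = "cdgScan",
                        mustWork = TRUE)
  tab <- utils::read.table(file, sep = "\t", header = FALSE, comment.char = "#",
                           col.names = c("alias", "type"),
                           stringsAsFactors = FALSE)
  bad <- setdiff(tab$type, c("GGDEF", "EAL", "PILZ"))
  if (length(bad))
    stop(sprintf("alias table maps to unknown types: %s",
                 paste(bad, collapse = ", ")))
  tab
}

mapDomainType <- function(names, aliases) {
  idx <- match(tolower(names), tolower(aliases$alias))
  type <- aliases$type[idx]
  type[is.na(idx)] <- "OTHER"
  type
}

#' Read a domain-hit table
#'
#' Reads either an \code{hmmscan --domtblout} file (space-delimited, comment
#' lines starting with \code{#}; per-domain independent E-value and alignment
#' coordinates on the protein are used) or a generic 5-column TSV
#' (\code{protein_id}, \code{domain_name}, \code{start}, \code{end},
#' \code{evalue}; a header line with these names is allowed). Hits with
#' E-value above the threshold are dropped and domain names are mapped to
#' canonical types through the alias table.
#'
#' @param path Path to the hit table.
#' @param evalueThreshold Retain hits with E-value \eqn{\le} this (default
#'   \code{1e-5}; the web-service cutoff behind published domain censuses is
#'   rarely reported, so the threshold is configurable).
#' @param aliases Alias table as from [domainAliases()].
#' @param proteinLengths Optional named vector of protein lengths; when
#'   given, hits with coordinates outside \code{[1, length]} raise an error.
#' @param format \code{"auto"} (default), \code{"tsv"} or \code{"domtblout"}.
#' @return Hit \code{data.frame} with columns \code{proteinId},
#'   \code{domainType}, \code{domainName}, \code{start}, \code{end},
#'   \code{score} (E-value), \code{source} (\code{"TABLE"}).
#' @export
readDomainTable <- function(path, evalueThreshold = 1e-5,
                            aliases = domainAliases(),
                            proteinLengths = NULL,
                            format = c("auto", "tsv", "domtblout")) {
  format <- match.arg(format)
  stopifnot(evalueThreshold > 0)
  lines <- readLines(path)
  if (format == "auto") {
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    nf <- if (length(body)) length(strsplit(trimws(body[1L]), "[[:space:]]+")[[1]]) else 0L
    format <- if (nf >= 22L) "domtblout" else "tsv"
  }
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    if (format == "domtblout") {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 22L)
        stop(sprintf("%s line %d: expected >= 22 domtblout fields, got %d",
                     path, i, length(f)))
      rows[[length(rows) + 1L]] <- data.frame(
        proteinId = f[4L], domainName = f[1L],
        start = suppressWarnings(as.integer(f[18L])),
        end = suppressWarnings(as.integer(f[19L])),
        score = suppressWarnings(as.numeric(f[13L])),
        stringsAsFactors = FALSE)
    } else {
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) == 1L)  # tolerate space-separated generic tables
        f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 5L)
        stop(sprintf("%s line %d: expected 5 columns (protein_id, domain_name, start, end, evalue)",
                     path, i))
      if (i == 1L && tolower(f[1L]) %in% c("protein_id", "proteinid")) next
      rows[[length(rows) + 1L]] <- data.frame(
        proteinId = f[1L], domainName = f[2L],
        start = suppressWarnings(as.integer(f[3L])),
        end = suppressWarnings(as.integer(f[4L])),
        score = suppressWarnings(as.numeric(f[5L])),
        stringsAsFactors = FALSE)
    }
    r <- rows[[length(rows)]]
    if (anyNA(r$start) || anyNA(r$end) || anyNA(r$score))
      stop(sprintf("%s line %d: non-numeric coordinates or E-value", path, i))
    if (r$start < 1L || r$end < r$start || r$score < 0)
      stop(sprintf("%s line %d: invalid coordinates or negative E-value", path, i))
  }
  if (length(rows) == 0L) return(emptyHits())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$score <= evalueThreshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(emptyHits())
  if (!is.null(proteinLengths)) {
    len <- proteinLengths[hits$proteinId]
    over <- which(!is.na(len) & hits$end > len)
    if (length(over))
      stop(sprintf("hit coordinates exceed protein length for: %s",
                   paste(unique(hits$proteinId[over]), collapse = ", ")))
  }
  data.frame(proteinId = hits$proteinId,
             domainType = mapDomainType(hits$domainName, aliases),
             domainName = hits$domainName,
             start = hits$start, end = hits$end, score = hits$score,
             source = "TABLE", stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a domain-hit table as generic TSV
#'
#' Inverse of the generic-TSV reading mode of [readDomainTable()]: writing
#' then re-reading (at a permissive threshold) reproduces the retained hits.
#'
#' @param hits Hit \code{data.frame}.
#' @param path Output path.
#' @export
writeDomainTable <- function(hits, path) {
  out <- data.frame(protein_id = hits$proteinId, domain_name = hits$domainName,
                    start = hits$start, end = hits$end, evalue = hits$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## strict total order on hits: better score first (TABLE: lower E-value;
## HEURISTIC: higher fraction), then earlier start, end, input order
hitOrder <- function(hits) {
  goodness <- ifelse(hits$source == "HEURISTIC", -hits$score, hits$score)
  order(goodness, hits$start, hits$end, seq_len(nrow(hits)))
}

#' Resolve overlapping same-type domain hits
#'
#' Among hits of the same protein and domain type that overlap by at least
#' one residue, the best-scoring hit is retained (lowest E-value for table
#' hits, highest match fraction for heuristic hits; ties broken by earlier
#' start). Overlaps between different domain types are all retained. The
#' procedure is greedy on the score order, which selects the
#' lexicographically best non-overlapping same-type subset.
#'
#' @param hits Hit \code{data.frame} (one protein or many; resolution is per
#'   protein and type).
#' @return The retained subset, ordered by \code{proteinId} then \code{start}.
#' @export
resolveOverlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$proteinId, hits$domainType, sep = "\r"))) {
    g <- hits[grp, , drop = FALSE]
    ord <- grp[hitOrder(g)]
    taken <- integer(0)
    for (i in ord) {
      clash <- any(hits$start[taken] <= hits$end[i] &
                   hits$end[taken] >= hits$start[i])
      if (!clash) taken <- c(taken, i)
    }
    keep[taken] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$proteinId, out$start, out$end), , drop = FALSE]
}

#' Locate a domain heuristically from its activity motif
#'
#' Fallback locator for proteins without an external domain-hit table: the
#' motif's best partial alignment over the whole protein is taken as the
#' domain location when the fraction of matched essential residues reaches
#' \code{minMatchFraction}. The reported span is the alignment padded by
#' \code{flank} residues on both sides (clipped to the protein). The default
#' fraction of 0.6 is deliberately permissive so that degenerate domains are
#' still surfaced for downstream classification.
#'
#' @param proteinSequence Amino-acid string.
#' @param pattern A [MotifPattern-class].
#' @param minMatchFraction Minimum fraction of essential residues matched,
#'   in \code{(0, 1]}.
#' @param flank Padding in residues around the alignment span.
#' @param proteinId Identifier to record in the hit.
#' @return Hit \code{data.frame} with zero or one row (\code{source}
#'   \code{"HEURISTIC"}, \code{score} = matched fraction).
#' @export
heuristicLocate <- function(proteinSequence, pattern, minMatchFraction = 0.6,
                            flank = 15L, proteinId = "protein") {
  stopifnot(minMatchFraction > 0, minMatchFraction <= 1)
  bp <- bestPartialMatch(proteinSequence, pattern)
  frac <- bp$matchedCount / bp$totalEssentials
  if (is.na(bp$start) || frac < minMatchFraction) return(emptyHits())
  L <- nchar(proteinSequence)
  data.frame(proteinId = proteinId, domainType = pattern@name,
             domainName = pattern@name,
             start = max(1L, bp$start - as.integer(flank)),
             end = min(L, bp$end + as.integer(flank)),
             score = frac, source = "HEURISTIC", stringsAsFactors = FALSE)
}

#' Domain architecture string of one protein
#'
#' Orders the retained hits of a protein by start coordinate and joins their
#' names with hyphens (e.g. \code{"HAMP-PAS-GGDEF"}); non-canonical domains
#' appear under their own names.
#'
#' @param hits Hit \code{data.frame} for one protein (after
#'   [resolveOverlaps()]).
#' @return A single architecture string ("" for no hits).
#' @export
architectureString <- function(hits) {
  if (nrow(hits) == 0L) return("")
  if (length(unique(hits$proteinId)) > 1L)
    stop("architectureString expects hits of a single protein")
  h <- hits[order(hits$start, hits$end), , drop = FALSE]
  nm <- ifelse(h$domainType == "OTHER", h$domainName, h$domainType)
  paste(nm, collapse = "-")
}
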