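#' @include genome-census.R
NULL

#' Percent G+C of a nucleotide sequence
#'
#' N bases are excluded from both numerator and denominator, so draft-genome
#' ambiguity does not bias the statistic.
#'
#' @param sequence Nucleotide string over \code{A,C,G,T,N} (case
#'   insensitive), or a \code{DNAString}.
#' @return Percent in \code{[0, 100]}; \code{NA} (with a warning) for an
#'   empty or all-N sequence.
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(sequence) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("unexpected letters in nucleotide sequence: %s",
                 paste(bad, collapse = "")))
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  eff <- sum(counts)
  if (eff == 0L) {
    warning("empty or all-N sequence; GC content not available")
    return(NA_real_)
  }
  100 * (counts[["G"]] + counts[["C"]]) / eff
}

#' Baseline %GC of a genome or replicon
#'
#' The baseline is the GC content of the full nucleotide sequence of the
#' scope (not a gene-wise average), matching how genome and replicon
#' averages are quoted in component censuses.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param scope \code{"genome"} or a replicon id.
#' @return Percent G+C.
#' @export
baselineGc <- function(annotation, scope = "genome") {
  seqs <- annotation@replicons
  if (!identical(scope, "genome")) {
    if (!scope %in% names(seqs))
      stop(sprintf("unknown replicon '%s'", scope))
    seqs <- seqs[scope]
  }
  fr <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  tot <- colSums(fr)
  100 * (tot[["C"]] + tot[["G"]]) / sum(tot)
}

#' Upstream intergenic region of a gene
#'
#' Walks 5'-ward from the gene's translation start on its own strand until
#' the nearest boundary of any other annotated gene on the same replicon
#' (either strand). On circular replicons the walk wraps across the origin
#' (bounded by the focal gene's own far end). If the nearest neighbor abuts
#' or overlaps the translation start, the region has length zero.
#'
#' @param geneId Focal gene id.
#' @param annotation A [GenomeAnnotation-class] containing the gene.
#' @return An [IntergenicRegion-class]; its \code{ranges} hold the
#'   forward-strand coordinates in the genomic order in which the region
#'   reads along the chromosome (two rows when wrapping the origin).
#' @export
upstreamIntergenic <- function(geneId, annotation) {
  g <- annotation@genes
  i <- match(geneId, g$geneId)
  if (is.na(i))
    stop(sprintf("gene '%s' not found in annotation", geneId))
  rid <- as.character(seqnames(g))[i]
  L <- Biostrings::width(annotation@replicons)[match(rid, names(annotation@replicons))]
  circular <- annotation@repliconInfo$topology[
    match(rid, annotation@repliconInfo$repliconId)] == "circular"
  str <- as.character(strand(g))[i]
  s <- GenomicRanges::start(g)[i]
  e <- GenomicRanges::end(g)[i]
  same <- which(as.character(seqnames(g)) == rid)
  others <- setdiff(same, i)
  oStart <- GenomicRanges::start(g)[others]
  oEnd <- GenomicRanges::end(g)[others]
  if (circular) {
    # unrolled copies of the blockers (and of the focal gene itself, so the
    # wrapped walk cannot run through the gene's own far side)
    oStart <- c(oStart, oStart - L, oStart + L, s - L, s + L)
    oEnd <- c(oEnd, oEnd - L, oEnd + L, e - L, e + L)
  }

  if (str == "+") {
    probe <- s - 1L  # first upstream position, unrolled coordinates
    lowBound <- if (circular) -Inf else 1L
    blocked <- length(oStart) && any(oStart <= probe & oEnd >= probe)
    if (probe < lowBound || blocked) {
      reg <- IRanges()
    } else {
      ends <- oEnd[oEnd < probe]
      lo <- if (length(ends)) max(ends) + 1L else lowBound
      if (!is.finite(lo)) lo <- probe - L + 1L  # no blockers at all
      reg <- IRanges(max(lo, probe - L + 1L), probe)
    }
  } else {
    probe <- e + 1L
    highBound <- if (circular) Inf else L
    blocked <- length(oStart) && any(oStart <= probe & oEnd >= probe)
    if (probe > highBound || blocked) {
      reg <- IRanges()
    } else {
      starts <- oStart[oStart > probe]
      hi <- if (length(starts)) min(starts) - 1L else highBound
      if (!is.finite(hi)) hi <- probe + L - 1L
      reg <- IRanges(probe, min(hi, probe + L - 1L))
    }
  }

  # map unrolled coordinates back onto [1, L], splitting at the origin;
  # segments are kept in the genomic order in which the region reads
  segs <- IRanges()
  seqtxt <- ""
  if (length(reg)) {
    a <- IRanges::start(reg); b <- IRanges::end(reg)
    if (a < 1L) {              # wraps: [a+L, L] then [1, b]
      parts <- list(c(a + L, L), if (b >= 1L) c(1L, b) else NULL)
    } else if (b > L) {        # wraps: [a, L] then [1, b-L]
      parts <- list(c(a, L), c(1L, b - L))
    } else parts <- list(c(a, b))
    parts <- Filter(Negate(is.null), parts)
    segs <- IRanges(vapply(parts, `[`, numeric(1), 1L),
                    vapply(parts, `[`, numeric(1), 2L))
    seqtxt <- paste(vapply(parts, function(p)
      as.character(subseq(annotation@replicons[[rid]], p[1L], p[2L])),
      character(1)), collapse = "")
  }
  new("IntergenicRegion", geneId = geneId, repliconId = rid,
      geneStrand = str, ranges = segs, sequence = seqtxt,
      gcPercent = if (nzchar(seqtxt))
        suppressWarnings(gcContent(seqtxt)) else NA_real_)
}

#' Upstream-intergenic %GC for a set of genes
#'
#' Convenience wrapper applying [upstreamIntergenic()] to a gene set.
#' Zero-length regions are kept in the table (with \code{NA} GC) but are the
#' rows to drop before group statistics.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param geneIds Gene ids (default: all genes).
#' @return \code{data.frame} with columns \code{geneId}, \code{repliconId},
#'   \code{length}, \code{gcPercent}.
#' @export
upstreamGcTable <- function(annotation, geneIds = NULL) {
  if (is.null(geneIds)) geneIds <- annotation@genes$geneId
  rows <- lapply(geneIds, function(id) {
    r <- upstreamIntergenic(id, annotation)
    data.frame(geneId = id, repliconId = r@repliconId,
               length = sum(IRanges::width(r@ranges)),
               gcPercent = r@gcPercent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a group of %GC values to a fixed baseline
#'
#' One-sample two-sided t-test of the group mean against a constant baseline
#' (e.g. the genome or replicon average GC). This mirrors comparisons of a
#' set of per-gene upstream-region values to a single replicon-wide figure.
#'
#' @param values Numeric vector of per-gene percentages (NAs dropped).
#' @param baseline Baseline percent.
#' @param groupLabel,baselineLabel Labels carried into the output.
#' @return One-row \code{data.frame}: \code{group}, \code{baselineLabel},
#'   \code{n}, \code{mean}, \code{baseline}, \code{t}, \code{df}, \code{p}.
#'   \code{t} and \code{p} are \code{NA} (with a warning) when fewer than
#'   two values are available or the values are constant.
#' @examples
#' compareToBaseline(c(2, 4, 6), 0)  # t = 2*sqrt(3), df = 2
#' @export
compareToBaseline <- function(values, baseline, groupLabel = "group",
                              baselineLabel = "baseline") {
  values <- values[!is.na(values)]
  n <- length(values)
  res <- data.frame(group = groupLabel, baselineLabel = baselineLabel,
                    n = n, mean = if (n) mean(values) else NA_real_,
                    baseline = baseline, t = NA_real_, df = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  if (n < 2L) {
    warning("fewer than two values; t-test not available")
    return(res)
  }
  if (stats::sd(values) < .Machine$double.eps^0.5 * max(1, abs(mean(values)))) {
    warning("values are constant to machine precision; t-test not available")
    return(res)
  }
  tt <- stats::t.test(values, mu = baseline)
  res$t <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p <- tt$p.value
  res
}
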