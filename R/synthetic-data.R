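#' @include expression.R
NULL

## pick one codon per amino acid under the bacterial code (table 11), so
## protein sequences reverse-translate deterministically
aaToCodon <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    gc <- Biostrings::getGeneticCode("11")
    m <- vapply(AA_STANDARD, function(a) names(gc)[gc == a][1L], character(1))
    map <<- m
    map
  }
})

sampleOne <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

randomProtein <- function(n, composition = NULL) {
  if (is.null(composition))
    paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
  else
    paste(sample(names(composition), n, replace = TRUE, prob = composition),
          collapse = "")
}

#' Generate a protein with one planted motif instance
#'
#' Builds a random-background protein containing exactly one planted
#' instance of the motif, with ranged-spacer widths drawn uniformly from
#' their ranges. Listed essential residues are mutated to a uniformly chosen
#' disallowed letter, making the planted domain degenerate with a known
#' mismatch set. Rejection sampling guarantees clean truth labels: the
#' background carries no accidental full-motif match, and within the planted
#' span the best partial alignment is the planted one with exactly the
#' planted mismatches.
#'
#' @param seed Integer seed (\code{NULL} to use the current RNG state, e.g.
#'   inside a seeded caller).
#' @param length Protein length; must be at least the pattern's maximal
#'   width plus 20.
#' @param pattern A [MotifPattern-class].
#' @param mutateEssentials Integer indices (1-based over the pattern's
#'   essential residue classes) to mutate.
#' @param plantISite Plant an RxxD submotif with its terminal D exactly 5
#'   residues before the A-site anchor (GGDEF-type patterns only).
#' @param iSiteAnchor Essential index anchoring the A-site block (5 for the
#'   GGDEF motif).
#' @param composition Optional named probability vector over amino-acid
#'   letters for the background (default uniform).
#' @param id Identifier recorded in the truth record.
#' @param maxAttempts Rejection-sampling cap (error when exceeded; use a
#'   longer protein).
#' @return A list: \code{sequence} and a one-row \code{truth} data.frame
#'   (\code{id}, \code{pattern}, \code{start}, \code{end},
#'   \code{spacerWidths}, \code{mutatedEssentials}, \code{iSitePlanted},
#'   \code{expectedStatus}).
#' @export
makeProtein <- function(seed = NULL, length, pattern,
                        mutateEssentials = integer(0), plantISite = FALSE,
                        iSiteAnchor = if (plantISite) 5L else NA_integer_,
                        composition = NULL, id = "protein1",
                        maxAttempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(pattern, "MotifPattern"))
  el <- pattern@elements
  isEss <- el$kind == "RESIDUE_CLASS"
  nEss <- sum(isEss)
  if (length(mutateEssentials) &&
      (any(mutateEssentials < 1L) || any(mutateEssentials > nEss)))
    stop(sprintf("essential indices must lie in 1..%d", nEss))
  wmax <- patternWidthRange(pattern)[2L]
  if (length < wmax + 20L)
    stop(sprintf("protein length must be at least pattern max width + 20 (%d)",
                 wmax + 20L))
  allowed <- strsplit(el$allowed[isEss], "")

  for (attempt in seq_len(maxAttempts)) {
    widths <- ifelse(el$kind == "SPACER",
                     mapply(function(lo, hi) sampleOne(lo:hi),
                            el$spanMin, el$spanMax),
                     1L)
    W <- sum(widths)
    offs <- essentialOffsets(widths, isEss)   # 0-based within the instance
    inst <- strsplit(randomProtein(W, composition), "")[[1]]
    for (j in seq_len(nEss))
      inst[offs[j] + 1L] <- sampleOne(allowed[[j]])
    for (j in mutateEssentials)
      inst[offs[j] + 1L] <- sampleOne(setdiff(AA_STANDARD, allowed[[j]]))
    if (!is.na(iSiteAnchor)) {
      aRel <- offs[iSiteAnchor] + 1L          # A-site start within instance
      dRel <- aRel - 5L; rRel <- dRel - 3L
      if (plantISite) {
        if (rRel < 1L)
          stop("pattern too narrow to plant an I-site upstream of the anchor")
        inst[rRel] <- "R"; inst[dRel] <- "D"
      }
    }
    start <- sampleOne(seq_len(length - W + 1L))
    chars <- strsplit(randomProtein(length, composition), "")[[1]]
    chars[start:(start + W - 1L)] <- inst
    seqStr <- paste(chars, collapse = "")

    # clean-label rejection: (a) no accidental full match outside the plant
    full <- scanMotif(seqStr, pattern)
    ok <- if (length(mutateEssentials) == 0L) {
      nrow(full) >= 1L && all(full$start == start & full$end == start + W - 1L) &&
        nrow(full) == 1L
    } else nrow(full) == 0L
    # (b) within the planted span the best partial alignment is the plant
    if (ok && length(mutateEssentials)) {
      bp <- bestPartialMatch(substr(seqStr, start, start + W - 1L), pattern)
      ok <- !is.na(bp$start) && bp$start == 1L &&
        identical(sort(bp$mismatches$essentialIndex),
                  sort(as.integer(unique(mutateEssentials))))
    }
    # (c) the I-site flag must reflect the plan, not background luck
    if (ok && !is.na(iSiteAnchor)) {
      aAbs <- start + offs[iSiteAnchor]
      dAbs <- aAbs - 5L; rAbs <- dAbs - 3L
      hasI <- rAbs >= 1L && chars[rAbs] == "R" && chars[dAbs] == "D"
      ok <- hasI == plantISite
    }
    if (ok) {
      truth <- data.frame(
        id = id, pattern = pattern@name, start = start, end = start + W - 1L,
        spacerWidths = paste(widths[el$kind == "SPACER"], collapse = ","),
        mutatedEssentials = paste(sort(unique(mutateEssentials)), collapse = ","),
        iSitePlanted = isTRUE(plantISite),
        expectedStatus = if (length(mutateEssentials)) "DEGENERATE" else "ACTIVE",
        stringsAsFactors = FALSE)
      return(list(sequence = seqStr, truth = truth, attempts = attempt))
    }
  }
  stop(sprintf("rejection-sampling cap (%d attempts) exceeded; try a longer protein",
               maxAttempts))
}

## background-only protein guaranteed free of all three full motifs
makeNullProtein <- function(length, motifs, composition = NULL,
                            maxAttempts = 1000L) {
  for (attempt in seq_len(maxAttempts)) {
    s <- randomProtein(length, composition)
    hitAny <- any(vapply(motifs, function(p) nrow(scanMotif(s, p)) > 0L,
                         logical(1)))
    if (!hitAny) return(s)
  }
  stop("could not generate a motif-free background protein")
}

randomDna <- function(n, gcTarget) {
  isGC <- stats::runif(n) < gcTarget / 100
  b <- character(n)
  b[isGC] <- sample(c("G", "C"), sum(isGC), replace = TRUE)
  b[!isGC] <- sample(c("A", "T"), sum(!isGC), replace = TRUE)
  paste(b, collapse = "")
}

reverseTranslate <- function(aa) {
  codons <- aaToCodon()[strsplit(aa, "")[[1]]]
  paste0(paste(codons, collapse = ""), "TAA")
}

#' Generate a synthetic annotated multi-replicon genome
#'
#' Lays out genes separated by intergenic spacers of controlled length and
#' GC content (base-wise Bernoulli G/C versus A/T at the target rate).
#' Protein sequences are built by [makeProtein()] according to the
#' architecture mix; coding sequences are deterministic reverse
#' translations under the bacterial code plus a TAA stop. Categories:
#' \code{"DGC"} (active GGDEF), \code{"DGC_degenerate"}, \code{"PDE"}
#' (active EAL), \code{"PDE_degenerate"}, \code{"bifunctional"} (active
#' GGDEF + active EAL), \code{"PilZ"}, \code{"none"} (motif-free
#' background).
#'
#' @param seed Integer seed.
#' @param nReplicons Number of replicons.
#' @param genesPerReplicon Genes per replicon (recycled).
#' @param architectureMix Character vector of category labels, recycled over
#'   all genes in layout order.
#' @param intergenicGcTargets Percent GC of intergenic spacers, one per
#'   replicon (recycled).
#' @param topology "circular" or "linear" (recycled per replicon).
#' @param intergenicLength Spacer length in bp between consecutive genes
#'   (also used for the leading/trailing spacers).
#' @param motifs Motif set, as from [cdgMotifs()].
#' @param outDir Optional directory; when given, GenBank
#'   (\code{genome.gbk}), GFF3 + FASTA (\code{genome.gff3},
#'   \code{genome.fna}), the domain-hit table (\code{domains.tsv}) and the
#'   truth table (\code{truth.tsv}) are written there.
#' @return List: \code{annotation} ([GenomeAnnotation-class]), \code{truth}
#'   (per-gene data.frame with planted category and motif details),
#'   \code{hits} (TABLE-style hit data.frame locating every planted domain),
#'   \code{files} (paths, when written).
#' @export
makeGenome <- function(seed, nReplicons = 1L, genesPerReplicon = 10L,
                       architectureMix = "DGC", intergenicGcTargets = 60,
                       topology = "circular", intergenicLength = 500L,
                       motifs = cdgMotifs(), outDir = NULL) {
  set.seed(seed)
  genesPerReplicon <- rep_len(genesPerReplicon, nReplicons)
  intergenicGcTargets <- rep_len(intergenicGcTargets, nReplicons)
  topology <- rep_len(topology, nReplicons)
  nGenes <- sum(genesPerReplicon)
  mix <- rep_len(architectureMix, nGenes)

  gLens <- list(GGDEF = patternWidthRange(motifs$GGDEF)[2L] + 40L,
                EAL = patternWidthRange(motifs$EAL)[2L] + 40L,
                PILZ = patternWidthRange(motifs$PILZ)[2L] + 40L)
  geneRows <- list()
  truthRows <- list()
  hitRows <- list()
  seqs <- character(nReplicons)
  names(seqs) <- sprintf("replicon%02d", seq_len(nReplicons))
  gi <- 0L
  for (ri in seq_len(nReplicons)) {
    rid <- names(seqs)[ri]
    parts <- character(0)
    pos <- 0L
    for (k in seq_len(genesPerReplicon[ri])) {
      gi <- gi + 1L
      gid <- sprintf("SYN%04d", gi)
      cat_k <- mix[gi]
      spacer <- randomDna(intergenicLength, intergenicGcTargets[ri])
      doms <- list()  # per-domain: type, protein-relative span, truth fields
      if (cat_k %in% c("DGC", "DGC_degenerate")) {
        mut <- if (cat_k == "DGC_degenerate") sampleOne(seq_len(9L)) else integer(0)
        p <- makeProtein(NULL, gLens$GGDEF, motifs$GGDEF,
                         mutateEssentials = mut, id = gid)
        aa <- p$sequence
        doms <- list(list(type = "GGDEF", truth = p$truth))
      } else if (cat_k %in% c("PDE", "PDE_degenerate")) {
        mut <- if (cat_k == "PDE_degenerate") sampleOne(seq_len(7L)) else integer(0)
        p <- makeProtein(NULL, gLens$EAL, motifs$EAL,
                         mutateEssentials = mut, id = gid)
        aa <- p$sequence
        doms <- list(list(type = "EAL", truth = p$truth))
      } else if (cat_k == "bifunctional") {
        pg <- makeProtein(NULL, gLens$GGDEF, motifs$GGDEF, id = gid)
        pe <- makeProtein(NULL, gLens$EAL, motifs$EAL, id = gid)
        aa <- paste0(pg$sequence, pe$sequence)
        pe$truth$start <- pe$truth$start + nchar(pg$sequence)
        pe$truth$end <- pe$truth$end + nchar(pg$sequence)
        doms <- list(list(type = "GGDEF", truth = pg$truth),
                     list(type = "EAL", truth = pe$truth))
      } else if (cat_k == "PilZ") {
        p <- makeProtein(NULL, gLens$PILZ, motifs$PILZ, id = gid)
        aa <- p$sequence
        doms <- list(list(type = "PILZ", truth = p$truth))
      } else if (cat_k == "none") {
        aa <- makeNullProtein(150L, motifs)
      } else stop(sprintf("unknown architecture category '%s'", cat_k))

      strandK <- if (k %% 2L == 0L) "-" else "+"
      cds <- reverseTranslate(aa)
      if (strandK == "-")
        cds <- as.character(reverseComplement(Biostrings::DNAString(cds)))
      parts <- c(parts, spacer, cds)
      gStart <- pos + intergenicLength + 1L
      gEnd <- gStart + nchar(cds) - 1L
      pos <- gEnd
      geneRows[[gi]] <- data.frame(
        geneId = gid, repliconId = rid, start = gStart, end = gEnd,
        strand = strandK, product = sprintf("synthetic %s protein", cat_k),
        proteinSequence = aa, stringsAsFactors = FALSE)
      truthRows[[gi]] <- data.frame(
        geneId = gid, repliconId = rid, category = cat_k,
        start = gStart, end = gEnd, strand = strandK,
        intergenicGcTarget = intergenicGcTargets[ri],
        domains = paste(vapply(doms, function(d) sprintf(
          "%s:%d-%d:%s", d$type, d$truth$start, d$truth$end,
          ifelse(nzchar(d$truth$mutatedEssentials),
                 d$truth$mutatedEssentials, "-")), character(1)),
          collapse = ";"),
        stringsAsFactors = FALSE)
      for (d in doms)
        hitRows[[length(hitRows) + 1L]] <- data.frame(
          proteinId = gid, domainType = d$type, domainName = d$type,
          start = d$truth$start, end = d$truth$end, score = 1e-30,
          source = "TABLE", stringsAsFactors = FALSE)
    }
    parts <- c(parts, randomDna(intergenicLength, intergenicGcTargets[ri]))
    seqs[ri] <- paste(parts, collapse = "")
  }
  genes <- do.call(rbind, geneRows)
  annotation <- GenomeAnnotation(sprintf("synthetic_seed%d", seed),
                                 Biostrings::DNAStringSet(seqs), genes,
                                 topology = topology, roles = "unknown")
  truth <- do.call(rbind, truthRows)
  hits <- if (length(hitRows)) do.call(rbind, hitRows) else emptyHits()
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(genbank = file.path(outDir, "genome.gbk"),
               gff3 = file.path(outDir, "genome.gff3"),
               fasta = file.path(outDir, "genome.fna"),
               domains = file.path(outDir, "domains.tsv"),
               truth = file.path(outDir, "truth.tsv"))
    writeGenbank(annotation, files[["genbank"]])
    writeGff3(annotation, files[["gff3"]], files[["fasta"]])
    writeDomainTable(hits, files[["domains"]])
    utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(annotation = annotation, truth = truth, hits = hits, files = files)
}

#' Generate a balanced negative-binomial count table with known effects
#'
#' Cell means are \code{exp(grand + gene + condition + interaction)};
#' counts are drawn from a negative-binomial distribution with the given
#' dispersion (\code{size = 1/dispersion}) around the cell mean, with
#' \code{r} replicate libraries per condition.
#'
#' @param seed Integer seed.
#' @param geneEffects Named numeric vector of per-gene log effects.
#' @param conditionEffects Named numeric vector of per-condition log
#'   effects.
#' @param interactionEffects Optional genes x conditions matrix of log
#'   interaction effects (default 0).
#' @param r Replicates per condition (>= 2).
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param grandLogMean Grand log mean (default \code{log(100)}).
#' @param geneLengths Gene lengths in bp for the count set (default 1000).
#' @return List: \code{se} (a \code{SummarizedExperiment} from
#'   [makeCountSet()]) and \code{truth} (list with the cell-mean matrix).
#' @export
makeCounts <- function(seed, geneEffects, conditionEffects,
                       interactionEffects = NULL, r = 3L, dispersion = 0.05,
                       grandLogMean = log(100), geneLengths = 1000) {
  set.seed(seed)
  if (r < 2L) stop("need r >= 2 replicates per condition")
  if (dispersion <= 0) stop("dispersion must be positive")
  nG <- length(geneEffects); nC <- length(conditionEffects)
  if (is.null(names(geneEffects)))
    names(geneEffects) <- sprintf("gene%d", seq_len(nG))
  if (is.null(names(conditionEffects)))
    names(conditionEffects) <- sprintf("cond%d", seq_len(nC))
  if (is.null(interactionEffects))
    interactionEffects <- matrix(0, nG, nC)
  stopifnot(nrow(interactionEffects) == nG, ncol(interactionEffects) == nC)
  mu <- exp(grandLogMean + outer(geneEffects, conditionEffects, "+") +
            interactionEffects)
  dimnames(mu) <- list(names(geneEffects), names(conditionEffects))
  counts <- matrix(0L, nG, nC * r)
  conds <- rep(names(conditionEffects), each = r)
  for (j in seq_len(nC))
    for (k in seq_len(r))
      counts[, (j - 1L) * r + k] <- stats::rnbinom(nG, mu = mu[, j],
                                                   size = 1 / dispersion)
  rownames(counts) <- names(geneEffects)
  colnames(counts) <- sprintf("%s_rep%d", conds, rep(seq_len(r), times = nC))
  se <- makeCountSet(counts, rep_len(geneLengths, nG), conds)
  list(se = se, truth = list(cellMeans = mu, dispersion = dispersion, r = r))
}
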