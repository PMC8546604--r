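#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges IRanges
NULL

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' MotifPattern: a spacing-constrained protein activity motif
#'
#' An ordered grammar of essential-residue classes (sets of allowed amino
#' acids) and anonymous spacers of fixed or ranged width. Activity motifs of
#' c-di-GMP signaling domains (GGDEF, EAL, PilZ) are expressed in this form:
#' the motif matches when every essential residue class is satisfied at the
#' spacing the pattern prescribes.
#'
#' @slot name Identifier of the motif (e.g. \code{"GGDEF"}).
#' @slot elements A \code{data.frame} with one row per element and columns
#'   \code{kind} (\code{"RESIDUE_CLASS"} or \code{"SPACER"}), \code{allowed}
#'   (string of allowed amino-acid letters, residue classes only),
#'   \code{spanMin}, \code{spanMax} (spacer widths; equal to 1 for residue
#'   classes).
#'
#' @seealso [compilePattern()], [scanMotif()], [cdgMotifs()]
#' @export
setClass("MotifPattern",
  representation(name = "character", elements = "data.frame"))

setValidity("MotifPattern", function(object) {
  el <- object@elements
  msg <- character(0)
  need <- c("kind", "allowed", "spanMin", "spanMax")
  if (!all(need %in% names(el)))
    return(sprintf("elements must have columns %s", paste(need, collapse = ", ")))
  if (nrow(el) == 0L)
    return("pattern has no elements")
  if (!all(el$kind %in% c("RESIDUE_CLASS", "SPACER")))
    msg <- c(msg, "element kind must be RESIDUE_CLASS or SPACER")
  if (el$kind[1L] != "RESIDUE_CLASS" || el$kind[nrow(el)] != "RESIDUE_CLASS")
    msg <- c(msg, "first and last elements must be residue classes (motifs anchor on residues)")
  rc <- el$kind == "RESIDUE_CLASS"
  if (any(rc)) {
    letters_ok <- vapply(strsplit(el$allowed[rc], ""), function(x)
      length(x) > 0L && all(x %in% AA_STANDARD), logical(1))
    if (!all(letters_ok))
      msg <- c(msg, "residue classes must be non-empty sets of the 20 standard amino acids")
  }
  sp <- el$kind == "SPACER"
  if (any(sp)) {
    if (any(el$spanMin[sp] < 0L) || any(el$spanMin[sp] > el$spanMax[sp]))
      msg <- c(msg, "spacers require 0 <= spanMin <= spanMax")
  }
  if (length(msg)) msg else TRUE
})

#' ActivityCall: ACTIVE/DEGENERATE classification of one domain
#'
#' Result of evaluating an activity motif over a domain sequence. A domain is
#' ACTIVE when the full motif matches somewhere in the sequence, and
#' DEGENERATE when at least one essential residue fails to match in the best
#' attainable alignment, which is recorded with per-residue diagnostics.
#'
#' @slot domainType Which motif was evaluated ("GGDEF", "EAL", "PILZ", ...).
#' @slot status \code{"ACTIVE"} or \code{"DEGENERATE"}.
#' @slot matchedCount Number of essential residues satisfied by the best
#'   alignment.
#' @slot totalEssentials Number of essential residue classes in the motif.
#' @slot mismatchedEssentials \code{data.frame} with columns
#'   \code{essentialIndex}, \code{expected}, \code{observed}, \code{position}
#'   describing the failures of the best alignment (empty when ACTIVE).
#' @slot iSitePresent Logical; for GGDEF calls, whether an allosteric I-site
#'   (RxxD) sits at the expected distance upstream of the A-site block.
#'   \code{NA} for non-GGDEF domains.
#' @slot bestMatch One-row \code{DataFrame} describing the best (partial)
#'   alignment: \code{start}, \code{end}, \code{residuePositions},
#'   \code{spacerWidths}; zero rows when no alignment fits the sequence.
#'
#' @seealso [classifyGgdef()], [classifyEal()], [classifyPilz()]
#' @export
setClass("ActivityCall",
  representation(domainType = "character", status = "character",
                 matchedCount = "integer", totalEssentials = "integer",
                 mismatchedEssentials = "data.frame", iSitePresent = "logical",
                 bestMatch = "DataFrame"))

setValidity("ActivityCall", function(object) {
  msg <- character(0)
  if (!object@status %in% c("ACTIVE", "DEGENERATE"))
    msg <- c(msg, "status must be ACTIVE or DEGENERATE")
  if ((object@status == "ACTIVE") != (nrow(object@mismatchedEssentials) == 0L))
    msg <- c(msg, "status is ACTIVE iff mismatchedEssentials is empty")
  if (object@matchedCount > object@totalEssentials)
    msg <- c(msg, "matchedCount cannot exceed totalEssentials")
  if (length(msg)) msg else TRUE
})

#' GenomeAnnotation: replicons plus gene records of one genome
#'
#' Container for a (possibly multipartite) bacterial genome: replicon
#' sequences with topology and role labels, and protein-coding gene records
#' as a \code{GRanges} carrying gene ids, products and protein sequences.
#'
#' @slot genomeId Genome identifier.
#' @slot replicons Named \code{DNAStringSet} of replicon sequences.
#' @slot repliconInfo \code{DataFrame} with one row per replicon: columns
#'   \code{repliconId}, \code{topology} ("circular"/"linear"), \code{role}
#'   ("chromosome", "chromid", "plasmid" or "unknown").
#' @slot genes \code{GRanges} (seqnames = replicon ids, 1-based forward-strand
#'   coordinates) with metadata columns \code{geneId}, \code{product},
#'   \code{proteinSequence}.
#'
#' @seealso [loadGenome()], [makeGenome()], [upstreamIntergenic()]
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", replicons = "DNAStringSet",
                 repliconInfo = "DataFrame", genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  rid <- names(object@replicons)
  if (is.null(rid) || anyDuplicated(rid))
    return("replicons must have unique names")
  if (!identical(sort(rid), sort(as.character(object@repliconInfo$repliconId))))
    msg <- c(msg, "repliconInfo rows must match replicon names")
  if (!all(object@repliconInfo$topology %in% c("circular", "linear")))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  g <- object@genes
  if (length(g)) {
    if (!all(as.character(GenomicRanges::seqnames(g)) %in% rid))
      msg <- c(msg, "gene replicon ids must exist among replicons")
    else {
      lens <- Biostrings::width(object@replicons)[match(
        as.character(GenomicRanges::seqnames(g)), rid)]
      if (any(GenomicRanges::start(g) < 1L) || any(GenomicRanges::end(g) > lens))
        msg <- c(msg, "gene coordinates must lie within replicon bounds")
    }
    mc <- S4Vectors::mcols(g)
    if (!all(c("geneId", "product", "proteinSequence") %in% names(mc)))
      msg <- c(msg, "genes need metadata columns geneId, product, proteinSequence")
    else if (anyDuplicated(mc$geneId))
      msg <- c(msg, "gene ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' IntergenicRegion: the upstream intergenic stretch of one gene
#'
#' The maximal run of unannotated positions immediately 5' of a gene's
#' translation start on its own strand, bounded by the nearest annotated gene
#' on either strand. On circular replicons the region may wrap across the
#' origin, in which case \code{ranges} holds two forward-strand intervals.
#'
#' @slot geneId Focal gene.
#' @slot repliconId Replicon the region lies on.
#' @slot geneStrand Strand of the focal gene ("+" or "-").
#' @slot ranges \code{IRanges} of forward-strand coordinates (1 row, 2 when
#'   wrapped across the origin, 0 when the neighbor abuts the gene).
#' @slot sequence Forward-strand sequence of the region, origin-wrapped
#'   segments concatenated in genomic order relative to the gene (may be "").
#' @slot gcPercent Percent G+C of the region (N excluded); \code{NA} for
#'   empty regions.
#'
#' @seealso [upstreamIntergenic()], [gcContent()]
#' @export
setClass("IntergenicRegion",
  representation(geneId = "character", repliconId = "character",
                 geneStrand = "character", ranges = "IRanges",
                 sequence = "character", gcPercent = "numeric"))

#' SignalingInventory: per-genome census of c-di-GMP components
#'
#' Tallies of the component categories used for genome panels: proteins with
#' putative DGC activity only, PDE activity only, bifunctional DGC-PDE
#' proteins, and PilZ-like receptor proteins (tallied independently, so a
#' PilZ-carrying enzyme appears in both a catalytic category and PilZ-like).
#' Domain-presence totals are kept alongside the activity-filtered layer so
#' either census reading is recoverable.
#'
#' @slot genomeId Genome identifier.
#' @slot counts Named integer vector with elements \code{ggdef_total},
#'   \code{ggdef_active}, \code{eal_total}, \code{eal_active},
#'   \code{pilz_total}, \code{DGC_only}, \code{PDE_only},
#'   \code{bifunctional}, \code{PilZ_like}.
#' @slot categoryGenes Named list of gene-id character vectors for the four
#'   census categories.
#'
#' @seealso [buildInventory()], [summarizePanel()]
#' @export
setClass("SignalingInventory",
  representation(genomeId = "character", counts = "integer",
                 categoryGenes = "list"))

setValidity("SignalingInventory", function(object) {
  need <- c("ggdef_total", "ggdef_active", "eal_total", "eal_active",
            "pilz_total", "DGC_only", "PDE_only", "bifunctional", "PilZ_like")
  if (!all(need %in% names(object@counts)))
    return(sprintf("counts must contain %s", paste(need, collapse = ", ")))
  cats <- c("DGC_only", "PDE_only", "bifunctional", "PilZ_like")
  if (!all(cats %in% names(object@categoryGenes)))
    return("categoryGenes must list the four census categories")
  n_ok <- vapply(cats, function(k)
    length(object@categoryGenes[[k]]) == object@counts[[k]], logical(1))
  if (!all(n_ok))
    return("category gene-list lengths must equal the counts")
  if (object@counts[["ggdef_active"]] > object@counts[["ggdef_total"]])
    return("ggdef_active cannot exceed ggdef_total")
  TRUE
})
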