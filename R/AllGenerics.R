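#' @include AllClasses.R
NULL

#' Accessors for cdgScan classes
#'
#' Small accessor generics: \code{motifName} and \code{patternElements} read
#' a [MotifPattern-class]; \code{callStatus}, \code{mismatchedEssentials} and
#' \code{iSitePresent} read an [ActivityCall-class]; \code{genomeId},
#' \code{repliconSeqs}, \code{repliconInfo} and \code{geneRanges} read a
#' [GenomeAnnotation-class]; \code{inventoryCounts} and \code{categoryGenes}
#' read a [SignalingInventory-class].
#'
#' @param x Object to access.
#' @return The slot content (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))
#' @rdname accessors
#' @export
setGeneric("patternElements", function(x) standardGeneric("patternElements"))
#' @rdname accessors
#' @export
setGeneric("callStatus", function(x) standardGeneric("callStatus"))
#' @rdname accessors
#' @export
setGeneric("mismatchedEssentials", function(x) standardGeneric("mismatchedEssentials"))
#' @rdname accessors
#' @export
setGeneric("iSitePresent", function(x) standardGeneric("iSitePresent"))
#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("repliconSeqs", function(x) standardGeneric("repliconSeqs"))
#' @rdname accessors
#' @export
setGeneric("repliconInfo", function(x) standardGeneric("repliconInfo"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("inventoryCounts", function(x) standardGeneric("inventoryCounts"))
#' @rdname accessors
#' @export
setGeneric("categoryGenes", function(x) standardGeneric("categoryGenes"))

#' @rdname accessors
setMethod("motifName", "MotifPattern", function(x) x@name)
#' @rdname accessors
setMethod("patternElements", "MotifPattern", function(x) x@elements)
#' @rdname accessors
setMethod("callStatus", "ActivityCall", function(x) x@status)
#' @rdname accessors
setMethod("mismatchedEssentials", "ActivityCall", function(x) x@mismatchedEssentials)
#' @rdname accessors
setMethod("iSitePresent", "ActivityCall", function(x) x@iSitePresent)
#' @rdname accessors
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)
#' @rdname accessors
setMethod("repliconSeqs", "GenomeAnnotation", function(x) x@replicons)
#' @rdname accessors
setMethod("repliconInfo", "GenomeAnnotation", function(x) x@repliconInfo)
#' @rdname accessors
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)
#' @rdname accessors
setMethod("inventoryCounts", "SignalingInventory", function(x) x@counts)
#' @rdname accessors
setMethod("categoryGenes", "SignalingInventory", function(x) x@categoryGenes)

setMethod("show", "MotifPattern", function(object) {
  n_ess <- sum(object@elements$kind == "RESIDUE_CLASS")
  cat(sprintf("MotifPattern '%s': %d elements (%d essential residue classes)\n",
              object@name, nrow(object@elements), n_ess))
  cat("  ", serializePattern(object), "\n", sep = "")
  w <- patternWidthRange(object)
  cat(sprintf("  match width %d", w[1L]))
  if (w[2L] > w[1L]) cat(sprintf("-%d", w[2L]))
  cat(" aa\n")
})

setMethod("show", "ActivityCall", function(object) {
  cat(sprintf("ActivityCall [%s]: %s (%d/%d essentials matched)\n",
              object@domainType, object@status,
              object@matchedCount, object@totalEssentials))
  if (!is.na(object@iSitePresent))
    cat(sprintf("  I-site (RxxD) present: %s\n", object@iSitePresent))
  mm <- object@mismatchedEssentials
  if (nrow(mm))
    cat(sprintf("  mismatched: %s\n",
                paste(sprintf("#%d (%s, saw '%s')", mm$essentialIndex,
                              mm$expected, mm$observed), collapse = ", ")))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation '%s': %d replicon(s), %d gene(s)\n",
              object@genomeId, length(object@replicons), length(object@genes)))
  info <- object@repliconInfo
  for (i in seq_len(nrow(info)))
    cat(sprintf("  %s: %d bp, %s, %s\n", info$repliconId[i],
                Biostrings::width(object@replicons)[match(info$repliconId[i],
                                                          names(object@replicons))],
                info$topology[i], info$role[i]))
})

setMethod("show", "IntergenicRegion", function(object) {
  cat(sprintf("IntergenicRegion upstream of %s (%s strand) on %s: %d bp",
              object@geneId, object@geneStrand, object@repliconId,
              sum(IRanges::width(object@ranges))))
  if (length(object@ranges) > 1L) cat(" (wraps origin)")
  if (!is.na(object@gcPercent)) cat(sprintf(", %.1f%% GC", object@gcPercent))
  cat("\n")
})

setMethod("show", "SignalingInventory", function(object) {
  cat(sprintf("SignalingInventory for '%s'\n", object@genomeId))
  ct <- object@counts
  cat(sprintf("  GGDEF: %d present (%d active); EAL: %d present (%d active); PilZ: %d\n",
              ct[["ggdef_total"]], ct[["ggdef_active"]],
              ct[["eal_total"]], ct[["eal_active"]], ct[["pilz_total"]]))
  cat(sprintf("  categories: DGC-only %d, PDE-only %d, bifunctional %d, PilZ-like %d\n",
              ct[["DGC_only"]], ct[["PDE_only"]], ct[["bifunctional"]],
              ct[["PilZ_like"]]))
})
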