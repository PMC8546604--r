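#' @include AllClasses.R
NULL

#' Compile a motif-spec string into a MotifPattern
#'
#' The motif grammar is whitespace-separated tokens, read left to right:
#' a single amino-acid letter (\code{D}) or a bracketed alternative set
#' (\code{[GSA]}) is an essential residue class; \code{x(n)} is an anonymous
#' spacer of exactly \code{n} residues and \code{x(n,m)} a spacer of
#' \code{n} to \code{m} residues inclusive. A pattern must begin and end with
#' a residue class. The diguanylate-cyclase activity motif, for example, is
#' \code{"D x(7) N x(8) D x(21) R x(1) [GSA] G [DE] E F"}.
#'
#' @param spec Motif-spec string.
#' @param name Name to give the pattern.
#' @return A [MotifPattern-class].
#' @examples
#' p <- compilePattern("R x(2,3) D", name = "toy")
#' serializePattern(p)
#' @export
compilePattern <- function(spec, name = "motif") {
  stopifnot(is.character(spec), length(spec) == 1L)
  tokens <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop("empty motif spec")
  rows <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (grepl("^[A-Z]$", tok)) {
      if (!tok %in% AA_STANDARD)
        stop(sprintf("token %d ('%s'): not a standard amino-acid letter", i, tok))
      rows[[i]] <- data.frame(kind = "RESIDUE_CLASS", allowed = tok,
                              spanMin = 1L, spanMax = 1L)
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      inner <- substr(tok, 2L, nchar(tok) - 1L)
      bad <- setdiff(strsplit(inner, "")[[1]], AA_STANDARD)
      if (length(bad))
        stop(sprintf("token %d ('%s'): non-standard letters %s", i, tok,
                     paste(bad, collapse = "")))
      rows[[i]] <- data.frame(kind = "RESIDUE_CLASS", allowed = inner,
                              spanMin = 1L, spanMax = 1L)
    } else if (grepl("^x\\([0-9]+(,[0-9]+)?\\)$", tok)) {
      nums <- as.integer(strsplit(gsub("^x\\(|\\)$", "", tok), ",")[[1]])
      lo <- nums[1L]
      hi <- if (length(nums) == 2L) nums[2L] else nums[1L]
      if (lo > hi)
        stop(sprintf("token %d ('%s'): spacer range minimum exceeds maximum", i, tok))
      rows[[i]] <- data.frame(kind = "SPACER", allowed = "",
                              spanMin = lo, spanMax = hi)
    } else {
      stop(sprintf("parse error at token %d: '%s'", i, tok))
    }
  }
  el <- do.call(rbind, rows)
  if (el$kind[1L] != "RESIDUE_CLASS" || el$kind[nrow(el)] != "RESIDUE_CLASS")
    stop("pattern must start and end with a residue class, not a spacer")
  new("MotifPattern", name = name, elements = el)
}

#' Serialize a MotifPattern back to its spec string
#'
#' @param pattern A [MotifPattern-class].
#' @return A single spec string; \code{compilePattern(serializePattern(p))}
#'   reproduces the element list of \code{p}.
#' @export
serializePattern <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  el <- pattern@elements
  toks <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    if (el$kind[i] == "RESIDUE_CLASS") {
      toks[i] <- if (nchar(el$allowed[i]) == 1L) el$allowed[i]
                 else paste0("[", el$allowed[i], "]")
    } else {
      toks[i] <- if (el$spanMin[i] == el$spanMax[i])
        sprintf("x(%d)", el$spanMin[i])
      else sprintf("x(%d,%d)", el$spanMin[i], el$spanMax[i])
    }
  }
  paste(toks, collapse = " ")
}

#' Minimal and maximal match width of a pattern
#'
#' @param pattern A [MotifPattern-class].
#' @return Integer vector \code{c(min, max)} of total match widths in residues.
#' @export
patternWidthRange <- function(pattern) {
  el <- pattern@elements
  c(sum(el$spanMin), sum(el$spanMax))
}

#' Indices of essential residue classes
#'
#' @param pattern A [MotifPattern-class].
#' @return Integer positions (within the element list) of every residue class.
#' @export
essentialIndices <- function(pattern) {
  which(pattern@elements$kind == "RESIDUE_CLASS")
}

## enumerate every admissible spacer-width assignment, ordered by
## total spacer width (ascending) so tie-breaking is deterministic
spacerCombos <- function(pattern) {
  el <- pattern@elements
  widths <- Map(function(lo, hi, kind) if (kind == "SPACER") lo:hi else 1L,
                el$spanMin, el$spanMax, el$kind)
  grid <- expand.grid(rev(widths), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid)[, rev(seq_len(nrow(el))), drop = FALSE]
  colnames(grid) <- NULL
  sp <- el$kind == "SPACER"
  totalSpacer <- if (any(sp)) rowSums(grid[, sp, drop = FALSE]) else
    rep(0L, nrow(grid))
  ord <- order(totalSpacer)
  list(widths = grid[ord, , drop = FALSE],
       totalSpacer = totalSpacer[ord],
       isSpacer = sp)
}

## 0-based offsets of each residue-class element for one width assignment
essentialOffsets <- function(widths, isEssential) {
  starts <- cumsum(c(0L, widths[-length(widths)]))
  starts[isEssential]
}

checkAaSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty sequence")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_STANDARD, "X"))
  if (length(bad))
    stop(sprintf("sequence contains non-amino-acid letters: %s",
                 paste(bad, collapse = "")))
  sequence
}

## fixed-width regular expression for one spacer-width assignment;
## residue classes list their letters explicitly so 'X' never matches them
comboRegex <- function(el, widths) {
  parts <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    if (el$kind[i] == "RESIDUE_CLASS") {
      parts[i] <- if (nchar(el$allowed[i]) == 1L) el$allowed[i]
                  else paste0("[", el$allowed[i], "]")
    } else {
      parts[i] <- sprintf(".{%d}", widths[i])
    }
  }
  paste0("(?=", paste(parts, collapse = ""), ")")
}

#' Scan a protein sequence for all matches of a motif
#'
#' Enumerates every start position and every admissible assignment of ranged
#' spacer widths; overlapping matches are all reported. The ambiguity letter
#' \code{X} in the input never satisfies a residue class.
#'
#' @param sequence Amino-acid string (standard letters, \code{X} tolerated).
#' @param pattern A [MotifPattern-class].
#' @return A \code{DataFrame} with one row per match, sorted by
#'   \code{(start, end)}: columns \code{start}, \code{end} (1-based
#'   inclusive), \code{residuePositions} (\code{IntegerList}; position of each
#'   essential residue) and \code{spacerWidths} (\code{IntegerList}; chosen
#'   width of each spacer element).
#' @examples
#' p <- compilePattern("R x(2,3) D")
#' scanMotif("RAAD", p)
#' @export
scanMotif <- function(sequence, pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  sequence <- checkAaSequence(sequence)
  el <- pattern@elements
  combos <- spacerCombos(pattern)
  isEss <- el$kind == "RESIDUE_CLASS"
  out <- list()
  for (k in seq_len(nrow(combos$widths))) {
    w <- combos$widths[k, ]
    total <- sum(w)
    if (total > nchar(sequence)) next
    re <- comboRegex(el, w)
    m <- gregexpr(re, sequence, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    offs <- essentialOffsets(w, isEss)
    out[[length(out) + 1L]] <- data.frame(
      start = starts, end = starts + total - 1L,
      combo = k,
      stringsAsFactors = FALSE)
    attr(out[[length(out)]], "offs") <- offs
    attr(out[[length(out)]], "spw") <- w[combos$isSpacer]
  }
  if (length(out) == 0L) {
    return(S4Vectors::DataFrame(
      start = integer(0), end = integer(0),
      residuePositions = IRanges::IntegerList(),
      spacerWidths = IRanges::IntegerList()))
  }
  resPos <- do.call(c, lapply(out, function(d)
    lapply(d$start, function(s) s + attr(d, "offs"))))
  spw <- do.call(c, lapply(out, function(d)
    rep(list(as.integer(attr(d, "spw"))), nrow(d))))
  flat <- do.call(rbind, lapply(out, function(d) d[c("start", "end")]))
  ord <- order(flat$start, flat$end)
  S4Vectors::DataFrame(
    start = flat$start[ord], end = flat$end[ord],
    residuePositions = IRanges::IntegerList(resPos[ord]),
    spacerWidths = IRanges::IntegerList(spw[ord]))
}

#' Best partial alignment of a motif to a sequence
#'
#' Over all start positions and ranged-spacer-width assignments, finds the
#' alignment maximizing the number of essential residues that match their
#' class. Ties are broken by earlier start, then smaller total spacer width.
#'
#' @inheritParams scanMotif
#' @return A list: \code{matchedCount}, \code{totalEssentials},
#'   \code{mismatches} (data.frame with \code{essentialIndex},
#'   \code{expected}, \code{observed}, \code{position}), and the winning
#'   alignment's \code{start}, \code{end}, \code{residuePositions},
#'   \code{spacerWidths} (all \code{NA}/empty when the sequence is shorter
#'   than the pattern's minimal width).
#' @export
bestPartialMatch <- function(sequence, pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  sequence <- checkAaSequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  el <- pattern@elements
  isEss <- el$kind == "RESIDUE_CLASS"
  allowed <- strsplit(el$allowed[isEss], "")
  nEss <- length(allowed)
  combos <- spacerCombos(pattern)

  best <- list(count = -1L, start = NA_integer_, combo = NA_integer_)
  for (k in seq_len(nrow(combos$widths))) {
    w <- combos$widths[k, ]
    total <- sum(w)
    if (total > L) next
    starts <- seq_len(L - total + 1L)
    offs <- essentialOffsets(w, isEss)
    counts <- integer(length(starts))
    for (j in seq_len(nEss))
      counts <- counts + (chars[starts + offs[j]] %in% allowed[[j]])
    kBest <- which.max(counts)
    # combos are visited in ascending total spacer width, so a strict
    # improvement in (count, -start) implements the documented tie-break
    if (counts[kBest] > best$count ||
        (counts[kBest] == best$count && starts[kBest] < best$start)) {
      best <- list(count = as.integer(counts[kBest]), start = starts[kBest],
                   combo = k)
    }
  }

  expected <- el$allowed[isEss]
  if (is.na(best$start)) {
    return(list(matchedCount = 0L, totalEssentials = nEss,
                mismatches = data.frame(essentialIndex = seq_len(nEss),
                                        expected = expected,
                                        observed = NA_character_,
                                        position = NA_integer_),
                start = NA_integer_, end = NA_integer_,
                residuePositions = integer(0), spacerWidths = integer(0)))
  }
  w <- combos$widths[best$combo, ]
  offs <- essentialOffsets(w, isEss)
  pos <- best$start + offs
  obs <- chars[pos]
  bad <- which(!mapply(function(o, a) o %in% a, obs, allowed))
  list(matchedCount = best$count, totalEssentials = nEss,
       mismatches = data.frame(essentialIndex = as.integer(bad),
                               expected = expected[bad],
                               observed = obs[bad],
                               position = as.integer(pos[bad])),
       start = best$start, end = best$start + sum(w) - 1L,
       residuePositions = as.integer(pos),
       spacerWidths = as.integer(w[combos$isSpacer]))
}

## shared classifier: full-motif match => ACTIVE, otherwise the best partial
## alignment's failures are reported and the call is DEGENERATE
activityCall <- function(sequence, pattern, domainType,
                         iSiteAnchor = NA_integer_) {
  sequence <- checkAaSequence(sequence)
  if (nchar(sequence) < 10L)
    stop(sprintf("sequence of %d residues is too short to classify (< 10)",
                 nchar(sequence)))
  full <- scanMotif(sequence, pattern)
  nEss <- length(essentialIndices(pattern))
  if (nrow(full) > 0L) {
    status <- "ACTIVE"
    matched <- nEss
    mism <- data.frame(essentialIndex = integer(0), expected = character(0),
                       observed = character(0), position = integer(0))
    bestMatch <- full[1L, ]
    aSiteStarts <- vapply(seq_len(nrow(full)), function(i)
      full$residuePositions[[i]][iSiteAnchor], integer(1)) # NA anchor => NA
  } else {
    bp <- bestPartialMatch(sequence, pattern)
    status <- "DEGENERATE"
    matched <- bp$matchedCount
    mism <- bp$mismatches
    bestMatch <- if (is.na(bp$start)) {
      S4Vectors::DataFrame(start = integer(0), end = integer(0),
                           residuePositions = IRanges::IntegerList(),
                           spacerWidths = IRanges::IntegerList())
    } else {
      S4Vectors::DataFrame(start = bp$start, end = bp$end,
                           residuePositions = IRanges::IntegerList(list(bp$residuePositions)),
                           spacerWidths = IRanges::IntegerList(list(bp$spacerWidths)))
    }
    aSiteStarts <- if (is.na(bp$start) || is.na(iSiteAnchor)) NA_integer_
                   else bp$residuePositions[iSiteAnchor]
  }
  iSite <- NA
  if (!is.na(iSiteAnchor)) {
    chars <- strsplit(sequence, "")[[1]]
    iSite <- any(vapply(aSiteStarts, function(a) {
      if (is.na(a)) return(FALSE)
      dPos <- a - 5L   # terminal D of RxxD sits 5 residues before the A-site
      rPos <- dPos - 3L
      rPos >= 1L && chars[rPos] == "R" && chars[dPos] == "D"
    }, logical(1)))
  }
  new("ActivityCall", domainType = domainType, status = status,
      matchedCount = as.integer(matched), totalEssentials = as.integer(nEss),
      mismatchedEssentials = mism, iSitePresent = iSite,
      bestMatch = if (is(bestMatch, "DataFrame")) bestMatch else
        S4Vectors::DataFrame(bestMatch))
}

#' Classify a GGDEF domain as ACTIVE or DEGENERATE
#'
#' A GGDEF (diguanylate cyclase) domain is called ACTIVE when the conserved
#' activity motif \code{D x(7) N x(8) D x(21) R x(1) [GSA] G [DE] E F}
#' matches somewhere in the domain sequence, and DEGENERATE when at least one
#' essential residue of the best attainable alignment fails its class. The
#' allosteric I-site is reported present when an \code{RxxD} submotif is
#' positioned so that its terminal D lies exactly 5 residues before the first
#' residue of the A-site block \code{[GSA]G[DE]EF} of a full motif match (or
#' of the best partial alignment for degenerate domains).
#'
#' @param domainSequence Amino-acid sequence of the GGDEF domain (at least 10
#'   residues; sequences shorter than the motif are called DEGENERATE).
#' @param pattern The GGDEF [MotifPattern-class]; defaults to the bundled one.
#' @return An [ActivityCall-class].
#' @examples
#' act <- paste0("D", strrep("A", 7), "N", strrep("A", 8), "D",
#'               strrep("A", 21), "R", "A", "GGDEF")
#' classifyGgdef(act)
#' @export
classifyGgdef <- function(domainSequence, pattern = cdgMotifs()[["GGDEF"]]) {
  # A-site block starts at the 5th essential ([GSA]) of the GGDEF motif
  activityCall(domainSequence, pattern, "GGDEF", iSiteAnchor = 5L)
}

#' Classify an EAL domain as ACTIVE or DEGENERATE
#'
#' Putative phosphodiesterase activity is called from the conserved motif
#' \code{E x(55,58) N x(31) E x(1) x(1) E x(26) D x(20) K x(35) E}; any
#' essential-residue failure in the best alignment makes the call DEGENERATE.
#'
#' @param domainSequence Amino-acid sequence of the EAL domain.
#' @param pattern The EAL [MotifPattern-class]; defaults to the bundled one.
#' @return An [ActivityCall-class] (no I-site concept; \code{iSitePresent}
#'   is \code{NA}).
#' @export
classifyEal <- function(domainSequence, pattern = cdgMotifs()[["EAL"]]) {
  activityCall(domainSequence, pattern, "EAL")
}

#' Classify a PilZ domain as a putative c-di-GMP receptor
#'
#' Receptor competence is called from the conserved binding motif
#' \code{R x(1) x(1) x(1) R x(20,30) [DN] x(1) [SA] x(1) x(1) G}.
#'
#' @param domainSequence Amino-acid sequence of the PilZ domain.
#' @param pattern The PilZ [MotifPattern-class]; defaults to the bundled one.
#' @return An [ActivityCall-class].
#' @export
classifyPilz <- function(domainSequence, pattern = cdgMotifs()[["PILZ"]]) {
  activityCall(domainSequence, pattern, "PILZ")
}

#' Load motif patterns from a motif-spec text file
#'
#' The file format is one motif per line: \code{name TAB spec-string}, with
#' \code{#} comment lines ignored. With no argument, the bundled activity
#' motifs for GGDEF, EAL and PilZ domains are returned.
#'
#' @param file Path to a motif-spec file, or \code{NULL} for the bundled set.
#' @return Named list of [MotifPattern-class] objects.
#' @examples
#' names(cdgMotifs())
#' @export
cdgMotifs <- local({
  cache <- NULL
  function(file = NULL) {
    if (is.null(file)) {
      if (!is.null(cache)) return(cache)
      file <- system.file("extdata", "cdg_motifs.tsv", package = "cdgScan",
                          mustWork = TRUE)
      cache <<- readMotifFile(file)
      return(cache)
    }
    readMotifFile(file)
  }
})

readMotifFile <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("motif file line %d: expected 'name TAB spec'", i))
    out[[trimws(parts[1L])]] <- compilePattern(parts[2L], name = trimws(parts[1L]))
  }
  out
}
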