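# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the scanner oracle walks the pattern
# element by element for every (start, spacer-width) combination, and the
# statistics oracles are closed-form or term-wise summations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomAaSeq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# all spacer-width assignments of a pattern, one row per combination
oracleWidthGrid <- function(el) {
  wlist <- lapply(seq_len(nrow(el)), function(i)
    if (el$kind[i] == "SPACER") el$spanMin[i]:el$spanMax[i] else 1L)
  as.matrix(expand.grid(wlist, KEEP.OUT.ATTRS = FALSE))
}

# brute-force scanner: every start x width combination, positional checks
oracleScan <- function(sequence, pattern) {
  el <- patternElements(pattern)
  chars <- strsplit(toupper(sequence), "")[[1]]
  grid <- oracleWidthGrid(el)
  allowed <- lapply(el$allowed, function(a) strsplit(a, "")[[1]])
  hits <- list()
  for (g in seq_len(nrow(grid))) {
    w <- as.integer(grid[g, ])
    W <- sum(w)
    if (W > length(chars)) next
    for (s in seq_len(length(chars) - W + 1L)) {
      pos <- s
      ok <- TRUE
      rp <- integer(0)
      for (i in seq_len(nrow(el))) {
        if (el$kind[i] == "RESIDUE_CLASS") {
          if (!(chars[pos] %in% allowed[[i]])) { ok <- FALSE; break }
          rp <- c(rp, pos)
          pos <- pos + 1L
        } else pos <- pos + w[i]
      }
      if (ok)
        hits[[length(hits) + 1L]] <- list(
          start = s, end = s + W - 1L, rp = rp,
          spw = w[el$kind == "SPACER"])
    }
  }
  hits
}

# canonical multiset keys for comparing scan output with the oracle
matchKeys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(vapply(seq_len(nrow(df)), function(i)
    paste(df$start[i], df$end[i],
          paste(df$residuePositions[[i]], collapse = ","),
          paste(df$spacerWidths[[i]], collapse = ","), sep = "|"),
    character(1)))
}

oracleKeys <- function(hits) {
  sort(vapply(hits, function(h)
    paste(h$start, h$end, paste(h$rp, collapse = ","),
          paste(h$spw, collapse = ","), sep = "|"), character(1)))
}

# brute-force best partial alignment: max matched essentials, ties broken
# by earlier start then smaller total spacer width
oracleBestPartial <- function(sequence, pattern) {
  el <- patternElements(pattern)
  chars <- strsplit(toupper(sequence), "")[[1]]
  grid <- oracleWidthGrid(el)
  allowed <- lapply(el$allowed, function(a) strsplit(a, "")[[1]])
  isSp <- el$kind == "SPACER"
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    w <- as.integer(grid[g, ])
    W <- sum(w)
    if (W > length(chars)) next
    tot <- sum(w[isSp])
    for (s in seq_len(length(chars) - W + 1L)) {
      pos <- s
      cnt <- 0L
      bad <- integer(0)
      ei <- 0L
      for (i in seq_len(nrow(el))) {
        if (el$kind[i] == "RESIDUE_CLASS") {
          ei <- ei + 1L
          if (chars[pos] %in% allowed[[i]]) cnt <- cnt + 1L
          else bad <- c(bad, ei)
          pos <- pos + 1L
        } else pos <- pos + w[i]
      }
      cand <- list(count = cnt, start = s, spacer = tot, bad = bad)
      if (is.null(best) || cnt > best$count ||
          (cnt == best$count && s < best$start) ||
          (cnt == best$count && s == best$start && tot < best$spacer))
        best <- cand
    }
  }
  best
}

# lexicographic-best non-overlapping same-type subset, by exhaustive search
oracleResolve <- function(hits) {
  rankOf <- function(h) {
    goodness <- ifelse(h$source == "HEURISTIC", -h$score, h$score)
    order(order(goodness, h$start, h$end, seq_len(nrow(h))))
  }
  keep <- integer(0)
  for (key in unique(paste(hits$proteinId, hits$domainType))) {
    idx <- which(paste(hits$proteinId, hits$domainType) == key)
    h <- hits[idx, , drop = FALSE]
    rk <- rankOf(h)
    n <- nrow(h)
    bestSig <- NULL
    bestSet <- integer(0)
    for (mask in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      if (length(sel) > 1L) {
        ok <- TRUE
        for (a in seq_along(sel))
          for (b in seq_along(sel))
            if (a < b &&
                h$start[sel[a]] <= h$end[sel[b]] &&
                h$end[sel[a]] >= h$start[sel[b]]) ok <- FALSE
        if (!ok) next
      }
      sig <- sort(rk[sel])
      better <- is.null(bestSig)
      if (!better) {
        m <- min(length(sig), length(bestSig))
        cmp <- 0L
        if (m > 0L) {
          diffAt <- which(sig[seq_len(m)] != bestSig[seq_len(m)])
          if (length(diffAt))
            cmp <- ifelse(sig[diffAt[1L]] < bestSig[diffAt[1L]], 1L, -1L)
        }
        if (cmp == 0L) cmp <- sign(length(sig) - length(bestSig))
        better <- cmp > 0L
      }
      if (better) { bestSig <- sig; bestSet <- sel }
    }
    keep <- c(keep, idx[bestSet])
  }
  out <- hits[sort(keep), , drop = FALSE]
  out[order(out$proteinId, out$start, out$end), , drop = FALSE]
}

# term-wise two-way ANOVA sums of squares from first principles
oracleAnovaSS <- function(vals, genes, conditions) {
  grand <- mean(vals)
  gm <- tapply(vals, genes, mean)
  cm <- tapply(vals, conditions, mean)
  cell <- tapply(vals, list(genes, conditions), mean)
  ssA <- 0; ssB <- 0; ssAB <- 0; ssE <- 0
  for (k in seq_along(vals)) {
    g <- as.character(genes[k]); cc <- as.character(conditions[k])
    ssE <- ssE + (vals[k] - cell[g, cc])^2
  }
  nPerGene <- table(genes)[1]
  nPerCond <- table(conditions)[1]
  r <- table(genes, conditions)[1, 1]
  ssA <- sum(nPerGene * (gm - grand)^2)
  ssB <- sum(nPerCond * (cm - grand)^2)
  for (g in rownames(cell))
    for (cc in colnames(cell))
      ssAB <- ssAB + r * (cell[g, cc] - gm[[g]] - cm[[cc]] + grand)^2
  c(gene = unname(ssA), condition = unname(ssB),
    interaction = unname(ssAB), residual = unname(ssE))
}

# assemble an ACTIVE motif instance with minimal spacers over an 'A' filler
motifInstance <- function(pattern, filler = "A", spacerOverrides = NULL) {
  el <- patternElements(pattern)
  w <- ifelse(el$kind == "SPACER", el$spanMin, 1L)
  if (!is.null(spacerOverrides)) {
    spIdx <- which(el$kind == "SPACER")
    for (nm in names(spacerOverrides))
      w[spIdx[as.integer(nm)]] <- spacerOverrides[[nm]]
  }
  parts <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    parts[i] <- if (el$kind[i] == "RESIDUE_CLASS")
      substr(el$allowed[i], 1L, 1L)
    else strrep(filler, w[i])
  }
  paste(parts, collapse = "")
}
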