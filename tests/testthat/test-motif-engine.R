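test_that("compilePattern parses the motif grammar and rejects malformed specs", {
  p <- compilePattern("D x(7) N x(8) D x(21) R x(1) [GSA] G [DE] E F", "GGDEF")
  el <- patternElements(p)
  expect_equal(nrow(el), 13L)
  expect_equal(sum(el$kind == "RESIDUE_CLASS"), 9L)
  expect_equal(length(essentialIndices(p)), 9L)

  # zero-width spacer is legal and equivalent to a contiguous pair
  p0 <- compilePattern("R x(0) D")
  expect_equal(nrow(scanMotif("ARDA", p0)), 1L)
  expect_equal(scanMotif("ARDA", p0)$start, 2L)

  expect_error(compilePattern(""), "empty")
  expect_error(compilePattern("D x(3)"), "start and end with a residue class")
  expect_error(compilePattern("x(2) D"), "start and end with a residue class")
  expect_error(compilePattern("D foo E"), "token 2")
  expect_error(compilePattern("D x(5,3) E"), "minimum exceeds maximum")
  expect_error(compilePattern("B x(1) D"), "not a standard amino-acid")
})

test_that("compile -> serialize -> compile round-trips random valid specs", {
  set.seed(42)
  for (rep in seq_len(100)) {
    n <- sample(3:11, 1)
    toks <- character(n)
    for (i in seq_len(n)) {
      isEdge <- i == 1L || i == n
      if (isEdge || stats::runif(1) < 0.5) {
        k <- sample(1:3, 1)
        cls <- paste(sample(AA20, k), collapse = "")
        toks[i] <- if (k == 1L) cls else paste0("[", cls, "]")
      } else {
        lo <- sample(0:12, 1)
        hi <- lo + sample(0:4, 1)
        toks[i] <- if (lo == hi) sprintf("x(%d)", lo) else sprintf("x(%d,%d)", lo, hi)
      }
    }
    spec <- paste(toks, collapse = " ")
    p1 <- compilePattern(spec)
    p2 <- compilePattern(serializePattern(p1))
    expect_identical(patternElements(p1), patternElements(p2))
  }
})

test_that("scanMotif enumerates matches and agrees with the brute-force oracle", {
  p <- compilePattern("R x(2,3) D")
  m <- scanMotif("RAAD", p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 4L)
  expect_equal(nrow(scanMotif("RAD", p)), 0L)
  # both admissible widths of the ranged spacer are reported
  m2 <- scanMotif("RAADD", p)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$end, c(4L, 5L))

  expect_error(scanMotif("", p), "empty")
  expect_error(scanMotif("RA*D", p), "non-amino-acid")
})

test_that("X in spacers is tolerated, X at essential positions never matches", {
  p <- compilePattern("R x(2) D")
  expect_equal(nrow(scanMotif("RXXD", p)), 1L)   # X inside the spacer is fine
  expect_equal(nrow(scanMotif("XAAD", p)), 0L)   # X cannot be the essential R
})

test_that("scan agrees exactly with the exhaustive oracle on random sequences", {
  motifs <- cdgMotifs()
  set.seed(7)
  for (nm in names(motifs)) {
    for (i in seq_len(40)) {
      s <- randomAaSeq(sample(150:250, 1))
      got <- matchKeys(scanMotif(s, motifs[[nm]]))
      want <- oracleKeys(oracleScan(s, motifs[[nm]]))
      expect_identical(got, want)
    }
  }
  # short sequences enriched for matches: plant instances in tiny contexts
  for (i in seq_len(30)) {
    inst <- motifInstance(motifs$PILZ,
                          spacerOverrides = list(`4` = sample(20:30, 1)))
    s <- paste0(randomAaSeq(5), inst, randomAaSeq(5))
    expect_identical(matchKeys(scanMotif(s, motifs$PILZ)),
                     oracleKeys(oracleScan(s, motifs$PILZ)))
  }
})

test_that("bestPartialMatch maximizes matched essentials with documented tie-breaks", {
  motifs <- cdgMotifs()
  g <- motifs$GGDEF

  # single planted mutation at the terminal F
  inst <- motifInstance(g)
  mut <- paste0(substr(inst, 1, nchar(inst) - 1), "A")
  bp <- bestPartialMatch(mut, g)
  expect_equal(bp$matchedCount, 8L)
  expect_equal(bp$mismatches$essentialIndex, 9L)
  expect_equal(bp$mismatches$observed, "A")

  # all-A sequence: only the [GSA] class can be satisfied
  allA <- strrep("A", 60)
  bp2 <- bestPartialMatch(allA, g)
  or2 <- oracleBestPartial(allA, g)
  expect_equal(bp2$matchedCount, or2$count)
  expect_equal(bp2$matchedCount, 1L)
  expect_equal(bp2$start, or2$start)

  # consistency with scan: a full match means zero mismatches
  s <- paste0(randomAaSeq(20), inst, randomAaSeq(20))
  stopifnot(nrow(scanMotif(s, g)) >= 1)
  bp3 <- bestPartialMatch(s, g)
  expect_equal(bp3$matchedCount, bp3$totalEssentials)
  expect_equal(nrow(bp3$mismatches), 0L)

  # random sequences agree with the oracle on count and winning start
  set.seed(11)
  for (i in seq_len(25)) {
    s <- randomAaSeq(80)
    bp <- bestPartialMatch(s, motifs$PILZ)
    orc <- oracleBestPartial(s, motifs$PILZ)
    expect_equal(bp$matchedCount, orc$count)
    expect_equal(bp$start, orc$start)
    expect_equal(sort(bp$mismatches$essentialIndex), sort(orc$bad))
  }
})

test_that("classifyGgdef calls the minimal construction ACTIVE and flags planted mutations", {
  inst <- motifInstance(cdgMotifs()$GGDEF)
  expect_equal(nchar(inst), 46L)
  call <- classifyGgdef(inst)
  expect_s4_class(call, "ActivityCall")
  expect_equal(callStatus(call), "ACTIVE")
  expect_false(iSitePresent(call))

  # the [DE] slot (essential 7) mutated to A
  pos7 <- 44L  # D of the A-site block G-G-[DE]-E-F
  mut <- paste0(substr(inst, 1, pos7 - 1), "A",
                substr(inst, pos7 + 1, nchar(inst)))
  call2 <- classifyGgdef(mut)
  expect_equal(callStatus(call2), "DEGENERATE")
  expect_equal(mismatchedEssentials(call2)$essentialIndex, 7L)

  expect_error(classifyGgdef("DANDAR"), "too short")
  # 10-45 residues: classifiable, necessarily DEGENERATE
  short <- substr(inst, 1, 20)
  expect_equal(callStatus(classifyGgdef(short)), "DEGENERATE")
})

test_that("the I-site rule fires only at the exact five-residue offset", {
  g <- cdgMotifs()$GGDEF
  inst <- strsplit(motifInstance(g), "")[[1]]
  aSite <- 42L  # first residue of the A-site block in the minimal instance
  for (offset in c(4L, 5L, 6L)) {
    chars <- inst
    dPos <- aSite - offset
    chars[dPos] <- "D"
    chars[dPos - 3L] <- "R"
    s <- paste0(strrep("L", 12), paste(chars, collapse = ""), strrep("L", 10))
    call <- classifyGgdef(s)
    expect_equal(callStatus(call), "ACTIVE")
    expect_equal(iSitePresent(call), offset == 5L,
                 label = sprintf("offset %d", offset))
  }
})

test_that("classifyEal respects the ranged first spacer and names failed essentials", {
  e <- cdgMotifs()$EAL
  expect_equal(callStatus(classifyEal(motifInstance(e))), "ACTIVE")
  # widths 55-58 are ACTIVE, 54 and 59 are DEGENERATE
  for (w in c(54L, 55L, 58L, 59L)) {
    s <- motifInstance(e, spacerOverrides = list(`1` = w))
    expect_equal(callStatus(classifyEal(s)),
                 if (w %in% 55:58) "ACTIVE" else "DEGENERATE",
                 label = sprintf("first spacer %d", w))
  }
  # K (essential 6) replaced by R
  inst <- motifInstance(e)
  kPos <- 1L + 55L + 1L + 31L + 1L + 2L + 1L + 26L + 1L + 20L + 1L
  stopifnot(substr(inst, kPos, kPos) == "K")
  mut <- paste0(substr(inst, 1, kPos - 1), "R",
                substr(inst, kPos + 1, nchar(inst)))
  call <- classifyEal(mut)
  expect_equal(callStatus(call), "DEGENERATE")
  expect_equal(mismatchedEssentials(call)$essentialIndex, 6L)
  expect_equal(mismatchedEssentials(call)$observed, "R")
  expect_true(is.na(iSitePresent(call)))
})

test_that("classifyPilz boundaries are inclusive and alternatives are allowed", {
  p <- cdgMotifs()$PILZ
  expect_equal(callStatus(classifyPilz("RAAARAAAAAAAAAAAAAAAAAAAAAAAAADASAAG")),
               "ACTIVE")  # mid-range spacer of 25
  for (w in c(19L, 20L, 30L, 31L)) {
    s <- motifInstance(p, spacerOverrides = list(`4` = w))
    expect_equal(callStatus(classifyPilz(s)),
                 if (w %in% 20:30) "ACTIVE" else "DEGENERATE",
                 label = sprintf("ranged spacer %d", w))
  }
  # N at the [DN] slot and A at the [SA] slot are allowed alternatives
  inst <- strsplit(motifInstance(p), "")[[1]]
  inst[1L + 3L + 1L + 20L + 1L] <- "N"
  inst[1L + 3L + 1L + 20L + 1L + 1L + 1L] <- "A"
  expect_equal(callStatus(classifyPilz(paste(inst, collapse = ""))), "ACTIVE")
})

test_that("single-essential mutations flip ACTIVE to DEGENERATE naming that essential", {
  motifs <- cdgMotifs()
  for (nm in names(motifs)) {
    pat <- motifs[[nm]]
    el <- patternElements(pat)
    essIdx <- which(el$kind == "RESIDUE_CLASS")
    inst <- motifInstance(pat)
    w <- ifelse(el$kind == "SPACER", el$spanMin, 1L)
    offs <- cumsum(c(0L, w[-length(w)]))[essIdx] + 1L
    classify <- switch(nm, GGDEF = classifyGgdef, EAL = classifyEal,
                       PILZ = classifyPilz)
    expect_equal(callStatus(classify(inst)), "ACTIVE", label = nm)
    for (j in seq_along(essIdx)) {
      allowed <- strsplit(el$allowed[essIdx[j]], "")[[1]]
      badLetter <- setdiff(AA20, allowed)[1]
      chars <- strsplit(inst, "")[[1]]
      chars[offs[j]] <- badLetter
      call <- classify(paste(chars, collapse = ""))
      expect_equal(callStatus(call), "DEGENERATE",
                   label = sprintf("%s essential %d", nm, j))
      expect_equal(mismatchedEssentials(call)$essentialIndex, j,
                   label = sprintf("%s essential %d identity", nm, j))
    }
  }
})

test_that("classification is deterministic and ignores surrounding context", {
  g <- cdgMotifs()$GGDEF
  inst <- motifInstance(g)
  set.seed(99)
  ctx1 <- paste0(randomAaSeq(30), inst, randomAaSeq(30))
  ctx2 <- paste0(randomAaSeq(50), inst, randomAaSeq(10))
  c1 <- classifyGgdef(ctx1); c1b <- classifyGgdef(ctx1); c2 <- classifyGgdef(ctx2)
  expect_identical(callStatus(c1), callStatus(c1b))
  expect_identical(callStatus(c1), callStatus(c2))
  expect_equal(callStatus(c1), "ACTIVE")
})

test_that("reported match widths stay within the pattern's width range", {
  motifs <- cdgMotifs()
  expect_equal(patternWidthRange(motifs$GGDEF), c(46L, 46L))
  expect_equal(patternWidthRange(motifs$PILZ), c(31L, 41L))
  set.seed(5)
  for (i in seq_len(20)) {
    inst <- motifInstance(cdgMotifs()$PILZ,
                          spacerOverrides = list(`4` = sample(20:30, 1)))
    s <- paste0(randomAaSeq(10), inst, randomAaSeq(10))
    m <- scanMotif(s, motifs$PILZ)
    expect_true(all(m$end - m$start + 1L >= 31L & m$end - m$start + 1L <= 41L))
  }
})
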