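# A tiny hand-written two-gene GenBank record used for parser checks.
twoGeneGenbank <- function(path) {
  # replicon: 400 bp; geneA (+) 51..140, geneB (-) 201..290
  set.seed(101)
  bases <- sample(c("a", "c", "g", "t"), 400, replace = TRUE)
  aaA <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"  # 33 aa -> 102 nt with stop
  cdsA <- vapply(strsplit(aaA, "")[[1]], function(a) {
    gc <- Biostrings::getGeneticCode("11")
    tolower(names(gc)[gc == a][1])
  }, character(1))
  cdsA <- c(cdsA, "taa")
  stopifnot(length(cdsA) * 3 == 102)
  bases[51:152] <- unlist(strsplit(paste(cdsA, collapse = ""), ""))
  seq <- paste(bases, collapse = "")
  lines <- c(
    "LOCUS       repA 400 bp    DNA     linear BCT 01-JAN-2026",
    "DEFINITION  two-gene fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "     CDS             51..152",
    "                     /locus_tag=\"geneA\"",
    "                     /product=\"alpha protein\"",
    "     CDS             complement(201..290)",
    "                     /locus_tag=\"geneB\"",
    "                     /product=\"beta protein\"",
    sprintf("                     /translation=\"%s\"",
            as.character(Biostrings::translate(Biostrings::reverseComplement(
              Biostrings::DNAString(toupper(substr(seq, 201, 287)))),
              genetic.code = Biostrings::getGeneticCode("11")))),
    "ORIGIN")
  for (p in seq(1, 400, 60)) {
    chunk <- substr(seq, p, min(p + 59, 400))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  list(sequence = toupper(seq), proteinA = aaA)
}

test_that("loadGenome parses a two-CDS GenBank fixture with strands and products", {
  gb <- tempfile(fileext = ".gbk")
  fix <- twoGeneGenbank(gb)
  ann <- loadGenome(gb, "genbank")
  g <- geneRanges(ann)
  expect_equal(length(g), 2L)
  expect_equal(g$geneId, c("geneA", "geneB"))
  expect_equal(as.character(GenomicRanges::strand(g)), c("+", "-"))
  expect_equal(g$product, c("alpha protein", "beta protein"))
  expect_equal(as.character(repliconSeqs(ann)[[1]]), fix$sequence)
  expect_equal(repliconInfo(ann)$topology, "linear")
  # geneA has no /translation: computed from coordinates, stop trimmed
  expect_equal(g$proteinSequence[1], fix$proteinA)
})

test_that("GenBank and GFF3+FASTA routes produce identical gene records", {
  g <- makeGenome(23, nReplicons = 2, genesPerReplicon = 4,
                  architectureMix = c("DGC", "PilZ", "none", "PDE"),
                  outDir = tempfile())
  a1 <- loadGenome(g$files[["genbank"]], "genbank")
  a2 <- loadGenome(g$files[["gff3"]], "gff3", fasta = g$files[["fasta"]])
  g1 <- geneRanges(a1); g2 <- geneRanges(a2)
  expect_equal(g1$geneId, g2$geneId)
  expect_equal(GenomicRanges::start(g1), GenomicRanges::start(g2))
  expect_equal(GenomicRanges::end(g1), GenomicRanges::end(g2))
  expect_equal(as.character(GenomicRanges::strand(g1)),
               as.character(GenomicRanges::strand(g2)))
  expect_equal(g1$proteinSequence, g2$proteinSequence)
  expect_equal(as.character(repliconSeqs(a1)), as.character(repliconSeqs(a2)))
})

test_that("an annotation without genes loads without error", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       bare 40 bp    DNA     circular BCT 01-JAN-2026",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  ann <- loadGenome(gb, "genbank")
  expect_equal(length(geneRanges(ann)), 0L)
  expect_equal(repliconInfo(ann)$topology, "circular")
  expect_equal(Biostrings::width(repliconSeqs(ann)), 40L)
})

test_that("a CDS whose length is not a multiple of three is skipped with a warning", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       bad 60 bp    DNA     linear BCT 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..14",
    "                     /locus_tag=\"broken\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  expect_warning(ann <- loadGenome(gb, "genbank"), "not a multiple of 3")
  expect_equal(length(geneRanges(ann)), 0L)
})

test_that("classifyProteome classifies hit sub-sequences and flags unknown proteins", {
  motifs <- cdgMotifs()
  set.seed(31)
  pG <- makeProtein(NULL, 120, motifs$GGDEF, id = "gA")
  pMut <- makeProtein(NULL, 240, motifs$EAL, mutateEssentials = 6L, id = "gB")
  ann <- GenomeAnnotation("toy", c(chr = strrep("ACGT", 400)), data.frame(
    geneId = c("gA", "gB"), repliconId = "chr",
    start = c(1, 601), end = c(360, 1320), strand = "+",
    product = "p", proteinSequence = c(pG$sequence, pMut$sequence),
    stringsAsFactors = FALSE))
  hits <- data.frame(
    proteinId = c("gA", "gB"),
    domainType = c("GGDEF", "EAL"), domainName = c("GGDEF", "EAL"),
    start = c(pG$truth$start, pMut$truth$start),
    end = c(pG$truth$end, pMut$truth$end),
    score = 1e-20, source = "TABLE", stringsAsFactors = FALSE)
  calls <- classifyProteome(ann, hits)
  expect_equal(calls$ggdef, c("ACTIVE", "ABSENT"))
  expect_equal(calls$eal, c("ABSENT", "DEGENERATE"))
  expect_equal(calls$pilz, c("ABSENT", "ABSENT"))
  expect_false(any(calls$iSite[calls$ggdef == "ABSENT"]))

  badHits <- hits; badHits$proteinId[1] <- "ghost"
  expect_error(classifyProteome(ann, badHits), "ghost")
})

test_that("a bifunctional protein with a degenerate EAL is called DGC-only", {
  # mirrors an active diguanylate cyclase carrying a dead phosphodiesterase
  # domain: GGDEF ACTIVE + EAL DEGENERATE must count as DGC_only
  motifs <- cdgMotifs()
  set.seed(37)
  pG <- makeProtein(NULL, 120, motifs$GGDEF, id = "gBi")
  pE <- makeProtein(NULL, 240, motifs$EAL, mutateEssentials = 6L, id = "gBi")
  aa <- paste0(pG$sequence, pE$sequence)
  ann <- GenomeAnnotation("toy", c(chr = strrep("ACGT", 400)), data.frame(
    geneId = "gBi", repliconId = "chr", start = 1, end = 3 * (nchar(aa) + 1),
    strand = "+", product = "p", proteinSequence = aa,
    stringsAsFactors = FALSE))
  hits <- data.frame(
    proteinId = "gBi", domainType = c("GGDEF", "EAL"),
    domainName = c("GGDEF", "EAL"),
    start = c(pG$truth$start, 120L + pE$truth$start),
    end = c(pG$truth$end, 120L + pE$truth$end),
    score = 1e-20, source = "TABLE", stringsAsFactors = FALSE)
  calls <- classifyProteome(ann, hits)
  expect_equal(calls$ggdef, "ACTIVE")
  expect_equal(calls$eal, "DEGENERATE")
  inv <- buildInventory(calls)
  expect_equal(unname(inventoryCounts(inv)[c("DGC_only", "bifunctional")]),
               c(1L, 0L))
  expect_equal(unname(inventoryCounts(inv)[["eal_total"]]), 1L)
})

test_that("buildInventory partitions categories and keeps PilZ independent", {
  calls <- data.frame(
    geneId = sprintf("g%d", 1:6),
    ggdef = c("ACTIVE", "ACTIVE", "ABSENT", "DEGENERATE", "ABSENT", "ABSENT"),
    eal = c("ABSENT", "ACTIVE", "ACTIVE", "ABSENT", "ABSENT", "ABSENT"),
    pilz = c("ACTIVE", "ABSENT", "ABSENT", "ABSENT", "ACTIVE", "ABSENT"),
    iSite = FALSE, architecture = "", stringsAsFactors = FALSE)
  inv <- buildInventory(calls, "toy")
  ct <- inventoryCounts(inv)
  expect_equal(unname(ct[c("DGC_only", "PDE_only", "bifunctional", "PilZ_like")]),
               c(1L, 1L, 1L, 2L))
  expect_equal(unname(ct[c("ggdef_total", "ggdef_active", "eal_total")]),
               c(3L, 2L, 2L))
  # g1 is both DGC_only and PilZ_like: categories may intersect PilZ
  expect_true("g1" %in% categoryGenes(inv)$DGC_only)
  expect_true("g1" %in% categoryGenes(inv)$PilZ_like)
  # empty input
  inv0 <- buildInventory(calls[0, ])
  expect_true(all(inventoryCounts(inv0) == 0L))
})

test_that("census of a synthetic genome reproduces planted category counts", {
  mix <- c(rep("DGC", 7), rep("PDE", 3), rep("bifunctional", 2),
           rep("PilZ", 5), rep("none", 3))
  g <- makeGenome(41, nReplicons = 2, genesPerReplicon = c(10, 10),
                  architectureMix = mix)
  calls <- classifyProteome(g$annotation, g$hits)
  inv <- buildInventory(calls, "syn")
  ct <- inventoryCounts(inv)
  expect_equal(unname(ct[c("DGC_only", "PDE_only", "bifunctional", "PilZ_like")]),
               c(7L, 3L, 2L, 5L))
  expect_equal(unname(ct[["ggdef_total"]]), 9L)   # 7 DGC + 2 bifunctional
  expect_equal(unname(ct[["eal_total"]]), 5L)     # 3 PDE + 2 bifunctional
})

test_that("the census is invariant to gene and replicon order", {
  mix <- c("DGC", "PDE", "bifunctional", "PilZ", "none", "DGC")
  g <- makeGenome(43, nReplicons = 2, genesPerReplicon = 3,
                  architectureMix = mix)
  inv1 <- buildInventory(classifyProteome(g$annotation, g$hits))

  gr <- geneRanges(g$annotation)
  set.seed(1)
  perm <- sample(length(gr))
  genes <- data.frame(
    geneId = gr$geneId, repliconId = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = gr$product, proteinSequence = gr$proteinSequence,
    stringsAsFactors = FALSE)[perm, ]
  seqs <- repliconSeqs(g$annotation)[c(2, 1)]
  annPerm <- GenomeAnnotation("perm", seqs, genes,
                              topology = rev(repliconInfo(g$annotation)$topology))
  inv2 <- buildInventory(classifyProteome(annPerm, g$hits[sample(nrow(g$hits)), ]))
  expect_equal(inventoryCounts(inv1), inventoryCounts(inv2))
  expect_equal(lapply(categoryGenes(inv1), sort), lapply(categoryGenes(inv2), sort))
})

test_that("summarizePanel computes mean and sample SD per category", {
  # the five published per-strain component counts average to 28.0
  pan <- summarizePanel(c(25, 26, 35, 26, 28))
  expect_equal(pan$mean, 28.0)
  expect_equal(pan$sd, stats::sd(c(25, 26, 35, 26, 28)))

  calls <- data.frame(geneId = "g1", ggdef = "ACTIVE", eal = "ABSENT",
                      pilz = "ABSENT", iSite = FALSE, architecture = "",
                      stringsAsFactors = FALSE)
  inv <- buildInventory(calls, "a")
  pan2 <- summarizePanel(list(inv, inv, inv))
  expect_true(all(pan2$sd == 0))
  expect_equal(pan2$mean[pan2$category == "DGC_only"], 1)
  # single genome: SD not available
  pan3 <- summarizePanel(list(inv))
  expect_true(all(is.na(pan3$sd)))
  expect_error(summarizePanel(list()), "at least one")
})
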