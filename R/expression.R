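#' @include promoter-gc.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Assemble a count table into a SummarizedExperiment
#'
#' @param counts Integer matrix, genes x libraries (non-negative).
#' @param geneLengths Gene lengths in bp (>= 1), one per row.
#' @param conditions Condition label per library.
#' @param replicates Optional replicate ids per library (defaults to a
#'   within-condition counter).
#' @return A \code{SummarizedExperiment} with assay \code{counts}, rowData
#'   column \code{lengthBp} and colData columns \code{condition},
#'   \code{replicate}.
#' @export
makeCountSet <- function(counts, geneLengths, conditions, replicates = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(geneLengths) != nrow(counts))
    stop("need one gene length per row")
  if (any(geneLengths < 1))
    stop("gene lengths must be >= 1 bp")
  if (length(conditions) != ncol(counts))
    stop("need one condition label per library")
  if (is.null(replicates))
    replicates <- stats::ave(seq_along(conditions), conditions,
                             FUN = seq_along)
  SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(lengthBp = as.numeric(geneLengths)),
    colData = S4Vectors::DataFrame(condition = as.character(conditions),
                                   replicate = replicates))
}

#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM[g, l] = count[g, l] / ((length_bp[g] / 1000) * (total[l] / 1e6))}.
#' The per-library total defaults to the column sum of the count table (the
#' totals available once counting is restricted to annotated genes); it can
#' be overridden per library.
#'
#' @param x A \code{SummarizedExperiment} from [makeCountSet()], or a count
#'   matrix (then \code{geneLengths} is required).
#' @param geneLengths Gene lengths in bp (ignored for SummarizedExperiment
#'   input).
#' @param librarySizes Optional per-library totals overriding the column
#'   sums.
#' @return Matrix of RPKM values; a library with zero total yields an
#'   all-\code{NA} column with a warning.
#' @export
rpkm <- function(x, geneLengths = NULL, librarySizes = NULL) {
  if (is(x, "SummarizedExperiment")) {
    counts <- assay(x, "counts")
    geneLengths <- rowData(x)$lengthBp
  } else {
    counts <- as.matrix(x)
    if (is.null(geneLengths))
      stop("matrix input requires geneLengths")
  }
  totals <- if (is.null(librarySizes)) colSums(counts) else librarySizes
  if (length(totals) != ncol(counts))
    stop("need one library total per column")
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("zero library total for column(s) %s; RPKM not available",
                    paste(which(zero), collapse = ", ")))
    totals[zero] <- NA_real_
  }
  counts / outer(geneLengths / 1000, totals / 1e6)
}

#' Two-way ANOVA variance partition with Bonferroni pairwise comparisons
#'
#' Partitions the total sum of squares of an expression table (genes x
#' libraries) into gene, condition, gene-by-condition interaction and
#' residual components under the classical two-factor factorial model, and
#' reports each component as a percentage of the total. Requires a balanced
#' complete design (each condition observed in the same number r >= 2 of
#' libraries). Pairwise gene comparisons are run within each condition using
#' the pooled residual mean square; each condition's family of all gene
#' pairs is Bonferroni-corrected independently.
#'
#' @param expr Numeric matrix of expression values (e.g. RPKM), genes x
#'   libraries, with rownames.
#' @param conditions Condition label per column.
#' @param response \code{"identity"} (default) analyses the values as given;
#'   \code{"log2"} applies \code{log2(x + 1)} first.
#' @return A list: \code{percentSS} (named vector gene / condition /
#'   interaction / residual, summing to 100), \code{anova} (term table with
#'   df, sum of squares, mean square, F and p), \code{pairwise}
#'   (per-condition gene pairs with \code{t}, \code{pRaw},
#'   \code{pBonferroni}), \code{r} (replicates per cell), \code{response}.
#'   When the total SS is zero the partition is \code{NA} with a warning.
#' @export
anovaPartition <- function(expr, conditions, response = c("identity", "log2")) {
  response <- match.arg(response)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("gene%d", seq_len(nrow(expr)))
  if (length(conditions) != ncol(expr))
    stop("need one condition label per column")
  if (anyNA(expr))
    stop("expression matrix contains NA values")
  reps <- table(conditions)
  if (length(unique(reps)) != 1L || reps[1L] < 2L)
    stop("unbalanced design: every condition needs the same replicate count r >= 2; subsample libraries first")
  r <- as.integer(reps[1L])
  if (nrow(expr) < 2L || length(reps) < 2L)
    stop("need at least two genes and two conditions")
  vals <- if (response == "log2") log2(expr + 1) else expr

  long <- data.frame(
    value = as.vector(vals),
    gene = factor(rep(rownames(expr), times = ncol(expr))),
    condition = factor(rep(conditions, each = nrow(expr))))
  fit <- stats::aov(value ~ gene * condition, data = long)
  # a zero-residual fit triggers a harmless "perfect fit" warning in the
  # F-test machinery; the SS decomposition itself is exact
  tab <- suppressWarnings(stats::anova(fit))
  terms <- rownames(tab)
  ss <- tab$`Sum Sq`
  names(ss) <- c("gene", "condition", "interaction", "residual")[
    match(terms, c("gene", "condition", "gene:condition", "Residuals"))]
  ssT <- sum(ss)
  percentSS <- if (ssT <= 1e-10 * (sum(vals^2) + 1)) {
    warning("total sum of squares is zero; partition not available")
    stats::setNames(rep(NA_real_, 4L), names(ss))
  } else 100 * ss / ssT

  anovaTab <- data.frame(term = names(ss), df = tab$Df, sumsq = ss,
                         meansq = tab$`Mean Sq`, statistic = tab$`F value`,
                         p = tab$`Pr(>F)`, row.names = NULL)

  # Bonferroni pairwise gene comparisons, one family per condition
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  genes <- rownames(expr)
  pairs <- utils::combn(genes, 2L)
  nPairs <- ncol(pairs)
  pw <- list()
  for (cond in unique(conditions)) {
    sel <- conditions == cond
    cellMeans <- rowMeans(vals[, sel, drop = FALSE])
    for (k in seq_len(nPairs)) {
      g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
      d <- cellMeans[[g1]] - cellMeans[[g2]]
      tStat <- if (mse > 0) d / sqrt(mse * 2 / r) else NA_real_
      pRaw <- if (is.na(tStat)) NA_real_ else
        2 * stats::pt(-abs(tStat), dfe)
      pw[[length(pw) + 1L]] <- data.frame(
        condition = cond, gene1 = g1, gene2 = g2, diff = d, t = tStat,
        pRaw = pRaw,
        pBonferroni = if (is.na(pRaw)) NA_real_ else min(1, pRaw * nPairs),
        stringsAsFactors = FALSE)
    }
  }
  list(percentSS = percentSS, anova = anovaTab,
       pairwise = do.call(rbind, pw), r = r, response = response)
}
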