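#' Published high-efficiency EMT phenotype patterns
#'
#' The eight signature expression patterns reported for TGF-beta-1-expressing
#' phenotypes whose simulated transformation efficiency toward the
#' mesenchymal endpoint exceeded 40%. The patterns fall into four couples
#' that differ only in the value of FOXO6, the comparison that isolated this
#' marker's effect on EMT paths. Bundled as a plain-text table.
#'
#' @return data.frame with columns \code{couple}, \code{phenotype} and one
#'   0/1 column per signature gene (TGFB1, BAMBI, CBLC, EGFR, ERBB2, FOXO6,
#'   ITGB1, MAPK1, TLR2); rownames are the phenotype ids.
#' @seealso [findSingleGeneCouples()], [mesenchymalReference()]
#' @export
highEfficiencyPhenotypes <- function() {
  path <- system.file("extdata", "high_efficiency_phenotypes.tsv",
                      package = "phenoflow", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE)
  rownames(df) <- df$phenotype
  df
}

#' Theoretical mesenchymal reference configurations
#'
#' The prototypal mesenchymal expression patterns for the A549 (lung) and
#' Panc1 (pancreas) cancer cell lines, obtained by setting to 1 the
#' signature markers upregulated by TGF-beta-1 induction and to 0 the
#' downregulated ones. They serve as the reference point of the
#' Jaccard-Needham distance; TGFB1 and FOXO6 are not part of the reference
#' and are masked out of the distance.
#'
#' @param cellLine \code{"A549"} or \code{"PANC1"}.
#' @return Named 0/1 vector over the seven reference genes.
#' @seealso [jaccardNeedham()], [weightedJND()]
#' @export
mesenchymalReference <- function(cellLine = c("A549", "PANC1")) {
  cellLine <- match.arg(cellLine)
  path <- system.file("extdata", "mesenchymal_reference.tsv",
                      package = "phenoflow", mustWork = TRUE)
  df <- read.delim(path)
  setNames(as.integer(df[[cellLine]]), df$gene)
}
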