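## ---- binary pattern distance ---------------------------------------------

.alignPatterns <- function(test, ref) {
  if (!is.null(names(ref)) && !is.null(names(test))) {
    if (!all(names(ref) %in% names(test)))
      stop("test pattern lacks gene(s): ",
           paste(setdiff(names(ref), names(test)), collapse = ", "))
    test <- test[names(ref)]
  } else if (length(test) != length(ref)) {
    stop("patterns differ in length")
  }
  keep <- !is.na(ref)           # genes absent from the reference are masked
  list(test = as.integer(test[keep]), ref = as.integer(ref[keep]))
}

#' Jaccard-Needham distance between binary expression patterns
#'
#' Dissimilarity between a phenotype pattern and a reference configuration.
#' The default \code{"standard"} mode is the binary Jaccard dissimilarity:
#' disagreements over the union of expressed genes,
#' \code{(a01 + a10) / (a11 + a01 + a10)}, which is 0 for identical patterns
#' and 1 for disjoint supports (two all-zero patterns give 0 by convention).
#' The \code{"literal"} mode instead counts genes off in both patterns (TF)
#' together with test-only genes (FT) in the numerator,
#' \code{(TF + FT) / (TT + TF + FT)}; it is kept for comparison but is not a
#' distance (identical patterns with any zero bit score above 0).
#' Reference positions set to \code{NA} are masked out of the computation;
#' when both vectors are named, the test pattern is aligned to the
#' reference's genes.
#'
#' @param test,ref 0/1 vectors (optionally named by gene); \code{ref} may
#'   contain \code{NA} for genes to ignore.
#' @param mode \code{"standard"} (default) or \code{"literal"}.
#' @return A number in [0, 1].
#' @export
jaccardNeedham <- function(test, ref, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  al <- .alignPatterns(test, ref)
  t1 <- al$test == 1
  r1 <- al$ref == 1
  a11 <- sum(t1 & r1)
  a10 <- sum(t1 & !r1)
  a01 <- sum(!t1 & r1)
  if (mode == "standard") {
    den <- a11 + a10 + a01
    if (den == 0) 0 else (a10 + a01) / den
  } else {
    tf <- sum(!t1 & !r1)
    den <- a11 + tf + a10
    if (den == 0) 0 else (tf + a10) / den
  }
}

## per-state JND against a reference, masked to the reference's genes
.stateJND <- function(patterns, genes, ref, mode = "standard") {
  m <- .patternMembership(patterns, genes)
  vapply(seq_along(patterns), function(i)
    jaccardNeedham(setNames(m[, i], genes), ref, mode = mode), 0)
}

#' Prevalence-weighted Jaccard-Needham distance along a trajectory
#'
#' For every iteration, the distances of the phenotype patterns from the
#' reference configuration are averaged with the phenotype prevalences as
#' weights. With \code{topFraction < 1} only the most prevalent fraction of
#' the states is kept at each iteration (prevalences renormalized) --
#' \code{topFraction = 0.1} restricts the average to the 10% most expressed
#' phenotypes.
#'
#' @param traj A [PopulationTrajectory-class].
#' @param ref Named 0/1 reference pattern over (a subset of) the signature
#'   genes; genes not named are ignored.
#' @param topFraction Fraction of states, by prevalence, entering the
#'   average (default 1 = all).
#' @param mode Distance mode, see [jaccardNeedham()].
#' @return Numeric vector, one weighted distance per iteration (first
#'   element = initial population).
#' @export
weightedJND <- function(traj, ref, topFraction = 1, mode = "standard") {
  stopifnot(topFraction > 0, topFraction <= 1)
  ref <- .refOverSignature(ref, traj@signatureGenes)
  jnd <- .stateJND(traj@patterns, traj@signatureGenes, ref, mode)
  k <- max(1L, ceiling(topFraction * length(jnd)))
  apply(traj@prevalence, 1, function(w) {
    top <- order(-w, seq_along(w))[seq_len(k)]
    ww <- w[top]
    if (sum(ww) == 0) return(0)
    sum(ww * jnd[top]) / sum(ww)
  })
}

## expand a reference over the full signature, NA-masking unnamed genes
.refOverSignature <- function(ref, genes) {
  if (is.null(names(ref))) {
    stopifnot(length(ref) == length(genes))
    names(ref) <- genes
    return(ref)
  }
  out <- setNames(rep(NA_real_, length(genes)), genes)
  common <- intersect(names(ref), genes)
  if (length(common) == 0) stop("reference names no signature gene")
  out[common] <- ref[common]
  out
}

#' Average a distance series over virtual populations
#'
#' Trajectories of different lengths are padded with their final (steady
#' state) value; the per-iteration mean and standard error across
#' populations are returned.
#'
#' @param trajs List of [PopulationTrajectory-class] objects from the same
#'   chain.
#' @inheritParams weightedJND
#' @return data.frame with columns \code{iteration} (0-based), \code{mean},
#'   \code{se}.
#' @export
averageJND <- function(trajs, ref, topFraction = 1, mode = "standard") {
  series <- lapply(trajs, weightedJND, ref = ref, topFraction = topFraction,
                   mode = mode)
  len <- max(lengths(series))
  mat <- vapply(series, function(x) c(x, rep(x[length(x)], len - length(x))),
                numeric(len))
  mat <- matrix(mat, nrow = len)
  data.frame(iteration = seq_len(len) - 1L,
             mean = rowMeans(mat),
             se = apply(mat, 1, function(x)
               if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0))
}

## ---- fold changes and agreement with experiments -------------------------

#' Log2 fold change of marker prevalence between trajectory endpoints
#'
#' For each signature gene, the fraction of the population in states
#' expressing it at the last iteration is compared to the first:
#' \code{log2(final / initial)}. Genes with zero initial prevalence are
#' excluded (fold change undefined) and listed in the \code{"excluded"}
#' attribute.
#'
#' @param traj A [PopulationTrajectory-class].
#' @param genes Genes to report (default: the whole signature).
#' @return data.frame with columns \code{gene}, \code{initial}, \code{final},
#'   \code{log2FC}; attribute \code{"excluded"} names skipped genes.
#' @export
log2FoldChanges <- function(traj, genes = traj@signatureGenes) {
  first <- geneMarginals(traj@patterns, traj@signatureGenes,
                         traj@prevalence[1, ])
  last <- geneMarginals(traj@patterns, traj@signatureGenes,
                        traj@prevalence[nrow(traj@prevalence), ])
  first <- first[genes]
  last <- last[genes]
  excl <- genes[first == 0]
  keep <- first > 0
  out <- data.frame(gene = genes[keep], initial = unname(first[keep]),
                    final = unname(last[keep]),
                    log2FC = unname(log2(last[keep] / first[keep])),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

#' Concordance index between modeled and experimental fold changes
#'
#' Fraction of markers whose modeled and measured variations have the same
#' sign; an exactly zero fold change is concordant only with zero.
#'
#' @param modelFC,experimentalFC Matched numeric vectors (aligned by name if
#'   both are named).
#' @return Fraction in [0, 1].
#' @export
concordanceIndex <- function(modelFC, experimentalFC) {
  if (!is.null(names(modelFC)) && !is.null(names(experimentalFC)))
    experimentalFC <- experimentalFC[names(modelFC)]
  stopifnot(length(modelFC) == length(experimentalFC), length(modelFC) > 0)
  mean(sign(modelFC) == sign(experimentalFC))
}

#' Bland-Altman agreement between modeled and experimental fold changes
#'
#' Per marker, the absolute difference between the paired values is related
#' to their mean; the bias is the mean absolute difference and the 95%
#' limits of agreement are \code{bias +/- 1.96 * sd} of the absolute
#' differences. Markers falling outside the limits are flagged.
#'
#' @inheritParams concordanceIndex
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh} and
#'   \code{table} (per-pair means, absolute differences and an
#'   \code{outside} flag).
#' @export
blandAltman <- function(modelFC, experimentalFC) {
  if (!is.null(names(modelFC)) && !is.null(names(experimentalFC)))
    experimentalFC <- experimentalFC[names(modelFC)]
  stopifnot(length(modelFC) == length(experimentalFC), length(modelFC) >= 2)
  d <- abs(modelFC - experimentalFC)
  mid <- (modelFC + experimentalFC) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- c(bias - 1.96 * sdd, bias + 1.96 * sdd)
  tab <- data.frame(pair = if (is.null(names(modelFC)))
                      seq_along(modelFC) else names(modelFC),
                    mean = unname(mid), absDiff = unname(d),
                    outside = unname(d < loa[1] | d > loa[2]),
                    stringsAsFactors = FALSE)
  list(bias = bias, loaLow = loa[1], loaHigh = loa[2], table = tab)
}

## ---- transient-state analysis --------------------------------------------

#' Transformation efficiency of a single starting phenotype
#'
#' Simulates a population initialized entirely in one phenotype and returns
#' the drop in prevalence-weighted Jaccard-Needham distance from the
#' reference configuration between the first and last iteration. A positive
#' value means the population moved toward the reference (e.g. the
#' mesenchymal endpoint); the value can never exceed the starting distance.
#'
#' @param dtmc A [PhenotypeDTMC-class].
#' @param stateId Index of the starting phenotype.
#' @param ref Named reference pattern (see [weightedJND()]).
#' @param maxSteps,tol Passed to [simulatePopulation()].
#' @param topFraction,mode Passed to [weightedJND()].
#' @return Efficiency (initial minus final weighted distance).
#' @export
transformationEfficiency <- function(dtmc, stateId, ref, maxSteps = 1000,
                                     tol = 1e-9, topFraction = 1,
                                     mode = "standard") {
  k <- nrow(dtmc@P)
  stopifnot(stateId >= 1, stateId <= k)
  s0 <- numeric(k)
  s0[stateId] <- 1
  traj <- simulatePopulation(dtmc, s0, maxSteps = maxSteps, tol = tol)
  series <- weightedJND(traj, ref, topFraction = topFraction, mode = mode)
  series[1] - series[length(series)]
}

#' Screen phenotypes for high transformation efficiency
#'
#' Evaluates [transformationEfficiency()] for every phenotype satisfying the
#' constraint (e.g. inducer-expressing states) and flags those whose
#' efficiency exceeds the threshold (0.40 marks "high" efficiency).
#'
#' @inheritParams transformationEfficiency
#' @param requireActive Gene ids that must be ON in a state for it to enter
#'   the screen.
#' @param threshold Efficiency above which a state is flagged (default 0.40).
#' @return data.frame with columns \code{stateId}, \code{pattern},
#'   \code{efficiency}, \code{high}, restricted to the screened states.
#' @export
screenHighEfficiency <- function(dtmc, ref, requireActive = character(),
                                 threshold = 0.40, maxSteps = 1000,
                                 topFraction = 1, mode = "standard") {
  states <- dtmc@states
  m <- .patternMembership(states@patterns, states@signatureGenes)
  eligible <- rep(TRUE, numPhenotypes(states))
  for (g in requireActive) {
    if (!g %in% states@signatureGenes)
      stop("requireActive gene not in the signature: ", g)
    eligible <- eligible & m[g, ] == 1
  }
  ids <- which(eligible)
  eff <- vapply(ids, transformationEfficiency, 0, dtmc = dtmc, ref = ref,
                maxSteps = maxSteps, topFraction = topFraction, mode = mode)
  data.frame(stateId = ids, pattern = states@patterns[ids],
             efficiency = eff, high = eff > threshold,
             stringsAsFactors = FALSE)
}

#' Find phenotype couples differing at exactly one gene
#'
#' Returns every unordered pair of patterns that differ at the given gene
#' and agree everywhere else -- the comparison used to isolate the effect of
#' a single marker (such as FOXO6) on the transition paths.
#'
#' @param patterns 0/1 matrix or data.frame, rows = phenotypes (rownames =
#'   phenotype ids), columns = genes.
#' @param gene Column name of the discriminating gene.
#' @return data.frame with columns \code{first}, \code{second} (phenotype
#'   ids; \code{first} has the gene off), one row per couple.
#' @export
findSingleGeneCouples <- function(patterns, gene) {
  patterns <- as.matrix(patterns)
  if (!gene %in% colnames(patterns)) stop("unknown gene: ", gene)
  ids <- rownames(patterns)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(patterns)))
  rest <- patterns[, setdiff(colnames(patterns), gene), drop = FALSE]
  key <- apply(rest, 1, paste, collapse = "")
  out <- list()
  for (grp in split(seq_len(nrow(patterns)), key)) {
    off <- grp[patterns[grp, gene] == 0]
    on <- grp[patterns[grp, gene] == 1]
    for (i in off) for (j in on)
      out[[length(out) + 1L]] <- data.frame(first = ids[i], second = ids[j],
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(first = character(), second = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(match(res$first, ids)), , drop = FALSE]
}
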