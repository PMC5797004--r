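# Differential-expression filtration: CPM/log2 normalization, log2 fold
# change, feature-wise Welch t / one-way ANOVA, multiplicity correction,
# and the 2-fold + significance filter. Test statistics are computed
# vectorized over the feature matrix; base R t.test/aov give the same
# answers feature by feature and serve as independent checks in the test
# suite.

groupColumns <- function(study, group) {
  g <- sampleGroups(study)
  idx <- which(g == group)
  if (!length(idx))
    stop("unknown group label '", group, "' (available: ",
         paste(unique(g), collapse = ", "), ")")
  idx
}

#' Counts-per-million, log2 normalization
#'
#' Scales each sample to counts per million, then applies
#' \code{log2(x + pseudocount)}.
#'
#' @param study an \linkS4class{ExpressionStudy} of raw counts.
#' @param pseudocount positive offset added before the log (default 1).
#' @return The study with normalized values and the \code{normalized} flag
#'   set.
#' @export
setGeneric("normalizeCpmLog2", function(study, pseudocount = 1)
  standardGeneric("normalizeCpmLog2"))

#' @rdname normalizeCpmLog2
#' @export
setMethod("normalizeCpmLog2", "ExpressionStudy",
          function(study, pseudocount = 1) {
  if (isNormalized(study)) stop("study is already normalized")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- assay(study)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  norm <- log2(sweep(m, 2, tot, "/") * 1e6 + pseudocount)
  SummarizedExperiment::assay(study, "exprs") <- norm
  study@normalized <- TRUE
  study
})

#' Log2 fold change between two groups
#'
#' Difference of group means on the log2 scale, test group minus
#' reference.
#'
#' @param study a normalized \linkS4class{ExpressionStudy}.
#' @param groupTest,groupRef group labels (test and reference).
#' @return named numeric vector of per-feature log2 fold changes.
#' @export
setGeneric("log2FoldChange", function(study, groupTest, groupRef)
  standardGeneric("log2FoldChange"))

#' @rdname log2FoldChange
#' @export
setMethod("log2FoldChange", "ExpressionStudy",
          function(study, groupTest, groupRef) {
  m <- assay(study)
  rowMeans(m[, groupColumns(study, groupTest), drop = FALSE]) -
    rowMeans(m[, groupColumns(study, groupRef), drop = FALSE])
})

# Vectorized two-sided Welch t over the rows of two matrices.
rowWelch <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    degen <- zero & (m1 != m2)
    if (any(degen)) {
      warning(sum(degen), " feature(s) with zero variance in both groups ",
              "but unequal means; excluded from testing (t, p set to NA)")
      t[degen] <- NA_real_; p[degen] <- NA_real_
    }
  }
  data.frame(t = t, p = p, row.names = rownames(a))
}

#' Feature-wise Welch (unequal-variance) t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of
#' freedom, per feature. Features with zero variance in both groups return
#' t = 0, p = 1 when the means agree; when they differ the feature is
#' excluded (NA) with a warning rather than fabricating an infinite
#' statistic.
#'
#' @param study a normalized \linkS4class{ExpressionStudy}.
#' @param groupTest,groupRef group labels; each needs >= 2 samples.
#' @return data.frame with columns \code{feature}, \code{t}, \code{p}.
#' @export
setGeneric("welchTest", function(study, groupTest, groupRef)
  standardGeneric("welchTest"))

#' @rdname welchTest
#' @export
setMethod("welchTest", "ExpressionStudy",
          function(study, groupTest, groupRef) {
  m <- assay(study)
  ia <- groupColumns(study, groupTest); ib <- groupColumns(study, groupRef)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each compared group needs >= 2 samples")
  res <- rowWelch(m[, ia, drop = FALSE], m[, ib, drop = FALSE])
  data.frame(feature = rownames(m), t = res$t, p = res$p,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Feature-wise one-way ANOVA
#'
#' Classical one-way ANOVA F and p per feature, across three or more
#' groups. The fully degenerate case (zero between- and within-group
#' variance) is defined to return p = 1.
#'
#' @param study a normalized \linkS4class{ExpressionStudy}.
#' @param groups group labels to compare (default: all groups in the
#'   study); must name >= 3 groups with >= 2 samples each.
#' @return data.frame with columns \code{feature}, \code{F}, \code{p}.
#' @export
setGeneric("anovaOneway", function(study, groups = NULL)
  standardGeneric("anovaOneway"))

#' @rdname anovaOneway
#' @export
setMethod("anovaOneway", "ExpressionStudy", function(study, groups = NULL) {
  g <- sampleGroups(study)
  if (is.null(groups)) groups <- unique(g)
  if (length(groups) < 3)
    stop("one-way ANOVA needs >= 3 groups; use welchTest() for two")
  idx <- lapply(groups, function(gr) groupColumns(study, gr))
  if (any(lengths(idx) < 2)) stop("every group needs >= 2 samples")
  m <- assay(study)[, unlist(idx), drop = FALSE]
  fac <- rep(seq_along(groups), lengths(idx))
  n <- ncol(m); k <- length(groups)
  grand <- rowMeans(m)
  ssb <- numeric(nrow(m)); ssw <- numeric(nrow(m))
  for (j in seq_along(groups)) {
    sub <- m[, fac == j, drop = FALSE]
    mj <- rowMeans(sub)
    ssb <- ssb + ncol(sub) * (mj - grand)^2
    ssw <- ssw + rowSums((sub - mj)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degen <- ssb == 0 & ssw == 0
  f[degen] <- 0; p[degen] <- 1
  data.frame(feature = rownames(m), F = f, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up or Bonferroni adjustment, order-preserving
#' with the input.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed for excluded
#'   features).
#' @param method \code{"BH"}, \code{"bonferroni"} or \code{"none"}.
#' @return adjusted p-values, same order as the input.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

deDirection <- function(log2fc, fcThreshold) {
  thr <- log2(fcThreshold)
  ifelse(is.na(log2fc), NA_character_,
         ifelse(log2fc >= thr, "up",
                ifelse(log2fc <= -thr, "down", "flat")))
}

#' Differential-expression table for one two-group comparison
#'
#' Runs the full per-comparison recipe: log2 fold change, feature-wise
#' Welch t-test, multiplicity correction. Normalizes first if the study
#' still holds raw counts.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param groupTest,groupRef test and reference group labels.
#' @param params a \linkS4class{DEFilterParams} (supplies the correction
#'   method and the fold-change threshold used for the direction call).
#' @param pseudocount passed to \code{\link{normalizeCpmLog2}} when
#'   normalization is needed.
#' @return data.frame with columns \code{feature}, \code{log2fc}, \code{p},
#'   \code{adj_p}, \code{direction}.
#' @export
runDE <- function(study, groupTest, groupRef, params = DEFilterParams(),
                  pseudocount = 1) {
  stopifnot(is(study, "ExpressionStudy"), is(params, "DEFilterParams"))
  if (!isNormalized(study)) study <- normalizeCpmLog2(study, pseudocount)
  lfc <- log2FoldChange(study, groupTest, groupRef)
  tt <- welchTest(study, groupTest, groupRef)
  adj <- adjustPvalues(tt$p, params@correction)
  data.frame(feature = tt$feature, log2fc = unname(lfc[tt$feature]),
             p = tt$p, adj_p = adj,
             direction = deDirection(unname(lfc[tt$feature]),
                                     params@fcThreshold),
             stringsAsFactors = FALSE)
}

#' Apply the fold-change + significance filter
#'
#' Retains features with |log2FC| >= log2(fcThreshold) and adjusted
#' p < alpha; the direction column is (re)assigned from the sign of the
#' fold change. Idempotent.
#'
#' @param records a DE table from \code{\link{runDE}} (columns
#'   \code{feature}, \code{log2fc}, \code{adj_p}).
#' @param params a \linkS4class{DEFilterParams}.
#' @return the retained rows, direction \code{"up"} or \code{"down"}.
#' @export
deFilter <- function(records, params = DEFilterParams()) {
  stopifnot(all(c("feature", "log2fc", "adj_p") %in% names(records)),
            is(params, "DEFilterParams"))
  keep <- !is.na(records$adj_p) &
    abs(records$log2fc) >= log2(params@fcThreshold) &
    records$adj_p < params@alpha
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
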