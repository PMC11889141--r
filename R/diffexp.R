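#' Effective library sizes
#'
#' \code{method = "libsize"} returns the column sums.  \code{method =
#' "tmm"} multiplies them by trimmed-mean-of-M-values normalization
#' factors (30\% trim on log-ratios, 5\% trim on average abundance,
#' precision-weighted, reference sample chosen by the upper-quartile rule)
#' that are geometric-mean-centred to 1.
#'
#' @param x a \code{\link{SialoCounts}} or a numeric count matrix.
#' @param method \code{"libsize"} or \code{"tmm"}.
#' @return named numeric vector of effective library sizes.
#' @export
normalizeLibSizes <- function(x, method = c("libsize", "tmm")) {
  method <- match.arg(method)
  m <- if (is(x, "SummarizedExperiment")) counts(x) else as.matrix(x)
  ls <- colSums(m)
  if (any(ls == 0))
    stop("all-zero sample: ", colnames(m)[ls == 0][1L])
  if (method == "libsize") return(ls)
  f75 <- apply(m, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(j)
    .tmmFactor(m[, j], m[, ref], ls[j], ls[ref]), numeric(1))
  fac <- fac / exp(mean(log(fac)))
  ls * fac
}

# weighted TMM factor of obs against ref (both raw count vectors)
.tmmFactor <- function(obs, ref, nO, nR, logratioTrim = 0.3,
                       sumTrim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1
  hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

# scale counts so every column has the geometric-mean library size
.equalizeCounts <- function(m, libSizes) {
  target <- exp(mean(log(libSizes)))
  sweep(m, 2, target / libSizes, "*")
}

# conditional NB log-likelihood of a count matrix (samples of one group,
# equal means), summed over genes, given the per-gene group totals
.condLogLik <- function(m, phi) {
  n <- ncol(m)
  r <- 1 / phi
  z <- rowSums(m)
  sum(lgamma(m + r)) - nrow(m) * n * lgamma(r) +
    nrow(m) * lgamma(n * r) - sum(lgamma(z + n * r))
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the conditional negative-binomial log-likelihood (conditioning
#' on the per-group totals, all genes sharing one dispersion) after scaling
#' the counts to equalized library sizes.  The likelihood is evaluated on a
#' logarithmic grid over [1e-6, 10] and the best grid cell is refined by
#' golden-section search.
#'
#' @param x a \code{\link{SialoCounts}} or a numeric count matrix.
#' @param groups vector of two group labels, one per sample (taken from
#'   \code{condition(x)} when missing).
#' @param libSizes optional effective library sizes
#'   (\code{\link{normalizeLibSizes}} with \code{"libsize"} by default).
#' @return list with \code{phi_common} (the dispersion) and \code{method}.
#' @export
estimateCommonDispersion <- function(x, groups = NULL, libSizes = NULL) {
  m <- if (is(x, "SummarizedExperiment")) counts(x) else as.matrix(x)
  if (is.null(groups) && is(x, "SialoCounts")) groups <- condition(x)
  if (is.null(groups)) stop("groups are required")
  if (length(unique(groups)) != 2L) stop("exactly 2 groups are required")
  if (all(m == 0)) stop("all-zero count matrix")
  if (is.null(libSizes)) libSizes <- colSums(m)
  q <- .equalizeCounts(m, libSizes)
  ll <- function(phi) {
    sum(vapply(unique(groups), function(g)
      .condLogLik(q[, groups == g, drop = FALSE], phi), numeric(1)))
  }
  grid <- exp(seq(log(1e-6), log(10), length.out = 31))
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(function(lp) ll(exp(lp)),
                         interval = log(c(lo, hi)), maximum = TRUE,
                         tol = 1e-6)
  phi <- exp(opt$maximum)
  if (ll(1e-6) >= opt$objective) phi <- 1e-6
  list(phi_common = phi, method = "conditional_likelihood")
}

# log conditional pmf of the reference-group total x given gene total s,
# group sizes nA (reference) and nB, dispersion phi; vectorized over x
.logCondProb <- function(x, s, nA, nB, phi) {
  if (phi < 1e-10) {
    stats::dbinom(x, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    (lgamma(x + rA) - lgamma(x + 1) - lgamma(rA)) +
      (lgamma(s - x + rB) - lgamma(s - x + 1) - lgamma(rB)) -
      (lgamma(s + rA + rB) - lgamma(s + 1) - lgamma(rA + rB))
  }
}

# exact two-sided p by the probability-mass rule for one gene
.exactPvalOne <- function(a, s, nA, nB, phi) {
  if (s == 0) return(1)
  xs <- 0:s
  lp <- .logCondProb(xs, s, nA, nB, phi)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pObs <- p[a + 1L]
  min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Negative-binomial exact test for two groups
#'
#' The classical two-group exact test: counts are scaled to a common
#' library size, summed within groups, and the reference-group total is
#' compared with its conditional null distribution given the gene total
#' (group totals negative binomial with means proportional to group sizes
#' and dispersion \code{phi / replicates}; for equal per-sample means this
#' conditional law is free of the mean).  The two-sided p-value sums the
#' probabilities of all splits as likely or less likely than the observed
#' one; \code{phi = 0} uses the Poisson limit (conditional binomial).
#' The reported log2 fold change is
#' \code{log2((meanB + c) / (meanA + c))} with pseudo-count
#' \code{c = 0.125} on the equalized scale and the reference group A in the
#' denominator; p-values never use pseudo-counts.
#'
#' @param x a \code{\link{SialoCounts}} or numeric count matrix.
#' @param groups two group labels per sample (default
#'   \code{condition(x)}).
#' @param phi common dispersion (e.g. from
#'   \code{\link{estimateCommonDispersion}}).
#' @param libSizes effective library sizes (default column sums).
#' @param reference the reference group label (default the first label in
#'   \code{groups}).
#' @return \code{data.frame} with columns \code{id}, \code{logFC},
#'   \code{pvalue}.
#' @export
exactTestNb <- function(x, groups = NULL, phi, libSizes = NULL,
                        reference = NULL) {
  m <- if (is(x, "SummarizedExperiment")) counts(x) else as.matrix(x)
  if (is.null(groups) && is(x, "SialoCounts")) groups <- condition(x)
  if (is.null(groups)) stop("groups are required")
  labs <- unique(groups)
  if (length(labs) != 2L) stop("exactly 2 groups are required")
  if (is.null(reference)) reference <- labs[1L]
  if (!reference %in% labs) stop("reference must be one of the group labels")
  other <- setdiff(labs, reference)
  if (phi < 0) stop("phi must be non-negative")
  if (is.null(libSizes)) libSizes <- colSums(m)
  q <- .equalizeCounts(m, libSizes)
  iA <- groups == reference
  nA <- sum(iA)
  nB <- sum(!iA)
  sumA <- rowSums(q[, iA, drop = FALSE])
  sumB <- rowSums(q[, !iA, drop = FALSE])
  logFC <- log2((sumB / nB + 0.125) / (sumA / nA + 0.125))
  # rounding the two group totals separately keeps the test exactly
  # antisymmetric under a swap of the reference label
  a <- round(sumA)
  s <- a + round(sumB)
  pv <- vapply(seq_along(a), function(i)
    .exactPvalOne(a[i], s[i], nA, nB, phi), numeric(1))
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  data.frame(id = ids, logFC = logFC, pvalue = pv, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (\code{stats::p.adjust}, method \code{"BH"})
#' with input validation.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values in the original order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression status
#'
#' A transcript is \code{up} (higher in the reference group) when
#' \code{logFC <= -lfcThresh} with \code{fdr < fdrThresh}, \code{down}
#' when \code{logFC >= lfcThresh} with \code{fdr < fdrThresh}, otherwise
#' \code{ns}.  The sign convention follows
#' \code{logFC = log2(other / reference)}: a transcript enriched in the
#' reference condition has a negative logFC.
#'
#' @param results \code{data.frame} with columns \code{logFC} and
#'   \code{fdr} (computed from \code{pvalue} via \code{\link{bhAdjust}}
#'   when absent).
#' @param lfcThresh |logFC| threshold (default 2).
#' @param fdrThresh FDR threshold (default 0.05).
#' @return the input with columns \code{fdr} and \code{status} added, and
#'   an attribute \code{census} = \code{c(n_up, n_down, n_modulated)}.
#' @export
callDe <- function(results, lfcThresh = 2, fdrThresh = 0.05) {
  if (!"fdr" %in% colnames(results))
    results$fdr <- bhAdjust(results$pvalue)
  status <- rep("ns", nrow(results))
  status[results$logFC <= -lfcThresh & results$fdr < fdrThresh] <- "up"
  status[results$logFC >= lfcThresh & results$fdr < fdrThresh] <- "down"
  results$status <- status
  census <- c(n_up = sum(status == "up"), n_down = sum(status == "down"),
              n_modulated = sum(status != "ns"))
  attr(results, "census") <- census
  results
}

#' Two-group differential expression, end to end
#'
#' Library-size normalization, common-dispersion estimation, the exact
#' test against the reference condition, BH adjustment and status calls.
#'
#' @param x a \code{\link{SialoCounts}}.
#' @param reference reference condition label.
#' @param norm \code{"libsize"} or \code{"tmm"}.
#' @param lfcThresh,fdrThresh call thresholds (defaults 2 and 0.05).
#' @return \code{data.frame} \code{id}, \code{logFC}, \code{pvalue},
#'   \code{fdr}, \code{status} with attributes \code{census} and
#'   \code{dispersion}.
#' @export
diffExpress <- function(x, reference, norm = c("libsize", "tmm"),
                        lfcThresh = 2, fdrThresh = 0.05) {
  norm <- match.arg(norm)
  ls <- normalizeLibSizes(x, norm)
  disp <- estimateCommonDispersion(x, libSizes = ls)
  res <- exactTestNb(x, phi = disp$phi_common, libSizes = ls,
                     reference = reference)
  res <- callDe(res, lfcThresh, fdrThresh)
  attr(res, "dispersion") <- disp$phi_common
  res
}

#' MDS sample coordinates from leading log fold changes
#'
#' The distance between two samples is the root-mean-square of the
#' \code{topN} largest absolute log2 fold changes between them, computed on
#' log-CPM with pseudo-count 2; classical metric MDS (\code{cmdscale}) maps
#' the samples into two dimensions.
#'
#' @param x a \code{\link{SialoCounts}} or numeric count matrix.
#' @param libSizes effective library sizes (default column sums).
#' @param topN number of leading fold changes per pair (default 500).
#' @return list with \code{coords} (samples x 2), \code{var_share}
#'   (per-axis fraction of retained variance) and \code{dist} (the sample
#'   distance matrix).
#' @export
mdsCoordinates <- function(x, libSizes = NULL, topN = 500L) {
  m <- if (is(x, "SummarizedExperiment")) counts(x) else as.matrix(x)
  if (ncol(m) < 3L) stop("mdsCoordinates needs at least 3 samples")
  if (is.null(libSizes)) libSizes <- colSums(m)
  lcpm <- log2(sweep(m + 2, 2, libSizes, "/") * 1e6)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  topN <- min(topN, nrow(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dif <- sort(abs(lcpm[, i] - lcpm[, j]), decreasing = TRUE)[seq_len(topN)]
      d[i, j] <- d[j, i] <- sqrt(mean(dif^2))
    }
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  eig <- pmax(fit$eig, 0)
  vs <- if (sum(eig) > 0) fit$eig[1:2] / sum(eig) else c(NA_real_, NA_real_)
  coords <- fit$points
  colnames(coords) <- c("dim1", "dim2")
  list(coords = coords, var_share = vs, dist = d)
}
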