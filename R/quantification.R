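#' @importFrom SummarizedExperiment assay rowData colData
NULL

#' Read a transcript count matrix with effective lengths
#'
#' Counts TSV schema: \code{transcript_id}, \code{eff_length}, then one
#' column per sample.  Metadata TSV schema: \code{sample},
#' \code{condition}.
#'
#' @param countsPath path to the counts TSV.
#' @param metaPath path to the sample-condition TSV.
#' @return a \code{\link{SialoCounts}}.
#' @export
readCounts <- function(countsPath, metaPath) {
  df <- utils::read.delim(countsPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "eff_length") %in% colnames(df)))
    stop("counts file needs columns transcript_id and eff_length")
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% colnames(meta)))
    stop("metadata file needs columns sample and condition")
  samples <- setdiff(colnames(df), c("transcript_id", "eff_length"))
  miss <- setdiff(samples, meta$sample)
  if (length(miss)) stop("sample without metadata: ", miss[1L])
  m <- as.matrix(df[, samples, drop = FALSE])
  rownames(m) <- df$transcript_id
  cond <- meta$condition[match(samples, meta$sample)]
  SialoCounts(m, effLength = df$eff_length, condition = cond)
}

#' Write counts and metadata TSVs for a SialoCounts object
#'
#' @param x a \code{\link{SialoCounts}}.
#' @param countsPath,metaPath output paths.
#' @return invisibly, the two paths.
#' @export
writeCounts <- function(x, countsPath, metaPath) {
  df <- data.frame(transcript_id = rownames(x),
                   eff_length = effLength(x),
                   as.data.frame(counts(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = colnames(x), condition = condition(x))
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(countsPath, metaPath))
}

#' Compute TPM from counts and effective lengths
#'
#' Per sample, \code{rate_i = count_i / eff_length_i} and
#' \code{TPM_i = rate_i / sum_j rate_j * 1e6}, so each sample's TPM column
#' sums to one million.  An all-zero sample yields an all-zero column with
#' a warning.
#'
#' @param x a \code{\link{SialoCounts}}.
#' @return a \code{\link{SialoExpr}} with the \code{tpm} assay, the sample
#'   conditions, and per-condition mean TPM in
#'   \code{rowData} columns \code{mean_<condition>}.
#' @examples
#' sc <- SialoCounts(matrix(c(10, 10), 2, 1,
#'                          dimnames = list(c("a", "b"), "s1")),
#'                   effLength = c(1000, 2000), condition = "x")
#' tpm(computeTpm(sc))
#' @export
computeTpm <- function(x) {
  stopifnot(is(x, "SialoCounts"))
  cts <- counts(x)
  if (any(cts < 0)) stop("negative count")
  rate <- cts / effLength(x)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(cts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpmMat <- sweep(rate, 2, tot, "/") * 1e6
  cond <- condition(x)
  condLevels <- unique(cond)
  means <- vapply(condLevels, function(cc)
    rowMeans(tpmMat[, cond == cc, drop = FALSE]), numeric(nrow(tpmMat)))
  if (nrow(tpmMat) == 1L) means <- matrix(means, nrow = 1L)
  colnames(means) <- paste0("mean_", condLevels)
  rd <- DataFrame(means, row.names = rownames(tpmMat), check.names = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpmMat), rowData = rd,
    colData = DataFrame(condition = cond, row.names = colnames(tpmMat)))
  new("SialoExpr", se)
}

#' Presence partition at a TPM floor
#'
#' A transcript is detected in a condition when its condition mean TPM is
#' at least \code{tpmMin}.  With exactly two conditions this partitions
#' the transcripts into detected-in-both, only condition A, only condition
#' B, and dropped; the retained set is the union of the first three.
#'
#' @param expr a \code{\link{SialoExpr}} (two conditions).
#' @param tpmMin detection floor (default 3).
#' @return list with character-vector elements \code{both},
#'   \code{only_<A>}, \code{only_<B>}, \code{dropped}, \code{retained} and
#'   an integer vector \code{counts}.
#' @export
presencePartition <- function(expr, tpmMin = 3) {
  cm <- condMeans(expr)
  if (ncol(cm) != 2L)
    stop("presencePartition needs exactly 2 conditions")
  ids <- rownames(cm)
  inA <- cm[, 1] >= tpmMin
  inB <- cm[, 2] >= tpmMin
  out <- list(both = ids[inA & inB],
              onlyA = ids[inA & !inB],
              onlyB = ids[!inA & inB],
              dropped = ids[!inA & !inB])
  names(out)[2:3] <- paste0("only_", colnames(cm))
  out$retained <- ids[inA | inB]
  out$counts <- c(both = length(out$both),
                  stats::setNames(lengths(out[2:3]), names(out)[2:3]),
                  dropped = length(out$dropped))
  out
}

#' Row z-scores of a TPM matrix
#'
#' Per transcript row, \code{z = (TPM - row mean) / row sd} with the
#' sample standard deviation (denominator n - 1).  Constant rows map to
#' all-zero rows.
#'
#' @param expr a \code{\link{SialoExpr}} or a numeric matrix with at least
#'   two columns.
#' @return numeric matrix of z-scores, same dimensions.
#' @export
zscoreMatrix <- function(expr) {
  m <- if (is(expr, "SummarizedExperiment")) tpm(expr) else as.matrix(expr)
  if (ncol(m) < 2L) stop("zscoreMatrix needs at least 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- Inf
  sweep(sweep(m, 1, mu, "-"), 1, sdv, "/")
}

#' Census of detected viral ORFs
#'
#' Counts the viral coding sequences whose condition mean TPM reaches
#' \code{tpmMin} in at least one condition, and reports which are absent.
#'
#' @param expr a \code{\link{SialoExpr}}.
#' @param viralIds character vector of viral record ids.
#' @param tpmMin detection floor (default 3).
#' @return list with \code{n_detected}, \code{n_total}, \code{detected}
#'   and \code{absent} id vectors.
#' @export
viralCensus <- function(expr, viralIds, tpmMin = 3) {
  cm <- condMeans(expr)
  viralIds <- intersect(viralIds, rownames(cm))
  det <- rownames(cm)[apply(cm >= tpmMin, 1, any)]
  detected <- intersect(viralIds, det)
  list(n_detected = length(detected), n_total = length(viralIds),
       detected = detected, absent = setdiff(viralIds, detected))
}
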