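#' Run the sialotranscriptome pipeline end to end
#'
#' From assembled transcripts, homology hit tables and a count matrix to
#' the annotated, quantified and tested coding set: six-frame ORF scan,
#' CDS extraction by homology coverage with signal-peptide start anchoring
#' as the fallback route (when both routes qualify the homology anchor
#' wins), merge with optional reference and viral CDS sets, consolidation
#' at the identity threshold, TPM quantification with the presence filter,
#' vocabulary classification, abundance summaries, the exact-test
#' differential expression, and the viral ORF census.
#'
#' @param transcripts named \code{DNAStringSet} of assembled transcripts.
#' @param hits combined hit table (\code{\link{readHitTable}} layout).
#' @param counts a \code{\link{SialoCounts}} keyed by transcript/CDS ids.
#' @param genomeCds,viralCds optional \code{DNAStringSet}s of annotated
#'   reference and viral coding sequences.
#' @param lexicon a \code{\link{Lexicon}} (default
#'   \code{\link{defaultLexicon}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param reference reference condition label for the exact test (default
#'   the first condition of \code{counts}).
#' @return list with elements \code{orfs}, \code{cds} (consolidated
#'   \code{CdsSet}), \code{consolidation} report, \code{expr}
#'   (\code{\link{SialoExpr}} over the retained coding set),
#'   \code{partition}, \code{annotation}, \code{abundance},
#'   \code{families}, \code{de} (with census and dispersion attributes)
#'   and \code{viral_census}.
#' @export
runPipeline <- function(transcripts, hits, counts, genomeCds = NULL,
                        viralCds = NULL, lexicon = defaultLexicon(),
                        config = pipelineConfig(),
                        reference = NULL) {
  orfs <- findOrfs(transcripts, minNt = config$min_orf_nt)
  homol <- extractCdsByHomology(orfs, hits, transcripts,
                                minSubjectCov = config$min_subject_cov)
  homolParents <- unique(cdsInfo(homol)$parent)
  spRecs <- list()
  for (tid in setdiff(unique(orfs$transcript_id), homolParents)) {
    sub <- orfs[orfs$transcript_id == tid, , drop = FALSE]
    best <- NULL
    for (k in order(-(sub$nt_end - sub$nt_start))) {
      orf <- sub[k, , drop = FALSE]
      calls <- spCallsForOrf(orf, minSpAa = config$min_sp_aa)
      cand <- anchorStartBySp(orf, calls, transcripts[[tid]])
      if (!is.null(cand)) { best <- cand; break }
    }
    if (!is.null(best)) spRecs[[tid]] <- best
  }
  spSet <- do.call(.concatCds, unname(spRecs))
  denovo <- .dedupeByParent(.concatCds(homol, spSet))
  genome <- if (!is.null(genomeCds) && length(genomeCds))
    CdsSet(genomeCds, source = "genome") else NULL
  viral <- if (!is.null(viralCds) && length(viralCds))
    CdsSet(viralCds, source = "viral") else NULL
  merged <- mergeCdsSources(denovo = denovo, genome = genome, viral = viral)
  cons <- consolidateIdentity(merged, threshold = config$dedup_identity)
  cds <- cons$cds
  keep <- intersect(rownames(counts), names(cds))
  sub <- counts[keep, ]
  expr <- computeTpm(sub)
  part <- presencePartition(expr, tpmMin = config$tpm_min)
  aa <- cdsAa(cds)
  long <- Biostrings::width(aa) >= config$min_sp_aa
  spCalls <- if (any(long)) predictSignalPeptides(aa[long]) else NULL
  ann <- annotateCds(cds, hits = hits, spCalls = spCalls, lexicon = lexicon)
  retained <- part$retained
  exprRet <- expr[retained, ]
  abundance <- classAbundanceSummary(ann, exprRet)
  families <- secretedFamilyTable(ann, exprRet, tpmMin = config$tpm_min,
                                  reference = reference)
  if (is.null(reference)) reference <- condition(sub)[1L]
  de <- diffExpress(sub[retained, ], reference = reference,
                    lfcThresh = config$lfc_thresh,
                    fdrThresh = config$fdr_thresh)
  census <- if (!is.null(viral)) viralCensus(expr, names(viral),
                                             tpmMin = config$tpm_min)
            else NULL
  list(orfs = orfs, cds = cds, consolidation = cons$report, expr = expr,
       partition = part, annotation = ann, abundance = abundance,
       families = families, de = de, viral_census = census)
}

# keep a single CDS per parent transcript: homology anchors beat
# signal-peptide anchors, longer records beat shorter ones
.dedupeByParent <- function(cds) {
  if (!length(cds)) return(cds)
  info <- cdsInfo(cds)
  parent <- ifelse(is.na(info$parent), names(cds), info$parent)
  pref <- ifelse(info$anchor == "homology", 0L, 1L)
  w <- Biostrings::width(cdsNt(cds))
  ord <- order(parent, pref, -w)
  keep <- ord[!duplicated(parent[ord])]
  keep <- sort(keep)
  out <- cds[keep]
  # a unique record per parent can carry the parent id directly
  ids <- names(out)
  par <- ifelse(is.na(cdsInfo(out)$parent), ids, cdsInfo(out)$parent)
  if (!anyDuplicated(par)) {
    names(out@nt) <- par
    names(out@aa) <- par
    rownames(out@info) <- par
  }
  out
}
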