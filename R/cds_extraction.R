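#' @importFrom Biostrings DNAString reverseComplement subseq translate
#'   pairwiseAlignment nmatch pattern
#' @importFrom IRanges IntegerList
NULL

#' Translate coding sequences
#'
#' Translates each CDS and strips the terminal stop, so the result is the
#' mature protein.  Widths must be multiples of 3.  Ambiguous codons
#' (containing \code{N}) translate to \code{X}.
#'
#' @param nt \code{DNAStringSet} of coding sequences.
#' @return \code{AAStringSet} of the same length.
#' @export
translateCds <- function(nt) {
  nt <- as(nt, "DNAStringSet")
  if (any(Biostrings::width(nt) %% 3 != 0))
    stop("CDS widths must be multiples of 3")
  if (!length(nt)) return(AAStringSet())
  aa <- vapply(as.character(nt), .translateChar, character(1),
               USE.NAMES = FALSE)
  aa <- sub("\\*$", "", aa)
  if (any(grepl("\\*", aa)))
    stop("internal stop codon in CDS: ",
         names(nt)[grepl("\\*", aa)][1L])
  out <- AAStringSet(aa)
  names(out) <- names(nt)
  out
}

# codon -> aa lookup; N-containing codons resolve to a unique amino acid
# when all expansions agree, otherwise X
.CODON_MAP <- local({
  gc <- Biostrings::GENETIC_CODE
  env <- new.env(parent = emptyenv())
  for (cod in names(gc)) assign(cod, unname(gc[cod]), envir = env)
  env
})

.lookupCodon <- function(cod) {
  hit <- get0(cod, envir = .CODON_MAP)
  if (!is.null(hit)) return(hit)
  idx <- gregexpr("N", cod, fixed = TRUE)[[1]]
  aa <- "X"
  if (idx[1] != -1 && length(idx) <= 2) {
    expand <- cod
    for (p in idx) {
      expand <- unlist(lapply(expand, function(x) {
        vapply(c("A", "C", "G", "T"), function(b) {
          substr(x, p, p) <- b; x
        }, character(1))
      }))
    }
    tr <- unique(vapply(expand, function(x)
      get0(x, envir = .CODON_MAP, ifnotfound = "X"), character(1)))
    if (length(tr) == 1) aa <- tr
  }
  assign(cod, aa, envir = .CODON_MAP)
  aa
}

# fast translation of an in-frame nucleotide string (length multiple of 3)
.translateChar <- function(s) {
  n <- nchar(s)
  if (n < 3) return("")
  cods <- substring(s, seq.int(1, n - 2, 3), seq.int(3, n, 3))
  aa <- unlist(mget(cods, envir = .CODON_MAP, ifnotfound = NA_character_),
               use.names = FALSE)
  if (anyNA(aa)) {
    miss <- which(is.na(aa))
    aa[miss] <- vapply(cods[miss], .lookupCodon, character(1))
  }
  paste(aa, collapse = "")
}

# translate the 3 forward frames of one DNAString; returns character(3)
.frameAa <- function(s) {
  ch <- as.character(s)
  L <- nchar(ch)
  vapply(0:2, function(f) {
    n3 <- ((L - f) %/% 3) * 3
    if (n3 < 3) return("")
    .translateChar(substr(ch, f + 1, f + n3))
  }, character(1))
}

#' Six-frame open reading frame scan
#'
#' Scans all six reading frames of each transcript.  An ORF is a maximal
#' stop-to-stop (or sequence-edge to stop/edge) segment; its nucleotide
#' length includes the terminal stop codon when one is present, and ORFs
#' abutting a sequence edge without a stop are retained.  Coordinates are
#' 0-based half-open on the forward strand of the transcript.
#'
#' @param transcripts a named \code{DNAStringSet} (or single
#'   \code{DNAString}/character with \code{id}).
#' @param minNt minimum ORF length in nucleotides (>= 3).
#' @param requireMet drop segments containing no in-frame methionine.  The
#'   reported \code{nt_start} stays at the segment start; the methionine
#'   offsets are reported in \code{met_positions} for downstream start
#'   selection.
#' @param id transcript id when \code{transcripts} is a single unnamed
#'   sequence.
#' @return \code{DataFrame} with columns \code{transcript_id},
#'   \code{strand} (\code{+}/\code{-}), \code{frame} (0-2 on the scanned
#'   strand), \code{nt_start}, \code{nt_end} (forward strand, 0-based
#'   half-open), \code{aa_seq} (stop excluded), \code{met_positions}
#'   (\code{IntegerList} of 0-based aa offsets) and
#'   \code{has_terminal_stop}.
#' @examples
#' findOrfs(Biostrings::DNAStringSet(c(t1 = "ATGAAATAA")), minNt = 9)
#' @export
findOrfs <- function(transcripts, minNt = 150L, requireMet = FALSE,
                     id = "transcript") {
  if (minNt < 3) stop("minNt must be >= 3")
  nms <- if (is.character(transcripts) && length(transcripts) == 1L &&
             is.null(names(transcripts))) id else names(transcripts)
  chars <- toupper(as.character(transcripts))
  if (is.null(nms)) stop("transcripts must be named")
  bad <- regexpr("[^ACGTN]", chars)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("non-nucleotide character in '%s' at position %d",
                 nms[i], bad[i]))
  }
  transcripts <- DNAStringSet(stats::setNames(chars, nms))
  res <- lapply(seq_along(transcripts), function(i)
    .findOrfsOne(transcripts[[i]], names(transcripts)[i], minNt, requireMet))
  do.call(rbind, res)
}

.findOrfsOne <- function(s, tid, minNt, requireMet) {
  L <- length(s)
  out <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") s else Biostrings::reverseComplement(s)
    aas <- .frameAa(s2)
    for (f in 0:2) {
      aa <- aas[f + 1]
      nc <- nchar(aa)
      if (nc == 0) next
      stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
      stops <- if (stops[1] == -1) integer(0) else as.integer(stops)
      starts <- c(1L, stops + 1L)
      ends <- c(stops, if (length(stops) == 0 || stops[length(stops)] < nc)
        nc else NULL)
      hasStop <- c(rep(TRUE, length(stops)),
                   if (length(ends) > length(stops)) FALSE else NULL)
      keep <- starts[seq_along(ends)] <= ends
      starts <- starts[seq_along(ends)][keep]
      hasStop <- hasStop[keep]
      ends <- ends[keep]
      if (!length(ends)) next
      ntLen <- 3L * (ends - starts + 1L)
      sel <- ntLen >= minNt
      if (!any(sel)) next
      for (k in which(sel)) {
        aaSeq <- substr(aa, starts[k], ends[k] - hasStop[k])
        mets <- gregexpr("M", aaSeq, fixed = TRUE)[[1]]
        mets <- if (mets[1] == -1) integer(0) else as.integer(mets) - 1L
        if (requireMet && !length(mets)) next
        st2 <- f + 3L * (starts[k] - 1L)
        en2 <- f + 3L * ends[k]
        if (strand == "+") {
          ntStart <- st2; ntEnd <- en2
        } else {
          ntStart <- L - en2; ntEnd <- L - st2
        }
        out[[length(out) + 1L]] <- list(
          transcript_id = tid, strand = strand, frame = f,
          nt_start = ntStart, nt_end = ntEnd, aa_seq = aaSeq,
          met_positions = mets, has_terminal_stop = hasStop[k])
      }
    }
  }
  if (!length(out)) {
    return(DataFrame(transcript_id = character(0), strand = character(0),
                     frame = integer(0), nt_start = integer(0),
                     nt_end = integer(0), aa_seq = character(0),
                     met_positions = IRanges::IntegerList(),
                     has_terminal_stop = logical(0)))
  }
  DataFrame(
    transcript_id = vapply(out, `[[`, "", "transcript_id"),
    strand = vapply(out, `[[`, "", "strand"),
    frame = vapply(out, `[[`, 0L, "frame"),
    nt_start = vapply(out, `[[`, 0L, "nt_start"),
    nt_end = vapply(out, `[[`, 0L, "nt_end"),
    aa_seq = vapply(out, `[[`, "", "aa_seq"),
    met_positions = IRanges::IntegerList(lapply(out, `[[`, "met_positions")),
    has_terminal_stop = vapply(out, `[[`, TRUE, "has_terminal_stop"))
}

# nucleotide sequence of one ORF row (forward-strand half-open coords)
.orfNtSeq <- function(transcript, ntStart, ntEnd, strand) {
  seg <- Biostrings::subseq(transcript, ntStart + 1L, ntEnd)
  if (strand == "-") seg <- Biostrings::reverseComplement(seg)
  as.character(seg)
}

#' Promote ORFs to coding sequences by homology coverage
#'
#' An ORF becomes a coding sequence when at least one protein hit of its
#' transcript covers at least \code{minSubjectCov} of the matching protein
#' (subject coverage \code{(send - sstart + 1)/slen}) and the hit's query
#' span fits inside the ORF translation.  Among qualifying hits the highest
#' bitscore defines the recorded evidence; ORF boundaries are not trimmed
#' to the hit.
#'
#' @param orfs \code{DataFrame} from \code{\link{findOrfs}}.
#' @param hits hit table (\code{\link{readHitTable}} layout, any mix of
#'   databases).  Hits naming transcripts absent from \code{orfs} raise a
#'   warning and are skipped.
#' @param transcripts named \code{DNAStringSet} holding the transcripts.
#' @param minSubjectCov minimum subject coverage (default 0.70).
#' @return \code{CdsSet} (source \code{denovo}, anchor \code{homology})
#'   with evidence columns \code{best_db}, \code{best_subject},
#'   \code{best_desc}, \code{best_pident}, \code{best_cov},
#'   \code{best_bitscore} in \code{cdsInfo}.
#' @export
extractCdsByHomology <- function(orfs, hits, transcripts,
                                 minSubjectCov = 0.70) {
  unknown <- setdiff(unique(hits$query_id), unique(orfs$transcript_id))
  if (length(unknown)) {
    warning("skipping hits for unknown transcript(s): ",
            paste(utils::head(unknown, 3), collapse = ", "))
    hits <- hits[!hits$query_id %in% unknown, , drop = FALSE]
  }
  hits$scov <- subjectCoverage(hits)
  hits <- hits[hits$scov >= minSubjectCov, , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(orfs))) {
    tid <- orfs$transcript_id[i]
    aaLen <- nchar(orfs$aa_seq[i])
    h <- hits[hits$query_id == tid & hits$qend <= aaLen, , drop = FALSE]
    if (!nrow(h)) next
    best <- h[which.max(h$bitscore), , drop = FALSE]
    nt <- .orfNtSeq(transcripts[[tid]], orfs$nt_start[i], orfs$nt_end[i],
                    orfs$strand[i])
    recs[[length(recs) + 1L]] <- list(
      tid = tid, nt = nt, aa = orfs$aa_seq[i],
      db = best$db_tag, subject = best$subject_id, desc = best$subject_desc,
      pident = best$pident, cov = best$scov, bitscore = best$bitscore)
  }
  .buildCdsFromRecs(recs, anchor = "homology")
}

.buildCdsFromRecs <- function(recs, anchor) {
  if (!length(recs)) {
    return(CdsSet(DNAStringSet(), aa = AAStringSet(),
                  source = character(0), anchor = character(0),
                  parent = character(0)))
  }
  tids <- vapply(recs, `[[`, "", "tid")
  ids <- tids
  dup <- tids %in% tids[duplicated(tids)]
  if (any(dup))
    ids[dup] <- paste0(tids[dup], ".orf",
                       stats::ave(seq_along(tids), tids,
                                  FUN = seq_along)[dup])
  nt <- DNAStringSet(stats::setNames(vapply(recs, `[[`, "", "nt"), ids))
  aa <- AAStringSet(stats::setNames(vapply(recs, `[[`, "", "aa"), ids))
  cds <- CdsSet(nt, aa = aa, source = "denovo", anchor = anchor,
                parent = tids)
  if (!is.null(recs[[1]]$db)) {
    cds@info$best_db <- vapply(recs, `[[`, "", "db")
    cds@info$best_subject <- vapply(recs, `[[`, "", "subject")
    cds@info$best_desc <- vapply(recs, `[[`, "", "desc")
    cds@info$best_pident <- vapply(recs, `[[`, 0, "pident")
    cds@info$best_cov <- vapply(recs, `[[`, 0, "cov")
    cds@info$best_bitscore <- vapply(recs, `[[`, 0, "bitscore")
  }
  cds
}

#' Signal-peptide calls for the Met-initiated sub-ORFs of one ORF
#'
#' Runs \code{\link{predictSignalPeptide}} on every methionine-initiated
#' sub-ORF of length at least \code{minSpAa}.
#'
#' @param orf one row of a \code{\link{findOrfs}} result.
#' @param minSpAa minimum sub-ORF length in aa (default 40).
#' @return \code{data.frame} with columns \code{met_offset} (0-based aa
#'   offset), \code{has_sp}, \code{cleavage_pos}.
#' @export
spCallsForOrf <- function(orf, minSpAa = 40L) {
  aa <- orf$aa_seq[1L]
  mets <- unlist(orf$met_positions[1L])
  aaLen <- nchar(aa)
  mets <- mets[aaLen - mets >= minSpAa]
  if (!length(mets))
    return(data.frame(met_offset = integer(0), has_sp = logical(0),
                      cleavage_pos = integer(0)))
  calls <- lapply(mets, function(m)
    predictSignalPeptide(substr(aa, m + 1L, aaLen)))
  data.frame(met_offset = mets,
             has_sp = vapply(calls, `[[`, TRUE, "has_sp"),
             cleavage_pos = vapply(calls, `[[`, 0L, "cleavage_pos"))
}

#' Anchor a coding sequence start at the most 5' signal-positive Met
#'
#' Given per-methionine signal-peptide predictions for an ORF, selects the
#' most 5' methionine whose sub-ORF carries a putative signal peptide and
#' returns the trimmed coding sequence, or \code{NULL} when no methionine
#' is signal-positive.
#'
#' @param orf one row of a \code{\link{findOrfs}} result.
#' @param spCalls \code{data.frame} as from \code{\link{spCallsForOrf}} (or
#'   imported external predictions mapped to \code{met_offset}).
#' @param transcript the \code{DNAString} of the parent transcript.
#' @return \code{CdsSet} with a single record (anchor
#'   \code{signal_peptide}), or \code{NULL}.
#' @export
anchorStartBySp <- function(orf, spCalls, transcript) {
  pos <- spCalls$met_offset[spCalls$has_sp]
  if (!length(pos)) return(NULL)
  m <- min(pos)
  strand <- orf$strand[1L]
  if (strand == "+") {
    ntStart <- orf$nt_start[1L] + 3L * m
    ntEnd <- orf$nt_end[1L]
  } else {
    ntStart <- orf$nt_start[1L]
    ntEnd <- orf$nt_end[1L] - 3L * m
  }
  nt <- .orfNtSeq(transcript, ntStart, ntEnd, strand)
  aa <- substr(orf$aa_seq[1L], m + 1L, nchar(orf$aa_seq[1L]))
  tid <- orf$transcript_id[1L]
  CdsSet(DNAStringSet(stats::setNames(nt, tid)),
         aa = AAStringSet(stats::setNames(aa, tid)),
         source = "denovo", anchor = "signal_peptide", parent = tid)
}

.concatCds <- function(...) {
  sets <- Filter(function(x) !is.null(x) && length(x) > 0, list(...))
  if (!length(sets))
    return(CdsSet(DNAStringSet(), aa = AAStringSet(),
                  source = character(0), anchor = character(0),
                  parent = character(0)))
  nt <- do.call(c, lapply(sets, cdsNt))
  aa <- do.call(c, lapply(sets, cdsAa))
  info <- do.call(rbind, lapply(sets, function(x)
    cdsInfo(x)[, c("source", "anchor", "parent"), drop = FALSE]))
  new("CdsSet", nt = nt, aa = aa, info = info)
}

#' Merge de novo, genome and viral coding-sequence sets
#'
#' Returns the union of the three sets.  On an id collision across sources
#' the precedence is genome > viral > de novo; a collision within one
#' source is an error (enforced by \code{CdsSet} validity).
#'
#' @param denovo,genome,viral \code{CdsSet} objects (\code{NULL} allowed).
#' @return merged \code{CdsSet}; record order is surviving de novo records,
#'   then genome, then surviving viral records.
#' @export
mergeCdsSources <- function(denovo = NULL, genome = NULL, viral = NULL) {
  gIds <- if (!is.null(genome)) names(genome) else character(0)
  vKeep <- if (!is.null(viral)) !(names(viral) %in% gIds) else logical(0)
  vIds <- if (!is.null(viral)) names(viral)[vKeep] else character(0)
  dKeep <- if (!is.null(denovo))
    !(names(denovo) %in% c(gIds, vIds)) else logical(0)
  .concatCds(if (!is.null(denovo)) denovo[dKeep] else NULL,
             genome,
             if (!is.null(viral)) viral[vKeep] else NULL)
}

.ntSubMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c("A", "C", "G", "T", "N")
      mm <- matrix(0, 5, 5, dimnames = list(letters, letters))
      diag(mm) <- 1
      mm["N", "N"] <- 0
      m <<- mm
    }
    m
  }
})

.aaSubMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
      mm <- matrix(0, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 1
      mm["X", "X"] <- 0
      m <<- mm
    }
    m
  }
})

#' Global pairwise identity
#'
#' Identity of a global (Needleman-Wunsch) alignment scored with match 1,
#' mismatch 0, gap opening 10 and gap extension 1; identity is the number
#' of matching columns divided by the total number of alignment columns.
#'
#' @param a,b sequences (character).
#' @param level \code{"nt"} or \code{"aa"}.
#' @return identity in [0, 1].
#' @export
pairIdentity <- function(a, b, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (level == "nt") {
    al <- Biostrings::pairwiseAlignment(
      DNAString(a), DNAString(b), type = "global",
      substitutionMatrix = .ntSubMatrix(),
      gapOpening = 10, gapExtension = 1)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = .aaSubMatrix(),
      gapOpening = 10, gapExtension = 1)
  }
  Biostrings::nmatch(al) / nchar(as.character(Biostrings::pattern(al)))
}

#' Consolidate coding sequences at an identity threshold
#'
#' Greedy longest-first clustering in the style of CD-HIT: sequences are
#' sorted by length descending (ties broken by id ascending) and each
#' sequence joins the first existing cluster whose representative aligns
#' with global identity at least \code{threshold}
#' (\code{\link{pairIdentity}}), otherwise it founds a new cluster.  A pair
#' whose length ratio is below the threshold cannot reach it and is skipped
#' without alignment.
#'
#' @param cds a \code{CdsSet}.
#' @param threshold identity threshold in (0, 1] (default 0.95).
#' @param level compare at the nucleotide (default) or protein level.
#' @return list with elements \code{cds} (the representatives, a subset of
#'   the input) and \code{report} (list with \code{clusters}, a named list
#'   mapping representative id to member ids, and
#'   \code{identity_threshold}).
#' @export
consolidateIdentity <- function(cds, threshold = 0.95,
                                level = c("nt", "aa")) {
  level <- match.arg(level)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  seqs <- if (level == "nt") cdsNt(cds) else cdsAa(cds)
  ids <- names(cds)
  w <- Biostrings::width(seqs)
  ord <- order(-w, ids)
  chars <- as.character(seqs)
  # distinct 8-mer sets for a cheap necessary-condition prescreen: an
  # alignment with identity >= t has at most (1-t)*(l1+l2) non-match
  # columns, each destroying at most k k-mers, so near-identical pairs
  # must share most of their k-mers
  k <- 8L
  kmers <- lapply(chars, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  repIdx <- integer(0)
  members <- list()
  for (i in ord) {
    joined <- FALSE
    for (kk in seq_along(repIdx)) {
      r <- repIdx[kk]
      if (min(w[i], w[r]) / max(w[i], w[r]) < threshold) next
      mmax <- (1 - threshold) * (w[i] + w[r])
      shared <- sum(kmers[[i]] %in% kmers[[r]])
      bound <- max(length(kmers[[i]]), length(kmers[[r]])) - k * mmax
      if (shared < bound) next
      if (pairIdentity(chars[i], chars[r], level) >= threshold) {
        members[[kk]] <- c(members[[kk]], ids[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      repIdx <- c(repIdx, i)
      members[[length(repIdx)]] <- character(0)
    }
  }
  clusters <- lapply(seq_along(repIdx), function(k)
    c(ids[repIdx[k]], members[[k]]))
  names(clusters) <- ids[repIdx]
  keep <- sort(repIdx)
  list(cds = cds[keep],
       report = list(clusters = clusters, identity_threshold = threshold))
}
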