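# Independent brute-force oracles used to pin the core algorithms.

randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revcompChar <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# six-frame ORF enumeration by direct codon walking (no shared code with
# the package's scanner beyond the genetic code table)
oracleOrfs <- function(seqChar, minNt = 150, requireMet = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  L <- nchar(seqChar)
  rows <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") seqChar else revcompChar(seqChar)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) next
      aa <- character(ncod)
      for (ci in seq_len(ncod)) {
        cod <- substr(s2, f + 3 * ci - 2, f + 3 * ci)
        aa[ci] <- if (grepl("N", cod)) "X" else unname(gc[cod])
      }
      segStart <- 1
      for (ci in seq_len(ncod)) {
        atEnd <- ci == ncod
        if (aa[ci] == "*" || atEnd) {
          segEnd <- ci
          hasStop <- aa[ci] == "*"
          ntLen <- 3 * (segEnd - segStart + 1)
          if (ntLen >= minNt) {
            aaSeq <- paste(aa[segStart:(segEnd - hasStop)][
              seq_len(max(0, segEnd - hasStop - segStart + 1))],
              collapse = "")
            mets <- which(strsplit(aaSeq, "")[[1]] == "M") - 1L
            if (!requireMet || length(mets)) {
              st2 <- f + 3 * (segStart - 1)
              en2 <- f + 3 * segEnd
              rows[[length(rows) + 1]] <- data.frame(
                strand = strand, frame = f,
                nt_start = if (strand == "+") st2 else L - en2,
                nt_end = if (strand == "+") en2 else L - st2,
                aa_seq = aaSeq, has_terminal_stop = hasStop,
                stringsAsFactors = FALSE)
            }
          }
          segStart <- ci + 1
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aa_seq = character(0), has_terminal_stop = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$frame, out$nt_start), ]
}

orfKey <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$strand, df$frame, df$nt_start), ]
  paste(df$strand, df$frame, df$nt_start, df$nt_end, df$aa_seq,
        df$has_terminal_stop, sep = "|")
}

# exact-test oracle: enumerate every split of the total s and sum the
# probabilities of splits as or less likely than the observed one,
# using dnbinom/dpois directly (the conditional law is mu-free)
oracleExactP <- function(a, s, nA, nB, phi, mu = 3.7) {
  if (s == 0) return(1)
  xs <- 0:s
  pr <- if (phi == 0) {
    stats::dpois(xs, mu * nA) * stats::dpois(s - xs, mu * nB)
  } else {
    stats::dnbinom(xs, size = nA / phi, mu = mu * nA) *
      stats::dnbinom(s - xs, size = nB / phi, mu = mu * nB)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[a + 1] * (1 + 1e-9)])
}

# greedy longest-first clustering from a precomputed all-pairs identity
# matrix (clustering logic re-derived from scratch)
oracleConsolidate <- function(chars, ids, threshold, level = "nt") {
  n <- length(chars)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- pairIdentity(chars[i], chars[j], level)
    }
  }
  ord <- order(-nchar(chars), ids)
  reps <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (idm[i, r] >= threshold) {
        assign[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  split(ids, ids[assign])
}

# small labelled count fixture: 2 conditions x nRep replicates
makeCounts <- function(m, conds, effLength = NULL) {
  if (is.null(effLength)) effLength <- rep(1000, nrow(m))
  SialoCounts(m, effLength = effLength, condition = conds)
}

# CdsSet around arbitrary (possibly non-coding) nucleotide fixtures: the
# translation slot is filled with a placeholder since only the nt level
# is exercised
mkCdsRaw <- function(seqs) {
  CdsSet(Biostrings::DNAStringSet(seqs),
         aa = Biostrings::AAStringSet(
           stats::setNames(rep("M", length(seqs)), names(seqs))))
}
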