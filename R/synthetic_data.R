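.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"), paste0),
                               c("T", "C", "A", "G"), paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

#' Simulation configuration
#'
#' Describes a two-condition (control vs virus-infected) salivary-gland
#' study design: host transcripts with planted Met-initiated ORFs, a
#' 108-member viral coding set with a fixed set of silent ORFs, three
#' replicates per condition, negative-binomial counts, and per-condition
#' class abundance targets expressed as percent of total TPM.
#'
#' @param n_host_transcripts number of host transcripts (default 300).
#' @param n_viral number of viral ORFs (default 108).
#' @param absent_viral indices (1-based) of viral ORFs receiving zero
#'   counts in every sample (default \code{c(6, 7, 8, 9, 26, 60, 61)}).
#' @param conditions two condition labels, reference first (default
#'   \code{c("PBS", "infected")}).
#' @param replicates replicates per condition (default 3).
#' @param phi negative-binomial dispersion of the counts (default 0.1).
#' @param fraction_de fraction of background host transcripts given a
#'   planted fold change (default 0.1).
#' @param planted_lfc absolute planted log2 fold change (default 3).
#' @param lib_size target reads per library (default 2e5).
#' @param decoy_fraction fraction of host transcripts that are non-coding
#'   decoys without any ORF of 150 nt (default 0.1).
#' @param dirichlet_alpha concentration of the symmetric Dirichlet that
#'   splits a class's abundance across its members (default 5).
#' @param class_targets named list (one element per condition) of named
#'   percent vectors: the target share of total TPM per class; the
#'   remainder is spread over the other classes.
#' @param seed mandatory integer seed.
#' @return list of class \code{"sialo_simconfig"}.
#' @export
simulationConfig <- function(n_host_transcripts = 300L, n_viral = 108L,
                             absent_viral = c(6L, 7L, 8L, 9L, 26L, 60L, 61L),
                             conditions = c("PBS", "infected"),
                             replicates = 3L, phi = 0.1,
                             fraction_de = 0.1, planted_lfc = 3,
                             lib_size = 2e5, decoy_fraction = 0.1,
                             dirichlet_alpha = 5,
                             class_targets = list(
                               PBS = c(secreted = 38.8, "Met/Energy" = 22.6,
                                       unknown = 20.2),
                               infected = c(virus = 62.1, unknown = 22.8,
                                            secreted = 4.3)),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(conditions) != 2L) stop("exactly two conditions")
  if (!setequal(names(class_targets), conditions))
    stop("class_targets must name both conditions")
  for (cc in conditions)
    if (sum(class_targets[[cc]]) > 100)
      stop("class target percentages exceed 100 for ", cc)
  if (any(absent_viral < 1 | absent_viral > n_viral))
    stop("absent_viral indices out of range")
  cfg <- list(n_host_transcripts = as.integer(n_host_transcripts),
              n_viral = as.integer(n_viral),
              absent_viral = as.integer(absent_viral),
              conditions = conditions, replicates = as.integer(replicates),
              phi = phi, fraction_de = fraction_de,
              planted_lfc = planted_lfc, lib_size = lib_size,
              decoy_fraction = decoy_fraction,
              dirichlet_alpha = dirichlet_alpha,
              class_targets = class_targets, seed = as.integer(seed))
  class(cfg) <- "sialo_simconfig"
  cfg
}

.randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# signal-peptide N-terminus (15 aa) from the generative template:
# positive n-region, hydrophobic h-region, A-X-A cleavage site
.spTemplateAa <- function() {
  paste0("MK", paste(sample(c("N", "S", "T", "Q"), 2, TRUE), collapse = ""),
         paste(sample(c("L", "V", "I", "A"), 8, TRUE), collapse = ""),
         "A", sample(c("Q", "S", "N"), 1), "A")
}

.AA_TO_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.codonsFor <- function(aa) {
  vapply(strsplit(aa, "")[[1]], function(a)
    sample(.AA_TO_CODON[[a]], 1), character(1))
}

# one coding ORF (nt, includes ATG and terminal stop) with given aa count
# (excluding stop); secreted ORFs start from the signal-peptide template
.plantOrf <- function(nCodons, secreted) {
  if (secreted) {
    sp <- .spTemplateAa()
    body <- sample(.SENSE_CODONS, nCodons - nchar(sp), replace = TRUE)
    paste0(paste(.codonsFor(sp), collapse = ""),
           paste(body, collapse = ""), sample(.STOP_CODONS, 1))
  } else {
    body <- sample(.SENSE_CODONS, nCodons - 1L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), sample(.STOP_CODONS, 1))
  }
}

# a decoy with no ORF of >= minNt in any of the six frames
.makeDecoy <- function(len = 240L, minNt = 150L) {
  repeat {
    s <- .randNt(len)
    orfs <- findOrfs(DNAStringSet(c(x = s)), minNt = minNt)
    if (nrow(orfs) == 0) return(s)
  }
}

#' Simulate a labelled transcriptome
#'
#' Generates host transcripts carrying planted Met-initiated ORFs (uniform
#' 150-1800 nt including the stop codon) embedded in random UTRs,
#' secreted-class transcripts with a signal-peptide N-terminus built from
#' the same rule family the predictor tests, non-coding decoys with no ORF
#' of 150 nt, and a viral coding set.  Deterministic given the seed.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{transcripts} (\code{DNAStringSet}),
#'   \code{viral_cds} (\code{DNAStringSet}) and \code{truth}
#'   (\code{data.frame}: transcript_id, class, family, has_sp, cds_start,
#'   cds_end (0-based half-open), strand, source, viral_orf, is_decoy).
#' @export
simulateTranscriptome <- function(cfg) {
  set.seed(cfg$seed)
  nHost <- cfg$n_host_transcripts
  nDecoy <- round(cfg$decoy_fraction * nHost)
  nCoding <- nHost - nDecoy
  hostClasses <- setdiff(sialoClasses(), c("virus"))
  bgClasses <- setdiff(hostClasses, c("secreted", "unknown", "Met/Energy"))
  nSec <- round(0.30 * nCoding)
  nUnk <- round(0.18 * nCoding)
  nMet <- round(0.12 * nCoding)
  nBg <- nCoding - nSec - nUnk - nMet
  classes <- c(rep("secreted", nSec), rep("unknown", nUnk),
               rep("Met/Energy", nMet),
               rep(bgClasses, length.out = nBg))
  classes <- sample(classes)
  lex <- defaultLexicon()
  e <- lexiconEntries(lex)
  secEntries <- which(e$class == "secreted" & !is.na(e$family))
  families <- rep(NA_character_, nCoding)
  isSec <- classes == "secreted"
  # ~20% of secreted records are the "unknown secreted" family: signal
  # peptide but no informative homology
  famPick <- ifelse(stats::runif(sum(isSec)) < 0.2, NA_integer_,
                    sample(secEntries, sum(isSec), replace = TRUE))
  families[isSec] <- ifelse(is.na(famPick), "Unknown",
                            e$family[famPick])
  termIdx <- rep(NA_integer_, nCoding)
  termIdx[isSec] <- famPick
  for (cl in unique(classes[!isSec])) {
    if (cl == "unknown") next
    opts <- which(e$class == cl)
    sel <- which(classes == cl)
    termIdx[sel] <- sample(opts, length(sel), replace = TRUE)
  }
  seqs <- character(nHost)
  truth <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(nHost)),
    class = c(classes, rep("decoy", nDecoy)),
    family = c(families, rep(NA_character_, nDecoy)),
    has_sp = FALSE, cds_start = NA_integer_, cds_end = NA_integer_,
    strand = "+", source = "denovo", viral_orf = NA_integer_,
    is_decoy = c(rep(FALSE, nCoding), rep(TRUE, nDecoy)),
    lexicon_term = NA_character_, stringsAsFactors = FALSE)
  truth$lexicon_term[seq_len(nCoding)] <-
    ifelse(is.na(termIdx), NA, e$term[termIdx])
  for (i in seq_len(nCoding)) {
    nCod <- sample(49:599, 1)
    orf <- .plantOrf(nCod, isSec[i])
    utr5 <- .randNt(sample(20:150, 1))
    utr3 <- .randNt(sample(20:150, 1))
    seqs[i] <- paste0(utr5, orf, utr3)
    truth$cds_start[i] <- nchar(utr5)
    truth$cds_end[i] <- nchar(utr5) + nchar(orf)
    truth$has_sp[i] <- isSec[i]
  }
  for (i in seq_len(nDecoy))
    seqs[nCoding + i] <- .makeDecoy()
  transcripts <- DNAStringSet(stats::setNames(seqs, truth$transcript_id))
  viral <- vapply(seq_len(cfg$n_viral), function(i) {
    paste0("ATG", paste(sample(.SENSE_CODONS, sample(100:300, 1),
                               replace = TRUE), collapse = ""),
           sample(.STOP_CODONS, 1))
  }, character(1))
  viralIds <- sprintf("vORF%03d", seq_len(cfg$n_viral))
  viralCds <- DNAStringSet(stats::setNames(viral, viralIds))
  vTruth <- data.frame(
    transcript_id = viralIds, class = "virus", family = NA_character_,
    has_sp = FALSE, cds_start = 0L,
    cds_end = Biostrings::width(viralCds), strand = "+",
    source = "viral", viral_orf = seq_len(cfg$n_viral), is_decoy = FALSE,
    lexicon_term = NA_character_, stringsAsFactors = FALSE)
  list(transcripts = transcripts, viral_cds = viralCds,
       truth = rbind(truth, vTruth))
}

.FILLERS <- c("putative", "salivary", "precursor", "isoform", "variant",
              "partial", "candidate", "predicted")

#' Simulate protein homology hit tables
#'
#' Every informative host transcript receives 1-5 hits whose description
#' embeds exactly the lexicon term matching its true class/family plus
#' neutral filler words, with identity U(40, 95) and subject coverage
#' U(0.55, 1).  Unknown-class transcripts receive either no hits or hits
#' below the acceptance identity threshold, decoys and "unknown secreted"
#' records receive none, and viral records never appear in host hit
#' tables.
#'
#' @param truth truth table from \code{\link{simulateTranscriptome}}.
#' @param cfg the \code{\link{simulationConfig}} used to build it.
#' @param dbTags database tags to draw from.
#' @return hit table \code{data.frame} in \code{\link{readHitTable}}
#'   layout.
#' @export
simulateHits <- function(truth, cfg, dbTags = c("nr", "refseq", "cdd")) {
  set.seed(cfg$seed + 1L)
  lexTerms <- lexiconEntries(defaultLexicon())$term
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$is_decoy || tr$source == "viral") next
    aaLen <- (tr$cds_end - tr$cds_start) / 3 - 1
    lowOnly <- FALSE
    if (tr$class == "unknown" || (tr$class == "secreted" &&
                                  identical(tr$family, "Unknown"))) {
      if (tr$class == "unknown" && stats::runif(1) < 0.5) lowOnly <- TRUE
      else next
    }
    desc <- if (lowOnly) {
      # distant homologs: a real term, but identity below acceptance, so
      # the record stays unknown at default thresholds yet classifies
      # once the identity gate is opened
      paste(paste(sample(.FILLERS, 2), collapse = " "),
            sample(lexTerms, 1))
    } else {
      paste(paste(sample(.FILLERS, 2), collapse = " "),
            tr$lexicon_term, sample(.FILLERS, 1))
    }
    nHits <- sample(1:5, 1)
    for (k in seq_len(nHits)) {
      slen <- sample(100:600, 1)
      cov <- stats::runif(1, 0.55, 1)
      send <- max(1L, round(cov * slen))
      alen <- min(aaLen, send)
      pid <- if (lowOnly) stats::runif(1, 10, 30) else stats::runif(1, 40, 95)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = tr$transcript_id,
        subject_id = sprintf("SUBJ%07d", sample.int(1e7, 1)),
        subject_desc = desc,
        db_tag = sample(dbTags, 1),
        pident = round(pid, 1), align_len = alen,
        qstart = 1L, qend = alen, sstart = 1L, send = send,
        evalue = 10^(-stats::runif(1, 10, 100)),
        bitscore = round(stats::runif(1, 60, 300), 1),
        qlen = aaLen, slen = slen, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      subject_desc = character(0), db_tag = character(0),
                      pident = numeric(0), align_len = numeric(0),
                      qstart = numeric(0), qend = numeric(0),
                      sstart = numeric(0), send = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      qlen = numeric(0), slen = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[, c("query_id", "subject_id", "subject_desc", "db_tag", "pident",
          "align_len", "qstart", "qend", "sstart", "send", "evalue",
          "bitscore", "qlen", "slen")]
}

.rdirichlet <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Simulate negative-binomial counts under the study design
#'
#' Per condition, a transcript's expected TPM share follows the class
#' targets of the configuration, split within a class by a symmetric
#' Dirichlet; remainder mass is spread over the untargeted classes
#' (including decoys) in proportion to class size.  A \code{fraction_de}
#' subset of background host transcripts gets its infected-condition mean
#' scaled by \code{2^(+/- planted_lfc)}.  Expected read counts are the
#' share-times-length rates renormalized to the library size; counts are
#' independent negative binomial draws per replicate
#' (\code{phi = 0} degenerates to Poisson).  Viral ORFs in the absent set
#' and all viral ORFs in the reference condition receive zero counts.
#'
#' @param truth truth table from \code{\link{simulateTranscriptome}} (host
#'   and viral rows).
#' @param cfg the \code{\link{simulationConfig}}.
#' @param effLength optional per-transcript effective lengths; defaults to
#'   the CDS length (transcript length for decoys).
#' @return list with \code{counts} (a \code{\link{SialoCounts}}) and
#'   \code{truth} (input plus columns \code{mean_<condition>} expected TPM
#'   share in percent, \code{true_logFC}, \code{de_planted}).
#' @export
simulateCounts <- function(truth, cfg, effLength = NULL) {
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  conds <- cfg$conditions
  ref <- conds[1L]
  if (is.null(effLength)) {
    effLength <- ifelse(is.na(truth$cds_start),
                        300, truth$cds_end - truth$cds_start)
  }
  share <- matrix(0, n, 2, dimnames = list(truth$transcript_id, conds))
  for (cc in conds) {
    targets <- cfg$class_targets[[cc]] / 100
    rest <- 1 - sum(targets)
    bgCc <- setdiff(unique(truth$class), names(targets))
    if (cc == ref) bgCc <- setdiff(bgCc, "virus")
    bgSizes <- table(truth$class)[bgCc]
    bgSizes <- bgSizes[!is.na(bgSizes)]
    bgShare <- rest * as.numeric(bgSizes) / sum(bgSizes)
    names(bgShare) <- names(bgSizes)
    allShare <- c(targets, bgShare)
    for (cl in names(allShare)) {
      idx <- which(truth$class == cl)
      if (!length(idx)) next
      if (cl == "virus") {
        present <- setdiff(seq_along(idx), cfg$absent_viral)
        if (cc == ref) next  # no viral expression in the reference
        w <- numeric(length(idx))
        w[present] <- .rdirichlet(length(present), cfg$dirichlet_alpha)
        share[idx, cc] <- allShare[[cl]] * w
      } else {
        share[idx, cc] <- allShare[[cl]] *
          .rdirichlet(length(idx), cfg$dirichlet_alpha)
      }
    }
  }
  # planted fold changes on background host transcripts (classes without
  # an abundance target, so the targets stay in place)
  plantable <- setdiff(unique(truth$class),
                       c(unlist(lapply(cfg$class_targets, names)),
                         "virus", "decoy"))
  bgIdx <- which(truth$class %in% plantable & !truth$is_decoy)
  nDe <- round(cfg$fraction_de * sum(!truth$is_decoy &
                                       truth$source == "denovo"))
  nDe <- min(nDe, length(bgIdx))
  deIdx <- sort(sample(bgIdx, nDe))
  dirUp <- rep(c(TRUE, FALSE), length.out = length(deIdx))
  other <- conds[2L]
  share[deIdx[dirUp], other] <- share[deIdx[dirUp], other] *
    2^cfg$planted_lfc
  share[deIdx[!dirUp], other] <- share[deIdx[!dirUp], other] *
    2^(-cfg$planted_lfc)
  nRep <- cfg$replicates
  samples <- paste0(rep(conds, each = nRep), "_", seq_len(nRep))
  condOf <- rep(conds, each = nRep)
  m <- matrix(0, n, length(samples),
              dimnames = list(truth$transcript_id, samples))
  for (j in seq_along(samples)) {
    cc <- condOf[j]
    w <- share[, cc] * effLength
    p <- w / sum(w)
    N <- round(cfg$lib_size * stats::runif(1, 0.9, 1.1))
    mu <- p * N
    y <- if (cfg$phi == 0) stats::rpois(n, mu)
         else stats::rnbinom(n, size = 1 / cfg$phi, mu = mu)
    y[mu == 0] <- 0
    m[, j] <- y
  }
  truth[[paste0("mean_", ref)]] <- share[, ref] * 100
  truth[[paste0("mean_", other)]] <- share[, other] * 100
  truth$true_logFC <- log2(share[, other] / share[, ref])
  truth$de_planted <- seq_len(n) %in% deIdx
  list(counts = SialoCounts(m, effLength = effLength, condition = condOf),
       truth = truth)
}

#' Simulate a simple two-group DE count matrix
#'
#' A minimal generator for calibrating the differential expression module:
#' genes with log-uniform baseline means, an optional planted fraction
#' with symmetric \code{2^(+/- lfc)} fold changes in group B, and
#' independent NB counts (Poisson when \code{phi = 0}).
#'
#' @param nGenes number of genes (default 2000).
#' @param fracDe fraction of genes with a planted fold change (default 0).
#' @param lfc absolute planted log2 fold change (default 3).
#' @param phi NB dispersion (default 0.1).
#' @param nPerGroup replicates per group (default 3).
#' @param meanRange range of baseline means, sampled log-uniformly
#'   (default \code{c(20, 200)}).
#' @param seed integer seed.
#' @return list with \code{counts} (matrix), \code{groups} (\code{"A"}
#'   reference / \code{"B"}), \code{de} (logical), \code{direction}
#'   (\code{+1}/\code{-1}/0).
#' @export
simulateDeCounts <- function(nGenes = 2000L, fracDe = 0, lfc = 3,
                             phi = 0.1, nPerGroup = 3L,
                             meanRange = c(20, 200), seed = 1L) {
  set.seed(seed)
  base <- exp(stats::runif(nGenes, log(meanRange[1]), log(meanRange[2])))
  de <- rep(FALSE, nGenes)
  dirn <- rep(0, nGenes)
  nDe <- round(fracDe * nGenes)
  if (nDe > 0) {
    idx <- sample.int(nGenes, nDe)
    de[idx] <- TRUE
    dirn[idx] <- rep(c(1, -1), length.out = nDe)
  }
  muA <- base
  muB <- base * 2^(dirn * lfc)
  draw <- function(mu) {
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
  }
  m <- cbind(
    vapply(seq_len(nPerGroup), function(i) draw(muA), numeric(nGenes)),
    vapply(seq_len(nPerGroup), function(i) draw(muB), numeric(nGenes)))
  dimnames(m) <- list(sprintf("g%05d", seq_len(nGenes)),
                      c(paste0("A", seq_len(nPerGroup)),
                        paste0("B", seq_len(nPerGroup))))
  list(counts = m, groups = rep(c("A", "B"), each = nPerGroup),
       de = de, direction = dirn)
}

#' Write a simulation to disk
#'
#' Writes \code{transcripts.fasta}, \code{viral.fasta},
#' \code{hits_<db>.tsv} (one per database tag, 15-column layout),
#' \code{counts.tsv}, \code{meta.tsv} and \code{truth.tsv}.
#'
#' @param sim list with \code{transcripts}, \code{viral_cds},
#'   \code{truth}, \code{hits}, \code{counts} (as produced by the
#'   simulate* functions).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(sim$transcripts, file.path(dir, "transcripts.fasta"))
  writeFasta(sim$viral_cds, file.path(dir, "viral.fasta"))
  if (!is.null(sim$hits)) {
    h <- sim$hits
    h$mismatch <- 0L
    h$gapopen <- 0L
    for (db in unique(h$db_tag)) {
      sub <- h[h$db_tag == db, .HIT_COLS]
      utils::write.table(sub, file.path(dir, paste0("hits_", db, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  if (!is.null(sim$counts))
    writeCounts(sim$counts, file.path(dir, "counts.tsv"),
                file.path(dir, "meta.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run a full synthetic study
#'
#' Convenience wrapper: \code{\link{simulateTranscriptome}},
#' \code{\link{simulateHits}} and \code{\link{simulateCounts}} under one
#' configuration.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{transcripts}, \code{viral_cds}, \code{truth},
#'   \code{hits}, \code{counts}.
#' @export
simulateStudy <- function(cfg) {
  sim <- simulateTranscriptome(cfg)
  hits <- simulateHits(sim$truth, cfg)
  cts <- simulateCounts(sim$truth, cfg)
  list(transcripts = sim$transcripts, viral_cds = sim$viral_cds,
       truth = cts$truth, hits = hits, counts = cts$counts)
}
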