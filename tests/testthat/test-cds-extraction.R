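test_that("ORF scanning follows the stop-to-stop definition", {
  tx <- Biostrings::DNAStringSet(c(t1 = "ATGAAATAA"))
  o <- findOrfs(tx, minNt = 9)
  fwd <- o[o$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$aa_seq, "MK")
  expect_true(fwd$has_terminal_stop)
  expect_equal(fwd$nt_start, 0L)
  expect_equal(fwd$nt_end, 9L)
  expect_equal(unlist(fwd$met_positions), 0L)

  expect_equal(nrow(findOrfs(tx, minNt = 150)), 0L)
  expect_error(findOrfs(Biostrings::BStringSet(c(x = "ATGQQQ"))),
               "non-nucleotide")
})

test_that("ORF scanning equals the six-frame brute-force oracle", {
  set.seed(101)
  for (rep in 1:8) {
    s <- randomNt(sample(c(200, 500, 2000), 1))
    for (minNt in c(30, 150)) {
      mine <- findOrfs(Biostrings::DNAStringSet(c(x = s)), minNt = minNt)
      orc <- oracleOrfs(s, minNt = minNt)
      expect_equal(orfKey(mine), orfKey(orc))
      mineM <- findOrfs(Biostrings::DNAStringSet(c(x = s)), minNt = minNt,
                        requireMet = TRUE)
      orcM <- oracleOrfs(s, minNt = minNt, requireMet = TRUE)
      expect_equal(orfKey(mineM), orfKey(orcM))
    }
  }
})

test_that("ORF sets mirror under reverse complement", {
  set.seed(202)
  for (rep in 1:5) {
    s <- randomNt(600)
    a <- as.data.frame(findOrfs(Biostrings::DNAStringSet(c(x = s)),
                                minNt = 60))[, 1:6]
    b <- as.data.frame(findOrfs(Biostrings::DNAStringSet(
      c(x = revcompChar(s))), minNt = 60))[, 1:6]
    L <- nchar(s)
    b$strand <- ifelse(b$strand == "+", "-", "+")
    tmp <- L - b$nt_end
    b$nt_end <- L - b$nt_start
    b$nt_start <- tmp
    key <- function(d) sort(paste(d$strand, d$nt_start, d$nt_end, d$aa_seq))
    expect_equal(key(a), key(b))
  }
})

test_that("every coding sequence translates consistently", {
  set.seed(30)
  cfg <- simulationConfig(n_host_transcripts = 40, n_viral = 10,
                          absent_viral = c(1L), seed = 5)
  sim <- simulateTranscriptome(cfg)
  cds <- CdsSet(sim$viral_cds, source = "viral")
  expect_equal(as.character(cdsAa(cds)),
               as.character(translateCds(cdsNt(cds))))
})

test_that("homology promotion applies the subject-coverage rule", {
  tx <- Biostrings::DNAStringSet(c(t1 = paste0(
    "ATG", strrep("GCT", 120), "TAA")))
  orfs <- findOrfs(tx, minNt = 150)
  orfs <- orfs[orfs$strand == "+" & orfs$aa_seq != "", ][1, ]
  hit <- function(send, slen, bitscore, tid = "t1")
    data.frame(query_id = tid, subject_id = "s", subject_desc = "amylase",
               db_tag = "nr", pident = 80, align_len = send, qstart = 1,
               qend = 50, sstart = 1, send = send, evalue = 1e-40,
               bitscore = bitscore, qlen = 121, slen = slen,
               stringsAsFactors = FALSE)

  promoted <- extractCdsByHomology(orfs, hit(160, 200, 90), tx)
  expect_equal(length(promoted), 1L)   # coverage 0.80
  expect_equal(cdsInfo(promoted)$anchor, "homology")

  notprom <- extractCdsByHomology(orfs, hit(120, 200, 90), tx)
  expect_equal(length(notprom), 0L)    # coverage 0.60

  # two qualifying hits: best bitscore wins, not best coverage
  hits2 <- rbind(hit(150, 200, 90), hit(190, 200, 50))
  both <- extractCdsByHomology(orfs, hits2, tx)
  expect_equal(cdsInfo(both)$best_bitscore, 90)
  expect_equal(cdsInfo(both)$best_cov, 0.75)

  expect_warning(extractCdsByHomology(orfs, hit(160, 200, 90, "ghost"), tx),
                 "unknown transcript")
})

test_that("signal-peptide anchoring selects the most 5' positive Met", {
  aa1 <- paste0("MKNSLLVVLLLAAQA", strrep("K", 5), "M", strrep("A", 60))
  ntBody <- paste(vapply(strsplit(aa1, "")[[1]], function(a)
    switch(a, M = "ATG", K = "AAA", N = "AAC", S = "AGC", L = "CTG",
           V = "GTG", A = "GCT", Q = "CAG", stop("?")), character(1)),
    collapse = "")
  tx <- Biostrings::DNAStringSet(c(t1 = paste0(ntBody, "TAA")))
  orfs <- findOrfs(tx, minNt = 60)
  orf <- orfs[orfs$strand == "+" & grepl("^MK", orfs$aa_seq), ][1, ]
  mets <- unlist(orf$met_positions)
  expect_true(all(c(0, 20) %in% mets))

  # both Mets positive -> the most 5' wins
  calls <- data.frame(met_offset = c(0L, 20L), has_sp = c(TRUE, TRUE))
  cds <- anchorStartBySp(orf, calls, tx[[1]])
  expect_equal(substr(unname(as.character(cdsAa(cds))), 1, 4), "MKNS")
  expect_equal(cdsInfo(cds)$anchor, "signal_peptide")

  # only the downstream Met positive -> start there
  calls2 <- data.frame(met_offset = c(0L, 20L), has_sp = c(FALSE, TRUE))
  cds2 <- anchorStartBySp(orf, calls2, tx[[1]])
  expect_equal(substr(unname(as.character(cdsAa(cds2))), 1, 2), "MA")
  expect_equal(unname(nchar(as.character(cdsAa(cds2)))),
               nchar(orf$aa_seq) - 20)

  # no positive call -> nothing
  calls3 <- data.frame(met_offset = c(0L, 20L), has_sp = c(FALSE, FALSE))
  expect_null(anchorStartBySp(orf, calls3, tx[[1]]))
})

test_that("CDS source merging applies genome > viral > de novo precedence", {
  mk <- function(ids, source) CdsSet(
    Biostrings::DNAStringSet(stats::setNames(
      rep("ATGAAATAA", length(ids)), ids)), source = source)
  m <- mergeCdsSources(mk(c("a", "b", "c"), "denovo"),
                       mk(c("d", "e"), "genome"), mk("f", "viral"))
  expect_equal(length(m), 6L)

  m2 <- mergeCdsSources(mk(c("a", "b"), "denovo"), mk("a", "genome"))
  expect_equal(length(m2), 2L)
  expect_equal(unname(cdsInfo(m2)["a", "source"]), "genome")

  m3 <- mergeCdsSources(mk("x", "denovo"), viral = mk("x", "viral"))
  expect_equal(unname(cdsInfo(m3)["x", "source"]), "viral")

  expect_error(mk(c("a", "a"), "denovo"), "duplicate")
})

test_that("identity consolidation is greedy, thresholded and matches the
           all-pairs oracle", {
  s <- randomNt(100)
  two <- mkCdsRaw(c(z2 = s, z1 = s))
  res <- consolidateIdentity(two, 0.95)
  expect_equal(length(res$cds), 1L)
  expect_equal(names(res$cds), "z1")  # lexicographically first id
  expect_setequal(res$report$clusters[["z1"]], c("z1", "z2"))

  # 10 mismatches in 100 nt: identity 0.90 < 0.95, both retained
  mut <- s
  set.seed(11)
  pos <- sample(100, 10)
  for (p in pos)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, p, p))[1]
  pairI <- pairIdentity(s, mut)
  expect_lt(pairI, 0.95)
  both <- consolidateIdentity(mkCdsRaw(c(a = s, b = mut)), 0.95)
  expect_equal(length(both$cds), 2L)

  # 30 random sequences with planted 96%-identity duplicates
  set.seed(77)
  n <- 20
  seqs <- vapply(sample(seq(90, 300, 3), n, replace = TRUE), randomNt,
                 character(1))
  dups <- vapply(seqs[1:10], function(x) {
    k <- max(1, round(0.04 * nchar(x)))
    for (p in sample(nchar(x), k))
      substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(x, p, p)), 1)
    x
  }, character(1))
  all30 <- c(seqs, dups)
  names(all30) <- sprintf("s%02d", seq_along(all30))
  cds <- mkCdsRaw(all30)
  res30 <- consolidateIdentity(cds, 0.95)
  orc <- oracleConsolidate(unname(all30), names(all30), 0.95)
  expect_setequal(names(res30$report$clusters), names(orc))
  for (nm in names(orc))
    expect_setequal(res30$report$clusters[[nm]], orc[[nm]])

  # partition property and representative separation
  expect_setequal(unlist(res30$report$clusters), names(all30))
  reps <- names(res30$report$clusters)
  for (i in seq_along(reps)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_lt(pairIdentity(all30[reps[i]], all30[reps[j]]), 0.95)
    }
  }
})
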