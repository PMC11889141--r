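mkHit <- function(desc, db = "nr", pident = 80, send = 150, slen = 200,
                  bitscore = 100, qid = "q1") {
  data.frame(query_id = qid, subject_id = "subj", subject_desc = desc,
             db_tag = db, pident = pident, align_len = send, qstart = 1,
             qend = 50, sstart = 1, send = send, evalue = 1e-40,
             bitscore = bitscore, qlen = 60, slen = slen,
             stringsAsFactors = FALSE)
}

test_that("the shipped lexicon loads and is well-formed", {
  lex <- defaultLexicon()
  e <- lexiconEntries(lex)
  expect_gte(length(unique(e$class)), 25)
  expect_true(all(e$term == tolower(e$term)))
  hit <- lexiconLookup(lex, "antigen 5")
  expect_equal(hit$class, "secreted")
  expect_equal(hit$family, "Antigen-5")
  # every family of the secreted table is reachable through some term
  fams <- c("Antigen-5", "Apolipoprotein", "Amylase", "Maltase",
            "Acid phosphatase", "Cysteine peptidase",
            "Dipeptidyl peptidase", "Metallo peptidase",
            "Serine peptidase", "Esterase", "Lipase",
            "Hormone-binding protein", "Attacin", "Lectin", "Diptericin",
            "Cecropin", "Lysozyme", "Defensin", "Mucin",
            "Odorant-binding protein", "Kunitz", "Kazal", "Cystatin",
            "Serpin", "Trypsin-inhibitor like (TIL)")
  expect_true(all(fams %in% e$family))
})

test_that("lexicon loading validates duplicates, classes and emptiness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tclass\tfamily\tpriority",
               "amylase\tsecreted\tAmylase\t0",
               "amylase\tsecreted\tAmylase\t0"), f)
  expect_error(loadLexicon(f), "duplicate lexicon term")
  writeLines(c("term\tclass\tfamily\tpriority",
               "thing\tnot-a-class\tNA\t0"), f)
  expect_error(loadLexicon(f), "unknown class")
  writeLines("term\tclass\tfamily\tpriority", f)
  expect_error(loadLexicon(f), "empty lexicon")
})

test_that("classification follows source, precedence, position and
           priority", {
  lex <- defaultLexicon()

  expect_equal(classifyCds("viral", NULL, FALSE, lex)$class, "virus")

  sp <- classifyCds("denovo", mkHit("venom allergen antigen 5-like protein"),
                    TRUE, lex)
  expect_equal(sp$class, "secreted")
  expect_equal(sp$family, "Antigen-5")

  # the compound-phrase fixture: the leftmost term must not beat the
  # higher-priority inhibitor family term
  kz <- classifyCds("denovo",
                    mkHit("serine protease inhibitor, Kunitz type"),
                    FALSE, lex)
  expect_equal(kz$family, "Kunitz")
  expect_equal(kz$matched_term, "kunitz")

  # no hits + signal peptide -> unknown secreted
  ns <- classifyCds("denovo", NULL, TRUE, lex)
  expect_equal(ns$class, "secreted")
  expect_equal(ns$family, "Unknown")
  expect_equal(classifyCds("denovo", NULL, FALSE, lex)$class, "unknown")

  # below-threshold hits never classify
  weak <- classifyCds("denovo", mkHit("amylase precursor", pident = 20),
                      FALSE, lex)
  expect_equal(weak$class, "unknown")
  weak2 <- classifyCds("denovo",
                       mkHit("amylase precursor", send = 80, slen = 200),
                       TRUE, lex)
  expect_equal(weak2$class, "secreted")
  expect_equal(weak2$family, "Unknown")

  # database precedence decides which description is scanned
  hits <- rbind(mkHit("amylase precursor", db = "cdd", bitscore = 500),
                mkHit("trypsin-like serine protease", db = "nr",
                      bitscore = 50))
  byPrec <- classifyCds("denovo", hits, FALSE, lex)
  expect_equal(byPrec$family, "Serine peptidase")

  # leftmost match wins within one priority tier
  lm <- classifyCds("denovo", mkHit("lysozyme and defensin precursor"),
                    FALSE, lex)
  expect_equal(lm$family, "Lysozyme")
})

test_that("class abundance shares sum to 100 and are sample-order
           invariant", {
  m <- matrix(c(750, 250, 740, 260), 2, 2,
              dimnames = list(c("x", "y"), c("s1", "s2")))
  e <- computeTpm(makeCounts(m, c("A", "B")))
  ann <- data.frame(id = c("x", "y"), class = c("secreted", "virus"))
  ab <- classAbundanceSummary(ann, e)
  expect_equal(unname(ab$per_sample["secreted", "s1"]), 75)
  expect_equal(unname(ab$per_sample["virus", "s1"]), 25)
  expect_equal(unname(colSums(ab$per_sample)), c(100, 100),
               tolerance = 1e-9)

  perm <- computeTpm(makeCounts(m[, c(2, 1)], c("B", "A")))
  ab2 <- classAbundanceSummary(ann, perm)
  expect_equal(ab2$summary[order(ab2$summary$class, ab2$summary$condition), ],
               ab$summary[order(ab$summary$class, ab$summary$condition), ],
               ignore_attr = TRUE)

  expect_error(classAbundanceSummary(ann[1, ], e), "without annotation")
})

test_that("the secreted family table reproduces the worked percent
           reductions", {
  # family TPM sums 35064.9 vs 186.9: reduction 99.47 percent
  cm <- matrix(c(35064.9, 500, 10, 186.9, 0, 20), 3, 2,
               dimnames = list(c("amy", "ag5", "kun"),
                               c("PBS", "infected")))
  # build an expression object holding exactly these condition means
  m <- cbind(PBS1 = cm[, 1], inf1 = cm[, 2])
  e <- computeTpm(makeCounts(m, c("PBS", "infected")))
  # computeTpm rescales columns; use raw means via a handmade object
  rd <- S4Vectors::DataFrame(mean_PBS = cm[, 1], mean_infected = cm[, 2],
                             row.names = rownames(cm))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = cm),
    rowData = rd,
    colData = S4Vectors::DataFrame(condition = c("PBS", "infected"),
                                   row.names = colnames(cm)))
  expr <- new("SialoExpr", se)
  ann <- data.frame(id = c("amy", "ag5", "kun"),
                    class = "secreted",
                    family = c("Amylase", "Antigen-5", "Kunitz"))
  tab <- secretedFamilyTable(ann, expr, tpmMin = 3, reference = "PBS")
  amy <- tab[tab$family == "Amylase", ]
  expect_equal(round(amy$pct_change, 2), 99.47)
  expect_equal(amy$n_PBS, 1L)
  expect_equal(amy$tpm_PBS, 35064.9)

  # family vanishing from the infected condition: 100 percent reduction
  ag5 <- tab[tab$family == "Antigen-5", ]
  expect_equal(ag5$n_infected, 0L)
  expect_equal(ag5$tpm_infected, 0)
  expect_equal(ag5$pct_change, 100)

  # an empty secreted set gives an empty table
  none <- secretedFamilyTable(data.frame(id = "amy", class = "virus",
                                         family = NA), expr)
  expect_equal(nrow(none), 0L)
})
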