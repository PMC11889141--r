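#' Canonical sialome class labels
#'
#' The default set of functional classes used by the shipped lexicon: the
#' classes named in salivary-transcriptome annotation practice (secreted,
#' virus, unknown, energetic metabolism, transcription machinery, immunity,
#' housekeeping subclasses, ...).  The list is a reconstruction and fully
#' user-replaceable; any lexicon may declare its own class list.
#'
#' @return character vector of class labels.
#' @export
sialoClasses <- function() {
  c("secreted", "virus", "unknown", "Met/Energy",
    "transcription machinery", "immunity", "protein synthesis",
    "protein export", "protein modification", "proteasome",
    "signal transduction", "cytoskeletal", "transporters/storage",
    "nuclear regulation", "carbohydrate metabolism", "lipid metabolism",
    "amino acid metabolism", "nucleotide metabolism",
    "oxidant metabolism/detoxification", "extracellular matrix",
    "transposable element", "cell cycle", "chaperone", "cuticle",
    "apoptosis", "RNA metabolism")
}

#' Load an annotation lexicon
#'
#' Reads a TSV with header columns \code{term}, \code{class},
#' \code{family}, \code{priority}.  Terms are lowercased and
#' whitespace-normalized; file order is preserved.  Duplicate terms and
#' classes outside \code{classes} are errors, as is an empty lexicon.
#'
#' @param path path to the lexicon TSV.
#' @param classes permitted class labels (default
#'   \code{\link{sialoClasses}}).
#' @param dbPrecedence ordered database tags for the classifier.
#' @return a \code{\link{Lexicon}}.
#' @export
loadLexicon <- function(path, classes = sialoClasses(),
                        dbPrecedence = c("nr", "refseq", "cdd")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!nrow(df)) stop("empty lexicon: a lexicon is required")
  need <- c("term", "class", "family", "priority")
  if (!all(need %in% colnames(df)))
    stop("lexicon needs columns: ", paste(need, collapse = ", "))
  term <- tolower(trimws(gsub("\\s+", " ", df$term)))
  if (anyDuplicated(term))
    stop("duplicate lexicon term: ", term[duplicated(term)][1L])
  bad <- setdiff(unique(df$class), classes)
  if (length(bad)) stop("unknown class in lexicon: ", bad[1L])
  entries <- DataFrame(term = term, class = df$class,
                       family = ifelse(is.na(df$family), NA_character_,
                                       df$family),
                       priority = as.integer(df$priority))
  new("Lexicon", entries = entries, classes = classes,
      dbPrecedence = dbPrecedence)
}

#' The shipped default lexicon
#'
#' Loads the reconstruction of an ordered salivary-annotation vocabulary
#' bundled with the package (\code{inst/extdata/sialome_lexicon.tsv}).  It
#' covers all canonical classes and the secreted-protein families of the
#' domain (antigen 5, amylase, peptidases, peptidase inhibitors,
#' antimicrobial peptides, odorant-binding proteins, ...).
#'
#' @param dbPrecedence ordered database tags.
#' @return a \code{\link{Lexicon}}.
#' @export
defaultLexicon <- function(dbPrecedence = c("nr", "refseq", "cdd")) {
  loadLexicon(system.file("extdata", "sialome_lexicon.tsv",
                          package = "SialoKit", mustWork = TRUE),
              dbPrecedence = dbPrecedence)
}

#' Look up a lexicon term
#'
#' @param lexicon a \code{\link{Lexicon}}.
#' @param term term text (matched after lowercasing).
#' @return one-row \code{DataFrame}, or \code{NULL} when absent.
#' @export
lexiconLookup <- function(lexicon, term) {
  e <- lexiconEntries(lexicon)
  i <- match(tolower(trimws(term)), e$term)
  if (is.na(i)) NULL else e[i, , drop = FALSE]
}

# scan one description; returns list(term, class, family) or NULL.
# matches ranked by priority (desc), then leftmost position, then longer
# term: the priority tier resolves compound phrases such as
# "serine protease inhibitor".
.scanDescription <- function(desc, lexicon) {
  e <- lexiconEntries(lexicon)
  d <- tolower(desc)
  pos <- vapply(e$term, function(tt)
    as.integer(regexpr(tt, d, fixed = TRUE)), 0L)
  hit <- pos > 0
  if (!any(hit)) return(NULL)
  idx <- which(hit)
  ord <- order(-e$priority[idx], pos[idx], -nchar(e$term[idx]))
  k <- idx[ord[1L]]
  list(term = e$term[k], class = e$class[k], family = e$family[k])
}

#' Classify one coding sequence
#'
#' Implements the vocabulary-driven classifier: (1) viral records are class
#' \code{virus}; (2) databases are considered in precedence order and,
#' within the first database holding an acceptable hit (\code{pident >=
#' minPident} and subject coverage \code{>= minCov}), the best hit by
#' bitscore supplies the description; (3) the description is scanned for
#' lexicon terms, ranked by priority then leftmost position; (4) a matched
#' term fixes the class (and the family when the class is
#' \code{secreted}); (5) with no acceptable hit or no matching term the
#' record is \code{secreted}/family \code{Unknown} when it carries a
#' putative signal peptide, otherwise \code{unknown}.
#'
#' @param source record source (\code{"denovo"}, \code{"genome"} or
#'   \code{"viral"}).
#' @param hits hit table rows for this record (possibly empty).
#' @param hasSp logical: putative signal peptide present.
#' @param lexicon a \code{\link{Lexicon}}.
#' @param minPident minimum percent identity of an informative hit
#'   (default 35).
#' @param minCov minimum subject coverage of an informative hit (default
#'   0.50).
#' @return list with \code{class}, \code{family}, \code{matched_term},
#'   \code{evidence} (best acceptable hit per database, a
#'   \code{data.frame}), \code{pident} and \code{subject_cov} of the
#'   classified evidence hit (\code{NA} when none).
#' @export
classifyCds <- function(source, hits, hasSp, lexicon, minPident = 35,
                        minCov = 0.50) {
  out <- list(class = "unknown", family = NA_character_,
              matched_term = NA_character_, evidence = NULL,
              pident = NA_real_, subject_cov = NA_real_)
  if (identical(source, "viral")) {
    out$class <- "virus"
    return(out)
  }
  acc <- NULL
  if (!is.null(hits) && nrow(hits)) {
    hits$scov <- subjectCoverage(hits)
    acc <- hits[hits$pident >= minPident & hits$scov >= minCov, ,
                drop = FALSE]
    if (nrow(acc)) {
      best <- do.call(rbind, lapply(split(acc, acc$db_tag), function(h)
        h[which.max(h$bitscore), , drop = FALSE]))
      out$evidence <- best
      for (db in lexicon@dbPrecedence) {
        b <- best[best$db_tag == db, , drop = FALSE]
        if (!nrow(b)) next
        out$pident <- b$pident
        out$subject_cov <- b$scov
        m <- .scanDescription(b$subject_desc, lexicon)
        if (!is.null(m)) {
          out$class <- m$class
          out$matched_term <- m$term
          if (identical(m$class, "secreted"))
            out$family <- if (is.na(m$family)) "Unknown" else m$family
          return(out)
        }
        break  # first database with an acceptable hit decides
      }
    }
  }
  if (isTRUE(hasSp)) {
    out$class <- "secreted"
    out$family <- "Unknown"
  }
  out
}

#' Classify a whole coding-sequence set
#'
#' Vectorized \code{\link{classifyCds}} over a \code{\link{CdsSet}}: hits
#' are matched to records by the parent transcript id (falling back to the
#' record id), signal-peptide status is taken from \code{spCalls}.
#'
#' @param cds a \code{\link{CdsSet}}.
#' @param hits combined hit table (all databases; matched on
#'   \code{query_id}).
#' @param spCalls \code{data.frame} with \code{query_id} and \code{has_sp}
#'   (ids as in \code{cds} or their parents); records absent from it count
#'   as signal-negative.  Records anchored by a signal peptide always
#'   count as signal-positive.
#' @param lexicon a \code{\link{Lexicon}}.
#' @param minPident,minCov acceptance thresholds (defaults 35 and 0.50).
#' @return \code{DataFrame} with one row per record: \code{id},
#'   \code{class}, \code{family}, \code{matched_term}, \code{db},
#'   \code{pident}, \code{subject_cov}.
#' @export
annotateCds <- function(cds, hits = NULL, spCalls = NULL, lexicon,
                        minPident = 35, minCov = 0.50) {
  info <- cdsInfo(cds)
  ids <- names(cds)
  keys <- ifelse(is.na(info$parent), ids, info$parent)
  hitSplit <- if (!is.null(hits) && nrow(hits))
    split(hits, hits$query_id) else list()
  spMap <- if (!is.null(spCalls) && nrow(spCalls))
    stats::setNames(spCalls$has_sp, spCalls$query_id) else c()
  rows <- lapply(seq_along(ids), function(i) {
    h <- hitSplit[[keys[i]]]
    if (is.null(h)) h <- hitSplit[[ids[i]]]
    sp <- isTRUE(spMap[keys[i]]) || isTRUE(spMap[ids[i]]) ||
      info$anchor[i] == "signal_peptide"
    cl <- classifyCds(info$source[i], h, sp, lexicon, minPident, minCov)
    db <- if (!is.na(cl$pident) && !is.null(cl$evidence)) {
      hitdb <- cl$evidence[cl$evidence$pident == cl$pident, "db_tag"]
      hitdb[1L]
    } else NA_character_
    DataFrame(id = ids[i], class = cl$class, family = cl$family,
              matched_term = cl$matched_term, db = db,
              pident = cl$pident, subject_cov = cl$subject_cov)
  })
  do.call(rbind, rows)
}

#' Per-class abundance shares
#'
#' For each sample the share of a class is the summed TPM of its members
#' divided by 1e6, in percent; shares per sample sum to 100.  Per
#' condition the mean and standard deviation of the shares across
#' replicates are reported.
#'
#' @param annotations \code{DataFrame}/\code{data.frame} with columns
#'   \code{id} and \code{class} covering every expressed transcript (an
#'   expressed transcript without an annotation is an error).
#' @param expr a \code{\link{SialoExpr}}.
#' @return list with \code{per_sample} (classes x samples percent matrix)
#'   and \code{summary} (\code{data.frame} class, condition, mean_pct,
#'   sd_pct).
#' @export
classAbundanceSummary <- function(annotations, expr) {
  tp <- tpm(expr)
  cls <- stats::setNames(annotations$class, annotations$id)
  miss <- setdiff(rownames(tp)[rowSums(tp) > 0], names(cls))
  if (length(miss))
    stop("expressed transcript without annotation: ", miss[1L])
  cl <- cls[rownames(tp)]
  cl[is.na(cl)] <- "unknown"
  shares <- rowsum(tp, group = cl) / 1e6 * 100
  cond <- condition(expr)
  sm <- do.call(rbind, lapply(unique(cond), function(cc) {
    s <- shares[, cond == cc, drop = FALSE]
    data.frame(class = rownames(shares), condition = cc,
               mean_pct = rowMeans(s),
               sd_pct = apply(s, 1, stats::sd), row.names = NULL)
  }))
  list(per_sample = shares, summary = sm)
}

#' Secreted-protein family table
#'
#' For each family of the secreted class: the number of members detected
#' per condition (condition mean TPM at least \code{tpmMin}), the sum of
#' the condition-mean TPMs of those members, and the percent change of
#' the summed TPM relative to the reference condition
#' (\code{(ref - other) / ref * 100}; 100 means the family disappeared,
#' negative values mean an increase).
#'
#' @param annotations annotation table with \code{id}, \code{class},
#'   \code{family}.
#' @param expr a \code{\link{SialoExpr}} with two conditions.
#' @param tpmMin detection floor (default 3).
#' @param reference reference condition (default the first condition).
#' @return \code{data.frame} with one row per family: \code{family},
#'   \code{n_<cond>} and \code{tpm_<cond>} per condition, and
#'   \code{pct_change}.
#' @export
secretedFamilyTable <- function(annotations, expr, tpmMin = 3,
                                reference = NULL) {
  cm <- condMeans(expr)
  if (ncol(cm) != 2L) stop("two conditions are required")
  conds <- colnames(cm)
  if (is.null(reference)) reference <- conds[1L]
  other <- setdiff(conds, reference)
  sec <- annotations[annotations$class == "secreted" &
                       annotations$id %in% rownames(cm), , drop = FALSE]
  if (!nrow(sec)) {
    out <- data.frame(family = character(0))
    out[[paste0("n_", reference)]] <- integer(0)
    out[[paste0("n_", other)]] <- integer(0)
    out[[paste0("tpm_", reference)]] <- numeric(0)
    out[[paste0("tpm_", other)]] <- numeric(0)
    out$pct_change <- numeric(0)
    return(out)
  }
  fam <- ifelse(is.na(sec$family), "Unknown", sec$family)
  rows <- lapply(sort(unique(fam)), function(ff) {
    ids <- sec$id[fam == ff]
    m <- cm[ids, , drop = FALSE]
    det <- m >= tpmMin
    tpmSum <- colSums(m * det)
    r <- data.frame(family = ff)
    r[[paste0("n_", reference)]] <- sum(det[, reference])
    r[[paste0("n_", other)]] <- sum(det[, other])
    r[[paste0("tpm_", reference)]] <- tpmSum[reference]
    r[[paste0("tpm_", other)]] <- tpmSum[other]
    r$pct_change <- if (tpmSum[reference] > 0)
      (tpmSum[reference] - tpmSum[other]) / tpmSum[reference] * 100
    else NA_real_
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
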