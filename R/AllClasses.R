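#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

#' CdsSet: a set of coding sequences with provenance
#'
#' Container for extracted or imported coding sequences.  Each record
#' carries the nucleotide CDS, its translation (terminal stop excluded),
#' the source the record came from (\code{denovo}, \code{genome} or
#' \code{viral}), the anchor that fixed its start codon (\code{none},
#' \code{homology} or \code{signal_peptide}) and, for de novo records,
#' the parent transcript id.
#'
#' @slot nt \code{DNAStringSet} of coding sequences, names are record ids.
#' @slot aa \code{AAStringSet} of translations, parallel to \code{nt}.
#' @slot info \code{DataFrame} with columns \code{source}, \code{anchor},
#'   \code{parent} (one row per record).
#' @exportClass CdsSet
setClass("CdsSet",
  slots = c(nt = "DNAStringSet", aa = "AAStringSet", info = "DataFrame"))

setValidity("CdsSet", function(object) {
  n <- length(object@nt)
  msgs <- character()
  if (length(object@aa) != n || nrow(object@info) != n)
    msgs <- c(msgs, "nt, aa and info must have one entry per record")
  if (n > 0) {
    ids <- names(object@nt)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "all records must be named")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate record id: %s",
                              ids[duplicated(ids)][1L]))
    if (!all(c("source", "anchor", "parent") %in% colnames(object@info)))
      msgs <- c(msgs, "info must have columns source, anchor, parent")
    else {
      if (!all(object@info$source %in% c("denovo", "genome", "viral")))
        msgs <- c(msgs, "source must be denovo, genome or viral")
      if (!all(object@info$anchor %in% c("none", "homology", "signal_peptide")))
        msgs <- c(msgs, "anchor must be none, homology or signal_peptide")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CdsSet
#'
#' @param nt \code{DNAStringSet} (named) of coding sequences.
#' @param aa optional \code{AAStringSet} of translations; computed from
#'   \code{nt} when missing.  A terminal stop codon in \code{nt} is allowed
#'   and is not represented in \code{aa}.
#' @param source character vector (recycled) in
#'   \code{c("denovo","genome","viral")}.
#' @param anchor character vector (recycled) in
#'   \code{c("none","homology","signal_peptide")}.
#' @param parent character vector of parent transcript ids (\code{NA} when
#'   not applicable).
#' @return A \code{CdsSet}.
#' @examples
#' nt <- Biostrings::DNAStringSet(c(cds1 = "ATGAAATAA"))
#' CdsSet(nt, source = "denovo")
#' @export
CdsSet <- function(nt, aa = NULL, source = "denovo", anchor = "none",
                   parent = NA_character_) {
  nt <- as(nt, "DNAStringSet")
  n <- length(nt)
  if (is.null(aa)) aa <- translateCds(nt)
  aa <- as(aa, "AAStringSet")
  names(aa) <- names(nt)
  info <- DataFrame(source = rep(source, length.out = n),
                    anchor = rep(anchor, length.out = n),
                    parent = rep(parent, length.out = n),
                    row.names = names(nt))
  new("CdsSet", nt = nt, aa = aa, info = info)
}

#' @describeIn CdsSet number of records
#' @param x,object a \code{CdsSet}
#' @export
setMethod("length", "CdsSet", function(x) length(x@nt))

#' @describeIn CdsSet record ids
#' @export
setMethod("names", "CdsSet", function(x) names(x@nt))

#' @describeIn CdsSet subset records
#' @param i index vector
#' @export
setMethod("[", "CdsSet", function(x, i) {
  new("CdsSet", nt = x@nt[i], aa = x@aa[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "CdsSet", function(object) {
  cat("CdsSet with", length(object), "coding sequences\n")
  if (length(object)) {
    src <- table(object@info$source)
    cat("  sources:",
        paste(sprintf("%s=%d", names(src), as.integer(src)), collapse = ", "),
        "\n")
    anc <- table(object@info$anchor)
    cat("  anchors:",
        paste(sprintf("%s=%d", names(anc), as.integer(anc)), collapse = ", "),
        "\n")
    cat("  nt length range:", paste(range(Biostrings::width(object@nt)),
                                    collapse = "-"), "\n")
  }
})

#' Accessors for CdsSet
#'
#' \code{cdsNt}, \code{cdsAa} and \code{cdsInfo} return the nucleotide
#' sequences, the translations, and the provenance table of a
#' \code{CdsSet}.
#'
#' @param x a \code{CdsSet}
#' @return \code{DNAStringSet}, \code{AAStringSet} or \code{DataFrame}.
#' @name cds-accessors
NULL

#' @rdname cds-accessors
#' @export
cdsNt <- function(x) x@nt

#' @rdname cds-accessors
#' @export
cdsAa <- function(x) x@aa

#' @rdname cds-accessors
#' @export
cdsInfo <- function(x) x@info

#' Lexicon: an ordered functional-annotation vocabulary
#'
#' The lexicon drives the classifier: each entry maps a lowercase phrase to
#' a sialome class (and, for the secreted class, a protein family) with an
#' integer priority that resolves compound phrases.  Entries keep the order
#' of the source file; the classifier ranks matches by priority first and
#' position second.
#'
#' @slot entries \code{DataFrame} with columns \code{term}, \code{class},
#'   \code{family}, \code{priority}.
#' @slot classes character vector of permitted class labels.
#' @slot dbPrecedence character vector of database tags in scan order.
#' @exportClass Lexicon
setClass("Lexicon",
  slots = c(entries = "DataFrame", classes = "character",
            dbPrecedence = "character"))

setValidity("Lexicon", function(object) {
  e <- object@entries
  msgs <- character()
  if (!all(c("term", "class", "family", "priority") %in% colnames(e)))
    msgs <- c(msgs, "entries must have columns term, class, family, priority")
  else {
    if (anyDuplicated(e$term))
      msgs <- c(msgs, sprintf("duplicate lexicon term: %s",
                              e$term[duplicated(e$term)][1L]))
    bad <- setdiff(unique(e$class), object@classes)
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown class in lexicon: %s", bad[1L]))
  }
  if (!length(object@dbPrecedence))
    msgs <- c(msgs, "dbPrecedence must be non-empty")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Lexicon", function(object) {
  cat("Lexicon with", nrow(object@entries), "terms,",
      length(unique(object@entries$class)), "classes in use\n")
  cat("  database precedence:",
      paste(object@dbPrecedence, collapse = " > "), "\n")
})

#' @describeIn Lexicon number of terms
#' @param x a \code{Lexicon}
#' @export
setMethod("length", "Lexicon", function(x) nrow(x@entries))

#' Accessors for Lexicon
#' @param x a \code{Lexicon}
#' @return \code{lexiconEntries}: the entry \code{DataFrame};
#'   \code{lexiconClasses}: the permitted class labels.
#' @name lexicon-accessors
NULL

#' @rdname lexicon-accessors
#' @export
lexiconEntries <- function(x) x@entries

#' @rdname lexicon-accessors
#' @export
lexiconClasses <- function(x) x@classes

#' SialoCounts: transcript read counts with effective lengths
#'
#' A \code{SummarizedExperiment} subclass holding one \code{counts} assay,
#' per-transcript effective lengths in \code{rowData(x)$eff_length} and a
#' \code{condition} column in \code{colData}.
#'
#' @exportClass SialoCounts
setClass("SialoCounts", contains = "SummarizedExperiment")

setValidity("SialoCounts", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msgs <- c(msgs, "counts must be non-negative")
  el <- SummarizedExperiment::rowData(object)$eff_length
  if (is.null(el) || any(!is.finite(el)) || any(el <= 0))
    msgs <- c(msgs, "rowData eff_length must be positive and finite")
  cond <- SummarizedExperiment::colData(object)$condition
  if (is.null(cond) || anyNA(cond))
    msgs <- c(msgs, "colData condition is required")
  else if (any(table(cond) < 1))
    msgs <- c(msgs, "each condition needs at least one sample")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SialoCounts object
#'
#' @param counts numeric matrix of read counts (transcripts x samples) with
#'   dimnames set.
#' @param effLength positive numeric vector of per-transcript effective
#'   lengths (nt), one per row.
#' @param condition character/factor of condition labels, one per column.
#' @return A \code{SialoCounts}.
#' @examples
#' m <- matrix(rpois(8, 20), 4, 2,
#'             dimnames = list(paste0("t", 1:4), c("s1", "s2")))
#' SialoCounts(m, effLength = c(500, 1000, 300, 800),
#'             condition = c("PBS", "infected"))
#' @export
SialoCounts <- function(counts, effLength, condition) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(eff_length = as.numeric(effLength),
                        row.names = rownames(counts)),
    colData = DataFrame(condition = as.character(condition),
                        row.names = colnames(counts)))
  new("SialoCounts", se)
}

#' SialoExpr: TPM expression with per-condition means
#'
#' A \code{SummarizedExperiment} subclass with one \code{tpm} assay, a
#' \code{condition} column in \code{colData} and per-condition mean TPM
#' columns \code{mean_<condition>} in \code{rowData}.
#'
#' @exportClass SialoExpr
setClass("SialoExpr", contains = "SummarizedExperiment")

setValidity("SialoExpr", function(object) {
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'tpm' is required")
  if (is.null(SummarizedExperiment::colData(object)$condition))
    return("colData condition is required")
  TRUE
})

#' Accessors for count and expression containers
#'
#' \code{effLength} returns per-transcript effective lengths,
#' \code{condition} the per-sample condition labels, \code{tpm} the TPM
#' matrix, and \code{condMeans} the per-condition mean-TPM matrix
#' (transcripts x conditions).
#'
#' @param x a \code{SialoCounts} or \code{SialoExpr}
#' @return numeric vector or matrix as described.
#' @name expr-accessors
NULL

#' @rdname expr-accessors
#' @export
effLength <- function(x) SummarizedExperiment::rowData(x)$eff_length

#' @rdname expr-accessors
#' @export
condition <- function(x) SummarizedExperiment::colData(x)$condition

#' @rdname expr-accessors
#' @export
tpm <- function(x) SummarizedExperiment::assay(x, "tpm")

#' @rdname expr-accessors
#' @export
condMeans <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cols <- grep("^mean_", colnames(rd), value = TRUE)
  m <- as.matrix(rd[, cols, drop = FALSE])
  colnames(m) <- sub("^mean_", "", cols)
  rownames(m) <- rownames(x)
  m
}

#' @importFrom BiocGenerics counts
#' @describeIn SialoCounts counts assay accessor
#' @param object a \code{SialoCounts}
#' @export
setMethod("counts", "SialoCounts", function(object)
  SummarizedExperiment::assay(object, "counts"))
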