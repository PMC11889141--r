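#' @importFrom Biostrings readBStringSet writeXStringSet width
#' @importFrom utils read.delim write.table
NULL

.NT_OK <- "ACGTN"
.AA_OK <- "ACDEFGHIKLMNPQRSTVWYX*"

#' Read a FASTA file with strict validation
#'
#' Thin validating layer over \code{Biostrings} FASTA parsing.  Sequences
#' are uppercased on read and, for nucleotide input, \code{U} is mapped to
#' \code{T}.  Duplicate ids, empty sequences and characters outside the
#' declared alphabet (nt: \code{ACGTN}; aa: the 20 standard letters plus
#' \code{X} and \code{*}) are errors.
#'
#' @param path path to a FASTA file.
#' @param kind \code{"nt"} or \code{"aa"}.
#' @return A \code{DNAStringSet} (\code{kind = "nt"}) or \code{AAStringSet}
#'   (\code{kind = "aa"}); names hold the first whitespace-delimited token
#'   of each header, the remainder of the header is kept in the
#'   \code{description} metadata column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GG", "TT"), f)
#' readFasta(f, "nt")
#' @export
readFasta <- function(path, kind = c("nt", "aa")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  hdr <- names(raw)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyNA(ids) || any(ids == ""))
    stop("FASTA header with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(raw))
  if (kind == "nt") seqs <- chartr("U", "T", seqs)
  empty <- which(nchar(seqs) == 0)
  if (length(empty))
    stop("empty sequence under header: ", ids[empty[1L]])
  ok <- if (kind == "nt") .NT_OK else .AA_OK
  bad <- regexpr(sprintf("[^%s]", gsub("\\*", "\\\\*", ok)), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal character '%s' at position %d in record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  out <- if (kind == "nt") DNAStringSet(seqs) else AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x a named \code{XStringSet} (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x))) stop("sequences must be named")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "pident", "align_len", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore", "qlen", "slen", "subject_desc")

#' Read a tabular protein-homology hit table
#'
#' Parses BLAST-style tabular output: the common 12-column layout followed
#' by query length, subject length and the subject title (15 columns in
#' total by default; the order is configurable).  Comment lines starting
#' with \code{#} are skipped.  All alignment coordinates stay 1-based
#' inclusive, the convention of the source format.
#'
#' @param path path to a tab-separated hit table.
#' @param dbTag database tag attached to every row (e.g. \code{"nr"}).
#' @param columns character vector giving the column order; must contain
#'   all of the default names.
#' @return \code{data.frame} with the columns of \code{columns} plus
#'   \code{db_tag}; numeric fields are validated (coordinates ordered,
#'   \code{pident} in [0,100], \code{slen > 0}).
#' @export
readHitTable <- function(path, dbTag, columns = .HIT_COLS) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!setequal(columns, .HIT_COLS))
    stop("columns must be a permutation of the standard hit-table layout")
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(columns)), columns))
    out$db_tag <- character(0)
    return(.coerceHitTypes(out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(columns)))
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 lineno[which(nf != length(columns))[1L]],
                 length(columns), nf[which(nf != length(columns))[1L]]))
  m <- do.call(rbind, parts)
  colnames(m) <- columns
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  num <- c("pident", "align_len", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore", "qlen", "slen")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("line %d: non-numeric value '%s' in column %s",
                   lineno[i], out[[cn]][i], cn))
    }
    out[[cn]] <- v
  }
  out$db_tag <- dbTag
  .validateHitTable(out, lineno)
  .coerceHitTypes(out)
}

.coerceHitTypes <- function(df) {
  df[, c("query_id", "subject_id", "subject_desc", "db_tag", "pident",
         "align_len", "qstart", "qend", "sstart", "send", "evalue",
         "bitscore", "qlen", "slen")]
}

.validateHitTable <- function(df, lineno = seq_len(nrow(df))) {
  bad <- which(df$qstart > df$qend | df$sstart > df$send)
  if (length(bad))
    stop(sprintf("line %d: alignment coordinates out of order", lineno[bad[1L]]))
  bad <- which(df$pident < 0 | df$pident > 100)
  if (length(bad))
    stop(sprintf("line %d: pident outside [0,100]", lineno[bad[1L]]))
  bad <- which(df$slen <= 0)
  if (length(bad))
    stop(sprintf("line %d: non-positive subject length", lineno[bad[1L]]))
  bad <- which(df$evalue < 0)
  if (length(bad))
    stop(sprintf("line %d: negative evalue", lineno[bad[1L]]))
  invisible(df)
}

#' Subject coverage of a hit
#'
#' Fraction of the matching protein covered by the alignment,
#' \code{(send - sstart + 1) / slen}.
#'
#' @param hits hit table as returned by \code{\link{readHitTable}}.
#' @return numeric vector of coverages in [0, 1].
#' @export
subjectCoverage <- function(hits) (hits$send - hits$sstart + 1) / hits$slen

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Hit tables keep the 1-based inclusive convention of the source format;
#' internal sequence coordinates are 0-based half-open.  These helpers are
#' the single conversion point.
#'
#' @param start,end interval in the convention being converted from.
#' @return two-column matrix \code{start}, \code{end} in the target
#'   convention.
#' @name coordinates
NULL

#' @rdname coordinates
#' @export
toHalfOpen <- function(start, end) cbind(start = start - 1L, end = end)

#' @rdname coordinates
#' @export
toOneBased <- function(start, end) cbind(start = start + 1L, end = end)

#' Write the final annotation table
#'
#' Emits a TSV with one row per coding sequence: id, class, family,
#' per-condition mean TPM (1 decimal), logFC (2 decimals), FDR (scientific,
#' 2 significant digits), DE status and one best-hit evidence column per
#' database.  Missing values become empty cells.
#'
#' @param rows \code{data.frame} with columns \code{id}, \code{class},
#'   \code{family}; any \code{tpm_*} columns are formatted as TPM, a
#'   \code{logFC} column as log fold change, an \code{fdr} column as FDR;
#'   remaining columns pass through as text.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTable <- function(rows, path) {
  rows <- as.data.frame(rows)
  need <- c("id", "class", "family")
  if (!all(need %in% colnames(rows)))
    stop("annotation rows need columns: ", paste(need, collapse = ", "))
  out <- rows
  for (cn in colnames(out)) {
    v <- out[[cn]]
    if (startsWith(cn, "tpm_") && is.numeric(v)) {
      out[[cn]] <- ifelse(is.na(v), "", sprintf("%.1f", v))
    } else if (cn == "logFC" && is.numeric(v)) {
      out[[cn]] <- ifelse(is.na(v), "", sprintf("%.2f", v))
    } else if (cn == "fdr" && is.numeric(v)) {
      out[[cn]] <- ifelse(is.na(v), "", sprintf("%.1e", v))
    } else {
      v <- as.character(v)
      out[[cn]] <- ifelse(is.na(v), "", v)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read back an annotation table written by \code{writeAnnotationTable}
#'
#' @param path path to the TSV.
#' @return \code{data.frame}; formatted numeric columns come back numeric,
#'   empty cells as \code{NA}.
#' @export
readAnnotationTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", check.names = FALSE,
                          colClasses = "character")
  for (cn in colnames(df)) {
    if (startsWith(cn, "tpm_") || cn %in% c("logFC", "fdr")) {
      df[[cn]] <- as.numeric(df[[cn]])
    }
  }
  df
}

#' Pipeline configuration
#'
#' Bundles the numeric cut-offs used across the pipeline: the minimum ORF
#' length in nt, the minimum length (aa) for signal-peptide screening, the
#' minimum subject coverage for homology-based CDS extraction, the
#' consolidation identity threshold, the TPM detection floor, the |logFC|
#' and FDR thresholds of the differential expression calls, and the
#' database precedence of the classifier.
#'
#' @param min_orf_nt minimum ORF length in nucleotides (default 150).
#' @param min_sp_aa minimum protein length screened for a signal peptide
#'   (default 40).
#' @param min_subject_cov minimum fraction of the matching protein covered
#'   (default 0.70).
#' @param dedup_identity consolidation identity threshold in (0, 1]
#'   (default 0.95).
#' @param tpm_min TPM detection floor (default 3).
#' @param lfc_thresh |logFC| threshold for DE calls (default 2).
#' @param fdr_thresh FDR threshold for DE calls (default 0.05).
#' @param db_precedence ordered character vector of database tags.
#' @param seed integer seed for stochastic steps.
#' @return a validated list of class \code{"sialo_config"}.
#' @export
pipelineConfig <- function(min_orf_nt = 150, min_sp_aa = 40,
                           min_subject_cov = 0.70, dedup_identity = 0.95,
                           tpm_min = 3, lfc_thresh = 2, fdr_thresh = 0.05,
                           db_precedence = c("nr", "refseq", "cdd"),
                           seed = 1L) {
  cfg <- list(min_orf_nt = min_orf_nt, min_sp_aa = min_sp_aa,
              min_subject_cov = min_subject_cov,
              dedup_identity = dedup_identity, tpm_min = tpm_min,
              lfc_thresh = lfc_thresh, fdr_thresh = fdr_thresh,
              db_precedence = db_precedence, seed = as.integer(seed))
  num <- c("min_orf_nt", "min_sp_aa", "min_subject_cov", "dedup_identity",
           "tpm_min", "lfc_thresh", "fdr_thresh")
  for (cn in num)
    if (!is.numeric(cfg[[cn]]) || length(cfg[[cn]]) != 1 || cfg[[cn]] <= 0)
      stop(cn, " must be a single positive number")
  if (cfg$dedup_identity > 1) stop("dedup_identity must lie in (0, 1]")
  if (!length(cfg$db_precedence)) stop("db_precedence must be non-empty")
  class(cfg) <- "sialo_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys missing from the file fall back to \code{\link{pipelineConfig}}
#' defaults; unknown keys are an error.
#'
#' @param path path to a YAML key-value file.
#' @return a \code{"sialo_config"} list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config key: ", extra[1L])
  do.call(pipelineConfig, raw)
}
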