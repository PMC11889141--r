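# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0)

.CHARGE <- c(K = 1, R = 1, D = -1, E = -1)
.SMALL_RES <- c("A", "G", "S", "C", "T")
.CHARGED_AROMATIC <- c("D", "E", "K", "R", "H", "F", "W", "Y")

#' Heuristic signal-peptide prediction
#'
#' A transparent rule-based caller for classical N-terminal signal
#' peptides, testing the three textbook features: (i) a non-negative net
#' charge over residues 1-5 (n-region), (ii) a hydrophobic core - some
#' 7-residue window within residues 3-20 with mean Kyte-Doolittle
#' hydropathy of at least \code{hThreshold} (h-region), and (iii) a
#' von Heijne-style (-3, -1) cleavage site: a small residue (A, G, S, C, T)
#' at a 0-based position \code{p} in [12, 35) with no charged or aromatic
#' residue at \code{p - 2}.  The reported cleavage position is the smallest
#' qualifying \code{p}.  External predictor output can be swapped in
#' through \code{\link{parseExternalSpTable}}.
#'
#' @param aaSeq amino-acid sequence starting with methionine.
#' @param hThreshold hydropathy threshold for the core window (default
#'   2.4, calibrated so that template-built signal peptides are recovered
#'   while scrambled N-termini are rejected).
#' @param windowSize width of the hydropathy window (default 7).
#' @return list with elements \code{has_sp}, \code{cleavage_pos} (0-based;
#'   \code{NA} on a negative call), \code{n_charge}, \code{max_h_window},
#'   \code{site_ok} and \code{too_short}.
#' @examples
#' predictSignalPeptide(paste0("MKFLVLLALVALSAAQA",
#'                             strrep("N", 30)))
#' @export
predictSignalPeptide <- function(aaSeq, hThreshold = 2.4, windowSize = 7L) {
  res <- strsplit(toupper(aaSeq), "")[[1]]
  L <- length(res)
  neg <- list(has_sp = FALSE, cleavage_pos = NA_integer_,
              n_charge = NA_real_, max_h_window = NA_real_,
              site_ok = FALSE, too_short = FALSE)
  if (L < 15) {
    neg$too_short <- TRUE
    return(neg)
  }
  kd <- unname(.KD[res])
  kd[is.na(kd)] <- 0
  charge <- sum(.CHARGE[res[1:5]], na.rm = TRUE)
  # windows fully inside residues 3..20 (1-based)
  lo <- 3L
  hi <- min(20L, L)
  maxH <- -Inf
  if (hi - lo + 1L >= windowSize) {
    for (s in lo:(hi - windowSize + 1L))
      maxH <- max(maxH, mean(kd[s:(s + windowSize - 1L)]))
  }
  cleave <- NA_integer_
  pMax <- min(34L, L - 1L)
  if (pMax >= 12L) {
    for (p in 12:pMax) {
      r1 <- res[p + 1L]          # residue at 0-based offset p
      r3 <- res[p - 1L]          # residue at 0-based offset p - 2
      if (r1 %in% .SMALL_RES && !(r3 %in% .CHARGED_AROMATIC)) {
        cleave <- p
        break
      }
    }
  }
  neg$n_charge <- charge
  neg$max_h_window <- maxH
  neg$site_ok <- !is.na(cleave)
  if (charge >= 0 && maxH >= hThreshold && !is.na(cleave)) {
    neg$has_sp <- TRUE
    neg$cleavage_pos <- cleave
  }
  neg
}

#' Predict signal peptides for a set of proteins
#'
#' Vectorized wrapper around \code{\link{predictSignalPeptide}}.
#'
#' @param aa named \code{AAStringSet} or named character vector.
#' @param ... passed to \code{\link{predictSignalPeptide}}.
#' @return \code{data.frame} with one row per sequence: \code{query_id},
#'   \code{has_sp}, \code{cleavage_pos}, \code{n_charge},
#'   \code{max_h_window}, \code{site_ok}, \code{too_short}.
#' @export
predictSignalPeptides <- function(aa, ...) {
  nms <- names(aa)
  seqs <- stats::setNames(as.character(aa), nms)
  if (is.null(nms)) stop("sequences must be named")
  calls <- lapply(seqs, predictSignalPeptide, ...)
  data.frame(
    query_id = names(seqs),
    has_sp = vapply(calls, `[[`, TRUE, "has_sp"),
    cleavage_pos = vapply(calls, `[[`, NA_integer_, "cleavage_pos"),
    n_charge = vapply(calls, `[[`, NA_real_, "n_charge"),
    max_h_window = vapply(calls, `[[`, NA_real_, "max_h_window"),
    site_ok = vapply(calls, `[[`, TRUE, "site_ok"),
    too_short = vapply(calls, `[[`, TRUE, "too_short"),
    row.names = NULL)
}

#' Import external signal-peptide predictions
#'
#' Reads a TSV with columns id, decision (\code{Y}/\code{N}) and cleavage
#' position (1-based between-residue index, \code{-} when absent) and
#' converts it to the internal convention (0-based), so that external
#' predictor output can replace the built-in heuristic.
#'
#' @param path path to the TSV (no header).
#' @return \code{data.frame} with columns \code{query_id}, \code{has_sp},
#'   \code{cleavage_pos}.
#' @export
parseExternalSpTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines))
    return(data.frame(query_id = character(0), has_sp = logical(0),
                      cleavage_pos = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("expected 3 tab-separated fields (id, decision, cleavage)")
  m <- do.call(rbind, parts)
  dec <- m[, 2]
  if (!all(dec %in% c("Y", "N")))
    stop("unknown decision token: ", setdiff(dec, c("Y", "N"))[1L])
  hasSp <- dec == "Y"
  pos <- rep(NA_integer_, length(hasSp))
  pos[hasSp] <- as.integer(m[hasSp, 3]) - 1L
  if (anyNA(pos[hasSp]))
    stop("positive call without a numeric cleavage position")
  data.frame(query_id = m[, 1], has_sp = hasSp, cleavage_pos = pos)
}
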