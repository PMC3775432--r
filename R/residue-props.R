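#' Amino-acid property table
#'
#' Loads the bundled (or a user-supplied) residue property table: one row per
#' canonical residue with its hydropathy value, side-chain pKa and the sign of
#' the charged form of the side chain. The bundled default is the
#' Kyte-Doolittle hydropathy scale (positive = hydrophobic) together with
#' standard side-chain pKa values (D 3.9, E 4.1, H 6.0, C 8.4, K 10.5, Y 10.5,
#' R 12.5).
#'
#' A replacement scale can be supplied as a tab-separated file with columns
#' \code{code}, \code{h}, \code{pka_side}, \code{charge_sign}; it must contain
#' exactly the 20 canonical residues.
#'
#' @param file Path to a property table, or \code{NULL} for the bundled table.
#' @return A data.frame with columns \code{code}, \code{h}, \code{pka_side},
#'   \code{charge_sign}, row names set to the one-letter codes.
#' @export
#' @examples
#' props <- aa_properties()
#' props["W", "h"]
aa_properties <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "aa_properties.tsv", package = "driftfold",
                        mustWork = TRUE)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "h", "pka_side", "charge_sign")
  if (!all(need %in% names(tab)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$code))
    stop("property table must contain exactly the 20 canonical residues")
  if (any(tab$charge_sign == 0 & !is.na(tab$pka_side)))
    stop("charge_sign 0 entries must have pka_side NA")
  rownames(tab) <- tab$code
  tab
}

#' Fractional side-chain charge at a given pH
#'
#' Henderson-Hasselbalch titration of the side chain. Acids (charge_sign -1)
#' carry \eqn{-1/(1 + 10^{pKa - pH})}, approaching -1 above their pKa; bases
#' (charge_sign +1) carry \eqn{+1/(1 + 10^{pH - pKa})}, approaching +1 below
#' their pKa. Residues without a titratable side chain return 0 at every pH.
#' Backbone/terminal ionisation is not modelled.
#'
#' @param code One-letter residue code(s).
#' @param pH Ambient pH, a single value in (0, 14).
#' @param props Property table from [aa_properties()].
#' @return Numeric vector of charges in elementary-charge units, in [-1, 1].
#' @export
#' @examples
#' charge_at_pH("D", 7)   # ~ -0.999
#' charge_at_pH("H", 6)   # exactly +0.5 at its pKa
charge_at_pH <- function(code, pH, props = aa_properties()) {
  if (!is.numeric(pH) || length(pH) != 1L || is.na(pH) || pH <= 0 || pH >= 14)
    stop("pH must be a single value strictly between 0 and 14")
  bad <- setdiff(code, props$code)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  sgn <- props[code, "charge_sign"]
  pka <- props[code, "pka_side"]
  q <- numeric(length(code))
  acid <- !is.na(pka) & sgn < 0
  base <- !is.na(pka) & sgn > 0
  q[acid] <- -1 / (1 + 10^(pka[acid] - pH))
  q[base] <- 1 / (1 + 10^(pH - pka[base]))
  unname(q)
}

#' Binary hydropathy classification
#'
#' A residue is classified hydrophobic when its hydropathy value exceeds the
#' threshold, hydrophilic otherwise (the boundary value is hydrophilic). The
#' default threshold of -3.3 on the Kyte-Doolittle scale makes exactly the
#' strongly polar residues (R, K, N, D, Q, E) hydrophilic; these are the
#' residues that open and close secondary-structure scan brackets. See the
#' package vignette for why this separation, rather than the sign of h, is the
#' operative one for the scan rules under a titration charge model.
#'
#' @param h Hydropathy value(s), same scale as the property table in use.
#' @param threshold Classification threshold (scale units).
#' @return Character vector, "hydrophobic" or "hydrophilic".
#' @export
classify_hydropathy <- function(h, threshold = -3.3) {
  if (!all(is.finite(h))) stop("h must be finite")
  ifelse(h > threshold, "hydrophobic", "hydrophilic")
}

#' Annotate a sequence with charge, hydropathy and class
#'
#' Builds the per-residue annotation consumed by the secondary-structure scan
#' and the force field: fractional side-chain charge at the ambient pH,
#' hydropathy value from the property table, and the binary
#' hydrophobic/hydrophilic class.
#'
#' @param seq Either a single string ("MKVL...") or a character vector of
#'   one-letter codes. Non-canonical letters are an error, never skipped.
#' @param pH Ambient pH.
#' @param props Property table from [aa_properties()].
#' @param threshold Hydropathy classification threshold, see
#'   [classify_hydropathy()].
#' @return An object of class \code{annotated_seq}: a list with elements
#'   \code{residues}, \code{q}, \code{h}, \code{hydropathy}, \code{pH},
#'   \code{threshold}.
#' @export
#' @examples
#' a <- annotate_sequence("NDKHA", pH = 7)
#' round(a$q, 3)
annotate_sequence <- function(seq, pH = 7, props = aa_properties(),
                              threshold = -3.3) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  seq <- toupper(as.character(seq))
  if (length(seq) == 0L || any(!nzchar(seq)))
    stop("sequence must be non-empty")
  bad <- setdiff(seq, props$code)
  if (length(bad))
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "))
  h <- unname(props[seq, "h"])
  out <- list(residues = seq,
              q = charge_at_pH(seq, pH, props),
              h = h,
              hydropathy = classify_hydropathy(h, threshold),
              pH = pH,
              threshold = threshold)
  class(out) <- "annotated_seq"
  out
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat("annotated_seq:", length(x$residues), "residues at pH", x$pH, "\n")
  cat(" ", paste(x$residues, collapse = ""), "\n")
  cat("  net charge:", round(sum(x$q), 3), "e;",
      sum(x$hydropathy == "hydrophilic"), "hydrophilic\n")
  invisible(x)
}

#' @export
length.annotated_seq <- function(x) length(x$residues)
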