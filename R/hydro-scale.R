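#' Intrinsic hydrophobicity scales
#'
#' The observed distribution weighs each residue pair by the sum of the two
#' residues' intrinsic hydrophobicities H^r. The scale is a mapping from
#' 3-letter amino-acid code to a non-negative value; any two-column text file
#' (`AAA value`, whitespace-delimited, `#` comments) can be used. The default
#' shipped with the package is the Kyte-Doolittle hydropathy index min-max
#' normalized to [0, 1], so that the most hydrophilic residue (Arg) maps to 0
#' and the most hydrophobic (Ile) to 1. Because the observed distribution is
#' normalized, multiplying a scale by a positive constant leaves it unchanged;
#' only the relative spacing of H^r values matters.
#'
#' @param path path to a two-column scale file.
#' @return named numeric vector mapping 3-letter codes to H^r values.
#' @examples
#' sc <- defaultHydroScale()
#' sc[["ILE"]]   # 1: most hydrophobic under Kyte-Doolittle
#' @export
loadHydroScale <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("resid", "value"))
  if (nrow(tab) == 0L) stop("hydrophobicity scale file is empty: ", path)
  vals <- as.numeric(tab$value)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("hydrophobicity values must be finite and non-negative")
  scale <- stats::setNames(vals, toupper(tab$resid))
  if (anyDuplicated(names(scale)))
    stop("duplicated residue codes in scale file: ",
         paste(unique(names(scale)[duplicated(names(scale))]), collapse = ", "))
  standard <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL")
  missing <- setdiff(standard, names(scale))
  if (length(missing))
    stop("scale does not cover the 20 standard amino acids; missing: ",
         paste(missing, collapse = ", "))
  scale
}

#' @rdname loadHydroScale
#' @export
defaultHydroScale <- function() {
  loadHydroScale(system.file("extdata", "kyte_doolittle_normalized.tsv",
                             package = "fodm", mustWork = TRUE))
}
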