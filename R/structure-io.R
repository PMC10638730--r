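#' Build an effective-atom chain from coordinates
#'
#' Low-level constructor used by the structure reader and the synthetic
#' generator. One coordinate row per residue, in sequence order.
#'
#' @param coords numeric matrix or data.frame with columns x, y, z (Angstrom).
#' @param resid 3-letter amino-acid codes (recycled "ALA" if missing).
#' @param resno residue numbers (default 1..N).
#' @param chain chain identifier (single id, recycled).
#' @param insert insertion codes (default none).
#' @return an [EffectiveAtomChain].
#' @export
effectiveAtomChain <- function(coords, resid = NULL, resno = NULL,
                               chain = "A", insert = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(resid)) resid <- rep("ALA", n)
  if (is.null(resno)) resno <- seq_len(n)
  residues <- data.frame(chain = rep_len(as.character(chain), n),
                         resno = as.integer(resno),
                         insert = rep_len(as.character(insert), n),
                         resid = toupper(as.character(resid)),
                         stringsAsFactors = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("EffectiveAtomChain", residues = residues, coords = coords)
}

#' Parse a residue-range specification
#'
#' Range specs select domains by residue number, e.g. `"115-130,152-228"`:
#' comma-separated, 1-based, inclusive ranges (single numbers allowed). The
#' empty string selects nothing explicitly and is interpreted downstream as
#' the whole chain.
#'
#' @param spec character range specification.
#' @return sorted integer vector of residue numbers (empty for `""`).
#' @examples
#' length(parseRangeSpec("115-130,152-228"))  # 93
#' parseRangeSpec("")                          # integer(0)
#' @export
parseRangeSpec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L)
    stop("range spec must be a single character string")
  spec <- trimws(spec)
  if (!nzchar(spec)) return(integer(0))
  out <- integer(0)
  for (token in trimws(strsplit(spec, ",", fixed = TRUE)[[1]])) {
    if (grepl("^[0-9]+$", token)) {
      out <- c(out, as.integer(token))
    } else if (grepl("^[0-9]+-[0-9]+$", token)) {
      ab <- as.integer(strsplit(token, "-", fixed = TRUE)[[1]])
      if (ab[1] > ab[2])
        stop("reversed range in spec: '", token, "'")
      out <- c(out, seq.int(ab[1], ab[2]))
    } else {
      stop("malformed range token: '", token, "'")
    }
  }
  sort(unique(out))
}

# element symbol per atom; falls back to the first letter of the atom name
# (leading digits stripped) when the element column is blank
.atomElement <- function(atom) {
  ele <- toupper(trimws(as.character(atom$elesy)))
  blank <- is.na(ele) | !nzchar(ele)
  if (any(blank)) {
    nm <- sub("^[0-9]*", "", trimws(as.character(atom$elety[blank])))
    ele[blank] <- toupper(substr(nm, 1L, 1L))
  }
  ele
}

#' Read a structure and reduce it to effective atoms
#'
#' Parses a PDB or mmCIF file, selects one chain (optionally restricted to a
#' residue-number range spec), and collapses every residue to the unweighted
#' mean of its heavy (non-hydrogen) atom coordinates. HETATM records (waters,
#' ligands) are excluded; alternate locations are resolved to the highest
#' occupancy (ties: first in file order); residues left with no heavy atom
#' are skipped with a warning.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain chain identifier to extract.
#' @param ranges range spec string (see [parseRangeSpec]); `""` = whole chain.
#' @return an [EffectiveAtomChain].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' ch <- synthChain(synthSpec(nResidues = 20, seed = 1))
#' writeChainPDB(ch, pdb)
#' loadStructure(pdb, chain = "A")
#' @export
loadStructure <- function(path, chain = "A", ranges = "") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  atom <- pdb$atom
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  atom$chain[is.na(atom$chain)] <- ""
  if (!chain %in% atom$chain)
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(atom$chain)), collapse = ", "))
  atom <- atom[atom$chain == chain, , drop = FALSE]

  keep <- parseRangeSpec(ranges)
  if (length(keep)) atom <- atom[atom$resno %in% keep, , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("empty selection: no residues of chain '", chain,
         "' match ranges '", ranges, "'")

  # resolve altlocs: highest occupancy wins, ties keep file order
  occ <- atom$o
  occ[is.na(occ)] <- 1
  atom <- atom[order(-occ), , drop = FALSE]
  akey <- paste(atom$resno, atom$insert, atom$elety, sep = "|")
  atom <- atom[!duplicated(akey), , drop = FALSE]
  atom <- atom[order(as.integer(rownames(atom))), , drop = FALSE]

  rkey <- paste(atom$resno, atom$insert, sep = "|")
  allRes <- unique(rkey)
  heavy <- !(.atomElement(atom) %in% c("H", "D"))
  dropped <- setdiff(allRes, unique(rkey[heavy]))
  if (length(dropped))
    warning("skipping ", length(dropped),
            " residue(s) with no heavy atoms: ",
            paste(sub("\\|", "", dropped), collapse = ", "))
  atom <- atom[heavy, , drop = FALSE]
  rkey <- rkey[heavy]

  ord <- unique(rkey)  # file order follows sequence order
  idx <- split(seq_len(nrow(atom)), factor(rkey, levels = ord))
  coords <- t(vapply(idx, function(i)
    colMeans(atom[i, c("x", "y", "z"), drop = FALSE]), numeric(3)))
  first <- vapply(idx, `[`, integer(1), 1L)
  ins <- as.character(atom$insert[first])
  ins[is.na(ins)] <- ""
  effectiveAtomChain(coords,
                     resid = atom$resid[first],
                     resno = atom$resno[first],
                     chain = chain,
                     insert = ins)
}

#' Orient a chain on its principal axes
#'
#' Centres the effective-atom cloud at the origin and rotates it so the
#' principal axes of the point cloud coincide with the coordinate axes, the
#' largest-variance axis on x. The axis-sign ambiguity is resolved by forcing
#' the point with the largest absolute coordinate on each axis to be positive,
#' which makes the transform deterministic. Pairwise distances are preserved
#' to numerical precision, so the observed distribution is unaffected.
#'
#' @param chain an [EffectiveAtomChain].
#' @return the oriented [EffectiveAtomChain].
#' @export
orientChain <- function(chain) {
  stopifnot(is(chain, "EffectiveAtomChain"))
  x <- chain@coords
  centered <- sweep(x, 2L, colMeans(x))
  if (max(abs(centered)) < 1e-9)
    stop("degenerate geometry: all effective atoms coincide")
  cv <- crossprod(centered) / nrow(centered)
  ev <- eigen(cv, symmetric = TRUE)   # eigenvalues in decreasing order
  rot <- centered %*% ev$vectors
  for (ax in 1:3) {
    i <- which.max(abs(rot[, ax]))
    if (rot[i, ax] < 0) rot[, ax] <- -rot[, ax]
  }
  out <- chain
  dimnames(rot) <- list(NULL, c("x", "y", "z"))
  out@coords <- rot
  out
}

#' Estimate the Gaussian envelope of an oriented chain
#'
#' The per-axis standard deviation is taken as the maximum absolute coordinate
#' along that axis divided by `divisor` (default 3), so the whole molecule
#' lies within the 3-sigma support of the Gaussian. Sigmas below `floorSigma`
#' (default 0.5 Angstrom) are raised to the floor, which keeps flat or
#' single-point clouds well-defined.
#'
#' @param oriented an oriented [EffectiveAtomChain] (centroid at the origin).
#' @param divisor positive divisor of the maximal extent.
#' @param floorSigma minimal sigma in Angstrom.
#' @return a [GaussianEnvelope] centred at the origin.
#' @export
estimateEnvelope <- function(oriented, divisor = 3, floorSigma = 0.5) {
  stopifnot(is(oriented, "EffectiveAtomChain"))
  if (!(is.numeric(divisor) && length(divisor) == 1L && divisor > 0))
    stop("divisor must be a positive number")
  ext <- unname(apply(abs(oriented@coords), 2L, max))
  new("GaussianEnvelope", center = c(0, 0, 0),
      sigmas = pmax(ext / divisor, floorSigma))
}
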