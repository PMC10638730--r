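# shared fixtures: everything is built in code at test time

# one fixed-width PDB ATOM/HETATM record
pdbLine <- function(type = "ATOM", eleno, name, resid, chain, resno,
                    x, y, z, occ = 1.00, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1L, 1L)
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, name4, alt, resid, chain, resno, x, y, z, occ, 0, element)
}

writePdbFixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# random strictly-positive normalized profile
randomProfile <- function(n) {
  v <- stats::runif(n, 0.05, 1)
  v / sum(v)
}

# random non-uniform theoretical-like profile (Gaussian evaluated at random points)
randomTProfile <- function(n) {
  p <- synthProfiles(synthSpec(nResidues = n, mode = "micelle",
                               seed = sample.int(1e6, 1)))
  profileValues(p$t)
}

# random proper rotation matrix
randomRotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3))) -> q
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# definition-based Pearson oracle, independent of stats::cor
pearsonOracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force KL / RD oracle
klOracle <- function(p, q) sum(p * log2(p / q))
rdOracle <- function(o, t) {
  r <- rep(1 / length(o), length(o))
  klOracle(o, t) / (klOracle(o, t) + klOracle(o, r))
}
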