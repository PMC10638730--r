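test_that("theoretical profile is the normalized Gaussian at effective atoms", {
  env3 <- new("GaussianEnvelope", center = c(0, 0, 0), sigmas = c(3, 3, 3))

  one <- effectiveAtomChain(matrix(c(4, -2, 1), 1))
  expect_equal(profileValues(theoreticalProfile(one, env3)), 1.0)

  mirror <- effectiveAtomChain(rbind(c(2, 1, -3), c(-2, -1, 3)))
  expect_equal(profileValues(theoreticalProfile(mirror, env3)), c(0.5, 0.5))

  tri <- effectiveAtomChain(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  expect_equal(profileValues(theoreticalProfile(tri, env3)),
               c(0.4519, 0.2741, 0.2741), tolerance = 1e-4)

  expect_s4_class(theoreticalProfile(tri, env3), "HydroProfile")
  expect_equal(profileRole(theoreticalProfile(tri, env3)), "T")
})

test_that("observed profile follows the pairwise interaction law", {
  # single residue: self-term only
  one <- effectiveAtomChain(matrix(0, 1, 3), resid = "ILE")
  expect_equal(profileValues(observedProfile(one)), 1.0)

  # all residues beyond the cutoff: O reduces to normalized intrinsic values
  far <- effectiveAtomChain(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0)),
                            resid = c("ILE", "GLY", "ALA"))
  sc <- defaultHydroScale()
  h <- unname(sc[c("ILE", "GLY", "ALA")])
  expect_equal(profileValues(observedProfile(far)), h / sum(h), tolerance = 1e-12)

  # two residues H = (1, 0) separated by c/2: frozen independent evaluation
  pairScale <- c(ALA = 1, GLY = 0)
  two <- effectiveAtomChain(rbind(c(0, 0, 0), c(4.5, 0, 0)),
                            resid = c("ALA", "GLY"))
  # raw = (2 + w, w) with w = 0.36914; normalized by independent evaluation
  expect_equal(profileValues(observedProfile(two, scale = pairScale, cutoff = 9)),
               c(0.865193, 0.134807), tolerance = 1e-5)
  # without the self pair both residues carry the same single interaction term
  expect_equal(profileValues(observedProfile(two, scale = pairScale, cutoff = 9,
                                             includeSelf = FALSE)),
               c(0.5, 0.5), tolerance = 1e-12)

  expect_error(observedProfile(two, scale = c(ALA = 1)), "absent")
})

test_that("observed profile is rigid-motion invariant and scale-multiplication invariant", {
  set.seed(7)
  ch <- synthChain(synthSpec(nResidues = 40, mode = "micelle", seed = 11))
  o1 <- profileValues(observedProfile(ch))
  moved <- effectiveAtomChain(chainCoords(ch) %*% randomRotation() + 5,
                              resid = residueTable(ch)$resid)
  expect_equal(profileValues(observedProfile(moved)), o1, tolerance = 1e-9)

  sc <- defaultHydroScale()
  expect_equal(profileValues(observedProfile(ch, scale = sc * 7.3)), o1,
               tolerance = 1e-12)
})

test_that("uniform reference is 1/N and rejects empty chains", {
  expect_equal(profileValues(uniformProfile(4)), rep(0.25, 4))
  expect_equal(profileValues(uniformProfile(1)), 1.0)
  expect_equal(sum(profileValues(uniformProfile(137))), 1.0)
  expect_error(uniformProfile(0), "at least 1")
})

test_that("divergence entropy matches hand evaluation and is a proper divergence", {
  expect_equal(klDivergence(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)), 0.736966, tolerance = 1e-5)
  expect_error(klDivergence(c(0.5, 0.5), c(1, 0, 0)), "lengths")

  set.seed(1)
  for (i in 1:25) {
    p <- randomProfile(12); q <- randomProfile(12)
    expect_gte(klDivergence(p, q), 0)
  }
  # identity of indiscernibles within clamping tolerance
  p <- randomProfile(8)
  expect_lt(klDivergence(p, p + 0), 1e-12)
  q <- p; q[1] <- q[1] + 0.01; q <- q / sum(q)
  expect_gt(klDivergence(p, q), 0)
})

test_that("relative distance spans [0, 1] with the expected endpoints", {
  t <- c(0.5, 0.3, 0.2); r <- rep(1/3, 3)
  expect_equal(rd(relativeDistance(t, t, r)), 0)
  expect_equal(rd(relativeDistance(r, t, r)), 1)
  expect_equal(rd(relativeDistance(c(0.40, 0.35, 0.25), t, r)), 0.531,
               tolerance = 1e-3)
  # against the brute-force oracle at high precision
  expect_equal(rd(relativeDistance(c(0.40, 0.35, 0.25), t, r)),
               rdOracle(c(0.40, 0.35, 0.25), t), tolerance = 1e-9)
  expect_error(relativeDistance(r, r, r), "undefined RD")

  set.seed(2)
  for (i in 1:20) {
    o <- randomProfile(15); tt <- randomProfile(15)
    val <- rd(relativeDistance(o, tt, uniformProfile(15)))
    expect_gte(val, 0); expect_lte(val, 1)
  }
})

test_that("RD is non-decreasing along the T-to-R mixing path", {
  set.seed(3)
  for (rep in 1:5) {
    t <- randomTProfile(40)
    r <- rep(1 / 40, 40)
    lambdas <- seq(0.02, 1, by = 0.02)
    rds <- vapply(lambdas, function(l)
      rd(relativeDistance((1 - l) * t + l * r, t, r)), numeric(1))
    expect_true(all(diff(rds) >= -1e-9))
  }
})

test_that("profiles carry residue labels aligned with the chain", {
  ch <- synthChain(synthSpec(nResidues = 10, seed = 5))
  a <- fodAnalysis(ch)
  expect_identical(profileLabels(a@tProfile), profileLabels(a@oProfile))
  expect_length(profileLabels(a@tProfile), 10L)
  tab <- profileTable(a)
  expect_named(tab, c("residue_number", "aa", "T", "O", "R", "M", "T_minus_O"))
  expect_equal(tab$T - tab$O, tab$T_minus_O)
})
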