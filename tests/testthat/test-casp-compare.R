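test_that("self-comparison yields zero deltas and no machinery asymmetry", {
  ch <- synthChain(synthSpec(nResidues = 60, mode = "micelle", seed = 21))
  rep1 <- compareStructures(ch, ch)
  expect_equal(rep1@deltaRd, 0)
  expect_equal(rep1@deltaK, 0)
  expect_equal(rep1@diffTrack$diff, rep(0, 60))

  # swapping target and model negates the deltas
  other <- synthChain(synthSpec(nResidues = 60, mode = "inverted", seed = 21))
  ab <- compareStructures(ch, other)
  ba <- compareStructures(other, ch)
  expect_equal(ab@deltaRd, -ba@deltaRd, tolerance = 1e-12)
  expect_equal(ab@deltaK, -ba@deltaK, tolerance = 1e-12)
})

test_that("micelle-like target vs membrane-like model shows positive RD and K deltas", {
  target <- synthChain(synthSpec(nResidues = 80, mode = "micelle", seed = 31))
  model <- synthChain(synthSpec(nResidues = 80, mode = "inverted", seed = 31))
  repAB <- compareStructures(target, model)
  expect_gt(repAB@deltaRd, 0)
  expect_gt(repAB@deltaK, 0)
  expect_true(all(c("start", "end", "length") %in% names(repAB@discordant)))
  if (nrow(repAB@discordant) > 0)
    expect_true(all(repAB@discordant$length >= 3))
})

test_that("residue pairing uses numbering intersection with a coverage floor", {
  ch <- synthChain(synthSpec(nResidues = 50, mode = "micelle", seed = 41))
  # model truncated to 60% of the target numbering
  short <- effectiveAtomChain(chainCoords(ch)[1:30, ],
                              resid = residueTable(ch)$resid[1:30],
                              resno = residueTable(ch)$resno[1:30])
  expect_error(compareStructures(ch, short), "alignment failure")

  # 90% coverage passes and analyses run on the intersection
  most <- effectiveAtomChain(chainCoords(ch)[1:45, ],
                             resid = residueTable(ch)$resid[1:45],
                             resno = residueTable(ch)$resno[1:45])
  repOK <- compareStructures(ch, most)
  expect_equal(length(repOK@target@chain), 45L)
  expect_equal(repOK@deltaRd, 0, tolerance = 1e-9)  # same coords on the overlap
})

test_that("RD / GDT_TS correlation matches the definition-based oracle", {
  rec <- data.frame(rd = c(0.2, 0.4, 0.6, 0.8),
                    gdt_ts = c(90, 70, 50, 30))
  expect_equal(correlateRdGdt(rec), -1.0)

  rec2 <- data.frame(rd = c(0.31, 0.55, 0.48, 0.72),
                     gdt_ts = c(81.2, 44.0, 63.3, 39.9))
  expect_equal(correlateRdGdt(rec2),
               pearsonOracle(rec2$rd, rec2$gdt_ts), tolerance = 1e-9)

  # Pearson is invariant under affine rescaling of either variable
  rec3 <- transform(rec2, rd = 3 * rd + 0.1, gdt_ts = 0.5 * gdt_ts - 2)
  expect_equal(correlateRdGdt(rec3), correlateRdGdt(rec2), tolerance = 1e-12)

  expect_error(correlateRdGdt(data.frame(rd = c(0.5, 0.5, 0.5),
                                         gdt_ts = c(1, 2, 3))), "zero variance")
  expect_error(correlateRdGdt(rec2[1:2, ]), "at least 3")
  expect_type(correlateRdGdt(rec2, method = "spearman"), "double")
})

test_that("RD binning is half-open with a closed final bin and conserves counts", {
  counts <- binByRd(c(0.05, 0.15, 0.15))
  expect_equal(unname(counts[1:3]), c(1L, 2L, 0L))
  expect_equal(sum(counts), 3L)

  expect_equal(unname(binByRd(1.0)[10]), 1L)     # boundary: 1.0 in final bin
  expect_equal(unname(binByRd(0.1)[2]), 1L)      # interior edges round up

  set.seed(9)
  u <- runif(1000)
  expect_equal(sum(binByRd(u)), 1000L)

  expect_error(binByRd(c(0.5), width = 0), "positive")
  expect_error(binByRd(c(1.2)), "\\[0, 1\\]")
})

test_that("scores tables parse with validation of the GDT_TS range", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("target\tmodel\tgdt_ts",
               "T0990-D3\tT0990TS001-1\t48.71",
               "",
               "T1024\tT1024TS043-1\t63.30",
               "T0953s2-D3\tT0953s2TS368-D3\t43.01"), path)
  tab <- readScoresTable(path)
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("target", "model", "gdt_ts"))
  expect_equal(tab$gdt_ts[1], 48.71)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("target\tmodel\tgdt_ts", "T1\tM1\t101"), bad)
  expect_error(readScoresTable(bad), "\\[0, 100\\]")

  noHeader <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tc", "T1\tM1\t50"), noHeader)
  expect_error(readScoresTable(noHeader), "header")
})
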