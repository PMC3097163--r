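test_that("omega classification respects the cis and trans bands", {
  expect_equal(classifyOmega(0), "CIS")
  expect_equal(classifyOmega(180), "TRANS")
  expect_equal(classifyOmega(90), "NEITHER")
  expect_equal(classifyOmega(205), "TRANS")  # normalises to -155
  # inclusive boundaries
  expect_equal(classifyOmega(c(30, -30, 150, -150, 210)),
               c("CIS", "CIS", "TRANS", "TRANS", "TRANS"))
  expect_equal(classifyOmega(c(30.001, 149.999)), c("NEITHER", "NEITHER"))
  expect_error(classifyOmega(NaN), "finite")
  expect_error(classifyOmega(Inf), "finite")
})

test_that("omega classification is periodic with period 360", {
  x <- seq(-720, 720, by = 7.3)
  expect_equal(classifyOmega(x), classifyOmega(x + 360))
  expect_equal(classifyOmega(x), classifyOmega(x - 720))
})

test_that("window extraction emits the 11-mer around a cis bond", {
  chain <- list(id = "p1", sequence = paste(rep(c("A", "C", "D", "E"), 5),
                                            collapse = ""))  # length 20
  bonds <- data.frame(residue_index = 10, omega_deg = 5)
  out <- extractRegions(chain, bonds)
  expect_equal(length(out$cis), 1L)
  expect_equal(nchar(regionSequences(out$cis)), 11L)
  expect_equal(regionSequences(out$cis), substr(chain$sequence, 5, 15))
  expect_equal(out$cis@center_index, 10L)
})

test_that("trans windows near a cis bond centre are excluded", {
  chain <- list(id = "p1",
                sequence = paste(rep("ACDEG", 6), collapse = ""))  # length 30
  bonds <- data.frame(residue_index = c(10, 13, 15, 20),
                      omega_deg = c(0, 180, 180, 180))
  out <- extractRegions(chain, bonds)
  expect_equal(length(out$cis), 1L)
  # trans at 13 and 15 are within 5 of the cis centre at 10; 20 is not
  expect_equal(out$trans@center_index, 20L)
  expect_equal(out$skipped[["near_cis"]], 2L)
  # invariant: every emitted trans centre is > 5 from every cis centre
  expect_true(all(abs(out$trans@center_index - 10L) > 5L))
})

test_that("terminal, proline and non-standard windows are skipped and counted", {
  chain <- list(id = "p2", sequence = "ACDEFGHIKPMNXRSTVWYA")  # X at 13, P at 10
  bonds <- data.frame(residue_index = c(3, 8, 10, 16, 18),
                      omega_deg = c(0, 0, 0, 0, 20))
  expect_message(out <- extractRegions(chain, bonds), "non-standard")
  # 3: too close to the N-terminus; 16, 18: too close to the C-terminus;
  # 10: proline centre; 8: window 3..13 crosses the X at 13
  expect_equal(length(out$cis), 0L)
  expect_equal(out$skipped[["terminal"]], 3L)
  expect_equal(out$skipped[["proline"]], 1L)
  expect_equal(out$skipped[["nonstandard"]], 1L)
  # emitted count never exceeds annotation count and skips are attributed
  expect_equal(sum(out$skipped[c("terminal", "proline", "nonstandard")]),
               nrow(bonds))
})

test_that("out-of-bounds annotations raise an error naming the protein", {
  chain <- list(id = "pX", sequence = "ACDEFGHIKL")
  expect_error(
    extractRegions(chain, data.frame(residue_index = 25, omega_deg = 0)),
    "pX")
  expect_error(
    extractRegions(chain, data.frame(residue_index = 1, omega_deg = 0)),
    "out of bounds")
})

test_that("region files round-trip and malformed rows are rejected", {
  r <- BondRegions(c("ACDEFGHIKLM", "CDEFGHIKLMN", "DEFGHIKLMNP"),
                   label = c("CIS", "TRANS", "CIS"),
                   region_id = c("a", "b", "c"),
                   protein_id = "p1", center_index = c(6L, 7L, 8L))
  path <- tempfile(fileext = ".tsv")
  writeRegions(r, path, header = "fixture")
  back <- readRegions(path)
  expect_equal(as.data.frame(back), as.data.frame(r))

  # wrong-length sequence reported with its line number
  lines <- readLines(path)
  lines[4] <- "b\tTRANS\tSHORTSEQ\tp1\t7"
  writeLines(lines, path)
  expect_error(readRegions(path), "line 4")

  # header-only file gives an empty region set
  writeLines("region_id\tlabel\tsequence\tprotein_id\tcenter_index", path)
  expect_equal(length(readRegions(path)), 0L)

  # malformed row (wrong field count)
  writeLines(c("region_id\tlabel\tsequence\tprotein_id\tcenter_index",
               "a\tCIS\tACDEFGHIKLM"), path)
  expect_error(readRegions(path), "malformed")
})

test_that("multi-chain extraction validates ids and concatenates", {
  chains <- c(p1 = "ACDEFGHIKLMNQRSTVWYA", p2 = "ACDEFGHIKLMNQRSTVWYA")
  omega <- data.frame(protein_id = c("p1", "p2"), residue_index = c(10, 8),
                      omega_deg = c(0, 0))
  out <- extractRegionsAll(chains, omega)
  expect_equal(length(out$cis), 2L)
  expect_setequal(out$cis@protein_id, c("p1", "p2"))
  omega$protein_id[2] <- "nope"
  expect_error(extractRegionsAll(chains, omega), "unknown protein")
})
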