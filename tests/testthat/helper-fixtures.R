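## Shared fixture builders: everything is generated in code at test time.

## a random discovery instance small enough for the brute-force oracle
randomTinyInstance <- function() {
  letters <- AA_STANDARD[seq_len(sample(4:8, 1))]
  n <- sample(2:6, 1)
  len <- sample(4:7, 1)
  regs <- vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, character(1))
  list(regs = regs,
       W = sample(3:len, 1), L = sample(2:3, 1), K = sample(2:3, 1),
       alphabet = sample(c("none", "chemical", "structural"), 1))
}

## windows with two planted degenerate motifs, no noise, clean trans set
cleanPlantedSpec <- function(nCis = 20L, nTrans = 2000L, seed = 11L,
                             noise = 0) {
  synthSpec(nCis, nTrans,
            planted = list(list(pattern = "AD[DE]AT", fraction = 0.5),
                           list(pattern = "W.HKY", fraction = 0.5)),
            noise = noise, clean = TRUE, seed = seed)
}

## a small in-code motif library written to a temp TSV
writeTestLibrary <- function(path = tempfile(fileext = ".tsv"),
                             extraRows = character()) {
  lines <- c(
    "motif_id\tpattern\tclass\tgo_terms",
    "LIG_TEST_1\tADEAT\tLIG\tGO:0005515",
    "LIG_TEST_2\tP.DEA\tLIG\tGO:0005515;GO:0019899",
    "MOD_TEST_1\tS.[ST]P\tMOD\tGO:0006468",
    "TRG_TEST_1\tKRKR.K\tTRG\tGO:0006886",
    "CLV_TEST_1\tDEVD\tCLV\tGO:0008234",
    extraRows)
  writeLines(lines, path)
  path
}
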