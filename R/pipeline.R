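## Pipeline orchestration and TSV/JSON artifact I/O. All artifacts are
## tab-separated UTF-8 with '#' comment lines and one header line; every
## file starts with a provenance header (package version, config hash,
## seed) so identical configs yield byte-identical outputs.

## tiny FNV-1a hash of a deparsed object, for provenance headers
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

provenanceHeader <- function(config, seed) {
  sprintf("cisPatterns %s; config=%s; seed=%s",
          as.character(utils::packageVersion("cisPatterns")),
          configHash(config), seed)
}

writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write pattern lists
#' @param x [PatternSet-class] or a scored data.frame.
#' @param path TSV file path.
#' @param header provenance comment line.
#' @return `readPatternTsv` returns a data.frame (at least `pattern`, and
#'   `support` or score columns if present in the file).
#' @export
writePatternTsv <- function(x, path, header = "patterns") {
  df <- if (methods::is(x, "PatternSet")) as.data.frame(x) else x
  writeTsv(df, path, header)
}

#' @rdname writePatternTsv
#' @export
readPatternTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"pattern" %in% names(df)) stop("pattern file needs a 'pattern' column")
  df
}

#' Default pipeline configuration
#'
#' The defaults are the study settings: 11-residue windows, discovery with
#' `W = 11`, `L = 3`, `K = 2`, score threshold 0.90 (strict), enrichment
#' alpha 0.01 with the library class fractions TRG 13% / MOD 25% / LIG 54%
#' / CLV 7%, a 2/3 train split and 5 trans test resamples.
#'
#' @param ... overrides for any field.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(W = 11L, L = 3L, K = 2L, alphabet = "none", threshold = 0.90,
              alpha = 0.01,
              expected_fractions = c(TRG = 0.13, MOD = 0.25, LIG = 0.54,
                                     CLV = 0.07),
              trainFrac = 2 / 3, nTestResamples = 5L, seed = 1L,
              classify = TRUE, min_shared = 3L,
              fasta = NULL, omega = NULL, cis = NULL, trans = NULL,
              library = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (cfg$L > cfg$W) stop("invalid config: L must not exceed W")
  stopifnot(cfg$K >= 1L, cfg$threshold >= 0, cfg$threshold <= 1,
            cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

#' Read a pipeline configuration file
#' @param path YAML (or JSON) key-value file with [pipelineConfig()] fields.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$expected_fractions)) {
    raw$expected_fractions <- unlist(raw$expected_fractions)
  }
  pipelineConfig(raw)
}

#' Run the full analysis pipeline
#'
#' Stage order: region construction (or loading), maximal pattern
#' discovery on the cis windows, propensity scoring against the trans
#' windows, strict threshold filtering, greedy non-redundant selection,
#' then optionally the split/train/test classification protocol and the
#' motif-library comparison with its enrichment test. Each stage's output
#' is written under `outDir` with a provenance header.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()].
#'   Input windows come either from `config$fasta` + `config$omega`
#'   (chains plus per-bond omega annotations) or from `config$cis` /
#'   `config$trans` (pre-built region TSVs).
#' @param outDir output directory (created if missing).
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
  validatePipelineConfig(config)
  if (!is.null(config$fasta)) {
    if (is.null(config$omega)) stop("config needs 'omega' alongside 'fasta'")
    if (!file.exists(config$fasta)) stop("missing input: ", config$fasta)
    if (!file.exists(config$omega)) stop("missing input: ", config$omega)
  } else {
    if (is.null(config$cis) || is.null(config$trans)) {
      stop("config needs either fasta+omega or cis+trans inputs")
    }
    if (!file.exists(config$cis)) stop("missing input: ", config$cis)
    if (!file.exists(config$trans)) stop("missing input: ", config$trans)
  }
  if (!is.null(config$library) && !file.exists(config$library)) {
    stop("missing input: ", config$library)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenanceHeader(config, config$seed)

  if (!is.null(config$fasta)) {
    chains <- readProteinChains(config$fasta)
    omega <- readOmegaTable(config$omega)
    ds <- extractRegionsAll(chains, omega)
    cnp <- ds$cis; tnp <- ds$trans
    writeRegions(cnp, file.path(outDir, "regions_cis.tsv"), header = hdr)
    writeRegions(tnp, file.path(outDir, "regions_trans.tsv"), header = hdr)
  } else {
    cnp <- readRegions(config$cis)
    tnp <- readRegions(config$trans)
  }

  ps <- discoverPatterns(cnp, W = config$W, L = config$L, K = config$K,
                         alphabet = config$alphabet)
  writePatternTsv(ps, file.path(outDir, "patterns.tsv"), hdr)

  scored <- scorePatterns(ps, cnp, tnp)
  writeTsv(scored, file.path(outDir, "scored.tsv"), hdr)

  kept <- filterPatterns(scored, config$threshold)
  sel <- selectNonredundant(kept, cnp, tnp)
  writeTsv(retainedPatterns(sel), file.path(outDir, "retained.tsv"), hdr)
  writeTsv(assignmentTable(sel), file.path(outDir, "assignment.tsv"), hdr)

  out <- list(cnp = cnp, tnp = tnp, patterns = ps, scored = scored,
              selection = sel)

  if (isTRUE(config$classify)) {
    cls <- runClassification(cnp, tnp, W = config$W, L = config$L,
                             K = config$K, alphabet = config$alphabet,
                             threshold = config$threshold,
                             trainFrac = config$trainFrac,
                             nTestResamples = config$nTestResamples,
                             seed = config$seed)
    metrics <- list(
      provenance = hdr, seed = config$seed,
      sensitivity_pct = cls$sensitivity_pct,
      specificity_pct = cls$specificity_pct,
      accuracy_pct = cls$accuracy_pct,
      split = as.list(cls$split),
      confusion = cls$confusion)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$classification <- cls
  }

  if (!is.null(config$library)) {
    lib <- loadMotifLibrary(config$library)
    hits <- compareToLibrary(retainedPatterns(sel), lib,
                             minShared = config$min_shared)
    writeTsv(hits, file.path(outDir, "hits.tsv"), hdr)
    prof <- classProfile(hits)
    enr <- if (sum(prof) >= 1) {
      motifEnrichment(prof, config$expected_fractions, alpha = config$alpha)
    } else NULL
    jsonlite::write_json(
      list(provenance = hdr, observed = as.list(prof),
           enrichment = if (is.null(enr)) NULL else
             list(chi2 = enr$chi2, df = enr$df, p_value = enr$p_value,
                  alpha = enr$alpha, significant = enr$significant)),
      file.path(outDir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
    out$hits <- hits
    out$enrichment <- enr
  }

  invisible(out)
}
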