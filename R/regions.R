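#' Classify a peptide bond from its omega dihedral
#'
#' Angles are normalised to (-180, 180] degrees before the interval tests.
#' A bond is `CIS` when the normalised omega lies within +/-30 degrees of 0,
#' `TRANS` when it lies within 30 degrees of 180 (i.e. in \[150, 180\] or
#' \[-180, -150\]), and `NEITHER` otherwise. Boundaries are inclusive.
#'
#' @param omega_deg numeric vector of omega dihedrals in degrees.
#' @return character vector of `"CIS"`, `"TRANS"`, `"NEITHER"`.
#' @examples
#' classifyOmega(c(0, 180, 90, 205))
#' @export
classifyOmega <- function(omega_deg) {
  if (!is.numeric(omega_deg) || any(!is.finite(omega_deg))) {
    stop("omega_deg must be finite numeric (invalid dihedral annotation)")
  }
  norm <- 180 - ((180 - omega_deg) %% 360)  # (-180, 180]
  out <- rep("NEITHER", length(omega_deg))
  out[abs(norm) <= 30] <- "CIS"
  out[abs(norm) >= 150] <- "TRANS"
  out
}

#' Build CIS/TRANS windows from a chain and its bond annotations
#'
#' The bond between residues i-1 and i is attributed to residue i; the
#' window is the 11-mer `chain[i-5 .. i+5]`. Emission rules:
#' \itemize{
#'   \item bonds whose bond-bearing residue is proline are skipped in both
#'     sets (the method targets non-proline bonds);
#'   \item windows that would run past either chain terminus (centre < 6 or
#'     > length-5) are skipped;
#'   \item windows containing a non-standard residue letter are skipped and
#'     counted;
#'   \item a trans window is additionally skipped when its centre lies
#'     within 5 positions of any cis-classified bond centre in the chain,
#'     so cis and trans windows never overlap around a cis bond.
#' }
#'
#' @param chain list with elements `id` (scalar) and `sequence` (residue
#'   string), or a named character scalar (name = id).
#' @param bonds data.frame with columns `residue_index` (1-based, >= 2) and
#'   `omega_deg`.
#' @param flank window half-width (5 gives the 11-residue windows).
#' @return list with [BondRegions-class] elements `cis` and `trans` and a
#'   named integer vector `skipped` (`terminal`, `proline`, `nonstandard`,
#'   `near_cis`, `neither`).
#' @export
extractRegions <- function(chain, bonds, flank = 5L) {
  if (is.character(chain)) {
    chain <- list(id = names(chain)[1L] %||% "chain", sequence = unname(chain[1L]))
  }
  seqc <- chain$sequence
  len <- nchar(seqc)
  idx <- as.integer(bonds$residue_index)
  if (any(idx < 2L | idx > len)) {
    bad <- idx[idx < 2L | idx > len][1L]
    stop(sprintf("bond index %d out of bounds for protein '%s' (length %d)",
                 bad, chain$id, len))
  }
  cls <- classifyOmega(bonds$omega_deg)
  chars <- strsplit(seqc, "")[[1L]]
  skipped <- c(terminal = 0L, proline = 0L, nonstandard = 0L,
               near_cis = 0L, neither = 0L)
  skipped["neither"] <- sum(cls == "NEITHER")

  cisCenters <- idx[cls == "CIS"]  # all cis bonds guard the trans exclusion

  emit <- function(centers, label) {
    keep_id <- integer(); keep_seq <- character()
    for (i in centers) {
      if (i < flank + 1L || i > len - flank) {
        skipped["terminal"] <<- skipped["terminal"] + 1L
        next
      }
      if (chars[i] == "P") {
        skipped["proline"] <<- skipped["proline"] + 1L
        next
      }
      win <- substr(seqc, i - flank, i + flank)
      if (!all(strsplit(win, "")[[1L]] %in% AA_STANDARD)) {
        skipped["nonstandard"] <<- skipped["nonstandard"] + 1L
        message(sprintf("skipping %s window at %s:%d: non-standard residue",
                        label, chain$id, i))
        next
      }
      if (label == "TRANS" && length(cisCenters) &&
          min(abs(i - cisCenters)) <= flank) {
        skipped["near_cis"] <<- skipped["near_cis"] + 1L
        next
      }
      keep_id <- c(keep_id, i); keep_seq <- c(keep_seq, win)
    }
    BondRegions(keep_seq, label = label,
                region_id = if (length(keep_id))
                  sprintf("%s:%d", chain$id, keep_id) else NULL,
                protein_id = chain$id, center_index = keep_id)
  }

  cis <- emit(idx[cls == "CIS"], "CIS")
  trans <- emit(idx[cls == "TRANS"], "TRANS")
  list(cis = cis, trans = trans, skipped = skipped)
}

#' Build region datasets from many chains
#'
#' Applies [extractRegions()] per chain and concatenates the results.
#'
#' @param chains named character vector of sequences (names are chain ids)
#'   or a `Biostrings::AAStringSet`.
#' @param omega data.frame with columns `protein_id`, `residue_index`,
#'   `omega_deg` (see [readOmegaTable()]).
#' @param flank window half-width.
#' @return list with elements `cis`, `trans` ([BondRegions-class]) and
#'   `skipped` (summed counts).
#' @export
extractRegionsAll <- function(chains, omega, flank = 5L) {
  if (methods::is(chains, "AAStringSet")) {
    chains <- stats::setNames(as.character(chains), names(chains))
  }
  if (anyDuplicated(names(chains))) stop("chain ids must be unique")
  unknown <- setdiff(unique(omega$protein_id), names(chains))
  if (length(unknown)) {
    stop("omega annotations refer to unknown protein(s): ",
         paste(unknown, collapse = ", "))
  }
  parts <- lapply(names(chains), function(id) {
    b <- omega[omega$protein_id == id, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    extractRegions(list(id = id, sequence = chains[[id]]), b, flank = flank)
  })
  parts <- Filter(Negate(is.null), parts)
  bindRegions <- function(field) {
    dfs <- lapply(parts, function(p) as.data.frame(p[[field]]))
    df <- do.call(rbind, dfs)
    if (is.null(df) || !nrow(df)) return(BondRegions(character(), character()))
    BondRegions(df$sequence, df$label, region_id = df$region_id,
                protein_id = df$protein_id, center_index = df$center_index)
  }
  skipped <- Reduce(`+`, lapply(parts, `[[`, "skipped"),
                    c(terminal = 0L, proline = 0L, nonstandard = 0L,
                      near_cis = 0L, neither = 0L))
  list(cis = bindRegions("cis"), trans = bindRegions("trans"),
       skipped = skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read protein chains from a FASTA file
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readProteinChains <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate chain ids in ", path)
  stats::setNames(as.character(x), ids)
}

#' Read a per-bond omega annotation table
#'
#' Tab-separated with header `protein_id  residue_index  omega_deg`;
#' lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @return data.frame with those three columns.
#' @export
readOmegaTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "omega_deg")
  if (!all(need %in% names(df))) {
    stop("omega table must have columns: ", paste(need, collapse = ", "))
  }
  df$residue_index <- as.integer(df$residue_index)
  df$omega_deg <- as.numeric(df$omega_deg)
  if (any(is.na(df$residue_index)) || any(!is.finite(df$omega_deg))) {
    stop("malformed omega table: non-numeric residue_index or omega_deg")
  }
  df[need]
}

#' Read / write labelled region windows
#'
#' TSV with header `region_id  label  sequence  protein_id  center_index`;
#' `#` lines are comments. Reading validates each row (label, window width)
#' and reports the first offending line number.
#'
#' @param path TSV file path.
#' @param width required window width (`NULL` to accept any single width).
#' @return [BondRegions-class] object.
#' @export
readRegions <- function(path, width = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty regions file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("region_id", "label", "sequence", "protein_id", "center_index")
  if (!identical(header, need)) {
    stop("regions file must have header: ", paste(need, collapse = "\t"))
  }
  body <- lines[-1L]; bodyNo <- lineNo[-1L]
  if (!length(body)) return(BondRegions(character(), character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    stop(sprintf("malformed row at line %d of %s (expected 5 fields, got %d)",
                 bodyNo[which(nf != 5L)[1L]], path, nf[nf != 5L][1L]))
  }
  m <- do.call(rbind, fields)
  lab <- m[, 2L]; sq <- m[, 3L]
  if (any(!lab %in% c("CIS", "TRANS"))) {
    stop(sprintf("invalid label at line %d of %s",
                 bodyNo[which(!lab %in% c("CIS", "TRANS"))[1L]], path))
  }
  w <- width %||% nchar(sq[1L])
  if (any(nchar(sq) != w)) {
    stop(sprintf("wrong sequence length at line %d of %s (expected %d)",
                 bodyNo[which(nchar(sq) != w)[1L]], path, w))
  }
  BondRegions(sq, lab, region_id = m[, 1L], protein_id = m[, 4L],
              center_index = suppressWarnings(as.integer(m[, 5L])))
}

#' @rdname readRegions
#' @param regions a [BondRegions-class] object.
#' @param header optional extra `#` comment lines written before the data.
#' @export
writeRegions <- function(regions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(regions), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
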