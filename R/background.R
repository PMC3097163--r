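#' Fit a Markov background model from a sequence corpus
#'
#' Counts residue transitions of context length 0..`order` over the corpus
#' and converts them to conditional probabilities with add-one smoothing,
#' so unseen contexts still have a proper distribution. Lower-order tables
#' serve the first positions of a string. Residues outside the model
#' alphabet are ignored (they break the context).
#'
#' @param x FASTA path, character vector of sequences, or
#'   `Biostrings::AAStringSet`.
#' @param order Markov order, 0, 1 or 2.
#' @param letters model alphabet.
#' @return a [MarkovBackground-class] object.
#' @examples
#' fitBackground(c("ACDEFGHIKLMNPQRSTVWY"), order = 0)
#' @export
fitBackground <- function(x, order = 2L, letters = AA_STANDARD) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- readProteinChains(x)
  }
  if (methods::is(x, "AAStringSet")) x <- as.character(x)
  if (!length(x) || !any(nzchar(x))) stop("empty background corpus")
  order <- as.integer(order)
  stopifnot(order %in% 0:2)
  nl <- length(letters)

  c0 <- stats::setNames(numeric(nl), letters)
  c1 <- matrix(0, nl, nl, dimnames = list(letters, letters))
  c2 <- array(0, c(nl, nl, nl), dimnames = list(letters, letters, letters))
  for (s in x) {
    cs <- strsplit(s, "")[[1L]]
    i <- match(cs, letters)
    ok <- !is.na(i)
    ii <- i[ok]
    if (length(ii)) {
      tab <- tabulate(ii, nl)
      c0 <- c0 + tab
    }
    if (order >= 1L && length(i) >= 2L) {
      a <- i[-length(i)]; b <- i[-1L]
      good <- !is.na(a) & !is.na(b)
      if (any(good)) {
        idx <- (b[good] - 1L) * nl + a[good]
        t1 <- tabulate(idx, nl * nl)
        c1 <- c1 + matrix(t1, nl, nl)
      }
    }
    if (order >= 2L && length(i) >= 3L) {
      a <- i[seq_len(length(i) - 2L)]
      b <- i[seq_len(length(i) - 2L) + 1L]
      d <- i[seq_len(length(i) - 2L) + 2L]
      good <- !is.na(a) & !is.na(b) & !is.na(d)
      if (any(good)) {
        idx <- ((d[good] - 1L) * nl + (b[good] - 1L)) * nl + a[good]
        t2 <- tabulate(idx, nl^3)
        c2 <- c2 + array(t2, c(nl, nl, nl))
      }
    }
  }
  p0 <- (c0 + 1) / sum(c0 + 1)
  p1 <- if (order >= 1L) (c1 + 1) / rowSums(c1 + 1) else matrix(0, 0, 0)
  p2 <- if (order >= 2L) {
    tot <- apply(c2 + 1, c(1, 2), sum)
    sweep(c2 + 1, c(1, 2), tot, "/")
  } else array(0, c(0, 0, 0))
  methods::new("MarkovBackground", order = order, letters = letters,
               p0 = p0, p1 = p1, p2 = p2)
}

#' Uniform order-0 background
#' @param letters model alphabet.
#' @return a [MarkovBackground-class] with equal residue probabilities.
#' @export
uniformBackground <- function(letters = AA_STANDARD) {
  nl <- length(letters)
  methods::new("MarkovBackground", order = 0L, letters = letters,
               p0 = stats::setNames(rep(1 / nl, nl), letters),
               p1 = matrix(0, 0, 0), p2 = array(0, c(0, 0, 0)))
}

## conditional probability vector over letters given a context of 0..order
## preceding letter indices
bgConditional <- function(bg, ctx) {
  k <- length(ctx)
  if (k == 0L || bg@order == 0L) return(bg@p0)
  if (k == 1L || bg@order == 1L) return(bg@p1[ctx[length(ctx)], ])
  bg@p2[ctx[1L], ctx[2L], ]
}

#' Log-likelihood of a pattern under a background model
#'
#' The base-10 log of the probability that a random string of the pattern's
#' length, drawn from the background model, matches the pattern at that
#' fixed offset. Computed by dynamic programming over Markov states,
#' summing over class members and over the whole alphabet at wildcards;
#' identical to brute-force summation over all matching strings.
#'
#' @param pattern pattern string or token vector.
#' @param bg a [MarkovBackground-class] object.
#' @return numeric scalar, log10 probability (<= 0).
#' @examples
#' logLikelihood("A.C", uniformBackground())  # log10(1/400)
#' @export
logLikelihood <- function(pattern, bg) {
  toks <- if (length(pattern) == 1L) parsePattern(pattern, allowNegation = TRUE) else pattern
  if (!length(toks)) stop("empty pattern")
  letters <- bg@letters
  allowed <- lapply(toks, function(tk) {
    idx <- match(tokenResidues(tk, letters), letters)
    if (any(is.na(idx))) stop("pattern residue absent from background alphabet")
    idx
  })
  ord <- bg@order
  ## state = last min(ord, position) letter indices, encoded as a keyed
  ## string ("s" prefix so the empty context is a valid key)
  states <- stats::setNames(1, "s")  # prob mass per state before position 1
  for (j in seq_along(toks)) {
    nxt <- new.env(parent = emptyenv())
    for (key in names(states)) {
      body <- substring(key, 2L)
      ctx <- if (nzchar(body)) as.integer(strsplit(body, ",")[[1L]]) else integer()
      pv <- bgConditional(bg, ctx)
      mass <- states[[key]]
      for (li in allowed[[j]]) {
        newCtx <- c(ctx, li)
        if (length(newCtx) > ord) newCtx <- newCtx[-1L]
        nk <- paste0("s", paste(newCtx, collapse = ","))
        prev <- if (is.null(nxt[[nk]])) 0 else nxt[[nk]]
        assign(nk, prev + mass * pv[[li]], envir = nxt)
      }
    }
    states <- unlist(as.list(nxt))
    if (is.null(states)) return(-Inf)
  }
  log10(sum(states))
}

#' Sample residue strings from a background model
#' @param bg a [MarkovBackground-class].
#' @param n number of strings.
#' @param len string length.
#' @return character vector of length `n`.
#' @export
sampleBackground <- function(bg, n, len) {
  letters <- bg@letters
  nl <- length(letters)
  if (n == 0L) return(character())
  mat <- matrix(0L, n, len)
  for (j in seq_len(len)) {
    if (j == 1L || bg@order == 0L) {
      mat[, j] <- sample.int(nl, n, replace = TRUE, prob = bg@p0)
    } else if (j == 2L || bg@order == 1L) {
      prev <- mat[, j - 1L]
      for (ctx in unique(prev)) {
        rows <- which(prev == ctx)
        mat[rows, j] <- sample.int(nl, length(rows), replace = TRUE,
                                   prob = bg@p1[ctx, ])
      }
    } else {
      key <- (mat[, j - 2L] - 1L) * nl + mat[, j - 1L]
      for (ctx in unique(key)) {
        rows <- which(key == ctx)
        a <- (ctx - 1L) %/% nl + 1L
        b <- (ctx - 1L) %% nl + 1L
        mat[rows, j] <- sample.int(nl, length(rows), replace = TRUE,
                                   prob = bg@p2[a, b, ])
      }
    }
  }
  apply(mat, 1L, function(r) paste(letters[r], collapse = ""))
}
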