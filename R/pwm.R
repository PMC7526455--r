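# Position-weight-matrix scanning with exact p-values.
#
# Scores are log2 odds of the motif model against a background base
# distribution. The null distribution of the per-window score is computed
# exactly by dynamic programming over the discretized per-position score
# distribution (bin width 1e-3 log2 units), so p-values are reproducible
# bit-for-bit given the configuration and need no simulation.

DNA_BASES <- c("A", "C", "G", "T")
.PWM_BIN <- 1e-3  # log2-odds discretization step for the DP

#' Construct a position weight matrix object
#'
#' @param tf_name transcription-factor name (uppercased for matching)
#' @param database source database label (e.g. "jaspar", "hocomoco")
#' @param mat L x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1 within 1e-6, and L >= 4
#' @param pseudocount probability pseudocount mixed into every cell before
#'   log-odds conversion (`p' = (p + pc) / (1 + 4 pc)`); 0 keeps the
#'   matrix as supplied
#' @return object of class `funsnp_pwm`
#' @export
pwm <- function(tf_name, database, mat, pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 4L) stop("PWM length must be >= 4")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  colnames(mat) <- DNA_BASES
  structure(list(tf_name = toupper(tf_name), database = database,
                 mat = mat, pseudocount = pseudocount),
            class = "funsnp_pwm")
}

#' @export
print.funsnp_pwm <- function(x, ...) {
  cat(sprintf("PWM %s [%s], length %d\n", x$tf_name, x$database, nrow(x$mat)))
  invisible(x)
}

# Pseudocounted log2-odds matrix vs background frequencies.
.pwm_logodds <- function(p, background = rep(0.25, 4)) {
  m <- (p$mat + p$pseudocount) / (1 + 4 * p$pseudocount)
  log2(sweep(m, 2L, background, "/"))
}

# Reverse-complement a log-odds (or probability) matrix.
.pwm_revcomp <- function(mat) {
  mat[rev(seq_len(nrow(mat))), rev(seq_len(ncol(mat))), drop = FALSE]
}

# Exact null distribution of the discretized window score by DP. The
# window score is the sum of per-cell log-odds rounded to `bin` units, so
# the DP support and the scanned scores live on the same integer lattice.
.pwm_null <- function(lom, background = rep(0.25, 4), bin = .PWM_BIN) {
  L <- nrow(lom)
  imat <- round(lom / bin)                      # integer scores per cell
  off <- apply(imat, 1L, min)                   # shift rows to start at 0
  sh <- imat - off
  width <- sum(apply(sh, 1L, max))              # max total shifted score
  dist <- numeric(width + 1L); dist[1L] <- 1    # P(shifted sum = k), k=0..
  upto <- 0L
  for (i in seq_len(L)) {
    nxt <- numeric(width + 1L)
    row <- sh[i, ]
    for (b in 1:4) {
      s <- row[b]
      nxt[(s + 1L):(s + upto + 1L)] <-
        nxt[(s + 1L):(s + upto + 1L)] + background[b] * dist[1L:(upto + 1L)]
    }
    dist <- nxt
    upto <- upto + max(row)
  }
  tail_p <- rev(cumsum(rev(dist)))              # P(shifted sum >= k)
  base <- sum(off)
  pv_int <- function(k) {
    ks <- k - base
    ifelse(ks > width, 0, tail_p[pmax(ks, 0) + 1L])
  }
  list(imat = imat, bin = bin, pv_int = pv_int,
       pv = function(score) pv_int(round(score / bin)))
}

.seq_to_idx <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)  # N etc. -> NA
}

# Score every window of `idx` (base indices, NA for ambiguous) under an
# integer score matrix; windows containing NA are skipped (NA score).
.scan_windows <- function(idx, imat) {
  L <- nrow(imat)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  scores <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    w <- idx[s:(s + L - 1L)]
    if (anyNA(w)) next
    scores[s] <- sum(imat[cbind(seq_len(L), w)])
  }
  scores
}

#' Scan a sequence with a PWM, with exact p-values
#'
#' Every window on both strands is scored by log2 odds against the
#' background, discretized at 1e-3 log2 units per cell; windows
#' containing non-ACGT bases are skipped. The p-value of a score is the
#' exact probability of an equal-or-higher discretized score in one
#' background-distributed window, from the DP null distribution over the
#' same integer lattice, so p-values are reproducible bit-for-bit.
#'
#' @param sequence character DNA string over A/C/G/T/N
#' @param pwm a [pwm()] object
#' @param background base frequencies (A, C, G, T), default uniform
#' @param p_threshold significance threshold recorded in the result,
#'   default 1e-4
#' @param scanner optional precomputed [pwm_scanner()]; avoids rebuilding
#'   the DP null distribution when the same motif is scanned repeatedly
#' @return `data.frame` with one row per strand: `strand`, `start`
#'   (1-based window start on the input sequence), `score`, `p`,
#'   `pass` (`p < p_threshold`); zero rows when the sequence is shorter
#'   than the motif
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4),
                     p_threshold = 1e-4, scanner = NULL) {
  if (is.null(scanner)) scanner <- pwm_scanner(pwm, background)
  idx <- .seq_to_idx(sequence)
  if (length(idx) < scanner$L)
    return(data.frame(strand = character(0), start = integer(0),
                      score = numeric(0), p = numeric(0), pass = logical(0)))
  out <- list()
  for (strand in c("+", "-")) {
    nul <- if (strand == "+") scanner$null_fwd else scanner$null_rev
    sc <- .scan_windows(idx, nul$imat)
    if (all(is.na(sc))) next
    best <- which.max(sc)
    out[[strand]] <- data.frame(strand = strand, start = best,
                                score = sc[best] * nul$bin,
                                p = nul$pv_int(sc[best]),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(strand = character(0), start = integer(0),
                      score = numeric(0), p = numeric(0), pass = logical(0)))
  res$pass <- res$p < p_threshold
  rownames(res) <- NULL
  res
}

#' Precompute the scoring machinery for a motif
#'
#' Builds the forward and reverse-complement log-odds matrices and their
#' exact DP null distributions once, so a motif can be scanned across
#' many sequences without recomputing them (the null distribution
#' differs between strands only under a skewed background).
#'
#' @inheritParams scan_pwm
#' @return a scanner list consumed by [scan_pwm()]'s `scanner` argument
#' @export
pwm_scanner <- function(pwm, background = rep(0.25, 4)) {
  lom <- .pwm_logodds(pwm, background)
  rml <- .pwm_revcomp(lom)
  nf <- .pwm_null(lom, background)
  nr <- .pwm_null(rml, background)
  list(L = nrow(lom), fwd = lom, rev = rml,
       null_fwd = nf, null_rev = nr,
       pv_fwd = nf$pv, pv_rev = nr$pv)
}

# Readers ------------------------------------------------------------------

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' @param path file path
#' @param database database label attached to every motif (default: file
#'   base name)
#' @param pseudocount passed to [pwm()]
#' @return list of [pwm()] objects
#' @export
read_meme <- function(path, database = NULL,
                      pseudocount = 0.001) {
  database <- database %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[(s + 1):length(lines)])[1] + s
    rows <- list()
    i <- hdr + 1L
    while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1L
    }
    mat <- do.call(rbind, rows)
    mat <- mat / rowSums(mat)  # guard against rounded rows in the file
    out[[name]] <- pwm(name, database, mat, pseudocount)
  }
  out
}

#' Read motifs in JASPAR PFM format
#'
#' Count matrices (`>name` header, then four `A [ ... ]` style rows) are
#' normalised to per-position probabilities.
#' @inheritParams read_meme
#' @return list of [pwm()] objects
#' @export
read_jaspar <- function(path, database = "jaspar", pseudocount = 0.001) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    name <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    block <- lines[(h + 1):(h + 4)]
    counts <- t(vapply(block, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(block[1], gregexpr("[0-9.]+", block[1]))[[1]]))))
    mat <- t(counts) / colSums(counts)  # positions x bases
    out[[name]] <- pwm(name, database, mat, pseudocount)
  }
  out
}

#' Write motifs in MEME minimal format
#' @param pwms list of [pwm()] objects
#' @param path output path
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$mat)), con)
    writeLines(apply(p$mat, 1L, function(r) paste(sprintf("%.6f", r),
                                                  collapse = " ")), con)
    writeLines("", con)
  }
}
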