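# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: quadratic scans, exhaustive enumeration, and
# direct-formula arithmetic.

# Quadratic all-pairs interval overlap (SNP 1-based, intervals BED).
brute_overlap <- function(snps, intervals) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(intervals$chrom == snps$chrom[i] &
          snps$pos[i] - 1 >= intervals$start &
          snps$pos[i] - 1 < intervals$end)
  }, logical(1))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins, using lchoose arithmetic only.
brute_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logdens <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  dens <- exp(logdens)
  obs <- dens[xs == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# All 4-ary words of length L as an integer matrix (rows = words).
all_words <- function(L) as.matrix(expand.grid(rep(list(1:4), L)))

# A random row-stochastic PWM probability matrix of length L.
random_pwm_matrix <- function(L) {
  m <- matrix(stats::rgamma(4 * L, 1), L, 4)
  m / rowSums(m)
}

# A tiny deterministic SNP/interval universe builder.
mk_snps <- function(pos, chrom = "chr1", ids = NULL) {
  data.frame(snp_id = ids %||% paste0("s", seq_along(pos)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
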