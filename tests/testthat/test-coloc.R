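# Colocalization: approximate Bayes factors and PICS credible sets.

mk_summary <- function(z, n = 5000, ids = NULL) {
  se <- 1 / sqrt(n)
  data.frame(snp_id = ids %||% paste0("s", seq_along(z)),
             beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = n,
             freq = 0.3, type = "quant", stringsAsFactors = FALSE)
}

test_that("posterior probabilities always sum to one and lie in [0, 1]", {
  set.seed(61)
  for (i in 1:10) {
    g <- mk_summary(rnorm(50, 0, 2))
    q <- mk_summary(rnorm(50, 0, 2))
    r <- coloc_abf(g, q)
    expect_equal(sum(r$pp), 1, tolerance = 1e-6)
    expect_true(all(r$pp >= 0 & r$pp <= 1))
  }
})

test_that("flat signals in both traits put the posterior mass on PP0", {
  set.seed(62)
  g <- mk_summary(runif(60, -0.9, 0.9))
  q <- mk_summary(runif(60, -0.9, 0.9))
  r <- coloc_abf(g, q)
  expect_equal(names(which.max(r$pp)), "PP0")
  # direct-arithmetic oracle for PP0: independent computation of the
  # hypothesis sums from the Wakefield ABF formula
  W <- 0.15^2
  labf <- function(d) {
    z <- d$beta / d$se; V <- d$se^2; rr <- W / (V + W)
    0.5 * (log(1 - rr) + rr * z^2)
  }
  l1 <- labf(g); l2 <- labf(q)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  s1 <- lse(l1); s2 <- lse(l2); s12 <- lse(l1 + l2)
  lh <- c(0, log(1e-4) + s1, log(1e-4) + s2,
          log(1e-4) + log(1e-4) + s1 + s2 + log1p(-exp(s12 - s1 - s2)),
          log(1e-5) + s12)
  expect_equal(unname(r$pp), exp(lh - lse(lh)) / sum(exp(lh - lse(lh))),
               tolerance = 1e-9)
})

test_that("swapping the traits exchanges PP1/PP2 and preserves PP3/PP4", {
  set.seed(63)
  g <- mk_summary(c(rnorm(49), 9))
  q <- mk_summary(rnorm(50, 0, 0.5))
  r1 <- coloc_abf(g, q)
  r2 <- coloc_abf(q, g)
  expect_equal(unname(r1$pp["PP1"]), unname(r2$pp["PP2"]), tolerance = 1e-12)
  expect_equal(unname(r1$pp["PP2"]), unname(r2$pp["PP1"]), tolerance = 1e-12)
  expect_equal(unname(r1$pp["PP3"]), unname(r2$pp["PP3"]), tolerance = 1e-12)
  expect_equal(unname(r1$pp["PP4"]), unname(r2$pp["PP4"]), tolerance = 1e-12)
})

test_that("PP4 is monotone in the shared prior p12 at fixed data", {
  set.seed(64)
  sc <- generate_coloc_scenario("shared", n = 5000, effect = 0.5,
                                snps = 100, seed = 9)
  pp4 <- vapply(c(1e-7, 1e-6, 1e-5, 1e-4),
                function(p12) coloc_abf(sc$gwas, sc$qtl, p12 = p12)$pp["PP4"],
                numeric(1))
  expect_true(all(diff(pp4) > 0))
})

test_that("colocalization needs at least two shared SNPs", {
  g <- mk_summary(c(1, 2), ids = c("a", "b"))
  q <- mk_summary(c(1, 2), ids = c("c", "d"))
  expect_error(coloc_abf(g, q), "shared SNPs")
})

test_that("z-scores can be recovered from p-values alone", {
  set.seed(65)
  z <- c(rnorm(30), 8)
  full <- mk_summary(z)
  ponly <- full[, c("snp_id", "p", "n", "freq", "type")]
  r1 <- coloc_abf(full, full)
  r2 <- coloc_abf(ponly, ponly)
  expect_equal(names(which.max(r2$pp)), names(which.max(r1$pp)))
})

test_that("PICS: degenerate and symmetric cases", {
  expect_equal(pics_probabilities(8, 1)$prob, 1)
  p2 <- pics_probabilities(8, c(1, 1))
  expect_equal(p2$prob, c(0.5, 0.5))
  expect_true(all(p2$in_credible))
})

test_that("PICS probabilities are non-increasing as r2 decreases at fixed lead strength", {
  for (S in c(6, 8, 12)) {
    r <- c(1, seq(0.99, 0.1, by = -0.01))
    p <- pics_probabilities(S, r)
    p <- p[order(-abs(p$r)), ]
    expect_true(all(diff(p$prob) <= 1e-12))
  }
})

test_that("PICS credible set is the smallest set reaching 95% mass", {
  p <- pics_probabilities(8, c(1, 0.95, 0.9, 0.5, 0.2))
  cum <- cumsum(p$prob)            # already sorted by decreasing probability
  k <- which(cum >= 0.95)[1]
  expect_equal(sum(p$in_credible), k)
})

test_that("PICS colocalization: point masses, disjoint sets and priors", {
  a <- pics_probabilities(8, 1, snp_ids = "s1")
  b <- pics_probabilities(8, 1, snp_ids = "s1")
  shared <- pics_coloc(a, b)
  expect_gt(shared$pp["PP4"], 0.99)
  expect_equal(sum(shared$pp), 1, tolerance = 1e-6)
  c_ <- pics_probabilities(8, 1, snp_ids = "s2")
  expect_warning(pics_coloc(a, c_), "disjoint")
  expect_equal(unname(suppressWarnings(pics_coloc(a, c_)$pp["PP4"])), 0)
  expect_equal(unname(suppressWarnings(pics_coloc(a, c_)$pp["PP3"])), 1)
})

test_that("PICS colocalization ranks shared loci above distinct loci like ABF", {
  set.seed(66)
  pp4_abf <- pp4_pics <- numeric(0)
  labels <- character(0)
  for (i in 1:10) {
    kind <- if (i %% 2 == 0) "shared" else "distinct"
    sc <- generate_coloc_scenario(kind, n = 5000, effect = 0.5, snps = 100,
                                  seed = 600 + i)
    r_abf <- coloc_abf(sc$gwas, sc$qtl)
    lead_g <- which.max(abs(sc$gwas$beta / sc$gwas$se))
    lead_q <- which.max(abs(sc$qtl$beta / sc$qtl$se))
    # LD to the lead approximated from the block structure used to simulate
    block <- 20L
    r_to <- function(lead) {
      idx <- seq_len(100)
      r <- ifelse((idx - 1) %/% block == (lead - 1) %/% block,
                  0.95^abs(idx - lead), 0)
      r
    }
    pg <- pics_probabilities(max(1, -log10(min(sc$gwas$p))), r_to(lead_g),
                             snp_ids = sc$gwas$snp_id)
    pq <- pics_probabilities(max(1, -log10(min(sc$qtl$p))), r_to(lead_q),
                             snp_ids = sc$qtl$snp_id)
    r_pics <- suppressWarnings(pics_coloc(pg, pq))
    pp4_abf <- c(pp4_abf, r_abf$pp["PP4"])
    pp4_pics <- c(pp4_pics, r_pics$pp["PP4"])
    labels <- c(labels, kind)
  }
  expect_gt(min(pp4_pics[labels == "shared"]),
            max(pp4_pics[labels == "distinct"]))
  expect_gt(min(pp4_abf[labels == "shared"]),
            max(pp4_abf[labels == "distinct"]))
})

test_that("null scenario z-scores have standard-normal marginals", {
  set.seed(67)
  zs <- unlist(lapply(1:6, function(i) {
    sc <- generate_coloc_scenario("null", n = 5000, snps = 100, seed = 700 + i)
    sc$gwas$beta / sc$gwas$se
  }))
  # marginals are standard normal but draws are LD-correlated, which
  # inflates the sampling error of the pooled moments
  expect_lt(abs(mean(zs)), 0.2)
  expect_lt(abs(sd(zs) - 1), 0.25)
  expect_gt(shapiro.test(sample(zs, 500))$p.value, 1e-4)
})

test_that("shared scenario with zero effect degenerates to the null", {
  sc <- generate_coloc_scenario("shared", n = 5000, effect = 0,
                                snps = 100, seed = 11)
  z <- sc$gwas$beta / sc$gwas$se
  expect_lt(max(abs(z)), 5)
  r <- coloc_abf(sc$gwas, sc$qtl)
  expect_equal(names(which.max(r$pp)), "PP0")
})
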