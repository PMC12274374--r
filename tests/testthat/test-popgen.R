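test_that("allele frequencies from counts match chromosome enumeration", {
  # published worked example: 0 / 18 / 109 -> 92.91%
  expect_equal(frequency_from_counts(0, 18, 109), 92.91)
  expect_equal(frequency_from_counts(10, 0, 0), 0)
  expect_true(is.na(frequency_from_counts(0, 0, 0)))

  # random count triples vs direct enumeration over chromosomes
  set.seed(21)
  for (i in 1:50) {
    cnt <- sample(0:60, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    chromosomes <- c(rep(0, 2 * cnt[1]), rep(c(0, 1), cnt[2]),
                     rep(1, 2 * cnt[3]))
    expect_equal(frequency_from_counts(cnt[1], cnt[2], cnt[3]),
                 round_half_up(100 * mean(chromosomes), 2))
  }
})

test_that("frequency tables are self-consistent and exclude no-calls", {
  calls <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    site = rep(c("A", "B"), each = 4),
    snp_id = "F1534C",
    genotype = c("hom_alt", "het", "het", "no_call",
                 "hom_ref", "hom_alt", "hom_alt", "het"),
    stringsAsFactors = FALSE
  )
  t2 <- frequency_table(calls, "overall")
  expect_equal(t2$n, 7L)        # the no_call is excluded
  expect_equal(t2$freq,
               frequency_from_counts(t2$n_hom_ref, t2$n_het, t2$n_hom_alt))
  t3 <- frequency_table(calls, "site", digits = 1)
  expect_equal(nrow(t3), 2L)
  expect_equal(t3$n[t3$group == "A"], 3L)
  # recompute-from-counts invariant on every row
  expect_equal(t3$freq, frequency_from_counts(t3$n_hom_ref, t3$n_het,
                                              t3$n_hom_alt, 1))

  empty <- frequency_table(calls[calls$genotype == "no_call", ], "overall")
  expect_true(is.na(empty$freq))
  expect_equal(empty$flag, "no_data")
})

test_that("cross-site chi-squared matches the closed form and chisq.test", {
  rows <- data.frame(n_hom_ref = c(5, 5), n_het = c(10, 10),
                     n_hom_alt = c(5, 5), n = 20)
  z <- chi_squared_sites(rows)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)

  rows2 <- data.frame(n_hom_ref = c(2, 10), n_het = c(8, 12),
                      n_hom_alt = c(15, 3), n = c(25, 25))
  O <- cbind(rows2$n_het + 2 * rows2$n_hom_alt,
             2 * rows2$n_hom_ref + rows2$n_het)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(chi_squared_sites(rows2)$statistic, sum((O - E)^2 / E))
  # independent implementation agrees
  ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
  expect_equal(chi_squared_sites(rows2)$statistic,
               unname(ref$statistic))
  expect_equal(chi_squared_sites(rows2)$p, unname(ref$p.value))

  expect_warning(chi_squared_sites(
    data.frame(n_hom_ref = c(20, 20), n_het = c(0, 1),
               n_hom_alt = c(0, 0), n = c(20, 21))), "expected cell")
  expect_error(chi_squared_sites(rows2[1, ]), "two sites")
})

test_that("chi-squared type-I error is nominal under the null", {
  set.seed(77)
  alpha <- 0.05
  reject <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    rows <- do.call(rbind, lapply(1:3, function(s) {
      g <- tabulate(rbinom(50, 2, 0.3) + 1L, 3L)
      data.frame(n_hom_ref = g[1], n_het = g[2], n_hom_alt = g[3], n = 50)
    }))
    z <- suppressWarnings(chi_squared_sites(rows))
    if (z$p < alpha) reject <- reject + 1L
  }
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(reject / n_rep - alpha), 3 * se)
})

test_that("LD r-squared: direct counts, complete LD and independence", {
  # haplotypes only AB and ab in equal counts: r2 = 1
  hA <- rep(c(1, 0), each = 50)
  hB <- rep(c(1, 0), each = 50)
  expect_equal(ld_r2(hA, hB, phase = "known")$r2, 1)
  # exact independence: all four haplotypes at 25 each
  hA2 <- rep(c(1, 1, 0, 0), 25)
  hB2 <- rep(c(1, 0, 1, 0), 25)
  z <- ld_r2(hA2, hB2, phase = "known")
  expect_equal(z$r2, 0)
  expect_equal(z$D, 0)
  expect_equal(z$p_AB + z$p_Ab + z$p_aB + z$p_ab, 1)

  # monomorphic locus: flagged, r2 undefined
  m <- ld_r2(rep(0L, 40), rbinom(40, 2, 0.5), phase = "em")
  expect_true(is.na(m$r2))
  expect_equal(m$flag, "monomorphic")
})

# multinomial log-likelihood of unphased two-locus genotype classes given
# haplotype frequencies (independent oracle used by the grid search)
geno_class_loglik <- function(x, y, p) {
  pr <- matrix(0, 3, 3)
  hap <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  for (i in 1:4) for (j in 1:4) {
    g1 <- hap[i, 1] + hap[j, 1]; g2 <- hap[i, 2] + hap[j, 2]
    pr[g1 + 1, g2 + 1] <- pr[g1 + 1, g2 + 1] + p[i] * p[j]
  }
  sum(log(pr[cbind(x + 1, y + 1)]))
}

test_that("EM haplotype frequencies match an exhaustive grid-search MLE", {
  set.seed(33)
  for (rep in 1:5) {
    # draw 50 diploids from a random haplotype distribution
    p_true <- as.vector(rmultinom(1, 40, c(.4, .2, .25, .15))) / 40
    hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    draw <- function(n) hap[sample(4, n, TRUE, prob = p_true), ]
    h1 <- draw(50); h2 <- draw(50)
    x <- h1[, 1] + h2[, 1]; y <- h1[, 2] + h2[, 2]
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next

    em <- ld_r2(x, y, phase = "em")
    # grid over p_AB at the (margin-preserving) MLE allele frequencies,
    # step 1e-3; the haplotype-frequency MLE keeps the sample margins
    pA <- mean(x) / 2; pB <- mean(y) / 2
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    grid <- seq(lo, hi, by = 1e-3)
    ll <- vapply(grid, function(pAB) {
      p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
      if (any(p < -1e-12)) return(-Inf)
      geno_class_loglik(x, y, pmax(p, 0))
    }, numeric(1))
    pAB_star <- grid[which.max(ll)]
    # refine the exhaustive search around the coarse optimum so the grid
    # resolution does not dominate the comparison
    fine <- seq(max(lo, pAB_star - 2e-3), min(hi, pAB_star + 2e-3),
                by = 1e-5)
    llf <- vapply(fine, function(pAB) {
      p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
      if (any(p < -1e-12)) return(-Inf)
      geno_class_loglik(x, y, pmax(p, 0))
    }, numeric(1))
    pAB_star <- fine[which.max(llf)]
    D <- pAB_star - pA * pB
    r2_star <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    expect_lt(abs(em$r2 - r2_star), 1e-3)
  }
})

test_that("EM equals direct-count r2 when phase is unambiguous", {
  set.seed(44)
  # construct genotypes with no double heterozygote: phase is determined
  h1a <- rbinom(80, 1, 0.4)
  h1b <- h1a                       # complete LD on chromosome 1
  h2a <- rep(0, 80); h2b <- rep(0, 80)
  x <- h1a + h2a; y <- h1b + h2b
  em <- ld_r2(x, y, phase = "em")
  known <- ld_r2(c(h1a, h2a), c(h1b, h2b), phase = "known")
  expect_equal(em$r2, known$r2, tolerance = 1e-9)
  expect_equal(em$p_AB, known$p_AB, tolerance = 1e-9)
})

test_that("LD screening honours the distance window and finds blocks", {
  # four-locus haplotype block in near-complete LD: all 6 pairs above 0.8
  loci <- data.frame(snp_id = c("a", "b", "c", "d"), freq = rep(0.5, 4))
  hb <- list(loci = loci$snp_id,
             hap = rbind(rep(1, 4), rep(0, 4)), freq = c(0.5, 0.5))
  ps <- population_spec("S", 200, loci, haplotypes = hb)
  g <- simulate_genotypes(fx_generic_panel, ps, seed = 71)
  pos <- setNames(c(1000L, 1500L, 3000L, 9000L), loci$snp_id)
  chrom <- setNames(rep("3", 4), loci$snp_id)
  sc <- ld_screen(g$geno, pos, chrom)
  expect_equal(nrow(sc$pairs), 6L)
  expect_equal(nrow(sc$hits), 6L)
  expect_true(all(sc$hits$r2 > 0.8))

  # unlinked loci at n = 500: nothing above 0.8
  ps2 <- population_spec("S", 500,
                         data.frame(snp_id = c("u", "v"), freq = c(.5, .5)))
  g2 <- simulate_genotypes(fx_generic_panel, ps2, seed = 72)
  sc2 <- ld_screen(g2$geno, setNames(c(100L, 5000L), c("u", "v")),
                   setNames(c("3", "3"), c("u", "v")))
  expect_equal(nrow(sc2$hits), 0L)

  # distance filters: 15 bp pair excluded, cross-chromosome excluded
  sc3 <- ld_screen(g2$geno, setNames(c(100L, 115L), c("u", "v")),
                   setNames(c("3", "3"), c("u", "v")))
  expect_equal(nrow(sc3$pairs), 0L)
  sc4 <- ld_screen(g2$geno, setNames(c(100L, 5000L), c("u", "v")),
                   setNames(c("2", "3"), c("u", "v")))
  expect_equal(nrow(sc4$pairs), 0L)
})

test_that("Spearman correlation handles ties and small-n permutation", {
  up <- spearman_mortality_freq(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  expect_equal(up$rho, 1)
  expect_equal(up$method, "exact_permutation")
  expect_equal(up$p, 2 / factorial(5))   # only the two monotone orderings

  down <- spearman_mortality_freq(1:5, 5:1)
  expect_equal(down$rho, -1)

  # midrank ties: agree with the standard implementation
  x <- c(2.2, 40.4, 21.4, 21.4, 87.2, 40.4)
  y <- c(82.8, 90.9, 100, 95, 91.3, 90.9)
  got <- spearman_mortality_freq(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))

  cons <- spearman_mortality_freq(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(cons$rho))
  expect_equal(cons$method, "constant")
  expect_error(spearman_mortality_freq(1:2, 1:2), "at least 3")
})
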