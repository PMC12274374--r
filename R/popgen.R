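## Genotype-count / allele-frequency tables, cross-site association tests,
## pairwise LD r-squared (direct from phase-known haplotypes, or EM over
## unphased diploid genotypes) and the mortality-frequency rank correlation.

#' Alternative-allele frequency from genotype counts
#'
#' f = (n_het + 2 n_hom_alt) / (2 n), reported as a percentage rounded
#' half-up.
#'
#' @param hom_ref,het,hom_alt genotype counts
#' @param digits decimal places (2 for the detailed table style, 1 for the
#'   per-site style)
#' @return frequency in percent (NA when n = 0)
#' @export
frequency_from_counts <- function(hom_ref, het, hom_alt, digits = 2) {
  n <- hom_ref + het + hom_alt
  ifelse(n > 0, round_half_up(100 * (het + 2 * hom_alt) / (2 * n), digits),
         NA_real_)
}

#' Genotype-count and allele-frequency table
#'
#' One row per mutation per group (overall, or per collection site) over
#' consensus QC-passed calls; no-calls are excluded from n.
#'
#' @param calls data frame with `sample_id`, `site`, `snp_id`, `genotype`
#' @param grouping `"overall"` or `"site"`
#' @param digits decimal places for the percentage
#' @return data frame with `snp_id`, `group`, `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n`, `freq` (percent; NA and flagged when n = 0)
#' @export
frequency_table <- function(calls, grouping = c("overall", "site"),
                            digits = 2) {
  grouping <- match.arg(grouping)
  calls$group <- if (grouping == "overall") "overall" else calls$site
  called <- calls[calls$genotype != "no_call", , drop = FALSE]
  combos <- unique(calls[, c("snp_id", "group")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- called[called$snp_id == combos$snp_id[i] &
                    called$group == combos$group[i], , drop = FALSE]
    cnt <- c(hom_ref = sum(sub$genotype == "hom_ref"),
             het = sum(sub$genotype == "het"),
             hom_alt = sum(sub$genotype == "hom_alt"))
    data.frame(snp_id = combos$snp_id[i], group = combos$group[i],
               n_hom_ref = cnt[["hom_ref"]], n_het = cnt[["het"]],
               n_hom_alt = cnt[["hom_alt"]], n = sum(cnt),
               freq = frequency_from_counts(cnt[["hom_ref"]], cnt[["het"]],
                                            cnt[["hom_alt"]], digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag <- ifelse(out$n == 0, "no_data", NA_character_)
  rownames(out) <- NULL
  out
}

#' Chi-squared test of allele-frequency differences across sites
#'
#' Pearson chi-squared on the site x allele (alt/ref chromosome counts)
#' table for one mutation, expected counts from the margins, df = sites - 1.
#'
#' @param freq_rows rows of [frequency_table()] for one mutation across
#'   sites (n > 0)
#' @return list with `statistic`, `df`, `p`, `expected` and
#'   `small_sample` (TRUE when any expected cell < 1)
#' @export
chi_squared_sites <- function(freq_rows) {
  freq_rows <- freq_rows[freq_rows$n > 0, , drop = FALSE]
  if (nrow(freq_rows) < 2) stop("need at least two sites with data")
  O <- cbind(alt = freq_rows$n_het + 2 * freq_rows$n_hom_alt,
             ref = 2 * freq_rows$n_hom_ref + freq_rows$n_het)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  small <- any(E < 1)
  if (small) warning("expected cell count below 1; chi-squared unreliable")
  stat <- sum((O - E)^2 / E)
  df <- nrow(O) - 1L
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = E, small_sample = small)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' With known phase, haplotype frequencies are counted directly from the two
#' haplotype allele vectors. With unphased diploid genotypes, haplotype
#' frequencies are the maximum-likelihood estimates from an EM that splits
#' double heterozygotes between cis and trans configurations by their
#' current expected proportions.
#'
#' @param x,y with `phase = "known"`: 0/1 haplotype allele vectors (length
#'   2n, chromosomes aligned); with `phase = "em"`: 0/1/2 diploid genotype
#'   vectors (length n; NAs excluded pairwise)
#' @param phase `"em"` or `"known"`
#' @param tol EM convergence tolerance on haplotype frequencies
#' @param max_iter EM iteration cap
#' @return list of class `ld_pair`: haplotype frequencies `p_AB`, `p_Ab`,
#'   `p_aB`, `p_ab`, `D`, `r2` (NA and flagged when a locus is
#'   monomorphic), `n`, `method`, `converged`, `iterations`
#' @export
ld_r2 <- function(x, y, phase = c("em", "known"), tol = 1e-8,
                  max_iter = 1000L) {
  phase <- match.arg(phase)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (phase == "known") {
    stopifnot(all(x %in% 0:1), all(y %in% 0:1))
    n2 <- length(x)
    p <- c(AB = sum(x == 1 & y == 1), Ab = sum(x == 1 & y == 0),
           aB = sum(x == 0 & y == 1), ab = sum(x == 0 & y == 0)) / n2
    return(finish_ld(p, n2 / 2, "known", TRUE, 0L))
  }
  stopifnot(all(x %in% 0:2), all(y %in% 0:2))
  n <- length(x)
  cls <- table(factor(x, 0:2), factor(y, 0:2))
  pA <- mean(x) / 2; pB <- mean(y) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
           ab = (1 - pA) * (1 - pB))
    out <- finish_ld(p, n, "em", TRUE, 0L)
    out$r2 <- NA_real_
    out$flag <- "monomorphic"
    return(out)
  }
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    cis <- unname(p["AB"] * p["ab"])
    trans <- unname(p["Ab"] * p["aB"])
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    dh <- unname(cls["1", "1"])
    cnt <- c(
      AB = 2 * cls["2", "2"] + cls["2", "1"] + cls["1", "2"] + dh * w,
      Ab = 2 * cls["2", "0"] + cls["2", "1"] + cls["1", "0"] + dh * (1 - w),
      aB = 2 * cls["0", "2"] + cls["1", "2"] + cls["0", "1"] + dh * (1 - w),
      ab = 2 * cls["0", "0"] + cls["1", "0"] + cls["0", "1"] + dh * w
    )
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new; converged <- TRUE
      break
    }
    p <- p_new
  }
  finish_ld(p, n, "em", converged, it)
}

finish_ld <- function(p, n, method, converged, it) {
  pA <- p[["AB"]] + p[["Ab"]]; pB <- p[["AB"]] + p[["aB"]]
  D <- p[["AB"]] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  structure(list(p_AB = p[["AB"]], p_Ab = p[["Ab"]], p_aB = p[["aB"]],
                 p_ab = p[["ab"]], D = D, r2 = r2, n = n, method = method,
                 converged = converged, iterations = it,
                 flag = if (is.na(r2)) "monomorphic" else NA_character_),
            class = "ld_pair")
}

#' Screen all locus pairs for high LD
#'
#' Computes r-squared for every pair of loci on the same chromosome whose
#' distance lies within the configured window, and reports pairs exceeding
#' the threshold.
#'
#' @param geno genotype matrix (individuals x loci, 0/1/2, NAs allowed)
#' @param positions named integer vector of genomic positions (names =
#'   colnames of `geno`)
#' @param chrom named character vector of chromosomes per locus
#' @param min_dist,max_dist distance window in bp (defaults 20 bp - 10 kbp)
#' @param threshold report pairs with r2 above this (default 0.8)
#' @param phase passed to [ld_r2()]
#' @return list with `pairs` (all computed pairs: loci, distance, r2) and
#'   `hits` (pairs with `r2 > threshold`)
#' @export
ld_screen <- function(geno, positions, chrom, min_dist = 20,
                      max_dist = 10000, threshold = 0.8, phase = "em") {
  loci <- colnames(geno)
  stopifnot(!is.null(loci), all(loci %in% names(positions)),
            all(loci %in% names(chrom)))
  cmb <- combn(loci, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1, k]; b <- cmb[2, k]
    if (chrom[[a]] != chrom[[b]]) return(NULL)
    d <- abs(positions[[a]] - positions[[b]])
    if (d < min_dist || d > max_dist) return(NULL)
    ld <- ld_r2(geno[, a], geno[, b], phase = phase)
    data.frame(locus_i = a, locus_j = b, pos_i = positions[[a]],
               pos_j = positions[[b]], distance = d, r2 = ld$r2,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(locus_i = character(), locus_j = character(),
                        pos_i = integer(), pos_j = integer(),
                        distance = integer(), r2 = numeric())
  list(pairs = pairs,
       hits = pairs[!is.na(pairs$r2) & pairs$r2 > threshold, , drop = FALSE])
}

#' Spearman rank correlation between site mortality and allele frequency
#'
#' Midrank-tied Spearman rho; for fewer than 10 paired sites the p-value is
#' a two-sided permutation p (exact enumeration when n <= 8), otherwise the
#' t approximation.
#'
#' @param mortality,freq paired per-site vectors (>= 3 sites)
#' @param n_mc Monte Carlo permutations when exact enumeration is
#'   infeasible
#' @return list with `rho`, `p`, `n`, `method` (`NA` rho and a flag when a
#'   vector is constant)
#' @export
spearman_mortality_freq <- function(mortality, freq, n_mc = 10000L) {
  keep <- !is.na(mortality) & !is.na(freq)
  x <- mortality[keep]; y <- freq[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "constant"))
  rho_of <- function(a, b) cor(rank(a), rank(b))
  rho <- rho_of(x, y)
  if (n < 10) {
    if (n <= 8) {
      perms <- perms_of(n)
      rhos <- apply(perms, 1, function(pm) rho_of(x, y[pm]))
      p <- mean(abs(rhos) >= abs(rho) - 1e-12)
      method <- "exact_permutation"
    } else {
      rhos <- vapply(seq_len(n_mc), function(i) rho_of(x, sample(y)),
                     numeric(1))
      p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_mc + 1)
      method <- "mc_permutation"
    }
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

## all permutations of 1..n as rows (n small)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
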