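## Synthetic-data generators: population genotypes with specified allele
## frequencies and linkage structure, dual-barcoded paired amplicon reads
## with substitution errors and index-hopping, and bottle-bioassay counts.
## Defaults reproduce the study conditions: per-site allele frequencies from
## the bundled site-frequency table, ~190-fold mean coverage with wide
## per-amplicon variation, >= 50,000 read pairs per pool, 8-bp dual tags.

#' Population specification
#'
#' @param site site label
#' @param n_individuals number of diploid individuals
#' @param loci data frame with columns `snp_id` and `freq` (alternative
#'   allele frequency, 0-1) for loci drawn independently under
#'   Hardy-Weinberg
#' @param haplotypes optional linked block: list with `loci` (character
#'   vector of snp_ids), `hap` (0/1 matrix, one row per haplotype) and
#'   `freq` (haplotype frequencies summing to 1). Loci listed here must also
#'   appear in `loci`, and the marginal frequencies implied by the table
#'   must equal the per-locus values within 1e-9.
#' @return list of class `population_spec`
#' @export
population_spec <- function(site, n_individuals, loci, haplotypes = NULL) {
  stopifnot(is.data.frame(loci), all(c("snp_id", "freq") %in% names(loci)),
            n_individuals >= 1)
  if (any(loci$freq < 0 | loci$freq > 1)) stop("allele frequencies must be in [0,1]")
  if (!is.null(haplotypes)) {
    stopifnot(is.matrix(haplotypes$hap),
              length(haplotypes$freq) == nrow(haplotypes$hap),
              length(haplotypes$loci) == ncol(haplotypes$hap))
    if (abs(sum(haplotypes$freq) - 1) > 1e-9)
      stop("haplotype frequencies must sum to 1")
    if (any(haplotypes$freq < 0)) stop("negative haplotype frequency")
    marg <- as.vector(haplotypes$freq %*% haplotypes$hap)
    j <- match(haplotypes$loci, loci$snp_id)
    if (anyNA(j)) stop("haplotype loci missing from loci table")
    if (any(abs(marg - loci$freq[j]) > 1e-9))
      stop("haplotype table inconsistent with per-locus frequencies")
  }
  out <- list(site = site, n_individuals = as.integer(n_individuals),
              loci = loci, haplotypes = haplotypes)
  class(out) <- "population_spec"
  out
}

#' Linked-block haplotype table for the four kdr mutations
#'
#' Builds a haplotype-frequency table over V410L, V1016I, V1016G and F1534C
#' from the four marginal frequencies by a single latent-uniform
#' (comonotone) coupling: each chromosome corresponds to one uniform draw u,
#' a locus carries its alternative allele when u falls below its frequency,
#' and V1016G occupies the interval directly above V1016I so the two
#' alternative codon-1016 alleles never share a chromosome. This
#' construction reproduces the marginals exactly while concentrating the
#' rare wild-type alleles on shared haplotypes, which yields the strong
#' positive pairwise association among the kdr loci seen in surveillance
#' data (r-squared well above 0.5 at these near-fixation frequencies).
#'
#' @param f410,f1016i,f1016g,f1534 marginal alternative-allele frequencies
#'   (0-1; `f1016i + f1016g` must not exceed 1)
#' @return list with `loci`, `hap` (0/1 matrix), `freq`, `marginals`
#' @export
kdr_haplotype_table <- function(f410, f1016i, f1016g, f1534) {
  stopifnot(f1016i + f1016g <= 1 + 1e-9)
  loci <- c("V410L", "V1016I", "V1016G", "F1534C")
  cuts <- sort(unique(pmin(pmax(
    c(0, f410, f1016i, f1016i + f1016g, f1534, 1), 0), 1)))
  lo <- head(cuts, -1); hi <- cuts[-1]
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  mid <- (lo + hi) / 2
  hap <- cbind(V410L = as.integer(mid < f410),
               V1016I = as.integer(mid < f1016i),
               V1016G = as.integer(mid >= f1016i & mid < f1016i + f1016g),
               F1534C = as.integer(mid < f1534))
  freq <- hi - lo
  ## merge duplicate haplotype patterns
  key <- apply(hap, 1, paste, collapse = "")
  freq <- as.vector(tapply(freq, key, sum)[unique(key)])
  hap <- hap[!duplicated(key), , drop = FALSE]
  list(loci = loci, hap = hap, freq = freq,
       marginals = as.vector(freq %*% hap))
}

#' Default study populations
#'
#' One [population_spec()] per site with the bundled per-site frequencies of
#' the six detected resistance mutations, count-table-derived frequencies
#' for the eight minor panel mutations, and the kdr linked block from
#' [kdr_haplotype_table()].
#'
#' @param n_per_site optional named vector overriding the per-site sample
#'   sizes (defaults to [site_sample_sizes()])
#' @return named list of `population_spec`
#' @export
default_populations <- function(n_per_site = site_sample_sizes()) {
  sf <- site_frequency_table()
  gc <- genotype_count_table()
  minor <- c("A482T", "I1845S", "Q1805stop", "G1738S", "V1716L", "F967C",
             "F943Y", "L895R")
  gi <- match(minor, gc$snp_id)
  minor_freq <- (gc$het[gi] + 2 * gc$hom_alt[gi]) /
    (2 * (gc$hom_ref[gi] + gc$het[gi] + gc$hom_alt[gi]))
  site_f <- function(site, id) sf$freq[sf$site == site & sf$snp_id == id] / 100
  lapply(setNames(names(n_per_site), names(n_per_site)), function(s) {
    linked <- kdr_haplotype_table(site_f(s, "V410L"), site_f(s, "V1016I"),
                                  site_f(s, "V1016G"), site_f(s, "F1534C"))
    loci <- data.frame(
      snp_id = c("A296S", "L944I", linked$loci, minor),
      freq = c(site_f(s, "A296S"), site_f(s, "L944I"), linked$marginals,
               minor_freq),
      stringsAsFactors = FALSE
    )
    population_spec(s, n_per_site[[s]], loci,
                    haplotypes = linked[c("loci", "hap", "freq")])
  })
}

#' Simulate diploid genotypes
#'
#' Unlinked loci are drawn under Hardy-Weinberg at their stated frequency
#' (each chromosome an independent Bernoulli draw); loci in the linked block
#' are drawn by sampling two haplotypes from the haplotype table.
#'
#' @param panel an `amplicon_panel` (loci not on the panel are permitted;
#'   only used downstream by the read simulator)
#' @param popspec a [population_spec()]
#' @param seed integer seed
#' @return list of class `sim_genotypes` with `sample_ids`, `site`,
#'   `snp_ids`, haplotype matrices `hap1`/`hap2` (individual x locus, 0/1)
#'   and `geno = hap1 + hap2`
#' @export
simulate_genotypes <- function(panel, popspec, seed = 1L) {
  stopifnot(inherits(popspec, "population_spec"))
  ## re-validate the haplotype table against the marginals (reject if stale)
  popspec <- population_spec(popspec$site, popspec$n_individuals,
                             popspec$loci, popspec$haplotypes)
  n <- popspec$n_individuals
  ids <- popspec$loci$snp_id
  with_seed(seed, {
    draw_hap <- function() {
      m <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
      hb <- popspec$haplotypes
      linked <- if (is.null(hb)) character(0) else hb$loci
      for (j in seq_along(ids)) {
        if (!(ids[j] %in% linked))
          m[, j] <- rbinom(n, 1L, popspec$loci$freq[j])
      }
      if (length(linked)) {
        hi <- sample.int(nrow(hb$hap), n, replace = TRUE, prob = hb$freq)
        m[, linked] <- hb$hap[hi, , drop = FALSE]
      }
      m
    }
    hap1 <- draw_hap()
    hap2 <- draw_hap()
    out <- list(sample_ids = sprintf("%s_%03d", popspec$site, seq_len(n)),
                site = popspec$site, snp_ids = ids,
                hap1 = hap1, hap2 = hap2, geno = hap1 + hap2)
    class(out) <- "sim_genotypes"
    out
  })
}

#' Combine per-site genotype sets into one cohort
#'
#' @param ... `sim_genotypes` objects (or a single list of them)
#' @return a `sim_genotypes` with stacked samples
#' @export
combine_genotypes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "sim_genotypes")) gs <- gs[[1]]
  ids <- gs[[1]]$snp_ids
  stopifnot(all(vapply(gs, function(g) identical(g$snp_ids, ids), logical(1))))
  out <- list(
    sample_ids = unlist(lapply(gs, `[[`, "sample_ids"), use.names = FALSE),
    site = unlist(lapply(gs, function(g) rep(g$site, length(g$sample_ids))),
                  use.names = FALSE),
    snp_ids = ids,
    hap1 = do.call(rbind, lapply(gs, `[[`, "hap1")),
    hap2 = do.call(rbind, lapply(gs, `[[`, "hap2"))
  )
  out$geno <- out$hap1 + out$hap2
  class(out) <- "sim_genotypes"
  out
}

#' Read-simulation specification
#'
#' @param mean_coverage mean read pairs per amplicon per sample (fold
#'   coverage; study value 190.5)
#' @param coverage_dispersion sdlog of the per-amplicon lognormal coverage
#'   multiplier (0 = uniform coverage across amplicons)
#' @param substitution_error_rate per-base substitution error rate
#' @param mistag_rate probability that a read pair carries one wrong
#'   (hopped) index tag
#' @param min_pool_reads minimum total read pairs per pool; coverage is
#'   scaled up if the expected yield falls short
#' @param read_length read length in bp (paired 250 bp geometry)
#' @param base_quality constant Phred quality assigned to simulated bases
#' @param divergent_intron simulate reads from the divergent-intron
#'   alternate haplotype for amplicons that define one
#' @return list of class `read_sim_spec`
#' @export
read_sim_spec <- function(mean_coverage = 190.5, coverage_dispersion = 0.6,
                          substitution_error_rate = 0.001, mistag_rate = 0,
                          min_pool_reads = 50000L, read_length = 250L,
                          base_quality = 37L, divergent_intron = TRUE) {
  stopifnot(mean_coverage > 0, coverage_dispersion >= 0,
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            mistag_rate >= 0, mistag_rate <= 1, read_length >= 36)
  out <- list(mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              substitution_error_rate = substitution_error_rate,
              mistag_rate = mistag_rate,
              min_pool_reads = as.integer(min_pool_reads),
              read_length = as.integer(read_length),
              base_quality = as.integer(base_quality),
              divergent_intron = isTRUE(divergent_intron))
  class(out) <- "read_sim_spec"
  out
}

#' Generate dual-index barcodes
#'
#' Random tags with pairwise Hamming distance >= `min_dist` (default 3) so a
#' one-mismatch-tolerant demultiplexer is unambiguous.
#'
#' @param n number of tags
#' @param length tag length in bp
#' @param min_dist minimum pairwise Hamming distance
#' @param seed integer seed
#' @return character vector of `n` tags
#' @export
generate_barcodes <- function(n, length = 8L, min_dist = 3L, seed = 1L) {
  with_seed(seed, {
    tags <- character(0)
    tries <- 0L
    while (length(tags) < n) {
      cand <- random_dna(length)
      if (!length(tags) || min(hamming_many(cand, tags)) >= min_dist) {
        tags <- c(tags, cand)
      }
      tries <- tries + 1L
      if (tries > 10000L * n) stop("cannot place ", n, " barcodes at distance ",
                                   min_dist)
    }
    tags
  })
}

#' Build a sample sheet with unique dual barcodes
#'
#' @param genotypes a `sim_genotypes` cohort
#' @param barcode_length tag length in bp
#' @param seed integer seed
#' @return data frame with `sample_id`, `site`, `fwd_tag`, `rev_tag`
#' @export
build_sample_sheet <- function(genotypes, barcode_length = 8L, seed = 1L) {
  n <- length(genotypes$sample_ids)
  fwd <- generate_barcodes(n, barcode_length, seed = seed)
  rev <- generate_barcodes(n, barcode_length, seed = seed + 1000L)
  data.frame(sample_id = genotypes$sample_ids, site = genotypes$site,
             fwd_tag = fwd, rev_tag = rev, stringsAsFactors = FALSE)
}

#' Simulate barcoded paired-end amplicon reads
#'
#' Each read pair is a primer-to-primer fragment of one of the sample's two
#' amplicon haplotypes: R1 is the first `read_length` bases (5' tag
#' prepended), R2 the reverse complement end (3' tag prepended). Coverage is
#' Poisson per sample x amplicon around a per-amplicon lognormal multiplier;
#' substitution errors hit insert bases uniformly; with probability
#' `mistag_rate` one of the two tags is swapped for another sample's tag
#' (index hopping). A truth table records every pair's source.
#'
#' @param panel an `amplicon_panel`
#' @param genotypes a `sim_genotypes` cohort covering every sample in
#'   `sample_sheet`
#' @param readspec a [read_sim_spec()]
#' @param sample_sheet data frame from [build_sample_sheet()]
#' @param seed integer seed
#' @return list with `reads` (data frame `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`) and `truth` (`read_id`, `sample_id`, `amplicon_id`,
#'   `hap_index`, `mistag`)
#' @export
simulate_reads <- function(panel, genotypes, readspec, sample_sheet,
                           seed = 1L) {
  stopifnot(inherits(readspec, "read_sim_spec"))
  miss <- setdiff(sample_sheet$sample_id, genotypes$sample_ids)
  if (length(miss)) stop("no genotypes for sample(s): ",
                         paste(miss, collapse = ", "))
  amp <- panel$amplicons
  n_samp <- nrow(sample_sheet)
  with_seed(seed, {
    mult <- if (readspec$coverage_dispersion > 0) {
      s <- readspec$coverage_dispersion
      rlnorm(nrow(amp), meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, nrow(amp))
    lambda <- readspec$mean_coverage * mult
    expected <- n_samp * sum(lambda)
    if (expected < readspec$min_pool_reads)
      lambda <- lambda * readspec$min_pool_reads / expected

    qchar <- rawToChar(as.raw(readspec$base_quality + 33L))
    e <- readspec$substitution_error_rate
    bases <- c("A", "C", "G", "T")

    seqs1 <- list(); seqs2 <- list(); truth <- list(); li <- 0L
    for (si in seq_len(n_samp)) {
      gi <- match(sample_sheet$sample_id[si], genotypes$sample_ids)
      for (ai in seq_len(nrow(amp))) {
        n_pairs <- rpois(1L, lambda[ai])
        if (n_pairs == 0L) next
        hap_idx <- sample.int(2L, n_pairs, replace = TRUE)
        for (h in 1:2) {
          nh <- sum(hap_idx == h)
          if (!nh) next
          hseq <- haplotype_sequence(panel, genotypes, gi, ai, h,
                                     readspec$divergent_intron)
          r1 <- substr(hseq, 1L, readspec$read_length)
          r2 <- substr(revcomp(hseq), 1L, readspec$read_length)
          s1 <- apply_errors(rep.int(r1, nh), e, bases)
          s2 <- apply_errors(rep.int(r2, nh), e, bases)
          li <- li + 1L
          seqs1[[li]] <- s1; seqs2[[li]] <- s2
          truth[[li]] <- data.frame(
            sample_id = sample_sheet$sample_id[si],
            amplicon_id = amp$amplicon_id[ai], hap_index = h,
            stringsAsFactors = FALSE
          )[rep(1L, nh), ]
        }
      }
    }
    s1 <- unlist(seqs1, use.names = FALSE)
    s2 <- unlist(seqs2, use.names = FALSE)
    tr <- do.call(rbind, truth)
    n_reads <- length(s1)
    rownames(tr) <- NULL
    tr$read_id <- sprintf("r%07d", seq_len(n_reads))

    ## index hopping: swap one tag for another sample's
    sidx <- match(tr$sample_id, sample_sheet$sample_id)
    fwd <- sample_sheet$fwd_tag[sidx]
    rev <- sample_sheet$rev_tag[sidx]
    mist <- rep(FALSE, n_reads)
    if (readspec$mistag_rate > 0 && n_samp > 1) {
      mist <- runif(n_reads) < readspec$mistag_rate
      k <- which(mist)
      if (length(k)) {
        other <- vapply(sidx[k], function(i)
          sample(setdiff(seq_len(n_samp), i), 1L), integer(1))
        swap_fwd <- runif(length(k)) < 0.5
        fwd[k[swap_fwd]] <- sample_sheet$fwd_tag[other[swap_fwd]]
        rev[k[!swap_fwd]] <- sample_sheet$rev_tag[other[!swap_fwd]]
      }
    }
    tr$mistag <- mist

    reads <- data.frame(
      read_id = tr$read_id,
      seq1 = paste0(fwd, s1),
      seq2 = paste0(rev, s2),
      stringsAsFactors = FALSE
    )
    reads$qual1 <- strrep(qchar, nchar(reads$seq1))
    reads$qual2 <- strrep(qchar, nchar(reads$seq2))
    list(reads = reads[, c("read_id", "seq1", "qual1", "seq2", "qual2")],
         truth = tr[, c("read_id", "sample_id", "amplicon_id", "hap_index",
                        "mistag")])
  })
}

## Amplicon haplotype sequence for one individual: alternate (divergent
## intron) backbone where configured, target-SNP alt alleles substituted
## where the haplotype carries them.
haplotype_sequence <- function(panel, genotypes, gi, ai, h, divergent) {
  amp <- panel$amplicons[ai, ]
  s <- if (divergent && !is.na(amp$alt_sequence)) amp$alt_sequence else amp$sequence
  snps <- panel$snps[panel$snps$amplicon_id == amp$amplicon_id, ]
  if (nrow(snps)) {
    hm <- if (h == 1L) genotypes$hap1 else genotypes$hap2
    for (k in seq_len(nrow(snps))) {
      j <- match(snps$snp_id[k], genotypes$snp_ids)
      if (!is.na(j) && hm[gi, j] == 1L) {
        o <- snps$offset[k] + 1L
        substr(s, o, o) <- snps$alt[k]
      }
    }
  }
  s
}

## Uniform per-base substitution errors on a vector of equal reads.
apply_errors <- function(reads, e, bases) {
  if (e <= 0 || !length(reads)) return(reads)
  len <- nchar(reads[1])
  k <- rbinom(length(reads), len, e)
  for (i in which(k > 0)) {
    pos <- sample.int(len, k[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Bioassay simulation specification
#'
#' @param cells data frame with columns `site`, `insecticide`,
#'   `dose_multiplier`, `dose_ug` and `p` (true mortality probability)
#' @param n_range bottle occupancy range (18-25 mosquitoes per CDC practice)
#' @param bottles_per_cell replicate bottles per cell
#' @return list of class `bioassay_sim_spec`
#' @export
bioassay_sim_spec <- function(cells, n_range = c(18L, 25L),
                              bottles_per_cell = 3L) {
  stopifnot(all(c("site", "insecticide", "dose_multiplier", "dose_ug", "p")
                %in% names(cells)),
            all(cells$p >= 0 & cells$p <= 1),
            n_range[1] >= 18L, n_range[2] <= 25L, n_range[1] <= n_range[2])
  out <- list(cells = cells, n_range = as.integer(n_range),
              bottles_per_cell = as.integer(bottles_per_cell))
  class(out) <- "bioassay_sim_spec"
  out
}

#' Simulate bottle-bioassay mortality counts
#'
#' Deaths per bottle are Binomial(n, p); bottles are aggregated per cell.
#'
#' @param spec a [bioassay_sim_spec()]
#' @param seed integer seed
#' @return data frame of bioassay records: `site`, `insecticide`,
#'   `dose_multiplier`, `dose_ug`, `n`, `deaths`, `pct`
#' @export
simulate_bioassay <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bioassay_sim_spec"))
  with_seed(seed, {
    cells <- spec$cells
    n <- integer(nrow(cells)); deaths <- integer(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      nb <- sample(seq(spec$n_range[1], spec$n_range[2]),
                   spec$bottles_per_cell, replace = TRUE)
      db <- rbinom(spec$bottles_per_cell, nb, cells$p[i])
      n[i] <- sum(nb); deaths[i] <- sum(db)
    }
    data.frame(site = cells$site, insecticide = cells$insecticide,
               dose_multiplier = cells$dose_multiplier,
               dose_ug = cells$dose_ug, n = n, deaths = deaths,
               pct = 100 * deaths / n, stringsAsFactors = FALSE)
  })
}
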