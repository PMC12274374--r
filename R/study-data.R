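## Bundled surveillance results from a 2022 Ae. aegypti survey across five
## Puerto Rico municipalities (Bayamon, Dorado, Guanica, Ponce, San Juan).
## These printed tables are inputs: the bioassay cells drive the mortality
## model, the genotype counts drive the frequency tables, and the per-site
## frequencies parameterise the synthetic populations.

#' CDC bottle-bioassay mortality table
#'
#' Per site x insecticide x dose cell: printed percentage mortality at the
#' diagnostic time (30 min deltamethrin, 15 min malathion) and the number of
#' mosquitoes tested. `treatment` distinguishes unexposed field controls
#' (`control`), the susceptible ROCK colony at diagnostic dose (`rock`) and
#' field mosquitoes at 1x/2x/3x/5x/10x the diagnostic dose.
#'
#' @return data frame with columns `site`, `insecticide`, `treatment`,
#'   `dose_multiplier`, `dose_ug`, `pct`, `n`
#' @export
bioassay_table <- function() {
  sites <- c("Bayamon", "Dorado", "Ponce", "SanJuan")
  cell <- function(insecticide, treatment, mult, dose, pct, n) {
    data.frame(site = sites, insecticide = insecticide, treatment = treatment,
               dose_multiplier = mult, dose_ug = dose, pct = pct, n = n,
               stringsAsFactors = FALSE)
  }
  rbind(
    cell("deltamethrin", "control", NA, 0,     c(0.0, 0.0, 0.0, 1.1),   c(91, 36, 46, 88)),
    cell("deltamethrin", "rock",    1,  0.75,  c(97.4, 100, 97.5, 100), c(78, 45, 40, 73)),
    cell("deltamethrin", "x1",      1,  0.75,  c(22.7, 2.2, 40.4, 21.4), c(97, 45, 47, 98)),
    cell("deltamethrin", "x5",      5,  3.75,  c(42.2, 46.7, 76.2, 41.8), c(64, 45, 42, 91)),
    cell("deltamethrin", "x10",     10, 7.5,   c(90, 87.2, 93.6, 89),   c(50, 39, 47, 100)),
    cell("malathion",    "control", NA, 0,     c(0.0, 0.0, 0.0, 0.0),   c(70, 105, 48, 60)),
    cell("malathion",    "rock",    1,  400,   c(96.1, 100, 95.2, 72.4), c(51, 45, 42, 69)),
    cell("malathion",    "x1",      1,  400,   c(36.4, 17.6, 87.2, 40), c(66, 91, 47, 70)),
    cell("malathion",    "x2",      2,  800,   c(51, 50.7, 91.7, 61.4), c(49, 69, 48, 70)),
    cell("malathion",    "x3",      3,  1200,  c(83.7, 82.6, 100, 62.3), c(49, 23, 27, 77))
  )
}

#' Genotype counts for the 14 non-synonymous panel mutations
#'
#' Diploid genotype counts (homozygous reference / heterozygous / homozygous
#' alternative) over the 178 field samples that passed QC, one row per
#' mutation, with the frequency as printed in the source table.
#' `printed_freq` for the Q1805stop row (3.61) is inconsistent with its own
#' counts (which imply 3.80); downstream frequency computation always works
#' from the counts.
#'
#' @return data frame with columns `snp_id`, `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `codon`, `hom_ref`, `het`, `hom_alt`, `printed_freq`
#' @export
genotype_count_table <- function() {
  data.frame(
    snp_id = c("A296S", "A482T", "I1845S", "Q1805stop", "G1738S", "V1716L",
               "F1534C", "V1016G", "V1016I", "F967C", "F943Y", "L944I",
               "L895R", "V410L"),
    gene = c("rdl", "ace1", rep("vgsc", 12)),
    chrom = c("2", rep("3", 13)),
    pos = c(41847790L, 161500150L, 315931756L, 315931943L, 315932144L,
            315932210L, 315939224L, 315983762L, 315983763L, 315984130L,
            315998386L, 315998453L, 315998530L, 316080722L),
    ref = c("G", "C", "A", "G", "C", "C", "A", "A", "C", "A", "A", "A",
            "A", "C"),
    alt = c("T", "T", "C", "A", "T", "A", "C", "C", "T", "C", "T", "T",
            "C", "A"),
    codon = c(301L, 482L, 1854L, 1814L, 1747L, 1725L, 1534L, 1016L, 1016L,
              979L, 932L, 910L, 884L, 410L),
    hom_ref = c(7L, 105L, 115L, 73L, 89L, 88L, 0L, 50L, 0L, 50L, 137L,
                95L, 118L, 0L),
    het = c(24L, 1L, 1L, 6L, 1L, 2L, 18L, 5L, 5L, 8L, 1L, 30L, 6L, 15L),
    hom_alt = c(28L, 0L, 0L, 0L, 0L, 0L, 109L, 0L, 50L, 0L, 0L, 2L, 0L,
                101L),
    printed_freq = c(67.7, 0.47, 0.43, 3.61, 0.56, 1.11, 92.91, 4.55,
                     95.45, 6.90, 0.36, 22.08, 2.42, 93.53),
    stringsAsFactors = FALSE
  )
}

#' Per-site allele frequencies (%) of the six resistance mutations
#'
#' @return data frame in long form with columns `snp_id`, `site`
#'   (`"Overall"` or a municipality) and `freq` (percent)
#' @export
site_frequency_table <- function() {
  sites <- c("Overall", "Bayamon", "Dorado", "Guanica", "Ponce", "SanJuan")
  f <- rbind(
    A296S  = c(66.8, 92.3, 40.6, 83.3, 55.9, 100),
    F1534C = c(92.9, 95.6, 82.8, 100, 90.9, 100),
    V1016G = c(4.7, 5.6, 11.1, 0.0, 10.0, 0.0),
    V1016I = c(95.3, 94.4, 88.9, 100, 90.0, 100),
    L944I  = c(13.4, 13.9, 8.1, 14.3, 14.0, 17.9),
    V410L  = c(93.5, 95.5, 84.6, 100, 91.3, 100)
  )
  data.frame(snp_id = rep(rownames(f), each = length(sites)),
             site = rep(sites, times = nrow(f)),
             freq = as.vector(t(f)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of QC-passing sequenced samples per site
#'
#' @return named integer vector (total 178)
#' @export
site_sample_sizes <- function() {
  c(Bayamon = 51L, Dorado = 42L, Guanica = 7L, Ponce = 33L, SanJuan = 45L)
}
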