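## Configuration-driven orchestration: simulate -> demux -> trim -> align ->
## genotype/phase -> frequency & LD tables -> bioassay model, with a run
## manifest. Every stage is also callable standalone.

#' Pipeline run configuration
#'
#' Builds (and validates) the configuration list consumed by
#' [run_pipeline()]. `config` may be a YAML/JSON file path or a named list;
#' values omitted fall back to defaults sized for a quick demonstration
#' run. Any entry named `*_file` must point to an existing file.
#'
#' @param config path to a YAML/JSON file, or a named list of overrides
#' @return list of class `run_config`
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 42L,
    outdir = file.path(tempdir(), "kdrseq_run"),
    n_per_site = list(Bayamon = 5L, Dorado = 4L, Guanica = 2L, Ponce = 4L,
                      SanJuan = 5L),
    mean_coverage = 50,
    coverage_dispersion = 0.3,
    substitution_error_rate = 0.001,
    mistag_rate = 0.01,
    min_pool_reads = 1L,
    max_mismatch = 1L,
    min_identity = 0.8,
    error_rate_caller = 0.01,
    min_depth = 10L,
    min_amplicons = 6L,
    ld_min_dist = 20,
    ld_max_dist = 10000,
    ld_threshold = 0.8,
    concentration_coding = "multiplier",
    write_fastq = TRUE
  )
  unknown <- setdiff(names(config),
                     c(names(defaults), "bioassay_file"))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in grep("_file$", names(cfg), value = TRUE)) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "' refers to a missing file: ", cfg[[f]])
  }
  cfg$n_per_site <- unlist(cfg$n_per_site)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full surveillance pipeline
#'
#' Simulates the study cohort under the configured conditions, pushes the
#' pooled reads through demultiplexing, trimming, alignment and genotype
#' calling, resolves the codon-1016 phase, and writes the frequency tables,
#' LD screens, VCF, bioassay analysis and a JSON manifest into the output
#' directory. Deterministic (byte-identical tables) for a fixed
#' configuration and seed.
#'
#' @param config a [run_config()], list of overrides, or config file path
#' @return invisibly, a list with all in-memory stage results
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run.log")
  cat(sprintf("kdrseq pipeline, seed %d\n", config$seed), file = logfile)
  manifest <- list(package_version = as.character(utils::packageVersion("kdrseq")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   parameters = unclass(config), stages = list())
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <- "failed"
    manifest$error <- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    manifest$stages[[name]] <<- "ok"
    res
  }

  panel <- stage("panel", build_panel(panel_config(), seed = config$seed))
  write_panel_fasta(panel, file.path(config$outdir, "panel.fasta"))
  note("panel", "%d amplicons, %d target SNPs", nrow(panel$amplicons),
       nrow(panel$snps))

  cohort <- stage("genotypes", {
    pops <- default_populations(config$n_per_site)
    gs <- lapply(seq_along(pops), function(i)
      simulate_genotypes(panel, pops[[i]], seed = config$seed + i))
    combine_genotypes(gs)
  })
  sheet <- stage("sample_sheet",
                 build_sample_sheet(cohort, panel$config$barcode_length,
                                    seed = config$seed + 100L))
  write.table(sheet, file.path(config$outdir, "sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sim <- stage("reads", {
    spec <- read_sim_spec(mean_coverage = config$mean_coverage,
                          coverage_dispersion = config$coverage_dispersion,
                          substitution_error_rate = config$substitution_error_rate,
                          mistag_rate = config$mistag_rate,
                          min_pool_reads = config$min_pool_reads)
    simulate_reads(panel, cohort, spec, sheet, seed = config$seed + 200L)
  })
  note("reads", "%d read pairs simulated", nrow(sim$reads))
  if (isTRUE(config$write_fastq))
    write_fastq_pairs(sim$reads, file.path(config$outdir, "pool"))
  write.table(sim$truth, file.path(config$outdir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  dmx <- stage("demux", demultiplex(sim$reads, sheet,
                                    max_mismatch = config$max_mismatch))
  note("demux", "assigned %d, mistag %d, unknown %d",
       dmx$counts[["assigned"]], dmx$counts[["mistag"]],
       dmx$counts[["unknown"]])
  write.table(dmx$discard_log, file.path(config$outdir, "demux_discards.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  trm <- stage("trim", trim_reads(dmx$assigned, trim_params()))
  note("trim", "%d pairs kept, %d dropped", nrow(trm$reads),
       nrow(trm$drop_log))

  per_sample <- stage("align_genotype", {
    index <- build_ref_index(panel)
    coi_ref <- panel$amplicons$sequence[panel$amplicons$role == "species"][1]
    lapply(setNames(sheet$sample_id, sheet$sample_id), function(s) {
      mates <- pairs_to_mates(trm$reads[trm$reads$sample_id == s, ,
                                        drop = FALSE])
      aligned <- align_reads(mates, panel, config$min_identity, index)
      pileups <- build_pileup(aligned, panel)
      covsum <- coverage_summary(pileups)
      calls <- call_sample_genotypes(pileups, panel,
                                     error_rate = config$error_rate_caller,
                                     min_depth = config$min_depth)
      calls$sample_id <- s
      phase <- resolve_codon_phase(panel, "vgsc_1016", 1016L, calls, aligned)
      sp <- species_check(pileups[["coi"]], coi_ref)
      list(aligned = aligned, pileups = pileups, covsum = covsum,
           qc_pass = sample_qc(covsum, config$min_amplicons),
           calls = calls, phase1016 = phase, species = sp)
    })
  })

  calls <- do.call(rbind, lapply(per_sample, `[[`, "calls"))
  calls$site <- sheet$site[match(calls$sample_id, sheet$sample_id)]
  qc <- vapply(per_sample, `[[`, logical(1), "qc_pass")
  calls_qc <- calls[qc[calls$sample_id], , drop = FALSE]
  note("qc", "%d/%d samples pass coverage QC", sum(qc), length(qc))

  tables <- stage("tables", {
    t2 <- frequency_table(calls_qc, "overall", digits = 2)
    t3 <- frequency_table(calls_qc, "site", digits = 1)
    write.table(t2, file.path(config$outdir, "frequencies_overall.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(t3, file.path(config$outdir, "frequencies_by_site.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ph <- do.call(rbind, lapply(names(per_sample), function(s) {
      p <- per_sample[[s]]$phase1016
      data.frame(sample_id = s, hap1 = p$haplotype_names[1],
                 hap2 = p$haplotype_names[2], status = p$status,
                 support1 = p$support[1], support2 = p$support[2],
                 stringsAsFactors = FALSE)
    }))
    write.table(ph, file.path(config$outdir, "codon1016_phase.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(overall = t2, by_site = t3, phase1016 = ph)
  })

  ld <- stage("ld", {
    ids <- panel$snps$snp_id
    geno <- matrix(NA_integer_, sum(qc), length(ids),
                   dimnames = list(names(per_sample)[qc], ids))
    code <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, no_call = NA_integer_)
    for (s in rownames(geno)) {
      cs <- per_sample[[s]]$calls
      geno[s, cs$snp_id] <- code[cs$genotype]
    }
    pos <- setNames(panel$snps$pos, ids)
    chrom <- setNames(panel$snps$chrom, ids)
    on3 <- ids[chrom == "3"]
    windowed <- ld_screen(geno[, on3, drop = FALSE], pos, chrom,
                          min_dist = config$ld_min_dist,
                          max_dist = config$ld_max_dist,
                          threshold = config$ld_threshold)
    kdr <- c("V410L", "V1016I", "V1016G", "F1534C")
    block <- ld_screen(geno[, kdr, drop = FALSE], pos, chrom,
                       min_dist = config$ld_min_dist, max_dist = Inf,
                       threshold = config$ld_threshold)
    write.table(windowed$pairs, file.path(config$outdir, "ld_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(block$pairs, file.path(config$outdir, "ld_kdr_block.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(windowed = windowed, kdr_block = block, geno = geno)
  })

  bio <- stage("bioassay", {
    tab <- if (!is.null(config$bioassay_file)) {
      read.table(config$bioassay_file, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
    } else bioassay_table()
    rec <- reconstruct_deaths(tab$pct, tab$n)
    tab$deaths <- rec$deaths
    tab$consistent <- rec$consistent
    tab$class <- classify_mortality(tab$pct)
    exposed <- tab[!(tab$treatment %in% c("control", "rock")), , drop = FALSE]
    pooled <- do.call(rbind, lapply(split(
      exposed, paste(exposed$insecticide, exposed$treatment)), function(g) {
        data.frame(insecticide = g$insecticide[1], treatment = g$treatment[1],
                   n = sum(g$n), pooled_pct = pooled_mortality(g),
                   stringsAsFactors = FALSE)
      }))
    fit <- fit_poisson_loglinear(exposed, config$concentration_coding)
    lrts <- lapply(setNames(fit$terms, fit$terms), function(tm) {
      red <- fit_poisson_loglinear(exposed, config$concentration_coding,
                                   formula_terms = setdiff(fit$terms, tm))
      likelihood_ratio_test(fit, red)
    })
    summ <- data.frame(term = names(fit$coefficients),
                       estimate = fit$coefficients, se = fit$se,
                       row.names = NULL)
    write.table(tab, file.path(config$outdir, "bioassay_classified.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pooled, file.path(config$outdir, "bioassay_pooled.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summ, file.path(config$outdir, "bioassay_model.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tab, pooled = pooled, fit = fit, lrt = lrts)
  })

  stage("vcf", {
    ph <- tables$phase1016
    resolved <- ph[ph$status == "resolved", , drop = FALSE]
    phase <- NULL
    if (nrow(resolved)) {
      v1016 <- panel$snps[panel$snps$snp_id %in% c("V1016G", "V1016I"), ]
      ps <- min(v1016$pos)
      phase <- do.call(rbind, lapply(seq_len(nrow(resolved)), function(i) {
        s <- resolved$sample_id[i]
        cs <- calls[calls$sample_id == s & calls$pos %in% v1016$pos, ]
        m <- match(v1016$pos, cs$pos)
        compound <- !anyNA(m) && all(cs$genotype[m] == "het")
        if (!compound) return(NULL)
        data.frame(sample_id = s, pos = v1016$pos,
                   gt = c("1|0", "0|1"), ps = ps, stringsAsFactors = FALSE)
      }))
    }
    write_vcf(calls, panel, file.path(config$outdir, "calls.vcf"),
              phase = phase)
  })

  manifest$counts <- list(samples = length(per_sample),
                          read_pairs = nrow(sim$reads),
                          assigned = unname(dmx$counts[["assigned"]]),
                          qc_pass = sum(qc))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = config, panel = panel, cohort = cohort,
                 sheet = sheet, sim = sim, demux = dmx, trimmed = trm,
                 per_sample = per_sample, calls = calls, qc = qc,
                 tables = tables, ld = ld, bioassay = bio))
}
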