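#' Run the full divergence-analysis pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> genotype QC -> FST -> per-ring mixed
#' model battery -> QST -> QST-vs-FST comparison as one logged, reproducible
#' run. Every stage writes its outputs (TSV/JSON/VCF) into `out_dir`, stages
#' communicate only through those files' in-memory equivalents, and a
#' manifest records the configuration, seed, package version and a checksum
#' of every file written. Re-running with the same configuration and seed
#' reproduces all outputs.
#'
#' The configuration is a named list (or path to a YAML file) with elements:
#' \describe{
#'   \item{seed}{mandatory integer seed.}
#'   \item{simulate}{a list of [sim_config()] arguments, \emph{or}}
#'   \item{vcf, popfile, phenotypes}{paths to input files (VCF + population
#'     table + long-format phenotype TSV).}
#'   \item{filters}{optional: `min_per_class` (default 5),
#'     `max_sample_missing`, `max_locus_missing` (default 0.7),
#'     `min_offspring_per_site` (default 4).}
#'   \item{rings}{optional: `max_ring` (13), `drop_innermost` (2).}
#'   \item{traits, qst_method, alpha}{optional analysis settings.}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `qst_fst` fit, the filter reports and
#'   the manifest. Outputs on disk: `genotypes.vcf`, `populations.tsv`,
#'   `phenotypes.tsv`, `filter_report.json`, `fst_per_snp.tsv`,
#'   `fst_summary.json`, `battery.tsv`, `verdicts.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("configuration error: 'seed' is mandatory")
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$phenotypes) && !is.null(config$vcf)
  if (!has_sim && !has_files)
    stop("configuration error: need either a 'simulate' block or 'vcf' + 'phenotypes' paths")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    r <- tryCatch(force(expr), error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage %s: done", name)
    r
  }

  set.seed(as.integer(config$seed))

  ## --- inputs -------------------------------------------------------------
  inputs <- stage("input", {
    if (has_sim) {
      cfg <- do.call(sim_config, c(config$simulate,
                                   list(seed = as.integer(config$seed))))
      sim <- simulate_study(cfg)
      write_vcf(sim$genotypes, file.path(out_dir, "genotypes.vcf"),
                file.path(out_dir, "populations.tsv"))
      utils::write.table(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(geno = sim$genotypes, pheno = sim$phenotypes)
    } else {
      list(geno = read_vcf(config$vcf, config$popfile),
           pheno = utils::read.delim(config$phenotypes,
                                     stringsAsFactors = FALSE))
    }
  })

  flt <- config$filters %||% list()
  rng <- config$rings %||% list()

  ## --- genotype QC --------------------------------------------------------
  qc <- stage("qc", {
    g1 <- filter_missingness(inputs$geno,
                             flt$max_sample_missing %||% 0.7,
                             flt$max_locus_missing %||% 0.7)
    g2 <- filter_genotype_class_count(g1, flt$min_per_class %||% 5L)
    reports <- list(missingness = unclass(attr(g1, "report")),
                    class_count = unclass(attr(g2, "report")))
    jsonlite::write_json(reports, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(geno = g2, reports = reports)
  })

  ## --- phenotype preparation ----------------------------------------------
  pheno <- stage("phenotypes", {
    p <- prepare_rings(inputs$pheno, rng$max_ring %||% 13L,
                       rng$drop_innermost %||% 2L,
                       rng$last_calendar_year)
    p <- filter_families(p, flt$min_offspring_per_site %||% 4L)
    p <- normalize_traits(p)
    utils::write.table(p, file.path(out_dir, "phenotypes_prepared.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  ## --- FST ----------------------------------------------------------------
  fst <- stage("fst", {
    d <- fst_distribution(qc$geno)
    utils::write.table(
      data.frame(chrom = d$loci$chrom, pos = d$loci$pos, fst = d$per_snp),
      file.path(out_dir, "fst_per_snp.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_fst = d$mean_fst,
           mean_fst_ratio_of_sums = d$mean_fst_ratio_of_sums,
           q95 = d$q95, n_loci = sum(!is.na(d$per_snp)),
           n_positive = length(d$positive_part)),
      file.path(out_dir, "fst_summary.json"), auto_unbox = TRUE, digits = NA)
    d
  })

  ## --- battery + QST + comparison ----------------------------------------
  fit <- stage("qst_fst", {
    traits <- config$traits %||% c("dbh", "rw", "wd", "trw", "ttw", "twt")
    f <- qst_fst(pheno, fst, traits = traits,
                 qst_method = config$qst_method %||% "printed",
                 include_abh = isTRUE(config$include_abh))
    utils::write.table(f$battery$results, file.path(out_dir, "battery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(f$verdicts, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  ## --- manifest -----------------------------------------------------------
  manifest <- stage("manifest", {
    files <- setdiff(list.files(out_dir), c("manifest.json", "run.log"))
    m <- list(package = "qstfst",
              version = as.character(utils::packageVersion("qstfst")),
              seed = as.integer(config$seed),
              config = config,
              files = as.list(tools::md5sum(file.path(out_dir, files))))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  invisible(list(fit = fit, qc = qc$reports, manifest = manifest,
                 out_dir = out_dir))
}
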