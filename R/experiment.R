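# build the pedigree a replicate induces: template structure and flags,
# affection (and phenotyped flag) replaced by the replicate's
replicate_pedigree <- function(template, rep) {
  aff <- rep$affection[template$id]
  pedigree(template$id, template$father, template$mother, template$sex,
           aff, genotyped = template$genotyped, phenotyped = aff != 0L)
}

#' Experiment configuration
#'
#' @param template_params a [template_params()] describing the template
#'   pedigree (ignored when `ped` is given).
#' @param ped optional pre-built template [pedigree()].
#' @param n_loci,spacing_cM,maf marker panel: number of SNPs, uniform
#'   spacing in cM, minor (risk) allele frequency.
#' @param prevalence assumed prevalence for the association test and for
#'   penetrance calibration.
#' @param modes,odds_ratios disease-model grid for the power study (all
#'   combinations).
#' @param n_reps replicates per model.
#' @param master_seed master seed; all stage seeds derive from it.
#' @param analyses subset of `"whole_mqls"`, `"split_mqls"`,
#'   `"twopoint_dom"`, `"twopoint_rec"`.
#' @param bit_limit bit-size limit for pedigree splitting.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(template_params = pedpower::template_params(),
                              ped = NULL, n_loci = 124, spacing_cM = 0.062,
                              maf = 0.2, prevalence = 106 / 798,
                              modes = c("dominant", "recessive", "additive"),
                              odds_ratios = c(1.1, 1.5, 2, 5),
                              n_reps = 1000, master_seed = 1,
                              analyses = c("whole_mqls", "split_mqls"),
                              bit_limit = 24) {
  structure(list(template_params = template_params, ped = ped,
                 n_loci = n_loci, spacing_cM = spacing_cM, maf = maf,
                 prevalence = prevalence, modes = modes,
                 odds_ratios = odds_ratios, n_reps = n_reps,
                 master_seed = master_seed, analyses = analyses,
                 bit_limit = bit_limit),
            class = "experiment_config")
}

# one pass over null replicates: p-value matrices for whole and/or split
# scans, streaming one replicate at a time
null_scan_pmatrices <- function(template, map, config, km = NULL,
                                split_set = NULL) {
  analyses <- config$analyses
  model <- disease_model("null", maf = config$maf,
                         prevalence = config$prevalence)
  out <- list()
  if ("whole_mqls" %in% analyses) {
    if (is.null(km))
      km <- kinship(template, template$id[template$genotyped | template$phenotyped])
    sw <- mqls_structure(km, template$id[template$genotyped])
    pw <- matrix(NA_real_, config$n_reps, map$n_loci)
  }
  if ("split_mqls" %in% analyses) {
    if (is.null(split_set))
      split_set <- split_pedigree(template, bit_limit = config$bit_limit)
    kms <- subpedigree_kinship_union(split_set)
    gsplit <- intersect(kms$ids, template$id[template$genotyped])
    ss <- mqls_structure(kms, gsplit)
    ps <- matrix(NA_real_, config$n_reps, map$n_loci)
  }
  for (i in seq_len(config$n_reps)) {
    rep <- simulate_replicate(template, map, model, i, config$master_seed)
    if ("whole_mqls" %in% analyses) {
      sc <- run_mqls_scan(rep, km, config$prevalence, struct = sw)
      pw[i, ] <- ifelse(sc$testable, sc$p, NA_real_)
    }
    if ("split_mqls" %in% analyses) {
      sc <- run_mqls_scan(rep, kms, config$prevalence, genotyped = gsplit,
                          struct = ss)
      ps[i, ] <- ifelse(sc$testable, sc$p, NA_real_)
    }
  }
  if ("whole_mqls" %in% analyses) out$whole_mqls <- pw
  if ("split_mqls" %in% analyses) out$split_mqls <- ps
  out
}

# one pass over disease-model replicates: disease-SNP p-values for whole
# and/or split scans (the split is recomputed per replicate because the
# affection pattern, hence the subjects of interest, is replicate-specific)
power_scan_pvalues <- function(template, map, config, model, km = NULL) {
  analyses <- config$analyses
  dli <- map$disease_locus_index
  if ("whole_mqls" %in% analyses) {
    if (is.null(km))
      km <- kinship(template, template$id[template$genotyped | template$phenotyped])
    sw <- mqls_structure(km, template$id[template$genotyped])
    pw <- rep(NA_real_, config$n_reps)
  }
  if ("split_mqls" %in% analyses) ps <- rep(NA_real_, config$n_reps)
  for (i in seq_len(config$n_reps)) {
    rep <- simulate_replicate(template, map, model, i, config$master_seed)
    if ("whole_mqls" %in% analyses) {
      prep <- mqls_prepare(km, template$id[template$genotyped],
                           rep$affection, config$prevalence, struct = sw)
      r <- mqls_statistic(prep, rep$genotypes[prep$N, dli])
      pw[i] <- if (r$testable) r$p else NA_real_
    }
    if ("split_mqls" %in% analyses) {
      rped <- replicate_pedigree(template, rep)
      subj <- subjects_of_interest(rped)
      if (length(subj)) {
        set <- split_pedigree(rped, subj, config$bit_limit)
        kms <- subpedigree_kinship_union(set)
        gsplit <- intersect(kms$ids, template$id[template$genotyped])
        sc <- run_mqls_scan(rep, kms, config$prevalence, genotyped = gsplit)
        ps[i] <- if (sc$testable[dli]) sc$p[dli] else NA_real_
      }
    }
  }
  out <- list()
  if ("whole_mqls" %in% analyses) out$whole_mqls <- pw
  if ("split_mqls" %in% analyses) out$split_mqls <- ps
  out
}

# two-point linkage HLOD matrix over null replicates on the split template
twopoint_null_hlods <- function(template, map, config,
                                mode = c("dominant", "recessive"),
                                split_set = NULL) {
  mode <- match.arg(mode)
  if (is.null(split_set))
    split_set <- split_pedigree(template, bit_limit = config$bit_limit)
  lmod <- linkage_model(mode)
  model <- disease_model("null", maf = config$maf,
                         prevalence = config$prevalence)
  H <- matrix(NA_real_, config$n_reps, map$n_loci)
  for (i in seq_len(config$n_reps)) {
    rep <- simulate_replicate(template, map, model, i, config$master_seed)
    sc <- twopoint_scan(split_set, rep, lmod, marker_freq = config$maf)
    H[i, ] <- sc$HLOD
  }
  H
}

#' Run a full simulation experiment
#'
#' Orchestrates template generation, replicate simulation, the requested
#' analyses (whole-pedigree association, split-pedigree association,
#' two-point linkage on split pedigrees) and threshold tallying into
#' type-1-error and power tables, with a reproducibility manifest.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory: tables are written as CSV, the
#'   manifest as JSON and a text log alongside.
#' @return list with `tables` (named list of tally data.frames) and
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  template <- if (!is.null(config$ped)) config$ped
              else generate_template(config$template_params)
  say("template: %d members, %d genotyped, %d affected, bit size %d",
      nrow(template), sum(template$genotyped),
      sum(template$affection == 2L), bit_size(template))
  map <- marker_map(config$n_loci, config$spacing_cM)
  km <- kinship(template, template$id[template$genotyped | template$phenotyped])
  tables <- list()

  want_split <- any(c("split_mqls", "twopoint_dom", "twopoint_rec")
                    %in% config$analyses)
  split_set <- if (want_split)
    split_pedigree(template, bit_limit = config$bit_limit) else NULL
  if (want_split)
    say("template split: %d subpedigrees under bit limit %d",
        length(split_set$subpedigrees), config$bit_limit)

  # null (type 1 error)
  pnull <- null_scan_pmatrices(template, map, config, km = km,
                               split_set = split_set)
  for (an in names(pnull)) {
    tables[[paste0("type1_", an)]] <-
      tally_type1(pnull[[an]], p_thresholds_null())
    say("type 1 error [%s]: %s", an,
        paste(sprintf("%.2f%%@%g", tables[[paste0("type1_", an)]]$rate_pct,
                      p_thresholds_null()), collapse = " "))
  }
  for (mode in c("dominant", "recessive")) {
    an <- paste0("twopoint_", substr(mode, 1, 3))
    if (an %in% config$analyses) {
      H <- twopoint_null_hlods(template, map, config, mode, split_set)
      tables[[paste0("type1_", an)]] <-
        tally_type1(H, hlod_thresholds(), denominator = map$n_loci,
                    stat_high = TRUE)
      say("type 1 error [%s]: %s", an,
          paste(sprintf("%.3f%%@HLOD>%g",
                        tables[[paste0("type1_", an)]]$rate_pct,
                        hlod_thresholds()), collapse = " "))
    }
  }

  # power grid
  power_rows <- list()
  for (mode in config$modes) for (psi in config$odds_ratios) {
    model <- disease_model(mode, psi, config$maf, config$prevalence)
    pv <- power_scan_pvalues(template, map, config, model, km = km)
    for (an in names(pv)) {
      tp <- tally_power(pv[[an]], p_thresholds_power())
      tp$model <- mode; tp$odds_ratio <- psi; tp$analysis <- an
      power_rows[[length(power_rows) + 1L]] <- tp
    }
    say("power %s OR %.1f done", mode, psi)
  }
  if (length(power_rows)) tables$power <- do.call(rbind, power_rows)

  manifest <- list(package = "pedpower",
                   version = as.character(utils::packageVersion("pedpower")),
                   master_seed = config$master_seed,
                   n_reps = config$n_reps,
                   n_loci = config$n_loci, spacing_cM = config$spacing_cM,
                   maf = config$maf, prevalence = config$prevalence,
                   modes = config$modes, odds_ratios = config$odds_ratios,
                   analyses = config$analyses, bit_limit = config$bit_limit,
                   template_params = if (is.null(config$ped))
                     unclass(config$template_params) else "user-supplied")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "experiment.log"))
  }
  list(tables = tables, manifest = manifest)
}
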