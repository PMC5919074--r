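#' Pipeline configuration
#'
#' Assembles every option of the end-to-end analysis (simulate or ingest
#' -> condition/age indices -> immunological distance -> population
#' genetics -> matrix comparisons -> SEM) into one validated object. All
#' randomness flows from `seed`.
#'
#' @param mode `"synthetic"` (generate a cohort from `synthetic`) or
#'   `"files"` (read the paths in `paths`).
#' @param synthetic a [synthetic_config()] used in synthetic mode.
#' @param paths named list for files mode: `cohort` (canonical schema),
#'   `genotypes`, `geographic` (site distance CSV); optional `pcs`
#'   (per-mouse PC scores, s3 schema) which bypasses the internal PCA —
#'   the reproduction path for published distances.
#' @param n_perm Mantel permutations (minimum 99).
#' @param hwe,hwe_chain_length run per-site Hardy-Weinberg tests, and the
#'   Markov-chain length to use.
#' @param nj_bootstraps locus-bootstrap replicates for the
#'   neighbour-joining tree (0 disables support values).
#' @param sem_models,sem_sexes which immune-compartment models to fit and
#'   for which sexes.
#' @param sem_site restrict SEM fitting to one site (e.g. the most deeply
#'   sampled); `NULL` uses all mice.
#' @param seed master seed; recorded in every output.
#' @param out_dir optional directory for the report bundle (CSV tables,
#'   Newick trees, JSON summary, run log).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            synthetic = synthetic_config(seed = seed),
                            paths = list(),
                            n_perm = 999,
                            hwe = FALSE, hwe_chain_length = 20000,
                            nj_bootstraps = 0,
                            sem_models = c("adaptive", "innate", "humoral"),
                            sem_sexes = c("female", "male"),
                            sem_site = NULL,
                            seed = 1, out_dir = NULL) {
  cfg <- list(mode = match.arg(mode), synthetic = synthetic, paths = paths,
              n_perm = n_perm, hwe = hwe,
              hwe_chain_length = hwe_chain_length,
              nj_bootstraps = nj_bootstraps, sem_models = sem_models,
              sem_sexes = sem_sexes, sem_site = sem_site, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return Character vector of problems; empty iff the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (config$mode == "files") {
    for (f in c("cohort", "genotypes", "geographic")) {
      if (is.null(config$paths[[f]])) {
        problems <- c(problems, paste0("files mode: missing path '", f, "'"))
      } else if (!file.exists(config$paths[[f]])) {
        problems <- c(problems, paste0("path '", f, "' does not exist: ",
                                       config$paths[[f]]))
      }
    }
  } else {
    ok <- tryCatch({ validate_synthetic_config(config$synthetic); TRUE },
                   error = function(e) e$message)
    if (!isTRUE(ok)) problems <- c(problems, paste0("synthetic: ", ok))
  }
  if (config$n_perm < 99) {
    problems <- c(problems, "n_perm below the minimum of 99")
  }
  if (!all(config$sem_models %in% c("adaptive", "innate", "humoral"))) {
    problems <- c(problems, "unknown SEM model name")
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic or file input and returns (and
#' optionally writes) the report bundle: condition indices, infection
#' descriptives, the immunological-distance summaries and MDS
#' coordinates, F_ST / F_IS and the neighbour-joining tree, Mantel tests
#' of site-level immunological vs geographic and vs genetic distance with
#' UPGMA trees, and the per-sex SEM fits with their fit-acceptance
#' verdicts. Identical config and seed give identical results.
#'
#' @param config a [pipeline_config()].
#' @return List with per-stage results and a `summary` list of headline
#'   numbers (seed and config echoed).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage, ...) {
    msg <- sprintf("[%7.2fs] %s: %s", proc.time()[["elapsed"]] - t0,
                   stage, paste0(...))
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("setup", "ecoimmune ", as.character(utils::packageVersion("ecoimmune")),
      ", seed ", config$seed, ", mode ", config$mode)

  ## -- input -----------------------------------------------------------
  pcs_supplied <- NULL
  if (config$mode == "synthetic") {
    sim <- stage("simulate", {
      list(cohort = gen_cohort(config$synthetic),
           geno = gen_genotypes(config$synthetic),
           geo = gen_geography(config$synthetic))
    })
    cohort <- sim$cohort$cohort
    truth <- sim$cohort$truth
    g <- sim$geno$genotypes
    geo <- sim$geo
  } else {
    cohort <- stage("read_cohort",
                    read_cohort(config$paths$cohort, "canonical"))
    truth <- NULL
    g <- stage("read_genotypes", read_genotypes(
      config$paths$genotypes,
      site_map = cohort[c("mouse_id", "site")]))
    geo <- stage("read_geographic",
                 read_distance_matrix(config$paths$geographic))
    if (!is.null(config$paths$pcs)) {
      pcs_supplied <- stage("read_pcs",
                            read_cohort(config$paths$pcs, "s3_pcs"))
    }
  }
  say("input", nrow(cohort), " mice, ", nrow(g$dosage), " loci, ",
      length(unique(cohort$site)), " sites")

  ## -- condition and infection ----------------------------------------
  cohort <- stage("condition", compute_smi(cohort))
  allom <- attr(cohort, "allometric_fit")
  cohort$bmi <- compute_bmi(cohort$body_mass, cohort$body_length)
  cohort <- stage("cell_scaling", scale_cell_counts(cohort))
  infections <- stage("infection", infection_descriptives(cohort))
  say("condition", "SMA exponents ",
      paste(round(allom$b_sma, 2), collapse = "/"),
      "; seroprevalence ", round(100 * infections$seroprevalence, 1), "%")

  ## -- immunological distance -----------------------------------------
  if (is.null(pcs_supplied)) {
    pca <- stage("immune_pca", immune_pca(
      cohort[c("mouse_id", .immune_cols)]))
    dm_mice <- immune_distance(pca)
  } else {
    pca <- NULL
    dm_mice <- immune_distance(pcs_supplied)
  }
  site_of <- setNames(cohort$site, cohort$mouse_id)
  summaries <- stage("site_summary",
                     site_distance_summary(dm_mice, site_of))
  wvn <- stage("within_vs_n",
               within_distance_vs_n(summaries, seed = config$seed))
  dm_sites <- among_site_distance(dm_mice, site_of)
  mds <- classical_mds(dm_sites, k = 2)
  say("immune", "within ",
      round(summaries$overall$mean[1], 2), " +/- ",
      round(summaries$overall$se[1], 3), ", among ",
      round(summaries$overall$mean[2], 2), " +/- ",
      round(summaries$overall$se[2], 3))

  ## -- population genetics --------------------------------------------
  fstm <- stage("fst", fst_matrix(g))
  fst_avg <- mean(fstm[lower.tri(fstm)])
  fis_res <- stage("fis", fis(g))
  hwe_tab <- if (config$hwe) {
    stage("hwe", locus_stats(g, per_site = TRUE, hwe = TRUE,
                             chain_length = config$hwe_chain_length,
                             seed = config$seed))
  } else NULL
  nj <- stage("nj_tree", nj_tree(g, bootstraps = config$nj_bootstraps,
                                 seed = config$seed))
  say("popgen", "mean pairwise F_ST ", round(fst_avg, 3),
      ", average F_IS ", signif(fis_res$average, 3))

  ## -- matrix comparisons ---------------------------------------------
  common <- intersect(rownames(dm_sites), rownames(geo))
  common <- intersect(common, rownames(fstm))
  dm_imm <- distance_matrix(dm_sites[common, common], common, tol = 1e-6)
  dm_geo <- distance_matrix(geo[common, common], common, tol = 1e-6)
  fst_d <- fstm[common, common]
  fst_d[fst_d < 0] <- 0
  diag(fst_d) <- 0
  dm_gen <- distance_matrix(fst_d, common, tol = 1e-6)
  mantels <- stage("mantel", list(
    immune_geo = mantel(dm_imm, dm_geo, n_perm = config$n_perm,
                        seed = config$seed),
    immune_geo_log = mantel(dm_imm, dm_geo, n_perm = config$n_perm,
                            seed = config$seed, transform = "log1p"),
    immune_genetic = mantel(dm_imm, dm_gen, n_perm = config$n_perm,
                            seed = config$seed)))
  trees <- list(immune = upgma(dm_imm), genetic = upgma(dm_gen),
                geographic = upgma(dm_geo))
  say("mantel", "immune~geo r = ", round(mantels$immune_geo$r, 3),
      " (p = ", round(mantels$immune_geo$p, 3), "), immune~genetic r = ",
      round(mantels$immune_genetic$r, 3))

  ## -- SEM --------------------------------------------------------------
  frame <- cohort[c("mouse_id", "site", "sex", "day_length", "age", "smi",
                    .immune_cols)]
  frame$burden <- infections$burden
  if (!is.null(config$sem_site)) frame <- frame[frame$site ==
                                                  config$sem_site, ]
  models <- default_models()
  sem_fits <- list()
  for (mn in config$sem_models) {
    for (sx in config$sem_sexes) {
      key <- paste(mn, sx, sep = "_")
      dat <- frame[frame$sex == sx, ]
      sem_fits[[key]] <- stage(paste0("sem_", key), {
        fit <- fit_ml(models[[mn]], dat, seed = config$seed)
        fit$acceptance <- acceptance_report(fit)
        fit
      })
      say("sem", key, ": chi2 = ", round(sem_fits[[key]]$chi2, 2),
          ", df = ", sem_fits[[key]]$df, ", verdict ",
          sem_fits[[key]]$acceptance$verdict)
    }
  }

  summary <- list(
    seed = config$seed, mode = config$mode,
    n_mice = nrow(cohort), n_loci = nrow(g$dosage),
    n_sites = length(unique(cohort$site)),
    median_age_weeks = median(cohort$age, na.rm = TRUE),
    male_fraction = mean(cohort$sex == "male", na.rm = TRUE),
    seroprevalence = infections$seroprevalence,
    syphacia_prevalence = infections$syphacia_prevalence,
    within_site_distance = summaries$overall$mean[1],
    among_site_distance = summaries$overall$mean[2],
    within_distance_vs_n_r = wvn$r,
    pca_variance_explained = if (!is.null(pca)) pca$variance_explained
      else NULL,
    mean_pairwise_fst = fst_avg,
    average_fis = fis_res$average,
    mantel_r_immune_geographic = mantels$immune_geo$r,
    mantel_r_immune_geographic_log = mantels$immune_geo_log$r,
    mantel_r_immune_genetic = mantels$immune_genetic$r,
    sem = lapply(sem_fits, function(f) list(
      chi2 = f$chi2, df = f$df, p = f$chi2_p, rmsea = f$rmsea,
      rmsea_ci = f$rmsea_ci, cfi = f$cfi, srmr = f$srmr, n = f$n,
      verdict = f$acceptance$verdict)))

  out <- list(config = config, cohort = cohort, truth = truth,
              allometry = allom, infections = infections, pca = pca,
              dm_mice = dm_mice, dm_sites = dm_sites,
              site_summaries = summaries, within_vs_n = wvn, mds = mds,
              fst_matrix = fstm, fis = fis_res, hwe = hwe_tab,
              nj_tree = nj, geo = dm_geo, mantel = mantels, trees = trees,
              sem = sem_fits, summary = summary, log = log)
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

.write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(res$cohort, file.path(dir, "cohort_condition.csv"))
  write.csv(res$site_summaries$per_site,
            file.path(dir, "immune_distance_sites.csv"), row.names = FALSE)
  write_distance_matrix(res$dm_sites,
                        file.path(dir, "immune_distance_matrix.csv"))
  write_distance_matrix(res$fst_matrix, file.path(dir, "fst_matrix.csv"))
  write_tree(res$nj_tree, file.path(dir, "nj_tree.nwk"))
  for (nm in names(res$trees)) {
    write_tree(res$trees[[nm]], file.path(dir, paste0("upgma_", nm, ".nwk")))
  }
  sem_tab <- do.call(rbind, lapply(names(res$sem), function(k) {
    et <- res$sem[[k]]$estimates
    cbind(fit = k, et)
  }))
  write.csv(sem_tab, file.path(dir, "sem_estimates.csv"), row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(dir, "run.log"))
  invisible(dir)
}
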