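# End-to-end pipeline: simulate or ingest a cohort, filter to complete
# individuals, fit growth trajectories, build the per-individual trait
# table, and run descriptive, univariate-twin, multivariate-Cholesky and
# polygenic-score analyses, writing every table plus a checksummed run
# manifest under one output directory.

PHENO_COLUMNS <- c("individual_id", "pair_id", "birth_order", "sex",
                   "zygosity", "opposite_sex", "wave", "age", "bmi")

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a cohort from `sim_config`) or
#'   `"files"` (ingest `paths$phenotypes`, `paths$prs`, `paths$pcs`).
#' @param sim_config a [simulation_config()] (simulate mode).
#' @param paths named list of input file paths (files mode).
#' @param out_dir output directory.
#' @param seed integer seed; mandatory in simulate mode (overrides the
#'   seed inside `sim_config` so one value governs the whole run).
#' @param univariate_traits traits to run the univariate twin models on.
#' @param cholesky_traits ordered traits for the Cholesky decomposition.
#' @param run list of logical toggles: `descriptives`, `univariate`,
#'   `cholesky`, `prs`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            sim_config = NULL, paths = NULL,
                            out_dir = tempfile("twintraj_run_"),
                            seed = NULL,
                            univariate_traits = c("bmi11.5", "bmi14",
                                                  "intercept", "slope"),
                            cholesky_traits = c("bmi11.5", "bmi14",
                                                "intercept", "slope"),
                            run = list(descriptives = TRUE,
                                       univariate = TRUE,
                                       cholesky = TRUE, prs = TRUE)) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(sim_config)) sim_config <- simulation_config()
    if (is.null(seed)) seed <- sim_config$seed
    if (is.null(seed)) stop("seed is mandatory in simulate mode")
    sim_config$seed <- as.integer(seed)
  } else {
    if (is.null(paths) || is.null(paths$phenotypes))
      stop("files mode requires paths$phenotypes")
  }
  structure(list(mode = mode, sim_config = sim_config, paths = paths,
                 out_dir = out_dir, seed = seed,
                 univariate_traits = univariate_traits,
                 cholesky_traits = cholesky_traits, run = run),
            class = "pipeline_config")
}

ingest_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PHENO_COLUMNS, names(d))
  if (length(miss))
    stop("phenotype table schema violation; missing columns: ",
         paste(miss, collapse = ", "))
  d$opposite_sex <- as.logical(d$opposite_sex)
  d
}

config_checksum <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg <- config
  cfg$out_dir <- NULL   # output location must not change the run identity
  jsonlite::write_json(
    rapply(unclass(cfg), function(x)
      if (is.numeric(x)) signif(x, 12) else x, how = "replace"),
    f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate/ingest, completeness filter on the adult
#' waves, growth-model trajectories, trait-table join, descriptives,
#' univariate twin models with model selection, per-sex Cholesky
#' decomposition, and polygenic-score analyses. Each stage writes its
#' table(s) under `config$out_dir`; a failure in one analysis stage is
#' recorded in the manifest without corrupting completed outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (invisibly also written to `manifest.json`):
#'   config checksum, per-stage status/row counts/-2LLs, and an MD5
#'   inventory of every file written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("twintraj")),
                   mode = config$mode, seed = config$seed,
                   config_md5 = config_checksum(config),
                   stages = list(), files = character(0))
  out_file <- function(name) file.path(config$out_dir, name)
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
  }
  register <- function(path) {
    manifest$files[basename(path)] <<- unname(tools::md5sum(path))
  }

  # -- input ------------------------------------------------------------
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim_config)
    pheno <- cohort$phenotypes
    prs_raw <- merge(cohort$prs, cohort$pcs, by = "individual_id")
    stage("input", list(status = "ok", source = "simulate",
                        n_individuals = nrow(cohort$traits),
                        n_pairs = length(unique(cohort$traits$pair_id))))
  } else {
    cohort <- NULL
    pheno <- ingest_phenotypes(config$paths$phenotypes)
    prs_raw <- NULL
    if (!is.null(config$paths$prs) && !is.null(config$paths$pcs)) {
      prs_tab <- utils::read.delim(config$paths$prs, stringsAsFactors = FALSE)
      pcs_tab <- utils::read.delim(config$paths$pcs, stringsAsFactors = FALSE)
      prs_raw <- merge(prs_tab, pcs_tab, by = "individual_id")
    }
    stage("input", list(status = "ok", source = "files",
                        n_individuals = length(unique(pheno$individual_id))))
  }
  register(write_tsv(pheno, out_file("phenotypes_used.tsv")))

  # -- completeness filter on adult waves -------------------------------
  pheno_adult <- suppressMessages(
    select_complete_individuals(pheno, required_waves = 3:5))
  stage("select_complete", list(
    status = "ok",
    n_in = length(unique(pheno$individual_id)),
    n_out = length(unique(pheno_adult$individual_id))))

  # -- trajectories -----------------------------------------------------
  gfit <- fit_growth_model(pheno_adult[pheno_adult$wave %in% 3:5, ],
                           center_age = 17.5, by_sex = TRUE)
  traj <- extract_individual_trajectories(gfit)
  register(write_tsv(traj, out_file("trajectories.tsv")))
  stage("trajectories", list(
    status = "ok", n_individuals = nrow(traj),
    log_likelihood = vapply(gfit, `[[`, 0, "log_likelihood")))

  # -- trait table ------------------------------------------------------
  meta <- unique(pheno[, c("individual_id", "pair_id", "birth_order",
                           "sex", "zygosity", "opposite_sex")])
  wave_traits <- c(`1` = "bmi11.5", `2` = "bmi14", `3` = "bmi17.5",
                   `4` = "bmi24", `5` = "bmi37")
  traits_tab <- meta
  for (w in names(wave_traits)) {
    dw <- pheno[pheno$wave == as.integer(w),
                c("individual_id", "bmi")]
    names(dw)[2L] <- wave_traits[[w]]
    traits_tab <- merge(traits_tab, dw, by = "individual_id", all.x = TRUE)
  }
  traits_tab <- merge(traits_tab, traj[, c("individual_id", "intercept",
                                           "slope")],
                      by = "individual_id", all.x = TRUE)
  register(write_tsv(traits_tab, out_file("traits.tsv")))
  stage("trait_join", list(status = "ok", n_individuals = nrow(traits_tab)))

  try_stage <- function(name, enabled, expr) {
    if (!isTRUE(enabled)) {
      stage(name, list(status = "skipped")); return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      stage(name, list(status = "failed", error = conditionMessage(res)))
      return(invisible(NULL))
    }
    res
  }

  # -- descriptives -----------------------------------------------------
  try_stage("descriptives", config$run$descriptives, {
    ws <- wave_summary(pheno, trajectories = traj)
    register(write_tsv(ws, out_file("wave_summary.tsv")))
    icc <- icc_table(traits_tab, intersect(c(unname(wave_traits),
                                             "intercept", "slope"),
                                           names(traits_tab)))
    register(write_tsv(icc, out_file("icc_by_group.tsv")))
    stage("descriptives", list(status = "ok", n_summary_rows = nrow(ws),
                               n_icc_rows = nrow(icc)))
  })

  # -- univariate twin models -------------------------------------------
  try_stage("twin_univariate", config$run$univariate, {
    rows <- list(); cmp_rows <- list(); assum_rows <- list()
    for (tr in config$univariate_traits) {
      groups <- build_twin_groups(traits_tab, tr)
      assum <- test_assumptions(groups)
      assum$trait <- tr
      assum_rows[[tr]] <- assum
      fits <- list(
        fit_variance_components(groups, twin_model_spec(c("A", "C", "E"),
                                                        "full")),
        fit_variance_components(groups, twin_model_spec(c("A", "E"),
                                                        "full")),
        fit_variance_components(groups, twin_model_spec(c("A", "E"),
                                                        "no_sex_difference")),
        fit_variance_components(groups, twin_model_spec("E", "full")))
      cmp <- compare_models(fits[-1L], reference = fits[[1L]])
      sel_label <- attr(cmp, "selected")
      sel <- fits[[match(sel_label, vapply(fits, `[[`, "", "label"))]]
      cmp$trait <- tr
      cmp_rows[[tr]] <- cmp
      sexes <- if (sel$spec$sex_mode == "no_sex_difference") "both"
               else c("M", "F")
      for (sx in sexes) {
        ci_a <- profile_ci(sel, "A", sx)
        ci_e <- profile_ci(sel, "E", sx)
        est_sx <- if (sx == "both") "M" else sx
        rows[[paste(tr, sx)]] <- data.frame(
          trait = tr, model = sel$label, sex = sx,
          a2 = sel$shares["A", est_sx], a2_lower = ci_a$lower,
          a2_upper = ci_a$upper,
          e2 = sel$shares["E", est_sx], e2_lower = ci_e$lower,
          e2_upper = ci_e$upper,
          minus2LL = sel$minus2LL, stringsAsFactors = FALSE)
      }
    }
    tab2 <- do.call(rbind, rows); rownames(tab2) <- NULL
    cmp_all <- do.call(rbind, cmp_rows); rownames(cmp_all) <- NULL
    assum_all <- do.call(rbind, assum_rows); rownames(assum_all) <- NULL
    register(write_tsv(tab2, out_file("variance_components.tsv")))
    register(write_tsv(cmp_all, out_file("model_comparison.tsv")))
    register(write_tsv(assum_all, out_file("assumption_tests.tsv")))
    stage("twin_univariate", list(status = "ok",
                                  traits = config$univariate_traits,
                                  minus2LL = stats::setNames(
                                    tab2$minus2LL[!duplicated(tab2$trait)],
                                    unique(tab2$trait))))
  })

  # -- multivariate Cholesky --------------------------------------------
  try_stage("twin_multivariate", config$run$cholesky, {
    rows <- list(); m2lls <- c()
    for (sx in c("M", "F")) {
      groups <- build_multitrait_groups(traits_tab, config$cholesky_traits,
                                        sex = sx)
      fit <- fit_cholesky(groups)
      m2lls[sx] <- fit$minus2LL
      cr <- derive_correlations(fit)
      idx <- which(upper.tri(diag(fit$k)), arr.ind = TRUE)
      for (q in seq_len(nrow(idx))) {
        i <- idx[q, 1L]; j <- idx[q, 2L]
        rows[[paste(sx, i, j)]] <- data.frame(
          sex = sx, trait_i = fit$traits[i], trait_j = fit$traits[j],
          r = cr$r[i, j], r_A = cr$r_A[i, j], r_E = cr$r_E[i, j],
          genetic_share = decompose_phenotypic_correlation(fit, i, j)[["A"]],
          stringsAsFactors = FALSE)
      }
    }
    tab3 <- do.call(rbind, rows); rownames(tab3) <- NULL
    register(write_tsv(tab3, out_file("cholesky_correlations.tsv")))
    stage("twin_multivariate", list(status = "ok", minus2LL = m2lls))
  })

  # -- polygenic score --------------------------------------------------
  try_stage("prs_analysis", config$run$prs && !is.null(prs_raw), {
    names(prs_raw)[names(prs_raw) == "score"] <- "score"
    resid <- residualize_prs(prs_raw)
    tab4 <- correlate_prs(resid, traits_tab,
                          intersect(c(unname(wave_traits), "intercept",
                                      "slope"), names(traits_tab)),
                          by_sex = TRUE)
    register(write_tsv(tab4, out_file("prs_correlations.tsv")))
    # genetic representativeness of the analyzed subsample
    kept <- resid$prs[resid$individual_id %in% traj$individual_id]
    dropped <- resid$prs[!resid$individual_id %in% traj$individual_id]
    ks <- NULL
    if (length(kept) && length(dropped)) {
      ks <- ks_compare(kept, dropped)
      jsonlite::write_json(ks, out_file("prs_ks.json"), auto_unbox = TRUE,
                           digits = NA)
      register(out_file("prs_ks.json"))
    }
    stage("prs_analysis", list(status = "ok", n_scored = nrow(resid),
                               ks = ks))
  })

  manifest$files <- as.list(manifest$files)
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
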