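# Umbrella driver: simulate -> ITT screen -> IV screen -> MR, with a
# YAML-configurable stage selection. Identical config + seed gives
# byte-identical outputs; stage-local random streams are derived from
# the one global seed by stable hashing of the stage name.

#' Assemble (or load) a pipeline run configuration
#'
#' @param config Either a named list or a path to a YAML file whose keys
#'   mirror the argument names of [trial_sim_config()],
#'   [gwas_sim_config()] and the stage options below. Recognised top-level
#'   keys: `stages` (subset of simulate, itt, iv, mr), `out_dir`, `seed`,
#'   `trial` (simulator options or `csv` path), `gwas` (simulator options
#'   or `exposure_tsv`/`outcome_tsv` paths), `itt` (`factor_name`,
#'   `adjusted`, `alpha`, `var_target`, `hc_type`), `iv` (`factor_name`,
#'   `adjusted`), `mr` (`p_threshold`, `bonferroni_m`, `n_boot`,
#'   `methods`, `palindrome_maf_limit`).
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(stages = c("simulate", "itt", "iv", "mr"),
                   out_dir = ".", seed = 1L,
                   trial = list(), gwas = list(),
                   itt = list(factor_name = "lycopene", adjusted = FALSE,
                              alpha = 0.05, var_target = 0.95,
                              hc_type = "HC1"),
                   iv = list(factor_name = "lycopene", adjusted = TRUE),
                   mr = list(p_threshold = 5e-8, bonferroni_m = NULL,
                             n_boot = 5000, palindrome_maf_limit = 0.42,
                             methods = c("ivw", "egger", "weighted_median")))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, c("simulate", "itt", "iv", "mr"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order. `simulate` writes a trial CSV
#' and paired exposure/outcome summary TSVs; `itt` screens every trait
#' against one factor's arms and annotates the PCA-based multiplicity
#' threshold; `iv` runs the 2SLS dose screen; `mr` selects instruments,
#' harmonises the two summary tables and runs the requested estimators.
#' Each output carries a provenance header (version, stage, seed, config
#' hash), and identical config + seed reproduce the files byte for byte.
#'
#' @param config See [run_config()].
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # fingerprint the analysis-relevant config; output location excluded
  hash <- config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  paths <- list()
  p_out <- function(f) file.path(cfg$out_dir, f)

  trial <- NULL
  exposure <- outcome <- NULL

  if ("simulate" %in% cfg$stages) {
    tcfg <- do.call(trial_sim_config,
                    utils::modifyList(
                      list(seed = substream_seed(cfg$seed, "trial")),
                      cfg$trial[setdiff(names(cfg$trial), "csv")]))
    trial <- simulate_trial(tcfg)
    paths$trial_csv <- write_trial_csv(trial, p_out("trial.csv"),
                                       seed = cfg$seed, hash = hash)
    gcfg <- do.call(gwas_sim_config,
                    utils::modifyList(
                      list(seed = substream_seed(cfg$seed, "gwas")),
                      cfg$gwas[setdiff(names(cfg$gwas),
                                       c("exposure_tsv", "outcome_tsv"))]))
    gw <- simulate_gwas_pair(gcfg)
    exposure <- gw$exposure
    outcome <- gw$outcome
    paths$exposure_tsv <- write_summary_tsv(exposure, p_out("exposure.tsv"),
                                            seed = cfg$seed, hash = hash)
    paths$outcome_tsv <- write_summary_tsv(outcome, p_out("outcome.tsv"),
                                           seed = cfg$seed, hash = hash)
  }

  need_trial <- function() {
    if (!is.null(trial)) return(trial)
    if (is.null(cfg$trial$csv))
      stop("stage needs trial data: run 'simulate' or set trial$csv")
    trial <<- read_trial_csv(cfg$trial$csv)
    trial
  }

  if ("itt" %in% cfg$stages) {
    d <- need_trial()
    res <- itt_screen(d, cfg$itt$factor_name, adjusted = cfg$itt$adjusted,
                      hc_type = cfg$itt$hc_type)
    thr <- pca_threshold(d$followup, var_target = cfg$itt$var_target,
                         alpha = cfg$itt$alpha)
    res$passes_threshold <- res$p < thr$threshold
    paths$itt_tsv <- write_with_header(res, p_out("itt.tsv"), "\t",
                                       sprintf("itt k=%d threshold=%.3g",
                                               thr$k_components,
                                               thr$threshold),
                                       cfg$seed, hash)
  }

  if ("iv" %in% cfg$stages) {
    d <- need_trial()
    res <- iv_screen(d, cfg$iv$factor_name, adjusted = cfg$iv$adjusted)
    paths$iv_tsv <- write_with_header(res, p_out("iv.tsv"), "\t", "iv",
                                      cfg$seed, hash)
  }

  if ("mr" %in% cfg$stages) {
    if (is.null(exposure)) {
      if (is.null(cfg$gwas$exposure_tsv) || is.null(cfg$gwas$outcome_tsv))
        stop("mr stage needs summary statistics: run 'simulate' or set ",
             "gwas$exposure_tsv and gwas$outcome_tsv")
      exposure <- read_summary_tsv(cfg$gwas$exposure_tsv)
      outcome <- read_summary_tsv(cfg$gwas$outcome_tsv)
    }
    inst <- select_instruments(exposure, cfg$mr$p_threshold)
    phenos <- if ("phenotype" %in% names(inst)) unique(inst$phenotype)
              else "exposure"
    m <- if (is.null(cfg$mr$bonferroni_m)) length(phenos)
         else cfg$mr$bonferroni_m
    res_rows <- list()
    audits <- list()
    for (ph in phenos) {
      sub <- if ("phenotype" %in% names(inst))
        inst[inst$phenotype == ph, , drop = FALSE] else inst
      h <- harmonize(sub, outcome,
                     palindrome_maf_limit = cfg$mr$palindrome_maf_limit)
      aud <- attr(h, "audit")
      aud <- aud[aud$rsid %in% c(sub$rsid), , drop = FALSE]
      aud$phenotype <- ph
      audits[[ph]] <- aud
      if (nrow(h) == 0) next
      r <- if (nrow(h) == 1)
        mr_result("wald", wald_ratio(h$bx, h$se_x, h$by, h$se_y)$beta,
                  wald_ratio(h$bx, h$se_x, h$by, h$se_y)$se, 1)
      else mr_all(h, methods = cfg$mr$methods, n_boot = cfg$mr$n_boot,
                  seed = substream_seed(cfg$seed, paste0("boot_", ph)))
      r <- report_or(r, bonferroni_m = m)
      r <- cbind(exposure = ph, r)
      res_rows[[ph]] <- r
    }
    res <- do.call(rbind, c(res_rows, list(make.row.names = FALSE)))
    paths$mr_tsv <- write_with_header(res, p_out("mr.tsv"), "\t", "mr",
                                      cfg$seed, hash)
    paths$audit_tsv <- write_with_header(
      do.call(rbind, c(audits, list(make.row.names = FALSE))),
      p_out("harmonization_audit.tsv"), "\t", "mr_audit", cfg$seed, hash)
  }

  invisible(paths)
}
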