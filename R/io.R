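# File dialects and the pipeline driver. Trial data travel as CSV (one
# row per participant), GWAS summary statistics as TSV (one row per
# variant). Missing values are empty fields; readers also accept
# "NA"/"nan" case-insensitively. Every writer prepends '#' provenance
# comment lines, which every reader skips.

pkg_version <- function() {
  as.character(utils::packageVersion("trialmr"))
}

# small stable config fingerprint (hex), for provenance lines
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum((v * (seq_along(v) %% 251 + 1)) %% 2147483647) %%
            4294967291)
}

provenance_lines <- function(stage, seed = NA, hash = NA) {
  c(sprintf("# trialmr %s stage=%s", pkg_version(), stage),
    sprintf("# seed=%s config_hash=%s", as.character(seed), as.character(hash)))
}

write_with_header <- function(df, path, sep, stage, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(stage, seed, hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

read_skip_comments <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    na.strings = c("", "NA", "na", "NaN", "nan"),
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

num_or_die <- function(x, what, path) {
  bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad))
    stop("non-numeric ", what, " in ", basename(path), ", e.g. row ",
         which(bad)[1], ": '", x[which(bad)[1]], "'")
  as.numeric(x)
}

#' Write a trial dataset to CSV
#'
#' Columns: id, lycopene_arm, greentea_arm, lycopene_umol_l, egcg_nm,
#' then `<trait>_base` and `<trait>_fu` per trait. Missing values are
#' empty fields.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output file.
#' @param seed,hash Optional provenance fields recorded in the header.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(dataset, path, seed = NA, hash = NA) {
  stopifnot(inherits(dataset, "trial_dataset"))
  base <- dataset$baseline
  fu <- dataset$followup
  colnames(base) <- paste0(dataset$trait_names, "_base")
  colnames(fu) <- paste0(dataset$trait_names, "_fu")
  df <- data.frame(id = dataset$id,
                   lycopene_arm = as.character(dataset$lycopene_arm),
                   greentea_arm = as.character(dataset$greentea_arm),
                   lycopene_umol_l = dataset$lycopene_umol_l,
                   egcg_nm = dataset$egcg_nm,
                   base, fu, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_with_header(df, path, ",", "trial", seed, hash)
}

normalize_arm <- function(x, column, path) {
  lab <- tolower(trimws(x))
  lab[lab == "drink"] <- "diet"      # green-tea dietary arm synonym
  bad <- !lab %in% arm_levels
  if (any(bad))
    stop("unknown arm label in ", column, " of ", basename(path), ": '",
         x[which(bad)[1]], "' (row ", which(bad)[1], ")")
  if (!all(lab == x))
    message("arm labels case-folded/renamed in ", column)
  factor(lab, levels = arm_levels)
}

#' Read a trial dataset from CSV
#'
#' Inverse of [write_trial_csv()]. Arm labels are case-folded
#' ("Placebo" -> "placebo") and the green-tea "drink" label is mapped to
#' "diet". Empty fields become missing values; participants with missing
#' cells are retained. Unknown arm labels, duplicated ids and non-numeric
#' concentrations are errors.
#'
#' @param path CSV file in the trial dialect.
#' @return A `trial_dataset`.
#' @export
read_trial_csv <- function(path) {
  df <- read_skip_comments(path, ",")
  need <- c("id", "lycopene_arm", "greentea_arm", "lycopene_umol_l", "egcg_nm")
  if (!all(need %in% names(df)))
    stop("trial CSV must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicated participant id: ", df$id[anyDuplicated(df$id)])
  base_cols <- grep("_base$", names(df), value = TRUE)
  fu_cols <- grep("_fu$", names(df), value = TRUE)
  traits <- sub("_base$", "", base_cols)
  if (!setequal(traits, sub("_fu$", "", fu_cols)))
    stop("baseline/follow-up trait columns do not pair up")
  fu_cols <- paste0(traits, "_fu")
  grab <- function(cols, tag) {
    m <- sapply(cols, function(cn) num_or_die(df[[cn]], cn, path))
    m <- matrix(as.numeric(m), nrow = nrow(df),
                dimnames = list(NULL, traits))
    m
  }
  message(nrow(df), " participants, ", length(traits), " traits; ",
          sum(is.na(df[base_cols])), " missing baseline and ",
          sum(is.na(df[fu_cols])), " missing follow-up cells")
  structure(list(id = df$id,
                 lycopene_arm = normalize_arm(df$lycopene_arm,
                                              "lycopene_arm", path),
                 greentea_arm = normalize_arm(df$greentea_arm,
                                              "greentea_arm", path),
                 lycopene_umol_l = num_or_die(df$lycopene_umol_l,
                                              "lycopene_umol_l", path),
                 egcg_nm = num_or_die(df$egcg_nm, "egcg_nm", path),
                 baseline = grab(base_cols, "_base"),
                 followup = grab(fu_cols, "_fu"),
                 trait_names = traits),
            class = "trial_dataset")
}

#' Write GWAS summary statistics to TSV
#'
#' Columns, in order: rsid, chr, pos, effect_allele, other_allele, eaf,
#' beta, se, pval, n.
#'
#' @param stats Summary-statistics `data.frame`.
#' @inheritParams write_trial_csv
#' @export
write_summary_tsv <- function(stats, path, seed = NA, hash = NA) {
  cols <- c("rsid", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  stopifnot(all(cols %in% names(stats)))
  write_with_header(stats[, cols], path, "\t", "summary_stats", seed, hash)
}

#' Read GWAS summary statistics from TSV
#'
#' Requires columns rsid, effect_allele, other_allele, eaf, beta, se,
#' pval (scientific notation accepted); chr/pos optional; n optional with
#' a global fallback. Validates allele codes (single characters from
#' A/C/G/T), `eaf` strictly inside (0,1) and positive `se`, reporting the
#' offending row.
#'
#' @param path TSV file in the summary-statistics dialect.
#' @param n_default Per-variant sample size to use when the `n` column is
#'   absent or has gaps.
#' @return Summary-statistics `data.frame`.
#' @export
read_summary_tsv <- function(path, n_default = NA_real_) {
  df <- read_skip_comments(path, "\t")
  need <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval")
  if (!all(need %in% names(df)))
    stop("summary TSV must contain columns: ", paste(need, collapse = ", "))
  for (ac in c("effect_allele", "other_allele")) {
    a <- toupper(trimws(df[[ac]]))
    bad <- !a %in% c("A", "C", "G", "T")
    if (any(bad))
      stop("malformed allele in ", ac, " of ", basename(path), ": '",
           df[[ac]][which(bad)[1]], "' (row ", which(bad)[1], ")")
    df[[ac]] <- a
  }
  out <- data.frame(rsid = df$rsid,
                    chr = if ("chr" %in% names(df)) df$chr else NA,
                    pos = if ("pos" %in% names(df))
                      num_or_die(gsub(",", "", df$pos), "pos", path) else NA,
                    effect_allele = df$effect_allele,
                    other_allele = df$other_allele,
                    eaf = num_or_die(df$eaf, "eaf", path),
                    beta = num_or_die(df$beta, "beta", path),
                    se = num_or_die(df$se, "se", path),
                    pval = num_or_die(df$pval, "pval", path),
                    n = if ("n" %in% names(df))
                      num_or_die(gsub(",", "", df$n), "n", path)
                    else NA_real_,
                    stringsAsFactors = FALSE)
  out$n[is.na(out$n)] <- n_default
  if ("phenotype" %in% names(df)) out$phenotype <- df$phenotype
  bad_eaf <- which(out$eaf <= 0 | out$eaf >= 1)
  if (length(bad_eaf))
    stop("eaf outside (0,1) in ", basename(path), " (row ", bad_eaf[1], ")")
  bad_se <- which(out$se <= 0)
  if (length(bad_se))
    stop("non-positive se in ", basename(path), " (row ", bad_se[1], ")")
  out
}
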