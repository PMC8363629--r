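#' Read and validate GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file (gzip
#' transparent), maps its columns onto the standard per-SNP fields, converts
#' the effect column to the log-odds scale, and drops records that fail
#' validation. Each dropped record is logged with a reason, retrievable with
#' [drop_log()].
#'
#' @param path Path to the summary-statistics file. A header line is required.
#' @param column_map Named character vector mapping standard field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, `n_total`, `n_case`, `n_control`, `eaf`) to column names in the
#'   file. Fields left unmapped are guessed from common aliases (`SNP`, `CHR`,
#'   `BP`, `A1`, `A2`, `BETA`/`OR`/`Z`, `SE`, `P`, `N`, ...). For
#'   `effect_scale = "oddsratio"` the `beta` mapping names the odds-ratio
#'   column; for `"zscore"` it names the z-score column.
#' @param effect_scale Scale of the effect column: `"logodds"` (default,
#'   used as is), `"oddsratio"` (converted with `log(OR)`), or `"zscore"`
#'   (converted with `z * se` when an SE column is present, otherwise kept as
#'   `z` with `se = 1`).
#' @param n_total,n_case,n_control Optional fixed sample sizes applied to all
#'   records when the file carries no such columns.
#'
#' @return A tibble of class `ddx_sumstats` with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `n_total`,
#'   `n_case`, `n_control`, `eaf` (the last four may be `NA`). Row order of
#'   the input is preserved for retained records. The drop log is attached as
#'   attribute `"drop_log"`.
#'
#' @details Mandatory fields are `snp_id`, `effect_allele`, `other_allele`,
#'   `beta` and `se`; a missing mandatory column is a fatal error. Records
#'   are dropped (never silently altered) when the SE is not positive
#'   (`nonpositive_se`), the odds ratio is not positive
#'   (`nonpositive_or`), an allele is not one of A/C/G/T (`bad_allele`),
#'   both alleles are identical (`identical_alleles`), the effect or SE is
#'   missing (`missing_beta`), or the p-value lies outside (0, 1]
#'   (`bad_pval`). Two consistency checks warn without dropping: a reported
#'   p-value far from `2 * pnorm(-abs(beta/se))`, and
#'   `n_case + n_control != n_total`.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP\tN",
#'              "rs1\t1\t1000\tA\tG\t1.105170918\t0.02\t2e-6\t50000"), f)
#' read_sumstats(f, effect_scale = "oddsratio")$beta # 0.1
#' @export
read_sumstats <- function(path, column_map = NULL,
                          effect_scale = c("logodds", "oddsratio", "zscore"),
                          n_total = NULL, n_case = NULL, n_control = NULL) {
  effect_scale <- match.arg(effect_scale)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  map <- resolve_column_map(names(raw), column_map, effect_scale)

  out <- tibble(
    snp_id = as.character(raw[[map["snp_id"]]]),
    chrom = if (!is.na(map["chrom"])) as.character(raw[[map["chrom"]]]) else NA_character_,
    pos = if (!is.na(map["pos"])) as.integer(raw[[map["pos"]]]) else NA_integer_,
    effect_allele = toupper(as.character(raw[[map["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[map["other_allele"]]])),
    beta = as.numeric(raw[[map["beta"]]]),
    se = as.numeric(raw[[map["se"]]]),
    pval = if (!is.na(map["pval"])) as.numeric(raw[[map["pval"]]]) else NA_real_,
    n_total = if (!is.na(map["n_total"])) as.numeric(raw[[map["n_total"]]]) else n_total %||% NA_real_,
    n_case = if (!is.na(map["n_case"])) as.numeric(raw[[map["n_case"]]]) else n_case %||% NA_real_,
    n_control = if (!is.na(map["n_control"])) as.numeric(raw[[map["n_control"]]]) else n_control %||% NA_real_,
    eaf = if (!is.na(map["eaf"])) as.numeric(raw[[map["eaf"]]]) else NA_real_
  )

  drop_reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(drop_reason) & cond, reason, drop_reason)
  }

  if (effect_scale == "oddsratio") {
    drop_reason <- flag(!is.na(out$beta) & out$beta <= 0, "nonpositive_or")
    out$beta <- ifelse(out$beta > 0, log(out$beta), NA_real_)
  } else if (effect_scale == "zscore") {
    out$beta <- ifelse(is.na(out$se), out$beta, out$beta * out$se)
    out$se[is.na(out$se)] <- 1
  }

  drop_reason <- flag(is.na(out$beta) | is.na(out$se), "missing_beta")
  drop_reason <- flag(out$se <= 0, "nonpositive_se")
  drop_reason <- flag(!(out$effect_allele %in% VALID_ALLELES) |
                        !(out$other_allele %in% VALID_ALLELES), "bad_allele")
  drop_reason <- flag(out$effect_allele == out$other_allele, "identical_alleles")
  drop_reason <- flag(!is.na(out$pval) & (out$pval <= 0 | out$pval > 1), "bad_pval")

  dropped <- tibble(snp_id = out$snp_id[!is.na(drop_reason)],
                    reason = drop_reason[!is.na(drop_reason)])
  if (nrow(dropped) > 0) {
    warn(sprintf("read_sumstats: dropped %d of %d records (%s)",
                 nrow(dropped), nrow(out),
                 paste(sprintf("%s: %d", names(table(dropped$reason)),
                               table(dropped$reason)), collapse = ", ")))
  }
  out <- out[is.na(drop_reason), , drop = FALSE]

  # warn-only consistency checks
  chk <- !is.na(out$pval) & out$se > 0
  if (any(chk)) {
    z_imp <- abs(out$beta[chk] / out$se[chk])
    z_rep <- qnorm(pmax(out$pval[chk], 1e-300) / 2, lower.tail = FALSE)
    bad <- abs(z_imp - z_rep) > pmax(0.1 * pmax(z_imp, 1), 0.1)
    if (any(bad)) {
      warn(sprintf("read_sumstats: %d records have p-values inconsistent with beta/se",
                   sum(bad)))
    }
  }
  nn <- !is.na(out$n_case) & !is.na(out$n_control) & !is.na(out$n_total)
  if (any(nn) && any(abs(out$n_case[nn] + out$n_control[nn] - out$n_total[nn]) > 0.5)) {
    warn("read_sumstats: n_case + n_control differs from n_total for some records")
  }

  new_sumstats(out, drop_log = dropped)
}

new_sumstats <- function(x, drop_log = tibble(snp_id = character(), reason = character())) {
  structure(as_tibble(x), drop_log = drop_log,
            class = c("ddx_sumstats", class(as_tibble(x))))
}

#' Retrieve the record drop log of a sumstats, harmonization or read step
#'
#' @param x An object produced by [read_sumstats()] or [harmonize_pair()].
#' @return A tibble with one row per dropped record and its reason.
#' @export
drop_log <- function(x) {
  attr(x, "drop_log") %||% tibble(snp_id = character(), reason = character())
}

# field -> known column-name aliases (upper case)
SUMSTAT_ALIASES <- list(
  snp_id = c("SNP", "ID", "RSID", "MARKERNAME", "VARIANT_ID"),
  chrom = c("CHR", "CHROM", "CHROMOSOME"),
  pos = c("BP", "POS", "POSITION", "BASE_PAIR_LOCATION"),
  effect_allele = c("A1", "EA", "EFFECT_ALLELE", "ALLELE1"),
  other_allele = c("A2", "OA", "NEA", "OTHER_ALLELE", "ALLELE2", "ALLELE0"),
  beta = c("BETA", "B", "LOGODDS", "BETA13", "EFFECT"),
  or_ = c("OR", "ODDSRATIO"),
  z_ = c("Z", "ZSCORE", "ZSTAT"),
  se = c("SE", "STDERR", "SE13", "STANDARD_ERROR"),
  pval = c("P", "PVAL", "PVALUE", "P_VALUE", "P_BOLT_LMM"),
  n_total = c("N", "NTOTAL", "N_TOTAL", "TOTALSAMPLESIZE"),
  n_case = c("N_CASE", "N_CASES", "NCAS", "NCASE", "NCASES"),
  n_control = c("N_CONTROL", "N_CONTROLS", "NCON", "NCONTROL", "NCONTROLS"),
  eaf = c("EAF", "FRQ", "AF", "FREQ", "A1FREQ", "EFFECT_ALLELE_FREQUENCY")
)

resolve_column_map <- function(cols, column_map, effect_scale) {
  fields <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "beta", "se", "pval", "n_total", "n_case", "n_control", "eaf")
  map <- setNames(rep(NA_character_, length(fields)), fields)
  up <- toupper(cols)
  for (f in fields) {
    if (!is.null(column_map) && f %in% names(column_map)) {
      if (!column_map[[f]] %in% cols) {
        abort(sprintf("mapped column `%s` (field `%s`) not present in file",
                      column_map[[f]], f))
      }
      map[f] <- column_map[[f]]
      next
    }
    aliases <- SUMSTAT_ALIASES[[f]]
    if (f == "beta" && effect_scale == "oddsratio") aliases <- SUMSTAT_ALIASES$or_
    if (f == "beta" && effect_scale == "zscore") aliases <- c(SUMSTAT_ALIASES$z_, aliases)
    hit <- which(up %in% aliases)
    if (length(hit) > 0) map[f] <- cols[hit[1]]
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  if (effect_scale == "zscore") mandatory <- setdiff(mandatory, "se")
  missing <- mandatory[is.na(map[mandatory])]
  if (length(missing) > 0) {
    abort(sprintf("mandatory column(s) not found or unmapped: %s",
                  paste(missing, collapse = ", ")))
  }
  map
}

#' Write a summary-statistics table as TSV
#'
#' @param x A `ddx_sumstats` tibble (or compatible data frame).
#' @param path Output file path; written atomically.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  cols <- c(SNP = "snp_id", CHR = "chrom", BP = "pos", A1 = "effect_allele",
            A2 = "other_allele", BETA = "beta", SE = "se", P = "pval",
            N = "n_total", N_CASE = "n_case", N_CONTROL = "n_control",
            EAF = "eaf")
  keep <- cols[cols %in% names(x)]
  out <- setNames(as.data.frame(x)[, keep, drop = FALSE], names(keep))
  write_tsv_atomic(out, path)
  invisible(path)
}
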