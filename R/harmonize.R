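#' Harmonize two summary-statistics tables to a shared allele convention
#'
#' Joins two validated summary-statistics tables on SNP ID and re-aligns the
#' second table to the first table's effect-allele orientation. Where the
#' second study reports the swapped allele pair, its effect sign is flipped
#' and its allele frequency complemented; where it reports the opposite
#' strand, alleles are complemented first. Palindromic (A/T, C/G) variants
#' are ambiguous between these two operations and are handled by policy.
#'
#' @param t1,t2 Summary-statistics tibbles from [read_sumstats()] (or any
#'   data frame with the same columns). Trait 1's allele orientation wins.
#' @param palindromic_policy `"drop"` (default) removes A/T and C/G variants;
#'   `"keep_if_eaf_informative"` retains a palindromic variant only when both
#'   studies report an effect-allele frequency outside
#'   `[0.5 - eaf_window, 0.5 + eaf_window]` and, after alignment, on the same
#'   side of 0.5.
#' @param eaf_window Half-width of the ambiguity window around 0.5 used by
#'   the `"keep_if_eaf_informative"` policy.
#' @param check_positions When `TRUE` (default) a warning is issued if joined
#'   records disagree on chromosome or position (the join itself is by ID).
#'
#' @return A tibble of class `ddx_harmonized` with per-SNP columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, suffixed statistics
#'   (`beta_t1`, `se_t1`, `pval_t1`, `n_total_t1`, `n_case_t1`,
#'   `n_control_t1`, `eaf_t1`, and the same with `_t2`), and
#'   `alignment_action` (one of `kept`, `sign_flipped`, `strand_flipped`).
#'   Variants dropped during alignment, and variants present in only one
#'   table (`dropped_missing`), are recorded in the [drop_log()]. Every input
#'   SNP appears exactly once in either the pair or the drop log.
#'
#' @examples
#' t1 <- tibble::tibble(snp_id = "rs1", chrom = "1", pos = 1L,
#'   effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.02,
#'   pval = NA, n_total = NA, n_case = NA, n_control = NA, eaf = 0.3)
#' t2 <- dplyr::mutate(t1, effect_allele = "G", other_allele = "A",
#'   beta = -0.1, eaf = 0.7)
#' harmonize_pair(t1, t2)$beta_t2 # +0.1, action "sign_flipped"
#' @export
harmonize_pair <- function(t1, t2,
                           palindromic_policy = c("drop", "keep_if_eaf_informative"),
                           eaf_window = 0.08, check_positions = TRUE) {
  palindromic_policy <- match.arg(palindromic_policy)
  t1 <- ensure_sumstat_cols(t1)
  t2 <- ensure_sumstat_cols(t2)

  j <- inner_join(
    rename_with_suffix(t1, "_t1"),
    rename_with_suffix(t2, "_t2"),
    by = "snp_id"
  )
  only1 <- setdiff(t1$snp_id, t2$snp_id)
  only2 <- setdiff(t2$snp_id, t1$snp_id)
  missing_log <- tibble(snp_id = c(only1, only2), reason = "dropped_missing")

  if (check_positions && nrow(j) > 0) {
    pos_ok <- is.na(j$pos_t1) | is.na(j$pos_t2) |
      (j$pos_t1 == j$pos_t2 & (is.na(j$chrom_t1) | is.na(j$chrom_t2) | j$chrom_t1 == j$chrom_t2))
    if (!all(pos_ok)) {
      warn(sprintf("harmonize_pair: %d joined SNPs disagree on chromosome/position",
                   sum(!pos_ok)))
    }
  }

  ea1 <- j$effect_allele_t1; oa1 <- j$other_allele_t1
  ea2 <- j$effect_allele_t2; oa2 <- j$other_allele_t2
  pal <- is_palindromic(ea1, oa1)

  same <- ea2 == ea1 & oa2 == oa1
  swap <- ea2 == oa1 & oa2 == ea1
  csame <- complement_allele(ea2) == ea1 & complement_allele(oa2) == oa1
  cswap <- complement_allele(ea2) == oa1 & complement_allele(oa2) == ea1

  action <- case_when(
    same ~ "kept",
    swap ~ "sign_flipped",
    csame ~ "strand_flipped",
    cswap ~ "sign_flipped", # strand complement plus allele swap
    TRUE ~ "dropped_mismatch"
  )
  # a palindromic pair always matches as `same` or `swap`; strand identity is
  # unknowable from alleles alone, so policy decides
  if (palindromic_policy == "drop") {
    action[pal & action != "dropped_mismatch"] <- "dropped_palindromic"
  } else {
    flip <- action == "sign_flipped"
    eaf2_aligned <- ifelse(flip, 1 - j$eaf_t2, j$eaf_t2)
    informative <- !is.na(j$eaf_t1) & !is.na(eaf2_aligned) &
      abs(j$eaf_t1 - 0.5) > eaf_window & abs(eaf2_aligned - 0.5) > eaf_window &
      (j$eaf_t1 - 0.5) * (eaf2_aligned - 0.5) > 0
    action[pal & action != "dropped_mismatch" & !informative] <- "dropped_palindromic"
  }

  flip <- action == "sign_flipped"
  out <- j |>
    mutate(
      alignment_action = action,
      beta_t2 = ifelse(flip, -.data$beta_t2, .data$beta_t2),
      eaf_t2 = ifelse(flip, 1 - .data$eaf_t2, .data$eaf_t2),
      chrom = .data$chrom_t1, pos = .data$pos_t1,
      effect_allele = .data$effect_allele_t1,
      other_allele = .data$other_allele_t1
    ) |>
    filter(!startsWith(.data$alignment_action, "dropped")) |>
    select("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           dplyr::ends_with("_t1"), dplyr::ends_with("_t2"), "alignment_action") |>
    select(-dplyr::any_of(c("chrom_t1", "pos_t1", "chrom_t2", "pos_t2",
                            "effect_allele_t1", "other_allele_t1",
                            "effect_allele_t2", "other_allele_t2")))

  dropped <- tibble(snp_id = j$snp_id[startsWith(action, "dropped")],
                    reason = action[startsWith(action, "dropped")])
  log <- bind_rows(dropped, missing_log)
  structure(out, drop_log = log,
            class = c("ddx_harmonized", class(as_tibble(out))))
}

ensure_sumstat_cols <- function(x) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("sumstats table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  defaults <- list(chrom = NA_character_, pos = NA_integer_, pval = NA_real_,
                   n_total = NA_real_, n_case = NA_real_, n_control = NA_real_,
                   eaf = NA_real_)
  for (f in names(defaults)) if (!f %in% names(x)) x[[f]] <- defaults[[f]]
  as_tibble(x)
}

rename_with_suffix <- function(x, suffix) {
  keep <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pval", "n_total", "n_case", "n_control", "eaf")
  x <- x[, keep]
  names(x)[-1] <- paste0(names(x)[-1], suffix)
  x
}

#' Split a harmonized pair back into two per-trait tables
#'
#' Inverse of the column-suffixing done by [harmonize_pair()]; useful for
#' re-harmonization checks and for feeding each trait to single-trait tools.
#'
#' @param pair A `ddx_harmonized` tibble.
#' @return A list with elements `t1` and `t2`, each a `ddx_sumstats` tibble.
#' @export
split_pair <- function(pair) {
  strip <- function(suffix) {
    cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              paste0(c("beta", "se", "pval", "n_total", "n_case", "n_control", "eaf"),
                     suffix))
    out <- pair[, cols]
    names(out) <- sub(paste0(suffix, "$"), "", names(out))
    new_sumstats(out)
  }
  list(t1 = strip("_t1"), t2 = strip("_t2"))
}

#' Write a harmonized pair (and its drop log) as TSV
#'
#' @param pair A `ddx_harmonized` tibble.
#' @param path Output TSV path; the drop log is written next to it with the
#'   suffix `.droplog.tsv` unless `droplog_path` is given.
#' @param droplog_path Optional explicit path for the drop log.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pair, path, droplog_path = NULL) {
  write_tsv_atomic(as.data.frame(pair), path)
  write_tsv_atomic(as.data.frame(drop_log(pair)),
                   droplog_path %||% paste0(path, ".droplog.tsv"))
  invisible(path)
}
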