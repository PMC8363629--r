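#' Read LD scores in the `.l2.ldscore` dialect
#'
#' Reads one or more `<prefix>.l2.ldscore(.gz)` tables (columns `CHR`, `SNP`,
#' `BP`, `L2`) together with their `<prefix>.l2.M_5_50` (or `.l2.M`) SNP
#' counts. `path` may be a single file prefix or a directory containing
#' per-chromosome files, whose scores are concatenated and whose M counts
#' are summed.
#'
#' @param path File prefix (the part before `.l2.ldscore`) or a directory.
#' @return A tibble of class `ddx_ldscores` with columns `snp_id`, `chrom`,
#'   `pos`, `l2`, and the reference SNP count as attribute `"M"`.
#' @export
read_ldscores <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.l2\\.ldscore(\\.gz)?$", full.names = TRUE)
    if (length(files) == 0) abort(sprintf("no .l2.ldscore files under %s", path))
    prefixes <- unique(sub("\\.l2\\.ldscore(\\.gz)?$", "", files))
  } else {
    prefixes <- sub("\\.l2\\.ldscore(\\.gz)?$", "", path)
  }
  read_one <- function(prefix) {
    f <- paste0(prefix, ".l2.ldscore")
    if (!file.exists(f)) f <- paste0(f, ".gz")
    if (!file.exists(f)) abort(sprintf("LD-score file not found for prefix %s", prefix))
    d <- data.table::fread(f, data.table = FALSE, showProgress = FALSE)
    need <- c("CHR", "SNP", "BP", "L2")
    if (!all(need %in% names(d))) {
      abort(sprintf("%s lacks columns %s", f,
                    paste(setdiff(need, names(d)), collapse = ", ")))
    }
    mfile <- paste0(prefix, ".l2.M_5_50")
    if (!file.exists(mfile)) mfile <- paste0(prefix, ".l2.M")
    M <- if (file.exists(mfile)) sum(scan(mfile, quiet = TRUE)) else nrow(d)
    list(tab = tibble(snp_id = as.character(d$SNP), chrom = as.character(d$CHR),
                      pos = as.integer(d$BP), l2 = as.numeric(d$L2)),
         M = M)
  }
  parts <- lapply(prefixes, read_one)
  tab <- bind_rows(lapply(parts, `[[`, "tab"))
  M <- sum(vapply(parts, `[[`, numeric(1), "M"))
  if (any(tab$l2 < 1 - 1e-6, na.rm = TRUE)) {
    warn("read_ldscores: some LD scores are below 1; check the reference panel")
  }
  new_ldscores(tab, M)
}

new_ldscores <- function(tab, M) {
  structure(as_tibble(tab), M = M,
            class = c("ddx_ldscores", class(as_tibble(tab))))
}

#' Flat (LD-free) scores for independent SNPs
#'
#' LD scores of 1 for every SNP with `M` equal to the number of SNPs; the
#' regression setting that matches simulated panels of independent variants.
#'
#' @param snp_id Character vector of SNP IDs.
#' @return A `ddx_ldscores` tibble.
#' @export
flat_ldscores <- function(snp_id) {
  new_ldscores(tibble(snp_id = as.character(snp_id), chrom = NA_character_,
                      pos = NA_integer_, l2 = 1), M = length(snp_id))
}
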