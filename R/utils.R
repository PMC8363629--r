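# internal helpers

VALID_ALLELES <- c("A", "C", "G", "T")

# strand complement of allele vectors ("A" -> "T", ...)
complement_allele <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(a1, a2) a1 == complement_allele(a2)

# natural chromosome ordering: 1..22 numerically, then X, Y, MT, then others
chrom_order <- function(chrom) {
  ch <- toupper(sub("^CHR", "", as.character(chrom), ignore.case = TRUE))
  num <- suppressWarnings(as.numeric(ch))
  special <- match(ch, c("X", "Y", "XY", "MT", "M"))
  ord <- ifelse(!is.na(num), num, ifelse(!is.na(special), 100 + special, 200))
  ord + as.numeric(factor(ch)) * 1e-6 # stable among unrecognized labels
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

assert_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) & (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok)) {
    abort(sprintf("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

# write a table atomically as TSV (temp file + rename)
write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  data.table::fwrite(x, tmp, sep = "\t", quote = FALSE, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}
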