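# Delimited-text interfaces: cohort tables as TSV with a JSON column
# dictionary sidecar, GWAS summary statistics in the conventional
# SNP/EA/NEA/BETA/SE/P/N layout.

#' Write / read a cohort table as TSV
#'
#' Writes one header row, UTF-8, "." decimal; a JSON sidecar
#' (`<path>.dict.json`) records each column's type so factors and metabolite
#' columns survive the round trip.
#'
#' @param cohort Cohort tibble.
#' @param path Output TSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   restored tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (j in seq_along(out)) if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  dict <- list(
    columns = purrr::imap(cohort, function(col, nm) {
      list(name = nm,
           type = if (is.factor(col)) "factor" else class(col)[1],
           levels = if (is.factor(col)) levels(col) else NULL)
    }),
    metabolite_names = attr(cohort, "metabolite_names"),
    snp_names = attr(cohort, "snp_names"),
    grs_weights = as.list(attr(cohort, "grs_weights") %||% list())
  )
  jsonlite::write_json(dict, paste0(path, ".dict.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  out <- as_tibble(tab)
  dict_path <- paste0(path, ".dict.json")
  if (file.exists(dict_path)) {
    dict <- jsonlite::read_json(dict_path, simplifyVector = FALSE)
    for (col in dict$columns) {
      nm <- col$name
      if (!nm %in% names(out)) next
      if (identical(col$type, "factor")) {
        out[[nm]] <- factor(out[[nm]], levels = unlist(col$levels))
      } else if (identical(col$type, "logical")) {
        out[[nm]] <- as.logical(out[[nm]])
      } else if (identical(col$type, "integer")) {
        out[[nm]] <- as.integer(out[[nm]])
      }
    }
    if (!is.null(dict$metabolite_names)) {
      attr(out, "metabolite_names") <- unlist(dict$metabolite_names)
    }
    if (!is.null(dict$snp_names)) attr(out, "snp_names") <- unlist(dict$snp_names)
    if (length(dict$grs_weights) > 0) {
      attr(out, "grs_weights") <- unlist(dict$grs_weights)
    }
  }
  out
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns `SNP`, `EA`, `NEA`, `BETA`, `SE`, `P`, `N` (one trait per file).
#'
#' @param stats Tibble with columns `snp`, `ea`, `nea`, `beta`, `se`, `p`,
#'   `n`.
#' @param path Output TSV path.
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   the tibble in the package's lower-case column layout.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp, EA = stats$ea, NEA = stats$nea,
                    BETA = stats$beta, SE = stats$se, P = stats$p, N = stats$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tibble(snp = tab$SNP, ea = tab$EA, nea = tab$NEA,
         beta = tab$BETA, se = tab$SE, p = tab$P, n = tab$N)
}
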