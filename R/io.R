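#' Read a variant table
#'
#' Tab-separated, UTF-8, header required. Columns: \code{raf} and at least
#' one of \code{grr}, \code{a}; optional \code{ve} and \code{id}. Decimal
#' point \code{'.'}, \code{NA} for missing.
#'
#' @param path TSV file path.
#' @return data frame of variants.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path))
    stop("sibrisk_parse_error: no such file: ", path, call. = FALSE)
  head <- readLines(path, n = 1L)
  cols <- strsplit(head, "\t", fixed = TRUE)[[1]]
  if (!"raf" %in% cols || !any(c("grr", "a") %in% cols))
    stop("sibrisk_parse_error: ", path, " line 1: header must name 'raf' ",
         "and 'grr' or 'a'", call. = FALSE)
  v <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = NA, check.names = FALSE),
    error = function(e)
      stop("sibrisk_parse_error: ", path, ": ", conditionMessage(e),
           call. = FALSE))
  for (cc in intersect(c("raf", "grr", "a", "ve"), names(v))) {
    x <- suppressWarnings(as.numeric(v[[cc]]))
    bad <- which(is.na(x) & !is.na(v[[cc]]) & v[[cc]] != "NA")
    if (length(bad))
      stop("sibrisk_parse_error: ", path, " line ", bad[1] + 1L,
           ": non-numeric '", cc, "' value", call. = FALSE)
    v[[cc]] <- x
  }
  v
}

#' Write a variant table
#'
#' @param variants data frame of variants.
#' @param path output TSV path.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged 30-variant Crohn's disease model
#'
#' Loads the packaged fixture of 30 known Crohn's disease risk variants
#' (risk-allele frequency, genotypic relative risk and additive liability
#' value per variant; the printed additive values are treated as
#' authoritative) and assembles the disease model used in the simulation
#' study: prevalence 1/250 and residual variance components 0.7 polygenic /
#' 0.2 shared environment / 0.1 nonshared, giving residual sibling
#' correlation 0.55. The variants jointly explain about 6.4% of liability
#' variance.
#'
#' @param prevalence population prevalence.
#' @param components residual \code{\link{variance_components}}.
#' @return a \code{\link{disease_model}}.
#' @export
crohns_model <- function(prevalence = 1/250,
                         components = variance_components(0.7, 0.2, 0.1)) {
  path <- system.file("extdata", "crohns30.tsv", package = "sibrisk",
                      mustWork = TRUE)
  disease_model(prevalence, components, read_variant_table(path))
}

#' The packaged single-locus example model
#'
#' One locus with risk-allele frequency 0.425 and additive value 0.083
#' (genotypic relative risk about 1.25), the locus used for the worked
#' single-locus illustration.
#'
#' @inheritParams crohns_model
#' @return a \code{\link{disease_model}} with one variant.
#' @export
single_locus_model <- function(prevalence = 1/250,
                               components = variance_components(0.7, 0.2, 0.1)) {
  path <- system.file("extdata", "single_locus.tsv", package = "sibrisk",
                      mustWork = TRUE)
  disease_model(prevalence, components, read_variant_table(path))
}

#' Calibrate a variant table
#'
#' Fills the additive value column \code{a} by root-finding from
#' \code{grr} where it is missing (rows with \code{a} present are kept
#' as-is) and (re)computes \code{ve}.
#'
#' @param variants data frame with \code{raf} and \code{grr} (and
#'   optionally \code{a}).
#' @param k population prevalence.
#' @return the variant table with \code{a} and \code{ve} filled.
#' @export
calibrate_variants <- function(variants, k) {
  normalize_variants(variants, k)
}

#' Read a two-row genotype TSV
#'
#' First column \code{id}, then one copy-count column per variant (aligned
#' with the variant table), \code{NA} for missing. Row 1 is the index
#' individual; an optional row 2 is the sibling.
#'
#' @param path TSV path.
#' @return list with \code{ids} and integer matrix \code{genotypes}.
#' @export
read_genotype_tsv <- function(path) {
  g <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE),
    error = function(e)
      stop("sibrisk_parse_error: ", path, ": ", conditionMessage(e),
           call. = FALSE))
  if (ncol(g) < 2 || names(g)[1] != "id")
    stop("sibrisk_parse_error: ", path,
         ": first column must be 'id'", call. = FALSE)
  m <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !(m %in% 0:2)))
    stop("sibrisk_domain_error: genotype copy counts must be 0, 1, 2 or NA",
         call. = FALSE)
  list(ids = as.character(g$id), genotypes = m)
}

#' Serialize a risk report
#'
#' Writes the five model risks and the per-locus log likelihood ratios as
#' JSON, and the risks as a one-row TSV.
#'
#' @param report a \code{risk_report} from
#'   \code{\link{predict.disease_model}}.
#' @param json_path,tsv_path output paths (either may be \code{NULL}).
#' @export
write_risk_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "risk_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(risks = as.list(report$risks), loci = report$loci,
           prior = report$prior, prevalence = report$prevalence),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    row <- as.data.frame(as.list(signif(report$risks, 4)))
    utils::write.table(row, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
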