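#' Construct a cohort genotype matrix
#'
#' The central container of the pipeline: an ordered sample sheet, an ordered
#' table of bi-allelic variant sites, and parallel samples x sites grids of
#' genotype dosage, read depth (DP), genotype quality (GQ) and allele depths
#' (AD). Dosage is the count of alternate alleles (0/1/2) with `NA` for a
#' missing call; downstream carrier logic treats `NA` as absent.
#'
#' @param samples data.frame with columns `sample_id` (unique character) and
#'   `status` (`"case"` or `"control"`).
#' @param sites data.frame with one row per bi-allelic site; required columns
#'   `site_id` (unique, `chrom:pos:ref:alt`), `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, `effect_term`, `lof_flag` (logical, `NA` allowed),
#'   `pred1`, `pred2`, `pred3` (each `"damaging"`, `"benign"` or `"missing"`),
#'   `vqslod` (numeric, `NA` allowed), `annotated` (logical).
#' @param dosage,dp,gq,ad_ref,ad_alt integer matrices, samples x sites,
#'   `NA` for unavailable values. `ad_ref`/`ad_alt` may be all-`NA` when the
#'   source VCF carries no AD field.
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(samples, sites, dosage, dp = NULL, gq = NULL,
                          ad_ref = NULL, ad_alt = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "status") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(samples$status), c("case", "control"))
  if (length(bad))
    stop("phenotype status must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  sites <- complete_site_table(sites)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site ids after canonicalization: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "))
  n_s <- nrow(samples); n_v <- nrow(sites)
  blank <- function() matrix(NA_integer_, n_s, n_v,
                             dimnames = list(samples$sample_id, sites$site_id))
  shape <- function(m, what) {
    if (is.null(m)) return(blank())
    if (!is.matrix(m) || !all(dim(m) == c(n_s, n_v)))
      stop(what, " matrix must be ", n_s, " x ", n_v)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(samples$sample_id, sites$site_id)
    m
  }
  obj <- list(samples = samples, sites = sites,
              dosage = shape(dosage, "dosage"), dp = shape(dp, "dp"),
              gq = shape(gq, "gq"), ad_ref = shape(ad_ref, "ad_ref"),
              ad_alt = shape(ad_alt, "ad_alt"))
  class(obj) <- "cohort_matrix"
  obj
}

# Fill optional site columns with defaults so constructors stay terse.
complete_site_table <- function(sites) {
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop("site table needs chrom, pos, ref, alt")
  if (is.null(sites$site_id))
    sites$site_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                           sep = ":")
  defaults <- list(gene = NA_character_, effect_term = NA_character_,
                   lof_flag = NA, pred1 = "missing", pred2 = "missing",
                   pred3 = "missing", vqslod = NA_real_, annotated = FALSE)
  for (nm in names(defaults))
    if (is.null(sites[[nm]])) sites[[nm]] <- defaults[[nm]]
  ok <- nchar(sites$ref) > 0 & nchar(sites$alt) > 0 &
    grepl("^[ACGT]+$", sites$ref) & grepl("^[ACGT]+$", sites$alt) &
    sites$ref != sites$alt
  if (!all(ok))
    stop("invalid alleles at: ", paste(sites$site_id[!ok], collapse = ", "))
  rownames(sites) <- NULL
  sites
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(factor(x$samples$status, levels = c("case", "control")))
  cat(sprintf("cohort_matrix: %d samples (%d cases / %d controls) x %d sites\n",
              nrow(x$samples), tab[["case"]], tab[["control"]],
              nrow(x$sites)))
  cat(sprintf("  missing dosage: %.1f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Number of samples / sites in a cohort matrix
#' @param x a `cohort_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

# Subset helpers: keep grids and tables in lockstep.
keep_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  for (m in c("dosage", "dp", "gq", "ad_ref", "ad_alt"))
    x[[m]] <- x[[m]][, keep, drop = FALSE]
  x
}

keep_samples <- function(x, keep) {
  x$samples <- x$samples[keep, , drop = FALSE]
  rownames(x$samples) <- NULL
  for (m in c("dosage", "dp", "gq", "ad_ref", "ad_alt"))
    x[[m]] <- x[[m]][keep, , drop = FALSE]
  x
}
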