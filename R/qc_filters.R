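#' Default QC thresholds
#'
#' Thresholds of the genotype/variant/sample QC cascade. Retention rules:
#' genotypes need read depth > `dp_min - 1` (i.e. DP > 6) and genotype
#' quality > `gq_min - 1` (GQ > 20); variants are excluded at missingness
#' strictly above 5%, Hardy-Weinberg exact p (controls only) below 1e-6,
#' case/control differential-missingness Fisher p below 1e-6, or mean
#' heterozygous allele balance outside \[0.25, 0.75\] / homozygous balance
#' below 0.90; samples are dropped at overall missingness strictly above 15%
#' or pairwise pi_hat relatedness above 0.15.
#'
#' @param dp_min minimum retained read depth (calls with DP < `dp_min` are
#'   masked).
#' @param gq_min minimum retained genotype quality.
#' @param variant_missing_max maximum per-variant missing fraction.
#' @param hwe_p Hardy-Weinberg exact-test exclusion threshold (controls).
#' @param diff_missing_p differential-missingness exclusion threshold.
#' @param ab_het_low,ab_het_high allowed range for the mean heterozygous
#'   alternate-allele fraction.
#' @param ab_hom_min minimum mean homozygous allele balance.
#' @param sample_missing_max maximum per-sample missing fraction.
#' @param pi_hat_max maximum pairwise relatedness.
#' @param vqslod_min optional minimum VQSLOD pass-through filter (`NULL` =
#'   off; tranche calibration itself is out of scope).
#' @return list of thresholds, class `qc_thresholds`.
#' @export
qc_thresholds <- function(dp_min = 7L, gq_min = 21L,
                          variant_missing_max = 0.05,
                          hwe_p = 1e-6, diff_missing_p = 1e-6,
                          ab_het_low = 0.25, ab_het_high = 0.75,
                          ab_hom_min = 0.90,
                          sample_missing_max = 0.15,
                          pi_hat_max = 0.15,
                          vqslod_min = NULL) {
  th <- list(dp_min = as.integer(dp_min), gq_min = as.integer(gq_min),
             variant_missing_max = variant_missing_max, hwe_p = hwe_p,
             diff_missing_p = diff_missing_p, ab_het_low = ab_het_low,
             ab_het_high = ab_het_high, ab_hom_min = ab_hom_min,
             sample_missing_max = sample_missing_max,
             pi_hat_max = pi_hat_max, vqslod_min = vqslod_min)
  props <- unlist(th[c("variant_missing_max", "hwe_p", "diff_missing_p",
                       "ab_het_low", "ab_het_high", "ab_hom_min",
                       "sample_missing_max", "pi_hat_max")])
  stopifnot(all(props >= 0 & props <= 1), th$dp_min > 0, th$gq_min > 0)
  class(th) <- "qc_thresholds"
  th
}

#' Mask low-confidence genotypes
#'
#' Sets dosage to missing for any call with DP below `dp_min` or GQ below
#' `gq_min` (the retention rule is DP > 6 and GQ > 20 at the defaults).
#' Calls with missing DP or GQ are masked conservatively. Idempotent.
#'
#' @param x a [cohort_matrix].
#' @param thresholds a [qc_thresholds] list.
#' @return the matrix with failing dosages set to `NA`.
#' @export
mask_genotypes <- function(x, thresholds = qc_thresholds()) {
  fail <- is.na(x$dp) | is.na(x$gq) |
    x$dp < thresholds$dp_min | x$gq < thresholds$gq_min
  n <- sum(fail & !is.na(x$dosage))
  x$dosage[fail] <- NA_integer_
  attr(x, "n_masked_genotypes") <- n
  x
}

#' Per-variant missing-call fraction
#' @param x a [cohort_matrix] (post genotype masking).
#' @return named numeric vector, one fraction per site.
#' @export
variant_missingness <- function(x) {
  colMeans(is.na(x$dosage))
}

#' Per-sample missing-call fraction
#' @param x a [cohort_matrix] (post genotype masking).
#' @return named numeric vector, one fraction per sample.
#' @export
sample_missingness <- function(x) {
  rowMeans(is.na(x$dosage))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, enumerate all
#' heterozygote counts of matching parity, weight each configuration by its
#' conditional probability, and sum the probabilities not exceeding that of
#' the observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative genotype count")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  na <- n_het + 2L * n_hom_alt          # alt allele count
  if (na == 0 || na == 2L * n) return(1)  # monomorphic
  hets <- seq.int(na %% 2L, min(na, 2L * n - na), by = 2L)
  # log P(het = h | n, na) = log multinomial + h log 2 - log C(2n, na)
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (na + hets) / 2) + hets * log(2) -
    (lfactorial(2 * n) - lfactorial(na) - lfactorial(2 * n - na))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count has wrong parity for allele count")
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Differential missingness test between cases and controls
#'
#' Two-sided Fisher exact test on the 2x2 table of missing vs non-missing
#' calls by phenotype, using the same exact-test kernel as the burden test.
#'
#' @param case_missing,case_total,ctrl_missing,ctrl_total counts.
#' @return two-sided exact p-value.
#' @export
differential_missingness_p <- function(case_missing, case_total,
                                       ctrl_missing, ctrl_total) {
  stopifnot(case_missing >= 0, ctrl_missing >= 0,
            case_missing <= case_total, ctrl_missing <= ctrl_total)
  fisher_two_sided(case_missing, case_total - case_missing,
                   ctrl_missing, ctrl_total - ctrl_missing)
}

#' Allele-balance check for one site
#'
#' Mean alternate-allele read fraction over heterozygous calls must lie in
#' \[`ab_het_low`, `ab_het_high`\]; mean supporting-allele fraction over
#' homozygous calls (alt reads for hom-alt, ref reads for hom-ref) must be at
#' least `ab_hom_min`. Categories with no usable calls impose no constraint;
#' a site with no AD information at all passes with a warning. Calls with
#' zero total allele depth are skipped.
#'
#' @param dosage,ad_ref,ad_alt per-sample vectors for one site.
#' @param thresholds a [qc_thresholds] list.
#' @return `TRUE` (pass) or `FALSE` (fail), with attributes `het_balance`
#'   and `hom_balance`.
#' @export
allele_balance_ok <- function(dosage, ad_ref, ad_alt,
                              thresholds = qc_thresholds()) {
  tot <- ad_ref + ad_alt
  usable <- !is.na(dosage) & !is.na(tot) & tot > 0
  if (!any(!is.na(dosage) & !is.na(tot))) {
    warning("no allele-depth information at site; allele balance not checked")
    return(structure(TRUE, het_balance = NA_real_, hom_balance = NA_real_))
  }
  het <- usable & dosage == 1L
  hom_alt <- usable & dosage == 2L
  hom_ref <- usable & dosage == 0L
  het_bal <- if (any(het)) mean(ad_alt[het] / tot[het]) else NA_real_
  hom_fracs <- c(if (any(hom_alt)) ad_alt[hom_alt] / tot[hom_alt],
                 if (any(hom_ref)) ad_ref[hom_ref] / tot[hom_ref])
  hom_bal <- if (length(hom_fracs)) mean(hom_fracs) else NA_real_
  ok <- TRUE
  if (!is.na(het_bal) &&
      (het_bal < thresholds$ab_het_low || het_bal > thresholds$ab_het_high))
    ok <- FALSE
  if (!is.na(hom_bal) && hom_bal < thresholds$ab_hom_min)
    ok <- FALSE
  structure(ok, het_balance = het_bal, hom_balance = hom_bal)
}

#' Pairwise relatedness (pi_hat) by method-of-moments IBD estimation
#'
#' PLINK-style moment estimator: per pair, identity-by-state counts at
#' common sites (within-matrix MAF >= `maf_min`) are compared with their
#' expectations under IBD states 0/1/2 given sample allele frequencies;
#' the implied P(IBD=0,1,2) are clamped to \[0,1\] and renormalized, and
#' pi_hat = P(IBD=1)/2 + P(IBD=2).
#'
#' @param x a [cohort_matrix].
#' @param maf_min minimum within-cohort MAF for a site to be used.
#' @param min_sites minimum number of informative sites; below this the
#'   estimate is skipped with a warning.
#' @return data.frame with columns `sample1`, `sample2`, `pi_hat`, or `NULL`
#'   when skipped.
#' @export
relatedness_pi_hat <- function(x, maf_min = 0.01, min_sites = 50L) {
  if (n_samples(x) < 2) stop("need at least 2 samples")
  g <- x$dosage
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  use <- !is.na(maf) & maf >= maf_min
  if (sum(use) < min_sites) {
    warning("fewer than ", min_sites,
            " informative sites; relatedness step skipped")
    return(NULL)
  }
  g <- g[, use, drop = FALSE]
  p <- af[use]; q <- 1 - p
  # per-site IBS expectations given IBD state
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2
  ids <- x$samples$sample_id
  pairs <- utils::combn(seq_along(ids), 2)
  out <- data.frame(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
                    pi_hat = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    gi <- g[pairs[1, j], ]; gj <- g[pairs[2, j], ]
    ok <- !is.na(gi) & !is.na(gj)
    if (sum(ok) < min_sites) next
    d <- abs(gi[ok] - gj[ok])
    n0 <- sum(d == 2); n1 <- sum(d == 1); n2 <- sum(d == 0)
    s0_0 <- sum(e0_ibs0[ok]); s0_1 <- sum(e0_ibs1[ok])
    s1_1 <- sum(e1_ibs1[ok]); s0_2 <- sum(e0_ibs2[ok])
    s1_2 <- sum(e1_ibs2[ok])
    z0 <- n0 / s0_0
    z1 <- (n1 - z0 * s0_1) / s1_1
    z2 <- (n2 - z0 * s0_2 - z1 * s1_2) / sum(ok)
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    out$pi_hat[j] <- z[2] / 2 + z[3]
  }
  out
}

#' Exclude sites falling in genomic masks
#'
#' @param x a [cohort_matrix].
#' @param masks a single `interval_set` or a list of them (e.g.
#'   low-complexity plus tandem-repeat masks).
#' @return the matrix without masked sites; attribute `n_masked_sites`
#'   records the exclusion count.
#' @export
apply_masks <- function(x, masks) {
  if (inherits(masks, "interval_set")) masks <- list(masks)
  hit <- rep(FALSE, n_sites(x))
  for (m in masks)
    hit <- hit | mask_contains(m, x$sites$chrom, x$sites$pos)
  out <- keep_sites(x, !hit)
  attr(out, "n_masked_sites") <- sum(hit)
  attr(out, "masked_sites") <- x$sites$site_id[hit]
  out
}

#' Run the full QC cascade
#'
#' Fixed order: genotype masking (DP/GQ); sample-missingness drop;
#' relatedness drop (higher-missingness member of each pair, ties broken to
#' the later sample-sheet entry); region masks; variant missingness;
#' Hardy-Weinberg (controls only); differential missingness; allele balance.
#' Returns the filtered matrix plus an audit report whose per-rule counts
#' reconcile exactly with the matrix size changes.
#'
#' @param x a [cohort_matrix].
#' @param thresholds a [qc_thresholds] list.
#' @param masks optional `interval_set` or list of them.
#' @param relatedness logical; set `FALSE` to skip the pi_hat step (e.g. for
#'   very small fixtures).
#' @return `list(matrix = filtered cohort_matrix, report = qc_report)`.
#' @export
run_qc <- function(x, thresholds = qc_thresholds(), masks = NULL,
                   relatedness = TRUE) {
  report <- list(
    n_samples_in = n_samples(x), n_sites_in = n_sites(x),
    masked_genotypes = 0L,
    samples_excluded = data.frame(sample_id = character(),
                                  rule = character(),
                                  stringsAsFactors = FALSE),
    sites_excluded = data.frame(site_id = character(), rule = character(),
                                stringsAsFactors = FALSE))
  drop_sites <- function(x, bad, rule) {
    if (any(bad)) {
      report$sites_excluded <<- rbind(
        report$sites_excluded,
        data.frame(site_id = x$sites$site_id[bad], rule = rule,
                   stringsAsFactors = FALSE))
      x <- keep_sites(x, !bad)
    }
    x
  }

  # 0. optional VQSLOD pass-through filter
  if (!is.null(thresholds$vqslod_min)) {
    vq <- x$sites$vqslod
    x <- drop_sites(x, !is.na(vq) & vq < thresholds$vqslod_min, "vqslod")
  }

  # 1. genotype-level masking
  x <- mask_genotypes(x, thresholds)
  report$masked_genotypes <- attr(x, "n_masked_genotypes")

  # 2. sample missingness
  sm <- sample_missingness(x)
  bad_s <- sm > thresholds$sample_missing_max
  if (any(bad_s)) {
    report$samples_excluded <- rbind(
      report$samples_excluded,
      data.frame(sample_id = x$samples$sample_id[bad_s],
                 rule = "sample_missingness", stringsAsFactors = FALSE))
    x <- keep_samples(x, !bad_s)
  }

  # 3. relatedness
  if (isTRUE(relatedness) && n_samples(x) >= 2) {
    ph <- relatedness_pi_hat(x)
    if (!is.null(ph)) {
      flagged <- ph[!is.na(ph$pi_hat) & ph$pi_hat > thresholds$pi_hat_max, ,
                    drop = FALSE]
      sm <- sample_missingness(x)
      order_in_sheet <- stats::setNames(seq_len(n_samples(x)),
                                        x$samples$sample_id)
      to_drop <- character()
      for (i in seq_len(nrow(flagged))) {
        s1 <- flagged$sample1[i]; s2 <- flagged$sample2[i]
        if (s1 %in% to_drop || s2 %in% to_drop) next
        worse <- if (sm[s1] > sm[s2]) s1
        else if (sm[s2] > sm[s1]) s2
        else if (order_in_sheet[s1] > order_in_sheet[s2]) s1 else s2
        to_drop <- c(to_drop, worse)
      }
      if (length(to_drop)) {
        report$samples_excluded <- rbind(
          report$samples_excluded,
          data.frame(sample_id = to_drop, rule = "relatedness",
                     stringsAsFactors = FALSE))
        x <- keep_samples(x, !(x$samples$sample_id %in% to_drop))
      }
    }
  }
  if (n_samples(x) == 0)
    stop("all samples removed by QC", call. = FALSE)

  # 4. region masks
  if (!is.null(masks)) {
    pre <- x$sites$site_id
    x <- apply_masks(x, masks)
    gone <- setdiff(pre, x$sites$site_id)
    if (length(gone))
      report$sites_excluded <- rbind(
        report$sites_excluded,
        data.frame(site_id = gone, rule = "region_mask",
                   stringsAsFactors = FALSE))
  }

  # 5. variant missingness
  x <- drop_sites(x, variant_missingness(x) > thresholds$variant_missing_max,
                  "variant_missingness")

  # 6. HWE in controls
  is_ctrl <- x$samples$status == "control"
  if (any(is_ctrl) && n_sites(x) > 0) {
    hwe_p <- vapply(seq_len(n_sites(x)), function(j) {
      d <- x$dosage[is_ctrl, j]
      d <- d[!is.na(d)]
      if (!length(d)) return(1)
      hwe_exact_p(sum(d == 0L), sum(d == 1L), sum(d == 2L))
    }, numeric(1))
    x <- drop_sites(x, hwe_p < thresholds$hwe_p, "hwe")
  }

  # 7. differential missingness
  is_case <- x$samples$status == "case"
  is_ctrl <- x$samples$status == "control"
  if (any(is_case) && any(is_ctrl) && n_sites(x) > 0) {
    dm_p <- vapply(seq_len(n_sites(x)), function(j) {
      differential_missingness_p(sum(is.na(x$dosage[is_case, j])),
                                 sum(is_case),
                                 sum(is.na(x$dosage[is_ctrl, j])),
                                 sum(is_ctrl))
    }, numeric(1))
    x <- drop_sites(x, dm_p < thresholds$diff_missing_p,
                    "differential_missingness")
  }

  # 8. allele balance
  if (n_sites(x) > 0) {
    ab_ok <- vapply(seq_len(n_sites(x)), function(j) {
      suppressWarnings(as.logical(allele_balance_ok(
        x$dosage[, j], x$ad_ref[, j], x$ad_alt[, j], thresholds)))
    }, logical(1))
    x <- drop_sites(x, !ab_ok, "allele_balance")
  }
  if (n_sites(x) == 0)
    stop("all variants removed by QC", call. = FALSE)

  report$n_samples_out <- n_samples(x)
  report$n_sites_out <- n_sites(x)
  report$rule_counts <- c(
    table(factor(report$sites_excluded$rule,
                 levels = c("vqslod", "region_mask", "variant_missingness",
                            "hwe", "differential_missingness",
                            "allele_balance"))),
    table(factor(report$samples_excluded$rule,
                 levels = c("sample_missingness", "relatedness"))))
  class(report) <- "qc_report"
  list(matrix = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d samples, %d -> %d sites; %d genotypes masked\n",
              x$n_samples_in, x$n_samples_out, x$n_sites_in, x$n_sites_out,
              x$masked_genotypes))
  for (nm in names(x$rule_counts))
    if (x$rule_counts[[nm]] > 0)
      cat(sprintf("  %-25s %d\n", nm, x$rule_counts[[nm]]))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [run_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(sprintf("samples_in\t%d", report$n_samples_in),
             sprintf("samples_out\t%d", report$n_samples_out),
             sprintf("sites_in\t%d", report$n_sites_in),
             sprintf("sites_out\t%d", report$n_sites_out),
             sprintf("masked_genotypes\t%d", report$masked_genotypes),
             sprintf("rule_%s\t%d", names(report$rule_counts),
                     report$rule_counts))
  writeLines(lines, path)
  invisible(path)
}
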