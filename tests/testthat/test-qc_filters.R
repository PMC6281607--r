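test_that("genotype masking enforces the DP>6 / GQ>20 retention rule", {
  d <- matrix(c(1L, 1L, 1L, 1L), 1, 4)
  x <- make_cohort(d, "case")
  x$dp <- matrix(c(7L, 6L, 50L, 7L), 1, 4, dimnames = dimnames(x$dp))
  x$gq <- matrix(c(21L, 99L, 20L, NA), 1, 4, dimnames = dimnames(x$gq))
  masked <- mask_genotypes(x)
  expect_equal(unname(masked$dosage[1, ]), c(1L, NA, NA, NA))
  expect_equal(attr(masked, "n_masked_genotypes"), 3L)
  # idempotent, and nothing but dosage changes
  again <- mask_genotypes(masked)
  expect_identical(again$dosage, masked$dosage)
  expect_identical(masked$dp, x$dp)
})

test_that("variant missingness filters strictly above 5%", {
  # 40 sites so per-sample missingness stays far below the sample rule
  d <- matrix(0L, 100, 40)
  d[seq_len(5), 2] <- NA     # exactly 5% -> retained
  d[seq_len(6), 3] <- NA     # 6% -> excluded
  x <- make_cohort(d, rep(c("case", "control"), 50))
  fr <- variant_missingness(x)
  expect_equal(unname(fr[1:3]), c(0, 0.05, 0.06))
  qc <- run_qc(x, relatedness = FALSE)
  expect_equal(n_sites(qc$matrix), 39L)
  expect_equal(qc$report$sites_excluded$rule, "variant_missingness")
})

test_that("the exact HWE test matches hand enumeration and handles degeneracy", {
  expect_equal(hwe_exact_p(100, 0, 0), 1)            # monomorphic
  expect_equal(hwe_exact_p(0, 4, 0), 22 / 70)        # enumerated by hand
  expect_error(hwe_exact_p(-1, 0, 2), "negative")
})

test_that("HWE p equals the enumeration oracle across configurations", {
  for (n in 2:20) {
    cfgs <- expand.grid(AA = 0:n, Aa = 0:n)
    cfgs$aa <- n - cfgs$AA - cfgs$Aa
    cfgs <- cfgs[cfgs$aa >= 0, ]
    p_impl <- mapply(hwe_exact_p, cfgs$AA, cfgs$Aa, cfgs$aa)
    p_orac <- mapply(oracle_hwe_p, cfgs$AA, cfgs$Aa, cfgs$aa)
    expect_equal(p_impl, p_orac, tolerance = 1e-10)
  }
  set.seed(11)
  cfgs <- t(replicate(200, as.vector(
    stats::rmultinom(1, sample(21:30, 1), c(0.5, 0.3, 0.2)))))
  expect_equal(apply(cfgs, 1, function(g) hwe_exact_p(g[1], g[2], g[3])),
               apply(cfgs, 1, function(g) oracle_hwe_p(g[1], g[2], g[3])),
               tolerance = 1e-10)
})

test_that("differential missingness reduces to the shared Fisher kernel", {
  expect_equal(differential_missingness_p(10, 100, 10, 100), 1)
  expect_equal(differential_missingness_p(0, 92, 0, 1051), 1)
  set.seed(5)
  for (i in 1:200) {
    ct <- sample(1:50, 2)
    cm <- c(sample(0:ct[1], 1), sample(0:ct[2], 1))
    expect_equal(differential_missingness_p(cm[1], ct[1], cm[2], ct[2]),
                 oracle_fisher_p(cm[1], ct[1] - cm[1], cm[2],
                                 ct[2] - cm[2]),
                 tolerance = 1e-10)
  }
})

test_that("allele-balance rule means over het and hom calls", {
  ok <- allele_balance_ok(c(1L, 1L), c(10L, 10L), c(10L, 10L))
  expect_true(as.logical(ok))
  expect_equal(attr(ok, "het_balance"), 0.5)
  # het mean 0.2 < 0.25 fails
  bad <- allele_balance_ok(c(1L, 1L), c(18L, 14L), c(2L, 6L))
  expect_false(as.logical(bad))
  expect_equal(attr(bad, "het_balance"), 0.2)
  # single hom-alt call with clean support passes
  hom <- allele_balance_ok(2L, 0L, 20L)
  expect_true(as.logical(hom))
  expect_equal(attr(hom, "hom_balance"), 1)
  # no AD at all: pass with warning
  expect_warning(res <- allele_balance_ok(c(0L, 1L), c(NA, NA), c(NA, NA)),
                 "allele")
  expect_true(as.logical(res))
  # zero-depth calls are skipped in the mean
  z <- allele_balance_ok(c(1L, 1L), c(0L, 5L), c(0L, 5L))
  expect_equal(attr(z, "het_balance"), 0.5)
})

test_that("sample missingness drops strictly above 15%", {
  d <- matrix(0L, 3, 100)
  d[2, 1:15] <- NA   # 15% -> kept
  d[3, 1:16] <- NA   # 16% -> dropped
  x <- make_cohort(d, c("case", "control", "control"))
  expect_equal(unname(sample_missingness(x)), c(0, 0.15, 0.16))
  qc <- run_qc(x, relatedness = FALSE)
  expect_equal(n_samples(qc$matrix), 2L)
  expect_equal(qc$report$samples_excluded$rule, "sample_missingness")
})

test_that("pi_hat recovers duplicates, unrelated pairs and parent-offspring", {
  set.seed(21)
  m <- 1500
  af <- runif(m, 0.2, 0.5)
  # founders drawn independently from population frequencies
  founder <- function() vapply(af, function(p) rbinom(1, 2, p), integer(1))
  f1 <- founder(); f2 <- founder()
  # offspring: one allele from each parent
  child <- vapply(seq_len(m), function(j) {
    a1 <- rbinom(1, 1, f1[j] / 2)
    a2 <- rbinom(1, 1, f2[j] / 2)
    as.integer(a1 + a2)
  }, integer(1))
  g <- rbind(f1, f1, f2, child)   # s1 & s2 duplicates; s4 child of s1, s3
  x <- make_cohort(unname(g), c("case", "control", "control", "control"))
  ph <- relatedness_pi_hat(x)
  get <- function(a, b) ph$pi_hat[(ph$sample1 == a & ph$sample2 == b) |
                                    (ph$sample1 == b & ph$sample2 == a)]
  expect_equal(get("s001", "s002"), 1, tolerance = 0.05)      # duplicate
  expect_equal(get("s001", "s003"), 0, tolerance = 0.05)      # unrelated
  expect_equal(get("s001", "s004"), 0.5, tolerance = 0.05)    # parent-child
  expect_equal(get("s003", "s004"), 0.5, tolerance = 0.05)
})

test_that("run_qc drops the worse member of a related pair", {
  set.seed(22)
  m <- 1200
  af <- runif(m, 0.2, 0.5)
  g <- t(vapply(1:4, function(i) vapply(af, function(p) rbinom(1, 2, p),
                                        integer(1)), integer(m)))
  g[2, ] <- g[1, ]
  g[2, 1:60] <- NA   # duplicate with worse missingness
  x <- make_cohort(unname(g), c("case", "control", "control", "control"))
  qc <- run_qc(x)
  expect_equal(qc$report$samples_excluded$sample_id, "s002")
  expect_equal(qc$report$samples_excluded$rule, "relatedness")
})

test_that("too few informative sites skips relatedness with a warning", {
  x <- make_cohort(matrix(0L, 3, 10), c("case", "control", "control"))
  expect_warning(out <- relatedness_pi_hat(x), "informative")
  expect_null(out)
})

test_that("region masks exclude exactly the contained sites", {
  d <- matrix(0L, 4, 3)
  x <- make_cohort(d, c("case", rep("control", 3)))   # pos 1010/1020/1030
  empty <- structure(list(), class = "interval_set")
  expect_equal(n_sites(apply_masks(x, empty)), 3L)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1015\t1025", bed)                 # covers 1-based 1016-1025
  mask <- read_mask(bed)
  out <- apply_masks(x, mask)
  expect_equal(out$sites$pos, c(1010L, 1030L))
  expect_equal(attr(out, "n_masked_sites"),
               sum(mask_contains(mask, x$sites$chrom, x$sites$pos)))
})

test_that("a clean cohort passes the cascade untouched", {
  set.seed(30)
  d <- matrix(rbinom(200 * 20, 1, 0.005), 200, 20)
  x <- make_cohort(d, rep(c("case", "control"), 100))
  qc <- run_qc(x, relatedness = FALSE)
  expect_equal(n_samples(qc$matrix), 200L)
  expect_equal(n_sites(qc$matrix), 20L)
  expect_equal(nrow(qc$report$sites_excluded), 0L)
  expect_equal(nrow(qc$report$samples_excluded), 0L)
  expect_true(all(qc$report$rule_counts == 0))
})

test_that("sample drops precede variant missingness in the cascade", {
  # a high-missingness sample pushes one site just over the 5% variant
  # threshold; once the sample is dropped the site falls back to exactly 5%
  d <- matrix(0L, 101, 50)
  d[1, 1:8] <- NA                       # sample 1: 16% missing
  d[2:6, 1] <- NA                       # site 1: 6/101 = 5.9% with s1
  x <- make_cohort(d, rep_len(c("case", "control"), 101))
  qc <- run_qc(x, relatedness = FALSE)
  expect_equal(qc$report$samples_excluded$sample_id, "s001")
  # 5/100 = 5% once s1 is gone: retained under the strict > 0.05 rule
  expect_true("chr1:1010:A:C" %in% qc$matrix$sites$site_id)
  expect_equal(nrow(qc$report$sites_excluded), 0L)
})

test_that("HWE and differential-missingness exclusions fire in run_qc", {
  set.seed(31)
  n <- 2000
  d <- matrix(rbinom(n * 10, 1, 0.005), n, 10)
  # site 1: gross HWE violation in controls (hom-alt excess, no hets)
  d[, 1] <- rep(c(0L, 2L), n / 2)
  # site 2: cases missing 9%, controls complete -> 4.5% overall (retained
  # by the missingness rule, caught by the differential rule)
  status <- rep(c("case", "control"), each = n / 2)
  d[seq_len(90), 2] <- NA
  x <- make_cohort(d, status)
  qc <- run_qc(x, relatedness = FALSE)
  rules <- qc$report$sites_excluded
  expect_true(any(rules$rule == "hwe" &
                    rules$site_id == x$sites$site_id[1]))
  expect_true(any(rules$rule == "differential_missingness" &
                    rules$site_id == x$sites$site_id[2]))
})

test_that("QC is monotone: carrier counts never increase", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 120; m <- 12
    d <- matrix(rbinom(n * m, 1, 0.03), n, m)
    x <- make_cohort(d, rep(c("case", "control"), n / 2))
    x$dp <- matrix(sample(c(4L, 50L), n * m, replace = TRUE,
                          prob = c(0.05, 0.95)), n, m,
                   dimnames = dimnames(x$dp))
    cl_before <- classify_variants(x, maf_max = 1)
    before <- collapse_carriers(x, cl_before, "G1",
                                "PTV+Mis3+Mis2+Mis1")
    qc <- tryCatch(run_qc(x, relatedness = FALSE),
                   error = function(e) NULL)
    if (is.null(qc)) next
    cl_after <- classify_variants(qc$matrix, maf_max = 1)
    after <- collapse_carriers(qc$matrix, cl_after, "G1",
                               "PTV+Mis3+Mis2+Mis1")
    expect_lte(after$case_carriers, before$case_carriers)
    expect_lte(after$control_carriers, before$control_carriers)
  }
})

test_that("QC report counts reconcile with matrix size changes", {
  d <- matrix(0L, 60, 40)
  d[1, 1:10] <- NA
  d[, 5] <- c(rep(NA, 6), rep(0L, 54))
  x <- make_cohort(d, rep(c("case", "control"), 30))
  qc <- run_qc(x, relatedness = FALSE)
  expect_equal(qc$report$n_samples_in - nrow(qc$report$samples_excluded),
               qc$report$n_samples_out)
  expect_equal(qc$report$n_sites_in - nrow(qc$report$sites_excluded),
               qc$report$n_sites_out)
})
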