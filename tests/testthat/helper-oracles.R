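# Independent brute-force oracles and small fixture builders.

# Two-sided Fisher p by direct combinatorial enumeration of all tables with
# the observed margins (counting allele arrangements with choose(), no
# distribution functions).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
  xs <- max(0, k - r2):min(r1, k)
  w <- choose(r1, xs) * choose(r2, k - xs)
  prob <- w / sum(w)
  obs <- prob[match(a, xs)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Exact HWE p by enumerating every genotype configuration compatible with
# the observed sample size and allele count, weighting each by the number
# of allele arrangements that realize it.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  cfgs <- expand.grid(AA = 0:n, Aa = 0:n)
  cfgs$aa <- n - cfgs$AA - cfgs$Aa
  cfgs <- cfgs[cfgs$aa >= 0 & cfgs$Aa + 2 * cfgs$aa == na, , drop = FALSE]
  w <- factorial(n) / (factorial(cfgs$AA) * factorial(cfgs$Aa) *
                         factorial(cfgs$aa)) * 2^cfgs$Aa
  prob <- w / sum(w)
  obs <- prob[cfgs$Aa == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Apply a (pos, ref, alt) edit to a reference window; the sequence-level
# ground truth for normalization equivalence.
apply_edit <- function(window, window_start, pos, ref, alt) {
  i <- pos - window_start + 1L
  stopifnot(substr(window, i, i + nchar(ref) - 1L) == ref)
  paste0(substr(window, 1L, i - 1L), alt,
         substr(window, i + nchar(ref), nchar(window)))
}

# Random repeat-rich window plus a random indel inside it.
random_indel_case <- function() {
  window <- paste(sample(c("A", "T", "C"), 40, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), collapse = "")
  pos <- sample(10:25, 1)
  len <- sample(1:3, 1)
  base <- substr(window, pos, pos)
  if (runif(1) < 0.5) {
    ref <- substr(window, pos, pos + len)   # deletion
    alt <- base
  } else {
    ref <- base                              # insertion
    alt <- paste0(base, paste(sample(c("A", "T"), len, replace = TRUE),
                              collapse = ""))
  }
  list(window = window, start = 1L, pos = pos, ref = ref, alt = alt)
}

# Minimal in-memory cohort: dosage matrix plus clean genotype metadata.
make_cohort <- function(dosage, status, genes = NULL,
                        effect = "missense_variant",
                        preds = c("damaging", "benign", "benign"),
                        dp = 50L, gq = 99L) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(genes)) genes <- rep("G1", m)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        status = status, stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = 1000L + 10L * seq_len(m),
                      ref = "A", alt = "C", gene = genes,
                      effect_term = effect, lof_flag = FALSE,
                      pred1 = preds[1], pred2 = preds[2], pred3 = preds[3],
                      vqslod = 10, annotated = TRUE,
                      stringsAsFactors = FALSE)
  dpm <- matrix(dp, n, m); gqm <- matrix(gq, n, m)
  ad_alt <- matrix(0L, n, m)
  ad_alt[dosage == 1L & !is.na(dosage)] <- dp %/% 2L
  ad_alt[dosage == 2L & !is.na(dosage)] <- dp
  cohort_matrix(samples, sites, dosage, dpm, gqm, dp - ad_alt, ad_alt)
}

# Write a small literal VCF for reader tests.
write_test_vcf <- function(path, records,
                           samples = c("S1", "S2", "S3"),
                           format = "GT:DP:GQ:AD") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##INFO=<ID=PRED,Number=1,Type=String,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

write_test_sheet <- function(path, ids, status) {
  writeLines(c("sample_id\tstatus", paste(ids, status, sep = "\t")), path)
  path
}
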