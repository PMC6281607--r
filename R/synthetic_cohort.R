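#' Simulation configuration for synthetic case-control cohorts
#'
#' Defaults emulate the target study design: 92 cases and 1051 controls,
#' rare heterozygous qualifying variants, deep exome genotypes (negative
#' binomial depth around 50x, genotype quality around 80), light genotype
#' missingness. Case enrichment is parameterized on the carrier odds scale,
#' so the odds ratio fed in is the odds ratio the burden test estimates.
#'
#' @param genes data.frame with one row per gene x damage class:
#'   `gene`, `damage_class` (`PTV`/`Mis3`/`Mis2`/`Mis1`/`benign`),
#'   `n_variants`, `control_freq` (per-class control carrier frequency),
#'   `or` (target carrier odds ratio).
#' @param n_case,n_control group sizes.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param gq_mean,gq_sd genotype-quality model (clamped to \[0, 99\]).
#' @param missing_rate per-genotype missingness probability.
#' @param het_ab_concentration Beta concentration of the heterozygous
#'   alternate-allele fraction around 0.5 (higher = tighter).
#' @param predictor_error_rate probability that each predictor verdict is
#'   flipped relative to the class-consistent verdict.
#' @param mask_fraction fraction of each gene's variants planted inside the
#'   emitted exclusion mask.
#' @param homozygous_rate probability a carrier is homozygous.
#' @param multi_variant_rate probability a carrier receives a second
#'   distinct qualifying variant (exercises union counting).
#' @param low_depth_sites,ab_skew_sites,case_missing_sites number of sites
#'   (taken from the start of the site list, in that order) planted with a
#'   QC violation: uniform low depth (DP ~ 3), skewed heterozygous allele
#'   balance (~0.1), or case-only extra missingness (30%).
#' @param reference_anmax reference-panel size used by
#'   [simulate_reference()].
#' @param seed mandatory integer root seed; component substreams are derived
#'   from it (variants/carriers: `seed`, genotype noise: `seed + 1`,
#'   reference: `seed + 2`).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(genes, n_case = 92L, n_control = 1051L,
                              depth_mean = 50, depth_size = 10,
                              gq_mean = 80, gq_sd = 15,
                              missing_rate = 0.01,
                              het_ab_concentration = 50,
                              predictor_error_rate = 0,
                              mask_fraction = 0,
                              homozygous_rate = 0,
                              multi_variant_rate = 0,
                              low_depth_sites = 0L,
                              ab_skew_sites = 0L,
                              case_missing_sites = 0L,
                              reference_anmax = 33370L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "damage_class", "n_variants", "control_freq",
                  "or") %in% names(genes)),
            all(genes$control_freq >= 0 & genes$control_freq <= 1),
            all(genes$or > 0), all(genes$n_variants >= 0))
  if (any(genes$n_variants == 0 & genes$control_freq > 0))
    stop("gene with zero variants but positive carrier frequency: ",
         paste(genes$gene[genes$n_variants == 0 & genes$control_freq > 0],
               collapse = ", "))
  cfg <- list(genes = genes, n_case = as.integer(n_case),
              n_control = as.integer(n_control), depth_mean = depth_mean,
              depth_size = depth_size, gq_mean = gq_mean, gq_sd = gq_sd,
              missing_rate = missing_rate,
              het_ab_concentration = het_ab_concentration,
              predictor_error_rate = predictor_error_rate,
              mask_fraction = mask_fraction,
              homozygous_rate = homozygous_rate,
              multi_variant_rate = multi_variant_rate,
              low_depth_sites = as.integer(low_depth_sites),
              ab_skew_sites = as.integer(ab_skew_sites),
              case_missing_sites = as.integer(case_missing_sites),
              reference_anmax = as.integer(reference_anmax),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Case carrier probability implied by a carrier odds ratio
#'
#' Solves `odds(p) = or * odds(q)` for the case carrier probability `p`
#' given the control carrier frequency `q`.
#'
#' @param q control carrier frequency.
#' @param or target carrier odds ratio.
#' @return case carrier probability.
#' @export
case_carrier_prob <- function(q, or) {
  odds <- or * q / (1 - q)
  odds / (1 + odds)
}

#' Draw carrier counts for one gene under the carrier-odds model
#'
#' The count-level core of the cohort generator, usable directly for
#' power / type-I-error studies without emitting genotypes.
#'
#' @param n_case,n_control group sizes.
#' @param q control carrier frequency.
#' @param or target carrier odds ratio.
#' @return list `case_carriers`, `control_carriers`, `p_case`.
#' @export
simulate_gene_counts <- function(n_case, n_control, q, or) {
  p <- case_carrier_prob(q, or)
  list(case_carriers = stats::rbinom(1, n_case, p),
       control_carriers = stats::rbinom(1, n_control, q),
       p_case = p)
}

#' Simulate a synthetic case-control exome cohort
#'
#' Draws carrier status per sample and gene x damage class with the
#' configured control frequency and carrier odds ratio, assigns each
#' carrier one qualifying (by default heterozygous) variant from the gene's
#' variant list, and overlays the genotype model (depth, quality, allele
#' depths, missingness). Fully reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes `cohort.vcf`,
#'   `samples.tsv`, `annotation.tsv`, `masks.bed` and `truth.tsv` there.
#' @return list with the in-memory `matrix` ([cohort_matrix]), `truth`
#'   (realized carrier counts per gene x collapsing class), `mask`
#'   (`interval_set`), and `paths` (when `dir` was given).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_case <- config$n_case; n_ctrl <- config$n_control
  n <- n_case + n_ctrl
  samples <- data.frame(
    sample_id = c(sprintf("case_%04d", seq_len(n_case)),
                  sprintf("ctrl_%04d", seq_len(n_ctrl))),
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
  is_case <- samples$status == "case"

  genes <- config$genes
  bases <- c("A", "C", "G", "T")
  site_rows <- list(); site_gene_row <- integer()
  for (i in seq_len(nrow(genes))) {
    v <- genes$n_variants[i]
    if (v == 0) next
    pos <- as.integer(i * 1e6 + 200L * seq_len(v))
    ref <- sample(bases, v, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    dc <- genes$damage_class[i]
    if (dc == "PTV") {
      eff <- "stop_gained"; lof <- TRUE; preds <- c("missing", "missing", "missing")
    } else {
      eff <- if (dc == "benign") "synonymous_variant" else "missense_variant"
      lof <- FALSE
      n_dam <- switch(dc, Mis3 = 3L, Mis2 = 2L, Mis1 = 1L, 0L)
      preds <- rep(c("damaging", "benign"), c(n_dam, 3L - n_dam))
    }
    for (j in seq_len(v)) {
      pj <- preds
      flip <- stats::runif(3) < config$predictor_error_rate
      pj[flip] <- ifelse(pj[flip] == "damaging", "benign", "damaging")
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = "chr1", pos = pos[j], ref = unname(ref[j]),
        alt = unname(alt[j]), gene = genes$gene[i], effect_term = eff,
        lof_flag = lof, pred1 = pj[1], pred2 = pj[2], pred3 = pj[3],
        vqslod = round(stats::rnorm(1, 10, 2), 3), annotated = TRUE,
        stringsAsFactors = FALSE)
      site_gene_row <- c(site_gene_row, i)
    }
  }
  sites <- do.call(rbind, site_rows)
  m <- nrow(sites)
  dosage <- matrix(0L, n, m)

  truth_rows <- list()
  for (i in seq_len(nrow(genes))) {
    q <- genes$control_freq[i]
    if (q == 0 || genes$n_variants[i] == 0) next
    p <- case_carrier_prob(q, genes$or[i])
    carrier <- stats::rbinom(n, 1, ifelse(is_case, p, q)) == 1
    site_idx <- which(site_gene_row == i)
    who <- which(carrier)
    if (length(who)) {
      pick <- site_idx[sample.int(length(site_idx), length(who),
                                  replace = TRUE)]
      dose <- ifelse(stats::runif(length(who)) < config$homozygous_rate,
                     2L, 1L)
      dosage[cbind(who, pick)] <- dose
      extra <- who[stats::runif(length(who)) < config$multi_variant_rate]
      if (length(extra) && length(site_idx) > 1) {
        pick2 <- site_idx[sample.int(length(site_idx), length(extra),
                                     replace = TRUE)]
        dosage[cbind(extra, pick2)] <-
          pmax(dosage[cbind(extra, pick2)], 1L)
      }
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene = genes$gene[i], damage_class = genes$damage_class[i],
      control_freq = q, or = genes$or[i], p_case = p,
      case_carriers = sum(carrier & is_case),
      control_carriers = sum(carrier & !is_case),
      stringsAsFactors = FALSE)
  }
  truth_dc <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame()

  # genotype model (independent substream)
  set.seed(config$seed + 1L)
  dp <- matrix(stats::rnbinom(n * m, size = config$depth_size,
                              mu = config$depth_mean), n, m)
  gq <- matrix(pmin(99L, pmax(0L, as.integer(round(
    stats::rnorm(n * m, config$gq_mean, config$gq_sd))))), n, m)
  ab <- config$het_ab_concentration / 2
  het_frac <- matrix(stats::rbeta(n * m, ab, ab), n, m)
  # planted violations: consecutive site blocks, in fixed order
  planted <- list()
  nxt <- 1L
  if (config$low_depth_sites > 0) {
    idx <- seq.int(nxt, length.out = min(config$low_depth_sites, m))
    dp[, idx] <- matrix(stats::rpois(n * length(idx), 3), n)
    planted$low_depth <- idx
    nxt <- nxt + length(idx)
  }
  if (config$ab_skew_sites > 0) {
    idx <- seq.int(nxt, length.out = min(config$ab_skew_sites, m - nxt + 1L))
    het_frac[, idx] <- matrix(stats::rbeta(n * length(idx), 2, 18), n)
    planted$ab_skew <- idx
    nxt <- nxt + length(idx)
  }
  miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
  if (config$case_missing_sites > 0) {
    idx <- seq.int(nxt, length.out = min(config$case_missing_sites,
                                         m - nxt + 1L))
    miss[is_case, idx] <- miss[is_case, idx] |
      matrix(stats::runif(n_case * length(idx)) < 0.30, n_case)
    planted$case_missing <- idx
    nxt <- nxt + length(idx)
  }
  ad_alt <- matrix(0L, n, m)
  het <- dosage == 1L
  ad_alt[het] <- stats::rbinom(sum(het), dp[het], het_frac[het])
  hom <- dosage == 2L
  ad_alt[hom] <- dp[hom]
  ad_ref <- dp - ad_alt
  dosage[miss] <- NA_integer_

  x <- cohort_matrix(samples, sites, dosage, dp, gq, ad_ref, ad_alt)

  # masked-region placement: first ceil(fraction * v) variants of each gene
  mask_pos <- integer()
  if (config$mask_fraction > 0) {
    for (i in unique(site_gene_row)) {
      idx <- which(site_gene_row == i)
      k <- ceiling(config$mask_fraction * length(idx))
      mask_pos <- c(mask_pos, sites$pos[idx[seq_len(k)]])
    }
  }
  mask <- if (length(mask_pos)) {
    iv <- cbind(start = sort(mask_pos) - 1L, end = sort(mask_pos))
    structure(list(chr1 = iv), class = "interval_set")
  } else structure(list(), class = "interval_set")

  # truth per gene x collapsing class (union of carrier sets)
  truth <- list()
  for (g in unique(genes$gene)) {
    for (cc in collapse_classes()) {
      rows_g <- which(genes$gene == g &
                        vapply(genes$damage_class,
                               function(d) cc %in% embedded_membership(d),
                               logical(1)))
      site_idx <- which(site_gene_row %in% rows_g)
      if (!length(site_idx)) next
      carrier <- rowSums(dosage[, site_idx, drop = FALSE] >= 1L,
                         na.rm = TRUE) > 0
      qsum <- sum(genes$control_freq[rows_g])
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g, class = cc, control_freq = qsum,
        or = genes$or[rows_g[1]],
        case_carriers = sum(carrier & is_case),
        control_carriers = sum(carrier & !is_case),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  attr(truth, "by_damage_class") <- truth_dc
  attr(truth, "planted") <- planted
  attr(truth, "seed") <- config$seed

  out <- list(matrix = x, truth = truth, mask = mask)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(dir, "cohort.vcf"),
                  sample_sheet = file.path(dir, "samples.tsv"),
                  annotation = file.path(dir, "annotation.tsv"),
                  masks = file.path(dir, "masks.bed"),
                  truth = file.path(dir, "truth.tsv"))
    write_cohort_vcf(x, paths$vcf)
    write_sample_sheet(x, paths$sample_sheet)
    write_annotation_tsv(x, paths$annotation)
    write_mask_bed(mask, paths$masks)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate a matching reference count table
#'
#' TAC per gene x collapsing class is drawn as a binomial allele count at
#' half the class carrier frequency (heterozygous-carrier approximation)
#' over `2 * anmax` alleles; per-gene multipliers deplete or inflate the
#' reference expectation to plant questionable / false-positive /
#' not-analyzable scenarios.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_cohort()].
#' @param multipliers named numeric vector (gene -> multiplier on the
#'   reference carrier frequency); default 1 for every gene. A multiplier
#'   above 1 makes the cohort controls look depleted, below 1 makes the
#'   reference look depleted (control excess).
#' @param path optional TSV output path.
#' @return data.frame `gene, class, tac, anmax`.
#' @export
simulate_reference <- function(config, truth, multipliers = NULL,
                               path = NULL) {
  set.seed(config$seed + 2L)
  anmax <- config$reference_anmax
  mult <- rep(1, nrow(truth))
  if (!is.null(multipliers)) {
    hit <- match(truth$gene, names(multipliers))
    mult[!is.na(hit)] <- multipliers[hit[!is.na(hit)]]
  }
  pfreq <- pmin(0.5, truth$control_freq * mult / 2)
  ref <- data.frame(gene = truth$gene, class = truth$class,
                    tac = stats::rbinom(nrow(truth), 2L * anmax, pfreq),
                    anmax = anmax, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(ref, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  ref
}

#' Write a cohort matrix as a VCF file
#'
#' Emits a VCF v4.2 with FORMAT `GT:DP:GQ:AD` and annotation carried in the
#' INFO subfields `GENE`, `EFFECT`, `LOF`, `PRED`, `VQSLOD`. Deterministic:
#' no timestamps.
#'
#' @param x a [cohort_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(x, path) {
  s <- x$sites
  ord <- order(s$chrom, s$pos, s$ref, s$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(s$chrom[ord]), ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Functional effect term\">",
    "##INFO=<ID=LOF,Number=1,Type=Integer,Description=\"Loss-of-function flag\">",
    "##INFO=<ID=PRED,Number=1,Type=String,Description=\"Pipe-delimited damage predictor verdicts\">",
    "##INFO=<ID=VQSLOD,Number=1,Type=Float,Description=\"Variant quality log-odds (pass-through)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t"))
  fmt_int <- function(v) ifelse(is.na(v), ".", as.character(v))
  body <- vapply(ord, function(j) {
    d <- x$dosage[, j]
    gt <- ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
    cells <- paste(gt, fmt_int(x$dp[, j]), fmt_int(x$gq[, j]),
                   paste0(fmt_int(x$ad_ref[, j]), ",",
                          fmt_int(x$ad_alt[, j])), sep = ":")
    info <- if (isTRUE(s$annotated[j])) {
      paste0("GENE=", s$gene[j], ";EFFECT=", s$effect_term[j],
             ";LOF=", as.integer(isTRUE(s$lof_flag[j])),
             ";PRED=", paste(substr(c(s$pred1[j], s$pred2[j], s$pred3[j]),
                                    1, 1), collapse = "|"),
             if (!is.na(s$vqslod[j])) paste0(";VQSLOD=", s$vqslod[j]) else "")
    } else "."
    paste(c(s$chrom[j], s$pos[j], ".", s$ref[j], s$alt[j], ".", "PASS",
            info, "GT:DP:GQ:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample sheet of a cohort matrix
#' @param x a [cohort_matrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(x$samples[, c("sample_id", "status")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the annotation sidecar of a cohort matrix
#' @param x a [cohort_matrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(x, path) {
  s <- x$sites
  ann <- data.frame(site_id = s$site_id, gene = s$gene,
                    effect_term = s$effect_term,
                    lof_flag = s$lof_flag, pred1 = s$pred1, pred2 = s$pred2,
                    pred3 = s$pred3, vqslod = s$vqslod,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interval set as BED
#' @param mask an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  lines <- character()
  for (chrom in names(mask)) {
    iv <- mask[[chrom]]
    lines <- c(lines, paste(chrom, iv[, "start"], iv[, "end"], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
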