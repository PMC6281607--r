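#' Read a case-control cohort from VCF plus sample sheet and annotation
#'
#' Loads a VCF (v4.x, FORMAT fields GT/DP/GQ/AD), splits multi-allelic records
#' into bi-allelic sites, trims shared allele prefixes/suffixes, and joins
#' per-sample phenotypes and per-site functional annotation. Annotation can
#' come from VCF INFO subfields (`GENE`, `EFFECT`, `LOF`, `PRED`, `VQSLOD`)
#' or from a sidecar TSV keyed by `site_id`; when both are present the sidecar
#' wins, with a warning on conflict. Sites lacking any annotation are retained
#' with all three predictor verdicts set to `"missing"` and are counted in the
#' load report (`attr(x, "load_report")`).
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF file.
#' @param sample_sheet_path TSV with columns `sample_id`, `status`
#'   (`case`/`control`); every VCF sample must appear.
#' @param annotation_path optional sidecar annotation TSV
#'   (`site_id  gene  effect_term  lof_flag  pred1  pred2  pred3 [vqslod]`).
#' @return A [cohort_matrix] with a `load_report` attribute.
#' @export
read_cohort <- function(vcf_path, sample_sheet_path, annotation_path = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  sheet <- read_sample_sheet(sample_sheet_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  fmt <- gt[, 1]
  vcf_samples <- colnames(gt)[-1]
  missing_samples <- setdiff(vcf_samples, sheet$sample_id)
  if (length(missing_samples))
    stop("VCF sample(s) absent from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  status <- sheet$status[match(vcf_samples, sheet$sample_id)]

  sites_list <- list()
  dosage_cols <- list(); dp_cols <- list(); gq_cols <- list()
  adr_cols <- list(); ada_cols <- list()
  n_multi <- 0L
  for (i in seq_len(nrow(fix))) {
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    fields <- strsplit(gt[i, -1], ":", fixed = TRUE)
    get_field <- function(key) {
      j <- match(key, keys)
      if (is.na(j)) return(rep(NA_character_, length(fields)))
      vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_,
             character(1))
    }
    gts <- get_field("GT")
    dp <- suppressWarnings(as.integer(get_field("DP")))
    gq <- suppressWarnings(as.integer(get_field("GQ")))
    ad <- get_field("AD")
    ad_parts <- strsplit(ad, ",", fixed = TRUE)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1) n_multi <- n_multi + 1L
    split <- split_multiallelic(fix[i, "CHROM"],
                                as.integer(fix[i, "POS"]),
                                fix[i, "REF"], alts, gts)
    info <- parse_info_annotation(fix[i, "INFO"])
    for (k in seq_along(split)) {
      rec <- split[[k]]
      ad_alt <- suppressWarnings(vapply(ad_parts, function(p) {
        if (length(p) >= k + 1 && !is.na(p[k + 1]) && p[k + 1] != ".")
          as.integer(p[k + 1]) else NA_integer_
      }, integer(1)))
      ad_ref <- suppressWarnings(vapply(ad_parts, function(p) {
        if (length(p) >= 1 && !is.na(p[1]) && nzchar(p[1]) && p[1] != ".")
          as.integer(p[1]) else NA_integer_
      }, integer(1)))
      site <- c(rec$site, info)
      sites_list[[length(sites_list) + 1L]] <- site
      dosage_cols[[length(dosage_cols) + 1L]] <- rec$dosage
      dp_cols[[length(dp_cols) + 1L]] <- dp
      gq_cols[[length(gq_cols) + 1L]] <- gq
      adr_cols[[length(adr_cols) + 1L]] <- ad_ref
      ada_cols[[length(ada_cols) + 1L]] <- ad_alt
    }
  }
  sites <- do.call(rbind, lapply(sites_list, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  sites$site_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                         sep = ":")
  bind <- function(cols) matrix(unlist(cols), nrow = length(vcf_samples),
                                dimnames = list(vcf_samples, sites$site_id))
  x <- cohort_matrix(
    samples = data.frame(sample_id = vcf_samples, status = status,
                         stringsAsFactors = FALSE),
    sites = sites, dosage = bind(dosage_cols), dp = bind(dp_cols),
    gq = bind(gq_cols), ad_ref = bind(adr_cols), ad_alt = bind(ada_cols))

  if (!is.null(annotation_path))
    x <- apply_annotation_sidecar(x, read_annotation(annotation_path))
  attr(x, "load_report") <- list(
    n_records = nrow(fix), n_sites = nrow(x$sites),
    n_multiallelic_records = n_multi,
    n_unannotated = sum(!x$sites$annotated),
    unannotated = x$sites$site_id[!x$sites$annotated])
  x
}

#' Read a sample sheet TSV
#'
#' @param path TSV with header columns `sample_id` and `status`.
#' @return data.frame with `sample_id` and `status` columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("cannot read sample sheet: ", path)
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(sheet)))
    stop("sample sheet needs columns sample_id and status")
  bad <- setdiff(unique(sheet$status), c("case", "control"))
  if (length(bad))
    stop("phenotype status must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  sheet
}

#' Read a variant annotation sidecar TSV
#'
#' Columns: `site_id`, `gene`, `effect_term`, `lof_flag`, `pred1`, `pred2`,
#' `pred3`, optionally `vqslod`. Predictor verdicts are `damaging`, `benign`
#' or `missing` (single-letter `d`/`b`/`m` also accepted).
#'
#' @param path file path.
#' @return data.frame of annotation rows.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("site_id", "gene", "effect_term", "lof_flag",
            "pred1", "pred2", "pred3")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  for (p in c("pred1", "pred2", "pred3"))
    ann[[p]] <- normalize_verdict(ann[[p]])
  ann$lof_flag <- as.logical(ann$lof_flag)
  if (is.null(ann$vqslod)) ann$vqslod <- NA_real_
  ann
}

normalize_verdict <- function(v) {
  v <- tolower(as.character(v))
  v[v %in% c("d", "damaging")] <- "damaging"
  v[v %in% c("b", "benign", "tolerated", "t")] <- "benign"
  v[is.na(v) | v %in% c("m", ".", "", "missing")] <- "missing"
  bad <- setdiff(unique(v), c("damaging", "benign", "missing"))
  if (length(bad)) stop("unknown predictor verdict: ", paste(bad, collapse = ", "))
  v
}

# INFO subfields understood as annotation transport:
# GENE=, EFFECT=, LOF=(0/1/true/false), PRED=d|b|m (pipe-delimited), VQSLOD=.
parse_info_annotation <- function(info) {
  out <- list(gene = NA_character_, effect_term = NA_character_,
              lof_flag = NA, pred1 = "missing", pred2 = "missing",
              pred3 = "missing", vqslod = NA_real_, annotated = FALSE)
  if (is.na(info) || info == "." || !nzchar(info)) return(out)
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  if (!is.na(get("GENE"))) { out$gene <- get("GENE"); out$annotated <- TRUE }
  if (!is.na(get("EFFECT"))) { out$effect_term <- get("EFFECT"); out$annotated <- TRUE }
  if (!is.na(get("LOF")))
    out$lof_flag <- get("LOF") %in% c("1", "true", "TRUE", "True")
  if (!is.na(get("PRED"))) {
    pr <- normalize_verdict(strsplit(get("PRED"), "|", fixed = TRUE)[[1]])
    if (length(pr) != 3) stop("PRED INFO subfield must have 3 entries: ", info)
    out$pred1 <- pr[1]; out$pred2 <- pr[2]; out$pred3 <- pr[3]
    out$annotated <- TRUE
  }
  if (!is.na(get("VQSLOD"))) out$vqslod <- as.numeric(get("VQSLOD"))
  out
}

apply_annotation_sidecar <- function(x, ann) {
  idx <- match(x$sites$site_id, ann$site_id)
  hit <- !is.na(idx)
  conflict <- hit & x$sites$annotated &
    (x$sites$gene != ann$gene[idx] | x$sites$effect_term != ann$effect_term[idx])
  conflict[is.na(conflict)] <- FALSE
  if (any(conflict))
    warning("annotation sidecar overrides VCF INFO annotation for ",
            sum(conflict), " site(s): ",
            paste(utils::head(x$sites$site_id[conflict], 5), collapse = ", "))
  for (col in c("gene", "effect_term", "lof_flag", "pred1", "pred2", "pred3"))
    x$sites[[col]][hit] <- ann[[col]][idx[hit]]
  vq <- ann$vqslod[idx[hit]]
  x$sites$vqslod[hit][!is.na(vq)] <- vq[!is.na(vq)]
  x$sites$annotated[hit] <- TRUE
  x
}

#' Split a multi-allelic VCF record into bi-allelic sites
#'
#' For alternate allele `k`, each sample's dosage is the count of allele `k`
#' in its genotype; alleles belonging to a different alternate contribute 0.
#' Genotypes with any missing allele become missing dosage. Each split record
#' is prefix/suffix-trimmed to its minimal representation.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref reference allele.
#' @param alts character vector of alternate alleles.
#' @param per_sample_gts character vector of GT strings (`"0/1"`, `"1|2"`,
#'   `"./."` ...).
#' @return list with one element per alternate allele, each
#'   `list(site = list(chrom, pos, ref, alt), dosage = integer vector)`.
#' @export
split_multiallelic <- function(chrom, pos, ref, alts, per_sample_gts) {
  if (!length(alts)) stop("no alternate alleles")
  allele_lists <- strsplit(per_sample_gts, "[/|]")
  parsed <- lapply(allele_lists, function(a) {
    if (!length(a) || any(a == "." | a == "")) return(NULL)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai)) stop("malformed genotype: ",
                        paste(a, collapse = "/"))
    ai
  })
  lapply(seq_along(alts), function(k) {
    dosage <- vapply(parsed, function(a) {
      if (is.null(a)) NA_integer_ else sum(a == k)
    }, integer(1))
    trimmed <- trim_alleles(pos, ref, alts[k])
    list(site = list(chrom = chrom, pos = trimmed$pos, ref = trimmed$ref,
                     alt = trimmed$alt),
         dosage = dosage)
  })
}

# Minimal representation: shared suffix then shared prefix trimmed, always
# keeping at least one base per allele. No reference context needed.
trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize (left-align) a variant against a reference window
#'
#' Trims shared suffix then prefix (keeping at least one base per allele) and
#' shifts indels left while the edit remains sequence-equivalent, in the style
#' of standard VCF normalization. Idempotent.
#'
#' @param site list or one-row data.frame with `pos`, `ref`, `alt` (1-based).
#' @param window reference sequence string covering the site and upstream
#'   context.
#' @param window_start 1-based genomic position of the first base of `window`.
#' @return the site with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(site, window, window_start = 1L) {
  pos <- as.integer(site$pos); ref <- site$ref; alt <- site$alt
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  at <- function(gpos) {
    i <- gpos - window_start + 1L
    if (i < 1L || i > length(w)) stop("window does not cover position ", gpos)
    w[i]
  }
  obs <- paste(vapply(pos:(pos + nchar(ref) - 1L), at, character(1)),
               collapse = "")
  if (obs != ref)
    stop("ref allele '", ref, "' disagrees with reference window ('",
         obs, "') at ", pos)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  repeat {
    if (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    } else if (length(r) != length(a) &&
               (length(r) == 1L || length(a) == 1L) &&
               r[length(r)] == a[length(a)] && pos > window_start) {
      prev <- at(pos - 1L)
      r <- c(prev, r[-length(r)]); a <- c(prev, a[-length(a)])
      pos <- pos - 1L
    } else break
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  site$pos <- as.integer(pos)
  site$ref <- paste(r, collapse = "")
  site$alt <- paste(a, collapse = "")
  if (!is.null(site$site_id) || !is.null(site$chrom))
    site$site_id <- paste(site$chrom, site$pos, site$ref, site$alt, sep = ":")
  site
}

#' Read a BED exclusion mask
#'
#' BED lines are `chrom  start  end` (0-based half-open). Overlapping or
#' adjacent input intervals are merged per chromosome.
#'
#' @param bed_path path to a BED file.
#' @return An `interval_set`: per-chromosome sorted, non-overlapping
#'   intervals.
#' @export
read_mask <- function(bed_path) {
  if (!file.exists(bed_path)) stop("cannot read BED: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(structure(list(), class = "interval_set"))
  parts <- strsplit(lines, "[ \t]+")
  bad <- vapply(parts, function(p) length(p) < 3, logical(1))
  if (any(bad)) stop("unparsable BED line: ", lines[which(bad)[1]])
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end))
    stop("unparsable BED coordinates in: ", bed_path)
  if (any(start >= end))
    stop("BED interval with start >= end: ",
         lines[which(start >= end)[1]])
  out <- lapply(split(data.frame(start, end), chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ms <- d$start[1]; me <- d$end[1]; res <- NULL
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= me) me <- max(me, d$end[i])
      else { res <- rbind(res, c(ms, me)); ms <- d$start[i]; me <- d$end[i] }
    }
    res <- rbind(res, c(ms, me))
    colnames(res) <- c("start", "end")
    res
  })
  structure(out, class = "interval_set")
}

#' Test whether positions fall inside a mask
#'
#' @param mask an `interval_set` from [read_mask()].
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return logical vector.
#' @export
mask_contains <- function(mask, chrom, pos) {
  chrom <- rep_len(as.character(chrom), length(pos))
  p0 <- as.integer(pos) - 1L
  vapply(seq_along(p0), function(i) {
    iv <- mask[[chrom[i]]]
    if (is.null(iv)) return(FALSE)
    any(iv[, "start"] <= p0[i] & p0[i] < iv[, "end"])
  }, logical(1))
}

result_columns <- c("gene", "class", "case_carriers", "case_n",
                    "control_carriers", "control_n", "or", "or_cmle",
                    "ci_low", "ci_high", "p", "q", "bonferroni_significant",
                    "robustness")

#' Write burden results to a TSV report
#'
#' Deterministic column order; `Inf`/`NA` written literally so that
#' [read_results()] round-trips losslessly.
#'
#' @param results data.frame of burden results (missing columns are filled
#'   with `NA`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  for (col in result_columns)
    if (is.null(results[[col]])) results[[col]] <- rep(NA, nrow(results))
  results <- results[, result_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to: ", path)
  invisible(path)
}

#' Read a burden results TSV written by [write_results()]
#' @param path file path.
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
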