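#' Damage and collapsing class vocabularies
#'
#' Variants are classified into one damage class: `PTV` (protein-truncating),
#' `Mis3`/`Mis2`/`Mis1` (missense called damaging by 3/2/1 of three in-silico
#' predictors), `benign` (missense with no damaging call, or any other
#' non-truncating coding effect), or `unclassified`. Association testing uses
#' four embedded (nested) collapsing classes.
#'
#' @return character vector of class labels, ordered from most to least
#'   restrictive for `collapse_classes()`.
#' @export
collapse_classes <- function() {
  c("PTV", "PTV+Mis3", "PTV+Mis3+Mis2", "PTV+Mis3+Mis2+Mis1")
}

#' @rdname collapse_classes
#' @export
damage_classes <- function() {
  c("PTV", "Mis3", "Mis2", "Mis1", "benign", "unclassified")
}

ptv_effect_terms <- c("stop_gained", "frameshift_variant",
                      "splice_donor_variant", "splice_acceptor_variant")
known_effect_terms <- c(ptv_effect_terms, "missense_variant",
                        "synonymous_variant", "stop_lost", "start_lost",
                        "inframe_insertion", "inframe_deletion",
                        "splice_region_variant")

#' Is a variant protein-truncating?
#'
#' A variant is a PTV when its loss-of-function annotation flag is present
#' and true. When the flag is absent, the fallback is effect-term based:
#' nonsense, frameshift, or canonical splice-site terms count, unless the
#' variant is marked as falling in the terminal exon (where truncation is
#' often tolerated); an unknown terminal-exon status is treated as
#' non-terminal with a warning.
#'
#' @param effect_term controlled functional term.
#' @param lof_flag logical or `NA` (annotation absent).
#' @param terminal_exon logical or `NA` (unknown).
#' @param warn emit the fallback warning (set `FALSE` in bulk paths that
#'   warn once).
#' @return logical.
#' @export
is_ptv <- function(effect_term, lof_flag = NA, terminal_exon = NA,
                   warn = TRUE) {
  if (!is.na(lof_flag)) return(isTRUE(lof_flag))
  if (!effect_term %in% ptv_effect_terms) return(FALSE)
  if (is.na(terminal_exon)) {
    if (warn)
      warning("LOF flag and terminal-exon status unknown for ", effect_term,
              " variant; treating as non-terminal (PTV)")
    terminal_exon <- FALSE
  }
  !terminal_exon
}

#' Consensus missense classification
#'
#' Counts damaging verdicts among the (available) predictor calls:
#' 3 damaging = `Mis3`, 2 = `Mis2`, 1 = `Mis1`, 0 = `benign`. With
#' `missing_verdicts = "count_available"` (default) missing verdicts simply
#' do not contribute; with `"exclude"` any missing verdict makes the variant
#' `unclassified`.
#'
#' @param predictor_calls character vector of exactly 3 verdicts
#'   (`damaging`/`benign`/`missing`).
#' @param missing_verdicts `"count_available"` or `"exclude"`.
#' @return one of `"Mis3"`, `"Mis2"`, `"Mis1"`, `"benign"`, `"unclassified"`.
#' @export
classify_missense <- function(predictor_calls,
                              missing_verdicts = c("count_available",
                                                   "exclude")) {
  missing_verdicts <- match.arg(missing_verdicts)
  if (length(predictor_calls) != 3)
    stop("predictor_calls must have exactly 3 entries")
  predictor_calls <- normalize_verdict(predictor_calls)
  if (missing_verdicts == "exclude" && any(predictor_calls == "missing"))
    return("unclassified")
  n_dam <- sum(predictor_calls == "damaging")
  c("benign", "Mis1", "Mis2", "Mis3")[n_dam + 1L]
}

#' Classify every site of a cohort
#'
#' Assigns one damage class per site and computes the within-cohort minor
#' allele frequency (denominator: 2 x non-missing samples, combined cases
#' and controls, post genotype masking). Rare means MAF strictly below
#' `maf_max`. Sites with an unknown effect term or with all calls missing
#' are flagged.
#'
#' @param x a post-QC [cohort_matrix].
#' @param maf_max rarity threshold on the cohort MAF (strict `<`).
#' @param missing_verdicts passed to [classify_missense()].
#' @return data.frame `site_id, gene, damage_class, maf, rare` plus one
#'   logical column per collapsing class.
#' @export
classify_variants <- function(x, maf_max = 0.01,
                              missing_verdicts = "count_available") {
  sites <- x$sites
  n <- nrow(sites)
  damage <- character(n)
  warned_terminal <- FALSE
  for (i in seq_len(n)) {
    eff <- sites$effect_term[i]
    lof <- sites$lof_flag[i]
    if (is.na(eff) && is.na(lof)) {
      damage[i] <- "unclassified"
    } else if (is_ptv(if (is.na(eff)) "" else eff, lof, warn = FALSE)) {
      damage[i] <- "PTV"
      if (is.na(lof) && !warned_terminal) warned_terminal <- TRUE
    } else if (!is.na(eff) && eff == "missense_variant") {
      damage[i] <- classify_missense(
        c(sites$pred1[i], sites$pred2[i], sites$pred3[i]), missing_verdicts)
    } else if (!is.na(eff) && eff %in% known_effect_terms) {
      damage[i] <- "benign"
    } else {
      damage[i] <- "unclassified"
    }
  }
  if (warned_terminal)
    warning("PTV fallback used for sites without LOF flag; ",
            "terminal-exon status unknown, treated as non-terminal")
  unknown <- !is.na(sites$effect_term) &
    !sites$effect_term %in% known_effect_terms
  if (any(unknown))
    warning("unknown effect term(s), left unclassified: ",
            paste(unique(sites$effect_term[unknown]), collapse = ", "))
  maf <- vapply(seq_len(n), function(j) cohort_maf(x$dosage[, j]),
                numeric(1))
  if (anyNA(maf))
    warning(sum(is.na(maf)), " site(s) with all calls missing excluded ",
            "from rarity selection")
  out <- data.frame(site_id = sites$site_id, gene = sites$gene,
                    damage_class = damage, maf = maf,
                    rare = !is.na(maf) & maf < maf_max,
                    stringsAsFactors = FALSE)
  for (cc in collapse_classes())
    out[[cc]] <- vapply(damage, function(d) cc %in% embedded_membership(d),
                        logical(1), USE.NAMES = FALSE)
  out
}

#' Within-cohort minor allele frequency
#'
#' @param dosages integer dosages (0/1/2, `NA` = missing call).
#' @return `min(f, 1 - f)` where `f` is the alternate-allele fraction over
#'   non-missing calls; `NA` when every call is missing.
#' @export
cohort_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) return(NA_real_)
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Embedded collapsing-class membership of a damage class
#'
#' `PTV` variants belong to all four nested classes, `Mis3` to the last
#' three, `Mis2` to the last two, `Mis1` to the last one; benign and
#' unclassified variants are excluded from association testing.
#'
#' @param damage_class one of [damage_classes()].
#' @return character vector of collapsing classes (possibly empty).
#' @export
embedded_membership <- function(damage_class) {
  cc <- collapse_classes()
  switch(damage_class,
         PTV = cc,
         Mis3 = cc[2:4],
         Mis2 = cc[3:4],
         Mis1 = cc[4],
         character(0))
}

#' Write a classification table as TSV
#' @param classification output of [classify_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  cls <- collapse_classes()
  out <- classification[, c("site_id", "gene", "damage_class", "maf", "rare")]
  out$classes <- vapply(seq_len(nrow(classification)), function(i)
    paste(cls[unlist(classification[i, cls])], collapse = ","),
    character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
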