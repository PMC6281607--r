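#' Read a reference count table
#'
#' Accepts either a pre-aggregated table (`gene  class  tac  anmax`) with
#' one row per gene x collapsing class, or a sitewise export
#' (`gene  damage_class  ac  an`) which is aggregated with
#' [aggregate_reference()].
#'
#' @param path TSV path.
#' @param ... passed to [aggregate_reference()] for sitewise input.
#' @return data.frame `gene, class, tac, anmax`.
#' @export
read_reference <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read reference table: ", path)
  ref <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (all(c("gene", "class", "tac", "anmax") %in% names(ref))) {
    bad <- ref$tac > 2 * ref$anmax | ref$anmax <= 0 | ref$tac < 0
    if (any(bad))
      stop("invalid reference counts for: ",
           paste(ref$gene[bad], collapse = ", "))
    return(ref[, c("gene", "class", "tac", "anmax")])
  }
  if (all(c("gene", "damage_class", "ac", "an") %in% names(ref)))
    return(aggregate_reference(ref, ...))
  stop("reference table needs columns gene/class/tac/anmax ",
       "or gene/damage_class/ac/an")
}

#' Aggregate a sitewise reference export into TAC/ANmax per gene x class
#'
#' Retains reference variants with allele frequency `ac/an` below `maf_max`
#' and per-variant missingness (relative to the largest AN observed in the
#' table) below `missing_max`. For each gene and embedded collapsing class,
#' TAC is the summed allele count of the qualifying variants and ANmax the
#' largest `an/2` (individuals with allele information), rounded down.
#'
#' @param sitewise data.frame `gene, damage_class, ac, an`.
#' @param maf_max reference rarity threshold (strict `<`).
#' @param missing_max maximum per-variant missingness (strict `<`).
#' @return data.frame `gene, class, tac, anmax`; genes with no qualifying
#'   variant in a class have no row for it.
#' @export
aggregate_reference <- function(sitewise, maf_max = 0.01,
                                missing_max = 0.20) {
  stopifnot(all(c("gene", "damage_class", "ac", "an") %in% names(sitewise)))
  an_cap <- max(sitewise$an)
  keep <- sitewise$an > 0 & sitewise$ac / sitewise$an < maf_max &
    (1 - sitewise$an / an_cap) < missing_max
  sitewise <- sitewise[keep, , drop = FALSE]
  rows <- list()
  for (g in unique(sitewise$gene)) {
    sub <- sitewise[sitewise$gene == g, , drop = FALSE]
    for (cc in collapse_classes()) {
      in_class <- vapply(sub$damage_class,
                         function(d) cc %in% embedded_membership(d),
                         logical(1))
      if (!any(in_class)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, class = cc, tac = sum(sub$ac[in_class]),
        anmax = floor(max(sub$an[in_class]) / 2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), class = character(),
                      tac = integer(), anmax = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Approximate reference carrier proportion
#'
#' `TAC / ANmax`, capped at 1. Valid under the rarity of double carriers
#' and near-uniform within-gene coverage.
#'
#' @param tac total aggregated alternate-allele count.
#' @param anmax maximum individuals with allele information.
#' @return proportion in \[0, 1\].
#' @export
carrier_proportion <- function(tac, anmax) {
  stopifnot(anmax > 0, tac >= 0)
  p <- tac / anmax
  if (any(p > 1)) {
    warning("TAC exceeds ANmax; carrier proportion capped at 1")
    p <- pmin(p, 1)
  }
  p
}

#' Compare cohort carriers with a reference gene count
#'
#' Builds the 2x2 table (carriers, n - carriers; TAC, ANmax - TAC), treating
#' TAC as the reference carrier count, and reuses the shared exact-test
#' kernel and odds-ratio machinery.
#'
#' @param carriers cohort carrier count.
#' @param n cohort group size.
#' @param tac,anmax reference counts.
#' @return list `or`, `ci_low`, `ci_high`, `p`.
#' @export
compare_to_reference <- function(carriers, n, tac, anmax) {
  stopifnot(carriers >= 0, carriers <= n, tac >= 0, anmax > 0, tac <= anmax)
  or <- odds_ratio(carriers, n - carriers, tac, anmax - tac)
  list(or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
       p = fisher_two_sided(carriers, n - carriers, tac, anmax - tac))
}

#' Robustness verdict for one gene
#'
#' Pools the control-vs-reference comparisons across all available embedded
#' classes: (i) any class with control excess (OR > 1) at
#' `p < severe_p` means the reference lacks variants and the gene is
#' `not_analyzable`; else (ii) any class with control depletion (OR < 1) at
#' `p < severe_p` flags a `potential_false_positive` (abnormally low variant
#' detection in the cohort controls); else (iii) mild control depletion at
#' `p < mild_p` makes the association `questionable`; otherwise it is
#' `reinforced`. No comparable class also yields `not_analyzable`.
#'
#' @param comparisons data.frame with columns `or_ctrl`, `p_ctrl` (one row
#'   per comparable class; `NA` rows are dropped).
#' @param severe_p,mild_p verdict thresholds.
#' @return one of `"reinforced"`, `"questionable"`,
#'   `"potential_false_positive"`, `"not_analyzable"`.
#' @export
classify_robustness <- function(comparisons, severe_p = 1e-3,
                                mild_p = 0.1) {
  cmp <- comparisons[!is.na(comparisons$p_ctrl) &
                       !is.na(comparisons$or_ctrl), , drop = FALSE]
  if (!nrow(cmp)) return("not_analyzable")
  if (any(cmp$or_ctrl > 1 & cmp$p_ctrl < severe_p)) return("not_analyzable")
  if (any(cmp$or_ctrl < 1 & cmp$p_ctrl < severe_p))
    return("potential_false_positive")
  if (any(cmp$or_ctrl < 1 & cmp$p_ctrl < mild_p)) return("questionable")
  "reinforced"
}

#' Reference consistency check for a set of burden results
#'
#' For every result row with a matching reference entry, runs the two exact
#' tests (cases vs reference, controls vs reference) and attaches a per-gene
#' robustness verdict pooled over all comparable classes of that gene.
#'
#' @param results burden results ([burden_scan()] output or any data.frame
#'   with `gene`, `class`, carrier counts and group sizes).
#' @param reference data.frame `gene, class, tac, anmax` (see
#'   [read_reference()]).
#' @param severe_p,mild_p thresholds for [classify_robustness()].
#' @return `results` with appended columns `tac`, `anmax`, `or_case`,
#'   `p_case`, `or_ctrl`, `p_ctrl`, `robustness` (the verdict repeated on
#'   every row of the gene; `not_analyzable` for genes with no comparable
#'   class).
#' @export
reference_compare <- function(results, reference, severe_p = 1e-3,
                              mild_p = 0.1) {
  key <- paste(results$gene, results$class)
  rkey <- paste(reference$gene, reference$class)
  idx <- match(key, rkey)
  results$tac <- reference$tac[idx]
  results$anmax <- reference$anmax[idx]
  results$or_case <- NA_real_; results$p_case <- NA_real_
  results$or_ctrl <- NA_real_; results$p_ctrl <- NA_real_
  for (i in which(!is.na(idx))) {
    cs <- compare_to_reference(results$case_carriers[i], results$case_n[i],
                               results$tac[i], results$anmax[i])
    ct <- compare_to_reference(results$control_carriers[i],
                               results$control_n[i],
                               results$tac[i], results$anmax[i])
    results$or_case[i] <- cs$or; results$p_case[i] <- cs$p
    results$or_ctrl[i] <- ct$or; results$p_ctrl[i] <- ct$p
  }
  results$robustness <- NA_character_
  for (g in unique(results$gene)) {
    rows <- results$gene == g
    results$robustness[rows] <- classify_robustness(
      data.frame(or_ctrl = results$or_ctrl[rows],
                 p_ctrl = results$p_ctrl[rows]),
      severe_p = severe_p, mild_p = mild_p)
  }
  results
}
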