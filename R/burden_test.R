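#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins. The two-sided p-value follows
#' the minimum-likelihood convention: the sum of hypergeometric probabilities
#' of all tables whose probability does not exceed that of the observed table
#' (up to a 1 + 1e-7 relative tolerance). This is the shared exact-test
#' kernel of the pipeline (burden tests, differential missingness, reference
#' comparison).
#'
#' @param a,b,c,d cell counts: `a` case carriers, `b` case non-carriers,
#'   `c` control carriers, `d` control non-carriers.
#' @return two-sided exact p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
  support <- max(0L, k - r2):min(r1, k)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) -
    lchoose(r1 + r2, k)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(a, support)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Odds ratio with exact 95% confidence interval
#'
#' The point estimate is the cross-product `(a d)/(b c)`; `Inf` when there
#' are case carriers but no control carriers, `NA` when neither group has a
#' carrier. The confidence interval inverts the exact conditional test (two
#' one-sided 2.5% bounds on the noncentral hypergeometric odds parameter, as
#' implemented by [stats::fisher.test()]); the conditional maximum-likelihood
#' estimate is returned alongside, since published tables may print either
#' convention.
#'
#' @param a,b,c,d cell counts as in [fisher_two_sided()].
#' @param conf_level confidence level.
#' @return list with `or`, `or_cmle`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  or <- if (a == 0 && c == 0) NA_real_
  else if (c == 0 || b == 0) Inf
  else (a * d) / (b * c)
  ft <- stats::fisher.test(matrix(c(a, c, b, d), 2), conf.level = conf_level)
  list(or = or, or_cmle = unname(ft$estimate),
       ci_low = ft$conf.int[1], ci_high = ft$conf.int[2])
}

#' Collapse qualifying variants of a gene to carrier counts
#'
#' A carrier is a sample with dosage >= 1 at at least one qualifying site
#' (rare variants of the gene whose damage class belongs to the collapsing
#' class); a sample carrying several qualifying variants counts once.
#' Denominators are the full phenotype-group sizes.
#'
#' @param x a post-QC [cohort_matrix].
#' @param classification output of [classify_variants()].
#' @param gene gene symbol.
#' @param collapse_class one of [collapse_classes()].
#' @return list `case_carriers`, `case_n`, `control_carriers`, `control_n`,
#'   `n_qualifying` (qualifying-variant count; 0 flags an untestable gene).
#' @export
collapse_carriers <- function(x, classification, gene, collapse_class) {
  stopifnot(collapse_class %in% collapse_classes())
  qual <- classification$rare & classification$gene %in% gene &
    classification[[collapse_class]]
  qual[is.na(qual)] <- FALSE
  sites <- classification$site_id[qual]
  is_case <- x$samples$status == "case"
  if (!length(sites)) {
    return(list(case_carriers = 0L, case_n = sum(is_case),
                control_carriers = 0L, control_n = sum(!is_case),
                n_qualifying = 0L))
  }
  d <- x$dosage[, x$sites$site_id %in% sites, drop = FALSE]
  carrier <- rowSums(d >= 1L, na.rm = TRUE) > 0
  list(case_carriers = sum(carrier & is_case), case_n = sum(is_case),
       control_carriers = sum(carrier & !is_case),
       control_n = sum(!is_case), n_qualifying = length(sites))
}

#' Bonferroni significance threshold
#'
#' @param n_genes theoretical number of genes tested (default 20,000, the
#'   approximate human gene count).
#' @param alpha family-wise error rate.
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes = 20000L, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (`method = "BH"`); q >= p
#' elementwise and order-preserving.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Gene-level collapsing burden scan
#'
#' For every gene x embedded class with at least one qualifying rare
#' variant: carrier counts, cross-product odds ratio with exact CI, CMLE,
#' two-sided Fisher exact p, FDR q (adjusted across genes within each
#' class), and a Bonferroni flag at `alpha / n_genes_bonferroni`. Results
#' are ordered by (p, gene); `best_in_gene` marks, per gene, the class of
#' minimal p (ties broken to the most restrictive class).
#'
#' @param x a post-QC [cohort_matrix].
#' @param classification output of [classify_variants()]; computed on the
#'   fly when `NULL`.
#' @param genes genes to test (default: all annotated genes with at least
#'   one rare qualifying variant).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param n_genes_bonferroni theoretical number of genes tested.
#' @param fdr_scope `"within_class"` (default; avoids mixing nested,
#'   correlated tests) or `"global"`.
#' @return data.frame of burden results.
#' @export
burden_scan <- function(x, classification = NULL, genes = NULL,
                        alpha = 0.05, n_genes_bonferroni = 20000L,
                        fdr_scope = c("within_class", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (is.null(classification)) classification <- classify_variants(x)
  if (is.null(genes)) {
    testable <- classification$rare &
      classification[[collapse_classes()[4]]] & !is.na(classification$gene)
    genes <- sort(unique(classification$gene[testable]))
  }
  if (!length(genes)) stop("no genes to test")
  # precomputed indices; the per-gene counting below mirrors
  # collapse_carriers() exactly (asserted by the fixture tests)
  col_of <- match(classification$site_id, x$sites$site_id)
  is_case <- x$samples$status == "case"
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  rare_rows <- which(classification$rare & !is.na(col_of))
  gene_rows <- split(rare_rows, classification$gene[rare_rows])
  rows <- list()
  for (g in genes) {
    rows_g <- gene_rows[[g]]
    if (is.null(rows_g)) next
    for (cc in collapse_classes()) {
      qual <- rows_g[classification[[cc]][rows_g]]
      if (!length(qual)) next
      d <- x$dosage[, col_of[qual], drop = FALSE]
      carrier <- rowSums(d >= 1L, na.rm = TRUE) > 0
      cnt <- list(case_carriers = sum(carrier & is_case),
                  case_n = n_case,
                  control_carriers = sum(carrier & !is_case),
                  control_n = n_ctrl, n_qualifying = length(qual))
      or <- odds_ratio(cnt$case_carriers,
                       cnt$case_n - cnt$case_carriers,
                       cnt$control_carriers,
                       cnt$control_n - cnt$control_carriers)
      p <- fisher_two_sided(cnt$case_carriers,
                            cnt$case_n - cnt$case_carriers,
                            cnt$control_carriers,
                            cnt$control_n - cnt$control_carriers)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, class = cc, case_carriers = cnt$case_carriers,
        case_n = cnt$case_n, control_carriers = cnt$control_carriers,
        control_n = cnt$control_n, n_qualifying = cnt$n_qualifying,
        or = or$or, or_cmle = or$or_cmle, ci_low = or$ci_low,
        ci_high = or$ci_high, p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no gene has a qualifying rare variant")
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  if (fdr_scope == "within_class") {
    for (cc in collapse_classes()) {
      idx <- res$class == cc
      res$q[idx] <- fdr_adjust(res$p[idx])
    }
  } else {
    res$q <- fdr_adjust(res$p)
  }
  res$bonferroni_significant <-
    res$p < bonferroni_threshold(n_genes_bonferroni, alpha)
  class_rank <- match(res$class, collapse_classes())
  ord <- order(res$p, res$gene, class_rank)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  best <- rep(FALSE, nrow(res))
  # first row per gene in (p, class-rank) order = minimal p, most
  # restrictive class on ties
  for (g in unique(res$gene)) {
    idx <- which(res$gene == g)
    pick <- idx[order(res$p[idx], match(res$class[idx],
                                        collapse_classes()))][1]
    best[pick] <- TRUE
  }
  res$best_in_gene <- best
  res
}
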