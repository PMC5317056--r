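#' Detect tissue-specific ("special tissue-related") genes
#'
#' For every gene and tissue, a two-sided 95% t-interval is built from
#' the gene's values in the remaining tissues; the tissue is flagged when
#' its value falls outside. The default interval is a prediction interval
#' (`mean +/- t * sd * sqrt(1 + 1/k)`), which asks whether a single
#' tissue's expression is consistent with the spread of the others;
#' `interval = "mean"` uses the narrower confidence interval for the
#' mean. Degenerate reference tissues (zero variance) flag any differing
#' focal value.
#'
#' @param expr Long tibble with columns `gene`, `tissue`, `fpkm` (>= 4
#'   tissues per gene).
#' @param alpha Significance level (default 0.05).
#' @param interval `"prediction"` (default) or `"mean"`.
#' @return Tibble of flagged pairs: `gene`, `tissue`, `fpkm`, `lower`,
#'   `upper`.
#' @export
tissue_specific_genes <- function(expr, alpha = 0.05,
                                  interval = c("prediction", "mean")) {
  interval <- match.arg(interval)
  stopifnot(all(c("gene", "tissue", "fpkm") %in% names(expr)))
  expr |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ {
      v <- .x$fpkm
      k <- length(v) - 1L
      if (k < 3L) stop("need >= 4 tissues per gene", call. = FALSE)
      out <- purrr::map_dfr(seq_along(v), function(i) {
        rest <- v[-i]
        m <- mean(rest); s <- stats::sd(rest)
        tq <- stats::qt(1 - alpha / 2, df = k - 1L)
        half <- if (interval == "prediction") tq * s * sqrt(1 + 1 / k)
                else tq * s / sqrt(k)
        lower <- m - half; upper <- m + half
        flag <- if (s == 0) v[i] != m else v[i] < lower || v[i] > upper
        if (!flag) return(NULL)
        tibble::tibble(tissue = .x$tissue[i], fpkm = v[i],
                       lower = lower, upper = upper)
      })
      out
    }) |>
    dplyr::ungroup()
}

#' Domesticated-versus-wild expression test
#'
#' Per gene, a two-sided Fisher exact test on the 2x2 count table
#' `[[count_dom, total_dom - count_dom], [count_wild, total_wild -
#' count_wild]]`; a gene is called differentially expressed when `p <
#' alpha` and the FPKM fold change exceeds `fc`. Fold change is
#' `fpkm_dom / fpkm_wild` (direction recorded by its sign relative to 1).
#'
#' @param counts Tibble with columns `gene`, `count_dom`, `count_wild`,
#'   `fpkm_dom`, `fpkm_wild`.
#' @param total_dom,total_wild Library sizes (positive integers).
#' @param fc Fold-change threshold (strict `>` on
#'   `max(fold, 1/fold)`; default 2).
#' @param alpha P-value threshold (default 0.05).
#' @return Input tibble plus `p_value`, `fold_change`, `direction`
#'   (`"up"`/`"down"` in domesticated), `called`.
#' @export
domestication_expression_test <- function(counts, total_dom, total_wild,
                                          fc = 2, alpha = 0.05) {
  if (total_dom <= 0 || total_wild <= 0) stop("zero library totals",
                                              call. = FALSE)
  p <- purrr::map2_dbl(counts$count_dom, counts$count_wild, function(a, b) {
    stats::fisher.test(rbind(c(a, total_dom - a),
                             c(b, total_wild - b)))$p.value
  })
  fold <- counts$fpkm_dom / counts$fpkm_wild
  dplyr::mutate(counts,
                p_value = p,
                fold_change = fold,
                direction = ifelse(fold >= 1, "up", "down"),
                called = p < alpha & pmax(fold, 1 / fold) > fc)
}
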