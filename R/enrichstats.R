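#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins, computed through the
#' log-space hypergeometric density so large totals are overflow-safe.
#' One-sided p-values are tail sums; the two-sided p-value follows either
#' the point-probability rule (`"minlike"`, the convention of most
#' statistical software: sum of all tables at the observed margins whose
#' probability does not exceed that of the observed table) or the doubling
#' rule (`"doubled"`: twice the smaller one-sided tail, capped at 1).
#'
#' @param table A 2x2 matrix or a length-4 vector `c(a, b, c, d)` read
#'   row-wise (rows = groups, columns = phenotype / no phenotype).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (odds ratio of
#'   the first row relative to the second).
#' @param two_sided_rule `"minlike"` (default) or `"doubled"`.
#' @return The p-value.
#' @examples
#' fisher_exact(c(27, 83, 14, 72), alternative = "greater")  # 0.108
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less"),
                         two_sided_rule = c("minlike", "doubled")) {
  alternative <- match.arg(alternative)
  two_sided_rule <- match.arg(two_sided_rule)
  if (is.matrix(table)) table <- as.vector(t(table))
  stopifnot(length(table) == 4L)
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers", call. = FALSE)
  a <- table[1]; b <- table[2]; cc <- table[3]; d <- table[4]
  if (a + b + cc + d == 0) stop("empty table", call. = FALSE)
  m <- a + b      # row-1 total
  n <- cc + d     # row-2 total
  k <- a + cc     # column-1 total
  lo <- max(0, k - n); hi <- min(k, m)
  p_greater <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  p_less <- stats::phyper(a, m, n, k)
  switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = {
      if (two_sided_rule == "doubled") return(min(1, 2 * min(p_greater, p_less)))
      support <- lo:hi
      logp <- stats::dhyper(support, m, n, k, log = TRUE)
      obs <- stats::dhyper(a, m, n, k, log = TRUE)
      # relative tolerance guards equal-probability tables against rounding
      min(1, sum(exp(logp[logp <= obs + 1e-7])))
    })
}

#' Knockout hit rate of a gene set
#'
#' The proportion of genes in a set whose knockout produced a non-wild-type
#' phenotype, with a per-class breakdown.
#'
#' @param phen A phenotype tibble (`species`, `gene`, `phenotype`).
#' @param gene_set Character vector of gene ids; every gene must have a
#'   phenotype call.
#' @param species Optional species filter applied to `phen` first.
#' @return A one-row tibble: `n_genes`, `n_hits`, `hit_rate`, and a nested
#'   `by_class` tibble of per-class counts.
#' @export
hit_rate <- function(phen, gene_set, species = NULL) {
  if (!is.null(species)) phen <- dplyr::filter(phen, .data$species == !!species)
  sub <- dplyr::filter(phen, .data$gene %in% gene_set)
  miss <- setdiff(gene_set, sub$gene)
  if (length(miss)) stop("no phenotype call for gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  by_class <- sub |> dplyr::count(.data$phenotype, name = "n_genes") |>
    dplyr::arrange(.data$phenotype)
  tibble::tibble(n_genes = length(gene_set),
                 n_hits = sum(sub$phenotype != "WT"),
                 hit_rate = sum(sub$phenotype != "WT") / length(gene_set),
                 by_class = list(by_class))
}

#' Enrichment of independently characterized genes in a ranked list
#'
#' Tests whether the overlap between a ranked candidate list (size `K` out
#' of `N` orthologs) and an independently characterized gene set (size `M`)
#' departs from the null expectation. Two 2x2 constructions are available:
#' `"marginal"` compares the two proportions exactly as printed —
#' `[[k, K-k], [M, N-M]]`, the characterized margin left whole — and
#' `"disjoint"` is the classical hypergeometric partition
#' `[[k, K-k], [M-k, N-K-M+k]]`. The marginal construction with the doubled
#' two-sided rule is the default because it reproduces published overlap
#' statistics quoted to two decimals; the disjoint construction with the
#' point-probability rule is the textbook variant.
#'
#' @param n_total Total ortholog count `N`.
#' @param list_size Ranked-list size `K`.
#' @param characterized Number of independently characterized genes `M`.
#' @param overlap Observed overlap `k`.
#' @param construction `"marginal"` (default) or `"disjoint"`.
#' @param two_sided_rule Passed to [fisher_exact()]; defaults to
#'   `"doubled"` for `"marginal"` and `"minlike"` for `"disjoint"`.
#' @return A one-row tibble with the table cells `a`, `b`, `c`, `d`, the
#'   `construction`, and the two-sided `p_value`.
#' @export
overlap_test <- function(n_total, list_size, characterized, overlap,
                         construction = c("marginal", "disjoint"),
                         two_sided_rule = NULL) {
  construction <- match.arg(construction)
  if (overlap > min(list_size, characterized) || list_size > n_total ||
      characterized > n_total)
    stop("inconsistent counts", call. = FALSE)
  cells <- if (construction == "disjoint") {
    c(overlap, list_size - overlap,
      characterized - overlap, n_total - list_size - characterized + overlap)
  } else {
    c(overlap, list_size - overlap,
      characterized, n_total - characterized)
  }
  if (any(cells < 0)) stop("inconsistent counts", call. = FALSE)
  if (is.null(two_sided_rule))
    two_sided_rule <- if (construction == "marginal") "doubled" else "minlike"
  tibble::tibble(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 construction = construction,
                 p_value = fisher_exact(cells, "two.sided", two_sided_rule))
}
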