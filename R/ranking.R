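#' Divergence in ancestral stage-to-stage expression change between two nodes
#'
#' For each gene, computes the per-transition difference
#' `Delta_t = d_hat_t(node_a) - d_hat_t(node_b)` between the two ancestral
#' fold-change vectors. The largest positive `Delta_t` is the gene's
#' "A-up" score (expression change evolved upward in the `node_a` lineage)
#' and the largest positive `-Delta_t` its "B-up" score; the gene's overall
#' direction is whichever maximum is larger (ties resolve to A-up), and the
#' signed score is `Delta` at the winning transition.
#'
#' @param est An `ancestral_profiles` object or its `states` tibble
#'   (`gene`, `node`, `transition`, `d`).
#' @param node_a,node_b Internal-node labels to contrast (e.g. `"MRCA-N"`
#'   vs `"MRCA-F"`).
#' @return A tibble with one row per gene: `gene`, `score` (signed
#'   `Delta` at the winning transition), `t_star`, `direction`
#'   (`"A-up"`/`"B-up"`), and the per-direction maxima `score_a_up`,
#'   `t_a_up`, `score_b_up`, `t_b_up`. Attributes `node_a`, `node_b`.
#' @export
divergence_scores <- function(est, node_a, node_b) {
  states <- if (inherits(est, "ancestral_profiles")) est$states else est
  stopifnot(all(c("gene", "node", "transition", "d") %in% names(states)))
  for (nd in c(node_a, node_b))
    if (!nd %in% states$node) stop("node not found in estimates: ", nd, call. = FALSE)
  wide <- states |>
    dplyr::filter(.data$node %in% c(node_a, node_b)) |>
    tidyr::pivot_wider(names_from = "node", values_from = "d")
  if (anyNA(wide[[node_a]]) || anyNA(wide[[node_b]]))
    stop("missing node estimates for some genes", call. = FALSE)
  out <- wide |>
    dplyr::mutate(delta = .data[[node_a]] - .data[[node_b]]) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      score_a_up = max(.data$delta),
      t_a_up = .data$transition[which.max(.data$delta)],
      score_b_up = max(-.data$delta),
      t_b_up = .data$transition[which.max(-.data$delta)],
      .groups = "drop") |>
    dplyr::mutate(
      direction = ifelse(.data$score_a_up >= .data$score_b_up, "A-up", "B-up"),
      score = ifelse(.data$direction == "A-up", .data$score_a_up, -.data$score_b_up),
      t_star = ifelse(.data$direction == "A-up", .data$t_a_up, .data$t_b_up)) |>
    dplyr::select("gene", "score", "t_star", "direction",
                  "score_a_up", "t_a_up", "score_b_up", "t_b_up")
  attr(out, "node_a") <- node_a
  attr(out, "node_b") <- node_b
  out
}

#' Directional knockout-priority lists
#'
#' Two ranked candidate lists, one per lineage: genes whose largest evolved
#' difference is an expression increase toward `node_a` enter the A-up list
#' (knockout candidates in the A lineage), and symmetrically for B-up.
#' Within each list genes are sorted by descending score with deterministic
#' ties broken by ascending gene id; the cut keeps
#' `floor(top_fraction * n_scored_genes)` genes (a fixed `list_size`
#' overrides the fraction).
#'
#' @param scores Output of [divergence_scores()].
#' @param top_fraction Fraction of all scored genes kept per list
#'   (default 0.10).
#' @param list_size Optional fixed list length overriding the fraction.
#' @return A tibble with columns `lineage` (`"A-up"`/`"B-up"`), `rank`,
#'   `gene`, `score`, `t_star`.
#' @export
priority_lists <- function(scores, top_fraction = 0.10, list_size = NULL) {
  if (nrow(scores) == 0L) stop("empty score set", call. = FALSE)
  n_keep <- if (is.null(list_size)) floor(top_fraction * nrow(scores)) else as.integer(list_size)
  dplyr::bind_rows(
    scores |> dplyr::filter(.data$direction == "A-up") |>
      dplyr::transmute(lineage = "A-up", gene = .data$gene,
                       score = .data$score_a_up, t_star = .data$t_a_up),
    scores |> dplyr::filter(.data$direction == "B-up") |>
      dplyr::transmute(lineage = "B-up", gene = .data$gene,
                       score = .data$score_b_up, t_star = .data$t_b_up)) |>
    dplyr::arrange(.data$lineage, dplyr::desc(.data$score), .data$gene) |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= n_keep) |>
    dplyr::ungroup() |>
    dplyr::select("lineage", "rank", "gene", "score", "t_star")
}

#' Per-stage ranked lists on the back-transformed profile scale
#'
#' Independently of the transition-based ranking, genes can be prioritized
#' within each canonical stage by the difference in estimated relative
#' expression level `X_stage(node_a) - X_stage(node_b)` on the
#' min-normalized profile scale.
#'
#' @param est An `ancestral_profiles` object or its `profiles` tibble
#'   (`gene`, `node`, `stage`, `x`).
#' @inheritParams divergence_scores
#' @return A tibble with columns `stage`, `rank`, `gene`, `score`, ranked
#'   descending within stage, ties broken by gene id.
#' @export
stagewise_lists <- function(est, node_a, node_b) {
  profiles <- if (inherits(est, "ancestral_profiles")) est$profiles else est
  stopifnot(all(c("gene", "node", "stage", "x") %in% names(profiles)))
  for (nd in c(node_a, node_b))
    if (!nd %in% profiles$node) stop("node not found in profiles: ", nd, call. = FALSE)
  profiles |>
    dplyr::filter(.data$node %in% c(node_a, node_b)) |>
    tidyr::pivot_wider(names_from = "node", values_from = "x") |>
    dplyr::mutate(score = .data[[node_a]] - .data[[node_b]]) |>
    dplyr::arrange(.data$stage, dplyr::desc(.data$score), .data$gene) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("stage", "rank", "gene", "score")
}

pheno_stage_num <- function(phenotype) {
  out <- rep(NA_integer_, length(phenotype))
  hit <- grepl("^Stage-[1-5]$", phenotype)
  out[hit] <- as.integer(sub("Stage-", "", phenotype[hit]))
  out
}

#' Knockout-phenotype / expression-stage concordance
#'
#' For each gene with a stageable knockout phenotype (classes Stage-1 to
#' Stage-5; WT, initiation, asynchronous and other calls are excluded from
#' the denominator), checks whether the phenotype stage equals the stage of
#' the gene's largest upregulatory ancestral difference. The transition
#' `t` (stage t -> t+1) is attributed to stage `t + 1` by default — the
#' stage in which the expression rise is manifest — with the `t -> t`
#' attribution selectable.
#'
#' @param scores Output of [divergence_scores()] (the A-up maxima are the
#'   upregulatory differences for the A lineage).
#' @param phen A phenotype tibble (`species`, `gene`, `phenotype`), e.g.
#'   from [read_phenotypes()].
#' @param species Optional species filter applied to `phen`.
#' @param mapping `"lead"` (transition t -> stage t+1, default) or
#'   `"same"` (t -> t).
#' @return A tibble with one row per stageable gene: `gene`, `phenotype`,
#'   `pheno_stage`, `t_star`, `shift_stage`, `concordant`; summary counts
#'   are available via [glance()].
#' @export
stage_concordance <- function(scores, phen, species = NULL, mapping = c("lead", "same")) {
  mapping <- match.arg(mapping)
  if (!is.null(species)) phen <- dplyr::filter(phen, .data$species == !!species)
  out <- phen |>
    dplyr::mutate(pheno_stage = pheno_stage_num(.data$phenotype)) |>
    dplyr::filter(!is.na(.data$pheno_stage)) |>
    dplyr::inner_join(scores[, c("gene", "t_a_up")], by = "gene") |>
    dplyr::rename(t_star = "t_a_up") |>
    dplyr::mutate(shift_stage = .data$t_star + if (mapping == "lead") 1L else 0L,
                  concordant = .data$pheno_stage == .data$shift_stage) |>
    dplyr::select("gene", "phenotype", "pheno_stage", "t_star", "shift_stage", "concordant")
  class(out) <- c("stage_concordance", class(out))
  out
}

#' @rdname tidy_methods
#' @export
glance.stage_concordance <- function(x, ...) {
  tibble::tibble(n_stageable = nrow(x),
                 n_concordant = sum(x$concordant),
                 prop_concordant = if (nrow(x)) mean(x$concordant) else NA_real_)
}
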