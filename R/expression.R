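#' Normalize stage-resolved counts to relative expression profiles
#'
#' Counts are scaled per sample to counts-per-million, a pseudocount is
#' added, replicates within a stage are combined by geometric mean, and each
#' gene's stage values are divided by its minimum so the stage of lowest
#' expression equals one. Only relative stage-to-stage levels feed the
#' downstream evolutionary analysis, so the normalizer is deliberately a
#' simple library-size scaler.
#'
#' @param table A [count_table()].
#' @param pseudocount Scaled-count offset added before ratio formation
#'   (default 0.5); must be > 0.
#' @param lib_size Optional named vector of library sizes per sample;
#'   defaults to the per-sample total count.
#' @return A tibble with columns `gene`, `stage`, `x` (relative expression,
#'   min stage = 1) and `all_zero` (gene had no reads in any sample; such
#'   genes are flagged for exclusion from ranking). Attribute `species`
#'   carries the species label.
#' @export
normalize_counts <- function(table, pseudocount = 0.5, lib_size = NULL) {
  stopifnot(inherits(table, "count_table"), pseudocount > 0)
  cts <- table$counts
  if (is.null(lib_size)) {
    ls_tab <- cts |> dplyr::group_by(.data$sample) |>
      dplyr::summarise(lib = sum(.data$count), .groups = "drop")
  } else {
    ls_tab <- tibble::tibble(sample = names(lib_size), lib = unname(lib_size))
  }
  if (any(ls_tab$lib <= 0)) ls_tab$lib[ls_tab$lib <= 0] <- 1  # empty library guard
  prof <- cts |>
    dplyr::left_join(ls_tab, by = "sample") |>
    dplyr::mutate(cpm = .data$count / .data$lib * 1e6) |>
    dplyr::left_join(table$stage_map, by = "sample") |>
    dplyr::group_by(.data$gene, .data$stage) |>
    dplyr::summarise(x = exp(mean(log(.data$cpm + pseudocount))), .groups = "drop_last") |>
    dplyr::mutate(x = .data$x / min(.data$x)) |>
    dplyr::ungroup()
  zero <- cts |> dplyr::group_by(.data$gene) |>
    dplyr::summarise(all_zero = all(.data$count == 0), .groups = "drop")
  out <- dplyr::left_join(prof, zero, by = "gene") |>
    dplyr::arrange(.data$gene, .data$stage)
  attr(out, "species") <- table$species
  out
}

fold_change_vec <- function(x) {
  if (any(x <= 0)) stop("non-positive expression value; use a pseudocount in normalize_counts()",
                        call. = FALSE)
  n <- length(x)
  (x[-1] - x[-n]) / pmin(x[-1], x[-n])
}

#' Signed stage-to-stage fold-change statistic
#'
#' For a positive expression profile `X_1..X_S` the statistic for the
#' transition t -> t+1 is `d_t = (X_{t+1} - X_t) / min(X_t, X_{t+1})`: a
#' k-fold increase and a k-fold decrease have the same magnitude and
#' opposite signs, and `d_t = 0` exactly when the two stages are equal.
#'
#' @param profile A numeric profile vector, or a tibble with columns
#'   `gene`, `stage`, `x` (as returned by [normalize_counts()]).
#' @return A numeric vector of length `S - 1`, or a tibble with columns
#'   `gene`, `transition`, `d`.
#' @export
stage_fold_change <- function(profile) {
  if (is.numeric(profile)) return(fold_change_vec(profile))
  stopifnot(all(c("gene", "stage", "x") %in% names(profile)))
  profile |>
    dplyr::arrange(.data$gene, .data$stage) |>
    dplyr::group_by(.data$gene) |>
    dplyr::reframe(transition = seq_len(dplyr::n() - 1L), d = fold_change_vec(.data$x))
}

invert_fold_change <- function(d) {
  if (anyNA(d) || any(!is.finite(d))) stop("fold changes must be finite", call. = FALSE)
  x <- cumprod(c(1, ifelse(d >= 0, 1 + d, 1 / (1 - d))))
  x / min(x)
}

#' Back-transform fold changes to a relative expression profile
#'
#' Exact inverse of [stage_fold_change()]: starting from a provisional
#' `X_1 = 1`, an increase `d_t >= 0` multiplies by `1 + d_t` and a decrease
#' `d_t < 0` divides by `1 - d_t`; the profile is then rescaled so the stage
#' of lowest expression equals one.
#'
#' @param d A numeric fold-change vector, or a tibble with columns `gene`,
#'   `transition`, `d` (extra grouping columns such as `node` are honoured).
#' @return A numeric profile of length `length(d) + 1`, or a tibble with
#'   columns (`gene`, grouping columns, `stage`, `x`).
#' @export
fold_change_to_profile <- function(d) {
  if (is.numeric(d)) return(invert_fold_change(d))
  stopifnot(all(c("gene", "transition", "d") %in% names(d)))
  grp <- setdiff(names(d), c("transition", "d"))
  d |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "transition")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::reframe(stage = seq_len(dplyr::n() + 1L), x = invert_fold_change(.data$d))
}

#' Collapse sample points onto the five canonical stages
#'
#' Species were sampled at different numbers of developmental time points
#' (eight for *Neurospora*, six for *Fusarium*); ancestral comparisons use
#' five canonical stages, with sample points sharing a canonical stage
#' treated as replicates.
#'
#' @param table A [count_table()].
#' @param mapping A data frame with columns `sample`, `stage`, or a named
#'   vector `sample -> canonical stage`. Must cover every sample.
#' @return A [count_table()] whose stage map is the canonical one.
#' @export
map_samples_to_stages <- function(table, mapping) {
  stopifnot(inherits(table, "count_table"))
  if (!is.data.frame(mapping))
    mapping <- tibble::tibble(sample = names(mapping), stage = as.integer(unname(mapping)))
  count_table(table$counts, mapping, table$species)
}

#' Default canonical stage mappings for the study's sampling designs
#'
#' The deposited series sampled eight points for the *Neurospora* species
#' and six for the *Fusarium* species; the original mapping onto the five
#' canonical stages is not published, so these defaults (8 points ->
#' 1,1,2,2,3,4,5,5; 6 points -> 1,2,2,3,4,5) are a documented configuration
#' choice, overridable via [map_samples_to_stages()].
#'
#' @param samples Character vector of sample ids, in time order.
#' @return A tibble with columns `sample`, `stage`.
#' @export
default_stage_mapping <- function(samples) {
  n <- length(samples)
  stages <- switch(as.character(n),
                   "8" = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L),
                   "6" = c(1L, 2L, 2L, 3L, 4L, 5L),
                   "5" = 1:5,
                   stop("no default mapping for ", n, " sample points", call. = FALSE))
  tibble::tibble(sample = samples, stage = stages)
}
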