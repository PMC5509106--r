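#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage on generated data: simulate a chronogram,
#' Brownian fold-change evolution, counts and phenotypes; write the input
#' bundle as TSV/Newick; read it back through the package readers;
#' normalize, compute fold changes, reconstruct ancestral profiles, rank
#' genes between MRCA-N and MRCA-F, score phenotype concordance, test
#' planted-gene enrichment in the top list, and learn consensus networks at
#' the three ancestral nodes. All outputs are written under `out_dir` with
#' floating point at six significant digits, so a rerun with the same
#' config and seed produces bitwise-identical files.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param network_genes Number of top-ranked genes carried into network
#'   learning (default 5, keeping enumeration exact).
#' @param top_fraction Ranked-list cut (default 0.10).
#' @param model_count Networks averaged per node (default 100).
#' @param consensus_threshold Consensus retention threshold (default 0.5).
#' @return A `run_manifest` list: config, seed, per-stage output paths and
#'   their md5 digests, and the key summary numbers (list recall,
#'   concordance, enrichment p-value).
#' @export
run_pipeline <- function(cfg = generator_config(), out_dir = tempfile("fbrun"),
                         network_genes = 5L, top_fraction = 0.10,
                         model_count = 100L, consensus_threshold = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                          ~ signif(.x, 6)))
    readr::write_tsv(df, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }
  fb_log("simulate: chronogram and gene evolution")
  tree <- make_chronogram(cfg)
  tree_path <- file.path(out_dir, "chronogram.nwk")
  write_newick(tree, tree_path); paths[["chronogram.nwk"]] <- tree_path
  evo <- simulate_gene_evolution(tree, cfg)
  wtsv(evo$fold_changes, "true_tip_fold_changes.tsv")
  wtsv(evo$planted, "planted_shifts.tsv")

  fb_log("simulate: counts and phenotypes")
  tip_profiles <- fold_change_to_profile(
    dplyr::rename(evo$fold_changes, node = "species")) |>
    dplyr::rename(species = "node")
  tabs <- simulate_counts(tip_profiles, cfg, seed = cfg$seed + 1L)
  for (sp in names(tabs)) {
    wide <- tidyr::pivot_wider(tabs[[sp]]$counts, names_from = "sample",
                               values_from = "count")
    wtsv(wide, paste0("counts_", gsub("[^A-Za-z]", "", sp), ".tsv"))
    wtsv(tabs[[sp]]$stage_map, paste0("stages_", gsub("[^A-Za-z]", "", sp), ".tsv"))
  }
  phen <- simulate_phenotypes(evo, cfg, species = "N.crassa", seed = cfg$seed + 2L)
  phen_path <- wtsv(phen, "phenotypes.tsv")

  fb_log("read back and normalize")
  tree2 <- read_newick(tree_path)
  phen2 <- read_phenotypes(phen_path)
  fc <- purrr::map_dfr(names(tabs), function(sp) {
    ct <- read_counts(paths[[paste0("counts_", gsub("[^A-Za-z]", "", sp), ".tsv")]],
                      paths[[paste0("stages_", gsub("[^A-Za-z]", "", sp), ".tsv")]],
                      species = sp)
    prof <- normalize_counts(ct, pseudocount = 0.5)
    stage_fold_change(prof[, c("gene", "stage", "x")]) |>
      dplyr::mutate(species = sp, .before = 1)
  })
  wtsv(fc, "fold_changes.tsv")

  fb_log("ancestral reconstruction")
  anc <- ancestral_profiles(tree2, fc)
  wtsv(anc$states, "ancestral_states.tsv")
  wtsv(anc$profiles, "ancestral_profiles.tsv")

  fb_log("ranking and concordance")
  scores <- divergence_scores(anc, "MRCA-N", "MRCA-F")
  lists <- priority_lists(scores, top_fraction = top_fraction)
  wtsv(scores, "divergence_scores.tsv")
  wtsv(lists, "priority_lists.tsv")
  conc <- stage_concordance(scores, phen2, species = "N.crassa")
  wtsv(conc, "concordance.tsv")

  top_n_up <- lists$gene[lists$lineage == "A-up"]
  planted <- evo$planted$gene
  recall <- if (length(planted)) mean(planted %in% top_n_up) else NA_real_
  enr <- overlap_test(n_total = nrow(scores), list_size = length(top_n_up),
                      characterized = length(planted),
                      overlap = sum(planted %in% top_n_up),
                      construction = "disjoint")

  fb_log("consensus networks per ancestral node")
  net_genes <- utils::head(top_n_up, network_genes)
  nets <- list()
  for (nd in c("MRCA-N", "MRCA-F", "MRCA-NF")) {
    obs <- anc$states |>
      dplyr::filter(.data$node == nd, .data$gene %in% net_genes) |>
      tidyr::pivot_wider(names_from = "gene", values_from = "d") |>
      dplyr::select(-"node", -"transition")
    dags <- learn_top_k(network_dataset(obs, nd), K = model_count, seed = cfg$seed)
    nets[[nd]] <- consensus(dags, threshold = consensus_threshold)
    p <- file.path(out_dir, paste0("network_", nd, ".graphml"))
    write_network(nets[[nd]], p, "graphml")
    paths[[basename(p)]] <- p
  }
  cons_edges <- conserved_edges(nets)
  wtsv(cons_edges, "conserved_edges.tsv")

  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    outputs = tibble::tibble(name = names(paths),
                             path = unname(unlist(paths)),
                             md5 = unname(tools::md5sum(unlist(paths)))),
    summary = list(n_genes = nrow(scores),
                   n_planted = length(planted),
                   top_list_recall = recall,
                   enrichment_p = enr$p_value,
                   concordance = glance(conc)))
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "|", nrow(x$outputs), "outputs\n")
  cat("  planted-gene top-list recall:", format(x$summary$top_list_recall, digits = 3),
      "| enrichment p:", format(x$summary$enrichment_p, digits = 3), "\n")
  invisible(x)
}
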