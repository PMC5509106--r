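#' Read a phylogeny from Newick text or a file
#'
#' Parses a rooted tree with branch lengths in millions of years (Myr).
#' Quoted labels, internal node labels and bracketed comments are accepted;
#' the tree is validated before it is returned, so a malformed input never
#' yields a partially constructed object.
#'
#' @param x A Newick string, or the path to a file containing one.
#' @return An object of class [ape::phylo] with `edge.length` set.
#' @examples
#' tr <- read_newick("(A:1,B:1):0;")
#' ape::Ntip(tr)
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("\\(", x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  txt <- gsub("\\[[^]]*\\]", "", txt)   # strip comments
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick input: could not parse tree", call. = FALSE)
  validate_phylogeny(tr)
  tr
}

#' Write a phylogeny as Newick text
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("non-finite branch length", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  invisible(tree)
}

#' Check that a tree is ultrametric (a chronogram)
#'
#' All root-to-tip path lengths of a chronogram agree; this reports the
#' maximum spread of tip depths and whether it is within tolerance relative
#' to the tree height.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on the depth spread (default `1e-6`).
#' @return A list with elements `ultrametric` (logical) and `spread`
#'   (max minus min root-to-tip depth, in branch-length units).
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  validate_phylogeny(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  spread <- max(depths) - min(depths)
  list(ultrametric = spread <= tol * max(max(depths), .Machine$double.eps),
       spread = spread)
}

new_count_table <- function(counts, stage_map, species) {
  structure(list(counts = counts, stage_map = stage_map, species = species),
            class = "count_table")
}

#' Construct a stage-resolved count table
#'
#' Bundles a long table of raw sequencing counts with the sample-to-stage
#' map and the species label, checking the invariants (non-negative integer
#' counts, every sample mapped to exactly one stage, contiguous 1-based
#' stage indices).
#'
#' @param counts A data frame with columns `gene`, `sample`, `count`.
#' @param stage_map A data frame with columns `sample`, `stage` (1-based).
#' @param species Species label.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, stage_map, species = NA_character_) {
  counts <- tibble::as_tibble(counts)
  stage_map <- tibble::as_tibble(stage_map)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  }
  req(counts, c("gene", "sample", "count"), "counts")
  req(stage_map, c("sample", "stage"), "stage map")
  if (anyNA(counts$count) || any(counts$count < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(counts$count != round(counts$count)))
    stop("non-integer counts", call. = FALSE)
  if (anyDuplicated(stage_map$sample))
    stop("stage map: sample mapped more than once: ",
         stage_map$sample[duplicated(stage_map$sample)][1], call. = FALSE)
  unmapped <- setdiff(unique(counts$sample), stage_map$sample)
  if (length(unmapped))
    stop("stage map: unmapped sample(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  st <- sort(unique(stage_map$stage))
  if (!identical(as.integer(st), seq_len(max(st))))
    stop("stage indices must be contiguous from 1", call. = FALSE)
  dup <- counts |> dplyr::count(.data$gene, .data$sample) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup)) stop("duplicate (gene, sample) rows, e.g. ", dup$gene[1], call. = FALSE)
  new_count_table(counts, dplyr::mutate(stage_map, stage = as.integer(.data$stage)), species)
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> species:", x$species,
      "|", dplyr::n_distinct(x$counts$gene), "genes x",
      dplyr::n_distinct(x$counts$sample), "samples |",
      max(x$stage_map$stage), "stages\n")
  invisible(x)
}

#' Read a count table, stage map attached
#'
#' The counts TSV has a `gene` column followed by one column per sample;
#' the stage-map TSV has columns `sample` and `stage`.
#'
#' @param path Path to the counts TSV.
#' @param stage_map Path to a stage-map TSV, or a data frame.
#' @param species Species label.
#' @return A [count_table()].
#' @export
read_counts <- function(path, stage_map, species = NA_character_) {
  wide <- readr::read_tsv(path, col_types = readr::cols(gene = readr::col_character(),
                                                        .default = readr::col_double()),
                          progress = FALSE)
  if (!"gene" %in% names(wide)) stop("counts TSV: missing 'gene' column", call. = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene", names_to = "sample", values_to = "count")
  if (is.character(stage_map))
    stage_map <- readr::read_tsv(stage_map, col_types = "ci", progress = FALSE)
  count_table(long, stage_map, species)
}

#' Read a single-copy ortholog map
#'
#' TSV with columns `ortholog_id`, `species`, `gene`: one gene per species
#' within each ortholog set, gene ids unique within a species.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per (ortholog set, species).
#' @export
read_orthologs <- function(path) {
  om <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  miss <- setdiff(c("ortholog_id", "species", "gene"), names(om))
  if (length(miss)) stop("ortholog TSV: missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- om |> dplyr::count(.data$ortholog_id, .data$species) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup))
    stop("ortholog set ", dup$ortholog_id[1], " has multiple genes for ", dup$species[1],
         call. = FALSE)
  dupg <- om |> dplyr::count(.data$species, .data$gene) |> dplyr::filter(.data$n > 1L)
  if (nrow(dupg))
    stop("gene ", dupg$gene[1], " appears in more than one ortholog set for ", dupg$species[1],
         call. = FALSE)
  om
}

#' Phenotype classes recognised in knockout calls
#'
#' The five canonical perithecium stages plus wild type, pre-Stage-1
#' initiation defects, asynchronous development, and a catch-all.
#' @export
phenotype_classes <- c("WT", "initiation", paste0("Stage-", 1:5), "asynchronous", "other")

#' Read a knockout phenotype-call table
#'
#' TSV with columns `species`, `gene`, `phenotype`; the phenotype must be
#' one of [phenotype_classes] and each (species, gene) pair appears once.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `species`, `gene`, `phenotype`.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  miss <- setdiff(c("species", "gene", "phenotype"), names(ph))
  if (length(miss)) stop("phenotype TSV: missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!ph$phenotype %in% phenotype_classes)
  if (length(bad))
    stop("phenotype TSV line ", bad[1] + 1L, ": unknown class '", ph$phenotype[bad[1]], "'",
         call. = FALSE)
  dup <- ph |> dplyr::count(.data$species, .data$gene) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup)) stop("duplicate phenotype call for ", dup$species[1], " / ", dup$gene[1], call. = FALSE)
  ph[, c("species", "gene", "phenotype")]
}

#' Write a weighted directed network to GraphML or DOT
#'
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `weight` (edge confidence), or a `consensus_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return The path, invisibly.
#' @export
write_network <- function(edges, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (inherits(edges, "consensus_network")) edges <- tidy(edges)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges need 'from' and 'to' columns", call. = FALSE)
    if (!"weight" %in% names(edges)) edges$weight <- 1
    edges$weight <- round(edges$weight, 6)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")], directed = TRUE)
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read a GraphML network back as an edge tibble
#'
#' @param path Path to a GraphML file produced by [write_network()].
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0L)
    return(tibble::tibble(from = character(), to = character(), weight = double()))
  df <- igraph::as_data_frame(g, what = "edges")
  tibble::as_tibble(df[, intersect(c("from", "to", "weight"), names(df))])
}

#' Read a run configuration file
#'
#' YAML with documented keys: `stages`, `tolerance`, `seed`, `top_fraction`,
#' `consensus_threshold`, `model_count`, `pseudocount`, `stage_mapping`.
#' Missing keys fall back to package defaults.
#'
#' @param path Path to the YAML file (optional).
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(stages = 5L, tolerance = 1e-6, seed = 1L, top_fraction = 0.10,
                   consensus_threshold = 0.5, model_count = 100L, pseudocount = 0.5,
                   stage_mapping = NULL)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  utils::modifyList(defaults, user)
}

fb_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}
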