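# End-to-end module inference for one chromosome:
#   stratify -> NB fits -> significance calls -> desert filter -> network ->
#   community detection -> module statistics.

#' Infer chromatin interaction modules from contacts of one chromosome
#'
#' Runs the full inference chain on a canonical contact table and returns the
#' stratum fits, the significant contacts before and after contact-desert
#' filtering, the interaction network and the scored modules.
#'
#' @param records canonical contact data.frame for one chromosome (see
#'   [read_contacts()] / [as_contacts()]).
#' @param resolution bin width in bp.
#' @param chrom chromosome name (default taken from the records).
#' @param max_distance largest 1D distance modeled (default 2 Mb).
#' @param min_obs minimum counts per stratum for a fit (default 30).
#' @param prob_threshold significance threshold on the lower-tail CDF
#'   (default 0.975, inclusive).
#' @param padding desert-filter window half-width in pixels (default 5).
#' @param min_mean desert-filter minimum window mean (default 1).
#' @param method community detection method (`"label_prop"` or `"louvain"`).
#' @param min_nodes minimum module size (default 4).
#' @param seed RNG seed for the (order-dependent) clustering.
#' @param include_zeros include implicit zero pairs in the stratum fits.
#' @param n_bins chromosome bin count (optional; inferred from the records).
#' @return a `hicnets_result` list: `chrom`, `resolution`, `params`, `fits`,
#'   `n_significant`, `significant` (post-filter), `network`, `modules`.
#' @export
find_modules <- function(records, resolution, chrom = NULL,
                         max_distance = 2e6, min_obs = 30L,
                         prob_threshold = 0.975, padding = 5L, min_mean = 1,
                         method = "label_prop", min_nodes = 4L, seed = 42L,
                         include_zeros = FALSE, n_bins = NULL) {
  chrom <- chrom %||% unique(records$chrom)[1]
  strata <- stratify_by_distance(records, resolution, max_distance,
                                 include_zeros, n_bins)
  fits <- fit_strata(strata, min_obs)
  sig <- call_significant(records, fits, prob_threshold)
  filt <- desert_filter(sig, records, resolution, padding, min_mean, n_bins)
  net <- build_network(filt, chrom, resolution)
  mods <- detect_modules(net, method, min_nodes, seed)
  structure(list(chrom = chrom, resolution = resolution,
                 params = list(max_distance = max_distance,
                               min_obs = min_obs,
                               prob_threshold = prob_threshold,
                               padding = padding, min_mean = min_mean,
                               method = method, min_nodes = min_nodes,
                               seed = seed, include_zeros = include_zeros),
                 fits = fits, n_significant = nrow(sig), significant = filt,
                 network = net, modules = mods),
            class = "hicnets_result")
}

#' @export
print.hicnets_result <- function(x, ...) {
  cat("hicnets result for", x$chrom, "at", x$resolution, "bp\n")
  cat("  fitted strata:       ", nrow(x$fits), "\n")
  cat("  significant contacts:", x$n_significant,
      "(", nrow(x$significant), "after desert filter )\n")
  cat("  network:             ", igraph::vcount(x$network), "nodes,",
      igraph::ecount(x$network), "edges\n")
  cat("  modules (>=", attr(x$modules, "min_nodes") %||% 4, "nodes):",
      nrow(x$modules), "\n")
  invisible(x)
}

#' Write the module table as TSV
#'
#' Columns: module_id, chrom, span_start, span_end, n_nodes, connectivity,
#' transitivity, central_node_start, central_node_score. Scores are rounded
#' to 6 digits so identical runs give byte-identical files.
#'
#' @param modules a `chromatin_modules` table.
#' @param path output path.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- as.data.frame(modules)
  df$transitivity <- round(df$transitivity, 6)
  df$central_node_score <- round(df$central_node_score, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module table written by [write_modules_tsv()]
#'
#' @param path TSV path.
#' @export
read_modules_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write module node membership as BED
#'
#' One row per node: chrom, bin start, bin end, module_id.
#'
#' @param modules a `chromatin_modules` table.
#' @param path output path.
#' @param resolution bin width; defaults to the modules' attribute.
#' @export
write_module_nodes_bed <- function(modules, path, resolution = NULL) {
  resolution <- resolution %||% attr(modules, "resolution")
  nodes <- attr(modules, "nodes")
  rows <- lapply(names(nodes), function(id) {
    s <- sort(as.numeric(nodes[[id]]))
    data.frame(chrom = modules$chrom[modules$module_id == id][1L],
               start = s, end = s + resolution, name = id)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a module comparison table as TSV
#'
#' @param comparison output of [connectivity_diff()].
#' @param path output path.
#' @export
write_comparison_tsv <- function(comparison, path) {
  df <- comparison
  df$fold_change <- round(df$fold_change, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
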