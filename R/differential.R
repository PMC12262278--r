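# Differential connectivity between two conditions: restrict each side to its
# highly connected modules (rank-curve elbow), evaluate every retained module's
# genomic span in the counterpart network, and label modules whose
# connectivity fold change exceeds the threshold as condition-specific.

#' Elbow point of a rank-value curve
#'
#' Sorts the values ascending, rescales ranks and values to `[0, 1]`, computes
#' forward-difference slopes, and returns the point whose slope is closest
#' to 1. Slope ties (within 1e-9) are broken toward the larger rank, i.e. the
#' stricter threshold.
#'
#' @param values numeric vector (>= 3 values, not all equal).
#' @return list with `index` (1-based rank position on the ascending curve),
#'   `threshold` (original-scale value at that position), `x` (normalized rank)
#'   and `slope`.
#' @export
elbow_point <- function(values) {
  n <- length(values)
  if (n < 3L) stop("elbow point needs at least 3 values")
  v <- sort(values)
  if (v[n] == v[1L]) stop("degenerate curve: all values equal")
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[1L]) / (v[n] - v[1L])
  slopes <- diff(y) / diff(x)
  dist1 <- abs(slopes - 1)
  idx <- max(which(dist1 <= min(dist1) + 1e-9))
  list(index = idx, threshold = v[idx], x = x[idx], slope = slopes[idx])
}

#' Connectivity of a genomic span in another network
#'
#' Counts the edges of `other_net` whose two anchor bins both fall inside
#' `[span_start, span_end)`. Used to evaluate one condition's module in the
#' counterpart condition, whose network generally lacks the exact same bins
#' as nodes.
#'
#' @param other_net counterpart interaction network.
#' @param span_start,span_end module span (bp, 0-based half-open).
#' @param resolution optional; when both this and the network's resolution
#'   attribute are set they must agree.
#' @return edge count.
#' @export
counterpart_connectivity <- function(other_net, span_start, span_end,
                                     resolution = NULL) {
  net_res <- igraph::graph_attr(other_net, "resolution")
  if (!is.null(resolution) && !is.null(net_res) && resolution != net_res)
    stop("resolution mismatch: network at ", net_res, " bp, modules at ",
         resolution, " bp")
  if (igraph::ecount(other_net) == 0L) return(0L)
  ends <- igraph::ends(other_net, igraph::E(other_net), names = TRUE)
  a <- as.numeric(ends[, 1L])
  b <- as.numeric(ends[, 2L])
  sum(a >= span_start & a < span_end & b >= span_start & b < span_end)
}

elbow_threshold_or_all <- function(conn) {
  if (length(conn) < 3L || max(conn) == min(conn)) {
    warning("too few or degenerate module connectivities for an elbow; ",
            "keeping all modules")
    return(min(conn))
  }
  elbow_point(conn)$threshold
}

#' Differentially connected modules between two conditions
#'
#' For each condition, modules are first restricted to the highly connected
#' set (connectivity at or above that condition's own [elbow_point()]
#' threshold). Each retained module is then scored in the counterpart network
#' via [counterpart_connectivity()] and assigned
#' `fold_change = conn_self / max(conn_other, 1)`; the floor of 1 keeps the
#' fold change finite when the counterpart span has no edges at all. Modules
#' with `fold_change > fc_threshold` (strict) are labeled condition-specific.
#'
#' @param modules_a,modules_b `chromatin_modules` tables of the two conditions
#'   (any data.frame with `module_id`, `chrom`, `span_start`, `span_end`,
#'   `connectivity` works).
#' @param net_a,net_b the matching interaction networks.
#' @param fc_threshold fold-change cutoff (default 1.3, strict).
#' @param names condition labels used in the `label` column.
#' @return data.frame with one row per retained module, columns `module_id`,
#'   `condition`, `chrom`, `span_start`, `span_end`, `conn_A`, `conn_B`,
#'   `fold_change`, `label`, sorted by fold change descending.
#' @export
connectivity_diff <- function(modules_a, net_a, modules_b, net_b,
                              fc_threshold = 1.3, names = c("A", "B")) {
  empty <- data.frame(module_id = character(), condition = character(),
                      chrom = character(), span_start = numeric(),
                      span_end = numeric(), conn_A = numeric(),
                      conn_B = numeric(), fold_change = numeric(),
                      label = character())
  if (nrow(modules_a) == 0L || nrow(modules_b) == 0L) {
    warning("empty module set on at least one side; empty comparison")
    return(empty)
  }
  one_side <- function(mods, net_other, self_name, a_side) {
    thr <- elbow_threshold_or_all(mods$connectivity)
    mods <- mods[mods$connectivity >= thr, , drop = FALSE]
    conn_other <- vapply(seq_len(nrow(mods)), function(i) {
      counterpart_connectivity(net_other, mods$span_start[i],
                               mods$span_end[i])
    }, numeric(1))
    fc <- mods$connectivity / pmax(conn_other, 1)
    data.frame(module_id = mods$module_id,
               condition = self_name,
               chrom = mods$chrom,
               span_start = mods$span_start,
               span_end = mods$span_end,
               conn_A = if (a_side) mods$connectivity else conn_other,
               conn_B = if (a_side) conn_other else mods$connectivity,
               fold_change = fc,
               label = ifelse(fc > fc_threshold,
                              paste0(self_name, "-specific"), "shared"))
  }
  out <- rbind(one_side(as.data.frame(modules_a), net_b, names[1L], TRUE),
               one_side(as.data.frame(modules_b), net_a, names[2L], FALSE))
  out <- out[order(-out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard index of two genomic intervals
#'
#' Overlap length divided by union length of `[a_start, a_end)` and
#' `[b_start, b_end)`.
#'
#' @param a_start,a_end,b_start,b_end interval bounds (bp).
#' @export
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  union <- (a_end - a_start) + (b_end - b_start) - inter
  ifelse(union > 0, inter / union, 0)
}
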