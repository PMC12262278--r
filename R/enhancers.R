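# Super-enhancer calling from H3K27ac peak occupancy (ROSE-style):
# gap-stitch peaks, rank stitched regions by summed occupancy, rescale the
# rank curve to the unit square and call regions above the slope-1 elbow.
# Modules can then be annotated with super-enhancer overlap and the signed
# distance from the module's central node.

#' Stitch peaks separated by at most a maximum gap
#'
#' Overlapping peaks are merged unconditionally; peaks whose gap
#' (`next.start - prev.end`) is at most `gap` are merged transitively. The
#' stitched occupancy is the sum of member occupancies and the span is the
#' union hull. Input order does not matter and stitching is idempotent.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `occupancy`.
#' @param gap maximum stitching gap in bp (default 12500).
#' @return data.frame of stitched regions with `chrom`, `start`, `end`,
#'   `occupancy`, `n_peaks`.
#' @export
stitch_peaks <- function(peaks, gap = 12500L) {
  stopifnot(all(c("chrom", "start", "end", "occupancy") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) stop("peaks must have start < end")
  if (any(peaks$occupancy < 0)) stop("occupancy must be non-negative")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), occupancy = numeric(),
                      n_peaks = integer()))
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  occ <- vapply(revmap, function(i) sum(peaks$occupancy[i]), numeric(1))
  npk <- lengths(revmap)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    occupancy = occ, n_peaks = npk)
  rownames(out) <- NULL
  out
}

#' Call super-enhancers from stitched regions
#'
#' Ranks stitched regions by occupancy ascending, rescales rank and occupancy
#' to `[0, 1]`, locates the slope-1 elbow of the curve ([elbow_point()]), and
#' flags regions whose occupancy strictly exceeds the elbow occupancy as
#' super-enhancers.
#'
#' @param stitched output of [stitch_peaks()] (>= 3 regions, occupancies not
#'   all equal).
#' @return the input with added `rank` (ascending occupancy rank) and
#'   `is_super` columns; the elbow threshold is attached as the
#'   `"threshold"` attribute.
#' @export
call_super_enhancers <- function(stitched) {
  if (nrow(stitched) < 3L)
    stop("super-enhancer calling needs at least 3 stitched regions")
  eb <- elbow_point(stitched$occupancy)
  out <- stitched
  out$rank <- rank(out$occupancy, ties.method = "first")
  out$is_super <- out$occupancy > eb$threshold
  attr(out, "threshold") <- eb$threshold
  out
}

#' Annotate modules with overlapping features
#'
#' For each module: whether any feature (e.g. a super-enhancer) overlaps the
#' module span, whether a feature overlaps the central node's bin, and the
#' signed 1D distance from the central node bin to the nearest feature
#' (0 when overlapping; negative when the nearest feature lies upstream of
#' the bin, positive downstream; upstream wins distance ties).
#'
#' @param modules a `chromatin_modules` table (needs `module_id`, `chrom`,
#'   `span_start`, `span_end`, `central_node_start`).
#' @param features data.frame of intervals with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param resolution bin width in bp; defaults to the modules' attribute.
#' @return data.frame with `module_id`, `has_feature`, `n_features`,
#'   `central_overlap`, `central_distance` (`NA` when the chromosome has no
#'   features).
#' @export
annotate_modules <- function(modules, features, resolution = NULL) {
  resolution <- resolution %||% attr(modules, "resolution")
  if (is.null(resolution)) stop("resolution is required")
  mods <- as.data.frame(modules)
  out <- lapply(seq_len(nrow(mods)), function(i) {
    f <- features[features$chrom == mods$chrom[i], , drop = FALSE]
    cs <- mods$central_node_start[i]
    ce <- cs + resolution
    if (nrow(f) == 0L)
      return(data.frame(module_id = mods$module_id[i], has_feature = FALSE,
                        n_features = 0L, central_overlap = FALSE,
                        central_distance = NA_real_))
    in_span <- f$start < mods$span_end[i] & f$end > mods$span_start[i]
    on_central <- f$start < ce & f$end > cs
    if (any(on_central)) {
      d <- 0
    } else {
      cand <- ifelse(f$end <= cs, f$end - cs, f$start - ce)
      d <- cand[order(abs(cand), cand)][1L]
    }
    data.frame(module_id = mods$module_id[i],
               has_feature = any(in_span),
               n_features = sum(in_span),
               central_overlap = any(on_central),
               central_distance = d)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
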