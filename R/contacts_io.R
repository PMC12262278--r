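# Internal contact representation: a plain data.frame with columns
#   chrom  - chromosome name (single chromosome per frame)
#   start1 - 0-based left edge of the first bin (bp)
#   start2 - 0-based left edge of the second bin (bp), start1 <= start2
#   count  - raw observed contact count (positive integer; zeros are implicit)
# All coordinates are 0-based, half-open, bin-left-edge, matching the
# convention of `straw` / `cooler dump` sparse text output.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and canonicalize a sparse contact table
#'
#' Enforces the internal contact contract: coordinates aligned to the bin
#' resolution, integer raw counts (balanced/normalized matrices are rejected),
#' canonical ordering `start1 <= start2`, and one row per bin pair (duplicate
#' pairs are summed with a warning). Rows with zero counts are dropped.
#'
#' @param records data.frame with columns `chrom`, `start1`, `start2`, `count`.
#' @param resolution bin width in bp.
#' @return Canonicalized contact data.frame sorted by (start1, start2).
#' @export
as_contacts <- function(records, resolution) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "start1", "start2", "count") %in% names(records)))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number of bp")
  df <- records[, c("chrom", "start1", "start2", "count")]
  if (nrow(df) == 0L) return(df)
  if (any(df$start1 < 0 | df$start2 < 0))
    stop("negative bin coordinates")
  if (any(df$start1 %% resolution != 0 | df$start2 %% resolution != 0))
    stop("bin starts are not multiples of the requested resolution (",
         resolution, " bp); wrong resolution for this dump?")
  if (any(abs(df$count - round(df$count)) > 1e-6))
    stop("non-integer contact counts detected; the negative binomial model ",
         "needs raw observed counts, not KR/ICE-balanced values")
  df$count <- round(df$count)
  df <- df[df$count > 0, , drop = FALSE]
  swap <- df$start1 > df$start2
  if (any(swap)) {
    tmp <- df$start1[swap]
    df$start1[swap] <- df$start2[swap]
    df$start2[swap] <- tmp
  }
  key <- paste(df$start1, df$start2)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate bin-pair rows summed")
    df <- stats::aggregate(count ~ chrom + start1 + start2, data = df, FUN = sum)
  }
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read sparse intra-chromosomal Hi-C contacts from a text dump
#'
#' Reads the 3-column sparse matrix text format produced by `straw` or
#' `cooler dump` (`start1  start2  count`, one chromosome per file) or a
#' 5-column variant with explicit chromosome names
#' (`chrom1 start1 chrom2 start2 count`). Inter-chromosomal rows in the
#' 5-column form are rejected with a warning stating how many were dropped.
#' Binary containers (.hic/.cool/.mcool) are not parsed directly; dump them
#' to text first.
#'
#' @param path path to the contact dump.
#' @param chrom chromosome name to assign (3-column input) or select
#'   (5-column input).
#' @param resolution bin width in bp of the dump.
#' @return Canonical contact data.frame (see [as_contacts()]).
#' @export
read_contacts <- function(path, chrom, resolution) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.(hic|cool|mcool)$", path, ignore.case = TRUE))
    stop("binary Hi-C containers are not read directly; dump the matrix to ",
         "sparse text first (e.g. 'straw NONE in.hic chr1 chr1 BP 10000' or ",
         "'cooler dump --join in.cool') and pass the text file")
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) == 3L && all(vapply(raw, is.numeric, logical(1)))) {
    df <- data.frame(chrom = chrom, start1 = raw[[1]], start2 = raw[[2]],
                     count = raw[[3]])
  } else if (ncol(raw) >= 5L) {
    inter <- raw[[1]] != raw[[3]]
    if (any(inter))
      warning(sum(inter), " inter-chromosomal rows rejected")
    keep <- !inter & raw[[1]] == chrom
    df <- data.frame(chrom = chrom, start1 = raw[[2]][keep],
                     start2 = raw[[4]][keep], count = raw[[5]][keep])
  } else {
    stop("unrecognized contact format: expected 3 columns ",
         "(start1 start2 count) or >= 5 (chrom1 start1 chrom2 start2 count)")
  }
  as_contacts(df, resolution)
}

#' Write contacts as a 3-column sparse text dump
#'
#' @param records canonical contact data.frame.
#' @param path output path.
#' @export
write_contacts <- function(records, path) {
  utils::write.table(records[, c("start1", "start2", "count")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write significant interactions as BEDPE
#'
#' Standard 8-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2 name
#' score`); the score column carries the contact probability. Coordinates are
#' 0-based half-open with `end = start + resolution`.
#'
#' @param records data.frame with `chrom`, `start1`, `start2` and a
#'   `probability` column (plus optionally `count`).
#' @param path output path.
#' @param resolution bin width in bp.
#' @export
write_interactions_bedpe <- function(records, path, resolution) {
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom1 = records$chrom,
                    start1 = records$start1,
                    end1 = records$start1 + resolution,
                    chrom2 = records$chrom,
                    start2 = records$start2,
                    end2 = records$start2 + resolution,
                    name = ".",
                    score = records$probability %||% ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read interactions back from BEDPE
#'
#' Inverse of [write_interactions_bedpe()]. The bin width is inferred from
#' `end1 - start1` and attached as the `"resolution"` attribute.
#'
#' @param path BEDPE file path.
#' @return data.frame with `chrom`, `start1`, `start2`, `probability`.
#' @export
read_interactions_bedpe <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  empty <- data.frame(chrom = character(), start1 = numeric(),
                      start2 = numeric(), probability = numeric())
  if (file.size(path) == 0L) return(empty)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 8L) stop("not a BEDPE file: ", path)
  out <- data.frame(chrom = raw[[1]], start1 = raw[[2]], start2 = raw[[5]],
                    probability = suppressWarnings(as.numeric(raw[[8]])))
  res <- unique(raw[[3]] - raw[[2]])
  if (length(res) == 1L) attr(out, "resolution") <- res
  out
}

#' Read peak intervals with occupancy from BED
#'
#' Accepts BED4 (`chrom start end occupancy`) or BED5+
#' (`chrom start end name score`); the occupancy is taken from column 4 when
#' numeric, otherwise from column 5. Coordinates are 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `occupancy`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("peak BED needs a numeric occupancy column")
  occ <- if (is.numeric(raw[[4]])) raw[[4]] else raw[[5]]
  if (!is.numeric(occ)) stop("peak BED needs a numeric occupancy column")
  data.frame(chrom = raw[[1]], start = raw[[2]], end = raw[[3]],
             occupancy = occ)
}

#' Write peaks or stitched regions as BED
#'
#' Writes `chrom start end occupancy` plus any further columns present
#' (e.g. `rank`, `is_super` for super-enhancer calls).
#'
#' @param peaks data.frame with at least `chrom`, `start`, `end`, `occupancy`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
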