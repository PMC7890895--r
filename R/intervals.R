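# Interval algebra on 0-based half-open coordinates.
#
# Tibbles with columns seq_id/start/end are the user-facing representation;
# GenomicRanges does the heavy lifting internally (1-based closed, hence the
# +1 on start at the boundary).

#' Validate an interval table
#'
#' Checks that `x` has `seq_id`, `start`, `end` columns, that coordinates are
#' non-negative integers and that `end > start` for every row (0-based
#' half-open convention, so zero-length intervals are invalid).
#'
#' @param x A data frame with at least `seq_id`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_intervals <- function(x, what = "interval table") {
  x <- as_tibble(x)
  need <- c("seq_id", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(x)
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(paste0(what, ": non-finite coordinates"))
  }
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0(
      what, ": end <= start at row(s) ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$seq_id),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble (0-based half-open)
gr_tbl <- function(gr) {
  tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Fraction of one interval covered by another
#'
#' Computes `|a intersect b| / |a|` row by row. `a` and `b` must have the
#' same number of rows (or one of them a single row, which is recycled).
#' Intervals on different sequences share no bases, so the fraction is 0.
#' Strand is ignored.
#'
#' @param a,b Data frames with `seq_id`, `start`, `end` (0-based half-open).
#' @return Numeric vector in `[0, 1]`, the fraction of each `a` interval
#'   covered by the corresponding `b` interval.
#' @examples
#' a <- tibble::tibble(seq_id = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(seq_id = "chr1", start = 50, end = 150)
#' overlap_fraction(a, b) # 0.5
#' @export
overlap_fraction <- function(a, b) {
  a <- validate_intervals(a, "overlap_fraction 'a'")
  b <- validate_intervals(b, "overlap_fraction 'b'")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  if (nrow(a) != nrow(b)) {
    abort("overlap_fraction: 'a' and 'b' must have equal row counts (or 1)")
  }
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  inter[as.character(a$seq_id) != as.character(b$seq_id)] <- 0
  inter / (a$end - a$start)
}

#' Merge overlapping and bookended intervals
#'
#' Returns the sorted, pairwise-disjoint union of the input intervals.
#' Bookended intervals (`[0,10)` and `[10,20)`) are merged, matching the
#' half-open convention in which they share a boundary but no base; the
#' union of covered bases is preserved exactly.
#'
#' @param x Data frame with `seq_id`, `start`, `end`.
#' @return Tibble of disjoint intervals sorted by `seq_id` then `start`.
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x, "merge_intervals")
  if (nrow(x) == 0) return(tibble(seq_id = character(), start = integer(), end = integer()))
  gr_tbl(GenomicRanges::reduce(as_gr(x)))
}

# All overlapping row pairs between two interval tables (>= 1 bp).
# Returns tibble(idx_a, idx_b, width, frac_a, frac_b).
overlap_pairs <- function(a, b, maxgap = -1L) {
  hits <- GenomicRanges::findOverlaps(as_gr(a), as_gr(b), maxgap = maxgap)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  w <- pmax(0, pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]))
  tibble(
    idx_a = ia, idx_b = ib, width = w,
    frac_a = w / (a$end[ia] - a$start[ia]),
    frac_b = w / (b$end[ib] - b$start[ib])
  )
}

# Edge-to-edge distance between interval rows (0 when overlapping/adjacent),
# vectorised over equal-length tables on the same seq_id.
edge_distance <- function(a, b) {
  d <- pmax(a$start, b$start) - pmin(a$end, b$end)
  pmax(0, d)
}

# Complement of a merged interval set within per-sequence bounds.
# genome: tibble(seq_id, length). Returns disjoint gaps as a tibble.
interval_complement <- function(x, genome) {
  x <- merge_intervals(x)
  out <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    sid <- genome$seq_id[i]
    len <- genome$length[i]
    xs <- x[x$seq_id == sid, , drop = FALSE]
    starts <- c(0, xs$end)
    ends <- c(xs$start, len)
    keep <- ends > starts
    tibble(seq_id = sid, start = starts[keep], end = ends[keep])
  })
  out
}
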