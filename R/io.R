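# Readers/writers for the tabular formats the pipeline consumes: BED3+,
# a simplified RepeatMasker-style repeat table, gapless pairwise
# alignment-map blocks, and species divergence times. All coordinates are
# 0-based half-open on disk and in memory; a `one_based` dialect flag on the
# readers converts 1-based inclusive input on the fly.

#' Read a BED3+ file
#'
#' Reads tab-separated BED with at least 3 columns. Columns beyond the
#' standard six are kept as `extra1`, `extra2`, ... Lines starting with `#`,
#' `track` or `browser` are skipped.
#'
#' @param path File path.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to 0-based half-open on read.
#' @return Tibble with `seq_id`, `start`, `end` and any further BED columns
#'   (`name`, `score`, `strand`, ...), rows in file order.
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) abort(paste0("read_bed: no such file: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("read_bed: fewer than 3 columns at line ", line_no[which(nf < 3)[1]]))
  }
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  bed_names <- c("seq_id", "start", "end", "name", "score", "strand")
  cn <- c(bed_names[seq_len(min(ncol_use, 6))],
          if (ncol_use > 6) paste0("extra", seq_len(ncol_use - 6)))
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE), .name_repair = "minimal")
  names(out) <- cn
  start <- suppressWarnings(as.integer(out$start))
  end <- suppressWarnings(as.integer(out$end))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(paste0("read_bed: non-integer coordinates at line ", line_no[bad]))
  }
  if (one_based) start <- start - 1L
  out$start <- start
  out$end <- end
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(paste0("read_bed: end <= start at line ", line_no[bad[1]]))
  }
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  out
}

#' Write a BED3+ file
#'
#' Emits tab-separated values with LF line endings and no header, preserving
#' column order (`seq_id`, `start`, `end` first).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, "write_bed")
  lead <- c("seq_id", "start", "end")
  x <- x[, c(lead, setdiff(names(x), lead))]
  lines <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR")

#' Read a simplified repeat-annotation table
#'
#' Expects a tab-separated table with header
#' `#seq start end strand class subgroup pct_div` (a flattened RepeatMasker
#' `.out` dialect). Classes outside DNA/LINE/SINE/LTR are mapped to
#' `"other"`; percent divergence must lie in `[0, 100]`.
#'
#' @param path File path.
#' @param one_based Convert 1-based inclusive coordinates on read.
#' @return Tibble with `seq_id`, `start`, `end`, `strand`, `repeat_class`,
#'   `subgroup`, `pct_divergence`.
#' @export
read_repeat_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) abort(paste0("read_repeat_table: no such file: ", path))
  x <- readr::read_tsv(
    path,
    col_names = c("seq_id", "start", "end", "strand", "class", "subgroup", "pct_div"),
    comment = "", skip = 1, show_col_types = FALSE,
    col_types = readr::cols(
      seq_id = "c", start = "i", end = "i", strand = "c",
      class = "c", subgroup = "c", pct_div = "d"
    )
  )
  if (any(x$pct_div < 0 | x$pct_div > 100, na.rm = TRUE)) {
    abort("read_repeat_table: pct_div outside [0, 100]")
  }
  out <- tibble(
    seq_id = x$seq_id,
    start = if (one_based) x$start - 1L else x$start,
    end = x$end,
    strand = x$strand,
    repeat_class = if_else(x$class %in% REPEAT_CLASSES, x$class, "other"),
    subgroup = x$subgroup,
    pct_divergence = x$pct_div
  )
  validate_intervals(out, "read_repeat_table")
}

#' Write a repeat-annotation table
#'
#' @param x Tibble as returned by [read_repeat_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(x, path) {
  header <- "#seq\tstart\tend\tstrand\tclass\tsubgroup\tpct_div"
  lines <- paste(x$seq_id, x$start, x$end, x$strand, x$repeat_class,
                 x$subgroup, x$pct_divergence, sep = "\t")
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read a pairwise alignment-map block table
#'
#' Eight tab-separated columns
#' (`species_a seq_a start_a end_a species_b seq_b start_b end_b`) after a
#' `#`-prefixed header line. Blocks are gapless: the two sides of every
#' block must have equal length, and violating rows raise an error.
#'
#' @param path File path.
#' @return Tibble of alignment blocks.
#' @export
read_alignment_map <- function(path) {
  if (!file.exists(path)) abort(paste0("read_alignment_map: no such file: ", path))
  x <- readr::read_tsv(
    path,
    col_names = c("species_a", "seq_a", "start_a", "end_a",
                  "species_b", "seq_b", "start_b", "end_b"),
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      species_a = "c", seq_a = "c", start_a = "i", end_a = "i",
      species_b = "c", seq_b = "c", start_b = "i", end_b = "i"
    )
  )
  bad <- which((x$end_a - x$start_a) != (x$end_b - x$start_b))
  if (length(bad) > 0) {
    abort(paste0("read_alignment_map: unequal block lengths at data row ", bad[1]))
  }
  as_tibble(x)
}

#' Write a pairwise alignment-map block table
#'
#' @param x Tibble of alignment blocks (see [read_alignment_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_map <- function(x, path) {
  header <- "#species_a\tseq_a\tstart_a\tend_a\tspecies_b\tseq_b\tstart_b\tend_b"
  lines <- paste(x$species_a, x$seq_a, x$start_a, x$end_a,
                 x$species_b, x$seq_b, x$start_b, x$end_b, sep = "\t")
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read a species divergence-time table
#'
#' Tab-separated columns `species_a`, `species_b`, `divergence_mya` with a
#' header line.
#'
#' @param path File path.
#' @return Tibble with one row per species pair.
#' @export
read_divergence_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species_a = "c", species_b = "c", divergence_mya = "d"
                  ))
}

# Reverse an alignment map (swap the a and b sides).
flip_alignment_map <- function(map) {
  tibble(
    species_a = map$species_b, seq_a = map$seq_b,
    start_a = map$start_b, end_a = map$end_b,
    species_b = map$species_a, seq_b = map$seq_a,
    start_b = map$start_a, end_b = map$end_a
  )
}
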