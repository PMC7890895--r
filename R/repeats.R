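# Transposable-element statistics: relative subgroup enrichment between two
# region sets (tissue-specific vs tissue-shared, or evolutionarily dynamic
# vs stable), repeat age/length comparisons across regulatory-overlap
# categories, and a shuffled-region null for LINE overlap.

#' Two-proportion z-test
#'
#' Tests `x1/n1` against `x2/n2` using the pooled-variance normal
#' approximation. Without continuity correction (the default) the squared
#' statistic equals the Pearson chi-square of the 2x2 table, so the
#' two-sided p-values agree exactly.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two samples (vectorised).
#' @param correct Apply the Yates continuity correction. Default `FALSE`.
#' @return Tibble with `estimate_1`, `estimate_2`, `z`, `p_value`.
#' @export
prop_z_test <- function(x1, n1, x2, n2, correct = FALSE) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  num <- abs(p1 - p2)
  if (correct) num <- pmax(0, num - 0.5 * (1 / n1 + 1 / n2))
  z <- num / se
  p <- 2 * pnorm(-z)
  p[se == 0] <- 1
  tibble(estimate_1 = p1, estimate_2 = p2,
         z = sign(p1 - p2) * z, p_value = pmin(1, p))
}

#' Relative repeat-subgroup enrichment between two region sets
#'
#' For each repeat class (DNA/LINE/SINE/LTR) and subgroup within it: among
#' the regions of each set overlapping any repeat of that class, the
#' percentage overlapping the given subgroup is computed; the enrichment
#' `delta` is the set-A percentage minus the set-B percentage (positive
#' values: over-represented in A). Significance is a two-proportion z-test
#' on the raw counts with Bonferroni correction over every cell of the
#' matrix; `displayed` marks cells passing the minimum-count filter
#' (>= `min_display` regions in both sets), which does not affect the
#' correction denominator.
#'
#' A region overlapping repeats of several subgroups counts once per
#' subgroup, but only once in the class total, so percentages within a
#' class can sum above 100; `strict = TRUE` instead attributes each region
#' to its largest-overlap subgroup only.
#'
#' @param set_A,set_B Interval tibbles (`seq_id`, `start`, `end`), same
#'   species and region class.
#' @param repeats Repeat tibble (see [read_repeat_table()]).
#' @param min_overlap `"one_bp"` (default) or `"half_region"` (a repeat
#'   must cover >= 50% of the region's length).
#' @param min_display Minimum count in both sets for `displayed`. Default 100.
#' @param correct Continuity-correct the z-test. Default `FALSE`.
#' @param strict Attribute multi-subgroup regions to their largest-overlap
#'   subgroup only. Default `FALSE`.
#' @return Tibble, one row per (repeat_class, subgroup): counts, totals,
#'   `pct_A`, `pct_B`, `delta`, `p_value`, `p_adj`, `displayed`.
#' @export
relative_enrichment <- function(set_A, set_B, repeats,
                                min_overlap = c("one_bp", "half_region"),
                                min_display = 100, correct = FALSE,
                                strict = FALSE) {
  min_overlap <- match.arg(min_overlap)
  set_A <- validate_intervals(as_tibble(set_A), "set_A")
  set_B <- validate_intervals(as_tibble(set_B), "set_B")
  repeats <- as_tibble(repeats)
  reps <- filter(repeats, .data$repeat_class %in% REPEAT_CLASSES)

  set_hits <- function(x) {
    ov <- overlap_pairs(x, reps)
    if (min_overlap == "half_region") ov <- filter(ov, .data$frac_a >= 0.5)
    h <- tibble(region = ov$idx_a,
                repeat_class = reps$repeat_class[ov$idx_b],
                subgroup = reps$subgroup[ov$idx_b],
                width = ov$width)
    if (strict && nrow(h) > 0) {
      h <- h |>
        group_by(.data$region, .data$repeat_class, .data$subgroup) |>
        summarise(width = sum(.data$width), .groups = "drop") |>
        group_by(.data$region, .data$repeat_class) |>
        arrange(dplyr::desc(.data$width), .data$subgroup) |>
        slice(1) |>
        ungroup()
    }
    h
  }
  ha <- set_hits(set_A)
  hb <- set_hits(set_B)
  tally <- function(h, suffix) {
    tot <- h |> distinct(.data$region, .data$repeat_class) |>
      count(.data$repeat_class, name = paste0("total_", suffix))
    cnt <- h |> distinct(.data$region, .data$repeat_class, .data$subgroup) |>
      count(.data$repeat_class, .data$subgroup, name = paste0("count_", suffix))
    list(tot = tot, cnt = cnt)
  }
  ta <- tally(ha, "A"); tb <- tally(hb, "B")
  cells <- dplyr::full_join(ta$cnt, tb$cnt, by = c("repeat_class", "subgroup")) |>
    left_join(ta$tot, by = "repeat_class") |>
    left_join(tb$tot, by = "repeat_class") |>
    mutate(across(dplyr::starts_with(c("count_", "total_")),
                  ~ tidyr::replace_na(.x, 0L)))
  if (nrow(cells) == 0) {
    return(mutate(cells, pct_A = double(), pct_B = double(), delta = double(),
                  z = double(), p_value = double(), p_adj = double(),
                  displayed = logical()))
  }
  zt <- prop_z_test(cells$count_A, cells$total_A, cells$count_B, cells$total_B,
                    correct = correct)
  cells |>
    mutate(pct_A = 100 * .data$count_A / .data$total_A,
           pct_B = 100 * .data$count_B / .data$total_B,
           delta = .data$pct_A - .data$pct_B,
           z = zt$z,
           p_value = zt$p_value,
           p_adj = pmin(1, .data$p_value * dplyr::n()),
           displayed = .data$count_A >= min_display & .data$count_B >= min_display) |>
    arrange(.data$repeat_class, .data$subgroup)
}

#' Partition repeat elements by regulatory-overlap category
#'
#' Each repeat element is assigned exactly one category by >= 1 bp overlap,
#' with precedence evolutionarily dynamic > recently evolved > other
#' regulatory overlap > inactive:
#' `evolutionarily_dynamic_overlap` (overlaps a region aligned across
#' species with a different signature), `recently_evolved_overlap`
#' (overlaps a recently evolved region), `other_regulatory_overlap`
#' (overlaps only maintained, stable regions) and `regulatorily_inactive`.
#'
#' @param repeats Repeat tibble for one species.
#' @param regulome Regulome tibble for the same species/coordinates.
#' @param recent_ids,dynamic_ids Character vectors of `region_id`s that are
#'   recently evolved and evolutionarily dynamic, respectively (from the
#'   evolution module).
#' @return `repeats` with a `category` column and `length` (bp).
#' @export
partition_repeats <- function(repeats, regulome, recent_ids, dynamic_ids) {
  repeats <- as_tibble(repeats)
  regulome <- as_tibble(regulome)
  ov <- overlap_pairs(repeats, regulome)
  cat_rank <- rep(0L, nrow(repeats)) # 0 inactive, 1 other, 2 recent, 3 dynamic
  if (nrow(ov) > 0) {
    rid <- regulome$region_id[ov$idx_b]
    r <- 1L + (rid %in% recent_ids) * 1L + (rid %in% dynamic_ids) * 2L
    r[rid %in% dynamic_ids] <- 3L
    mx <- tapply(r, ov$idx_a, max)
    cat_rank[as.integer(names(mx))] <- as.integer(mx)
  }
  labels <- c("regulatorily_inactive", "other_regulatory_overlap",
              "recently_evolved_overlap", "evolutionarily_dynamic_overlap")
  mutate(repeats,
         category = labels[cat_rank + 1L],
         length = .data$end - .data$start)
}

#' Compare a repeat attribute between overlap categories
#'
#' One-sided Wilcoxon rank-sum (Mann-Whitney) tests of `attribute` between
#' every ordered pair of categories, with the per-category medians. The
#' alternative is that the first category of each pair is `"greater"` (or
#' `"less"`) than the second.
#'
#' @param partition Output of [partition_repeats()] (or any tibble with a
#'   `category` column and the attribute).
#' @param attribute Column to compare: `"pct_divergence"` or `"length"`.
#' @param alternative `"greater"` (default) or `"less"`.
#' @param categories Categories to include (default: all present, in order
#'   of appearance). Empty categories are skipped with a warning.
#' @return Tibble with `category_1`, `category_2`, `median_1`, `median_2`,
#'   `n_1`, `n_2`, `p_value`.
#' @export
compare_repeat_attribute <- function(partition,
                                     attribute = c("pct_divergence", "length"),
                                     alternative = c("greater", "less"),
                                     categories = NULL) {
  attribute <- match.arg(attribute)
  alternative <- match.arg(alternative)
  partition <- as_tibble(partition)
  if (is.null(categories)) categories <- unique(partition$category)
  vals <- lapply(categories, function(cc) {
    partition[[attribute]][partition$category == cc]
  })
  names(vals) <- categories
  empty <- lengths(vals) == 0
  if (any(empty)) {
    warn(paste0("compare_repeat_attribute: empty category skipped: ",
                paste(categories[empty], collapse = ", ")))
    categories <- categories[!empty]
  }
  if (length(categories) < 2) return(tibble())
  pairs <- expand.grid(category_1 = categories, category_2 = categories,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$category_1 != pairs$category_2, ]
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    c1 <- pairs$category_1[k]; c2 <- pairs$category_2[k]
    wt <- stats::wilcox.test(vals[[c1]], vals[[c2]], alternative = alternative)
    tibble(category_1 = c1, category_2 = c2,
           median_1 = median(vals[[c1]]), median_2 = median(vals[[c2]]),
           n_1 = length(vals[[c1]]), n_2 = length(vals[[c2]]),
           p_value = wt$p.value)
  })
}

#' LINE overlap of matched random regions
#'
#' Places, uniformly at random outside an exclusion set, one random region
#' per input region with the same length and compares the fraction of
#' random vs real regions covered >= `min_frac` of their length by a LINE
#' element. Placement is deterministic under `seed`.
#'
#' @param regions Interval tibble of real regulatory regions.
#' @param genome_sizes Tibble with `seq_id`, `length`.
#' @param exclude Interval tibble to exclude from placement (typically all
#'   regulatorily active regions).
#' @param repeats Repeat tibble; only `repeat_class == "LINE"` rows are used.
#' @param seed Integer seed.
#' @param min_frac Minimum fraction of the region covered by a single LINE
#'   element. Default 0.5.
#' @return List with `real_fraction`, `random_fraction`, `p_value` (two
#'   proportion z-test) and the `placements` tibble.
#' @export
shuffle_control <- function(regions, genome_sizes, exclude, repeats, seed,
                            min_frac = 0.5) {
  regions <- validate_intervals(as_tibble(regions), "shuffle_control regions")
  gaps <- interval_complement(exclude, genome_sizes)
  gaps$width <- gaps$end - gaps$start
  lens <- regions$end - regions$start
  placements <- withr::with_seed(seed, {
    purrr::map_dfr(seq_along(lens), function(i) {
      L <- lens[i]
      ok <- gaps[gaps$width >= L, , drop = FALSE]
      if (nrow(ok) == 0) {
        abort(paste0("shuffle_control: region ", i, " (length ", L,
                     ") exceeds every placeable gap"))
      }
      w <- ok$width - L + 1
      g <- sample.int(nrow(ok), 1, prob = w)
      s <- ok$start[g] + sample.int(w[g], 1) - 1L
      tibble(seq_id = ok$seq_id[g], start = s, end = s + L)
    })
  })
  lines <- filter(as_tibble(repeats), .data$repeat_class == "LINE")
  frac_hit <- function(x) {
    if (nrow(x) == 0) return(0)
    ov <- overlap_pairs(x, lines)
    mean(seq_len(nrow(x)) %in% unique(ov$idx_a[ov$frac_a >= min_frac]))
  }
  real_f <- frac_hit(regions)
  rand_f <- frac_hit(placements)
  zt <- prop_z_test(round(real_f * nrow(regions)), nrow(regions),
                    round(rand_f * nrow(placements)), nrow(placements))
  list(real_fraction = real_f, random_fraction = rand_f,
       p_value = zt$p_value, placements = placements)
}
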