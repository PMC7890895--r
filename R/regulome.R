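# Building per-tissue regulomes from replicate peak calls.
#
# Stage 1: reproducible consensus peaks per mark (reciprocal-50% rule across
# biological replicates). Stage 2: signature calling — active promoters
# (H3K4me3 backed by H3K27ac), active enhancers (H3K27ac backed by H3K4me1),
# primed enhancers (H3K4me1 alone) — with an exclusion set that keeps the
# three signature classes base-disjoint within a tissue. Stage 3:
# cross-tissue activity, tissue specificity, and intra-species dynamic flags.

#' Consensus peaks reproducible across biological replicates
#'
#' Two peaks from different replicates support each other when they overlap
#' reciprocally by at least `min_frac` of each peak's own length. A peak is
#' reproducible when it has such partners in at least `min_replicates - 1`
#' other replicates; the union span of each connected group of reproducible
#' peaks is emitted as one consensus interval. Non-reproducible peaks are
#' dropped.
#'
#' If `peaks` carries `species`/`tissue`/`mark` columns the rule is applied
#' within each group and the grouping columns are kept on the output.
#'
#' @param peaks Tibble of per-replicate peaks with `seq_id`, `start`, `end`,
#'   `replicate_id` (and optionally `species`, `tissue`, `mark`).
#' @param min_replicates Minimum number of replicates a peak must appear in
#'   (including its own); also the minimum number of replicate lists
#'   required. Default 2.
#' @param min_frac Reciprocal overlap fraction threshold. Default 0.5.
#' @return Tibble of consensus intervals, sorted within group.
#' @export
merge_reproducible_peaks <- function(peaks, min_replicates = 2, min_frac = 0.5) {
  peaks <- validate_intervals(peaks, "merge_reproducible_peaks")
  if (!"replicate_id" %in% names(peaks)) {
    abort("merge_reproducible_peaks: 'replicate_id' column required")
  }
  grp_cols <- intersect(c("species", "tissue", "mark"), names(peaks))
  one_group <- function(g) {
    reps <- unique(g$replicate_id)
    if (length(reps) < min_replicates) {
      abort(paste0(
        "merge_reproducible_peaks: ", length(reps), " replicate(s) present, ",
        min_replicates, " required"
      ))
    }
    pr <- overlap_pairs(g, g)
    pr <- pr[pr$idx_a != pr$idx_b &
               g$replicate_id[pr$idx_a] != g$replicate_id[pr$idx_b] &
               pr$frac_a >= min_frac & pr$frac_b >= min_frac, , drop = FALSE]
    if (nrow(pr) == 0) {
      return(tibble(seq_id = character(), start = integer(), end = integer()))
    }
    n_support <- tapply(g$replicate_id[pr$idx_b], pr$idx_a,
                        function(z) length(unique(z)))
    good <- as.integer(names(n_support))[n_support >= (min_replicates - 1)]
    if (length(good) == 0) {
      return(tibble(seq_id = character(), start = integer(), end = integer()))
    }
    merge_intervals(g[good, c("seq_id", "start", "end")])
  }
  if (length(grp_cols) == 0) return(one_group(peaks))
  peaks |>
    group_by(across(dplyr::all_of(grp_cols))) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      res <- one_group(g)
      for (cc in grp_cols) res[[cc]] <- g[[cc]][1]
      res[, c(grp_cols, "seq_id", "start", "end")]
    })
}

#' Call regulatory-region signatures for one species and tissue
#'
#' Applies the three signature definitions to consensus peak sets:
#' \describe{
#'   \item{AP (active promoter)}{an H3K4me3 interval at least half covered
#'     by some single H3K27ac interval; the H3K4me3 span is the region. The
#'     exclusion set grows by the union of the promoter and every H3K27ac
#'     interval touching it by >= 1 bp.}
#'   \item{AE (active enhancer)}{an H3K27ac interval not touching the
#'     exclusion set, at least half covered by some H3K4me1 interval; the
#'     H3K27ac span is the region.}
#'   \item{PE (primed enhancer)}{an H3K4me1 interval with zero overlap
#'     against any raw H3K27ac or H3K4me3 interval.}
#' }
#' Remaining mark intervals are returned with signature `"unclassified"`.
#' The AP/AE/PE sets are pairwise base-disjoint by construction.
#'
#' @param k4me3,k27ac,k4me1 Consensus interval tibbles (`seq_id`, `start`,
#'   `end`) for the three marks, post reproducibility filtering.
#' @param min_frac Coverage threshold for the AP and AE rules. Default 0.5.
#' @return Tibble with `seq_id`, `start`, `end`, `signature`, `source_mark`.
#' @export
call_regulatory_regions <- function(k4me3, k27ac, k4me1, min_frac = 0.5) {
  k4me3 <- validate_intervals(as_tibble(k4me3), "k4me3")
  k27ac <- validate_intervals(as_tibble(k27ac), "k27ac")
  k4me1 <- validate_intervals(as_tibble(k4me1), "k4me1")
  core <- c("seq_id", "start", "end")
  k4me3 <- k4me3[, core]; k27ac <- k27ac[, core]; k4me1 <- k4me1[, core]

  # active promoters
  pr <- overlap_pairs(k4me3, k27ac)
  is_ap <- rep(FALSE, nrow(k4me3))
  if (nrow(pr) > 0) {
    hit <- unique(pr$idx_a[pr$frac_a >= min_frac])
    is_ap[hit] <- TRUE
  }
  ap <- k4me3[is_ap, , drop = FALSE]
  # exclusion set: promoters plus every K27ac interval touching them
  excl_parts <- ap
  if (nrow(pr) > 0) {
    touching <- unique(pr$idx_b[is_ap[pr$idx_a]])
    excl_parts <- bind_rows(excl_parts, k27ac[touching, , drop = FALSE])
  }
  excl <- merge_intervals(excl_parts)

  # active enhancers: K27ac free of the exclusion set, half-covered by K4me1
  if (nrow(k27ac) > 0 && nrow(excl) > 0) {
    in_excl <- overlap_pairs(k27ac, excl)
    free <- setdiff(seq_len(nrow(k27ac)), unique(in_excl$idx_a))
  } else {
    free <- seq_len(nrow(k27ac))
  }
  ac_free <- k27ac[free, , drop = FALSE]
  is_ae_free <- rep(FALSE, nrow(ac_free))
  if (nrow(ac_free) > 0 && nrow(k4me1) > 0) {
    am <- overlap_pairs(ac_free, k4me1)
    is_ae_free[unique(am$idx_a[am$frac_a >= min_frac])] <- TRUE
  }
  ae <- ac_free[is_ae_free, , drop = FALSE]
  is_ae <- rep(FALSE, nrow(k27ac)); is_ae[free[is_ae_free]] <- TRUE

  # primed enhancers: K4me1 untouched by any raw K27ac or K4me3 interval
  raw_active <- bind_rows(k27ac, k4me3)
  if (nrow(k4me1) > 0 && nrow(raw_active) > 0) {
    touch <- overlap_pairs(k4me1, raw_active)
    is_pe <- !seq_len(nrow(k4me1)) %in% unique(touch$idx_a)
  } else {
    is_pe <- rep(TRUE, nrow(k4me1))
  }
  pe <- k4me1[is_pe, , drop = FALSE]

  bind_rows(
    mutate(ap, signature = "AP", source_mark = "H3K4me3"),
    mutate(ae, signature = "AE", source_mark = "H3K27ac"),
    mutate(pe, signature = "PE", source_mark = "H3K4me1"),
    mutate(k4me3[!is_ap, , drop = FALSE], signature = "unclassified", source_mark = "H3K4me3"),
    mutate(k27ac[!is_ae, , drop = FALSE], signature = "unclassified", source_mark = "H3K27ac"),
    mutate(k4me1[!is_pe, , drop = FALSE], signature = "unclassified", source_mark = "H3K4me1")
  ) |>
    arrange(.data$seq_id, .data$start)
}

#' Build a multi-tissue regulome from per-replicate peak calls
#'
#' Convenience wrapper: runs [merge_reproducible_peaks()] per
#' species x tissue x mark, then [call_regulatory_regions()] per
#' species x tissue, then [cross_tissue_classify()] per species.
#'
#' @param peaks Tibble of per-replicate peaks with `species`, `tissue`,
#'   `mark`, `replicate_id`, `seq_id`, `start`, `end`.
#' @param min_replicates,min_frac Passed to [merge_reproducible_peaks()].
#' @param keep_unclassified Keep `"unclassified"` rows in the output
#'   (default `FALSE`).
#' @return Regulome tibble: one row per regulatory region with `region_id`,
#'   `species`, `tissue`, coordinates, `signature`, and the cross-tissue
#'   columns added by [cross_tissue_classify()].
#' @export
build_regulome <- function(peaks, min_replicates = 2, min_frac = 0.5,
                           keep_unclassified = FALSE) {
  need <- c("species", "tissue", "mark", "replicate_id")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("build_regulome: missing column(s): ", paste(missing, collapse = ", ")))
  }
  consensus <- merge_reproducible_peaks(peaks, min_replicates, min_frac)
  reg <- consensus |>
    group_by(.data$species, .data$tissue) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      sel <- function(m) g[g$mark == m, c("seq_id", "start", "end")]
      call_regulatory_regions(sel("H3K4me3"), sel("H3K27ac"), sel("H3K4me1")) |>
        mutate(species = g$species[1], tissue = g$tissue[1], .before = 1)
    })
  if (!keep_unclassified) reg <- filter(reg, .data$signature != "unclassified")
  reg <- reg |>
    arrange(.data$species, .data$tissue, .data$seq_id, .data$start) |>
    mutate(region_id = paste(.data$species, .data$tissue, .data$signature,
                             row_number(), sep = "."))
  cross_tissue_classify(reg)
}

#' Classify cross-tissue activity, specificity and intra-species dynamics
#'
#' Within each species, two regions in different tissues are linked when
#' either overlaps the other by at least `min_frac` of its own length.
#' Same-signature links define the activity-tissue set of a region (home
#' tissue plus tissues of directly linked partners; no transitive closure
#' unless `transitive = TRUE`). Cross-signature links flag both partners as
#' intra-species dynamic: promoter vs either enhancer class gives
#' `dynamic_PE`, active vs primed enhancer gives `dynamic_E` (`dynamic_PE`
#' takes precedence when both apply).
#'
#' @param regulome Regulome tibble with `region_id`, `species`, `tissue`,
#'   `signature`, `seq_id`, `start`, `end`.
#' @param min_frac Either-side overlap threshold. Default 0.5.
#' @param transitive Propagate activity links through chains of tissues
#'   (sensitivity analysis; default `FALSE`).
#' @return The input with `activity_tissues` (comma-separated, sorted),
#'   `n_activity_tissues`, `specificity`
#'   (`tissue_specific`/`tissue_shared`/`four_tissue_shared`) and
#'   `intra_dynamic` (`none`/`dynamic_PE`/`dynamic_E`) columns.
#' @export
cross_tissue_classify <- function(regulome, min_frac = 0.5, transitive = FALSE) {
  regulome <- validate_intervals(as_tibble(regulome), "cross_tissue_classify")
  out <- regulome |>
    group_by(.data$species) |>
    group_split() |>
    purrr::map_dfr(classify_one_species, min_frac = min_frac,
                   transitive = transitive)
  out
}

classify_one_species <- function(reg, min_frac, transitive) {
  n <- nrow(reg)
  if (n == 0) {
    return(mutate(reg, activity_tissues = character(), n_activity_tissues = integer(),
                  specificity = character(), intra_dynamic = character()))
  }
  pr <- overlap_pairs(reg, reg)
  pr <- pr[pr$idx_a != pr$idx_b &
             reg$tissue[pr$idx_a] != reg$tissue[pr$idx_b] &
             pmax(pr$frac_a, pr$frac_b) >= min_frac, , drop = FALSE]
  same_sig <- reg$signature[pr$idx_a] == reg$signature[pr$idx_b]

  # activity tissues from same-signature links
  act <- lapply(seq_len(n), function(i) reg$tissue[i])
  if (any(same_sig)) {
    links <- pr[same_sig, , drop = FALSE]
    if (transitive) {
      # connected components over same-signature links (union-find)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(links))) {
        ra <- find(links$idx_a[k]); rb <- find(links$idx_b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      comp <- vapply(seq_len(n), find, integer(1))
      act <- lapply(seq_len(n), function(i) unique(reg$tissue[comp == comp[i]]))
    } else {
      extra <- tapply(reg$tissue[links$idx_b], links$idx_a,
                      function(z) unique(z), simplify = FALSE)
      for (nm in names(extra)) {
        i <- as.integer(nm)
        act[[i]] <- unique(c(act[[i]], extra[[nm]]))
      }
    }
  }
  n_act <- lengths(act)
  act_str <- vapply(act, function(z) paste(sort(z), collapse = ","), character(1))

  # intra-species dynamic flags from cross-signature links
  dyn <- rep("none", n)
  if (any(!same_sig)) {
    cross <- pr[!same_sig, , drop = FALSE]
    sig_a <- reg$signature[cross$idx_a]
    sig_b <- reg$signature[cross$idx_b]
    kind <- if_else(sig_a == "AP" | sig_b == "AP", "dynamic_PE", "dynamic_E")
    for (k in c("dynamic_E", "dynamic_PE")) { # PE precedence applied last
      idx <- unique(c(cross$idx_a[kind == k], cross$idx_b[kind == k]))
      dyn[idx] <- k
    }
  }

  mutate(reg,
         activity_tissues = act_str,
         n_activity_tissues = n_act,
         specificity = dplyr::case_when(
           n_act == 1 ~ "tissue_specific",
           n_act == 4 ~ "four_tissue_shared",
           TRUE ~ "tissue_shared"
         ),
         intra_dynamic = dyn)
}

#' Associate enhancers to their nearest active promoter
#'
#' Within each species x tissue, every active and primed enhancer is
#' assigned to the active promoter of the same tissue minimising the
#' edge-to-edge distance (0 when they touch or overlap). Enhancers with no
#' promoter within `max_dist` are left unassigned (`promoter_id` `NA`).
#' Ties break to the lower start coordinate, then lexicographic `seq_id`.
#'
#' @param regulome Regulome tibble (one or more tissues).
#' @param max_dist Maximum assignment distance in bp. Default 1e6.
#' @return Tibble with `region_id` (the enhancer), `promoter_id`,
#'   `distance`, plus `species`/`tissue`.
#' @export
associate_enhancers <- function(regulome, max_dist = 1e6) {
  regulome |>
    group_by(.data$species, .data$tissue) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      enh <- filter(g, .data$signature %in% c("AE", "PE"))
      ap <- filter(g, .data$signature == "AP")
      if (nrow(enh) == 0) return(tibble())
      res <- nearest_within(enh, ap, max_dist)
      tibble(species = g$species[1], tissue = g$tissue[1],
             region_id = enh$region_id,
             promoter_id = if (nrow(ap)) ap$region_id[res$idx] else NA_character_,
             distance = res$distance)
    })
}

# For each row of `query`, index of the nearest `subject` row within
# max_dist (edge distance), deterministic tie-break (lower start, then
# seq_id). Returns tibble(idx, distance) with NA where none qualifies.
nearest_within <- function(query, subject, max_dist) {
  n <- nrow(query)
  out <- tibble(idx = rep(NA_integer_, n), distance = rep(NA_real_, n))
  if (nrow(subject) == 0 || n == 0) return(out)
  hits <- overlap_pairs(query, subject, maxgap = as.integer(max_dist))
  if (nrow(hits) == 0) return(out)
  d <- edge_distance(query[hits$idx_a, ], subject[hits$idx_b, ])
  cand <- tibble(q = hits$idx_a, s = hits$idx_b, d = d,
                 s_start = subject$start[hits$idx_b],
                 s_seq = subject$seq_id[hits$idx_b]) |>
    filter(.data$d <= max_dist) |>
    arrange(.data$q, .data$d, .data$s_start, .data$s_seq) |>
    distinct(.data$q, .keep_all = TRUE)
  out$idx[cand$q] <- cand$s
  out$distance[cand$q] <- cand$d
  out
}

#' Assign active promoters to their nearest gene TSS
#'
#' Each promoter is assigned the gene whose transcription start site (a
#' single-base position) lies nearest by edge distance, within `max_dist`.
#' Ties break to the lower coordinate, then lexicographic `seq_id`. Use the
#' output together with [associate_enhancers()] to propagate gene
#' assignments from promoters to their enhancers.
#'
#' @param promoters Regulome rows with `signature == "AP"` (other rows are
#'   ignored).
#' @param tss Tibble with `seq_id`, `pos` (0-based TSS coordinate) and
#'   `gene_id`.
#' @param max_dist Maximum distance in bp. Default 1e6.
#' @return Tibble `region_id`, `gene_id`, `distance` (`NA` when no TSS in
#'   range).
#' @export
assign_nearest_gene <- function(promoters, tss, max_dist = 1e6) {
  ap <- filter(as_tibble(promoters), .data$signature == "AP")
  tss_iv <- tibble(seq_id = tss$seq_id, start = tss$pos, end = tss$pos + 1)
  res <- nearest_within(ap, tss_iv, max_dist)
  tibble(region_id = ap$region_id,
         gene_id = if_else(is.na(res$idx), NA_character_, tss$gene_id[res$idx]),
         distance = res$distance)
}
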