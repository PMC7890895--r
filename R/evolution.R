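# Cross-species projection of regulatory regions through gapless
# alignment-map blocks, the maintained / recently-evolved partition,
# maintenance-fraction summaries with replicate zero points, evolutionary
# rate regressions, and the signature-switching decomposition of maintained
# regions.

#' Project regulatory regions into another species
#'
#' Every region is intersected with the alignment blocks of its species
#' side; the covered sub-intervals are mapped block-wise (blocks are
#' gapless, so the mapping is a rigid offset) and clustered on the target
#' genome. Pieces landing on the same sequence within `cluster_gap` bp form
#' one cluster; a region whose pieces form more than one cluster maps to
#' multiple locations and is excluded (`multi_mapped_excluded`). Otherwise
#' the region is `unaligned` (no covering block), `maintained` (projected
#' footprint overlaps a target regulatory region of any signature and any
#' tissue by >= 1 bp) or `aligned_no_regulation`.
#'
#' @param regions Regulome tibble for the query species (needs `region_id`,
#'   `seq_id`, `start`, `end`).
#' @param map Alignment-map tibble whose `a` side matches the query species
#'   coordinates (see [read_alignment_map()]).
#' @param target_regulome Regulome tibble for the target species, or `NULL`
#'   to classify alignment only (`maintained` then never assigned).
#' @param cluster_gap Gap in bp within which projected pieces are considered
#'   one location. Default 10000.
#' @return Tibble with `region_id`, `status`, `n_partners` and `partners`
#'   (list-column of target `region_id`s overlapping the footprint).
#' @export
project_regions <- function(regions, map, target_regulome = NULL,
                            cluster_gap = 1e4) {
  regions <- as_tibble(regions)
  n <- nrow(regions)
  blocks_a <- tibble(seq_id = map$seq_a, start = map$start_a, end = map$end_a)
  hits <- overlap_pairs(regions, blocks_a)
  # map covered sub-intervals to the target side
  pieces <- tibble(
    region = hits$idx_a,
    sub_start = pmax(regions$start[hits$idx_a], map$start_a[hits$idx_b]),
    sub_end = pmin(regions$end[hits$idx_a], map$end_a[hits$idx_b]),
    seq_id = map$seq_b[hits$idx_b],
    off = map$start_b[hits$idx_b] - map$start_a[hits$idx_b]
  ) |>
    mutate(start = .data$sub_start + .data$off, end = .data$sub_end + .data$off) |>
    select("region", "seq_id", "start", "end") |>
    arrange(.data$region, .data$seq_id, .data$start)

  # cluster pieces per region: new cluster at sequence change or large gap
  if (nrow(pieces) > 0) {
    np <- nrow(pieces)
    key <- paste(pieces$region, pieces$seq_id)
    run_max_end <- cummax_by(pieces$end, key)
    new_grp <- c(TRUE, key[-1] != key[-np] |
                   (pieces$start[-1] - run_max_end[-np]) > cluster_gap)
    n_clusters <- tapply(cumsum(new_grp), pieces$region, function(z) length(unique(z)))
  } else {
    n_clusters <- integer(0)
  }
  status <- rep("unaligned", n)
  idx_aligned <- as.integer(names(n_clusters))
  status[idx_aligned[n_clusters == 1]] <- "aligned_no_regulation"
  status[idx_aligned[n_clusters > 1]] <- "multi_mapped_excluded"

  partners <- rep(list(character(0)), n)
  if (!is.null(target_regulome) && nrow(pieces) > 0 && nrow(target_regulome) > 0) {
    keep <- pieces$region %in% idx_aligned[n_clusters == 1]
    fp <- pieces[keep, , drop = FALSE]
    if (nrow(fp) > 0) {
      ov <- overlap_pairs(fp, as_tibble(target_regulome))
      if (nrow(ov) > 0) {
        pl <- tapply(target_regulome$region_id[ov$idx_b], fp$region[ov$idx_a],
                     function(z) sort(unique(z)), simplify = FALSE)
        for (nm in names(pl)) partners[[as.integer(nm)]] <- pl[[nm]]
        status[as.integer(names(pl))] <- "maintained"
      }
    }
  }
  tibble(region_id = regions$region_id, status = status,
         n_partners = lengths(partners), partners = partners)
}

# running max of `x` restarted at each change of `g` (g sorted)
cummax_by <- function(x, g) {
  out <- x
  if (length(x) > 1) {
    for (i in 2:length(x)) {
      if (g[i] == g[i - 1] && out[i - 1] > out[i]) out[i] <- out[i - 1]
    }
  }
  out
}

#' Collapse a multi-tissue regulome to species-level regions
#'
#' A region active in several tissues is one genomic element but several
#' regulome rows (one per tissue). For cross-species analyses each element
#' must count once: same-signature rows of one species are merged into
#' their union footprint. The collapsed region keeps the union of its
#' constituents' tissues, the widest specificity
#' (`four_tissue_shared` > `tissue_shared` > `tissue_specific`), the
#' strongest intra-dynamic flag (`dynamic_PE` > `dynamic_E` > `none`) and
#' the `region_id` of the left-most constituent.
#'
#' @param regulome Regulome tibble (one species or several).
#' @return Tibble with one row per species-level region.
#' @export
collapse_species_regions <- function(regulome) {
  regulome <- as_tibble(regulome)
  if (nrow(regulome) == 0) return(regulome)
  regulome |>
    group_by(.data$species, .data$signature) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      m <- merge_intervals(g[, c("seq_id", "start", "end")])
      ov <- overlap_pairs(m, g)
      k <- nrow(m)
      firsts <- tibble(idx_m = ov$idx_a, idx_g = ov$idx_b,
                       start_g = g$start[ov$idx_b],
                       id_g = g$region_id[ov$idx_b]) |>
        arrange(.data$idx_m, .data$start_g, .data$id_g) |>
        distinct(.data$idx_m, .keep_all = TRUE)
      pick <- function(values, choose) {
        out <- tapply(values[ov$idx_b], ov$idx_a, choose)
        unname(out[as.character(seq_len(k))])
      }
      tibble(
        species = g$species[1], signature = g$signature[1],
        seq_id = m$seq_id, start = m$start, end = m$end,
        region_id = firsts$id_g[match(seq_len(k), firsts$idx_m)],
        tissue = pick(g$tissue, function(z) sort(unique(z))[1]),
        activity_tissues = pick(g$tissue, function(z)
          paste(sort(unique(z)), collapse = ",")),
        specificity = pick(g$specificity, function(z) {
          if ("four_tissue_shared" %in% z) "four_tissue_shared"
          else if ("tissue_shared" %in% z) "tissue_shared"
          else "tissue_specific"
        }),
        intra_dynamic = pick(g$intra_dynamic, function(z) {
          if ("dynamic_PE" %in% z) "dynamic_PE"
          else if ("dynamic_E" %in% z) "dynamic_E"
          else "none"
        })
      )
    })
}

#' Project a species pair in both directions with 1-to-1 flags
#'
#' Runs [project_regions()] in both directions of `map` and marks a
#' maintained region as `one_to_one` when it has exactly one partner whose
#' own single partner is the region itself.
#'
#' @inheritParams project_regions
#' @param regulome_i,regulome_j Regulome tibbles for the two species; the
#'   `a` side of `map` must be in `regulome_i` coordinates.
#' @return List with tibbles `ij` and `ji`, each the [project_regions()]
#'   output plus `one_to_one` and `partner_id` (the unique partner when
#'   one-to-one, else `NA`).
#' @export
cross_projection <- function(regulome_i, regulome_j, map, cluster_gap = 1e4) {
  regulome_i <- collapse_species_regions(regulome_i)
  regulome_j <- collapse_species_regions(regulome_j)
  pij <- project_regions(regulome_i, map, regulome_j, cluster_gap)
  pji <- project_regions(regulome_j, flip_alignment_map(map), regulome_i, cluster_gap)
  one2one <- function(p, q) {
    single <- p$n_partners == 1
    partner <- if_else(single, vapply(p$partners, function(z) z[1] %||% NA_character_, character(1)), NA_character_)
    back <- match(partner, q$region_id)
    recip <- !is.na(back) & q$n_partners[back] == 1 &
      vapply(seq_along(back), function(k) {
        if (is.na(back[k])) return(FALSE)
        identical(q$partners[[back[k]]], p$region_id[k])
      }, logical(1))
    p$one_to_one <- single & recip
    p$partner_id <- if_else(p$one_to_one, partner, NA_character_)
    p
  }
  list(ij = one2one(pij, pji), ji = one2one(pji, pij),
       regulome_i = regulome_i, regulome_j = regulome_j)
}

#' Maintained / recently-evolved partition for one species pair
#'
#' For each signature class (optionally further split by tissue
#' specificity), counts the partition of considered regions into unaligned
#' (`P_N`), aligned without regulatory overlap (`P_L`) and maintained
#' (`P_M`), in both directions. `P_A = P_N + P_L + P_M` is the number of
#' considered regions; `P_R = P_N + P_L` the recently evolved ones.
#' Multi-mapping regions and intra-species dynamic regions are excluded
#' from consideration (counted separately in `n_excluded`). The maintenance
#' fraction is the mean over the two directions of
#' `100 * P_M / (P_M + P_L)`, i.e. maintained as a percentage of alignable
#' regions.
#'
#' @inheritParams cross_projection
#' @param divergence_mya Divergence time of the pair in million years.
#' @param by_specificity Also stratify by the query region's `specificity`
#'   (tissue-specific vs shared). Default `FALSE`.
#' @param include_dynamic Keep intra-species dynamic regions in the tally
#'   (default `FALSE`).
#' @return Tibble, one row per signature (x specificity), with directional
#'   counts, `maintenance_fraction_pct` and the per-direction fractions.
#' @export
summarize_pair <- function(regulome_i, regulome_j, map, divergence_mya = NA_real_,
                           cluster_gap = 1e4, by_specificity = FALSE,
                           include_dynamic = FALSE) {
  cp <- cross_projection(regulome_i, regulome_j, map, cluster_gap)
  sp_i <- regulome_i$species[1]
  sp_j <- regulome_j$species[1]
  regulome_i <- cp$regulome_i
  regulome_j <- cp$regulome_j
  one_dir <- function(reg, proj) {
    x <- bind_cols(as_tibble(reg)[, intersect(c("signature", "specificity", "intra_dynamic"), names(reg))],
                   proj[, c("status", "n_partners")])
    if (!include_dynamic && "intra_dynamic" %in% names(x)) {
      x <- filter(x, .data$intra_dynamic == "none")
    }
    keys <- c("signature", if (by_specificity) "specificity")
    x |>
      mutate(specific_group = if (by_specificity)
        if_else(.data$specificity == "tissue_specific", "tissue_specific", "tissue_shared")
        else NA_character_) |>
      group_by(across(dplyr::all_of(if (by_specificity) c("signature", "specific_group") else "signature"))) |>
      summarise(
        n_excluded = sum(.data$status == "multi_mapped_excluded"),
        P_N = sum(.data$status == "unaligned"),
        P_L = sum(.data$status == "aligned_no_regulation"),
        P_M = sum(.data$status == "maintained"),
        .groups = "drop"
      ) |>
      mutate(P_A = .data$P_N + .data$P_L + .data$P_M,
             P_R = .data$P_N + .data$P_L,
             fraction_pct = 100 * .data$P_M / (.data$P_M + .data$P_L))
  }
  di <- one_dir(regulome_i, cp$ij)
  dj <- one_dir(regulome_j, cp$ji)
  keys <- intersect(c("signature", "specific_group"), names(di))
  out <- dplyr::full_join(di, dj, by = keys, suffix = c("_i", "_j")) |>
    mutate(species_i = sp_i, species_j = sp_j,
           divergence_mya = divergence_mya,
           maintenance_fraction_pct =
             (.data$fraction_pct_i + .data$fraction_pct_j) / 2) |>
    dplyr::relocate("species_i", "species_j", "divergence_mya")
  if (by_specificity) out <- rename(out, specificity = "specific_group")
  out
}

#' Replicate-level reproducibility (the divergence-zero point)
#'
#' Compares two regulomes of the same species and tissue built from
#' disjoint replicate subsets: per signature class, the fraction of regions
#' in one subset overlapping (>= 1 bp) any regulatory region of the other,
#' averaged over the two directions and expressed as a percentage.
#'
#' @param regulome_k,regulome_l Regulome tibbles from disjoint replicate
#'   subsets of one species x tissue.
#' @param by_specificity Also stratify by `specificity`.
#' @return Tibble per signature (x specificity) with directional counts and
#'   `fraction_pct`.
#' @export
replicate_zero_point <- function(regulome_k, regulome_l, by_specificity = FALSE) {
  one_dir <- function(a, b) {
    a <- as_tibble(a); b <- as_tibble(b)
    ov <- overlap_pairs(a, b)
    hit <- seq_len(nrow(a)) %in% unique(ov$idx_a)
    keys <- if (by_specificity) c("signature", "specificity") else "signature"
    a <- mutate(a, .hit = hit)
    if (by_specificity) {
      a <- mutate(a, specificity = if_else(.data$specificity == "tissue_specific",
                                           "tissue_specific", "tissue_shared"))
    }
    a |>
      group_by(across(dplyr::all_of(keys))) |>
      summarise(P_I = sum(.data$.hit), P_A = n(), .groups = "drop") |>
      mutate(fraction = 100 * .data$P_I / .data$P_A)
  }
  dk <- one_dir(regulome_k, regulome_l)
  dl <- one_dir(regulome_l, regulome_k)
  keys <- intersect(c("signature", "specificity"), names(dk))
  dplyr::full_join(dk, dl, by = keys, suffix = c("_kl", "_lk")) |>
    mutate(fraction_pct = (.data$fraction_kl + .data$fraction_lk) / 2)
}

#' Fit evolutionary rates by linear regression
#'
#' Ordinary least squares of maintenance (or switching) percentage on
#' divergence time, one line per category, plus the two-way
#' interaction test between each category pair: the ANOVA F-test of the
#' `divergence x category` term in the joint linear model. Zero points
#' (replicate reproducibility at divergence 0) enter as ordinary points.
#'
#' @param points Tibble with `divergence_mya`, `fraction_pct`, `category`.
#' @return Object of class `regevo_rate_fit` with elements `points`, `fits`
#'   (slope %/MY, intercept, per-category lm summaries) and `interactions`
#'   (pairwise interaction p-values). Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_rate <- function(points) {
  points <- as_tibble(points)
  need <- c("divergence_mya", "fraction_pct", "category")
  if (!all(need %in% names(points))) {
    abort("fit_rate: points need divergence_mya, fraction_pct, category")
  }
  cats <- unique(points$category)
  fits <- purrr::map_dfr(cats, function(cc) {
    d <- filter(points, .data$category == cc)
    if (nrow(d) < 2) abort(paste0("fit_rate: category '", cc, "' has < 2 points"))
    if (length(unique(d$divergence_mya)) < 2) {
      abort(paste0("fit_rate: singular design in category '", cc, "'"))
    }
    m <- lm(fraction_pct ~ divergence_mya, data = d)
    sm <- summary(m)
    tibble(category = cc,
           intercept = unname(coef(m)[1]),
           slope = unname(coef(m)[2]),
           slope_se = sm$coefficients["divergence_mya", "Std. Error"],
           r_squared = sm$r.squared,
           n_points = nrow(d))
  })
  inter <- if (length(cats) >= 2) {
    purrr::map_dfr(utils::combn(cats, 2, simplify = FALSE), function(pp) {
      d <- filter(points, .data$category %in% pp)
      m <- lm(fraction_pct ~ divergence_mya * category, data = d)
      a <- anova(m)
      tibble(category_1 = pp[1], category_2 = pp[2],
             interaction_p = a["divergence_mya:category", "Pr(>F)"])
    })
  } else {
    tibble(category_1 = character(), category_2 = character(),
           interaction_p = double())
  }
  structure(list(points = points, fits = fits, interactions = inter),
            class = "regevo_rate_fit")
}

#' @export
print.regevo_rate_fit <- function(x, ...) {
  cat("Evolutionary rate fit (", nrow(x$fits), " categories)\n", sep = "")
  print(x$fits)
  if (nrow(x$interactions) > 0) {
    cat("Divergence x category interactions:\n")
    print(x$interactions)
  }
  invisible(x)
}

#' Signature-switching decomposition of maintained regions
#'
#' Restricted to maintained regions with a 1-to-1 alignment partner (and
#' not intra-species dynamic on the query side), counts per source
#' signature how partners distribute over: same/other stable signatures
#' (`partner_AP`, `partner_AE`, `partner_PE`) and intra-species dynamic
#' partners (`partner_dynPE`, `partner_dynE`). `NP_M` is the row total.
#' Switching fractions: `P_W_pct` — maintained active promoters whose
#' partner is an active or primed enhancer, averaged over the two
#' directions; `AE_W_pct` — maintained active enhancers whose partner is a
#' primed enhancer, reported per direction.
#'
#' @inheritParams cross_projection
#' @return List of class `regevo_signature_decomposition` with `counts`
#'   (per direction x source signature) and `switching` (the directional
#'   fractions).
#' @export
signature_decomposition <- function(regulome_i, regulome_j, map, cluster_gap = 1e4) {
  cp <- cross_projection(regulome_i, regulome_j, map, cluster_gap)
  regulome_i <- cp$regulome_i
  regulome_j <- cp$regulome_j
  one_dir <- function(src, proj, dst, direction) {
    x <- bind_cols(as_tibble(src)[, c("region_id", "signature", "intra_dynamic")],
                   proj[, c("status", "one_to_one", "partner_id")]) |>
      filter(.data$intra_dynamic == "none", .data$status == "maintained",
             .data$one_to_one)
    pd <- as_tibble(dst)[match(x$partner_id, dst$region_id), c("signature", "intra_dynamic")]
    x$partner_class <- dplyr::case_when(
      pd$intra_dynamic == "dynamic_PE" ~ "dynPE",
      pd$intra_dynamic == "dynamic_E" ~ "dynE",
      TRUE ~ pd$signature
    )
    x |>
      count(.data$signature, .data$partner_class) |>
      tidyr::pivot_wider(names_from = "partner_class", values_from = "n",
                         values_fill = 0L, names_prefix = "partner_") |>
      mutate(direction = direction, .before = 1)
  }
  counts <- bind_rows(
    one_dir(regulome_i, cp$ij, regulome_j,
            paste0(regulome_i$species[1], "->", regulome_j$species[1])),
    one_dir(regulome_j, cp$ji, regulome_i,
            paste0(regulome_j$species[1], "->", regulome_i$species[1]))
  )
  for (cc in c("partner_AP", "partner_AE", "partner_PE", "partner_dynPE", "partner_dynE")) {
    if (!cc %in% names(counts)) counts[[cc]] <- 0L
  }
  counts <- counts |>
    mutate(NP_M = .data$partner_AP + .data$partner_AE + .data$partner_PE +
             .data$partner_dynPE + .data$partner_dynE)
  dir_frac <- function(sig, num_cols) {
    rows <- counts[counts$signature == sig, , drop = FALSE]
    if (nrow(rows) == 0) return(tibble())
    num <- rowSums(rows[, num_cols, drop = FALSE])
    tibble(direction = rows$direction, signature = sig,
           switch_fraction = 100 * num / rows$NP_M)
  }
  ap <- dir_frac("AP", c("partner_AE", "partner_PE"))
  ae <- dir_frac("AE", "partner_PE")
  switching <- tibble(
    P_W_pct = if (nrow(ap)) mean(ap$switch_fraction) else NA_real_,
    AE_W_directional = list(ae)
  )
  structure(list(counts = counts, switching = switching),
            class = "regevo_signature_decomposition")
}

#' @export
print.regevo_signature_decomposition <- function(x, ...) {
  cat("Signature decomposition of 1-to-1 maintained regions\n")
  print(x$counts)
  cat("Promoter switch fraction P_W (% of maintained APs, mean of directions): ",
      format(x$switching$P_W_pct), "\n", sep = "")
  invisible(x)
}
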