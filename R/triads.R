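# Outgroup analysis on species triads and the parsimony transition model.
#
# A triad (ingroup_a, ingroup_b, outgroup) restricts attention to genomic
# regions maintained with 1-to-1 alignment in all three species and not
# intra-species dynamic in any of them. The table of (unordered ingroup
# signature pair) x (outgroup signature) counts feeds (i) chi-square tests
# of each ingroup combination against the background outgroup distribution
# and (ii) the ancestral->derived transition matrix, using only
# configurations where parsimony pins the ancestral state: ingroups {X,X}
# with outgroup X (stay) and ingroups {X,Y} with outgroup X (one switch on
# an ingroup branch).

TRIAD_ROWS <- c("AP/AP", "AP/AE", "AP/PE", "AE/AE", "AE/PE", "PE/PE")

#' Build an outgroup triad table
#'
#' Anchors on the first ingroup's regions and keeps those with consistent
#' 1-to-1 maintained alignments to the second ingroup and the outgroup
#' (the two partners must themselves be 1-to-1 aligned to each other), with
#' no species flagging the region intra-species dynamic. Each kept region
#' contributes one count to its unordered ingroup-pair row and outgroup
#' signature column, and to the background (`All`) row.
#'
#' @param regulome_a,regulome_b,regulome_out Regulome tibbles for the two
#'   ingroup species and the outgroup.
#' @param map_ab,map_ao,map_bo Alignment maps with the `a` side in the
#'   coordinates of the first-named species of each pair.
#' @param cluster_gap Passed to [project_regions()].
#' @return Tibble of class `regevo_triad_table`: `ingroup_pair` (six
#'   unordered pairs plus `"All"`), `out_AP`, `out_AE`, `out_PE`, `total`.
#' @export
build_triad_table <- function(regulome_a, regulome_b, regulome_out,
                              map_ab, map_ao, map_bo, cluster_gap = 1e4) {
  cab <- cross_projection(regulome_a, regulome_b, map_ab, cluster_gap)
  cao <- cross_projection(regulome_a, regulome_out, map_ao, cluster_gap)
  cbo <- cross_projection(regulome_b, regulome_out, map_bo, cluster_gap)
  # species-level (tissue-collapsed) regions; identical across the pairwise
  # projections by construction
  a <- cab$regulome_i
  regulome_b <- cab$regulome_j
  regulome_out <- cao$regulome_j
  keep <- a$intra_dynamic == "none" &
    cab$ij$status == "maintained" & cab$ij$one_to_one &
    cao$ij$status == "maintained" & cao$ij$one_to_one
  idx <- which(keep)
  pb <- cab$ij$partner_id[idx]
  po <- cao$ij$partner_id[idx]
  jb <- match(pb, regulome_b$region_id)
  jo <- match(po, regulome_out$region_id)
  ok <- regulome_b$intra_dynamic[jb] == "none" &
    regulome_out$intra_dynamic[jo] == "none"
  # triangle consistency: the b partner must be 1-to-1 maintained to the
  # same outgroup region
  kb <- match(pb, cbo$ij$region_id)
  ok <- ok & cbo$ij$one_to_one[kb] & !is.na(cbo$ij$partner_id[kb]) &
    cbo$ij$partner_id[kb] == po
  idx <- idx[ok]; jb <- jb[ok]; jo <- jo[ok]

  sig_a <- a$signature[idx]
  sig_b <- regulome_b$signature[jb]
  sig_o <- regulome_out$signature[jo]
  pair <- purrr::map2_chr(sig_a, sig_b, function(x, y) {
    paste(SIGNATURES[sort(match(c(x, y), SIGNATURES))], collapse = "/")
  })
  tab <- tibble(ingroup_pair = pair, out = sig_o) |>
    count(.data$ingroup_pair, .data$out) |>
    tidyr::pivot_wider(names_from = "out", values_from = "n", values_fill = 0L,
                       names_prefix = "out_")
  full <- tibble(ingroup_pair = TRIAD_ROWS)
  tab <- left_join(full, tab, by = "ingroup_pair")
  for (cc in c("out_AP", "out_AE", "out_PE")) {
    if (!cc %in% names(tab)) tab[[cc]] <- 0L
    tab[[cc]][is.na(tab[[cc]])] <- 0L
  }
  tab <- tab[, c("ingroup_pair", "out_AP", "out_AE", "out_PE")]
  all_row <- tibble(ingroup_pair = "All",
                    out_AP = sum(tab$out_AP), out_AE = sum(tab$out_AE),
                    out_PE = sum(tab$out_PE))
  out <- bind_rows(tab, all_row) |>
    mutate(total = .data$out_AP + .data$out_AE + .data$out_PE)
  class(out) <- c("regevo_triad_table", class(out))
  out
}

#' Chi-square test of an ingroup row against the background
#'
#' Tests whether the outgroup-signature distribution of one ingroup
#' combination differs from the background (`All`) distribution: expected
#' counts are the background proportions scaled to the row total,
#' `chisq = sum((obs - exp)^2 / exp)` with 2 degrees of freedom, two-tailed
#' p from the upper tail.
#'
#' @param table A `regevo_triad_table`.
#' @param rows Ingroup pairs to test (default: all six).
#' @return Tibble with `ingroup_pair`, `chisq`, `df`, `p_value`.
#' @export
triad_chi_square <- function(table, rows = TRIAD_ROWS) {
  bg <- table[table$ingroup_pair == "All", ]
  if (nrow(bg) != 1) abort("triad_chi_square: table lacks an 'All' background row")
  p_bg <- unlist(bg[, c("out_AP", "out_AE", "out_PE")]) / bg$total
  purrr::map_dfr(rows, function(rw) {
    obs <- table[table$ingroup_pair == rw, ]
    if (nrow(obs) != 1) abort(paste0("triad_chi_square: no row '", rw, "'"))
    o <- as.numeric(unlist(obs[, c("out_AP", "out_AE", "out_PE")]))
    if (sum(o) == 0) abort(paste0("triad_chi_square: row '", rw, "' has zero total"))
    e <- p_bg * sum(o)
    if (any(e == 0)) {
      abort(paste0("triad_chi_square: zero expected count in row '", rw,
                   "'; merge rows or drop the empty outgroup class"))
    }
    stat <- sum((o - e)^2 / e)
    tibble(ingroup_pair = rw, chisq = stat, df = 2L,
           p_value = pchisq(stat, df = 2, lower.tail = FALSE))
  })
}

#' Estimate the ancestral->derived transition model from triad tables
#'
#' Uses only parsimony-resolvable configurations: for ancestral state X,
#' `X -> X` counts come from row `{X,X}` with outgroup X, and `X -> Y`
#' (Y != X) from row `{X,Y}` with outgroup X. Configurations whose ancestral
#' state is ambiguous (e.g. ingroups `{X,X}` with outgroup Y) are ignored.
#' Multiple tables are pooled by summing raw counts before row
#' normalisation.
#'
#' @param tables A `regevo_triad_table` or a list of them.
#' @return Object of class `regevo_transition_model`: a list with `prob`
#'   (3x3 row-stochastic matrix over AP/AE/PE), `counts` (raw parsimony
#'   counts) and `totals` (row sums). Rows with zero total are `NA` and
#'   flagged via a warning.
#' @export
estimate_transition_model <- function(tables) {
  if (inherits(tables, "regevo_triad_table")) tables <- list(tables)
  counts <- matrix(0, 3, 3, dimnames = list(SIGNATURES, SIGNATURES))
  for (tab in tables) {
    for (anc in SIGNATURES) {
      for (der in SIGNATURES) {
        pair <- paste(SIGNATURES[sort(match(c(anc, der), SIGNATURES))],
                      collapse = "/")
        row <- tab[tab$ingroup_pair == pair, ]
        counts[anc, der] <- counts[anc, der] +
          as.numeric(row[[paste0("out_", anc)]])
      }
    }
  }
  totals <- rowSums(counts)
  prob <- counts / totals
  if (any(totals == 0)) {
    warn(paste0("estimate_transition_model: zero parsimony counts for state(s) ",
                paste(SIGNATURES[totals == 0], collapse = ", "),
                "; corresponding rows are NA"))
  }
  structure(list(prob = prob, counts = counts, totals = totals),
            class = "regevo_transition_model")
}

#' @export
print.regevo_transition_model <- function(x, digits = 3, ...) {
  cat("Ancestral -> derived signature transition probabilities\n")
  print(round(x$prob, digits))
  cat("Parsimony-resolvable counts per ancestral state: ",
      paste(names(x$totals), x$totals, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
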