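# Forward simulator of regulome evolution on a phylogeny.
#
# Ancestral regulatory regions are placed on a small multi-sequence genome,
# inherit survival (linear-in-time loss) and signature switching (a
# row-stochastic per-MY matrix raised to the branch length) along each
# branch, and are emitted as per-replicate histone-mark peaks with boundary
# jitter, replicate dropout and irreproducible noise peaks. Pairwise
# alignment maps are derived from shared ancestral blocks with
# divergence-dependent alignability loss; L1/L2 (and other) repeat elements
# are placed with a configurable odds ratio favouring tissue-specific
# regions. Ground truth is recorded for every region and species.

#' Simulation configuration
#'
#' Builds a configuration for [simulate_regulome_evolution()]. Defaults
#' describe a three-species rodent-like triad (two ingroups split 25 MY
#' ago, outgroup at 82 MY), four tissues, three histone marks and three
#' biological replicates.
#'
#' @param newick Tree with branch lengths in million years.
#' @param tissues Tissue names.
#' @param n_regions Number of ancestral regulatory regions.
#' @param n_replicates Biological replicates per species x tissue x mark.
#' @param region_length_range Min/max region length (bp).
#' @param signature_proportions Named proportions over AP/AE/PE.
#' @param tissue_specific_fraction Per signature, probability that a region
#'   is active in exactly one tissue (otherwise 2-4 tissues).
#' @param loss_slope Percent of regions lost per MY of branch, named by
#'   `tissue_specific` / `tissue_shared`.
#' @param switch_matrix Row-stochastic 3x3 per-MY signature transition
#'   matrix (rows/cols AP, AE, PE).
#' @param peak_jitter_sd Gaussian SD (bp) of per-replicate peak boundary
#'   jitter.
#' @param replicate_dropout Probability a peak is missing from a replicate.
#' @param noise_peak_rate Irreproducible noise peaks per Mb per
#'   species x tissue x mark x replicate.
#' @param n_seqs,seq_length Number and length (bp) of genome sequences.
#' @param block_size Ancestral alignment-block size (bp); regions never
#'   cross block boundaries.
#' @param indel_rate Mean inserted bp between consecutive blocks per
#'   species (Poisson), drifting coordinates apart.
#' @param alignability_loss Probability per MY of divergence that a block
#'   is unalignable for a species pair.
#' @param repeat_families List of repeat families; each a list with
#'   `class`, `subgroup`, `density_per_mb`, `length_range`,
#'   `divergence_mean`, `divergence_sd`, `odds_tissue_specific` (placement
#'   odds vs tissue-shared regions among region-targeted elements).
#' @param repeat_target_prob Probability a repeat element is placed
#'   overlapping a regulatory region (vs uniformly in the background).
#' @param min_gap Minimum spacing between placed regions (bp).
#' @return A list of class `regevo_sim_config`.
#' @export
sim_config <- function(newick = "((ingroupA:25,ingroupB:25):57,outgroup:82);",
                       tissues = c("liver", "muscle", "brain", "testis"),
                       n_regions = 2000,
                       n_replicates = 3,
                       region_length_range = c(300, 1500),
                       signature_proportions = c(AP = 0.30, AE = 0.35, PE = 0.35),
                       tissue_specific_fraction = c(AP = 0.50, AE = 0.76, PE = 0.83),
                       loss_slope = c(tissue_specific = 0.45, tissue_shared = 0.25),
                       switch_matrix = default_switch_matrix(),
                       peak_jitter_sd = 30,
                       replicate_dropout = 0.05,
                       noise_peak_rate = 5,
                       n_seqs = 3,
                       seq_length = 1e6,
                       block_size = 5e4,
                       indel_rate = 30,
                       alignability_loss = 0.002,
                       repeat_families = default_repeat_families(),
                       repeat_target_prob = 0.4,
                       min_gap = 200) {
  switch_matrix <- as.matrix(switch_matrix)
  dimnames(switch_matrix) <- list(SIGNATURES, SIGNATURES)
  if (any(switch_matrix < 0) || any(abs(rowSums(switch_matrix) - 1) > 1e-9)) {
    abort("sim_config: switch_matrix rows must be non-negative and sum to 1")
  }
  if (abs(sum(signature_proportions) - 1) > 1e-9) {
    abort("sim_config: signature_proportions must sum to 1")
  }
  cfg <- list(
    newick = newick, tissues = tissues, n_regions = n_regions,
    n_replicates = n_replicates, region_length_range = region_length_range,
    signature_proportions = signature_proportions,
    tissue_specific_fraction = tissue_specific_fraction,
    loss_slope = loss_slope, switch_matrix = switch_matrix,
    peak_jitter_sd = peak_jitter_sd, replicate_dropout = replicate_dropout,
    noise_peak_rate = noise_peak_rate, n_seqs = n_seqs,
    seq_length = seq_length, block_size = block_size,
    indel_rate = indel_rate, alignability_loss = alignability_loss,
    repeat_families = repeat_families,
    repeat_target_prob = repeat_target_prob, min_gap = min_gap
  )
  structure(cfg, class = "regevo_sim_config")
}

default_switch_matrix <- function() {
  # per-MY transition intensities; promoters the most stable state,
  # enhancer -> promoter more common than the reverse
  m <- matrix(c(
    0.9980, 0.0013, 0.0007,
    0.0030, 0.9950, 0.0020,
    0.0010, 0.0030, 0.9960
  ), 3, 3, byrow = TRUE, dimnames = list(SIGNATURES, SIGNATURES))
  m
}

default_repeat_families <- function() {
  list(
    L1 = list(class = "LINE", subgroup = "L1", density_per_mb = 40,
              length_range = c(500, 6000), divergence_mean = 15,
              divergence_sd = 5, odds_tissue_specific = 2),
    L2 = list(class = "LINE", subgroup = "L2", density_per_mb = 30,
              length_range = c(100, 500), divergence_mean = 30,
              divergence_sd = 4, odds_tissue_specific = 1),
    B1 = list(class = "SINE", subgroup = "B1", density_per_mb = 30,
              length_range = c(100, 200), divergence_mean = 20,
              divergence_sd = 6, odds_tissue_specific = 1)
  )
}

# fractional matrix power via eigendecomposition; falls back to repeated
# multiplication over whole MYs when the decomposition misbehaves
switch_matrix_power <- function(P, t) {
  if (t == 0) {
    return(matrix(diag(3), 3, 3, dimnames = list(SIGNATURES, SIGNATURES)))
  }
  e <- eigen(P)
  M <- tryCatch({
    V <- e$vectors
    out <- V %*% diag(as.complex(e$values)^t) %*% solve(V)
    if (max(abs(Im(out))) > 1e-9) stop("complex")
    out <- Re(out)
    if (min(out) < -1e-9) stop("negative")
    out
  }, error = function(err) {
    out <- diag(3)
    for (k in seq_len(max(0, round(t)))) out <- out %*% P
    out
  })
  M[M < 0] <- 0
  M <- M / rowSums(M)
  dimnames(M) <- list(SIGNATURES, SIGNATURES)
  M
}

#' Simulate regulome evolution with recorded ground truth
#'
#' Runs the forward model described in [sim_config()] and returns all the
#' inputs the analysis pipeline consumes, plus the truth tables tests
#' compare against. Deterministic for a given `config` and `seed`.
#'
#' @param config A `regevo_sim_config`.
#' @param seed Integer seed.
#' @return List of class `regevo_sim`: `peaks` (per-replicate peak calls
#'   with a `noise` flag), `truth` (per species x region: presence,
#'   signature, coordinates, tissues), `maps` (pairwise alignment blocks),
#'   `repeats`, `tss`, `divergence` (pairwise times), `genome` (per-species
#'   sequence lengths), `species`, and the `config`.
#' @export
simulate_regulome_evolution <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "regevo_sim_config"))
  withr::with_seed(seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  tree <- ape::read.tree(text = cfg$newick)
  if (is.null(tree$edge.length)) abort("simulate: tree needs branch lengths")
  species <- tree$tip.label
  n_tip <- length(species)

  # --- ancestral region placement (block-confined, capacity-aware) ---
  n <- cfg$n_regions
  lens <- round(runif(n, cfg$region_length_range[1], cfg$region_length_range[2]))
  sig <- sample(SIGNATURES, n, replace = TRUE, prob = cfg$signature_proportions)
  n_tissue <- ifelse(runif(n) < cfg$tissue_specific_fraction[sig], 1L,
                     sample(2:length(cfg$tissues), n, replace = TRUE))
  tissue_sets <- vapply(n_tissue, function(k) {
    paste(sort(sample(cfg$tissues, k)), collapse = ",")
  }, character(1))

  blocks <- tidyr::crossing(
    seq_id = paste0("seq", seq_len(cfg$n_seqs)),
    block_start = seq(0, cfg$seq_length - 1, by = cfg$block_size)
  ) |>
    mutate(block_end = pmin(.data$block_start + cfg$block_size, cfg$seq_length),
           block = row_number())
  capacity <- blocks$block_end - blocks$block_start
  need <- lens + cfg$min_gap
  if (sum(need) > 0.9 * sum(capacity)) {
    abort("simulate: infeasible config — regions exceed 90% of genome capacity")
  }
  remaining <- capacity - cfg$min_gap
  block_of <- integer(n)
  for (i in sample.int(n)) { # random order, capacity-aware block choice
    ok <- which(remaining >= need[i])
    if (length(ok) == 0) abort("simulate: could not place all regions; lower n_regions")
    b <- ok[sample.int(length(ok), 1)]
    block_of[i] <- b
    remaining[b] <- remaining[b] - need[i]
  }
  # within-block positions: spread slack uniformly between regions
  anc_start <- integer(n)
  for (b in unique(block_of)) {
    ids <- which(block_of == b)
    ids <- ids[sample.int(length(ids))]
    m <- length(ids)
    slack <- (blocks$block_end[b] - blocks$block_start[b]) -
      sum(lens[ids]) - (m + 1) * cfg$min_gap
    u <- runif(m + 1)
    gaps <- cfg$min_gap + floor(u / sum(u) * slack)
    pos <- blocks$block_start[b] + cumsum(gaps[seq_len(m)]) +
      c(0, cumsum(lens[ids]))[seq_len(m)]
    anc_start[ids] <- pos
  }
  anc <- tibble(
    region = seq_len(n), seq_id = blocks$seq_id[block_of],
    start = anc_start, end = anc_start + lens, block = block_of,
    signature = sig, tissues = tissue_sets, n_tissues = n_tissue,
    specificity = if_else(n_tissue == 1L, "tissue_specific", "tissue_shared")
  )

  # --- evolve presence and signature along the tree ---
  n_node <- max(tree$edge)
  root <- n_tip + 1L
  state <- vector("list", n_node)
  state[[root]] <- list(present = rep(TRUE, n), signature = anc$signature)
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE] # parents first
  edge_len <- tree$edge.length[order(tree$edge[, 1])]
  slope <- unname(cfg$loss_slope[anc$specificity])
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; chd <- edges[k, 2]; t <- edge_len[k]
    ps <- state[[par]]
    p_loss <- pmin(1, pmax(0, slope * t / 100))
    present <- ps$present & (runif(n) >= p_loss)
    Mt <- switch_matrix_power(cfg$switch_matrix, t)
    sig_new <- ps$signature
    for (s in SIGNATURES) {
      ii <- which(ps$signature == s & present)
      if (length(ii) > 0) {
        sig_new[ii] <- sample(SIGNATURES, length(ii), replace = TRUE,
                              prob = Mt[s, ])
      }
    }
    state[[chd]] <- list(present = present, signature = sig_new)
  }

  # --- per-species coordinates: insertion-only drift between blocks ---
  n_block <- nrow(blocks)
  offsets <- matrix(0L, n_block, n_tip, dimnames = list(NULL, species))
  genome <- tibble()
  for (sp in seq_len(n_tip)) {
    ind <- rpois(n_block, cfg$indel_rate)
    off <- as.integer(cumsum(c(0L, ind[-n_block])))
    # restart offsets at 0 on each new sequence
    first_of_seq <- !duplicated(blocks$seq_id)
    for (q in which(first_of_seq)) {
      base <- off[q]
      same <- blocks$seq_id == blocks$seq_id[q]
      off[same] <- off[same] - base
    }
    offsets[, sp] <- off
    genome <- bind_rows(genome, blocks |>
      group_by(.data$seq_id) |>
      summarise(length = max(.data$block_end + off[.data$block]), .groups = "drop") |>
      mutate(species = species[sp], .before = 1))
  }

  # --- truth table (species coordinates) ---
  truth <- purrr::map_dfr(seq_len(n_tip), function(sp) {
    st <- state[[sp]]
    off <- offsets[anc$block, sp]
    tibble(species = species[sp], region = anc$region,
           seq_id = anc$seq_id,
           start = anc$start + off, end = anc$end + off,
           present = st$present,
           signature = if_else(st$present, st$signature, NA_character_),
           ancestral_signature = anc$signature,
           tissues = anc$tissues, n_tissues = anc$n_tissues,
           specificity = anc$specificity)
  })

  # --- pairwise divergence times and alignment maps ---
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth[seq_len(n_tip)])
  pair_div <- function(i, j) {
    mrca <- ape::getMRCA(tree, c(species[i], species[j]))
    (total - depth[mrca])
  }
  pairs <- utils::combn(n_tip, 2, simplify = FALSE)
  divergence <- purrr::map_dfr(pairs, function(pp) {
    tibble(species_a = species[pp[1]], species_b = species[pp[2]],
           divergence_mya = pair_div(pp[1], pp[2]))
  })
  maps <- purrr::map_dfr(pairs, function(pp) {
    i <- pp[1]; j <- pp[2]
    t <- pair_div(i, j)
    alive <- runif(n_block) < (1 - cfg$alignability_loss)^t
    b <- blocks[alive, , drop = FALSE]
    tibble(species_a = species[i], seq_a = b$seq_id,
           start_a = b$block_start + offsets[b$block, i],
           end_a = b$block_end + offsets[b$block, i],
           species_b = species[j], seq_b = b$seq_id,
           start_b = b$block_start + offsets[b$block, j],
           end_b = b$block_end + offsets[b$block, j])
  })

  # --- peaks ---
  mark_sets <- list(AP = c("H3K4me3", "H3K27ac"),
                    AE = c("H3K27ac", "H3K4me1"),
                    PE = "H3K4me1")
  base <- truth |>
    filter(.data$present) |>
    mutate(tissue = strsplit(.data$tissues, ",", fixed = TRUE)) |>
    tidyr::unnest("tissue")
  base <- base |>
    mutate(mark = purrr::map(.data$signature, ~ mark_sets[[.x]])) |>
    tidyr::unnest("mark")
  R <- cfg$n_replicates
  reps <- base[rep(seq_len(nrow(base)), each = R), , drop = FALSE]
  reps$replicate_id <- rep(paste0("rep", seq_len(R)), times = nrow(base))
  keep <- runif(nrow(reps)) >= cfg$replicate_dropout
  reps <- reps[keep, , drop = FALSE]
  js <- function(m) as.integer(round(rnorm(m, 0, cfg$peak_jitter_sd)))
  m <- nrow(reps)
  p_start <- pmax(0L, reps$start + js(m))
  p_end <- pmax(p_start + 50L, reps$end + js(m))
  peaks <- tibble(species = reps$species, tissue = reps$tissue,
                  mark = reps$mark, replicate_id = reps$replicate_id,
                  seq_id = reps$seq_id, start = p_start, end = p_end,
                  region = reps$region, noise = FALSE)

  # --- irreproducible noise peaks ---
  noise <- simulate_noise_peaks(cfg, truth, genome, species)
  peaks <- bind_rows(peaks, noise)

  # --- repeats ---
  repeats <- simulate_repeats(cfg, truth, genome, species)

  # --- TSS annotation: one gene per ancestrally promoter-type region ---
  tss <- truth |>
    filter(.data$ancestral_signature == "AP") |>
    mutate(pos = .data$start, gene_id = paste0("gene", .data$region)) |>
    select("species", "seq_id", "pos", "gene_id")

  structure(list(
    peaks = peaks, truth = truth, maps = maps, repeats = repeats, tss = tss,
    divergence = divergence, genome = genome, species = species, config = cfg
  ), class = "regevo_sim")
}

# noise peaks: per species x tissue x mark x replicate, Poisson count per
# Mb, placed to overlap neither truth regions (500 bp buffer) nor any other
# noise peak of the same species/tissue/mark, so they can never form a
# reproducible pair
simulate_noise_peaks <- function(cfg, truth, genome, species) {
  out <- list()
  for (sp in species) {
    g <- genome[genome$species == sp, ]
    mb <- sum(g$length) / 1e6
    tr <- truth[truth$species == sp & truth$present, ]
    # keep noise clear of true peaks (incl. jitter) so a noise peak can
    # never reach a reciprocal-50% partnership with a reproducible peak
    buf <- 4 * cfg$peak_jitter_sd + 50
    avoid_base <- tibble(seq_id = tr$seq_id,
                         start = pmax(0, tr$start - buf), end = tr$end + buf)
    gaps0 <- interval_complement(avoid_base,
                                 tibble(seq_id = g$seq_id, length = g$length))
    for (ti in cfg$tissues) {
      for (mk in MARKS) {
        pool <- gaps0
        for (rp in seq_len(cfg$n_replicates)) {
          k <- rpois(1, cfg$noise_peak_rate * mb)
          if (k == 0) next
          lens <- round(runif(k, 200, 800))
          res <- place_in_gap_pool(lens, pool)
          pool <- res$pool
          out[[length(out) + 1]] <- mutate(
            res$placed, species = sp, tissue = ti, mark = mk,
            replicate_id = paste0("rep", rp), region = NA_integer_, noise = TRUE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(species = character(), tissue = character(), mark = character(),
                  replicate_id = character(), seq_id = character(),
                  start = integer(), end = integer(), region = integer(),
                  noise = logical()))
  }
  bind_rows(out)[, c("species", "tissue", "mark", "replicate_id",
                     "seq_id", "start", "end", "region", "noise")]
}

# place intervals of the given lengths into a pool of free gaps, choosing
# a gap with probability proportional to the number of admissible starts
# and splitting it around the placement; the shrinking pool keeps all
# placements mutually disjoint
place_in_gap_pool <- function(lens, pool) {
  gs <- pool$start; ge <- pool$end; gseq <- pool$seq_id
  out_seq <- character(length(lens))
  out_start <- integer(length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    w <- (ge - gs) - L + 1
    ok <- which(w > 0)
    if (length(ok) == 0) {
      abort("simulate: could not place noise peak; genome too crowded")
    }
    gi <- ok[sample.int(length(ok), 1, prob = w[ok])]
    s <- gs[gi] + sample.int(w[gi], 1) - 1L
    out_seq[i] <- gseq[gi]
    out_start[i] <- s
    # split the gap around [s, s + L)
    old_end <- ge[gi]
    ge[gi] <- s
    gs <- c(gs, s + L); ge <- c(ge, old_end); gseq <- c(gseq, gseq[gi])
  }
  list(placed = tibble(seq_id = out_seq, start = out_start, end = out_start + lens),
       pool = tibble(seq_id = gseq, start = gs, end = ge))
}

# repeat elements per species: region-targeted with odds favouring
# tissue-specific regions, otherwise uniform background
simulate_repeats <- function(cfg, truth, genome, species) {
  purrr::map_dfr(species, function(sp) {
    g <- genome[genome$species == sp, ]
    mb <- sum(g$length) / 1e6
    tr <- truth[truth$species == sp & truth$present, ]
    ts <- tr[tr$specificity == "tissue_specific", ]
    sh <- tr[tr$specificity != "tissue_specific", ]
    purrr::map_dfr(names(cfg$repeat_families), function(fam) {
      fc <- cfg$repeat_families[[fam]]
      k <- round(fc$density_per_mb * mb)
      if (k == 0) return(tibble())
      lens <- round(runif(k, fc$length_range[1], fc$length_range[2]))
      on_region <- runif(k) < cfg$repeat_target_prob &
        (nrow(ts) + nrow(sh)) > 0
      w_ts <- fc$odds_tissue_specific * nrow(ts)
      w_sh <- nrow(sh)
      use_ts <- (runif(k) < (w_ts / (w_ts + w_sh)) & nrow(ts) > 0) | nrow(sh) == 0
      # region-targeted starts: uniform over positions overlapping the
      # target region by >= 1 bp
      tgt_row <- integer(k)
      tgt_row[on_region & use_ts] <- sample.int(max(1, nrow(ts)),
                                                sum(on_region & use_ts), replace = TRUE)
      tgt_row[on_region & !use_ts] <- sample.int(max(1, nrow(sh)),
                                                 sum(on_region & !use_ts), replace = TRUE)
      seq_id <- character(k)
      start <- integer(k)
      if (any(on_region)) {
        ii <- which(on_region)
        tg <- ifelse(use_ts[ii], "ts", "sh")
        r_start <- ifelse(tg == "ts", ts$start[tgt_row[ii]], sh$start[tgt_row[ii]])
        r_end <- ifelse(tg == "ts", ts$end[tgt_row[ii]], sh$end[tgt_row[ii]])
        r_seq <- ifelse(tg == "ts", ts$seq_id[tgt_row[ii]], sh$seq_id[tgt_row[ii]])
        lo <- r_start - lens[ii] + 1
        hi <- r_end - 1
        s <- lo + floor(runif(length(ii)) * (hi - lo + 1))
        seq_id[ii] <- r_seq
        start[ii] <- pmax(0L, as.integer(s))
      }
      if (any(!on_region)) {
        ii <- which(!on_region)
        gi <- sample.int(nrow(g), length(ii), replace = TRUE, prob = g$length)
        s <- floor(runif(length(ii)) * pmax(1, g$length[gi] - lens[ii]))
        seq_id[ii] <- g$seq_id[gi]
        start[ii] <- as.integer(s)
      }
      res <- tibble(seq_id = seq_id, start = start, end = start + lens)
      mutate(res, species = sp,
             strand = sample(c("+", "-"), k, replace = TRUE),
             repeat_class = fc$class, subgroup = fc$subgroup,
             pct_divergence = pmin(100, pmax(0, rnorm(k, fc$divergence_mean,
                                                      fc$divergence_sd))))
    })
  })
}

#' @export
print.regevo_sim <- function(x, ...) {
  cat("Simulated regulome evolution: ", length(x$species), " species (",
      paste(x$species, collapse = ", "), "), ",
      max(x$truth$region), " ancestral regions, ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the file dialects the readers consume: one peak BED per
#' species x tissue x mark x replicate, one alignment map per species pair,
#' one repeat table per species, a TSS BED per species, the divergence-time
#' table, the truth table and the resolved configuration (YAML).
#'
#' @param sim A `regevo_sim` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wp <- function(p) { paths <<- c(paths, p); p }
  sim$peaks |>
    group_by(.data$species, .data$tissue, .data$mark, .data$replicate_id) |>
    group_split() |>
    purrr::walk(function(g) {
      f <- file.path(dir, paste0("peaks_", g$species[1], "_", g$tissue[1], "_",
                                 g$mark[1], "_", g$replicate_id[1], ".bed"))
      write_bed(arrange(g[, c("seq_id", "start", "end")], .data$seq_id, .data$start), wp(f))
    })
  sim$maps |>
    group_by(.data$species_a, .data$species_b) |>
    group_split() |>
    purrr::walk(function(g) {
      f <- file.path(dir, paste0("map_", g$species_a[1], "_", g$species_b[1], ".tsv"))
      write_alignment_map(g, wp(f))
    })
  sim$repeats |>
    group_by(.data$species) |>
    group_split() |>
    purrr::walk(function(g) {
      f <- file.path(dir, paste0("repeats_", g$species[1], ".tsv"))
      write_repeat_table(g, wp(f))
    })
  sim$tss |>
    group_by(.data$species) |>
    group_split() |>
    purrr::walk(function(g) {
      f <- file.path(dir, paste0("tss_", g$species[1], ".bed"))
      write_bed(tibble(seq_id = g$seq_id, start = g$pos, end = g$pos + 1,
                       name = g$gene_id), wp(f))
    })
  readr::write_tsv(sim$divergence, wp(file.path(dir, "divergence.tsv")))
  readr::write_tsv(sim$truth, wp(file.path(dir, "truth.tsv")))
  cfg <- sim$config
  cfg$switch_matrix <- as.vector(t(cfg$switch_matrix))
  cfg$signature_switch_note <- "switch matrix serialised row-major (AP,AE,PE); branch transitions use eigen fractional powers with a whole-MY fallback"
  yaml::write_yaml(unclass(cfg), wp(file.path(dir, "config.yaml")))
  invisible(paths)
}

#' Bundled small fixtures
#'
#' Generates one of three deterministic small datasets:
#' \describe{
#'   \item{tiny}{2 species x 2 tissues x 3 marks x 3 replicates; exercises
#'     peak merging, signature calling and tissue logic.}
#'   \item{triad}{3 species on the default triad tree, 2000 regions; for
#'     outgroup/transition-model analyses.}
#'   \item{enrichment}{2 species with an L1 placement odds ratio of 3 in
#'     tissue-specific regions; for repeat-enrichment statistics.}
#' }
#'
#' @param name One of `"tiny"`, `"triad"`, `"enrichment"`.
#' @param seed Integer seed. Default 42.
#' @return A `regevo_sim` object.
#' @export
make_fixture <- function(name, seed = 42) {
  cfg <- switch(name,
    tiny = sim_config(
      newick = "(speciesA:20,speciesB:20);",
      tissues = c("liver", "brain"), n_regions = 300,
      n_seqs = 3, seq_length = 2e5, noise_peak_rate = 3
    ),
    triad = sim_config(n_regions = 2000),
    enrichment = {
      fams <- default_repeat_families()
      fams$L1$odds_tissue_specific <- 3
      sim_config(newick = "(speciesA:20,speciesB:20);", n_regions = 1500,
                 repeat_families = fams)
    },
    abort("make_fixture: unknown fixture; options are tiny, triad, enrichment")
  )
  simulate_regulome_evolution(cfg, seed = seed)
}
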