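# End-to-end orchestration: call -> tissue -> evolve -> triad -> repeats on
# an in-memory simulated dataset or a directory of input files, with a
# manifest of written artifacts and resolved-parameter logging.

#' Pipeline configuration
#'
#' Collects inputs, stage toggles and every analysis threshold in one
#' place. Thresholds default to the values used throughout the package
#' (reciprocal replicate overlap 0.5, signature-call coverage 0.5,
#' cross-tissue either-side overlap 0.5, 1 Mb association distance, 10 kb
#' projection cluster gap, display minimum of 100, Bonferroni over all
#' matrix cells).
#'
#' @param input A `regevo_sim` object or a directory written by
#'   [write_simulation()].
#' @param out_dir Output directory for stage artifacts.
#' @param stages Character subset of
#'   `c("call", "tissue", "evolve", "triad", "repeats")`.
#' @param min_replicates,overlap_frac,max_assoc_dist,cluster_gap,min_display
#'   Analysis thresholds (see module functions).
#' @param triad Character vector of three species
#'   `(ingroup_a, ingroup_b, outgroup)`; defaults to the first three
#'   species when available.
#' @return List of class `regevo_pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = tempfile("regevo_out"),
                            stages = c("call", "tissue", "evolve", "triad", "repeats"),
                            min_replicates = 2, overlap_frac = 0.5,
                            max_assoc_dist = 1e6, cluster_gap = 1e4,
                            min_display = 100, triad = NULL) {
  structure(list(input = input, out_dir = out_dir, stages = stages,
                 min_replicates = min_replicates, overlap_frac = overlap_frac,
                 max_assoc_dist = max_assoc_dist, cluster_gap = cluster_gap,
                 min_display = min_display, triad = triad),
            class = "regevo_pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: consensus peak
#' merging and signature calling (`call`), cross-tissue classification and
#' enhancer/gene association (`tissue`), pairwise maintenance summaries and
#' rate fits (`evolve`), the outgroup triad table and transition model
#' (`triad`, needs >= 3 species), and repeat-enrichment statistics
#' (`repeats`). Every produced table is written as TSV under
#' `config$out_dir` and listed in the returned manifest with an MD5 content
#' hash; resolved thresholds are echoed to the log.
#'
#' @param config A `regevo_pipeline_config` (or a `regevo_sim`, which is
#'   wrapped with default settings).
#' @param quiet Suppress log messages. Default `FALSE`.
#' @return List of class `regevo_pipeline_result` with `manifest` (tibble:
#'   `artifact`, `path`, `md5`) and `results` (the in-memory tibbles per
#'   stage).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (inherits(config, "regevo_sim")) config <- pipeline_config(config)
  stopifnot(inherits(config, "regevo_pipeline_config"))
  log_msg <- function(...) if (!quiet) message("[regevo] ", ...)
  sim <- load_pipeline_input(config$input)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("thresholds: min_replicates=", config$min_replicates,
          " overlap_frac=", config$overlap_frac,
          " max_assoc_dist=", config$max_assoc_dist,
          " cluster_gap=", config$cluster_gap,
          " min_display=", config$min_display)
  results <- list()
  artifacts <- list()
  emit <- function(name, x) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(x, p)
    artifacts[[name]] <<- p
  }
  stages <- config$stages

  if (!"call" %in% stages) {
    abort("run_pipeline: the 'call' stage is required by all later stages")
  }
  t0 <- Sys.time()
  regulome <- build_regulome(sim$peaks, min_replicates = config$min_replicates,
                             min_frac = config$overlap_frac)
  results$regulome <- regulome
  emit("regulome", select(regulome, -dplyr::any_of("partners")))
  log_msg("call: ", nrow(regulome), " regulatory regions in ",
          length(unique(regulome$species)), " species (",
          round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")

  if ("tissue" %in% stages) {
    t0 <- Sys.time()
    assoc <- associate_enhancers(regulome, max_dist = config$max_assoc_dist)
    genes <- purrr::map_dfr(split(regulome, regulome$species), function(rg) {
      ts <- sim$tss[sim$tss$species == rg$species[1], ]
      if (nrow(ts) == 0) return(tibble())
      assign_nearest_gene(rg, ts, max_dist = config$max_assoc_dist)
    })
    assoc <- left_join(assoc,
                       rename(genes, promoter_gene = "gene_id",
                              gene_distance = "distance"),
                       by = c("promoter_id" = "region_id"))
    results$enhancer_assignments <- assoc
    emit("enhancer_assignments", assoc)
    log_msg("tissue: ", sum(!is.na(assoc$promoter_id)), "/", nrow(assoc),
            " enhancers assigned to promoters (",
            round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")
  }

  species <- unique(regulome$species)
  get_map <- function(a, b) {
    m <- sim$maps[sim$maps$species_a == a & sim$maps$species_b == b, ]
    if (nrow(m) > 0) return(m)
    m <- sim$maps[sim$maps$species_a == b & sim$maps$species_b == a, ]
    if (nrow(m) == 0) abort(paste0("run_pipeline: no alignment map for ", a, "/", b))
    flip_alignment_map(m)
  }
  get_div <- function(a, b) {
    d <- sim$divergence
    hit <- (d$species_a == a & d$species_b == b) |
      (d$species_a == b & d$species_b == a)
    if (!any(hit)) return(NA_real_)
    d$divergence_mya[hit][1]
  }

  if ("evolve" %in% stages) {
    t0 <- Sys.time()
    prs <- utils::combn(species, 2, simplify = FALSE)
    pair_summary <- purrr::map_dfr(prs, function(pp) {
      summarize_pair(regulome[regulome$species == pp[1], ],
                     regulome[regulome$species == pp[2], ],
                     get_map(pp[1], pp[2]), get_div(pp[1], pp[2]),
                     cluster_gap = config$cluster_gap,
                     by_specificity = TRUE)
    })
    results$pair_summary <- pair_summary
    emit("pair_summary", pair_summary)
    points <- pair_summary |>
      tidyr::drop_na("maintenance_fraction_pct") |>
      mutate(category = paste(.data$signature, .data$specificity, sep = "_")) |>
      select(divergence_mya = "divergence_mya",
             fraction_pct = "maintenance_fraction_pct", "category")
    fit <- tryCatch(fit_rate(points), error = function(e) NULL)
    if (!is.null(fit)) {
      results$rate_fit <- fit
      emit("rate_fit", tidy(fit))
    }
    decomp <- purrr::map(prs, function(pp) {
      signature_decomposition(regulome[regulome$species == pp[1], ],
                              regulome[regulome$species == pp[2], ],
                              get_map(pp[1], pp[2]),
                              cluster_gap = config$cluster_gap)
    })
    names(decomp) <- vapply(prs, paste, character(1), collapse = "_")
    results$signature_decomposition <- decomp
    emit("signature_decomposition",
         purrr::map_dfr(decomp, ~ .x$counts, .id = "pair"))
    log_msg("evolve: ", length(prs), " species pairs summarised (",
            round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")
  }

  if ("triad" %in% stages) {
    tri <- config$triad %||% head(species, 3)
    if (length(species) < 3) {
      log_msg("triad: skipped, fewer than 3 species")
    } else {
      t0 <- Sys.time()
      rg <- function(s) regulome[regulome$species == s, ]
      tt <- build_triad_table(rg(tri[1]), rg(tri[2]), rg(tri[3]),
                              get_map(tri[1], tri[2]), get_map(tri[1], tri[3]),
                              get_map(tri[2], tri[3]),
                              cluster_gap = config$cluster_gap)
      results$triad_table <- tt
      emit("triad_table", as_tibble(tt))
      rows_ok <- tt$ingroup_pair[tt$ingroup_pair != "All" & tt$total > 0]
      chi <- tryCatch(triad_chi_square(tt, rows_ok), error = function(e) tibble())
      results$triad_tests <- chi
      if (nrow(chi) > 0) emit("triad_tests", chi)
      tm <- estimate_transition_model(tt)
      results$transition_model <- tm
      emit("transition_model", tidy(tm))
      log_msg("triad: ", tt$total[tt$ingroup_pair == "All"],
              " triad regions; transition rows sum to ",
              paste(round(rowSums(tm$prob), 3), collapse = ","), " (",
              round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")
    }
  }

  if ("repeats" %in% stages && "evolve" %in% stages) {
    t0 <- Sys.time()
    enr <- purrr::map_dfr(species, function(sp) {
      rg <- collapse_species_regions(
        regulome[regulome$species == sp & regulome$intra_dynamic == "none", ])
      status <- region_evolution_status(rg, regulome, sim, species, config)
      rec <- rg[rg$region_id %in% status$recent_ids, ]
      purrr::map_dfr(SIGNATURES, function(sg) {
        a <- rec[rec$signature == sg & rec$specificity == "tissue_specific", ]
        b <- rec[rec$signature == sg & rec$specificity != "tissue_specific", ]
        if (nrow(a) == 0 || nrow(b) == 0) return(tibble())
        relative_enrichment(a, b, sim$repeats[sim$repeats$species == sp, ],
                            min_display = config$min_display) |>
          mutate(species = sp, region_class = sg, .before = 1)
      })
    })
    results$repeat_enrichment <- enr
    if (nrow(enr) > 0) emit("repeat_enrichment", enr)
    log_msg("repeats: ", nrow(enr), " enrichment cells (",
            round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")
  }

  manifest <- tibble(
    artifact = names(artifacts),
    path = unname(unlist(artifacts)),
    md5 = unname(tools::md5sum(unlist(artifacts)))
  )
  structure(list(manifest = manifest, results = results, config = config),
            class = "regevo_pipeline_result")
}

# recently-evolved / evolutionarily-dynamic region_id sets for one species
# against all others
region_evolution_status <- function(rg, regulome, sim, species, config) {
  others <- setdiff(species, rg$species[1])
  maintained <- rep(FALSE, nrow(rg))
  dynamic <- rep(FALSE, nrow(rg))
  for (o in others) {
    m <- sim$maps[sim$maps$species_a == rg$species[1] & sim$maps$species_b == o, ]
    if (nrow(m) == 0) {
      m <- flip_alignment_map(sim$maps[sim$maps$species_a == o &
                                         sim$maps$species_b == rg$species[1], ])
    }
    other_reg <- collapse_species_regions(regulome[regulome$species == o, ])
    pr <- project_regions(rg, m, other_reg, cluster_gap = config$cluster_gap)
    maintained <- maintained | pr$status == "maintained"
    one <- pr$n_partners == 1
    psig <- rep(NA_character_, nrow(rg))
    psig[one] <- other_reg$signature[match(
      vapply(pr$partners[one], `[`, character(1), 1), other_reg$region_id)]
    dynamic <- dynamic | (!is.na(psig) & psig != rg$signature)
  }
  list(recent_ids = rg$region_id[!maintained],
       dynamic_ids = rg$region_id[dynamic])
}

#' @export
print.regevo_pipeline_result <- function(x, ...) {
  cat("regevo pipeline run: ", nrow(x$manifest), " artifacts in ",
      x$config$out_dir, "\n", sep = "")
  print(x$manifest)
  invisible(x)
}

# accepts a regevo_sim or a directory written by write_simulation()
load_pipeline_input <- function(input) {
  if (inherits(input, "regevo_sim")) return(input)
  if (!is.character(input) || !dir.exists(input)) {
    abort("run_pipeline: input must be a regevo_sim or a directory")
  }
  files <- list.files(input, full.names = TRUE)
  parse_tagged <- function(prefix, ext, reader, fields) {
    fs <- files[grepl(paste0("^", prefix, "_.*\\.", ext, "$"), basename(files))]
    purrr::map_dfr(fs, function(f) {
      tags <- strsplit(sub(paste0("\\.", ext, "$"), "", basename(f)), "_")[[1]][-1]
      x <- reader(f)
      for (k in seq_along(fields)) x[[fields[k]]] <- tags[k]
      x
    })
  }
  peaks <- parse_tagged("peaks", "bed", read_bed,
                        c("species", "tissue", "mark", "replicate_id"))
  if (nrow(peaks) == 0) abort("run_pipeline: no peak files found (stage call)")
  maps <- purrr::map_dfr(files[grepl("^map_.*\\.tsv$", basename(files))],
                         read_alignment_map)
  repeats <- parse_tagged("repeats", "tsv", read_repeat_table, "species")
  tss_files <- files[grepl("^tss_.*\\.bed$", basename(files))]
  tss <- purrr::map_dfr(tss_files, function(f) {
    x <- read_bed(f)
    tibble(species = strsplit(sub("\\.bed$", "", basename(f)), "_")[[1]][2],
           seq_id = x$seq_id, pos = x$start, gene_id = x$name)
  })
  div_file <- file.path(input, "divergence.tsv")
  divergence <- if (file.exists(div_file)) read_divergence_table(div_file) else
    tibble(species_a = character(), species_b = character(), divergence_mya = double())
  list(peaks = peaks, maps = maps, repeats = repeats, tss = tss,
       divergence = divergence)
}
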