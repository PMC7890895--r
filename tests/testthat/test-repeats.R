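# build a region set where `frac` of the regions overlap an L1 and the
# rest an L2, all on a private coordinate stripe
enrichment_case <- function(n_l1, n_l2, offset = 0) {
  n <- n_l1 + n_l2
  pos <- offset + seq(0, by = 2000, length.out = n)
  regions <- iv(pos, pos + 400)
  repeats <- tibble::tibble(
    seq_id = "chr1", start = pos + 100, end = pos + 300, strand = "+",
    repeat_class = "LINE",
    subgroup = c(rep("L1", n_l1), rep("L2", n_l2)),
    pct_divergence = 10
  )
  list(regions = regions, repeats = repeats)
}

test_that("relative enrichment reproduces subgroup-share differences", {
  # 47% vs 31% L1 shares among LINE-overlapping regions differ by 16
  a <- enrichment_case(47, 53)
  b <- enrichment_case(31, 69, offset = 1e6)
  cells <- relative_enrichment(a$regions, b$regions,
                               dplyr::bind_rows(a$repeats, b$repeats))
  l1 <- cells[cells$subgroup == "L1", ]
  expect_equal(l1$pct_A, 47)
  expect_equal(l1$pct_B, 31)
  expect_equal(l1$delta, 16)

  # 63% vs 74% give -11 (dynamic-vs-stable direction)
  a <- enrichment_case(63, 37)
  b <- enrichment_case(74, 26, offset = 1e6)
  cells <- relative_enrichment(a$regions, b$regions,
                               dplyr::bind_rows(a$repeats, b$repeats))
  expect_equal(cells$delta[cells$subgroup == "L1"], -11)

  # identical sets: zero deltas, unit p-values
  cells <- relative_enrichment(a$regions, a$regions,
                               dplyr::bind_rows(a$repeats, b$repeats))
  expect_true(all(cells$delta == 0))
  expect_true(all(cells$p_value == 1))
})

test_that("enrichment deltas are antisymmetric and respect the display filter", {
  a <- enrichment_case(30, 10)
  b <- enrichment_case(10, 30, offset = 1e6)
  reps <- dplyr::bind_rows(a$repeats, b$repeats)
  ab <- relative_enrichment(a$regions, b$regions, reps)
  ba <- relative_enrichment(b$regions, a$regions, reps)
  expect_equal(ab$delta, -ba$delta)
  expect_false(any(ab$displayed)) # fewer than 100 in both sets
  expect_true(all(relative_enrichment(a$regions, b$regions, reps,
                                      min_display = 10)$displayed))
  # Bonferroni never lowers a p-value
  expect_true(all(ab$p_adj >= ab$p_value))
})

test_that("strict attribution makes subgroup percentages sum to 100", {
  # one region overlapping both an L1 (wider) and an L2
  regions <- iv(0, 1000)
  repeats <- tibble::tibble(
    seq_id = "chr1", start = c(0, 500), end = c(600, 700), strand = "+",
    repeat_class = "LINE", subgroup = c("L1", "L2"), pct_divergence = 5
  )
  loose <- relative_enrichment(regions, regions, repeats)
  expect_equal(sum(loose$pct_A), 200) # counted once per subgroup
  strict <- relative_enrichment(regions, regions, repeats, strict = TRUE)
  expect_equal(sum(strict$pct_A), 100)
  expect_equal(strict$subgroup[strict$count_A == 1], "L1") # larger overlap wins
})

test_that("repeat partition applies the dynamic > recent > inactive precedence", {
  regulome <- mk_regulome(c(0, 2000, 4000), c(1000, 3000, 5000),
                          c("AP", "AE", "PE"), "sp")
  repeats <- tibble::tibble(
    seq_id = "chr1", start = c(500, 2500, 9000, 800), end = c(1500, 3500, 9500, 2500),
    strand = "+", repeat_class = "LINE", subgroup = "L1",
    pct_divergence = c(5, 10, 20, 15)
  )
  out <- partition_repeats(repeats, regulome,
                           recent_ids = regulome$region_id[1],
                           dynamic_ids = regulome$region_id[2])
  expect_equal(out$category,
               c("recently_evolved_overlap", "evolutionarily_dynamic_overlap",
                 "regulatorily_inactive", "evolutionarily_dynamic_overlap"))
  expect_equal(out$length, repeats$end - repeats$start)
})

test_that("attribute comparisons use exact one-sided rank-sum tests", {
  part <- tibble::tibble(
    category = rep(c("low", "high"), each = 3),
    pct_divergence = c(1, 2, 3, 4, 5, 6),
    length = c(10, 20, 30, 40, 50, 60)
  )
  out <- compare_repeat_attribute(part, "pct_divergence", "greater")
  # the fully separated ordering has probability 1/choose(6,3)
  p_hl <- out$p_value[out$category_1 == "high"]
  expect_equal(p_hl, 0.05)
  expect_equal(p_hl, wilcox_enum_p(c(4, 5, 6), c(1, 2, 3), "greater"))
  expect_equal(out$median_1[out$category_1 == "high"], 5)

  # identical distributions cannot be one-sidedly separated
  part2 <- tibble::tibble(category = rep(c("u", "v"), each = 4),
                          pct_divergence = rep(c(1, 5, 9, 13), 2),
                          length = 1)
  out2 <- suppressWarnings(compare_repeat_attribute(part2, "pct_divergence", "greater"))
  expect_true(all(out2$p_value >= 0.5))

  expect_warning(
    compare_repeat_attribute(
      tibble::tibble(category = "only", pct_divergence = 1, length = 1),
      categories = c("only", "missing")
    ),
    "empty"
  )
})

test_that("exact rank-sum p-values match full enumeration on small samples", {
  set.seed(19)
  for (k in 1:10) {
    # tie-free values keep the rank-sum distribution exact
    x <- sample(seq(1, 199, by = 2), sample(3:8, 1))
    y <- sample(seq(2, 200, by = 2), sample(3:8, 1))
    part <- tibble::tibble(category = rep(c("a", "b"), c(length(x), length(y))),
                           pct_divergence = c(x, y), length = 1)
    out <- compare_repeat_attribute(part, "pct_divergence", "greater")
    expect_equal(out$p_value[out$category_1 == "a"], wilcox_enum_p(x, y, "greater"),
                 tolerance = 1e-12)
    expect_equal(out$p_value[out$category_1 == "b"], wilcox_enum_p(y, x, "greater"),
                 tolerance = 1e-12)
  }
})

test_that("two-proportion z-test matches the 2x2 chi-square oracle", {
  set.seed(11)
  for (k in 1:20) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    x1 <- sample.int(n1, 1) - 1L; x2 <- sample.int(n2, 1) - 1L
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    expect_equal(prop_z_test(x1, n1, x2, n2)$p_value,
                 chisq_2x2_p(x1, n1, x2, n2), tolerance = 1e-6)
    expect_equal(prop_z_test(x1, n1, x2, n2, correct = TRUE)$p_value,
                 chisq_2x2_p(x1, n1, x2, n2, correct = TRUE), tolerance = 1e-6)
  }
})

test_that("shuffle control hits the saturation and empty extremes deterministically", {
  genome <- tibble::tibble(seq_id = "chr1", length = 100000L)
  regions <- iv(c(1000, 5000, 9000), c(1400, 5400, 9400))
  exclude <- regions
  all_line <- tibble::tibble(seq_id = "chr1", start = 0L, end = 100000L,
                             strand = "+", repeat_class = "LINE",
                             subgroup = "L1", pct_divergence = 1)
  res <- shuffle_control(regions, genome, exclude, all_line, seed = 4)
  expect_equal(res$random_fraction, 1)
  expect_equal(res$real_fraction, 1)

  no_line <- all_line[0, ]
  res <- shuffle_control(regions, genome, exclude, no_line, seed = 4)
  expect_equal(res$random_fraction, 0)

  r1 <- shuffle_control(regions, genome, exclude, all_line, seed = 99)
  r2 <- shuffle_control(regions, genome, exclude, all_line, seed = 99)
  expect_identical(r1$placements, r2$placements)
  # placements avoid the exclusion zone entirely
  expect_equal(nrow(regevo:::overlap_pairs(r1$placements, exclude)), 0)
})

test_that("simulated tissue-specific L1 bias yields positive L1 deltas", {
  sim <- cached("enrich_sim", function() make_fixture("enrichment"))
  reg <- cached("enrich_reg", function() build_regulome(sim$peaks))
  sp <- sim$species[1]
  rg <- collapse_species_regions(
    reg[reg$species == sp & reg$intra_dynamic == "none", ])
  a <- rg[rg$specificity == "tissue_specific", ]
  b <- rg[rg$specificity != "tissue_specific", ]
  cells <- relative_enrichment(a, b, sim$repeats[sim$repeats$species == sp, ])
  expect_gt(cells$delta[cells$repeat_class == "LINE" & cells$subgroup == "L1"], 0)
})
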