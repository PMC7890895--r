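test_that("projection classifies unaligned, maintained and multi-mapped regions", {
  reg <- mk_regulome(c(100, 60000), c(200, 60100), c("AP", "AP"), "a")
  tgt <- mk_regulome(199, 350, "AE", "b")
  map <- tibble::tibble(species_a = "a", seq_a = "chr1", start_a = 0L, end_a = 10000L,
                        species_b = "b", seq_b = "chr1", start_b = 0L, end_b = 10000L)
  pr <- project_regions(reg, map, tgt)
  # single-base overlap with any-signature partner counts as maintained
  expect_equal(pr$status, c("maintained", "unaligned"))
  expect_equal(pr$partners[[1]], tgt$region_id)

  # a region split across blocks projecting 1 Mb apart maps to two places
  map2 <- tibble::tibble(
    species_a = "a", seq_a = "chr1", start_a = c(0L, 150L),
    end_a = c(150L, 300L),
    species_b = "b", seq_b = "chr1", start_b = c(0L, 1000150L),
    end_b = c(150L, 1000300L)
  )
  pr2 <- project_regions(mk_regulome(100, 200, "AP", "a"), map2, tgt)
  expect_equal(pr2$status, "multi_mapped_excluded")

  # within the cluster gap the two pieces remain one location
  map3 <- map2
  map3$start_b[2] <- 5150L; map3$end_b[2] <- 5300L
  pr3 <- project_regions(mk_regulome(100, 200, "AP", "a"), map3, tgt)
  expect_false(pr3$status == "multi_mapped_excluded")
})

test_that("pairwise summary reproduces the directional-mean maintenance fraction", {
  # species a: 8 maintained + 2 aligned-without-partner promoters -> 80%
  # species b: 6 maintained + 4 aligned-without-partner           -> 60%
  a <- mk_regulome(
    start = c(seq(0, 5000, by = 1000), 200, 5200, 30000, 31000),
    end = c(seq(0, 5000, by = 1000) + 100, 300, 5300, 30100, 31100),
    signature = "AP", species = "a",
    tissue = c(rep("liver", 6), "brain", "brain", "liver", "liver")
  )
  b <- mk_regulome(
    start = c(seq(0, 5000, by = 1000), seq(20000, 23000, by = 1000)),
    end = c(seq(0, 5000, by = 1000) + 500, seq(20000, 23000, by = 1000) + 100),
    signature = "AP", species = "b",
    tissue = "liver"
  )
  out <- summarize_pair(a, b, identity_map("a", "b", 50000), divergence_mya = 10)
  expect_equal(out$P_M_i, 8)
  expect_equal(out$P_L_i, 2)
  expect_equal(out$P_M_j, 6)
  expect_equal(out$P_L_j, 4)
  expect_equal(out$maintenance_fraction_pct, 70)
  expect_equal(out$P_A_i, out$P_N_i + out$P_L_i + out$P_M_i)

  # swapping the species order leaves the pair fraction unchanged
  swapped <- summarize_pair(b, a, identity_map("b", "a", 50000), divergence_mya = 10)
  expect_equal(swapped$maintenance_fraction_pct, out$maintenance_fraction_pct)
})

test_that("maintained fraction is 100 when every region is maintained", {
  # maintenance counts partners of any signature class
  a <- mk_regulome(c(0, 1000), c(100, 1100), c("AP", "AE"), "a")
  b <- mk_regulome(c(0, 1000), c(100, 1100), c("AE", "AP"), "b")
  out <- summarize_pair(a, b, identity_map("a", "b", 5000), 1)
  expect_equal(out$maintenance_fraction_pct, c(100, 100))
})

test_that("partition identities hold on simulated data", {
  sim <- evolved_sim()
  reg <- evolved_regulome()
  sp <- sim$species
  for (pp in utils::combn(sp, 2, simplify = FALSE)) {
    out <- summarize_pair(species_regulome(reg, pp[1]), species_regulome(reg, pp[2]),
                          sim_map(sim, pp[1], pp[2]))
    expect_equal(out$P_A_i, out$P_N_i + out$P_L_i + out$P_M_i)
    expect_equal(out$P_A_j, out$P_N_j + out$P_L_j + out$P_M_j)
    expect_equal(out$P_R_i, out$P_N_i + out$P_L_i)
  }
})

test_that("replicate zero points average the two directional fractions", {
  # identical regulomes reproduce at 100%
  k <- mk_regulome(seq(0, 9000, by = 1000), seq(0, 9000, by = 1000) + 100, "AP", "s")
  expect_equal(replicate_zero_point(k, k)$fraction_pct, 100)

  # 9/10 and 8/8 average to 95
  l <- mk_regulome(
    start = c(50, seq(2200, 8200, by = 1000)),
    end = c(1250, seq(2200, 8200, by = 1000) + 100),
    signature = "AP", species = "s"
  )
  k2 <- mk_regulome(seq(0, 9000, by = 1000), seq(0, 9000, by = 1000) + 250, "AP", "s")
  out <- replicate_zero_point(k2, l)
  expect_equal(out$P_I_kl, 9)
  expect_equal(out$P_I_lk, 8)
  expect_equal(out$fraction_pct, 95)

  # disjoint regulomes give 0
  far <- mk_regulome(50000, 50100, "AP", "s")
  expect_equal(replicate_zero_point(k, far)$fraction_pct, 0)
})

test_that("rate fits recover exact lines and match the normal equations", {
  pts <- tibble::tibble(divergence_mya = c(0, 100), fraction_pct = c(95, 45),
                        category = "x")
  fit <- fit_rate(pts)
  expect_equal(fit$fits$slope, -0.5)
  expect_equal(fit$fits$intercept, 95)

  set.seed(3)
  pts <- tibble::tibble(divergence_mya = rep(seq(5, 80, by = 15), 2),
                        fraction_pct = 90 - 0.4 * rep(seq(5, 80, by = 15), 2) +
                          rnorm(12, 0, 2),
                        category = rep(c("u", "v"), each = 6))
  fit <- fit_rate(pts)
  for (cc in c("u", "v")) {
    d <- pts[pts$category == cc, ]
    ne <- normal_equations_fit(d$divergence_mya, d$fraction_pct)
    expect_equal(fit$fits$intercept[fit$fits$category == cc], ne[1],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(fit$fits$slope[fit$fits$category == cc], ne[2],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # two categories with identical points: no interaction by construction
  x <- c(0, 20, 40, 60)
  y <- 95 - 0.3 * x + c(1.2, -0.8, 0.5, -0.9)
  pts <- tibble::tibble(divergence_mya = rep(x, 2), fraction_pct = rep(y, 2),
                        category = rep(c("u", "v"), each = 4))
  expect_gt(fit_rate(pts)$interactions$interaction_p, 0.99)

  expect_error(fit_rate(tibble::tibble(divergence_mya = c(5, 5),
                                       fraction_pct = c(1, 2), category = "x")),
               "singular")
})

test_that("tidiers summarise rate fits", {
  pts <- tibble::tibble(divergence_mya = c(0, 50, 100), fraction_pct = c(90, 71, 50),
                        category = "x")
  fit <- fit_rate(pts)
  expect_equal(tidy(fit)$slope, -0.4)
  expect_equal(glance(fit)$n_points, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("signature decomposition counts partner classes and switch fractions", {
  pos <- seq(0, 11000, by = 1000)
  sig_i <- c(rep("AP", 10), "AE", "PE")
  sig_j <- c(rep("AP", 8), "AE", "PE", "AP", "AP")
  i <- mk_regulome(pos, pos + 100, sig_i, "a")
  j <- mk_regulome(pos, pos + 100, sig_j, "b")
  dec <- signature_decomposition(i, j, identity_map("a", "b", 50000))
  ap_rows <- dec$counts[dec$counts$signature == "AP", ]
  expect_equal(sort(ap_rows$NP_M), c(10, 10))
  expect_equal(dec$switching$P_W_pct, 20)
  # partition identity of the decomposition row totals
  expect_equal(dec$counts$NP_M,
               dec$counts$partner_AP + dec$counts$partner_AE +
                 dec$counts$partner_PE + dec$counts$partner_dynPE +
                 dec$counts$partner_dynE)
  # AE -> PE switching absent here
  ae <- dec$counts[dec$counts$signature == "AE", ]
  expect_true(all(ae$partner_PE == 0))
})

test_that("no switching is reported when the simulator switches nothing", {
  sim <- clean_sim()
  reg <- clean_regulome()
  sp <- sim$species
  dec <- signature_decomposition(species_regulome(reg, sp[1]),
                                 species_regulome(reg, sp[2]),
                                 sim_map(sim, sp[1], sp[2]))
  expect_equal(dec$switching$P_W_pct, 0)
  ae <- dec$counts[dec$counts$signature == "AE", ]
  expect_true(all(ae$partner_PE == 0))
})
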