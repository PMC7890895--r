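rep_peaks <- function(...) {
  # build per-replicate peak tibble from named lists rep1 = iv(...), ...
  lst <- list(...)
  dplyr::bind_rows(lapply(names(lst), function(r) {
    dplyr::mutate(lst[[r]], replicate_id = r)
  }))
}

test_that("reciprocal-50% rule decides replicate reproducibility", {
  # reciprocal overlaps 50/100 and 50/100: both reproducible, union emitted
  out <- merge_reproducible_peaks(rep_peaks(rep1 = iv(100, 200), rep2 = iv(150, 250)))
  expect_equal(out, iv(100, 250))
  # overlaps 10/100 and 10/110: not reciprocal, nothing survives
  out <- merge_reproducible_peaks(rep_peaks(rep1 = iv(100, 200), rep2 = iv(190, 300)))
  expect_equal(nrow(out), 0)
  # identical peak in three replicates collapses to itself
  out <- merge_reproducible_peaks(rep_peaks(rep1 = iv(100, 200), rep2 = iv(100, 200),
                                            rep3 = iv(100, 200)))
  expect_equal(out, iv(100, 200))
  expect_error(merge_reproducible_peaks(rep_peaks(rep1 = iv(1, 2))), "replicate")
})

test_that("signature calling follows the three-mark rules with exclusion", {
  # promoter consumes its acetylation block; leftover K4me1 touching raw
  # K27ac is neither primed nor active enhancer
  out <- call_regulatory_regions(iv(100, 300), iv(150, 400), iv(350, 500))
  expect_equal(out$signature[out$start == 100], "AP")
  expect_false(any(out$signature %in% c("AE", "PE")))
  expect_true(all(out$signature[out$start %in% c(150, 350)] == "unclassified"))

  # K27ac half-covered by K4me1, no promoter: active enhancer on the K27ac span
  out <- call_regulatory_regions(iv(integer(0), integer(0)), iv(0, 100), iv(40, 200))
  expect_equal(out$signature[out$start == 0], "AE")
  expect_false("PE" %in% out$signature)

  # lone K4me1 is a primed enhancer
  out <- call_regulatory_regions(iv(integer(0), integer(0)),
                                 iv(integer(0), integer(0)), iv(0, 100))
  expect_equal(out$signature, "PE")
})

test_that("signature classes are base-disjoint and order-invariant", {
  set.seed(23)
  for (k in 1:5) {
    # consensus peaks are disjoint within a mark (post-reproducibility)
    mk <- function(n) {
      s <- cumsum(sample(420:900, n))
      iv(s, s + sample(50:400, n, replace = TRUE))
    }
    me3 <- mk(8); ac <- mk(10); me1 <- mk(10)
    out <- call_regulatory_regions(me3, ac, me1)
    called <- out[out$signature %in% c("AP", "AE", "PE"), ]
    if (nrow(called) > 1) {
      m <- merge_intervals(called)
      expect_equal(sum(m$end - m$start), sum(called$end - called$start))
    }
    shuf <- call_regulatory_regions(me3[sample(nrow(me3)), ],
                                    ac[sample(nrow(ac)), ],
                                    me1[sample(nrow(me1)), ])
    expect_equal(dplyr::arrange(out, signature, start),
                 dplyr::arrange(shuf, signature, start))
  }
})

test_that("cross-tissue links set activity tissues and dynamic flags", {
  reg <- mk_regulome(start = c(0, 50, 300, 300, 800),
                     end = c(100, 160, 400, 400, 900),
                     signature = c("AP", "AP", "AP", "AE", "PE"),
                     species = "sp",
                     tissue = c("liver", "brain", "liver", "testis", "muscle"))
  out <- cross_tissue_classify(reg)
  # 50/100 either-side rule links the two promoters
  expect_equal(out$activity_tissues[1], "brain,liver")
  expect_equal(out$activity_tissues[2], "brain,liver")
  expect_equal(out$specificity[1], "tissue_shared")
  # promoter/enhancer overlap marks both partners dynamic
  expect_equal(out$intra_dynamic[3], "dynamic_PE")
  expect_equal(out$intra_dynamic[4], "dynamic_PE")
  # untouched region stays tissue-specific
  expect_equal(out$specificity[5], "tissue_specific")
  expect_equal(out$activity_tissues[5], "muscle")
  expect_equal(out$intra_dynamic[5], "none")
})

test_that("activity links are symmetric", {
  set.seed(31)
  for (k in 1:5) {
    n <- 30
    s <- sample(0:20000, n)
    reg <- mk_regulome(start = s, end = s + sample(100:500, n, replace = TRUE),
                       signature = sample(c("AP", "AE", "PE"), n, replace = TRUE),
                       species = "sp",
                       tissue = sample(c("liver", "brain", "testis"), n, replace = TRUE))
    out <- cross_tissue_classify(reg)
    for (i in seq_len(n)) {
      for (ti in setdiff(strsplit(out$activity_tissues[i], ",")[[1]], out$tissue[i])) {
        partners <- out[out$tissue == ti & out$signature == out$signature[i], ]
        expect_true(any(grepl(out$tissue[i], partners$activity_tissues)))
      }
    }
  }
})

test_that("enhancers attach to the nearest promoter within 1 Mb", {
  reg <- dplyr::bind_rows(
    mk_regulome(5000, 5400, "AE", "sp"),
    mk_regulome(c(0, 9000), c(200, 9200), "AP", "sp")
  )
  out <- associate_enhancers(reg)
  expect_equal(out$distance, 3600) # 3600 beats 4600
  expect_match(out$promoter_id, "AP\\.2")

  far <- dplyr::bind_rows(
    mk_regulome(0, 400, "AE", "sp"),
    mk_regulome(1300000, 1300200, "AP", "sp")
  )
  expect_true(is.na(associate_enhancers(far)$promoter_id))

  touching <- dplyr::bind_rows(
    mk_regulome(100, 300, "AE", "sp"),
    mk_regulome(250, 500, "AP", "sp")
  )
  expect_equal(associate_enhancers(touching)$distance, 0)
})

test_that("promoters pick the nearest TSS with deterministic ties", {
  ap <- mk_regulome(1000, 1200, "AP", "sp")
  tss <- tibble::tibble(seq_id = "chr1", pos = c(1100, 2000), gene_id = c("gA", "gB"))
  out <- assign_nearest_gene(ap, tss)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$distance, 0)

  out <- assign_nearest_gene(mk_regulome(0, 100, "AP", "sp"),
                             tibble::tibble(seq_id = "chr1", pos = 2100000,
                                            gene_id = "far"))
  expect_true(is.na(out$gene_id))

  # equidistant TSS break to the lower coordinate
  ap <- mk_regulome(1000, 1100, "AP", "sp")
  tss <- tibble::tibble(seq_id = "chr1", pos = c(1150, 949), gene_id = c("hi", "lo"))
  expect_equal(assign_nearest_gene(ap, tss)$gene_id, "lo")
})

test_that("vectorised classification matches the per-base brute force", {
  set.seed(77)
  for (k in 1:6) {
    mk <- function(n) {
      s <- sample(0:8000, n)
      iv(s, s + sample(40:300, n, replace = TRUE))
    }
    me3 <- mk(5); ac <- mk(6); me1 <- mk(6)
    fast <- call_regulatory_regions(me3, ac, me1)
    fast <- fast[fast$signature %in% c("AP", "AE", "PE"),
                 c("seq_id", "start", "end", "signature")]
    slow <- brute_classify(me3, ac, me1)
    key <- function(x) sort(paste(x$seq_id, x$start, x$end, x$signature))
    expect_equal(key(fast), key(if (is.null(slow)) fast[0, ] else slow))
  }
})
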