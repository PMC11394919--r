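test_that("heterozygote pooling applies depth and minor-fraction rules", {
  d <- dplyr::bind_rows(
    make_depths(pos = 1, assay = "H3K4me3", ref = 15, alt = 10), # kept
    make_depths(pos = 2, assay = "H3K4me3", ref = 17, alt = 4),  # minor .19
    make_depths(pos = 3, assay = "H3K4me3", ref = 10, alt = 10)  # depth 20
  )
  het <- pool_and_call_het(d)
  expect_equal(het$pos, 1L)
  expect_equal(het$pooled_depth, 25L)
  expect_equal(het$pooled_minor_fraction, 0.4)
})

test_that("pooling sums across assays and errors on conflicting bases", {
  d <- dplyr::bind_rows(
    make_depths(pos = 7, assay = "H3K4me3", ref = 8, alt = 5),
    make_depths(pos = 7, assay = "RNA", ref = 7, alt = 6)
  )
  het <- pool_and_call_het(d)
  expect_equal(het$pooled_depth, 26L)
  bad <- d
  bad$alt_base[2] <- "T"
  expect_error(pool_and_call_het(bad), "chr1:7")
  expect_error(pool_and_call_het(dplyr::bind_rows(
    make_depths(ind = "a"), make_depths(ind = "b"))), "single individual")
})

test_that("binomial asymmetry p matches closed forms and the oracle", {
  expect_equal(binomial_asymmetry_p(5, 5), 1.0)
  expect_equal(binomial_asymmetry_p(10, 0), 2 * 0.5^10)
  expect_equal(binomial_asymmetry_p(15, 5), 0.04138946533203125,
               tolerance = 1e-12)
  # exhaustive agreement with pmf enumeration for all totals 1..60
  for (n in 1:60) {
    k <- 0:n
    expect_equal(binomial_asymmetry_p(k, n - k),
                 vapply(k, function(x) oracle_binom_p(x, n - x), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("binomial asymmetry p agrees with stats::binom.test", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    expect_equal(binomial_asymmetry_p(k, n - k),
                 stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-10)
  }
})

test_that("binomial p is symmetric and monotone in imbalance", {
  k <- 0:40
  expect_equal(binomial_asymmetry_p(k, 40 - k),
               binomial_asymmetry_p(40 - k, k))
  upper <- binomial_asymmetry_p(20:40, 40 - (20:40))
  expect_true(all(diff(upper) <= 1e-12))
  expect_error(binomial_asymmetry_p(0, 0), "at least one read")
})

test_that("BH adjustment matches hand-computed step-up vectors", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  # hand application: sorted p * n/i with running minimum from the top
  p <- c(0.009, 0.2, 0.04, 0.9)
  expect_equal(bh_adjust(p), c(0.036, 0.2666666666666667, 0.08, 0.9),
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone: adjusted >= raw, order preserved
  set.seed(2)
  q <- runif(100)
  adj <- bh_adjust(q)
  expect_true(all(adj >= q - 1e-12))
  expect_equal(order(adj[order(q)]), seq_along(q))
})

test_that("event calling separates assays and respects significance", {
  d <- dplyr::bind_rows(
    make_depths(pos = 1, assay = "RNA", ref = 25, alt = 25),
    make_depths(pos = 1, assay = "H3K4me3", ref = 48, alt = 2)
  )
  het <- pool_and_call_het(d)
  calls <- call_events(het, d)
  rna <- calls[calls$assay == "RNA", ]
  expect_equal(rna$event_class, "ASE")
  expect_false(rna$significant)
  expect_true(rna$tie)
  chip <- calls[calls$assay == "H3K4me3", ]
  expect_equal(chip$event_class, "ASB")
  expect_true(chip$significant)
  expect_equal(chip$preferred_allele, "ref")
  # a site absent from RNA produces no ASE record
  d2 <- make_depths(pos = 9, assay = "H3K27ac", ref = 30, alt = 1)
  calls2 <- call_events(pool_and_call_het(d2), d2)
  expect_false(any(calls2$event_class == "ASE"))
})

test_that("planted imbalance is recovered with FDR near nominal", {
  # 500 null + 50 planted sites at maf 0.9, depth 60, over 20 seeds
  res <- sapply(1:20, function(s) {
    withr::with_seed(s, {
      n <- 550; planted <- seq_len(50)
      dp <- rpois(n, 60); dp[dp == 0] <- 1L
      p <- rep(0.5, n); p[planted] <- 0.9
      rc <- rbinom(n, dp, p)
      d <- make_depths(pos = seq_len(n), assay = "H3K4me3",
                       ref = rc, alt = dp - rc)
      calls <- call_events(pool_and_call_het(d, min_depth = 0,
                                             min_minor_fraction = 0), d)
      sig <- calls$pos[calls$significant]
      c(sens = mean(planted %in% sig),
        fdp = sum(!(sig %in% planted)) / max(length(sig), 1))
    })
  })
  expect_gt(mean(res["sens", ]), 0.8)
  expect_lt(mean(res["fdp", ]), 0.12)
})

test_that("pure-null calls control the false discovery rate", {
  rates <- sapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      dp <- rpois(400, 60); dp[dp == 0] <- 1L
      rc <- rbinom(400, dp, 0.5)
      d <- make_depths(pos = seq_len(400), assay = "RNA",
                       ref = rc, alt = dp - rc)
      calls <- call_events(pool_and_call_het(d, min_depth = 0,
                                             min_minor_fraction = 0), d)
      mean(calls$significant)
    })
  })
  expect_lt(mean(rates), 0.1 + 0.02)
})

test_that("rs identifier assignment is a total join", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L))
  idm <- tibble::tibble(chrom = "chr1", pos = 10L, rs_id = "rs123")
  out <- assign_rs_ids(calls, idm)
  expect_equal(nrow(out), 2L)
  expect_equal(out$rs_id, c("rs123", "novel_chr1_20"))
})
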