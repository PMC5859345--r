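test_that("fragment patterns call the documented genotypes", {
  cases <- list(
    # assay, fragments, expected call
    list("CYP2C9_star2_AvaII", c(397, 57), "*1/*1"),
    list("CYP2C9_star2_AvaII", c(454, 397, 57), "*1/*2"),
    list("CYP2C9_star2_AvaII", 454, "*2/*2"),
    list("CYP2C9_star3_KpnI", 105, "*1/*1"),
    list("CYP2C9_star3_KpnI", c(105, 85, 20), "*1/*3"),
    list("CYP2C9_star3_KpnI", c(85, 20), "*3/*3"),
    list("VKORC1_1639_MspI", c(167, 123), "GG"),
    list("VKORC1_1639_MspI", c(290, 167, 123), "GA"),
    list("VKORC1_1639_MspI", 290, "AA")
  )
  for (case in cases) {
    expect_identical(
      as.character(call_rflp_genotype(case[[1]], case[[2]])), case[[3]],
      info = paste(case[[1]], paste(case[[2]], collapse = ","))
    )
    # fragment sets are unordered
    expect_identical(
      as.character(call_rflp_genotype(case[[1]], rev(case[[2]]))), case[[3]]
    )
  }
})

test_that("sub-resolution fragments may be absent without losing the call", {
  # 57 and 20 bp bands run off 2.5-3.5% agarose gels
  expect_identical(as.character(call_rflp_genotype("CYP2C9_star2_AvaII", 397)), "*1/*1")
  expect_identical(
    as.character(call_rflp_genotype("CYP2C9_star2_AvaII", c(454, 397))), "*1/*2"
  )
  expect_identical(as.character(call_rflp_genotype("CYP2C9_star3_KpnI", 85)), "*3/*3")
  expect_identical(
    as.character(call_rflp_genotype("CYP2C9_star3_KpnI", c(105, 85))), "*1/*3"
  )
  # but a missing resolvable band is an incomplete digest, not a call
  bad <- call_rflp_genotype("VKORC1_1639_MspI", c(290, 167))
  expect_true(is.na(bad))
  expect_match(attr(bad, "diagnostic"), "incomplete")
})

test_that("unrecognized or empty fragment sets yield a no-call with diagnostic", {
  nc <- call_rflp_genotype("CYP2C9_star2_AvaII", c(397, 300))
  expect_true(is.na(nc))
  expect_match(attr(nc, "diagnostic"), "300")
  empty <- call_rflp_genotype("VKORC1_1639_MspI", integer())
  expect_true(is.na(empty))
  expect_match(attr(empty, "diagnostic"), "empty")
  expect_error(call_rflp_genotype("NoSuchAssay", 100), class = "warfpgx_schema_error")
})

test_that("assay registry fragments sum to the amplicon length", {
  assays <- rflp_assays()
  for (i in seq_len(nrow(assays))) {
    expect_equal(sum(assays$cut_fragments_bp[[i]]), assays$amplicon_bp[i])
  }
})

test_that("single-site calls combine into the six-class CYP2C9 diplotype", {
  expect_identical(combine_cyp2c9("*1/*1", "*1/*1"), "*1/*1")
  expect_identical(combine_cyp2c9("*1/*2", "*1/*1"), "*1/*2")
  expect_identical(combine_cyp2c9("*1/*1", "*1/*3"), "*1/*3")
  expect_identical(combine_cyp2c9("*2/*2", "*1/*1"), "*2/*2")
  expect_identical(combine_cyp2c9("*1/*2", "*1/*3"), "*2/*3")
  expect_identical(combine_cyp2c9("*1/*1", "*3/*3"), "*3/*3")
  expect_identical(combine_cyp2c9(NA, "*1/*1"), "unknown")
  expect_error(combine_cyp2c9("*2/*2", "*1/*3"), class = "warfpgx_record_error")
})

test_that("genotype frequencies reproduce the observed cohort proportions", {
  f_cyp <- genotype_frequencies(genotype_counts(75, 25, 1))
  expect_true(all(abs(unname(f_cyp) - c(0.743, 0.248, 0.010)) < 5e-4))
  f_vko <- genotype_frequencies(genotype_counts(30, 49, 22))
  expect_true(all(abs(unname(f_vko) - c(0.297, 0.485, 0.218)) < 5e-4))
  expect_equal(sum(f_cyp), 1)
  expect_equal(unname(genotype_frequencies(genotype_counts(12, 0, 0))), c(1, 0, 0))
})

test_that("allele frequencies come from direct gene counting", {
  expect_equal(
    unname(allele_frequencies(genotype_counts(75, 25, 1))[["variant"]]),
    27 / 202
  )
  expect_equal(
    unname(allele_frequencies(genotype_counts(30, 49, 22))[["variant"]]),
    93 / 202
  )
  expect_equal(unname(allele_frequencies(genotype_counts(0, 0, 5))[["variant"]]), 1)
  expect_equal(sum(allele_frequencies(genotype_counts(30, 49, 22))), 1)
})

test_that("allele frequency equals mean per-patient variant dosage over two", {
  cohort <- simulate_cohort(sim_params(n = 200, seed = 99))
  counts <- genotype_counts_from_cohort(cohort, "vkorc1")
  dosage <- c(GG = 0, GA = 1, AA = 2)[cohort$vkorc1]
  expect_equal(
    unname(allele_frequencies(counts)[["variant"]]),
    mean(dosage) / 2
  )
})

test_that("Hardy-Weinberg chi-square matches hand computation and edge cases", {
  h_cyp <- hwe_chi_square(genotype_counts(75, 25, 1))
  expect_equal(h_cyp$chi_square, 0.478, tolerance = 2e-3)
  expect_equal(h_cyp$p_value, 0.489, tolerance = 2e-3)
  expect_false(h_cyp$monomorphic)
  expect_equal(sum(h_cyp$expected_counts), 101)

  h_vko <- hwe_chi_square(genotype_counts(30, 49, 22))
  expect_equal(h_vko$p_value, 0.81, tolerance = 0.01)

  # exact Hardy-Weinberg proportions give a zero statistic
  exact <- genotype_counts(64, 32, 4) # p = 0.8, N = 100
  h0 <- hwe_chi_square(exact)
  expect_equal(h0$chi_square, 0)
  expect_equal(h0$p_value, 1)

  mono <- hwe_chi_square(genotype_counts(50, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("Hardy-Weinberg statistic agrees with a first-principles oracle", {
  # brute-force Pearson computation over every polymorphic count triple
  # with total <= 30
  oracle <- function(a, b, c) {
    n <- a + b + c
    q <- (b + 2 * c) / (2 * n)
    p <- 1 - q
    e <- n * c(p^2, 2 * p * q, q^2)
    sum((c(a, b, c) - e)^2 / e)
  }
  for (n in c(5, 12, 30)) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        c_ <- n - a - b
        q <- (b + 2 * c_) / (2 * n)
        if (q == 0 || q == 1) next
        got <- hwe_chi_square(genotype_counts(a, b, c_))
        expect_equal(got$chi_square, oracle(a, b, c_), tolerance = 1e-12)
      }
    }
  }
})

test_that("cohort genotype tallies reduce diplotypes to variant copy number", {
  cohort <- dplyr::bind_rows(
    patient_record(id = "1", cyp2c9 = "*1/*1", vkorc1 = "GG",
      visits = make_visits(35, 2.2)),
    patient_record(id = "2", cyp2c9 = "*1/*2", vkorc1 = "GA",
      visits = make_visits(35, 2.2)),
    patient_record(id = "3", cyp2c9 = "*2/*3", vkorc1 = "AA",
      visits = make_visits(35, 2.2)),
    patient_record(id = "4", cyp2c9 = "unknown", vkorc1 = "unknown",
      visits = make_visits(35, 2.2))
  )
  star2 <- genotype_counts_from_cohort(cohort, "cyp2c9", variant = "*2")
  expect_equal(unname(star2$counts), c(1, 2, 0)) # *2/*3 counts as het for *2
  star3 <- genotype_counts_from_cohort(cohort, "cyp2c9", variant = "*3")
  expect_equal(unname(star3$counts), c(2, 1, 0))
  vko <- genotype_counts_from_cohort(cohort, "vkorc1")
  expect_equal(unname(vko$counts), c(1, 1, 1)) # unknown excluded
})
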