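make_toy_panel <- function(n = 3, seed = 101) {
  loc <- simulate_locus(n_snps = n, length = 3000 + 500 * n, seed = seed,
                        margin = 700)
  b <- build_extension_panel(loc$targets, loc$context)
  panel_design("toy", loc$targets, b$ext_primers)
}

test_that("expected product size is total length + 1 under identity mobility", {
  panel <- make_toy_panel(3)
  e <- expected_product_size(panel)
  expect_true(all(e$nominal == panel$ext_primers$total_len[
    match(e$rsid, panel$ext_primers$rsid)] + 1L))
  expect_identical(e$observed, as.numeric(e$nominal))
})

test_that("dye-specific mobility shifts only the matching allele", {
  panel <- make_toy_panel(3)
  ext <- panel$ext_primers[1, , drop = FALSE]
  mob <- mobility_model(offset = stats::setNames(-0.8, ext$dye_ref))
  e <- expected_product_size(ext, mob)
  er <- e[e$allele == "ref", ]
  ea <- e[e$allele == "alt", ]
  expect_equal(er$observed, er$nominal - 0.8)
  if (ea$dye != ext$dye_ref) expect_equal(ea$observed, as.numeric(ea$nominal))
  expect_error(mobility_model(slope = c(green = -1)), "> 0")
})

test_that("noise-free peak counts follow the het/hom rule", {
  panel <- make_toy_panel(5)
  het <- het_genotypes(panel)
  p_het <- simulate_peaks(panel, het, seed = 1)
  expect_identical(nrow(p_het), 10L)
  hom <- het
  hom$allele2 <- hom$allele1
  p_hom <- simulate_peaks(panel, hom, seed = 1)
  expect_identical(nrow(p_hom), 5L)
  mixed <- het
  mixed$allele2[1:2] <- mixed$allele1[1:2]
  p_mix <- simulate_peaks(panel, mixed, nonspecific = 2L, seed = 1)
  expect_identical(nrow(p_mix), 2L * 3L + 2L + 2L)
  # determinism under a fixed seed
  expect_identical(simulate_peaks(panel, mixed, size_jitter_sd = 0.3,
                                  nonspecific = 2L, seed = 7),
                   simulate_peaks(panel, mixed, size_jitter_sd = 0.3,
                                  nonspecific = 2L, seed = 7))
  bad <- het
  bad$allele1[1] <- setdiff(c("A", "C", "G", "T"),
                            c(panel$targets$ref_allele[1],
                              panel$targets$alt_allele[1]))[1]
  expect_error(simulate_peaks(panel, bad, seed = 1), "ref/alt")
})

test_that("calls recover single-allele, het and no-call cases with flags", {
  panel <- make_toy_panel(1, seed = 103)
  ext <- panel$ext_primers
  t <- panel$targets
  nominal <- ext$total_len + 1
  # single blue-ish peak near the ref allele -> hom ref
  pk <- data.frame(sample = "s", dye = ext$dye_ref, size_nt = nominal + 0.1,
                   height = 1000)
  calls <- call_genotypes(panel, pk)
  expect_identical(calls$status, "hom_ref")
  expect_identical(calls$allele1, t$ref_allele)
  # both dyes, balanced heights -> het
  pk2 <- rbind(pk, data.frame(sample = "s", dye = ext$dye_alt,
                              size_nt = nominal - 0.1, height = 800))
  calls2 <- call_genotypes(panel, pk2)
  expect_identical(calls2$status, "het")
  expect_setequal(c(calls2$allele1, calls2$allele2),
                  c(t$ref_allele, t$alt_allele))
  # an unassignable far peak changes nothing but is flagged non-specific
  pk3 <- rbind(pk2, data.frame(sample = "s", dye = "red", size_nt = 110,
                               height = 60))
  calls3 <- call_genotypes(panel, pk3)
  expect_identical(calls3$status, calls2$status)
  expect_identical(attr(calls3, "nonspecific_peaks"), 3L)
  # no peaks -> no-call
  calls4 <- call_genotypes(panel, pk3[3, , drop = FALSE])
  expect_identical(calls4$status, "no_call")
  expect_true(is.na(calls4$allele1))
  # extreme imbalance -> hom call for the major allele with a flag
  pk5 <- pk2
  pk5$height[2] <- 50
  calls5 <- call_genotypes(panel, pk5, het_ratio_min = 0.15)
  expect_identical(calls5$status, "hom_ref")
  expect_match(calls5$flags, "imbalance")
  # two same-dye peaks in one allele window -> ambiguity flag, not an error
  pk6 <- rbind(pk, transform(pk, size_nt = size_nt - 0.4, height = 400))
  calls6 <- call_genotypes(panel, pk6)
  expect_match(calls6$flags, "ambiguous_ref")
})

test_that("calls are invariant to peak-table row order", {
  panel <- make_toy_panel(6, seed = 104)
  gt <- random_genotypes(panel, seed = 11)
  peaks <- simulate_peaks(panel, gt, size_jitter_sd = 0.2, nonspecific = 2L,
                          seed = 12)
  c1 <- call_genotypes(panel, peaks)
  set.seed(13)
  shuffled <- peaks[sample(nrow(peaks)), , drop = FALSE]
  c2 <- call_genotypes(panel, shuffled)
  expect_identical(c1[, c("rsid", "allele1", "allele2", "status")],
                   c2[, c("rsid", "allele1", "allele2", "status")])
})

test_that("simulate -> call round trip is exact at zero noise", {
  panel <- make_toy_panel(8, seed = 105)
  for (s in 1:10) {
    gt <- random_genotypes(panel, seed = s)
    peaks <- simulate_peaks(panel, gt, size_jitter_sd = 0, nonspecific = 0L,
                            seed = s)
    calls <- call_genotypes(panel, peaks)
    expect_true(all(genotypes_match(gt, calls)))
  }
})

test_that("mobility fitting recovers planted parameters", {
  # exact recovery from noise-free observations with a planted red offset
  obs <- data.frame(dye = rep(c("red", "green", "blue", "black"), each = 4),
                    nominal = rep(c(20, 40, 60, 80), times = 4))
  obs$observed <- obs$nominal + ifelse(obs$dye == "red", 0.5, 0)
  m <- fit_mobility(obs)
  expect_equal(unname(m$offset["red"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(m$slope["red"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$offset["green"]), 0, tolerance = 1e-9)
  # single observation per dye: offset-only fit
  one <- data.frame(dye = c("red", "green", "blue", "black"),
                    nominal = 30, observed = c(30.4, 29.9, 30, 30.2))
  m1 <- fit_mobility(one)
  expect_equal(unname(m1$offset["red"]), 0.4, tolerance = 1e-9)
  expect_equal(unname(m1$slope["red"]), 1)
  # a dye with no observations is left at identity with a warning
  expect_warning(fit_mobility(obs[obs$dye != "black", ]), "black")
  # noisy recovery: 20 observations per dye, sd 0.2
  set.seed(106)
  noisy <- data.frame(dye = rep(c("red", "green", "blue", "black"), each = 20),
                      nominal = rep(seq(20, 115, length.out = 20), times = 4))
  true_off <- c(red = 0.6, green = -0.3, blue = 0.2, black = 0)
  true_slp <- c(red = 0.995, green = 1.004, blue = 1, black = 1.001)
  noisy$observed <- true_off[noisy$dye] + true_slp[noisy$dye] * noisy$nominal +
    rnorm(nrow(noisy), 0, 0.2)
  m2 <- fit_mobility(noisy)
  for (d in names(true_off)) {
    fit <- stats::lm(observed ~ nominal, data = noisy[noisy$dye == d, ])
    se <- sqrt(diag(stats::vcov(fit)))
    expect_lt(abs(m2$offset[d] - true_off[d]), 3 * se[1])
    expect_lt(abs(m2$slope[d] - true_slp[d]), 3 * se[2])
  }
})

test_that("genotype class arithmetic matches the biallelic model", {
  g <- genotype_classes(12)
  expect_identical(g$het_classes, 12L)
  expect_identical(g$hom_classes, 24L)
  expect_identical(g$min_peaks, 12L)
  expect_identical(g$max_peaks, 24L)
})
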