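test_that("digest_fragments cuts at recognition sites and conserves length", {
  set.seed(201)
  # no site
  amp <- gsub("GTAC", "GTTC", random_dna(100), fixed = TRUE)
  expect_identical(digest_fragments(amp, "GTAC"), nchar(amp))
  # one planted palindromic site at offset 40 (cut at the 5' end of the match)
  left <- gsub("CCGG", "CCTG", random_dna(40), fixed = TRUE)
  right <- gsub("CCGG", "CCTG", random_dna(56), fixed = TRUE)
  amp2 <- paste0(left, "CCGG", right)
  expect_identical(digest_fragments(amp2, "CCGG"), c(40L, 60L))
  expect_error(digest_fragments(amp2, "CCG"), ">= 4")
  expect_error(digest_fragments(amp2, "CCXG"), "IUPAC")
})

test_that("fragments partition the amplicon for random sequences and patterns", {
  set.seed(202)
  enz <- restriction_enzymes()
  for (i in 1:200) {
    L <- sample(50:300, 1)
    amp <- random_dna(L)
    pat <- sample(enz$pattern, 1)
    fr <- digest_fragments(amp, pat)
    expect_identical(sum(fr), L)
    expect_true(all(fr > 0))
  }
})

test_that("the seven verification enzymes ship with IUPAC patterns", {
  enz <- restriction_enzymes()
  expect_setequal(enz$enzyme, c("AvaII", "AatII", "BstXI", "RsaI", "MspI",
                                "HinfI", "Hpy188III"))
  expect_identical(enz$pattern[enz$enzyme == "AvaII"], "GGWCC")
  # AvaII's W expands to both A and T
  expect_identical(digest_fragments(paste0(strrep("T", 20), "GGACC",
                                           strrep("T", 20)), "GGWCC"),
                   digest_fragments(paste0(strrep("T", 20), "GGTCC",
                                           strrep("T", 20)), "GGWCC"))
})

test_that("differential digest distinguishes allele-destroying SNPs", {
  # alt allele destroys the only RsaI site -> informative
  set.seed(203)
  body <- gsub("GTAC", "GTTC", random_dna(96), fixed = TRUE)
  amp <- paste0(substr(body, 1, 38), "GTAC", substr(body, 39, 96))
  ctx <- reference_context("chr1", 1, amp)
  tgt <- snp_targets("s", "chr1", 40, "T", "G")   # GTAC -> GGAC
  res <- rflp_differential(tgt, ctx, "GTAC")
  expect_true(res$informative)
  expect_identical(res$fragments_ref, sort(c(38L, nchar(amp) - 38L)))
  expect_identical(res$fragments_alt, nchar(amp))
  # SNP outside any site, creating none -> uninformative
  tgt2 <- snp_targets("s2", "chr1", 10, substr(amp, 10, 10),
                      setdiff(c("A", "C", "G", "T"),
                              c(substr(amp, 10, 10), "G"))[1])
  res2 <- rflp_differential(tgt2, ctx, "GACGTC")
  expect_false(res2$informative)
  expect_error(rflp_differential(tgt, ctx, "GTAC", amplicon_start = 60),
               "inside the amplicon")
})

test_that("informativeness agrees with direct construction on random cases", {
  set.seed(204)
  enz <- restriction_enzymes()
  n_informative <- 0L
  for (i in 1:100) {
    L <- sample(60:200, 1)
    amp <- random_dna(L)
    pos <- sample(10:(L - 10), 1)
    ref <- substr(amp, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    pat <- sample(enz$pattern, 1)
    ctx <- reference_context("chrR", 1, amp)
    tgt <- snp_targets("r", "chrR", pos, ref, alt)
    res <- rflp_differential(tgt, ctx, pat)
    # oracle: digest the two explicitly substituted sequences
    alt_amp <- amp
    substr(alt_amp, pos, pos) <- alt
    want <- !identical(sort(digest_fragments(amp, pat)),
                       sort(digest_fragments(alt_amp, pat)))
    expect_identical(res$informative, want)
    n_informative <- n_informative + res$informative
  }
  expect_gt(n_informative, 0L)
})

test_that("check_panel rejects corrupted spacing and off-window products", {
  loc <- simulate_locus(n_snps = 6, length = 6000, seed = 205, margin = 700)
  b <- build_extension_panel(loc$targets, loc$context)
  panel <- panel_design("toy6", loc$targets, b$ext_primers)
  expect_identical(sum(check_panel(panel, "design")$severity == "error"), 0L)
  # corrupt a same-dye gap: give two primers sharing a dye the same length
  ext <- panel$ext_primers
  share <- NULL
  for (i in 1:(nrow(ext) - 1)) for (j in (i + 1):nrow(ext)) {
    if (length(intersect(c(ext$dye_ref[i], ext$dye_alt[i]),
                         c(ext$dye_ref[j], ext$dye_alt[j])))) {
      share <- c(i, j); break
    }
  }
  skip_if(is.null(share), "no same-dye pair in this toy panel")
  ext$total_len[share[2]] <- ext$total_len[share[1]]
  ext$tail_len[share[2]] <- ext$total_len[share[2]] - nchar(ext$core_seq[share[2]])
  skip_if(ext$tail_len[share[2]] < 0, "corruption would need a negative tail")
  ext$tail_seq[share[2]] <- tail_sequence(ext$tail_len[share[2]])
  bad <- panel_design("corrupt", loc$targets, ext)
  rep_bad <- check_panel(bad, "design")
  expect_gt(sum(rep_bad$severity == "error" & rep_bad$rule == "same_dye_gap"), 0L)
  # import mode downgrades the same violation to a warning
  rep_imp <- check_panel(bad, "import")
  expect_identical(sum(rep_imp$severity == "error"), 0L)
  expect_gt(sum(rep_imp$rule == "same_dye_gap"), 0L)
})

test_that("a product beyond the sizing standard is an error", {
  loc <- simulate_locus(n_snps = 1, length = 3000, seed = 206, margin = 700)
  b <- build_extension_panel(loc$targets, loc$context)
  ext <- b$ext_primers
  ext$total_len <- 121L
  ext$tail_len <- ext$total_len - nchar(ext$core_seq)
  ext$tail_seq <- tail_sequence(ext$tail_len)
  panel <- panel_design("long", loc$targets, ext)
  rep <- check_panel(panel, "design")
  expect_gt(sum(rep$severity == "error" & rep$rule == "readable_window"), 0L)
})

test_that("imported published 16-plex warns on nominal same-dye ties, no errors", {
  panel <- fixture_panel("HBS1L-MYB")
  rep <- check_panel(panel, mode = "import")
  expect_identical(sum(rep$severity == "error"), 0L)
  gap_msgs <- rep$message[rep$rule == "same_dye_gap"]
  # the three 32-nt primers share dyes pairwise through the middle primer
  expect_true(any(grepl("rs9399137", gap_msgs) & grepl("rs35959442", gap_msgs)))
  expect_true(any(grepl("rs9399137", gap_msgs) & grepl("rs11759553", gap_msgs)))
  # the 12-plex has no nominal same-dye conflicts at all
  rep12 <- check_panel(fixture_panel("BCL11A"), mode = "import")
  expect_identical(sum(rep12$rule == "same_dye_gap"), 0L)
  expect_identical(sum(rep12$severity == "error"), 0L)
})
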