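test_that("in_silico_pcr recovers a constructed product and handles absences", {
  set.seed(61)
  amp <- random_dna(50)
  fwd <- substr(amp, 1, 18)
  rev <- oracle_revcomp(substr(amp, 31, 50))
  hits <- in_silico_pcr(fwd, rev, c(chrA = amp))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length, 50L)
  none <- in_silico_pcr(fwd, "ACGTACGTACGTACGT", c(chrA = amp))
  expect_identical(nrow(none), 0L)
  expect_error(in_silico_pcr("ACGTACGT", rev, c(chrA = amp)), "12 nt")
})

test_that("in_silico_pcr respects window coordinates of a reference context", {
  set.seed(62)
  seq <- random_dna(200)
  ctx <- reference_context("chr2", 1001, seq)
  fwd <- substr(seq, 41, 60)
  rev <- oracle_revcomp(substr(seq, 121, 140))
  hits <- in_silico_pcr(fwd, rev, ctx)
  expect_identical(hits$start, 1041L)
  expect_identical(hits$end, 1140L)
  expect_identical(hits$length, 100L)
})

test_that("uniqueness_scan counts both orientations and matches a naive scan", {
  set.seed(63)
  g <- random_dna(5000)
  primer <- substr(g, 2001, 2020)
  expect_identical(uniqueness_scan(primer, c(g = g)), 1L +
                     length(gregexpr(oracle_revcomp(primer), g, fixed = TRUE)[[1]][
                       gregexpr(oracle_revcomp(primer), g, fixed = TRUE)[[1]] > 0]))
  pal <- "ACGTGCATATGCACGT"   # own reverse complement
  expect_identical(oracle_revcomp(pal), pal)
  expect_identical(uniqueness_scan(pal, c(s = paste0("AAAA", pal, "AAAA"))), 2L)
  # naive sliding-window oracle on a random subject
  probe <- substr(g, 101, 114)
  naive <- 0L
  rc <- oracle_revcomp(probe)
  for (i in 1:(nchar(g) - nchar(probe) + 1)) {
    w <- substr(g, i, i + nchar(probe) - 1)
    naive <- naive + (w == probe) + (w == rc)
  }
  expect_identical(uniqueness_scan(probe, c(g = g)), naive)
})

test_that("candidate enumeration encloses the SNP and respects bounds", {
  set.seed(64)
  loc <- simulate_locus(n_snps = 1, length = 400, seed = 64, margin = 150)
  cand <- enumerate_pcr_candidates(loc$targets, loc$context,
                                   max_amplicon = 120, max_candidates = 1000)
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$amplicon_len <= 120))
  expect_true(all(cand$amplicon_start < loc$targets$pos))
  expect_true(all(cand$amplicon_end > loc$targets$pos))
  cs <- design_constraints()
  expect_true(all(nchar(cand$fwd_seq) >= cs$pcr_len_min &
                    nchar(cand$fwd_seq) <= cs$pcr_len_max))
  expect_true(all(cand$tm_fwd >= cs$tm_min & cand$tm_fwd <= cs$tm_max))
  # deterministic ordering: score, then amplicon length, then start
  expect_false(is.unsorted(cand$score))
})

test_that("impossible SNP enclosure raises a coverage error", {
  set.seed(65)
  seq <- random_dna(400)
  tg <- snp_targets(c("a", "b"), "chr1", c(150, 230), c("A", "A"), c("C", "C"))
  ctx <- reference_context("chr1", 1, seq)
  expect_error(enumerate_pcr_candidates(tg, ctx, max_amplicon = 60),
               "coverage error")
})

test_that("top candidate equals brute-force enumeration of all legal pairs", {
  loc <- simulate_locus(n_snps = 1, length = 260, seed = 66, margin = 100)
  cs <- design_constraints()
  cand <- enumerate_pcr_candidates(loc$targets, loc$context, constraints = cs,
                                   max_amplicon = 100, max_candidates = 5)
  # oracle: enumerate every primer pair directly from the window sequence,
  # pre-scoring per-primer quantities once
  pos <- loc$targets$pos
  seq <- loc$context$sequence
  tmt <- (cs$tm_min + cs$tm_max) / 2
  fwd <- list()
  for (fs in max(1, pos - 100 + 1):(pos - cs$pcr_len_min)) {
    for (fl in cs$pcr_len_min:cs$pcr_len_max) {
      fe <- fs + fl - 1
      if (fe > pos - 1) break
      f <- substr(seq, fs, fe)
      tf <- melting_temperature(f)
      if (tf < cs$tm_min || tf > cs$tm_max) next
      fwd[[length(fwd) + 1]] <- list(fs = fs, f = f, tf = tf,
                                     hp = hairpin_screen(f))
    }
  }
  rev <- list()
  for (rs in (pos + 1):min(nchar(seq), pos + 99)) {
    for (rl in cs$pcr_len_min:cs$pcr_len_max) {
      re <- rs + rl - 1
      if (re > nchar(seq)) break
      r <- oracle_revcomp(substr(seq, rs, re))
      tr <- melting_temperature(r)
      if (tr < cs$tm_min || tr > cs$tm_max) next
      rev[[length(rev) + 1]] <- list(re = re, r = r, tr = tr,
                                     hp = hairpin_screen(r))
    }
  }
  best <- NULL
  for (F in fwd) for (R in rev) {
    alen <- R$re - F$fs + 1
    if (alen > 100) next
    pen <- max(0, F$hp - cs$hairpin_max_stem + 1) * 5 +
      max(0, R$hp - cs$hairpin_max_stem + 1) * 5 +
      max(0, duplex_screen(F$f, R$r)$run3 - cs$dimer_max_run3 + 1) * 5
    sc <- abs(F$tf - tmt) + abs(R$tr - tmt) + pen
    if (is.null(best) || sc < best$sc - 1e-12 ||
        (abs(sc - best$sc) < 1e-12 &&
         (alen < best$len || (alen == best$len && F$fs < best$fs)))) {
      best <- list(sc = sc, len = alen, fs = F$fs, f = F$f, r = R$r)
    }
  }
  expect_identical(cand$fwd_seq[1], best$f)
  expect_identical(cand$rev_seq[1], best$r)
  expect_equal(cand$score[1], best$sc)
})

test_that("reaction partitioning colours conflict graphs greedily and safely", {
  pairs <- data.frame(fwd_seq = replicate(5, random_dna(20, seed = NULL)),
                      rev_seq = replicate(5, random_dna(20, seed = NULL)),
                      stringsAsFactors = FALSE)
  no_conflict <- matrix(FALSE, 5, 5)
  ra <- partition_reactions(pairs, conflict = no_conflict)
  expect_identical(ra$n_reactions, 1L)
  expect_true(all(ra$reaction == "A"))
  full <- matrix(TRUE, 3, 3); diag(full) <- FALSE
  ra2 <- partition_reactions(pairs[1:3, ], conflict = full)
  expect_identical(ra2$n_reactions, 3L)
  expect_identical(sort(ra2$reaction), c("A", "B", "C"))
})

test_that("no conflicting pairs ever share a label on random graphs", {
  set.seed(68)
  for (i in 1:20) {
    n <- 6L
    adj <- matrix(FALSE, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      adj[a, b] <- adj[b, a] <- stats::runif(1) < 0.4
    }
    pairs <- data.frame(fwd_seq = rep("ACGTACGTACGTACGTA", n),
                        rev_seq = rep("ACGTACGTACGTACGTA", n))
    ra <- partition_reactions(pairs, conflict = adj)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (adj[a, b]) expect_false(ra$reaction[a] == ra$reaction[b])
    }
  }
})
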