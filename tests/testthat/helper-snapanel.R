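# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration / direct construction) and never call the code paths
# they are used to check.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

comp_chr <- c(A = "T", C = "G", G = "C", T = "A")

# naive reverse complement, independent of the package implementation
oracle_revcomp <- function(s) {
  paste(rev(comp_chr[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# exhaustive hairpin oracle: all (i, j, stem) triples checked directly
oracle_hairpin <- function(seq, min_stem = 3L, min_loop = 3L) {
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  best <- 0L
  for (s in seq_len(n)) {          # stem length
    for (i in s:n) {               # 3' end of 5' arm (arm = i-s+1 .. i)
      j <- i + min_loop + 1L
      while (j + s - 1L <= n) {
        arm5 <- b[(i - s + 1L):i]
        arm3 <- b[j:(j + s - 1L)]
        if (all(comp_chr[arm5] == rev(arm3))) best <- max(best, s)
        j <- j + 1L
      }
    }
  }
  if (best >= min_stem) best else 0L
}

# brute-force spacing oracle for small instances: enumerate every assignment
# with totals in [lb_i, cap], keep those satisfying the same-dye gap, pick
# minimal makespan then lexicographically smallest
oracle_spacing <- function(core_len, dye_pairs, constraints) {
  win <- constraints$readable_window
  cap <- as.integer(floor(win[2])) - 1L
  lb <- pmax(as.integer(core_len), as.integer(ceiling(win[1])) - 1L)
  doms <- lapply(lb, function(l) l:cap)
  grid <- as.matrix(expand.grid(doms, KEEP.OUT.ATTRS = FALSE))
  n <- length(core_len)
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(intersect(dye_pairs[[i]], dye_pairs[[j]]))) {
      ok <- ok & abs(grid[, i] - grid[, j]) >= constraints$same_dye_min_gap
    }
  }
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  mk <- apply(grid, 1, max)
  grid <- grid[mk == min(mk), , drop = FALSE]
  ord <- do.call(order, as.data.frame(grid))
  unname(grid[ord[1], ])
}

# exact chromatic number of a small graph by trying k = 1, 2, ... colourings
oracle_chromatic <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  for (k in 1:n) {
    cols <- rep(1L, n)
    repeat {
      bad <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (adj[i, j] && cols[i] == cols[j]) { bad <- TRUE; break }
        }
        if (bad) break
      }
      if (!bad) return(k)
      # increment base-k counter
      p <- 1L
      while (p <= n) {
        cols[p] <- cols[p] + 1L
        if (cols[p] <= k) break
        cols[p] <- 1L
        p <- p + 1L
      }
      if (p > n) break
    }
  }
  n
}

# all-heterozygous genotype table for a panel
het_genotypes <- function(panel) {
  tg <- panel$targets
  data.frame(rsid = tg$rsid, allele1 = tg$ref_allele, allele2 = tg$alt_allele,
             stringsAsFactors = FALSE)
}

# random genotype table (hom-ref / het / hom-alt equally likely)
random_genotypes <- function(panel, seed) {
  set.seed(seed)
  tg <- panel$targets
  pick <- sample(1:3, nrow(tg), replace = TRUE)
  data.frame(rsid = tg$rsid,
             allele1 = ifelse(pick == 3L, tg$alt_allele, tg$ref_allele),
             allele2 = ifelse(pick == 1L, tg$ref_allele, tg$alt_allele),
             stringsAsFactors = FALSE)
}

# genotype equality between a truth table and calls (unordered allele pairs)
genotypes_match <- function(truth, calls) {
  m <- merge(truth, as.data.frame(calls), by = "rsid")
  mapply(function(t1, t2, c1, c2) {
    !is.na(c1) && setequal(c(t1, t2), c(c1, c2)) &&
      (t1 == t2) == (c1 == c2)
  }, m$allele1.x, m$allele2.x, m$allele1.y, m$allele2.y)
}
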