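# Flanking PCR primer search, in-silico PCR, genome-uniqueness screening and
# multiplex reaction partitioning.

# all exact match start positions of pattern in subject (fixed string match)
.match_starts <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# sequences of a context-like object as a named character vector
.as_seq_set <- function(x) {
  if (inherits(x, "reference_context")) {
    stats::setNames(x$sequence, x$chrom)
  } else if (inherits(x, "toy_genome")) {
    x$sequences
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    toupper(x)
  } else {
    stop("expected a reference_context, toy_genome or character vector")
  }
}

#' In-silico PCR: exact-match amplicon prediction
#'
#' Finds every interval where `fwd_seq` matches the plus strand exactly and
#' `rev_seq` matches the minus strand exactly (i.e. its reverse complement
#' matches the plus strand), with the forward site 5' of the reverse site.
#' Amplicon length is the distance from the forward primer's 5' start to the
#' reverse primer's 3'-most plus-strand coordinate, inclusive.
#'
#' @param fwd_seq,rev_seq primer sequences (>= 12 nt), 5'->3'.
#' @param context a [reference_context()], a toy genome, or a (named)
#'   character vector of plus-strand sequences.
#' @return data.frame with columns `seqname`, `start`, `end`, `length`;
#'   zero rows when there is no product.
#' @export
in_silico_pcr <- function(fwd_seq, rev_seq, context) {
  fwd_seq <- toupper(fwd_seq); rev_seq <- toupper(rev_seq)
  if (nchar(fwd_seq) < 12L || nchar(rev_seq) < 12L) {
    stop("primers must be at least 12 nt for in-silico PCR")
  }
  seqs <- .as_seq_set(context)
  rc_rev <- reverse_complement(rev_seq)
  out <- list()
  offset <- if (inherits(context, "reference_context")) context$window_start - 1L else 0L
  for (nm in names(seqs)) {
    f <- .match_starts(fwd_seq, seqs[[nm]])
    r <- .match_starts(rc_rev, seqs[[nm]])
    if (!length(f) || !length(r)) next
    for (fs in f) {
      fe <- fs + nchar(fwd_seq) - 1L
      for (rs in r) {
        re <- rs + nchar(rev_seq) - 1L
        if (rs > fe) {
          out[[length(out) + 1L]] <- data.frame(
            seqname = nm, start = fs + offset, end = re + offset,
            length = re - fs + 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$seqname, res$start, res$end), , drop = FALSE]
}

#' Exact-occurrence uniqueness scan
#'
#' Counts exact occurrences of a primer and of its reverse complement across
#' a sequence set. This is the package's network-free stand-in for a BLAST
#' homology screen: a count above 1 flags the primer as non-unique. A
#' palindromic primer present once counts twice (both orientations match).
#'
#' @param primer_seq primer sequence (>= 12 nt).
#' @param context sequences to scan (see [in_silico_pcr()] for accepted types).
#' @return integer hit count.
#' @export
uniqueness_scan <- function(primer_seq, context) {
  primer_seq <- toupper(primer_seq)
  if (nchar(primer_seq) < 12L) stop("primer must be at least 12 nt")
  seqs <- .as_seq_set(context)
  rc <- reverse_complement(primer_seq)
  sum(vapply(seqs, function(s) {
    length(.match_starts(primer_seq, s)) + length(.match_starts(rc, s))
  }, integer(1)))
}

#' Enumerate and rank flanking PCR primer-pair candidates
#'
#' Enumerates every (forward, reverse) primer pair inside the reference
#' window whose amplicon strictly encloses all given SNP positions, is at
#' most `max_amplicon` bp, and whose primer lengths lie within the
#' constraint bounds. Candidates whose primer melting temperatures lie in the
#' constraint window are scored by
#' `|Tm_fwd - Tm_target| + |Tm_rev - Tm_target|` plus hairpin and cross-dimer
#' penalties, and returned in deterministic order (score, then smaller
#' amplicon, then leftmost start).
#'
#' @param targets [snp_targets()] rows to enclose (all in one amplicon).
#' @param context a [reference_context()] covering the targets with enough
#'   flank (at least `max_amplicon` each side).
#' @param constraints [design_constraints()].
#' @param max_amplicon maximum amplicon length (bp).
#' @param tm_target Tm the score is centred on; default midpoint of the
#'   constraint window.
#' @param tm_params Tm method, a [tm_params()].
#' @param max_candidates maximum number of candidates returned.
#' @return data.frame of class `pcr_candidates`: `fwd_seq`, `rev_seq`,
#'   `amplicon_start`, `amplicon_end`, `amplicon_len`, `tm_fwd`, `tm_rev`,
#'   `hairpin_fwd`, `hairpin_rev`, `cross_run3`, `score`, `tm_pass`. When no
#'   primer pair passes, the empty frame carries a per-rule failure tally in
#'   `attr(, "failure_tally")`.
#' @export
enumerate_pcr_candidates <- function(targets, context,
                                     constraints = design_constraints(),
                                     max_amplicon = 650L,
                                     tm_target = NULL,
                                     tm_params = snapanel::tm_params(),
                                     max_candidates = 50L) {
  stopifnot(inherits(context, "reference_context"))
  pos <- sort(targets$pos)
  span_lo <- pos[1]; span_hi <- pos[length(pos)]
  win_lo <- context$window_start
  win_hi <- context$window_start + nchar(context$sequence) - 1L
  if (span_hi - span_lo + 1L + 2L > max_amplicon) {
    stop(sprintf("coverage error: SNP span %d bp cannot be strictly enclosed in a %d bp amplicon",
                 span_hi - span_lo + 1L, max_amplicon))
  }
  if (any(targets$pos < win_lo) || any(targets$pos > win_hi)) {
    stop("coverage error: target positions outside the reference window")
  }
  if (is.null(tm_target)) tm_target <- (constraints$tm_min + constraints$tm_max) / 2

  lens <- constraints$pcr_len_min:constraints$pcr_len_max
  # forward primers: must end strictly before the leftmost SNP
  fwd <- .enumerate_primers(context, lens,
                            start_min = max(win_lo, span_lo - max_amplicon + 1L),
                            start_max = span_lo - min(lens),
                            end_max = span_lo - 1L)
  # reverse primers: plus-strand site must start strictly after the rightmost SNP
  rev <- .enumerate_primers(context, lens,
                            start_min = span_hi + 1L,
                            start_max = min(win_hi, span_lo + max_amplicon - 1L),
                            end_max = min(win_hi, span_lo + max_amplicon - 1L))
  tally <- c(no_fwd_site = nrow(fwd) == 0L, no_rev_site = nrow(rev) == 0L,
             fwd_tm = 0L, rev_tm = 0L, amplicon_len = 0L)
  empty <- data.frame(fwd_seq = character(0), rev_seq = character(0),
                      amplicon_start = integer(0), amplicon_end = integer(0),
                      amplicon_len = integer(0), tm_fwd = numeric(0),
                      tm_rev = numeric(0), hairpin_fwd = integer(0),
                      hairpin_rev = integer(0), cross_run3 = integer(0),
                      score = numeric(0), tm_pass = logical(0))
  class(empty) <- c("pcr_candidates", "data.frame")
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  fwd$tm <- melting_temperature(fwd$seq, tm_params)
  rev$tm <- melting_temperature(reverse_complement(rev$seq), tm_params)
  fwd_ok <- fwd$tm >= constraints$tm_min & fwd$tm <= constraints$tm_max
  rev_ok <- rev$tm >= constraints$tm_min & rev$tm <= constraints$tm_max
  tally["fwd_tm"] <- sum(!fwd_ok); tally["rev_tm"] <- sum(!rev_ok)
  fwd <- fwd[fwd_ok, , drop = FALSE]; rev <- rev[rev_ok, , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  alen <- rev$end[grid$r] - fwd$start[grid$f] + 1L
  keep <- alen <= max_amplicon
  tally["amplicon_len"] <- sum(!keep)
  grid <- grid[keep, , drop = FALSE]; alen <- alen[keep]
  if (nrow(grid) == 0L) {
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  fseq <- fwd$seq[grid$f]
  rseq <- reverse_complement(rev$seq[grid$r])
  hp_fwd_all <- vapply(fwd$seq, hairpin_screen, integer(1))
  hp_rev_all <- vapply(stats::setNames(reverse_complement(rev$seq), NULL),
                       hairpin_screen, integer(1))
  hp_f <- hp_fwd_all[grid$f]
  hp_r <- hp_rev_all[grid$r]
  base <- abs(fwd$tm[grid$f] - tm_target) + abs(rev$tm[grid$r] - tm_target) +
    pmax(0L, hp_f - constraints$hairpin_max_stem + 1L) * 5 +
    pmax(0L, hp_r - constraints$hairpin_max_stem + 1L) * 5
  # the cross-dimer penalty only adds to the base score, so pairs visited in
  # ascending base order can stop once none can enter the reported set
  ord <- order(base, alen, fwd$start[grid$f])
  cross <- integer(length(ord))
  final <- rep(NA_real_, length(ord))
  kth <- Inf
  done <- 0L
  for (idx in ord) {
    if (done >= max_candidates && base[idx] > kth + 1e-9) break
    cross[idx] <- duplex_screen(fseq[idx], rseq[idx])$run3
    final[idx] <- base[idx] +
      max(0L, cross[idx] - constraints$dimer_max_run3 + 1L) * 5
    done <- done + 1L
    if (done >= max_candidates) {
      kth <- sort(final[!is.na(final)], partial = max_candidates)[max_candidates]
    }
  }
  keep2 <- which(!is.na(final))
  res <- data.frame(fwd_seq = fseq[keep2], rev_seq = rseq[keep2],
                    amplicon_start = fwd$start[grid$f][keep2],
                    amplicon_end = rev$end[grid$r][keep2],
                    amplicon_len = alen[keep2],
                    tm_fwd = fwd$tm[grid$f][keep2],
                    tm_rev = rev$tm[grid$r][keep2],
                    hairpin_fwd = hp_f[keep2], hairpin_rev = hp_r[keep2],
                    cross_run3 = cross[keep2],
                    score = final[keep2], tm_pass = TRUE,
                    stringsAsFactors = FALSE)
  res <- res[order(res$score, res$amplicon_len, res$amplicon_start), , drop = FALSE]
  res <- utils::head(res, max_candidates)
  rownames(res) <- NULL
  class(res) <- c("pcr_candidates", "data.frame")
  attr(res, "failure_tally") <- tally
  res
}

# enumerate plus-strand primer sites with start in [start_min, start_max],
# end <= end_max, lengths in lens; returns genomic coords and sequences
.enumerate_primers <- function(context, lens, start_min, start_max, end_max) {
  out <- list()
  start_min <- max(start_min, context$window_start)
  win_hi <- context$window_start + nchar(context$sequence) - 1L
  end_max <- min(end_max, win_hi)
  if (start_max >= start_min) {
    for (st in start_min:start_max) {
      for (L in lens) {
        en <- st + L - 1L
        if (en > end_max) break
        out[[length(out) + 1L]] <- c(st, en)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  seqs <- substring(context$sequence,
                    m[, 1] - context$window_start + 1L,
                    m[, 2] - context$window_start + 1L)
  keep <- !grepl("N", seqs, fixed = TRUE)
  data.frame(start = m[keep, 1], end = m[keep, 2], seq = seqs[keep],
             stringsAsFactors = FALSE)
}

#' Partition primer pairs into compatible multiplex reactions
#'
#' Builds a conflict graph over amplicon primer pairs (default conflict: some
#' cross-pair 3'-anchored complementary run of at least the constraint
#' threshold) and greedily colours it, visiting nodes by descending conflict
#' degree with ties broken by input order. Labels are A, B, C, ...
#'
#' @param pairs data.frame with columns `fwd_seq` and `rev_seq` (one row per
#'   amplicon), e.g. the fixture PCR table.
#' @param conflict optional logical adjacency matrix, or a function
#'   `f(pairs, i, j)` returning TRUE when rows i and j must not share a
#'   reaction; default uses the cross-dimer rule.
#' @param constraints [design_constraints()] (threshold for the default rule).
#' @return object of class `reaction_assignment`: list with `reaction`
#'   (character vector per row) and `n_reactions`.
#' @export
partition_reactions <- function(pairs, conflict = NULL,
                                constraints = design_constraints()) {
  n <- nrow(pairs)
  if (is.matrix(conflict)) {
    adj <- conflict
  } else {
    if (is.null(conflict)) {
      conflict <- function(pairs, i, j) {
        ps <- c(pairs$fwd_seq[i], pairs$rev_seq[i])
        qs <- c(pairs$fwd_seq[j], pairs$rev_seq[j])
        for (a in ps) for (b in qs) {
          if (duplex_screen(a, b)$run3 >= constraints$dimer_max_run3) return(TRUE)
        }
        FALSE
      }
    }
    adj <- matrix(FALSE, n, n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        adj[i, j] <- adj[j, i] <- isTRUE(conflict(pairs, i, j))
      }
    }
  }
  deg <- rowSums(adj)
  ord <- order(-deg, seq_len(n))
  colour <- integer(n)
  for (v in ord) {
    used <- colour[adj[v, ] & colour > 0L]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    colour[v] <- c0
  }
  structure(list(reaction = LETTERS[colour], n_reactions = max(colour)),
            class = "reaction_assignment")
}

#' @export
print.reaction_assignment <- function(x, ...) {
  cat(sprintf("<reaction_assignment> %d reaction(s): %s\n", x$n_reactions,
              paste(x$reaction, collapse = " ")))
  invisible(x)
}
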