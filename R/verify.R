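# Independent panel-constraint checker and in-silico PCR-RFLP predictor.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# IUPAC pattern -> regex character-class pattern (used with perl lookahead
# for overlapping matches)
.iupac_regex <- function(pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (any(!chars %in% names(.IUPAC))) {
    stop("invalid IUPAC code in recognition pattern: ",
         paste(setdiff(chars, names(.IUPAC)), collapse = ", "))
  }
  paste0(vapply(chars, function(ch) {
    ex <- .IUPAC[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

# reverse complement of an IUPAC pattern
.iupac_revcomp <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(pattern), "")[[1]]]), collapse = "")
}

# overlapping match starts of an IUPAC pattern in a plain sequence
.iupac_match_starts <- function(pattern, seq) {
  rx <- paste0("(?=", .iupac_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Built-in restriction enzyme recognition patterns
#'
#' The seven enzymes used for orthogonal PCR-RFLP verification of the
#' packaged panels, with their IUPAC recognition patterns.
#'
#' @return data.frame with columns `enzyme`, `pattern`, `assayed_rsid`.
#' @export
restriction_enzymes <- function() {
  utils::read.delim(system.file("extdata", "enzymes.tsv", package = "snapanel"),
                    stringsAsFactors = FALSE)
}

#' Predict restriction fragments of an amplicon
#'
#' Matches the IUPAC recognition pattern against the plus strand (overlapping
#' matches included) and cuts at the 5' end of each match plus `cut_offset`.
#' Non-palindromic patterns are additionally scanned in reverse-complement
#' orientation (sites read on the minus strand), unless `scan_reverse` is
#' FALSE. Fragment lengths always partition the amplicon.
#'
#' @param amplicon_seq amplicon sequence (plus strand).
#' @param pattern IUPAC recognition pattern, length >= 4.
#' @param cut_offset cut position relative to the 5' end of the match
#'   (0 = immediately before the first matched base).
#' @param scan_reverse also scan the reverse complement of a non-palindromic
#'   pattern; default is automatic (TRUE only when non-palindromic).
#' @return sorted integer vector of fragment lengths (bp).
#' @export
digest_fragments <- function(amplicon_seq, pattern, cut_offset = 0L,
                             scan_reverse = NULL) {
  amplicon_seq <- toupper(amplicon_seq)
  if (nchar(pattern) < 4L) stop("recognition pattern must be >= 4 nt")
  L <- nchar(amplicon_seq)
  starts <- .iupac_match_starts(pattern, amplicon_seq)
  rc_pat <- .iupac_revcomp(pattern)
  if (is.null(scan_reverse)) scan_reverse <- !identical(rc_pat, toupper(pattern))
  if (scan_reverse && !identical(rc_pat, toupper(pattern))) {
    # minus-strand sites: a cut at the 5' end of the minus-strand match sits
    # at the 3' end of its plus-strand image
    rs <- .iupac_match_starts(rc_pat, amplicon_seq)
    starts <- c(starts, rs + nchar(pattern) - 2L * cut_offset)
  }
  cuts <- sort(unique(starts - 1L + cut_offset))
  cuts <- cuts[cuts > 0L & cuts < L]
  diff(c(0L, cuts, L))
}

#' Differential-digest (PCR-RFLP) prediction for a SNP
#'
#' Builds the two allele-specific amplicon sequences, digests each with the
#' given recognition pattern, and reports whether the fragment profiles
#' differ (an informative assay: one allele creates or destroys a site) or
#' not (uninformative).
#'
#' @param target one row of [snp_targets()].
#' @param context a [reference_context()] whose window is (or contains) the
#'   amplicon.
#' @param pattern IUPAC recognition pattern.
#' @param amplicon_start,amplicon_end amplicon bounds (default: the whole
#'   context window).
#' @param ... passed to [digest_fragments()].
#' @return object of class `rflp_assay`: list with `rsid`, `pattern`,
#'   `fragments_ref`, `fragments_alt`, `informative`.
#' @export
rflp_differential <- function(target, context, pattern,
                              amplicon_start = NULL, amplicon_end = NULL, ...) {
  if (is.null(amplicon_start)) amplicon_start <- context$window_start
  if (is.null(amplicon_end)) {
    amplicon_end <- context$window_start + nchar(context$sequence) - 1L
  }
  pos <- target$pos[1]
  if (pos < amplicon_start || pos > amplicon_end) {
    stop("SNP must lie inside the amplicon")
  }
  amp <- context_subseq(context, amplicon_start, amplicon_end)
  off <- pos - amplicon_start + 1L
  mk_allele <- function(base) {
    s <- amp
    substr(s, off, off) <- base
    s
  }
  fr <- digest_fragments(mk_allele(target$ref_allele[1]), pattern, ...)
  fa <- digest_fragments(mk_allele(target$alt_allele[1]), pattern, ...)
  structure(list(rsid = target$rsid[1], pattern = toupper(pattern),
                 fragments_ref = sort(fr), fragments_alt = sort(fa),
                 informative = !identical(sort(fr), sort(fa))),
            class = "rflp_assay")
}

#' @export
print.rflp_assay <- function(x, ...) {
  cat(sprintf("<rflp_assay> %s (%s): ref [%s] vs alt [%s] -> %s\n",
              x$rsid, x$pattern,
              paste(x$fragments_ref, collapse = ", "),
              paste(x$fragments_alt, collapse = ", "),
              if (x$informative) "informative" else "uninformative"))
  invisible(x)
}

#' Independent panel-constraint checker
#'
#' Verifies a panel against its design constraints and returns per-rule
#' verdicts instead of raising errors. In `design` mode a nominal same-dye
#' length gap below `same_dye_min_gap` is an error; in `import` mode the same
#' gap is downgraded to a warning, because published panels may rely on
#' dye/sequence-specific mobility to separate nominally coincident products.
#' Melting-temperature window checks are always report-only warnings (the
#' published window's exact formula is not known).
#'
#' @param panel a [panel_design()].
#' @param mode "design" (newly designed panel) or "import" (published panel).
#' @param tm_params a [tm_params()] for the report-only Tm checks.
#' @return object of class `panel_report`: data.frame with columns `rule`,
#'   `severity` ("error"/"warning"), `message`; a panel passes iff zero
#'   errors (`attr(, "pass")`).
#' @export
check_panel <- function(panel, mode = c("design", "import"),
                        tm_params = snapanel::tm_params()) {
  mode <- match.arg(mode)
  cs <- panel$constraints
  ext <- panel$ext_primers
  verdicts <- list()
  add <- function(rule, severity, message) {
    verdicts[[length(verdicts) + 1L]] <<- data.frame(
      rule = rule, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }

  # readable sizing window on extension products (nominal size = total + 1)
  nominal <- ext$total_len + 1L
  off <- nominal < cs$readable_window[1] | nominal > cs$readable_window[2]
  for (i in which(off)) {
    add("readable_window", "error",
        sprintf("%s: product %d nt outside readable window [%g, %g]",
                ext$rsid[i], nominal[i], cs$readable_window[1],
                cs$readable_window[2]))
  }

  # dye validity
  map <- dye_map()
  for (i in seq_len(nrow(ext))) {
    exp_ref <- dye_for_base(ext$detected_base_ref[i], map)
    exp_alt <- dye_for_base(ext$detected_base_alt[i], map)
    if (ext$dye_ref[i] != exp_ref || ext$dye_alt[i] != exp_alt) {
      add("dye_map", "error", sprintf("%s: dyes do not match detected bases",
                                      ext$rsid[i]))
    }
    if (ext$dye_ref[i] == ext$dye_alt[i]) {
      add("dye_map", "error", sprintf("%s: both alleles map to the same dye",
                                      ext$rsid[i]))
    }
  }

  # same-dye nominal length gaps
  sev_gap <- if (mode == "design") "error" else "warning"
  if (nrow(ext) > 1L) {
    for (i in seq_len(nrow(ext) - 1L)) for (j in (i + 1L):nrow(ext)) {
      shared <- intersect(c(ext$dye_ref[i], ext$dye_alt[i]),
                          c(ext$dye_ref[j], ext$dye_alt[j]))
      if (!length(shared)) next
      gap <- abs(ext$total_len[i] - ext$total_len[j])
      if (gap < cs$same_dye_min_gap) {
        add("same_dye_gap", sev_gap,
            sprintf("%s vs %s: same-dye (%s) nominal gap %d nt < %d nt%s",
                    ext$rsid[i], ext$rsid[j], paste(shared, collapse = "/"),
                    gap, cs$same_dye_min_gap,
                    if (gap < cs$empirical_min_gap)
                      sprintf(" (below the %d nt empirical resolution floor)",
                              cs$empirical_min_gap) else ""))
      }
    }
  }

  # primer structure invariants
  for (i in seq_len(nrow(ext))) {
    if (!is.na(ext$tail_seq[i]) &&
        nchar(ext$tail_seq[i]) + nchar(ext$core_seq[i]) != ext$total_len[i]) {
      add("total_length", "error",
          sprintf("%s: tail (%d) + core (%d) != total (%d)", ext$rsid[i],
                  nchar(ext$tail_seq[i]), nchar(ext$core_seq[i]),
                  ext$total_len[i]))
    }
  }

  # coverage: one extension primer per target
  missing <- setdiff(panel$targets$rsid, ext$rsid)
  for (rs in missing) add("coverage", "error", paste0(rs, ": no extension primer"))

  # PCR primer rules (when PCR pairs are attached)
  if (is.data.frame(panel$pcr_pairs) && nrow(panel$pcr_pairs) > 0L) {
    pp <- panel$pcr_pairs
    sev_len <- if (mode == "design") "error" else "warning"
    for (i in seq_len(nrow(pp))) {
      for (side in c("fwd_seq", "rev_seq")) {
        L <- nchar(pp[[side]][i])
        if (L < cs$pcr_len_min || L > cs$pcr_len_max) {
          add("pcr_primer_length", sev_len,
              sprintf("pair %d %s: length %d outside [%d, %d]", i, side, L,
                      cs$pcr_len_min, cs$pcr_len_max))
        }
        tm <- melting_temperature(pp[[side]][i], tm_params)
        if (tm < cs$tm_min || tm > cs$tm_max) {
          add("pcr_primer_tm", "warning",
              sprintf("pair %d %s: estimated Tm %.1f outside [%g, %g] (report only)",
                      i, side, tm, cs$tm_min, cs$tm_max))
        }
      }
    }
    covered <- unlist(strsplit(pp$covered_rsids, ",", fixed = TRUE))
    uncovered <- setdiff(panel$targets$rsid, trimws(covered))
    for (rs in uncovered) add("coverage", "error", paste0(rs, ": no PCR amplicon"))
  }

  out <- if (length(verdicts)) do.call(rbind, verdicts) else
    data.frame(rule = character(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("panel_report", "data.frame")
  attr(out, "pass") <- !any(out$severity == "error")
  attr(out, "mode") <- mode
  out
}

#' @export
print.panel_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat(sprintf("<panel_report> (%s mode) %s: %d error(s), %d warning(s)\n",
              attr(x, "mode"), if (attr(x, "pass")) "PASS" else "FAIL",
              n_err, n_warn))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
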