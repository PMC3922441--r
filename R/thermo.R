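# Melting-temperature estimation and combinatorial primer screening.
#
# The dimer/hairpin screens are exact run-finding over all ungapped
# antiparallel alignments, not free-energy folds: a primer is flagged on the
# length of its longest Watson-Crick complementary run, which is what matters
# for extension artefacts at the 3' end.

# unified nearest-neighbour parameters (Allawi & SantaLucia):
# dH kcal/mol, dS cal/(mol K), keyed by the top-strand dinucleotide
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.NN_INIT <- list(GC = c(dh = 0.1, ds = -2.8), AT = c(dh = 2.3, ds = 4.1))
.GAS_R <- 1.987 # cal/(mol K)

#' Melting-temperature estimation parameters
#'
#' @param method "nearest_neighbor" (unified parameters with entropy salt
#'   correction; the default scoring method) or "wallace" (2AT + 4GC rule,
#'   cheap and closed-form).
#' @param na_mM monovalent salt concentration, mM.
#' @param oligo_nM total oligonucleotide concentration, nM.
#' @return object of class `tm_params`.
#' @export
tm_params <- function(method = c("nearest_neighbor", "wallace"),
                      na_mM = 50, oligo_nM = 250) {
  method <- match.arg(method)
  if (na_mM <= 0 || oligo_nM <= 0) stop("concentrations must be > 0")
  structure(list(method = method, na_mM = na_mM, oligo_nM = oligo_nM),
            class = "tm_params")
}

#' Oligonucleotide melting temperature
#'
#' Wallace rule: `2(#A + #T) + 4(#G + #C)`. Nearest-neighbour: unified
#' dinucleotide enthalpies/entropies, duplex-initiation terms per terminal
#' base pair, entropy salt correction `0.368 (N-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15` for non-self-complementary
#' oligos at total strand concentration CT.
#'
#' @param seq character vector of sequences (>= 8 nt, A/C/G/T only).
#' @param params a [tm_params()].
#' @return numeric vector of temperatures in degrees C.
#' @export
melting_temperature <- function(seq, params = tm_params()) {
  seq <- toupper(as.character(seq))
  if (any(grepl("[^ACGT]", seq))) stop("Tm input must be A/C/G/T only")
  min_len <- if (params$method == "wallace") 2L else 8L
  if (any(nchar(seq) < min_len)) {
    stop("Tm input must be at least ", min_len, " nt")
  }
  if (params$method == "wallace") {
    vapply(seq, function(s) {
      b <- table(factor(strsplit(s, "")[[1]], levels = .BASES))
      2 * (b[["A"]] + b[["T"]]) + 4 * (b[["G"]] + b[["C"]])
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    vapply(seq, .tm_nn, numeric(1), params = params, USE.NAMES = FALSE)
  }
}

.tm_nn <- function(s, params) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  for (term in c(b[1], b[n])) {
    init <- if (term %in% c("G", "C")) .NN_INIT$GC else .NN_INIT$AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1) * log(params$na_mM / 1000)
  k <- params$oligo_nM * 1e-9 / 4
  1000 * dh / (ds + .GAS_R * log(k)) - 273.15
}

# longest equal run between strings a and d over all diagonal offsets;
# anchored = run touching a's last char or d's first char
.diag_runs <- function(a, d) {
  av <- strsplit(a, "")[[1]]
  dv <- strsplit(d, "")[[1]]
  na <- length(av); nd <- length(dv)
  best <- 0L; best_anchor <- 0L
  for (k in (-(nd - 1L)):(na - 1L)) {
    i <- max(1L, 1L + k):min(na, nd + k)
    eq <- av[i] == dv[i - k]
    r <- rle(eq)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      len <- r$lengths[j]
      if (len > best) best <- len
      ia <- i[starts[j]:ends[j]]
      if ((na %in% ia || 1L %in% (ia - k)) && len > best_anchor) {
        best_anchor <- len
      }
    }
  }
  c(max_run = best, run3 = best_anchor)
}

#' Cross/self-dimer screen
#'
#' Scans all ungapped antiparallel alignments of `seq_a` against `seq_b` and
#' reports the longest contiguous Watson-Crick complementary run, plus the
#' longest such run that involves either sequence's 3' terminus (the run that
#' matters for polymerase-extendable dimers). Self-dimers: pass the same
#' sequence twice.
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @return object of class `duplex_report`: list with `max_run`, `run3`,
#'   `score` (`max_run + 2 * run3`).
#' @export
duplex_screen <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  r <- .diag_runs(seq_a, reverse_complement(seq_b))
  structure(list(max_run = unname(r["max_run"]), run3 = unname(r["run3"]),
                 score = unname(r["max_run"] + 2L * r["run3"])),
            class = "duplex_report")
}

#' @export
print.duplex_report <- function(x, ...) {
  cat(sprintf("<duplex_report> max run %d bp, 3'-anchored %d bp (score %d)\n",
              x$max_run, x$run3, x$score))
  invisible(x)
}

#' Hairpin screen by exhaustive stem enumeration
#'
#' Finds the longest self-complementary stem closing a loop of at least
#' `min_loop` nt, by scanning every candidate closing pair and extending
#' outward. Returns 0 when no stem of at least `min_stem` bp exists.
#'
#' @param seq nucleotide sequence.
#' @param min_stem minimum reportable stem length (bp), >= 3.
#' @param min_loop minimum loop length (nt), >= 3.
#' @return integer, longest stem length (bp), or 0.
#' @export
hairpin_screen <- function(seq, min_stem = 3L, min_loop = 3L) {
  if (min_stem < 3L || min_loop < 3L) stop("min_stem and min_loop must be >= 3")
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  comp <- .COMP[b]
  best <- 0L
  if (n < 2L * min_stem + min_loop) return(best)
  for (i in seq_len(n)) {        # i = 3' base of the 5' stem arm
    jmin <- i + min_loop + 1L
    if (jmin > n) break
    for (j in jmin:n) {          # j = 5' base of the 3' stem arm
      if (comp[i] != b[j]) next
      s <- 1L
      while (i - s >= 1L && j + s <= n && comp[i - s] == b[j + s]) s <- s + 1L
      if (s > best) best <- s
    }
  }
  if (best >= min_stem) best else 0L
}
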