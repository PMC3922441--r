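# Electropherogram simulation and decoding of peak tables into genotypes.
#
# Nominal product sizes are integers (primer total length + 1 incorporated
# ddNTP); observed sizes are fractional because capillary sizing against the
# internal standard is continuous and dye- and sequence-dependent mobility
# shifts the apparent size, especially below ~50 nt on POP-7.

#' Per-dye affine mobility model
#'
#' Maps nominal product size to predicted observed size as
#' `observed = offset + slope * nominal`, independently per dye. The default
#' is the identity for all four dyes.
#'
#' @param offset named numeric, offset in nt per dye colour.
#' @param slope named numeric, slope per dye colour (must be > 0).
#' @param map a [dye_map()] (defines the colour set).
#' @return object of class `mobility_model`.
#' @export
mobility_model <- function(offset = NULL, slope = NULL, map = dye_map()) {
  dyes <- unname(unclass(map))
  off <- stats::setNames(rep(0, length(dyes)), dyes)
  slp <- stats::setNames(rep(1, length(dyes)), dyes)
  if (!is.null(offset)) off[names(offset)] <- offset
  if (!is.null(slope)) slp[names(slope)] <- slope
  if (any(slp <= 0)) stop("mobility slopes must be > 0 (predicted size must increase with nominal size)")
  structure(list(offset = off, slope = slp), class = "mobility_model")
}

#' @export
print.mobility_model <- function(x, ...) {
  cat("<mobility_model> observed = offset + slope * nominal\n")
  print(data.frame(dye = names(x$offset), offset = unname(x$offset),
                   slope = unname(x$slope)))
  invisible(x)
}

predict_observed_size <- function(mobility, dye, nominal) {
  unname(mobility$offset[dye] + mobility$slope[dye] * nominal)
}

#' Expected product sizes for a panel's extension primers
#'
#' Each extension product is the primer plus one incorporated ddNTP, so the
#' nominal size is `total_len + 1` for both alleles; the observed size may
#' differ between alleles through the dye-specific mobility parameters.
#'
#' @param panel a [panel_design()], or an extension-primer data.frame with
#'   columns `rsid`, `total_len`, `detected_base_ref/alt`, `dye_ref/alt`.
#' @param mobility a [mobility_model()]; defaults to the panel's own.
#' @return data.frame with one row per (primer, allele): `rsid`, `allele`
#'   ("ref"/"alt"), `base` (primer-strand incorporated base), `dye`,
#'   `nominal`, `observed`.
#' @export
expected_product_size <- function(panel, mobility = NULL) {
  ext <- if (inherits(panel, "panel_design")) panel$ext_primers else panel
  if (is.null(mobility)) {
    mobility <- if (inherits(panel, "panel_design")) panel$mobility else mobility_model()
  }
  nominal <- ext$total_len + 1L
  out <- rbind(
    data.frame(rsid = ext$rsid, allele = "ref", base = ext$detected_base_ref,
               dye = ext$dye_ref, nominal = nominal, stringsAsFactors = FALSE),
    data.frame(rsid = ext$rsid, allele = "alt", base = ext$detected_base_alt,
               dye = ext$dye_alt, nominal = nominal, stringsAsFactors = FALSE))
  out$observed <- predict_observed_size(mobility, out$dye, out$nominal)
  out[order(match(out$rsid, ext$rsid), out$allele), , drop = FALSE]
}

#' Simulate an electropherogram peak table
#'
#' Produces one peak per carried allele per SNP (two same-size peaks of
#' different colour for a heterozygote, one for a homozygote) at the expected
#' observed size plus Gaussian sizing jitter, plus optional low-height
#' non-specific peaks placed uniformly in the readable window.
#'
#' @param panel a [panel_design()].
#' @param genotypes data.frame with columns `rsid`, `allele1`, `allele2`
#'   (plus-strand bases drawn from each target's ref/alt pair).
#' @param size_jitter_sd Gaussian sd of the sizing error, nt.
#' @param height_mean,height_cv lognormal-ish peak height model: heights are
#'   `height_mean * exp(rnorm(0, height_cv))`.
#' @param nonspecific number of non-specific peaks to add.
#' @param seed integer seed fixing all randomness.
#' @return data.frame of class `peak_table` with columns `sample`, `dye`,
#'   `size_nt`, `height`.
#' @export
simulate_peaks <- function(panel, genotypes, size_jitter_sd = 0,
                           height_mean = 1000, height_cv = 0.15,
                           nonspecific = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- panel$ext_primers
  tg <- panel$targets
  exp_sz <- expected_product_size(panel)
  peaks <- list()
  for (i in seq_len(nrow(ext))) {
    rs <- ext$rsid[i]
    g <- genotypes[genotypes$rsid == rs, , drop = FALSE]
    if (nrow(g) != 1L) stop("genotypes must cover every panel target exactly once (", rs, ")")
    t <- tg[tg$rsid == rs, , drop = FALSE]
    alleles <- unique(c(g$allele1, g$allele2))
    if (any(!alleles %in% c(t$ref_allele, t$alt_allele))) {
      stop("genotype allele not in the target's ref/alt pair for ", rs)
    }
    for (a in alleles) {
      which_allele <- if (a == t$ref_allele) "ref" else "alt"
      e <- exp_sz[exp_sz$rsid == rs & exp_sz$allele == which_allele, , drop = FALSE]
      peaks[[length(peaks) + 1L]] <- data.frame(
        sample = "sim", dye = e$dye,
        size_nt = e$observed + stats::rnorm(1, 0, size_jitter_sd),
        height = height_mean * exp(stats::rnorm(1, 0, height_cv)),
        stringsAsFactors = FALSE)
    }
  }
  if (nonspecific > 0L) {
    win <- panel$constraints$readable_window
    dyes <- unname(unclass(dye_map()))
    for (j in seq_len(nonspecific)) {
      peaks[[length(peaks) + 1L]] <- data.frame(
        sample = "sim", dye = sample(dyes, 1L),
        size_nt = stats::runif(1, win[1], win[2]),
        height = stats::runif(1, 0.03, 0.08) * height_mean,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Decode a peak table into genotype calls
#'
#' A peak supports an allele when its dye matches and its observed size is
#' within `size_tol` of the allele's expected observed size. Per SNP: both
#' alleles supported with minor/major height ratio at least `het_ratio_min`
#' gives a heterozygous call; exactly one supported allele gives a homozygous
#' call; none gives a no-call. Genotypes are reported as plus-strand allele
#' pairs. Peaks supporting no allele are flagged non-specific and never
#' change calls; two same-dye peaks inside one allele's window flag the call
#' as ambiguous (the taller peak is used).
#'
#' @param panel a [panel_design()].
#' @param peaks a peak table (`dye`, `size_nt`, `height`), e.g. from
#'   [simulate_peaks()] or [read_peaks()].
#' @param size_tol size matching tolerance, nt.
#' @param het_ratio_min minimum minor/major height ratio for a het call.
#' @return data.frame of class `genotype_calls`: `rsid`, `allele1`,
#'   `allele2`, `status` (hom_ref/hom_alt/het/no_call), `supporting`
#'   (comma-separated peak row indices), `flags`. The indices of peaks
#'   assigned to no allele are in `attr(, "nonspecific_peaks")`.
#' @export
call_genotypes <- function(panel, peaks, size_tol = 1.0, het_ratio_min = 0.15) {
  if (size_tol <= 0) stop("size_tol must be > 0")
  ext <- panel$ext_primers
  tg <- panel$targets
  exp_sz <- expected_product_size(panel)
  used <- rep(FALSE, nrow(peaks))
  calls <- vector("list", nrow(ext))
  for (i in seq_len(nrow(ext))) {
    rs <- ext$rsid[i]
    t <- tg[tg$rsid == rs, , drop = FALSE]
    flags <- character(0)
    support <- list(ref = integer(0), alt = integer(0))
    height <- c(ref = NA_real_, alt = NA_real_)
    for (al in c("ref", "alt")) {
      e <- exp_sz[exp_sz$rsid == rs & exp_sz$allele == al, , drop = FALSE]
      hit <- which(peaks$dye == e$dye & abs(peaks$size_nt - e$observed) <= size_tol)
      if (length(hit) > 1L) {
        flags <- c(flags, paste0("ambiguous_", al))
        hit <- hit[which.max(peaks$height[hit])]
      }
      support[[al]] <- hit
      if (length(hit)) height[al] <- peaks$height[hit]
      used[hit] <- TRUE
    }
    n_sup <- sum(lengths(support) > 0L)
    plus_allele <- c(ref = t$ref_allele, alt = t$alt_allele)
    if (n_sup == 2L) {
      ratio <- min(height) / max(height)
      if (ratio >= het_ratio_min) {
        status <- "het"; a1 <- plus_allele["ref"]; a2 <- plus_allele["alt"]
      } else {
        major <- names(height)[which.max(height)]
        flags <- c(flags, "imbalance")
        status <- paste0("hom_", major)
        a1 <- a2 <- plus_allele[major]
      }
    } else if (n_sup == 1L) {
      al <- names(support)[lengths(support) > 0L]
      status <- paste0("hom_", al)
      a1 <- a2 <- plus_allele[al]
    } else {
      status <- "no_call"; a1 <- a2 <- NA_character_
    }
    calls[[i]] <- data.frame(
      rsid = rs, allele1 = unname(a1), allele2 = unname(a2), status = status,
      supporting = paste(sort(unlist(support)), collapse = ","),
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  attr(out, "nonspecific_peaks") <- which(!used)
  out
}

#' Fit per-dye mobility parameters from control observations
#'
#' Least-squares affine fit of observed versus nominal size per dye. Dyes
#' with a single observation get an offset-only fit (slope 1); dyes with no
#' observations are left at the identity with a warning.
#'
#' @param observations data.frame with columns `dye`, `nominal`, `observed`.
#' @param map a [dye_map()].
#' @return a [mobility_model()]; per-dye residuals in `attr(, "residuals")`.
#' @export
fit_mobility <- function(observations, map = dye_map()) {
  dyes <- unname(unclass(map))
  off <- stats::setNames(rep(0, length(dyes)), dyes)
  slp <- stats::setNames(rep(1, length(dyes)), dyes)
  resid <- list()
  for (d in dyes) {
    o <- observations[observations$dye == d, , drop = FALSE]
    if (nrow(o) == 0L) {
      warning("no observations for dye ", d, "; left at identity")
      next
    }
    if (nrow(o) == 1L || length(unique(o$nominal)) == 1L) {
      off[d] <- mean(o$observed - o$nominal)
      resid[[d]] <- o$observed - (off[d] + o$nominal)
    } else {
      fit <- stats::lm(observed ~ nominal, data = o)
      off[d] <- stats::coef(fit)[1]
      slp[d] <- stats::coef(fit)[2]
      resid[[d]] <- stats::residuals(fit)
    }
  }
  m <- mobility_model(offset = off, slope = slp, map = map)
  attr(m, "residuals") <- resid
  m
}

#' Genotype-class space of a panel
#'
#' For n biallelic SNPs there are n heterozygous and 2n homozygous genotype
#' classes (one het and two hom classes per SNP), and noise-free
#' electropherograms carry between n peaks (all-homozygous) and 2n peaks
#' (all-heterozygous).
#'
#' @param panel a [panel_design()] or an integer number of targets.
#' @return list with `n_targets`, `het_classes`, `hom_classes`,
#'   `min_peaks`, `max_peaks`.
#' @export
genotype_classes <- function(panel) {
  n <- if (inherits(panel, "panel_design")) nrow(panel$targets) else as.integer(panel)
  list(n_targets = n, het_classes = n, hom_classes = 2L * n,
       min_peaks = n, max_peaks = 2L * n)
}
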