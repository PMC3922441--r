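# Readers/writers for external formats, packaged panel fixtures, and the
# toy-genome / synthetic-locus generators used for network-free end-to-end
# runs.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "snapanel")
  if (path == "") stop("packaged fixture missing: ", file)
  path
}

#' Load the packaged published panel fixtures
#'
#' Returns the transcribed target, multiplex-PCR and extension-primer tables
#' of the two published fetal-haemoglobin modifier panels (12-plex BCL11A,
#' 16-plex HBS1L-MYB), validated against their structural invariants: 12 + 16
#' targets, 9 + 13 PCR rows, 12 + 16 extension rows, every printed extension
#' size equal to the sequence length, all sequences ACGT after case folding.
#'
#' @return object of class `fixture_set`: list with data.frames `targets`,
#'   `pcr`, `ext`.
#' @export
load_fixtures <- function() {
  targets <- utils::read.delim(.extdata("snp_targets.tsv"), stringsAsFactors = FALSE)
  pcr <- utils::read.delim(.extdata("pcr_primers.tsv"), stringsAsFactors = FALSE)
  ext <- utils::read.delim(.extdata("ext_primers.tsv"), stringsAsFactors = FALSE)

  counts <- table(targets$panel)
  if (!identical(sort(as.integer(counts)), c(12L, 16L))) {
    stop("fixture corruption: expected 12 + 16 targets")
  }
  pc <- table(pcr$panel)
  if (!identical(sort(as.integer(pc)), c(9L, 13L))) {
    stop("fixture corruption: expected 9 + 13 PCR amplicons")
  }
  if (!identical(as.integer(table(ext$panel)), as.integer(counts))) {
    stop("fixture corruption: one extension primer per target required")
  }
  if (any(nchar(ext$primer_seq) != ext$size_bp)) {
    stop("fixture corruption: printed extension size != sequence length")
  }
  seqs <- toupper(c(pcr$fwd_seq, pcr$rev_seq, ext$primer_seq))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("fixture corruption: non-ACGT base in a primer sequence")
  }
  # tail = lower-case prefix, core = upper-case remainder
  ext$tail_seq <- sub("^([acgt]*).*$", "\\1", ext$primer_seq)
  ext$core_seq <- substring(ext$primer_seq, nchar(ext$tail_seq) + 1L)
  if (any(grepl("[a-z]", ext$core_seq))) {
    stop("fixture corruption: lower-case base after the core started")
  }
  structure(list(targets = targets, pcr = pcr, ext = ext),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %d targets, %d PCR pairs, %d extension primers (%s)\n",
              nrow(x$targets), nrow(x$pcr), nrow(x$ext),
              paste(unique(x$targets$panel), collapse = ", ")))
  invisible(x)
}

# infer the primer-sense strand of a fixture extension primer from the printed
# detected-allele pair (order-sensitive match against ref/alt or complement)
.infer_fixture_strand <- function(detected, ref, alt, direction) {
  parts <- strsplit(detected, "/", fixed = TRUE)[[1]]
  if (identical(parts, c(ref, alt))) return("plus")
  if (identical(parts, complement_base(c(ref, alt)))) return("minus")
  if (setequal(parts, c(ref, alt))) return("plus")
  if (setequal(parts, complement_base(c(ref, alt)))) return("minus")
  if (direction == "F") "plus" else "minus"
}

#' Assemble a packaged published panel as a `panel_design`
#'
#' Builds one of the two published panels from the fixtures, deriving each
#' extension primer's strand, detected bases and dye colours from the
#' printed detected-allele pair under the package's primer-sense convention.
#'
#' @param name "BCL11A" or "HBS1L-MYB".
#' @param constraints [design_constraints()].
#' @param mobility [mobility_model()].
#' @return a [panel_design()].
#' @export
fixture_panel <- function(name = c("BCL11A", "HBS1L-MYB"),
                          constraints = design_constraints(),
                          mobility = mobility_model()) {
  name <- match.arg(name)
  fx <- load_fixtures()
  tg <- fx$targets[fx$targets$panel == name, , drop = FALSE]
  targets <- snp_targets(tg$rsid, tg$chrom, tg$pos, tg$ref_allele,
                         tg$alt_allele, locus_label = name)
  ext_raw <- fx$ext[fx$ext$panel == name, , drop = FALSE]
  map <- dye_map()
  rows <- lapply(seq_len(nrow(ext_raw)), function(i) {
    e <- ext_raw[i, ]
    t <- tg[tg$rsid == e$rsid, ]
    strand <- .infer_fixture_strand(e$detected_alleles, t$ref_allele,
                                    t$alt_allele, e$direction)
    db <- detected_bases(snp_targets(t$rsid, t$chrom, t$pos, t$ref_allele,
                                     t$alt_allele), strand)
    data.frame(rsid = e$rsid, strand = strand,
               core_seq = toupper(e$core_seq), tail_seq = e$tail_seq,
               tail_len = nchar(e$tail_seq), total_len = e$size_bp,
               detected_base_ref = db$ref_base, detected_base_alt = db$alt_base,
               dye_ref = dye_for_base(db$ref_base, map),
               dye_alt = dye_for_base(db$alt_base, map),
               conc_uM = e$conc_uM, direction = e$direction,
               stringsAsFactors = FALSE)
  })
  ext <- do.call(rbind, rows)
  pcr <- fx$pcr[fx$pcr$panel == name, , drop = FALSE]
  panel_design(name, targets, ext, pcr_pairs = pcr,
               constraints = constraints, mobility = mobility)
}

#' Build a deterministic toy genome embedding the fixture amplicons
#'
#' For each fixture PCR row a pseudo-amplicon is constructed as the forward
#' primer, seeded random filler, and the reverse complement of the reverse
#' primer, with total length equal to the printed amplicon length. (The real
#' amplicon interior is not part of the fixtures, so the interior is
#' synthesized; primers are the published sequences.) Pseudo-amplicons are
#' embedded in seeded random background, one sequence per panel, and the true
#' coordinates recorded, so in-silico PCR and uniqueness scans can be
#' exercised without any genome download.
#'
#' @param fixtures a [load_fixtures()] result.
#' @param seed integer seed.
#' @param spacer_len background bases between consecutive amplicons.
#' @return object of class `toy_genome`: list with `sequences` (named
#'   character) and `amplicons` (data.frame panel, covered_rsids, seqname,
#'   start, end, length).
#' @export
build_toy_genome <- function(fixtures = load_fixtures(), seed = 1L,
                             spacer_len = 300L) {
  set.seed(seed)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  seqs <- character(0)
  coords <- list()
  for (panel in unique(fixtures$pcr$panel)) {
    rows <- fixtures$pcr[fixtures$pcr$panel == panel, , drop = FALSE]
    chunks <- character(0)
    cursor <- 0L
    for (i in seq_len(nrow(rows))) {
      fwd <- toupper(rows$fwd_seq[i])
      rev <- toupper(rows$rev_seq[i])
      alen <- rows$amplicon_len[i]
      fill <- alen - nchar(fwd) - nchar(rev)
      if (fill < 0L) {
        stop(sprintf("construction error: printed amplicon length %d < primer lengths (%s)",
                     alen, rows$covered_rsids[i]))
      }
      spacer <- rand_dna(spacer_len)
      amp <- paste0(fwd, rand_dna(fill), reverse_complement(rev))
      chunks <- c(chunks, spacer, amp)
      start <- cursor + spacer_len + 1L
      coords[[length(coords) + 1L]] <- data.frame(
        panel = panel, covered_rsids = rows$covered_rsids[i],
        seqname = paste0("toy_", panel), start = start,
        end = start + alen - 1L, length = alen, stringsAsFactors = FALSE)
      cursor <- cursor + spacer_len + alen
    }
    chunks <- c(chunks, rand_dna(spacer_len))
    seqs[paste0("toy_", panel)] <- paste(chunks, collapse = "")
  }
  structure(list(sequences = seqs, amplicons = do.call(rbind, coords),
                 seed = seed),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %d sequence(s) (%s bp), %d embedded amplicons, seed %d\n",
              length(x$sequences),
              paste(nchar(x$sequences), collapse = " + "),
              nrow(x$amplicons), x$seed))
  invisible(x)
}

#' Write a toy genome (or any sequence set) as FASTA
#'
#' @param x a `toy_genome` or named character vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- .as_seq_set(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA reference into one or more reference contexts
#'
#' @param path FASTA file.
#' @param window_start 1-based genomic coordinate of each sequence's first
#'   base (recycled).
#' @return list of [reference_context()] objects, one per FASTA record.
#' @export
read_reference_fasta <- function(path, window_start = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  window_start <- rep_len(as.integer(window_start), length(ss))
  out <- lapply(seq_along(ss), function(i) {
    reference_context(names(ss)[i], window_start[i], as.character(ss[[i]]))
  })
  names(out) <- names(ss)
  out
}

#' Simulate a synthetic locus with embedded SNV targets
#'
#' Generates a random reference window and places biallelic SNV targets at
#' evenly spread positions, taking the reference base at each position as the
#' ref allele and a different random base as the alt allele. Used for
#' end-to-end design tests that need a genome but not the real one.
#'
#' @param n_snps number of targets.
#' @param length window length (bp).
#' @param seed integer seed.
#' @param chrom sequence name.
#' @param margin minimum distance of any SNP from the window edges.
#' @return list with `context` ([reference_context()]) and `targets`
#'   ([snp_targets()]).
#' @export
simulate_locus <- function(n_snps = 12L, length = 6000L, seed = 1L,
                           chrom = "toy_locus", margin = 700L) {
  set.seed(seed)
  if (length <= 2L * margin) stop("window too short for the requested margin")
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  pos <- sort(as.integer(round(seq.int(margin, length - margin,
                                       length.out = n_snps))))
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  list(context = reference_context(chrom, 1L, seq),
       targets = snp_targets(sprintf("snp%02d", seq_len(n_snps)), chrom, pos,
                             ref, alt, locus_label = "synthetic"))
}

#' Read SNV targets from TSV or VCF
#'
#' TSV columns: `rsid`, `chrom`, `pos`, `ref_allele`, `alt_allele` (extra
#' columns ignored with a warning). VCF: biallelic SNV records; the ID column
#' provides the rsid.
#'
#' @param path input file; format chosen by extension (.vcf / anything else
#'   is TSV).
#' @return a [snp_targets()].
#' @export
read_targets <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(body)) stop("no records in VCF ", path)
    f <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 5L)
    if (length(bad)) stop("malformed VCF record at data line ", bad[1])
    df <- data.frame(chrom = vapply(f, `[`, "", 1L),
                     pos = as.integer(vapply(f, `[`, "", 2L)),
                     rsid = vapply(f, `[`, "", 3L),
                     ref = vapply(f, `[`, "", 4L),
                     alt = vapply(f, `[`, "", 5L), stringsAsFactors = FALSE)
    multi <- grepl(",", df$alt, fixed = TRUE) | nchar(df$ref) != 1L |
      nchar(df$alt) != 1L
    if (any(multi)) {
      stop("only biallelic SNVs are supported; offending record: ",
           df$rsid[multi][1])
    }
    snp_targets(df$rsid, df$chrom, df$pos, df$ref, df$alt)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("rsid", "chrom", "pos", "ref_allele", "alt_allele")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("targets file missing column(s): ",
                           paste(miss, collapse = ", "))
    extra <- setdiff(names(df), c(need, "locus_label", "panel", "hgvs"))
    if (length(extra)) warning("ignoring unknown column(s): ",
                               paste(extra, collapse = ", "))
    lab <- if ("locus_label" %in% names(df)) df$locus_label
           else if ("panel" %in% names(df)) df$panel else NA_character_
    snp_targets(df$rsid, df$chrom, df$pos, df$ref_allele, df$alt_allele, lab)
  }
}

#' Serialize a panel design to JSON
#'
#' The JSON round-trips through [read_panel()] losslessly. Neutral tails are
#' kept lower case in the serialized form.
#'
#' @param panel a [panel_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  obj <- list(
    format = "snapanel_panel",
    version = 1L,
    name = panel$name,
    targets = as.data.frame(panel$targets),
    pcr_pairs = panel$pcr_pairs,
    ext_primers = panel$ext_primers,
    constraints = unclass(panel$constraints),
    mobility = list(offset = as.list(panel$mobility$offset),
                    slope = as.list(panel$mobility$slope)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a panel design from JSON
#'
#' @param path a file written by [write_panel()].
#' @return a [panel_design()].
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "snapanel_panel")) {
    stop("not a snapanel panel file: ", path)
  }
  cs <- do.call(design_constraints,
                obj$constraints[names(obj$constraints) != "readable_window"])
  cs$readable_window <- as.numeric(obj$constraints$readable_window)
  mob <- mobility_model(offset = unlist(obj$mobility$offset),
                        slope = unlist(obj$mobility$slope))
  tg <- obj$targets
  targets <- snp_targets(tg$rsid, tg$chrom, tg$pos, tg$ref_allele,
                         tg$alt_allele, tg$locus_label)
  pcr <- obj$pcr_pairs
  if (!is.data.frame(pcr) || nrow(pcr) == 0L) pcr <- NULL
  panel_design(obj$name, targets, obj$ext_primers,
               pcr_pairs = pcr, constraints = cs, mobility = mob)
}

#' Write the extension-primer table of a panel as TSV
#'
#' Columns mirror the published panel tables: rsid, primer sequence with the
#' neutral tail lower case, size, concentration, detected bases.
#'
#' @param panel a [panel_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  ext <- panel$ext_primers
  out <- data.frame(rsid = ext$rsid, strand = ext$strand,
                    primer_seq = paste0(ext$tail_seq, ext$core_seq),
                    size_bp = ext$total_len,
                    conc_uM = ext$conc_uM,
                    detected_ref = ext$detected_base_ref,
                    detected_alt = ext$detected_base_alt,
                    dye_ref = ext$dye_ref, dye_alt = ext$dye_alt,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a capillary peak table from CSV
#'
#' GeneMapper-style table export with columns `sample`, `dye`, `size_nt`,
#' `height`.
#'
#' @param path CSV file.
#' @return data.frame of class `peak_table`.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "dye", "size_nt", "height")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$size_nt) | df$size_nt <= 0)
  if (length(bad)) stop("invalid observed size at peak CSV row ", bad[1])
  bad_h <- which(!is.finite(df$height) | df$height < 0)
  if (length(bad_h)) stop("invalid peak height at peak CSV row ", bad_h[1])
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Write a peak table as CSV
#'
#' @param peaks a peak table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotype calls as a VCF
#'
#' One record per target, plus-strand ref/alt alleles, a single sample with a
#' GT field; no-calls are written as `./.`.
#'
#' @param calls a [call_genotypes()] result.
#' @param targets the panel's [snp_targets()].
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, targets, path, sample = "sample1") {
  m <- merge(as.data.frame(targets), as.data.frame(calls), by = "rsid",
             sort = FALSE)
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  gt <- ifelse(m$status == "hom_ref", "0/0",
        ifelse(m$status == "het", "0/1",
        ifelse(m$status == "hom_alt", "1/1", "./.")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snapanel",
    sprintf("##contig=<ID=%s>", unique(m$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"))
  records <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT\t%s",
                     m$chrom, m$pos, m$rsid, m$ref_allele, m$alt_allele, gt)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write genotype calls as TSV
#'
#' @param calls a [call_genotypes()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
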