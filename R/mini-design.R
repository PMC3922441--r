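# Extension (minisequencing) primer design: placement immediately adjacent to
# the SNP, flanking-variant conflict detection, neutral-tail construction and
# the dye-aware length-staggering solver.

#' Genomic core of an extension primer
#'
#' The primer's 3' base is the template base immediately adjacent to the SNP
#' on the primer-sense strand: a plus-strand primer covers plus-strand bases
#' `[pos - core_len, pos - 1]`; a minus-strand primer is the reverse
#' complement of plus-strand bases `[pos + 1, pos + core_len]`.
#'
#' @param target one row of [snp_targets()].
#' @param context a [reference_context()] covering the footprint.
#' @param strand "plus" or "minus".
#' @param core_len core length in nt (>= 14).
#' @return the core sequence, 5'->3' on the primer-sense strand.
#' @export
place_extension_primer <- function(target, context, strand, core_len) {
  strand <- match.arg(strand, c("plus", "minus"))
  if (core_len < 14L) stop("core_len must be >= 14")
  pos <- target$pos[1]
  core <- if (strand == "plus") {
    context_subseq(context, pos - core_len, pos - 1L)
  } else {
    reverse_complement(context_subseq(context, pos + 1L, pos + core_len))
  }
  if (grepl("N", core, fixed = TRUE)) {
    stop("ambiguity error: extension-primer footprint contains N")
  }
  core
}

#' Flanking-variant conflict detection
#'
#' A known variant blocks the plus strand when it intersects
#' `[pos - footprint_len, pos]` (the primer footprint plus the interrogated
#' base), and the minus strand when it intersects `[pos, pos + footprint_len]`.
#' A target with both strands blocked cannot be genotyped by a single
#' extension primer. This is the situation that forced the published assay to
#' drop rs7775698, which has two 3-bp deletions and a 2-bp insertion
#' overlapping or immediately adjacent to it.
#'
#' @param target one row of [snp_targets()].
#' @param variants [variant_features()] on the same chromosome.
#' @param footprint_len primer footprint length in nt (>= 14).
#' @return object of class `conflict_report`: list with `rsid`,
#'   `plus_blocked`, `minus_blocked`, `blockers_plus`, `blockers_minus`,
#'   `undesignable`.
#' @export
flanking_conflict <- function(target, variants, footprint_len = 40L) {
  if (footprint_len < 14L) stop("footprint_len must be >= 14")
  pos <- target$pos[1]
  if (is.null(variants) || nrow(variants) == 0L) {
    hits_plus <- hits_minus <- character(0)
  } else {
    ip <- variants$end >= pos - footprint_len & variants$start <= pos
    im <- variants$end >= pos & variants$start <= pos + footprint_len
    hits_plus <- variants$id[ip]
    hits_minus <- variants$id[im]
  }
  structure(list(rsid = target$rsid[1],
                 plus_blocked = length(hits_plus) > 0L,
                 minus_blocked = length(hits_minus) > 0L,
                 blockers_plus = hits_plus,
                 blockers_minus = hits_minus,
                 undesignable = length(hits_plus) > 0L && length(hits_minus) > 0L),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf("<conflict_report> %s: plus %s, minus %s%s\n", x$rsid,
              if (x$plus_blocked) "BLOCKED" else "clear",
              if (x$minus_blocked) "BLOCKED" else "clear",
              if (x$undesignable) " -- undesignable by a single primer" else ""))
  invisible(x)
}

#' Neutral 5' tail of a given length
#'
#' Tails are suffixes of a fixed 40-nt neutral master sequence; lengths beyond
#' the master are reached by prepending poly(C) padding, as in the published
#' panels. Tails are returned lower case to distinguish them from the genomic
#' core.
#'
#' @param k tail length in nt (>= 0).
#' @param constraints [design_constraints()] supplying `master_tail` and
#'   `pad_base`.
#' @return tail sequence of length `k` (lower case).
#' @export
tail_sequence <- function(k, constraints = design_constraints()) {
  if (k < 0L) stop("tail length must be >= 0")
  master <- constraints$master_tail
  m <- nchar(master)
  if (k == 0L) return("")
  if (k <= m) {
    substr(master, m - k + 1L, m)
  } else {
    paste0(strrep(tolower(constraints$pad_base), k - m), master)
  }
}

# conflict graph over dye pairs: edge when two primers share >= 1 dye
.dye_conflicts <- function(dye_pairs) {
  n <- length(dye_pairs)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (length(intersect(dye_pairs[[i]], dye_pairs[[j]]))) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

# connected components of a logical adjacency matrix (BFS)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# DFS with forward checking: is there an assignment of values[i] in
# lb[i]..cap such that connected (adj) nodes differ by >= gap? Assigns in
# index order with values tried ascending, so the first solution found is the
# lexicographically smallest one.
.spacing_dfs <- function(lb, cap, gap, adj) {
  n <- length(lb)
  if (cap < max(lb)) return(NULL)
  dom <- lapply(seq_len(n), function(i) {
    d <- rep(FALSE, cap)
    d[lb[i]:cap] <- TRUE
    d
  })
  assign_rec <- function(vals, dom, i) {
    if (i > n) return(vals)
    for (v in which(dom[[i]])) {
      vals[i] <- v
      nd <- dom
      ok <- TRUE
      if (i < n) {
        for (j in seq.int(i + 1L, n)) {
          if (!adj[i, j]) next
          d <- nd[[j]]
          d[max(1L, v - gap + 1L):min(cap, v + gap - 1L)] <- FALSE
          if (!any(d)) { ok <- FALSE; break }
          nd[[j]] <- d
        }
      }
      if (ok) {
        res <- assign_rec(vals, nd, i + 1L)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  assign_rec(integer(n), dom, 1L)
}

# lower bound on the makespan of a component: primers sharing a dye form a
# clique whose values must be pairwise >= gap apart
.spacing_lower_bound <- function(lb, dye_pairs, gap) {
  bound <- max(lb)
  for (d in unique(unlist(dye_pairs))) {
    in_class <- vapply(dye_pairs, function(p) d %in% p, logical(1))
    m <- sum(in_class)
    if (m > 1L) {
      bound <- max(bound, min(lb[in_class]) + (m - 1L) * gap)
    }
  }
  bound
}

#' Dye-aware length-staggering solver
#'
#' Assigns each extension primer a total length (core + neutral tail) such
#' that any two primers sharing at least one dye differ in total length by at
#' least `same_dye_min_gap`, every extension product (total length + 1) lies
#' inside the readable sizing window, and the maximum total length is
#' minimised. Among minimal-makespan solutions the lexicographically smallest
#' assignment in input order is returned, so the solver is deterministic.
#'
#' @param core_len integer vector of genomic core lengths (>= 14 nt).
#' @param dye_pairs list of length-2 character vectors, the two dye colours
#'   each primer can produce.
#' @param constraints [design_constraints()].
#' @return integer vector of total lengths, same order as the input.
#' @export
solve_spacing <- function(core_len, dye_pairs,
                          constraints = design_constraints()) {
  n <- length(core_len)
  stopifnot(n >= 1L, length(dye_pairs) == n)
  if (any(core_len < 14L)) stop("core lengths must be >= 14 nt")
  win <- constraints$readable_window
  lb <- pmax(as.integer(core_len), as.integer(ceiling(win[1])) - 1L)
  cap_max <- as.integer(floor(win[2])) - 1L   # product = total + 1 must fit
  if (any(lb > cap_max)) {
    stop(sprintf("capacity error: a core of %d nt cannot fit the readable window [%g, %g]",
                 max(core_len), win[1], win[2]))
  }
  gap <- constraints$same_dye_min_gap
  adj <- .dye_conflicts(dye_pairs)
  comp <- .components(adj)
  # pass 1: minimal makespan = max over per-component minima
  comp_caps <- integer(max(comp))
  for (k in unique(comp)) {
    idx <- which(comp == k)
    sub_adj <- adj[idx, idx, drop = FALSE]
    sub_lb <- lb[idx]
    best_cap <- NA_integer_
    start_cap <- .spacing_lower_bound(sub_lb, dye_pairs[idx], gap)
    if (start_cap > cap_max) {
      stop(sprintf("capacity error: %d same-dye primers cannot be staggered by %d nt inside the readable window [%g, %g]",
                   length(idx), gap, win[1], win[2]))
    }
    for (cap in start_cap:cap_max) {
      if (!is.null(.spacing_dfs(sub_lb, cap, gap, sub_adj))) {
        best_cap <- cap
        break
      }
    }
    if (is.na(best_cap)) {
      stop(sprintf("capacity error: %d same-dye primers cannot be staggered by %d nt inside the readable window [%g, %g]",
                   length(idx), gap, win[1], win[2]))
    }
    comp_caps[k] <- best_cap
  }
  makespan <- max(comp_caps)
  # pass 2: lexicographically smallest assignment (input order) with every
  # total <= the minimal makespan; the critical component pins the makespan
  totals <- integer(n)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    totals[idx] <- .spacing_dfs(lb[idx], makespan, gap,
                                adj[idx, idx, drop = FALSE])
  }
  totals
}

#' Design a full extension-primer panel
#'
#' For each target: checks flanking-variant conflicts, chooses a strand
#' (default policy: the strand whose shortest screen-passing core exists;
#' tie broken in favour of plus), picks the minimal core length in
#' `core_len_range` that passes the hairpin and self-dimer screens, then
#' solves the dye-aware spacing problem across the panel and attaches neutral
#' tails. Per-target failures (blocked strands, no clean core) are collected
#' in the report rather than aborting the panel.
#'
#' @param targets [snp_targets()].
#' @param context a [reference_context()] covering every footprint.
#' @param constraints [design_constraints()].
#' @param variants optional [variant_features()] of known flanking variants.
#' @param core_len_range candidate core lengths, default 17-24 nt.
#' @param map a [dye_map()].
#' @return list of class `extension_panel_build`: `ext_primers`
#'   (data.frame with rsid, strand, core/tail/total fields, detected bases
#'   and dyes) and `failures` (data.frame rsid, reason).
#' @export
build_extension_panel <- function(targets, context,
                                  constraints = design_constraints(),
                                  variants = NULL,
                                  core_len_range = c(17L, 24L),
                                  map = dye_map()) {
  core_lens <- core_len_range[1]:core_len_range[2]
  picked <- list()
  failures <- list()
  for (i in seq_len(nrow(targets))) {
    tgt <- targets[i, , drop = FALSE]
    cr <- flanking_conflict(tgt, variants,
                            footprint_len = max(core_lens))
    if (cr$undesignable) {
      failures[[length(failures) + 1L]] <- data.frame(
        rsid = tgt$rsid, reason = paste0("undesignable: both strands blocked by ",
                                         paste(unique(c(cr$blockers_plus, cr$blockers_minus)),
                                               collapse = ",")),
        stringsAsFactors = FALSE)
      next
    }
    strands <- c("plus", "minus")
    strands <- strands[c(!cr$plus_blocked, !cr$minus_blocked)]
    choice <- NULL
    for (s in strands) {     # plus first: the tie-break is part of the policy
      for (L in core_lens) {
        core <- tryCatch(place_extension_primer(tgt, context, s, L),
                         error = function(e) NULL)
        if (is.null(core)) next
        if (hairpin_screen(core) >= constraints$hairpin_max_stem) next
        if (duplex_screen(core, core)$run3 >= constraints$dimer_max_run3) next
        choice <- list(strand = s, core = core)
        break
      }
      if (!is.null(choice)) break
    }
    if (is.null(choice)) {
      failures[[length(failures) + 1L]] <- data.frame(
        rsid = tgt$rsid, reason = "no screen-passing core in the length range",
        stringsAsFactors = FALSE)
      next
    }
    db <- detected_bases(tgt, choice$strand)
    picked[[length(picked) + 1L]] <- data.frame(
      rsid = tgt$rsid, strand = choice$strand, core_seq = choice$core,
      detected_base_ref = db$ref_base, detected_base_alt = db$alt_base,
      dye_ref = dye_for_base(db$ref_base, map),
      dye_alt = dye_for_base(db$alt_base, map),
      stringsAsFactors = FALSE)
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(rsid = character(0), reason = character(0))
  if (!length(picked)) {
    return(structure(list(ext_primers = NULL, failures = failures),
                     class = "extension_panel_build"))
  }
  ext <- do.call(rbind, picked)
  totals <- solve_spacing(nchar(ext$core_seq),
                          Map(c, ext$dye_ref, ext$dye_alt),
                          constraints)
  ext$tail_len <- totals - nchar(ext$core_seq)
  ext$tail_seq <- vapply(ext$tail_len, tail_sequence, character(1),
                         constraints = constraints)
  ext$total_len <- totals
  ext$conc_uM <- NA_real_
  rownames(ext) <- NULL
  structure(list(ext_primers = ext, failures = failures),
            class = "extension_panel_build")
}

#' @export
print.extension_panel_build <- function(x, ...) {
  cat(sprintf("<extension_panel_build> %d primers designed, %d failures\n",
              if (is.null(x$ext_primers)) 0L else nrow(x$ext_primers),
              nrow(x$failures)))
  invisible(x)
}
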