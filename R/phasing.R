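# Long-read isoform phasing: map reads to the region segments of a
# canonicalized reference, classify reads that span an inverted repeat
# into the two structural conformations, and estimate the isoform ratio.

#' Build a reusable k-mer index of the partition regions
#'
#' @param reference Canonicalized reference sequence.
#' @param part Its partition (any `plastid_partition`, including a
#'   collapsed three-region one).
#' @param k Seed k-mer size.
#' @return A `segment_index` for [map_read_segments()].
#' @export
segment_index <- function(reference, part, k = 15) {
  idx <- list()
  for (i in seq_len(nrow(part))) {
    lab <- part$label[i]
    s <- region_sequence(reference, part, lab)
    m <- nchar(s)
    for (strand in c("+", "-")) {
      kmers <- seq_kmers(if (strand == "+") s else revcomp(s), k)
      idx[[paste0(lab, strand)]] <- list(
        label = lab, strand = strand, kmers = kmers,
        region_start = part$start[i], region_end = part$end[i],
        region_len = m
      )
    }
  }
  structure(list(entries = idx, k = k,
                 genome_length = attr(part, "genome_length"),
                 partition = part),
            class = "segment_index")
}

#' Map a read onto the partition segments of a reference
#'
#' Finds maximal seed-chained matches of read substrings to each region
#' sequence on either strand: exact k-mer matches are grouped by diagonal
#' (with a tolerance for indel drift), chained with increasing read and
#' region coordinates, and reported as segment hits in read-coordinate
#' order. The `identity` of a hit is a per-base identity estimate derived
#' from exact-seed coverage: `(covered fraction)^(1/k)`. Hits whose read
#' intervals conflict (overlap by more than half of the shorter) are
#' resolved by highest identity, then length, then label/strand.
#'
#' @param read Read sequence (character scalar).
#' @param index A [segment_index()] (or pass `reference` + `part`).
#' @param reference,part Alternative to `index`.
#' @param k Seed size (when building an index on the fly).
#' @param min_hit_len Minimum read-interval length of a reported hit.
#' @param diag_tol Diagonal clustering tolerance (bp).
#' @return Tibble of segment hits ordered by `read_start`: `label`,
#'   `read_start`, `read_end`, `ref_start`, `ref_end`, `strand`,
#'   `identity`. Reference coordinates are global on the reference.
#' @export
map_read_segments <- function(read, index = NULL, reference = NULL,
                              part = NULL, k = 15, min_hit_len = 50,
                              diag_tol = 30) {
  if (is.null(index)) index <- segment_index(reference, part, k)
  k <- index$k
  L <- nchar(read)
  if (L < k) return(empty_hits())
  rk <- seq_kmers(read, k)
  hits <- list()
  for (entry in index$entries) {
    if (length(entry$kmers) == 0) next
    mi <- match(rk, entry$kmers)
    p <- which(!is.na(mi))
    if (length(p) < 2) next
    q <- mi[p]
    d <- q - p
    ord <- order(d, p)
    p <- p[ord]; q <- q[ord]; d <- d[ord]
    grp <- cumsum(c(TRUE, diff(d) > diag_tol))
    for (g in split(seq_along(p), grp)) {
      pg <- p[g]; qg <- q[g]
      o <- order(pg)
      pg <- pg[o]; qg <- qg[o]
      # greedy monotone filter on region coordinate
      sel <- logical(length(pg)); lastq <- -Inf
      for (i in seq_along(pg)) {
        if (qg[i] > lastq) { sel[i] <- TRUE; lastq <- qg[i] }
      }
      pg <- pg[sel]; qg <- qg[sel]
      span <- max(pg) + k - 1 - min(pg) + 1
      if (length(pg) < 2 || span < min_hit_len) next
      covered <- coverage_count(pg, k, min(pg), max(pg) + k - 1)
      identity <- (covered / span)^(1 / k)
      # region-local interval -> global reference coordinates
      r1 <- min(qg); r2 <- max(qg) + k - 1
      if (entry$strand == "+") {
        ref_s <- entry$region_start + r1 - 1
        ref_e <- entry$region_start + r2 - 1
      } else {
        ref_s <- entry$region_start + (entry$region_len - r2)
        ref_e <- entry$region_start + (entry$region_len - r1)
      }
      gl <- index$genome_length
      hits[[length(hits) + 1L]] <- tibble(
        label = entry$label,
        read_start = min(pg), read_end = max(pg) + k - 1,
        ref_start = as.integer(((ref_s - 1) %% gl) + 1),
        ref_end = as.integer(((ref_e - 1) %% gl) + 1),
        strand = entry$strand, identity = identity
      )
    }
  }
  if (length(hits) == 0) return(empty_hits())
  hits <- bind_rows(hits)
  hits <- resolve_conflicts(hits)
  hits[order(hits$read_start, hits$read_end), ]
}

empty_hits <- function() {
  tibble(label = character(0), read_start = integer(0), read_end = integer(0),
         ref_start = integer(0), ref_end = integer(0), strand = character(0),
         identity = numeric(0))
}

# number of read positions covered by seed k-mers starting at pg
coverage_count <- function(pg, k, lo, hi) {
  delta <- integer(hi - lo + 2)
  s <- pg - lo + 1
  e <- pmin(pg + k - 1, hi) - lo + 1
  for (i in seq_along(s)) {
    delta[s[i]] <- delta[s[i]] + 1L
    delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
  }
  sum(cumsum(delta[-length(delta)]) > 0)
}

# Drop hits that conflict (read-interval overlap > 50% of the shorter)
# with a better hit; better = higher identity, then longer, then
# label/strand order for determinism.
resolve_conflicts <- function(hits) {
  ord <- order(-hits$identity, -(hits$read_end - hits$read_start),
               hits$label, hits$strand)
  hits <- hits[ord, ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    for (j in (i + 1):nrow(hits)) {
      if (!keep[j]) next
      ov <- min(hits$read_end[i], hits$read_end[j]) -
        max(hits$read_start[i], hits$read_start[j]) + 1
      shorter <- min(hits$read_end[i] - hits$read_start[i],
                     hits$read_end[j] - hits$read_start[j]) + 1
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  hits[keep, ]
}

#' Classify a read from its segment hits into a structural conformation
#'
#' A read is *spanning* iff some inverted-repeat region is fully covered
#' by one hit and the nearest single-copy hits on either side (in read
#' order) are one LSC and one SSC anchor, each at least `anchor_min` bp.
#' The call is `canonical` when the two single-copy anchors have the same
#' orientation (collinear with the canonical layout) and `noncanonical`
#' when they differ (the SSC-flipped layout); this rule is independent of
#' which IR copy the middle hit is labelled with and of the read strand.
#' A read spanning both IRs must give agreeing calls at both, else it is
#' `unclassified`. Reads that do not fully cover an IR get call `NA`
#' (not spanning).
#'
#' @param hits Hit tibble from [map_read_segments()], read-coordinate
#'   ordered.
#' @param part The reference partition.
#' @param anchor_min Minimum single-copy anchor length (bp).
#' @param cover_slack Tolerance (bp) on full-IR coverage: seed-anchored
#'   hit boundaries fall short of the true segment ends by a few bases per
#'   sequencing error, so a hit within `cover_slack` of the full IR length
#'   still counts as covering it. A read must in any case carry anchors in
#'   both flanking single-copy regions, which forces a true traversal of
#'   the repeat.
#' @return One-row tibble: `call` (`canonical` / `noncanonical` /
#'   `unclassified` / `NA`), `ir_label`, `anchor_lsc`, `anchor_ssc`.
#' @export
classify_spanning_read <- function(hits, part, anchor_min = 500,
                                   cover_slack = 100) {
  gl <- attr(part, "genome_length")
  no_call <- tibble(call = NA_character_, ir_label = NA_character_,
                    anchor_lsc = NA_integer_, anchor_ssc = NA_integer_)
  if (nrow(hits) == 0) return(no_call)
  hits <- hits[order(hits$read_start), ]
  ir_rows <- which(hits$label %in% c("IR1", "IR2", "IR"))
  calls <- character(0); ir_used <- character(0)
  anch_l <- integer(0); anch_s <- integer(0)
  covering <- FALSE
  for (i in ir_rows) {
    reg <- part[part$label == hits$label[i], ]
    reg_len <- region_length(reg$start, reg$end, gl)
    hit_len <- region_length(hits$ref_start[i], hits$ref_end[i], gl)
    if (hit_len < reg_len - cover_slack) next
    covering <- TRUE
    sc <- which(hits$label %in% c("LSC", "SSC"))
    before <- sc[sc < i]
    after <- sc[sc > i]
    if (length(before) == 0 || length(after) == 0) next
    b <- max(before); a <- min(after)
    labs <- sort(c(hits$label[b], hits$label[a]))
    if (!identical(labs, c("LSC", "SSC"))) next
    alen <- setNames(
      c(hits$read_end[b] - hits$read_start[b] + 1L,
        hits$read_end[a] - hits$read_start[a] + 1L),
      c(hits$label[b], hits$label[a])
    )
    if (any(alen < anchor_min)) next
    calls <- c(calls,
               if (hits$strand[b] == hits$strand[a]) "canonical"
               else "noncanonical")
    ir_used <- c(ir_used, hits$label[i])
    anch_l <- c(anch_l, unname(alen["LSC"]))
    anch_s <- c(anch_s, unname(alen["SSC"]))
  }
  if (length(calls) == 0) {
    if (covering) return(tibble(call = "unclassified",
                                ir_label = NA_character_,
                                anchor_lsc = NA_integer_,
                                anchor_ssc = NA_integer_))
    return(no_call)
  }
  if (length(unique(calls)) > 1) {
    return(tibble(call = "unclassified", ir_label = paste(ir_used, collapse = ","),
                  anchor_lsc = anch_l[1], anchor_ssc = anch_s[1]))
  }
  tibble(call = calls[1], ir_label = ir_used[1],
         anchor_lsc = anch_l[1], anchor_ssc = anch_s[1])
}

#' Phase long reads into the two plastome structural conformations
#'
#' Maps every read onto the reference segments, classifies reads spanning
#' an inverted repeat, and aggregates counts into a phasing result with a
#' Wilson confidence interval and an exact binomial test of the 1:1
#' flip-flop equilibrium. Optionally writes one FASTQ per conformation
#' (plus one for unclassified spanning reads, preserving mutual
#' exclusivity) and per-read calls as TSV.
#'
#' @param reads Tibble (`read_id`, `sequence`) or path to a FASTQ file.
#' @param reference Canonicalized reference sequence.
#' @param part Its [partition()].
#' @param anchor_min Minimum single-copy anchor (bp).
#' @param identity_min Minimum hit identity retained for classification
#'   (the mapping-quality gate).
#' @param k Seed k-mer size.
#' @param cover_slack Full-IR coverage tolerance in bp, see
#'   [classify_spanning_read()].
#' @param out_dir If non-`NULL`, directory for the conformation read sets
#'   and call tables.
#' @return A `phasing_result`: list with `calls` (per-read tibble),
#'   counts, `ratio_noncanonical`, `ci95`, `p_equal`.
#' @export
phase_reads <- function(reads, reference, part, anchor_min = 500,
                        identity_min = 0.85, k = 15, cover_slack = 100,
                        out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1) {
    reads <- read_reads_fastq(reads)
  }
  idx <- segment_index(reference, part, k)
  calls <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    hits <- map_read_segments(reads$sequence[i], idx)
    hits <- hits[hits$identity >= identity_min, , drop = FALSE]
    cl <- classify_spanning_read(hits, part, anchor_min, cover_slack)
    cl$read_id <- reads$read_id[i]
    calls[[i]] <- cl
  }
  calls <- bind_rows(calls)[, c("read_id", "call", "ir_label",
                                "anchor_lsc", "anchor_ssc")]
  n_can <- sum(calls$call == "canonical", na.rm = TRUE)
  n_non <- sum(calls$call == "noncanonical", na.rm = TRUE)
  n_unc <- sum(calls$call == "unclassified", na.rm = TRUE)
  est <- if (n_can + n_non >= 1) estimate_ratio(n_can, n_non) else NULL
  res <- structure(list(
    calls = calls,
    n_reads = nrow(reads),
    n_spanning = n_can + n_non + n_unc,
    n_canonical = n_can, n_noncanonical = n_non, n_unclassified = n_unc,
    ratio_noncanonical = if (is.null(est)) NA_real_ else est$ratio_noncanonical,
    ci95 = if (is.null(est)) c(NA_real_, NA_real_) else c(est$ci_lo, est$ci_hi),
    p_equal = if (is.null(est)) NA_real_ else est$p_equal
  ), class = "phasing_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sets <- list(canonical = "canonical", noncanonical = "noncanonical",
                 unclassified = "unclassified")
    for (nm in names(sets)) {
      ids <- calls$read_id[!is.na(calls$call) & calls$call == nm]
      write_reads_fastq(reads[reads$read_id %in% ids, ],
                        file.path(out_dir, paste0(nm, ".fastq")))
    }
    readr::write_tsv(calls, file.path(out_dir, "span_calls.tsv"),
                     progress = FALSE)
    readr::write_tsv(glance(res), file.path(out_dir, "phasing_summary.tsv"),
                     progress = FALSE)
  }
  res
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Phasing of %d reads: %d span an IR\n",
    "  canonical %d : noncanonical %d (unclassified %d)\n"),
    x$n_reads, x$n_spanning, x$n_canonical, x$n_noncanonical,
    x$n_unclassified))
  if (!is.na(x$ratio_noncanonical)) {
    cat(sprintf("  noncanonical fraction %.3f (95%% CI %.3f-%.3f), p(1:1) = %.4f\n",
                x$ratio_noncanonical, x$ci95[1], x$ci95[2], x$p_equal))
  }
  invisible(x)
}

#' Estimate the structural isoform ratio
#'
#' The non-canonical fraction among classified spanning reads with a
#' Wilson 95% score interval and an exact two-sided binomial test against
#' the 1:1 flip-flop recombination equilibrium (the two-sided p sums the
#' probabilities of all outcomes no more likely than the observed one).
#'
#' @param n_canonical,n_noncanonical Classified spanning-read counts
#'   (their sum must be >= 1).
#' @return One-row tibble: `n`, `ratio_noncanonical`, `ci_lo`, `ci_hi`,
#'   `p_equal`.
#' @examples
#' estimate_ratio(9, 11)  # ratio 0.55, p = 0.8238
#' @export
estimate_ratio <- function(n_canonical, n_noncanonical) {
  if (n_canonical < 0 || n_noncanonical < 0 ||
      n_canonical + n_noncanonical < 1) {
    abort("Ratio undefined: need at least one classified spanning read.",
          class = "plastidkit_param_error")
  }
  n <- n_canonical + n_noncanonical
  x <- n_noncanonical
  ci <- wilson_ci(x, n)
  p <- stats::binom.test(x, n, p = 0.5, alternative = "two.sided")$p.value
  tibble(n = n, ratio_noncanonical = x / n,
         ci_lo = ci[1], ci_hi = ci[2], p_equal = p)
}

# Wilson score interval (no continuity correction)
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Collapse a quadripartite reference to its single-IR representation
#'
#' The assembly-graph view of a plastome has three segments (LSC, one IR,
#' SSC); mapping reads to it doubles the depth over the IR. Returns the
#' collapsed sequence LSC+IR1+SSC and its three-region partition.
#'
#' @param sequence Canonicalized plastome sequence.
#' @param part Its [partition()].
#' @return List with `sequence` and `partition` (labels LSC, IR1, SSC).
#' @export
collapse_reference <- function(sequence, part) {
  L <- region_sequence(sequence, part, "LSC")
  I <- region_sequence(sequence, part, "IR1")
  S <- region_sequence(sequence, part, "SSC")
  p <- tibble(
    label = c("LSC", "IR1", "SSC"),
    start = as.integer(c(1, nchar(L) + 1, nchar(L) + nchar(I) + 1)),
    end = as.integer(c(nchar(L), nchar(L) + nchar(I),
                       nchar(L) + nchar(I) + nchar(S))),
    strand = "+"
  )
  attr(p, "genome_length") <- nchar(L) + nchar(I) + nchar(S)
  class(p) <- c("plastid_partition", class(tibble()))
  list(sequence = paste0(L, I, S), partition = p)
}

#' Mean mapped depth per region and the IR/single-copy depth ratio
#'
#' Maps reads to a reference (typically the collapsed single-IR
#' representation) and accumulates per-base depth from the retained hits.
#' On a collapsed reference the IR depth is expected to be about twice the
#' single-copy depth, the classic signature of the collapsed duplicated
#' repeat.
#'
#' @inheritParams phase_reads
#' @return List with `depth` (tibble: `label`, `mean_depth`) and
#'   `ir_sc_ratio`.
#' @export
region_depth_ratio <- function(reads, reference, part, identity_min = 0.85,
                               k = 15) {
  if (is.character(reads) && length(reads) == 1) reads <- read_reads_fastq(reads)
  idx <- segment_index(reference, part, k)
  gl <- attr(part, "genome_length")
  depth <- numeric(gl)
  for (i in seq_len(nrow(reads))) {
    hits <- map_read_segments(reads$sequence[i], idx)
    hits <- hits[hits$identity >= identity_min, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      s <- hits$ref_start[j]; e <- hits$ref_end[j]
      if (s <= e) depth[s:e] <- depth[s:e] + 1
      else depth[c(s:gl, 1:e)] <- depth[c(s:gl, 1:e)] + 1
    }
  }
  per_region <- lapply(seq_len(nrow(part)), function(i) {
    s <- part$start[i]; e <- part$end[i]
    posns <- if (s <= e) s:e else c(s:gl, 1:e)
    tibble(label = part$label[i], mean_depth = mean(depth[posns]))
  })
  per_region <- bind_rows(per_region)
  ir <- mean(per_region$mean_depth[grepl("^IR", per_region$label)])
  sc <- mean(per_region$mean_depth[per_region$label %in% c("LSC", "SSC")])
  list(depth = per_region, ir_sc_ratio = ir / sc)
}
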