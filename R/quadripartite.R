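#' Find inverted repeat pairs in a (circular) DNA sequence
#'
#' Locates pairs of intervals whose sequences are reverse complements of
#' one another, the hallmark of the plastome inverted repeat. Detection is
#' seed-and-extend: exact k-mer matches between the sequence and its
#' reverse complement are chained on common diagonals and extended
#' base-by-base under a mismatch budget. Circular sequences are handled by
#' searching the doubled sequence and folding coordinates back.
#'
#' @param sequence DNA sequence (character scalar).
#' @param min_len Minimum repeat length to report (bp, >= 8).
#' @param max_mismatch_frac Mismatch budget as a fraction of the repeat
#'   length (0 = exact repeats only).
#' @param k Seed k-mer size.
#' @param circular Treat the sequence as circular.
#' @return A tibble of repeat pairs, one row per pair, sorted by length
#'   (desc) then `copy1_start`: columns `copy1_start`, `copy1_end`,
#'   `copy2_start`, `copy2_end`, `length`, `mismatches`. Intervals are
#'   1-based inclusive and may wrap (`start > end`) on circular input.
#' @examples
#' x <- "ACGGTTCAGGCAT"
#' find_inverted_repeats(paste0(x, "AAAA", revcomp(x), "TTTT"),
#'                       min_len = 10, circular = FALSE)
#' @export
find_inverted_repeats <- function(sequence, min_len, max_mismatch_frac = 0.01,
                                  k = 15, circular = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be a non-empty character scalar.",
          class = "plastidkit_param_error")
  }
  if (min_len < 8) {
    abort("`min_len` must be >= 8.", class = "plastidkit_param_error")
  }
  n <- nchar(sequence)
  k <- min(k, min_len)
  D <- if (circular) paste0(sequence, sequence) else sequence
  m <- nchar(D)
  if (m < k) return(empty_ir_pairs())
  RC <- revcomp(D)
  kd <- seq_kmers(D, k)
  kr <- seq_kmers(RC, k)

  shared <- intersect(kd, kr)
  if (length(shared) == 0) return(empty_ir_pairs())
  id <- which(kd %in% shared)
  ir <- which(kr %in% shared)
  pos_d <- split(id, kd[id])
  pos_r <- split(ir, kr[ir])
  pos_r <- pos_r[names(pos_d)]
  # cartesian product per shared k-mer
  seeds <- do.call(rbind, mapply(function(di, ri) {
    cbind(i = rep(di, each = length(ri)), j = rep(ri, times = length(di)))
  }, pos_d, pos_r, SIMPLIFY = FALSE))
  if (is.null(seeds) || nrow(seeds) == 0) return(empty_ir_pairs())

  diag <- seeds[, "j"] - seeds[, "i"]
  ord <- order(diag, seeds[, "i"])
  seeds <- seeds[ord, , drop = FALSE]
  diag <- diag[ord]

  # split into exact runs: same diagonal, consecutive i
  brk <- c(TRUE, diff(diag) != 0 | diff(seeds[, "i"]) != 1)
  run_id <- cumsum(brk)
  runs <- tibble(
    i1 = as.integer(unname(tapply(seeds[, "i"], run_id, min))),
    i2 = as.integer(unname(tapply(seeds[, "i"], run_id, max))),
    j1 = as.integer(unname(tapply(seeds[, "j"], run_id, min)))
  )
  Dv <- strsplit(D, "")[[1]]
  RCv <- strsplit(RC, "")[[1]]

  # X-drop extension: walk outwards scoring +1 per match, -3 per mismatch,
  # stop when the score drops 6 below its maximum, and keep the
  # best-scoring endpoint. With a zero mismatch budget this reduces to
  # exact maximal extension.
  xdrop_extend <- function(pos_d, pos_r, step, limit_d, limit_r) {
    if (max_mismatch_frac == 0) {
      adv <- 0L
      while (pos_d + step * (adv + 1) >= 1 && pos_d + step * (adv + 1) <= limit_d &&
             pos_r + step * (adv + 1) >= 1 && pos_r + step * (adv + 1) <= limit_r &&
             Dv[pos_d + step * (adv + 1)] == RCv[pos_r + step * (adv + 1)]) {
        adv <- adv + 1L
      }
      return(c(adv = adv, mm = 0L))
    }
    score <- 0; best <- 0; best_adv <- 0L; mm_run <- 0L; best_mm <- 0L
    adv <- 0L
    repeat {
      nd <- pos_d + step * (adv + 1); nr <- pos_r + step * (adv + 1)
      if (nd < 1 || nd > limit_d || nr < 1 || nr > limit_r) break
      adv <- adv + 1L
      if (Dv[nd] == RCv[nr]) score <- score + 1 else {
        score <- score - 3; mm_run <- mm_run + 1L
      }
      if (score > best) { best <- score; best_adv <- adv; best_mm <- mm_run }
      if (best - score > 6) break
    }
    c(adv = best_adv, mm = best_mm)
  }
  cand <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    a <- runs$i1[r]; b <- runs$i2[r] + k - 1
    ja <- runs$j1[r]; jb <- ja + (b - a)
    right <- xdrop_extend(b, jb, +1L, m, m)
    b <- b + right[["adv"]]; jb <- jb + right[["adv"]]
    left <- xdrop_extend(a, ja, -1L, m, m)
    a <- a - left[["adv"]]; ja <- ja - left[["adv"]]
    mm <- right[["mm"]] + left[["mm"]]
    # enforce the mismatch budget by shrinking the worse-scoring end
    while (mm > floor(max_mismatch_frac * (b - a + 1)) && b > a) {
      if (Dv[b] != RCv[jb]) mm <- mm - 1L
      b <- b - 1; jb <- jb - 1
      while (b > a && Dv[b] != RCv[jb]) { mm <- mm - 1L; b <- b - 1; jb <- jb - 1 }
    }
    cand[[r]] <- c(a = a, b = b, ja = ja, jb = jb, mm = mm)
  }
  cand <- do.call(rbind, cand)
  # split exact inverted palindromes (an interval matching itself reversed)
  # into their two halves, the actual repeat pair
  s2d <- m - cand[, "jb"] + 1
  e2d <- m - cand[, "ja"] + 1
  selfpal <- cand[, "a"] == s2d & cand[, "b"] == e2d
  if (any(selfpal)) {
    sp <- cand[selfpal, , drop = FALSE]
    h <- (sp[, "b"] - sp[, "a"] + 1) %/% 2
    halves <- cbind(a = sp[, "a"], b = sp[, "a"] + h - 1,
                    ja = sp[, "ja"], jb = sp[, "ja"] + h - 1,
                    mm = sp[, "mm"] %/% 2)
    cand <- rbind(cand[!selfpal, , drop = FALSE], halves)
  }
  len <- cand[, "b"] - cand[, "a"] + 1
  keep <- len >= min_len & len <= n
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_ir_pairs())

  # second copy in D coordinates, then fold both to the circle
  s1 <- cand[, "a"]; e1 <- cand[, "b"]
  s2 <- m - cand[, "jb"] + 1; e2 <- m - cand[, "ja"] + 1
  fold <- function(x) ((x - 1) %% n) + 1
  pairs <- tibble(
    s1 = fold(s1), e1 = fold(e1), s2 = fold(s2), e2 = fold(e2),
    length = as.integer(e1 - s1 + 1), mismatches = as.integer(cand[, "mm"])
  )
  # canonical orientation of the pair: copy1 = smaller start
  swap <- pairs$s2 < pairs$s1
  tmp <- pairs[swap, c("s1", "e1")]
  pairs[swap, c("s1", "e1")] <- pairs[swap, c("s2", "e2")]
  pairs[swap, c("s2", "e2")] <- tmp
  pairs <- dplyr::distinct(pairs)

  # drop pairs whose copies overlap on the circle
  circ_overlap <- function(s1, l1, s2, l2) {
    ((s2 - s1) %% n) < l1 | ((s1 - s2) %% n) < l2
  }
  pairs <- pairs[!circ_overlap(pairs$s1, pairs$length, pairs$s2, pairs$length), ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(empty_ir_pairs())
  out <- tibble(
    copy1_start = as.integer(pairs$s1), copy1_end = as.integer(pairs$e1),
    copy2_start = as.integer(pairs$s2), copy2_end = as.integer(pairs$e2),
    length = pairs$length, mismatches = pairs$mismatches
  )
  out <- dplyr::distinct(out)
  out[order(-out$length, out$copy1_start), ]
}

empty_ir_pairs <- function() {
  tibble(copy1_start = integer(0), copy1_end = integer(0),
         copy2_start = integer(0), copy2_end = integer(0),
         length = integer(0), mismatches = integer(0))
}

#' Partition a circular plastome given its inverted-repeat pair
#'
#' The two single-copy arcs between the IR copies are labelled LSC (the
#' longer) and SSC (the shorter); ties are broken by assigning LSC to the
#' arc starting at the smaller coordinate. Regions are returned in
#' circular order starting from the LSC; IR1 is the repeat copy that
#' follows the LSC.
#'
#' @param sequence Circular DNA sequence.
#' @param pair One row of [find_inverted_repeats()] output (or a list with
#'   `copy1_start`, `copy1_end`, `copy2_start`, `copy2_end`).
#' @return A [partition()].
#' @export
partition_genome <- function(sequence, pair) {
  n <- nchar(sequence)
  pair <- as.list(pair[1, , drop = FALSE])
  s1 <- pair$copy1_start; e1 <- pair$copy1_end
  s2 <- pair$copy2_start; e2 <- pair$copy2_end
  nxt <- function(x) (x %% n) + 1L
  arc_len <- function(from_end, to_start) (to_start - from_end - 1L) %% n
  # arc A: after copy1, before copy2; arc B: after copy2, before copy1
  lenA <- arc_len(e1, s2)
  lenB <- arc_len(e2, s1)
  if (lenA == 0 || lenB == 0) {
    bad <- if (lenA == 0) "between copy1 and copy2" else "between copy2 and copy1"
    abort(paste0("IR copies are adjacent: zero-length single-copy arc ", bad, "."),
          class = "plastidkit_structure_error")
  }
  ir_len <- region_length(s1, e1, n)
  if (2L * ir_len + lenA + lenB != n) {
    abort("IR pair does not leave two valid single-copy arcs.",
          class = "plastidkit_structure_error")
  }
  arcA <- c(nxt(e1), (s2 - 2L) %% n + 1L)
  arcB <- c(nxt(e2), (s1 - 2L) %% n + 1L)
  if (lenA > lenB || (lenA == lenB && arcA[1] < arcB[1])) {
    lsc <- arcA; ssc <- arcB; ir1 <- c(s2, e2); ir2 <- c(s1, e1)
  } else {
    lsc <- arcB; ssc <- arcA; ir1 <- c(s1, e1); ir2 <- c(s2, e2)
  }
  partition(lsc, ir1, ssc, ir2, n)
}

#' Detect the quadripartite structure of a plastome
#'
#' Convenience wrapper: [find_inverted_repeats()] then [partition_genome()]
#' on the longest pair.
#'
#' @inheritParams find_inverted_repeats
#' @param min_len Minimum IR length (default 1000, typical for real
#'   plastomes; lower it for toy genomes).
#' @return A [partition()].
#' @export
detect_structure <- function(sequence, min_len = 1000,
                             max_mismatch_frac = 0.01, k = 15) {
  pairs <- find_inverted_repeats(sequence, min_len = min_len,
                                 max_mismatch_frac = max_mismatch_frac, k = k)
  if (nrow(pairs) == 0) {
    abort("No inverted repeat pair found; not a quadripartite plastome.",
          class = "plastidkit_structure_error")
  }
  partition_genome(sequence, pairs[1, ])
}

#' Normalize rotation and orientation of a quadripartite plastome
#'
#' Rotates (and if needed reverse-complements) the circular sequence so
#' the output starts at LSC position 1 in the order LSC-IR1-SSC-IR2. The
#' global orientation is fixed deterministically by choosing, of the two
#' possible orientations, the one whose LSC-first string is
#' lexicographically smaller, which makes the result invariant under any
#' rotation or reverse-complementation of the input. Idempotent.
#'
#' @param sequence Circular DNA sequence.
#' @param part Its [partition()].
#' @return List with `sequence` (canonical string) and `partition`
#'   (canonical-layout partition).
#' @export
canonicalize <- function(sequence, part) {
  validate_partition(part)
  L  <- region_sequence(sequence, part, "LSC")
  I1 <- region_sequence(sequence, part, "IR1")
  S  <- region_sequence(sequence, part, "SSC")
  I2 <- region_sequence(sequence, part, "IR2")
  fwd <- paste0(L, I1, S, I2)
  rev <- paste0(revcomp(L), revcomp(I2), revcomp(S), revcomp(I1))
  seq_out <- if (fwd <= rev) fwd else rev
  list(
    sequence = seq_out,
    partition = layout_partition(nchar(L), nchar(I1), nchar(S))
  )
}

#' Build one structural isoform of a plastome
#'
#' The two structural isoforms generated by flip-flop recombination differ
#' only in the orientation of the SSC. `canonical` returns the input;
#' `noncanonical` returns the sequence with the SSC replaced by its
#' reverse complement. Flipping twice is the identity.
#'
#' @param sequence Circular DNA sequence.
#' @param part Its [partition()].
#' @param which `"canonical"` or `"noncanonical"`.
#' @return A circular DNA sequence of identical length.
#' @export
build_isoform <- function(sequence, part, which = c("canonical", "noncanonical")) {
  which <- match.arg(which)
  validate_partition(part)
  if (sum(region_length(part$start, part$end, attr(part, "genome_length"))) !=
      nchar(sequence)) {
    abort("Partition does not match sequence length.",
          class = "plastidkit_structure_error")
  }
  if (which == "canonical") return(sequence)
  n <- nchar(sequence)
  ssc <- part[part$label == "SSC", ]
  flipped <- revcomp(circular_substr(sequence, ssc$start, ssc$end))
  if (ssc$start <= ssc$end) {
    paste0(substr(sequence, 1, ssc$start - 1), flipped,
           substr(sequence, ssc$end + 1, n))
  } else {
    # SSC wraps the origin: tail of flipped goes to the front
    head_len <- n - ssc$start + 1
    paste0(substr(flipped, head_len + 1, nchar(flipped)),
           substr(sequence, ssc$end + 1, ssc$start - 1),
           substr(flipped, 1, head_len))
  }
}
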