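# Shared fixtures and independent oracles, built in code.

toy_alignment <- function() {
  new_alignment(c(s1 = "ACGTAC-GT", s2 = "ACATAC-GT", s3 = "ACGTACCGT"))
}

small_sim <- function(seed = 1, lsc = 3000, ssc = 800, ir = 400, gc = 0.5) {
  simulate_plastome(plastome_spec(lsc, ssc, ir, gc_content = gc, seed = seed))
}

# O(n^2) brute-force inverted-repeat finder: maximal exact common
# substrings between the sequence and its reverse complement, enumerated
# diagonal by diagonal, then reported with the same pair conventions as
# find_inverted_repeats (copy1 = smaller start; exact self-palindromes
# split into halves; overlapping copies dropped). Linear sequences only.
brute_force_ir <- function(s, min_len) {
  n <- nchar(s)
  S <- strsplit(s, "")[[1]]
  RC <- strsplit(revcomp(s), "")[[1]]
  rows <- list()
  for (d in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 + d):min(n, n + d)
    j <- i - d
    m <- S[i] == RC[j]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      a <- i[starts[h]]; b <- i[ends[h]]
      ja <- j[starts[h]]; jb <- j[ends[h]]
      rows[[length(rows) + 1L]] <- c(a = a, b = b, ja = ja, jb = jb)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(copy1_start = integer(0), copy1_end = integer(0),
                          copy2_start = integer(0), copy2_end = integer(0),
                          length = integer(0), mismatches = integer(0)))
  }
  cand <- do.call(rbind, rows)
  cs2 <- n - cand[, "jb"] + 1
  ce2 <- n - cand[, "ja"] + 1
  selfpal <- cand[, "a"] == cs2 & cand[, "b"] == ce2
  if (any(selfpal)) {
    sp <- cand[selfpal, , drop = FALSE]
    h <- (sp[, "b"] - sp[, "a"] + 1) %/% 2
    sp2 <- cbind(a = sp[, "a"], b = sp[, "a"] + h - 1,
                 ja = sp[, "ja"], jb = sp[, "ja"] + h - 1)
    cand <- rbind(cand[!selfpal, , drop = FALSE], sp2)
    cs2 <- n - cand[, "jb"] + 1
    ce2 <- n - cand[, "ja"] + 1
  }
  first <- cand[, "a"] <= cs2
  df <- tibble::tibble(
    s1 = as.integer(pmin(cand[, "a"], cs2)),
    e1 = as.integer(ifelse(first, cand[, "b"], ce2)),
    s2 = as.integer(pmax(cand[, "a"], cs2)),
    e2 = as.integer(ifelse(first, ce2, cand[, "b"])),
    length = as.integer(cand[, "b"] - cand[, "a"] + 1L)
  )
  df <- df[df$length >= min_len & df$e1 < df$s2, , drop = FALSE]
  df <- dplyr::distinct(tibble::tibble(
    copy1_start = as.integer(df$s1), copy1_end = as.integer(df$e1),
    copy2_start = as.integer(df$s2), copy2_end = as.integer(df$e2),
    length = as.integer(df$length), mismatches = 0L
  ))
  df[order(-df$length, df$copy1_start), ]
}

# brute-force per-column scan used as the classify_columns oracle
brute_force_columns <- function(al, min_minor_count = 1) {
  m <- do.call(rbind, strsplit(toupper(unclass(al)), ""))
  snv <- integer(0)
  indel_cols <- integer(0)
  patterns <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) {
      if (!all(col == "-")) {
        patterns[j] <- paste(as.integer(col == "-"), collapse = "")
        indel_cols <- c(indel_cols, j)
      }
      next
    }
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (length(tab) >= 2 && sum(tab) - max(tab) >= min_minor_count) {
      snv <- c(snv, j)
    }
  }
  # count events: consecutive indel columns with identical pattern
  events <- 0L
  prev <- ""
  for (j in seq_len(ncol(m))) {
    p <- patterns[j]
    if (nzchar(p)) {
      if (p != prev) events <- events + 1L
      prev <- p
    } else prev <- ""
  }
  list(snv = snv, indel_cols = indel_cols, n_events = events)
}

random_alignment <- function(n_seq, n_col, gap_prob = 0.1, n_prob = 0.02) {
  base <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- base
    mut <- runif(n_col) < 0.15
    chars[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    gap <- runif(n_col) < gap_prob
    chars[gap] <- "-"
    nn <- runif(n_col) < n_prob
    chars[nn & !gap] <- "N"
    paste(chars, collapse = "")
  }, character(1))
  new_alignment(setNames(seqs, paste0("t", seq_len(n_seq))))
}

balanced_tree_12 <- function(bl = 0.02) {
  nwk <- paste0("((((L1:B,L2:B):B,(L3:B,L4:B):B):B,((L5:B,L6:B):B,",
                "(L7:B,L8:B):B):B):B,((L9:B,L10:B):B,(L11:B,L12:B):B):B);")
  ape::read.tree(text = gsub("B", format(bl, scientific = FALSE), nwk))
}

random_ancestor <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
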