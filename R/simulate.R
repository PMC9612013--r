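#' Specification of a synthetic quadripartite plastome
#'
#' Region lengths and base composition for [simulate_plastome()]. Real
#' plastomes are ~120-160 kb with an LSC of ~80-90 kb, an SSC of ~12-20 kb
#' and IRs of ~20-25 kb each; defaults are desk-scale but keep the same
#' shape (LSC longest, two equal IRs flanking the SSC).
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp; `lsc_len > ssc_len`
#'   and `ir_len >= 1`.
#' @param gc_content GC fraction in `[0, 1]` (maize plastome is ~0.38).
#' @param seed Integer RNG seed.
#' @return A `plastome_spec` list.
#' @export
plastome_spec <- function(lsc_len = 3000, ssc_len = 800, ir_len = 400,
                          gc_content = 0.38, seed = 1) {
  if (lsc_len <= ssc_len) {
    abort("`lsc_len` must exceed `ssc_len` (LSC is the longer single-copy region).",
          class = "plastidkit_param_error")
  }
  if (ir_len < 1 || lsc_len < 1 || ssc_len < 1) {
    abort("Region lengths must be positive.", class = "plastidkit_param_error")
  }
  if (gc_content < 0 || gc_content > 1) {
    abort("`gc_content` must be in [0, 1].", class = "plastidkit_param_error")
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc_content = gc_content,
                 seed = seed),
            class = "plastome_spec")
}

#' Simulate a circular quadripartite plastome
#'
#' Draws an i.i.d. random sequence with the requested GC content, laid out
#' LSC-IR1-SSC-IR2 from position 1 with IR2 the exact reverse complement
#' of IR1. The molecule is rejection-sampled so that no spurious inverted
#' repeat of length >= `ir_len` exists outside the planted pair, keeping
#' the quadripartite truth unambiguous for detector tests. Deterministic
#' for a fixed seed.
#'
#' @param spec A [plastome_spec()].
#' @return List with `sequence` (character), `partition` (the planted
#'   [partition()]) and `spec`.
#' @examples
#' sim <- simulate_plastome(plastome_spec(3000, 800, 400, 0.5, seed = 1))
#' nchar(sim$sequence)  # 4600
#' @export
simulate_plastome <- function(spec) {
  stopifnot(inherits(spec, "plastome_spec"))
  part <- layout_partition(spec$lsc_len, spec$ir_len, spec$ssc_len)
  with_seed(spec$seed, {
    for (attempt in 1:25) {
      lsc <- random_dna(spec$lsc_len, spec$gc_content)
      ir1 <- random_dna(spec$ir_len, spec$gc_content)
      ssc <- random_dna(spec$ssc_len, spec$gc_content)
      seqn <- paste0(lsc, ir1, ssc, revcomp(ir1))
      pairs <- find_inverted_repeats(seqn, min_len = max(spec$ir_len, 8),
                                     max_mismatch_frac = 0)
      planted <- nrow(pairs) == 1 &&
        pairs$copy1_start[1] == spec$lsc_len + 1L &&
        pairs$length[1] == spec$ir_len
      if (planted) {
        return(list(sequence = seqn, partition = part, spec = spec))
      }
    }
  })
  abort("Could not sample a plastome free of spurious inverted repeats.",
        class = "plastidkit_simulation_error")
}

#' @rdname build_isoform
#' @details `make_isoform()` is an alias of [build_isoform()]; the
#'   simulator and the real-data path share one implementation.
#' @export
make_isoform <- build_isoform

#' Parameters for long-read simulation
#'
#' @param n_reads Number of reads.
#' @param length_mean,length_sd Mean and sd of read length in bp
#'   (log-normal, truncated to `[200, genome length]`).
#' @param mismatch_rate,ins_rate,del_rate Per-base error rates; their sum
#'   must be < 1.
#' @param mixture_ratio Probability a read originates from the
#'   non-canonical isoform (0.5 emulates the 1:1 flip-flop equilibrium).
#' @param seed Integer RNG seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(n_reads = 200, length_mean = 3000,
                            length_sd = 1000, mismatch_rate = 0,
                            ins_rate = 0, del_rate = 0,
                            mixture_ratio = 0.5, seed = 1) {
  rates <- c(mismatch_rate, ins_rate, del_rate)
  if (n_reads < 0) abort("`n_reads` must be >= 0.", class = "plastidkit_param_error")
  if (any(rates < 0) || sum(rates) >= 1) {
    abort("Error rates must be in [0, 1) and sum to < 1.",
          class = "plastidkit_param_error")
  }
  if (mixture_ratio < 0 || mixture_ratio > 1) {
    abort("`mixture_ratio` must be in [0, 1].", class = "plastidkit_param_error")
  }
  if (length_mean <= 0 || length_sd < 0) {
    abort("Read length parameters must be positive.",
          class = "plastidkit_param_error")
  }
  structure(list(n_reads = as.integer(n_reads), length_mean = length_mean,
                 length_sd = length_sd, mismatch_rate = mismatch_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 mixture_ratio = mixture_ratio, seed = seed),
            class = "read_sim_params")
}

#' Simulate long reads from a two-isoform plastome mixture
#'
#' Each read is drawn from the canonical isoform with probability
#' `1 - mixture_ratio`, else from the non-canonical isoform; the start is
#' uniform on the circle (sampling from the doubled sequence), the strand
#' random, and the length log-normal truncated to `[200, genome length]`.
#' Per-base substitution, insertion and deletion errors are applied at the
#' given rates. A truth record is emitted per read.
#'
#' @param iso_canonical,iso_noncanonical The two isoform sequences (equal
#'   length).
#' @param params A [read_sim_params()].
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `isoform`, `start`, `strand`, `length`). `start`
#'   is the 1-based origin offset on the source isoform of the forward-
#'   strand template; `length` the error-free template length.
#' @export
simulate_reads <- function(iso_canonical, iso_noncanonical, params) {
  stopifnot(inherits(params, "read_sim_params"))
  if (nchar(iso_canonical) != nchar(iso_noncanonical)) {
    abort("Isoform sequences must have equal length.",
          class = "plastidkit_param_error")
  }
  n <- nchar(iso_canonical)
  if (params$n_reads == 0) {
    return(list(
      reads = tibble(read_id = character(0), sequence = character(0)),
      truth = tibble(read_id = character(0), isoform = character(0),
                     start = integer(0), strand = character(0),
                     length = integer(0))
    ))
  }
  doubled <- c(canonical = paste0(iso_canonical, iso_canonical),
               noncanonical = paste0(iso_noncanonical, iso_noncanonical))
  with_seed(params$seed, {
    iso <- ifelse(runif(params$n_reads) < params$mixture_ratio,
                  "noncanonical", "canonical")
    sdlog <- sqrt(log(1 + (params$length_sd / params$length_mean)^2))
    meanlog <- log(params$length_mean) - sdlog^2 / 2
    len <- pmin(pmax(round(rlnorm(params$n_reads, meanlog, sdlog)), 200), n)
    start <- sample.int(n, params$n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), params$n_reads, replace = TRUE)
    template <- vapply(seq_len(params$n_reads), function(i) {
      substr(doubled[[iso[i]]], start[i], start[i] + len[i] - 1)
    }, character(1))
    template[strand == "-"] <- revcomp(template[strand == "-"])
    seqs <- vapply(template, apply_read_errors,
                   character(1),
                   mismatch = params$mismatch_rate,
                   ins = params$ins_rate, del = params$del_rate,
                   USE.NAMES = FALSE)
    ids <- sprintf("read%05d", seq_len(params$n_reads))
    list(
      reads = tibble(read_id = ids, sequence = seqs),
      truth = tibble(read_id = ids, isoform = iso,
                     start = as.integer(start), strand = strand,
                     length = as.integer(len))
    )
  })
}

apply_read_errors <- function(template, mismatch, ins, del) {
  if (mismatch + ins + del == 0) return(template)
  chars <- strsplit(template, "")[[1]]
  L <- length(chars)
  keep <- runif(L) >= del
  chars <- chars[keep]
  sub_mask <- runif(length(chars)) < mismatch
  if (any(sub_mask)) {
    bases <- c("A", "C", "G", "T")
    chars[sub_mask] <- vapply(chars[sub_mask], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  ins_mask <- runif(length(chars)) < ins
  if (any(ins_mask)) {
    out <- character(length(chars) + sum(ins_mask))
    j <- 1L
    for (i in seq_along(chars)) {
      out[j] <- chars[i]; j <- j + 1L
      if (ins_mask[i]) {
        out[j] <- sample(c("A", "C", "G", "T"), 1); j <- j + 1L
      }
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Write simulated reads as FASTQ
#'
#' Quality strings are constant Phred 20 (`"5"`); qualities are not used
#' downstream.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(n) strrep("5", n), character(1))
  )
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file.
#' @return Tibble with `read_id`, `sequence`.
#' @export
read_reads_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(paste0("Could not read FASTQ '", path, "': ", conditionMessage(e)),
            class = "plastidkit_io_error")
    }
  )
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Evolve a population of plastomes on a known tree
#'
#' Simulates sequence evolution of `ancestor` along a rooted tree with
#' branch lengths in substitutions/site: substitutions are placed by a
#' Poisson process per branch under a single-site Jukes-Cantor model, and
#' indels as gap events with geometric lengths. The emitted alignment
#' retains the ancestor coordinate system, so planted variant columns and
#' indel events are recoverable exactly.
#'
#' @param ancestor Ancestral DNA sequence (character scalar).
#' @param tree A rooted `ape::phylo` with non-negative branch lengths and
#'   unique tip labels.
#' @param subst_rate_scale Multiplier on branch lengths for substitutions.
#' @param indel_rate Indel events per site per unit branch length.
#' @param indel_len_geom_p Geometric length parameter (event length is
#'   `1 + rgeom(p)`).
#' @param seed Integer RNG seed.
#' @return List with `alignment` (a [new_alignment()] over the leaves),
#'   `column_keys` (numeric key per alignment column; integer keys are
#'   ancestor positions, fractional keys are insertions), `leaves`
#'   (named ungapped sequences), `variant_truth` (tibble of distinct
#'   substituted sites: `key`, `ancestor_pos`, plus one allele column per
#'   leaf, `-` where deleted), `events` (per-branch mutation log) and
#'   `tree`.
#' @export
simulate_population <- function(ancestor, tree, subst_rate_scale = 1,
                                indel_rate = 0, indel_len_geom_p = 0.5,
                                seed = 1) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape::phylo.", class = "plastidkit_param_error")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("All branch lengths must be present and >= 0.",
          class = "plastidkit_param_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("Leaf labels must be unique.", class = "plastidkit_param_error")
  }
  if (nchar(ancestor) == 0) {
    abort("`ancestor` must be non-empty.", class = "plastidkit_param_error")
  }
  L0 <- nchar(ancestor)
  root_df <- tibble(key = as.numeric(seq_len(L0)),
                    char = strsplit(ancestor, "")[[1]])
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  leaves_df <- vector("list", ntip)
  events <- list()
  with_seed(seed, {
    walk <- function(node, df) {
      kids <- children[[as.character(node)]]
      if (is.null(kids)) {
        leaves_df[[node]] <<- df
        return(invisible(NULL))
      }
      for (e in kids) {
        child <- tree$edge[e, 2]
        bl <- tree$edge.length[e]
        res <- evolve_branch(df, bl, subst_rate_scale, indel_rate,
                             indel_len_geom_p)
        if (nrow(res$events) > 0) {
          res$events$node <- child
          events[[length(events) + 1L]] <<- res$events
        }
        walk(child, res$df)
      }
    }
    walk(root_node, root_df)
  })
  events <- if (length(events)) bind_rows(events) else {
    tibble(type = character(0), key = numeric(0), from = character(0),
           to = character(0), length = integer(0), node = integer(0))
  }

  keys <- sort(unique(unlist(lapply(leaves_df, function(d) d$key))))
  aln_mat <- vapply(leaves_df, function(d) {
    col <- rep("-", length(keys))
    col[match(d$key, keys)] <- d$char
    col
  }, character(length(keys)))
  colnames(aln_mat) <- tree$tip.label
  aligned <- apply(aln_mat, 2, paste, collapse = "")
  al <- new_alignment(aligned)

  sub_keys <- sort(unique(events$key[events$type == "sub"]))
  if (length(sub_keys)) {
    idx <- match(sub_keys, keys)
    vt <- tibble(key = sub_keys,
                 ancestor_pos = ifelse(sub_keys == floor(sub_keys),
                                       as.integer(sub_keys), NA_integer_))
    for (tip in tree$tip.label) {
      vt[[tip]] <- aln_mat[idx, tip]
    }
  } else {
    vt <- tibble(key = numeric(0), ancestor_pos = integer(0))
  }
  list(alignment = al, column_keys = keys,
       leaves = setNames(gsub("-", "", aligned, fixed = TRUE),
                         names(aligned)),
       variant_truth = vt, events = events, tree = tree)
}

# One branch of evolution: substitutions then indels on the current
# (gapless view of the) sequence. df has numeric `key` and `char` ("-" for
# positions deleted earlier in this lineage).
evolve_branch <- function(df, bl, subst_rate_scale, indel_rate, geom_p) {
  ev <- list()
  alive <- function() which(df$char != "-")
  bases <- c("A", "C", "G", "T")

  la <- length(alive())
  n_sub <- rpois(1, bl * subst_rate_scale * la)
  if (n_sub > 0 && la > 0) {
    for (s in seq_len(n_sub)) {
      pos <- sample(alive(), 1)
      from <- df$char[pos]
      to <- sample(setdiff(bases, from), 1)
      df$char[pos] <- to
      ev[[length(ev) + 1L]] <- tibble(type = "sub", key = df$key[pos],
                                      from = from, to = to, length = 1L)
    }
  }
  if (indel_rate > 0) {
    la <- length(alive())
    n_indel <- rpois(1, bl * indel_rate * la)
    for (s in seq_len(n_indel)) {
      len <- 1L + rgeom(1, geom_p)
      av <- alive()
      if (length(av) == 0) break
      if (runif(1) < 0.5) {  # deletion
        start_i <- sample(seq_along(av), 1)
        span <- av[start_i:min(start_i + len - 1, length(av))]
        ev[[length(ev) + 1L]] <- tibble(type = "del", key = df$key[span[1]],
                                        from = paste(df$char[span], collapse = ""),
                                        to = "-", length = length(span))
        df$char[span] <- "-"
      } else {           # insertion after a uniformly chosen gapless slot
        slot <- sample(0:length(av), 1)
        key_lo <- if (slot == 0) min(df$key) - 1 else df$key[av[slot]]
        key_hi <- if (slot == length(av)) max(df$key) + 1 else df$key[av[slot + 1]]
        new_keys <- key_lo + (key_hi - key_lo) * seq_len(len) / (len + 1)
        new_chars <- sample(bases, len, replace = TRUE)
        ins_at <- if (slot == 0) 0L else av[slot]
        df <- bind_rows(
          df[seq_len(ins_at), , drop = FALSE],
          tibble(key = new_keys, char = new_chars),
          if (ins_at < nrow(df)) df[(ins_at + 1L):nrow(df), , drop = FALSE]
        )
        ev[[length(ev) + 1L]] <- tibble(type = "ins", key = new_keys[1],
                                        from = "-",
                                        to = paste(new_chars, collapse = ""),
                                        length = len)
      }
    }
  }
  list(df = df,
       events = if (length(ev)) bind_rows(ev) else
         tibble(type = character(0), key = numeric(0), from = character(0),
                to = character(0), length = integer(0)))
}

#' Which simulated reads truly span an inverted repeat?
#'
#' Computed from the read truth table and the planted partition: a read is
#' spanning iff its error-free template interval fully covers an IR region
#' plus at least `anchor_min` bp of both flanking single-copy regions
#' (strand-symmetric; works in unwrapped circular coordinates).
#'
#' @param truth Read truth tibble from [simulate_reads()].
#' @param part The planted [partition()] (canonical layout).
#' @param anchor_min Minimum flanking anchor (bp).
#' @return Logical vector along the rows of `truth`.
#' @export
spanning_truth <- function(truth, part, anchor_min = 500) {
  gl <- attr(part, "genome_length")
  s <- truth$start
  e <- truth$start + truth$length - 1
  covers <- function(lo, hi) {
    (s <= lo & e >= hi) | (s <= lo + gl & e >= hi + gl)
  }
  spans <- rep(FALSE, nrow(truth))
  for (lab in c("IR1", "IR2")) {
    r <- part[part$label == lab, ]
    spans <- spans | covers(r$start - anchor_min, r$end + anchor_min)
  }
  spans
}
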