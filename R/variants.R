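#' Multiple sequence alignment container
#'
#' A thin container for an aligned set of sequences over the alphabet
#' `A/C/G/T/N/-`: a named character vector with equal-length elements and
#' unique ids, upper-cased on construction.
#'
#' @param x Named character vector of aligned sequences.
#' @return A `plastid_alignment`.
#' @export
new_alignment <- function(x) {
  if (length(x) == 0) {
    abort("Alignment must contain at least one sequence.",
          class = "plastidkit_format_error")
  }
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x))) {
    abort("Alignment sequences must have unique non-empty ids.",
          class = "plastidkit_format_error")
  }
  x <- toupper(x)
  w <- nchar(x)
  if (length(unique(w)) != 1) {
    bad <- names(x)[w != w[1]][1]
    abort(paste0("Ragged alignment: sequence '", bad,
                 "' has a different length."),
          class = "plastidkit_format_error")
  }
  structure(x, class = "plastid_alignment")
}

#' @export
print.plastid_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x), alignment_ncol(x)))
  invisible(x)
}

alignment_ncol <- function(al) nchar(al[[1]])

# sequences x columns character matrix
alignment_matrix <- function(al) {
  m <- do.call(rbind, strsplit(unclass(al), ""))
  rownames(m) <- names(al)
  m
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA.
#' @return A [new_alignment()].
#' @export
read_alignment <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Could not read aligned FASTA '", path, "': ",
                   conditionMessage(e)),
            class = "plastidkit_format_error")
    }
  )
  if (length(x) == 0) {
    abort(paste0("Aligned FASTA '", path, "' contains no sequences."),
          class = "plastidkit_format_error")
  }
  new_alignment(setNames(as.character(x), names(x)))
}

#' Write an alignment as FASTA
#'
#' @param al A [new_alignment()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(al, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(unclass(al), names(al))), path
  )
  invisible(path)
}

#' Classify alignment columns into SNVs and indel events
#'
#' A column is an SNV iff it contains no gap and has at least two distinct
#' alleles among A/C/G/T with minor-allele count `>= min_minor_count`;
#' `N` is missing data and a column whose only variation involves `N` is
#' invariant. Gap-containing columns belong to indel events: maximal runs
#' of adjacent columns sharing an identical, non-trivial gap
#' presence/absence pattern (at least one gapped and one ungapped
#' sequence) count as one event. The default `min_minor_count = 1` keeps
#' singleton variants (no low-frequency filter).
#'
#' @param al A [new_alignment()].
#' @param min_minor_count Minimum minor-allele count for an SNV column.
#' @return A `variant_scan`: list with `variants` (tibble: `column`,
#'   `n_alleles`, `minor_count`, plus one allele column per sequence id),
#'   `indels` (tibble: `start`, `end`, `length`, `n_gapped`, `pattern`),
#'   `n_indel_columns` (total gap-patterned columns, the column-count
#'   alternative to event counting) and `ids`.
#' @examples
#' al <- new_alignment(c(s1 = "ACGTAC-GT", s2 = "ACATAC-GT", s3 = "ACGTACCGT"))
#' classify_columns(al)
#' @export
classify_columns <- function(al, min_minor_count = 1) {
  stopifnot(inherits(al, "plastid_alignment"))
  m <- alignment_matrix(al)
  ids <- rownames(m)
  nc <- ncol(m)

  gap <- m == "-"
  has_gap <- colSums(gap) > 0

  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(m == b))
  if (nc == 1) counts <- matrix(counts, nrow = 1,
                                dimnames = list(NULL, c("A", "C", "G", "T")))
  n_alleles <- rowSums(counts > 0)
  tot <- rowSums(counts)
  minor <- tot - apply(counts, 1, max)
  is_snv <- !has_gap & n_alleles >= 2 & minor >= min_minor_count

  snv_cols <- which(is_snv)
  variants <- tibble(column = snv_cols,
                     n_alleles = as.integer(n_alleles[snv_cols]),
                     minor_count = as.integer(minor[snv_cols]))
  for (id in ids) variants[[id]] <- m[id, snv_cols]

  # indel events: runs of identical non-trivial gap patterns
  nontrivial <- has_gap & colSums(gap) < nrow(m)
  indels <- tibble(start = integer(0), end = integer(0), length = integer(0),
                   n_gapped = integer(0), pattern = character(0))
  if (any(nontrivial)) {
    pat <- rep(NA_character_, nc)
    pat[nontrivial] <- apply(gap[, nontrivial, drop = FALSE], 2,
                             function(g) paste(as.integer(g), collapse = ""))
    runs <- rle(ifelse(is.na(pat), "", pat))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != ""
    indels <- tibble(
      start = starts[keep], end = ends[keep],
      length = runs$lengths[keep],
      n_gapped = vapply(strsplit(runs$values[keep], ""),
                        function(p) sum(p == "1"), integer(1)),
      pattern = runs$values[keep]
    )
  }
  structure(list(variants = variants, indels = indels,
                 n_indel_columns = sum(nontrivial), ids = ids,
                 n_columns = nc),
            class = "variant_scan")
}

#' @export
print.variant_scan <- function(x, ...) {
  cat(sprintf("Variant scan of %d columns: %d SNVs, %d indel events (%d columns)\n",
              x$n_columns, nrow(x$variants), nrow(x$indels), x$n_indel_columns))
  invisible(x)
}

#' Gap-aware coordinate map between alignment and reference positions
#'
#' @param al A [new_alignment()].
#' @param reference_id Id of the reference sequence in the alignment.
#' @return A `coordinate_map`: tibble with `column` and `ref_pos`
#'   (`NA` where the reference has a gap), plus attributes.
#' @export
build_coordinate_map <- function(al, reference_id) {
  stopifnot(inherits(al, "plastid_alignment"))
  if (!reference_id %in% names(al)) {
    abort(paste0("Unknown reference id '", reference_id, "'."),
          class = "plastidkit_param_error")
  }
  chars <- strsplit(unclass(al)[[reference_id]], "")[[1]]
  is_base <- chars != "-"
  map <- tibble(column = seq_along(chars),
                ref_pos = ifelse(is_base, cumsum(is_base), NA_integer_))
  map$ref_pos <- as.integer(map$ref_pos)
  attr(map, "reference_id") <- reference_id
  attr(map, "ref_length") <- sum(is_base)
  class(map) <- c("coordinate_map", class(tibble()))
  map
}

#' Lift a position between alignment and reference coordinates
#'
#' @param map A [build_coordinate_map()].
#' @param position 1-based position(s).
#' @param direction `"aln_to_ref"` or `"ref_to_aln"`.
#' @return Integer position(s); `NA` for an alignment column that is a gap
#'   in the reference.
#' @export
liftover <- function(map, position, direction = c("aln_to_ref", "ref_to_aln")) {
  direction <- match.arg(direction)
  if (direction == "aln_to_ref") {
    if (any(position < 1 | position > nrow(map))) {
      abort("Alignment position out of range.", class = "plastidkit_param_error")
    }
    map$ref_pos[position]
  } else {
    rl <- attr(map, "ref_length")
    if (any(position < 1 | position > rl)) {
      abort("Reference position out of range.", class = "plastidkit_param_error")
    }
    map$column[match(position, map$ref_pos)]
  }
}

#' Read a single-column marker position list
#'
#' @param path TSV with one reference position per line (optionally with a
#'   header line `pos`).
#' @return Integer vector of positions.
#' @export
read_marker_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(trimws(lines[1])), "pos")) {
    lines <- lines[-1]
  }
  vals <- suppressWarnings(as.integer(trimws(lines)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort(paste0("Malformed marker list '", path, "' at line ", bad,
                 ": not an integer position."),
          class = "plastidkit_format_error")
  }
  vals
}

#' Intersect SNV positions with two external marker lists
#'
#' SNV columns are lifted to reference coordinates; positions falling in
#' reference gaps are excluded and counted. The high-confidence set is the
#' intersection of the SNVs with both external lists.
#'
#' @param scan A [classify_columns()] result (or a tibble with a `column`
#'   column).
#' @param map A [build_coordinate_map()].
#' @param list_a,list_b Integer position vectors or paths to single-column
#'   TSV lists (reference coordinates).
#' @return A `marker_intersection`: list with `snv_ref_pos`,
#'   `shared_with_a`, `shared_with_b`, `high_confidence`, their sizes and
#'   `n_unmapped`.
#' @export
intersect_markers <- function(scan, map, list_a, list_b) {
  cols <- if (inherits(scan, "variant_scan")) scan$variants$column else scan$column
  if (is.character(list_a)) list_a <- read_marker_positions(list_a)
  if (is.character(list_b)) list_b <- read_marker_positions(list_b)
  ref <- liftover(map, cols, "aln_to_ref")
  n_unmapped <- sum(is.na(ref))
  ref <- sort(ref[!is.na(ref)])
  a <- sort(intersect(ref, list_a))
  b <- sort(intersect(ref, list_b))
  hc <- sort(intersect(a, b))
  structure(list(
    snv_ref_pos = ref, shared_with_a = a, shared_with_b = b,
    high_confidence = hc,
    n_snv = length(ref), n_shared_a = length(a), n_shared_b = length(b),
    n_high_confidence = length(hc), n_unmapped = n_unmapped
  ), class = "marker_intersection")
}

#' @export
print.marker_intersection <- function(x, ...) {
  cat(sprintf(paste0(
    "Marker intersection: %d SNVs on reference (%d unmapped);\n",
    "  shared with list A: %d, with list B: %d, with both: %d\n"),
    x$n_snv, x$n_unmapped, x$n_shared_a, x$n_shared_b, x$n_high_confidence))
  invisible(x)
}

#' Write a variant table as TSV and minimal VCF
#'
#' VCF positions are 1-based reference coordinates; the REF allele is
#' checked against the reference sequence and alternates are listed
#' comma-separated. SNVs at reference-gap columns are written to the TSV
#' with `ref_pos = NA` and omitted from the VCF.
#'
#' @param scan A [classify_columns()] result.
#' @param map A [build_coordinate_map()].
#' @param reference_sequence Ungapped reference sequence (must match the
#'   map's reference).
#' @param tsv_path,vcf_path Output paths (either may be `NULL` to skip).
#' @param chrom CHROM value for VCF rows.
#' @return Tibble of the variant rows written, invisibly.
#' @export
write_variants <- function(scan, map, reference_sequence,
                           tsv_path = NULL, vcf_path = NULL,
                           chrom = "plastome") {
  stopifnot(inherits(scan, "variant_scan"))
  v <- scan$variants
  ids <- scan$ids
  ref_id <- attr(map, "reference_id")
  if (nchar(reference_sequence) != attr(map, "ref_length")) {
    abort("Reference sequence length does not match the coordinate map.",
          class = "plastidkit_consistency_error")
  }
  ref_pos <- if (nrow(v)) liftover(map, v$column, "aln_to_ref") else integer(0)
  rows <- v
  rows$ref_pos <- ref_pos
  rows <- rows[, c("column", "ref_pos", "n_alleles", "minor_count", ids)]
  if (!is.null(tsv_path)) readr::write_tsv(rows, tsv_path, progress = FALSE)

  if (!is.null(vcf_path)) {
    vcf_rows <- rows[!is.na(rows$ref_pos), , drop = FALSE]
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", chrom,
                        nchar(reference_sequence)),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- character(nrow(vcf_rows))
    for (i in seq_len(nrow(vcf_rows))) {
      pos <- vcf_rows$ref_pos[i]
      ref_base <- substr(reference_sequence, pos, pos)
      alleles <- setNames(as.character(vcf_rows[i, ids]), ids)
      obs <- setdiff(unique(alleles[alleles %in% c("A", "C", "G", "T")]),
                     ref_base)
      row_ref <- unname(alleles[ref_id])
      if (!identical(row_ref, ref_base)) {
        abort(sprintf(
          "REF mismatch at reference position %d: alignment has %s, reference %s.",
          pos, row_ref, ref_base), class = "plastidkit_consistency_error")
      }
      body[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos,
                         ref_base, paste(obs, collapse = ","))
    }
    writeLines(c(header, body), vcf_path)
  }
  invisible(rows)
}
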