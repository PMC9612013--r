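#' Quadripartite partition of a circular plastome
#'
#' A partition records the coordinates of the four canonical plastome
#' regions — the long single-copy region (LSC), the two inverted repeats
#' (IR1/IRa and IR2/IRb) and the small single-copy region (SSC) — on a
#' circular sequence. Coordinates are 1-based inclusive; a region with
#' `start > end` wraps through the origin. Regions are stored in circular
#' order starting from the LSC, tile the genome exactly once, the two IRs
#' have equal length and the LSC is at least as long as the SSC.
#'
#' @param lsc Integer vector `c(start, end)` of the LSC.
#' @param ir1 Integer vector `c(start, end)` of the IR following the LSC.
#' @param ssc Integer vector `c(start, end)` of the SSC.
#' @param ir2 Integer vector `c(start, end)` of the IR preceding the LSC.
#' @param genome_length Total length of the circular sequence in bp.
#' @return A `plastid_partition`: a tibble with columns `label`, `start`,
#'   `end`, `strand` and attribute `genome_length`.
#' @examples
#' partition(c(1, 3000), c(3001, 3400), c(3401, 4200), c(4201, 4600), 4600)
#' @export
partition <- function(lsc, ir1, ssc, ir2, genome_length) {
  p <- tibble(
    label  = c("LSC", "IR1", "SSC", "IR2"),
    start  = as.integer(c(lsc[1], ir1[1], ssc[1], ir2[1])),
    end    = as.integer(c(lsc[2], ir1[2], ssc[2], ir2[2])),
    strand = "+"
  )
  attr(p, "genome_length") <- as.integer(genome_length)
  class(p) <- c("plastid_partition", class(tibble()))
  validate_partition(p)
  p
}

region_length <- function(start, end, genome_length) {
  ifelse(start <= end, end - start + 1L, genome_length - start + end + 1L)
}

validate_partition <- function(p) {
  gl <- attr(p, "genome_length")
  if (!setequal(p$label, c("LSC", "IR1", "SSC", "IR2")) || nrow(p) != 4) {
    abort("A partition must have exactly the regions LSC, IR1, SSC, IR2.",
          class = "plastidkit_structure_error")
  }
  len <- region_length(p$start, p$end, gl)
  if (sum(len) != gl) {
    abort("Partition regions must tile the circular genome exactly once.",
          class = "plastidkit_structure_error")
  }
  if (len[p$label == "IR1"] != len[p$label == "IR2"]) {
    abort("The two inverted repeats must have equal length.",
          class = "plastidkit_structure_error")
  }
  if (len[p$label == "LSC"] < len[p$label == "SSC"]) {
    abort("LSC must be at least as long as SSC.",
          class = "plastidkit_structure_error")
  }
  # contiguity in circular order LSC -> IR1 -> SSC -> IR2 -> LSC
  nxt <- function(e) (e %% gl) + 1L
  ord <- match(c("LSC", "IR1", "SSC", "IR2"), p$label)
  for (i in seq_len(4)) {
    j <- ord[(i %% 4) + 1]
    if (nxt(p$end[ord[i]]) != p$start[j]) {
      abort("Partition regions must be contiguous in circular order.",
            class = "plastidkit_structure_error")
    }
  }
  invisible(p)
}

# Canonical-layout partition for given region lengths (LSC starts at 1).
layout_partition <- function(lsc_len, ir_len, ssc_len) {
  partition(
    lsc = c(1L, lsc_len),
    ir1 = c(lsc_len + 1L, lsc_len + ir_len),
    ssc = c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len),
    ir2 = c(lsc_len + ir_len + ssc_len + 1L, lsc_len + 2L * ir_len + ssc_len),
    genome_length = lsc_len + 2L * ir_len + ssc_len
  )
}

# Extract the sequence of one region (circular-aware).
region_sequence <- function(sequence, part, label) {
  r <- part[part$label == label, ]
  circular_substr(sequence, r$start, r$end)
}

#' Write a partition as BED
#'
#' BED uses 0-based half-open coordinates; a wrapping region is split into
#' two BED lines sharing the region name.
#'
#' @param part A `plastid_partition`.
#' @param path Output file.
#' @param chrom Chromosome/sequence name for the BED lines.
#' @return The path, invisibly.
#' @export
write_partition_bed <- function(part, path, chrom = "plastome") {
  gl <- attr(part, "genome_length")
  rows <- lapply(seq_len(nrow(part)), function(i) {
    s <- part$start[i]; e <- part$end[i]
    if (s <= e) {
      tibble(chrom = chrom, start = s - 1L, end = e, name = part$label[i])
    } else {
      tibble(chrom = chrom, start = c(s - 1L, 0L), end = c(gl, e),
             name = part$label[i])
    }
  })
  bed <- bind_rows(rows)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a partition from a BED file written by [write_partition_bed()]
#'
#' @param path BED file (0-based half-open), one or two lines per region.
#' @param genome_length Length of the circular sequence.
#' @return A `plastid_partition`.
#' @export
read_partition_bed <- function(path, genome_length) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", progress = FALSE)
  get1 <- function(lab) {
    b <- bed[bed$name == lab, ]
    if (nrow(b) == 1) c(b$start + 1L, b$end)
    else if (nrow(b) == 2) c(b$start[1] + 1L, b$end[2])  # wrapping region
    else abort(paste0("Region ", lab, " missing or split oddly in BED."),
               class = "plastidkit_structure_error")
  }
  partition(get1("LSC"), get1("IR1"), get1("SSC"), get1("IR2"), genome_length)
}

#' @export
print.plastid_partition <- function(x, ...) {
  gl <- attr(x, "genome_length")
  cat(sprintf("Quadripartite partition of a %d bp circular plastome\n", gl))
  len <- region_length(x$start, x$end, gl)
  df <- as_tibble(unclass_partition(x))
  df$length <- len
  print(df, ...)
  invisible(x)
}

unclass_partition <- function(x) {
  class(x) <- setdiff(class(x), "plastid_partition")
  x
}

#' @export
autoplot.plastid_partition <- function(object, ...) {
  gl <- attr(object, "genome_length")
  df <- as_tibble(unclass_partition(object))
  df$length <- region_length(df$start, df$end, gl)
  df$label <- factor(df$label, levels = c("LSC", "IR1", "SSC", "IR2"))
  # unwrap for display: plot in circular order from LSC start
  df$x0 <- cumsum(c(0, head(df$length, -1)))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0, xmax = .data$x0 + .data$length,
      ymin = 0, ymax = 1, fill = .data$label
    )) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "position (bp, unwrapped from LSC start)",
                  fill = "region",
                  title = sprintf("Quadripartite structure (%d bp)", gl)) +
    ggplot2::theme_minimal()
}
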