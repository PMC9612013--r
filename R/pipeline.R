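# End-to-end pipeline: simulate -> detect structure -> phase reads ->
# variants -> tree, with a single validated config, a manifest of output
# checksums and reproducible seeds.

config_schema <- list(
  out_dir = NULL, overwrite = NULL, stages = NULL, inputs = NULL,
  plastome = c("lsc_len", "ssc_len", "ir_len", "gc_content", "seed"),
  reads = c("n_reads", "length_mean", "length_sd", "mismatch_rate",
            "ins_rate", "del_rate", "mixture_ratio", "seed"),
  detect = c("min_len", "max_mismatch_frac"),
  phase = c("anchor_min", "identity_min", "k"),
  population = c("newick", "subst_rate_scale", "indel_rate",
                 "indel_len_geom_p", "seed"),
  variants = c("min_minor_count", "reference_id", "marker_list_a",
               "marker_list_b"),
  tree = c("mode", "bootstrap", "seed", "outgroup", "query")
)
stage_names <- c("simulate", "detect", "phase", "variants", "tree")
input_names <- c("genome_fasta", "reads_fastq", "partition_bed",
                 "alignment_fasta")

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), rejects unknown keys (strict
#' mode), checks that every enabled stochastic stage carries an explicit
#' seed, and fills stage defaults.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config),
            class = "plastidkit_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("Config must be a list or a YAML file path.",
          class = "plastidkit_config_error")
  }
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "plastidkit_config_error")
  }
  for (sec in setdiff(names(config_schema), c("out_dir", "overwrite",
                                              "stages", "inputs"))) {
    bad <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      abort(paste0("Unknown key(s) in `", sec, "`: ",
                   paste(bad, collapse = ", ")),
            class = "plastidkit_config_error")
    }
  }
  bad_stage <- setdiff(names(config$stages), stage_names)
  if (length(bad_stage)) {
    abort(paste0("Unknown stage(s): ", paste(bad_stage, collapse = ", ")),
          class = "plastidkit_config_error")
  }
  bad_in <- setdiff(names(config$inputs), input_names)
  if (length(bad_in)) {
    abort(paste0("Unknown input(s): ", paste(bad_in, collapse = ", ")),
          class = "plastidkit_config_error")
  }
  stages <- lapply(stage_names, function(s) isTRUE(config$stages[[s]]))
  names(stages) <- stage_names

  if (stages$simulate) {
    for (sec in c("plastome", "reads", "population")) {
      if (!is.null(config[[sec]]) && is.null(config[[sec]]$seed)) {
        abort(paste0("Stochastic section `", sec,
                     "` needs an explicit `seed`."),
              class = "plastidkit_config_error")
      }
    }
    if (is.null(config$plastome$seed)) {
      abort("Stage `simulate` needs `plastome$seed`.",
            class = "plastidkit_config_error")
    }
    if (!is.null(config$population) && is.null(config$population$newick)) {
      abort("Population simulation needs `population$newick`.",
            class = "plastidkit_config_error")
    }
  }
  if (stages$tree && !is.null(config$tree$bootstrap) &&
      config$tree$bootstrap > 0 && is.null(config$tree$seed)) {
    abort("Bootstrap needs `tree$seed`.", class = "plastidkit_config_error")
  }
  if (!is.null(config$plastome)) {
    # constructor performs the numeric validation
    do.call(plastome_spec, config$plastome)
  }
  if (!is.null(config$reads)) do.call(read_sim_params, config$reads)

  cfg <- list(
    out_dir = config$out_dir %||% tempfile("plastidkit_run_"),
    overwrite = isTRUE(config$overwrite),
    stages = stages,
    inputs = config$inputs,
    plastome = config$plastome,
    reads = config$reads,
    detect = utils::modifyList(list(min_len = NULL, max_mismatch_frac = 0.01),
                               config$detect %||% list()),
    phase = utils::modifyList(list(anchor_min = 500, identity_min = 0.85,
                                   k = 15), config$phase %||% list()),
    population = config$population,
    variants = utils::modifyList(list(min_minor_count = 1),
                                 config$variants %||% list()),
    tree = utils::modifyList(list(mode = "all_columns", bootstrap = 0),
                             config$tree %||% list())
  )
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full plastome analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every stage
#' output (FASTA/FASTQ/BED/TSV/newick) under `out_dir` and logging a
#' manifest of per-stage wall-clock times, output checksums and warnings.
#' Deterministic stages reproduce identical checksums on re-run with the
#' same config.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return A `pipeline_report`: list with `manifest` (tibble), `phasing`,
#'   `variants`, `markers`, `tree` (newick string), `monophyly`,
#'   `accuracy` (truth-checked phasing accuracy when simulating) and
#'   `warnings`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$out_dir
  if (dir.exists(out) && length(list.files(out)) > 0 && !cfg$overwrite) {
    abort(paste0("Output directory ", out,
                 " is not empty; set `overwrite: true`."),
          class = "plastidkit_config_error")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  warnings <- character(0)
  state <- list()
  note <- function(stage, outputs, elapsed) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, output = outputs,
      md5 = unname(tools::md5sum(outputs)), seconds = round(elapsed, 3)
    )
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fn(), error = function(e) {
      abort(paste0("Stage `", stage, "` failed: ", conditionMessage(e)),
            class = "plastidkit_stage_error")
    })
    note(stage, outputs, proc.time()[["elapsed"]] - t0)
  }
  need <- function(stage, what, ok) {
    if (!ok) {
      abort(paste0("Stage `", stage, "` needs ", what,
                   " from an earlier stage or `inputs`."),
            class = "plastidkit_dependency_error")
    }
  }

  if (cfg$stages$simulate) {
    run_stage("simulate", function() {
      spec <- do.call(plastome_spec, cfg$plastome)
      sim <- simulate_plastome(spec)
      state$genome <<- sim$sequence
      state$partition <<- sim$partition
      outs <- file.path(out, "genome.fasta")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(plastome = sim$sequence)), outs[1])
      bed <- file.path(out, "partition_truth.bed")
      write_partition_bed(sim$partition, bed)
      outs <- c(outs, bed)
      if (!is.null(cfg$reads)) {
        isoA <- build_isoform(sim$sequence, sim$partition, "canonical")
        isoB <- build_isoform(sim$sequence, sim$partition, "noncanonical")
        rs <- simulate_reads(isoA, isoB, do.call(read_sim_params, cfg$reads))
        state$reads <<- rs$reads
        state$read_truth <<- rs$truth
        fq <- file.path(out, "reads.fastq")
        write_reads_fastq(rs$reads, fq)
        tt <- file.path(out, "read_truth.tsv")
        readr::write_tsv(rs$truth, tt, progress = FALSE)
        outs <- c(outs, fq, tt)
      }
      if (!is.null(cfg$population)) {
        pop <- simulate_population(
          sim$sequence, ape::read.tree(text = cfg$population$newick),
          subst_rate_scale = cfg$population$subst_rate_scale %||% 1,
          indel_rate = cfg$population$indel_rate %||% 0,
          indel_len_geom_p = cfg$population$indel_len_geom_p %||% 0.5,
          seed = cfg$population$seed
        )
        state$population <<- pop
        state$alignment <<- pop$alignment
        af <- file.path(out, "population_alignment.fasta")
        write_alignment(pop$alignment, af)
        vt <- file.path(out, "variant_truth.tsv")
        readr::write_tsv(pop$variant_truth, vt, progress = FALSE)
        outs <- c(outs, af, vt)
      }
      outs
    })
  }

  if (!is.null(cfg$inputs$genome_fasta) && is.null(state$genome)) {
    state$genome <- as.character(
      Biostrings::readDNAStringSet(cfg$inputs$genome_fasta))[1]
  }
  if (!is.null(cfg$inputs$reads_fastq) && is.null(state$reads)) {
    state$reads <- read_reads_fastq(cfg$inputs$reads_fastq)
  }
  if (!is.null(cfg$inputs$alignment_fasta) && is.null(state$alignment)) {
    state$alignment <- read_alignment(cfg$inputs$alignment_fasta)
  }
  if (!is.null(cfg$inputs$partition_bed) && is.null(state$partition) &&
      !is.null(state$genome)) {
    state$partition <- read_partition_bed(cfg$inputs$partition_bed,
                                          nchar(state$genome))
  }

  report <- list(manifest = NULL, phasing = NULL, variants = NULL,
                 markers = NULL, tree = NULL, monophyly = NULL,
                 accuracy = NA_real_, warnings = character(0))

  if (cfg$stages$detect) {
    need("detect", "a genome sequence", !is.null(state$genome))
    run_stage("detect", function() {
      min_len <- cfg$detect$min_len %||% if (!is.null(state$partition)) {
        p <- state$partition
        region_length(p$start[p$label == "IR1"], p$end[p$label == "IR1"],
                      attr(p, "genome_length"))
      } else 1000
      det <- detect_structure(state$genome, min_len = min_len,
                              max_mismatch_frac = cfg$detect$max_mismatch_frac)
      if (!is.null(state$partition) &&
          !isTRUE(all.equal(as.data.frame(det),
                            as.data.frame(state$partition)))) {
        warnings <<- c(warnings,
                       "detected partition differs from planted truth")
      }
      state$partition <<- det
      bed <- file.path(out, "partition_detected.bed")
      write_partition_bed(det, bed)
      bed
    })
  }

  if (cfg$stages$phase) {
    need("phase", "reads, a genome and a partition",
         !is.null(state$reads) && !is.null(state$genome) &&
           !is.null(state$partition))
    run_stage("phase", function() {
      pdir <- file.path(out, "phasing")
      ph <- phase_reads(state$reads, state$genome, state$partition,
                        anchor_min = cfg$phase$anchor_min,
                        identity_min = cfg$phase$identity_min,
                        k = cfg$phase$k, out_dir = pdir)
      report$phasing <<- ph
      if (!is.null(state$read_truth)) {
        cmp <- dplyr::inner_join(ph$calls, state$read_truth, by = "read_id")
        cls <- cmp[!is.na(cmp$call) & cmp$call != "unclassified", ]
        if (nrow(cls)) {
          report$accuracy <<- mean(cls$call == cls$isoform) * 100
        }
      }
      list.files(pdir, full.names = TRUE)
    })
  }

  if (cfg$stages$variants) {
    need("variants", "an alignment", !is.null(state$alignment))
    run_stage("variants", function() {
      al <- state$alignment
      scan <- classify_columns(al, cfg$variants$min_minor_count)
      report$variants <<- scan
      ref_id <- cfg$variants$reference_id %||% names(al)[1]
      cmap <- build_coordinate_map(al, ref_id)
      ref_seq <- gsub("-", "", unclass(al)[[ref_id]], fixed = TRUE)
      tsv <- file.path(out, "variants.tsv")
      vcf <- file.path(out, "variants.vcf")
      write_variants(scan, cmap, ref_seq, tsv, vcf)
      outs <- c(tsv, vcf)
      if (!is.null(cfg$variants$marker_list_a) &&
          !is.null(cfg$variants$marker_list_b)) {
        mi <- intersect_markers(scan, cmap, cfg$variants$marker_list_a,
                                cfg$variants$marker_list_b)
        report$markers <<- mi
        mk <- file.path(out, "marker_intersection.tsv")
        readr::write_tsv(tidy(mi), mk, progress = FALSE)
        outs <- c(outs, mk)
      }
      state$scan <<- scan
      outs
    })
  }

  if (cfg$stages$tree) {
    need("tree", "an alignment", !is.null(state$alignment))
    run_stage("tree", function() {
      al <- state$alignment
      nb <- cfg$tree$bootstrap %||% 0
      tr <- if (nb > 0) {
        bootstrap_support(al, n_reps = nb, seed = cfg$tree$seed,
                          mode = cfg$tree$mode)
      } else {
        nj_tree(p_distance_matrix(al, cfg$tree$mode))
      }
      if (!is.null(attr(tr, "clamped")) && attr(tr, "clamped") > 0) {
        warnings <<- c(warnings, sprintf(
          "negative NJ branch lengths clamped (total deficit %.3g)",
          attr(tr, "clamped")))
      }
      if (!is.null(cfg$tree$outgroup)) {
        tr <- root_tree(tr, unlist(cfg$tree$outgroup))
      }
      nwk <- file.path(out, "tree.nwk")
      ape::write.tree(tr, nwk)
      report$tree <<- readLines(nwk)
      outs <- nwk
      if (!is.null(cfg$tree$query)) {
        rep_tree <- if (!is.null(cfg$tree$outgroup)) tr else {
          # monophyly needs a rooted tree; root at the first tip
          root_tree(tr, tr$tip.label[1])
        }
        mono <- clade_test(rep_tree, unlist(cfg$tree$query))
        report$monophyly <<- mono
        mf <- file.path(out, "monophyly.tsv")
        readr::write_tsv(glance(mono), mf, progress = FALSE)
        outs <- c(outs, mf)
      }
      outs
    })
  }

  report$manifest <- if (length(manifest)) bind_rows(manifest) else {
    tibble(stage = character(0), output = character(0), md5 = character(0),
           seconds = numeric(0))
  }
  report$warnings <- warnings
  readr::write_tsv(report$manifest, file.path(out, "manifest.tsv"),
                   progress = FALSE)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("plastidkit pipeline report\n")
  cat(sprintf("  stages run: %s\n",
              paste(unique(x$manifest$stage), collapse = ", ")))
  if (!is.null(x$phasing)) print(x$phasing)
  if (!is.na(x$accuracy)) {
    cat(sprintf("  truth-checked phasing accuracy: %.1f%%\n", x$accuracy))
  }
  if (!is.null(x$variants)) print(x$variants)
  if (!is.null(x$markers)) print(x$markers)
  if (!is.null(x$monophyly)) print(x$monophyly)
  if (length(x$warnings)) {
    cat("  warnings:\n", paste0("    - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Demo configuration for a small end-to-end synthetic run
#'
#' A desk-scale run: a 4.6 kb plastome, 120 error-free reads at 1:1
#' isoform mixture, an 8-leaf population with two well-separated clades,
#' structure detection, phasing, variant classification and a
#' bootstrapped NJ tree with a monophyly query split across the clades.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for all stochastic sections.
#' @return A named list accepted by [validate_config()].
#' @export
demo_config <- function(out_dir = tempfile("plastidkit_demo_"), seed = 1) {
  list(
    out_dir = out_dir,
    overwrite = TRUE,
    stages = list(simulate = TRUE, detect = TRUE, phase = TRUE,
                  variants = TRUE, tree = TRUE),
    plastome = list(lsc_len = 3000, ssc_len = 800, ir_len = 400,
                    gc_content = 0.38, seed = seed),
    reads = list(n_reads = 120, length_mean = 2200, length_sd = 500,
                 mismatch_rate = 0, ins_rate = 0, del_rate = 0,
                 mixture_ratio = 0.5, seed = seed + 1),
    detect = list(max_mismatch_frac = 0),
    phase = list(anchor_min = 300),
    population = list(
      newick = paste0("(((P1:0.01,P2:0.01):0.02,(P3:0.01,P4:0.01):0.02)",
                      ":0.02,((Q1:0.01,Q2:0.01):0.02,(Q3:0.01,Q4:0.01)",
                      ":0.02):0.02);"),
      subst_rate_scale = 1, indel_rate = 0.05, indel_len_geom_p = 0.5,
      seed = seed + 2
    ),
    variants = list(min_minor_count = 1),
    tree = list(mode = "all_columns", bootstrap = 100, seed = seed + 3,
                outgroup = list("Q1", "Q2", "Q3", "Q4"),
                query = list("P1", "Q1"))
  )
}
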