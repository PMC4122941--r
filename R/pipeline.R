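#' Assemble repeat families from consensus sequences and alignments
#'
#' @param consensi named character vector of consensus sequences (e.g. from
#'   [read_fasta()]); names are family ids.
#' @param alignments list of [pairwise_alignment()] objects.
#' @param family_map optional data.frame `family_id`, `superfamily` (and
#'   optionally `te_class`) labelling each family.
#' @return named list of [repeat_family()] objects (families without a
#'   consensus are dropped with a message).
#' @export
assemble_families <- function(consensi, alignments, family_map = NULL) {
  fam_ids <- vapply(alignments, `[[`, character(1), "family_id")
  missing <- setdiff(unique(fam_ids), names(consensi))
  if (length(missing)) {
    message("assemble_families: dropping ", length(missing),
            " family(ies) without a consensus: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  keep <- intersect(names(consensi), unique(fam_ids))
  out <- lapply(keep, function(fid) {
    sf <- "Unknown"
    if (!is.null(family_map)) {
      m <- match(fid, family_map$family_id)
      if (!is.na(m)) sf <- family_map$superfamily[m]
    }
    repeat_family(fid, consensi[[fid]], alignments[fam_ids == fid],
                  superfamily = sf)
  })
  names(out) <- keep
  out
}

#' Read a family map TSV
#'
#' Columns `family_id`, `superfamily`.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) stop("family map not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("family_id", first, fixed = TRUE)
  utils::read.table(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE,
                    col.names = c("family_id", "superfamily"))
}

#' Build a run configuration
#'
#' All thresholds default to the published analysis values: copy filter
#' `>100` bp / `>=80%` identity, consensus acceptance `>330` bp from `>=5`
#' copies each `>300` bp / `>=80%`, chi-square alpha 0.05, small-indel cap
#' 30 bp, homopolymer minimum run 5, 1% divergence bins.
#'
#' @param alignments,consensi,family_map,annotations input paths (optional
#'   depending on the stages run).
#' @param out_dir output directory.
#' @param genome_size_gb genome size in Gb (no default is hard-coded into
#'   the estimators; configure per species).
#' @param dataset_bp total dataset size in bp for landscape percentages.
#' @param seed integer seed for any simulation stage.
#' @param preset name of a [preset_scenarios()] scenario to simulate inputs
#'   from (used when no alignment input is given).
#' @param n_copies copies per simulated family in the simulate stage.
#' @param min_len_bp,min_identity,bin_width_pct,weighting age-distribution
#'   thresholds.
#' @param min_consensus_len,min_copies,min_copy_len loss-rate consensus
#'   acceptance thresholds.
#' @param alpha,indel_cap,homopolymer_min_run,orf_frame_offset loss-rate
#'   estimation parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(alignments = NULL, consensi = NULL, family_map = NULL,
                       annotations = NULL, out_dir = "retroscape_out",
                       genome_size_gb = 55, dataset_bp = NULL, seed = 1L,
                       preset = "old_burst", n_copies = 500L,
                       min_len_bp = 100L, min_identity = 0.80,
                       bin_width_pct = 1.0, weighting = "bp",
                       min_consensus_len = 330L, min_copies = 5L,
                       min_copy_len = 300L, alpha = 0.05, indel_cap = 30L,
                       homopolymer_min_run = 5L, orf_frame_offset = 0L) {
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a plain-text `key: value` configuration
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return the path (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "" else as.character(v), character(1))
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  defaults <- run_config()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    old <- defaults[[key]]
    defaults[[key]] <- if (!nzchar(val)) NULL
      else if (is.numeric(old)) as.numeric(val)
      else val
  }
  class(defaults) <- "run_config"
  defaults
}

stage_msg <- function(...) message("[retroscape] ", ...)

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) obtain inputs -- either read the
#' configured alignment/consensus files, or simulate a preset family when no
#' alignment input is configured; (2) age distribution (filtered, refined,
#' binned; TSV); (3) DNA loss rate (TSV); (4) landscape summary when
#' annotations are configured (TSV). A JSON manifest records the package
#' version, the full configuration, the seed, input digests and per-stage
#' counts; identical config + inputs reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "retroscape",
                   version = as.character(utils::packageVersion("retroscape")),
                   r_version = R.version.string,
                   config = config[!vapply(config, is.null, logical(1))],
                   inputs = list(), counts = list())

  if (is.null(config$alignments)) {
    stage_msg("simulate: preset '", config$preset, "', seed ", config$seed)
    scen <- preset_scenarios(n_copies = config$n_copies,
                             seed = config$seed)[[config$preset]]
    if (is.null(scen)) stop("unknown preset: ", config$preset)
    sim <- simulate_family(scen, family_id = paste0(config$preset, "_fam"))
    families <- list(sim$family)
    write_fasta(stats::setNames(sim$family$consensus, sim$family$family_id),
                file.path(config$out_dir, "consensus.fasta"))
    write_canonical_alignments(sim$family$alignments,
                               file.path(config$out_dir, "alignments.aln"))
    utils::write.table(sim$truth$copies,
                       file.path(config$out_dir, "truth_copies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$simulated_copies <- length(sim$family$alignments)
  } else {
    for (p in c(config$alignments, config$consensi, config$family_map,
                config$annotations)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
    stage_msg("read: ", config$alignments)
    alns <- tryCatch(read_canonical_alignments(config$alignments),
                     error = function(e) read_repeatmasker_align(config$alignments))
    consensi <- read_fasta(config$consensi)
    fmap <- if (!is.null(config$family_map)) read_family_map(config$family_map)
    families <- assemble_families(consensi, alns, fmap)
    manifest$inputs <- lapply(
      stats::setNames(nm = c(config$alignments, config$consensi)),
      function(p) unname(tools::md5sum(p)))
    manifest$counts$alignments_read <- length(alns)
  }
  manifest$counts$families <- length(families)

  # --- age distribution -------------------------------------------------
  stage_msg("teage: ", length(families), " family(ies)")
  recs <- do.call(rbind, lapply(families, function(f)
    divergence_records(f, detect_master_substitutions(
      f, min_copies = scaled_min_copies(f)))))
  kept <- filter_copies(recs, config$min_len_bp, config$min_identity)
  manifest$counts$copies_total <- nrow(recs)
  manifest$counts$copies_filtered_out <- nrow(recs) - nrow(kept)
  hist <- age_histogram(kept, bin_width_pct = config$bin_width_pct,
                        weighting = config$weighting)
  write_age_histogram(hist, file.path(config$out_dir, "age_histogram.tsv"))

  # --- DNA loss ---------------------------------------------------------
  stage_msg("dnaloss")
  acc <- lapply(families, accept_consensus,
                min_consensus_len = config$min_consensus_len,
                min_copies = config$min_copies,
                min_copy_len = config$min_copy_len,
                min_identity = config$min_identity)
  accepted <- families[vapply(acc, `[[`, logical(1), "accepted")]
  manifest$counts$families_accepted <- length(accepted)
  if (length(accepted)) {
    lr <- loss_rate(accepted, alpha = config$alpha,
                    min_run = config$homopolymer_min_run,
                    indel_cap = config$indel_cap,
                    orf_frame_offset = config$orf_frame_offset)
    manifest$counts$families_chisq_excluded <-
      sum(attr(lr, "codon_tests")$excluded)
    lr_df <- data.frame(n_copies = lr$n_copies, n_deletions = lr$n_deletions,
                        n_insertions = lr$n_insertions,
                        bp_deleted = lr$bp_deleted, bp_inserted = lr$bp_inserted,
                        n_substitutions_jc = lr$n_substitutions_jc,
                        loss_rate = lr$loss_rate,
                        mean_del_size = lr$mean_del_size,
                        mean_ins_size = lr$mean_ins_size,
                        del_ins_ratio = lr$del_ins_ratio)
    utils::write.table(lr_df, file.path(config$out_dir, "loss_rate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(attr(lr, "codon_tests"),
                       file.path(config$out_dir, "codon_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stage_msg("dnaloss: no family passes consensus acceptance; stage skipped")
  }

  # --- landscape --------------------------------------------------------
  if (!is.null(config$annotations)) {
    stage_msg("landscape: ", config$annotations)
    ann <- resolve_overlaps(read_annotations(config$annotations))
    ls <- summarize_landscape(ann, genome_size_gb = config$genome_size_gb,
                              dataset_bp = config$dataset_bp)
    write_landscape(ls, file.path(config$out_dir, "landscape.tsv"))
    manifest$counts$annotation_records <- nrow(ann)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
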