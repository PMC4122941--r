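CATEGORY_LEVELS <- c("known_TE", "unknown_repeat", "simple_repeat")

#' Read per-read repeat annotations (BED-like TSV)
#'
#' Columns: `read_id`, `start`, `end` (0-based half-open), `label`
#' (superfamily string), `category` (one of `known_TE`, `unknown_repeat`,
#' `simple_repeat`).
#'
#' @param path path to the TSV (header optional, detected).
#' @return annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("read_id", first, fixed = TRUE)
  ann <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           col.names = c("read_id", "start", "end",
                                         "label", "category"))
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  stopifnot(all(c("read_id", "start", "end", "label", "category") %in% names(ann)))
  if (any(ann$end <= ann$start)) stop("annotation with end <= start")
  bad <- setdiff(unique(ann$category), CATEGORY_LEVELS)
  if (length(bad)) stop("unknown annotation category: ", paste(bad, collapse = ", "))
  invisible(ann)
}

#' Resolve overlapping annotations within each read
#'
#' Overlaps are resolved by category precedence
#' `known_TE > unknown_repeat > simple_repeat`; ties by longer annotation,
#' then lexicographic label. Lower-precedence annotations are trimmed to the
#' positions not already claimed (an annotation split in two emits two
#' records).
#'
#' @param ann annotation data.frame as from [read_annotations()].
#' @return disjoint annotation data.frame (same columns).
#' @export
resolve_overlaps <- function(ann) {
  validate_annotations(ann)
  if (nrow(ann) == 0L) return(ann)
  pieces <- lapply(split(ann, ann$read_id), function(g) {
    o <- order(match(g$category, CATEGORY_LEVELS), -(g$end - g$start), g$label)
    g <- g[o, , drop = FALSE]
    covered <- IRanges::IRanges()
    out <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      r <- IRanges::IRanges(start = g$start[i] + 1L, end = g$end[i])
      free <- IRanges::setdiff(r, covered)
      if (length(free) > 0L) {
        out[[i]] <- data.frame(read_id = g$read_id[i],
                               start = IRanges::start(free) - 1L,
                               end = IRanges::end(free),
                               label = g$label[i], category = g$category[i],
                               stringsAsFactors = FALSE)
        covered <- IRanges::union(covered, free)
      }
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$read_id, out$start), , drop = FALSE]
}

#' Summarize disjoint annotations into a repeat landscape
#'
#' Per-label masked bp, percent of the dataset, and genome Gb
#' (`percent/100 * genome_size_gb`), plus per-category totals, the
#' nonrepetitive remainder, and the sequencing coverage
#' `100 * dataset_bp / (genome_size_gb * 1e9)`.
#'
#' @param ann disjoint annotations (run [resolve_overlaps()] first).
#' @param genome_size_gb haploid genome size in Gb.
#' @param dataset_bp total bp of the shotgun dataset the annotations cover.
#' @return object of class `landscape_summary`: list with `labels`
#'   (data.frame `label`, `category`, `bp`, `percent`, `gb`), `categories`
#'   (incl. `nonrepetitive`), `dataset_bp`, `genome_size_gb`, `coverage_pct`.
#' @export
summarize_landscape <- function(ann, genome_size_gb, dataset_bp) {
  if (!is.numeric(dataset_bp) || dataset_bp <= 0) stop("dataset_bp must be > 0")
  validate_annotations(ann)
  width <- ann$end - ann$start
  if (sum(width) > dataset_bp) {
    stop("annotated bp exceed dataset_bp; annotations unresolved or dataset_bp wrong")
  }
  if (nrow(ann) == 0L) {
    labels <- data.frame(label = character(0), category = character(0),
                         bp = numeric(0), stringsAsFactors = FALSE)
  } else {
    bp <- tapply(width, ann$label, sum)
    cat_of <- tapply(ann$category, ann$label, function(x) x[1L])
    labels <- data.frame(label = names(bp),
                         category = as.character(cat_of[names(bp)]),
                         bp = as.numeric(bp), stringsAsFactors = FALSE)
  }
  labels$percent <- 100 * labels$bp / dataset_bp
  labels$gb <- labels$percent / 100 * genome_size_gb
  labels <- labels[order(-labels$bp, labels$label), , drop = FALSE]
  rownames(labels) <- NULL
  cat_bp <- vapply(CATEGORY_LEVELS,
                   function(k) sum(labels$bp[labels$category == k]), numeric(1))
  cat_bp <- c(cat_bp, nonrepetitive = dataset_bp - sum(labels$bp))
  categories <- data.frame(category = names(cat_bp), bp = as.numeric(cat_bp),
                           percent = 100 * as.numeric(cat_bp) / dataset_bp,
                           gb = as.numeric(cat_bp) / dataset_bp * genome_size_gb,
                           stringsAsFactors = FALSE)
  structure(list(labels = labels, categories = categories,
                 dataset_bp = dataset_bp, genome_size_gb = genome_size_gb,
                 coverage_pct = 100 * dataset_bp / (genome_size_gb * 1e9)),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("<landscape_summary> %s bp dataset, %.4g Gb genome (%.2f%% coverage)\n",
              format(x$dataset_bp, big.mark = ","), x$genome_size_gb,
              x$coverage_pct))
  print(utils::head(x$labels, 10L))
  invisible(x)
}

#' Rank TE superfamilies by abundance
#'
#' @param summary a [summarize_landscape()] result.
#' @param k number of labels to return (default all).
#' @return character vector of `known_TE` labels, bp-descending, ties
#'   lexicographic.
#' @export
rank_superfamilies <- function(summary, k = Inf) {
  te <- summary$labels[summary$labels$category == "known_TE", , drop = FALSE]
  te <- te[order(-te$bp, te$label), , drop = FALSE]
  utils::head(te$label, k)
}

#' Write a landscape summary as TSV
#'
#' @param summary a [summarize_landscape()] result.
#' @param path output path.
#' @export
write_landscape <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset_bp\t%s", format(summary$dataset_bp, scientific = FALSE)), con)
  writeLines(sprintf("# genome_size_gb\t%g", summary$genome_size_gb), con)
  writeLines(sprintf("# coverage_pct\t%.6g", summary$coverage_pct), con)
  utils::write.table(summary$labels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
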