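#' Extract observed substitutions from a copy-vs-consensus alignment
#'
#' One substitution per column where both rows carry a base in `{A,C,G,T}`
#' and the bases differ. Gap and `N` columns never yield substitutions.
#'
#' @param aln a [pairwise_alignment()].
#' @return data.frame with columns `copy_id`, `consensus_pos` (1-based on
#'   the consensus), `ancestral_base`, `derived_base`.
#' @export
extract_substitutions <- function(aln) {
  cols <- aln_columns(aln)
  pos <- aln_consensus_positions(aln, cols)
  hit <- cols$cons %in% ALN_BASES & cols$copy %in% ALN_BASES & cols$cons != cols$copy
  data.frame(copy_id = rep(aln$copy_id, sum(hit)),
             consensus_pos = pos[hit],
             ancestral_base = cols$cons[hit],
             derived_base = cols$copy[hit],
             stringsAsFactors = FALSE)
}

# substitution key used for the shared-substitution (master-lineage) logic
sub_key <- function(consensus_pos, derived_base) {
  paste0(consensus_pos, ":", derived_base)
}

copy_sub_keys <- function(family) {
  keys <- lapply(family$alignments, function(a) {
    s <- extract_substitutions(a)
    unique(sub_key(s$consensus_pos, s$derived_base))
  })
  names(keys) <- vapply(family$alignments, `[[`, character(1), "copy_id")
  keys
}

#' Detect substitutions inherited from active master-element lineages
#'
#' Copies of a family generated by several sequentially active master
#' elements share the substitutions that accumulated on the master lineage
#' before their insertion; counting those inflates divergence. The rule:
#' for every pair of copies, collect the substitution keys
#' `(consensus_pos, derived_base)` present in both; whenever a group of
#' `min_copies` copies shares at least `min_shared_subs` keys, that whole
#' shared set is flagged. The result is the union over all groups.
#'
#' The pairwise default (`min_copies = 2`) mirrors the published rule and
#' is the most exclusion-prone reading; it is appropriate for small copy
#' sets. For large families, identical private substitutions are shared by
#' chance with probability that grows with copy number
#' (`1 - exp(-(n-1) p/3)` per key), so raising `min_copies` (e.g. to ~5% of
#' the copy number) keeps master events flagged while making chance
#' flagging negligible; see the methods vignette.
#'
#' @param family a [repeat_family()] with member alignments.
#' @param min_shared_subs minimum number of jointly shared substitutions for
#'   a group to be flagged (default 2).
#' @param min_copies group size over which sharing is assessed (default 2,
#'   i.e. pairwise).
#' @return character vector of flagged keys `"<pos>:<base>"` (possibly empty).
#' @export
detect_master_substitutions <- function(family, min_shared_subs = 2L,
                                        min_copies = 2L) {
  stopifnot(min_shared_subs >= 1L, min_copies >= 2L)
  keys <- copy_sub_keys(family)
  n <- length(keys)
  if (n < min_copies) return(character(0))
  # only keys present in >= min_copies copies can ever be flagged
  tab <- table(unlist(keys, use.names = FALSE))
  cand <- names(tab)[tab >= min_copies]
  if (length(cand) == 0L) return(character(0))
  keys_c <- lapply(keys, intersect, cand)
  if (min_shared_subs == 1L) {
    # every candidate key is, alone, a shared set of size >= 1
    return(sort(cand))
  }
  if (min_copies == 2L) {
    # literal pairwise enumeration
    nonempty <- which(lengths(keys_c) > 0L)
    if (length(nonempty) < 2L) return(character(0))
    flagged <- character(0)
    combs <- utils::combn(nonempty, 2L)
    for (j in seq_len(ncol(combs))) {
      shared <- intersect(keys_c[[combs[1L, j]]], keys_c[[combs[2L, j]]])
      if (length(shared) >= min_shared_subs) flagged <- union(flagged, shared)
    }
    return(sort(flagged))
  }
  if (min_shared_subs == 2L) {
    # a group of m copies with >= 2 jointly shared keys exists iff some key
    # PAIR has common support >= m; count key-pair co-occurrence per copy
    pair_ids <- unlist(lapply(keys_c, function(k) {
      if (length(k) < 2L) return(character(0))
      k <- sort(k)
      cb <- utils::combn(k, 2L)
      paste(cb[1L, ], cb[2L, ], sep = "\r")
    }), use.names = FALSE)
    if (length(pair_ids) == 0L) return(character(0))
    pt <- table(pair_ids)
    hot <- names(pt)[pt >= min_copies]
    if (length(hot) == 0L) return(character(0))
    return(sort(unique(unlist(strsplit(hot, "\r", fixed = TRUE)))))
  }
  # general (rarely used) path: enumerate copy groups among candidates
  nonempty <- which(lengths(keys_c) >= min_shared_subs)
  if (length(nonempty) < min_copies) return(character(0))
  if (choose(length(nonempty), min_copies) > 2e5) {
    stop("detect_master_substitutions: group enumeration too large for ",
         "min_copies = ", min_copies, ", min_shared_subs = ", min_shared_subs)
  }
  flagged <- character(0)
  combs <- utils::combn(nonempty, min_copies)
  for (j in seq_len(ncol(combs))) {
    shared <- Reduce(intersect, keys_c[combs[, j]])
    if (length(shared) >= min_shared_subs) flagged <- union(flagged, shared)
  }
  sort(flagged)
}

#' Group-size threshold scaled to family size
#'
#' Convenience for [detect_master_substitutions()] on large families: the
#' pairwise default over-excludes once chance key sharing
#' (`1 - exp(-(n-1) p/3)` per key) becomes common, so the group size is
#' scaled to `frac` of the copy number (at least 2).
#'
#' @param family a [repeat_family()].
#' @param frac fraction of copies a group must reach (default 0.05).
#' @return integer `min_copies`.
#' @export
scaled_min_copies <- function(family, frac = 0.05) {
  max(2L, as.integer(ceiling(frac * length(family$alignments))))
}

#' Jukes-Cantor distance
#'
#' Corrects an observed mismatch proportion `p` for multiple hits under the
#' one-parameter substitution model: `d = -(3/4) * log(1 - 4p/3)`, in
#' expected substitutions per site.
#'
#' @param p observed proportion(s) of mismatching sites, `0 <= p < 0.75`.
#' @return corrected distance(s) `d >= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p >= 0.75, na.rm = TRUE)) {
    stop("jukes_cantor: p must lie in [0, 0.75); the model saturates at 0.75")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Per-copy raw and refined divergence from consensus
#'
#' For each copy: `aligned_sites` counts columns with an `{A,C,G,T}` base in
#' both rows; `p_raw` is the observed mismatch proportion; `p_refined`
#' removes substitutions whose key is in `flagged` (master-lineage
#' exclusion); both are Jukes-Cantor corrected to `d_raw`, `d_refined`.
#' Copies with no aligned sites are skipped (count reported via `message`);
#' copies at or beyond JC saturation (`p >= 0.75`) get `NA` distances.
#'
#' @param family a [repeat_family()].
#' @param flagged keys from [detect_master_substitutions()] on this family
#'   (default: computed here).
#' @return data.frame, one row per retained copy, columns `copy_id`,
#'   `family_id`, `copy_len_bp`, `aligned_sites`, `raw_sub_count`,
#'   `excluded_sub_count`, `p_raw`, `p_refined`, `d_raw`, `d_refined`.
#' @export
divergence_records <- function(family, flagged = detect_master_substitutions(family)) {
  rows <- lapply(family$alignments, function(a) {
    cols <- aln_columns(a)
    aligned <- sum(cols$cons %in% ALN_BASES & cols$copy %in% ALN_BASES)
    s <- extract_substitutions(a)
    nraw <- nrow(s)
    nexcl <- sum(sub_key(s$consensus_pos, s$derived_base) %in% flagged)
    data.frame(copy_id = a$copy_id, family_id = a$family_id,
               copy_len_bp = sum(cols$copy != "-"),
               aligned_sites = aligned, raw_sub_count = nraw,
               excluded_sub_count = nexcl, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  skipped <- sum(rec$aligned_sites == 0L)
  if (skipped > 0L) {
    message("divergence_records: skipped ", skipped, " cop(ies) with no aligned sites")
    rec <- rec[rec$aligned_sites > 0L, , drop = FALSE]
  }
  rec$p_raw <- rec$raw_sub_count / rec$aligned_sites
  rec$p_refined <- (rec$raw_sub_count - rec$excluded_sub_count) / rec$aligned_sites
  jc_safe <- function(p) ifelse(p < 0.75, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.xmin)), NA_real_)
  rec$d_raw <- jc_safe(rec$p_raw)
  rec$d_refined <- jc_safe(rec$p_refined)
  rownames(rec) <- NULL
  rec
}

#' Filter copies by length and identity
#'
#' Keeps copies strictly longer than `min_len_bp` and at least
#' `min_identity` identical to the consensus; identity is `1 - p_raw`
#' (pre-refinement, matching masking-tool identity).
#'
#' @param records output of [divergence_records()].
#' @param min_len_bp length threshold, strict `>` (default 100).
#' @param min_identity identity threshold, `>=` (default 0.80).
#' @return the retained rows.
#' @export
filter_copies <- function(records, min_len_bp = 100L, min_identity = 0.80) {
  keep <- records$copy_len_bp > min_len_bp & (1 - records$p_raw) >= min_identity
  records[keep, , drop = FALSE]
}

#' Bin copy divergences into an age histogram
#'
#' Each copy contributes its weight (its length in bp, or 1 read) to the
#' half-open bin `[k*w, (k+1)*w)` containing `100 * d_refined`; bin values
#' are percent of `total_data`.
#'
#' @param records filtered [divergence_records()] rows.
#' @param bin_width_pct bin width in percent divergence (default 1).
#' @param weighting `"bp"` (copy length) or `"read_count"` (1 per copy).
#' @param total_data denominator in the weighting unit (total dataset bp or
#'   total read count); defaults to the summed weight of `records`, in which
#'   case the histogram integrates to 100.
#' @param max_pct upper edge of the histogram range (default 20; the 80%
#'   identity filter bounds divergence well below JC(0.20)).
#' @return object of class `age_histogram`: data.frame `bin_low`, `bin_high`,
#'   `percent`, with attributes `weighting` and `total_data`.
#' @export
age_histogram <- function(records, bin_width_pct = 1.0,
                          weighting = c("bp", "read_count"),
                          total_data = NULL, max_pct = 20) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "bp") records$copy_len_bp else rep(1, nrow(records))
  if (is.null(total_data)) total_data <- sum(w)
  if (!is.numeric(total_data) || total_data <= 0) stop("total_data must be > 0")
  edges <- seq(0, max_pct, by = bin_width_pct)
  if (edges[length(edges)] < max_pct) edges <- c(edges, max_pct)
  d_pct <- 100 * records$d_refined
  bin <- findInterval(d_pct, edges, rightmost.closed = FALSE, left.open = FALSE)
  ok <- !is.na(d_pct) & bin >= 1L & bin < length(edges)
  vals <- vapply(seq_len(length(edges) - 1L),
                 function(k) sum(w[ok & bin == k]), numeric(1))
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                    percent = 100 * vals / total_data)
  structure(out, class = c("age_histogram", "data.frame"),
            weighting = weighting, total_data = total_data,
            bin_width = bin_width_pct)
}

#' Count modes of an age histogram
#'
#' Merges runs of adjacent equal-valued bins, then counts strict local
#' maxima among bins with positive mass.
#'
#' @param hist an [age_histogram()].
#' @return integer number of local maxima.
#' @export
histogram_modes <- function(hist) {
  v <- rle(hist$percent)$values           # merge adjacent equal bins
  n <- length(v)
  if (n == 0L) return(0L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1L], -Inf)
  sum(v > left & v > right & v > 0)
}

#' @export
plot.age_histogram <- function(x, ...) {
  graphics::barplot(x$percent, names.arg = sprintf("%g", x$bin_low),
                    xlab = "sequence divergence from consensus (%)",
                    ylab = paste0("% of total data (", attr(x, "weighting"), ")"),
                    space = 0, ...)
  invisible(x)
}

#' Write an age histogram as TSV
#'
#' @param hist an [age_histogram()].
#' @param path output path.
#' @export
write_age_histogram <- function(hist, path) {
  utils::write.table(as.data.frame(hist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
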