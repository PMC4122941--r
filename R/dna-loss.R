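#' Family-level consensus acceptance for DNA loss analysis
#'
#' A consensus is accepted iff it is strictly longer than
#' `min_consensus_len` bp and is supported by at least `min_copies`
#' qualifying copies, a qualifying copy being strictly longer than
#' `min_copy_len` bp and at least `min_identity` identical to the consensus.
#'
#' @param family a [repeat_family()].
#' @param min_consensus_len consensus length threshold, strict `>` (default 330).
#' @param min_copies minimum number of qualifying copies (default 5).
#' @param min_copy_len qualifying copy length threshold, strict `>` (default 300).
#' @param min_identity qualifying copy identity threshold, `>=` (default 0.80).
#' @return list with `family_id`, `consensus_len`, `n_qualifying_copies`,
#'   `accepted`.
#' @export
accept_consensus <- function(family, min_consensus_len = 330L, min_copies = 5L,
                             min_copy_len = 300L, min_identity = 0.80) {
  rec <- divergence_records(family, flagged = character(0))
  qual <- rec$copy_len_bp > min_copy_len & (1 - rec$p_raw) >= min_identity
  nq <- sum(qual)
  clen <- nchar(family$consensus)
  list(family_id = family$family_id, consensus_len = clen,
       n_qualifying_copies = nq,
       accepted = clen > min_consensus_len && nq >= min_copies)
}

#' Pooled codon-position substitution counts for a family
#'
#' Substitutions from all member copies are pooled and assigned to codon
#' positions 1..3 by `((consensus_pos - 1 - offset) mod 3) + 1`, with the
#' consensus assumed trimmed to a protein-coding region. Substitutions
#' upstream of the frame start (`consensus_pos <= offset`) are excluded.
#'
#' @param family a [repeat_family()].
#' @param orf_frame_offset reading-frame offset 0, 1 or 2 relative to
#'   consensus coordinate 1.
#' @return integer vector `c(n1, n2, n3)`.
#' @export
codon_substitution_counts <- function(family, orf_frame_offset = 0L) {
  stopifnot(orf_frame_offset %in% 0:2)
  subs <- do.call(rbind, lapply(family$alignments, extract_substitutions))
  if (is.null(subs) || nrow(subs) == 0L) return(c(0L, 0L, 0L))
  pos <- subs$consensus_pos[subs$consensus_pos > orf_frame_offset]
  codon <- ((pos - 1L - orf_frame_offset) %% 3L) + 1L
  as.integer(tabulate(codon, nbins = 3L))
}

#' Chi-square test of codon-position uniformity
#'
#' Tests observed counts against the uniform expectation `n/3` per position
#' (2 degrees of freedom). Families with substitutions distributed
#' non-uniformly across codon positions (`p < alpha`) show selection-era
#' (master-lineage) substitution signal and are excluded from neutral-decay
#' indel accounting. With zero substitutions the test is not applicable and
#' the family is retained, flagged via `applicable = FALSE`.
#'
#' @param counts integer vector `c(n1, n2, n3)`.
#' @param alpha significance level (default 0.05).
#' @return list with `counts`, `chi2_stat`, `p_value`, `excluded`, `applicable`.
#' @export
chi_square_uniform <- function(counts, alpha = 0.05) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) {
    return(list(counts = counts, chi2_stat = NA_real_, p_value = NA_real_,
                excluded = FALSE, applicable = FALSE))
  }
  e <- n / 3
  stat <- sum((counts - e)^2 / e)
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(counts = counts, chi2_stat = stat, p_value = p,
       excluded = p < alpha, applicable = TRUE)
}

#' Call small indel events from an alignment
#'
#' Each maximal run of `-` in the copy row is one deletion (of the spanned
#' consensus bases); each maximal run of `-` in the consensus row is one
#' insertion (of the spanned copy bases). Events longer than `max_indel_bp`
#' are discarded (count attached as attribute `"capped"`). `consensus_pos`
#' is the consensus coordinate of the column preceding the event.
#'
#' @param aln a [pairwise_alignment()].
#' @param max_indel_bp small-indel cap, inclusive (default 30).
#' @return data.frame `copy_id`, `kind` (insertion/deletion), `consensus_pos`,
#'   `length_bp`, `seq`, `in_homopolymer` (NA until flagged); attribute
#'   `capped` counts discarded oversize events.
#' @export
count_indels <- function(aln, max_indel_bp = 30L) {
  cols <- aln_columns(aln)
  pos <- aln_consensus_positions(aln, cols)
  ev <- function(gaprow, seqrow, kind) {
    r <- rle(gaprow == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values)
    if (length(i) == 0L) return(NULL)
    data.frame(copy_id = aln$copy_id, kind = kind,
               consensus_pos = ifelse(starts[i] == 1L, aln$consensus_start - 1L,
                                      pos[starts[i] - 1L]),
               length_bp = r$lengths[i],
               seq = vapply(i, function(k) paste(seqrow[starts[k]:ends[k]],
                                                 collapse = ""), character(1)),
               stringsAsFactors = FALSE)
  }
  events <- rbind(ev(cols$copy, cols$cons, "deletion"),
                  ev(cols$cons, cols$copy, "insertion"))
  if (is.null(events)) {
    events <- data.frame(copy_id = character(0), kind = character(0),
                         consensus_pos = integer(0), length_bp = integer(0),
                         seq = character(0), stringsAsFactors = FALSE)
  }
  capped <- sum(events$length_bp > max_indel_bp)
  events <- events[events$length_bp <= max_indel_bp, , drop = FALSE]
  events$in_homopolymer <- rep(NA, nrow(events))
  rownames(events) <- NULL
  attr(events, "capped") <- capped
  events
}

#' Flag indels inside long homopolymer stretches
#'
#' Pyrosequencing miscalls homopolymer lengths, producing spurious 1-bp
#' indels. An event is flagged iff its indel sequence is a single repeated
#' base and the run formed by the event bases plus adjacent same-base
#' consensus neighbours reaches `min_run`. Flagged events are excluded from
#' all tallies downstream.
#'
#' @param aln the [pairwise_alignment()] the events came from.
#' @param events output of [count_indels()] on `aln`.
#' @param min_run minimum homopolymer run length to flag (default 5).
#' @return `events` with `in_homopolymer` set.
#' @export
flag_homopolymer_indels <- function(aln, events, min_run = 5L) {
  if (nrow(events) == 0L) return(events)
  cons <- strsplit(gsub("-", "", aln$gapped_consensus, fixed = TRUE), "",
                   fixed = TRUE)[[1L]]
  run_at <- function(base, left_local, right_local) {
    # extend over consensus neighbours equal to `base`
    ext <- 0L
    i <- left_local
    while (i >= 1L && i <= length(cons) && cons[i] == base) { ext <- ext + 1L; i <- i - 1L }
    j <- right_local
    while (j >= 1L && j <= length(cons) && cons[j] == base) { ext <- ext + 1L; j <- j + 1L }
    ext
  }
  flags <- logical(nrow(events))
  for (k in seq_len(nrow(events))) {
    s <- strsplit(events$seq[k], "", fixed = TRUE)[[1L]]
    if (length(unique(s)) != 1L || !(s[1L] %in% ALN_BASES)) next
    base <- s[1L]
    p_local <- events$consensus_pos[k] - aln$consensus_start + 1L
    if (events$kind[k] == "deletion") {
      left <- p_local; right <- p_local + events$length_bp[k] + 1L
    } else {
      left <- p_local; right <- p_local + 1L
    }
    flags[k] <- events$length_bp[k] + run_at(base, left, right) >= min_run
  }
  events$in_homopolymer <- flags
  events
}

#' Pick a reading frame for a consensus sequence
#'
#' Returns the offset (0, 1 or 2) whose translation contains the longest
#' stop-codon-free stretch; a pragmatic stand-in when the true ORF is
#' unknown.
#'
#' @param consensus ungapped consensus sequence.
#' @return integer offset in `0:2`.
#' @export
pick_orf_frame <- function(consensus) {
  s <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  stops <- c("TAA", "TAG", "TGA")
  best_off <- 0L; best_run <- -1L
  for (off in 0:2) {
    starts <- seq(1L + off, length(s) - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- vapply(starts, function(i) paste(s[i:(i + 2L)], collapse = ""),
                     character(1))
    r <- rle(!codons %in% stops)
    run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (run > best_run) { best_run <- run; best_off <- off }
  }
  best_off
}

#' Assemble a loss-rate result from pooled tallies
#'
#' Pure arithmetic over pooled indel/substitution tallies, factored out of
#' [loss_rate()] so the derived statistics (loss rate `(bp deleted - bp
#' inserted)/substitutions`, mean event sizes, deletion:insertion event
#' ratio) can be computed and checked independently of alignment parsing.
#'
#' @param n_insertions,n_deletions event counts.
#' @param bp_inserted,bp_deleted total bp in events.
#' @param n_substitutions_jc Jukes-Cantor-corrected substitution total.
#' @param n_copies number of copies pooled.
#' @return object of class `loss_rate_result`.
#' @export
loss_rate_result <- function(n_insertions, n_deletions, bp_inserted, bp_deleted,
                             n_substitutions_jc, n_copies = NA_integer_) {
  structure(list(
    n_insertions = n_insertions, n_deletions = n_deletions,
    bp_inserted = bp_inserted, bp_deleted = bp_deleted,
    n_substitutions_jc = n_substitutions_jc, n_copies = n_copies,
    loss_rate = if (n_substitutions_jc > 0)
      (bp_deleted - bp_inserted) / n_substitutions_jc
    else if (bp_deleted == 0 && bp_inserted == 0) 0 else NA_real_,
    mean_del_size = if (n_deletions > 0) bp_deleted / n_deletions else NA_real_,
    mean_ins_size = if (n_insertions > 0) bp_inserted / n_insertions else NA_real_,
    del_ins_ratio = if (n_insertions > 0) n_deletions / n_insertions else NA_real_),
    class = "loss_rate_result")
}

#' @export
print.loss_rate_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<loss_rate_result> %s copies: %d deletions (%d bp), %d insertions (%d bp),\n",
    "  %.1f JC substitutions; loss rate %.4f bp/substitution,\n",
    "  mean del %.2f bp, mean ins %.2f bp, del:ins %.2f\n"),
    format(x$n_copies), x$n_deletions, x$bp_deleted, x$n_insertions,
    x$bp_inserted, x$n_substitutions_jc, x$loss_rate,
    x$mean_del_size, x$mean_ins_size, x$del_ins_ratio))
  invisible(x)
}

#' Genome-wide DNA loss rate through small indels
#'
#' For each family (assumed to have passed [accept_consensus()]), pooled
#' codon-position substitution counts are chi-square tested against
#' uniformity; families with non-uniform counts (`p < alpha`) are excluded
#' as carrying master-lineage substitution signal. Over all copies of the
#' retained families, small indel events are counted ([count_indels()] with
#' `indel_cap`), homopolymer-artifact events removed
#' ([flag_homopolymer_indels()] with `min_run`), and the substitution total
#' accumulated as `aligned_sites * jukes_cantor(p_copy)` per copy (JC is
#' nonlinear, so correction is applied per copy, then summed). The loss rate
#' is `(bp deleted - bp inserted) / substitutions`.
#'
#' @param families list of [repeat_family()] objects.
#' @param alpha chi-square significance level (default 0.05).
#' @param min_run homopolymer flag threshold (default 5).
#' @param indel_cap small-indel cap in bp, inclusive (default 30).
#' @param orf_frame_offset frame offset per family: a single value recycled,
#'   or `NULL` to pick per family via [pick_orf_frame()] (default 0).
#' @param per_copy_chisq apply the chi-square filter per copy instead of per
#'   family (default FALSE).
#' @return a `loss_rate_result`, with attributes `codon_tests` (one row per
#'   family) and `n_saturated` (copies skipped at JC saturation).
#' @export
loss_rate <- function(families, alpha = 0.05, min_run = 5L, indel_cap = 30L,
                      orf_frame_offset = 0L, per_copy_chisq = FALSE) {
  if (is.null(orf_frame_offset)) {
    offs <- vapply(families, function(f) pick_orf_frame(f$consensus), integer(1))
  } else {
    offs <- rep_len(as.integer(orf_frame_offset), length(families))
  }
  tests <- lapply(seq_along(families), function(i) {
    tr <- chi_square_uniform(codon_substitution_counts(families[[i]], offs[i]),
                             alpha = alpha)
    data.frame(family_id = families[[i]]$family_id,
               n1 = tr$counts[1], n2 = tr$counts[2], n3 = tr$counts[3],
               chi2_stat = tr$chi2_stat, p_value = tr$p_value,
               excluded = tr$excluded, applicable = tr$applicable,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  retained <- families[!tests$excluded]
  n_ins <- 0L; n_del <- 0L; bp_ins <- 0L; bp_del <- 0L
  subs_jc <- 0; n_copies <- 0L; n_sat <- 0L
  for (fam in retained) {
    for (a in fam$alignments) {
      if (per_copy_chisq) {
        one <- repeat_family(fam$family_id, fam$consensus, list(a),
                             superfamily = fam$superfamily)
        tr <- chi_square_uniform(
          codon_substitution_counts(one, offs[match(fam$family_id, tests$family_id)]),
          alpha = alpha)
        if (isTRUE(tr$excluded)) next
      }
      cols <- aln_columns(a)
      aligned <- sum(cols$cons %in% ALN_BASES & cols$copy %in% ALN_BASES)
      if (aligned == 0L) next
      p <- sum(cols$cons %in% ALN_BASES & cols$copy %in% ALN_BASES &
                 cols$cons != cols$copy) / aligned
      if (p >= 0.75) { n_sat <- n_sat + 1L; next }
      ev <- count_indels(a, max_indel_bp = indel_cap)
      ev <- flag_homopolymer_indels(a, ev, min_run = min_run)
      ev <- ev[!ev$in_homopolymer | is.na(ev$in_homopolymer), , drop = FALSE]
      ins <- ev$kind == "insertion"
      n_ins <- n_ins + sum(ins); n_del <- n_del + sum(!ins)
      bp_ins <- bp_ins + sum(ev$length_bp[ins])
      bp_del <- bp_del + sum(ev$length_bp[!ins])
      subs_jc <- subs_jc + aligned * jukes_cantor(p)
      n_copies <- n_copies + 1L
    }
  }
  out <- loss_rate_result(n_ins, n_del, bp_ins, bp_del, subs_jc, n_copies)
  attr(out, "codon_tests") <- tests
  attr(out, "n_saturated") <- n_sat
  out
}
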