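# shared toy-data builders and independent oracles

aln <- function(copy, cons, id = "c1", fam = "famA", start = 1L, ...) {
  pairwise_alignment(id, fam, copy, cons, consensus_start = start, ...)
}

# family from an ungapped consensus and a named list of gapped copy rows;
# each copy row must align column-for-column against `cons_rows[[i]]`
# (default: the ungapped consensus itself)
toy_family <- function(consensus, copies, fam = "famA", cons_rows = NULL,
                       superfamily = "LTR/Gypsy") {
  alns <- lapply(seq_along(copies), function(i) {
    cr <- if (is.null(cons_rows)) consensus else cons_rows[[i]]
    pairwise_alignment(names(copies)[i], fam, copies[[i]], cr)
  })
  repeat_family(fam, consensus, alns, superfamily = superfamily)
}

# copy = consensus with substitutions at `at` replaced by `to`
mutate_copy <- function(consensus, at, to) {
  s <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  s[at] <- to
  paste(s, collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# random valid toy alignment: substitutions, N columns, small gaps
random_toy_alignment <- function(id = "c1", fam = "famA", len = 30L) {
  cons <- strsplit(random_seq(len), "", fixed = TRUE)[[1L]]
  copy <- cons
  nsub <- sample(0:5, 1L)
  if (nsub > 0) {
    at <- sample(len, nsub)
    copy[at] <- vapply(copy[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  if (stats::runif(1) < 0.3) copy[sample(len, 1L)] <- "N"
  if (stats::runif(1) < 0.4) {           # deletion
    p <- sample(len - 2L, 1L)
    copy[p:(p + sample(2L, 1L) - 1L)] <- "-"
  }
  if (stats::runif(1) < 0.4) {           # insertion
    j <- sample(len - 1L, 1L)
    copy <- append(copy, sample(c("A", "C", "G", "T"), 1L), after = j)
    cons <- append(cons, "-", after = j)
  }
  pairwise_alignment(id, fam, paste(copy, collapse = ""),
                     paste(cons, collapse = ""))
}

random_toy_family <- function(n_copies = 4L, len = 30L, fam = "famA") {
  alns <- lapply(seq_len(n_copies), function(i)
    random_toy_alignment(sprintf("c%02d", i), fam, len))
  f <- repeat_family(fam, random_seq(len), list())
  f$alignments <- alns   # consensus row differs per copy; fine for key logic
  f
}

# independent oracle for the shared-substitution rule: character-by-character
# key extraction, exhaustive loop over all copy pairs
brute_force_master <- function(family, min_shared = 2L) {
  keyset <- lapply(family$alignments, function(a) {
    cp <- strsplit(a$gapped_copy, "", fixed = TRUE)[[1L]]
    cs <- strsplit(a$gapped_consensus, "", fixed = TRUE)[[1L]]
    keys <- character(0)
    pos <- a$consensus_start - 1L
    for (j in seq_along(cs)) {
      if (cs[j] != "-") pos <- pos + 1L
      if (cs[j] %in% c("A", "C", "G", "T") && cp[j] %in% c("A", "C", "G", "T") &&
          cs[j] != cp[j]) {
        keys <- c(keys, paste0(pos, ":", cp[j]))
      }
    }
    unique(keys)
  })
  flagged <- character(0)
  n <- length(keyset)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shared <- intersect(keyset[[i]], keyset[[j]])
        if (length(shared) >= min_shared) flagged <- union(flagged, shared)
      }
    }
  }
  sort(flagged)
}

swap_rows <- function(a) {
  pairwise_alignment(a$copy_id, a$family_id, a$gapped_consensus, a$gapped_copy,
                     consensus_start = 1L)
}
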