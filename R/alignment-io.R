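ALN_BASES <- c("A", "C", "G", "T")

#' Construct a pairwise copy-vs-consensus alignment
#'
#' The unit record consumed by every estimator: one repeat element copy
#' aligned against its family consensus ("master gene") sequence, stored
#' gapped in consensus (+) orientation.
#'
#' @param copy_id identifier of the element copy.
#' @param family_id identifier of the repeat family the copy belongs to.
#' @param gapped_copy copy row of the alignment, string over `A,C,G,T,N,-`.
#' @param gapped_consensus consensus row, same alphabet, same length.
#' @param consensus_start,consensus_end 1-based inclusive span of the
#'   alignment on the ungapped consensus. `consensus_end` defaults to
#'   `consensus_start + <non-gap consensus characters> - 1`.
#' @param strand `"+"` or `"-"` (minus-strand hits are stored already
#'   reverse-complemented into consensus orientation).
#' @param source_read_id shotgun read the copy was observed on.
#'
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(copy_id, family_id, gapped_copy, gapped_consensus,
                               consensus_start = 1L, consensus_end = NULL,
                               strand = "+", source_read_id = copy_id) {
  gapped_copy <- toupper(gapped_copy)
  gapped_consensus <- toupper(gapped_consensus)
  if (nchar(gapped_copy) != nchar(gapped_consensus)) {
    stop("alignment rows for copy '", copy_id, "' have unequal lengths (",
         nchar(gapped_copy), " vs ", nchar(gapped_consensus), ")")
  }
  cc <- strsplit(gapped_copy, "", fixed = TRUE)[[1L]]
  kk <- strsplit(gapped_consensus, "", fixed = TRUE)[[1L]]
  bad <- !(cc %in% c(ALN_BASES, "N", "-")) | !(kk %in% c(ALN_BASES, "N", "-"))
  if (any(bad)) {
    stop("alignment for copy '", copy_id, "' contains characters outside {A,C,G,T,N,-}")
  }
  if (any(cc == "-" & kk == "-")) {
    stop("alignment for copy '", copy_id, "' has a column gapped in both rows")
  }
  ncons <- sum(kk != "-")
  consensus_start <- as.integer(consensus_start)
  if (is.null(consensus_end)) consensus_end <- consensus_start + ncons - 1L
  consensus_end <- as.integer(consensus_end)
  if (consensus_end - consensus_start + 1L != ncons) {
    stop("alignment for copy '", copy_id, "': consensus span [",
         consensus_start, ",", consensus_end,
         "] does not match ", ncons, " aligned consensus bases")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(copy_id = as.character(copy_id), family_id = as.character(family_id),
         gapped_copy = gapped_copy, gapped_consensus = gapped_consensus,
         consensus_start = consensus_start, consensus_end = consensus_end,
         strand = strand, source_read_id = as.character(source_read_id)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s [%d-%d] (%s), %d columns\n",
              x$copy_id, x$family_id, x$consensus_start, x$consensus_end,
              x$strand, nchar(x$gapped_copy)))
  invisible(x)
}

# split both rows into character vectors once; every estimator goes through this
aln_columns <- function(aln) {
  list(copy = strsplit(aln$gapped_copy, "", fixed = TRUE)[[1L]],
       cons = strsplit(aln$gapped_consensus, "", fixed = TRUE)[[1L]])
}

# per-column consensus coordinate (coordinate of the consensus base in the
# column; columns where the consensus is gapped carry the coordinate of the
# preceding consensus base, which is the convention used for insertion events)
aln_consensus_positions <- function(aln, cols = aln_columns(aln)) {
  aln$consensus_start - 1L + cumsum(cols$cons != "-")
}

#' Group a consensus with its member alignments into a repeat family
#'
#' @param family_id family identifier; every member alignment must carry it.
#' @param consensus ungapped consensus (master/ancestral) sequence.
#' @param alignments list of [pairwise_alignment()] objects.
#' @param superfamily superfamily label, e.g. `"LTR/Gypsy"`, `"LINE/L1"`,
#'   `"Unknown"`, `"Simple"`.
#' @param te_class one of `LTR`, `non-LTR`, `DNA`, `unknown`, `simple`;
#'   inferred from `superfamily` when missing.
#'
#' @return An object of class `repeat_family`.
#' @export
repeat_family <- function(family_id, consensus, alignments = list(),
                          superfamily = "Unknown", te_class = NULL) {
  consensus <- toupper(consensus)
  if (grepl("-", consensus, fixed = TRUE)) {
    stop("family '", family_id, "': consensus must be ungapped")
  }
  ok <- vapply(alignments, function(a) identical(a$family_id, as.character(family_id)),
               logical(1))
  if (!all(ok)) {
    stop("family '", family_id, "': member alignment(s) carry a different family_id")
  }
  if (is.null(te_class)) te_class <- classify_superfamily(superfamily)
  structure(
    list(family_id = as.character(family_id), consensus = consensus,
         superfamily = superfamily, te_class = te_class, alignments = alignments),
    class = "repeat_family")
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family> %s (%s, %s): consensus %d bp, %d copies\n",
              x$family_id, x$superfamily, x$te_class,
              nchar(x$consensus), length(x$alignments)))
  invisible(x)
}

#' Map a superfamily label to a coarse element class
#'
#' @param superfamily character vector of labels such as `"LTR/Gypsy"`.
#' @return character vector over `{LTR, non-LTR, DNA, unknown, simple}`.
#' @export
classify_superfamily <- function(superfamily) {
  top <- toupper(sub("/.*$", "", superfamily))
  out <- rep("unknown", length(superfamily))
  out[top %in% c("LTR", "ERV", "DIRS")] <- "LTR"
  out[top %in% c("LINE", "SINE", "PENELOPE", "NONLTR", "NON-LTR")] <- "non-LTR"
  out[top %in% c("DNA", "RC", "HELITRON", "MAVERICK")] <- "DNA"
  out[top %in% c("SIMPLE", "SIMPLE_REPEAT", "SATELLITE", "LOW_COMPLEXITY")] <- "simple"
  out
}

#' Read a FASTA file
#'
#' Sequences are uppercased and characters outside `{A,C,G,T,N}` are mapped
#' to `N`; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("FASTA file is empty: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA record in ", path, ": sequence before any header at line ",
         idx[1L])
  }
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- rep("", sum(is_hdr))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  empty <- which(!nzchar(out))
  if (length(empty)) {
    stop("malformed FASTA record in ", path, ": empty record '",
         ids[empty[1L]], "' at line ", idx[which(is_hdr)[empty[1L]]])
  }
  out <- toupper(out)
  out[] <- gsub("[^ACGTN]", "N", out)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read alignments in the canonical text format
#'
#' Records are separated by blank lines; each record is three lines:
#' `#aln <copy_id> <family_id> <consensus_start> <consensus_end> <strand>
#' <source_read_id>`, the gapped copy row, and the gapped consensus row.
#'
#' @param path path to a canonical alignment file.
#' @return list of [pairwise_alignment()] objects.
#' @export
read_canonical_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, "#aln"))
  if (length(hdr) == 0L) stop("no canonical alignment records in ", path)
  lapply(hdr, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) != 7L) {
      stop("malformed #aln header at line ", i, " of ", path)
    }
    if (i + 2L > length(lines)) stop("truncated record at line ", i, " of ", path)
    pairwise_alignment(copy_id = f[2L], family_id = f[3L],
                       gapped_copy = lines[i + 1L],
                       gapped_consensus = lines[i + 2L],
                       consensus_start = as.integer(f[4L]),
                       consensus_end = as.integer(f[5L]),
                       strand = f[6L], source_read_id = f[7L])
  })
}

#' Write alignments in the canonical text format
#'
#' Inverse of [read_canonical_alignments()]: write-then-read is the identity.
#'
#' @param alignments list of [pairwise_alignment()] objects.
#' @param path output path.
#' @export
write_canonical_alignments <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    writeLines(c(paste("#aln", a$copy_id, a$family_id, a$consensus_start,
                       a$consensus_end, a$strand, a$source_read_id),
                 a$gapped_copy, a$gapped_consensus, ""), con)
  }
  invisible(path)
}

#' Reverse-complement a (possibly gapped) sequence
#'
#' @param x character vector of sequences over `A,C,G,T,N,-`.
#' @return reverse-complemented sequences; gaps stay gaps.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN-", "TGCAN-",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse RepeatMasker-style `.align` output (best effort)
#'
#' Converts alignment blocks (score header, interleaved gapped read and
#' consensus lines) into [pairwise_alignment()] records. Complemented (`C`)
#' hits are reverse-complemented into + consensus orientation with ascending
#' coordinates. Blocks that cannot be parsed or that violate the alignment
#' invariants are skipped; the number skipped is reported via `message()` and
#' attached as attribute `"skipped"`.
#'
#' @param path path to a `.align`-style file.
#' @return list of [pairwise_alignment()] objects, attribute `skipped`.
#' @export
read_repeatmasker_align <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # score header: score, three divergence percentages, read id, coords ...
  hdr_re <- "^\\s*\\d+\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s+\\S+\\s+\\d+\\s+\\d+"
  hdr <- grep(hdr_re, lines)
  if (length(hdr) == 0L) stop("no RepeatMasker alignment blocks found in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  skipped <- 0L
  out <- list()
  for (b in seq_along(hdr)) {
    block <- lines[hdr[b]:(bounds[b + 1L] - 1L)]
    aln <- tryCatch(parse_rm_block(block), error = function(e) NULL)
    if (is.null(aln)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- aln
  }
  if (skipped > 0L) {
    message("read_repeatmasker_align: skipped ", skipped, " unparseable block(s)")
  }
  if (length(out) == 0L) stop("no parseable RepeatMasker alignment blocks in ", path)
  attr(out, "skipped") <- skipped
  out
}

parse_rm_block <- function(block) {
  hf <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
  read_id <- hf[5L]
  complemented <- length(hf) >= 9L && hf[9L] == "C"
  if (complemented) {
    cons_id <- hf[10L]
    cs <- as.integer(hf[13L]); ce <- as.integer(hf[12L])
  } else {
    cons_id <- hf[9L]
    cs <- as.integer(hf[10L]); ce <- as.integer(hf[11L])
  }
  m <- regmatches(block, regexec(
    "^\\s*(C\\s+)?(\\S+)\\s+(\\d+)\\s+([ACGTNacgtnXx-]+)\\s+(\\d+)\\s*$", block))
  seqs <- Filter(function(x) length(x) == 6L, m)
  if (length(seqs) < 2L) stop("no sequence lines")
  names_seen <- vapply(seqs, `[`, character(1), 3L)
  read_rows <- names_seen == read_id
  # consensus rows: everything that is not the read; RepeatMasker truncates
  # long names, so match by "not the read id" rather than by cons_id
  read_seq <- paste(vapply(seqs[read_rows], `[`, character(1), 5L), collapse = "")
  cons_seq <- paste(vapply(seqs[!read_rows], `[`, character(1), 5L), collapse = "")
  if (!nzchar(read_seq) || !nzchar(cons_seq)) stop("missing row")
  read_seq <- gsub("[^ACGTN-]", "N", toupper(read_seq))
  cons_seq <- gsub("[^ACGTN-]", "N", toupper(cons_seq))
  strand <- "+"
  if (complemented) {
    read_seq <- revcomp(read_seq)
    cons_seq <- revcomp(cons_seq)
    strand <- "-"
  }
  lo <- min(cs, ce); hi <- max(cs, ce)
  pairwise_alignment(copy_id = paste0(read_id, ":", hf[6L], "-", hf[7L]),
                     family_id = sub("#.*$", "", cons_id),
                     gapped_copy = read_seq, gapped_consensus = cons_seq,
                     consensus_start = lo, consensus_end = hi,
                     strand = strand, source_read_id = read_id)
}
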