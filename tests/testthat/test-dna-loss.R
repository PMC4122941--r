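test_that("accept_consensus applies the 330/5x300/80% rule with strict lengths", {
  set.seed(201)
  cons400 <- random_seq(400)
  # 6 copies, each 350 bp of the consensus with ~15% divergence
  copies <- lapply(1:6, function(i) {
    at <- sample(350, 52)
    sub <- substr(cons400, 1, 350)
    pairwise_alignment(paste0("c", i), "famA",
                       mutate_copy(sub, at, vapply(strsplit(sub, "")[[1]][at],
                         function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                         character(1))),
                       sub)
  })
  fam <- repeat_family("famA", cons400, copies, superfamily = "LINE/L1")
  acc <- accept_consensus(fam)
  expect_identical(acc$n_qualifying_copies, 6L)
  expect_true(acc$accepted)

  # consensus exactly 330 bp: rejected (strict '>')
  fam330 <- fam; fam330$consensus <- substr(cons400, 1, 330)
  expect_false(accept_consensus(fam330)$accepted)

  # only 4 qualifying copies: rejected
  fam4 <- repeat_family("famA", cons400, copies[1:4], superfamily = "LINE/L1")
  expect_false(accept_consensus(fam4)$accepted)

  # copy exactly 300 bp does not qualify (strict '>')
  copies300 <- lapply(copies, function(a) {
    pairwise_alignment(a$copy_id, "famA", substr(a$gapped_copy, 1, 300),
                       substr(a$gapped_consensus, 1, 300))
  })
  fam300 <- repeat_family("famA", cons400, copies300, superfamily = "LINE/L1")
  expect_identical(accept_consensus(fam300)$n_qualifying_copies, 0L)
})

test_that("codon_substitution_counts assigns positions mod 3 with offset", {
  cons <- paste(rep("ACGTAAGTC", 2), collapse = "")  # 18 bp
  f <- function(at, to) toy_family(cons, list(X = mutate_copy(cons, at, to)))
  expect_identical(codon_substitution_counts(f(1:3, c("C", "G", "T"))),
                   c(1L, 1L, 1L))
  expect_identical(codon_substitution_counts(f(c(3, 6, 9), c("T", "C", "A"))),
                   c(0L, 0L, 3L))
  expect_identical(codon_substitution_counts(toy_family(cons, list(X = cons))),
                   c(0L, 0L, 0L))
  # offset shifts the frame and drops upstream positions
  expect_identical(codon_substitution_counts(f(c(1, 2), c("C", "G")),
                                             orf_frame_offset = 1L),
                   c(1L, 0L, 0L))
})

test_that("chi_square_uniform matches hand-derived statistics", {
  r <- chi_square_uniform(c(10, 10, 10))
  expect_equal(r$chi2_stat, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$excluded)

  r <- chi_square_uniform(c(5, 5, 50))   # e = 20: (225 + 225 + 900)/20
  expect_equal(r$chi2_stat, 67.5)
  expect_true(r$excluded)

  r <- chi_square_uniform(c(0, 0, 1))    # e = 1/3: (1/9 + 1/9 + 4/9)/(1/3)
  expect_equal(r$chi2_stat, 2.0)
  expect_equal(r$p_value, exp(-1), tolerance = 1e-6)  # pchisq(2, 2) upper
  expect_false(r$excluded)

  r <- chi_square_uniform(c(0, 0, 0))
  expect_false(r$excluded)
  expect_false(r$applicable)
})

test_that("count_indels merges maximal gap runs and applies the 30 bp cap", {
  ev <- count_indels(aln("ACG--CGT", "ACGTACGT"))
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$length_bp, 2L)
  expect_identical(ev$seq, "TA")
  expect_identical(ev$consensus_pos, 3L)

  ev <- count_indels(aln("ACGTAACGT", "ACGT-ACGT"))
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$length_bp, 1L)
  expect_identical(ev$seq, "A")
  expect_identical(ev$consensus_pos, 4L)

  # a 31 bp gap run is discarded and logged; a 30 bp run is kept
  cons <- random_seq(80)
  gap31 <- mutate_copy(cons, 21:51, rep("-", 31))
  ev <- count_indels(aln(gap31, cons))
  expect_identical(nrow(ev), 0L)
  expect_identical(attr(ev, "capped"), 1L)
  gap30 <- mutate_copy(cons, 21:50, rep("-", 30))
  expect_identical(count_indels(aln(gap30, cons))$length_bp, 30L)
})

test_that("swapping alignment rows swaps indel tallies exactly", {
  set.seed(202)
  sims <- simulate_family(sim_scenario(master_len = 600, n_copies = 15,
                                       age_model = age_burst(0.05, 0.01)))
  for (a in sims$family$alignments) {
    e1 <- count_indels(a)
    e2 <- count_indels(swap_rows(a))
    expect_identical(sum(e1$kind == "deletion"), sum(e2$kind == "insertion"))
    expect_identical(sum(e1$kind == "insertion"), sum(e2$kind == "deletion"))
    expect_identical(sort(e1$length_bp[e1$kind == "deletion"]),
                     sort(e2$length_bp[e2$kind == "insertion"]))
  }
})

test_that("deletion bp are conserved against raw gap counts", {
  set.seed(203)
  for (i in 1:10) {
    a <- random_toy_alignment(len = 40L)
    ev <- count_indels(a, max_indel_bp = 10000L)
    gaps <- lengths(regmatches(a$gapped_copy, gregexpr("-+", a$gapped_copy)))
    expect_identical(sum(ev$length_bp[ev$kind == "deletion"]),
                     sum(nchar(unlist(regmatches(a$gapped_copy,
                                                 gregexpr("-+", a$gapped_copy))))))
  }
})

test_that("homopolymer flagging follows the run-length rule", {
  # inserted A adjacent to an AAAA consensus run: total run 5 -> flagged
  a <- aln("CGTAAAAACC", "CGT-AAAACC")
  ev <- flag_homopolymer_indels(a, count_indels(a))
  expect_true(ev$in_homopolymer)

  # multi-base indels are never mononucleotide
  b <- aln("CGT--AAACC", "CGTACAAACC")
  ev <- flag_homopolymer_indels(b, count_indels(b))
  expect_false(ev$in_homopolymer)

  # run of 3 stays below min_run = 5
  d <- aln("CGTAAACCGG", "CGT-AACCGG")
  ev <- flag_homopolymer_indels(d, count_indels(d))
  expect_false(ev$in_homopolymer)

  # deletion of one A inside a 5-run is flagged
  e <- aln("CG-AAAACCG", "CGAAAAACCG")
  ev <- flag_homopolymer_indels(e, count_indels(e))
  expect_true(ev$in_homopolymer)
})

test_that("pick_orf_frame prefers the longest stop-free frame", {
  stopless <- paste(rep("ACC", 30), collapse = "")
  expect_identical(pick_orf_frame(stopless), 0L)
  # frame 0 is all stop codons; frames 1 and 2 are stop-free and tie,
  # so the first best (1) wins
  expect_identical(pick_orf_frame(strrep("TAG", 20)), 1L)
})

test_that("loss_rate_result arithmetic matches the stated formulas", {
  r <- loss_rate_result(n_insertions = 10, n_deletions = 20,
                        bp_inserted = 40, bp_deleted = 120,
                        n_substitutions_jc = 1000)
  expect_equal(r$loss_rate, 0.08)
  expect_equal(r$mean_del_size, 6)
  expect_equal(r$mean_ins_size, 4)
  expect_equal(r$del_ins_ratio, 2)

  # no indels at all -> loss rate 0
  r0 <- loss_rate_result(0, 0, 0, 0, 500)
  expect_equal(r0$loss_rate, 0)
  expect_true(is.na(r0$del_ins_ratio))

  # zero substitutions with indels -> rate undefined (missing)
  expect_true(is.na(loss_rate_result(1, 1, 3, 5, 0)$loss_rate))
})

test_that("loss_rate pools per-copy JC-corrected substitutions over families", {
  set.seed(204)
  fams <- lapply(1:3, function(j)
    simulate_family(sim_scenario(master_len = 600, n_copies = 6,
                                 age_model = age_burst(0.04, 0.01),
                                 master_sub_count = 0),
                    family_id = paste0("f", j))$family)
  lr <- loss_rate(fams)
  expect_s3_class(lr, "loss_rate_result")
  tests <- attr(lr, "codon_tests")
  expect_identical(nrow(tests), 3L)
  expect_identical(lr$n_copies,
                   sum(vapply(fams[!tests$excluded],
                              function(f) length(f$alignments), integer(1))))
  # manual recomputation of the substitution denominator
  subs <- 0
  for (f in fams[!tests$excluded]) for (a in f$alignments) {
    cp <- strsplit(a$gapped_copy, "")[[1]]
    cs <- strsplit(a$gapped_consensus, "")[[1]]
    both <- cp %in% c("A","C","G","T") & cs %in% c("A","C","G","T")
    subs <- subs + sum(both) * jukes_cantor(sum(both & cp != cs) / sum(both))
  }
  expect_equal(lr$n_substitutions_jc, subs)
  expect_equal(lr$loss_rate, (lr$bp_deleted - lr$bp_inserted) / subs)
})

test_that("chi-square exclusion removes biased families from the pool", {
  set.seed(205)
  neutral <- simulate_family(sim_scenario(master_len = 900, n_copies = 4,
                                          age_model = age_burst(0.04, 0.005),
                                          master_sub_count = 0),
                             family_id = "neutral")$family
  biased <- simulate_family(sim_scenario(master_len = 900, n_copies = 4,
                                         age_model = age_burst(0.01, 0.002),
                                         master_sub_count = 200,
                                         neutral_sub_rate = 0.02,
                                         codon_bias = 8),
                            family_id = "biased")$family
  lr <- loss_rate(list(neutral, biased))
  tests <- attr(lr, "codon_tests")
  expect_false(tests$excluded[tests$family_id == "neutral"])
  expect_true(tests$excluded[tests$family_id == "biased"])
  expect_identical(lr$n_copies, 4L)
})
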