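serialize_family <- function(fam) {
  paste(vapply(fam$alignments, function(a)
    paste(a$copy_id, a$gapped_copy, a$gapped_consensus), character(1)),
    collapse = "\n")
}

test_that("all-zero rates yield copies identical to the master", {
  scen <- sim_scenario(master_len = 200, n_copies = 10,
                       age_model = age_burst(0.05, 0.01),
                       neutral_sub_rate = 0, master_sub_count = 0,
                       del_rate = 0, ins_rate = 0, seed = 1L)
  sim <- simulate_family(scen)
  for (a in sim$family$alignments) {
    expect_identical(a$gapped_copy, sim$family$consensus)
  }
  rec <- divergence_records(sim$family, character(0))
  expect_true(all(rec$d_raw == 0))
})

test_that("the same seed reproduces byte-identical output", {
  scen <- sim_scenario(master_len = 400, n_copies = 20, seed = 99L)
  s1 <- simulate_family(scen)
  s2 <- simulate_family(scen)
  expect_identical(serialize_family(s1$family), serialize_family(s2$family))
  expect_identical(s1$truth, s2$truth)
})

test_that("truth bookkeeping is exact: re-parsing recovers the observed keys", {
  set.seed(401)
  for (i in 1:5) {
    sim <- simulate_family(sim_scenario(master_len = 500, n_copies = 15,
                                        age_model = age_burst(0.04, 0.01),
                                        master_sub_count = 8))
    parsed <- do.call(rbind, lapply(sim$family$alignments, extract_substitutions))
    k1 <- sort(paste(parsed$copy_id, parsed$consensus_pos, parsed$derived_base))
    k2 <- sort(paste(sim$truth$observed$copy_id,
                     sim$truth$observed$consensus_pos,
                     sim$truth$observed$derived_base))
    expect_identical(k1, k2)
    # indel tallies match the truth record exactly
    ev <- do.call(rbind, lapply(sim$family$alignments,
                                count_indels, max_indel_bp = 10000L))
    expect_identical(sum(ev$kind == "deletion"), sim$truth$totals$n_deletions)
    expect_identical(sum(ev$kind == "insertion"), sim$truth$totals$n_insertions)
    expect_identical(sum(ev$length_bp[ev$kind == "deletion"]),
                     sim$truth$totals$bp_deleted)
    expect_identical(sum(ev$length_bp[ev$kind == "insertion"]),
                     sim$truth$totals$bp_inserted)
  }
})

test_that("copies inherit exactly the master substitutions older than them", {
  set.seed(402)
  sim <- simulate_family(sim_scenario(master_len = 800, n_copies = 30,
                                      age_model = age_burst(0.02, 0.01),
                                      master_sub_count = 15,
                                      del_rate = 0, ins_rate = 0))
  ev <- sim$truth$master_events
  for (i in seq_len(nrow(sim$truth$copies))) {
    cid <- sim$truth$copies$copy_id[i]
    age <- sim$truth$copies$true_age[i]
    inh <- sim$truth$inherited[sim$truth$inherited$copy_id == cid, ]
    older <- ev[ev$age > age, ]
    # every inherited position comes from an older master event, and every
    # older event position is inherited (possibly overwritten by a later
    # older event at the same position)
    expect_true(all(inh$consensus_pos %in% older$consensus_pos))
    surviving <- older[!duplicated(older$consensus_pos, fromLast = TRUE), ,
                       drop = FALSE]
    if (nrow(surviving) > 0) {
      cons_base <- substring(sim$family$consensus, surviving$consensus_pos,
                             surviving$consensus_pos)
      surviving <- surviving[surviving$to != cons_base, , drop = FALSE]
    }
    expect_setequal(paste(inh$consensus_pos, inh$derived_base),
                    paste(surviving$consensus_pos, surviving$to))
  }
})

test_that("master-lineage flagging finds simulated master events", {
  set.seed(403)
  sim <- simulate_family(sim_scenario(master_len = 1000, n_copies = 25,
                                      age_model = age_burst(0.01, 0.003),
                                      master_sub_count = 12))
  fl <- detect_master_substitutions(sim$family)
  expect_gt(length(fl), 0)
  inh_keys <- unique(paste0(sim$truth$inherited$consensus_pos, ":",
                            sim$truth$inherited$derived_base))
  expect_gt(length(intersect(fl, inh_keys)), 0)

  # without master events the scaled detector flags (almost) nothing
  sim0 <- simulate_family(sim_scenario(master_len = 1000, n_copies = 25,
                                       age_model = age_burst(0.01, 0.003),
                                       master_sub_count = 0))
  fl0 <- detect_master_substitutions(
    sim0$family, min_copies = scaled_min_copies(sim0$family, frac = 0.2))
  expect_identical(fl0, character(0))
})

test_that("mean copy divergence tracks the age-model mean", {
  set.seed(404)
  sim <- simulate_family(sim_scenario(master_len = 1500, n_copies = 300,
                                      age_model = age_burst(0.03, 0.005),
                                      master_sub_count = 0,
                                      del_rate = 0, ins_rate = 0))
  rec <- divergence_records(sim$family, character(0))
  se <- sd(rec$d_raw) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$d_raw) - 0.03), 4 * se)
})

test_that("neutral simulation gives uniform codon-position counts", {
  set.seed(405)
  counts <- c(0L, 0L, 0L)
  for (i in 1:30) {
    sim <- simulate_family(sim_scenario(master_len = 900, n_copies = 2,
                                        age_model = age_burst(0.03, 0.005),
                                        master_sub_count = 0,
                                        del_rate = 0, ins_rate = 0))
    counts <- counts + codon_substitution_counts(sim$family)
  }
  expect_gt(sum(counts), 1000)
  expect_gt(chi_square_uniform(counts)$p_value, 0.01)
})

test_that("scenario validation rejects impossible parameter combinations", {
  expect_error(sim_scenario(age_model = age_burst(2, 0.1)),
               "exceed sites")
  expect_error(sim_scenario(master_len = 100, master_sub_count = 200),
               "master length")
  expect_error(sim_scenario(del_size_p = 0), "del_size_p")
})

test_that("shredding conserves copies and their substitution sets", {
  set.seed(406)
  scen <- sim_scenario(master_len = 1200, n_copies = 6,
                       age_model = age_burst(0.05, 0.01),
                       read_len_mean = 300, read_len_sd = 50)
  sim <- simulate_family(scen)
  sh <- shred_to_reads(sim, scen)
  for (a in sim$family$alignments) {
    ids <- grep(paste0("^", a$copy_id, "_r"), names(sh$reads), value = TRUE)
    expect_identical(paste(sh$reads[ids], collapse = ""),
                     gsub("-", "", a$gapped_copy, fixed = TRUE))
  }
  # pooled fragment substitutions equal the parent copy substitutions
  frag_subs <- do.call(rbind, lapply(sh$alignments, extract_substitutions))
  frag_subs$parent <- sub("_r[0-9]+$", "", frag_subs$copy_id)
  parent_subs <- do.call(rbind, lapply(sim$family$alignments,
                                       extract_substitutions))
  expect_setequal(paste(frag_subs$parent, frag_subs$consensus_pos,
                        frag_subs$derived_base),
                  paste(parent_subs$copy_id, parent_subs$consensus_pos,
                        parent_subs$derived_base))
})

test_that("a read longer than its copy yields a single identical fragment", {
  set.seed(407)
  scen <- sim_scenario(master_len = 150, n_copies = 2,
                       age_model = age_burst(0.02, 0.005),
                       read_len_mean = 1000, read_len_sd = 1)
  sim <- simulate_family(scen)
  sh <- shred_to_reads(sim, scen)
  expect_identical(length(sh$reads), 2L)
  expect_identical(unname(sh$reads[1]),
                   gsub("-", "", sim$family$alignments[[1]]$gapped_copy))
})

test_that("the homopolymer error injector produces flaggable 1-bp indels", {
  set.seed(408)
  hits <- 0L
  for (i in 1:20) {
    sim <- simulate_family(sim_scenario(master_len = 800, n_copies = 4,
                                        age_model = age_burst(0.02, 0.005),
                                        master_sub_count = 0, del_rate = 0,
                                        ins_rate = 0,
                                        homopolymer_error_rate = 1))
    art <- sim$truth$indels[sim$truth$indels$artifact, , drop = FALSE]
    if (nrow(art) == 0) next
    for (a in sim$family$alignments) {
      ev <- flag_homopolymer_indels(a, count_indels(a))
      aa <- art[art$copy_id == a$copy_id, , drop = FALSE]
      if (nrow(aa) > 0 && nrow(ev) > 0) {
        hits <- hits + sum(ev$in_homopolymer)
        expect_true(all(ev$in_homopolymer[ev$consensus_pos %in% aa$consensus_pos]))
      }
    }
  }
  expect_gt(hits, 0)
})

test_that("preset catalog covers the three proliferation regimes", {
  ps <- preset_scenarios(n_copies = 50, seed = 5L)
  expect_setequal(names(ps), c("ongoing", "old_burst", "two_burst"))
  expect_identical(ps$ongoing$age_model$kind, "exponential")
  expect_identical(ps$old_burst$age_model$kind, "burst")
  expect_gt(ps$old_burst$age_model$mean, 0.01)
  expect_identical(ps$two_burst$age_model$kind, "two_burst")
})
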