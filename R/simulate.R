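#' Age models for the family simulator
#'
#' Copy insertion ages are parameterised directly in expected-divergence
#' units (substitutions per site), the same proxy the estimators report:
#' `age_burst` is a normal burst truncated at 0, `age_exponential` models
#' ongoing proliferation (mode at the present), `age_two_burst` a bimodal
#' mixture (a horizontal-transfer-like control).
#'
#' @param mean,sd,m1,m2,mix model parameters (divergence units; `mix` is the
#'   weight of the first burst).
#' @return an `age_model` list.
#' @export
age_burst <- function(mean, sd) {
  structure(list(kind = "burst", mean = mean, sd = sd), class = "age_model")
}

#' @rdname age_burst
#' @export
age_exponential <- function(mean) {
  structure(list(kind = "exponential", mean = mean), class = "age_model")
}

#' @rdname age_burst
#' @export
age_two_burst <- function(m1, m2, sd, mix = 0.5) {
  stopifnot(mix >= 0, mix <= 1)
  structure(list(kind = "two_burst", m1 = m1, m2 = m2, sd = sd, mix = mix),
            class = "age_model")
}

age_model_mean <- function(model) {
  switch(model$kind,
         burst = model$mean,
         exponential = model$mean,
         two_burst = model$mix * model$m1 + (1 - model$mix) * model$m2,
         stop("unknown age model: ", model$kind))
}

draw_ages <- function(model, n) {
  switch(model$kind,
         burst = {
           x <- stats::rnorm(n, model$mean, model$sd)
           while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), model$mean, model$sd)
           x
         },
         exponential = stats::rexp(n, rate = 1 / model$mean),
         two_burst = {
           comp <- stats::runif(n) < model$mix
           mu <- ifelse(comp, model$m1, model$m2)
           x <- stats::rnorm(n, mu, model$sd)
           while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mu[x < 0], model$sd)
           x
         })
}

#' Define a master-gene family simulation scenario
#'
#' The generative model: a master element of length `master_len` is drawn
#' uniformly over `{A,C,G,T}`; its sequence is the family consensus.
#' Master-lineage substitutions occur as a time-ordered Poisson sequence
#' (expected `master_sub_count` events over the family's age span), with
#' third codon positions favoured `codon_bias`-fold. Each copy is born at an
#' age drawn from `age_model`, inherits exactly the master substitutions
#' older than its birth, then accrues private substitutions
#' (`Poisson(neutral_sub_rate * len * age)` events; positions uniform with
#' replacement, so multiple hits occur and Jukes-Cantor is the exact inverse
#' model) and small indels (`Poisson(rate * len * age)` events, geometric
#' sizes). Emitted alignments are exact by construction.
#'
#' Default indel parameters mirror a large decaying non-LTR copy set from a
#' giant-genome amphibian: deletion and insertion events per substitution
#' 29,755/658,447 and 39,258/658,447, mean sizes 2.60 and 1.47 bp.
#'
#' @param master_len master/consensus length, bp.
#' @param n_copies copies to simulate.
#' @param age_model an [age_burst()], [age_exponential()] or
#'   [age_two_burst()].
#' @param neutral_sub_rate substitution events per site per unit age
#'   (default 1: ages read directly as expected divergence).
#' @param master_sub_count expected master-lineage substitutions over the
#'   family age span.
#' @param del_rate,ins_rate indel events per site per unit age.
#' @param del_size_p,ins_size_p geometric size parameters (mean `1/p` bp).
#' @param codon_bias third-codon-position weight for master-lineage
#'   substitutions (1 = unbiased).
#' @param read_len_mean,read_len_sd shotgun read-length model, normal
#'   truncated at 50 bp.
#' @param homopolymer_error_rate per-run probability of injecting a spurious
#'   1-bp indel into consensus homopolymer runs >= 5 bp (default 0, off).
#' @param seed optional integer; when set, [simulate_family()] is fully
#'   reproducible from the scenario alone.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(master_len = 1500L, n_copies = 100L,
                         age_model = age_burst(0.05, 0.015),
                         neutral_sub_rate = 1,
                         master_sub_count = 5,
                         del_rate = 29755 / 658447,
                         ins_rate = 39258 / 658447,
                         del_size_p = 1 / 2.60,
                         ins_size_p = 1 / 1.47,
                         codon_bias = 1,
                         read_len_mean = 400, read_len_sd = 100,
                         homopolymer_error_rate = 0,
                         seed = NULL) {
  stopifnot(master_len >= 3L, n_copies >= 1L,
            inherits(age_model, "age_model"),
            neutral_sub_rate >= 0, master_sub_count >= 0,
            del_rate >= 0, ins_rate >= 0,
            del_size_p > 0, del_size_p <= 1, ins_size_p > 0, ins_size_p <= 1,
            codon_bias >= 0, read_len_mean >= 50)
  if (neutral_sub_rate * age_model_mean(age_model) > 1) {
    stop("expected substitutions exceed sites: neutral_sub_rate * mean age > 1")
  }
  if (master_sub_count > master_len) {
    stop("expected master-lineage substitutions exceed master length")
  }
  structure(list(master_len = as.integer(master_len),
                 n_copies = as.integer(n_copies), age_model = age_model,
                 neutral_sub_rate = neutral_sub_rate,
                 master_sub_count = master_sub_count,
                 del_rate = del_rate, ins_rate = ins_rate,
                 del_size_p = del_size_p, ins_size_p = ins_size_p,
                 codon_bias = codon_bias,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 homopolymer_error_rate = homopolymer_error_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_scenario")
}

# place `sizes` non-overlapping, non-adjacent runs on 1..len avoiding
# `occupied`; returns data.frame(start, size) of the runs actually placed
place_runs <- function(sizes, len, occupied, max_tries = 30L) {
  out <- data.frame(start = integer(0), size = integer(0))
  for (sz in sizes) {
    if (sz >= len) next
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(len - sz + 1L, 1L)
      span <- max(1L, s - 1L):min(len, s + sz)  # 1-base buffer: runs stay maximal
      if (!any(occupied[span])) {
        occupied[s:(s + sz - 1L)] <- TRUE
        out <- rbind(out, data.frame(start = s, size = sz))
        placed <- TRUE
        break
      }
    }
  }
  list(runs = out, occupied = occupied)
}

#' Simulate one repeat family with exact ground truth
#'
#' See [sim_scenario()] for the generative model. The returned truth records
#' the realised per-copy state: true age, inherited master-substitution keys
#' (master state at birth vs consensus), number of private substitution
#' events, the observed substitution keys (final copy state vs consensus at
#' non-deleted sites -- exactly what an alignment parser must recover), and
#' every indel event placed.
#'
#' @param scenario a [sim_scenario()].
#' @param family_id identifier for the emitted family.
#' @param superfamily superfamily label for the emitted family.
#' @return list with elements `family` (a [repeat_family()]) and `truth`
#'   (list: `master_events`, `copies`, `observed`, `inherited`, `indels`,
#'   `totals`).
#' @export
simulate_family <- function(scenario, family_id = "fam1",
                            superfamily = "LTR/Gypsy") {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  len <- scenario$master_len
  consensus <- sample(ALN_BASES, len, replace = TRUE)
  ages <- draw_ages(scenario$age_model, scenario$n_copies)
  A <- max(ages)

  # master-lineage substitution events, oldest first
  n_ev <- stats::rpois(1L, scenario$master_sub_count)
  codon_w <- rep_len(c(1, 1, scenario$codon_bias), len)
  ev_age <- sort(stats::runif(n_ev, 0, A), decreasing = TRUE)
  ev_pos <- if (n_ev > 0)
    sample.int(len, n_ev, replace = TRUE, prob = codon_w) else integer(0)
  master_state <- consensus
  ev_from <- character(n_ev); ev_to <- character(n_ev)
  master_states <- vector("list", n_ev)   # state after each event
  for (k in seq_len(n_ev)) {
    ev_from[k] <- master_state[ev_pos[k]]
    ev_to[k] <- sample(setdiff(ALN_BASES, ev_from[k]), 1L)
    master_state[ev_pos[k]] <- ev_to[k]
    master_states[[k]] <- master_state
  }
  master_events <- data.frame(age = ev_age, consensus_pos = ev_pos,
                              from = ev_from, to = ev_to,
                              stringsAsFactors = FALSE)

  copy_ids <- sprintf("%s_c%03d", family_id, seq_len(scenario$n_copies))
  alignments <- vector("list", scenario$n_copies)
  obs_list <- vector("list", scenario$n_copies)
  inh_list <- vector("list", scenario$n_copies)
  indel_list <- vector("list", scenario$n_copies)
  n_priv <- integer(scenario$n_copies)
  tot_del_bp <- 0L; tot_ins_bp <- 0L; tot_del <- 0L; tot_ins <- 0L

  for (i in seq_len(scenario$n_copies)) {
    a <- ages[i]
    k <- sum(ev_age > a)                     # events older than this copy's birth
    seq_i <- if (k > 0) master_states[[k]] else consensus
    inh <- which(seq_i != consensus)
    inh_list[[i]] <- data.frame(copy_id = rep(copy_ids[i], length(inh)),
                                consensus_pos = inh,
                                derived_base = seq_i[inh],
                                stringsAsFactors = FALSE)
    # private substitutions: uniform positions WITH replacement (multi-hit)
    np <- stats::rpois(1L, scenario$neutral_sub_rate * len * a)
    n_priv[i] <- np
    for (e in seq_len(np)) {
      p <- sample.int(len, 1L)
      seq_i[p] <- sample(setdiff(ALN_BASES, seq_i[p]), 1L)
    }
    # indels: non-overlapping, non-adjacent maximal runs
    nd <- stats::rpois(1L, scenario$del_rate * len * a)
    ni <- stats::rpois(1L, scenario$ins_rate * len * a)
    dsz <- if (nd > 0) stats::rgeom(nd, scenario$del_size_p) + 1L else integer(0)
    isz <- if (ni > 0) stats::rgeom(ni, scenario$ins_size_p) + 1L else integer(0)
    occupied <- logical(len)
    pl <- place_runs(dsz, len, occupied)
    dels <- pl$runs; occupied <- pl$occupied
    # insertion junctions: between pos j and j+1, j in 0..len; a junction
    # interior to a deletion run would split it, so it must stay clear
    junctions <- integer(0)
    ins_sz <- integer(0)
    for (sz in isz) {
      for (try in 1:30) {
        j <- sample.int(len + 1L, 1L) - 1L
        interior <- j >= 1L && j <= len - 1L && occupied[j] && occupied[j + 1L]
        if (!interior && !(j %in% junctions)) {
          junctions <- c(junctions, j); ins_sz <- c(ins_sz, sz)
          break
        }
      }
    }
    ins_seq <- vapply(ins_sz, function(s)
      paste(sample(ALN_BASES, s, replace = TRUE), collapse = ""), character(1))

    events <- data.frame(copy_id = character(0), kind = character(0),
                         consensus_pos = integer(0), length_bp = integer(0),
                         seq = character(0), artifact = logical(0),
                         stringsAsFactors = FALSE)
    if (nrow(dels) > 0) {
      events <- rbind(events, data.frame(
        copy_id = copy_ids[i], kind = "deletion",
        consensus_pos = dels$start - 1L, length_bp = dels$size,
        seq = vapply(seq_len(nrow(dels)), function(r)
          paste(consensus[dels$start[r]:(dels$start[r] + dels$size[r] - 1L)],
                collapse = ""), character(1)),
        artifact = FALSE, stringsAsFactors = FALSE))
    }
    if (length(junctions) > 0) {
      events <- rbind(events, data.frame(
        copy_id = copy_ids[i], kind = "insertion",
        consensus_pos = junctions, length_bp = ins_sz,
        seq = ins_seq, artifact = FALSE, stringsAsFactors = FALSE))
    }
    # optional 454-like homopolymer length-call errors
    if (scenario$homopolymer_error_rate > 0) {
      hp <- homopolymer_artifacts(consensus, occupied, junctions,
                                  scenario$homopolymer_error_rate, copy_ids[i])
      events <- rbind(events, hp$events)
      occupied <- hp$occupied
      junctions <- c(junctions, hp$junctions)
      ins_sz <- c(ins_sz, hp$events$length_bp[hp$events$kind == "insertion"])
      ins_seq <- c(ins_seq, hp$events$seq[hp$events$kind == "insertion"])
    }
    deleted <- occupied
    obs <- which(seq_i != consensus & !deleted)
    obs_list[[i]] <- data.frame(copy_id = rep(copy_ids[i], length(obs)),
                                consensus_pos = obs,
                                derived_base = seq_i[obs],
                                stringsAsFactors = FALSE)
    indel_list[[i]] <- events
    ddel <- events$kind == "deletion" & !events$artifact
    dins <- events$kind == "insertion" & !events$artifact
    tot_del <- tot_del + sum(ddel); tot_ins <- tot_ins + sum(dins)
    tot_del_bp <- tot_del_bp + sum(events$length_bp[ddel])
    tot_ins_bp <- tot_ins_bp + sum(events$length_bp[dins])

    alignments[[i]] <- build_gapped_pair(
      copy_ids[i], family_id, consensus, seq_i, deleted,
      junctions, ins_seq)
  }

  fam <- repeat_family(family_id, paste(consensus, collapse = ""),
                       alignments, superfamily = superfamily)
  truth <- list(
    master_events = master_events,
    copies = data.frame(copy_id = copy_ids, true_age = ages,
                        n_private_events = n_priv,
                        n_inherited = vapply(inh_list, nrow, integer(1)),
                        stringsAsFactors = FALSE),
    inherited = do.call(rbind, inh_list),
    observed = do.call(rbind, obs_list),
    indels = do.call(rbind, indel_list),
    totals = list(n_deletions = tot_del, n_insertions = tot_ins,
                  bp_deleted = tot_del_bp, bp_inserted = tot_ins_bp,
                  n_sub_events = sum(n_priv)))
  list(family = fam, truth = truth)
}

# inject spurious 1-bp indels into consensus homopolymer runs >= 5
homopolymer_artifacts <- function(consensus, occupied, junctions, rate, copy_id) {
  r <- rle(consensus)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  long <- which(r$lengths >= 5L)
  events <- data.frame(copy_id = character(0), kind = character(0),
                       consensus_pos = integer(0), length_bp = integer(0),
                       seq = character(0), artifact = logical(0),
                       stringsAsFactors = FALSE)
  new_j <- integer(0)
  for (k in long) {
    if (stats::runif(1) >= rate) next
    base <- r$values[k]
    if (stats::runif(1) < 0.5) {  # deletion of one base mid-run
      p <- starts[k] + 1L
      span <- max(1L, p - 1L):min(length(consensus), p + 1L)
      if (any(occupied[span])) next
      occupied[p] <- TRUE
      events <- rbind(events, data.frame(
        copy_id = copy_id, kind = "deletion", consensus_pos = p - 1L,
        length_bp = 1L, seq = base, artifact = TRUE, stringsAsFactors = FALSE))
    } else {                      # duplicate one base mid-run
      j <- starts[k] + 1L
      interior <- j >= 1L && j <= length(consensus) - 1L &&
        occupied[j] && occupied[j + 1L]
      if (interior || j %in% c(junctions, new_j)) next
      new_j <- c(new_j, j)
      events <- rbind(events, data.frame(
        copy_id = copy_id, kind = "insertion", consensus_pos = j,
        length_bp = 1L, seq = base, artifact = TRUE, stringsAsFactors = FALSE))
    }
  }
  list(events = events, occupied = occupied, junctions = new_j)
}

# assemble the gapped pair from per-position state + indel placements
build_gapped_pair <- function(copy_id, family_id, consensus, seq_final,
                              deleted, junctions, ins_seq) {
  len <- length(consensus)
  copy_chars <- seq_final
  copy_chars[deleted] <- "-"
  cons_chars <- consensus
  if (length(junctions) > 0) {
    o <- order(junctions)
    junctions <- junctions[o]; ins_seq <- ins_seq[o]
    cpieces <- character(0); kpieces <- character(0)
    last <- 0L
    for (q in seq_along(junctions)) {
      j <- junctions[q]
      if (j > last) {
        cpieces <- c(cpieces, copy_chars[(last + 1L):j])
        kpieces <- c(kpieces, cons_chars[(last + 1L):j])
      }
      cpieces <- c(cpieces, strsplit(ins_seq[q], "", fixed = TRUE)[[1L]])
      kpieces <- c(kpieces, rep("-", nchar(ins_seq[q])))
      last <- j
    }
    if (last < len) {
      cpieces <- c(cpieces, copy_chars[(last + 1L):len])
      kpieces <- c(kpieces, cons_chars[(last + 1L):len])
    }
    copy_chars <- cpieces; cons_chars <- kpieces
  }
  pairwise_alignment(copy_id, family_id,
                     paste(copy_chars, collapse = ""),
                     paste(cons_chars, collapse = ""),
                     consensus_start = 1L, consensus_end = len)
}

#' Shred simulated copies into shotgun-read-like fragments
#'
#' Each copy's ungapped sequence is cut into consecutive fragments with
#' lengths drawn from the scenario's read-length model (normal, truncated at
#' 50 bp; the final fragment takes the remainder). Per-read alignments are
#' consistent sub-alignments of the parent copy's alignment, so the
#' concatenated fragments reproduce the copy and the pooled fragment
#' substitutions reproduce the copy's substitution set.
#'
#' @param simfam result of [simulate_family()] (or any [repeat_family()]).
#' @param scenario the [sim_scenario()] providing the read-length model.
#' @return list with `reads` (named character vector) and `alignments`
#'   (list of per-read [pairwise_alignment()]).
#' @export
shred_to_reads <- function(simfam, scenario) {
  fam <- if (inherits(simfam, "repeat_family")) simfam else simfam$family
  reads <- character(0)
  alns <- list()
  for (a in fam$alignments) {
    cols <- aln_columns(a)
    base_cols <- which(cols$copy != "-")
    L <- length(base_cols)
    lens <- integer(0)
    while (sum(lens) < L) {
      l <- round(stats::rnorm(1L, scenario$read_len_mean, scenario$read_len_sd))
      while (l < 50) l <- round(stats::rnorm(1L, scenario$read_len_mean,
                                             scenario$read_len_sd))
      lens <- c(lens, l)
    }
    lens[length(lens)] <- L - sum(lens[-length(lens)])
    if (lens[length(lens)] == 0L) lens <- lens[-length(lens)]
    stops <- cumsum(lens)
    starts <- stops - lens + 1L
    for (k in seq_along(lens)) {
      col_a <- base_cols[starts[k]]; col_b <- base_cols[stops[k]]
      sub_copy <- cols$copy[col_a:col_b]
      sub_cons <- cols$cons[col_a:col_b]
      pos <- aln_consensus_positions(a, cols)
      cons_cols <- which(cols$cons[col_a:col_b] != "-")
      read_id <- sprintf("%s_r%02d", a$copy_id, k)
      cs <- if (length(cons_cols)) pos[col_a:col_b][cons_cols[1L]] else a$consensus_start
      alns[[length(alns) + 1L]] <- pairwise_alignment(
        read_id, a$family_id,
        paste(sub_copy, collapse = ""), paste(sub_cons, collapse = ""),
        consensus_start = cs, strand = a$strand, source_read_id = read_id)
      reads[read_id] <- paste(sub_copy[sub_copy != "-"], collapse = "")
    }
  }
  list(reads = reads, alignments = alns)
}

#' Preset simulation scenarios
#'
#' Three named scenarios spanning the qualitative proliferation regimes seen
#' in divergence distributions: `ongoing` (age mode at the present, mass in
#' the `[0,1)%` bin), `old_burst` (a past proliferation peak well above 1%
#' divergence with reduced recent activity), and `two_burst` (a bimodal,
#' horizontal-transfer-like control with two well-separated peaks).
#'
#' @param n_copies copies per family (default 500).
#' @param seed optional seed stored in each scenario.
#' @return named list of [sim_scenario()] objects.
#' @export
preset_scenarios <- function(n_copies = 500L, seed = NULL) {
  list(
    ongoing = sim_scenario(n_copies = n_copies, seed = seed,
                           age_model = age_exponential(0.015),
                           master_sub_count = 5),
    old_burst = sim_scenario(n_copies = n_copies, seed = seed,
                             age_model = age_burst(0.06, 0.015),
                             master_sub_count = 5),
    two_burst = sim_scenario(n_copies = n_copies, seed = seed,
                             age_model = age_two_burst(0.02, 0.10, 0.008),
                             master_sub_count = 5))
}
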