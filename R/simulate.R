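AA20 <- setdiff(AA_ALPHABET_21, "X")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(residues, n_subs) {
  pos <- sample(nchar(residues), min(n_subs, nchar(residues)))
  mutate_protein_at(residues, pos)
}

mutate_protein_at <- function(residues, pos) {
  chars <- strsplit(residues, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

with_seed <- function(seed, code) {
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, code)
  } else {
    set.seed(seed)
    code
  }
}

#' Specification of a synthetic RBP head-domain family set
#'
#' Defaults emulate the identity structure observed across Skunavirus head
#' domains: within-group (or within-subgroup) pairwise identity in the 85-95%
#' band, cross-subgroup identity between the 50% group floor and the 65%
#' subgroup threshold, and between-group identity at most 35%.
#'
#' @param n_groups Number of groups.
#' @param members_per_group Members per group (recycled).
#' @param subgroup_plan Optional list (one element per group) of subgroup
#'   size vectors; `NULL` entries mean no planned substructure.
#' @param head_length Head-domain length (default 110).
#' @param within_identity_band Percent band for same-(sub)group pairs.
#' @param subgroup_cross_identity_band Percent band for pairs in the same
#'   group but different subgroups; must lie strictly between the group and
#'   subgroup thresholds for the plan to be recoverable.
#' @param between_identity_max Maximum identity between different groups (and
#'   to ungrouped sequences).
#' @param n_ungrouped Number of singleton sequences unrelated to any group.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_groups = 5, members_per_group = 8,
                        subgroup_plan = NULL, head_length = 110,
                        within_identity_band = c(85, 95),
                        subgroup_cross_identity_band = c(52, 64),
                        between_identity_max = 35,
                        n_ungrouped = 0, seed = 1) {
  if (within_identity_band[1] <= between_identity_max) {
    abort("within_identity_band low must exceed between_identity_max.")
  }
  if (subgroup_cross_identity_band[1] <= between_identity_max) {
    abort("subgroup_cross_identity_band low must exceed between_identity_max.")
  }
  if (subgroup_cross_identity_band[2] >= within_identity_band[1]) {
    abort("subgroup_cross_identity_band must lie below within_identity_band.")
  }
  structure(
    list(
      n_groups = n_groups,
      members_per_group = rep_len(members_per_group, n_groups),
      subgroup_plan = subgroup_plan,
      head_length = head_length,
      within_identity_band = within_identity_band,
      subgroup_cross_identity_band = subgroup_cross_identity_band,
      between_identity_max = between_identity_max,
      n_ungrouped = n_ungrouped,
      seed = seed
    ),
    class = "family_spec"
  )
}

draw_until <- function(propose, ok, cap = 1000, what = "sequence") {
  for (i in seq_len(cap)) {
    x <- propose()
    if (ok(x)) return(x)
  }
  abort(paste0(
    "Could not generate a ", what, " satisfying the identity bands in ",
    cap, " attempts; the configured bands are likely infeasible."
  ))
}

#' Simulate RBP head-domain families with known labels
#'
#' One random ancestor per group (and per planned subgroup); members are
#' derived by point substitutions, and every candidate is rejection-sampled
#' against the measured pairwise identities (computed with the same
#' alignment machinery the classifier uses) until all band constraints hold:
#' same-(sub)group pairs inside `within_identity_band`, cross-subgroup pairs
#' inside `subgroup_cross_identity_band`, and everything else at or below
#' `between_identity_max`. No indels are introduced, so pair coverage is
#' always 100.
#'
#' @param spec A [family_spec()].
#' @param scheme A [scoring_scheme()] used for the calibration measurements.
#' @return A list: `sequences` (tibble `id`, `description`, `residues`) and
#'   `truth` (tibble `id`, `true_group`, `true_subgroup`).
#' @export
simulate_rbp_families <- function(spec, scheme = scoring_scheme()) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$head_length
    wb <- spec$within_identity_band
    xb <- spec$subgroup_cross_identity_band
    bmax <- spec$between_identity_max
    seqs <- character()
    ids <- character()
    grp <- character()
    sub <- character()

    ident_to_all <- function(cand, pool) {
      if (length(pool) == 0) return(numeric())
      pairwise_identity_many(cand, pool, scheme)$identity_pct
    }

    # per-member substitution count targeting ~ (100 - band) pairwise
    # identity; kept low when cross-subgroup constraints also apply, so
    # members do not drift below the cross band floor
    member_subs <- function(constrained = FALSE) {
      lo <- ceiling((100 - wb[2]) / 100 * L / 2)
      hi <- floor((100 - wb[1]) / 100 * L / 2)
      if (constrained) hi <- max(lo, hi - 2)
      sample(seq(max(lo, 1), max(hi, lo, 1)), 1)
    }

    for (g in seq_len(spec$n_groups)) {
      plan <- if (!is.null(spec$subgroup_plan) && length(spec$subgroup_plan) >= g) {
        spec$subgroup_plan[[g]]
      } else NULL
      other_idx <- seq_along(seqs)
      # group ancestor: far from every other group's sequences
      anc <- draw_until(
        function() random_protein(L),
        function(x) all(ident_to_all(x, seqs[other_idx]) <= bmax),
        what = "group ancestor"
      )
      if (is.null(plan) || length(plan) < 2) {
        sizes <- spec$members_per_group[g]
        sub_ancestors <- list(anc)
        sub_names <- NA_character_
      } else {
        sizes <- plan
        sub_names <- LETTERS[seq_along(plan)]
        # subgroup ancestors: pairwise identity inside the cross band
        sub_ancestors <- list()
        # subgroup ancestors mutate disjoint position blocks of the group
        # ancestor, so any two differ at exactly m_i + m_j positions and
        # their pairwise identity sits near the top of the cross band;
        # member-level substitutions then pull cross-pair identities down
        # into the band
        anc_target <- min(xb[1] + 8, xb[2] - 2)
        anc_lo <- anc_target - 3
        anc_hi <- min(anc_target + 3, xb[2] - 1)
        m_block <- round((100 - anc_target) / 100 * L / 2)
        if (length(plan) * m_block > L) {
          abort("Too many subgroups for the configured cross-identity band.")
        }
        pos_pool <- sample(L)
        for (s in seq_along(plan)) {
          block <- pos_pool[((s - 1) * m_block + 1):(s * m_block)]
          sub_ancestors[[s]] <- draw_until(
            function() mutate_protein_at(anc, block),
            function(x) {
              prev <- unlist(sub_ancestors)
              ok_cross <- length(prev) == 0 ||
                all(dplyr::between(ident_to_all(x, prev), anc_lo, anc_hi))
              ok_cross && all(ident_to_all(x, seqs[other_idx]) <= bmax)
            },
            what = "subgroup ancestor"
          )
        }
      }
      group_member_idx <- list()
      for (s in seq_along(sub_ancestors)) {
        same_sub_idx <- integer()
        cross_sub_idx <- unlist(group_member_idx)
        constrained <- length(sub_ancestors) > 1
        for (k in seq_len(sizes[s])) {
          cand <- draw_until(
            function() mutate_protein(sub_ancestors[[s]], member_subs(constrained)),
            function(x) {
              all(dplyr::between(ident_to_all(x, seqs[same_sub_idx]), wb[1], wb[2])) &&
                all(dplyr::between(ident_to_all(x, seqs[cross_sub_idx]), xb[1], xb[2])) &&
                all(ident_to_all(x, seqs[other_idx]) <= bmax)
            },
            what = "group member"
          )
          id <- sprintf(
            "g%02d%s_m%02d", g,
            if (is.na(sub_names[1])) "" else sub_names[s], k
          )
          seqs <- c(seqs, cand)
          ids <- c(ids, id)
          grp <- c(grp, sprintf("G%02d", g))
          sub <- c(sub, if (is.na(sub_names[1])) NA_character_ else
            sprintf("G%02d%s", g, sub_names[s]))
          same_sub_idx <- c(same_sub_idx, length(seqs))
        }
        group_member_idx[[s]] <- same_sub_idx
      }
    }
    if (spec$n_ungrouped > 0) {
      for (u in seq_len(spec$n_ungrouped)) {
        cand <- draw_until(
          function() random_protein(L),
          function(x) all(ident_to_all(x, seqs) <= bmax),
          what = "ungrouped sequence"
        )
        seqs <- c(seqs, cand)
        ids <- c(ids, sprintf("singleton_%02d", u))
        grp <- c(grp, NA_character_)
        sub <- c(sub, NA_character_)
      }
    }
    list(
      sequences = tibble(
        id = ids,
        description = ifelse(is.na(grp), "ungrouped",
                             paste0("group ", grp,
                                    ifelse(is.na(sub), "", paste0(" subgroup ", sub)))),
        residues = seqs
      ),
      truth = tibble(id = ids, true_group = grp, true_subgroup = sub)
    )
  })
}

#' Specification of a simulated binding-assay plate
#'
#' Emulates the plate design of the GFP-RBP binding assay: cells grown to
#' mid-log (OD600 around 0.4-0.7), no-cell control wells per RBP, and
#' additive Gaussian measurement noise proportional to signal.
#'
#' @param true_affinity Numeric matrix (RBPs x strains, dimnames required)
#'   of affinities in [0, 1].
#' @param signal_gain Fluorescence units per OD per unit affinity.
#' @param background Baseline fluorescence of an RBP-only well.
#' @param noise_sd_fraction Noise standard deviation as a fraction of the
#'   expected signal (default 0.05).
#' @param od_range OD600 range sample wells are drawn from.
#' @param replicates Sample replicates per (RBP, strain) (default 3).
#' @param n_controls Control wells per RBP (default 3).
#' @param seed Integer seed.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(true_affinity, signal_gain = 1e5, background = 500,
                       noise_sd_fraction = 0.05, od_range = c(0.3, 0.7),
                       replicates = 3, n_controls = 3, seed = 1) {
  true_affinity <- as.matrix(true_affinity)
  if (is.null(rownames(true_affinity)) || is.null(colnames(true_affinity))) {
    abort("`true_affinity` needs RBP row names and strain column names.")
  }
  if (any(true_affinity < 0 | true_affinity > 1)) {
    abort("Affinities must be in [0, 1].")
  }
  if (noise_sd_fraction < 0) abort("`noise_sd_fraction` must be >= 0.")
  structure(
    list(
      true_affinity = true_affinity, signal_gain = signal_gain,
      background = background, noise_sd_fraction = noise_sd_fraction,
      od_range = od_range, replicates = replicates,
      n_controls = n_controls, seed = seed
    ),
    class = "plate_spec"
  )
}

#' Simulate a fluorescence binding-assay plate
#'
#' Sample wells read `background + od * signal_gain * affinity` plus Gaussian
#' noise with standard deviation `noise_sd_fraction` times the expected
#' signal; control wells read `background` plus noise at the same fraction
#' of the background. The truth table carries the relative binding scores
#' implied by the affinities (100 at each RBP's row maximum).
#'
#' @param spec A [plate_spec()].
#' @return A list: `plate` (tibble in the plate TSV schema) and `truth`
#'   (tibble `rbp_id`, `strain_id`, `true_affinity`, `true_score_pct`).
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  with_seed(spec$seed, {
    aff <- spec$true_affinity
    rbps <- rownames(aff)
    strains <- colnames(aff)
    rows <- list()
    for (r in rbps) {
      for (s in strains) {
        od <- stats::runif(spec$replicates, spec$od_range[1], spec$od_range[2])
        signal <- od * spec$signal_gain * aff[r, s]
        raw <- spec$background + signal +
          stats::rnorm(spec$replicates, 0, spec$noise_sd_fraction * signal)
        rows[[length(rows) + 1]] <- tibble(
          rbp_id = r, strain_id = s, replicate = seq_len(spec$replicates),
          raw_fluorescence = pmax(raw, 0), od600 = od, is_control = FALSE
        )
      }
      ctrl <- spec$background +
        stats::rnorm(spec$n_controls, 0, spec$noise_sd_fraction * spec$background)
      rows[[length(rows) + 1]] <- tibble(
        rbp_id = r, strain_id = NA_character_,
        replicate = seq_len(spec$n_controls),
        raw_fluorescence = pmax(ctrl, 0), od600 = NA_real_, is_control = TRUE
      )
    }
    truth <- tibble(
      rbp_id = rep(rbps, each = length(strains)),
      strain_id = rep(strains, times = length(rbps)),
      true_affinity = as.vector(t(aff))
    ) |>
      group_by(.data$rbp_id) |>
      mutate(true_score_pct = if (max(.data$true_affinity) > 0) {
        100 * .data$true_affinity / max(.data$true_affinity)
      } else NA_real_) |>
      ungroup()
    list(plate = bind_rows(rows), truth = truth)
  })
}

#' Specification of a simulated read-mapping corpus
#'
#' @param refs A [reference_set()] tibble.
#' @param true_weights Named numeric vector of category proportions (sums
#'   to 1).
#' @param n_reads Total reads including unmapped.
#' @param read_length Read length in bp.
#' @param pass_prob Probability that a mapped read passes both filters.
#' @param identity_pass_range,identity_fail_range Percent-identity ranges
#'   for passing/failing reads (keep a margin from the threshold so integer
#'   edit-distance rounding cannot flip a read across it).
#' @param aligned_pass_range,aligned_fail_range Aligned-fraction (percent of
#'   read length) ranges for passing/failing reads.
#' @param unmapped_fraction Fraction of reads emitted unmapped.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(refs, true_weights, n_reads = 10000,
                          read_length = 150, pass_prob = 0.9,
                          identity_pass_range = c(90, 100),
                          identity_fail_range = c(60, 78),
                          aligned_pass_range = c(98, 100),
                          aligned_fail_range = c(20, 45),
                          unmapped_fraction = 0, seed = 1) {
  if (abs(sum(true_weights) - 1) > 1e-8) abort("`true_weights` must sum to 1.")
  if (!all(names(true_weights) %in% refs$category)) {
    abort("Every weight must name a category present in `refs`.")
  }
  if (unmapped_fraction < 0 || unmapped_fraction > 1) {
    abort("`unmapped_fraction` must be in [0, 1].")
  }
  structure(
    list(
      refs = refs, true_weights = true_weights, n_reads = n_reads,
      read_length = read_length, pass_prob = pass_prob,
      identity_pass_range = identity_pass_range,
      identity_fail_range = identity_fail_range,
      aligned_pass_range = aligned_pass_range,
      aligned_fail_range = aligned_fail_range,
      unmapped_fraction = unmapped_fraction, seed = seed
    ),
    class = "read_sim_spec"
  )
}

#' Simulate read-to-reference alignment records with known truth
#'
#' Each read is unmapped with probability `unmapped_fraction`; otherwise its
#' category is drawn from `true_weights`, its reference within the category
#' proportional to reference length, and its start position uniformly. With
#' probability `pass_prob` the read's identity and aligned fraction are
#' drawn from the passing ranges; otherwise at least one is drawn from the
#' failing range, so the intended filter outcome of every record is known.
#'
#' The truth list reports both the sampling weights and the analytic
#' expectation of the length-normalized relative-abundance estimator under
#' this sampling scheme (they coincide when references within each category
#' have equal length-normalization totals).
#'
#' @param spec A [read_sim_spec()].
#' @return A list: `records` (alignment record tibble with extra columns
#'   `true_category`, `intended_pass`), `expected_abundance` (tibble
#'   `category`, `expected_pct`, ending with `unmapped`).
#' @export
simulate_alignments <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  with_seed(spec$seed, {
    refs <- spec$refs
    cats <- names(spec$true_weights)
    n <- spec$n_reads
    L <- spec$read_length
    unmapped <- stats::runif(n) < spec$unmapped_fraction
    n_mapped <- sum(!unmapped)
    category <- rep(NA_character_, n)
    category[!unmapped] <- sample(cats, n_mapped, replace = TRUE,
                                  prob = spec$true_weights)
    pass <- rep(FALSE, n)
    pass[!unmapped] <- stats::runif(n_mapped) < spec$pass_prob
    ref_id <- rep(NA_character_, n)
    for (cat in cats) {
      sel <- which(!unmapped & category == cat)
      rc <- refs[refs$category == cat, , drop = FALSE]
      ref_id[sel] <- sample(rc$ref_id, length(sel), replace = TRUE,
                            prob = rc$length_bp)
    }
    ref_len <- refs$length_bp[match(ref_id, refs$ref_id)]
    ref_start <- ifelse(
      is.na(ref_len), NA_integer_,
      1L + floor(stats::runif(n) * pmax(ref_len - L + 1, 1))
    )
    # identity / aligned fraction mixtures
    draw_range <- function(k, range) stats::runif(k, range[1], range[2])
    identity <- rep(NA_real_, n)
    aligned_frac <- rep(NA_real_, n)
    mapped_idx <- which(!unmapped)
    p_idx <- mapped_idx[pass[mapped_idx]]
    f_idx <- setdiff(mapped_idx, p_idx)
    identity[p_idx] <- draw_range(length(p_idx), spec$identity_pass_range)
    aligned_frac[p_idx] <- draw_range(length(p_idx), spec$aligned_pass_range)
    # failing reads fail identity, aligned fraction, or both
    which_fail <- sample(1:3, length(f_idx), replace = TRUE)
    identity[f_idx] <- ifelse(
      which_fail != 2,
      draw_range(length(f_idx), spec$identity_fail_range),
      draw_range(length(f_idx), spec$identity_pass_range)
    )
    aligned_frac[f_idx] <- ifelse(
      which_fail != 1,
      draw_range(length(f_idx), spec$aligned_fail_range),
      draw_range(length(f_idx), spec$aligned_pass_range)
    )
    aligned_length <- ifelse(is.na(aligned_frac), NA_integer_,
                             pmax(1L, round(aligned_frac / 100 * L)))
    # quantize identity to an integer edit distance over the aligned length
    nm <- round((1 - identity / 100) * aligned_length)
    percent_identity <- 100 * (aligned_length - nm) / aligned_length
    records <- tibble(
      read_id = sprintf("read_%06d", seq_len(n)),
      mapped = !unmapped,
      ref_id = ref_id,
      ref_start = as.integer(ref_start),
      aligned_length = as.integer(aligned_length),
      read_length = L,
      percent_identity = percent_identity,
      true_category = category,
      intended_pass = pass
    )
    w <- spec$true_weights
    expected <- tibble(
      category = names(w),
      expected_pct = 100 * (1 - spec$unmapped_fraction) * spec$pass_prob *
        as.numeric(w * purrr::map_dbl(names(w), function(cat) {
          rc <- refs[refs$category == cat, , drop = FALSE]
          sum((rc$length_bp / sum(rc$length_bp)) / rc$length_bp)
        })) /
        sum(purrr::map_dbl(names(w), function(cat) {
          rc <- refs[refs$category == cat, , drop = FALSE]
          w[[cat]] * sum((rc$length_bp / sum(rc$length_bp)) / rc$length_bp)
        }))
    )
    expected <- bind_rows(
      expected,
      tibble(category = "unmapped",
             expected_pct = 100 - sum(expected$expected_pct))
    )
    list(records = records, expected_abundance = expected)
  })
}

#' Write alignment records as a plain SAM file
#'
#' Emits a headerful SAM with one @SQ line per reference, an `nnMnnS` CIGAR
#' (trailing soft clip for the unaligned read tail) and the standard NM
#' edit-distance tag, so the records round-trip through
#' [read_sam_records()].
#'
#' @param records Alignment record tibble.
#' @param refs A [reference_set()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_records <- function(records, refs, path) {
  records <- validate_alignment_records(records)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", refs$ref_id, as.integer(refs$length_bp))
  )
  seq_of <- function(len) strrep("A", len)
  body <- purrr::map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!r$mapped) {
      return(paste(
        r$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
        seq_of(r$read_length), "*",
        sep = "\t"
      ))
    }
    clip <- r$read_length - r$aligned_length
    cigar <- if (clip > 0) sprintf("%dM%dS", r$aligned_length, clip) else
      sprintf("%dM", r$aligned_length)
    nm <- as.integer(round((1 - r$percent_identity / 100) * r$aligned_length))
    paste(
      r$read_id, 0L, r$ref_id, r$ref_start, 60L, cigar, "*", 0L, 0L,
      seq_of(r$read_length), "*", sprintf("NM:i:%d", nm),
      sep = "\t"
    )
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a plate tibble as TSV
#'
#' @param plate Plate tibble (see [read_plate_tsv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_tsv <- function(plate, path) {
  readr::write_tsv(validate_plate(plate), path)
  invisible(path)
}
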