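random_identity_matrix <- function(n, p_edge = 0.3) {
  ident <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2, 0, 100)
  ident[upper.tri(ident)] <- vals
  ident <- ident + t(ident)
  diag(ident) <- 100
  cov <- matrix(100, n, n)
  identity_matrix(sprintf("s%02d", seq_len(n)), ident, cov)
}

test_that("identity matrix build matches independent per-pair calls", {
  set.seed(61)
  heads <- tibble::tibble(
    id = paste0("h", 1:5),
    residues = replicate(5, random_aa(40))
  )
  m <- build_identity_matrix(heads)
  expect_equal(unname(diag(m$identity)), rep(100, 5))
  expect_equal(m$identity, t(m$identity))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      ic <- identity_and_coverage(
        align_global(heads$residues[i], heads$residues[j])
      )
      expect_equal(m$identity[i, j], unname(ic["identity_pct"]))
      expect_equal(m$coverage[i, j], unname(ic["coverage_pct"]))
    }
  }
  expect_error(
    build_identity_matrix(tibble::tibble(id = c("a", "a"),
                                         residues = c("ACD", "ACD"))),
    "unique"
  )
})

test_that("trivial grouping cases behave as defined", {
  # complete graph -> one group of 3
  ident <- matrix(90, 3, 3); diag(ident) <- 100
  m <- identity_matrix(c("A", "B", "C"), ident)
  a <- assign_groups(m)
  expect_equal(sum(!a$ungrouped), 3)
  expect_equal(length(unique(a$component[!a$ungrouped])), 1)

  # chain joins through single linkage even when one pair is below threshold
  ident <- matrix(c(100, 55, 30, 55, 100, 52, 30, 52, 100), 3, 3)
  cov <- matrix(c(100, 95, 95, 95, 100, 93, 95, 93, 100), 3, 3)
  m <- identity_matrix(c("A", "B", "C"), ident, cov)
  a <- assign_groups(m)
  expect_equal(length(unique(a$component)), 1)
  expect_false(any(a$ungrouped))

  # all below threshold -> everyone ungrouped
  ident <- matrix(40, 4, 4); diag(ident) <- 100
  m <- identity_matrix(paste0("s", 1:4), ident)
  a <- assign_groups(m)
  expect_true(all(a$ungrouped))
})

test_that("coverage below threshold blocks an edge even at high identity", {
  ident <- matrix(c(100, 90, 90, 100), 2, 2)
  cov <- matrix(c(100, 80, 80, 100), 2, 2)
  m <- identity_matrix(c("A", "B"), ident, cov)
  a <- assign_groups(m)
  expect_true(all(a$ungrouped))
})

test_that("groups equal brute-force DFS components on random matrices", {
  set.seed(71)
  thr <- grouping_thresholds()
  for (case in 1:40) {
    n <- sample(2:12, 1)
    m <- random_identity_matrix(n)
    adj <- m$identity >= thr$group_min_identity &
      m$coverage >= thr$group_min_coverage
    diag(adj) <- FALSE
    oracle <- bf_components(adj)
    got <- assign_groups(m, thr)
    # same partition up to relabelling
    expect_equal(ari(oracle, ifelse(got$ungrouped, paste0("u", seq_len(n)),
                                    got$component)), 1)
    # singleton flag agrees with component sizes
    expect_equal(got$ungrouped, table(oracle)[as.character(oracle)] == 1,
                 ignore_attr = TRUE)
  }
})

test_that("raising the group identity threshold only refines the partition", {
  set.seed(81)
  for (case in 1:10) {
    n <- sample(4:10, 1)
    m <- random_identity_matrix(n)
    lo <- assign_groups(m, grouping_thresholds(40, 90, 65))
    hi <- assign_groups(m, grouping_thresholds(60, 90, 65))
    key_lo <- ifelse(lo$ungrouped, paste0("u", seq_len(n)), lo$component)
    key_hi <- ifelse(hi$ungrouped, paste0("u", seq_len(n)), hi$component)
    # each high-threshold class maps into exactly one low-threshold class
    expect_true(all(tapply(key_lo, key_hi, function(x) length(unique(x))) == 1))
  }
})

test_that("subgroup clustering matches the minimal valid partition", {
  ident <- matrix(50, 4, 4)
  ident[1, 2] <- ident[2, 1] <- 80
  ident[3, 4] <- ident[4, 3] <- 78
  diag(ident) <- 100
  m <- identity_matrix(c("A", "B", "C", "D"), ident)
  thr <- grouping_thresholds(30, 90, 65)
  got <- assign_subgroups(c("A", "B", "C", "D"), m, thr)
  expect_equal(got$subgroup[1], got$subgroup[2])
  expect_equal(got$subgroup[3], got$subgroup[4])
  expect_false(got$subgroup[1] == got$subgroup[3])

  # exhaustive check: {AB},{CD} is the unique minimal partition where all
  # within-block pairs reach the 65% subgroup threshold
  parts <- all_partitions(4)
  valid <- Filter(function(p) {
    all(sapply(unique(p), function(b) {
      idx <- which(p == b)
      length(idx) < 2 ||
        all(ident[idx, idx][upper.tri(diag(length(idx)))] >= 65)
    }))
  }, parts)
  sizes <- sapply(valid, function(p) length(unique(p)))
  minimal <- valid[sizes == min(sizes)]
  expect_length(minimal, 1)
  expect_equal(ari(minimal[[1]], got$subgroup), 1)
})

test_that("subgroups: undivided and singleton groups carry no letters", {
  ident <- matrix(70, 3, 3); diag(ident) <- 100
  m <- identity_matrix(c("A", "B", "C"), ident)
  got <- assign_subgroups(c("A", "B", "C"), m)
  expect_true(all(is.na(got$subgroup)))
  got1 <- assign_subgroups("A", m)
  expect_true(is.na(got1$subgroup))
  expect_error(assign_subgroups(c("A", "Z"), m), "present")
})

test_that("every within-subgroup pair reaches the subgroup threshold", {
  set.seed(91)
  thr <- grouping_thresholds()
  for (case in 1:20) {
    n <- sample(3:9, 1)
    m <- random_identity_matrix(n)
    got <- assign_subgroups(m$ids, m, thr)
    if (all(is.na(got$subgroup))) next
    for (b in unique(got$subgroup)) {
      idx <- which(got$subgroup == b)
      if (length(idx) < 2) next
      pairs <- m$identity[idx, idx][upper.tri(diag(length(idx)))]
      expect_true(all(pairs >= thr$subgroup_min_identity))
    }
  }
})

test_that("group naming is deterministic and permutation-invariant", {
  # sizes 5, 3, 3: ties broken by smallest member id
  assignment <- tibble::tibble(
    id = c(paste0("x", 1:5), "b1", "b2", "b3", "a_c1", "c2", "c3"),
    component = c(rep(1L, 5), rep(2L, 3), rep(3L, 3)),
    ungrouped = FALSE
  )
  named <- name_groups(assignment)
  expect_equal(unique(named$group[named$component == 1]), "I")
  expect_equal(unique(named$group[named$component == 3]), "II") # has "a_c1"
  expect_equal(unique(named$group[named$component == 2]), "III")

  one <- name_groups(tibble::tibble(id = c("a", "b"), component = 1L,
                                    ungrouped = FALSE))
  expect_equal(unique(one$group), "I")

  set.seed(101)
  fam <- simulate_rbp_families(
    family_spec(n_groups = 3, members_per_group = c(5, 3, 4), seed = 5)
  )
  heads <- extract_head_domains(fam$sequences)
  m <- build_identity_matrix(heads)
  base <- rbp_group(m)$assignment
  for (shuffle in 1:20) {
    perm <- sample(length(m$ids))
    mp <- identity_matrix(m$ids[perm], m$identity[perm, perm],
                          m$coverage[perm, perm])
    got <- rbp_group(mp)$assignment
    merged <- dplyr::left_join(base, got, by = "id", suffix = c("", ".p"))
    expect_equal(merged$group, merged$group.p)
    expect_equal(merged$subgroup, merged$subgroup.p)
  }
})

test_that("within-group summary statistics are exact on known matrices", {
  ident <- matrix(c(100, 90, 85, 90, 100, 95, 85, 95, 100), 3, 3)
  m <- identity_matrix(c("A", "B", "C"), ident)
  g <- rbp_group(m, grouping_thresholds(50, 90, 65))
  s <- summarize_groups(g)
  expect_equal(s$min_identity, 85)
  expect_equal(s$max_identity, 95)
  expect_equal(s$mean_identity, 90)

  ident2 <- matrix(c(100, 70, 70, 100), 2, 2)
  m2 <- identity_matrix(c("A", "B"), ident2)
  g2 <- rbp_group(m2, grouping_thresholds(50, 90, 65))
  s2 <- summarize_groups(g2)
  expect_equal(s2$min_identity, 70)
  expect_equal(s2$mean_identity, 70)
  expect_equal(s2$max_identity, 70)
})

test_that("conserved residues are reported at reference coordinates", {
  set.seed(111)
  ref <- random_aa(200)
  heads <- tibble::tibble(
    id = c("same1", "same2"),
    residues = c(substr(ref, 91, 200), substr(ref, 91, 200))
  )
  rep1 <- conserved_residue_report(heads, ref, c(100, 150, 200))
  expect_true(all(rep1$conserved$conserved))
  expect_true(all(rep1$table$agrees))

  # one substitution at a queried position flips its conservation flag
  mutated <- heads
  chars <- strsplit(mutated$residues[1], "")[[1]]
  pos_in_head <- 150 - 90
  chars[pos_in_head] <- setdiff(c("A", "C", "D"), chars[pos_in_head])[1]
  mutated$residues[1] <- paste(chars, collapse = "")
  rep2 <- conserved_residue_report(mutated, ref, c(100, 150, 200))
  flags <- rep2$conserved
  expect_true(flags$conserved[flags$position == 100])
  expect_false(flags$conserved[flags$position == 150])

  expect_error(conserved_residue_report(heads, ref, 201), "within")
})

test_that("group and subgroup labels recover the generating plan exactly", {
  fam <- simulate_rbp_families(
    family_spec(n_groups = 3, members_per_group = 5,
                subgroup_plan = list(c(3, 2), NULL, NULL),
                n_ungrouped = 1, seed = 13)
  )
  g <- rbp_group(extract_head_domains(fam$sequences))
  merged <- dplyr::left_join(tidy(g), fam$truth, by = "id")
  expect_equal(ari(merged$true_group, merged$group), 1)
  sub_key <- paste(merged$group, merged$subgroup)
  true_key <- paste(merged$true_group, merged$true_subgroup)
  expect_equal(ari(true_key, sub_key), 1)
  expect_equal(sum(merged$group == "ungrouped"), 1)
})
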