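#' Grouping thresholds for two-tier RBP classification
#'
#' Default thresholds: two head domains belong to the same group when they
#' share at least 50% identity across at least 90% of the head domain, and to
#' the same subgroup when every member pair shares at least 65% identity.
#'
#' @param group_min_identity,group_min_coverage,subgroup_min_identity
#'   Percentages in (0, 100].
#' @return An object of class `grouping_thresholds`.
#' @export
grouping_thresholds <- function(group_min_identity = 50,
                                group_min_coverage = 90,
                                subgroup_min_identity = 65) {
  if (!(subgroup_min_identity > 0 && subgroup_min_identity <= 100)) {
    abort("`subgroup_min_identity` must be in (0, 100].")
  }
  if (group_min_identity > subgroup_min_identity) {
    abort("`group_min_identity` must not exceed `subgroup_min_identity`.")
  }
  structure(
    list(
      group_min_identity = group_min_identity,
      group_min_coverage = group_min_coverage,
      subgroup_min_identity = subgroup_min_identity
    ),
    class = "grouping_thresholds"
  )
}

#' All-against-all identity/coverage matrix over head domains
#'
#' Computes each of the n(n-1)/2 global alignments once and mirrors it; the
#' diagonal is filled analytically (identity and coverage 100).
#'
#' @param heads A tibble of head domains (see [extract_head_domains()]) with
#'   unique `id` and `residues` columns.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `identity_matrix`: list with `ids`, `identity`
#'   and `coverage` (symmetric matrices with `ids` dimnames).
#' @export
build_identity_matrix <- function(heads, scheme = scoring_scheme()) {
  heads <- as_tibble(heads)
  if (nrow(heads) < 1L) abort("Need at least one head domain.")
  if (anyDuplicated(heads$id) > 0) abort("Head domain ids must be unique.")
  n <- nrow(heads)
  ident <- matrix(100, n, n, dimnames = list(heads$id, heads$id))
  cov <- matrix(100, n, n, dimnames = list(heads$id, heads$id))
  if (n > 1L) {
    for (j in 2:n) {
      res <- pairwise_identity_many(
        heads$residues[[j]], heads$residues[seq_len(j - 1L)], scheme
      )
      ident[j, seq_len(j - 1L)] <- res$identity_pct
      ident[seq_len(j - 1L), j] <- res$identity_pct
      cov[j, seq_len(j - 1L)] <- res$coverage_pct
      cov[seq_len(j - 1L), j] <- res$coverage_pct
    }
  }
  new_identity_matrix(heads$id, ident, cov)
}

new_identity_matrix <- function(ids, identity, coverage) {
  structure(
    list(ids = ids, identity = identity, coverage = coverage),
    class = "identity_matrix"
  )
}

#' Construct an identity matrix object from precomputed matrices
#'
#' @param ids Sequence ids (row/column order).
#' @param identity,coverage Symmetric matrices of percentages; the diagonal
#'   of `identity` must be 100.
#' @return An `identity_matrix`.
#' @export
identity_matrix <- function(ids, identity, coverage = NULL) {
  identity <- as.matrix(identity)
  if (is.null(coverage)) {
    coverage <- matrix(100, length(ids), length(ids))
  }
  coverage <- as.matrix(coverage)
  if (nrow(identity) != length(ids) || ncol(identity) != length(ids) ||
      nrow(coverage) != length(ids) || ncol(coverage) != length(ids)) {
    abort("Matrix dimensions must match the number of ids.")
  }
  if (!isTRUE(all.equal(identity, t(identity))) ||
      !isTRUE(all.equal(coverage, t(coverage)))) {
    abort("Identity and coverage matrices must be symmetric.")
  }
  if (!isTRUE(all.equal(unname(diag(identity)), rep(100, length(ids))))) {
    abort("Identity diagonal must be 100.")
  }
  dimnames(identity) <- list(ids, ids)
  dimnames(coverage) <- list(ids, ids)
  new_identity_matrix(ids, identity, coverage)
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("<identity_matrix> ", length(x$ids), " sequences\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long tibble of pairwise identities
#'
#' @param x An `identity_matrix`.
#' @param ... Unused.
#' @return One row per unordered pair: `id_a`, `id_b`, `identity_pct`,
#'   `coverage_pct`.
#' @method tidy identity_matrix
#' @export
tidy.identity_matrix <- function(x, ...) {
  n <- length(x$ids)
  if (n < 2L) {
    return(tibble(
      id_a = character(), id_b = character(),
      identity_pct = numeric(), coverage_pct = numeric()
    ))
  }
  idx <- which(upper.tri(x$identity), arr.ind = TRUE)
  tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    identity_pct = x$identity[idx],
    coverage_pct = x$coverage[idx]
  )
}

#' Assign sequences to groups by thresholded connected components
#'
#' An undirected edge joins two sequences when their identity is at least
#' `group_min_identity` and their pair-level coverage at least
#' `group_min_coverage` (both inclusive). Groups are the connected components
#' with two or more members (single linkage); singleton components are
#' flagged ungrouped, mirroring RBPs that fall within no group. A
#' complete-linkage variant is available via `linkage = "complete"`.
#'
#' @param m An `identity_matrix`.
#' @param thresholds A [grouping_thresholds()].
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"` (agglomerative complete linkage cut at the group identity
#'   threshold; coverage-failing pairs are treated as distance 100).
#' @return A tibble with columns `id`, `component` (integer; NA for
#'   ungrouped), `ungrouped`.
#' @export
assign_groups <- function(m, thresholds = grouping_thresholds(),
                          linkage = c("single", "complete")) {
  stopifnot(inherits(m, "identity_matrix"))
  linkage <- match.arg(linkage)
  edge_ok <- m$identity >= thresholds$group_min_identity &
    m$coverage >= thresholds$group_min_coverage
  diag(edge_ok) <- TRUE
  if (linkage == "single") {
    g <- igraph::graph_from_adjacency_matrix(edge_ok, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
  } else {
    d <- 100 - m$identity
    d[!(m$coverage >= thresholds$group_min_coverage)] <- 100
    diag(d) <- 0
    if (length(m$ids) == 1L) {
      comp <- stats::setNames(1L, m$ids)
    } else {
      hc <- stats::hclust(stats::as.dist(d), method = "complete")
      comp <- stats::cutree(hc, h = 100 - thresholds$group_min_identity)
    }
  }
  sizes <- table(comp)
  single <- as.integer(names(sizes)[sizes == 1L])
  tibble(
    id = m$ids,
    component = ifelse(comp %in% single, NA_integer_, as.integer(comp)),
    ungrouped = comp %in% single
  )
}

#' Split one group into subgroups by complete-linkage identity clustering
#'
#' Agglomerative complete-linkage clustering on distance `100 - identity`,
#' cut at `100 - subgroup_min_identity`, so that every pair within a
#' subgroup shares at least the subgroup identity threshold. Subgroup labels
#' are reported only when the group actually divides (two or more clusters);
#' an undivided group carries no letters.
#'
#' @param group_ids Ids of the members of one group.
#' @param m The `identity_matrix` containing them.
#' @param thresholds A [grouping_thresholds()].
#' @return A tibble `id`, `subgroup` (integer cluster index, or NA for all
#'   rows when the group is undivided).
#' @export
assign_subgroups <- function(group_ids, m, thresholds = grouping_thresholds()) {
  stopifnot(inherits(m, "identity_matrix"))
  if (!all(group_ids %in% m$ids)) {
    abort("`group_ids` must all be present in the identity matrix.")
  }
  if (length(group_ids) < 2L) {
    return(tibble(id = group_ids, subgroup = NA_integer_))
  }
  sub <- m$identity[group_ids, group_ids, drop = FALSE]
  d <- stats::as.dist(100 - sub)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, h = 100 - thresholds$subgroup_min_identity)
  if (length(unique(cl)) < 2L) {
    return(tibble(id = group_ids, subgroup = NA_integer_))
  }
  tibble(id = group_ids, subgroup = as.integer(cl))
}

#' Deterministic roman-numeral group and letter subgroup labels
#'
#' Groups are ordered by descending size, ties broken by the
#' lexicographically smallest member id, and labelled I, II, III, ...
#' Subgroups within a divided group are lettered A, B, ... by descending
#' size then smallest member id. Ungrouped sequences keep the label
#' `"ungrouped"`. Labels are invariant under permutation of the input.
#'
#' @param assignment Tibble from [assign_groups()], optionally carrying a
#'   `subgroup` column from [assign_subgroups()].
#' @return The assignment tibble with `group` (roman numeral or
#'   `"ungrouped"`) and `subgroup` (letter or NA) columns.
#' @export
name_groups <- function(assignment) {
  assignment <- as_tibble(assignment)
  if (!"subgroup" %in% names(assignment)) assignment$subgroup <- NA_integer_
  grouped <- assignment[!assignment$ungrouped, , drop = FALSE]
  out <- assignment
  out$group <- "ungrouped"
  out$subgroup_letter <- NA_character_
  if (nrow(grouped) > 0) {
    ord <- grouped |>
      group_by(.data$component) |>
      summarise(size = n(), min_id = min(.data$id), .groups = "drop") |>
      arrange(dplyr::desc(.data$size), .data$min_id)
    label_map <- stats::setNames(as.character(utils::as.roman(seq_len(nrow(ord)))), ord$component)
    out$group[!out$ungrouped] <- label_map[as.character(grouped$component)]
    for (comp in ord$component) {
      sel <- which(!out$ungrouped & out$component == comp)
      subs <- out$subgroup[sel]
      if (all(is.na(subs))) next
      sord <- tibble(id = out$id[sel], sub = subs) |>
        group_by(.data$sub) |>
        summarise(size = n(), min_id = min(.data$id), .groups = "drop") |>
        arrange(dplyr::desc(.data$size), .data$min_id)
      letter_map <- stats::setNames(LETTERS[seq_len(nrow(sord))], sord$sub)
      out$subgroup_letter[sel] <- letter_map[as.character(subs)]
    }
  }
  out |>
    select("id", "group", subgroup = "subgroup_letter", "component", "ungrouped")
}

#' Two-tier group/subgroup classification of RBP head domains
#'
#' Convenience wrapper: builds (or accepts) the identity matrix, forms
#' groups, splits each group into subgroups where it divides, and assigns
#' deterministic labels.
#'
#' @param x A tibble of head domains, or a prebuilt `identity_matrix`.
#' @param thresholds A [grouping_thresholds()].
#' @param scheme A [scoring_scheme()] (ignored when `x` is a matrix).
#' @param linkage Group-formation linkage, see [assign_groups()].
#' @return An object of class `rbp_grouping`: list with `assignment` (tibble
#'   `id`, `group`, `subgroup`, `ungrouped`), `matrix` (the
#'   `identity_matrix`) and `thresholds`.
#' @export
rbp_group <- function(x, thresholds = grouping_thresholds(),
                      scheme = scoring_scheme(), linkage = "single") {
  m <- if (inherits(x, "identity_matrix")) x else build_identity_matrix(x, scheme)
  raw <- assign_groups(m, thresholds, linkage = linkage)
  subs <- raw |>
    filter(!.data$ungrouped) |>
    group_by(.data$component) |>
    dplyr::group_map(~ assign_subgroups(.x$id, m, thresholds)) |>
    bind_rows()
  if (nrow(subs) > 0) {
    # make subgroup indices unique across components before labelling
    raw <- left_join(raw, subs, by = "id")
  } else {
    raw$subgroup <- NA_integer_
  }
  named <- name_groups(raw)
  structure(
    list(assignment = named, matrix = m, thresholds = thresholds),
    class = "rbp_grouping"
  )
}

#' @export
print.rbp_grouping <- function(x, ...) {
  a <- x$assignment
  cat(
    "<rbp_grouping> ", nrow(a), " sequences: ",
    length(unique(a$group[a$group != "ungrouped"])), " groups, ",
    sum(a$group == "ungrouped"), " ungrouped\n", sep = ""
  )
  invisible(x)
}

#' @method tidy rbp_grouping
#' @export
tidy.rbp_grouping <- function(x, ...) {
  x$assignment |> select("id", "group", "subgroup", "ungrouped")
}

#' @method glance rbp_grouping
#' @export
glance.rbp_grouping <- function(x, ...) {
  a <- x$assignment
  s <- summarize_groups(x)
  tibble(
    n_sequences = nrow(a),
    n_groups = length(unique(a$group[a$group != "ungrouped"])),
    n_ungrouped = sum(a$group == "ungrouped"),
    mean_within_identity = if (nrow(s) > 0) mean(s$mean_identity) else NA_real_
  )
}

#' Within-group identity statistics
#'
#' Min/mean/max pairwise identity over all within-group pairs, per group;
#' ungrouped sequences are excluded. Published Skunavirus groups typically
#' show within-group identities between roughly 82 and 95%, well above the
#' 50% floor.
#'
#' @param x An `rbp_grouping`, or an assignment tibble (then `m` is needed).
#' @param m The `identity_matrix` when `x` is a tibble.
#' @return A tibble `group`, `size`, `min_identity`, `mean_identity`,
#'   `max_identity`.
#' @export
summarize_groups <- function(x, m = NULL) {
  if (inherits(x, "rbp_grouping")) {
    assignment <- x$assignment
    m <- x$matrix
  } else {
    assignment <- as_tibble(x)
    if (is.null(m)) abort("Provide the identity matrix `m` with a raw assignment.")
  }
  grouped <- assignment |> filter(.data$group != "ungrouped")
  if (nrow(grouped) == 0) {
    return(tibble(
      group = character(), size = integer(),
      min_identity = numeric(), mean_identity = numeric(), max_identity = numeric()
    ))
  }
  grouped |>
    group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      vals <- m$identity[df$id, df$id, drop = FALSE][upper.tri(diag(nrow(df)))]
      if (length(vals) == 0) vals <- 100 # single member within pairs undefined; not reached
      tibble(
        size = nrow(df),
        min_identity = min(vals),
        mean_identity = mean(vals),
        max_identity = max(vals)
      )
    }) |>
    ungroup() |>
    arrange(.data$group)
}

#' Residue conservation at reference positions
#'
#' Aligns each head domain to a reference RBP and reports the residue found
#' in the column homologous to each queried 1-based reference position
#' (`"-"` where the head is gapped). A position is flagged conserved when
#' every head agrees with the reference residue — e.g. the sugar-binding
#' crevice residues Trp 144, Arg 256, Asp 234 and His 232 shared by group I
#' RBPs relative to the phage p2 RBP.
#'
#' @param heads Tibble of head domains (`id`, `residues`).
#' @param reference A one-row tibble or character scalar: the reference
#'   protein.
#' @param positions Integer vector of 1-based positions in the reference.
#' @param scheme A [scoring_scheme()].
#' @return A list with `table` (tibble `id`, `position`,
#'   `reference_residue`, `residue`, `agrees`) and `conserved` (tibble
#'   `position`, `reference_residue`, `conserved`).
#' @export
conserved_residue_report <- function(heads, reference, positions,
                                     scheme = scoring_scheme()) {
  heads <- as_tibble(heads)
  ref <- seq_input(reference, "reference")
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > nchar(ref$residues))) {
    abort("All positions must lie within the reference sequence.")
  }
  ref_chars <- strsplit(ref$residues, "")[[1]]
  rows <- purrr::map(seq_len(nrow(heads)), function(i) {
    aln <- align_global(heads[i, ], ref$residues, scheme)
    ga <- strsplit(aln$aligned_a, "")[[1]] # head
    gb <- strsplit(aln$aligned_b, "")[[1]] # reference
    ref_pos <- cumsum(gb != "-")
    col_of <- match(positions, ref_pos)
    tibble(
      id = heads$id[[i]],
      position = positions,
      reference_residue = ref_chars[positions],
      residue = ifelse(is.na(col_of), "-", ga[col_of])
    )
  })
  tab <- bind_rows(rows) |>
    mutate(agrees = .data$residue == .data$reference_residue)
  cons <- tab |>
    group_by(.data$position, .data$reference_residue) |>
    summarise(conserved = all(.data$agrees), .groups = "drop") |>
    arrange(.data$position)
  list(table = tab, conserved = cons)
}
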