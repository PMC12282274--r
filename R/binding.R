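#' Read a fluorescence plate table
#'
#' Expected columns: `rbp_id`, `strain_id` (empty for control wells),
#' `replicate`, `raw_fluorescence`, `od600` (empty for control wells),
#' `is_control`. Control wells hold the GFP-RBP fusion in buffer with no
#' cells; sample wells must carry both a strain and an OD600 reading.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_plate_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("Plate file not found: ", path))
  plate <- readr::read_tsv(
    path,
    col_types = readr::cols(
      rbp_id = readr::col_character(),
      strain_id = readr::col_character(),
      replicate = readr::col_integer(),
      raw_fluorescence = readr::col_double(),
      od600 = readr::col_double(),
      is_control = readr::col_logical()
    )
  )
  validate_plate(plate)
}

#' Validate a plate measurement tibble
#'
#' @param plate Tibble with the plate TSV schema.
#' @return The validated tibble.
#' @export
validate_plate <- function(plate) {
  plate <- as_tibble(plate)
  need <- c("rbp_id", "strain_id", "replicate", "raw_fluorescence",
            "od600", "is_control")
  if (!all(need %in% names(plate))) {
    abort(paste0("Plate data needs columns: ", paste(need, collapse = ", ")))
  }
  ctrl <- plate$is_control
  if (any(!ctrl & (is.na(plate$strain_id) | is.na(plate$od600)))) {
    bad <- plate$rbp_id[!ctrl & (is.na(plate$strain_id) | is.na(plate$od600))]
    abort(paste0("Sample wells missing strain_id or od600 for RBP: ",
                 paste(unique(utils::head(bad, 5)), collapse = ", ")))
  }
  if (any(!ctrl & plate$od600 <= 0)) abort("Sample wells must have od600 > 0.")
  if (any(plate$raw_fluorescence < 0, na.rm = TRUE)) {
    abort("Raw fluorescence must be >= 0.")
  }
  plate
}

#' Normalize a plate to fluorescence units (FU)
#'
#' For each sample well, `fu = (raw - control_mean) / od600`, where
#' `control_mean` is the mean raw fluorescence of the no-cell control wells
#' of the same RBP. Negative values (fluorescence deficits below the
#' control, i.e. noise) are clamped to 0 and flagged.
#'
#' @param plate A validated plate tibble.
#' @return A tibble `rbp_id`, `strain_id`, `replicate`, `fu`, `clamped`.
#' @export
normalize_plate <- function(plate) {
  plate <- validate_plate(plate)
  controls <- plate |>
    filter(.data$is_control) |>
    group_by(.data$rbp_id) |>
    summarise(control_mean = mean(.data$raw_fluorescence), .groups = "drop")
  samples <- plate |> filter(!.data$is_control)
  missing <- setdiff(unique(samples$rbp_id), controls$rbp_id)
  if (length(missing) > 0) {
    abort(paste0("No control wells for RBP(s): ",
                 paste(missing, collapse = ", ")))
  }
  samples |>
    left_join(controls, by = "rbp_id") |>
    mutate(
      fu_raw = (.data$raw_fluorescence - .data$control_mean) / .data$od600,
      clamped = .data$fu_raw < 0,
      fu = pmax(.data$fu_raw, 0)
    ) |>
    select("rbp_id", "strain_id", "replicate", "fu", "clamped")
}

#' Normalize a single well
#'
#' Scalar form of [normalize_plate()] for one measurement.
#'
#' @param raw_fluorescence Raw well fluorescence.
#' @param control_mean Mean raw fluorescence of the RBP's control wells.
#' @param od600 Optical density of the sample well (> 0).
#' @return A list with `fu` and `clamped`.
#' @export
normalize_fu <- function(raw_fluorescence, control_mean, od600) {
  if (is.na(od600) || od600 <= 0) abort("od600 must be > 0.")
  fu <- (raw_fluorescence - control_mean) / od600
  list(fu = max(fu, 0), clamped = fu < 0)
}

#' Relative binding-affinity scores for one RBP
#'
#' The optimal host is the strain with the highest mean FU (ties broken by
#' smallest strain id); each strain scores its mean FU as a percentage of
#' the optimal host's, so the optimal host scores 100. When no strain shows
#' any binding all scores are undefined and flagged.
#'
#' @param fus Normalized FU tibble (see [normalize_plate()]).
#' @param rbp One RBP id present in `fus`.
#' @return A tibble `rbp_id`, `strain_id`, `mean_fu`, `sd_fu`, `n`,
#'   `relative_score_pct`, `optimal_host`, `no_binding`.
#' @export
relative_binding_score <- function(fus, rbp) {
  fus <- as_tibble(fus)
  x <- fus |> filter(.data$rbp_id == rbp)
  if (nrow(x) == 0) abort(paste0("No FU rows for RBP: ", rbp))
  s <- x |>
    group_by(.data$rbp_id, .data$strain_id) |>
    summarise(
      mean_fu = mean(.data$fu),
      sd_fu = stats::sd(.data$fu),
      n = n(),
      .groups = "drop"
    ) |>
    arrange(.data$strain_id)
  if (all(s$mean_fu == 0)) {
    return(s |> mutate(
      relative_score_pct = NA_real_,
      optimal_host = FALSE,
      no_binding = TRUE
    ))
  }
  best <- s$strain_id[order(-s$mean_fu, s$strain_id)][1]
  best_mean <- s$mean_fu[s$strain_id == best]
  s |> mutate(
    relative_score_pct = 100 * .data$mean_fu / best_mean,
    optimal_host = .data$strain_id == best,
    no_binding = FALSE
  )
}

#' Welch's t-test between two strains for one RBP
#'
#' Two-sided unequal-variance t-test on replicate FU values. When both
#' strains have zero variance the test statistic is undefined: p is reported
#' as 1 when the means are equal and 0 otherwise, with a `zero_variance`
#' flag.
#'
#' @param fus Normalized FU tibble.
#' @param rbp RBP id.
#' @param strain_a,strain_b Strain ids to compare.
#' @return A tibble `rbp_id`, `strain_a`, `strain_b`, `statistic`, `df`,
#'   `p_value`, `zero_variance`.
#' @export
compare_strains <- function(fus, rbp, strain_a, strain_b) {
  fus <- as_tibble(fus)
  xa <- fus$fu[fus$rbp_id == rbp & fus$strain_id == strain_a]
  xb <- fus$fu[fus$rbp_id == rbp & fus$strain_id == strain_b]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("Welch's test needs at least 2 replicates per strain.")
  }
  degenerate <- function() {
    tibble(
      rbp_id = rbp, strain_a = strain_a, strain_b = strain_b,
      statistic = if (isTRUE(all.equal(mean(xa), mean(xb)))) 0 else Inf,
      df = NA_real_,
      p_value = if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0,
      zero_variance = TRUE
    )
  }
  if (stats::var(xa) == 0 && stats::var(xb) == 0) return(degenerate())
  # t.test also refuses data whose spread is negligible against its mean
  tt <- tryCatch(
    stats::t.test(xa, xb, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(tt)) return(degenerate())
  tibble(
    rbp_id = rbp, strain_a = strain_a, strain_b = strain_b,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    zero_variance = FALSE
  )
}

#' Assemble the full binding matrix
#'
#' Per (RBP, strain): mean/sd FU, replicate count, relative binding-affinity
#' score and optimal-host flag; plus all pairwise strain comparisons per RBP
#' (Welch's test at significance level `alpha`).
#'
#' @param fus Normalized FU tibble.
#' @param alpha Significance level used to flag significant pairs (default
#'   0.01).
#' @return An object of class `binding_matrix`: list with `scores` (long
#'   tibble), `p_values` (pairwise comparisons) and `alpha`.
#' @export
binding_matrix <- function(fus, alpha = 0.01) {
  fus <- as_tibble(fus)
  if (nrow(fus) == 0) abort("No normalized FU data.")
  rbps <- sort(unique(fus$rbp_id))
  scores <- purrr::map(rbps, ~ relative_binding_score(fus, .x)) |> bind_rows()
  pvals <- purrr::map(rbps, function(r) {
    strains <- sort(unique(fus$strain_id[fus$rbp_id == r]))
    reps_ok <- purrr::map_int(strains, ~ sum(fus$rbp_id == r & fus$strain_id == .x)) >= 2
    strains <- strains[reps_ok]
    if (length(strains) < 2) return(NULL)
    pairs <- utils::combn(strains, 2, simplify = FALSE)
    purrr::map(pairs, ~ compare_strains(fus, r, .x[1], .x[2])) |> bind_rows()
  }) |> bind_rows()
  if (nrow(pvals) > 0) pvals$significant <- pvals$p_value < alpha
  structure(
    list(scores = scores, p_values = pvals, alpha = alpha),
    class = "binding_matrix"
  )
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(
    "<binding_matrix> ", length(unique(x$scores$rbp_id)), " RBP(s) x ",
    length(unique(x$scores$strain_id)), " strain(s); alpha = ", x$alpha,
    "\n", sep = ""
  )
  invisible(x)
}

#' @method tidy binding_matrix
#' @export
tidy.binding_matrix <- function(x, ...) x$scores

#' @method glance binding_matrix
#' @export
glance.binding_matrix <- function(x, ...) {
  tibble(
    n_rbps = length(unique(x$scores$rbp_id)),
    n_strains = length(unique(x$scores$strain_id)),
    n_comparisons = nrow(x$p_values),
    n_significant = if (nrow(x$p_values) > 0) sum(x$p_values$significant) else 0L,
    alpha = x$alpha
  )
}

#' Wide matrix of relative binding scores
#'
#' @param x A `binding_matrix`.
#' @return A tibble: one row per RBP, one column per strain, values are
#'   relative binding-affinity scores.
#' @export
binding_score_wide <- function(x) {
  stopifnot(inherits(x, "binding_matrix"))
  x$scores |>
    select("rbp_id", "strain_id", "relative_score_pct") |>
    tidyr::pivot_wider(names_from = "strain_id",
                       values_from = "relative_score_pct")
}
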