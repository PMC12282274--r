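#' Read-filter parameters
#'
#' The two published filter presets: genome mode (relative abundance) keeps
#' reads with at least 80% identity aligned over at least 50% of the read;
#' contig mode (RPKM over representative RBP genes) uses 86% identity, 95%
#' aligned fraction, and additionally requires at least 55% of the reference
#' to be covered by kept reads.
#'
#' @param min_identity Minimum percent identity over the aligned region
#'   (inclusive).
#' @param min_aligned_pct Minimum aligned residues as percent of read length
#'   (inclusive).
#' @param min_covered_fraction Optional minimum percent of the reference
#'   covered by at least one kept read; references below it report RPKM 0.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_identity, min_aligned_pct,
                          min_covered_fraction = NA_real_) {
  vals <- c(min_identity, min_aligned_pct)
  if (any(vals < 0 | vals > 100)) abort("Filter thresholds must be in [0, 100].")
  if (!is.na(min_covered_fraction) &&
      (min_covered_fraction < 0 || min_covered_fraction > 100)) {
    abort("`min_covered_fraction` must be in [0, 100].")
  }
  structure(
    list(
      min_identity = min_identity,
      min_aligned_pct = min_aligned_pct,
      min_covered_fraction = min_covered_fraction
    ),
    class = "filter_params"
  )
}

#' @rdname filter_params
#' @export
genome_mode_filters <- function() filter_params(80, 50)

#' @rdname filter_params
#' @export
contig_mode_filters <- function() filter_params(86, 95, 55)

#' Read alignment records from a SAM file
#'
#' Accepts plain (headerful) SAM. One primary alignment per read is assumed;
#' secondary and supplementary records are dropped on input. The aligned
#' length is the number of read bases in alignment operations (soft/hard
#' clips excluded), and percent identity is derived from the standard
#' edit-distance tag as `100 * (aligned_length - NM) / aligned_length`;
#' mapped records lacking the tag are rejected.
#'
#' @param path Path to a SAM file.
#' @return A tibble: `read_id`, `mapped`, `ref_id`, `ref_start`,
#'   `aligned_length`, `read_length`, `percent_identity`.
#' @export
read_sam_records <- function(path) {
  if (!file.exists(path)) abort(paste0("SAM file not found: ", path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- x$flag
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep <- !secondary
  mapped <- bitwAnd(flag[keep], 4L) == 0L
  cigar <- x$cigar[keep]
  read_length <- ifelse(
    is.na(cigar),
    Biostrings::width(x$seq[keep]),
    GenomicAlignments::cigarWidthAlongQuerySpace(
      ifelse(is.na(cigar), "1M", cigar), after.soft.clipping = FALSE
    )
  )
  aligned_length <- ifelse(
    mapped,
    GenomicAlignments::cigarWidthAlongQuerySpace(
      ifelse(is.na(cigar), "1M", cigar), after.soft.clipping = TRUE
    ),
    NA_integer_
  )
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  nm <- nm[keep]
  if (any(mapped & is.na(nm))) {
    abort(paste0(
      "Mapped records without an NM edit-distance tag: ",
      paste(utils::head(x$qname[keep][mapped & is.na(nm)], 5), collapse = ", "),
      ". Percent identity cannot be derived."
    ))
  }
  records <- tibble(
    read_id = x$qname[keep],
    mapped = mapped,
    ref_id = ifelse(mapped, as.character(x$rname[keep]), NA_character_),
    ref_start = ifelse(mapped, x$pos[keep], NA_integer_),
    aligned_length = as.integer(aligned_length),
    read_length = as.integer(read_length),
    percent_identity = ifelse(
      mapped, 100 * (aligned_length - nm) / aligned_length, NA_real_
    )
  )
  validate_alignment_records(records)
}

#' Validate a tibble of alignment records
#'
#' @param records Tibble with columns `read_id`, `mapped`, `ref_id`,
#'   `ref_start`, `aligned_length`, `read_length`, `percent_identity`.
#' @return The validated tibble.
#' @export
validate_alignment_records <- function(records) {
  records <- as_tibble(records)
  need <- c("read_id", "mapped", "ref_id", "ref_start",
            "aligned_length", "read_length", "percent_identity")
  if (!all(need %in% names(records))) {
    abort(paste0("Records need columns: ", paste(need, collapse = ", ")))
  }
  mp <- records$mapped
  if (any(mp & (is.na(records$ref_start) | records$ref_start < 1))) {
    abort("Mapped records must have ref_start >= 1.")
  }
  if (any(mp & (records$aligned_length <= 0 |
                records$aligned_length > records$read_length))) {
    abort("Mapped records must satisfy 0 < aligned_length <= read_length.")
  }
  if (any(mp & (records$percent_identity < 0 | records$percent_identity > 100))) {
    abort("percent_identity must be in [0, 100].")
  }
  records
}

#' Reference table constructor
#'
#' @param ref_id Unique reference ids.
#' @param length_bp Positive reference lengths.
#' @param category Category label per reference (phage genus or RBP group).
#' @return A tibble `ref_id`, `length_bp`, `category`.
#' @export
reference_set <- function(ref_id, length_bp, category) {
  if (anyDuplicated(ref_id) > 0) abort("Reference ids must be unique.")
  if (any(length_bp <= 0)) abort("Reference lengths must be positive.")
  tibble(ref_id = ref_id, length_bp = as.numeric(length_bp),
         category = category)
}

#' Apply identity and aligned-fraction filters to alignment records
#'
#' Keeps mapped records with `percent_identity >= min_identity` and
#' `100 * aligned_length / read_length >= min_aligned_pct` (both inclusive).
#' Unmapped and failing records are tallied separately.
#'
#' @param records Alignment record tibble.
#' @param params A [filter_params()].
#' @return A list: `kept` (tibble of passing records), `n_total`, `n_kept`,
#'   `n_unmapped`, `n_failed` (mapped but failing a filter).
#' @export
filter_records <- function(records, params) {
  records <- validate_alignment_records(records)
  stopifnot(inherits(params, "filter_params"))
  mapped <- records$mapped
  frac <- 100 * records$aligned_length / records$read_length
  pass <- mapped &
    records$percent_identity >= params$min_identity &
    frac >= params$min_aligned_pct
  pass[is.na(pass)] <- FALSE
  list(
    kept = records[pass, , drop = FALSE],
    n_total = nrow(records),
    n_kept = sum(pass),
    n_unmapped = sum(!mapped),
    n_failed = sum(mapped & !pass)
  )
}

#' Fraction of a reference covered by kept reads
#'
#' Percent of reference positions overlapped by at least one kept record,
#' by interval union (duplicate reads do not inflate it).
#'
#' @param kept Tibble of kept (mapped) records.
#' @param ref One reference id.
#' @param refs A [reference_set()] tibble.
#' @return Percent in [0, 100].
#' @export
covered_fraction <- function(kept, ref, refs) {
  if (!ref %in% refs$ref_id) abort(paste0("Unknown reference id: ", ref))
  len <- refs$length_bp[refs$ref_id == ref]
  r <- kept[!is.na(kept$ref_id) & kept$ref_id == ref, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  ir <- IRanges::IRanges(
    start = r$ref_start,
    end = pmin(r$ref_start + r$aligned_length - 1, len)
  )
  100 * sum(IRanges::width(IRanges::reduce(ir))) / len
}

#' Relative abundance per category, with an unmapped row
#'
#' Applies the filters, then weights each category by the sum over its
#' references of kept reads divided by reference length, rescales the
#' category percentages by the mapped-and-kept fraction, and reports the
#' remainder (unmapped plus filter-failing reads) as `unmapped`, so the
#' table always sums to 100.
#'
#' @param records Alignment record tibble.
#' @param refs A [reference_set()] tibble.
#' @param params A [filter_params()]; defaults to the genome-mode preset.
#' @return A tibble `category`, `relative_abundance_pct` (ending with the
#'   `unmapped` row), with attribute `per_reference` (tibble `ref_id`,
#'   `category`, `filtered_read_count`, `covered_fraction_pct`).
#' @export
relative_abundance <- function(records, refs, params = genome_mode_filters()) {
  fl <- filter_records(records, params)
  kept <- fl$kept
  unknown <- setdiff(unique(kept$ref_id), refs$ref_id)
  if (length(unknown) > 0) {
    abort(paste0("Records map to unknown reference(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  per_ref <- refs |>
    left_join(
      kept |> dplyr::count(.data$ref_id, name = "filtered_read_count"),
      by = "ref_id"
    ) |>
    mutate(filtered_read_count = dplyr::coalesce(.data$filtered_read_count, 0L)) |>
    mutate(covered_fraction_pct = purrr::map_dbl(
      .data$ref_id, ~ covered_fraction(kept, .x, refs)
    ))
  weights <- per_ref |>
    group_by(.data$category) |>
    summarise(weight = sum(.data$filtered_read_count / .data$length_bp),
              .groups = "drop")
  total_w <- sum(weights$weight)
  mapped_frac <- if (fl$n_total == 0) 0 else fl$n_kept / fl$n_total
  weights$relative_abundance_pct <- if (total_w > 0) {
    100 * mapped_frac * weights$weight / total_w
  } else {
    rep(0, nrow(weights))
  }
  # unmapped row is the exact complement so the column sums to 100
  out <- bind_rows(
    weights |> select("category", "relative_abundance_pct"),
    tibble(
      category = "unmapped",
      relative_abundance_pct = 100 - sum(weights$relative_abundance_pct)
    )
  )
  attr(out, "per_reference") <- per_ref |>
    select("ref_id", "category", "filtered_read_count", "covered_fraction_pct")
  attr(out, "filter_tally") <- fl[c("n_total", "n_kept", "n_unmapped", "n_failed")]
  out
}

#' RPKM per reference
#'
#' Reads per kilobase of reference per million kept reads:
#' `RPKM = kept_reads / ((length_bp / 1000) * (total_kept / 1e6))`.
#' References whose covered fraction falls below `min_covered_fraction`
#' report RPKM 0 and are flagged `below_covered_threshold`.
#'
#' @param records Alignment record tibble.
#' @param refs A [reference_set()] tibble.
#' @param params A [filter_params()]; defaults to the contig-mode preset.
#' @return A tibble `ref_id`, `category`, `filtered_read_count`,
#'   `covered_fraction_pct`, `rpkm`, `below_covered_threshold`.
#' @export
rpkm <- function(records, refs, params = contig_mode_filters()) {
  fl <- filter_records(records, params)
  kept <- fl$kept
  unknown <- setdiff(unique(kept$ref_id), refs$ref_id)
  if (length(unknown) > 0) {
    abort(paste0("Records map to unknown reference(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  total_kept <- fl$n_kept
  if (total_kept == 0) warn("No reads pass the filters; all RPKM values are 0.")
  out <- refs |>
    left_join(
      kept |> dplyr::count(.data$ref_id, name = "filtered_read_count"),
      by = "ref_id"
    ) |>
    mutate(filtered_read_count = dplyr::coalesce(.data$filtered_read_count, 0L)) |>
    mutate(
      covered_fraction_pct = purrr::map_dbl(
        .data$ref_id, ~ covered_fraction(kept, .x, refs)
      ),
      rpkm = if (total_kept > 0) {
        .data$filtered_read_count / ((.data$length_bp / 1000) * (total_kept / 1e6))
      } else {
        0
      },
      below_covered_threshold = !is.na(params$min_covered_fraction) &
        .data$covered_fraction_pct < params$min_covered_fraction
    )
  out$rpkm[out$below_covered_threshold] <- 0
  out |>
    select("ref_id", "category", "filtered_read_count",
           "covered_fraction_pct", "rpkm", "below_covered_threshold")
}
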