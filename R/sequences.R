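#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join group_by ungroup
#'   summarise bind_rows row_number n across all_of distinct rename pull
NULL

# the 20 standard residues plus the ambiguity letter 'X'
AA_ALPHABET_21 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

#' Validate a tibble of protein sequences
#'
#' Checks that ids are unique and non-empty and that every residue string is
#' non-empty, uppercase, and drawn from the 20 standard amino-acid letters
#' plus `X`.
#'
#' @param seqs A data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @return The input as a tibble with a `description` column guaranteed,
#'   invisibly usable in pipes.
#' @export
validate_protein_sequences <- function(seqs) {
  seqs <- as_tibble(seqs)
  if (!all(c("id", "residues") %in% names(seqs))) {
    abort("`seqs` must have columns `id` and `residues`.")
  }
  if (!"description" %in% names(seqs)) seqs$description <- ""
  if (anyDuplicated(seqs$id) > 0) {
    abort("Sequence ids must be unique.")
  }
  if (any(is.na(seqs$residues) | nchar(seqs$residues) == 0L)) {
    abort("Every sequence must have non-empty residues.")
  }
  bad <- stringr::str_detect(
    seqs$residues,
    paste0("[^", paste(AA_ALPHABET_21, collapse = ""), "]")
  )
  if (any(bad)) {
    abort(paste0(
      "Residues outside the 21-letter amino-acid alphabet in: ",
      paste(utils::head(seqs$id[bad], 5), collapse = ", ")
    ))
  }
  seqs[, c("id", "description", "residues")]
}

#' Read protein sequences from a FASTA file
#'
#' The sequence id is the first whitespace-delimited token of the header;
#' the remainder is kept as the description. Residues are uppercased and
#' validated against the 21-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Could not parse FASTA file ", path, ": ", conditionMessage(e)))
  )
  if (length(ss) == 0L) abort(paste0("FASTA file is empty: ", path))
  headers <- names(ss)
  ids <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  validate_protein_sequences(tibble(
    id = ids,
    description = desc,
    residues = unname(toupper(as.character(ss)))
  ))
}

#' Write protein sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns. The header is `id` followed by the
#' description when present.
#'
#' @param seqs A tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  seqs <- validate_protein_sequences(seqs)
  ss <- Biostrings::BStringSet(seqs$residues)
  names(ss) <- ifelse(
    nchar(seqs$description) > 0,
    paste(seqs$id, seqs$description),
    seqs$id
  )
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Extract the C-terminal head domain of each RBP
#'
#' Skunavirus RBPs carry a conserved N-terminal shoulder/neck region and a
#' variable C-terminal head domain of roughly 110 residues that contacts the
#' host cell-wall polysaccharide. This returns the last `head_length`
#' residues of each sequence. Sequences shorter than `head_length` are
#' returned whole with a warning and flagged `truncated`.
#'
#' @param seqs A tibble with columns `id`, `residues` (see
#'   [read_protein_fasta()]).
#' @param head_length Number of C-terminal residues to keep (default 110).
#' @return A tibble with columns `id` (the parent id), `residues` (the head
#'   window), `offset` (0-based start of the window within the parent) and
#'   `truncated`.
#' @export
extract_head_domains <- function(seqs, head_length = 110L) {
  seqs <- validate_protein_sequences(seqs)
  if (length(head_length) != 1L || is.na(head_length) || head_length < 1) {
    abort("`head_length` must be a single positive integer.")
  }
  len <- nchar(seqs$residues)
  keep <- pmin(len, as.integer(head_length))
  offset <- len - keep
  short <- len < head_length
  if (any(short)) {
    warn(paste0(
      sum(short), " sequence(s) shorter than head_length = ", head_length,
      " returned whole: ", paste(utils::head(seqs$id[short], 5), collapse = ", ")
    ))
  }
  tibble(
    id = seqs$id,
    residues = substr(seqs$residues, offset + 1L, len),
    offset = offset,
    truncated = short
  )
}
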