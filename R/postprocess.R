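#' Call intrinsically disordered regions
#'
#' Per-residue disorder propensities are binarized at `threshold` (binary
#' flags are used as-is); maximal runs of at least `min_run` consecutive
#' disordered residues are reported as IDRs. The default minimum of 29
#' residues matches the shortest protein the predictor set contains.
#'
#' @param profiles Tibble with `accession` and list-column `disorder`
#'   (numeric 0-1 propensities or 0/1 flags, one value per residue).
#' @param threshold Binarization threshold for propensities.
#' @param min_run Minimum run length, in residues.
#' @param protein_length Optional named vector of protein lengths to validate
#'   profile lengths against.
#' @return Tibble with `accession`, `start`, `end` (0-based half-open
#'   residue indices) and `length`; zero rows when no region qualifies.
#' @export
call_idrs <- function(profiles, threshold = 0.5, min_run = 29L,
                      protein_length = NULL) {
  stopifnot(all(c("accession", "disorder") %in% names(profiles)))
  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles$disorder[[i]]
    if (!length(p)) abort("empty disorder profile")
    if (!is.null(protein_length)) {
      want <- protein_length[[profiles$accession[i]]]
      if (!is.null(want) && !is.na(want) && length(p) != want) {
        abort(paste0("disorder profile length mismatch for ",
                     profiles$accession[i]))
      }
    }
    flags <- p >= threshold
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) next
    out[[i]] <- tibble(accession = profiles$accession[i],
                       start = starts[keep], end = ends[keep])
  }
  res <- bind_rows(out)
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(accession = character(0), start = integer(0),
                  end = integer(0), length = integer(0)))
  }
  res %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           length = .data$end - .data$start) %>%
    arrange(.data$accession, .data$start)
}

#' Filter short linear motifs by disorder
#'
#' A SLiM match is retained only when every residue of its span is predicted
#' disordered; motifs with at least one ordered residue are filtered out.
#'
#' @param slims Tibble with `accession`, `motif`, `start`, `end`
#'   (0-based half-open residue indices).
#' @param profiles Disorder profiles as in [call_idrs()].
#' @param threshold Binarization threshold for propensities.
#' @return Retained rows of `slims`.
#' @export
filter_slims <- function(slims, profiles, threshold = 0.5) {
  if (nrow(slims) == 0L) return(slims)
  if (any(slims$end <= slims$start)) abort("SLiM span with end <= start")
  prof <- setNames(profiles$disorder, profiles$accession)
  keep <- logical(nrow(slims))
  for (i in seq_len(nrow(slims))) {
    p <- prof[[slims$accession[i]]]
    if (is.null(p)) abort(paste0("no disorder profile for ", slims$accession[i]))
    if (slims$start[i] < 0L || slims$end[i] > length(p)) {
      abort("SLiM span outside protein")
    }
    keep[i] <- all(p[(slims$start[i] + 1L):slims$end[i]] >= threshold)
  }
  slims[keep, , drop = FALSE]
}

#' Bin a pLDDT confidence score
#'
#' Bins: `very_high` (> 90), `high` (70, 90], `medium` (50, 70],
#' `very_low` (<= 50). Boundary values fall in the lower bin; the medium bin
#' is a package convention for the unnamed interval between the quoted
#' high-confidence band and the < 50 disorder-prone band.
#'
#' @param plddt Numeric vector in [0, 100].
#' @return Character vector of bins.
#' @export
bin_plddt <- function(plddt) {
  if (any(is.na(plddt)) || any(plddt < 0) || any(plddt > 100)) {
    abort("pLDDT must lie in [0, 100]")
  }
  case_when(
    plddt > 90 ~ "very_high",
    plddt > 70 ~ "high",
    plddt > 50 ~ "medium",
    TRUE ~ "very_low"
  )
}

#' Route a protein to a structure predictor
#'
#' Proteins whose multiple sequence alignment holds fewer than 30 sequences
#' are routed to a single-sequence predictor (OmegaFold-like); deeper
#' alignments use an MSA-based predictor (AlphaFold-like).
#'
#' @param msa_depth Integer vector of MSA sequence counts (query included,
#'   so always >= 1).
#' @return Character vector: `"omegafold-like"` or `"alphafold-like"`.
#' @export
route_predictor <- function(msa_depth) {
  if (any(msa_depth < 1)) abort("MSA depth must be >= 1 (the query counts)")
  if_else(msa_depth < 30, "omegafold-like", "alphafold-like")
}

#' Per-class prevalence of proteins with at least one IDR
#'
#' @param proteins Accessioned protein table.
#' @param idrs IDR table from [call_idrs()].
#' @return Tibble with `class`, `n_proteins`, `n_with_idr`, `fraction`;
#'   classes with no proteins are absent.
#' @export
idr_prevalence <- function(proteins, idrs) {
  with_idr <- unique(idrs$accession)
  tibble(class = proteins$class, accession = proteins$accession) %>%
    group_by(.data$class) %>%
    summarise(n_proteins = n(),
              n_with_idr = sum(.data$accession %in% with_idr),
              .groups = "drop") %>%
    mutate(fraction = .data$n_with_idr / .data$n_proteins)
}

#' Read per-residue disorder profiles from TSV
#'
#' Expects columns `accession` and `disorder`, the latter a comma-separated
#' string of per-residue scores (or 0/1 flags).
#'
#' @param path TSV path.
#' @return Tibble with `accession` and list-column `disorder`.
#' @export
read_disorder_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  tibble(accession = x$accession,
         disorder = lapply(strsplit(x$disorder, ",", fixed = TRUE), as.numeric))
}

#' Read SLiM matches from TSV
#'
#' Input spans are 1-based inclusive and converted to the internal 0-based
#' half-open convention.
#'
#' @param path TSV with columns `accession`, `motif`, `start`, `end`.
#' @return Tibble with internal coordinates.
#' @export
read_slim_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  tibble(accession = x$accession, motif = x$motif,
         start = as.integer(x$start) - 1L, end = as.integer(x$end))
}
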