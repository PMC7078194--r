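#' Quantify one peptide from its MRM transitions
#'
#' Endogenous amount = (sum of light intensities / sum of heavy intensities)
#' x spiked amount of the heavy synthetic peptide. Intensities are summed
#' across transitions before taking the ratio.
#'
#' @param records Data frame with columns `light_intensity` and
#'   `heavy_intensity`, one row per transition of one peptide.
#' @param spike Spiked heavy-peptide amount in fmol (> 0).
#' @return One-row tibble: `endogenous_fmol`, `light_sum`, `heavy_sum`,
#'   `ok` (FALSE when the heavy sum is zero and the ratio is undefined).
#' @export
quantify_peptide <- function(records, spike) {
  records <- tibble::as_tibble(records)
  stopifnot(
    nrow(records) >= 1, spike > 0,
    all(records$light_intensity >= 0), all(records$heavy_intensity >= 0)
  )
  ls <- sum(records$light_intensity)
  hs <- sum(records$heavy_intensity)
  if (hs == 0) {
    warning("heavy intensity sum is zero; ratio undefined")
    return(tibble::tibble(endogenous_fmol = NA_real_, light_sum = ls, heavy_sum = hs, ok = FALSE))
  }
  tibble::tibble(endogenous_fmol = ls / hs * spike, light_sum = ls, heavy_sum = hs, ok = TRUE)
}

#' Quantify every peptide in a transition table
#'
#' Vectorized form of [quantify_peptide()] over the canonical transition CSV
#' schema (`protein`, `peptide`, `transition`, `light_intensity`,
#' `heavy_intensity`, `spike_fmol`, plus optional `sample` and `replicate`).
#' Peptides with a zero heavy sum are dropped with a warning.
#'
#' @param transitions Transition-level data frame.
#' @return Tibble with one row per protein x peptide (x sample x replicate)
#'   and column `endogenous_fmol`.
#' @export
quantify_peptides <- function(transitions) {
  transitions <- tibble::as_tibble(transitions)
  keys <- intersect(
    c("protein", "peptide", "sample", "replicate", "spike_fmol"),
    names(transitions)
  )
  out <- transitions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      light_sum = sum(.data$light_intensity),
      heavy_sum = sum(.data$heavy_intensity),
      .groups = "drop"
    ) |>
    dplyr::mutate(endogenous_fmol = .data$light_sum / .data$heavy_sum * .data$spike_fmol)
  bad <- out$heavy_sum == 0
  if (any(bad)) {
    warning(sum(bad), " peptide(s) with zero heavy sum excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Aggregate peptide amounts to a protein estimate
#'
#' Mean and sample standard deviation across peptide x replicate estimates.
#' A single estimate yields s.d. 0 by convention and is flagged low-evidence.
#'
#' @param peptides Data frame with column `endogenous_fmol` (and optionally
#'   `protein` to aggregate several proteins at once).
#' @return Tibble: `mean_fmol`, `sd_fmol`, `n`, `low_evidence`.
#' @export
aggregate_protein <- function(peptides) {
  peptides <- tibble::as_tibble(peptides)
  stopifnot(nrow(peptides) >= 1)
  grp <- intersect(c("protein", "sample"), names(peptides))
  peptides |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_fmol = mean(.data$endogenous_fmol),
      sd_fmol = ifelse(dplyr::n() > 1, stats::sd(.data$endogenous_fmol), 0),
      n = dplyr::n(),
      low_evidence = dplyr::n() < 2,
      .groups = "drop"
    )
}

AVOGADRO <- 6.02214076e23

#' Convert abundance per microgram of lysate to copies per cell
#'
#' `copies = abundance_fmol_per_ug * 1e-15 mol/fmol * protein_per_cell_ug *
#' Avogadro`.
#'
#' @param abundance_fmol_per_ug Protein abundance (fmol per microgram lysate),
#'   >= 0.
#' @param protein_per_cell_ug Total protein per cell in micrograms (> 0),
#'   e.g. 2.5e-4.
#' @return Copies per cell.
#' @export
copies_per_cell <- function(abundance_fmol_per_ug, protein_per_cell_ug) {
  stopifnot(all(abundance_fmol_per_ug >= 0), protein_per_cell_ug > 0)
  abundance_fmol_per_ug * 1e-15 * protein_per_cell_ug * AVOGADRO
}

#' Enzyme panel summary: z-scores and the PPAT/GLS1 ratio
#'
#' Row-standardizes a protein x sample abundance matrix (z-scores across
#' samples, sample s.d. by default) and computes the per-sample PPAT/GLS1
#' abundance ratio, the marker of glutamine-nitrogen fate balance.
#'
#' @param panel Data frame with column `protein` and one numeric column per
#'   sample.
#' @param sd_type `"sample"` (ddof 1, default) or `"population"`.
#' @return List: `zscores` (long tibble `protein`, `sample`, `z`, `flagged`),
#'   `ratio` (tibble `sample`, `ppat_gls1_ratio`) when both enzymes are
#'   present, else `NULL`.
#' @export
panel_summary <- function(panel, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  panel <- tibble::as_tibble(panel)
  stopifnot("protein" %in% names(panel), ncol(panel) >= 2)
  long <- tidyr::pivot_longer(panel, -"protein",
    names_to = "sample", values_to = "abundance"
  )
  z <- long |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(
      sdv = if (sd_type == "sample") {
        stats::sd(.data$abundance)
      } else {
        stats::sd(.data$abundance) * sqrt((dplyr::n() - 1) / dplyr::n())
      },
      flagged = is.na(.data$sdv) | .data$sdv == 0,
      z = ifelse(.data$flagged, 0, (.data$abundance - mean(.data$abundance)) / .data$sdv)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("protein", "sample", "z", "flagged")
  ratio <- NULL
  if (all(c("PPAT", "GLS1") %in% panel$protein)) {
    wide <- long |>
      dplyr::filter(.data$protein %in% c("PPAT", "GLS1")) |>
      tidyr::pivot_wider(names_from = "protein", values_from = "abundance")
    ratio <- tibble::tibble(
      sample = wide$sample,
      ppat_gls1_ratio = wide$PPAT / wide$GLS1
    )
    if (any(wide$GLS1 == 0)) warning("GLS1 abundance of zero yields infinite ratio")
  }
  list(zscores = z, ratio = ratio)
}
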