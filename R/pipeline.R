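#' Assemble a run configuration
#'
#' @param ... Named configuration entries; see [run_tracer_pipeline()] and
#'   [run_meta_pipeline()] for the keys each pipeline reads. A character
#'   scalar naming a JSON file is read with [jsonlite::read_json()] first and
#'   the remaining arguments override its keys.
#' @param file Optional JSON config file.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- if (!is.null(file)) jsonlite::read_json(file, simplifyVector = TRUE) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_provenance <- function(out_dir, config, extra = list()) {
  prov <- c(
    list(
      package = "glnfate",
      version = as.character(utils::packageVersion("glnfate")),
      r_version = R.version.string,
      config = unclass(config)
    ),
    extra
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

#' Run the tracer pipeline: peaks to corrected MIDs to pathway scores
#'
#' Chains peak assignment, natural-abundance correction, the percent-labeled
#' statistic and the early/late pathway-dissection scores for every sample in
#' a centroid peak table. Config keys: `peaks` (TSV path with columns
#' `sample_id`, `time_h`, `metabolite`, `mz`, `intensity`) or `peaks_df` (the
#' same as a data frame); `registry` (CSV path `metabolite`, `formula`,
#' `polarity`, `charge`; defaults to the built-in panel); `tolerance_ppm`
#' (default 5); `resolution` (list `r_ref`, `mz_ref`, `exponent`,
#' `sep_factor`); `early`/`late` time points (defaults 0.25 and 6);
#' `out_dir` (optional; CSVs and provenance are written there).
#'
#' @param config A [run_config()] or plain named list.
#' @return List: `mids` (long tibble with `fraction_raw` and
#'   `fraction_corrected`), `scores` (per sample), `unassigned` counts.
#' @export
run_tracer_pipeline <- function(config) {
  peaks <- if (!is.null(config$peaks_df)) {
    tibble::as_tibble(config$peaks_df)
  } else {
    if (is.null(config$peaks) || !file.exists(config$peaks)) {
      stop("peak file not found: ", config$peaks %||% "<missing>", call. = FALSE)
    }
    readr::read_tsv(config$peaks, show_col_types = FALSE)
  }
  if (nrow(peaks) == 0) stop("peak table is empty", call. = FALSE)
  stopifnot(all(c("sample_id", "time_h", "metabolite", "mz", "intensity") %in% names(peaks)))
  reg <- if (is.null(config$registry)) {
    metabolite_registry()
  } else {
    readr::read_csv(config$registry, show_col_types = FALSE)
  }
  tol <- config$tolerance_ppm %||% 5
  table <- isotope_table()

  mids <- peaks |>
    dplyr::group_by(.data$sample_id, .data$time_h, .data$metabolite) |>
    dplyr::group_modify(function(pk, key) {
      r <- dplyr::filter(reg, .data$metabolite == key$metabolite)
      if (nrow(r) == 0) {
        warning("metabolite not in registry, skipped: ", key$metabolite)
        return(tibble::tibble())
      }
      formula <- parse_formula(r$formula)
      grid <- enumerate_grid(formula, charge = r$charge, table = table)
      asn <- assign_peaks(pk, grid, tolerance_ppm = tol)
      M <- build_correction(formula, table = table)
      corrected <- correct_mid(asn$mid, M)
      dplyr::left_join(
        dplyr::rename(asn$mid, fraction_raw = "fraction"),
        dplyr::rename(corrected, fraction_corrected = "fraction"),
        by = c("n13C", "n15N")
      )
    }) |>
    dplyr::ungroup()

  scores <- mids |>
    dplyr::rename(fraction = "fraction_corrected") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ pathway_scores(.x,
      early = config$early %||% 0.25,
      late = config$late %||% 6
    )) |>
    dplyr::ungroup()

  out <- list(mids = mids, scores = scores)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(mids, file.path(config$out_dir, "mids.csv"))
    readr::write_csv(scores, file.path(config$out_dir, "scores.csv"))
    write_provenance(config$out_dir, config, list(
      n_peaks = nrow(peaks), n_samples = dplyr::n_distinct(peaks$sample_id)
    ))
  }
  out
}

#' Run the prognostic meta-analysis pipeline
#'
#' Reads a cohort manifest, runs [integrate_enzymes()] and writes the
#' per-gene integrated table, per-organ tables, per-cohort effects and the
#' skip report. Config keys: `manifest` (CSV path) or `cohorts` (tibble from
#' [gen_cohorts()] / [read_cohorts()]); `genes` (character vector);
#' `min_followup_months` (default 84); `out_dir` (optional).
#'
#' @param config A [run_config()] or plain named list.
#' @return The [integrate_enzymes()] result.
#' @export
run_meta_pipeline <- function(config) {
  cohorts <- if (!is.null(config$cohorts)) {
    config$cohorts
  } else {
    read_cohorts(config$manifest)
  }
  genes <- config$genes %||% setdiff(
    names(cohorts$data[[1]]),
    c("subject_id", "time_months", "event")
  )
  res <- integrate_enzymes(cohorts, genes,
    min_followup_months = config$min_followup_months %||% 84
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res$integrated, file.path(config$out_dir, "integrated.csv"))
    readr::write_csv(res$per_organ, file.path(config$out_dir, "per_organ.csv"))
    readr::write_csv(res$per_cohort, file.path(config$out_dir, "per_cohort.csv"))
    readr::write_csv(res$skipped, file.path(config$out_dir, "skipped.csv"))
    write_provenance(config$out_dir, config, list(
      n_cohorts = nrow(cohorts), n_genes = length(genes),
      n_skipped = nrow(res$skipped)
    ))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
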