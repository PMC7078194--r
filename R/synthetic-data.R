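# multiplicative log-normal noise with unit mean and coefficient of
# variation cv (sigma^2 = log(1 + cv^2))
lognormal_noise <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Named scenario presets for the synthetic generators
#'
#' Parameter bundles encoding the study contrasts: a premalignant
#' "TSM-like" state (high glutaminolysis, low de novo nucleotide flux), a
#' malignant "AIG3-like" state (glutamine nitrogen shifted toward PPAT:
#' lower v_GLS, higher v_PPAT) and a "physiological-medium" variant (reduced
#' glutamine uptake reflecting a 0.6 mM medium pool). Each preset carries the
#' kinetic pool model, an MRM ground-truth panel (copies per cell) and
#' survival ground truth (per-gene true hazard ratios at the neuroendocrine
#' scale, exponential baseline hazard, censoring rate, tau2).
#'
#' @param name Preset name; `NULL` (default) lists all presets.
#' @return A preset list (`name`, `pool_model`, `mrm_truth`, `survival`) or a
#'   named list of presets.
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    `TSM-like` = list(
      name = "TSM-like",
      pool_model = pool_model(v_GLS = 12, v_PPAT = 0.2, v_pyr = 0.15),
      mrm_truth = c(PPAT = 2e5, GLS1 = 8e5, GLS2 = 1e5, GMPS = 1.5e5),
      survival = list(
        true_hr = c(PPAT = 5.21, GLS1 = 0.38),
        baseline_hazard = 0.02, censor_rate = 0.3, tau2 = 0
      )
    ),
    `AIG3-like` = list(
      name = "AIG3-like",
      pool_model = pool_model(v_GLS = 5, v_PPAT = 1, v_pyr = 0.6),
      mrm_truth = c(PPAT = 8e5, GLS1 = 3e5, GLS2 = 0.8e5, GMPS = 4e5),
      survival = list(
        true_hr = c(PPAT = 5.21, GLS1 = 0.38),
        baseline_hazard = 0.02, censor_rate = 0.3, tau2 = 0
      )
    ),
    `physiological-medium` = list(
      name = "physiological-medium",
      pool_model = pool_model(v_upt = 9, v_GLS = 5, v_PPAT = 1, v_pyr = 0.6),
      mrm_truth = c(PPAT = 8e5, GLS1 = 3e5, GLS2 = 0.8e5, GMPS = 4e5),
      survival = list(
        true_hr = c(PPAT = 5.21, GLS1 = 0.38),
        baseline_hazard = 0.02, censor_rate = 0.3, tau2 = 0
      )
    )
  )
  if (is.null(name)) {
    return(presets)
  }
  if (!name %in% names(presets)) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  presets[[name]]
}

#' Generate synthetic centroid peak lists with known ground truth
#'
#' Forward model of the dual-tracer measurements: true MIDs from
#' [simulate_labeling()], natural-abundance convolution with the same
#' correction matrix used downstream, merging of theoretical species closer
#' than the instrument FWHM, and multiplicative log-normal intensity noise.
#'
#' @param preset A preset from [scenario_presets()] (or its name).
#' @param metabolites Character subset of the built-in registry to emit.
#' @param times Labeling time points in hours.
#' @param tracer Tracer name.
#' @param model Instrument [resolution_model()], or `NULL` for infinite
#'   resolution (no merging).
#' @param cv Multiplicative coefficient of variation of intensities (>= 0).
#' @param total_intensity Total intensity per metabolite spectrum.
#' @param seed Random seed (required for reproducibility).
#' @param map Atom map.
#' @return List: `peaks` (tibble `sample_id`, `time_h`, `metabolite`, `mz`,
#'   `intensity`, `merged`), `true_mids`, `observed_mids` (after
#'   natural-abundance convolution, before noise).
#' @export
gen_ms_peaklists <- function(preset, metabolites = c("glutamine", "glutamate", "aKG", "fumarate", "IMP"),
                             times = c(0.25, 6, 24), tracer = "gln-13C5-15N2",
                             model = resolution_model(), cv = 0,
                             total_intensity = 1e6, seed = 1,
                             map = default_atom_map()) {
  if (is.character(preset)) preset <- scenario_presets(preset)
  stopifnot(cv >= 0)
  set.seed(seed)
  reg <- dplyr::filter(metabolite_registry(), .data$metabolite %in% metabolites)
  tc <- simulate_labeling(preset$pool_model, map, times, tracer)
  tc <- dplyr::filter(tc, .data$metabolite %in% metabolites)

  peaks <- list()
  observed <- list()
  for (met in unique(tc$metabolite)) {
    r <- dplyr::filter(reg, .data$metabolite == met)
    formula <- parse_formula(r$formula)
    sub <- dplyr::filter(tc, .data$metabolite == met)
    maxC <- max(sub$n13C)
    maxN <- max(sub$n15N)
    M <- build_correction(formula, maxC = maxC, maxN = maxN)
    layout <- attr(M, "layout")
    grid <- enumerate_grid(formula, maxC, maxN, charge = r$charge)
    for (t in unique(sub$time_h)) {
      true <- dplyr::filter(sub, .data$time_h == t)
      obs <- as.vector(M %*% mid_vector(true, layout))
      obs_df <- tibble::tibble(
        metabolite = met, time_h = t,
        n13C = layout$n13C, n15N = layout$n15N, fraction = obs
      )
      observed[[length(observed) + 1]] <- obs_df
      pk <- dplyr::left_join(grid, obs_df, by = c("n13C", "n15N"))
      pk$intensity <- pk$fraction * total_intensity
      pk <- merge_unresolved(pk, model)
      pk$intensity <- pk$intensity * lognormal_noise(nrow(pk), cv)
      peaks[[length(peaks) + 1]] <- tibble::tibble(
        sample_id = preset$name, time_h = t, metabolite = met,
        mz = pk$mz, intensity = pk$intensity, merged = pk$merged
      )
    }
  }
  list(
    peaks = dplyr::arrange(dplyr::bind_rows(peaks), .data$metabolite, .data$time_h, .data$mz),
    true_mids = tc,
    observed_mids = dplyr::bind_rows(observed)
  )
}

# collapse theoretical species closer than the instrument FWHM into single
# centroids (intensity-weighted mean m/z)
merge_unresolved <- function(pk, model) {
  pk <- dplyr::arrange(pk, .data$mz)
  if (is.null(model) || nrow(pk) < 2) {
    pk$merged <- FALSE
    return(pk)
  }
  fwhm <- pk$mz / resolving_power_at(model, pk$mz)
  linked <- diff(pk$mz) < pmin(fwhm[-length(fwhm)], fwhm[-1])
  grp <- cumsum(c(TRUE, !linked))
  pk |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      mz = if (sum(.data$intensity) > 0) {
        sum(.data$mz * .data$intensity) / sum(.data$intensity)
      } else {
        mean(.data$mz)
      },
      intensity = sum(.data$intensity),
      merged = dplyr::n() > 1,
      .groups = "drop"
    ) |>
    dplyr::select(-"grp")
}

#' Generate a synthetic MRM transition table with known copy numbers
#'
#' Inverse model of [quantify_peptides()]: ground-truth copies per cell are
#' converted to fmol-per-microgram abundances, light/heavy transition
#' intensities are drawn so that the summed light/heavy ratio times the spike
#' recovers the abundance, and multiplicative log-normal noise is applied to
#' each transition.
#'
#' @param truth Named vector of true copies per cell per protein.
#' @param peptides_per_protein,transitions_per_peptide Counts >= 1.
#' @param cv Multiplicative noise CV on transition intensities.
#' @param spike_fmol Heavy spike per peptide (fmol).
#' @param protein_per_cell_ug Protein content per cell (µg).
#' @param seed Random seed.
#' @return List: `transitions` (canonical transition tibble), `truth`
#'   (tibble `protein`, `copies`, `abundance_fmol_per_ug`).
#' @export
gen_transition_table <- function(truth, peptides_per_protein = 3,
                                 transitions_per_peptide = 3, cv = 0.1,
                                 spike_fmol = 10, protein_per_cell_ug = 2.5e-4,
                                 seed = 1) {
  stopifnot(peptides_per_protein >= 1, transitions_per_peptide >= 1, cv >= 0)
  set.seed(seed)
  abund <- truth / (1e-15 * protein_per_cell_ug * AVOGADRO)
  rows <- tidyr::expand_grid(
    protein = names(truth),
    peptide = paste0("pep", seq_len(peptides_per_protein)),
    transition = paste0("y", seq_len(transitions_per_peptide))
  )
  rows$peptide <- paste(rows$protein, rows$peptide, sep = "_")
  heavy_base <- stats::rlnorm(nrow(rows), log(1e5), 0.3)
  ratio <- abund[rows$protein] / spike_fmol
  rows$heavy_intensity <- heavy_base * lognormal_noise(nrow(rows), cv)
  rows$light_intensity <- heavy_base * ratio * lognormal_noise(nrow(rows), cv)
  rows$spike_fmol <- spike_fmol
  list(
    transitions = tibble::as_tibble(rows),
    truth = tibble::tibble(
      protein = names(truth), copies = unname(truth),
      abundance_fmol_per_ug = unname(abund)
    )
  )
}

#' Generate synthetic survival cohorts with a known hazard ratio
#'
#' Exponential event times under a proportional-hazards model: subjects above
#' their cohort's median expression of a gene have their hazard multiplied by
#' a cohort-specific HR drawn as `log HR ~ Normal(log true_hr, tau2)` (the
#' DerSimonian-Laird heterogeneity model). With several genes the per-subject
#' hazard is multiplicative across the high-group indicators. Censoring is
#' independent exponential calibrated so that the expected censored fraction
#' equals `censor_rate`.
#'
#' @param true_hr Named vector of true hazard ratios per gene.
#' @param k_cohorts Number of cohorts.
#' @param n_per_cohort Subjects per cohort (>= 10).
#' @param censor_rate Target censored fraction in `[0, 1)`.
#' @param tau2 Between-cohort variance of the log HR (>= 0).
#' @param baseline_hazard Events per month for the all-low group.
#' @param organs Organ labels recycled across cohorts.
#' @param seed Random seed.
#' @return List: `cohorts` (tibble `cohort_id`, `organ`, `data`), `truth`
#'   (per cohort x gene drawn log HR).
#' @export
gen_cohorts <- function(true_hr, k_cohorts = 10, n_per_cohort = 500,
                        censor_rate = 0.3, tau2 = 0, baseline_hazard = 0.02,
                        organs = c("neuroendocrine", "colorectal"), seed = 1) {
  stopifnot(n_per_cohort >= 10, censor_rate >= 0, censor_rate < 1, tau2 >= 0)
  set.seed(seed)
  genes <- names(true_hr)
  truth <- list()
  cohorts <- purrr::map_dfr(seq_len(k_cohorts), function(k) {
    id <- sprintf("cohort%02d", k)
    organ <- organs[(k - 1) %% length(organs) + 1]
    expr <- matrix(stats::rlnorm(n_per_cohort * length(genes)),
      ncol = length(genes), dimnames = list(NULL, genes)
    )
    log_hr_k <- stats::rnorm(length(genes), log(true_hr), sqrt(tau2))
    truth[[k]] <<- tibble::tibble(
      cohort_id = id, gene = genes, log_hr_true = log_hr_k
    )
    high <- apply(expr, 2, function(v) v > stats::median(v))
    haz <- baseline_hazard * exp(as.vector(high %*% log_hr_k))
    t_event <- stats::rexp(n_per_cohort, haz)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n_per_cohort, haz * censor_rate / (1 - censor_rate))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n_per_cohort)
    }
    data <- tibble::as_tibble(expr)
    data$subject_id <- sprintf("%s_s%04d", id, seq_len(n_per_cohort))
    data$time_months <- time
    data$event <- event
    tibble::tibble(
      cohort_id = id, organ = organ,
      data = list(dplyr::select(
        data, "subject_id", "time_months", "event",
        dplyr::all_of(genes)
      ))
    )
  })
  list(cohorts = cohorts, truth = dplyr::bind_rows(truth))
}

#' Write generated cohorts to per-cohort CSVs plus a manifest
#'
#' @param cohorts Tibble from [gen_cohorts()]`$cohorts`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohorts <- function(cohorts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(cohorts$cohort_id, ".csv")
  purrr::walk2(cohorts$data, files, ~ readr::write_csv(.x, file.path(dir, .y)))
  man <- tibble::tibble(
    cohort_id = cohorts$cohort_id, organ = cohorts$organ, filename = files
  )
  man_path <- file.path(dir, "manifest.csv")
  readr::write_csv(man, man_path)
  invisible(man_path)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `volume = length * width^2 / 2` in cubic millimetres, with length the
#' longer axis; swapped inputs are corrected with a warning.
#'
#' @param length,width Caliper measurements in mm (>= 0).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  stopifnot(length >= 0, width >= 0)
  if (width > length) {
    warning("width > length; swapping axes")
    tmp <- length
    length <- width
    width <- tmp
  }
  length * width^2 / 2
}
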