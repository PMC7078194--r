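PROTON_MASS <- 1.00727646

#' Instrument resolution model
#'
#' FWHM resolving power as a function of m/z, `R(mz) = r_ref * (mz_ref/mz)^exponent`,
#' the Orbitrap-like scaling with default exponent 1/2. `sep_factor` is the
#' number of FWHM widths required between two species to call them resolved.
#'
#' @param r_ref Resolving power (FWHM definition) at `mz_ref`. Default 70000.
#' @param mz_ref Reference m/z, default 200.
#' @param exponent Scaling exponent in `[0, 1]`, default 0.5.
#' @param sep_factor Multiples of FWHM required for resolution, default 1.
#' @return A list of class `resolution_model`.
#' @export
resolution_model <- function(r_ref = 70000, mz_ref = 200, exponent = 0.5,
                             sep_factor = 1) {
  stopifnot(r_ref > 0, mz_ref > 0, exponent >= 0, exponent <= 1, sep_factor >= 1)
  structure(
    list(r_ref = r_ref, mz_ref = mz_ref, exponent = exponent, sep_factor = sep_factor),
    class = "resolution_model"
  )
}

resolving_power_at <- function(model, mz) {
  model$r_ref * (model$mz_ref / mz)^model$exponent
}

#' Exact mass and m/z of a dual-label isotopologue
#'
#' Neutral mass is the monoisotopic mass plus `n13C` times the 13C mass shift
#' (1.0033548 Da) and `n15N` times the 15N mass shift (0.9970349 Da). For a
#' non-zero charge the m/z follows the protonation convention
#' `mz = (M + charge * 1.00727646) / abs(charge)`, i.e. \[M+H\]+ for charge +1
#' and \[M-H\]- for charge -1.
#'
#' @param formula An `elemental_formula` (see [parse_formula()]).
#' @param n13C,n15N Heavy-substitution counts, bounded by the formula.
#' @param charge Signed integer charge; 0 returns the neutral mass as m/z.
#' @param table Isotope table, see [isotope_table()].
#' @return One-row tibble: `n13C`, `n15N`, `neutral_mass`, `mz`, `charge`.
#' @examples
#' isotopologue_mz(parse_formula("C5H10N2O3"), 0, 0, charge = 0)
#' @export
isotopologue_mz <- function(formula, n13C, n15N, charge = 0L,
                            table = isotope_table()) {
  stopifnot(n13C >= 0, n15N >= 0)
  if (n13C > formula[["C"]] || n15N > formula[["N"]]) {
    stop("isotopologue state (", n13C, ",", n15N, ") exceeds formula bounds",
      call. = FALSE
    )
  }
  m <- monoisotopic_mass(formula, table) +
    n13C * delta_mass("C", table) + n15N * delta_mass("N", table)
  mz <- if (charge == 0L) m else (m + charge * PROTON_MASS) / abs(charge)
  tibble::tibble(
    n13C = as.integer(n13C), n15N = as.integer(n15N),
    neutral_mass = m, mz = mz, charge = as.integer(charge)
  )
}

#' Can two m/z species be resolved at a given resolving power?
#'
#' The required resolving power to separate masses `mzA` and `mzB` is
#' `mean(mz) / abs(diff) * sep_factor`; the pair is resolved when the
#' instrument resolving power at the mean m/z meets or exceeds it. This is the
#' mass-defect criterion that separates a 13C substitution (+1.0033548 Da)
#' from a 15N substitution (+0.9970349 Da).
#'
#' @param mzA,mzB Distinct positive m/z values.
#' @param model A [resolution_model()].
#' @return Tibble: `required_rp`, `instrument_rp`, `resolved`.
#' @export
separability <- function(mzA, mzB, model = resolution_model()) {
  stopifnot(mzA > 0, mzB > 0)
  if (mzA == mzB) stop("mzA and mzB must differ", call. = FALSE)
  mid <- mean(c(mzA, mzB))
  required <- mid / abs(mzA - mzB) * model$sep_factor
  inst <- resolving_power_at(model, mid)
  # >= with a relative epsilon so the exact-FWHM boundary counts as resolved
  tibble::tibble(
    required_rp = required, instrument_rp = inst,
    resolved = inst >= required * (1 - 1e-9)
  )
}

#' Enumerate the theoretical (13C, 15N) isotopologue grid
#'
#' @param formula An `elemental_formula`.
#' @param maxC,maxN Upper substitution bounds (default: all C and N atoms).
#' @param charge Signed integer charge passed to [isotopologue_mz()].
#' @param table Isotope table.
#' @param model Optional [resolution_model()]; when given, species whose m/z
#'   gap is below the instrument FWHM are flagged with a shared `merge_group`.
#' @return Tibble sorted by m/z with one row per state; `merge_group` is `NA`
#'   for cleanly resolved species.
#' @export
enumerate_grid <- function(formula, maxC = formula[["C"]], maxN = formula[["N"]],
                           charge = 0L, table = isotope_table(), model = NULL) {
  if (maxC > formula[["C"]] || maxN > formula[["N"]]) {
    stop("maxC/maxN exceed the formula's atom counts", call. = FALSE)
  }
  grid <- tidyr::expand_grid(n13C = 0:maxC, n15N = 0:maxN)
  out <- purrr::pmap_dfr(grid, function(n13C, n15N) {
    isotopologue_mz(formula, n13C, n15N, charge, table)
  })
  out <- dplyr::arrange(out, .data$mz)
  out$merge_group <- NA_integer_
  if (!is.null(model) && nrow(out) > 1) {
    fwhm <- out$mz / resolving_power_at(model, out$mz)
    gap <- diff(out$mz)
    # consecutive species closer than the local FWHM share a merge group
    linked <- gap < pmin(fwhm[-length(fwhm)], fwhm[-1])
    grp <- cumsum(c(TRUE, !linked))
    sizes <- tabulate(grp)
    out$merge_group <- ifelse(sizes[grp] > 1, grp, NA_integer_)
  }
  out
}

#' Assign centroid peaks to theoretical isotopologues
#'
#' Each peak is matched to the nearest theoretical m/z within a ppm tolerance;
#' intensities are accumulated per (n13C, n15N) state and normalized to a
#' fractional grid. When two theoretical species fall within tolerance of one
#' peak, the nearest mass wins (ties toward the lower substitution count) and
#' the peak is flagged ambiguous.
#'
#' @param peaks Data frame with columns `mz` and `intensity` (plus any id
#'   columns, which are ignored here).
#' @param grid Theoretical grid from [enumerate_grid()] (must use the same
#'   charge state as the acquisition).
#' @param tolerance_ppm Match tolerance in parts per million, default 5.
#' @return List with `mid` (tibble `n13C`, `n15N`, `fraction`), `unassigned`
#'   (peaks with no match) and `ambiguous` (peaks with > 1 candidate).
#' @export
assign_peaks <- function(peaks, grid, tolerance_ppm = 5) {
  stopifnot(nrow(grid) > 0, tolerance_ppm > 0)
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)), all(peaks$intensity >= 0))
  acc <- stats::setNames(numeric(nrow(grid)), seq_len(nrow(grid)))
  unassigned <- ambiguous <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    dmz <- abs(grid$mz - peaks$mz[i])
    tol <- tolerance_ppm * 1e-6 * peaks$mz[i]
    hits <- which(dmz <= tol)
    if (length(hits) == 0) {
      unassigned <- c(unassigned, i)
      next
    }
    if (length(hits) > 1) ambiguous <- c(ambiguous, i)
    best <- hits[order(dmz[hits], grid$n13C[hits] + grid$n15N[hits])][1]
    acc[best] <- acc[best] + peaks$intensity[i]
  }
  total <- sum(acc)
  if (total == 0) warning("no peaks assigned; returning all-zero grid")
  mid <- tibble::tibble(
    n13C = grid$n13C, n15N = grid$n15N,
    fraction = if (total > 0) unname(acc) / total else unname(acc)
  )
  mid <- dplyr::arrange(mid, .data$n15N, .data$n13C)
  list(
    mid = mid,
    unassigned = peaks[unassigned, , drop = FALSE],
    ambiguous = peaks[ambiguous, , drop = FALSE]
  )
}

# single-element correction matrix: column j (true count j-1 of n_label
# positions) is the distribution of observed heavy counts, from tracer
# impurity on labeled positions and natural abundance on the rest
element_axis_matrix <- function(n_atoms, n_max, abundance, purity = 1) {
  A <- matrix(0, n_max + 1, n_max + 1)
  for (j in 0:n_max) {
    # retained labels ~ Binom(j, purity); natural extras ~ Binom(n_atoms - j, a)
    retained <- stats::dbinom(0:j, j, purity)
    natural <- stats::dbinom(0:(n_atoms - j), n_atoms - j, abundance)
    conv <- pracma::conv(retained, natural)
    keep <- seq_len(min(length(conv), n_max + 1))
    A[keep, j + 1] <- conv[keep]
  }
  A
}

# nominal-mass (+k) distribution from heavy isotopes of non-tracer elements;
# folded into a tracer axis when that axis is not mass-resolved
nominal_shift_distribution <- function(formula, table, elements, k_max) {
  dist <- 1
  for (el in elements) {
    n <- formula[[el]]
    if (n == 0) next
    iso <- table[[el]]
    shifts <- round(iso$mass - iso$mass[1])
    per_atom <- numeric(max(shifts) + 1)
    for (i in seq_along(shifts)) {
      per_atom[shifts[i] + 1] <- per_atom[shifts[i] + 1] + iso$abundance[i]
    }
    for (a in seq_len(n)) dist <- pracma::conv(dist, per_atom)
  }
  dist <- dist[seq_len(min(length(dist), k_max + 1))]
  dist
}

#' Build the natural-abundance / tracer-impurity correction matrix
#'
#' Maps a true flattened MID grid (n13C fastest, then n15N) to the observed
#' grid. In high-resolution mode (an element present in `resolved`), that
#' tracer axis only sees its own element's natural abundance over the
#' unlabeled positions; heavy isotopes of H, O, P and S are folded into the
#' carbon axis as same-nominal-mass contaminants only when carbon is not
#' resolved (or into the nitrogen axis when only carbon is resolved).
#'
#' @param formula An `elemental_formula`.
#' @param maxC,maxN Grid bounds (default all C and N atoms).
#' @param table Isotope table.
#' @param purity Named tracer purity fractions in (0, 1], e.g. `c(C = 1, N = 1)`.
#' @param resolved Character subset of `c("C", "N")` whose mass defects the
#'   instrument separates from other same-nominal-mass species.
#' @return Square matrix of dimension `(maxC+1)*(maxN+1)` with attribute
#'   `layout` (tibble of n13C, n15N per flattened index). Columns sum to <= 1
#'   (mass leaving the grid bounds is dropped).
#' @export
build_correction <- function(formula, maxC = formula[["C"]], maxN = formula[["N"]],
                             table = isotope_table(),
                             purity = c(C = 1, N = 1),
                             resolved = c("C", "N")) {
  stopifnot(all(purity > 0), all(purity <= 1), all(resolved %in% c("C", "N")))
  a13C <- if (nrow(table$C) > 1) table$C$abundance[2] else 0
  a15N <- if (nrow(table$N) > 1) table$N$abundance[2] else 0
  Ac <- element_axis_matrix(formula[["C"]], maxC, a13C, purity[["C"]])
  An <- element_axis_matrix(formula[["N"]], maxN, a15N, purity[["N"]])
  others <- c("H", "O", "P", "S")
  if (!("C" %in% resolved)) {
    Ac <- fold_axis(Ac, nominal_shift_distribution(formula, table, others, maxC))
  } else if (!("N" %in% resolved)) {
    An <- fold_axis(An, nominal_shift_distribution(formula, table, others, maxN))
  }
  M <- An %x% Ac # flattened order: n13C fastest
  layout <- tidyr::expand_grid(n15N = 0:maxN, n13C = 0:maxC)[, c("n13C", "n15N")]
  attr(M, "layout") <- layout
  M
}

# convolve every column of an axis matrix with a +k nominal-shift distribution
fold_axis <- function(A, dist) {
  n <- nrow(A)
  for (j in seq_len(ncol(A))) {
    conv <- pracma::conv(A[, j], dist)
    A[, j] <- conv[seq_len(n)]
  }
  A
}

# flatten / unflatten a MID tibble against a correction-matrix layout
mid_vector <- function(mid, layout) {
  key <- paste(layout$n13C, layout$n15N)
  v <- stats::setNames(numeric(nrow(layout)), key)
  mk <- paste(mid$n13C, mid$n15N)
  stopifnot(all(mk %in% key))
  v[mk] <- mid$fraction
  unname(v)
}

#' Correct an observed MID for natural abundance and tracer impurity
#'
#' Solves `observed = M %*% true` by non-negative least squares and
#' renormalizes the solution to sum 1.
#'
#' @param mid Observed MID tibble (`n13C`, `n15N`, `fraction`).
#' @param correction Matrix from [build_correction()].
#' @return Corrected MID tibble with attributes `residual` (NNLS residual
#'   norm) and `condition` (condition number of the correction matrix).
#' @export
correct_mid <- function(mid, correction) {
  layout <- attr(correction, "layout")
  stopifnot(!is.null(layout))
  obs <- mid_vector(mid, layout)
  kond <- kappa(correction, exact = TRUE)
  if (!is.finite(kond) || kond > 1e12) {
    stop("correction matrix is ill-conditioned (condition number ",
      format(kond, digits = 3), ")",
      call. = FALSE
    )
  }
  fit <- pracma::lsqnonneg(correction, obs)
  x <- fit$x
  if (sum(x) > 0) x <- x / sum(x)
  out <- tibble::tibble(n13C = layout$n13C, n15N = layout$n15N, fraction = x)
  attr(out, "residual") <- sqrt(fit$resid.norm)
  attr(out, "condition") <- kond
  out
}

#' Percent-labeled statistic of a MID
#'
#' The proportion of atoms of one element derived from the tracer: the
#' abundance-weighted mean substitution count divided by the number of atoms,
#' `sum_k k * f_k / n_atoms`, where `f_k` is the marginal fraction with `k`
#' substitutions of that element.
#'
#' @param mid MID tibble (`n13C`, `n15N`, `fraction`).
#' @param element `"C"` or `"N"`.
#' @param n_atoms Number of atoms of that element in the metabolite.
#' @return Atom fraction in `[0, 1]`.
#' @export
percent_labeled <- function(mid, element = c("C", "N"), n_atoms) {
  element <- match.arg(element)
  stopifnot(n_atoms >= 1)
  f <- mid$fraction
  tot <- sum(f)
  if (tot <= 0) {
    return(0)
  }
  k <- if (element == "C") mid$n13C else mid$n15N
  sum(k * f) / tot / n_atoms
}

#' Fraction of molecules carrying at least one label
#'
#' Complementary statistic to [percent_labeled()]: the fraction of molecules
#' with any heavy substitution of the element.
#'
#' @inheritParams percent_labeled
#' @return Fraction in `[0, 1]`.
#' @export
frac_any_labeled <- function(mid, element = c("C", "N")) {
  element <- match.arg(element)
  f <- mid$fraction
  tot <- sum(f)
  if (tot <= 0) {
    return(0)
  }
  k <- if (element == "C") mid$n13C else mid$n15N
  sum(f[k > 0]) / tot
}
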