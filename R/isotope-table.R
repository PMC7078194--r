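#' Natural isotope table for C, H, N, O, P and S
#'
#' Exact isotope masses (Da) and natural abundance fractions for the six
#' elements handled by the isotopologue engine. Masses are NIST monoisotopic
#' values; abundances are IUPAC representative terrestrial values. The first
#' isotope of each element is the lightest (monoisotopic) species.
#'
#' @param overrides Optional named list replacing whole elements, each entry a
#'   data frame with columns `mass` and `abundance` (abundances must sum to 1).
#' @return A named list of tibbles, one per element, with columns `mass` (Da,
#'   strictly increasing) and `abundance` (summing to 1 per element).
#' @examples
#' isotope_table()$C
#' @export
isotope_table <- function(overrides = NULL) {
  tab <- list(
    C = tibble::tibble(mass = c(12, 13.00335484), abundance = c(0.9893, 0.0107)),
    H = tibble::tibble(mass = c(1.00782503, 2.01410178), abundance = c(0.999885, 0.000115)),
    N = tibble::tibble(mass = c(14.00307401, 15.00010890), abundance = c(0.99636, 0.00364)),
    O = tibble::tibble(
      mass = c(15.99491462, 16.99913176, 17.99915961),
      abundance = c(0.99757, 0.00038, 0.00205)
    ),
    P = tibble::tibble(mass = 30.97376200, abundance = 1),
    S = tibble::tibble(
      mass = c(31.97207117, 32.97145891, 33.96786701, 35.96708071),
      abundance = c(0.9499, 0.0075, 0.0425, 0.0001)
    )
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (el in names(overrides)) {
      ov <- tibble::as_tibble(overrides[[el]])
      stopifnot(all(c("mass", "abundance") %in% names(ov)))
      tab[[el]] <- ov[, c("mass", "abundance")]
    }
  }
  validate_isotope_table(tab)
  tab
}

validate_isotope_table <- function(tab) {
  for (el in names(tab)) {
    e <- tab[[el]]
    if (abs(sum(e$abundance) - 1) > 1e-9) {
      stop("isotope abundances for ", el, " do not sum to 1", call. = FALSE)
    }
    if (any(e$mass <= 0) || is.unsorted(e$mass, strictly = TRUE)) {
      stop("isotope masses for ", el, " must be positive and strictly increasing",
        call. = FALSE
      )
    }
  }
  invisible(tab)
}

# mass shift of one heavy-isotope substitution relative to the monoisotopic
# species; 13C adds 1.0033548 Da, 15N adds 0.9970349 Da
delta_mass <- function(element, table = isotope_table(), which = 2L) {
  e <- table[[element]]
  if (nrow(e) < which) stop("element ", element, " has no isotope ", which, call. = FALSE)
  e$mass[which] - e$mass[1]
}

#' Parse a molecular formula restricted to C, H, N, O, P, S
#'
#' @param text Formula string in Hill-like notation, e.g. `"C5H10N2O3"`.
#' @return Named integer vector of element counts (class `elemental_formula`).
#' @examples
#' parse_formula("C5H10N2O3") # glutamine
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L, S = 0L)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    if (!el %in% names(counts)) stop("unknown element symbol: ", el, call. = FALSE)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (is.na(n)) stop("malformed count in formula: ", tk, call. = FALSE)
    counts[el] <- counts[el] + n
  }
  if (sum(counts) == 0L) stop("formula must contain at least one atom", call. = FALSE)
  structure(counts, class = "elemental_formula")
}

monoisotopic_mass <- function(formula, table = isotope_table()) {
  sum(vapply(names(formula), function(el) {
    formula[[el]] * table[[el]]$mass[1]
  }, numeric(1)))
}

#' Built-in metabolite registry for the dual-tracer panel
#'
#' Formulas and ion conventions for the metabolites read out in the tracing
#' experiments: glutamine, glutamate and aspartate (amino acids, measured as
#' protonated cations) and the organic acids / nucleotide monophosphates
#' (measured as deprotonated anions on the ion-chromatography channel).
#'
#' @return Tibble with columns `metabolite`, `formula`, `polarity`, `charge`.
#' @export
metabolite_registry <- function() {
  tibble::tribble(
    ~metabolite, ~formula, ~polarity, ~charge,
    "glutamine", "C5H10N2O3", "positive", 1L,
    "glutamate", "C5H9NO4", "positive", 1L,
    "aspartate", "C4H7NO4", "positive", 1L,
    "aKG", "C5H6O5", "negative", -1L,
    "fumarate", "C4H4O4", "negative", -1L,
    "citrate", "C6H8O7", "negative", -1L,
    "IMP", "C10H13N4O8P", "negative", -1L,
    "AMP", "C10H14N5O7P", "negative", -1L,
    "GMP", "C10H14N5O8P", "negative", -1L,
    "UMP", "C9H13N2O9P", "negative", -1L
  )
}
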