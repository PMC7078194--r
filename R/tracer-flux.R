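#' Default atom-transition map for the two-pathway labeling model
#'
#' Nitrogen position sources and carbon-block sources for each modeled
#' metabolite. Purine ring nitrogens: two from the glutamine amide (the PPAT
#' step plus the downstream amidotransferase), one from aspartate, one from
#' glycine (unlabeled here); AMP adds the aspartate-derived exocyclic N6 and
#' GMP the amide-derived N2; UMP carries one carbamoyl-phosphate nitrogen from
#' the glutamine amide and one from aspartate. Carbon travels as an intact
#' backbone block (glutamine C5 through glutamate and alpha-ketoglutarate,
#' C4 after decarboxylation to fumarate) or as glucose-derived ribose.
#'
#' The map ships as a plain CSV (`atom_map_default.csv` under `extdata`) so
#' that routings can be edited, e.g. to disable aspartate-derived nitrogen.
#'
#' @param path Optional path to a CSV with columns `metabolite`, `element`,
#'   `positions`, `source`; defaults to the bundled map.
#' @return Tibble atom map.
#' @export
default_atom_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atom_map_default.csv", package = "glnfate")
  }
  map <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("metabolite", "element", "positions", "source") %in% names(map)))
  ok_n <- c("gln_amide", "gln_amine", "aspartate", "unlabeled")
  ok_c <- c("gln_backbone", "glucose", "unlabeled")
  bad <- !((map$element == "N" & map$source %in% ok_n) |
    (map$element == "C" & map$source %in% ok_c))
  if (any(bad)) stop("unknown atom-map source(s): ", paste(map$source[bad], collapse = ", "))
  map
}

#' Kinetic pool model for dual-tracer glutamine labeling
#'
#' Well-mixed metabolite pools of constant size with first-order enrichment
#' balance equations. `v_GLS` is the glutaminolysis flux (glutamine ->
#' glutamate -> alpha-ketoglutarate -> fumarate), `v_PPAT` the de novo purine
#' entry (glutamine amide nitrogen -> IMP/AMP/GMP), `v_TA` the transamination
#' flux labeling aspartate nitrogen from glutamate, and `v_pyr` the pyrimidine
#' entry (UMP). `d_*` are unlabeled dilution influxes into each pool and
#' `enrichment` the tracer fraction in the medium.
#'
#' @param v_upt Glutamine uptake flux (amount/h). Default 20.
#' @param v_GLS,v_PPAT,v_TA,v_pyr Pathway fluxes (amount/h).
#' @param v_rib Ribose (PRPP) turnover flux used for nucleotide carbon.
#' @param d_gln,d_glu,d_akg,d_fum,d_asp Unlabeled dilution influxes.
#' @param pools Named vector of pool sizes (amount units), all > 0.
#' @param enrichment Medium tracer enrichment fraction in `[0, 1]`.
#' @return List of class `pool_model`.
#' @export
pool_model <- function(v_upt = 30, v_GLS = 10, v_PPAT = 1, v_TA = 4, v_pyr = 0.5,
                       v_rib = 2,
                       d_gln = 1, d_glu = 2, d_akg = 4, d_fum = 4, d_asp = 2,
                       pools = c(
                         gln = 5, glu = 10, akg = 2, fum = 2, asp = 8,
                         rib = 2, IMP = 4, AMP = 8, GMP = 3, UMP = 4
                       ),
                       enrichment = 1) {
  fluxes <- c(
    v_upt = v_upt, v_GLS = v_GLS, v_PPAT = v_PPAT, v_TA = v_TA,
    v_pyr = v_pyr, v_rib = v_rib,
    d_gln = d_gln, d_glu = d_glu, d_akg = d_akg, d_fum = d_fum, d_asp = d_asp
  )
  if (any(fluxes < 0)) stop("fluxes must be non-negative", call. = FALSE)
  if (any(pools <= 0)) stop("pool sizes must be positive", call. = FALSE)
  stopifnot(enrichment >= 0, enrichment <= 1)
  structure(
    list(fluxes = fluxes, pools = pools, enrichment = enrichment),
    class = "pool_model"
  )
}

# synthesis flux driving each nucleotide's position turnover
nucleotide_flux <- function(met) {
  switch(met,
    IMP = ,
    AMP = ,
    GMP = "v_PPAT",
    UMP = "v_pyr",
    stop("no synthesis flux defined for ", met, call. = FALSE)
  )
}

core_states <- c(
  "gln_c", "gln_amide", "gln_amine", "glu_c", "glu_n",
  "akg_c", "fum_c", "asp_n", "rib_c"
)

# enrichment states appended for nucleotide position classes, one per
# (metabolite, labeled source) pair present in the atom map
nucleotide_states <- function(map) {
  nuc <- dplyr::filter(
    map, .data$element == "N",
    .data$metabolite %in% c("IMP", "AMP", "GMP", "UMP"),
    .data$source != "unlabeled"
  )
  nuc <- dplyr::distinct(nuc, .data$metabolite, .data$source)
  if (nrow(nuc) == 0) {
    return(nuc[, c("metabolite", "source")])
  }
  nuc$state <- paste(nuc$metabolite, nuc$source, sep = ".")
  nuc
}

#' Simulate a dual-tracer labeling time course
#'
#' Integrates the linear first-order enrichment balance equations of the pool
#' model (constant pool sizes, well-mixed pools) with a stiff-capable solver
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-10), then assembles mass isotopomer
#' distributions assuming independent positions: carbon travels as an intact
#' backbone or ribose block, nitrogen positions follow the atom map, and the
#' (13C, 15N) grid is the outer product of the two marginals.
#'
#' @param model A [pool_model()].
#' @param map Atom map tibble, see [default_atom_map()].
#' @param times Time points in hours (non-negative).
#' @param tracer `"gln-13C5-15N2"` or `"glc-13C6"`.
#' @return Long tibble: `metabolite`, `time_h`, `n13C`, `n15N`, `fraction`,
#'   with attribute `states` holding the raw enrichment trajectories.
#' @export
simulate_labeling <- function(model, map = default_atom_map(),
                              times = c(0, 0.25, 6, 24),
                              tracer = c("gln-13C5-15N2", "glc-13C6")) {
  tracer <- match.arg(tracer)
  stopifnot(inherits(model, "pool_model"), all(times >= 0))
  times <- sort(unique(times))
  E <- model$enrichment
  med <- if (tracer == "gln-13C5-15N2") {
    c(gln = E, glc = 0)
  } else {
    c(gln = 0, glc = E)
  }
  nuc <- nucleotide_states(map)
  states <- c(core_states, nuc$state)
  y0 <- stats::setNames(numeric(length(states)), states)
  fx <- as.list(model$fluxes)
  P <- model$pools

  # the enrichment balance is linear time-invariant, dx/dt = A x + b;
  # assemble A and b once and hand the linear system to the solver
  n_st <- length(states)
  A <- matrix(0, n_st, n_st, dimnames = list(states, states))
  b <- stats::setNames(numeric(n_st), states)
  put <- function(state, src, v_in, v_out, pool, input = 0) {
    A[state, state] <<- -v_out / pool
    if (!is.null(src)) A[state, src] <<- A[state, src] + v_in / pool
    b[state] <<- b[state] + input / pool
  }
  up <- fx$v_upt
  for (s in c("gln_c", "gln_amide", "gln_amine")) {
    put(s, NULL, 0, up + fx$d_gln, P[["gln"]], up * med[["gln"]])
  }
  put("glu_c", "gln_c", fx$v_GLS, fx$v_GLS + fx$d_glu, P[["glu"]])
  put("glu_n", "gln_amine", fx$v_GLS, fx$v_GLS + fx$d_glu, P[["glu"]])
  put("akg_c", "glu_c", fx$v_GLS, fx$v_GLS + fx$d_akg, P[["akg"]])
  put("fum_c", "akg_c", fx$v_GLS, fx$v_GLS + fx$d_fum, P[["fum"]])
  put("asp_n", "glu_n", fx$v_TA, fx$v_TA + fx$d_asp, P[["asp"]])
  put("rib_c", NULL, 0, fx$v_rib, P[["rib"]], fx$v_rib * med[["glc"]])
  if (nrow(nuc) > 0) {
    src_state <- c(
      gln_amide = "gln_amide", aspartate = "asp_n", gln_amine = "gln_amine"
    )
    for (i in seq_len(nrow(nuc))) {
      v <- fx[[nucleotide_flux(nuc$metabolite[i])]]
      put(nuc$state[i], src_state[[nuc$source[i]]], v, v, P[[nuc$metabolite[i]]])
    }
  }
  deriv <- function(t, y, parms) list(A %*% y + b)

  ode_times <- unique(c(0, times))
  if (length(ode_times) < 2) {
    sol <- data.frame(time = 0, t(y0), check.names = FALSE)
  } else {
    sol <- as.data.frame(deSolve::ode(y0, ode_times, deriv,
      parms = NULL, method = "lsoda",
      rtol = 1e-8, atol = 1e-10
    ))
  }
  sol <- sol[sol$time %in% times, , drop = FALSE]

  map_split <- split(as.data.frame(map), map$metabolite)
  chunks <- vector("list", length(map_split) * nrow(sol))
  ci <- 0
  for (met in unique(map$metabolite)) {
    sub <- map_split[[met]]
    for (ti in seq_len(nrow(sol))) {
      grid <- assemble_mid(met, sub, sol[ti, , drop = FALSE], nuc)
      grid$time_h <- sol$time[ti]
      ci <- ci + 1
      chunks[[ci]] <- grid
    }
  }
  out <- tibble::as_tibble(do.call(rbind, chunks[seq_len(ci)]))
  out <- out[, c("metabolite", "time_h", "n13C", "n15N", "fraction")]
  attr(out, "states") <- tibble::as_tibble(sol)
  out
}

# carbon-block and nitrogen-position marginals -> outer-product grid
assemble_mid <- function(met, sub, y, nuc) {
  crow <- sub[sub$element == "C", , drop = FALSE]
  nrowz <- sub[sub$element == "N", , drop = FALSE]
  n_block <- if (nrow(crow) > 0) crow$positions[1] else 0
  xc <- if (nrow(crow) == 0) {
    0
  } else {
    switch(crow$source[1],
      gln_backbone = switch(met,
        glutamine = y[["gln_c"]],
        glutamate = y[["glu_c"]],
        aKG = y[["akg_c"]],
        fumarate = y[["fum_c"]],
        stop("no backbone carbon state for ", met, call. = FALSE)
      ),
      glucose = y[["rib_c"]],
      unlabeled = 0
    )
  }
  c_marg <- numeric(n_block + 1)
  c_marg[1] <- 1 - xc
  c_marg[n_block + 1] <- c_marg[n_block + 1] + xc

  pos_enr <- numeric(0)
  if (nrow(nrowz) > 0) {
    for (i in seq_len(nrow(nrowz))) {
      src <- nrowz$source[i]
      p <- if (src == "unlabeled") {
        0
      } else if (met %in% c("IMP", "AMP", "GMP", "UMP")) {
        y[[paste(met, src, sep = ".")]]
      } else {
        switch(src,
          gln_amide = y[["gln_amide"]],
          gln_amine = switch(met,
            glutamine = y[["gln_amine"]],
            glutamate = y[["glu_n"]],
            y[["glu_n"]]
          ),
          aspartate = y[["asp_n"]]
        )
      }
      pos_enr <- c(pos_enr, rep(p, nrowz$positions[i]))
    }
  }
  n_marg <- poisson_binomial(pos_enr)
  grid <- outer(c_marg, n_marg)
  data.frame(
    metabolite = met,
    n13C = rep(0:n_block, times = length(n_marg)),
    n15N = rep(seq_along(n_marg) - 1L, each = n_block + 1L),
    fraction = as.vector(grid)
  )
}

# distribution of the number of successes of independent Bernoulli positions
poisson_binomial <- function(p) {
  dist <- 1
  for (pi in p) dist <- pracma::conv(dist, c(1 - pi, pi))
  dist
}

#' Pathway-dissection scores from early and late time points
#'
#' The glutaminolysis score is the carbon percent-labeled of
#' alpha-ketoglutarate (or fumarate) at the early time point — rapid 13C entry
#' reflects GLS1-mediated anaplerosis. The de novo score is the nitrogen
#' percent-labeled of IMP (or another nucleotide) at the late time point —
#' slow 15N accumulation reflects PPAT-mediated amide transfer. The nitrogen
#' shift index is `log2(denovo / glutaminolysis)`.
#'
#' @param tc Time-course tibble from [simulate_labeling()] or assigned spectra.
#' @param early,late Time points in hours, defaults 0.25 and 6.
#' @param glycolytic Metabolite for the early carbon readout, default `"aKG"`.
#' @param purine Metabolite for the late nitrogen readout, default `"IMP"`.
#' @return One-row tibble: `glutaminolysis_score`, `denovo_score`,
#'   `nitrogen_shift_index`.
#' @export
pathway_scores <- function(tc, early = 0.25, late = 6,
                           glycolytic = "aKG", purine = "IMP") {
  grab <- function(met, t) {
    g <- dplyr::filter(tc, .data$metabolite == met, .data$time_h == t)
    if (nrow(g) == 0) {
      stop("time course lacks ", met, " at ", t, " h", call. = FALSE)
    }
    g
  }
  g_early <- grab(glycolytic, early)
  g_late <- grab(purine, late)
  gls <- percent_labeled(g_early, "C", max(g_early$n13C))
  dn <- percent_labeled(g_late, "N", max(g_late$n15N))
  tibble::tibble(
    glutaminolysis_score = gls,
    denovo_score = dn,
    nitrogen_shift_index = log2(dn / gls)
  )
}

#' Recover pathway fluxes from an observed labeling time course
#'
#' Bounded non-negative least squares over [simulate_labeling()] outputs:
#' the named free fluxes are adjusted to minimize the sum of squared
#' differences between observed and simulated MID fractions across all
#' metabolites and time points present in the observations.
#'
#' @param observed Long MID tibble (`metabolite`, `time_h`, `n13C`, `n15N`,
#'   `fraction`).
#' @param model Skeleton [pool_model()] supplying fixed parameters and
#'   starting values for the free fluxes.
#' @param map Atom map.
#' @param tracer Tracer name, as in [simulate_labeling()].
#' @param free Names of free fluxes, default `c("v_GLS", "v_PPAT")`.
#' @return Object of class `flux_fit`: list with `estimates` (named vector),
#'   `rss`, `converged`, `model`.
#' @export
fit_fluxes <- function(observed, model, map = default_atom_map(),
                       tracer = "gln-13C5-15N2",
                       free = c("v_GLS", "v_PPAT")) {
  stopifnot(all(free %in% names(model$fluxes)))
  times <- sort(unique(observed$time_h))
  mets <- unique(observed$metabolite)
  if (length(times) < 2 || length(mets) < 2) {
    stop("need >= 2 time points and >= 2 metabolites to fit fluxes", call. = FALSE)
  }
  map_used <- dplyr::filter(map, .data$metabolite %in% mets)
  obs_key <- observed[order(observed$metabolite, observed$time_h,
    observed$n15N, observed$n13C,
    method = "radix"
  ), , drop = FALSE]
  # simulation output order is fixed by the map, so the permutation aligning
  # it with the sorted observations is computed once
  template <- simulate_labeling(model, map_used, times, tracer)
  perm <- order(template$metabolite, template$time_h, template$n15N, template$n13C,
    method = "radix"
  )
  stopifnot(nrow(template) == nrow(obs_key))
  objective <- function(theta) {
    m <- model
    m$fluxes[free] <- theta
    sim <- simulate_labeling(m, map_used, times, tracer)
    sum((obs_key$fraction - sim$fraction[perm])^2)
  }
  start <- pmax(model$fluxes[free], 1e-3)
  opt <- stats::optim(start, objective,
    method = "L-BFGS-B",
    lower = rep(0, length(free)),
    control = list(factr = 1e4, maxit = 500)
  )
  structure(
    list(
      estimates = stats::setNames(opt$par, free),
      rss = opt$value,
      converged = opt$convergence == 0,
      message = opt$message,
      model = model
    ),
    class = "flux_fit"
  )
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("Flux fit (", if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(x$estimates, 4))
  cat("RSS:", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.flux_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged)
}

#' Paired two-tailed Student's t-test
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return One-row tibble: `t`, `df`, `p`. Zero variance of the paired
#'   differences is flagged with a warning (p reported as NA unless all
#'   differences are zero, where t = 0 and p = 1).
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences")
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = length(d) - 1, p = 1))
    }
    return(tibble::tibble(t = NA_real_, df = length(d) - 1, p = NA_real_))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value
  )
}
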