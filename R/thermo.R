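# Statistical-thermodynamic model of P_RM autoregulation with CI-mediated
# looping between O_L and O_R (Shea-Ackers framework).
#
# A state is one configuration of CI dimers on the six operator subsites
# (O_L1-3, O_R1-3) together with its cooperative-pairing arrangement and
# looping status. Its statistical weight is d * [CI2]^i * exp(-dG/RT):
# d the degeneracy, i the number of bound dimers, dG the state free energy
# (intrinsic binding + pairwise cooperativity + looping terms).

#' Thermodynamic model parameters
#'
#' Fixed physical parameters are read from a YAML config (see
#' `system.file("extdata", "ci_params.yaml", package = "smloop")`); the
#' four free parameters of the model — the octamer and tetramer looping
#' free energies and the unlooped/looped activated transcription rates —
#' are supplied here.
#'
#' `dG_oct` is the free energy of bringing O_L and O_R together when each
#' carries an adjacent cooperative CI dimer pair, forming the
#' loop-securing octamer. `dG_tet` is the free energy of adding the
#' O_L3:O_R3 CI tetramer to a loop already secured by an octamer.
#' `R_unloop` and `R_loop` are the P_RM rates (nM/min) when O_R1.O_R2 is
#' CI-bound and the DNA is unlooped or looped; transcription with O_R3
#' occupied is fully repressed, and the basal (unactivated) rate defaults
#' to `R_basal_frac * R_unloop`.
#'
#' @param dG_oct,dG_tet looping free energies in kcal/mol.
#' @param R_unloop,R_loop activated P_RM rates in nM/min (>= 0).
#' @param config path to a YAML config, or a pre-parsed list; `NULL` loads
#'   the packaged defaults.
#' @param ci_molecules_per_cell optional override of the wild-type CI
#'   level in molecules/cell (converted with `nM_per_molecule`).
#' @param phi_dimer optional override of the free-dimer fraction.
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(dG_oct = 0, dG_tet = 0, R_unloop = 1, R_loop = 1,
                          config = NULL, ci_molecules_per_cell = NULL,
                          phi_dimer = NULL) {
  if (R_unloop < 0 || R_loop < 0) stop("rates must be >= 0")
  cfg <- if (is.list(config)) config else {
    path <- if (is.null(config))
      system.file("extdata", "ci_params.yaml", package = "smloop") else config
    yaml::read_yaml(path)
  }
  p <- list(
    G = with(cfg$binding, c(OL1 = OL1, OL2 = OL2, OL3 = OL3,
                            OR1 = OR1, OR2 = OR2, OR3 = OR3)),
    coop = cfg$cooperativity,
    RT = cfg$RT,
    ci_wt_nM = cfg$ci_wt_nM,
    nM_per_molecule = cfg$nM_per_molecule,
    phi_dimer = cfg$phi_dimer,
    k_deg = log(2) / cfg$doubling_time_min,
    R_basal_frac = cfg$R_basal_frac,
    dG_oct = dG_oct, dG_tet = dG_tet,
    R_unloop = R_unloop, R_loop = R_loop)
  if (!is.null(ci_molecules_per_cell))
    p$ci_wt_nM <- ci_molecules_per_cell * p$nM_per_molecule
  if (!is.null(phi_dimer)) p$phi_dimer <- phi_dimer
  if (p$phi_dimer <= 0 || p$phi_dimer > 1) stop("phi_dimer must be in (0, 1]")
  structure(p, class = "thermo_params")
}

#' Strain specification for the lambda operator constructs
#'
#' @param name one of `"WT"` (all six subsites bindable), `"dOL"` (O_L
#'   deleted: no O_L binding, looping impossible), `"OR3m"` / `"OL3m"`
#'   (O_R3 / O_L3 mutated so CI never binds there).
#' @return object of class `strain_spec`.
#' @export
lambda_strain <- function(name = c("WT", "dOL", "OR3m", "OL3m")) {
  name <- match.arg(name)
  Ls <- c(TRUE, TRUE, TRUE); Rs <- c(TRUE, TRUE, TRUE); hasL <- TRUE
  if (name == "dOL") { hasL <- FALSE; Ls <- c(FALSE, FALSE, FALSE) }
  if (name == "OR3m") Rs[3] <- FALSE
  if (name == "OL3m") Ls[3] <- FALSE
  structure(list(name = name, L_sites = Ls, R_sites = Rs, has_OL = hasL),
            class = "strain_spec")
}

# All configurations of one operator triple: occupancy of 3 subsites plus
# an optional cooperative pairing of adjacent bound dimers (none/1-2/2-3).
operator_side_states <- function(sites) {
  out <- list()
  occs <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE)))
  for (k in seq_len(nrow(occs))) {
    occ <- occs[k, ]
    if (any(occ & !sites)) next
    pairs <- "none"
    if (occ[1] && occ[2]) pairs <- c(pairs, "p12")
    if (occ[2] && occ[3]) pairs <- c(pairs, "p23")
    for (p in pairs) out[[length(out) + 1]] <- list(occ = occ, pair = p)
  }
  out
}

thermo_rate_class <- function(occR, looped) {
  if (occR[3]) "repressed"
  else if (occR[1] && occR[2]) { if (looped) "active_looped" else "active_unlooped" }
  else "basal"
}

#' Enumerate CI-binding/looping states
#'
#' Full mode enumerates every occupancy x cooperativity x looping x
#' orientation microstate and groups microstates with identical occupancy,
#' cooperative-pair count, looping status and rate class into unique
#' states with integer degeneracies (loop orientation contributes a factor
#' 2, since looping free energies are taken to be orientation
#' independent). For the wild-type strain this yields 176 microstates in
#' 122 unique states. The loop-securing octamer may join any adjacent
#' cooperative pair on O_L with any on O_R (`octamer_pairs = "any"`), or
#' be restricted to O_L12:O_R12; the O_L3:O_R3 tetramer forms whenever the
#' octamer is at O_L12:O_R12 and both 3-subsites are bound (it is what
#' holds those dimers in the loop, so no "both bound, no tetramer" looped
#' state is enumerated).
#'
#' Minimal mode keeps only states likely to be populated near lysogenic CI
#' concentrations: O_L1.O_L2 occupied (the reference configuration) and
#' O_R either empty or with O_R1.O_R2 occupied.
#'
#' @param strain a [lambda_strain()].
#' @param mode `"full"` or `"minimal"`.
#' @param octamer_pairs `"any"` (default) or `"only12"`.
#' @return object of class `thermo_states`: data.frame with occupancy
#'   columns `L1..R3`, `n_pairs`, `oct`, `tet`, `i` (bound dimers), `d`
#'   (degeneracy), `rate_class`, `looped`; attribute `n_microstates`.
#' @export
enumerate_states <- function(strain = lambda_strain("WT"),
                             mode = c("full", "minimal"),
                             octamer_pairs = c("any", "only12")) {
  mode <- match.arg(mode)
  octamer_pairs <- match.arg(octamer_pairs)
  if (!inherits(strain, "strain_spec")) stop("`strain` must be a strain_spec")
  st <- list()
  add <- function(occL, occR, n_pairs, oct, tet, mult) {
    st[[length(st) + 1]] <<- list(occL = occL, occR = occR, n_pairs = n_pairs,
                                  oct = oct, tet = tet, mult = mult)
  }
  Ls <- if (strain$has_OL) operator_side_states(strain$L_sites)
        else list(list(occ = c(FALSE, FALSE, FALSE), pair = "none"))
  Rs <- operator_side_states(strain$R_sites)
  for (l in Ls) for (r in Rs)
    add(l$occ, r$occ, (l$pair != "none") + (r$pair != "none"), 0L, 0L, 1L)
  if (strain$has_OL) {
    pair_set <- if (octamer_pairs == "any") c("p12", "p23") else "p12"
    for (lp in pair_set) for (rp in pair_set)
      for (l3 in c(FALSE, TRUE)) for (r3 in c(FALSE, TRUE)) {
        occL <- c(lp == "p12" || (l3 && lp == "p23"), TRUE,
                  lp == "p23" || (l3 && lp == "p12"))
        occR <- c(rp == "p12" || (r3 && rp == "p23"), TRUE,
                  rp == "p23" || (r3 && rp == "p12"))
        if (any(occL & !strain$L_sites) || any(occR & !strain$R_sites)) next
        tet <- as.integer(lp == "p12" && rp == "p12" && l3 && r3)
        add(occL, occR, 2L, 1L, tet, 2L)  # x2: parallel/antiparallel loop
      }
  }
  df <- do.call(rbind, lapply(st, function(s) {
    data.frame(L1 = s$occL[1], L2 = s$occL[2], L3 = s$occL[3],
               R1 = s$occR[1], R2 = s$occR[2], R3 = s$occR[3],
               n_pairs = s$n_pairs, oct = s$oct, tet = s$tet,
               i = sum(s$occL) + sum(s$occR),
               rate_class = thermo_rate_class(s$occR, s$oct > 0),
               mult = s$mult)
  }))
  if (mode == "minimal") {
    keepL <- if (strain$has_OL) df$L1 & df$L2 else rep(TRUE, nrow(df))
    keepR <- (!df$R1 & !df$R2 & !df$R3) | (df$R1 & df$R2)
    df <- df[keepL & keepR, , drop = FALSE]
  }
  key <- apply(df[, c("L1", "L2", "L3", "R1", "R2", "R3",
                      "n_pairs", "oct", "tet", "rate_class")], 1,
               paste, collapse = "|")
  agg <- split(seq_len(nrow(df)), key)
  out <- do.call(rbind, lapply(agg, function(ix) {
    row <- df[ix[1], , drop = FALSE]
    row$d <- sum(df$mult[ix])
    row
  }))
  out$mult <- NULL
  out$looped <- out$oct > 0
  rownames(out) <- NULL
  structure(out[order(out$i, -out$d), ],
            class = c("thermo_states", "data.frame"),
            n_microstates = sum(df$mult))
}

#' State free energies under a parameter set
#'
#' @param states a [enumerate_states()] table.
#' @param params a [thermo_params()].
#' @return numeric vector of free energies in kcal/mol.
#' @export
state_energies <- function(states, params) {
  occ <- as.matrix(states[, c("L1", "L2", "L3", "R1", "R2", "R3")])
  as.numeric(occ %*% params$G) + states$n_pairs * params$coop +
    states$oct * params$dG_oct + states$tet * params$dG_tet
}

#' Boltzmann state probabilities at a free-dimer concentration
#'
#' Weights `d * [CI2]^i * exp(-dG/RT)` normalized by the partition
#' function, computed in the log domain for stability. Concentrations are
#' molar inside the weights (binding free energies are referenced to 1 M).
#'
#' @param states a [enumerate_states()] table.
#' @param ci2 free CI dimer concentration in nM (>= 0).
#' @param params a [thermo_params()].
#' @return probability vector summing to 1.
#' @export
state_probabilities <- function(states, ci2, params) {
  if (ci2 < 0) stop("ci2 must be >= 0")
  dG <- state_energies(states, params)
  logc <- if (ci2 > 0) log(ci2 * 1e-9) else -Inf
  lw <- log(states$d) + states$i * logc - dG / params$RT
  lw[states$i == 0] <- log(states$d[states$i == 0]) - dG[states$i == 0] / params$RT
  if (all(!is.finite(lw))) stop("no populated state")
  m <- max(lw[is.finite(lw)])
  w <- exp(lw - m)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

state_rates <- function(states, params) {
  r <- setNames(c(0, unname(params$R_basal_frac * params$R_unloop),
                  unname(params$R_unloop), unname(params$R_loop)),
                c("repressed", "basal", "active_unlooped", "active_looped"))
  unname(r[states$rate_class])
}

#' Mean P_RM expression rate at a free-dimer concentration
#'
#' Occupancy-weighted average of the state transcription rates,
#' `sum(R_s * P_s)`, in nM/min.
#'
#' @inheritParams state_probabilities
#' @return mean rate in nM/min.
#' @export
mean_expression_rate <- function(states, ci2, params)
  sum(state_probabilities(states, ci2, params) * state_rates(states, params))

#' Probability that the DNA is looped
#'
#' @inheritParams state_probabilities
#' @return summed probability of looped states, in \[0, 1\].
#' @export
loop_probability <- function(states, ci2, params)
  sum(state_probabilities(states, ci2, params)[states$looped])

#' Steady-state CI concentration of a strain
#'
#' Solves `mean_rate([CI2](c)) = k_deg * c` for the total CI concentration
#' `c` by bracketed root finding, with `[CI2] = phi_dimer * c / 2` (free
#' dimers per monomer-equivalent concentration). Expression in wild-type
#' lambda units is `c / ci_wt_nM`.
#'
#' @param strain a [lambda_strain()] or a pre-enumerated
#'   [enumerate_states()] table.
#' @param params a [thermo_params()].
#' @param mode passed to [enumerate_states()] when `strain` is a spec.
#' @return list with `c_nM`, `wlu`, `ci2_nM`, `rate_nM_min`.
#' @export
steady_state_concentration <- function(strain, params, mode = "full") {
  states <- if (inherits(strain, "thermo_states")) strain
            else enumerate_states(strain, mode = mode)
  rates <- state_rates(states, params)
  if (max(rates) <= 0)
    return(list(c_nM = 0, wlu = 0, ci2_nM = 0, rate_nM_min = 0))
  net <- function(c) mean_expression_rate(states, params$phi_dimer * c / 2, params) -
    params$k_deg * c
  upper <- max(rates) / params$k_deg * 1.01
  lo <- 1e-9
  if (net(lo) <= 0)
    return(list(c_nM = 0, wlu = 0, ci2_nM = 0, rate_nM_min = 0))
  if (net(upper) >= 0) stop("no sign change in steady-state bracket")
  c_ss <- uniroot(net, c(lo, upper), tol = 1e-9)$root
  list(c_nM = c_ss, wlu = c_ss / params$ci_wt_nM,
       ci2_nM = params$phi_dimer * c_ss / 2,
       rate_nM_min = params$k_deg * c_ss)
}

#' Measured observables of the looping study
#'
#' Convenience constructor for the seven-fit-target observable set:
#' looping frequencies for the wild type and the two subsite-3 mutants,
#' and expression levels (WLU) for those plus the O_L deletion. Defaults
#' are the values measured in the original study.
#'
#' @param f named looping frequencies (fractions).
#' @param wlu named expression levels in wild-type lambda units.
#' @param f_sem,wlu_sem measurement errors (1 sem).
#' @return object of class `observable_set`.
#' @export
observable_set <- function(f = c(WT = 0.79, OR3m = 0.53, OL3m = 0.60),
                           wlu = c(dOL = 1.38, WT = 1.00, OR3m = 2.50, OL3m = 2.51),
                           f_sem = c(WT = 0.06, OR3m = 0.07, OL3m = 0.07),
                           wlu_sem = c(dOL = 0.05, WT = 0.05, OR3m = 0.07, OL3m = 0.07)) {
  if (any(f < 0 | f > 1)) stop("frequencies must be in [0, 1]")
  if (any(wlu <= 0)) stop("WLU must be > 0")
  structure(list(f = f, wlu = wlu, f_sem = f_sem, wlu_sem = wlu_sem),
            class = "observable_set")
}

#' Model-predicted observables at a parameter set
#'
#' Each strain's steady state is solved; looping frequencies are evaluated
#' at the strain's steady-state free-dimer concentration and expression
#' levels are steady-state concentrations in wild-type lambda units
#' (relative to the fixed lysogenic `ci_wt_nM`).
#'
#' @param params a [thermo_params()].
#' @param mode enumeration mode.
#' @param states_list optional pre-enumerated state tables named by
#'   strain, to avoid re-enumeration inside fitting loops.
#' @return `observable_set` (sem fields NA) with attribute `steady_states`.
#' @export
predict_observables <- function(params, mode = "full", states_list = NULL) {
  strains <- c("WT", "dOL", "OR3m", "OL3m")
  if (is.null(states_list))
    states_list <- setNames(lapply(strains, function(s)
      enumerate_states(lambda_strain(s), mode = mode)), strains)
  ss <- lapply(states_list, steady_state_concentration, params = params)
  f <- vapply(c("WT", "OR3m", "OL3m"), function(s)
    loop_probability(states_list[[s]], ss[[s]]$ci2_nM, params), numeric(1))
  wlu <- vapply(strains[c(2, 1, 3, 4)], function(s) ss[[s]]$wlu, numeric(1))
  out <- structure(list(f = f, wlu = wlu,
                        f_sem = rep(NA_real_, 3), wlu_sem = rep(NA_real_, 4)),
                   class = "observable_set")
  attr(out, "steady_states") <- ss
  out
}

observable_sse <- function(pred, obs) {
  sum((pred$f - obs$f[names(pred$f)])^2) +
    sum((pred$wlu - obs$wlu[names(pred$wlu)])^2)
}

#' Fit the four free parameters to measured observables
#'
#' Minimizes the unweighted sum of squared differences between modeled and
#' measured observables (frequencies as fractions, expression in WLU) over
#' `(dG_oct, dG_tet, R_unloop, R_loop)`: a coarse grid scan followed by
#' Nelder-Mead refinement. Deterministic given the options.
#'
#' @param observables an [observable_set()].
#' @param params a [thermo_params()] carrying the fixed parameters.
#' @param mode enumeration mode (`"full"` or `"minimal"`).
#' @param grid named list of candidate vectors `dG_oct`, `dG_tet`,
#'   `R_unloop`, `R_loop` for the coarse scan.
#' @param reltol relative tolerance of the refinement.
#' @return object of class `thermo_fit`: list with `params` (fitted
#'   [thermo_params()]), `par`, `sse`, `activation_ratio`
#'   (`R_loop/R_unloop`), `predicted`, `grid_best`.
#' @export
fit_free_parameters <- function(observables, params = thermo_params(),
                                mode = "full",
                                grid = list(dG_oct = seq(-1, 2, 0.5),
                                            dG_tet = seq(-5, -1, 0.5),
                                            R_unloop = seq(1, 4, 0.75),
                                            R_loop = seq(2, 8, 1.5)),
                                reltol = 1e-10) {
  strains <- c("WT", "dOL", "OR3m", "OL3m")
  states_list <- setNames(lapply(strains, function(s)
    enumerate_states(lambda_strain(s), mode = mode)), strains)
  with_par <- function(x) {
    p <- params
    p$dG_oct <- x[1]; p$dG_tet <- x[2]; p$R_unloop <- x[3]; p$R_loop <- x[4]
    p
  }
  sse <- function(x) {
    if (x[3] < 0 || x[4] < 0) return(1e6)
    pred <- tryCatch(predict_observables(with_par(x), states_list = states_list),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    observable_sse(pred, observables)
  }
  g <- as.matrix(expand.grid(grid$dG_oct, grid$dG_tet, grid$R_unloop, grid$R_loop))
  vals <- apply(g, 1, sse)
  x0 <- g[which.min(vals), ]
  op <- optim(x0, sse, method = "Nelder-Mead",
              control = list(maxit = 4000, reltol = reltol))
  op <- optim(op$par, sse, method = "Nelder-Mead",      # restart polishes
              control = list(maxit = 4000, reltol = reltol))
  if (!is.finite(op$value) || op$value >= 1e6)
    stop("fit failed to converge; inspect the residual landscape")
  pfit <- with_par(op$par)
  structure(list(params = pfit,
                 par = setNames(unname(op$par),
                                c("dG_oct", "dG_tet", "R_unloop", "R_loop")),
                 sse = op$value,
                 activation_ratio = unname(op$par[4] / op$par[3]),
                 predicted = predict_observables(pfit, states_list = states_list),
                 grid_best = setNames(x0, c("dG_oct", "dG_tet", "R_unloop", "R_loop"))),
            class = "thermo_fit")
}

#' Residual landscape over a parameter pair
#'
#' For each value of the fixed pair, the sum of squared residuals is
#' minimized over the other pair; the log10 of that minimum is returned on
#' the grid. Well-defined minima indicate uniquely determined parameters.
#'
#' @param observables an [observable_set()].
#' @param fit a [fit_free_parameters()] result (supplies fixed parameters
#'   and starting values).
#' @param pair `"energies"` (grid over dG_oct, dG_tet) or `"rates"`.
#' @param grid1,grid2 grid vectors for the two fixed parameters.
#' @param mode enumeration mode.
#' @return list with `grid1`, `grid2`, `log10_min_sse` (matrix), `pair`.
#' @export
residual_landscape <- function(observables, fit, pair = c("energies", "rates"),
                               grid1, grid2, mode = "full") {
  pair <- match.arg(pair)
  strains <- c("WT", "dOL", "OR3m", "OL3m")
  states_list <- setNames(lapply(strains, function(s)
    enumerate_states(lambda_strain(s), mode = mode)), strains)
  base <- fit$par
  sse4 <- function(x) {
    p <- fit$params
    p$dG_oct <- x[1]; p$dG_tet <- x[2]; p$R_unloop <- x[3]; p$R_loop <- x[4]
    if (x[3] < 0 || x[4] < 0) return(1e6)
    pred <- tryCatch(predict_observables(p, states_list = states_list),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    observable_sse(pred, observables)
  }
  fixed_idx <- if (pair == "energies") 1:2 else 3:4
  free_idx <- setdiff(1:4, fixed_idx)
  m <- matrix(NA_real_, length(grid1), length(grid2))
  for (a in seq_along(grid1)) for (b in seq_along(grid2)) {
    x <- base
    x[fixed_idx] <- c(grid1[a], grid2[b])
    op <- optim(base[free_idx], function(y) { x[free_idx] <- y; sse4(x) },
                method = "Nelder-Mead", control = list(maxit = 400, reltol = 1e-8))
    m[a, b] <- log10(op$value)
  }
  list(grid1 = grid1, grid2 = grid2, log10_min_sse = m, pair = pair)
}

#' Sensitivity of the fit to the fixed CI level and dimer fraction
#'
#' Refits the four free parameters for each combination of wild-type CI
#' level (molecules/cell) and free-dimer fraction, recording the refit
#' results; per-point failures are recorded and the scan continues.
#'
#' @param observables an [observable_set()].
#' @param ci_levels wild-type CI levels in molecules/cell.
#' @param dimer_fractions free-dimer fractions in (0, 1].
#' @param params base [thermo_params()].
#' @param mode enumeration mode.
#' @param grid coarse grid passed to [fit_free_parameters()].
#' @return data.frame with one refit per grid point: `ci_molecules`,
#'   `phi_dimer`, `dG_oct`, `dG_tet`, `R_unloop`, `R_loop`,
#'   `activation_ratio`, `sse`, `ok`.
#' @export
sensitivity_scan <- function(observables, ci_levels = c(110, 150, 220),
                             dimer_fractions = c(0.05, 0.1, 0.2),
                             params = thermo_params(), mode = "full",
                             grid = NULL) {
  rows <- list()
  for (nci in ci_levels) for (phi in dimer_fractions) {
    p <- params
    p$ci_wt_nM <- nci * p$nM_per_molecule
    p$phi_dimer <- phi
    res <- tryCatch({
      args <- list(observables = observables, params = p, mode = mode)
      if (!is.null(grid)) args$grid <- grid
      do.call(fit_free_parameters, args)
    }, error = function(e) NULL)
    rows[[length(rows) + 1]] <- if (is.null(res))
      data.frame(ci_molecules = nci, phi_dimer = phi, dG_oct = NA, dG_tet = NA,
                 R_unloop = NA, R_loop = NA, activation_ratio = NA, sse = NA,
                 ok = FALSE)
    else
      data.frame(ci_molecules = nci, phi_dimer = phi,
                 dG_oct = unname(res$par[1]), dG_tet = unname(res$par[2]),
                 R_unloop = unname(res$par[3]), R_loop = unname(res$par[4]),
                 activation_ratio = res$activation_ratio, sse = res$sse,
                 ok = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
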