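#' Candidate tandem-SH2 binding modes
#'
#' A tandem-SH2 phosphatase can engage a dual-phosphotyrosine receptor in
#' six ways: four monovalent (one SH2 domain on one motif) and two
#' bivalent. The *parallel* bivalent mode pairs nSH2 with the N-terminal
#' ITIM and cSH2 with the C-terminal ITSM; the *antiparallel* mode is the
#' crossed arrangement (nSH2:ITSM, cSH2:ITIM).
#'
#' @format A character vector of the six mode labels.
#' @export
BINDING_MODES <- c("MONO_nSH2_ITIM", "MONO_nSH2_ITSM",
                   "MONO_cSH2_ITIM", "MONO_cSH2_ITSM",
                   "BIVALENT_PARALLEL", "BIVALENT_ANTIPARALLEL")

mode_pairs <- function(mode) {
  switch(mode,
         MONO_nSH2_ITIM = list(c("nSH2", "ITIM")),
         MONO_nSH2_ITSM = list(c("nSH2", "ITSM")),
         MONO_cSH2_ITIM = list(c("cSH2", "ITIM")),
         MONO_cSH2_ITSM = list(c("cSH2", "ITSM")),
         BIVALENT_PARALLEL = list(c("nSH2", "ITIM"), c("cSH2", "ITSM")),
         BIVALENT_ANTIPARALLEL = list(c("nSH2", "ITSM"), c("cSH2", "ITIM")),
         stop_invalid("unknown mode ", mode))
}

#' Enumerate binding-mode free energies
#'
#' Converts the four pairwise motif:SH2 dissociation constants of one
#' receptor:phosphatase combination into standard free energies for all
#' six candidate binding modes. Monovalent modes use
#' \eqn{\Delta G = RT\ln(K_d/c^\circ)}. Bivalent modes use the
#' effective-concentration avidity cycle
#' \eqn{\Delta G_{biv} = \Delta G_1 + \Delta G_2 - RT\ln(C_{eff}/c^\circ)}:
#' once the first arm is docked, the second binds as a pseudo-intramolecular
#' event at local concentration `c_eff`. A mode containing a not-detected
#' constituent is infeasible and carries no free energy.
#'
#' @param table an [affinity_table()].
#' @param receptor,phosphatase which combination to analyse.
#' @param c_eff effective concentration in M (default 1e-3, i.e. 1 mM; the
#'   parallel-vs-antiparallel ordering does not depend on it).
#' @param temperature K (default 298).
#' @return a `mode_energies` data.frame: `mode`, `delta_g` (kcal/mol,
#'   `NA` if infeasible), `feasible`, `c_eff`, `bivalent`.
#' @export
enumerate_modes <- function(table, receptor, phosphatase, c_eff = 1e-3,
                            temperature = 298) {
  assert_that(c_eff > 0, "c_eff must be positive")
  kd <- sapply(c("nSH2.ITIM", "nSH2.ITSM", "cSH2.ITIM", "cSH2.ITSM"),
               function(key) {
                 parts <- strsplit(key, ".", fixed = TRUE)[[1]]
                 lookup_kd(table, receptor, parts[2], phosphatase, parts[1])
               })
  rt <- GAS_CONSTANT_KCAL * temperature
  rows <- lapply(BINDING_MODES, function(mode) {
    pairs <- mode_pairs(mode)
    kds <- vapply(pairs, function(p) kd[[paste(p[1], p[2], sep = ".")]], 0)
    bivalent <- length(pairs) == 2L
    if (anyNA(kds)) {
      data.frame(mode = mode, delta_g = NA_real_, feasible = FALSE,
                 c_eff = if (bivalent) c_eff else NA_real_, bivalent = bivalent)
    } else {
      dg <- sum(vapply(kds, function(k) delta_g(k, temperature)$delta_g, 0))
      if (bivalent) dg <- dg - rt * log(c_eff)
      data.frame(mode = mode, delta_g = dg, feasible = TRUE,
                 c_eff = if (bivalent) c_eff else NA_real_, bivalent = bivalent)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "receptor") <- receptor
  attr(out, "phosphatase") <- phosphatase
  attr(out, "temperature") <- temperature
  structure(out, class = c("mode_energies", "data.frame"))
}

#' Rank binding modes by free energy
#'
#' Orders feasible modes by ascending free energy (most favorable first);
#' infeasible modes are appended last. For two bivalent modes the ordering
#' is independent of the effective concentration and equals the ordering of
#' the products of their constituent Kd's.
#'
#' @param modes a `mode_energies` table from [enumerate_modes()].
#' @return the same table, reordered, with a `rank` column (`NA` for
#'   infeasible modes).
#' @export
rank_modes <- function(modes) {
  stopifnot(inherits(modes, "mode_energies"))
  feas <- modes[modes$feasible, , drop = FALSE]
  if (!nrow(feas)) stop_invalid("no feasible binding mode to rank")
  feas <- feas[order(feas$delta_g), , drop = FALSE]
  feas$rank <- seq_len(nrow(feas))
  infeas <- modes[!modes$feasible, , drop = FALSE]
  if (nrow(infeas)) infeas$rank <- NA_integer_
  out <- rbind(feas, infeas)
  rownames(out) <- NULL
  for (a in c("receptor", "phosphatase", "temperature"))
    attr(out, a) <- attr(modes, a)
  structure(out, class = c("mode_energies", "data.frame"))
}

#' Equilibrium occupancy of binding modes
#'
#' Boltzmann-weighted partition over the unbound state and all feasible
#' modes at a given free phosphatase concentration. Each mode's statistical
#' weight is \eqn{(c/c^\circ)\,e^{-\Delta G/RT}} (one phosphatase is
#' consumed per complex, whatever the mode); the unbound receptor has
#' weight 1. Absolute occupancies depend on the free-energy zero, but
#' occupancies conditional on being bound are invariant under a uniform
#' shift of all mode energies.
#'
#' @param modes a `mode_energies` table.
#' @param free_phosphatase_conc free phosphatase concentration in M.
#' @return data.frame `mode`, `occupancy` with one extra `UNBOUND` row;
#'   occupancies sum to 1.
#' @export
mode_occupancy <- function(modes, free_phosphatase_conc) {
  stopifnot(inherits(modes, "mode_energies"))
  assert_that(free_phosphatase_conc > 0, "concentration must be positive")
  feas <- modes[modes$feasible, , drop = FALSE]
  if (!nrow(feas)) stop_invalid("no feasible binding mode")
  rt <- GAS_CONSTANT_KCAL * (attr(modes, "temperature") %||% 298)
  # log-weights, stabilized against overflow
  lw <- log(free_phosphatase_conc) - feas$delta_g / rt
  lw <- c(0, lw)  # unbound state
  w <- exp(lw - max(lw))
  occ <- w / sum(w)
  data.frame(mode = c("UNBOUND", feas$mode), occupancy = occ)
}

#' Minimal effective concentration for bivalent advantage
#'
#' The smallest effective concentration at which the bivalent parallel
#' mode becomes more favorable than the best monovalent mode. From
#' \eqn{\Delta G_1 + \Delta G_2 - RT\ln(C_{eff}/c^\circ) <
#' RT\ln(K_{d,best}/c^\circ)} the closed form is
#' \eqn{C^*_{eff} = K_{d,1} K_{d,2} / K_{d,best\,mono}} (all in M).
#'
#' @param table an [affinity_table()].
#' @param receptor,phosphatase combination to analyse.
#' @return threshold effective concentration in M.
#' @export
min_ceff_for_bivalent_advantage <- function(table, receptor, phosphatase) {
  kd_n_itim <- lookup_kd(table, receptor, "ITIM", phosphatase, "nSH2")
  kd_c_itsm <- lookup_kd(table, receptor, "ITSM", phosphatase, "cSH2")
  if (is.na(kd_n_itim) || is.na(kd_c_itsm))
    stop_invalid("parallel mode infeasible: a constituent Kd is NOT_DETECTED")
  monos <- c(kd_n_itim,
             lookup_kd(table, receptor, "ITSM", phosphatase, "nSH2"),
             lookup_kd(table, receptor, "ITIM", phosphatase, "cSH2"),
             kd_c_itsm)
  best_mono <- min(monos, na.rm = TRUE)
  (kd_n_itim * 1e-6) * (kd_c_itsm * 1e-6) / (best_mono * 1e-6)
}
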