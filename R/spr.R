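#' Equilibrium binding isotherm
#'
#' Container for an equilibrium SPR concentration-response series: analyte
#' concentrations (nM) and equilibrium responses (RU). Points are sorted by
#' concentration on construction.
#'
#' @param concentration_nM analyte concentrations, nM; strictly positive.
#' @param response_RU equilibrium responses, RU.
#' @param analyte_id,ligand_id free-text labels (e.g. "SHP2-cSH2",
#'   "PD-1-ITSM").
#' @return an object of class `isotherm` (a data.frame with attributes).
#' @export
isotherm <- function(concentration_nM, response_RU,
                     analyte_id = "analyte", ligand_id = "ligand") {
  assert_that(length(concentration_nM) == length(response_RU),
              "concentration and response lengths differ")
  assert_that(all(concentration_nM > 0), "concentrations must be strictly positive")
  ord <- order(concentration_nM)
  assert_that(!anyDuplicated(concentration_nM), "duplicate concentrations")
  df <- data.frame(concentration_nM = concentration_nM[ord],
                   response_RU = response_RU[ord])
  structure(df, analyte_id = analyte_id, ligand_id = ligand_id,
            class = c("isotherm", "data.frame"))
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("Isotherm %s : %s (%d points)\n", attr(x, "analyte_id"),
              attr(x, "ligand_id"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Fit a 1:1 Langmuir isotherm
#'
#' Unweighted nonlinear least squares of
#' \eqn{R_{eq} = R_{max} C / (K_d + C)} against an equilibrium isotherm,
#' mirroring an EC50-style equilibrium evaluation of SPR sensorgram
#' plateaus (no kinetic information is used). Near-zero response series are
#' classified as not-detected rather than fitted: the binding partner of a
#' series whose maximal response stays below `nd_threshold` times the
#' response-noise estimate is reported as having no detectable binding.
#'
#' @param iso an [isotherm()] with >= 4 points.
#' @param init_strategy initializer: `"heuristic"` (default; `r_max` is
#'   1.1 x the maximal response and `kd` the concentration nearest half of
#'   that) or a numeric `c(kd =, r_max =)` vector in nM/RU.
#' @param nd_threshold multiple of the noise scale below which the series
#'   counts as no detectable binding (default 3).
#' @return an `isotherm_fit`: list with `kd_uM`, `r_max`, standard errors,
#'   `rss`, `converged`, and `not_detected`.
#' @examples
#' fit_isotherm(gen_isotherm(100, 100, noise_sd = 0)$isotherm)
#' @export
fit_isotherm <- function(iso, init_strategy = "heuristic", nd_threshold = 3) {
  stopifnot(inherits(iso, "isotherm"))
  assert_that(nrow(iso) >= 4, "need >= 4 points to fit")
  C <- iso$concentration_nM; R <- iso$response_RU

  noise <- diff_sigma(R)
  if (max(R) < nd_threshold * max(noise, .Machine$double.eps)) {
    return(structure(list(kd_uM = NA_real_, r_max = NA_real_,
                          kd_se_uM = NA_real_, r_max_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          not_detected = TRUE,
                          analyte_id = attr(iso, "analyte_id"),
                          ligand_id = attr(iso, "ligand_id")),
                     class = "isotherm_fit"))
  }

  if (identical(init_strategy, "heuristic")) {
    r0 <- 1.1 * max(R)
    k0 <- C[which.min(abs(R - r0 / 2))]
  } else {
    k0 <- init_strategy[["kd"]]; r0 <- init_strategy[["r_max"]]
  }

  fit <- tryCatch(
    stats::nls(R ~ rmax * C / (kd + C),
               start = list(kd = k0, rmax = r0),
               lower = c(kd = 1e-9, rmax = 1e-9), algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(kd_uM = NA_real_, r_max = NA_real_,
                          kd_se_uM = NA_real_, r_max_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          not_detected = FALSE,
                          analyte_id = attr(iso, "analyte_id"),
                          ligand_id = attr(iso, "ligand_id")),
                     class = "isotherm_fit"))
  }
  co <- summary(fit)$coefficients
  structure(list(kd_uM = unname(co["kd", "Estimate"]) / 1e3,
                 r_max = unname(co["rmax", "Estimate"]),
                 kd_se_uM = unname(co["kd", "Std. Error"]) / 1e3,
                 r_max_se = unname(co["rmax", "Std. Error"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv,
                 not_detected = FALSE,
                 analyte_id = attr(iso, "analyte_id"),
                 ligand_id = attr(iso, "ligand_id")),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (x$not_detected) {
    cat(sprintf("Isotherm fit %s : %s -- no detectable binding\n",
                x$analyte_id, x$ligand_id))
  } else {
    cat(sprintf("Isotherm fit %s : %s\n  Kd = %.3g uM (se %.2g), Rmax = %.4g RU, RSS = %.3g%s\n",
                x$analyte_id, x$ligand_id, x$kd_uM, x$kd_se_uM, x$r_max,
                x$rss, if (x$converged) "" else "  [NOT CONVERGED]"))
  }
  invisible(x)
}

#' Affinity fold ratio
#'
#' Ratio of two dissociation constants. `fold_ratio(kd_a, kd_b)` returns
#' `kd_a / kd_b`, the fold by which partner B binds more tightly than
#' partner A ("x-fold higher affinity" of B over A).
#'
#' @param kd_a,kd_b dissociation constants in the same units; both must be
#'   present (not `NA`/not-detected) and positive.
#' @return the dimensionless ratio, with attribute `nearest_integer`.
#' @examples
#' fold_ratio(1.7, 0.10)   # 17
#' @export
fold_ratio <- function(kd_a, kd_b) {
  if (is.na(kd_a) || is.na(kd_b))
    stop_invalid("fold ratio undefined: an operand is NOT_DETECTED")
  assert_that(kd_a > 0 && kd_b > 0, "Kd values must be positive")
  r <- kd_a / kd_b
  attr(r, "nearest_integer") <- round(r)
  r
}

#' Standard binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(K_d / c^\circ)} with standard state
#' \eqn{c^\circ = 1} M and \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K).
#' Sub-molar dissociation constants give negative free energies.
#'
#' @param kd_uM dissociation constant in micromolar; `NA` denotes a
#'   not-detected interaction.
#' @param temperature absolute temperature in K (default 298).
#' @return a `free_energy` list: `delta_g` (kcal/mol), `temperature`,
#'   `gas_constant`, `censored`. For a not-detected Kd the energy is
#'   censored: `delta_g` is `NA` with a finite `lower_bound` of 0 (the
#'   interaction is at best unmeasurably weak), never a number.
#' @examples
#' delta_g(0.10)  # about -9.55 kcal/mol at 298 K
#' @export
delta_g <- function(kd_uM, temperature = 298) {
  assert_that(temperature > 0, "temperature must be positive")
  if (is.na(kd_uM)) {
    return(structure(list(delta_g = NA_real_, censored = TRUE,
                          lower_bound = 0,
                          temperature = temperature,
                          gas_constant = GAS_CONSTANT_KCAL),
                     class = "free_energy"))
  }
  assert_that(kd_uM > 0, "kd must be positive")
  structure(list(delta_g = GAS_CONSTANT_KCAL * temperature * log(kd_uM * 1e-6),
                 censored = FALSE, lower_bound = NA_real_,
                 temperature = temperature,
                 gas_constant = GAS_CONSTANT_KCAL),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  if (x$censored)
    cat(sprintf("dG censored (no detectable binding), T = %g K\n", x$temperature))
  else
    cat(sprintf("dG = %.3f kcal/mol at T = %g K\n", x$delta_g, x$temperature))
  invisible(x)
}

#' Simulate a 1:1 SPR sensorgram
#'
#' Pseudo-first-order 1:1 interaction model. During association at analyte
#' concentration C, \eqn{R(t) = R_{eq}(1 - e^{-(k_{on} C + k_{off}) t})}
#' with \eqn{R_{eq} = R_{max} C / (K_d + C)}; after `t_assoc` the analyte
#' is washed out and the response decays as \eqn{e^{-k_{off} t}}. This is a
#' forward simulator only; kinetic constants are never estimated from it.
#'
#' @param k_on association rate, 1/(M s).
#' @param k_off dissociation rate, 1/s.
#' @param C analyte concentration, M (may be 0).
#' @param times time grid, s.
#' @param r_max saturation response, RU.
#' @param t_assoc end of the association phase, s (default `max(times)`,
#'   i.e. association only).
#' @return data.frame `time_s`, `response_RU`.
#' @export
simulate_sensorgram <- function(k_on, k_off, C, times, r_max = 100,
                                t_assoc = max(times)) {
  assert_that(k_on > 0 && k_off > 0, "rates must be positive")
  assert_that(C >= 0, "concentration must be non-negative")
  kd <- k_off / k_on
  r_eq <- r_max * C / (kd + C)
  kobs <- k_on * C + k_off
  resp <- ifelse(times <= t_assoc,
                 r_eq * (1 - exp(-kobs * times)),
                 r_eq * (1 - exp(-kobs * t_assoc)) *
                   exp(-k_off * (times - t_assoc)))
  data.frame(time_s = times, response_RU = resp)
}

NOT_DETECTED <- NA_real_

#' Affinity table of motif:SH2 dissociation constants
#'
#' One record per (receptor, motif, phosphatase, SH2 domain) combination,
#' with the dissociation constant in micromolar or `NA` for interactions
#' with no detectable binding. This table is the quantitative backbone of
#' the binding-mode analysis.
#'
#' @param receptor,motif,phosphatase,sh2 character vectors; motif in
#'   `{"ITIM","ITSM"}`, sh2 in `{"nSH2","cSH2"}`.
#' @param kd_uM numeric Kd in uM; `NA` = not detected.
#' @param source optional provenance label per record.
#' @return an `affinity_table` data.frame.
#' @seealso [affinity_fixture()] for the bundled PD-1/BTLA table.
#' @export
affinity_table <- function(receptor, motif, phosphatase, sh2, kd_uM,
                           source = NA_character_) {
  df <- data.frame(receptor = receptor, motif = motif,
                   phosphatase = phosphatase, sh2 = sh2, kd_uM = kd_uM,
                   source = source, stringsAsFactors = FALSE)
  assert_that(all(df$motif %in% c("ITIM", "ITSM")), "motif must be ITIM or ITSM")
  assert_that(all(df$sh2 %in% c("nSH2", "cSH2")), "sh2 must be nSH2 or cSH2")
  key <- with(df, paste(receptor, motif, phosphatase, sh2))
  assert_that(!anyDuplicated(key), "duplicate (receptor, motif, phosphatase, sh2) record")
  assert_that(all(is.na(df$kd_uM) | df$kd_uM > 0), "kd must be positive when present")
  structure(df, class = c("affinity_table", "data.frame"))
}

#' Bundled PD-1/BTLA affinity fixture
#'
#' The measured dissociation constants between individual SH2 domains of
#' SHP1/SHP2 and the lone-tyrosine ITIM/ITSM variants of PD-1 and BTLA.
#' All eight PD-1 records and two BTLA records (SHP1-nSH2:BTLA-ITIM,
#' SHP1-cSH2:BTLA-ITSM) are measured values; the remaining six BTLA
#' records are synthetic stand-ins (flagged `source == "synthetic"`)
#' chosen to respect the qualitatively reported domain preferences (nSH2
#' prefers BTLA-ITIM, cSH2 prefers BTLA-ITSM, for both phosphatases).
#' SHP1-cSH2 showed no detectable binding to PD-1-ITIM (`NA`).
#'
#' @param printed_only drop the synthetic BTLA stand-ins (default FALSE).
#' @return an [affinity_table()].
#' @export
affinity_fixture <- function(printed_only = FALSE) {
  path <- system.file("extdata", "affinity_table.csv", package = "sh2spec")
  tab <- read_affinity_table(path)
  if (printed_only) tab <- tab[tab$source == "printed", , drop = FALSE]
  structure(tab, class = c("affinity_table", "data.frame"))
}

#' Read / write an affinity table (CSV)
#'
#' CSV columns `receptor,motif,phosphatase,sh2,kd_uM` (plus optional
#' `source`); the string `ND` in `kd_uM` denotes no detectable binding.
#'
#' @param path file path.
#' @return an [affinity_table()].
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(kd_uM = "character"))
  kd <- suppressWarnings(as.numeric(ifelse(df$kd_uM %in% c("ND", ""), NA, df$kd_uM)))
  affinity_table(df$receptor, df$motif, df$phosphatase, df$sh2, kd,
                 source = df$source %||% NA_character_)
}

#' @rdname read_affinity_table
#' @param tab an [affinity_table()].
#' @export
write_affinity_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$kd_uM <- ifelse(is.na(out$kd_uM), "ND", format(out$kd_uM, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# look up one Kd (uM); error if the record is absent
lookup_kd <- function(tab, receptor, motif, phosphatase, sh2) {
  hit <- tab$receptor == receptor & tab$motif == motif &
    tab$phosphatase == phosphatase & tab$sh2 == sh2
  if (sum(hit) != 1)
    stop_invalid("affinity table has no record for ",
                 paste(receptor, motif, phosphatase, sh2, sep = ":"))
  tab$kd_uM[hit]
}

#' Read / write isotherms (CSV)
#'
#' Long-format CSV `analyte,ligand,concentration_nM,response_RU`; one
#' isotherm per (analyte, ligand) pair.
#'
#' @param path file path.
#' @return a list of [isotherm()] objects.
#' @export
read_isotherms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("analyte", "ligand")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$analyte == keys$analyte[i] & df$ligand == keys$ligand[i], ]
    isotherm(sub$concentration_nM, sub$response_RU,
             analyte_id = keys$analyte[i], ligand_id = keys$ligand[i])
  })
}

#' @rdname read_isotherms
#' @param isos a list of [isotherm()] objects (or a single one).
#' @export
write_isotherms <- function(isos, path) {
  if (inherits(isos, "isotherm")) isos <- list(isos)
  rows <- do.call(rbind, lapply(isos, function(iso) {
    data.frame(analyte = attr(iso, "analyte_id"),
               ligand = attr(iso, "ligand_id"),
               concentration_nM = iso$concentration_nM,
               response_RU = iso$response_RU)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
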