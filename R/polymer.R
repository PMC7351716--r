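#' Apparent hydrodynamic volume of a polymer coil
#'
#' Sphere volume from the hydrodynamic radius, `V = (4/3) * pi * Rh^3`.
#' Canonical units: `Rh` in nanometres, volume in cubic micrometres.
#'
#' @param RhNm Hydrodynamic radius in nm (> 0).
#' @return Apparent volume in um^3.
#' @examples
#' apparentVolume(100)  # ~4.19e-3 um^3
#' @export
apparentVolume <- function(RhNm) {
  if (any(RhNm <= 0)) stop("radius must be > 0")
  (4 / 3) * pi * (RhNm / 1000)^3
}

#' Hydrodynamic radius from an apparent volume
#'
#' Cube-root inversion of [apparentVolume()].
#'
#' @param VumCubed Apparent volume in um^3 (> 0).
#' @return Radius in nm.
#' @export
radiusFromVolume <- function(VumCubed) {
  if (any(VumCubed <= 0)) stop("volume must be > 0")
  1000 * (3 * VumCubed / (4 * pi))^(1 / 3)
}

#' Apparent density of a polymer coil
#'
#' `rho = Mw / (V * N_A)`: the mass of one chain spread over its
#' hydrodynamic volume. For multi-megadalton coils occupying ~1e-3 um^3
#' this comes out at a few mg/cm^3 - the coil is almost entirely solvent,
#' which is what keeps grafted anchor strands accessible.
#'
#' @param Mw Weight-average molecular weight in g/mol (> 0).
#' @param VumCubed Apparent volume in um^3 (> 0).
#' @return Apparent density in g/cm^3.
#' @examples
#' apparentDensity(5.73e6, 2.7e-3)  # ~3.5e-3 g/cm^3
#' @export
apparentDensity <- function(Mw, VumCubed) {
  if (any(Mw <= 0) || any(VumCubed <= 0)) stop("inputs must be > 0")
  Mw / (VumCubed * 1e-12 * .N_AVOGADRO)  # 1 um^3 = 1e-12 cm^3
}

#' Water mass fraction inside a polymer coil
#'
#' `100 * (1 - rho_app / rho_solution)`, the percentage of the coil's
#' hydrodynamic volume that is solvent.
#'
#' @param rhoApp Apparent coil density in g/cm^3.
#' @param rhoSolution Solution density in g/cm^3 (default 1.0).
#' @return Water fraction in percent.
#' @export
waterFraction <- function(rhoApp, rhoSolution = 1.0) {
  if (any(rhoApp <= 0)) stop("apparent density must be > 0")
  if (any(rhoApp >= rhoSolution))
    stop("apparent density must be below the solution density")
  100 * (1 - rhoApp / rhoSolution)
}

#' Fit the conformation scaling exponent
#'
#' Ordinary least squares on `log Rg = log K + nu * log M` across a
#' fractionation series. The exponent diagnoses chain conformation:
#' about 0.33 for a compact (hard-sphere-like) globule, about 0.5 for a
#' statistical chain in a theta solvent; branched, compact architectures
#' fall in between.
#'
#' @param M Molar masses (g/mol), >= 3 strictly increasing values.
#' @param Rg Gyration radii (same length as `M`).
#' @return List with `nu`, `K`, and `nuSE` (standard error of `nu`).
#' @examples
#' M <- c(1e6, 2e6, 4e6, 8e6)
#' fitScalingExponent(M, 0.05 * M^0.5)$nu  # 0.5
#' @export
fitScalingExponent <- function(M, Rg) {
  if (length(M) < 3L || length(Rg) != length(M))
    stop("need >= 3 (M, Rg) pairs")
  if (any(diff(M) <= 0)) stop("masses must be strictly increasing")
  if (any(M <= 0) || any(Rg <= 0)) stop("masses and radii must be > 0")
  fit <- lm(log(Rg) ~ log(M))
  # summary.lm warns on noiseless power laws ("essentially perfect fit");
  # exact recovery is a supported use here
  cf <- suppressWarnings(coef(summary(fit)))
  list(nu = unname(cf["log(M)", "Estimate"]),
       K = exp(unname(cf["(Intercept)", "Estimate"])),
       nuSE = unname(cf["log(M)", "Std. Error"]))
}

#' Theoretical anchor capacity of a polymer
#'
#' Moles of hybridization sites per unit polymer mass, `o / chainMass`,
#' reported in nmol per mg (1 mol/g = 1e6 nmol/mg). A chain with ~100
#' anchors at ~5 MDa offers ~20 nmol/mg - one to two orders of magnitude
#' above what interfacial crowding allows on streptavidin microbeads.
#'
#' @param o Anchor strands per chain (>= 0).
#' @param chainMass Chain molecular weight in g/mol (> 0).
#' @return Capacity in nmol anchor per mg polymer.
#' @examples
#' theoreticalCapacity(100, 5e6)  # 20 nmol/mg
#' @export
theoreticalCapacity <- function(o, chainMass) {
  if (any(o < 0)) stop("anchor count must be >= 0")
  if (any(chainMass <= 0)) stop("chain mass must be > 0")
  o / chainMass * 1e6
}

#' Measured-over-theoretical capacity utilization
#'
#' @param measured Measured binding capacity (nmol/mg).
#' @param theoretical Theoretical capacity (nmol/mg, > 0).
#' @return Utilization in percent.
#' @examples
#' capacityUtilization(15, 20)  # 75
#' @export
capacityUtilization <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical capacity must be > 0")
  100 * measured / theoretical
}

#' Construct a polymer specification
#'
#' @param name Variant name.
#' @param m,n,o Acrylate units, acrylamide units, anchor strands per chain.
#' @param Mw Weight-average molecular weight (g/mol).
#' @param Rh,Rg Hydrodynamic and gyration radii (nm).
#' @param nu,K Scaling exponent and prefactor of `Rg = K * M^nu`.
#' @return A [PolymerSpec-class].
#' @examples
#' polymerSpec("variant-100", m = 900, n = 90000, o = 130, Mw = 8.47e6)
#' @export
polymerSpec <- function(name, m = NA_real_, n = NA_real_, o = NA_real_,
                        Mw = NA_real_, Rh = NA_real_, Rg = NA_real_,
                        nu = NA_real_, K = NA_real_) {
  new("PolymerSpec", name = name, m = m, n = n, o = o, Mw = Mw, Rh = Rh,
      Rg = Rg, nu = nu, K = K)
}

#' Characterize a polymer specification
#'
#' Derives every conformation and capacity quantity computable from the
#' populated slots: apparent volume (from `Rh`), apparent density and water
#' fraction (with `Mw`), and theoretical anchor capacity (from `o` and
#' `Mw`). Optionally relates a measured capacity to the theoretical one.
#'
#' @param spec A [PolymerSpec-class].
#' @param measuredCapacity Optional measured capacity (nmol/mg).
#' @param VumCubed Optional apparent volume (um^3) to use instead of
#'   deriving it from `Rh`.
#' @return A data.frame with `quantity`, `value`, `unit`.
#' @export
characterizePolymer <- function(spec, measuredCapacity = NA_real_,
                                VumCubed = NA_real_) {
  stopifnot(is(spec, "PolymerSpec"))
  rows <- list()
  add <- function(q, v, u)
    rows[[length(rows) + 1L]] <<- data.frame(quantity = q, value = v,
                                             unit = u)
  V <- VumCubed
  if (is.na(V) && !is.na(spec@Rh)) V <- apparentVolume(spec@Rh)
  if (!is.na(V)) add("apparent_volume", V, "um^3")
  if (!is.na(V) && !is.na(spec@Mw)) {
    rho <- apparentDensity(spec@Mw, V)
    add("apparent_density", rho, "g/cm^3")
    add("water_fraction", waterFraction(rho), "%")
  }
  if (!is.na(spec@o) && !is.na(spec@Mw)) {
    theo <- theoreticalCapacity(spec@o, spec@Mw)
    add("theoretical_capacity", theo, "nmol/mg")
    if (!is.na(measuredCapacity))
      add("capacity_utilization",
          capacityUtilization(measuredCapacity, theo), "%")
  }
  if (!is.na(spec@nu)) add("scaling_exponent", spec@nu, "")
  if (!length(rows))
    return(data.frame(quantity = character(), value = numeric(),
                      unit = character()))
  do.call(rbind, rows)
}
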