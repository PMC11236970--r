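# Closed-form order-of-magnitude mechanics of the deformed cortex-membrane
# composite.  All formulas are evaluated in SI units with unit prefactors,
# as scaling estimates; outputs are order-of-magnitude numbers, not
# calibrated measurements.

.om_string <- function(x) sprintf("~10^%d", round(log10(x)))

#' Mechanical model inputs
#'
#' Collects the physical inputs of the cortex mechanics estimates, in SI
#' units.  Defaults are the typical values for a ~20 µm liposome carrying an
#' Arp2/3-anchored cortex: R = 20 µm, h = 0.29 µm, deformation depth
#' delta = 1.1 µm, deformation size theta_c = 28 deg (correlation length
#' xi_c = R theta_c in radians, ~9.7 µm), branched-network elastic modulus
#' E = 4e3 Pa, membrane tension gamma_m = 1e-7 N/m, membrane viscosity
#' eta_m = 1e-5 Pa s m, N_link = 5e5 cortex-membrane links, cortical flow
#' speed v_act = 13.3 µm/min.
#'
#' @param R_m liposome radius (m).
#' @param h_m cortex thickness (m).
#' @param delta_m deformation depth (m).
#' @param xi_c_m correlation length (m); if `NULL`, computed as
#'   `R_m * theta_c_deg` in radians.
#' @param theta_c_deg deformation size (degrees), used when `xi_c_m` is
#'   `NULL`.
#' @param E_Pa cortex elastic modulus (Pa).
#' @param gamma_m_N_per_m membrane tension (N/m).
#' @param eta_m_Pa_s_m membrane viscosity (Pa s m).
#' @param N_link number of cortex-to-membrane links.
#' @param v_act_m_per_s cortical flow speed (m/s).
#' @return list of class `mechanics_inputs`.
#' @export
mechanics_inputs <- function(R_m = 20e-6, h_m = 0.29e-6, delta_m = 1.1e-6,
                             xi_c_m = NULL, theta_c_deg = 28,
                             E_Pa = 4e3, gamma_m_N_per_m = 1e-7,
                             eta_m_Pa_s_m = 1e-5, N_link = 5e5,
                             v_act_m_per_s = 13.3e-6 / 60) {
  if (is.null(xi_c_m)) xi_c_m <- R_m * theta_c_deg * pi / 180
  vals <- list(R_m = R_m, h_m = h_m, delta_m = delta_m, xi_c_m = xi_c_m,
               E_Pa = E_Pa, gamma_m_N_per_m = gamma_m_N_per_m,
               eta_m_Pa_s_m = eta_m_Pa_s_m, N_link = N_link,
               v_act_m_per_s = v_act_m_per_s)
  missing <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && is.finite(v) && v > 0, logical(1))]
  if (length(missing)) {
    stop("missing or non-positive mechanics inputs: ",
         paste(missing, collapse = ", "))
  }
  if (xi_c_m > pi * R_m) stop("correlation length xi_c exceeds pi R")
  structure(vals, class = "mechanics_inputs")
}

#' Deformation energy budget of the cortex-membrane composite
#'
#' Scaling energies for deforming a patch of size `xi_c` to depth `delta`:
#' cortex bending \eqn{F_{bend} = E h^3 \delta^2 / \xi_c^2}, cortex
#' stretching \eqn{F_{stretch} = E h \xi_c^2 \delta^2 / R^2 \,
#' (1 + \xi_c^2/R^2)} and membrane area cost \eqn{F_{memb} = \gamma_m
#' \xi_c^2 \delta / R}, all with unit prefactors.  The work done by
#' contraction at deformation onset balances the total:
#' \eqn{W_{contract} = F_{bend} + F_{stretch} + F_{memb}}.
#'
#' @param inputs a [mechanics_inputs] list.
#' @param stretch_geom_factor `"multiply"` (default) applies the
#'   \eqn{(1 + \xi_c^2/R^2)} geometric factor multiplicatively;
#'   `"divide"` divides by it (the alternative reading of the scaling form).
#' @return list with `F_bend_J`, `F_stretch_J`, `F_memb_J`, `W_contract_J`.
#' @export
deformation_energies <- function(inputs,
                                 stretch_geom_factor = c("multiply",
                                                         "divide")) {
  stretch_geom_factor <- match.arg(stretch_geom_factor)
  with(inputs, {
    F_bend <- E_Pa * h_m^3 * delta_m^2 / xi_c_m^2
    geom <- 1 + xi_c_m^2 / R_m^2
    F_stretch <- E_Pa * h_m * xi_c_m^2 * delta_m^2 / R_m^2
    F_stretch <- if (stretch_geom_factor == "multiply") F_stretch * geom
                 else F_stretch / geom
    F_memb <- gamma_m_N_per_m * xi_c_m^2 * delta_m / R_m
    list(F_bend_J = F_bend, F_stretch_J = F_stretch, F_memb_J = F_memb,
         W_contract_J = F_bend + F_stretch + F_memb)
  })
}

#' Cortex tension from the mechanical work of deformation
#'
#' Inverts \eqn{W_{contract} = h \sigma_{act} \xi_c^2 \delta / R} for the
#' active stress and applies \eqn{\gamma_c = h\,\sigma_{act}}; note that h
#' cancels in \eqn{\gamma_c = W R / (\xi_c^2 \delta)}.
#'
#' @param W_contract_J mechanical work (J).
#' @param R_m,xi_c_m,delta_m geometry (m); all > 0.
#' @param h_m cortex thickness (m), needed only for `sigma_act`.
#' @return list with `sigma_act_Pa`, `gamma_c_N_per_m`.
#' @export
cortex_tension_from_energy <- function(W_contract_J, R_m, xi_c_m, delta_m,
                                       h_m = 0.29e-6) {
  if (delta_m <= 0 || xi_c_m <= 0) stop("delta and xi_c must be positive")
  sigma_act <- W_contract_J * R_m / (h_m * xi_c_m^2 * delta_m)
  list(sigma_act_Pa = sigma_act, gamma_c_N_per_m = h_m * sigma_act)
}

#' Cortex tension from the cortical-flow friction balance
#'
#' Balances the active stress against the membrane-induced friction stress
#' \eqn{f_{fric} = \zeta v_{act}} with friction coefficient
#' \eqn{\zeta = \eta_m N_{link} / (4\pi R^2)}, then
#' \eqn{\gamma_c = h\,\sigma_{act}} with \eqn{\sigma_{act} = f_{fric}}.
#'
#' @param h_m cortex thickness (m).
#' @param v_act_m_per_s cortical flow speed (m/s); zero gives zero tension.
#' @param eta_m_Pa_s_m membrane viscosity (Pa s m).
#' @param N_link number of cortex-to-membrane links.
#' @param R_m liposome radius (m).
#' @return list with `zeta_Pa_s_per_m`, `f_fric_Pa`, `sigma_act_Pa`,
#'   `gamma_c_N_per_m`.
#' @export
cortex_tension_from_flow <- function(h_m = 0.29e-6,
                                     v_act_m_per_s = 13.3e-6 / 60,
                                     eta_m_Pa_s_m = 1e-5, N_link = 5e5,
                                     R_m = 20e-6) {
  stopifnot(h_m > 0, eta_m_Pa_s_m > 0, N_link > 0, R_m > 0,
            v_act_m_per_s >= 0)
  zeta <- eta_m_Pa_s_m * N_link / (4 * pi * R_m^2)
  f_fric <- zeta * v_act_m_per_s
  list(zeta_Pa_s_per_m = zeta, f_fric_Pa = f_fric, sigma_act_Pa = f_fric,
       gamma_c_N_per_m = h_m * f_fric)
}

#' Bending-to-stretching energy ratio scale
#'
#' When the deformation size is comparable to the liposome radius
#' (\eqn{\xi_c \sim R}), the ratio of bending to stretching energy scales as
#' \eqn{F_{bend}/F_{stretch} \sim h^2 / R^2}: smaller liposomes pay a much
#' higher relative bending cost, which suppresses their deformation.  The
#' exact ratio from [deformation_energies] at \eqn{\xi_c = R} is returned as
#' a cross-check (it differs by the geometric factor
#' \eqn{(1 + \xi_c^2/R^2) = 2}).
#'
#' @param h_m cortex thickness (m).
#' @param R_m liposome radius (m).
#' @return list with `ratio_scale` (\eqn{h^2/R^2}) and `ratio_exact_xiR`.
#' @export
bend_stretch_ratio <- function(h_m = 0.29e-6, R_m = 20e-6) {
  stopifnot(h_m > 0, R_m > 0)
  inp <- mechanics_inputs(R_m = R_m, h_m = h_m, xi_c_m = R_m)
  en <- deformation_energies(inp)
  list(ratio_scale = h_m^2 / R_m^2,
       ratio_exact_xiR = en$F_bend_J / en$F_stretch_J)
}

#' Membrane binding-site budget for His-tagged proteins
#'
#' Order-of-magnitude counts: total lipids \eqn{N_{tot} = 4\pi R^2 /
#' a_{head}}, Ni-NTA anchor lipids \eqn{N_{NiNTA} = f_{NTA} N_{tot}},
#' encapsulated protein copies \eqn{N_{prot} = c\,V\,N_A}, and the
#' footprint-limited maximum of membrane-bound protein
#' \eqn{N^{max} = 4\pi R^2 / (\pi r_{prot}^2) = 4 R^2 / r_{prot}^2}.
#'
#' @param R_m liposome radius (m).
#' @param lipid_head_area_nm2 lipid head-group area (nm^2; default 0.55,
#'   EPC).
#' @param nta_fraction molar fraction of Ni-NTA lipids (default 0.1).
#' @param protein_conc_M encapsulated protein concentration (mol/L).
#' @param protein_radius_nm protein radius (nm); ~4 for mDia1 (178 kDa),
#'   ~2 for the VCA fragment (~43 kDa).
#' @return object of class `binding_budget`: list with exact counts
#'   `N_tot`, `N_NiNTA`, `N_prot`, `N_max_protein` and order-of-magnitude
#'   strings `N_*_om`.
#' @export
binding_site_budget <- function(R_m = 20e-6, lipid_head_area_nm2 = 0.55,
                                nta_fraction = 0.1, protein_conc_M = 1e-6,
                                protein_radius_nm = 4) {
  stopifnot(R_m > 0, lipid_head_area_nm2 > 0, nta_fraction > 0,
            protein_conc_M > 0, protein_radius_nm > 0)
  area_m2 <- 4 * pi * R_m^2
  N_tot <- area_m2 / (lipid_head_area_nm2 * 1e-18)
  N_NiNTA <- nta_fraction * N_tot
  vol_L <- 4 / 3 * pi * R_m^3 * 1e3
  N_prot <- protein_conc_M * vol_L * 6.02214076e23
  N_max <- 4 * R_m^2 / (protein_radius_nm * 1e-9)^2
  structure(
    list(N_tot = N_tot, N_NiNTA = N_NiNTA, N_prot = N_prot,
         N_max_protein = N_max,
         N_tot_om = .om_string(N_tot), N_NiNTA_om = .om_string(N_NiNTA),
         N_prot_om = .om_string(N_prot),
         N_max_protein_om = .om_string(N_max)),
    class = "binding_budget"
  )
}

#' Remaining ATP after sustained actin hydrolysis
#'
#' Simple depletion arithmetic: starting concentration minus the actin
#' ATP-hydrolysis rate times the elapsed time (~4 µM/min at ~6 µM actin,
#' so ~5 mM remains after the ~10 min polymerisation period).
#'
#' @param initial_mM starting ATP concentration (mM, default 5).
#' @param rate_uM_per_min hydrolysis rate (µM/min, default 4).
#' @param minutes elapsed time (min).
#' @return remaining concentration (mM), floored at 0.
#' @export
atp_remaining_mM <- function(initial_mM = 5, rate_uM_per_min = 4,
                             minutes = 10) {
  max(initial_mM - rate_uM_per_min * 1e-3 * minutes, 0)
}

#' Full mechanics report
#'
#' Evaluates the energy budget, both tension routes and the bend/stretch
#' ratio from one set of inputs.
#'
#' @param inputs a [mechanics_inputs] list.
#' @param W_contract_J optional externally supplied mechanical work (J);
#'   default is the sum of the computed energy components.
#' @return list of class `mechanics_report` combining
#'   [deformation_energies], [cortex_tension_from_energy],
#'   [cortex_tension_from_flow] and [bend_stretch_ratio] outputs.
#' @export
mechanics_report <- function(inputs = mechanics_inputs(),
                             W_contract_J = NULL) {
  en <- deformation_energies(inputs)
  W <- W_contract_J %||% en$W_contract_J
  te <- cortex_tension_from_energy(W, inputs$R_m, inputs$xi_c_m,
                                   inputs$delta_m, inputs$h_m)
  tf <- cortex_tension_from_flow(inputs$h_m, inputs$v_act_m_per_s,
                                 inputs$eta_m_Pa_s_m, inputs$N_link,
                                 inputs$R_m)
  bs <- bend_stretch_ratio(inputs$h_m, inputs$R_m)
  structure(
    c(en, list(W_contract_used_J = W),
      list(sigma_act_energy_Pa = te$sigma_act_Pa,
           gamma_c_energy_N_per_m = te$gamma_c_N_per_m,
           zeta_Pa_s_per_m = tf$zeta_Pa_s_per_m,
           f_fric_Pa = tf$f_fric_Pa,
           gamma_c_flow_N_per_m = tf$gamma_c_N_per_m,
           bend_stretch_ratio = bs$ratio_scale)),
    class = "mechanics_report"
  )
}
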