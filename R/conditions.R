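# Literature-derived parameter sets for the channel archetypes studied with
# the activator RPR260243: wild-type, split (S4-S5 severed), N-terminal
# deleted, C-terminal deleted and D540K hERG1a channels, each under control
# conditions and in the presence of 30 µM RPR. Drug conditions are encoded
# purely as alternative parameter sets, not as a drug-binding model.
#
# Where a quantity was never reported (Hill endpoints, C-del and
# D540K(-140 mV) time constants) a plausible synthetic value is used and
# marked "synthetic" below.

#' Study condition parameter library
#'
#' Returns the parameter sets that drive the synthetic-data generators:
#' Hill concentration-response parameters for the RPR effects on split
#' hERG1a currents, 6-state gating parameters for split channels, deactivation
#' time constants per channel archetype and return potential, double-
#' Boltzmann G-V descriptions for D540K, and the tail-ratio read-out times.
#' Values are literature-derived fit results for oocyte recordings;
#' `replicates` carries the reported number of oocytes per experiment.
#' Hill endpoints (`Amax`/`Amin`) are synthetic fold-change anchors
#' (baseline 1), since only EC50 and nH were reported.
#'
#' @return A nested list with elements `hill`, `gating`, `deactivation`,
#'   `d540k_gv` and `tail_ratio`.
#' @examples
#' herg_conditions()$gating$split_control
#' @export
herg_conditions <- function() {
  list(
    hill = list(
      # split-channel cumulative concentration-response relationships
      split_Itailpeak = list(params = hill_params(Amax = 2.5, Amin = 1,
                                                  ec50_uM = 15.0, nH = 1.3),
                             replicates = 7L),
      split_Ipeak = list(params = hill_params(Amax = 1.5, Amin = 1,
                                              ec50_uM = 8.2, nH = 1.2),
                         replicates = 7L),
      split_tau_deact_m60 = list(params = hill_params(Amax = 4, Amin = 1,
                                                      ec50_uM = 7.9, nH = 1.9),
                                 replicates = 5L)),
    gating = list(
      split_control = list(params = gating_params(K0 = 0.155, z1 = 1.71,
                                                  Ko0 = 0.32, z2 = 0.73),
                           replicates = 7L),
      split_rpr30 = list(params = gating_params(K0 = 0.023, z1 = 2.98,
                                                Ko0 = 0.513, z2 = 0.81),
                         replicates = 7L)),
    deactivation = list(
      split = list(
        control = list(`-40` = exp_mixture(67, 1),
                       `-140` = exp_mixture(3.4, 1)),
        rpr30 = list(`-40` = exp_mixture(272, 1),
                     `-140` = exp_mixture(16.6, 1)),
        replicates = 7L),
      ndel = list(
        control = list(`-60` = exp_mixture(17.4, 1),
                       `-140` = exp_mixture(3.6, 1)),
        # slow-component fraction reported as 0.32-0.47; 0.4 used
        rpr30 = list(`-60` = exp_mixture(c(44, 1451), c(0.6, 0.4)),
                     `-140` = exp_mixture(c(9.3, 62), c(0.6, 0.4))),
        replicates = 6L),
      cdel = list(
        # tau not reported; synthetic value, identical for control and RPR
        # (RPR does not alter C-del deactivation)
        control = list(`-60` = exp_mixture(15, 1)),
        rpr30 = list(`-60` = exp_mixture(15, 1)),
        replicates = 5L),
      d540k = list(
        # return to -70 mV after depolarizing (+10 mV) activation
        control = list(`-70` = exp_mixture(c(24, 79), c(0.65, 0.35))),
        rpr30 = list(`-70` = exp_mixture(c(35, 442, 1970),
                                         c(0.4, 0.3, 0.3))),
        # after hyperpolarizing (-140 mV) activation RPR has no effect;
        # tau not reported: synthetic value shared by both conditions
        control_hyp = list(`-70` = exp_mixture(50, 1)),
        rpr30_hyp = list(`-70` = exp_mixture(50, 1)),
        replicates = 10L)),
    d540k_gv = list(
      control = list(v05_hyp_mV = -118, k_hyp_mV = 10.6,
                     v05_dep_mV = -24.7, k_dep_mV = 7.2,
                     trough = 0.02, replicates = 10L),
      rpr30 = list(v05_hyp_mV = -114, k_hyp_mV = 9.2,
                   v05_dep_mV = -23.9, k_dep_mV = 14.2,
                   trough = 0.17, replicates = 10L)),
    tail_ratio = list(wt_t_end_ms = 2500, split_t_end_ms = 25)
  )
}
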