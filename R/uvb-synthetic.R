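#' Synthetic 11-state UV-B photoreceptor signalling network
#'
#' A SYNTHETIC stand-in for a plant photomorphogenic UV-B signalling model:
#' 11 protein/mRNA species coupled by 10 interaction channels, with a
#' 5-dimensional output that is a linear combination of 7 distinct state
#' variables.  The kinetic constants and initial conditions here are chosen
#' by this package to give well-behaved dynamics at laboratory time scales —
#' they are NOT transcribed from any published parameterisation, and results
#' on this model are not comparable to published figures.  Use [load_sbml()]
#' to analyse a curated model instead.
#'
#' The network follows the canonical UV-B signalling architecture: UV-B light
#' (`u`, irradiance) monomerises the UVR8 photoreceptor dimer; monomers bind
#' the E3-ligase COP1; the UVR8–COP1 complex drives expression of the
#' transcription factors HY5 and HYH (via their mRNAs); HY5 induces the
#' negative regulator RUP, which accelerates UVR8 redimerisation; HY5 also
#' drives a downstream structural gene (mRNA + protein) that does not feed
#' back.  Two conservation relations hold (total UVR8 monomer-equivalents and
#' total COP1).
#'
#' The downstream structural-gene states (`chs_mrna`, `chs`) do not reach any
#' output: hidden inputs on them have no output effect, so the 9 remaining
#' states are the effective candidate target nodes for model-error
#' localisation (giving 36 distinct node pairs).
#'
#' @return an [ode_model()] with 11 states, 5 outputs and known input `u`.
#' @export
uvb_model <- function() {
  ode_model(
    odes = list(
      # photoreceptor cycle (RUP-assisted redimerisation)
      uvr8_dimer = quote(-k1 * u * uvr8_dimer +
                           k2 * uvr8_mono^2 * (1 + kr * rup)),
      uvr8_mono  = quote(2 * k1 * u * uvr8_dimer -
                           2 * k2 * uvr8_mono^2 * (1 + kr * rup) -
                           k3 * uvr8_mono * cop1 + k4 * complex),
      cop1       = quote(-k3 * uvr8_mono * cop1 + k4 * complex),
      complex    = quote(k3 * uvr8_mono * cop1 - k4 * complex),
      # UVR8-COP1 driven gene expression
      hy5_mrna   = quote(k5 * complex - d5 * hy5_mrna),
      hy5        = quote(k6 * hy5_mrna - d6 * hy5),
      hyh_mrna   = quote(k7 * complex - d7 * hyh_mrna),
      hyh        = quote(k8 * hyh_mrna - d8 * hyh),
      # negative feedback regulator
      rup        = quote(k9 * hy5 - d9 * rup),
      # downstream structural gene: no path back to any output
      chs_mrna   = quote(k10 * hy5 - d10 * chs_mrna),
      chs        = quote(k11 * chs_mrna - d11 * chs)
    ),
    outputs = list(
      total_uvr8 = quote(uvr8_dimer + uvr8_mono),
      total_cop1 = quote(cop1 + complex),
      hy5_level  = quote(hy5),
      hyh_level  = quote(hyh),
      rup_level  = quote(rup)
    ),
    parameters = c(k1 = 1, k2 = 0.5, kr = 1, k3 = 2, k4 = 0.5,
                   k5 = 1, d5 = 1, k6 = 0.5, d6 = 0.3,
                   k7 = 0.6, d7 = 0.6, k8 = 0.4, d8 = 0.3,
                   k9 = 0.4, d9 = 0.2, k10 = 0.5, d10 = 0.4,
                   k11 = 0.6, d11 = 0.3),
    initial_state = c(2, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    input_names = "u",
    name = "uvb_synthetic",
    conserved = list(
      quote(2 * uvr8_dimer + uvr8_mono + complex),  # UVR8 monomer-equivalents
      quote(cop1 + complex)                         # total COP1
    )
  )
}
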