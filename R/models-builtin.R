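#' The four-state JAK-STAT signalling model
#'
#' Nominal model of STAT5 phosphorylation upon erythropoietin-receptor
#' activation: unphosphorylated cytoplasmic STAT5 (`stat5`) is phosphorylated
#' at a rate proportional to the receptor activity `u(t)`, phosphorylated
#' monomers (`pstat5`) dimerise (`pstat5_dim`), and dimers are imported into
#' the nucleus (`npstat5_dim`), which in this draft model is a dead end.
#' Outputs are the quantities accessible by immunoblotting: phosphorylated
#' cytoplasmic STAT5 (monomers plus both halves of each dimer) and total
#' cytoplasmic STAT5.
#'
#' Rate constants are taken from the original estimation work on this pathway
#' (Swameye et al. 2003, in units of 1/min with concentrations in arbitrary
#' units normalised to total STAT5 = 1); the output scale factors `s1`, `s2`
#' are kept at 1 in those units.
#'
#' The monomer-equivalent total `stat5 + pstat5 + 2*pstat5_dim +
#' 2*npstat5_dim` is conserved along every trajectory, which the test-suite
#' verifies both symbolically and numerically.
#'
#' @return an [ode_model()] with 4 states and 2 outputs; known input `u`
#'   (receptor phosphorylation, linearly interpolated between measurements).
#' @export
jak_stat_model <- function() {
  ode_model(
    odes = list(
      stat5       = quote(-k1 * stat5 * u),
      pstat5      = quote(k1 * stat5 * u - k2 * pstat5^2),
      pstat5_dim  = quote(0.5 * k2 * pstat5^2 - k3 * pstat5_dim),
      npstat5_dim = quote(k3 * pstat5_dim)
    ),
    outputs = list(
      p_cyt_stat5     = quote(s1 * (pstat5 + 2 * pstat5_dim)),
      total_cyt_stat5 = quote(s2 * (stat5 + pstat5 + 2 * pstat5_dim))
    ),
    parameters = c(k1 = 0.021, k2 = 2.46, k3 = 0.1066, s1 = 1, s2 = 1),
    initial_state = c(1, 0, 0, 0),
    input_names = "u",
    name = "jak_stat",
    conserved = list(quote(stat5 + pstat5 + 2 * pstat5_dim + 2 * npstat5_dim))
  )
}

#' Small network-motif fixture models
#'
#' A collection of linear mass-action motifs used throughout the test-suite
#' and the synthetic benchmarks: a linear activation chain, a feed-forward
#' motif, a negative-feedback motif, and a deliberately symmetric motif: two
#' of its branch nodes (`m2`, `m3`) have exactly identical output signatures
#' because only their sum is observed, so hidden inputs to either branch are
#' mutually unobservable — the textbook failure case for error localisation.
#'
#' All motifs have a single known input `u` driving the first node and zero
#' initial state.  The chain is fully observed (one output per node), so
#' hidden inputs on any node are uniquely localisable — the reference case
#' for target-recovery benchmarks.  The feed-forward and feedback motifs
#' expose two outputs (an upstream combination and the terminal node), a
#' partially-observed setting.  The symmetric motif observes its hub, its
#' independent branch and the SUM of the two symmetric branches, so only the
#' symmetric pair is confusable.  Being
#' linear, the motifs obey superposition, admit matrix-exponential closed
#' forms, and their observability can be checked by a rank test on the
#' linearisation — all of which the test-suite exploits as independent
#' oracles.
#'
#' @param which optional character vector selecting a subset by name.
#' @return named list of [ode_model()] objects:
#'   `chain`, `feedforward`, `feedback`, `symmetric`.
#' @export
motif_models <- function(which = NULL) {
  models <- list(
    chain = ode_model(
      odes = list(
        m1 = quote(u - a1 * m1),
        m2 = quote(a1 * m1 - a2 * m2),
        m3 = quote(a2 * m2 - a3 * m3)
      ),
      outputs = list(y1 = quote(m1), y2 = quote(m2), y3 = quote(m3)),
      parameters = c(a1 = 1, a2 = 0.7, a3 = 0.4),
      initial_state = c(0, 0, 0),
      input_names = "u", name = "chain"
    ),
    feedforward = ode_model(
      odes = list(
        m1 = quote(u - a1 * m1),
        m2 = quote(b1 * m1 - a2 * m2),
        m3 = quote(b2 * m1 + b3 * m2 - a3 * m3)
      ),
      outputs = list(y1 = quote(m1 + m2), y2 = quote(m3)),
      parameters = c(a1 = 1, a2 = 0.6, a3 = 0.5, b1 = 0.8, b2 = 0.4, b3 = 0.7),
      initial_state = c(0, 0, 0),
      input_names = "u", name = "feedforward"
    ),
    feedback = ode_model(
      odes = list(
        m1 = quote(u - a1 * m1 - c1 * m3),
        m2 = quote(b1 * m1 - a2 * m2),
        m3 = quote(b2 * m2 - a3 * m3)
      ),
      outputs = list(y1 = quote(m1 + m2), y2 = quote(m3)),
      parameters = c(a1 = 0.8, a2 = 0.9, a3 = 0.5, b1 = 1, b2 = 0.8, c1 = 0.6),
      initial_state = c(0, 0, 0),
      input_names = "u", name = "feedback"
    ),
    symmetric = ode_model(
      odes = list(
        m1 = quote(u - a1 * m1),
        m2 = quote(b1 * m1 - a2 * m2),
        m3 = quote(b1 * m1 - a2 * m3),
        m4 = quote(b2 * m1 - a4 * m4)
      ),
      outputs = list(y1 = quote(m2 + m3), y2 = quote(m4), y3 = quote(m1)),
      parameters = c(a1 = 1, a2 = 0.5, a4 = 0.6, b1 = 0.8, b2 = 0.5),
      initial_state = c(0, 0, 0, 0),
      input_names = "u", name = "symmetric"
    )
  )
  if (!is.null(which)) models <- models[which]
  models
}
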