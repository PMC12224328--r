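#' Michaelis-Menten kinetic parameters
#'
#' Parameters of the hyperbolic saturation rate law
#' \eqn{v = V_{max} [S] / (K_m + [S])}, used here for the glucose-oxidation
#' half of the cascade. `v_max` is defined at `ref_catalyst_conc`; rates at
#' other catalyst loadings scale linearly with the catalyst ratio.
#'
#' @param v_max Maximal rate (mM/min) at the reference catalyst concentration.
#' @param k_m Michaelis constant (mM): substrate concentration at half `v_max`.
#' @param ref_catalyst_conc Catalyst concentration (mg/mL) at which `v_max`
#'   is defined.
#' @return An object of class `mm_kinetics`.
#' @examples
#' mm_kinetics(v_max = 10, k_m = 2.9)
#' @export
mm_kinetics <- function(v_max, k_m, ref_catalyst_conc = 0.1) {
  stopifnot(is.numeric(v_max), is.numeric(k_m), is.numeric(ref_catalyst_conc))
  if (v_max <= 0) abort("`v_max` must be > 0.")
  if (k_m <= 0) abort("`k_m` must be > 0.")
  if (ref_catalyst_conc <= 0) abort("`ref_catalyst_conc` must be > 0.")
  structure(
    list(v_max = v_max, k_m = k_m, ref_catalyst_conc = ref_catalyst_conc),
    class = "mm_kinetics"
  )
}

#' Hill (allosteric sigmoidal) kinetic parameters
#'
#' Parameters of the sigmoidal rate law
#' \eqn{v = V_{max} [S]^h / (K_{0.5}^h + [S]^h)}, used here for the
#' H2O2-decomposition half of the cascade. Reduces to Michaelis-Menten at
#' `hill_h = 1`.
#'
#' @param v_max Maximal rate (mM/min) at the reference catalyst concentration.
#' @param k_half Half-saturation constant \eqn{K_{0.5}} (mM).
#' @param hill_h Hill slope (dimensionless, > 0); cooperativity exponent.
#' @inheritParams mm_kinetics
#' @return An object of class `hill_kinetics`.
#' @examples
#' hill_kinetics(v_max = 5, k_half = 155.1, hill_h = 2)
#' @export
hill_kinetics <- function(v_max, k_half, hill_h = 1, ref_catalyst_conc = 0.1) {
  if (v_max <= 0) abort("`v_max` must be > 0.")
  if (k_half <= 0) abort("`k_half` must be > 0.")
  if (hill_h <= 0) abort("`hill_h` must be > 0.")
  if (ref_catalyst_conc <= 0) abort("`ref_catalyst_conc` must be > 0.")
  structure(
    list(v_max = v_max, k_half = k_half, hill_h = hill_h,
         ref_catalyst_conc = ref_catalyst_conc),
    class = "hill_kinetics"
  )
}

#' Single-catalyst cascade model
#'
#' Couples glucose -> H2O2 production (Michaelis-Menten) with H2O2 -> H2O +
#' O2 decomposition (Hill) on one catalyst. Each half-reaction scales with
#' catalyst concentration as `(C / ref)^exponent`; both rate laws are
#' evaluated at their reference catalyst concentration and then scaled, so the
#' exponents fully control catalyst dependence. Equal exponents make the
#' steady-state H2O2 concentration catalyst-independent (the k1/k2 ratio
#' cancels); a smaller decomposition exponent — the default 0.5 — makes the
#' steady state rise with catalyst loading, the regime in which decomposition
#' lags behind production.
#'
#' @param production `mm_kinetics` for glucose oxidation.
#' @param decomposition `hill_kinetics` for H2O2 decomposition.
#' @param production_catalyst_exponent,decomposition_catalyst_exponent
#'   Non-negative exponents of the catalyst ratio applied to each
#'   half-reaction.
#' @return An object of class `cascade_model`.
#' @examples
#' cascade_model(mm_kinetics(10, 2.9), hill_kinetics(5, 155.1, 2))
#' @export
cascade_model <- function(production, decomposition,
                          production_catalyst_exponent = 1,
                          decomposition_catalyst_exponent = 0.5) {
  if (!inherits(production, "mm_kinetics")) {
    abort("`production` must be an mm_kinetics object.")
  }
  if (!inherits(decomposition, "hill_kinetics")) {
    abort("`decomposition` must be a hill_kinetics object.")
  }
  if (production_catalyst_exponent < 0 || decomposition_catalyst_exponent < 0) {
    abort("Catalyst exponents must be >= 0.")
  }
  structure(
    list(production = production, decomposition = decomposition,
         production_catalyst_exponent = production_catalyst_exponent,
         decomposition_catalyst_exponent = decomposition_catalyst_exponent),
    class = "cascade_model"
  )
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model>\n")
  cat(sprintf("  production:    MM  v_max = %g mM/min, K_m = %g mM (ref %g mg/mL)\n",
              x$production$v_max, x$production$k_m,
              x$production$ref_catalyst_conc))
  cat(sprintf("  decomposition: Hill v_max = %g mM/min, K_0.5 = %g mM, h = %g (ref %g mg/mL)\n",
              x$decomposition$v_max, x$decomposition$k_half,
              x$decomposition$hill_h, x$decomposition$ref_catalyst_conc))
  cat(sprintf("  catalyst exponents: production %g, decomposition %g\n",
              x$production_catalyst_exponent,
              x$decomposition_catalyst_exponent))
  invisible(x)
}

#' Michaelis-Menten rate
#'
#' Evaluates \eqn{v = V_{max} (C/C_{ref}) [S] / (K_m + [S])}. Vectorised over
#' `substrate`.
#'
#' @param params An [mm_kinetics()] object.
#' @param substrate Substrate concentration(s), mM; must be `>= 0`.
#' @param catalyst_conc Catalyst concentration, mg/mL.
#' @return Rate(s) in mM/min.
#' @examples
#' mm_rate(mm_kinetics(10, 2.9), substrate = 2.9)  # exactly v_max / 2
#' @export
mm_rate <- function(params, substrate, catalyst_conc = params$ref_catalyst_conc) {
  if (any(substrate < 0)) abort("`substrate` must be >= 0.")
  ratio <- catalyst_conc / params$ref_catalyst_conc
  params$v_max * ratio * substrate / (params$k_m + substrate)
}

#' Hill rate
#'
#' Evaluates \eqn{v = V_{max} (C/C_{ref}) [S]^h / (K_{0.5}^h + [S]^h)}.
#' Vectorised over `substrate`; equals [mm_rate()] when `hill_h = 1`.
#'
#' @param params A [hill_kinetics()] object.
#' @inheritParams mm_rate
#' @return Rate(s) in mM/min.
#' @export
hill_rate <- function(params, substrate,
                      catalyst_conc = params$ref_catalyst_conc) {
  if (any(substrate < 0)) abort("`substrate` must be >= 0.")
  ratio <- catalyst_conc / params$ref_catalyst_conc
  sh <- substrate^params$hill_h
  params$v_max * ratio * sh / (params$k_half^params$hill_h + sh)
}

#' Pseudo-order rate constants
#'
#' Container for the reduced description of the cascade near operating
#' conditions: pseudo-zero-order H2O2 production at rate `k1` (mM/min) and
#' first-order decomposition at rate `k2` (1/min), i.e.
#' \eqn{d[H_2O_2]/dt = k_1 - k_2 [H_2O_2]}.
#'
#' @param k1 Production rate, mM/min (`>= 0`).
#' @param k2 First-order decomposition rate, 1/min (`> 0`).
#' @param first_order_exact Logical: `FALSE` when the reduction was taken at
#'   a Hill slope different from 1, where first-order decomposition is only an
#'   approximation near H2O2 = K0.5-scaled linear regime.
#' @return An object of class `pseudo_order_rates`.
#' @export
pseudo_order_rates <- function(k1, k2, first_order_exact = TRUE) {
  if (k1 < 0) abort("`k1` must be >= 0.")
  if (k2 <= 0) abort("`k2` must be > 0 (no steady state otherwise).")
  structure(list(k1 = k1, k2 = k2, first_order_exact = first_order_exact),
            class = "pseudo_order_rates")
}

#' Reduce the cascade to pseudo-order rate constants
#'
#' At fixed glucose, H2O2 production is pseudo-zero-order with
#' `k1 = mm_rate(production, glucose)` scaled by the catalyst ratio to the
#' production exponent. Far below `k_half` the Hill decomposition is
#' first-order with `k2 = v_max / k_half` (times the scaled catalyst ratio);
#' this linearisation is exact only at Hill slope 1, so for `hill_h != 1` the
#' same formula is returned with `first_order_exact = FALSE` and a warning.
#'
#' @param model A [cascade_model()].
#' @param catalyst_conc Catalyst concentration, mg/mL.
#' @param glucose Glucose concentration, mM (`>= 0`).
#' @return A [pseudo_order_rates()] object.
#' @examples
#' m <- cascade_model(mm_kinetics(10, 2.9), hill_kinetics(5, 155.1, 1))
#' pseudo_order_reduction(m, catalyst_conc = 0.1, glucose = 5)
#' @export
pseudo_order_reduction <- function(model, catalyst_conc, glucose) {
  if (glucose < 0) abort("`glucose` must be >= 0.")
  prod <- model$production
  dec <- model$decomposition
  k1 <- mm_rate(prod, glucose) *
    (catalyst_conc / prod$ref_catalyst_conc)^model$production_catalyst_exponent
  k2 <- dec$v_max / dec$k_half *
    (catalyst_conc / dec$ref_catalyst_conc)^model$decomposition_catalyst_exponent
  exact <- isTRUE(all.equal(dec$hill_h, 1))
  if (!exact) {
    warn(paste("First-order reduction of the decomposition law is only exact",
               "at Hill slope h = 1; k2 uses the h = 1 formula."))
  }
  pseudo_order_rates(k1 = k1, k2 = k2, first_order_exact = exact)
}

#' Analytic steady-state H2O2 concentration
#'
#' In the pseudo-order regime \eqn{d[H_2O_2]/dt = k_1 - k_2[H_2O_2]} the
#' concentration relaxes to \eqn{k_1/k_2}.
#'
#' @param rates A [pseudo_order_rates()] object.
#' @return Steady-state H2O2 concentration, mM.
#' @examples
#' steady_state_analytic(pseudo_order_rates(k1 = 1, k2 = 0.1))  # 10 mM
#' @export
steady_state_analytic <- function(rates) {
  if (!inherits(rates, "pseudo_order_rates")) {
    abort("`rates` must be a pseudo_order_rates object.")
  }
  rates$k1 / rates$k2
}
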