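#' Measurement-noise specification
#'
#' Describes how synthetic observations are perturbed around their noiseless
#' model values. Three families are supported:
#'
#' * `"none"` — observations equal the model exactly (used for exact
#'   closure tests);
#' * `"additive-gaussian"` — independent Gaussian noise with standard
#'   deviation `sd`, in the same units as the perturbed signal;
#' * `"proportional-gaussian"` — Gaussian noise with standard deviation
#'   `sd * |signal|`, i.e. `sd` is a dimensionless fraction (0.05 means 5%
#'   relative noise). This is the multiplicative-equivalent model used for
#'   quantities spanning decades, such as exponentially growing dry mass.
#'
#' @param kind One of `"none"`, `"additive-gaussian"`,
#'   `"proportional-gaussian"`.
#' @param sd Noise scale; units of the signal for additive noise, a fraction
#'   for proportional noise. Must be `>= 0`.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("additive-gaussian", sd = 0.05)
#' noise_spec()  # no noise
#' @export
noise_spec <- function(kind = c("none", "additive-gaussian",
                                "proportional-gaussian"),
                       sd = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number.")
  }
  if (kind == "none" && sd != 0) sd <- 0
  structure(list(kind = kind, sd = sd), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> kind =", x$kind, "sd =", format(x$sd), "\n")
  invisible(x)
}

as_noise_spec <- function(x) {
  if (inherits(x, "noise_spec")) return(x)
  if (is.null(x)) return(noise_spec("none"))
  if (is.list(x)) return(noise_spec(x$kind %||% "none", x$sd %||% 0))
  abort("Cannot interpret `noise` as a noise_spec.")
}

# Perturb a numeric vector according to a noise_spec. Caller owns the RNG
# state (generators wrap calls in withr::with_seed).
apply_noise <- function(values, noise) {
  noise <- as_noise_spec(noise)
  switch(noise$kind,
    "none" = values,
    "additive-gaussian" = values + rnorm(length(values), 0, noise$sd),
    "proportional-gaussian" =
      values + rnorm(length(values), 0, noise$sd * abs(values))
  )
}
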