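#' Parameters of the visual-acuity drug-disease model
#'
#' Constructs and validates the full parameter set of the indirect-response
#' PK/PD model. Untreated visual acuity (VA, ETDRS letters) relaxes towards a
#' disease steady state `g_ss` at deterioration rate `k_out`
#' (`dg/dt = k_in - k_out * g` with `k_in = g_ss * k_out`). Intravitreal
#' ranibizumab stimulates the VA production rate through a saturable effect
#' `Emax(t) * C(t) / (ec50 + C(t))`, where `C(t)` is the vitreous drug amount
#' following bolus injections with first-order elimination at rate `k_drug`.
#' The maximal effect decays from `Emax_ss + alpha * d_emax0` at baseline
#' (diagnosis) towards the steady state `Emax_ss` at rate `k_emax`, reflecting
#' the larger benefit of early (loading) injections; `Emax_ss` depends on age
#' through `log(Emax_ss) = log(emax0_ss) + beta * log(age / 77)`, and `alpha`
#' scales the transient component by pre-treatment status.
#'
#' Concentration is carried in dose units (mg): the vitreous volume is not
#' modelled separately, so `ec50` absorbs the volume scale and is expressed in
#' the same dose-normalised units as `C(t)`.
#'
#' The default values are this package's own pilot-calibrated reference set,
#' chosen to reproduce the qualitative behaviour of treated and untreated
#' real-world nAMD cohorts (see the methods vignette); they are not estimates
#' taken from any published study.
#'
#' @param g_ss Steady-state VA without treatment (letters), in (0, 100].
#' @param k_out VA deterioration rate (1/day), > 0.
#' @param ec50 Half-effect drug amount (dose-normalised units, mg), > 0.
#' @param emax0_ss Population steady-state Emax at the reference age of 77
#'   years (dimensionless), > 0.
#' @param d_emax0 Baseline increment of Emax (dimensionless); the transient
#'   extra effect at diagnosis is `alpha * d_emax0`.
#' @param k_emax Decay rate of the Emax increment (1/day), >= 0.
#' @param beta Age exponent on log-Emax (dimensionless).
#' @param alpha_naive Pre-treatment scaling for treatment-naive patients
#'   (fixed at 1 by convention).
#' @param alpha_pretreated Pre-treatment scaling for anti-VEGF pre-treated
#'   patients, in \[0, 1\].
#' @param alpha_possibly Scaling for possibly pre-treated patients; defaults
#'   to `alpha_pretreated`.
#' @param k_drug First-order vitreous elimination rate of ranibizumab
#'   (1/day), > 0. Fixed (never estimated); the default corresponds to a
#'   9-day vitreous half-life.
#'
#' @return An object of class `va_params` (a validated named list).
#' @seealso [default_params()], [steady_state()], [simulate_trajectory()]
#' @examples
#' p <- va_params(g_ss = 45, k_out = 0.005)
#' steady_state(p)
#' @export
va_params <- function(g_ss = 40,
                      k_out = 0.004,
                      ec50 = 0.003,
                      emax0_ss = 0.4,
                      d_emax0 = 1.2,
                      k_emax = 0.02,
                      beta = -1.5,
                      alpha_naive = 1,
                      alpha_pretreated = 0.4,
                      alpha_possibly = alpha_pretreated,
                      k_drug = log(2) / 9) {
  p <- structure(
    list(g_ss = g_ss, k_out = k_out, ec50 = ec50,
         emax0_ss = emax0_ss, d_emax0 = d_emax0, k_emax = k_emax,
         beta = beta, alpha_naive = alpha_naive,
         alpha_pretreated = alpha_pretreated,
         alpha_possibly = alpha_possibly, k_drug = k_drug),
    class = "va_params")
  validate_params(p)
  p
}

#' Default (reference) model parameters
#'
#' @return A `va_params` object with the package's pilot-calibrated defaults.
#' @export
default_params <- function() va_params()

#' Validate a `va_params` object
#'
#' Checks all structural invariants: positivity of rates, `g_ss` within the
#' ETDRS range, and non-negativity of baseline Emax
#' (`emax0_ss + alpha * d_emax0 >= 0` for every pre-treatment scaling in use).
#'
#' @param params A `va_params` object (or a named list with the same fields).
#' @return The validated object, invisibly. Errors on violation.
#' @export
validate_params <- function(params) {
  need <- c("g_ss", "k_out", "ec50", "emax0_ss", "d_emax0", "k_emax",
            "beta", "alpha_naive", "alpha_pretreated", "alpha_possibly",
            "k_drug")
  miss <- setdiff(need, names(params))
  if (length(miss))
    .stopf("parameter set is missing fields: %s", paste(miss, collapse = ", "))
  for (nm in need) .assert_number(params[[nm]], nm)
  .assert_number(params$g_ss, "g_ss", lower = 0, upper = 100,
                 allow_equal_lower = FALSE)
  .assert_number(params$k_out, "k_out", lower = 0, allow_equal_lower = FALSE)
  .assert_number(params$ec50, "ec50", lower = 0, allow_equal_lower = FALSE)
  .assert_number(params$k_emax, "k_emax", lower = 0)
  .assert_number(params$k_drug, "k_drug", lower = 0, allow_equal_lower = FALSE)
  .assert_number(params$emax0_ss, "emax0_ss", lower = 0,
                 allow_equal_lower = FALSE)
  for (a in c(params$alpha_naive, params$alpha_pretreated,
              params$alpha_possibly)) {
    if (params$emax0_ss + a * params$d_emax0 < 0)
      .stopf("baseline Emax is negative: emax0_ss + alpha * d_emax0 = %g",
             params$emax0_ss + a * params$d_emax0)
  }
  invisible(params)
}

#' Untreated steady-state visual acuity
#'
#' The equilibrium of the no-treatment model, `g_ss = k_in / k_out`. `k_in`
#' is never stored; it is derived as `g_ss * k_out` wherever needed.
#'
#' @param params A `va_params` object.
#' @return Steady-state VA in letters (equal to `params$g_ss`).
#' @export
steady_state <- function(params) {
  validate_params(params)
  params$g_ss
}

# derived VA production rate (letters/day)
.k_in <- function(params) params$g_ss * params$k_out

#' Pre-treatment scaling factor for a patient
#'
#' @param params A `va_params` object.
#' @param pretreatment Character vector with values among
#'   `"naive"`, `"pretreated"`, `"possibly_pretreated"`.
#' @return Numeric vector of alpha values.
#' @export
alpha_for <- function(params, pretreatment) {
  ok <- c("naive", "pretreated", "possibly_pretreated")
  bad <- setdiff(unique(pretreatment), ok)
  if (length(bad))
    .stopf("unknown pre-treatment status: %s", paste(bad, collapse = ", "))
  unname(c(naive = params$alpha_naive,
           pretreated = params$alpha_pretreated,
           possibly_pretreated = params$alpha_possibly)[pretreatment])
}

#' @export
print.va_params <- function(x, ...) {
  cat("VA drug-disease model parameters (va_params)\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-16s %g (derived)\n", "k_in", .k_in(x)))
  invisible(x)
}

#' Read / write model parameters as JSON
#'
#' @param params A `va_params` object.
#' @param path File path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a validated `va_params` object.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(va_params, x[names(x) %in% names(formals(va_params))])
}
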