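#' Construct and validate a parameter set for the two-reference binning model
#'
#' Bundles every parameter of the two-reference-species coalescent model of
#' read assignment: the species divergence times, the effective population
#' size, the mutation rate, the read length, the ages of the three samples
#' and the completeness (breadth of coverage) of the two reference
#' sequences.
#'
#' Time is measured in generations throughout.  The coalescence rate for a
#' pair of lineages is `1/(2N)` per generation, i.e. `N` is the diploid-scaled
#' effective population size appearing in exponents of the form
#' `exp(-t/2N)`.  Tools differ on the haploid/diploid convention, so this is
#' worth checking when importing parameter values from elsewhere.
#'
#' The per-read mutation rate `mu_read = mu_site * read_length` is always
#' derived from the per-site rate and the read length; it cannot be set
#' directly, which prevents inconsistent `(mu_site, read_length)` pairs.
#'
#' @param T_tf Divergence time of the true and false reference species, in
#'   generations.  Must exceed `T_qt`.
#' @param T_qt Divergence time of the query and true species, in
#'   generations (0 when the query is drawn from the same panmictic
#'   population as the true reference).
#' @param N Effective population size (diploid-scaled; pairwise coalescence
#'   rate `1/2N`).
#' @param mu_site Mutation rate per site per generation.
#' @param read_length Query read length in bases.
#' @param A_q,A_t,A_f Ages of the query, true and false samples in
#'   generations (0 = present day).  Consistency requires
#'   `A_q, A_t < T_qt` whenever `T_qt > 0` (and `A_q = A_t = 0` when
#'   `T_qt = 0`), and `A_f, A_t < T_tf`.
#' @param C_t,C_f Completeness of the true and false reference sequences:
#'   the fraction of genome positions represented (breadth of coverage, not
#'   depth), each in `[0, 1]`.  At least one must be positive.
#'
#' @return An object of class `"coalbin_params"`: a named list with the
#'   fields above plus the derived `mu_read`.
#'
#' @examples
#' p <- model_params(T_tf = 400000, T_qt = 0, N = 10000,
#'                   mu_site = 1e-8, read_length = 96)
#' p$mu_read  # 9.6e-07
#'
#' @seealso [validate_params()], [assignment_probabilities()]
#' @export
model_params <- function(T_tf, T_qt = 0, N = 10000, mu_site = 1e-8,
                         read_length = 96, A_q = 0, A_t = 0, A_f = 0,
                         C_t = 1, C_f = 1) {
  p <- structure(
    list(T_tf = as.numeric(T_tf), T_qt = as.numeric(T_qt), N = as.numeric(N),
         mu_site = as.numeric(mu_site), read_length = as.numeric(read_length),
         A_q = as.numeric(A_q), A_t = as.numeric(A_t), A_f = as.numeric(A_f),
         C_t = as.numeric(C_t), C_f = as.numeric(C_f),
         mu_read = as.numeric(mu_site) * as.numeric(read_length)),
    class = "coalbin_params")
  validate_params(p)
}

#' Validate a binning-model parameter set
#'
#' Checks every model invariant and recomputes the derived per-read mutation
#' rate.  Called by [model_params()]; exposed so that programmatically
#' modified parameter lists can be re-checked.
#'
#' @param p An object of class `"coalbin_params"`, or a named list with the
#'   same fields.
#' @return The validated parameter set (class `"coalbin_params"`), with
#'   `mu_read` recomputed.
#' @export
validate_params <- function(p) {
  fields <- c("T_tf", "T_qt", "N", "mu_site", "read_length",
              "A_q", "A_t", "A_f", "C_t", "C_f")
  missing_f <- setdiff(fields, names(p))
  if (length(missing_f))
    stop("missing parameter field(s): ", paste(missing_f, collapse = ", "))
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  fail <- function(...) stop(..., call. = FALSE)
  if (p$T_qt < 0) fail("divergence time T_qt must be non-negative")
  if (!(p$T_qt < p$T_tf))
    fail("divergence ordering violated: require T_qt < T_tf (got T_qt = ",
         p$T_qt, ", T_tf = ", p$T_tf, ")")
  if (p$N <= 0) fail("effective population size N must be positive")
  if (p$mu_site < 0) fail("mutation rate mu_site must be non-negative")
  if (p$read_length < 1) fail("read_length must be at least 1")
  if (p$A_q < 0 || p$A_t < 0 || p$A_f < 0) fail("sample ages must be non-negative")
  if (p$T_qt > 0) {
    if (p$A_q >= p$T_qt)
      fail("age exceeds query-true divergence: require A_q < T_qt")
    if (p$A_t >= p$T_qt)
      fail("age exceeds query-true divergence: require A_t < T_qt")
  } else {
    if (p$A_q != 0 || p$A_t != 0)
      fail("age exceeds query-true divergence: A_q = A_t = 0 required when T_qt = 0")
  }
  if (p$A_f >= p$T_tf || p$A_t >= p$T_tf)
    fail("age exceeds true-false divergence: require A_f, A_t < T_tf")
  if (p$C_t < 0 || p$C_t > 1 || p$C_f < 0 || p$C_f > 1)
    fail("completeness C_t, C_f must lie in [0, 1]")
  if (p$C_t + p$C_f <= 0)
    fail("at least one reference completeness must be positive")
  p$mu_read <- p$mu_site * p$read_length
  class(p) <- "coalbin_params"
  p
}

#' @export
print.coalbin_params <- function(x, ...) {
  cat("Two-reference binning model parameters\n")
  cat(sprintf("  divergence times (generations): T_tf = %g, T_qt = %g\n",
              x$T_tf, x$T_qt))
  cat(sprintf("  effective population size:      N = %g (coalescence rate 1/2N)\n",
              x$N))
  cat(sprintf("  mutation: mu_site = %g /site/gen, read length k = %g, mu_read = %g\n",
              x$mu_site, x$read_length, x$mu_read))
  cat(sprintf("  sample ages (generations):      A_q = %g, A_t = %g, A_f = %g\n",
              x$A_q, x$A_t, x$A_f))
  cat(sprintf("  reference completeness:         C_t = %g, C_f = %g\n",
              x$C_t, x$C_f))
  invisible(x)
}

#' Rescale time to evaluate the model at smaller population sizes
#'
#' The assignment probabilities are invariant under a simultaneous rescaling
#' of time: dividing the effective population size and all divergence times
#' and ages by a factor while multiplying the mutation rate by the same
#' factor leaves every branch-length x mutation-rate product, and every
#' `t/2N` exponent, unchanged.  Evaluating at a rescaled (smaller) `N` is
#' the standard workaround when an implementation's integrand terms underflow
#' at very large population sizes.
#'
#' @param p A validated `"coalbin_params"` object.
#' @param factor Positive scaling factor; `N -> N/factor`,
#'   `mu_site -> mu_site * factor`, all times and ages divided by `factor`.
#' @return A validated `"coalbin_params"` object.
#' @examples
#' p <- model_params(T_tf = 400000)
#' p10 <- rescale_params(p, 10)
#' p10$N       # 1000
#' p10$mu_read # 9.6e-06
#' @export
rescale_params <- function(p, factor) {
  p <- validate_params(p)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a single positive number")
  model_params(T_tf = p$T_tf / factor, T_qt = p$T_qt / factor,
               N = p$N / factor, mu_site = p$mu_site * factor,
               read_length = p$read_length,
               A_q = p$A_q / factor, A_t = p$A_t / factor, A_f = p$A_f / factor,
               C_t = p$C_t, C_f = p$C_f)
}
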