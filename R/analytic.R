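#' Prior probabilities of the four genealogy cases
#'
#' Looking backward in time, the query lineage and the true-reference
#' lineage become joinable at `max(T_qt, A_q, A_t)` and either coalesce
#' before the true-false species split at `T_tf` (Case 1, complete lineage
#' sorting) or fail to (Case 2).  Conditional on Case 2, three lineages
#' enter the ancestral population and each pair is equally likely to
#' coalesce first, giving subcases 2.1 (query-true first), 2.2 (true-false
#' first) and 2.3 (query-false first, i.e. incomplete lineage sorting with
#' a discordant topology), each with conditional probability 1/3.
#'
#' @param p A validated `"coalbin_params"` object.
#' @return An object of class `"coalbin_case_weights"`: a named numeric
#'   vector with entries `w_case1`, `w_case21`, `w_case22`, `w_case23`
#'   summing to 1.
#' @examples
#' case_weights(model_params(T_tf = 400000))            # Case 1 dominates
#' case_weights(model_params(T_tf = 20000, N = 10000))  # w_case1 = 1 - exp(-1)
#' @export
case_weights <- function(p) {
  p <- validate_params(p)
  s <- max(p$T_qt, p$A_q, p$A_t)
  w1 <- 1 - exp(-(p$T_tf - s) / (2 * p$N))
  w2 <- (1 - w1) / 3
  structure(c(w_case1 = w1, w_case21 = w2, w_case22 = w2, w_case23 = w2),
            class = "coalbin_case_weights")
}

#' @export
print.coalbin_case_weights <- function(x, ...) {
  cat("Genealogy case weights\n")
  print(unclass(x), ...)
  invisible(x)
}

# ---- quadrature core ---------------------------------------------------
#
# Each case's pair of coalescence times is mapped onto the unit square by
# exponential substitution (u = exp(-t/2N) style), under which the
# conditional time densities become exactly uniform.  Expectations are then
# tensor-product Gauss-Legendre sums of bounded integrands.
#
# Branch-segment decomposition per case (generations), with ages:
#   shared  = the query-lineage segment common to the q->t and q->f paths
#   excl_t  = segments on the q->t path only
#   excl_f  = segments on the q->f path only
# Case 1 / 2.1: excl_t = t1 - A_t, excl_f = 2*t2 - t1 - A_f, shared = t1 - A_q
# Case 2.2:     excl_t = t2 - A_t, excl_f = t2 - A_f, shared = 2*t1 - t2 - A_q
# Case 2.3:     excl_t = 2*t1 - t3 - A_t, excl_f = t3 - A_f, shared = t3 - A_q

.case_ids <- c(1L, 21L, 22L, 23L)

# Map unit-square nodes (u, v) to branch-segment lengths for one case.
.case_segments <- function(p, case_id, u, v) {
  twoN <- 2 * p$N
  T <- p$T_tf
  if (case_id == 1L) {
    a <- max(p$T_qt, p$A_q, p$A_t)
    t1 <- a - twoN * log(1 - u * (1 - exp(-(T - a) / twoN)))
    t2 <- T - twoN * log(v)
    list(sh = t1 - p$A_q, et = t1 - p$A_t, ef = 2 * t2 - t1 - p$A_f)
  } else if (case_id == 21L) {
    t1 <- T - (twoN / 2) * log(u)   # first of two remaining exponentials
    t2 <- t1 - twoN * log(v)
    list(sh = t1 - p$A_q, et = t1 - p$A_t, ef = 2 * t2 - t1 - p$A_f)
  } else if (case_id == 22L) {
    t2 <- T - (twoN / 2) * log(u)   # true-false coalescence
    t1 <- t2 - twoN * log(v)        # root: query joins the (t,f) ancestor
    list(sh = 2 * t1 - t2 - p$A_q, et = t2 - p$A_t, ef = t2 - p$A_f)
  } else if (case_id == 23L) {
    t3 <- T - (twoN / 2) * log(u)   # query-false coalescence (ILS topology)
    t1 <- t3 - twoN * log(v)        # root: true joins the (q,f) ancestor
    list(sh = t3 - p$A_q, et = 2 * t1 - t3 - p$A_t, ef = t3 - p$A_f)
  } else stop("unknown case id: ", case_id)
}

# Gauss-Legendre nodes on (0, 1), cached per order.
.coalbin_cache <- new.env(parent = emptyenv())

.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.coalbin_cache[[key]]))
    .coalbin_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .coalbin_cache[[key]]
}

# All conditional expectations needed by both rules, on an n x n grid.
.case_expectations_at <- function(p, case_id, n, series_tol) {
  gl <- .gl_nodes(n)
  u <- rep(gl$x, each = n)
  v <- rep(gl$x, times = n)
  W <- rep(gl$w, each = n) * rep(gl$w, times = n)
  seg <- .case_segments(p, case_id, u, v)
  mu <- p$mu_read
  l_sh <- mu * seg$sh
  l_et <- mu * seg$et
  l_ef <- mu * seg$ef
  if (any(seg$sh < -1e-9) || any(seg$et < -1e-9) || any(seg$ef < -1e-9))
    stop("negative branch segment encountered in case ", case_id)
  tri <- .poisson_triple(l_et, l_ef, series_tol)
  e_t0 <- exp(-(l_sh + l_et))   # P(K_t = 0) given the times
  e_f0 <- exp(-(l_sh + l_ef))
  c(lm_correct   = sum(W * tri$lt),   # fewer mismatches to true
    lm_incorrect = sum(W * tri$gt),
    lm_none      = sum(W * tri$eq),
    em_correct   = sum(W * e_t0 * (1 - exp(-l_ef))),
    em_incorrect = sum(W * e_f0 * (1 - exp(-l_et))),
    em_zero_t    = sum(W * e_t0),
    em_zero_f    = sum(W * e_f0))
}

# Adaptive refinement: double the per-axis node count until successive
# estimates agree within tol.
.case_expectations <- function(p, case_id, tol = 1e-6, series_tol = 1e-10,
                               n_start = 48L, n_max = 384L) {
  prev <- .case_expectations_at(p, case_id, n_start, series_tol)
  n <- 2L * n_start
  repeat {
    cur <- .case_expectations_at(p, case_id, n, series_tol)
    if (max(abs(cur - prev)) < tol)
      return(c(cur, n_nodes = n))
    if (n >= n_max)
      stop(sprintf(paste0("quadrature failed to converge for case %d ",
                          "(last change %.3g at %d nodes per axis); ",
                          "parameters: T_tf=%g T_qt=%g N=%g mu_read=%g"),
                   case_id, max(abs(cur - prev)), n,
                   p$T_tf, p$T_qt, p$N, p$mu_read))
    prev <- cur
    n <- 2L * n
  }
}

#' Conditional assignment probabilities for one genealogy case
#'
#' Evaluates the normalized case integral: the expectation, over the case's
#' coalescence-time density, of the conditional probability of the given
#' assignment outcome.  Under the least-mismatch rule only the exclusive
#' path segments matter (mutations on the shared query segment hit both
#' comparisons and cancel); the exact-match rule additionally requires zero
#' mutations on the shared segment.
#'
#' @param p A validated `"coalbin_params"` object.
#' @param case_id One of 1, 21, 22, 23 (cases 1, 2.1, 2.2, 2.3).
#' @param rule `"least_mismatch"` or `"exact_match"`.
#' @param outcome Optional: `"correct"`, `"incorrect"` or `"none"` to return
#'   a single probability; omit for the full triple.
#' @param tol Quadrature tolerance.
#' @return If `outcome` is given, a single probability; otherwise an object
#'   of class `"coalbin_probs"` with the conditional triple for this case.
#' @examples
#' p <- model_params(T_tf = 400000)
#' case_probability(p, 1, "least_mismatch")
#' @export
case_probability <- function(p, case_id,
                             rule = c("least_mismatch", "exact_match"),
                             outcome = NULL, tol = 1e-6) {
  p <- validate_params(p)
  rule <- match.arg(rule)
  case_id <- as.integer(case_id)
  if (!case_id %in% .case_ids)
    stop("case_id must be one of 1, 21, 22, 23")
  w <- case_weights(p)
  if (w[[match(case_id, .case_ids)]] <= 0)
    stop("case ", case_id, " has zero prior weight for these parameters")
  e <- .case_expectations(p, case_id, tol = tol)
  tr <- if (rule == "least_mismatch") {
    c(correct = unname(e["lm_correct"]), incorrect = unname(e["lm_incorrect"]),
      none = unname(e["lm_none"]))
  } else {
    c(correct = unname(e["em_correct"]), incorrect = unname(e["em_incorrect"]),
      none = 1 - unname(e["em_correct"]) - unname(e["em_incorrect"]))
  }
  res <- .new_probs(tr["correct"], tr["incorrect"], tr["none"], rule)
  if (is.null(outcome)) return(res)
  outcome <- match.arg(outcome, c("correct", "incorrect", "none"))
  switch(outcome, correct = res$p_correct, incorrect = res$p_incorrect,
         none = res$p_none)
}

.new_probs <- function(pc, pi_, pn, rule) {
  structure(list(p_correct = unname(pc), p_incorrect = unname(pi_),
                 p_none = unname(pn), rule = rule),
            class = "coalbin_probs")
}

#' @export
print.coalbin_probs <- function(x, digits = 3, ...) {
  cat(sprintf("Assignment probabilities (%s rule)\n", x$rule))
  cat(sprintf("  correct:   %.*g\n  incorrect: %.*g\n  none:      %.*g\n",
              digits, x$p_correct, digits, x$p_incorrect, digits, x$p_none))
  ratio <- tryCatch(correct_per_incorrect(x), error = function(e) NA_real_)
  if (is.finite(ratio))
    cat(sprintf("  correct per incorrect: %.1f\n", ratio))
  invisible(x)
}

#' Overall assignment probabilities for a query read
#'
#' Combines the four genealogy cases, weighted by their prior probabilities,
#' into the unconditional probabilities that a query read is assigned to the
#' correct reference, to the wrong reference, or left unassigned, and then
#' adjusts for incomplete reference sequences.
#'
#' With completenesses `C_t`, `C_f` the read aligns to both references, only
#' the true one, or only the false one with probabilities proportional to
#' `C_t*C_f`, `C_t*(1-C_f)` and `(1-C_t)*C_f` (normalized by
#' `1 - (1-C_t)*(1-C_f)`, conditioning on at least one alignment).  Under
#' least mismatch a single-alignment read is assigned to that reference
#' ("if a read aligns to only one reference, assign it there").  Under exact
#' match the default (`exact_single_alignment = "zero_mismatch"`) still
#' requires zero mismatches against the single aligned reference, so the
#' contribution is `P(K = 0)` rather than 1; set `"always_assign"` for the
#' simpler convention in which any single-alignment read is assigned.
#'
#' When `T_tf - T_qt >> 2N` the three Case-2 terms are negligible;
#' `skip_ils_cases = TRUE` evaluates Case 1 only (renormalized by its
#' weight), with relative error bounded by `exp(-(T_tf - T_qt)/2N)`.
#'
#' @inheritParams case_probability
#' @param skip_ils_cases If `TRUE`, evaluate only Case 1 (see Details).
#' @param exact_single_alignment Exact-match convention for reads aligning
#'   to a single reference: `"zero_mismatch"` (default) or `"always_assign"`.
#' @return An object of class `"coalbin_probs"` with fields `p_correct`,
#'   `p_incorrect`, `p_none` (summing to 1) and `rule`.
#' @examples
#' p <- model_params(T_tf = 400000, read_length = 96, mu_site = 1e-8)
#' ap <- assignment_probabilities(p, "least_mismatch")
#' correct_per_incorrect(ap)  # about 60.6
#' @export
assignment_probabilities <- function(p,
                                     rule = c("least_mismatch", "exact_match"),
                                     tol = 1e-6, skip_ils_cases = FALSE,
                                     exact_single_alignment =
                                       c("zero_mismatch", "always_assign")) {
  p <- validate_params(p)
  rule <- match.arg(rule)
  exact_single_alignment <- match.arg(exact_single_alignment)
  w <- as.numeric(case_weights(p))
  if (skip_ils_cases) {
    ids <- 1L
    wts <- 1              # condition on complete lineage sorting
  } else {
    ids <- .case_ids
    wts <- w
  }
  keys <- c("lm_correct", "lm_incorrect", "lm_none",
            "em_correct", "em_incorrect", "em_zero_t", "em_zero_f")
  mix <- stats::setNames(numeric(length(keys)), keys)
  n_nodes <- 0L
  for (i in seq_along(ids)) {
    if (wts[i] <= 0) next
    e <- .case_expectations(p, ids[i], tol = tol)
    n_nodes <- max(n_nodes, as.integer(e[["n_nodes"]]))
    mix <- mix + wts[i] * e[keys]
  }
  if (rule == "least_mismatch") {
    pc <- mix[["lm_correct"]]; pi_ <- mix[["lm_incorrect"]]
    pn <- mix[["lm_none"]]
  } else {
    pc <- mix[["em_correct"]]; pi_ <- mix[["em_incorrect"]]
    pn <- sum(wts) - pc - pi_
  }
  # completeness adjustment
  D <- 1 - (1 - p$C_t) * (1 - p$C_f)
  pb <- p$C_t * p$C_f / D
  pt <- p$C_t * (1 - p$C_f) / D
  pf <- (1 - p$C_t) * p$C_f / D
  if (rule == "least_mismatch") {
    out_c <- pb * pc + pt
    out_i <- pb * pi_ + pf
    out_n <- pb * pn
  } else if (exact_single_alignment == "always_assign") {
    out_c <- pb * pc + pt
    out_i <- pb * pi_ + pf
    out_n <- pb * pn + 0  # single-alignment reads always assigned
  } else {
    out_c <- pb * pc + pt * mix[["em_zero_t"]]
    out_i <- pb * pi_ + pf * mix[["em_zero_f"]]
    out_n <- pb * pn + pt * (1 - mix[["em_zero_t"]]) +
      pf * (1 - mix[["em_zero_f"]])
  }
  res <- .new_probs(out_c, out_i, out_n, rule)
  attr(res, "n_nodes") <- n_nodes   # per-axis quadrature order used
  res
}

#' Expected correct assignments per incorrect assignment
#'
#' @param a A `"coalbin_probs"` object (or any list with `p_correct` and
#'   `p_incorrect`).
#' @return `p_correct / p_incorrect`; `Inf` when `p_incorrect` is zero and
#'   `p_correct` positive.  An error when both are zero (the ratio is
#'   undefined).
#' @examples
#' correct_per_incorrect(list(p_correct = 0.5, p_incorrect = 0.25))  # 2
#' @export
correct_per_incorrect <- function(a) {
  pc <- a$p_correct; pi_ <- a$p_incorrect
  if (is.null(pc) || is.null(pi_) || pi_ < 0)
    stop("need non-negative p_correct and p_incorrect")
  if (pi_ == 0) {
    if (pc > 0) return(Inf)
    stop("correct-per-incorrect ratio undefined: both probabilities are zero")
  }
  pc / pi_
}

#' Sweep one model parameter over a grid
#'
#' Re-evaluates the assignment probabilities while one parameter varies and
#' all others are held at their baseline values -- the standard sensitivity
#' design for ranking the relative impact of population-genetic and database
#' parameters.
#'
#' @param base Baseline `"coalbin_params"` object.
#' @param vary Name of the parameter to vary (any field of
#'   [model_params()] except the derived `mu_read`).
#' @param grid Numeric vector of values; each resulting parameter set must
#'   validate.
#' @param rule Assignment rule passed to [assignment_probabilities()].
#' @param tol Quadrature tolerance.
#' @return A data frame with one row per grid value and columns
#'   `parameter`, `value`, `rule`, `p_correct`, `p_incorrect`, `p_none`,
#'   `ratio` (correct per incorrect).  Exportable as TSV with
#'   [utils::write.table()].
#' @examples
#' base <- model_params(T_tf = 400000)
#' sweep_parameter(base, "N", c(1e3, 1e4, 1e5))
#' @export
sweep_parameter <- function(base, vary, grid,
                            rule = c("least_mismatch", "exact_match"),
                            tol = 1e-6) {
  base <- validate_params(base)
  rule <- match.arg(rule)
  settable <- c("T_tf", "T_qt", "N", "mu_site", "read_length",
                "A_q", "A_t", "A_f", "C_t", "C_f")
  if (!is.character(vary) || length(vary) != 1L || !vary %in% settable)
    stop("vary must name one of: ", paste(settable, collapse = ", "))
  rows <- lapply(grid, function(val) {
    q <- base
    q[[vary]] <- as.numeric(val)
    q <- validate_params(q)
    ap <- assignment_probabilities(q, rule, tol = tol)
    data.frame(parameter = vary, value = as.numeric(val), rule = rule,
               p_correct = ap$p_correct, p_incorrect = ap$p_incorrect,
               p_none = ap$p_none,
               ratio = if (ap$p_incorrect > 0)
                 ap$p_correct / ap$p_incorrect else Inf,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(parameter = character(), value = numeric(),
                      rule = character(), p_correct = numeric(),
                      p_incorrect = numeric(), p_none = numeric(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
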