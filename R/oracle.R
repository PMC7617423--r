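# Vectorized genealogy sampler shared by the oracle and the sequence
# simulator.  Times are drawn from the model's case-wise densities:
#  - the query-true pair becomes joinable at s = max(T_qt, A_q, A_t) and
#    coalesces before T_tf (Case 1) with probability 1 - exp(-(T_tf-s)/2N),
#    the time being a truncated exponential on [s, T_tf];
#  - conditional on Case 2 the subcase is uniform over the three pairs, the
#    first of the two remaining coalescence gaps is Exp(2/2N)-distributed
#    beyond T_tf and the second Exp(1/2N) beyond the first.
# Returns times plus the shared / exclusive branch-segment lengths.
.sample_genealogy_core <- function(p, n) {
  twoN <- 2 * p$N
  T <- p$T_tf
  s <- max(p$T_qt, p$A_q, p$A_t)
  w1 <- 1 - exp(-(T - s) / twoN)
  in1 <- stats::runif(n) < w1
  sub <- sample.int(3L, n, replace = TRUE)     # subcase for non-Case-1 draws
  case <- ifelse(in1, 1L, c(21L, 22L, 23L)[sub])
  t1 <- t2 <- t3 <- rep(NA_real_, n)
  i <- which(case == 1L)
  if (length(i)) {
    u <- stats::runif(length(i))
    t1[i] <- s - twoN * log(1 - u * w1)
    t2[i] <- T + stats::rexp(length(i), rate = 1 / twoN)
  }
  i <- which(case == 21L)
  if (length(i)) {
    t1[i] <- T + stats::rexp(length(i), rate = 2 / twoN)
    t2[i] <- t1[i] + stats::rexp(length(i), rate = 1 / twoN)
  }
  i <- which(case == 22L)
  if (length(i)) {
    t2[i] <- T + stats::rexp(length(i), rate = 2 / twoN)   # (t,f) coalesce
    t1[i] <- t2[i] + stats::rexp(length(i), rate = 1 / twoN)  # root
  }
  i <- which(case == 23L)
  if (length(i)) {
    t3[i] <- T + stats::rexp(length(i), rate = 2 / twoN)   # (q,f) coalesce
    t1[i] <- t3[i] + stats::rexp(length(i), rate = 1 / twoN)  # root
  }
  sh <- et <- ef <- numeric(n)
  conc <- case %in% c(1L, 21L)
  sh[conc] <- t1[conc] - p$A_q
  et[conc] <- t1[conc] - p$A_t
  ef[conc] <- 2 * t2[conc] - t1[conc] - p$A_f
  i22 <- case == 22L
  sh[i22] <- 2 * t1[i22] - t2[i22] - p$A_q
  et[i22] <- t2[i22] - p$A_t
  ef[i22] <- t2[i22] - p$A_f
  i23 <- case == 23L
  sh[i23] <- t3[i23] - p$A_q
  et[i23] <- 2 * t1[i23] - t3[i23] - p$A_t
  ef[i23] <- t3[i23] - p$A_f
  data.frame(case = case, t1 = t1, t2 = t2, t3 = t3,
             len_shared = sh, len_excl_t = et, len_excl_f = ef)
}

#' Draw genealogies and per-branch mutation counts from the model
#'
#' Monte Carlo realization of the model underlying the analytic integrals:
#' the genealogy case is sampled with its prior weight, the coalescence
#' times from the case's (truncated) exponential densities, and Poisson
#' mutation counts are placed on the shared and exclusive branch segments
#' with mean `mu_read x length`.
#'
#' @param p A validated `"coalbin_params"` object.
#' @param n Number of independent draws.
#' @param seed Optional integer seed.
#' @return A data frame of class `"coalbin_genealogy"` with one row per
#'   draw: `case` (1, 21, 22, 23), times `t1`, `t2`, `t3` (NA where not
#'   defined for the case), segment lengths `len_shared`, `len_excl_t`,
#'   `len_excl_f`, and mutation counts `k_shared`, `k_excl_t`, `k_excl_f`.
#' @examples
#' g <- sample_genealogy(model_params(T_tf = 400000), n = 5, seed = 1)
#' @export
sample_genealogy <- function(p, n = 1, seed = NULL) {
  p <- validate_params(p)
  if (!is.null(seed)) set.seed(seed)
  g <- .sample_genealogy_core(p, n)
  g$k_shared <- stats::rpois(n, p$mu_read * g$len_shared)
  g$k_excl_t <- stats::rpois(n, p$mu_read * g$len_excl_t)
  g$k_excl_f <- stats::rpois(n, p$mu_read * g$len_excl_f)
  class(g) <- c("coalbin_genealogy", "data.frame")
  g
}

# Outcome logic shared by the oracle and the sequence scorer.  kt/kf are the
# mismatch (mutation) counts against the true and false references counted
# over whatever segments the rule sees; ksh the shared-segment count
# (exact match only); at/af whether the read aligns to each reference.
.assign_outcome <- function(rule, kt, kf, ksh, at, af) {
  n <- length(kt)
  out <- rep.int("none", n)
  if (rule == "least_mismatch") {
    both <- at & af
    out[both & (kt < kf)] <- "correct"
    out[both & (kt > kf)] <- "incorrect"
    out[at & !af] <- "correct"    # single alignment: assign to the other
    out[!at & af] <- "incorrect"
  } else {
    Kt <- ksh + kt
    Kf <- ksh + kf
    both <- at & af
    out[both & Kt == 0 & Kf > 0] <- "correct"
    out[both & Kf == 0 & Kt > 0] <- "incorrect"
    out[at & !af & Kt == 0] <- "correct"   # still requires an exact match
    out[!at & af & Kf == 0] <- "incorrect"
  }
  factor(out, levels = c("correct", "incorrect", "none"))
}

#' Assignment outcome of one (or more) genealogy draws
#'
#' Applies the assignment rule to the mutation counts of a
#' [sample_genealogy()] draw, given indicators for whether the read aligned
#' to each reference.  Under least mismatch the shared-segment count cancels
#' and only the exclusive counts are compared; a read aligning to a single
#' reference is assigned to it.  Under exact match the total count against a
#' reference (shared + exclusive) must be zero.
#'
#' @param g A `"coalbin_genealogy"` data frame.
#' @param rule `"least_mismatch"` or `"exact_match"`.
#' @param completeness_draw Logical matrix / data frame with columns
#'   `aligns_t`, `aligns_f` (recycled if a single row); every row must have
#'   at least one `TRUE`.
#' @return Factor with levels `correct`, `incorrect`, `none`.
#' @export
assign_draw <- function(g, rule = c("least_mismatch", "exact_match"),
                        completeness_draw = NULL) {
  rule <- match.arg(rule)
  n <- nrow(g)
  if (is.null(completeness_draw)) {
    at <- rep.int(TRUE, n); af <- rep.int(TRUE, n)
  } else {
    cd <- as.data.frame(completeness_draw)
    at <- rep_len(as.logical(cd$aligns_t), n)
    af <- rep_len(as.logical(cd$aligns_f), n)
  }
  if (any(!at & !af))
    stop("completeness_draw must have at least one alignment per read")
  .assign_outcome(rule, g$k_excl_t, g$k_excl_f, g$k_shared, at, af)
}

# Sample the alignment configuration conditional on at least one alignment.
.sample_alignment <- function(n, C_t, C_f) {
  D <- 1 - (1 - C_t) * (1 - C_f)
  u <- stats::runif(n)
  pb <- C_t * C_f / D
  pt <- C_t * (1 - C_f) / D
  list(aligns_t = u < pb + pt, aligns_f = u < pb | u >= pb + pt)
}

#' Monte Carlo estimate of the assignment probabilities
#'
#' Brute-force estimate of [assignment_probabilities()] by repeated
#' genealogy draws: the long-run frequencies of correct, incorrect and no
#' assignment across independent reads, with binomial standard errors.
#' Serves as the independent validation oracle for the analytic engine.
#'
#' @inheritParams sample_genealogy
#' @param rule `"least_mismatch"` or `"exact_match"`.
#' @param n_draws Number of independent genealogy draws (reads).
#' @param seed Integer seed; estimates are deterministic given the seed.
#' @return An object of class `"coalbin_oracle"`: list with `p_correct`,
#'   `p_incorrect`, `p_none`, matching standard errors `se_correct` etc.,
#'   `n_draws`, `rule`, `seed`.
#' @examples
#' est <- estimate_probs(model_params(T_tf = 400000), n_draws = 1e4, seed = 1)
#' @export
estimate_probs <- function(p, rule = c("least_mismatch", "exact_match"),
                           n_draws = 1e5, seed = 1) {
  p <- validate_params(p)
  rule <- match.arg(rule)
  if (n_draws < 1) stop("n_draws must be at least 1")
  set.seed(seed)
  g <- sample_genealogy(p, n_draws)
  al <- .sample_alignment(n_draws, p$C_t, p$C_f)
  out <- .assign_outcome(rule, g$k_excl_t, g$k_excl_f, g$k_shared,
                         al$aligns_t, al$aligns_f)
  freq <- as.numeric(table(out)) / n_draws
  se <- sqrt(freq * (1 - freq) / n_draws)
  structure(list(p_correct = freq[1], p_incorrect = freq[2], p_none = freq[3],
                 se_correct = se[1], se_incorrect = se[2], se_none = se[3],
                 n_draws = n_draws, rule = rule, seed = seed),
            class = "coalbin_oracle")
}

#' @export
print.coalbin_oracle <- function(x, ...) {
  cat(sprintf("Monte Carlo assignment estimate (%s rule, %d draws, seed %d)\n",
              x$rule, x$n_draws, x$seed))
  cat(sprintf("  correct:   %.4f (se %.2g)\n", x$p_correct, x$se_correct))
  cat(sprintf("  incorrect: %.4f (se %.2g)\n", x$p_incorrect, x$se_incorrect))
  cat(sprintf("  none:      %.4f (se %.2g)\n", x$p_none, x$se_none))
  invisible(x)
}
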