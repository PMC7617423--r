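# Shared fixtures: parameter sets and small utilities, built in code.

baseline_params <- function(...) {
  args <- utils::modifyList(
    list(T_tf = 400000, T_qt = 0, N = 10000, mu_site = 1e-8,
         read_length = 96),
    list(...))
  do.call(model_params, args)
}

# Parameter sets spanning the four genealogy cases, used for the
# cross-implementation agreement checks (chosen for their case-weight
# profiles, not tuned to any observed result):
#  P1: complete lineage sorting dominates (baseline).
#  P2: shallow true-false split, substantial incomplete lineage sorting.
#  P3: diverged query with non-contemporaneous samples.
#  P4: short reads, shallow splits, larger population.
agreement_params <- function() {
  list(
    P1 = baseline_params(),
    P2 = model_params(T_tf = 30000, T_qt = 0, N = 10000, mu_site = 1e-8,
                      read_length = 96),
    P3 = model_params(T_tf = 400000, T_qt = 50000, N = 10000, mu_site = 1e-8,
                      read_length = 96, A_q = 20000, A_t = 10000, A_f = 50000),
    P4 = model_params(T_tf = 100000, T_qt = 10000, N = 20000, mu_site = 1e-8,
                      read_length = 40))
}

# Independent reverse-complement used to test strand handling.
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

probs_vec <- function(x) c(x$p_correct, x$p_incorrect, x$p_none)
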