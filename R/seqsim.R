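# Sequence-level simulator: three-taxon genomes along a recombining
# sequence, query reads with known coordinates, positional mismatch
# counting.  Genealogies vary along the genome: segment breakpoints arrive
# as an exponential process with per-site rate recomb_rate x (local tree
# branch length), and each new segment's genealogy is redrawn independently
# from the model's case-wise coalescence densities.
#
# The query is diploid: its two haplotypes coalesce at a time tq drawn from
# an Exp(1/2N) truncated below the query lineage's first merge, so each
# haplotype's marginal genealogy is exactly the single-lineage model.
# References are simulated as single lineages (marginally identical to a
# diploid individual with one haplotype chosen at random).
#
# Bases are stored as raw vectors with 0,1,2,3 = A,C,G,T; complement is
# 3 - x.

.DNA_LUT <- charToRaw("ACGT")

.raw_to_dna <- function(x) rawToChar(.DNA_LUT[as.integer(x) + 1L])

.dna_to_raw <- function(s) {
  v <- utf8ToInt(s)
  out <- integer(length(v))
  out[v == utf8ToInt("C")] <- 1L
  out[v == utf8ToInt("G")] <- 2L
  out[v == utf8ToInt("T")] <- 3L
  if (!all(v %in% c(65L, 67L, 71L, 84L)))  # A C G T
    stop("non-ACGT base in sequence")
  as.raw(out)
}

# One batch of per-segment genealogies with their edge decomposition.
# Edge columns: 1 = query hap 1 private, 2 = query hap 2 private,
# 3 = query ancestral lineage, 4:6 = case-dependent (true, false, internal).
# mask bits: 1 = q1, 2 = q2, 4 = t, 8 = f.  top = older end of the edge,
# used to order mutation application (ancestral first).
.seg_batch <- function(p, m) {
  g <- .sample_genealogy_core(p, m)
  twoN <- 2 * p$N
  tjoin <- ifelse(g$case == 23L, g$t3, g$t1)
  u <- stats::runif(m)
  tq <- p$A_q - twoN * log(1 - u * (1 - exp(-(tjoin - p$A_q) / twoN)))
  len <- matrix(0, m, 6L)
  mask <- matrix(0L, m, 6L)
  top <- matrix(0, m, 6L)
  len[, 1] <- tq - p$A_q; mask[, 1] <- 1L; top[, 1] <- tq
  len[, 2] <- tq - p$A_q; mask[, 2] <- 2L; top[, 2] <- tq
  len[, 3] <- tjoin - tq; mask[, 3] <- 3L; top[, 3] <- tjoin
  i <- g$case %in% c(1L, 21L)        # ((q, t), f): root at t2
  len[i, 4] <- g$t1[i] - p$A_t;        mask[i, 4] <- 4L;  top[i, 4] <- g$t1[i]
  len[i, 5] <- g$t2[i] - g$t1[i];      mask[i, 5] <- 7L;  top[i, 5] <- g$t2[i]
  len[i, 6] <- g$t2[i] - p$A_f;        mask[i, 6] <- 8L;  top[i, 6] <- g$t2[i]
  i <- g$case == 22L                 # (q, (t, f)): root at t1
  len[i, 4] <- g$t2[i] - p$A_t;        mask[i, 4] <- 4L;  top[i, 4] <- g$t2[i]
  len[i, 5] <- g$t2[i] - p$A_f;        mask[i, 5] <- 8L;  top[i, 5] <- g$t2[i]
  len[i, 6] <- g$t1[i] - g$t2[i];      mask[i, 6] <- 12L; top[i, 6] <- g$t1[i]
  i <- g$case == 23L                 # ((q, f), t): ILS topology, root at t1
  len[i, 4] <- g$t3[i] - p$A_f;        mask[i, 4] <- 8L;  top[i, 4] <- g$t3[i]
  len[i, 5] <- g$t1[i] - g$t3[i];      mask[i, 5] <- 11L; top[i, 5] <- g$t1[i]
  len[i, 6] <- g$t1[i] - p$A_t;        mask[i, 6] <- 4L;  top[i, 6] <- g$t1[i]
  list(len = len, mask = mask, top = top, tree_len = rowSums(len))
}

# Segment lengths are drawn at a constant per-site breakpoint rate
# recomb_rate x (mean tree length, estimated from a pilot batch), and the
# genealogy of every segment is drawn independently.  Keeping lengths
# independent of the local tree makes the per-base marginal genealogy
# distribution exactly the model's (coupling length to the local tree
# length would over-sample small-tree genealogies, which persist over
# longer stretches).
.draw_segments <- function(p, L, recomb_rate) {
  if (recomb_rate == 0) {
    b <- .seg_batch(p, 1L)
    b$seg <- L
    b$start <- 1
    b$n <- 1L
    return(b)
  }
  pilot <- .seg_batch(p, 256L)
  rate <- recomb_rate * mean(pilot$tree_len)
  batches <- list(pilot)
  lens <- list(pmax(1, ceiling(stats::rexp(256L, rate))))
  covered <- sum(lens[[1]])
  while (covered < L) {
    need <- max(64L, as.integer(ceiling((L - covered) * rate * 1.2)))
    batches[[length(batches) + 1L]] <- .seg_batch(p, need)
    lens[[length(lens) + 1L]] <- pmax(1, ceiling(stats::rexp(need, rate)))
    covered <- covered + sum(lens[[length(lens)]])
  }
  len <- do.call(rbind, lapply(batches, `[[`, "len"))
  mask <- do.call(rbind, lapply(batches, `[[`, "mask"))
  top <- do.call(rbind, lapply(batches, `[[`, "top"))
  seg <- unlist(lens)
  cs <- cumsum(seg)
  n <- which(cs >= L)[1L]
  seg <- seg[seq_len(n)]
  seg[n] <- L - (if (n > 1) cs[n - 1L] else 0)
  list(len = len[seq_len(n), , drop = FALSE],
       mask = mask[seq_len(n), , drop = FALSE],
       top = top[seq_len(n), , drop = FALSE],
       seg = seg, start = c(1, cumsum(seg)[-n] + 1), n = n)
}

# Poisson mutation events on every (segment, edge) cell.
.draw_mutations <- function(p, segs) {
  m <- segs$n
  lam <- p$mu_site * segs$len * segs$seg   # recycles seg down columns
  nm <- stats::rpois(length(lam), lam)
  cell <- rep.int(seq_along(nm), nm)
  segi <- (cell - 1L) %% m + 1L
  edge <- (cell - 1L) %/% m + 1L
  ne <- length(cell)
  list(pos = as.integer(segs$start[segi] +
                          floor(stats::runif(ne) * segs$seg[segi])),
       mask = segs$mask[cbind(segi, edge)],
       top = segs$top[cbind(segi, edge)],
       delta = sample.int(3L, ne, replace = TRUE))
}

# Derive the four leaf sequences from a random root.  Events are applied
# oldest-first so that at multiply-hit sites the youngest mutation stands.
.apply_mutations <- function(root, ev) {
  root_int <- as.integer(root)
  leaf_bit <- c(q1 = 1L, q2 = 2L, t = 4L, f = 8L)
  out <- vector("list", length(leaf_bit))
  names(out) <- names(leaf_bit)
  for (nm in names(leaf_bit)) {
    s <- root
    idx <- which(bitwAnd(ev$mask, leaf_bit[[nm]]) > 0L)
    if (length(idx)) {
      o <- idx[order(ev$top[idx], decreasing = TRUE)]
      pos <- ev$pos[o]
      s[pos] <- as.raw((root_int[pos] + ev$delta[o]) %% 4L)
    }
    out[[nm]] <- s
  }
  out
}

#' Simulate a three-taxon dataset with query reads
#'
#' End-to-end sequence-level simulation of the binning experiment: true and
#' false reference sequences plus a diploid query individual are generated
#' along a recombining genome under the coalescent model, invariant sites
#' are filled with random nucleotides, and query reads are sampled uniformly
#' from both query haplotypes and both strands with their true coordinates
#' recorded.  Reads are error-free; ancient-DNA damage can be layered on
#' afterwards with [apply_deamination()].
#'
#' A query-true divergence time of exactly zero is simulated as a small
#' epsilon (`t_qt_epsilon` generations, default `1e-4`), the conventional
#' workaround for engines that reject zero-length branches; at these scales
#' the difference is far below anything measurable.
#'
#' @param p A validated `"coalbin_params"` object (`read_length` is taken
#'   from it).
#' @param genome_length Genome length in bases; must be at least
#'   `read_length`.
#' @param recomb_rate Recombination rate per site per generation; 0 gives a
#'   single genealogy genome-wide.
#' @param n_reads Number of query reads to sample.
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @param t_qt_epsilon Substitute for `T_qt = 0` (generations).
#' @return An object of class `"coalbin_sim"`: list with `sequences`
#'   (`$true`, `$false` and `$query` = two haplotypes, raw-coded), `reads`
#'   (data frame: `id`, `start`, `strand`, `hap`, `bases`),
#'   `genome_length`, `recomb_rate`, `n_segments`, `read_length`, `params`,
#'   `seed`.
#' @examples
#' p <- model_params(T_tf = 50000, read_length = 50)
#' ds <- simulate_dataset(p, genome_length = 1e5, n_reads = 100, seed = 1)
#' @export
simulate_dataset <- function(p, genome_length = 1e7, recomb_rate = 1e-8,
                             n_reads = 10000, seed = 1,
                             t_qt_epsilon = 1e-4) {
  p <- validate_params(p)
  L <- as.integer(genome_length)
  k <- as.integer(p$read_length)
  if (L < k) stop("genome_length must be at least read_length")
  if (n_reads < 0) stop("n_reads must be non-negative")
  if (recomb_rate < 0) stop("recomb_rate must be non-negative")
  set.seed(seed)
  psim <- p
  if (psim$T_qt == 0) psim$T_qt <- t_qt_epsilon
  psim <- validate_params(psim)
  segs <- .draw_segments(psim, L, recomb_rate)
  ev <- .draw_mutations(psim, segs)
  root <- as.raw(sample.int(4L, L, replace = TRUE) - 1L)
  seqs <- .apply_mutations(root, ev)
  starts <- if (n_reads > 0)
    sample.int(L - k + 1L, n_reads, replace = TRUE) else integer()
  hap <- sample.int(2L, n_reads, replace = TRUE)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  haps <- list(seqs$q1, seqs$q2)
  bases <- character(n_reads)
  for (i in seq_len(n_reads)) {
    r <- haps[[hap[i]]][starts[i]:(starts[i] + k - 1L)]
    if (strand[i] == "-") r <- rev(as.raw(3L - as.integer(r)))
    bases[i] <- .raw_to_dna(r)
  }
  structure(list(
    sequences = list(true = seqs$t, false = seqs$f,
                     query = list(seqs$q1, seqs$q2)),
    reads = data.frame(id = seq_len(n_reads), start = starts,
                       strand = strand, hap = hap, bases = bases,
                       stringsAsFactors = FALSE),
    genome_length = L, recomb_rate = recomb_rate, n_segments = segs$n,
    read_length = k, params = p, seed = seed),
    class = "coalbin_sim")
}

#' @export
print.coalbin_sim <- function(x, ...) {
  cat(sprintf(paste0("Simulated binning dataset: genome %d bp, %d reads of ",
                     "length %d,\n  %d genealogy segments (recombination ",
                     "rate %g), seed %d\n"),
              x$genome_length, nrow(x$reads), x$read_length, x$n_segments,
              x$recomb_rate, x$seed))
  invisible(x)
}

# ---- reference completeness masks --------------------------------------
# Periodic covered/uncovered blocks with a random phase: each period of
# `period` bases starts with round(period * C) covered sites, so the
# realized covered fraction equals C up to a single partial period, and a
# read of length k lies wholly inside a covered block with probability
# C - (k - 1)/period.  The period is kept much longer than a read so this
# geometric correction stays negligible.

.coverage_mask <- function(L, C, period = 1e5) {
  if (C >= 1) return(NULL)
  if (C <= 0) return(list(none = TRUE))
  list(none = FALSE, period = as.integer(period),
       cov_len = as.integer(round(period * C)),
       phase = sample.int(period, 1L) - 1L)
}

.is_covered <- function(mask, s, e) {
  if (is.null(mask)) return(rep.int(TRUE, length(s)))
  if (isTRUE(mask$none)) return(rep.int(FALSE, length(s)))
  ((s - 1L - mask$phase) %% mask$period) + (e - s) < mask$cov_len
}

#' Score simulated reads under an assignment rule
#'
#' Counts mismatches between each query read and the two reference
#' sequences positionally at the read's true coordinates (no alignment
#' heuristic: mapper behaviour is deliberately out of scope) and applies
#' the assignment rule.  Minus-strand reads are reverse-complemented back
#' before comparison.  With incomplete references, covered/uncovered blocks
#' are drawn for each reference and a read aligns only where fully covered;
#' reads aligning to a single reference follow the single-alignment rule
#' (least mismatch: assign to it; exact match: assign only with zero
#' mismatches).  Reads aligning to neither reference are excluded, matching
#' the model's conditioning on at least one alignment.
#'
#' @param ds A `"coalbin_sim"` dataset (possibly deaminated).
#' @param rule `"least_mismatch"` or `"exact_match"`.
#' @param completeness Length-2 numeric `(C_t, C_f)` in `[0, 1]`.
#' @param seed Seed for the completeness masks (required when any
#'   completeness is below 1).
#' @return An object of class `"coalbin_counts"`: a one-row data frame with
#'   `rule`, `n_reads` (scored), `correct`, `incorrect`, `none`, `assigned`
#'   and frequency columns `f_correct`, `f_incorrect`, `f_none`; the number
#'   of reads excluded as aligning to neither reference is in attribute
#'   `n_unaligned`.
#' @examples
#' p <- model_params(T_tf = 50000, read_length = 50)
#' ds <- simulate_dataset(p, genome_length = 1e5, n_reads = 200, seed = 1)
#' score_assignments(ds, "least_mismatch")
#' @export
score_assignments <- function(ds, rule = c("least_mismatch", "exact_match"),
                              completeness = c(1, 1), seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(ds, "coalbin_sim"))
  if (length(completeness) != 2L || any(completeness < 0) ||
      any(completeness > 1) || sum(completeness) <= 0)
    stop("completeness must be (C_t, C_f) in [0,1], not both zero")
  C_t <- completeness[1]; C_f <- completeness[2]
  if ((C_t < 1 || C_f < 1)) {
    if (is.null(seed)) stop("seed is required when completeness < 1")
    set.seed(seed)
  }
  L <- ds$genome_length
  k <- ds$read_length
  mask_t <- .coverage_mask(L, C_t)
  mask_f <- .coverage_mask(L, C_f)
  reads <- ds$reads
  n <- nrow(reads)
  ends <- reads$start + k - 1L
  at <- .is_covered(mask_t, reads$start, ends)
  af <- .is_covered(mask_f, reads$start, ends)
  mm_t <- mm_f <- integer(n)
  tru <- ds$sequences$true
  fal <- ds$sequences$false
  for (i in seq_len(n)) {
    r <- .dna_to_raw(reads$bases[i])
    if (reads$strand[i] == "-") r <- rev(as.raw(3L - as.integer(r)))
    w <- reads$start[i]:ends[i]
    mm_t[i] <- sum(r != tru[w])
    mm_f[i] <- sum(r != fal[w])
  }
  keep <- at | af
  out <- .assign_outcome(rule, mm_t[keep], mm_f[keep],
                         integer(sum(keep)), at[keep], af[keep])
  tab <- table(out)
  nk <- sum(keep)
  res <- data.frame(rule = rule, n_reads = nk,
                    correct = as.integer(tab[["correct"]]),
                    incorrect = as.integer(tab[["incorrect"]]),
                    none = as.integer(tab[["none"]]),
                    assigned = as.integer(tab[["correct"]] + tab[["incorrect"]]),
                    f_correct = as.numeric(tab[["correct"]]) / nk,
                    f_incorrect = as.numeric(tab[["incorrect"]]) / nk,
                    f_none = as.numeric(tab[["none"]]) / nk,
                    stringsAsFactors = FALSE)
  attr(res, "n_unaligned") <- n - nk
  class(res) <- c("coalbin_counts", "data.frame")
  res
}
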