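#' Parametric ancient-DNA deamination profile
#'
#' Post-mortem cytosine deamination appears in sequenced ancient reads as
#' C->T substitutions near the 5' end and G->A substitutions near the 3'
#' end, with per-position rates decaying from the fragment ends (the
#' single-stranded overhangs where damage concentrates).  The default
#' profile is exponential: position `i` from the relevant end is damaged
#' with probability `rate * exp(-(i - 1) / decay)`.
#'
#' @param rate_ct Maximum C->T rate at the first 5' position.
#' @param rate_ga Maximum G->A rate at the last 3' position (defaults to
#'   `rate_ct`).
#' @param decay Overhang decay length in bases.
#' @param length Number of positions from each end carrying damage.
#' @return An object of class `"coalbin_damage"`: list with per-position
#'   probability vectors `p5` (C->T from the 5' end) and `p3` (G->A from
#'   the 3' end).
#' @examples
#' prof <- deamination_profile(rate_ct = 0.3, decay = 3)
#' @seealso [apply_deamination()], [read_misincorporation()]
#' @export
deamination_profile <- function(rate_ct = 0.3, rate_ga = rate_ct,
                                decay = 3, length = 25) {
  if (rate_ct < 0 || rate_ct > 1 || rate_ga < 0 || rate_ga > 1)
    stop("damage rates must lie in [0, 1]")
  if (decay <= 0 || length < 1) stop("decay and length must be positive")
  i <- seq_len(length) - 1
  structure(list(p5 = rate_ct * exp(-i / decay),
                 p3 = rate_ga * exp(-i / decay)),
            class = "coalbin_damage")
}

#' Load a misincorporation matrix as a deamination profile
#'
#' Reads a tab-separated table of per-position damage rates (as produced by
#' damage-profiling tools): a position column plus C->T and G->A rate
#' columns.  Row order follows position; the C->T column is read as the
#' 5'-end profile and the G->A column as the 3'-end profile.
#'
#' @param path Path to a TSV with columns `position`, `C>T`, `G>A`
#'   (header matching is forgiving about punctuation).
#' @return A `"coalbin_damage"` profile.
#' @export
read_misincorporation <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  names(d) <- tolower(gsub("[^a-z>A-Z]", "", names(d)))
  ct <- intersect(c("c>t", "ct"), names(d))[1]
  ga <- intersect(c("g>a", "ga"), names(d))[1]
  pos <- intersect(c("position", "pos"), names(d))[1]
  if (is.na(ct) || is.na(ga) || is.na(pos))
    stop("misincorporation table needs position, C>T and G>A columns")
  d <- d[order(d[[pos]]), ]
  p5 <- as.numeric(d[[ct]])
  p3 <- as.numeric(d[[ga]])
  if (any(p5 < 0 | p5 > 1 | p3 < 0 | p3 > 1))
    stop("misincorporation rates must lie in [0, 1]")
  structure(list(p5 = p5, p3 = p3), class = "coalbin_damage")
}

#' Apply deamination damage to simulated reads
#'
#' Flips C->T near the 5' end and G->A near the 3' end of each read with
#' the profile's per-position probabilities, in the read's own (sequenced)
#' orientation.  Read count, coordinates and lengths are unchanged --
#' damage effectively adds mutations to the query branch only.
#'
#' @param ds A `"coalbin_sim"` dataset.
#' @param profile A `"coalbin_damage"` profile.
#' @param seed Optional integer seed.
#' @return The dataset with damaged read bases (and `deaminated = TRUE`).
#' @examples
#' p <- model_params(T_tf = 50000, read_length = 50)
#' ds <- simulate_dataset(p, genome_length = 1e5, n_reads = 100, seed = 1)
#' dsd <- apply_deamination(ds, deamination_profile(0.3), seed = 2)
#' @export
apply_deamination <- function(ds, profile, seed = NULL) {
  stopifnot(inherits(ds, "coalbin_sim"), inherits(profile, "coalbin_damage"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$reads)
  if (n == 0) return(ds)
  k <- ds$read_length
  m <- matrix(unlist(strsplit(ds$reads$bases, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  p5 <- profile$p5
  p3 <- profile$p3
  for (i in seq_along(p5)) {
    if (i > k) break
    if (p5[i] <= 0) next
    hit <- m[, i] == "C" & stats::runif(n) < p5[i]
    m[hit, i] <- "T"
  }
  for (i in seq_along(p3)) {
    j <- k - i + 1L
    if (j < 1L) break
    if (p3[i] <= 0) next
    hit <- m[, j] == "G" & stats::runif(n) < p3[i]
    m[hit, j] <- "A"
  }
  ds$reads$bases <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  ds$deaminated <- TRUE
  ds
}
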