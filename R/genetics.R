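#' Map-distance helpers for inbred-line populations
#'
#' `haldane_r()` converts a genetic distance in centimorgans to a per-meiosis
#' recombination fraction under the Haldane (no-interference) map function,
#' \eqn{r = (1 - e^{-2d})/2} with \eqn{d} in Morgans.  `ril_transition()`
#' converts a distance to the probability that two fixed loci of a selfed
#' recombinant inbred line carry alleles from different parents,
#' \eqn{R = 2r / (1 + 2r)} (the classical two-locus RIL expansion of the
#' recombination fraction).
#'
#' Intermated populations such as the IBM carry extra effective recombination;
#' `expansion` scales the genetic distance before conversion so that the same
#' transition model can be used on intermating-expanded maps (for a map whose
#' centimorgan coordinates already reflect the expansion, such as IBM2, leave
#' `expansion = 1`).
#'
#' @param d_cm Genetic distance in centimorgans (vectorised, non-negative).
#' @param expansion Multiplicative map-expansion factor applied to `d_cm`.
#' @return Numeric vector of probabilities in `[0, 0.5]` (`haldane_r`) or
#'   `[0, 2/3]` (`ril_transition`).
#' @examples
#' haldane_r(10)
#' ril_transition(10) # ~0.153, the RIL recombinant fraction at 10 cM
#' @export
haldane_r <- function(d_cm) {
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' @rdname haldane_r
#' @export
ril_transition <- function(d_cm, expansion = 1) {
  r <- haldane_r(d_cm * expansion)
  2 * r / (1 + 2 * r)
}

# P(A at query | nearest informative flanking markers), two-state Markov chain
# over {A, B} with transition probability ril_transition(d).  obs_state is
# 1 for parent-A, 0 for parent-B.  Vectorised over q_pos; obs_pos must be
# strictly increasing.  With no informative flank on a side the prior (0.5)
# is used; with none at all P(A) = 0.5 everywhere.
.flank_prob_a <- function(obs_pos, obs_state, q_pos, expansion = 1) {
  nq <- length(q_pos)
  if (length(obs_pos) == 0L) {
    return(rep(0.5, nq))
  }
  li <- findInterval(q_pos, obs_pos)
  ri <- li + 1L
  has_l <- li >= 1L
  has_r <- ri <= length(obs_pos)
  lix <- pmax(li, 1L)
  rix <- pmin(ri, length(obs_pos))
  rl <- ril_transition(q_pos - obs_pos[lix], expansion)
  rr <- ril_transition(obs_pos[rix] - q_pos, expansion)
  l_is_a <- obs_state[lix] == 1L
  r_is_a <- obs_state[rix] == 1L
  w_la <- ifelse(has_l, ifelse(l_is_a, 1 - rl, rl), 0.5)
  w_lb <- ifelse(has_l, ifelse(l_is_a, rl, 1 - rl), 0.5)
  w_ra <- ifelse(has_r, ifelse(r_is_a, 1 - rr, rr), 0.5)
  w_rb <- ifelse(has_r, ifelse(r_is_a, rr, 1 - rr), 0.5)
  wa <- w_la * w_ra
  wb <- w_lb * w_rb
  wa / (wa + wb)
}
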