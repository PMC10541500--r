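# David's score from a matrix of dyadic win proportions P (zero diagonal):
# w_i  = sum_j P_ij          (summed win proportions)
# w2_i = sum_j P_ij * w_j    (wins weighted by opponents' wins)
# l_i  = sum_j P_ji          (summed loss proportions)
# l2_i = sum_j P_ji * l_j    (losses weighted by opponents' losses)
# DS_i = w_i + w2_i - l_i - l2_i
davids_score_from_prop <- function(P) {
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  stats::setNames(w + w2 - l - l2, rownames(P))
}

#' David's score dominance index
#'
#' Ranks genotypes by dyadic competitive mating success. From a square win
#' matrix of counts `s_ij` (i beats j) the dyadic proportions
#' `P_ij = s_ij / n_ij` with `n_ij = s_ij + s_ji` are formed, and the score
#' of genotype i is `DS_i = w_i + w2_i - l_i - l2_i` where `w_i` sums i's
#' win proportions, `w2_i` weights them by each opponent's own wins, and
#' `l_i`, `l2_i` are the loss-side analogues. Scores sum to zero over
#' genotypes.
#'
#' @param wins square numeric matrix of win counts with zero diagonal and
#'   dimnames identifying genotypes; every off-diagonal dyad must have at
#'   least one trial.
#' @return named numeric vector of David's scores.
#' @examples
#' s <- matrix(c(0, 5, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' davids_score(s)  # A: 1, B: -1
#' @export
davids_score <- function(wins) {
  if (!is.matrix(wins) || nrow(wins) != ncol(wins))
    stop("wins must be a square matrix")
  if (any(wins < 0) || any(diag(wins) != 0))
    stop("wins must be nonnegative with zero diagonal")
  n <- wins + t(wins)
  off <- row(n) != col(n)
  if (any(n[off] == 0)) stop("every dyad needs at least one trial")
  P <- wins / n
  diag(P) <- 0
  davids_score_from_prop(P)
}
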