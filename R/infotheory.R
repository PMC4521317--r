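# Plug-in (maximum-likelihood) estimators of discrete information measures.
# All quantities are in bits (log base 2); the 0 * log2(0) = 0 convention is
# applied throughout by summing over non-empty cells only.

#' Empirical distribution over bin indices
#'
#' Counts occurrences of each bin index and normalizes to probabilities.
#' Bins with no observations get probability zero.
#'
#' @param bin_indices Integer vector of bin indices in `[0, n_bins - 1]`.
#' @param n_bins Number of bins (length of the returned vector).
#' @return Numeric probability vector of length `n_bins`, summing to 1.
#' @examples
#' empirical_distribution(c(0, 0, 1, 1), n_bins = 2)
#' @export
empirical_distribution <- function(bin_indices, n_bins) {
  if (length(bin_indices) == 0) {
    abort("`bin_indices` must be non-empty.")
  }
  bin_indices <- as.integer(bin_indices)
  if (anyNA(bin_indices) || any(bin_indices < 0L) || any(bin_indices >= n_bins)) {
    abort(sprintf("All bin indices must lie in [0, %d].", n_bins - 1L))
  }
  tabulate(bin_indices + 1L, nbins = n_bins) / length(bin_indices)
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' Computes \eqn{H(X) = -\sum_i P(x_i) \log_2 P(x_i)} with the convention
#' \eqn{0 \log_2 0 = 0}. For a distribution over \eqn{B} bins the result lies
#' in `[0, log2(B)]`; the maximum `log2(20) = 4.32` bits is attained by the
#' uniform distribution over 20 bins.
#'
#' @param probabilities Numeric vector (or matrix, for a joint distribution)
#'   of probabilities; must be non-negative and sum to 1 within `1e-9`.
#' @return Entropy in bits.
#' @examples
#' entropy(rep(1 / 20, 20)) # log2(20) = 4.32 bits
#' entropy(c(0.9, 0.1))     # 0.469 bits, less than a fair coin's 1 bit
#' @export
entropy <- function(probabilities) {
  p <- as.numeric(probabilities)
  check_distribution(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

check_distribution <- function(p, tol = 1e-9) {
  if (anyNA(p)) abort("Probabilities must not contain NA.")
  if (any(p < -tol)) abort("Probabilities must be non-negative.")
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("Probabilities must sum to 1 (got %.12f).", sum(p)))
  }
  invisible(TRUE)
}

#' Empirical joint distribution of paired bin indices
#'
#' @param x_bins,y_bins Equal-length integer vectors of paired bin indices.
#' @param n_bins_x,n_bins_y Number of bins for each margin.
#' @return A `n_bins_x` x `n_bins_y` matrix of joint probabilities; row sums
#'   are the X marginal and column sums the Y marginal.
#' @examples
#' joint_distribution(c(0, 1), c(0, 1), 2, 2)
#' @export
joint_distribution <- function(x_bins, y_bins, n_bins_x, n_bins_y = n_bins_x) {
  if (length(x_bins) != length(y_bins)) {
    abort("`x_bins` and `y_bins` must have the same length.")
  }
  if (length(x_bins) == 0) abort("Paired bins must be non-empty.")
  px <- empirical_distribution(x_bins, n_bins_x) # validates range
  py <- empirical_distribution(y_bins, n_bins_y)
  n <- length(x_bins)
  joint <- matrix(0, n_bins_x, n_bins_y)
  counts <- table(factor(x_bins, levels = 0:(n_bins_x - 1L)),
                  factor(y_bins, levels = 0:(n_bins_y - 1L)))
  joint[] <- as.numeric(counts) / n
  stopifnot(max(abs(rowSums(joint) - px)) < 1e-12,
            max(abs(colSums(joint) - py)) < 1e-12)
  joint
}

#' Mutual information of a joint distribution, in bits
#'
#' Computes \eqn{I(X;Y) = \sum_j \sum_i P(x_i, y_j)
#' \log_2[P(x_i, y_j) / (P(x_i) P(y_j))]} where the marginals are taken from
#' the joint's own row and column sums. Using the joint's own marginals
#' guarantees \eqn{I \ge 0} and \eqn{I \le \min(H(X), H(Y))} exactly.
#'
#' @param joint Matrix of joint probabilities (non-negative, summing to 1).
#' @return Mutual information in bits (non-negative).
#' @examples
#' mutual_information(diag(4) / 4)            # log2(4) = 2 bits
#' mutual_information(outer(1:2, 1:2) / 9)    # independent -> 0 bits
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  check_distribution(as.numeric(joint))
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / expected[nz]))
  max(mi, 0)
}

#' Conditional entropy from entropy and mutual information
#'
#' \eqn{H(X|Y) = H(X) - I(X;Y)}: the expected novel information left in X
#' once Y is known. The result is floored at zero to absorb rounding.
#'
#' @param h_x Entropy of X in bits.
#' @param mi Mutual information I(X;Y) in bits; must not exceed `h_x` by more
#'   than `tol` (a larger violation signals that H and I were computed on
#'   inconsistent samples).
#' @param tol Numerical tolerance for the `mi <= h_x` check.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(h_x, mi, tol = 1e-9) {
  if (mi > h_x + tol) {
    abort(sprintf(
      "I(X;Y) = %.9f exceeds H(X) = %.9f: H and I appear to come from inconsistent samples.",
      mi, h_x
    ))
  }
  max(h_x - mi, 0)
}

#' Full information decomposition of paired bin indices
#'
#' From within-patient paired bins, computes the empirical joint distribution
#' and reports H(X), H(Y) (on the paired subset, via the joint's marginals),
#' I(X;Y), and both conditional entropies. The identities
#' `h_x_given_y = h_x - mi` and `h_y_given_x = h_y - mi` hold by construction.
#'
#' @inheritParams joint_distribution
#' @param n_bins Number of bins for both margins.
#' @param correction Entropy/MI bias correction: `"none"` (plug-in, the
#'   default) or `"miller_madow"`, which adds `(m - 1) / (2 N ln 2)` bits to
#'   each entropy, with `m` the number of occupied cells.
#' @return A one-row tibble with columns `h_x`, `h_y`, `mi`, `h_x_given_y`,
#'   `h_y_given_x` (bits) and `n_pairs`.
#' @examples
#' decompose_pairs(c(0, 1, 2, 3), c(0, 1, 2, 3), n_bins = 4)
#' @export
decompose_pairs <- function(x_bins, y_bins, n_bins,
                            correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  joint <- joint_distribution(x_bins, y_bins, n_bins, n_bins)
  n <- length(x_bins)
  h_x <- entropy(rowSums(joint))
  h_y <- entropy(colSums(joint))
  mi <- mutual_information(joint)
  if (correction == "miller_madow") {
    mm <- function(h, m) h + (m - 1) / (2 * n * log(2))
    h_x_c <- mm(h_x, sum(rowSums(joint) > 0))
    h_y_c <- mm(h_y, sum(colSums(joint) > 0))
    h_xy_c <- mm(entropy(joint), sum(joint > 0))
    mi <- max(h_x_c + h_y_c - h_xy_c, 0)
    h_x <- h_x_c
    h_y <- h_y_c
    mi <- min(mi, h_x, h_y)
  }
  tibble::tibble(
    h_x = h_x,
    h_y = h_y,
    mi = mi,
    h_x_given_y = conditional_entropy(h_x, mi),
    h_y_given_x = conditional_entropy(h_y, mi),
    n_pairs = n
  )
}

#' Brute-force mutual information of an explicit probability table
#'
#' An independent reference evaluation of the mutual-information sum as a
#' direct double loop over cells, sharing no code with
#' [mutual_information()]. Intended for cross-checking the main estimator on
#' small tables.
#'
#' @param joint_table Matrix of joint probabilities.
#' @return Mutual information in bits.
#' @export
oracle_mi <- function(joint_table) {
  joint_table <- as.matrix(joint_table)
  nr <- nrow(joint_table)
  nc <- ncol(joint_table)
  px <- numeric(nr)
  py <- numeric(nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      px[i] <- px[i] + joint_table[i, j]
      py[j] <- py[j] + joint_table[i, j]
    }
  }
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- joint_table[i, j]
      if (p > 0) {
        total <- total + p * log2(p / (px[i] * py[j]))
      }
    }
  }
  total
}
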