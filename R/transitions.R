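#' Default transition-matrix bin edges
#'
#' Bins 5 mmol/mol wide anchored at the diagnostic cut-point of 48 mmol/mol
#' (so the diagnostically interesting 48-53 cell exists), clipped to the
#' plausible cleaned range.
#'
#' @param lo,hi Outer edges, defaults 20.1 and 195.1 mmol/mol.
#' @param width Bin width, mmol/mol.
#' @param anchor A value that must be a bin edge.
#' @return Sorted numeric vector of edges.
#' @export
default_bin_edges <- function(lo = 20.1, hi = 195.1, width = 5, anchor = 48) {
  inner <- seq(anchor - width * ceiling((anchor - lo) / width),
               anchor + width * ceiling((hi - anchor) / width),
               by = width)
  sort(unique(c(lo, inner[inner > lo & inner < hi], hi)))
}

#' First and second chronological results per patient
#'
#' @param cohort Cleaned lab-record tibble with ordered dates.
#' @return A tibble with `patient_id`, `first`, `second` — one row per
#'   patient with at least two records (after cleaning every patient has at
#'   least two).
#' @export
first_second_pairs <- function(cohort) {
  ord <- order(cohort$patient_id, cohort$date)
  x <- cohort[ord, , drop = FALSE]
  first <- !duplicated(x$patient_id)
  idx1 <- which(first)
  # the second record is the row after the first, provided it is the same
  # patient (patients with a single record contribute no pair)
  idx2 <- idx1 + 1L
  ok <- idx2 <= nrow(x) & x$patient_id[pmin(idx2, nrow(x))] == x$patient_id[idx1]
  tibble::tibble(patient_id = x$patient_id[idx1[ok]],
                 first = x$value[idx1[ok]],
                 second = x$value[idx2[ok]])
}

bin_index <- function(v, edges, what) {
  out_of_range <- v < edges[1] | v > edges[length(edges)]
  if (any(out_of_range)) {
    stop("build_transition_matrix: ", what, " value ",
         v[which(out_of_range)[1]], " lies outside the bin edges [",
         edges[1], ", ", edges[length(edges)], "]", call. = FALSE)
  }
  findInterval(v, edges, rightmost.closed = TRUE)
}

new_transition_matrix <- function(bin_edges, counts, row_probs,
                                  n_pairs_per_row, mcid, mcid_probs, type) {
  structure(
    list(bin_edges = bin_edges, counts = counts, row_probs = row_probs,
         n_pairs_per_row = n_pairs_per_row, mcid = mcid,
         mcid_probs = mcid_probs, type = type),
    class = "transition_matrix"
  )
}

#' Empirical first-to-second result transition matrix
#'
#' Bins the (first, second) result pairs, counts every combination, and
#' row-normalises by the number of patients whose first result fell in the
#' row's bin, giving the empirical probability of the second result's bin
#' conditional on the first. Exceedance probabilities of the minimal
#' clinically important difference (MCID) — a drop of at least `mcid`, a
#' rise of at least `mcid`, and either — are computed per first-result bin
#' from the raw (unbinned) pair values.
#'
#' @param pairs Tibble from [first_second_pairs()].
#' @param bin_edges Ordered edges covering all pair values; bins are
#'   left-closed, the last bin closed on both sides.
#' @param mcid Minimal clinically important difference, mmol/mol; default
#'   5.5 (0.5%); 5 is the common display alternative.
#' @return A `transition_matrix`: integer `counts`, `row_probs` (rows sum to
#'   1 for populated rows, `NA` otherwise), `n_pairs_per_row`, and
#'   `mcid_probs` (per-row `p_drop`, `p_rise`, `p_change`).
#' @export
build_transition_matrix <- function(pairs, bin_edges = default_bin_edges(),
                                    mcid = 5.5) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2L,
            !is.unsorted(bin_edges, strictly = TRUE), mcid >= 0)
  b1 <- bin_index(pairs$first, bin_edges, "first")
  b2 <- bin_index(pairs$second, bin_edges, "second")
  nb <- length(bin_edges) - 1L
  bin_labels <- paste0("[", bin_edges[-length(bin_edges)], ",",
                       bin_edges[-1], ")")
  bin_labels[nb] <- sub("\\)$", "]", bin_labels[nb])
  counts <- table(factor(b1, seq_len(nb)), factor(b2, seq_len(nb)))
  counts <- matrix(as.integer(counts), nb, nb,
                   dimnames = list(first = bin_labels, second = bin_labels))
  n_row <- rowSums(counts)
  row_probs <- counts / ifelse(n_row == 0, NA_real_, n_row)
  drop_ <- pairs$second <= pairs$first - mcid
  rise <- pairs$second >= pairs$first + mcid
  mcid_probs <- tibble::tibble(
    bin = bin_labels,
    n_pairs = as.integer(n_row),
    p_drop = as.numeric(tapply(drop_, factor(b1, seq_len(nb)), mean)),
    p_rise = as.numeric(tapply(rise, factor(b1, seq_len(nb)), mean)),
    p_change = as.numeric(tapply(drop_ | rise, factor(b1, seq_len(nb)), mean))
  )
  new_transition_matrix(bin_edges, counts, row_probs, as.integer(n_row),
                        mcid, mcid_probs, "empirical")
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch on the Jacobi matrix).
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Analytic transition matrix under the normal measurement model
#'
#' Closed-form companion to [build_transition_matrix()]: two conditionally
#' independent measurements `X, Y ~ Normal(mu, cv * mu)` per patient, with
#' `mu` mixed over a discrete grid of true means. Single-draw bin
#' probabilities are normal CDF differences, renormalised for the mass
#' inside the outer edges (mirroring the range cleaning applied to real
#' records); MCID exceedance probabilities per first-result bin integrate
#' `P(Y <= x - mcid)` over the bin with Gauss-Legendre quadrature.
#'
#' @param bin_edges Ordered bin edges.
#' @param mean_law Tibble or data.frame with columns `mu` and `weight`
#'   (weights are normalised internally).
#' @param cv Within-patient CV; `cv = 0` gives a degenerate matrix with all
#'   mass on the diagonal of each true mean's bin.
#' @param mcid Minimal clinically important difference, mmol/mol.
#' @return A `transition_matrix` with `type = "analytic"`; `counts` holds
#'   the mixture probability mass of each (first, second) cell and
#'   `n_pairs_per_row` the first-result bin masses.
#' @export
expected_matrix_normal <- function(bin_edges, mean_law, cv, mcid = 5.5) {
  stopifnot(cv >= 0, all(c("mu", "weight") %in% names(mean_law)))
  mu <- mean_law$mu
  w <- mean_law$weight / sum(mean_law$weight)
  nb <- length(bin_edges) - 1L
  bin_labels <- paste0("[", bin_edges[-length(bin_edges)], ",",
                       bin_edges[-1], ")")
  bin_labels[nb] <- sub("\\)$", "]", bin_labels[nb])

  if (cv == 0) {
    b <- findInterval(mu, bin_edges, rightmost.closed = TRUE)
    if (any(b < 1L | b > nb)) {
      stop("expected_matrix_normal: a true mean lies outside the bin edges",
           call. = FALSE)
    }
    joint <- matrix(0, nb, nb, dimnames = list(first = bin_labels,
                                               second = bin_labels))
    for (m in seq_along(mu)) joint[b[m], b[m]] <- joint[b[m], b[m]] + w[m]
    row_mass <- rowSums(joint)
    row_probs <- joint / ifelse(row_mass == 0, NA_real_, row_mass)
    mcid_probs <- tibble::tibble(
      bin = bin_labels, n_pairs = row_mass,
      p_drop = ifelse(row_mass > 0, ifelse(mcid == 0, 1, 0), NA_real_),
      p_rise = ifelse(row_mass > 0, ifelse(mcid == 0, 1, 0), NA_real_),
      p_change = ifelse(row_mass > 0, ifelse(mcid == 0, 1, 0), NA_real_)
    )
    return(new_transition_matrix(bin_edges, joint, row_probs, row_mass,
                                 mcid, mcid_probs, "analytic"))
  }

  sd_ <- cv * mu
  # per-mean single-draw bin probabilities, truncated to the edge range
  p_edge <- vapply(bin_edges, function(e) stats::pnorm((e - mu) / sd_),
                   numeric(length(mu)))
  p_edge <- matrix(p_edge, nrow = length(mu))
  p_bin <- p_edge[, -1, drop = FALSE] - p_edge[, -ncol(p_edge), drop = FALSE]
  in_range <- p_edge[, ncol(p_edge)] - p_edge[, 1]
  p_bin <- p_bin / in_range

  joint <- matrix(0, nb, nb, dimnames = list(first = bin_labels,
                                             second = bin_labels))
  for (m in seq_along(mu)) {
    joint <- joint + w[m] * tcrossprod(p_bin[m, ], p_bin[m, ])
  }
  row_mass <- rowSums(joint)
  row_probs <- joint / ifelse(row_mass == 0, NA_real_, row_mass)

  # MCID exceedance per first bin: E_mu[ int_bin phi(x) P(Y <= x - d) dx ]
  p_drop <- p_rise <- numeric(nb)
  for (a in seq_len(nb)) {
    gq <- gauss_legendre(32L, bin_edges[a], bin_edges[a + 1L])
    num_drop <- num_rise <- denom <- 0
    lo_edge <- bin_edges[1]; hi_edge <- bin_edges[length(bin_edges)]
    for (m in seq_along(mu)) {
      dens <- stats::dnorm(gq$nodes, mu[m], sd_[m]) / in_range[m]
      # second draw is conditioned on lying inside the edge range, mirroring
      # the range cleaning of empirical records
      pd <- (stats::pnorm(pmax(pmin(gq$nodes - mcid, hi_edge), lo_edge),
                          mu[m], sd_[m]) -
               stats::pnorm(lo_edge, mu[m], sd_[m])) / in_range[m]
      pr <- (stats::pnorm(hi_edge, mu[m], sd_[m]) -
               stats::pnorm(pmax(pmin(gq$nodes + mcid, hi_edge), lo_edge),
                            mu[m], sd_[m])) / in_range[m]
      num_drop <- num_drop + w[m] * sum(gq$weights * dens * pd)
      num_rise <- num_rise + w[m] * sum(gq$weights * dens * pr)
      denom <- denom + w[m] * sum(gq$weights * dens)
    }
    p_drop[a] <- if (denom > 0) num_drop / denom else NA_real_
    p_rise[a] <- if (denom > 0) num_rise / denom else NA_real_
  }
  mcid_probs <- tibble::tibble(bin = bin_labels, n_pairs = row_mass,
                               p_drop = p_drop, p_rise = p_rise,
                               p_change = p_drop + p_rise)
  new_transition_matrix(bin_edges, joint, row_probs, row_mass, mcid,
                        mcid_probs, "analytic")
}

#' @export
print.transition_matrix <- function(x, ...) {
  nb <- length(x$bin_edges) - 1L
  cat("<transition_matrix/", x$type, "> ", nb, " bins on [",
      x$bin_edges[1], ", ", x$bin_edges[length(x$bin_edges)],
      "], MCID ", x$mcid, " mmol/mol\n", sep = "")
  populated <- if (x$type == "empirical") sum(x$n_pairs_per_row > 0) else
    sum(x$n_pairs_per_row > 1e-12)
  cat("  populated rows:", populated, "of", nb, "\n")
  invisible(x)
}
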