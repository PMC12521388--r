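# shared fixtures: all synthetic, built in code at test time

fd3m_curve <- function(a, weight = 1, noise_seed = NULL, ...) {
  generate_curve(tibble::tibble(phase = "Fd3m", lattice_a = a,
                                weight = weight),
                 noise_seed = noise_seed, ...)
}

h2_curve <- function(q10, weight = 1, ...) {
  generate_curve(tibble::tibble(phase = "H2",
                                lattice_a = 4 * pi / (sqrt(3) * q10),
                                weight = weight), ...)
}

# closed-form integral of a pseudo-Voigt over [lo, hi]: independent
# oracle for conservation checks (arctan + erf primitives)
pv_integral <- function(lo, hi, center, height, fwhm, eta = 0.5) {
  hf <- fwhm / 2
  lor <- eta * height * hf *
    (atan((hi - center) / hf) - atan((lo - center) / hf))
  s <- sqrt(log(2)) / hf
  gau <- (1 - eta) * height * sqrt(pi) / (2 * s) *
    (pracma::erf(s * (hi - center)) - pracma::erf(s * (lo - center)))
  lor + gau
}

# q^2-weighted pseudo-Voigt integral by brute-force quadrature on a fine
# grid, for invariant oracles
pv_q2_integral <- function(lo, hi, center, height, fwhm, eta = 0.5) {
  qq <- seq(lo, hi, length.out = 20001)
  pracma::trapz(qq, qq^2 * pseudo_voigt(qq, center, height, fwhm, eta))
}

# independent single-round indexing oracle: exhaustively enumerate all
# (phase, anchor-peak) hypotheses and pick the best by the scoring rule
# (matches desc, mean residual asc, ladder completeness desc, library
# order)
brute_force_best_hypothesis <- function(peak_q, rel_tol = 0.015,
                                        library = phase_library()) {
  best <- NULL
  for (i in seq_len(nrow(library))) {
    for (j in seq_along(peak_q)) {
      pred <- peak_q[j] * library$ratios[[i]]
      pred <- pred[pred <= max(peak_q) * (1 + rel_tol)]
      used <- rep(FALSE, length(peak_q))
      res <- c()
      for (p in pred) {
        rel <- abs(peak_q / p - 1)
        rel[used] <- Inf
        k <- which.min(rel)
        if (rel[k] <= rel_tol) {
          used[k] <- TRUE
          res <- c(res, rel[k])
        }
      }
      if (length(res) >= 2) {
        cand <- list(phase = library$phase[i], n = length(res),
                     resid = mean(res), compl = length(res) / length(pred),
                     order = i)
        better <- is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$resid < best$resid - 1e-15) ||
          (cand$n == best$n && abs(cand$resid - best$resid) <= 1e-15 &&
             (cand$compl > best$compl + 1e-15 ||
                (abs(cand$compl - best$compl) <= 1e-15 &&
                   cand$order < best$order)))
        if (better) best <- cand
      }
    }
  }
  best
}
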