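#' Assign mesophases to a peak list by reflection-ratio indexing
#'
#' Greedy best-first indexing against the reflection-ratio ladders of
#' [phase_library()]. Every (phase, anchor peak) hypothesis treats one
#' observed peak as the phase's first reflection, predicts the full
#' ladder, and counts observed peaks matching each predicted position
#' within `rel_tol` (relative). The best hypothesis — most matches, then
#' lowest mean relative residual, then highest ladder completeness
#' (fraction of predicted in-range reflections observed; this separates
#' H2 from the Pm3n ladder that contains it), then library order — is
#' accepted when
#' it matches at least two reflections (one suffices for lamellar only
#' when a single unexplained peak remains), its peaks are removed, and
#' the search repeats on the remainder. An Fd3m hypothesis whose anchor
#' lies in the (111) window takes precedence over an H2 hypothesis with
#' equal score, resolving the Fd3m (220) / H2 (10) overlap. An empty peak
#' list classifies as isotropic.
#'
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param library Phase ladder table, see [phase_library()].
#' @param rel_tol Relative tolerance for ratio matching, in `(0, 0.05]`.
#' @param fd3m_window (111) search window used for the overlap rule.
#' @return An `indexing_result`: list with `assignments` (tibble of
#'   `phase`, `lattice_a`, `n_matched`, `residual`, `peak_q` list),
#'   `unassigned` (peak tibble) and `flags`.
#' @examples
#' pk <- tibble::tibble(q = c(0.0633, 0.1034, 0.1212, 0.1266),
#'                      height = c(1, .5, .25, .125),
#'                      fwhm = 0.0025, prominence = c(1, .5, .25, .125))
#' index_phases(pk)$assignments
#' @export
index_phases <- function(peaks, library = phase_library(), rel_tol = 0.015,
                         fd3m_window = c(0.058, 0.085)) {
  if (rel_tol <= 0 || rel_tol > 0.05) {
    abort("`rel_tol` must lie in (0, 0.05]")
  }
  empty_assign <- tibble::tibble(phase = character(), lattice_a = double(),
                                 n_matched = integer(), residual = double(),
                                 peak_q = list())
  if (nrow(peaks) == 0) {
    return(structure(list(assignments = tibble::tibble(
      phase = "isotropic", lattice_a = NA_real_, n_matched = 0L,
      residual = NA_real_, peak_q = list(numeric())),
      unassigned = peaks, flags = "low_confidence_isotropic"),
      class = "indexing_result"))
  }
  remaining <- dplyr::arrange(tibble::as_tibble(peaks), .data$q)
  assignments <- empty_assign
  flags <- character()
  repeat {
    hyp <- score_hypotheses(remaining, library, rel_tol)
    if (nrow(hyp) > 0) {
      # overlap rule: prefer Fd3m anchored in the (111) window over an
      # equally scoring H2 hypothesis
      hyp <- dplyr::mutate(
        hyp,
        fd3m_in_window = .data$phase == "Fd3m" &
          .data$anchor_q >= fd3m_window[1] & .data$anchor_q <= fd3m_window[2]
      )
      hyp <- hyp[order(-hyp$n_matched, hyp$residual,
                       -hyp$completeness, -hyp$fd3m_in_window,
                       match(hyp$phase, library$phase)), ]
      best <- hyp[1, ]
      ok <- best$n_matched >= 2L ||
        (best$phase == "lamellar" && best$n_matched >= 1L &&
           nrow(remaining) == 1L)
    } else ok <- FALSE
    if (!ok) break
    assignments <- dplyr::bind_rows(assignments, tibble::tibble(
      phase = best$phase, lattice_a = best$lattice_a,
      n_matched = best$n_matched, residual = best$residual,
      peak_q = list(remaining$q[best$matched[[1]]])
    ))
    remaining <- remaining[-best$matched[[1]], , drop = FALSE]
    if (nrow(remaining) == 0) break
  }
  if (nrow(assignments) == 0) {
    assignments <- tibble::tibble(phase = "isotropic", lattice_a = NA_real_,
                                  n_matched = 0L, residual = NA_real_,
                                  peak_q = list(numeric()))
    flags <- c(flags, "peaks_unindexed")
  }
  structure(list(assignments = assignments, unassigned = remaining,
                 flags = flags),
            class = "indexing_result")
}

# enumerate and score every (phase, anchor-peak) hypothesis
score_hypotheses <- function(peaks, library, rel_tol) {
  out <- list()
  for (i in seq_len(nrow(library))) {
    ratios <- library$ratios[[i]]
    for (j in seq_len(nrow(peaks))) {
      q1 <- peaks$q[j]
      pred <- q1 * ratios
      pred <- pred[pred <= max(peaks$q) * (1 + rel_tol)]
      matched <- integer()
      resids <- double()
      used <- rep(FALSE, nrow(peaks))
      for (p in pred) {
        rel <- abs(peaks$q / p - 1)
        rel[used] <- Inf
        k <- which.min(rel)
        if (rel[k] <= rel_tol) {
          used[k] <- TRUE
          matched <- c(matched, k)
          resids <- c(resids, rel[k])
        }
      }
      if (length(matched) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          phase = library$phase[i], anchor_q = q1,
          lattice_a = library$lattice_k[i] / q1,
          n_matched = length(matched), residual = mean(resids),
          completeness = length(matched) / length(pred),
          matched = list(sort(matched))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Fd3m lattice parameter from the (111) peak
#'
#' Selects the highest peak inside the search window as the Fd3m (111)
#' reflection and converts its position with `a = 2 pi sqrt(3) / q`.
#' The default window is 0.058--0.085 1/Angstrom (endpoints inclusive),
#' covering the (111) positions observed across all depot ages.
#'
#' @param peaks A `peak_list`.
#' @param window Length-2 numeric q-interval in 1/Angstrom.
#' @return Lattice parameter in Angstrom, or `NA_real_` when no peak
#'   falls in the window. When several equal-height peaks tie, the lowest
#'   q is taken and an `"ambiguous"` attribute is set.
#' @examples
#' fd3m_lattice(tibble::tibble(q = 0.0633, height = 1,
#'                             fwhm = 0.0025, prominence = 1))
#' @export
fd3m_lattice <- function(peaks, window = c(0.058, 0.085)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  inw <- peaks$q >= window[1] & peaks$q <= window[2]
  if (!any(inw)) return(NA_real_)
  cand <- peaks[inw, , drop = FALSE]
  hmax <- max(cand$height)
  top <- cand[cand$height >= hmax * (1 - 1e-9), , drop = FALSE]
  a <- 2 * pi * sqrt(3) / min(top$q)
  if (nrow(top) > 1) attr(a, "ambiguous") <- TRUE
  a
}

#' @export
print.indexing_result <- function(x, ...) {
  cat("<indexing_result>\n")
  print(x$assignments)
  if (nrow(x$unassigned) > 0) {
    cat("unassigned peaks at q =",
        paste(signif(x$unassigned$q, 4), collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
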