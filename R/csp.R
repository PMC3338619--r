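# Chemical shift perturbations, significance thresholds and
# exchange-regime classification.

#' Combined amide chemical shift perturbation
#'
#' The displacement of an HSQC cross-peak between the free and the bound
#' (or partially bound) state, combining the proton and nitrogen
#' dimensions on the proton ppm scale:
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' The nitrogen weight \eqn{\alpha} compensates for the wider ppm range of
#' \eqn{^{15}N}; 0.2 is the conventional value for backbone amides.
#'
#' @param dH_free,dH_bound \eqn{^1H} shifts (ppm).
#' @param dN_free,dN_bound \eqn{^{15}N} shifts (ppm).
#' @param alpha nitrogen weight (> 0, default 0.2).
#' @return CSP in ppm (vectorized, always >= 0).
#' @export
combined_csp <- function(dH_free, dH_bound, dN_free, dN_bound, alpha = 0.2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  sqrt((dH_bound - dH_free)^2 + (alpha * (dN_bound - dN_free))^2)
}

#' Iterative mean +/- 2 sigma significance threshold
#'
#' Starting from all values, the mean and sample standard deviation of the
#' retained set are computed and values beyond mean + 2*sd (direction
#' \code{"upper"}) or below mean - 2*sd (\code{"lower"}) are removed; the
#' statistics are then recomputed on the survivors, and the trimming is
#' repeated until no value is removed. The final mean +/- 2*sd of the
#' unperturbed residues is the significance threshold; everything removed
#' along the way is flagged significant.
#'
#' Removal uses a strict inequality, so an all-equal input converges
#' immediately with nothing flagged, and the loop terminates in at most
#' \code{length(values)} passes.
#'
#' @param values named non-negative numeric vector (CSPs in ppm, or
#'   dimensionless intensity ratios), one per residue.
#' @param direction \code{"upper"} flags large values (CSP),
#'   \code{"lower"} flags small ones (intensity ratios).
#' @return An object of class \code{threshold_result}: list with
#'   \code{threshold}, \code{n_iterations}, \code{retained} and
#'   \code{flagged} (names), \code{direction} and \code{degenerate}
#'   (\code{TRUE} when trimming had to stop because fewer than two values
#'   would remain; the last valid threshold is reported).
#' @export
iterative_threshold <- function(values, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (length(values) < 2L)
    stop("need at least 2 values to estimate a threshold")
  if (any(is.na(values))) stop("values must not contain NA")
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  retained <- values
  flagged <- values[0]
  n_iter <- 0L
  degenerate <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    m <- mean(retained)
    s <- stats::sd(retained)
    thr <- if (direction == "upper") m + 2 * s else m - 2 * s
    out <- if (direction == "upper") retained > thr else retained < thr
    if (!any(out)) break
    if (sum(!out) < 2L) {
      warning("threshold trimming stopped: fewer than 2 values would remain")
      degenerate <- TRUE
      break
    }
    flagged <- c(flagged, retained[out])
    retained <- retained[!out]
  }
  structure(list(threshold = thr,
                 n_iterations = n_iter,
                 retained = names(retained),
                 flagged = names(flagged),
                 direction = direction,
                 degenerate = degenerate),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "%s threshold %.4g after %d iteration(s): %d retained, %d flagged%s\n",
    x$direction, x$threshold, x$n_iterations,
    length(x$retained), length(x$flagged),
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Trajectory linearity of a titration cross-peak
#'
#' In fast exchange a single binding event moves a cross-peak along a
#' straight line from the free toward the bound position; curvature
#' suggests more than one event. The score is the dominant-eigenvalue
#' fraction \eqn{\lambda_1/(\lambda_1+\lambda_2)} of the 2x2 covariance of
#' the trajectory points \eqn{(\delta_H, \alpha\,\delta_N)}: exactly 1 for
#' collinear points, 0.5 for an isotropic cloud.
#'
#' @param points two-column matrix of trajectory positions, the nitrogen
#'   coordinate already scaled by \eqn{\alpha}.
#' @return Score in [0, 1], or \code{NA} when fewer than 3 distinct points
#'   are available (not assessable).
#' @export
trajectory_linearity <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(unique(points)) < 3L) return(NA_real_)
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  ev[1] / sum(ev)
}

#' Saturation of a CSP trajectory
#'
#' A perturbation is saturated when the CSP gain over the last titration
#' step is small relative to the final CSP: the binding site is close to
#' fully occupied, a prerequisite for a reliable dissociation-constant fit
#' and one of the criteria for counting a residue into the binding surface.
#'
#' @param csp CSP values (ppm) over the titration, reference first.
#' @param rel_tol maximal final-step increment as a fraction of the final
#'   CSP (default 0.15).
#' @return \code{TRUE}/\code{FALSE}; an all-zero trajectory is never
#'   saturated (nothing to saturate), fewer than 3 points is an error.
#' @export
saturation_check <- function(csp, rel_tol = 0.15) {
  csp <- csp[!is.na(csp)]
  if (length(csp) < 3L) stop("need at least 3 titration points")
  final <- csp[length(csp)]
  if (final <= 0) return(FALSE)
  inc <- final - csp[length(csp) - 1L]
  inc <= rel_tol * final
}

#' Classify the exchange regime of one residue
#'
#' Applies the HSQC titration taxonomy: in slow exchange the free-state
#' peak loses intensity at (nearly) fixed position while a bound-state
#' peak grows elsewhere, so the intensity ratio falls below its threshold
#' (or the peak disappears) while the CSP stays within its threshold. In
#' fast exchange a single population-averaged peak moves, so the final CSP
#' exceeds its threshold with the intensity retained. Intermediate
#' exchange broadens the moving peak: both thresholds are crossed.
#'
#' @param csp_final final observed CSP (ppm).
#' @param intensity_final final free-peak intensity ratio \eqn{I/I_0}
#'   (0 when the peak disappeared; \code{NA} when intensities are
#'   unavailable).
#' @param csp_threshold,intensity_threshold \code{threshold_result}s (or
#'   bare numbers) from \code{\link{iterative_threshold}}.
#' @param disappeared did the free-state peak vanish during the titration?
#' @return One of \code{"fast"}, \code{"intermediate"}, \code{"slow"},
#'   \code{"unperturbed"}. Without intensity data only \code{"fast"} and
#'   \code{"unperturbed"} can be assigned and a warning is raised.
#' @export
classify_exchange <- function(csp_final, intensity_final,
                              csp_threshold, intensity_threshold,
                              disappeared = FALSE) {
  cthr <- if (inherits(csp_threshold, "threshold_result"))
    csp_threshold$threshold else csp_threshold
  csp_sig <- !is.na(csp_final) && csp_final > cthr
  if (is.na(intensity_final) && !disappeared) {
    warning("intensity unavailable: classification restricted to fast/unperturbed")
    return(if (csp_sig) "fast" else "unperturbed")
  }
  ithr <- if (inherits(intensity_threshold, "threshold_result"))
    intensity_threshold$threshold else intensity_threshold
  int_low <- disappeared ||
    (!is.na(intensity_final) && !is.na(ithr) && intensity_final < ithr)
  if (csp_sig && !int_low) return("fast")
  if (csp_sig && int_low) return("intermediate")
  if (!csp_sig && int_low) return("slow")
  "unperturbed"
}

#' Per-residue CSP and intensity-ratio trajectories of a titration
#'
#' The core per-titration analysis: for every residue observed in the
#' reference spectrum, computes the combined CSP relative to the reference
#' position and the free-peak intensity ratio \eqn{I/I_0} at each
#' titration point, derives the significance thresholds for both by the
#' iterative 2-sigma procedure, classifies the exchange regime, and scores
#' trajectory linearity and saturation.
#'
#' Peaks absent at a point get intensity ratio 0 and CSP \code{NA} from
#' that point on; disappearance is the slow-exchange signature and is kept
#' visible, never imputed. The CSP threshold is estimated from the final
#' observed CSPs (direction \code{"upper"}), the intensity threshold from
#' the final intensity ratios (direction \code{"lower"}).
#'
#' @param series a \code{titration_series} from
#'   \code{\link{assemble_series}}.
#' @param alpha nitrogen weight of \code{\link{combined_csp}}.
#' @param rel_tol saturation tolerance of \code{\link{saturation_check}}.
#' @return An object of class \code{csp_titration}: list with
#'   \code{profiles} (data frame: \code{residue_id},
#'   \code{exchange_class}, \code{csp_final}, \code{intensity_final},
#'   \code{linearity}, \code{saturated}, \code{disappeared}),
#'   \code{csp} and \code{intensity_ratio} (residue x point matrices),
#'   \code{thresholds} (list \code{csp}, \code{intensity}),
#'   \code{ligand_conc}, \code{protein_conc}, \code{alpha}.
#' @export
csp_titration <- function(series, alpha = 0.2, rel_tol = 0.15) {
  stopifnot(inherits(series, "titration_series"))
  ref <- series$points[[1]]$peaks
  ref <- ref[ref$state == "free", , drop = FALSE]
  if (nrow(ref) < 2L) stop("reference spectrum has fewer than 2 free peaks")
  ids <- ref$residue_id
  np <- length(series$points)
  csp <- matrix(NA_real_, nrow = length(ids), ncol = np,
                dimnames = list(ids, series$ligand_conc))
  ratio <- matrix(NA_real_, nrow = length(ids), ncol = np,
                  dimnames = list(ids, series$ligand_conc))
  dH <- csp; dN <- csp
  have_int <- !all(is.na(ref$intensity))
  for (j in seq_len(np)) {
    pk <- series$points[[j]]$peaks
    pk <- pk[pk$state == "free", , drop = FALSE]
    idx <- match(ids, pk$residue_id)
    present <- !is.na(idx)
    csp[present, j] <- combined_csp(ref$delta_H[present], pk$delta_H[idx[present]],
                                    ref$delta_N[present], pk$delta_N[idx[present]],
                                    alpha = alpha)
    dH[present, j] <- pk$delta_H[idx[present]]
    dN[present, j] <- pk$delta_N[idx[present]]
    if (have_int) {
      ratio[present, j] <- pk$intensity[idx[present]] / ref$intensity[present]
      ratio[!present, j] <- 0
    }
  }
  disappeared <- apply(csp, 1L, function(x) any(is.na(x)))
  last_obs <- apply(csp, 1L, function(x) {
    obs <- which(!is.na(x)); if (length(obs) == 0L) NA_real_ else x[max(obs)]
  })
  final_ratio <- if (have_int) ratio[, np] else rep(NA_real_, length(ids))

  thr_csp <- iterative_threshold(
    stats::setNames(last_obs[!is.na(last_obs)],
                    ids[!is.na(last_obs)]), "upper")
  thr_int <- if (have_int)
    iterative_threshold(stats::setNames(final_ratio, ids), "lower") else NULL

  cls <- character(length(ids))
  for (i in seq_along(ids)) {
    cls[i] <- classify_exchange(last_obs[i], final_ratio[i],
                                thr_csp,
                                if (have_int) thr_int else NA_real_,
                                disappeared = disappeared[i])
  }
  lin <- vapply(seq_along(ids), function(i) {
    trajectory_linearity(cbind(dH[i, ], alpha * dN[i, ]))
  }, numeric(1))
  sat <- vapply(seq_along(ids), function(i) {
    x <- csp[i, ][!is.na(csp[i, ])]
    if (length(x) < 3L) NA else saturation_check(x, rel_tol = rel_tol)
  }, logical(1))

  structure(list(
    profiles = data.frame(residue_id = ids,
                          residue_name = ref$residue_name,
                          exchange_class = cls,
                          csp_final = unname(last_obs),
                          intensity_final = unname(final_ratio),
                          linearity = lin,
                          saturated = sat,
                          disappeared = unname(disappeared),
                          stringsAsFactors = FALSE),
    csp = csp,
    intensity_ratio = if (have_int) ratio else NULL,
    thresholds = list(csp = thr_csp, intensity = thr_int),
    ligand_conc = series$ligand_conc,
    protein_conc = series$protein_conc,
    alpha = alpha,
    rel_tol = rel_tol), class = "csp_titration")
}

#' @export
print.csp_titration <- function(x, ...) {
  tab <- table(factor(x$profiles$exchange_class,
                      levels = c("fast", "intermediate", "slow", "unperturbed")))
  cat(sprintf("CSP titration analysis: %d residues over %d points ([P]0 = %g uM)\n",
              nrow(x$profiles), length(x$ligand_conc), x$protein_conc))
  cat(sprintf("  CSP threshold <CSP>+2s = %.4f ppm (%d iterations)\n",
              x$thresholds$csp$threshold, x$thresholds$csp$n_iterations))
  if (!is.null(x$thresholds$intensity))
    cat(sprintf("  I/I0 threshold <I/I0>-2s = %.3f (%d iterations)\n",
                x$thresholds$intensity$threshold,
                x$thresholds$intensity$n_iterations))
  cat(sprintf("  exchange: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.csp_titration <- function(object, ...) {
  print(object)
  sig <- object$profiles[object$profiles$exchange_class != "unperturbed", ]
  cat(sprintf("  significant residues (%d): %s\n", nrow(sig),
              paste(sig$residue_id, collapse = ", ")))
  invisible(object$profiles)
}

#' @export
plot.csp_titration <- function(x, residues = NULL, ...) {
  pr <- x$profiles
  if (is.null(residues)) {
    graphics::barplot(stats::setNames(pr$csp_final, pr$residue_id),
                      xlab = "residue", ylab = "CSP (ppm)",
                      border = NA, ...)
    graphics::abline(h = x$thresholds$csp$threshold, lty = 2, col = "red3")
  } else {
    cols <- seq_along(residues)
    idx <- match(as.character(residues), rownames(x$csp))
    graphics::matplot(x$ligand_conc, t(x$csp[idx, , drop = FALSE]),
                      type = "b", pch = 19, col = cols, lty = 1,
                      xlab = "[L] (uM)", ylab = "CSP (ppm)", ...)
    graphics::legend("bottomright", legend = residues, col = cols,
                     pch = 19, bty = "n")
  }
  invisible(x)
}

#' Write the per-residue profile and threshold reports
#'
#' @param x a \code{csp_titration}.
#' @param profile_path,threshold_path output TSV files.
#' @export
write_csp_report <- function(x, profile_path, threshold_path) {
  stopifnot(inherits(x, "csp_titration"))
  utils::write.table(x$profiles, profile_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  thr <- data.frame(
    quantity = c("csp", "intensity_ratio"),
    direction = c("upper", "lower"),
    threshold = c(x$thresholds$csp$threshold,
                  if (is.null(x$thresholds$intensity)) NA
                  else x$thresholds$intensity$threshold),
    n_iterations = c(x$thresholds$csp$n_iterations,
                     if (is.null(x$thresholds$intensity)) NA
                     else x$thresholds$intensity$n_iterations),
    n_flagged = c(length(x$thresholds$csp$flagged),
                  if (is.null(x$thresholds$intensity)) NA
                  else length(x$thresholds$intensity$flagged)))
  utils::write.table(thr, threshold_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}
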