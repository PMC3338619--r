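# Single-site binding isotherm: shared bound-fraction kernel,
# per-residue K_D fits, exclusion-based aggregation, native-MS K_D fit.

#' Bound protein fraction under single-site binding
#'
#' Exact solution of the 1:1 equilibrium \eqn{P + L \rightleftharpoons PL}
#' at total concentrations \eqn{[P]_0} and \eqn{[L]}:
#' \deqn{f_b = \frac{([P]_0+[L]+K_D) - \sqrt{([P]_0+[L]+K_D)^2 - 4[P]_0[L]}}{2[P]_0}}
#' No "excess ligand" approximation is made, so the expression remains
#' valid when ligand and protein concentrations are comparable, as in
#' protein-observed NMR titrations. The same kernel underlies both the
#' CSP isotherm and the native-MS bound fraction.
#'
#' @param L total ligand concentration (uM), vectorized.
#' @param P0 total protein concentration (uM), > 0.
#' @param kd dissociation constant (uM), >= 0.
#' @return Bound fraction in [0, 1]; monotone nondecreasing in \code{L},
#'   nonincreasing in \code{kd}; tends to the hyperbolic isotherm
#'   \eqn{L/(K_D+L)} as \eqn{[P]_0 \to 0} and to the stoichiometric limit
#'   \eqn{\min(L, [P]_0)/[P]_0} as \eqn{K_D \to 0}.
#' @export
bound_fraction_model <- function(L, P0, kd) {
  if (!is.numeric(P0) || length(P0) != 1L || P0 <= 0)
    stop("P0 must be a single positive concentration; for the P0 -> 0 ",
         "hyperbolic limit use L/(kd + L) explicitly")
  if (any(kd < 0)) stop("kd must be >= 0")
  if (any(L < 0)) stop("L must be >= 0")
  b <- P0 + L + kd
  disc <- b^2 - 4 * P0 * L
  disc[disc < 0] <- 0  # guard rounding at the stoichiometric corner
  fb <- (b - sqrt(disc)) / (2 * P0)
  pmin(pmax(fb, 0), 1)
}

#' Quadratic CSP isotherm
#'
#' Expected chemical shift perturbation at ligand concentration \code{L}
#' in fast exchange: the saturation perturbation scaled by the bound
#' fraction, \eqn{CSP(L) = CSP_{max} \cdot f_b(L; [P]_0, K_D)}.
#'
#' @inheritParams bound_fraction_model
#' @param csp_max asymptotic perturbation at full saturation (ppm).
#' @return CSP in ppm.
#' @export
quadratic_csp_model <- function(L, P0, kd, csp_max) {
  csp_max * bound_fraction_model(L, P0, kd)
}

#' Fit a per-residue dissociation constant
#'
#' Nonlinear least squares of the quadratic CSP isotherm over
#' \eqn{(K_D, CSP_{max})}, both kept positive. Starting values follow the
#' shape of the data: \eqn{K_{D,0}} is the ligand concentration at which
#' the CSP first reaches half its final value (linear interpolation) and
#' \eqn{CSP_{max,0} = 1.2 \times} the final CSP. \eqn{CSP_{max}} floats
#' per residue; no parameter is shared across residues.
#'
#' @param L ligand concentrations (uM), including the reference 0.
#' @param csp observed CSPs (ppm) at those concentrations.
#' @param P0 total protein concentration (uM).
#' @param residue_id optional identifier carried into the result.
#' @return Object of class \code{kd_fit}: \code{kd}, \code{csp_max} (the
#'   estimates), \code{rss}, \code{r_squared}, \code{converged},
#'   \code{included} / \code{exclusion_reason} (filled by
#'   \code{\link{aggregate_kd}}), \code{data}, \code{P0}. A fit that does
#'   not converge is returned flagged \code{poor_fit}, not an error.
#' @export
fit_residue_kd <- function(L, csp, P0, residue_id = NA_integer_) {
  keep <- !is.na(L) & !is.na(csp)
  L <- L[keep]; csp <- csp[keep]
  if (length(L) < 4L)
    stop("need at least 4 titration points to fit K_D (got ", length(L), ")")
  if (all(csp <= 0))
    stop("non-binder: all CSP values are zero for residue ", residue_id)
  ord <- order(L)
  L <- L[ord]; csp <- csp[ord]
  final <- csp[length(csp)]
  half <- final / 2
  above <- which(csp >= half)
  kd0 <- if (length(above) == 0L || above[1] == 1L) {
    max(L[2], 1e-3)
  } else {
    i <- above[1]
    L[i - 1] + (half - csp[i - 1]) / (csp[i] - csp[i - 1]) * (L[i] - L[i - 1])
  }
  kd0 <- max(kd0, 1e-3)
  dat <- data.frame(L = L, csp = csp)
  # positivity is structural, so optimize on the log scale; tight-binding
  # (near-stoichiometric) curves make the Jacobian ill-conditioned for
  # plain Levenberg-Marquardt, which is only used as a final polish
  obj <- function(p) sum((csp - quadratic_csp_model(L, P0, exp(p[1]),
                                                    exp(p[2])))^2)
  opt <- tryCatch(
    stats::optim(c(log(kd0), log(1.2 * final)), obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    out <- list(residue_id = residue_id, kd = NA_real_, csp_max = NA_real_,
                rss = NA_real_, r_squared = NA_real_, converged = FALSE,
                included = FALSE, exclusion_reason = "poor_fit",
                data = dat, P0 = P0)
    return(structure(out, class = "kd_fit"))
  }
  est <- c(kd = exp(opt$par[1]), csp_max = exp(opt$par[2]))
  rss <- opt$value
  polish <- tryCatch(
    minpack.lm::nlsLM(csp ~ quadratic_csp_model(L, P0, kd, csp_max),
                      data = dat, start = as.list(est),
                      lower = c(kd = 1e-12, csp_max = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(stats::residuals(polish)^2) <= rss) {
    est <- stats::coef(polish)
    rss <- sum(stats::residuals(polish)^2)
  }
  tss <- sum((csp - mean(csp))^2)
  structure(list(residue_id = residue_id,
                 kd = unname(est["kd"]),
                 csp_max = unname(est["csp_max"]),
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = opt$convergence == 0 || !is.null(polish),
                 included = TRUE,
                 exclusion_reason = "none",
                 data = dat, P0 = P0),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("K_D fit%s: K_D = %.4g uM, CSP_max = %.4g ppm, R2 = %.4f (%d points)\n",
              if (is.na(x$residue_id)) "" else paste0(" [residue ", x$residue_id, "]"),
              x$kd, x$csp_max, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, csp_max = object$csp_max)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else newdata$L
  quadratic_csp_model(L, object$P0, object$kd, object$csp_max)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$csp - predict(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  Lg <- seq(0, max(x$data$L), length.out = 200)
  graphics::plot(x$data$L, x$data$csp, pch = 19,
                 xlab = "[L] (uM)", ylab = "CSP (ppm)", ...)
  graphics::lines(Lg, quadratic_csp_model(Lg, x$P0, x$kd, x$csp_max),
                  col = "red3")
  invisible(x)
}

#' Fit K_D for every fast-exchange residue of a titration analysis
#'
#' @param ct a \code{\link{csp_titration}}.
#' @param residues residue ids to fit; default all fast-exchange residues.
#' @return A list of \code{kd_fit} objects (class \code{kd_fits}).
#' @export
fit_kd <- function(ct, residues = NULL) {
  stopifnot(inherits(ct, "csp_titration"))
  if (is.null(residues))
    residues <- ct$profiles$residue_id[ct$profiles$exchange_class == "fast"]
  if (length(residues) == 0L)
    stop("no fast-exchange residues to fit")
  fits <- lapply(residues, function(r) {
    fit_residue_kd(ct$ligand_conc, ct$csp[as.character(r), ],
                   P0 = ct$protein_conc, residue_id = r)
  })
  structure(fits, class = "kd_fits")
}

#' @export
print.kd_fits <- function(x, ...) {
  cat(sprintf("Per-residue K_D fits (%d residues)\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' Aggregate per-residue dissociation constants
#'
#' Residues reporting on the same binding event should agree on
#' \eqn{K_D}; the average over them is the titration's binding constant.
#' Residues are excluded, in order: (a) poor fits
#' (non-convergence or \eqn{R^2} below \code{r2_min}); (b) residues
#' labelled \code{buried} or \code{isolated} when a binding-surface
#' discrimination is supplied, and \code{low_intensity} residues when
#' flagged upstream; (c) \eqn{K_D} outliers outside median +/- 3 MAD
#' (scaled, consistent with the normal), applied iteratively until
#' stable. The survivors' mean and sample standard deviation are reported
#' together with the full exclusion ledger.
#'
#' @param fits a \code{kd_fits} list (or list of \code{kd_fit}).
#' @param surface optional \code{\link{binding_surface}} (or a named
#'   character vector of labels) used for the buried/isolated exclusions.
#' @param r2_min minimal \eqn{R^2} for a fit to count (default 0.9).
#' @param mad_mult MAD multiplier of the outlier rule (default 3).
#' @return Object of class \code{kd_aggregate}: \code{mean_kd},
#'   \code{sd_kd}, \code{n_used}, \code{excluded} (data frame residue_id,
#'   reason), \code{fits}.
#' @export
aggregate_kd <- function(fits, surface = NULL, r2_min = 0.9, mad_mult = 3) {
  if (inherits(fits, "kd_fit")) fits <- list(fits)
  if (length(fits) < 1L) stop("need at least one fit")
  ids <- vapply(fits, function(f) f$residue_id, numeric(1))
  kd <- vapply(fits, function(f) f$kd, numeric(1))
  reason <- rep("none", length(fits))

  bad <- vapply(fits, function(f) {
    !isTRUE(f$converged) || (!is.na(f$r_squared) && f$r_squared < r2_min)
  }, logical(1))
  reason[bad] <- "poor_fit"

  if (!is.null(surface)) {
    labels <- if (inherits(surface, "binding_surface")) surface$labels else surface
    lab <- labels[as.character(ids)]
    reason[reason == "none" & !is.na(lab) & lab == "buried"] <- "buried"
    reason[reason == "none" & !is.na(lab) & lab == "isolated"] <- "isolated"
    reason[reason == "none" & !is.na(lab) & lab == "low_intensity"] <- "low_intensity"
  }

  # iterative scaled-MAD outlier rule on the surviving K_D values
  repeat {
    ok <- reason == "none"
    if (sum(ok) < 3L) break
    med <- stats::median(kd[ok])
    madv <- stats::mad(kd[ok])     # includes the 1.4826 consistency factor
    # floor the spread at a relative epsilon so numerically identical
    # estimates (noiseless round-trips) are never mutual outliers
    if (madv <= 1e-6 * med) break
    out <- ok & abs(kd - med) > mad_mult * madv
    if (!any(out)) break
    reason[out] <- "outlier_kd"
  }

  ok <- reason == "none"
  if (!any(ok)) {
    msg <- paste(sprintf("%d:%s", ids, reason), collapse = ", ")
    stop("all residues excluded from aggregation [", msg, "]")
  }
  if (sum(ok) == 1L)
    warning("aggregate K_D rests on a single residue; sd reported as 0")
  structure(list(mean_kd = mean(kd[ok]),
                 sd_kd = if (sum(ok) > 1L) stats::sd(kd[ok]) else 0,
                 n_used = sum(ok),
                 excluded = data.frame(residue_id = ids[!ok],
                                       reason = reason[!ok],
                                       stringsAsFactors = FALSE),
                 fits = fits),
            class = "kd_aggregate")
}

#' @export
print.kd_aggregate <- function(x, ...) {
  cat(sprintf("Average K_D = %.4g +/- %.4g uM from %d residues",
              x$mean_kd, x$sd_kd, x$n_used))
  if (nrow(x$excluded) > 0L)
    cat(sprintf(" (%d excluded: %s)", nrow(x$excluded),
                paste(sprintf("%d %s", x$excluded$residue_id,
                              x$excluded$reason), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
coef.kd_aggregate <- function(object, ...) {
  c(mean_kd = object$mean_kd, sd_kd = object$sd_kd)
}

#' Write per-residue fit table and aggregate report
#'
#' @param agg a \code{kd_aggregate}.
#' @param fits_path,aggregate_path output TSV files.
#' @export
write_kd_report <- function(agg, fits_path, aggregate_path) {
  stopifnot(inherits(agg, "kd_aggregate"))
  tab <- do.call(rbind, lapply(agg$fits, function(f)
    data.frame(residue_id = f$residue_id, kd = f$kd, csp_max = f$csp_max,
               rss = f$rss, r_squared = f$r_squared,
               converged = f$converged)))
  excl <- stats::setNames(agg$excluded$reason,
                          as.character(agg$excluded$residue_id))
  tab$included <- !(as.character(tab$residue_id) %in% names(excl))
  tab$exclusion_reason <- ifelse(tab$included, "none",
                                 excl[as.character(tab$residue_id)])
  utils::write.table(tab, fits_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  summ <- data.frame(mean_kd = agg$mean_kd, sd_kd = agg$sd_kd,
                     n_used = agg$n_used, n_excluded = nrow(agg$excluded))
  utils::write.table(summ, aggregate_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(agg)
}

#' Fit K_D from native mass spectrometry bound fractions
#'
#' Native (non-denaturing) electrospray MS resolves free protein from the
#' 1:1 complex, so the bound protein fraction can be read off peak
#' intensities at each total ligand concentration. A single-parameter
#' least-squares fit of \code{\link{bound_fraction_model}} in \eqn{K_D}
#' yields the affinity; uncertainty comes from a percentile bootstrap over
#' titration points.
#'
#' A reliable fit needs dynamic range on both flanks of the isotherm
#' (points below bound fraction 0.2 and above 0.6); without it the fit is
#' still returned but flagged low-confidence with a warning.
#'
#' @param data data frame with columns \code{ligand_total} (uM) and
#'   \code{bound_fraction} (in [0,1]), or a two-column matrix.
#' @param P0 total protein concentration (uM).
#' @param n_boot bootstrap resamples for the confidence interval
#'   (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return Object of class \code{ms_kd_fit}: \code{kd}, \code{ci}
#'   (percentile interval), \code{boot} (resampled estimates),
#'   \code{rss}, \code{low_confidence}, \code{data}, \code{P0}.
#' @export
fit_ms_kd <- function(data, P0, n_boot = 1000, conf = 0.95, seed = NULL) {
  data <- as.data.frame(data)
  if (!all(c("ligand_total", "bound_fraction") %in% names(data))) {
    stopifnot(ncol(data) >= 2L)
    names(data)[1:2] <- c("ligand_total", "bound_fraction")
  }
  L <- data$ligand_total; fb <- data$bound_fraction
  if (length(L) < 4L) stop("need at least 4 MS titration points")
  if (any(fb < 0 | fb > 1)) stop("bound fractions must lie in [0, 1]")
  if (all(fb <= 0)) stop("no binding signal: bound fraction is zero throughout")
  low_conf <- FALSE
  if (!(any(fb < 0.2) && any(fb > 0.6))) {
    warning("titration does not span bound fractions < 0.2 and > 0.6; ",
            "K_D flagged low-confidence")
    low_conf <- TRUE
  }
  obj <- function(kd, Lv, fv) sum((fv - bound_fraction_model(Lv, P0, kd))^2)
  fit_one <- function(Lv, fv) {
    stats::optimize(obj, interval = c(1e-6, 1e7), Lv = Lv, fv = fv,
                    tol = 1e-10)$minimum
  }
  kd <- fit_one(L, fb)
  boot <- numeric(0)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(L), replace = TRUE)
      if (all(fb[idx] <= 0)) return(NA_real_)
      fit_one(L[idx], fb[idx])
    }, numeric(1))
    boot <- boot[!is.na(boot)]
  }
  a <- (1 - conf) / 2
  structure(list(kd = kd,
                 ci = if (length(boot) > 0)
                   unname(stats::quantile(boot, c(a, 1 - a))) else c(NA, NA),
                 boot = boot,
                 rss = obj(kd, L, fb),
                 low_confidence = low_conf,
                 conf = conf,
                 data = data.frame(ligand_total = L, bound_fraction = fb),
                 P0 = P0),
            class = "ms_kd_fit")
}

#' @export
print.ms_kd_fit <- function(x, ...) {
  cat(sprintf("Native-MS K_D fit: K_D = %.4g uM", x$kd))
  if (!any(is.na(x$ci)))
    cat(sprintf(" (%d%% CI %.4g-%.4g, %d resamples)",
                round(100 * x$conf), x$ci[1], x$ci[2], length(x$boot)))
  if (x$low_confidence) cat("  [low confidence: narrow dynamic range]")
  cat("\n")
  invisible(x)
}

#' @export
coef.ms_kd_fit <- function(object, ...) c(kd = object$kd)

#' @export
predict.ms_kd_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$ligand_total else newdata$ligand_total
  bound_fraction_model(L, object$P0, object$kd)
}

#' @export
plot.ms_kd_fit <- function(x, ...) {
  Lg <- seq(0, max(x$data$ligand_total), length.out = 200)
  graphics::plot(x$data$ligand_total, x$data$bound_fraction, pch = 19,
                 xlab = "[L]tot (uM)", ylab = "bound fraction",
                 ylim = c(0, 1), ...)
  graphics::lines(Lg, bound_fraction_model(Lg, x$P0, x$kd), col = "red3")
  invisible(x)
}

#' Read an MS titration from a two-column CSV
#'
#' Expected columns: \code{ligand_total_uM, bound_fraction}.
#'
#' @param path CSV file.
#' @return data frame with columns \code{ligand_total},
#'   \code{bound_fraction}.
#' @export
read_ms_titration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("MS titration CSV needs two columns")
  names(df)[1:2] <- c("ligand_total", "bound_fraction")
  df[, 1:2]
}
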