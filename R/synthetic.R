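# Synthetic titration, MS and structure generators, plus the published
# hPEBP1 residue-set fixtures used for accounting checks.

#' Scenario configuration for the titration generator
#'
#' Describes a simulated protein-ligand titration: the underlying
#' single-site equilibrium, the residues observed (with their saturation
#' shift changes and exchange regimes), and the noise model.
#'
#' @param true_kd dissociation constant (uM, > 0).
#' @param P0 total protein concentration (uM, > 0).
#' @param ligand_series total ligand concentrations (uM), starting at 0
#'   and strictly increasing.
#' @param residues data frame with columns \code{residue_id},
#'   \code{csp_max_H} and \code{csp_max_N} (saturation shift changes in
#'   ppm for the two dimensions) and \code{regime} (\code{"fast"},
#'   \code{"intermediate"}, \code{"slow"} or \code{"unperturbed"});
#'   optional \code{residue_name} (one-letter code).
#' @param noise_ppm standard deviation of Gaussian position noise on the
#'   \eqn{^1H} shifts (ppm); \eqn{^{15}N} shifts receive 5x this value so
#'   that both dimensions contribute comparably after the 0.2 weighting.
#' @param noise_intensity standard deviation of multiplicative Gaussian
#'   intensity noise.
#' @param broadening_beta intermediate-exchange attenuation depth in
#'   [0, 1]: peak intensity is scaled by
#'   \eqn{1 - \beta \cdot 4 f_b (1-f_b)}, maximally attenuated at half
#'   saturation. A phenomenological stand-in for exchange broadening.
#' @param detection_limit peaks whose expected intensity falls below this
#'   fraction of the initial intensity are not emitted (noise floor);
#'   drives slow-exchange peak disappearance. Default 0.05.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return Validated list of class \code{scenario_config}.
#' @export
scenario_config <- function(true_kd, P0, ligand_series, residues,
                            noise_ppm = 0, noise_intensity = 0,
                            broadening_beta = 0.8, detection_limit = 0.05,
                            seed = 1L) {
  stopifnot(is.numeric(true_kd), length(true_kd) == 1L, true_kd > 0,
            is.numeric(P0), length(P0) == 1L, P0 > 0,
            is.numeric(ligand_series), length(ligand_series) >= 2L)
  if (ligand_series[1] != 0 || any(diff(ligand_series) <= 0))
    stop("ligand_series must start at 0 and increase strictly")
  stopifnot(is.data.frame(residues),
            all(c("residue_id", "csp_max_H", "csp_max_N", "regime")
                %in% names(residues)))
  if (!all(residues$regime %in% c("fast", "intermediate", "slow",
                                  "unperturbed")))
    stop("unknown regime: ",
         paste(setdiff(residues$regime,
                       c("fast", "intermediate", "slow", "unperturbed")),
               collapse = ", "))
  if (anyDuplicated(residues$residue_id))
    stop("duplicate residue_id in scenario residues")
  stopifnot(noise_ppm >= 0, noise_intensity >= 0,
            broadening_beta >= 0, broadening_beta <= 1,
            detection_limit >= 0, detection_limit < 1)
  structure(list(true_kd = true_kd, P0 = P0,
                 ligand_series = as.numeric(ligand_series),
                 residues = residues,
                 noise_ppm = noise_ppm, noise_intensity = noise_intensity,
                 broadening_beta = broadening_beta,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' A ready-made nucleotide-titration scenario
#'
#' Emulates a fast-exchange nucleotide titration against 270 uM protein
#' over the six-point ligand series 0 / 270 / 540 / 1000 / 2000 / 4000 uM:
#' \code{n_binders} fast-exchange residues with saturation shifts spread
#' over 0.05--0.25 ppm (proton) sit on a background of
#' \code{n_background} unperturbed residues.
#'
#' @param true_kd generator dissociation constant (uM, default 669).
#' @param n_binders,n_background residue counts.
#' @param seed,noise_ppm,noise_intensity passed through.
#' @return A \code{\link{scenario_config}}.
#' @export
nucleotide_scenario <- function(true_kd = 669, n_binders = 6,
                                n_background = 24, seed = 1L,
                                noise_ppm = 0, noise_intensity = 0) {
  n <- n_binders + n_background
  ids <- seq_len(n) + 10L
  csp_H <- c(seq(0.05, 0.25, length.out = n_binders), rep(0, n_background))
  csp_N <- c(seq(0.3, 1.2, length.out = n_binders), rep(0, n_background))
  scenario_config(
    true_kd = true_kd, P0 = 270,
    ligand_series = c(0, 270, 540, 1000, 2000, 4000),
    residues = data.frame(residue_id = ids, csp_max_H = csp_H,
                          csp_max_N = csp_N,
                          regime = rep(c("fast", "unperturbed"),
                                       c(n_binders, n_background))),
    noise_ppm = noise_ppm, noise_intensity = noise_intensity, seed = seed)
}

#' Generate a synthetic HSQC titration series
#'
#' For every residue the bound fraction at each ligand concentration
#' follows the single-site kernel \code{\link{bound_fraction_model}};
#' the regime then dictates the observable:
#' \itemize{
#'   \item fast: one peak at the population-weighted position
#'     \eqn{\delta_{free} + f_b \Delta\delta_{max}}, intensity retained;
#'   \item slow: a free-state peak at fixed position with intensity
#'     \eqn{I_0 (1-f_b)} and a bound-state peak at
#'     \eqn{\delta_{free} + \Delta\delta_{max}} with intensity
#'     \eqn{I_0 f_b}, tagged \code{state = "bound"} so the reader keeps
#'     the two trackable; peaks below the detection limit disappear;
#'   \item intermediate: population-weighted position with intensity
#'     \eqn{I_0 (1 - \beta\, 4 f_b (1-f_b))};
#'   \item unperturbed: fixed position, full intensity.
#' }
#' Gaussian position and multiplicative intensity noise are applied after
#' the ideal values; the whole series is deterministic given the seed.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return A \code{titration_series}.
#' @export
gen_titration <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  res <- config$residues
  n <- nrow(res)
  if (is.null(res$residue_name))
    res$residue_name <- sample(setdiff(names(AA1), "P"), n, replace = TRUE)
  dH0 <- stats::runif(n, 7.0, 9.5)
  dN0 <- stats::runif(n, 105, 130)
  I0 <- stats::runif(n, 0.5e6, 2e6)
  fb <- vapply(config$ligand_series,
               function(L) bound_fraction_model(L, config$P0, config$true_kd),
               numeric(1))
  lists <- vector("list", length(config$ligand_series))
  for (j in seq_along(config$ligand_series)) {
    rows <- list()
    for (i in seq_len(n)) {
      f <- fb[j]
      reg <- res$regime[i]
      if (reg == "unperturbed") f <- 0
      pos_H <- dH0[i] + f * res$csp_max_H[i]
      pos_N <- dN0[i] + f * res$csp_max_N[i]
      if (reg == "slow") {
        # free-state peak stays put and fades
        ints <- I0[i] * (1 - f)
        if (1 - f >= config$detection_limit || j == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            residue_id = res$residue_id[i],
            residue_name = res$residue_name[i],
            delta_H = dH0[i], delta_N = dN0[i],
            intensity = ints, state = "free")
        }
        if (f >= config$detection_limit) {
          rows[[length(rows) + 1L]] <- data.frame(
            residue_id = res$residue_id[i],
            residue_name = res$residue_name[i],
            delta_H = dH0[i] + res$csp_max_H[i],
            delta_N = dN0[i] + res$csp_max_N[i],
            intensity = I0[i] * f, state = "bound")
        }
      } else {
        ints <- switch(reg,
                       fast = I0[i],
                       intermediate = I0[i] *
                         (1 - config$broadening_beta * 4 * f * (1 - f)),
                       unperturbed = I0[i])
        if (ints / I0[i] >= config$detection_limit || j == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            residue_id = res$residue_id[i],
            residue_name = res$residue_name[i],
            delta_H = pos_H, delta_N = pos_N,
            intensity = ints, state = "free")
        }
      }
    }
    pk <- do.call(rbind, rows)
    if (config$noise_ppm > 0) {
      pk$delta_H <- pk$delta_H + stats::rnorm(nrow(pk), 0, config$noise_ppm)
      pk$delta_N <- pk$delta_N + stats::rnorm(nrow(pk), 0,
                                              5 * config$noise_ppm)
    }
    if (config$noise_intensity > 0) {
      pk$intensity <- pmax(0, pk$intensity *
                             (1 + stats::rnorm(nrow(pk), 0,
                                               config$noise_intensity)))
    }
    lists[[j]] <- peaklist(pk, ligand_conc = config$ligand_series[j],
                           protein_conc = config$P0)
  }
  assemble_series(lists, P0 = config$P0)
}

#' Write a titration series to peak-list files plus manifest
#'
#' Emits one peak-list file per titration point in the requested dialect
#' together with a YAML manifest readable by
#' \code{\link{read_series_manifest}}.
#'
#' @param series a \code{titration_series}.
#' @param dir output directory (created if needed).
#' @param dialect \code{"csv"} or \code{"sparky"}.
#' @return Path of the manifest, invisibly.
#' @export
write_series_files <- function(series, dir, dialect = c("csv", "sparky")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "titration_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "csv") "csv" else "list"
  files <- sprintf("point_%02d.%s", seq_along(series$points), ext)
  for (i in seq_along(series$points))
    write_peaklist(series$points[[i]], file.path(dir, files[i]), dialect)
  man <- list(protein_conc = series$protein_conc, dialect = dialect,
              points = lapply(seq_along(files), function(i)
                list(file = files[i],
                     ligand_conc = series$ligand_conc[i])))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Generate a synthetic native-MS titration
#'
#' Bound fractions from the single-site kernel with additive Gaussian
#' noise clipped to [0, 1]; deterministic given the seed.
#'
#' @param true_kd,P0 equilibrium parameters (uM).
#' @param ligand_series total ligand concentrations (uM).
#' @param noise standard deviation of the bound-fraction noise.
#' @param seed integer seed.
#' @return data frame \code{ligand_total}, \code{bound_fraction}.
#' @export
gen_ms_titration <- function(true_kd, P0, ligand_series, noise = 0,
                             seed = 1L) {
  stopifnot(true_kd > 0, P0 > 0, all(ligand_series >= 0))
  set.seed(seed)
  fb <- bound_fraction_model(ligand_series, P0, true_kd)
  if (noise > 0)
    fb <- pmin(pmax(fb + stats::rnorm(length(fb), 0, noise), 0), 1)
  data.frame(ligand_total = as.numeric(ligand_series),
             bound_fraction = fb)
}

#' Generate an idealized structure fixture with known burial
#'
#' Builds a deterministic compact lattice fold: residues occupy a snake
#' path through a cubic lattice (5 A spacing) so that consecutive
#' residues are adjacent, each residue contributing five heavy atoms in a
#' fixed local arrangement. Interior lattice sites are occluded by their
#' neighbours and form the designed buried core; sites on the top face
#' form a designed contiguous exposed cluster. Ground-truth labels are
#' returned alongside, and a small seed-controlled coordinate jitter
#' (0.05 A) breaks exact degeneracies without affecting the design.
#'
#' @param n_residues number of residues (>= 20).
#' @param seed integer seed; the emitted PDB is byte-identical for a
#'   given seed.
#' @param path optional file to write the structure to in PDB format.
#' @return list with \code{structure} (a \code{structure_model}),
#'   \code{buried} and \code{top_face} (residue numbers of the designed
#'   core and exposed cluster) and \code{path} (if written).
#' @export
gen_structure_fixture <- function(n_residues, seed = 1L, path = NULL) {
  if (n_residues < 20L) stop("need at least 20 residues for a lattice fold")
  set.seed(seed)
  m <- ceiling(n_residues^(1 / 3))
  a <- 5.0
  # snake path: consecutive residues occupy adjacent lattice sites
  sites <- matrix(0L, nrow = n_residues, ncol = 3L)
  k <- 0L
  for (z in 0:(m - 1)) {
    ys <- if (z %% 2L == 0L) 0:(m - 1) else (m - 1):0
    for (y in ys) {
      xs <- if ((z * m + y) %% 2L == 0L) 0:(m - 1) else (m - 1):0
      for (x in xs) {
        k <- k + 1L
        if (k > n_residues) break
        sites[k, ] <- c(x, y, z)
      }
      if (k > n_residues) break
    }
    if (k > n_residues) break
  }
  occ <- new.env(hash = TRUE)
  for (i in seq_len(n_residues))
    assign(paste(sites[i, ], collapse = ","), i, envir = occ)
  has <- function(s) exists(paste(s, collapse = ","), envir = occ)
  face_nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  buried <- which(vapply(seq_len(n_residues), function(i) {
    all(vapply(seq_len(6), function(j) has(sites[i, ] + face_nb[j, ]),
               logical(1)))
  }, logical(1)))
  zmax <- max(sites[, 3])
  top_face <- which(sites[, 3] == zmax)
  # local atom offsets (A): N, CA, C, O, CB of an idealized alanine
  off <- rbind(N = c(-1.3, 0.2, 0), CA = c(0, 0, 0), C = c(1.3, 0.2, 0),
               O = c(1.4, 1.2, 0.6), CB = c(-0.2, -1.1, 1.0))
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    p <- sites[i, ] * a
    data.frame(resno = i, resid = "ALA",
               elety = rownames(off),
               element = substr(rownames(off), 1L, 1L),
               x = p[1] + off[, 1], y = p[2] + off[, 2], z = p[3] + off[, 3],
               stringsAsFactors = FALSE)
  }))
  jit <- matrix(stats::runif(3L * nrow(atoms), -0.05, 0.05), ncol = 3L)
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  sm <- structure_model(atoms)
  if (!is.null(path)) {
    lines <- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      seq_len(nrow(atoms)), atoms$elety, atoms$resid, atoms$resno,
      atoms$x, atoms$y, atoms$z, atoms$element)
    writeLines(c(lines, "END"), path)
  }
  list(structure = sm, buried = buried, top_face = top_face, path = path)
}

#' Published hPEBP1 titration residue sets
#'
#' Machine-readable encodings of the reported per-ligand residue
#' classifications, exclusions and binding constants for hPEBP1 (187
#' residues; conserved pocket of 16 residues, PDB entry 2QYQ) titrated
#' with GTP, FMN and the Raf-1 peptide (residues 331--349 of Raf-1) in
#' tri-phosphorylated and non-phosphorylated forms. These sets drive the
#' filter-accounting checks of the analysis pipeline: counts of perturbed
#' residues per exchange regime, buried/isolated discrimination, patch
#' sizes and the residues retained for K_D averaging.
#'
#' @return A named list with elements \code{protein}, \code{pocket},
#'   \code{gtp}, \code{fmn}, \code{raf1_3p}, \code{raf1_np} and
#'   \code{ms}.
#' @export
pebp1_reference_sets <- function() {
  pocket <- data.frame(
    residue_id = c(70L, 73L, 74L, 81L, 84L, 86L, 107L, 108L, 110L, 111L,
                   112L, 118L, 120L, 180L, 181L, 184L),
    residue_name = c("D", "A", "P", "Y", "W", "H", "V", "G", "G", "P",
                     "P", "H", "Y", "L", "Y", "L"),
    stringsAsFactors = FALSE)
  list(
    protein = list(n_residues = 187L, n_non_proline = 172L,
                   n_assigned = 166L, pdb_id = "2QYQ"),
    pocket = pocket,
    gtp = list(
      n_fast = 34L,
      excluded = data.frame(
        residue_id = c(27L, 57L, 106L, 110L),
        residue_name = c("V", "G", "Y", "G"),
        reason = c("isolated", "isolated", "outlier_kd", "low_intensity"),
        stringsAsFactors = FALSE),
      n_kd_residues = 30L,
      kd_uM = 669, kd_sd_uM = 140,
      kd_phys_uM = 3425, kd_phys_sd_uM = 1967,
      csp_threshold_ppm = 0.087, csp_threshold_phys_ppm = 0.058,
      P0_uM = 270, P0_phys_uM = 100,
      ligand_series_uM = c(0, 270, 540, 1000, 2000, 4000),
      ligand_max_phys_uM = 6400),
    fmn = list(
      counts = c(slow = 39L, fast = 15L, intermediate = 13L),
      n_total = 67L,
      kd_uM = 14, kd_sd_uM = 9,
      kd_phys_uM = 252, kd_phys_sd_uM = 84,
      n_kd_residues = 14L, P0_uM = 270),
    raf1_3p = list(
      counts = c(slow = 54L, intermediate = 11L, fast = 8L),
      n_total = 73L,
      buried = c(27L, 67L, 68L, 69L, 72L, 109L, 121L, 122L, 124L, 151L,
                 168L),
      isolated = c(15L, 57L, 58L),
      n_surface = 59L,
      ms_kd_uM = 45, ms_kd_sd_uM = 12,
      ms_kd_phys_uM = 11, ms_kd_phys_sd_uM = 3,
      ms_P0_uM = 18, ms_incubation_L_uM = 67.6),
    raf1_np = list(
      counts = c(slow = 16L, intermediate = 6L, fast = 11L),
      n_total = 33L,
      buried = c(27L, 46L, 72L, 109L),
      isolated = c(29L),
      small_patches = list(c(25L, 26L, 34L, 166L),
                           c(55L, 56L, 57L, 58L, 164L)),
      pocket_patch_size = 19L),
    ms = list(gtp_kd_uM = 89, gtp_kd_sd_uM = 48,
              fmn_kd_uM = 5, fmn_kd_sd_uM = 4))
}
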