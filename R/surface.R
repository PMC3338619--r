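# Structure mapping: solvent accessibility, buried/isolated
# discrimination and contiguous binding-surface patches.

# Van der Waals radii (A) by element for the SASA calculation.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

# Maximal per-residue solvent accessibility (A^2) in a Gly-X-Gly
# tripeptide (theoretical values of Tien et al. 2013), used to normalize
# absolute SASA into relative exposure.
MAX_ACC_GXG <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
                 CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
                 HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
                 MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
                 THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Read a protein structure into a structure model
#'
#' Heavy atoms of one chain of a PDB file, indexed by author residue
#' numbering (no renumbering is performed). Hydrogens and waters are
#' dropped; altLoc duplicates keep the first location.
#'
#' @param path PDB file.
#' @param chain chain identifier; default the first chain in the file.
#' @return Object of class \code{structure_model}: \code{atoms} (data
#'   frame \code{resno}, \code{resid}, \code{elety}, \code{element},
#'   \code{x}, \code{y}, \code{z}), \code{residues} (vector of residue
#'   numbers), and, after \code{\link{compute_sasa}}, per-residue
#'   \code{sasa} and \code{rel_sasa}.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  elem <- toupper(substr(trimws(at$elety), 1L, 1L))
  at <- at[elem != "H", , drop = FALSE]
  elem <- elem[elem != "H"]
  if (nrow(at) == 0L) stop("no heavy atoms found in ", path)
  structure_model(data.frame(resno = at$resno,
                             resid = toupper(at$resid),
                             elety = trimws(at$elety),
                             element = elem,
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE))
}

#' @rdname read_structure
#' @param atoms atom table as described under the return value.
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety", "element", "x", "y", "z")
                %in% names(atoms)))
  residues <- sort(unique(atoms$resno))
  counts <- table(atoms$resno)
  if (any(counts == 0L))
    stop("residue(s) without atoms: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  structure(list(atoms = atoms, residues = residues,
                 sasa = NULL, rel_sasa = NULL),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d residues, %d heavy atoms%s\n",
              length(x$residues), nrow(x$atoms),
              if (is.null(x$sasa)) "" else " (SASA computed)"))
  invisible(x)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each heavy atom is inflated by the probe radius and
#' covered with a deterministic quasi-uniform point mesh; the accessible
#' area is the fraction of mesh points not falling inside any
#' neighbouring inflated sphere. Per-residue SASA is the sum over the
#' residue's atoms; relative SASA divides by the residue type's
#' Gly-X-Gly maximal exposure (so values slightly above 1 can occur for
#' extended conformations).
#'
#' @param structure a \code{\link{structure_model}}.
#' @param probe_radius solvent probe radius (A), default 1.4 (water).
#' @param n_sphere_points mesh points per atom (default 240; doubling
#'   changes residue SASA by well under 2 percent on typical folds).
#' @return The structure model with \code{sasa} and \code{rel_sasa}
#'   filled (named by residue number).
#' @export
compute_sasa <- function(structure, probe_radius = 1.4,
                         n_sphere_points = 240) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  n <- nrow(at)
  radii <- VDW_RADII[at$element]
  radii[is.na(radii)] <- VDW_DEFAULT
  R <- radii + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  mesh <- sphere_points(n_sphere_points)
  area <- numeric(n)
  # neighbour candidates via squared-distance cutoff against max pair reach
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    pts <- mesh * R[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
          (pts[free, 3] - xyz[j, 3])^2
        free[free] <- dj2 >= R[j]^2
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * R[i]^2 * frac
  }
  res_sasa <- tapply(area, at$resno, sum)
  res_name <- tapply(at$resid, at$resno, function(r) r[1])
  ref <- MAX_ACC_GXG[res_name]
  ref[is.na(ref)] <- mean(MAX_ACC_GXG)
  out <- structure
  out$sasa <- stats::setNames(as.numeric(res_sasa), names(res_sasa))
  out$rel_sasa <- stats::setNames(as.numeric(res_sasa) / as.numeric(ref),
                                  names(res_sasa))
  out
}

# Representative side-chain coordinate per residue for contiguity:
# C-beta, falling back to C-alpha (glycine), then to the first atom.
residue_coords <- function(structure, residues = NULL) {
  at <- structure$atoms
  if (is.null(residues)) residues <- structure$residues
  t(vapply(residues, function(r) {
    ra <- at[at$resno == r, , drop = FALSE]
    if (nrow(ra) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    i <- match("CB", ra$elety)
    if (is.na(i)) i <- match("CA", ra$elety)
    if (is.na(i)) i <- 1L
    as.numeric(ra[i, c("x", "y", "z")])
  }, numeric(3)))
}

#' Discriminate buried and isolated residues among significant ones
#'
#' Significant perturbation of a residue does not by itself place it in
#' the binding surface: buried residues report indirect (allosteric or
#' packing) effects, and a lone perturbed residue far from any other is
#' not a surface. A residue is \emph{buried} when its relative SASA is
#' below \code{burial_thr}; a surface-exposed residue is \emph{isolated}
#' when no other significant surface-exposed residue lies within
#' \code{neighbor_cutoff} (C-beta distance, C-alpha for glycine). The
#' remaining residues are the candidates for patch construction.
#'
#' @param significant named character vector mapping residue number to
#'   exchange class (or a bare vector of residue numbers).
#' @param structure a \code{structure_model} with SASA computed (if
#'   missing, \code{\link{compute_sasa}} is run with defaults).
#' @param burial_thr relative-SASA burial threshold (default 0.15).
#' @param neighbor_cutoff contiguity distance (A, default 8).
#' @return list with \code{buried}, \code{isolated}, \code{candidates}
#'   (residue numbers) and \code{labels} (named vector over all
#'   significant residues).
#' @export
discriminate_residues <- function(significant, structure,
                                  burial_thr = 0.15, neighbor_cutoff = 8) {
  if (is.null(names(significant))) {
    ids <- as.integer(significant)
  } else {
    ids <- as.integer(names(significant))
  }
  if (length(ids) == 0L)
    return(list(buried = integer(0), isolated = integer(0),
                candidates = integer(0),
                labels = stats::setNames(character(0), character(0))))
  stopifnot(inherits(structure, "structure_model"))
  if (is.null(structure$rel_sasa)) structure <- compute_sasa(structure)
  absent <- setdiff(ids, structure$residues)
  if (length(absent) > 0L)
    stop("significant residue(s) absent from the structure: ",
         paste(absent, collapse = ", "))
  rel <- structure$rel_sasa[as.character(ids)]
  buried <- ids[rel < burial_thr]
  exposed <- setdiff(ids, buried)
  isolated <- integer(0)
  if (length(exposed) > 1L) {
    xyz <- residue_coords(structure, exposed)
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    isolated <- exposed[apply(d, 1L, min) > neighbor_cutoff]
  } else if (length(exposed) == 1L) {
    isolated <- exposed
  }
  candidates <- setdiff(exposed, isolated)
  labels <- stats::setNames(rep("candidate", length(ids)), ids)
  labels[as.character(buried)] <- "buried"
  labels[as.character(isolated)] <- "isolated"
  list(buried = buried, isolated = isolated, candidates = candidates,
       labels = labels)
}

#' Apply a precomputed buried/isolated discrimination
#'
#' Accounting variant of \code{\link{discriminate_residues}} for the case
#' where burial and isolation calls already exist (e.g. published residue
#' classifications): removes them from the significant set and returns
#' the same bookkeeping without requiring coordinates.
#'
#' @param significant residue numbers (or named class vector).
#' @param buried,isolated residue numbers to exclude.
#' @return Same shape as \code{\link{discriminate_residues}}.
#' @export
apply_discrimination <- function(significant, buried = integer(0),
                                 isolated = integer(0)) {
  ids <- if (is.null(names(significant))) as.integer(significant)
  else as.integer(names(significant))
  buried <- intersect(as.integer(buried), ids)
  isolated <- setdiff(intersect(as.integer(isolated), ids), buried)
  candidates <- setdiff(ids, c(buried, isolated))
  labels <- stats::setNames(rep("candidate", length(ids)), ids)
  labels[as.character(buried)] <- "buried"
  labels[as.character(isolated)] <- "isolated"
  list(buried = buried, isolated = isolated, candidates = candidates,
       labels = labels)
}

#' Contiguous binding-surface patches
#'
#' Builds the contact graph over candidate residues (edges between
#' residues within \code{neighbor_cutoff}, C-beta distance, C-alpha for
#' glycine) and takes its connected components as surface patches.
#' Patches smaller than \code{min_patch_size} are reported but labelled
#' \code{small_patch} and excluded from the accepted binding surfaces.
#'
#' @param candidates residue numbers (surface-exposed, non-isolated).
#' @param structure a \code{structure_model}.
#' @param neighbor_cutoff contiguity distance (A, default 8).
#' @param min_patch_size minimal accepted patch size (default 6).
#' @param classes optional named exchange-class vector used to annotate
#'   accepted-patch members in the labels.
#' @return Object of class \code{binding_surface}: \code{patches} (list
#'   of residue-number vectors, largest first), \code{accepted} (indices
#'   of patches meeting the size rule), \code{labels} (named vector:
#'   exchange class or \code{small_patch} for every candidate, plus any
#'   \code{buried}/\code{isolated} labels merged in by
#'   \code{\link{map_binding_surface}}), and the parameters used.
#' @export
surface_patches <- function(candidates, structure, neighbor_cutoff = 8,
                            min_patch_size = 6, classes = NULL) {
  candidates <- as.integer(candidates)
  stopifnot(inherits(structure, "structure_model"))
  if (length(candidates) == 0L) {
    return(structure(list(patches = list(), accepted = integer(0),
                          labels = stats::setNames(character(0), character(0)),
                          neighbor_cutoff = neighbor_cutoff,
                          min_patch_size = min_patch_size),
                     class = "binding_surface"))
  }
  absent <- setdiff(candidates, structure$residues)
  if (length(absent) > 0L)
    stop("candidate residue(s) absent from the structure: ",
         paste(absent, collapse = ", "))
  xyz <- residue_coords(structure, candidates)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= neighbor_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  patches <- split(candidates, comp)
  patches <- patches[order(-vapply(patches, length, integer(1)))]
  names(patches) <- NULL
  sizes <- vapply(patches, length, integer(1))
  accepted <- which(sizes >= min_patch_size)
  labels <- stats::setNames(rep("small_patch", length(candidates)),
                            candidates)
  for (k in accepted) {
    memb <- as.character(patches[[k]])
    labels[memb] <- if (is.null(classes)) "patch"
    else ifelse(is.na(classes[memb]), "patch", classes[memb])
  }
  structure(list(patches = patches, accepted = accepted, labels = labels,
                 neighbor_cutoff = neighbor_cutoff,
                 min_patch_size = min_patch_size),
            class = "binding_surface")
}

#' @export
print.binding_surface <- function(x, ...) {
  sizes <- vapply(x$patches, length, integer(1))
  cat(sprintf("Binding surface: %d patch(es), %d accepted (>= %d residues)\n",
              length(x$patches), length(x$accepted), x$min_patch_size))
  for (i in seq_along(x$patches)) {
    cat(sprintf("  patch %d (%d residues%s): %s\n", i, sizes[i],
                if (i %in% x$accepted) "" else ", rejected",
                paste(x$patches[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Map significant residues of a titration onto a structure
#'
#' End-to-end structure stage: discriminates buried and isolated residues
#' among the significantly perturbed ones, builds contiguous patches from
#' the rest, and merges all labels (exchange class for accepted-patch
#' members; \code{buried}, \code{isolated}, \code{small_patch} otherwise).
#' Prolines carry no amide proton and cannot appear in an HSQC; a
#' significant proline therefore indicates an assignment problem and is
#' warned about.
#'
#' @param ct a \code{\link{csp_titration}} (or a named class vector over
#'   residue numbers).
#' @param structure a \code{structure_model}.
#' @param burial_thr,neighbor_cutoff,min_patch_size see
#'   \code{\link{discriminate_residues}} and
#'   \code{\link{surface_patches}}.
#' @return A \code{binding_surface} whose \code{labels} cover every
#'   significant residue exactly once.
#' @export
map_binding_surface <- function(ct, structure, burial_thr = 0.15,
                                neighbor_cutoff = 8, min_patch_size = 6) {
  classes <- if (inherits(ct, "csp_titration")) {
    pr <- ct$profiles[ct$profiles$exchange_class != "unperturbed", ]
    stats::setNames(pr$exchange_class, pr$residue_id)
  } else {
    ct
  }
  ids <- as.integer(names(classes))
  pro <- ids[structure$atoms$resid[match(ids, structure$atoms$resno)] == "PRO"]
  pro <- pro[!is.na(pro)]
  if (length(pro) > 0L)
    warning("proline(s) marked significant despite lacking an amide proton: ",
            paste(pro, collapse = ", "))
  disc <- discriminate_residues(classes, structure,
                                burial_thr = burial_thr,
                                neighbor_cutoff = neighbor_cutoff)
  bs <- surface_patches(disc$candidates, structure,
                        neighbor_cutoff = neighbor_cutoff,
                        min_patch_size = min_patch_size,
                        classes = classes)
  labels <- c(bs$labels,
              stats::setNames(rep("buried", length(disc$buried)),
                              disc$buried),
              stats::setNames(rep("isolated", length(disc$isolated)),
                              disc$isolated))
  bs$labels <- labels[as.character(sort(as.integer(names(labels))))]
  bs$buried <- disc$buried
  bs$isolated <- disc$isolated
  bs$burial_thr <- burial_thr
  bs
}

#' Write the per-residue surface annotation and patch summary
#'
#' The annotation TSV (residue_id, label, patch_id) is suitable for
#' coloring residues in a molecular viewer; the header records the
#' discrimination parameters used.
#'
#' @param bs a \code{binding_surface}.
#' @param annotation_path,patch_path output TSV files.
#' @export
write_surface_report <- function(bs, annotation_path, patch_path) {
  stopifnot(inherits(bs, "binding_surface"))
  ids <- as.integer(names(bs$labels))
  patch_id <- rep(NA_integer_, length(ids))
  for (i in seq_along(bs$patches))
    patch_id[ids %in% bs$patches[[i]]] <- i
  hdr <- sprintf("# neighbor_cutoff=%g min_patch_size=%d%s",
                 bs$neighbor_cutoff, bs$min_patch_size,
                 if (is.null(bs$burial_thr)) ""
                 else sprintf(" burial_thr=%g", bs$burial_thr))
  con <- file(annotation_path, "w")
  writeLines(hdr, con)
  utils::write.table(data.frame(residue_id = ids,
                                label = unname(bs$labels),
                                patch_id = patch_id),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  sizes <- vapply(bs$patches, length, integer(1))
  utils::write.table(
    data.frame(patch_id = seq_along(bs$patches), size = sizes,
               accepted = seq_along(bs$patches) %in% bs$accepted,
               residues = vapply(bs$patches, paste, character(1),
                                 collapse = ",")),
    patch_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(bs)
}
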