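# Shared fixtures and independent oracles, all built in code.

# A small peak table with the given residues.
make_peaks <- function(ids, dH = NULL, dN = NULL, I = NULL,
                       names_ = NULL, state = NULL) {
  n <- length(ids)
  data.frame(residue_id = ids,
             residue_name = if (is.null(names_)) rep("A", n) else names_,
             delta_H = if (is.null(dH)) seq(7.5, 9, length.out = n) else dH,
             delta_N = if (is.null(dN)) seq(110, 125, length.out = n) else dN,
             intensity = if (is.null(I)) rep(1e6, n) else I,
             state = if (is.null(state)) rep("free", n) else state,
             stringsAsFactors = FALSE)
}

# Independent oracle for the upper-direction iterative threshold:
# enumerate prefixes of the descending-sorted values and return the first
# removal count satisfying the fixed-point condition (all removed values
# strictly above mean+2sd of the rest, none of the rest above it).
threshold_oracle_upper <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  for (k in 0:(n - 2)) {
    retained <- v[(k + 1):n]
    cut <- mean(retained) + 2 * stats::sd(retained)
    removed_ok <- k == 0 || all(v[seq_len(k)] > cut)
    retained_ok <- all(retained <= cut)
    if (removed_ok && retained_ok)
      return(list(k = k, threshold = cut, flagged = v[seq_len(k)]))
  }
  NULL
}

# Brute-force connected components by BFS over the explicit adjacency,
# independent of igraph.
components_oracle <- function(ids, xyz, cutoff) {
  n <- length(ids)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff & row(d) != col(d)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(ids[comp])
  }
  comps[order(-vapply(comps, length, integer(1)))]
}

# Noiseless multi-regime scenario: fast + intermediate + slow binders on
# an unperturbed background, with fb reaching > 0.9 at the last point.
regime_scenario <- function(seed = 1, true_kd = 50, noise_ppm = 0,
                            noise_intensity = 0) {
  res <- data.frame(
    residue_id = c(1:4, 11:13, 21:22, 31:70),
    csp_max_H = c(seq(0.08, 0.22, length.out = 4),
                  seq(0.1, 0.16, length.out = 3),
                  c(0.2, 0.3), rep(0, 40)),
    csp_max_N = c(seq(0.4, 1.1, length.out = 4),
                  seq(0.5, 0.8, length.out = 3),
                  c(1.0, 1.5), rep(0, 40)),
    regime = rep(c("fast", "intermediate", "slow", "unperturbed"),
                 c(4, 3, 2, 40)))
  scenario_config(true_kd = true_kd, P0 = 100,
                  ligand_series = c(0, 50, 100, 250, 500, 1500, 5000),
                  residues = res, noise_ppm = noise_ppm,
                  noise_intensity = noise_intensity, seed = seed)
}
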