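# Independent oracles and small fixture builders used across the suite.

# O(m^2) enumeration oracle for Kendall tau-a: every unordered pair of
# entries contributes sign(dx) * sign(dy); ties contribute 0; denominator
# is the full pair count.
tau_a_enum <- function(x, y) {
  m <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  sum(sx[ut] * sy[ut]) / (m * (m - 1) / 2)
}

# Projected-gradient oracle for non-negative least squares on the normal
# equations: minimize 0.5 x' AtA x - Atb' x subject to x >= 0.
nnls_pg <- function(AtA, Atb, iters = 20000) {
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(rep(0, length(Atb)))
  x <- pmax(Atb / L, 0)
  for (i in seq_len(iters)) {
    g <- drop(AtA %*% x) - Atb
    x_new <- pmax(x - g / L, 0)
    if (max(abs(x_new - x)) < 1e-13) { x <- x_new; break }
    x <- x_new
  }
  x
}

nnls_objective <- function(X, y, w) sum((y - drop(X %*% w))^2)

stim_ids <- function(n) sprintf("s%02d", seq_len(n))

# random RDM over n stimuli with continuous (almost surely tie-free) entries
random_rdm <- function(n, meta = "random") {
  rdm(runif(rdmfit::num_pairs(n)), stim_ids(n), meta = meta)
}

# random activity-pattern set
random_patterns <- function(n_stim = 6, n_chan = 10, subject_id = "s1") {
  pattern_set(matrix(rnorm(n_stim * n_chan), n_stim, n_chan),
              stimulus_ids = stim_ids(n_stim),
              subject_id = subject_id)
}

# an exactly 2-D-embeddable RDM built from planted planar coordinates
planar_rdm <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(runif(2 * n, 0, 10), n, 2)
  m <- as.matrix(dist(pts))
  from_square(m, stim_ids(n), meta = "planar")
}

# small binary dimension matrix fixture
toy_dims <- function() {
  vals <- rbind(d1 = c(1, 0, 1, 0),
                d2 = c(1, 1, 0, 0),
                d3 = c(0, 1, 1, 1))
  dimension_matrix(vals, stimulus_ids = paste0("s", 1:4))
}
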