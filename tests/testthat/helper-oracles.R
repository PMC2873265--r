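# Independent oracles used across the suite. These deliberately take a
# different computational route from the implementation they check.

# Ancestry oracle: enumerate the root-to-leaf node path with ape::nodepath
# (edge-matrix traversal) instead of the package's top-down depth sweep.
# Internal nodes on the path = path length minus the leaf itself; depth
# subtracts one more so a leaf hanging off the root scores 0.
oracle_ancestry <- function(newick) {
  tree <- ape::read.tree(text = newick)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depths <- vapply(seq_len(ntip), function(i)
    length(ape::nodepath(tree, from = root, to = i)) - 2L, integer(1))
  mx <- max(depths)
  anc <- if (mx == 0) rep(0, ntip) else depths / mx
  stats::setNames(anc, tree$tip.label)
}

# AUC oracle: midpoint Riemann sum of the empirical CDF of the census
# ancestries over [0, theta].
oracle_auc_riemann <- function(ancestries, theta, grid = 1e-5) {
  if (theta <= 0) return(0)
  a <- sort(ancestries)
  cdf_at <- function(x) findInterval(x, a) / length(a)
  m <- floor(theta / grid)
  total <- grid * sum(cdf_at((seq_len(m) - 0.5) * grid))
  r <- theta - m * grid                       # partial last cell
  if (r > 0) total <- total + r * cdf_at(m * grid + r / 2)
  100 * total
}

# Random rooted binary Newick with n leaves labelled L1..Ln.
random_newick <- function(n) {
  tree <- ape::rtree(n, rooted = TRUE, br = NULL)
  tree$tip.label <- sprintf("L%d", seq_len(n))
  ape::write.tree(tree)
}

uniform_grid_table <- function(n_points) {
  ancestry_table(sprintf("G%06d", seq_len(n_points) - 1L),
                 (seq_len(n_points) - 1L) / (n_points - 1L))
}

random_census <- function(size) {
  toy_census(round(stats::runif(size), 6))
}
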