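# Shared fixtures, built in code.  Expensive objects are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard two-block family: tight core (columns 1-40), divergent loops
std_family <- function() memo("std_family",
  synth_family(family_spec(length = 60, n_members = 20,
                           sigma = c(rep(0.1, 40), rep(1.5, 20)), seed = 7)))

std_superposition <- function() memo("std_sup",
  ml_superpose(std_family()$correspondence, std_family()$traces))

# a small two-level synthetic tree plus its run, shared by tree/acceptance tests
std_tree <- function() memo("std_tree", {
  dir <- file.path(tempdir(), "polsuper-std-tree")
  unlink(dir, recursive = TRUE)
  fx <- synth_tree(dir, levels = 2, members_per_set = 3, seed = 11)
  fx
})

std_tree_run <- function() memo("std_tree_run", {
  out <- file.path(tempdir(), "polsuper-std-tree-out")
  unlink(out, recursive = TRUE)
  run_tree(load_tree(std_tree()$config), out_dir = out)
})

# independent generalized-Procrustes oracle: iterated unweighted LS fitting,
# written without reference to ml_superpose internals
gpa_oracle <- function(coords_list, max_iter = 200, tol = 1e-12) {
  m <- length(coords_list)
  tr <- vector("list", m)
  tr[[1]] <- rigid_transform()
  for (i in 2:m) tr[[i]] <- kabsch_fit(coords_list[[i]], coords_list[[1]])
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    fitted <- lapply(seq_len(m), function(i)
      transform_points(coords_list[[i]], tr[[i]]))
    mu <- Reduce(`+`, fitted) / m
    ss <- sum(vapply(fitted, function(f) sum((f - mu)^2), 0))
    if (abs(obj_old - ss) < tol * max(1, abs(obj_old))) break
    obj_old <- ss
    for (i in seq_len(m)) tr[[i]] <- kabsch_fit(coords_list[[i]], mu)
  }
  tr
}

# brute-force rotation search oracle for the Kabsch fit
brute_force_best_residual <- function(moving, fixed, weights, n_trials) {
  w <- weights / sum(weights)
  cm <- colSums(moving * w); cf <- colSums(fixed * w)
  mct <- t(sweep(moving, 2, cm)); fct <- t(sweep(fixed, 2, cf))
  best <- Inf
  for (k in seq_len(n_trials)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    a <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + a * z), 2 * (x * z - a * y),
                  2 * (x * y - a * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + a * x),
                  2 * (x * z + a * y), 2 * (y * z - a * x), 1 - 2 * (x^2 + y^2)),
                3, 3)
    E <- R %*% mct - fct
    ss <- sum(weights * colSums(E^2))
    if (ss < best) best <- ss
  }
  best
}

weighted_residual <- function(transform, moving, fixed, weights) {
  sum(weights * rowSums((transform_points(moving, transform) - fixed)^2))
}
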