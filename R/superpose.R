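# Rigid-body fitting.  kabsch_fit() is the weighted least-squares primitive;
# ml_superpose() is the iterative maximum-likelihood multiple superposition
# that estimates an isotropic per-column coordinate variance and uses its
# inverse as the fitting weight, so structurally divergent columns are
# down-weighted instead of dragging the fit.

#' Weighted Kabsch rigid-body fit
#'
#' Returns the proper rotation and translation minimizing
#' `sum_i w_i |R m_i + t - f_i|^2`.  A reflection in the SVD solution is
#' corrected by flipping the sign of the smallest singular value, so the
#' result is always a proper rotation.
#'
#' @param moving,fixed n x 3 coordinate matrices (n >= 3).
#' @param weights non-negative per-point weights; default uniform.
#' @return A [rigid_transform()] mapping `moving` onto `fixed`.
#' @export
kabsch_fit <- function(moving, fixed, weights = NULL) {
  moving <- rbind(moving); fixed <- rbind(fixed)
  n <- nrow(moving)
  if (nrow(fixed) != n) stop("point sets differ in length")
  if (n < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || !any(weights > 0))
    stop("weights must be non-negative with at least one positive entry")
  if (sum(weights > 0) < 3) stop("need at least 3 points with positive weight")
  w <- weights / sum(weights)
  cm <- colSums(moving * w); cf <- colSums(fixed * w)
  mc <- sweep(moving, 2, cm); fc <- sweep(fixed, 2, cf)
  # degeneracy: weighted point clouds must span a plane
  for (pts in list(mc, fc)) {
    sv <- svd(pts * sqrt(w), nu = 0, nv = 0)$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-12))
      stop("degenerate point set (collinear or coincident)")
  }
  B <- crossprod(mc * w, fc)            # sum_i w_i m_ci f_ci^T
  sv <- svd(B)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cf - as.vector(R %*% cm))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain RMSD; no fitting is performed.
#'
#' @param a,b n x 3 coordinate matrices of equal length (n >= 1).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) != nrow(b) || nrow(a) < 1) stop("coordinate sets differ in length")
  sqrt(mean(rowSums((a - b)^2)))
}

superposition_objective <- function(resid_ss, n_present, variances) {
  # negative log-likelihood up to constants:
  # sum_j [ n_j * 3 * log sigma_j^2 + SS_j / sigma_j^2 ]
  sum(n_present * 3 * log(variances) + resid_ss / variances)
}

#' Maximum-likelihood multiple structure superposition
#'
#' Iterative estimator for superposing two or more Calpha sets that share a
#' residue correspondence.  Each iteration (i) computes the per-column mean
#' over present members, (ii) re-estimates an isotropic per-column variance
#' `sigma_j^2` (mean squared deviation from the mean over present members and
#' the three coordinates, floored at `var_floor`), and (iii) refits every
#' member to the mean by weighted Kabsch with weights `1/sigma_j^2` over its
#' present columns.  Initialization fits every member to the first member
#' (the set's seed) with uniform weights.  MISSING entries are excluded from
#' means, variances and fits.
#'
#' @param table a [correspondence_table()].
#' @param coords list of coordinate sources parallel to `table$members`: each
#'   a [ca_trace()] or an n x 3 matrix indexed by the table.
#' @param options list of control values: `tol` (relative objective change for
#'   convergence, default 1e-8), `max_iter` (default 200), `var_floor`
#'   (default 1e-4 A^2), `uniform_variance` (pin all column weights equal,
#'   giving the iterated unweighted least-squares limit; default FALSE).
#' @return Object of class `ml_superposition` with elements
#'   `member_transforms`, `mean_coords`, `column_variances`, `n_present`,
#'   `iterations`, `objective_trace`, `columns_used`, `converged`, `members`.
#'   Non-convergence is reported via `converged = FALSE`, never an error.
#' @export
ml_superpose <- function(table, coords, options = list()) {
  stopifnot(inherits(table, "correspondence_table"))
  opt <- utils::modifyList(list(tol = 1e-8, max_iter = 200L, var_floor = 1e-4,
                                uniform_variance = FALSE), options)
  m <- nrow(table$index)
  if (m < 2) stop("need at least 2 members")
  if (length(coords) != m) stop("coords must have one element per member")
  xyz <- lapply(coords, function(cc) if (inherits(cc, "ca_trace")) cc$xyz else rbind(cc))

  keep <- colSums(!is.na(table$index)) >= 2
  idx <- table$index[, keep, drop = FALSE]
  src <- table$source_columns[keep]
  ncol_used <- ncol(idx)
  ids <- member_ids(table$members)

  # member coordinate matrices over table columns (NA rows where MISSING)
  X <- lapply(seq_len(m), function(i) {
    out <- matrix(NA_real_, ncol_used, 3)
    pres <- !is.na(idx[i, ])
    out[pres, ] <- xyz[[i]][idx[i, pres], , drop = FALSE]
    out
  })
  present <- vapply(X, function(x) !is.na(x[, 1]), logical(ncol_used))
  for (i in seq_len(m)) {
    if (sum(present[, i]) < 3)
      stop("fewer than 3 usable columns for member ", ids[i])
  }

  # initialization: unweighted Kabsch onto the first member
  transforms <- vector("list", m)
  transforms[[1]] <- rigid_transform()
  for (i in seq_len(m)[-1]) {
    sh <- present[, i] & present[, 1]
    if (sum(sh) < 3)
      stop("fewer than 3 columns shared with the seed for member ", ids[i])
    transforms[[i]] <- kabsch_fit(X[[i]][sh, , drop = FALSE],
                                  X[[1]][sh, , drop = FALSE])
  }

  n_present <- rowSums(present)
  fit_coords <- function() lapply(seq_len(m), function(i)
    transform_points(X[[i]], transforms[[i]]))

  objective_trace <- numeric(0)
  converged <- FALSE
  variances <- rep(opt$var_floor, ncol_used)
  mu <- matrix(0, ncol_used, 3)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Y <- fit_coords()
    # per-column mean over present members
    sums <- matrix(0, ncol_used, 3); cnt <- n_present
    for (i in seq_len(m)) {
      p <- present[, i]
      sums[p, ] <- sums[p, ] + Y[[i]][p, , drop = FALSE]
    }
    mu <- sums / cnt
    # isotropic per-column variance, floored
    ss <- numeric(ncol_used)
    for (i in seq_len(m)) {
      p <- present[, i]
      d <- Y[[i]][p, , drop = FALSE] - mu[p, , drop = FALSE]
      ss[p] <- ss[p] + rowSums(d^2)
    }
    variances <- pmax(ss / (3 * cnt), opt$var_floor)
    if (opt$uniform_variance)
      variances <- rep(max(sum(ss) / (3 * sum(cnt)), opt$var_floor), ncol_used)
    obj <- superposition_objective(ss, cnt, variances)
    objective_trace <- c(objective_trace, obj)
    if (iter > 1L) {
      prev <- objective_trace[iter - 1L]
      if (abs(obj - prev) < opt$tol * max(1, abs(prev))) { converged <- TRUE; break }
    }
    if (iter >= opt$max_iter) break
    # refit each member to the mean with weights 1/sigma^2
    w <- 1 / variances
    for (i in seq_len(m)) {
      p <- present[, i]
      transforms[[i]] <- kabsch_fit(X[[i]][p, , drop = FALSE],
                                    mu[p, , drop = FALSE], w[p])
    }
  }

  structure(list(members = table$members,
                 member_ids = ids,
                 member_transforms = stats::setNames(transforms, ids),
                 mean_coords = mu,
                 column_variances = variances,
                 n_present = n_present,
                 iterations = iter,
                 objective_trace = objective_trace,
                 columns_used = src,
                 present = present,
                 input_coords = X,
                 converged = converged,
                 options = opt),
            class = "ml_superposition")
}

#' @export
print.ml_superposition <- function(x, ...) {
  cat(sprintf(paste0("Maximum-likelihood superposition: %d members, %d columns\n",
                     "  %d iteration(s), %s (objective %.4f)\n",
                     "  column sigma^2 range [%.4g, %.4g] A^2\n"),
              length(x$member_transforms), length(x$column_variances),
              x$iterations, if (x$converged) "converged" else "NOT converged",
              tail(x$objective_trace, 1),
              min(x$column_variances), max(x$column_variances)))
  invisible(x)
}

#' @export
summary.ml_superposition <- function(object, ...) {
  fit <- fitted(object)
  rms <- vapply(seq_along(fit), function(i) {
    p <- object$present[, i]
    rmsd(fit[[i]][p, , drop = FALSE], object$mean_coords[p, , drop = FALSE])
  }, numeric(1))
  out <- list(members = data.frame(member = object$member_ids,
                                   columns = colSums(object$present),
                                   rmsd_to_mean = rms),
              variance_quartiles = stats::quantile(object$column_variances),
              pseudo_b_range = range(pseudo_b(object$column_variances)),
              iterations = object$iterations,
              converged = object$converged)
  class(out) <- "summary.ml_superposition"
  out
}

#' @export
print.summary.ml_superposition <- function(x, ...) {
  cat("ML superposition summary\n")
  print(x$members, row.names = FALSE)
  cat(sprintf("iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("column variance quartiles (A^2):\n"); print(x$variance_quartiles)
  invisible(x)
}

#' @export
coef.ml_superposition <- function(object, ...) object$member_transforms

#' @export
fitted.ml_superposition <- function(object, ...) {
  stats::setNames(lapply(seq_along(object$input_coords), function(i)
    transform_points(object$input_coords[[i]], object$member_transforms[[i]])),
    object$member_ids)
}

#' @export
residuals.ml_superposition <- function(object, ...) {
  fit <- fitted(object)
  res <- matrix(NA_real_, length(fit), length(object$column_variances),
                dimnames = list(object$member_ids, NULL))
  for (i in seq_along(fit)) {
    p <- object$present[, i]
    res[i, p] <- sqrt(rowSums((fit[[i]][p, , drop = FALSE] -
                                 object$mean_coords[p, , drop = FALSE])^2))
  }
  res
}

#' Simulate members from a fitted superposition model
#'
#' Draws synthetic members from the fitted Gaussian model: the column mean
#' plus isotropic noise with the estimated per-column variance.
#'
#' @param object a fitted `ml_superposition`.
#' @param nsim number of members to draw.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of `nsim` coordinate matrices.
#' @export
simulate.ml_superposition <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nc <- nrow(object$mean_coords)
  lapply(seq_len(nsim), function(k)
    object$mean_coords +
      matrix(rnorm(nc * 3), nc, 3) * sqrt(object$column_variances))
}

#' @export
plot.ml_superposition <- function(x, ...) {
  b <- pseudo_b(x$column_variances)
  graphics::plot(x$columns_used, b, type = "h", lwd = 2,
                 xlab = "alignment column", ylab = expression(pseudo - B ~ (ring(A)^2)),
                 main = "Positional heterogeneity (8*pi^2 * variance)", ...)
  invisible(x)
}

#' Pseudo B-factor from positional variance
#'
#' `B_j = 8 * pi^2 * sigma_j^2`, the crystallographic B-factor a position
#' would have if its coordinate spread across the superposed family were
#' thermal motion.  Written into the B column of the average structure to
#' visualize structural heterogeneity.
#'
#' @param variances per-column variances (A^2, non-negative).
#' @return Per-column pseudo B-values (A^2).
#' @examples
#' pseudo_b(1.0)  # 78.9568
#' @export
pseudo_b <- function(variances) {
  if (any(variances < 0)) stop("negative variance")
  8 * pi^2 * variances
}

#' Average structure of a superposition
#'
#' One Calpha pseudo-residue per column at the mean coordinates, sequentially
#' numbered, with the pseudo B-factor in the B column.
#'
#' @param result an `ml_superposition`.
#' @param pdb_id,chain identifiers for the emitted model.
#' @return A [pdb_structure()].
#' @export
mean_structure <- function(result, pdb_id = "AVE", chain = "A") {
  stopifnot(inherits(result, "ml_superposition"))
  nc <- nrow(result$mean_coords)
  b <- pmin(pseudo_b(result$column_variances), 999.99)
  atoms <- data.frame(kind = "ATOM", serial = seq_len(nc), name = " CA ",
                      altloc = " ", resname = "ALA", chain = chain,
                      resseq = seq_len(nc), icode = " ",
                      x = result$mean_coords[, 1], y = result$mean_coords[, 2],
                      z = result$mean_coords[, 3], occ = 1, b = b,
                      element = "C", tag = "", stringsAsFactors = FALSE)
  pdb_structure(atoms, pdb_id = pdb_id,
                title = "AVERAGE STRUCTURE OF ML SUPERPOSITION",
                model_number = 1L)
}

#' Write the per-column variance listing
#'
#' One line per column: column index, mean coordinates, `sigma^2`, pseudo-B.
#'
#' @param result an `ml_superposition`.
#' @param path output path (conventionally `super/theseus_variances.txt`).
#' @return Invisibly, `path`.
#' @export
write_variances <- function(result, path) {
  stopifnot(inherits(result, "ml_superposition"))
  lines <- c("# column   mean_x   mean_y   mean_z   variance     pseudoB",
             sprintf("%8d %8.3f %8.3f %8.3f %10.6f %11.4f",
                     result$columns_used,
                     result$mean_coords[, 1], result$mean_coords[, 2],
                     result$mean_coords[, 3], result$column_variances,
                     pseudo_b(result$column_variances)))
  writeLines(lines, path)
  invisible(path)
}
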