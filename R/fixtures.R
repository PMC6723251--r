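# Ground-truth synthetic inputs.  Helix-based Calpha templates keep the
# package download-free while emulating what the ML model assumes: a tight
# conserved core plus divergent, noisy regions.  All generators are pure
# functions of their spec and seed.

AA_CYCLE <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")

#' Ideal alpha-helical Calpha spiral
#'
#' Rise 1.5 A per residue, 100 degrees per residue, radius 2.3 A, giving the
#' canonical ~3.8 A consecutive Calpha spacing.
#'
#' @param n residue count (>= 1).
#' @return n x 3 coordinate matrix.
#' @export
ideal_helix <- function(n) {
  if (n < 1) stop("n must be >= 1")
  t <- seq_len(n) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

#' Compact helical-bundle Calpha template
#'
#' Three antiparallel ideal helices side by side.  Family and tree fixtures
#' use this rather than a single helix because a lone helix is rod-like and
#' leaves rotation about its long axis weakly determined, which no globular
#' protein domain does; the bundle is extended in all three dimensions.
#'
#' @param n residue count (>= 1); split as evenly as possible over the
#'   helices.
#' @param spacing distance between helix axes (Angstrom).
#' @return n x 3 coordinate matrix, centred at the origin.
#' @export
helical_bundle <- function(n, spacing = 14) {
  if (n < 1) stop("n must be >= 1")
  per <- diff(round(seq(0, n, length.out = 4)))
  offsets <- rbind(c(0, 0, 0), c(spacing, 0, 0),
                   c(spacing / 2, spacing * sqrt(3) / 2, 0))
  segs <- lapply(seq_len(3), function(k) {
    if (per[k] == 0) return(NULL)
    h <- ideal_helix(per[k])
    if (k %% 2 == 0) h[, 3] <- max(h[, 3]) - h[, 3]  # antiparallel
    sweep(h, 2, offsets[k, ], "+")
  })
  xyz <- do.call(rbind, segs)
  sweep(xyz, 2, colMeans(xyz))
}

#' Specification for a synthetic Calpha family
#'
#' @param length template residue count.
#' @param n_members number of members (ignored if `transforms` given).
#' @param sigma per-position noise standard deviation in Angstrom (scalar or
#'   length `length`); applied independently to each coordinate.
#' @param transforms optional list of planted [rigid_transform()]s, one per
#'   member; by default random rotations/translations drawn from the seed.
#' @param deletions optional data frame with columns `member`, `start`,
#'   `length`: residues deleted from individual members.
#' @param seed mandatory RNG seed.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(length, n_members = 3, sigma = 0.1, transforms = NULL,
                        deletions = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  sigma <- rep_len(sigma, length)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (!is.null(transforms)) n_members <- base::length(transforms)
  if (!is.null(deletions)) {
    stopifnot(all(c("member", "start", "length") %in% names(deletions)))
    if (any(deletions$start < 1 | deletions$start + deletions$length - 1 > length))
      stop("deletions outside template")
  }
  structure(list(length = as.integer(length), n_members = as.integer(n_members),
                 sigma = sigma, transforms = transforms, deletions = deletions,
                 seed = as.integer(seed)),
            class = "family_spec")
}

random_rotation <- function() {
  # uniform rotation via normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Generate a synthetic Calpha family with known ground truth
#'
#' Member i is `planted_transform_i(template + noise_i)` with optional
#' per-member deletions; the template, the noisy common-frame coordinates, the
#' planted transforms and the ground-truth correspondence are all returned, so
#' recovery can be checked exactly.  The template is a centred ideal helix and
#' the residue sequence cycles through the 20 standard amino acids.
#'
#' @param spec a [family_spec()].
#' @return List with `template` (n x 3), `traces` (list of [ca_trace()]),
#'   `transforms` (planted, per member), `truth` (per-member common-frame
#'   coordinates, template + noise, full length), `correspondence`
#'   (ground-truth [correspondence_table()]) and `spec`.
#' @export
synth_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  n <- spec$length
  template <- helical_bundle(n)
  resname <- AA_CYCLE[((seq_len(n) - 1) %% 20) + 1]
  transforms <- spec$transforms
  if (is.null(transforms)) {
    transforms <- lapply(seq_len(spec$n_members), function(i)
      rigid_transform(random_rotation(), stats::runif(3, -20, 20)))
  }
  m <- length(transforms)
  traces <- vector("list", m)
  truth <- vector("list", m)
  index <- matrix(NA_integer_, m, n)
  for (i in seq_len(m)) {
    noise <- matrix(rnorm(n * 3), n, 3) * spec$sigma
    common <- template + noise
    truth[[i]] <- common
    keep <- rep(TRUE, n)
    if (!is.null(spec$deletions)) {
      del <- spec$deletions[spec$deletions$member == i, , drop = FALSE]
      for (k in seq_len(nrow(del)))
        keep[del$start[k]:(del$start[k] + del$length[k] - 1)] <- FALSE
    }
    member_xyz <- transform_points(common[keep, , drop = FALSE], transforms[[i]])
    traces[[i]] <- ca_trace(sprintf("m%03d", i), "A",
                            resseq = which(keep), icode = " ",
                            resname = resname[keep], xyz = member_xyz)
    index[i, keep] <- seq_len(sum(keep))
  }
  members <- data.frame(pdb_id = sprintf("m%03d", seq_len(m)), chain = "A",
                        stringsAsFactors = FALSE)
  list(template = template, traces = traces, transforms = transforms,
       truth = truth,
       correspondence = correspondence_table(members, index, seq_len(n), n),
       spec = spec)
}

#' Generate a synthetic PDB entry around the common-frame anchors
#'
#' Writes a parseable PDB file with a polymerase-like Calpha chain whose motif
#' A and motif C aspartate Calpha atoms sit at specified positions (defaults:
#' exactly at the frame anchors), plus optional RNA chain, second protein
#' chain, metal HETATM ions, waters, alternate locations and extra MODELs.
#'
#' @param path output file path.
#' @param seed RNG seed (jitters the helical scaffold deterministically).
#' @param n_res scaffold residue count (default 30).
#' @param asp_a_pos,asp_c_pos Calpha positions for the motif A / C aspartates.
#' @param asp_resname residue name planted at the two positions (default
#'   "ASP"; use "ASN" to construct an active-site-free decoy).
#' @param center scaffold centre (default the base-pair anchor).
#' @param rna_dist if non-NULL, adds an RNA chain "R" of `rna_len` phosphate
#'   atoms laid out radially so its nearest atom is `rna_dist` Angstrom from
#'   the base-pair anchor.
#' @param rna_len number of RNA residues (default 8, 2 A spacing, pointing
#'   away from the anchor).
#' @param second_chain_dist if non-NULL, adds a second protein chain "B"
#'   centred this far from the base-pair anchor.
#' @param ions NULL, a character vector of site names resolved against
#'   `sites`, or a data frame with columns `element`, `x`, `y`, `z`.
#' @param sites [ion_site_model()] used to resolve ion site names.
#' @param n_waters number of HOH molecules scattered near the scaffold.
#' @param altloc_residue if non-NULL, that residue of chain A is written with
#'   two alternate Calpha locations (altloc A occupancy 0.6, altloc B 0.4,
#'   displaced 0.5 A).
#' @param n_models write this many MODEL blocks; models beyond the first are
#'   shifted copies missing the last 5 atoms, so per-model atom counts differ.
#' @param title TITLE text.
#' @return Invisibly, `path`.
#' @export
synth_pdb_entry <- function(path, seed = 1, n_res = 30,
                            asp_a_pos = polymerase_anchors()$asp_a$position,
                            asp_c_pos = polymerase_anchors()$asp_c$position,
                            asp_resname = "ASP",
                            center = polymerase_anchors()$base_pair$position,
                            rna_dist = NULL, rna_len = 8,
                            second_chain_dist = NULL,
                            ions = NULL, sites = default_ion_sites(),
                            n_waters = 0, altloc_residue = NULL,
                            n_models = 1,
                            title = "SYNTHETIC POLYMERASE-LIKE TEST ENTRY") {
  set.seed(seed)
  helix <- ideal_helix(n_res)
  helix <- sweep(helix, 2, colMeans(helix))
  xyz <- sweep(helix + matrix(rnorm(n_res * 3, sd = 0.05), n_res, 3), 2,
               center, "+")
  resname <- AA_CYCLE[((seq_len(n_res) - 1) %% 20) + 1]
  ia <- max(1, round(n_res / 3)); ic <- max(ia + 2, round(2 * n_res / 3))
  xyz[ia, ] <- asp_a_pos; xyz[ic, ] <- asp_c_pos
  resname[c(ia, ic)] <- asp_resname

  rows <- list()
  add <- function(kind, name, resname, chain, resseq, x, y, z,
                  altloc = " ", occ = 1, element = NULL) {
    element <- element %||% infer_element(name)
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, serial = 0L, name = name, altloc = altloc,
      resname = resname, chain = chain, resseq = as.integer(resseq),
      icode = " ", x = x, y = y, z = z, occ = occ, b = 0,
      element = element, tag = "", stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    if (!is.null(altloc_residue) && i == altloc_residue) {
      add("ATOM", " CA ", resname[i], "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3],
          altloc = "A", occ = 0.6)
      add("ATOM", " CA ", resname[i], "A", i, xyz[i, 1] + 0.5, xyz[i, 2],
          xyz[i, 3], altloc = "B", occ = 0.4)
    } else {
      add("ATOM", " CA ", resname[i], "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3])
    }
  }
  if (!is.null(rna_dist)) {
    dirv <- c(0, 1, 0)
    for (k in seq_len(rna_len)) {
      p <- center + dirv * (rna_dist + 2 * (k - 1))
      add("ATOM", " P  ", "  U", "R", k, p[1], p[2], p[3], element = "P")
    }
  }
  if (!is.null(second_chain_dist)) {
    h2 <- sweep(sweep(ideal_helix(n_res), 2, colMeans(ideal_helix(n_res))),
                2, center + c(second_chain_dist, 0, 0), "+")
    for (i in seq_len(n_res))
      add("ATOM", " CA ", resname[i], "B", i, h2[i, 1], h2[i, 2], h2[i, 3])
  }
  if (!is.null(ions)) {
    if (is.character(ions)) {
      ions <- data.frame(element = rep("MG", length(ions)),
                         x = sites$centroids[ions, 1],
                         y = sites$centroids[ions, 2],
                         z = sites$centroids[ions, 3],
                         stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(ions)))
      add("HETATM", sprintf("%2s  ", ions$element[k]),
          sprintf("%3s", ions$element[k]), "M", 900 + k,
          ions$x[k], ions$y[k], ions$z[k], element = ions$element[k])
  }
  for (k in seq_len(n_waters)) {
    p <- center + stats::runif(3, -15, 15)
    add("HETATM", " O  ", "HOH", "W", 800 + k, p[1], p[2], p[3], element = "O")
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(pos) > 1 && min(dist(pos)) < 0.5)
    stop("colliding atoms (< 0.5 A) in generated layout")

  model <- pdb_structure(atoms, pdb_id = substr(basename(path), 1, 4),
                         title = title)
  if (n_models <= 1) {
    write_structure(model, path)
  } else {
    lines <- format_title_records(title)
    for (mno in seq_len(n_models)) {
      at <- atoms
      if (mno > 1) {
        at <- at[seq_len(max(1, nrow(at) - 5)), , drop = FALSE]
        at$x <- at$x + 10 * (mno - 1)
      }
      body <- vapply(seq_len(nrow(at)), function(i) format_coord_line(at[i, ]),
                     character(1))
      lines <- c(lines, sprintf("MODEL     %4d", mno), body, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Generate a miniature alignment tree with ground truth
#'
#' Builds a chain of superposition sets emulating the region growth of the
#' real tree: the root aligns a 13-column motif-like core, deeper levels use
#' 40, 65 and finally all columns.  Region segments sit on different helices
#' of the bundle, as the catalytic motifs do: distant in sequence, adjacent
#' in space.  Every member file is a planted rigid transform of the
#' common template plus position-dependent noise (tight through the first 65
#' columns, divergent beyond); the root seed is planted with the identity
#' transform, so the common frame equals the template frame and ground-truth
#' coordinates are known for every member.  Each child set is seeded by a
#' non-seed member of its parent, exercising orientation inheritance.
#'
#' @param out_dir directory to create (input files, `tree.yaml`).
#' @param levels number of sets in the chain (>= 1).
#' @param members_per_set members in each set (>= 2).
#' @param seed RNG seed.
#' @param n_res template length (default 80).
#' @param sigma_core,sigma_tail noise sd (A) for columns 1-65 and beyond.
#' @return List with `config` (path to `tree.yaml`), `dir`, `template`,
#'   `truth` (named list: member id -> full-length common-frame coordinates),
#'   `sigma` (per-column noise profile) and `region_cols` (per-set region
#'   sizes).
#' @export
synth_tree <- function(out_dir, levels = 2, members_per_set = 3, seed = 1,
                       n_res = 80, sigma_core = 0.04, sigma_tail = 0.3) {
  stopifnot(levels >= 1, members_per_set >= 2)
  set.seed(seed)
  dir.create(file.path(out_dir, "input"), recursive = TRUE, showWarnings = FALSE)
  template <- helical_bundle(n_res)
  sigma <- rep(sigma_tail, n_res)
  sigma[seq_len(min(65, n_res))] <- sigma_core
  resname <- AA_CYCLE[((seq_len(n_res) - 1) %% 20) + 1]

  # Motif-like regions: segments spread over different helices of the bundle
  # (like motifs A and C: distant in sequence, adjacent in space), growing
  # 13 -> 40 -> 65 columns and FULL beyond, mirroring the real tree.
  region_for_level <- function(lv) {
    if (n_res < 70) return("FULL")
    switch(min(lv, 4),
           list(motif_a = list(c(8, 14)), motif_c = list(c(30, 35))),
           list(motif_a = list(c(5, 17)), motif_c = list(c(28, 40)),
                motif_f = list(c(55, 68))),
           list(motif_a = list(c(5, 17)), motif_c = list(c(28, 40)),
                motif_f = list(c(55, 68)), motif_b = list(c(41, 54)),
                flank = list(c(18, 24), c(1, 4))),
           "FULL")
  }

  counter <- 0
  truth <- list()
  new_member <- function(transform) {
    counter <<- counter + 1
    id <- sprintf("p%03d", counter)
    noise <- matrix(rnorm(n_res * 3), n_res, 3) * sigma
    common <- template + noise
    truth[[paste0(id, "_A")]] <<- common
    xyz <- transform_points(common, transform)
    f <- file.path(out_dir, "input", paste0(id, ".pdb"))
    write_structure(trace_to_structure(
      ca_trace(id, "A", seq_len(n_res), " ", resname, xyz),
      title = paste("SYNTHETIC TREE MEMBER", toupper(id))), f)
    list(pdb = id, chain = "A", file = file.path("input", paste0(id, ".pdb")))
  }

  sets <- list()
  prev_name <- "ROOT"
  handoff <- NULL  # member of the previous set that seeds the next one
  for (lv in seq_len(levels)) {
    nm <- sprintf("se%02d", lv)
    members <- list()
    if (lv == 1) {
      members[[1]] <- new_member(rigid_transform())  # identity: defines the frame
    } else {
      members[[1]] <- handoff
    }
    for (k in 2:members_per_set)
      members[[k]] <- new_member(rigid_transform(random_rotation(),
                                                 stats::runif(3, -20, 20)))
    reg <- region_for_level(lv)
    sets[[lv]] <- list(
      name = nm, parent = prev_name,
      seed = list(pdb = members[[1]]$pdb, chain = "A"),
      alignment = "AUTO",
      region = reg,
      members = members)
    # next level is seeded by this level's second member
    handoff <- members[[2]]
    prev_name <- nm
  }
  cfg <- file.path(out_dir, "tree.yaml")
  yaml::write_yaml(list(sets = sets), cfg)
  list(config = cfg, dir = out_dir, template = template, truth = truth,
       sigma = sigma,
       region_cols = lapply(seq_len(levels), region_for_level))
}
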