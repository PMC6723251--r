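# Spatial analyses over superposed structures.  Because every file sits in the
# same frame, fixed "pseudoatom" anchor coordinates select equivalent regions
# in all of them: the two catalytic aspartates, the nascent base pair, and the
# metal-ion sites.

#' Pseudoatom anchor point
#'
#' A fixed coordinate in the common superposed frame plus a selection radius
#' ("expand" semantics: any atom within the radius, boundary closed).
#'
#' @param label name of the anchor.
#' @param position numeric length-3 coordinate (Angstrom).
#' @param radius selection radius (Angstrom, > 0).
#' @return Object of class `anchor_point`.
#' @export
anchor_point <- function(label, position, radius) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3, is.finite(radius), radius > 0)
  structure(list(label = label, position = position, radius = radius),
            class = "anchor_point")
}

#' Standard anchors of the common polymerase frame
#'
#' The motif A aspartate Calpha sits at approximately (3.5, -17.0, -11.5)
#' (selection radius 2.5 A, widened to accommodate its movement between the
#' open and closed active-site conformations), the motif C / GDD aspartate at
#' (10.0, -16.3, -13.8) (radius 2.0 A), and the centre of the nascent base
#' pair at (14.5, -4.5, -15.5) (radius 22 A, used for monomer trimming).
#'
#' @return Named list of [anchor_point()]s: `asp_a`, `asp_c`, `base_pair`.
#' @export
polymerase_anchors <- function() {
  list(asp_a = anchor_point("PolAspA", c(3.5, -17.0, -11.5), 2.5),
       asp_c = anchor_point("PolAspC", c(10.0, -16.3, -13.8), 2.0),
       base_pair = anchor_point("PseudoBP", c(14.5, -4.5, -15.5), 22))
}

#' Select atoms within an anchor radius
#'
#' @param model a [pdb_structure()].
#' @param anchor an [anchor_point()].
#' @param predicate optional function taking the atom table and returning a
#'   logical vector; only atoms passing it are eligible.
#' @param by_chain if TRUE, close the selection by chain: return all atoms of
#'   any chain with at least one selected atom.
#' @return Integer vector of row indices into `model$atoms` (possibly empty).
#' @export
select_within <- function(model, anchor, predicate = NULL, by_chain = FALSE) {
  stopifnot(inherits(model, "pdb_structure"), inherits(anchor, "anchor_point"))
  at <- model$atoms
  if (!nrow(at)) return(integer(0))
  d2 <- (at$x - anchor$position[1])^2 + (at$y - anchor$position[2])^2 +
    (at$z - anchor$position[3])^2
  sel <- d2 <= anchor$radius^2
  if (!is.null(predicate)) sel <- sel & predicate(at)
  if (by_chain && any(sel)) sel <- at$chain %in% unique(at$chain[sel])
  which(sel)
}

no_active_site <- function(msg) {
  stop(structure(class = c("no_active_site", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

nearest_asp_ca <- function(model, anchor) {
  at <- model$atoms
  cand <- select_within(model, anchor, predicate = function(a)
    a$kind == "ATOM" & toupper(a$resname) == "ASP" & trimws(a$name) == "CA")
  if (!length(cand))
    no_active_site(paste0("no aspartate Calpha within ", anchor$radius,
                          " A of anchor ", anchor$label))
  d2 <- (at$x[cand] - anchor$position[1])^2 +
    (at$y[cand] - anchor$position[2])^2 + (at$z[cand] - anchor$position[3])^2
  i <- cand[which.min(d2)]
  list(chain = at$chain[i], resseq = at$resseq[i], icode = at$icode[i],
       position = c(at$x[i], at$y[i], at$z[i]), distance = sqrt(min(d2)))
}

#' Locate the catalytic aspartates of a superposed structure
#'
#' Finds the motif A and motif C aspartate Calpha atoms as the Asp Calpha
#' nearest to the corresponding frame anchors (within the anchor radii).  The
#' structure must be in the common superposed frame; frame dependence is
#' intentional.
#'
#' @param model a [pdb_structure()] in the common frame.
#' @param anchors anchor list as from [polymerase_anchors()].
#' @return List with elements `motif_a` and `motif_c` (chain, resseq, icode,
#'   position, distance to anchor).  Throws a `no_active_site` condition when
#'   either anchor finds no aspartate.
#' @export
locate_catalytic_aspartates <- function(model, anchors = polymerase_anchors()) {
  list(motif_a = nearest_asp_ca(model, anchors$asp_a),
       motif_c = nearest_asp_ca(model, anchors$asp_c))
}

#' Catalytic aspartate DD distance
#'
#' The Calpha-Calpha distance between the motif A and motif C aspartates: a
#' scalar readout of the open/closed state of the active site.
#'
#' @inheritParams locate_catalytic_aspartates
#' @return Distance in Angstrom.
#' @export
dd_distance <- function(model, anchors = polymerase_anchors()) {
  asp <- locate_catalytic_aspartates(model, anchors)
  sqrt(sum((asp$motif_a$position - asp$motif_c$position)^2))
}

#' Survey DD distances over a set of superposed files
#'
#' Computes one DD record per file; files whose active site cannot be located
#' are listed as skipped, never fatal.  Also bins the distances into a
#' histogram and summarises per class.
#'
#' @param paths character vector of PDB file paths (common frame).
#' @param labels optional named character vector mapping file basenames to
#'   polymerase classes; unlisted files get class "all".
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @param bin_range default histogram span `c(5, 9)` A (extended if the data
#'   exceed it).
#' @param anchors anchor list as from [polymerase_anchors()].
#' @return List with `records` (data frame: source_file, class, motif-A and
#'   motif-C residue ids, dd), `skipped` (file, reason), `histogram`
#'   (bin midpoints and counts) and `summaries` (per-class min/max/mean/n).
#' @export
survey_dd <- function(paths, labels = NULL, bin_width = 0.1,
                      bin_range = c(5, 9), anchors = polymerase_anchors()) {
  records <- data.frame(source_file = character(0), class = character(0),
                        asp_a = character(0), asp_c = character(0),
                        dd = numeric(0), stringsAsFactors = FALSE)
  skipped <- data.frame(file = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (p in paths) {
    base <- basename(p)
    cls <- if (!is.null(labels) && base %in% names(labels)) labels[[base]] else "all"
    res <- tryCatch({
      model <- read_structure(p)
      asp <- locate_catalytic_aspartates(model, anchors)
      dd <- sqrt(sum((asp$motif_a$position - asp$motif_c$position)^2))
      data.frame(source_file = base, class = cls,
                 asp_a = paste0(asp$motif_a$chain, asp$motif_a$resseq),
                 asp_c = paste0(asp$motif_c$chain, asp$motif_c$resseq),
                 dd = round(dd, 2), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error"))
      skipped <- rbind(skipped, data.frame(file = base,
                                           reason = conditionMessage(res)))
    else records <- rbind(records, res)
  }
  lo <- min(bin_range[1], if (nrow(records)) floor(min(records$dd) / bin_width) * bin_width else bin_range[1])
  hi <- max(bin_range[2], if (nrow(records)) ceiling(max(records$dd) / bin_width) * bin_width else bin_range[2])
  nbins <- ceiling((hi - lo) / bin_width + 1e-9)
  # epsilon guard so a distance sitting exactly on a bin edge (e.g. 7.80 with
  # 0.1 A bins) lands in the right-hand bin
  counts <- if (nrow(records))
    tabulate(pmin(nbins, floor((records$dd - lo) / bin_width + 1e-9) + 1),
             nbins = nbins)
  else integer(nbins)
  histogram <- data.frame(mid = lo + (seq_len(nbins) - 0.5) * bin_width,
                          count = counts)
  summaries <- if (nrow(records))
    do.call(rbind, lapply(split(records$dd, records$class), function(v)
      data.frame(min = min(v), max = max(v), mean = mean(v), n = length(v))))
  else NULL
  list(records = records, skipped = skipped, histogram = histogram,
       summaries = summaries)
}

#' Trim a superposed structure to the active monomer
#'
#' Keeps every chain that has at least one atom within `radius` of the
#' base-pair anchor (the polymerase chain used for the superposition and any
#' bound nucleic acid); all other chains are removed.
#'
#' @param model a [pdb_structure()] in the common frame.
#' @param radius selection radius in Angstrom (default 22; reduce it when a
#'   neighbouring polymerase chain is caught, increase to keep more chains).
#' @param anchor base-pair anchor; default from [polymerase_anchors()].
#' @return The trimmed `pdb_structure`.
#' @export
trim_to_monomer <- function(model, radius = 22,
                            anchor = polymerase_anchors()$base_pair) {
  stopifnot(inherits(model, "pdb_structure"))
  if (!nrow(model$atoms)) stop("empty model")
  a <- anchor_point(anchor$label, anchor$position, radius)
  keep <- select_within(model, a, by_chain = TRUE)
  if (!length(keep)) stop("no monomer at anchor")
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Pool metal ions across superposed files
#'
#' Collects every metal HETATM from every file and writes them as one
#' `IONS-<set>.pdb` file whose coordinate lines are appended with the source
#' file names after column 80.  No deduplication is performed (structures
#' solved with strict non-crystallographic symmetry simply contribute
#' duplicate ions, mirroring the no-NCS-check policy of the alignment
#' pipeline).
#'
#' @param paths character vector of PDB file paths.
#' @param set_name set label used in the output file name.
#' @param out_dir directory for the IONS file.
#' @param metal_set element symbols treated as metals; default
#'   [METAL_ELEMENTS].
#' @return List with `records` (ion data frame in input order) and `file`
#'   (path of the written IONS file).
#' @export
pool_ions <- function(paths, set_name, out_dir = ".",
                      metal_set = METAL_ELEMENTS) {
  records <- NULL
  for (p in paths) {
    res <- tryCatch(read_structure(p), error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping unreadable file ", p, ": ", conditionMessage(res),
              call. = FALSE)
      next
    }
    ions <- extract_metal_ions(res, source_file = basename(p),
                               metal_set = metal_set)
    records <- if (is.null(records)) ions else rbind(records, ions)
  }
  if (is.null(records))
    records <- extract_metal_ions(pdb_structure(empty_atoms()), "none")[0, ]
  out_file <- file.path(out_dir, paste0("IONS-", set_name, ".pdb"))
  n <- nrow(records)
  atoms <- data.frame(kind = rep("HETATM", n), serial = seq_len(n),
                      name = sprintf("%2s  ", records$element),
                      altloc = " ",
                      resname = sprintf("%3s", records$element),
                      chain = records$source_chain, resseq = records$resseq,
                      icode = " ", x = records$x, y = records$y, z = records$z,
                      occ = 1, b = 0, element = records$element,
                      tag = records$source_file, stringsAsFactors = FALSE)
  if (n == 0) atoms <- empty_atoms()
  write_structure(pdb_structure(atoms, pdb_id = toupper(set_name),
                                title = paste("POOLED METAL IONS FOR SET",
                                              toupper(set_name))),
                  out_file)
  list(records = records, file = out_file)
}

empty_atoms <- function() {
  data.frame(kind = character(0), serial = integer(0), name = character(0),
             altloc = character(0), resname = character(0), chain = character(0),
             resseq = integer(0), icode = character(0), x = numeric(0),
             y = numeric(0), z = numeric(0), occ = numeric(0), b = numeric(0),
             element = character(0), tag = character(0),
             stringsAsFactors = FALSE)
}

#' Metal-ion binding-site model
#'
#' Three site centroids near the active site: the catalytic metal A (arrives
#' with the NTP), metal B (pre-bound) and the offset meB' site seen mainly in
#' viral RdRPs.  Ions are assigned to the nearest centroid within `cutoff`.
#'
#' @param meA,meB,meBp centroid coordinates (length-3, Angstrom).
#' @param cutoff assignment cutoff in Angstrom (default 3.0).
#' @return Object of class `ion_site_model`.
#' @export
ion_site_model <- function(meA, meB, meBp, cutoff = 3.0) {
  cents <- rbind(meA = as.numeric(meA), meB = as.numeric(meB),
                 meBp = as.numeric(meBp))
  stopifnot(ncol(cents) == 3, cutoff > 0)
  if (min(dist(cents)) < 1e-6) stop("site centroids must be pairwise distinct")
  structure(list(centroids = cents, cutoff = cutoff), class = "ion_site_model")
}

#' Default ion-site model
#'
#' Centroid coordinates estimated by the package authors from superposed
#' structures between and beside the two catalytic aspartate anchors; they are
#' a working default, not a published constant, and should be overridden with
#' [ion_site_model()] when a better estimate is available.
#'
#' @return An [ion_site_model()].
#' @export
default_ion_sites <- function() {
  ion_site_model(meA = c(6.0, -14.0, -14.5),
                 meB = c(10.0, -13.0, -16.5),
                 meBp = c(13.5, -15.5, -19.0))
}

#' Assign pooled ions to binding sites
#'
#' Labels each ion with the nearest site centroid when within the cutoff and
#' "OTHER" otherwise, and tabulates counts per site (and per class when a
#' class column or vector is supplied).
#'
#' @param ions ion data frame as returned by [pool_ions()] /
#'   [extract_metal_ions()].
#' @param sites an [ion_site_model()]; default [default_ion_sites()].
#' @param classes optional per-ion class labels (e.g. polymerase type) for the
#'   per-class breakdown.
#' @return List with `ions` (input plus `site` and `site_distance` columns),
#'   `site_counts`, and `class_counts` (site x class table or NULL).
#' @export
assign_ion_sites <- function(ions, sites = default_ion_sites(), classes = NULL) {
  stopifnot(inherits(sites, "ion_site_model"))
  n <- nrow(ions)
  if (n == 0) {
    ions$site <- character(0); ions$site_distance <- numeric(0)
    return(list(ions = ions,
                site_counts = table(factor(character(0),
                                           levels = c(rownames(sites$centroids), "OTHER"))),
                class_counts = NULL))
  }
  pos <- as.matrix(ions[, c("x", "y", "z")])
  d <- vapply(seq_len(nrow(sites$centroids)), function(k)
    sqrt(rowSums(sweep(pos, 2, sites$centroids[k, ])^2)), numeric(n))
  d <- rbind(d)
  nearest <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(n), nearest)]
  site <- ifelse(dmin <= sites$cutoff, rownames(sites$centroids)[nearest], "OTHER")
  ions$site <- site
  ions$site_distance <- dmin
  lv <- c(rownames(sites$centroids), "OTHER")
  site_counts <- table(factor(site, levels = lv))
  class_counts <- if (!is.null(classes))
    table(factor(site, levels = lv), classes) else NULL
  list(ions = ions, site_counts = site_counts, class_counts = class_counts)
}
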