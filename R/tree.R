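# The alignment tree: every node ("superposition set") is one multiple
# structure alignment whose orientation is inherited from its parent through a
# shared seed structure, so all outputs land in a single common frame.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an alignment-tree configuration
#'
#' The configuration is a YAML document with a `sets` list; each set names its
#' parent (`ROOT` for the first), a seed member, an alignment source (`AUTO`
#' for the built-in aligner or a CLUSTAL file path), a region (`FULL` or named
#' alignment-column ranges) and its members (`pdb`, `chain`, `file`, optional
#' `representative` name under which an upper-case seed file is emitted).  A
#' seed may carry a `frame` entry naming the parent representative file whose
#' orientation it inherits; by default the seed's own output in the parent set
#' is used.  Pivot ("open/closed"-style) sets need no special syntax: they are
#' FULL-region sets whose children simply name a different member as seed.
#'
#' @param path YAML file path.
#' @return Object of class `alignment_tree_config` with validated sets in
#'   topological order.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$sets) || !length(doc$sets)) stop("config has no sets")
  cfg_dir <- dirname(normalizePath(path))
  sets <- lapply(doc$sets, parse_set_config, cfg_dir = cfg_dir)
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         names(sets)[duplicated(names(sets))][1])
  parents <- vapply(sets, `[[`, "", "parent")
  if (parents[1] != "ROOT") stop("first set must have parent ROOT")
  if (sum(parents == "ROOT") != 1) stop("exactly one set may have parent ROOT")
  unknown <- setdiff(parents, c("ROOT", names(sets)))
  if (length(unknown)) stop("unknown parent: ", unknown[1])

  # topological order + cycle detection
  order <- character(0)
  placed <- c(ROOT = TRUE)
  remaining <- names(sets)
  while (length(remaining)) {
    ready <- remaining[parents[remaining] %in% c("ROOT", order)]
    if (!length(ready)) stop("cycle in alignment tree involving: ",
                             paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  # child seeds must be obtainable from the parent's outputs
  for (nm in order) {
    s <- sets[[nm]]
    if (s$parent == "ROOT") next
    p <- sets[[s$parent]]
    if (!is.null(s$seed$frame)) {
      reps <- p$members$representative
      if (!s$seed$frame %in% reps[!is.na(reps)])
        stop(sprintf("set %s: seed frame '%s' is not a representative of parent %s",
                     nm, s$seed$frame, s$parent))
    } else {
      hit <- p$members$pdb == s$seed$pdb & p$members$chain == s$seed$chain
      if (!any(hit))
        stop(sprintf("set %s: seed %s_%s not found among parent %s members",
                     nm, s$seed$pdb, s$seed$chain, s$parent))
    }
  }
  structure(list(sets = sets[order], order = order, dir = cfg_dir),
            class = "alignment_tree_config")
}

parse_set_config <- function(raw, cfg_dir = ".") {
  name <- raw$name
  if (is.null(name) || nchar(name) != 4)
    stop("set name must be a 4-character string, got: ",
         if (is.null(name)) "<missing>" else name)
  if (is.null(raw$members) || !length(raw$members)) stop("set ", name, " has no members")
  members <- do.call(rbind.data.frame, lapply(raw$members, function(m) {
    data.frame(pdb = as.character(m$pdb), chain = as.character(m$chain %||% "A"),
               file = as.character(m$file %||% NA_character_),
               representative = as.character(m$representative %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  members$file <- ifelse(!is.na(members$file) & !grepl("^/", members$file),
                         file.path(cfg_dir, members$file), members$file)
  seed <- raw$seed
  if (is.null(seed$pdb)) stop("set ", name, " has no seed pdb")
  seed <- list(pdb = as.character(seed$pdb),
               chain = as.character(seed$chain %||% "A"),
               frame = seed$frame)
  if (!any(members$pdb == seed$pdb & members$chain == seed$chain))
    stop("set ", name, ": seed ", seed$pdb, "_", seed$chain,
         " is not among its members")
  region <- raw$region %||% "FULL"
  if (!identical(region, "FULL")) {
    region <- do.call(motif_regions, lapply(region, function(r)
      if (is.list(r)) r else list(unlist(r))))
  }
  aln <- raw$alignment %||% "AUTO"
  if (!identical(aln, "AUTO") && !grepl("^/", aln)) aln <- file.path(cfg_dir, aln)
  structure(list(name = name, parent = raw$parent %||% "ROOT",
                 prefix = raw$prefix %||% "", seed = seed,
                 alignment = aln, region = region, members = members),
            class = "alignment_set_config")
}

#' @export
print.alignment_tree_config <- function(x, ...) {
  cat("Alignment tree:", length(x$sets), "set(s)\n")
  for (nm in x$order) {
    s <- x$sets[[nm]]
    cat(sprintf("  %s%s <- %s (%d members, region %s)\n", s$prefix, nm, s$parent,
                nrow(s$members),
                if (identical(s$region, "FULL")) "FULL"
                else paste0(region_size(s$region), " columns")))
  }
  invisible(x)
}

#' Re-anchor a superposition onto the parent frame
#'
#' Computes the rigid transform `G` mapping the seed member's fitted (ML-frame)
#' region coordinates onto its parent-frame coordinates by unweighted Kabsch
#' (the inherited frame must be matched exactly, not statistically), then
#' premultiplies every member transform by `G`.  Relative geometry among
#' members is unchanged.
#'
#' @param result an [ml_superpose()] result.
#' @param seed_index which member is the seed (default 1).
#' @param seed_parent_coords n x 3 matrix of the seed's parent-frame
#'   coordinates covering exactly the seed's present columns, in column order.
#' @return Named list of per-member [rigid_transform()]s, with the anchoring
#'   transform attached as attribute `"anchor"`.
#' @export
anchor_to_parent <- function(result, seed_index = 1L, seed_parent_coords) {
  stopifnot(inherits(result, "ml_superposition"))
  p <- result$present[, seed_index]
  seed_parent_coords <- rbind(seed_parent_coords)
  if (nrow(seed_parent_coords) != sum(p))
    stop("parent-frame coordinates do not cover the seed's columns (",
         nrow(seed_parent_coords), " vs ", sum(p), ")")
  seed_fit <- transform_points(result$input_coords[[seed_index]][p, , drop = FALSE],
                               result$member_transforms[[seed_index]])
  G <- kabsch_fit(seed_fit, seed_parent_coords)
  out <- lapply(result$member_transforms, function(tr) compose_transforms(G, tr))
  attr(out, "anchor") <- G
  out
}

compress_ranges <- function(resseq) {
  if (!length(resseq)) return("")
  breaks <- c(0, which(diff(resseq) != 1), length(resseq))
  paste(vapply(seq_len(length(breaks) - 1), function(k) {
    a <- resseq[breaks[k] + 1]; b <- resseq[breaks[k + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, ""), collapse = ", ")
}

#' Execute one superposition set
#'
#' Runs the per-set pipeline: read members, extract Calpha traces, obtain the
#' residue alignment (built-in progressive aligner or curated file), build the
#' correspondence, restrict to the configured region, fit by
#' [ml_superpose()], re-anchor onto the parent frame via the seed, reorient
#' the complete original entries (one output per polymerase chain) and write
#' the set directory: `pdb/` outputs, representative files,
#' `super/theseus_ave.pdb`, `super/theseus_variances.txt` and `_readme.txt`.
#'
#' @param config an `alignment_set_config` (see [load_tree()]).
#' @param parent_frame a [ca_trace()] of the seed chain in the parent frame,
#'   or `NULL` to keep the seed's original orientation (root behaviour).
#' @param out_dir output directory root.
#' @param strict escalate skipped members to errors.
#' @return Object of class `set_result`.
#' @export
run_set <- function(config, parent_frame = NULL, out_dir = ".", strict = FALSE) {
  stopifnot(inherits(config, "alignment_set_config"))
  mem <- config$members
  # seed first: it is the initialization member and the anchoring reference
  seed_row <- which(mem$pdb == config$seed$pdb & mem$chain == config$seed$chain)[1]
  mem <- mem[c(seed_row, setdiff(seq_len(nrow(mem)), seed_row)), , drop = FALSE]
  ids <- paste(mem$pdb, mem$chain, sep = "_")

  models <- vector("list", nrow(mem))
  traces <- vector("list", nrow(mem))
  skipped <- data.frame(member = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mem))) {
    res <- tryCatch({
      mdl <- read_structure(mem$file[i], pdb_id = mem$pdb[i])
      list(model = mdl, trace = extract_ca_trace(mdl, mem$chain[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (i == 1)
        stop("set ", config$name, ": seed member unreadable: ",
             conditionMessage(res))
      if (strict)
        stop("set ", config$name, ": member ", ids[i], " failed: ",
             conditionMessage(res))
      warning("set ", config$name, ": skipping member ", ids[i], ": ",
              conditionMessage(res), call. = FALSE)
      skipped <- rbind(skipped, data.frame(member = ids[i],
                                           reason = conditionMessage(res)))
      next
    }
    models[[i]] <- res$model
    traces[[i]] <- res$trace
  }
  ok <- !vapply(models, is.null, TRUE)
  if (sum(ok) < 2) stop("set ", config$name, ": fewer than 2 usable members")
  mem_ok <- mem[ok, , drop = FALSE]
  ids_ok <- ids[ok]
  models <- models[ok]; traces <- traces[ok]

  if (identical(config$alignment, "AUTO")) {
    aln <- progressive_msa(vapply(traces, trace_sequence, ""), names = ids_ok)
  } else {
    full <- parse_alignment(config$alignment)
    missing <- setdiff(ids_ok, full$names)
    if (length(missing))
      stop("set ", config$name, ": curated alignment lacks rows for: ",
           paste(missing, collapse = ", "))
    aln <- seq_alignment(ids_ok, full$rows[match(ids_ok, full$names)])
  }
  table <- build_correspondence(aln, traces)
  if (!identical(config$region, "FULL"))
    table <- restrict_regions(table, config$region)

  sup <- ml_superpose(table, traces)

  # parent-frame coordinates of the seed over its present columns
  p <- sup$present[, 1]
  seed_idx <- table$index[1, ]
  seed_res <- seed_idx[p]
  if (is.null(parent_frame)) {
    parent_coords <- traces[[1]]$xyz[seed_res, , drop = FALSE]
  } else {
    key_seed <- paste(traces[[1]]$resseq[seed_res], traces[[1]]$icode[seed_res])
    key_parent <- paste(parent_frame$resseq, parent_frame$icode)
    pos <- match(key_seed, key_parent)
    if (anyNA(pos))
      stop("set ", config$name,
           ": parent frame lacks seed residues: ",
           paste(head(key_seed[is.na(pos)], 3), collapse = ", "))
    parent_coords <- parent_frame$xyz[pos, , drop = FALSE]
  }
  final <- anchor_to_parent(sup, 1L, parent_coords)
  anchor <- attr(final, "anchor")

  # write outputs
  set_dir <- file.path(out_dir, paste0(config$prefix, config$name))
  pdb_dir <- file.path(set_dir, "pdb")
  super_dir <- file.path(set_dir, "super")
  dir.create(pdb_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(super_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character(0)
  info <- data.frame(member = ids_ok, file = NA_character_,
                     title = NA_character_, ranges = NA_character_,
                     atoms_used = colSums(sup$present), stringsAsFactors = FALSE)
  for (i in seq_along(models)) {
    moved <- apply_transform(models[[i]], final[[i]])
    fn <- output_filename(mem_ok$pdb[i], mem_ok$chain[i], config$name)
    write_structure(moved, file.path(pdb_dir, fn))
    files <- c(files, file.path(pdb_dir, fn))
    pres_i <- sup$present[, i]
    res_i <- table$index[i, pres_i]
    info$file[i] <- fn
    info$title[i] <- moved$title
    info$ranges[i] <- compress_ranges(traces[[i]]$resseq[res_i])
    if (!is.na(mem_ok$representative[i])) {
      tr <- traces[[i]]
      rep_xyz <- transform_points(tr$xyz, final[[i]])
      rep_model <- trace_to_structure(
        ca_trace(mem_ok$representative[i], tr$chain, tr$resseq, tr$icode,
                 tr$resname, rep_xyz),
        title = sprintf("REPRESENTATIVE %s EXTRACTED FROM %s CHAIN %s",
                        toupper(mem_ok$representative[i]),
                        toupper(mem_ok$pdb[i]), mem_ok$chain[i]))
      rep_fn <- output_filename(mem_ok$representative[i], representative = TRUE)
      write_structure(rep_model, file.path(pdb_dir, rep_fn))
      files <- c(files, file.path(pdb_dir, rep_fn))
    }
  }

  # anchored mean structure + variance listing
  anchored <- sup
  anchored$mean_coords <- transform_points(sup$mean_coords, anchor)
  ave <- mean_structure(anchored, pdb_id = toupper(config$name))
  write_structure(ave, file.path(super_dir, "theseus_ave.pdb"))
  write_variances(anchored, file.path(super_dir, "theseus_variances.txt"))

  seed_out <- transform_points(traces[[1]]$xyz[seed_res, , drop = FALSE],
                               final[[1]])
  # full-precision aligned traces, kept so child sets can inherit the frame
  # without passing through the 3-decimal file format
  aligned <- stats::setNames(lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    ca_trace(tr$pdb_id, tr$chain, tr$resseq, tr$icode, tr$resname,
             transform_points(tr$xyz, final[[i]]))
  }), ids_ok)
  result <- structure(list(name = config$name, set_dir = set_dir,
                           pdb_dir = pdb_dir,
                           transforms = stats::setNames(final, ids_ok),
                           anchor = anchor,
                           superposition = sup,
                           member_info = info, skipped = skipped,
                           files = files,
                           aligned_traces = aligned,
                           seed_id = ids_ok[1],
                           seed_rmsd = rmsd(seed_out, parent_coords)),
                      class = "set_result")
  write_set_readme(result, file.path(set_dir, "_readme.txt"))
  result
}

trace_to_structure <- function(trace, title = "") {
  n <- length(trace$resseq)
  atoms <- data.frame(kind = "ATOM", serial = seq_len(n), name = " CA ",
                      altloc = " ", resname = trace$resname, chain = trace$chain,
                      resseq = trace$resseq, icode = trace$icode,
                      x = trace$xyz[, 1], y = trace$xyz[, 2], z = trace$xyz[, 3],
                      occ = 1, b = 0, element = "C", tag = "",
                      stringsAsFactors = FALSE)
  pdb_structure(atoms, pdb_id = trace$pdb_id, title = title)
}

#' @export
print.set_result <- function(x, ...) {
  cat(sprintf("Set %s: %d member(s) aligned, %d skipped; seed frame RMSD %.2e A\n",
              x$name, nrow(x$member_info), nrow(x$skipped), x$seed_rmsd))
  invisible(x)
}

#' Write the set readme
#'
#' One block per member: output file name, TITLE, residue ranges used for the
#' superposition and the atom count; skipped members are listed with their
#' reason.
#'
#' @param result a [run_set()] result.
#' @param path output path (conventionally `<set>/_readme.txt`).
#' @return Invisibly, `path`.
#' @export
write_set_readme <- function(result, path) {
  stopifnot(inherits(result, "set_result"))
  out <- c(sprintf("Superposition set %s", result$name),
           sprintf("Members aligned: %d   skipped: %d",
                   nrow(result$member_info), nrow(result$skipped)), "")
  for (i in seq_len(nrow(result$member_info))) {
    m <- result$member_info[i, ]
    out <- c(out,
             sprintf("%s", m$file),
             sprintf("  TITLE: %s", m$title),
             sprintf("  residues used: %s", m$ranges),
             sprintf("  atoms used: %d", m$atoms_used), "")
  }
  for (i in seq_len(nrow(result$skipped))) {
    out <- c(out, sprintf("%s  SKIPPED: %s", result$skipped$member[i],
                          result$skipped$reason[i]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Execute an alignment tree
#'
#' Runs every set in topological order.  Each child inherits its frame by
#' reading the seed's reoriented coordinates from its parent's outputs (or the
#' parent's representative file when the seed names one), so the whole tree
#' lands in the root's coordinate frame.  All `pdb/` outputs are duplicated
#' into a top-level `_All_PDBs/` directory.
#'
#' @param tree an [load_tree()] configuration.
#' @param out_dir output directory root.
#' @param root_seed_frame optional [ca_trace()] giving the root seed's frame;
#'   by default the root seed keeps its original orientation.
#' @param strict escalate skipped members to errors.
#' @return Named list of [run_set()] results (class `tree_result`).
#' @export
run_tree <- function(tree, out_dir = ".", root_seed_frame = NULL,
                     strict = FALSE) {
  stopifnot(inherits(tree, "alignment_tree_config"))
  results <- list()
  for (nm in tree$order) {
    s <- tree$sets[[nm]]
    parent_frame <- if (s$parent == "ROOT") {
      root_seed_frame
    } else {
      pres <- results[[s$parent]]
      if (is.null(pres)) stop("set ", nm, ": parent ", s$parent, " was not run")
      seed_id <- if (!is.null(s$seed$frame)) {
        pm <- tree$sets[[s$parent]]$members
        hit <- which(!is.na(pm$representative) & pm$representative == s$seed$frame)
        if (length(hit)) paste(pm$pdb[hit[1]], pm$chain[hit[1]], sep = "_") else ""
      } else paste(s$seed$pdb, s$seed$chain, sep = "_")
      if (seed_id %in% names(pres$aligned_traces)) {
        # in-memory, full-precision parent-frame coordinates
        pres$aligned_traces[[seed_id]]
      } else {
        fn <- if (!is.null(s$seed$frame))
          output_filename(s$seed$frame, representative = TRUE)
        else output_filename(s$seed$pdb, s$seed$chain, s$parent)
        fp <- file.path(pres$pdb_dir, fn)
        if (!file.exists(fp))
          stop("set ", nm, ": seed frame file not found in parent outputs: ", fp)
        extract_ca_trace(read_structure(fp, pdb_id = s$seed$pdb), s$seed$chain)
      }
    }
    results[[nm]] <- tryCatch(
      run_set(s, parent_frame = parent_frame, out_dir = out_dir,
              strict = strict),
      error = function(e) stop("set ", nm, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  all_dir <- file.path(out_dir, "_All_PDBs")
  dir.create(all_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in results) {
    for (f in list.files(r$pdb_dir, full.names = TRUE))
      file.copy(f, file.path(all_dir, basename(f)), overwrite = TRUE)
  }
  structure(results, class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("Alignment tree run:", length(x), "set(s)\n")
  for (r in x) print(r)
  invisible(x)
}
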