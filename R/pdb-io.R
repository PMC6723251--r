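# Fixed-column PDB (v3.3) reading/writing with the project's file conventions:
# TITLE is the only header kept, symmetry/CRYST1 records are never emitted, and
# coordinate lines may carry a source-file tag after column 80 (ion pools).

#' Default metal element set
#'
#' Elements recognised as metal ions by [extract_metal_ions()].  Magnesium and
#' calcium are the catalytically relevant species; the remainder are common
#' crystallisation additives.
#' @export
METAL_ELEMENTS <- c("MG", "MN", "CA", "ZN", "NA", "K", "SR", "CS", "CD",
                    "CO", "NI", "PB", "LU")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Convert three-letter residue names to one-letter codes
#' @param resnames character vector of three-letter residue names.
#' @return Character vector of one-letter codes; unknown residues map to "X".
#' @export
three_to_one <- function(resnames) {
  out <- AA3[toupper(trimws(resnames))]
  out[is.na(out)] <- "X"
  unname(out)
}

TWO_LETTER_ELEMENTS <- c(METAL_ELEMENTS, "FE", "CU", "CL", "BR", "SE")

infer_element <- function(name_raw) {
  # PDB convention: a two-character element symbol starts in column 13 of the
  # atom-name field; organic elements are a single letter after the leading
  # blank/digit.
  two <- toupper(substr(name_raw, 1, 2))
  if (two %in% TWO_LETTER_ELEMENTS && substr(name_raw, 1, 1) != " ") return(two)
  stripped <- gsub("[^A-Za-z]", "", name_raw)
  if (nchar(stripped) == 0) return("X")
  toupper(substr(stripped, 1, 1))
}

#' Construct a structure model
#'
#' A structure model is the in-memory image of one PDB entry: an ordered atom
#' table covering one coordinate model, plus the TITLE text.  Atom order is
#' preserved exactly as read.
#'
#' @param atoms data frame with columns `kind` ("ATOM"/"HETATM"), `serial`,
#'   `name` (raw four-character name field), `altloc`, `resname`, `chain`,
#'   `resseq`, `icode`, `x`, `y`, `z`, `occ`, `b`, `element`, `tag`.
#' @param pdb_id identifier (typically the four-character PDB code).
#' @param title TITLE text.
#' @param model_number which MODEL the atoms came from.
#' @return An object of class `pdb_structure`.
#' @export
pdb_structure <- function(atoms, pdb_id = "xxxx", title = "", model_number = 1L) {
  need <- c("kind", "serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "x", "y", "z", "occ", "b", "element", "tag")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, title = title,
                 atoms = atoms[, need], model_number = as.integer(model_number)),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("PDB structure %s: %d atoms, %d chain(s)%s\n", x$pdb_id,
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0("\n  TITLE: ", x$title) else ""))
  invisible(x)
}

parse_coord_line <- function(line, lineno) {
  pad <- formatC(line, width = 80, flag = "-")
  num <- function(a, b, what, required = TRUE) {
    s <- trimws(substr(pad, a, b))
    if (!nzchar(s)) {
      if (required)
        stop(sprintf("malformed coordinate line %d: empty %s field", lineno, what))
      return(NA_real_)
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop(sprintf("malformed coordinate line %d: bad %s field '%s'", lineno, what, s))
    v
  }
  elem <- toupper(trimws(substr(pad, 77, 78)))
  name_raw <- substr(pad, 13, 16)
  if (!nzchar(elem)) elem <- infer_element(name_raw)
  occ <- num(55, 60, "occupancy", required = FALSE)
  b <- num(61, 66, "B-factor", required = FALSE)
  list(kind = trimws(substr(pad, 1, 6)),
       serial = as.integer(num(7, 11, "serial")),
       name = name_raw,
       altloc = substr(pad, 17, 17),
       resname = trimws(substr(pad, 18, 20)),
       chain = substr(pad, 22, 22),
       resseq = as.integer(num(23, 26, "residue number")),
       icode = substr(pad, 27, 27),
       x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
       occ = if (is.na(occ)) 1 else occ,
       b = if (is.na(b)) 0 else b,
       element = elem,
       tag = trimws(substring(line, 81)))
}

#' Read a PDB-format coordinate file
#'
#' Parses the fixed-column format, keeping ATOM/HETATM records of a single
#' model and the TITLE text.  All other header records are discarded.
#'
#' @param path path to a PDB file.
#' @param model_choice which MODEL to keep when several are present (default
#'   the first).
#' @param pdb_id identifier to store; defaults to the first four characters of
#'   the file name.
#' @return A [pdb_structure()].
#' @export
read_structure <- function(path, model_choice = 1L, pdb_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pdb_id)) {
    base <- tools::file_path_sans_ext(basename(path))
    pdb_id <- substr(base, 1, 4)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  title_lines <- lines[trimws(rec) == "TITLE"]
  title <- paste(trimws(substr(formatC(title_lines, width = 80, flag = "-"), 11, 80)),
                 collapse = " ")
  title <- trimws(title)

  model_no <- 1L
  current <- 0L  # 0 = before any MODEL record
  keep <- logical(length(lines))
  model_of <- integer(length(lines))
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r == "MODEL") {
      current <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 14))))
      if (is.na(current)) current <- sum(model_of > 0) + 1L
    } else if (r %in% c("ATOM", "HETATM")) {
      keep[i] <- TRUE
      model_of[i] <- max(current, 1L)
    }
  }
  if (!any(keep)) stop("no coordinate records in ", path)
  models <- sort(unique(model_of[keep]))
  model_no <- if (length(models) >= model_choice) models[model_choice] else
    stop(sprintf("model %d not present (%d model(s) in file)", model_choice, length(models)))
  idx <- which(keep & model_of == model_no)
  parsed <- lapply(idx, function(i) parse_coord_line(lines[i], i))
  atoms <- do.call(rbind.data.frame, c(parsed, list(stringsAsFactors = FALSE)))
  pdb_structure(atoms, pdb_id = pdb_id, title = title, model_number = model_no)
}

format_coord_line <- function(a) {
  line <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$kind, a$serial %% 100000L, a$name, a$altloc, a$resname,
                  a$chain, a$resseq, a$icode, a$x, a$y, a$z, a$occ, a$b,
                  a$element)
  if (nzchar(a$tag))   # source tag sits after column 80
    line <- paste0(formatC(line, width = 80, flag = "-"), " ", a$tag)
  line
}

format_title_records <- function(title) {
  if (!nzchar(title)) return(character(0))
  words <- strsplit(title, " +")[[1]]
  lines <- character(0); cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) > 69 && nzchar(cur)) { lines <- c(lines, cur); cur <- w }
    else cur <- cand
  }
  lines <- c(lines, cur)
  vapply(seq_along(lines), function(i) {
    if (i == 1) paste0("TITLE     ", lines[i])
    else sprintf("TITLE   %2d %s", i, lines[i])
  }, character(1))
}

#' Write a structure model as a PDB file
#'
#' Emits TITLE records first (with continuation lines for long titles), then
#' the atom records in stored order with TER records at chain boundaries, and
#' a final END.  No CRYST1 or symmetry records are written: after reorientation
#' the original symmetry operators are no longer valid.
#'
#' @param model a [pdb_structure()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "pdb_structure"))
  at <- model$atoms
  out <- format_title_records(model$title)
  if (nrow(at)) {
    body <- vapply(seq_len(nrow(at)), function(i) format_coord_line(at[i, ]), character(1))
    # TER after the last ATOM record of each chain's polymer block
    is_atom <- at$kind == "ATOM"
    ter_after <- integer(0)
    if (any(is_atom)) {
      chain_run <- rle(paste(at$chain, is_atom))
      ends <- cumsum(chain_run$lengths)
      ter_after <- ends[grepl("TRUE$", chain_run$values)]
    }
    lines <- character(0)
    last <- 0L
    for (e in sort(ter_after)) {
      lines <- c(lines, body[(last + 1L):e], "TER")
      last <- e
    }
    if (last < length(body)) lines <- c(lines, body[(last + 1L):length(body)])
    out <- c(out, lines)
  }
  out <- c(out, "END")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Apply a rigid transform to a complete structure
#'
#' Every atom of every chain (heteroatoms included) moves together; atom order
#' and identities are untouched, so all pairwise distances are preserved.
#'
#' @param model a [pdb_structure()].
#' @param transform a [rigid_transform()]; improper rotations are rejected at
#'   construction.
#' @return The transformed `pdb_structure`.
#' @export
apply_transform <- function(model, transform) {
  stopifnot(inherits(model, "pdb_structure"), is_rigid_transform(transform))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- transform_points(xyz, transform)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}

#' Construct a Calpha trace
#' @param pdb_id,chain source identifiers.
#' @param resseq,icode,resname per-residue identity vectors.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @return Object of class `ca_trace`.
#' @export
ca_trace <- function(pdb_id, chain, resseq, icode, resname, xyz) {
  xyz <- rbind(xyz)
  stopifnot(length(resseq) == nrow(xyz), length(resname) == length(resseq))
  structure(list(pdb_id = pdb_id, chain = chain,
                 resseq = as.integer(resseq), icode = as.character(icode),
                 resname = as.character(resname),
                 xyz = unname(xyz)),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("Calpha trace %s chain %s: %d residues\n",
              x$pdb_id, x$chain, length(x$resseq)))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) length(x$resseq)

#' One-letter sequence of a Calpha trace
#' @param trace a [ca_trace()].
#' @return Single string of one-letter residue codes.
#' @export
trace_sequence <- function(trace) paste(three_to_one(trace$resname), collapse = "")

#' Extract the Calpha trace of one chain
#'
#' Keeps one Calpha per residue, in file order.  Alternate locations are
#' resolved by highest occupancy, ties by altloc character order, so traces are
#' deterministic single-conformer objects.  HETATM records never contribute
#' (a calcium ion named "CA" is not a Calpha).
#'
#' @param model a [pdb_structure()].
#' @param chain_id single chain identifier.
#' @return A [ca_trace()].
#' @export
extract_ca_trace <- function(model, chain_id) {
  stopifnot(inherits(model, "pdb_structure"))
  at <- model$atoms
  if (!chain_id %in% at$chain[at$kind == "ATOM"])
    stop("chain not found: ", chain_id)
  ca <- at[at$kind == "ATOM" & at$chain == chain_id & trimws(at$name) == "CA", ,
           drop = FALSE]
  if (!nrow(ca)) stop("chain ", chain_id, " has no Calpha atoms")
  key <- paste(ca$resseq, ca$icode, sep = "\r")
  first_seen <- !duplicated(key)
  order_keys <- key[first_seen]
  pick <- vapply(order_keys, function(k) {
    cand <- which(key == k)
    cand[order(-ca$occ[cand], ca$altloc[cand])][1]
  }, integer(1))
  ca <- ca[pick, , drop = FALSE]
  ca_trace(model$pdb_id, chain_id, ca$resseq, ca$icode, ca$resname,
           as.matrix(ca[, c("x", "y", "z")]))
}

#' Output file name under the set naming convention
#'
#' Ordinary aligned entries are named `pdbid_Chain-set.pdb` with a lower-case
#' PDB code (chain case kept as given); representative seed structures get an
#' upper-case basename with no chain or set suffix.
#'
#' @param pdb_id PDB identifier (or representative name).
#' @param chain_id chain identifier (ignored for representatives).
#' @param set_name four-letter set name (ignored for representatives).
#' @param representative logical flag.
#' @return File name string.
#' @examples
#' output_filename("5d98", "B", "fluv")        # "5d98_B-fluv.pdb"
#' output_filename("flav", representative = TRUE)  # "FLAV.pdb"
#' @export
output_filename <- function(pdb_id, chain_id = "", set_name = "",
                            representative = FALSE) {
  if (!nzchar(pdb_id)) stop("empty pdb_id")
  if (representative) return(paste0(toupper(pdb_id), ".pdb"))
  if (!nzchar(set_name)) stop("empty set_name")
  if (!grepl("^[A-Za-z0-9]{4}$", set_name)) stop("set_name must be 4 characters")
  paste0(tolower(pdb_id), "_", chain_id, "-", tolower(set_name), ".pdb")
}

#' Extract metal-ion records from a structure
#'
#' Returns HETATM records whose element belongs to the metal set.  Waters and
#' protein atoms never qualify; the record kind discriminates a calcium ion
#' from a Calpha atom.
#'
#' @param model a [pdb_structure()].
#' @param source_file label recorded on every returned ion (typically the file
#'   the structure was read from).
#' @param metal_set character vector of element symbols; default
#'   [METAL_ELEMENTS].
#' @return Data frame with columns `element`, `x`, `y`, `z`, `source_file`,
#'   `source_chain`, `resseq` (zero rows when no ions present).
#' @export
extract_metal_ions <- function(model, source_file = model$pdb_id,
                               metal_set = METAL_ELEMENTS) {
  stopifnot(inherits(model, "pdb_structure"))
  at <- model$atoms
  sel <- at$kind == "HETATM" & at$element %in% metal_set
  data.frame(element = at$element[sel], x = at$x[sel], y = at$y[sel],
             z = at$z[sel], source_file = rep(source_file, sum(sel)),
             source_chain = at$chain[sel], resseq = at$resseq[sel],
             stringsAsFactors = FALSE)
}
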