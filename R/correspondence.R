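# Correspondence tables map alignment columns to residue indices of each
# member trace; MISSING entries (NA) mark gaps and unmodeled residues.

#' Construct a correspondence table
#'
#' @param members data frame with columns `pdb_id`, `chain`.
#' @param index members x columns integer matrix of residue indices into each
#'   member's trace; `NA` marks MISSING.
#' @param source_columns original alignment column of each table column
#'   (provenance kept through [restrict_regions()]).
#' @param alignment_length width of the alignment the table was built from.
#' @return Object of class `correspondence_table`.
#' @export
correspondence_table <- function(members, index, source_columns = seq_len(ncol(index)),
                                 alignment_length = max(source_columns, 0L)) {
  index <- rbind(index)
  stopifnot(nrow(members) == nrow(index),
            length(source_columns) == ncol(index))
  # colinearity: per member, non-missing indices strictly increasing
  for (i in seq_len(nrow(index))) {
    v <- index[i, !is.na(index[i, ])]
    if (length(v) > 1 && any(diff(v) <= 0))
      stop("correspondence not colinear for member ",
           paste(members$pdb_id[i], members$chain[i], sep = "_"))
  }
  keep <- colSums(!is.na(index)) >= 2
  structure(list(members = members,
                 index = index[, keep, drop = FALSE],
                 source_columns = as.integer(source_columns[keep]),
                 alignment_length = as.integer(alignment_length)),
            class = "correspondence_table")
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("Correspondence table: %d members x %d columns (%d MISSING entries)\n",
              nrow(x$index), ncol(x$index), sum(is.na(x$index))))
  invisible(x)
}

#' @export
dim.correspondence_table <- function(x) dim(x$index)

member_ids <- function(members) paste(members$pdb_id, members$chain, sep = "_")

#' Build residue correspondences from an alignment and traces
#'
#' Each alignment column maps to the residue of each member that occupies it;
#' gaps become MISSING.  Every alignment row's ungapped sequence must equal
#' its trace's one-letter sequence exactly (an `X` in either matches anything,
#' so curated alignments may mask nonstandard residues).  Trace residues
#' without finite coordinates are also MISSING.  Columns present in fewer than
#' two members are dropped.
#'
#' @param aln a [seq_alignment()]; row order must match `traces`.
#' @param traces list of [ca_trace()] objects.
#' @return A [correspondence_table()].
#' @export
build_correspondence <- function(aln, traces) {
  stopifnot(inherits(aln, "seq_alignment"), length(traces) == length(aln$names))
  members <- data.frame(pdb_id = vapply(traces, function(t) t$pdb_id, ""),
                        chain = vapply(traces, function(t) t$chain, ""),
                        stringsAsFactors = FALSE)
  m <- length(traces)
  index <- matrix(NA_integer_, m, aln$width)
  for (i in seq_len(m)) {
    row_chars <- strsplit(aln$rows[i], "")[[1]]
    res_chars <- three_to_one(traces[[i]]$resname)
    row_seq <- row_chars[row_chars != "-"]
    if (length(row_seq) != length(res_chars))
      stop(sprintf("sequence/trace length mismatch for member %s (%d vs %d residues)",
                   aln$names[i], length(row_seq), length(res_chars)))
    mism <- which(row_seq != res_chars & row_seq != "X" & res_chars != "X")
    if (length(mism))
      stop(sprintf("alignment row disagrees with trace for member %s at residue %d ('%s' vs '%s')",
                   aln$names[i], mism[1], row_seq[mism[1]], res_chars[mism[1]]))
    pos <- cumsum(row_chars != "-")
    pos[row_chars == "-"] <- NA_integer_
    bad <- !is.finite(rowSums(traces[[i]]$xyz))
    if (any(bad)) pos[!is.na(pos) & pos %in% which(bad)] <- NA_integer_
    index[i, ] <- pos
  }
  correspondence_table(members, index, seq_len(aln$width), aln$width)
}

#' Define motif regions as alignment-column ranges
#'
#' @param ... named arguments, each a vector of column indices or a list of
#'   `c(start, end)` ranges.
#' @param alignment_length optional width for bounds checking.
#' @return Object of class `motif_regions` (named list of integer column
#'   vectors).
#' @examples
#' motif_regions(motif_a = list(c(10, 22)), motif_c = list(c(40, 52)))
#' @export
motif_regions <- function(..., alignment_length = NULL) {
  args <- list(...)
  if (!length(args) || is.null(names(args)) || any(!nzchar(names(args))))
    stop("motif_regions needs named regions")
  regions <- lapply(args, function(a) {
    if (is.list(a))
      unlist(lapply(a, function(r) {
        r <- as.integer(unlist(r))
        if (length(r) == 2) seq.int(r[1], r[2]) else r
      }))
    else as.integer(a)
  })
  all_cols <- unlist(regions)
  if (any(all_cols < 1)) stop("region columns must be positive")
  if (anyDuplicated(all_cols)) stop("motif regions must be disjoint")
  if (!is.null(alignment_length) && any(all_cols > alignment_length))
    stop("region columns exceed alignment length ", alignment_length)
  structure(regions, class = "motif_regions")
}

#' Total number of columns covered by a region set
#' @param regions a [motif_regions()] object.
#' @return Integer count.
#' @export
region_size <- function(regions) length(unlist(regions))

#' Restrict a correspondence table to motif regions
#'
#' Keeps only the columns named by `regions`, in region order; the member list
#' is unchanged.
#'
#' @param table a [correspondence_table()].
#' @param regions a [motif_regions()] object (columns refer to the original
#'   alignment).
#' @return A restricted `correspondence_table`.
#' @export
restrict_regions <- function(table, regions) {
  stopifnot(inherits(table, "correspondence_table"),
            inherits(regions, "motif_regions"))
  want <- unlist(regions)
  if (any(want > table$alignment_length))
    stop("region columns exceed alignment length ", table$alignment_length)
  sel <- match(want, table$source_columns)
  sel <- sel[!is.na(sel)]
  if (!length(sel)) stop("no usable columns after region restriction")
  out <- correspondence_table(table$members, table$index[, sel, drop = FALSE],
                              table$source_columns[sel], table$alignment_length)
  if (ncol(out$index) == 0) stop("no usable columns after region restriction")
  out
}
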