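# Residue-equivalence machinery: global pairwise alignment with affine gaps,
# a progressive multiple aligner (k-mer distances -> UPGMA guide tree ->
# profile-profile alignment), and CLUSTAL-dialect file I/O.  The aligner is
# deliberately simple: the downstream maximum-likelihood superposition
# down-weights any residual misassignments, so a reasonable global MSA is all
# that is required.

#' Construct a sequence alignment object
#'
#' @param names member identifiers (unique).
#' @param rows equal-length gapped sequences ("-" gap symbol).
#' @return Object of class `seq_alignment`.
#' @export
seq_alignment <- function(names, rows) {
  names <- as.character(names); rows <- toupper(as.character(rows))
  if (length(names) != length(rows)) stop("names/rows length mismatch")
  if (anyDuplicated(names)) stop("duplicate member names in alignment")
  widths <- nchar(rows)
  if (length(unique(widths)) > 1)
    stop("alignment rows have inconsistent lengths: ",
         paste(names[widths != widths[1]], collapse = ", "))
  structure(list(names = names, rows = rows, width = widths[1]),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("Sequence alignment: %d rows x %d columns\n",
              length(x$names), x$width))
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

ungapped <- function(row) gsub("-", "", row)

sanitize_seq <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% blosum62_alphabet)
  if (any(bad)) {
    warning("non-standard residue letters mapped to X: ",
            paste(unique(chars[bad]), collapse = ""))
    chars[bad] <- "X"
  }
  chars
}

# Affine-gap global DP over two profiles.  A profile is a character matrix
# (rows = sequences, columns = alignment columns); column-vs-column score is
# the mean BLOSUM62 score over all non-gap residue pairs.  A gap of length L
# costs gap_open + L * gap_extend.
align_profiles <- function(pa, pb, gap_open = 10, gap_extend = 0.5) {
  subst <- blosum62()
  n <- ncol(pa); m <- ncol(pb)
  # column-vs-column score = mean BLOSUM62 over non-gap residue pairs,
  # computed via per-column letter-frequency matrices
  freq <- function(p) {
    f <- matrix(0, length(blosum62_alphabet), ncol(p),
                dimnames = list(blosum62_alphabet, NULL))
    for (l in blosum62_alphabet) f[l, ] <- colSums(p == l)
    f
  }
  fa <- freq(pa); fb <- freq(pb)
  na_ <- colSums(fa); nb_ <- colSums(fb)
  denom <- outer(na_, nb_)
  S <- crossprod(fa, subst %*% fb)
  S <- ifelse(denom > 0, S / pmax(denom, 1), 0)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- -gap_open - gap_extend * seq_len(n)
  if (m > 0) Y[1, 2:(m + 1)] <- -gap_open - gap_extend * seq_len(m)
  # traceback state: 1 = diagonal (M), 2 = up/gap-in-b (X), 3 = left/gap-in-a (Y)
  tbM <- matrix(0L, n + 1, m + 1); tbX <- tbM; tbY <- tbM
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + S[i - 1, j - 1]; tbM[i, j] <- k
      cand <- c(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      k <- which.max(cand)
      X[i, j] <- cand[k]; tbX[i, j] <- k
      cand <- c(M[i, j - 1] - gap_open - gap_extend, NEG, Y[i, j - 1] - gap_extend)
      k <- which.max(cand)
      Y[i, j] <- cand[k]; tbY[i, j] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  ops <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    if (i == 1L) { ops <- c("Y", ops); j <- j - 1L; next }
    if (j == 1L) { ops <- c("X", ops); i <- i - 1L; next }
    if (state == 1L) {
      prev <- tbM[i, j]; ops <- c("M", ops); i <- i - 1L; j <- j - 1L
      state <- prev
    } else if (state == 2L) {
      prev <- tbX[i, j]; ops <- c("X", ops); i <- i - 1L
      state <- if (prev == 1L) 1L else 2L
    } else {
      prev <- tbY[i, j]; ops <- c("Y", ops); j <- j - 1L
      state <- if (prev == 1L) 1L else 3L
    }
  }
  ai <- 0L; bj <- 0L
  out_a <- matrix("-", nrow(pa), length(ops))
  out_b <- matrix("-", nrow(pb), length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op != "Y") { ai <- ai + 1L; out_a[, k] <- pa[, ai] }
    if (op != "X") { bj <- bj + 1L; out_b[, k] <- pb[, bj] }
  }
  list(a = out_a, b = out_b, score = score)
}

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`) and BLOSUM62 scoring.  Non-standard residue
#' letters are mapped to `X` with a warning, never rejected.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @param names row names for the result.
#' @return A two-row [seq_alignment()] with attribute `"score"`.
#' @examples
#' pairwise_align("YGDD", "YGCDD")
#' @export
pairwise_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                           names = c("a", "b")) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  pa <- matrix(sanitize_seq(seq_a), nrow = 1)
  pb <- matrix(sanitize_seq(seq_b), nrow = 1)
  res <- align_profiles(pa, pb, gap_open, gap_extend)
  out <- seq_alignment(names, c(paste(res$a[1, ], collapse = ""),
                                paste(res$b[1, ], collapse = "")))
  attr(out, "score") <- res$score
  out
}

kmer_distance <- function(chars_list, k = 3) {
  n <- length(chars_list)
  counts <- lapply(chars_list, function(ch) {
    kk <- min(k, length(ch))
    if (length(ch) < kk) return(table(character(0)))
    kmers <- vapply(seq_len(length(ch) - kk + 1),
                    function(i) paste(ch[i:(i + kk - 1)], collapse = ""), "")
    table(kmers)
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- sum(pmin(ci[names(cj)], cj)[names(cj) %in% names(ci)], na.rm = TRUE)
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- 1 - if (denom > 0) shared / denom else 0
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from k-mer distances (k = 3) and aligns profiles
#' progressively along it with the affine-gap BLOSUM62 aligner.  Row order of
#' the result matches input order.
#'
#' @param seqs list or character vector of at least two amino-acid strings.
#' @param names member identifiers; default `seq1`, `seq2`, ...
#' @param gap_open,gap_extend gap penalties.
#' @return A [seq_alignment()].
#' @export
progressive_msa <- function(seqs, names = NULL,
                            gap_open = 10, gap_extend = 0.5) {
  seqs <- as.character(unlist(seqs))
  n <- length(seqs)
  if (n < 2) stop("progressive_msa needs at least 2 sequences")
  if (is.null(names)) names <- paste0("seq", seq_len(n))
  chars <- lapply(seqs, sanitize_seq)
  if (any(lengths(chars) == 0)) stop("empty sequence")

  if (n == 2) {
    merged <- align_profiles(matrix(chars[[1]], 1), matrix(chars[[2]], 1),
                             gap_open, gap_extend)
    rows <- rbind(merged$a, merged$b)
    return(seq_alignment(names, apply(rows, 1, paste, collapse = "")))
  }

  D <- kmer_distance(chars)
  hc <- hclust(stats::as.dist(D), method = "average")
  profiles <- vector("list", n)          # leaf profiles
  members <- vector("list", n)           # leaf index sets
  node_profile <- vector("list", nrow(hc$merge))
  node_members <- vector("list", nrow(hc$merge))
  get_node <- function(id) {
    if (id < 0) list(p = matrix(chars[[-id]], nrow = 1), m = -id)
    else list(p = node_profile[[id]], m = node_members[[id]])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[s, 1]); b <- get_node(hc$merge[s, 2])
    merged <- align_profiles(a$p, b$p, gap_open, gap_extend)
    node_profile[[s]] <- rbind(merged$a, merged$b)
    node_members[[s]] <- c(a$m, b$m)
  }
  final <- node_profile[[nrow(hc$merge)]]
  ord <- order(node_members[[nrow(hc$merge)]])
  rows <- apply(final[ord, , drop = FALSE], 1, paste, collapse = "")
  seq_alignment(names, rows)
}

#' Read a CLUSTAL-dialect alignment file
#'
#' Accepts the interleaved CLUSTAL layout (header line beginning "CLUSTAL",
#' blocks of `name  sequence` lines separated by blanks; conservation lines
#' and trailing column counts are ignored).  Curated alignments may contain
#' non-overlapping sections -- blocks where a divergent segment occupies
#' columns gapped in every other row; these are ordinary columns here.
#'
#' @param path alignment file path.
#' @return A [seq_alignment()].
#' @export
parse_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1]))
    stop("not a CLUSTAL alignment (missing CLUSTAL header): ", path)
  body <- lines[-1]
  acc <- list(); order <- character(0)
  block_seen <- character(0); blank_break <- TRUE
  for (ln in body) {
    if (!nzchar(trimws(ln))) { block_seen <- character(0); next }
    if (grepl("^\\s", ln)) next  # conservation line
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) next
    name <- parts[1]
    chunk <- gsub("[0-9]", "", paste(parts[-1], collapse = ""))
    if (name %in% block_seen)
      stop("duplicate name within one alignment block: ", name)
    block_seen <- c(block_seen, name)
    if (!name %in% order) { order <- c(order, name); acc[[name]] <- "" }
    acc[[name]] <- paste0(acc[[name]], chunk)
  }
  if (!length(order)) stop("no sequences found in ", path)
  rows <- unlist(acc[order], use.names = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1)
    stop("inconsistent row lengths in ", path, " (row ",
         order[which(widths != widths[1])[1]], ")")
  seq_alignment(order, rows)
}

#' Read sequences from a FASTA file
#'
#' Convenience input path for [progressive_msa()].
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}

#' Write an alignment in CLUSTAL format
#'
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @param block_width residues per interleaved block (default 60).
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, block_width = 60) {
  stopifnot(inherits(aln, "seq_alignment"))
  namew <- max(nchar(aln$names)) + 4
  out <- c("CLUSTAL multiple sequence alignment", "")
  starts <- seq(1, max(aln$width, 1), by = block_width)
  for (s in starts) {
    e <- min(s + block_width - 1, aln$width)
    for (i in seq_along(aln$names)) {
      out <- c(out, paste0(formatC(aln$names[i], width = -namew),
                           substr(aln$rows[i], s, e)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
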