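#' Construct a multiple sequence alignment object
#'
#' @param seqs character vector of equal-length aligned sequences
#'   (amino-acid letters plus `-` gaps), named by sequence label.
#' @return object of class `gef_msa`: list with `names` and `rows`.
#' @export
gef_msa <- function(seqs) {
  if (!length(seqs)) stop("empty MSA")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(letters_used, c(strsplit("ACDEFGHIKLMNPQRSTVWYXBZU", "")[[1]], "-"))
  if (length(bad)) stop("invalid MSA characters: ", paste(bad, collapse = " "))
  if ("X" %in% letters_used) message("MSA contains ambiguous residues (X)")
  structure(list(names = names(seqs), rows = unname(seqs)), class = "gef_msa")
}

#' @export
print.gef_msa <- function(x, ...) {
  cat(sprintf("<gef_msa> %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return a `gef_msa`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  s <- as.character(Biostrings::unmasked(aln))
  gef_msa(gsub("\\.", "-", s))
}

#' Read unaligned protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, ""))
}

#' Pairwise percent-identity matrix of an MSA
#'
#' `identity(i, j) = 100 * matches / denominator`, where matches counts
#' alignment columns at which both sequences carry the same non-gap
#' residue. The denominator is either the number of columns where both
#' sequences are ungapped (default, the common reporting convention) or
#' the full alignment length.
#'
#' @param m a `gef_msa`.
#' @param mode `"both_ungapped"` or `"alignment_length"`.
#' @return object of class `identity_matrix`: symmetric percent matrix
#'   with 100 on the diagonal, labels as dimnames, and a `mode` attribute.
#' @export
pairwise_identity_matrix <- function(m, mode = c("both_ungapped",
                                                 "alignment_length")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "gef_msa"))
  n <- length(m$rows)
  if (n < 2) stop("need at least 2 sequences")
  mat <- msa_matrix(m)
  ncol_aln <- ncol(mat)
  out <- matrix(100, n, n, dimnames = list(m$names, m$names))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      matches <- sum(both & mat[i, ] == mat[j, ])
      denom <- if (mode == "both_ungapped") sum(both) else ncol_aln
      val <- if (denom == 0) 0 else 100 * matches / denom
      out[i, j] <- out[j, i] <- val
    }
  }
  structure(out, mode = mode, class = c("identity_matrix", "matrix", "array"))
}

square_satisfies <- function(im, i, j, threshold, criterion) {
  if (i == j) return(TRUE)
  sub <- im[i:j, i:j]
  off <- sub[row(sub) != col(sub)]
  if (criterion == "mean_offdiag") mean(off) >= threshold else min(off) >= threshold
}

#' Diagonal square-neighborhood clusters of an identity matrix
#'
#' Partitions the sequences (in MSA order) into the largest possible
#' contiguous square neighborhoods along the matrix diagonal whose
#' pairwise identities meet a threshold — the subfamily-clustering rule
#' behind identity heatmaps. A greedy left-to-right scan takes, at each
#' start index, the largest square satisfying the criterion, then
#' continues after it; singletons always qualify.
#'
#' The phrase "at least X% identity" is ambiguous between the square's
#' mean off-diagonal identity (default) and its minimum pairwise
#' identity (`"min_pairwise"`, the strict reading); both are offered.
#'
#' @param im an `identity_matrix` (or plain symmetric percent matrix).
#' @param threshold percent identity threshold (default 35).
#' @param criterion `"mean_offdiag"` or `"min_pairwise"`.
#' @return object of class `cluster_set`: data.frame with `start`,
#'   `end` (1-based inclusive indices) and `size`; `threshold` and
#'   `criterion` kept as attributes.
#' @export
diagonal_square_clusters <- function(im, threshold = 35,
                                     criterion = c("mean_offdiag",
                                                   "min_pairwise")) {
  criterion <- match.arg(criterion)
  im <- as.matrix(im)
  n <- nrow(im)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n) {
    j_best <- i
    for (j in i:n) {
      if (square_satisfies(im, i, j, threshold, criterion)) j_best <- j
    }
    starts <- c(starts, i)
    ends <- c(ends, j_best)
    i <- j_best + 1L
  }
  out <- data.frame(start = starts, end = ends, size = ends - starts + 1L)
  if (!is.null(rownames(im))) {
    out$labels <- vapply(seq_len(nrow(out)), function(k) {
      paste(rownames(im)[out$start[k]:out$end[k]], collapse = ",")
    }, "")
  }
  attr(out, "threshold") <- threshold
  attr(out, "criterion") <- criterion
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Average off-diagonal identity per sequence
#'
#' For each sequence, the mean identity to all other sequences; the
#' label with the lowest average (the outlier of the family) is carried
#' as an attribute.
#'
#' @param im an `identity_matrix`.
#' @return named numeric vector of averages (percent), with attribute
#'   `min_label`.
#' @export
average_identity <- function(im) {
  im <- as.matrix(im)
  n <- nrow(im)
  if (n < 2) stop("need at least 2 labels")
  avg <- vapply(seq_len(n), function(i) mean(im[i, -i]), numeric(1))
  names(avg) <- rownames(im)
  attr(avg, "min_label") <- rownames(im)[which.min(avg)]
  avg
}

#' Divergence of one sequence at key alignment columns
#'
#' Audits a set of functionally important alignment columns: at each
#' column, the majority residue among all non-query sequences is found
#' (gaps excluded); if the majority reaches the conservation quorum the
#' column counts as conserved, and the query is flagged as deviating
#' when its residue differs from that majority. Columns below the quorum
#' are reported as not conserved and excluded from the divergence count.
#'
#' @param m a `gef_msa`.
#' @param query_label sequence being audited (e.g. the obscurin row).
#' @param positions alignment column indices to audit, or positions in
#'   `reference_label`'s ungapped sequence when that argument is given.
#' @param reference_label optional: interpret `positions` as ungapped
#'   residue positions of this sequence.
#' @param quorum fraction of non-gap entries the majority residue must
#'   reach for a column to count as conserved (default 0.8).
#' @return object of class `divergence_report`: data.frame per audited
#'   column (`column`, `majority`, `conserved`, `query_residue`,
#'   `deviates`), with attributes `count` (deviations at conserved
#'   columns) and `n_conserved`.
#' @export
key_residue_divergence <- function(m, query_label, positions,
                                   reference_label = NULL, quorum = 0.8) {
  stopifnot(inherits(m, "gef_msa"))
  qi <- match(query_label, m$names)
  if (is.na(qi)) stop("query label not found in MSA")
  mat <- msa_matrix(m)
  if (!is.null(reference_label)) {
    ri <- match(reference_label, m$names)
    if (is.na(ri)) stop("reference label not found in MSA")
    ungapped_cols <- which(mat[ri, ] != "-")
    if (any(positions < 1 | positions > length(ungapped_cols))) {
      stop("position out of range of the reference sequence")
    }
    positions <- ungapped_cols[positions]
  }
  if (any(positions < 1 | positions > ncol(mat))) {
    stop("alignment column out of range")
  }
  rows <- setdiff(seq_len(nrow(mat)), qi)
  audit <- lapply(positions, function(p) {
    col <- mat[rows, p]
    col <- col[col != "-"]
    if (!length(col)) {
      return(data.frame(column = p, majority = NA_character_,
                        conserved = FALSE, query_residue = mat[qi, p],
                        deviates = FALSE))
    }
    tab <- sort(table(col), decreasing = TRUE)
    maj <- names(tab)[1]
    conserved <- tab[1] / length(col) >= quorum
    data.frame(column = p, majority = maj, conserved = conserved,
               query_residue = mat[qi, p],
               deviates = conserved && mat[qi, p] != maj)
  })
  out <- do.call(rbind, audit)
  rownames(out) <- NULL
  attr(out, "count") <- sum(out$deviates)
  attr(out, "n_conserved") <- sum(out$conserved)
  attr(out, "query") <- query_label
  class(out) <- c("divergence_report", "data.frame")
  out
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, extend 0.5
#' by default, the EMBOSS-needle-like setting; a gap of length L costs
#' open + L x extend). Percent identity is computed over columns where
#' both sequences are ungapped.
#'
#' @param a,b protein sequences (plain strings).
#' @param substitution substitution matrix name available in Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM50").
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class `global_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`, `identity` (percent).
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  submat <- get_substitution_matrix(substitution)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  both <- ca != "-" & cb != "-"
  identity <- if (any(both)) 100 * sum(both & ca == cb) / sum(both) else 0
  structure(list(aligned_a = sa, aligned_b = sb,
                 score = Biostrings::score(aln), identity = identity),
            class = "global_alignment")
}

get_substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> score %.1f, identity %.1f%%\n",
              x$score, x$identity))
  cat("  ", x$aligned_a, "\n  ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Write an identity matrix to CSV
#' @param im an `identity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_identity_csv <- function(im, path) {
  utils::write.csv(as.data.frame(as.matrix(im)), path, row.names = TRUE)
  invisible(path)
}

#' Write cluster intervals to CSV
#' @param cs a `cluster_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters_csv <- function(cs, path) {
  utils::write.csv(as.data.frame(cs), path, row.names = FALSE)
  invisible(path)
}

#' Write a divergence report to CSV
#' @param dr a `divergence_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_divergence_csv <- function(dr, path) {
  utils::write.csv(as.data.frame(dr), path, row.names = FALSE)
  invisible(path)
}
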