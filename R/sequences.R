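#' Sequence alignment container
#'
#' A `seq_alignment` holds equal-length DNA sequences (A/C/G/T only in this
#' version) with unique sample labels, stored internally as a character
#' matrix (samples x sites).
#'
#' @param labels Character vector of unique sample identifiers.
#' @param sequences Character vector of equal-length ACGT strings, or a
#'   character matrix of single bases with one row per sample.
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(labels, sequences) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1)
      stop("all sequences must have the same length (ragged alignment)")
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  if (length(labels) != nrow(mat)) stop("one label per sequence required")
  if (anyDuplicated(labels)) stop("duplicate sequence labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!all(mat %in% c("A", "C", "G", "T")))
    stop("alignment restricted to A/C/G/T (no gaps or ambiguity codes)")
  rownames(mat) <- labels
  structure(list(labels = as.character(labels), seq = mat), class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d sequences x %d sites\n", nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

n_sequences <- function(aln) nrow(aln$seq)
alignment_length <- function(aln) ncol(aln$seq)

#' Read / write FASTA alignments
#'
#' Thin wrappers around Biostrings for standard FASTA I/O, enforcing the
#' alignment invariants (unique labels, equal lengths, ACGT alphabet).
#' `write_fasta` then `read_fasta` reproduces the object exactly.
#'
#' @param path File path.
#' @param aln A [seq_alignment()].
#' @return `read_fasta` returns a `seq_alignment`; `write_fasta` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1) stop("no sequences in ", path)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) != 1)
    stop("ragged alignment in ", path, ": record '",
         names(ss)[which(widths != widths[1])[1]],
         "' has length ", widths[widths != widths[1]][1],
         " but the first record has length ", widths[1])
  seq_alignment(names(ss), as.character(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  ss <- Biostrings::DNAStringSet(apply(aln$seq, 1, paste0, collapse = ""))
  names(ss) <- aln$labels
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# base codes 1..4 = A C G T; transition partner swaps within purines /
# pyrimidines (A<->G, C<->T), i.e. code -> ((code+1) %% 4) + 1.
BASES <- c("A", "C", "G", "T")
TI_PARTNER <- c(3L, 4L, 1L, 2L)
TV_TARGETS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

# Apply n_mut sequential point mutations to an integer-coded sequence.
# Each mutation hits a uniform site; it is a transition with probability
# R/(R+1), otherwise one of the two transversions with equal probability.
mutate_sequence <- function(seq_codes, n_mut, R) {
  for (i in seq_len(n_mut)) {
    site <- sample.int(length(seq_codes), 1)
    b <- seq_codes[site]
    if (stats::runif(1) < R / (R + 1)) {
      seq_codes[site] <- TI_PARTNER[b]
    } else {
      seq_codes[site] <- TV_TARGETS[[b]][sample.int(2, 1)]
    }
  }
  seq_codes
}

#' Evolve sequences along a genealogy
#'
#' Drops mutations on the tree as a Poisson process with rate `theta_seq/2`
#' per site per coalescent time unit, starting from a uniformly random
#' ancestral sequence. Each mutation is a transition with probability
#' `R/(R+1)`, otherwise one of the two transversions with equal probability
#' (a Kimura-type two-parameter process with Ti:Tv event ratio `R`).
#'
#' @param genealogy A [new_genealogy()] object.
#' @param L Number of sites.
#' @param theta_seq Per-site population-scaled mutation rate (>= 0); under
#'   this scaling the expected pairwise difference per site equals
#'   `theta_seq`.
#' @param R Transition/transversion event ratio (> 0); the study organism's
#'   control region was modelled with R = 33.
#' @param seed Optional integer seed.
#' @return A [seq_alignment()] with one sequence per tip, labels `t1..tn`.
#' @export
evolve_sequences <- function(genealogy, L, theta_seq, R = 33, seed = NULL) {
  validate_genealogy(genealogy)
  assert_number(L, "L", lo = 1)
  assert_number(theta_seq, "theta_seq", lo = 0)
  assert_number(R, "R", lo = 0, allow_zero = FALSE)
  with_seed_opt(seed, {
    n <- genealogy$n_tips
    n_nodes <- 2 * n - 1
    seqs <- matrix(0L, n_nodes, L)
    rt <- root_node(genealogy)
    seqs[rt, ] <- sample.int(4, L, replace = TRUE)
    # preorder: internal nodes by decreasing time, children after parents
    internal <- order(genealogy$node_time[(n + 1):n_nodes], decreasing = TRUE) + n
    for (node in internal) {
      for (child in genealogy$children[node - n, ]) {
        dt <- genealogy$node_time[node] - genealogy$node_time[child]
        n_mut <- stats::rpois(1, theta_seq / 2 * L * dt)
        seqs[child, ] <- mutate_sequence(seqs[node, ], n_mut, R)
      }
    }
    mat <- matrix(BASES[seqs[seq_len(n), , drop = FALSE]], nrow = n)
    seq_alignment(paste0("t", seq_len(n)), mat)
  })
}
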